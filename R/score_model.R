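#' Construct a prognostic score model
#'
#' A `score_model` is a linear risk score: `score(x) = sum_i beta_i * x_i`
#' over named input columns. Four kinds are used in the pipeline:
#' `tcmf` (LASSO-Cox over the 142 collagen features), `tacs` (ridge-Cox over
#' the 8 TACS indicators), `cli` (Cox over encoded clinical covariates) and
#' `combined` (Cox-derived weights over component scores).
#'
#' @param kind one of `"tcmf"`, `"tacs"`, `"cli"`, `"combined"`.
#' @param features character vector of input column names.
#' @param coefficients numeric vector, same length as `features`.
#' @param normalization optional [fit_normalizer()] parameters applied to the
#'   inputs before the linear combination (used by `tcmf` models so raw
#'   feature tables can be scored directly).
#' @param meta named list of training metadata (lambda, folds, seed, ...).
#' @return An object of class `score_model`.
#' @export
score_model <- function(kind, features, coefficients, normalization = NULL,
                        meta = list()) {
  kind <- match.arg(kind, c("tcmf", "tacs", "cli", "combined"))
  features <- as.character(features)
  coefficients <- as.numeric(coefficients)
  if (length(features) != length(coefficients))
    stop("`features` and `coefficients` must have equal length", call. = FALSE)
  if (length(coefficients) && !all(is.finite(coefficients)))
    stop("coefficients must be finite", call. = FALSE)
  structure(
    list(kind = kind, features = features,
         coefficients = setNames(coefficients, features),
         normalization = normalization, meta = meta, version = "1.0"),
    class = "score_model"
  )
}

#' @export
print.score_model <- function(x, ...) {
  cat(sprintf("<score_model kind='%s'> %d feature(s)\n", x$kind,
              length(x$features)))
  if (length(x$features)) {
    show <- head(seq_along(x$features), 10)
    for (i in show)
      cat(sprintf("  %-32s %+.5f\n", x$features[i], x$coefficients[i]))
    if (length(x$features) > 10) cat(sprintf("  ... %d more\n",
                                             length(x$features) - 10))
  } else cat("  (empty model; score is identically 0)\n")
  invisible(x)
}

#' Evaluate a score model on a table
#'
#' Computes the linear predictor for each row. Missing model features abort;
#' an empty model scores 0 for every row. If the model embeds normalization
#' parameters they are applied first (training-cohort Z-scoring).
#'
#' @param model a `score_model`.
#' @param data data.frame (or matrix) containing the model's feature columns.
#' @return numeric vector of scores, one per row.
#' @export
score <- function(model, data) {
  stopifnot(inherits(model, "score_model"))
  n <- nrow(data)
  if (!length(model$features)) return(rep(0, n))
  if (!is.null(model$meta$levels_map) &&
      !all(model$features %in% colnames(data))) {
    data <- encode_clinical(as.data.frame(data), model$meta$covariates,
                            levels_map = model$meta$levels_map)$x
  }
  missing_f <- setdiff(model$features, colnames(data))
  if (length(missing_f))
    stop("data lacks model feature(s): ",
         paste(head(missing_f, 5), collapse = ", "), call. = FALSE)
  x <- as.matrix(as.data.frame(data)[, model$features, drop = FALSE])
  storage.mode(x) <- "double"
  if (!is.null(model$normalization)) {
    np <- model$normalization
    mu <- np$mean[model$features]
    sdv <- np$sd[model$features]
    x <- sweep(sweep(x, 2, mu, "-"), 2, sdv, "/")
  }
  drop(x %*% model$coefficients)
}

#' Serialize / deserialize a score model as JSON
#'
#' The round trip preserves feature names, coefficients and normalization
#' parameters at full double precision. Reading a file written by a
#' different serialization version aborts.
#'
#' @param model a `score_model`.
#' @param path file path.
#' @return `read_score_model` returns a `score_model`; `write_score_model`
#'   returns `path` invisibly.
#' @export
write_score_model <- function(model, path) {
  stopifnot(inherits(model, "score_model"))
  payload <- list(
    version = model$version, kind = model$kind, features = model$features,
    coefficients = unname(model$coefficients),
    normalization = if (!is.null(model$normalization)) list(
      features = names(model$normalization$mean),
      mean = unname(model$normalization$mean),
      sd = unname(model$normalization$sd),
      dropped = model$normalization$dropped
    ),
    meta = model$meta
  )
  writeLines(jsonlite::toJSON(payload, digits = I(17), auto_unbox = TRUE,
                              null = "null"), path)
  invisible(path)
}

#' @rdname write_score_model
#' @export
read_score_model <- function(path) {
  if (!file.exists(path))
    stop(sprintf("model file not found: '%s'", path), call. = FALSE)
  p <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (is.null(p$version) || !identical(p$version, "1.0"))
    stop(sprintf("unsupported score_model version '%s' (expected 1.0)",
                 p$version), call. = FALSE)
  norm <- NULL
  if (!is.null(p$normalization)) {
    norm <- list(mean = setNames(p$normalization$mean,
                                 p$normalization$features),
                 sd = setNames(p$normalization$sd, p$normalization$features),
                 dropped = p$normalization$dropped)
    class(norm) <- "tcmf_normalizer"
  }
  score_model(p$kind, as.character(p$features), p$coefficients,
              normalization = norm, meta = as.list(p$meta))
}
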