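# Prognostic score construction: LASSO-Cox TCMF-score, ridge-Cox
# TACS-score, clinical Cox CLI-score, and Cox-weighted combinations.
# All Cox partial likelihoods use the Efron tie approximation.

# event-stratified cross-validation fold assignment, seeded
stratified_foldid <- function(event, cv_folds, seed) {
  with_seed(seed, {
    fold <- integer(length(event))
    for (g in unique(event)) {
      idx <- which(event == g)
      fold[idx] <- sample(rep_len(seq_len(cv_folds), length(idx)))
    }
    fold
  })
}

#' Fit a LASSO-Cox feature-selection model (TCMF-score)
#'
#' L1-penalized Cox partial likelihood over the feature matrix; the penalty
#' is chosen by cross-validated partial likelihood with event-stratified,
#' seeded folds. Features with nonzero coefficients at the chosen penalty
#' form the model; the score of a patient is the linear combination of the
#' selected features weighted by their LASSO coefficients.
#'
#' @param x numeric feature matrix (rows = patients, named columns),
#'   normalized upstream (see [fit_normalizer()]); no missing values.
#' @param time,event survival outcome (months; 1 = event, 0 = censored).
#' @param cv_folds number of cross-validation folds (default 10).
#' @param lambda_rule `"1se"` (default) or `"min"`.
#' @param lambda_grid optional penalty grid (decreasing).
#' @param seed fold-assignment seed; identical data + seed give identical
#'   selected sets and coefficients.
#' @param normalization optional `tcmf_normalizer` embedded in the model so
#'   raw feature tables can be scored directly.
#' @return A [score_model()] of kind `tcmf`. If every coefficient is zero at
#'   the chosen penalty an empty model (score identically 0) is returned
#'   with a warning.
#' @export
fit_lasso_cox <- function(x, time, event, cv_folds = 10,
                          lambda_rule = c("1se", "min"), lambda_grid = NULL,
                          seed = 1, normalization = NULL) {
  lambda_rule <- match.arg(lambda_rule)
  x <- as.matrix(x)
  if (anyNA(x)) stop("feature matrix contains missing values", call. = FALSE)
  if (sum(event) < 2) stop("need at least 2 events", call. = FALSE)
  y <- survival::Surv(time, event)
  foldid <- stratified_foldid(event, cv_folds, seed)
  cv <- glmnet::cv.glmnet(x, y, family = "cox", alpha = 1, foldid = foldid,
                          lambda = lambda_grid, standardize = FALSE)
  lam <- if (lambda_rule == "1se") cv$lambda.1se else cv$lambda.min
  beta <- as.matrix(coef(cv, s = lam))[, 1]
  sel <- beta != 0
  if (!any(sel))
    warning("LASSO selected no features at the chosen penalty; ",
            "returning an empty model")
  score_model("tcmf", names(beta)[sel], beta[sel],
              normalization = normalization,
              meta = list(lambda = lam, lambda_rule = lambda_rule,
                          cv_folds = cv_folds, seed = seed,
                          n_candidates = ncol(x)))
}

#' Fit a ridge-Cox model on the TACS indicators (TACS-score)
#'
#' L2-penalized Cox fit retaining all eight TACS1-8 coefficients; the
#' penalty is chosen by cross-validated partial likelihood over a log grid.
#'
#' @param x matrix of the 8 TACS indicator columns (`tacs_1`..`tacs_8`).
#' @inheritParams fit_lasso_cox
#' @param penalty optional fixed penalty (skips cross-validation).
#' @return A [score_model()] of kind `tacs` with all columns retained.
#' @export
fit_ridge_cox <- function(x, time, event, cv_folds = 10, penalty = NULL,
                          seed = 1) {
  x <- as.matrix(x)
  if (sum(event) < 2) stop("need at least 2 events", call. = FALSE)
  const <- apply(x, 2, function(v) diff(range(v)) == 0)
  if (any(const))
    warning("constant indicator column(s): ",
            paste(colnames(x)[const], collapse = ", "))
  y <- survival::Surv(time, event)
  if (is.null(penalty)) {
    foldid <- stratified_foldid(event, cv_folds, seed)
    cv <- glmnet::cv.glmnet(x, y, family = "cox", alpha = 0, foldid = foldid,
                            standardize = FALSE)
    penalty <- cv$lambda.min
    fit <- cv$glmnet.fit
  } else {
    fit <- glmnet::glmnet(x, y, family = "cox", alpha = 0,
                          standardize = FALSE)
  }
  beta <- as.matrix(coef(fit, s = penalty, exact = FALSE))[, 1]
  score_model("tacs", colnames(x), beta,
              meta = list(lambda = penalty, cv_folds = cv_folds, seed = seed))
}

# canonical category orders; the first level is the reference
clinical_levels <- function() {
  list(age_group = c("<=50", ">50"),
       subtype = c("LuminalA", "LuminalB", "HER2", "TripleNegative"),
       tumor_size = c("T1", "T2", "T3"),
       nodal_status = c("N0", "N1", "N2"),
       stage = c("I", "II", "III"),
       grade = c("G1", "G2", "G3"),
       er = c("Negative", "Positive"), pr = c("Negative", "Positive"),
       her2 = c("Negative", "Positive"),
       chemotherapy = c("No", "Yes"), radiation_therapy = c("No", "Yes"),
       endocrine_therapy = c("No", "Yes"), targeted_therapy = c("No", "Yes"))
}

#' Encode clinical covariates as indicator contrasts
#'
#' Categorical covariates expand to treatment contrasts against a fixed
#' reference level (the first level of [clinical_levels()] where defined,
#' otherwise the first sorted observed level); numeric covariates pass
#' through unchanged. Indicator columns are named `<covariate>.<level>`.
#'
#' @param table data.frame with the covariate columns.
#' @param covariates covariate names to encode.
#' @param levels_map optional list of level orders (as stored in a fitted
#'   model) to guarantee identical encoding of new data.
#' @return list with `x` (numeric matrix) and `levels_map`.
#' @export
encode_clinical <- function(table, covariates, levels_map = NULL) {
  canon <- clinical_levels()
  if (is.null(levels_map)) {
    levels_map <- lapply(setNames(covariates, covariates), function(cv) {
      v <- table[[cv]]
      if (is.numeric(v)) return(NULL)
      lv <- canon[[cv]]
      obs <- unique(as.character(v))
      if (is.null(lv)) sort(obs) else {
        if (length(setdiff(obs, lv)))
          stop(sprintf("unknown level(s) in '%s': %s", cv,
                       paste(setdiff(obs, lv), collapse = ", ")),
               call. = FALSE)
        lv
      }
    })
  }
  cols <- list()
  for (cv in covariates) {
    v <- table[[cv]]
    if (is.null(v)) stop(sprintf("covariate '%s' not in table", cv),
                         call. = FALSE)
    lv <- levels_map[[cv]]
    if (is.null(lv)) {
      cols[[cv]] <- as.numeric(v)
    } else {
      unk <- setdiff(unique(as.character(v)), lv)
      if (length(unk))
        stop(sprintf("unknown level(s) in '%s': %s", cv,
                     paste(unk, collapse = ", ")), call. = FALSE)
      for (l in lv[-1])
        cols[[paste(cv, l, sep = ".")]] <- as.numeric(as.character(v) == l)
    }
  }
  list(x = do.call(cbind, cols), levels_map = levels_map)
}

#' Fit the clinical Cox model (CLI-score)
#'
#' Unpenalized Cox proportional-hazards fit on encoded clinical covariates;
#' the CLI-score is the fitted linear predictor. Default covariates are the
#' clinical risk factors of the prognostic pipeline: age group, molecular
#' subtype, tumor size, nodal status, histological grade, clinical stage,
#' chemotherapy and radiation therapy.
#'
#' @param table data.frame with covariate columns.
#' @param time,event survival outcome.
#' @param covariates covariate column names.
#' @return A [score_model()] of kind `cli`; the encoding level map is kept
#'   in `meta$levels_map` so [score()] can encode raw tables.
#' @export
fit_cli_cox <- function(table, time, event,
                        covariates = c("age_group", "subtype", "tumor_size",
                                       "nodal_status", "grade", "stage",
                                       "chemotherapy", "radiation_therapy")) {
  enc <- encode_clinical(table, covariates)
  const <- apply(enc$x, 2, function(v) diff(range(v)) == 0)
  if (any(const)) {
    warning("dropping constant encoded covariate column(s): ",
            paste(colnames(enc$x)[const], collapse = ", "))
    enc$x <- enc$x[, !const, drop = FALSE]
    if (!ncol(enc$x))
      return(score_model("cli", character(0), numeric(0),
                         meta = list(covariates = covariates,
                                     levels_map = enc$levels_map)))
  }
  fit <- survival::coxph(survival::Surv(time, event) ~ enc$x,
                         ties = "efron")
  if (!fit$iter || any(!is.finite(coef(fit))))
    stop("clinical Cox model did not converge (possible separation)",
         call. = FALSE)
  beta <- setNames(coef(fit), colnames(enc$x))
  score_model("cli", colnames(enc$x), beta,
              meta = list(covariates = covariates,
                          levels_map = enc$levels_map))
}

#' Combine component scores with Cox-derived relative weights
#'
#' Fits a multivariate Cox model over the component score columns of the
#' training table; the fitted coefficients are the relative weights and the
#' combined score is their weighted linear combination.
#'
#' @param table data.frame containing the component score columns.
#' @param components names of the score columns to combine (e.g.
#'   `c("tcmf_score", "tacs_score")`).
#' @param time,event survival outcome.
#' @return A [score_model()] of kind `combined` whose features are the
#'   component names and whose coefficients are the relative weights.
#' @export
combine_scores <- function(table, components, time, event) {
  x <- as.matrix(as.data.frame(table)[, components, drop = FALSE])
  if (ncol(x) > 1) {
    kap <- kappa(cor(x), exact = TRUE)
    if (!is.finite(kap) || kap > 1e6)
      warning("component scores are (near-)collinear; weights are unstable")
  }
  fit <- survival::coxph(survival::Surv(time, event) ~ x, ties = "efron")
  score_model("combined", components, coef(fit),
              meta = list(n = nrow(x)))
}
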