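# Survival evaluation machinery: IPCW cumulative/dynamic ROC and iAUC,
# Youden cutoffs, Kaplan-Meier risk stratification with log-rank tests,
# Cox hazard ratios, Harrell's C, nomogram construction and calibration.

# Kaplan-Meier estimate of the censoring survival G(t); returns a function
# G(t, minus) with G(t^-) available for case weighting
km_censoring <- function(time, event) {
  fit <- survival::survfit(survival::Surv(time, 1 - event) ~ 1)
  st <- fit$time; sv <- fit$surv
  function(t, minus = FALSE) {
    vapply(t, function(ti) {
      keep <- if (minus) st < ti else st <= ti
      if (!any(keep)) 1 else max(min(sv[keep]), 1e-10)
    }, numeric(1))
  }
}

# IPCW cumulative/dynamic AUC at one horizon; cases = events by the
# horizon (weight 1/G(T-)), controls = still at risk past it (weight
# 1/G(horizon)); ties in score count 1/2
ipcw_auc <- function(scores, time, event, horizon, G = NULL) {
  case <- event == 1 & time <= horizon
  ctrl <- time > horizon
  if (!any(case) || !any(ctrl))
    stop("no cases or no controls at the requested horizon", call. = FALSE)
  if (is.null(G)) G <- km_censoring(time, event)
  w_case <- 1 / G(time[case], minus = TRUE)
  w_ctrl <- rep(1 / G(horizon), sum(ctrl))
  s_case <- scores[case]; s_ctrl <- scores[ctrl]
  os <- sort(unique(s_ctrl))
  cum_below <- c(0, cumsum(vapply(os, function(u) sum(w_ctrl[s_ctrl == u]),
                                  numeric(1))))
  pos <- findInterval(s_case, os)                    # ctrl scores <= s_case
  eq <- vapply(s_case, function(u) sum(w_ctrl[s_ctrl == u]), numeric(1))
  below <- cum_below[pos + 1] - eq
  sum(w_case * (below + 0.5 * eq)) / (sum(w_case) * sum(w_ctrl))
}

# weighted sensitivity/specificity over candidate cutoffs (high risk =
# score >= cutoff); returns the Youden-optimal row, ties toward the lower
# cutoff
youden_cutoff <- function(scores, time, event, horizon, G = NULL) {
  case <- event == 1 & time <= horizon
  ctrl <- time > horizon
  if (is.null(G)) G <- km_censoring(time, event)
  w_case <- 1 / G(time[case], minus = TRUE)
  w_ctrl <- rep(1 / G(horizon), sum(ctrl))
  s_case <- scores[case]; s_ctrl <- scores[ctrl]
  su <- sort(unique(c(s_case, s_ctrl)))
  cand <- c(su[1] - 1, if (length(su) > 1) (su[-1] + su[-length(su)]) / 2,
            su[length(su)] + 1)
  sens <- vapply(cand, function(cc) sum(w_case[s_case >= cc]) / sum(w_case),
                 numeric(1))
  spec <- vapply(cand, function(cc) sum(w_ctrl[s_ctrl < cc]) / sum(w_ctrl),
                 numeric(1))
  j <- sens + spec - 1
  best <- which(j == max(j))[1]                     # lowest cutoff on ties
  acc <- (sum(w_case[s_case >= cand[best]]) +
            sum(w_ctrl[s_ctrl < cand[best]])) /
    (sum(w_case) + sum(w_ctrl))
  list(cutoff = cand[best], sensitivity = sens[best],
       specificity = spec[best], accuracy = acc)
}

#' ROC analysis of a risk score at a survival horizon
#'
#' Cumulative/dynamic definition with inverse-probability-of-censoring
#' weights (IPCW): cases are patients with an observed event by the horizon,
#' controls are patients still event-free past it; patients censored before
#' the horizon contribute through the Kaplan-Meier estimate of the
#' censoring distribution. The optimal cutoff maximizes the Youden index
#' (sensitivity + specificity - 1, ties broken toward the lower cutoff) and
#' the AUC confidence interval is a seeded patient-level percentile
#' bootstrap.
#'
#' @param scores numeric risk scores (higher = higher risk).
#' @param time,event survival outcome in months.
#' @param horizon horizon in months (default 60 = 5 years).
#' @param bootstrap_reps bootstrap replicates for the CI (default 1000).
#' @param seed bootstrap seed.
#' @return List of class `roc_result`: `auc`, `ci_lower`, `ci_upper`,
#'   `cutoff`, `sensitivity`, `specificity`, `accuracy`,
#'   `horizon_months`, `n_cases`, `n_controls`.
#' @export
roc_at_horizon <- function(scores, time, event, horizon = 60,
                           bootstrap_reps = 1000, seed = 1) {
  stopifnot(length(scores) == length(time), length(time) == length(event))
  G <- km_censoring(time, event)
  auc <- ipcw_auc(scores, time, event, horizon, G)
  yj <- youden_cutoff(scores, time, event, horizon, G)
  boots <- with_seed(seed, {
    vapply(seq_len(bootstrap_reps), function(b) {
      idx <- sample(length(scores), replace = TRUE)
      tryCatch(ipcw_auc(scores[idx], time[idx], event[idx], horizon),
               error = function(e) NA_real_)
    }, numeric(1))
  })
  ci <- quantile(boots, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  structure(list(auc = auc, ci_lower = ci[1], ci_upper = ci[2],
                 cutoff = yj$cutoff, sensitivity = yj$sensitivity,
                 specificity = yj$specificity, accuracy = yj$accuracy,
                 horizon_months = horizon,
                 n_cases = sum(event == 1 & time <= horizon),
                 n_controls = sum(time > horizon)),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUC at %g months: %.3f [%.3f-%.3f]\n", x$horizon_months,
              x$auc, x$ci_lower, x$ci_upper))
  cat(sprintf("Youden cutoff %.4f: sens %.3f, spec %.3f, acc %.3f\n",
              x$cutoff, x$sensitivity, x$specificity, x$accuracy))
  invisible(x)
}

#' Risk stratification with Kaplan-Meier curves and the log-rank test
#'
#' Splits patients at a (training-derived) cutoff into low- and high-risk
#' groups, estimates product-limit survival curves with Greenwood variance,
#' tests the difference with the log-rank test and reports the
#' between-group hazard ratio from a univariate Cox fit on the group
#' indicator.
#'
#' @param scores risk scores.
#' @param cutoff risk cutoff (high risk = score >= cutoff); obtain it from
#'   [roc_at_horizon()] on the training cohort and keep it frozen for
#'   validation cohorts.
#' @param time,event survival outcome.
#' @return List of class `km_strata`: `km` (a `survfit` object),
#'   `logrank_chisq`, `logrank_p`, `hr`, `hr_ci`, `n_low`, `n_high`,
#'   `group` (the assignment).
#' @export
stratify_and_km <- function(scores, cutoff, time, event) {
  group <- factor(ifelse(scores >= cutoff, "high", "low"),
                  levels = c("low", "high"))
  if (min(table(group)) == 0)
    stop("a risk group is empty at this cutoff", call. = FALSE)
  if (sum(event) == 0)
    stop("no events in either group; log-rank test undefined", call. = FALSE)
  y <- survival::Surv(time, event)
  km <- survival::survfit(y ~ group, conf.type = "log")
  sd_ <- survival::survdiff(y ~ group)
  chisq <- sd_$chisq
  p <- pchisq(chisq, df = 1, lower.tail = FALSE)
  cx <- survival::coxph(y ~ group, ties = "efron")
  hr <- exp(coef(cx))[1]
  ci <- exp(confint(cx))[1, ]
  structure(list(km = km, logrank_chisq = chisq, logrank_p = p,
                 hr = unname(hr), hr_ci = unname(ci),
                 n_low = sum(group == "low"), n_high = sum(group == "high"),
                 group = group),
            class = "km_strata")
}

#' Univariate and multivariate Cox proportional-hazards analysis
#'
#' Efron tie handling, Wald confidence intervals and likelihood-ratio
#' p-values. In univariate mode each covariate is fit alone; in
#' multivariate mode all covariates enter jointly and each p-value is the
#' likelihood-ratio test of dropping that covariate from the joint model.
#'
#' @param covariates data.frame or matrix of numeric covariates.
#' @param time,event survival outcome.
#' @param mode `"univariate"` or `"multivariate"`.
#' @return data.frame with one row per covariate: `term`, `hr`, `ci_lower`,
#'   `ci_upper`, `p_value`, `n_events`, `adjusted_for`.
#' @export
cox_regression <- function(covariates, time, event,
                           mode = c("univariate", "multivariate")) {
  mode <- match.arg(mode)
  x <- as.matrix(as.data.frame(covariates))
  storage.mode(x) <- "double"
  if (sum(event) < 5 * ncol(x) && mode == "multivariate")
    warning(sprintf("only %d events for %d covariates (< 5 per covariate)",
                    sum(event), ncol(x)))
  y <- survival::Surv(time, event)
  one_row <- function(term, fit, k, adjusted_for) {
    b <- coef(fit)
    if (any(!is.finite(b)))
      stop("Cox fit produced non-finite coefficients (collinear or ",
           "separated covariates)", call. = FALSE)
    ci <- exp(confint(fit)[k, ])
    data.frame(term = term, hr = exp(b[[k]]), ci_lower = ci[[1]],
               ci_upper = ci[[2]], p_value = NA_real_,
               n_events = sum(event),
               adjusted_for = paste(adjusted_for, collapse = ";"),
               stringsAsFactors = FALSE)
  }
  if (mode == "univariate") {
    out <- do.call(rbind, lapply(seq_len(ncol(x)), function(k) {
      fit <- survival::coxph(y ~ x[, k], ties = "efron")
      r <- one_row(colnames(x)[k], fit, 1, character(0))
      r$p_value <- pchisq(2 * diff(fit$loglik), df = 1, lower.tail = FALSE)
      r
    }))
  } else {
    fit <- survival::coxph(y ~ x, ties = "efron")
    ll_full <- fit$loglik[2]
    out <- do.call(rbind, lapply(seq_len(ncol(x)), function(k) {
      r <- one_row(colnames(x)[k], fit, k,
                   setdiff(colnames(x), colnames(x)[k]))
      red <- if (ncol(x) == 1) {
        survival::coxph(y ~ 1, ties = "efron")
      } else survival::coxph(y ~ x[, -k, drop = FALSE], ties = "efron")
      ll_red <- red$loglik[length(red$loglik)]
      r$p_value <- pchisq(2 * (ll_full - ll_red), df = 1, lower.tail = FALSE)
      r
    }))
  }
  rownames(out) <- NULL
  out
}

#' Time-dependent AUC curve and integrated AUC (iAUC)
#'
#' Computes the IPCW cumulative/dynamic AUC (same estimator as
#' [roc_at_horizon()]) at every grid time and integrates it with weights
#' proportional to the observed event-time density over the grid intervals
#' (Riemann sum), so time regions with more events contribute more.
#'
#' @param scores risk scores.
#' @param time,event survival outcome.
#' @param time_grid increasing evaluation times within follow-up range.
#' @return List: `time` (usable grid times), `auc` (AUC(t)), `iauc`.
#'   Grid points with no cases or no controls are dropped with a warning.
#' @export
time_dependent_auc <- function(scores, time, event, time_grid) {
  time_grid <- sort(time_grid)
  G <- km_censoring(time, event)
  aucs <- vapply(time_grid, function(h)
    tryCatch(ipcw_auc(scores, time, event, h, G),
             error = function(e) NA_real_), numeric(1))
  if (anyNA(aucs)) {
    warning(sprintf("%d grid point(s) without comparable pairs dropped",
                    sum(is.na(aucs))))
    time_grid <- time_grid[!is.na(aucs)]
    aucs <- aucs[!is.na(aucs)]
  }
  if (!length(aucs)) stop("no usable grid points", call. = FALSE)
  ev_times <- time[event == 1]
  brk <- c(0, time_grid)
  w <- vapply(seq_along(time_grid), function(k)
    sum(ev_times > brk[k] & ev_times <= brk[k + 1]), numeric(1))
  if (sum(w) == 0) w <- rep(1, length(aucs))
  list(time = time_grid, auc = aucs, iauc = sum(aucs * w) / sum(w))
}

#' Harrell's concordance index
#'
#' Probability that of two comparable patients (the one with the shorter
#' observed time having an event) the higher-risk score belongs to the
#' earlier failure; score ties count 1/2. Computed with
#' `survival::concordance` (higher score = higher risk) with a normal
#' confidence interval from its standard error.
#'
#' @param scores risk scores.
#' @param time,event survival outcome.
#' @param conf_level confidence level (default 0.95).
#' @return List: `c`, `ci_lower`, `ci_upper`, `n_pairs`.
#' @export
concordance_index <- function(scores, time, event, conf_level = 0.95) {
  fit <- survival::concordance(survival::Surv(time, event) ~ scores,
                               reverse = TRUE)
  counts <- fit$count
  usable <- sum(counts[c("concordant", "discordant", "tied.x")])
  if (usable == 0) stop("no comparable pairs", call. = FALSE)
  z <- qnorm(1 - (1 - conf_level) / 2)
  se <- sqrt(fit$var)
  list(c = unname(fit$concordance),
       ci_lower = unname(fit$concordance - z * se),
       ci_upper = unname(fit$concordance + z * se),
       n_pairs = unname(usable))
}

#' Build a nomogram from a multivariate Cox model
#'
#' Assigns each covariate a point scale proportional to `|beta| x range`
#' (the widest covariate spans 100 points), maps total points to survival
#' probabilities at the requested horizons through the Breslow baseline,
#' and evaluates discrimination (C-index) and calibration
#' (bootstrap-resampled predicted vs Kaplan-Meier-observed survival in risk
#' quantile bins).
#'
#' @param covariates data.frame/matrix of numeric predictors.
#' @param time,event survival outcome.
#' @param horizons months at which survival maps are tabulated.
#' @param n_bins risk quantile bins for calibration (default 4).
#' @param calibration_reps bootstrap replicates (default 200).
#' @param seed bootstrap seed.
#' @return List of class `nomogram_spec`: `points` (per-covariate data.frame
#'   with `beta`, `min`, `max`, `points_per_unit`, `max_points`),
#'   `point_scale`, `lp0` (linear predictor at zero points),
#'   `survival_maps` (per horizon, data.frame of total points vs predicted
#'   survival), `cindex`, `calibration` (per bin: predicted and observed
#'   survival at the first horizon with bootstrap sd), `mace` (mean
#'   absolute calibration error), `fit` (the `coxph` object).
#' @export
build_nomogram <- function(covariates, time, event, horizons = c(12, 36, 60),
                           n_bins = 4, calibration_reps = 200, seed = 1) {
  x <- as.matrix(as.data.frame(covariates))
  storage.mode(x) <- "double"
  if (max(horizons) > max(time[event == 1]))
    stop("horizon beyond the last observed event time", call. = FALSE)
  y <- survival::Surv(time, event)
  fit <- survival::coxph(y ~ x, ties = "efron")
  beta <- coef(fit)
  rng <- apply(x, 2, range)
  span <- abs(beta) * (rng[2, ] - rng[1, ])
  point_scale <- 100 / max(span)
  pts <- data.frame(
    term = colnames(x), beta = unname(beta),
    min = rng[1, ], max = rng[2, ],
    points_per_unit = unname(abs(beta) * point_scale),
    max_points = unname(span * point_scale), row.names = NULL)
  # linear predictor at zero total points (each covariate at its low-risk end)
  x0 <- ifelse(beta >= 0, rng[1, ], rng[2, ])
  lp0 <- sum(beta * x0)
  bh <- survival::basehaz(fit, centered = FALSE)
  H0 <- function(t) {
    vapply(t, function(ti) {
      keep <- bh$time <= ti
      if (!any(keep)) 0 else max(bh$hazard[keep])
    }, numeric(1))
  }
  total_max <- sum(pts$max_points)
  grid <- seq(0, total_max, length.out = 101)
  survival_maps <- lapply(setNames(horizons, paste0("m", horizons)),
                          function(h) {
    data.frame(total_points = grid,
               survival = exp(-H0(h) * exp(lp0 + grid / point_scale)))
  })
  lp <- drop(x %*% beta)
  cidx <- concordance_index(lp, time, event)
  # calibration at the last horizon in risk quantile bins
  h_cal <- max(horizons)
  pred <- exp(-H0(h_cal) * exp(lp))
  qs <- quantile(pred, probs = seq(0, 1, length.out = n_bins + 1))
  bin <- cut(pred, unique(qs), include.lowest = TRUE)
  km_at <- function(tt, ee, h) {
    sf <- survival::survfit(survival::Surv(tt, ee) ~ 1)
    keep <- sf$time <= h
    if (!any(keep)) 1 else min(sf$surv[keep])
  }
  obs <- vapply(levels(bin), function(b)
    km_at(time[bin == b], event[bin == b], h_cal), numeric(1))
  prd <- vapply(levels(bin), function(b) mean(pred[bin == b]), numeric(1))
  boot_obs <- with_seed(seed, {
    vapply(seq_len(calibration_reps), function(r) {
      idx <- sample(length(time), replace = TRUE)
      vapply(levels(bin), function(b) {
        sel <- idx[bin[idx] == b]
        if (!length(sel)) NA_real_ else km_at(time[sel], event[sel], h_cal)
      }, numeric(1))
    }, numeric(length(levels(bin))))
  })
  boot_obs <- matrix(boot_obs, nrow = length(levels(bin)))
  calib <- data.frame(bin = levels(bin), predicted = unname(prd),
                      observed = unname(obs),
                      observed_sd = apply(boot_obs, 1, sd, na.rm = TRUE),
                      row.names = NULL)
  structure(list(points = pts, point_scale = point_scale, lp0 = lp0,
                 survival_maps = survival_maps, cindex = cidx,
                 calibration = calib,
                 mace = mean(abs(calib$predicted - calib$observed)),
                 fit = fit),
            class = "nomogram_spec")
}

#' Predicted survival probability as a function of the risk score
#'
#' Fits a univariate Cox model on the score and evaluates
#' `S(h | s) = S0(h)^exp(beta s)` (Breslow baseline) over a score grid --
#' the score-to-5-year-DFS curve. Strictly decreasing in the score when
#' `beta > 0`.
#'
#' @param scores risk scores.
#' @param time,event survival outcome.
#' @param horizon months (default 60).
#' @param score_grid evaluation grid; defaults to 101 points spanning the
#'   observed score range.
#' @return data.frame with columns `score` and `dfs_prob`; attributes
#'   `beta` and `baseline_survival` (S0 at the horizon).
#' @export
score_to_dfs_curve <- function(scores, time, event, horizon = 60,
                               score_grid = NULL) {
  if (is.null(score_grid))
    score_grid <- seq(min(scores), max(scores), length.out = 101)
  fit <- survival::coxph(survival::Surv(time, event) ~ scores,
                         ties = "efron")
  beta <- unname(coef(fit))
  bh <- survival::basehaz(fit, centered = FALSE)
  keep <- bh$time <= horizon
  H0h <- if (!any(keep)) 0 else max(bh$hazard[keep])
  out <- data.frame(score = score_grid,
                    dfs_prob = exp(-H0h * exp(beta * score_grid)))
  attr(out, "beta") <- beta
  attr(out, "baseline_survival") <- exp(-H0h)
  out
}

#' Subgroup analysis of risk stratification and horizon AUC
#'
#' For every level of every grouping variable, applies the risk
#' stratification ([stratify_and_km()]) and horizon ROC machinery to each
#' score and emits a long-format table -- the per-subgroup HR/AUC driver.
#'
#' @param table data.frame with score columns, grouping columns and
#'   outcome columns.
#' @param group_vars names of grouping (clinical) columns.
#' @param score_cols names of score columns to evaluate.
#' @param cutoffs named numeric vector of frozen (training) cutoffs, one
#'   per score column; defaults to each score's cohort median.
#' @param time_col,event_col outcome column names.
#' @param horizon ROC horizon in months.
#' @return data.frame: `variable`, `level`, `score`, `n`, `n_events`,
#'   `hr`, `auc`. Subgroups without events are skipped with a warning.
#' @export
subgroup_report <- function(table, group_vars, score_cols, cutoffs = NULL,
                            time_col = "dfs_months", event_col = "event",
                            horizon = 60) {
  if (is.null(cutoffs))
    cutoffs <- vapply(score_cols, function(s) median(table[[s]]), numeric(1))
  out <- list()
  for (gv in group_vars) {
    for (lev in unique(as.character(table[[gv]]))) {
      sub <- table[as.character(table[[gv]]) == lev, , drop = FALSE]
      if (!nrow(sub) || sum(sub[[event_col]]) == 0) {
        warning(sprintf("subgroup %s=%s has no events; skipped", gv, lev))
        next
      }
      for (sc in score_cols) {
        hr <- tryCatch(
          stratify_and_km(sub[[sc]], cutoffs[[sc]], sub[[time_col]],
                          sub[[event_col]])$hr,
          error = function(e) NA_real_)
        auc <- tryCatch(
          ipcw_auc(sub[[sc]], sub[[time_col]], sub[[event_col]], horizon),
          error = function(e) NA_real_)
        out[[length(out) + 1L]] <- data.frame(
          variable = gv, level = lev, score = sc, n = nrow(sub),
          n_events = sum(sub[[event_col]]), hr = hr, auc = auc,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) stop("no usable subgroups", call. = FALSE)
  do.call(rbind, out)
}
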