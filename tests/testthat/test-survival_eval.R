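test_that("horizon ROC hits exact endpoints and symmetry", {
  set.seed(2)
  n <- 120
  tt <- sort(rexp(n, 0.02))
  ev <- rep(1, n)
  # score = -event time: perfect discrimination at any horizon
  r <- roc_at_horizon(-tt, tt, ev, horizon = median(tt),
                      bootstrap_reps = 25, seed = 1)
  expect_equal(r$auc, 1)
  expect_true(r$ci_lower <= r$auc && r$auc <= r$ci_upper)
  # negation flips the AUC exactly
  r2 <- roc_at_horizon(tt, tt, ev, horizon = median(tt),
                       bootstrap_reps = 25, seed = 1)
  expect_equal(r2$auc, 1 - r$auc, tolerance = 1e-12)
  # degenerate horizons
  expect_error(roc_at_horizon(-tt, tt, ev, horizon = max(tt) + 1,
                              bootstrap_reps = 5), "cases|controls")
})

test_that("IPCW AUC equals the naive double-loop implementation", {
  tab <- simulate_cohort(cohort_sim_params(
    n_patients = 250, beta = c(latent_1 = 1), censor_target = 0.3,
    seed = 13))
  s <- tab$true_eta
  for (h in c(36, 60, 84)) {
    got <- roc_at_horizon(s, tab$dfs_months, tab$event, horizon = h,
                          bootstrap_reps = 5, seed = 1)$auc
    want <- oracle_ipcw_auc(s, tab$dfs_months, tab$event, h)
    expect_equal(got, want, tolerance = 1e-10, label = paste("h =", h))
  }
})

test_that("KM stratification matches the hand-worked 6-patient fixture", {
  tt <- 1:6
  ev <- c(1, 1, 0, 1, 0, 1)
  grp_score <- c(1, 1, 1, 0, 0, 0)     # A = high risk (score 1), B = low
  res <- stratify_and_km(grp_score, 0.5, tt, ev)
  km <- summary(res$km)
  # group A (high): S(1) = 2/3, S(2) = 1/3; group B (low): S(4) = 2/3,
  # S(6) = 0  -- product-limit by hand
  sv <- split(km$surv, as.character(km$strata))
  expect_equal(sv[["group=high"]], c(2 / 3, 1 / 3), tolerance = 1e-12)
  expect_equal(sv[["group=low"]], c(2 / 3, 0), tolerance = 1e-12)
  # hand log-rank: O_A = 2, E_A = 0.9, V = 0.49
  expect_equal(res$logrank_chisq, (2 - 0.9)^2 / 0.49, tolerance = 1e-10)
  expect_equal(res$logrank_p, pchisq((2 - 0.9)^2 / 0.49, 1,
                                     lower.tail = FALSE), tolerance = 1e-10)
  # no-event input is an explicit error
  expect_error(stratify_and_km(grp_score, 0.5, tt, rep(0, 6)),
               "undefined")
})

test_that("Cox regression matches a brute-force partial likelihood", {
  x <- c(0.5, -1.2, 2.0, 0.1, -0.7, 1.5)
  tt <- c(3, 6, 2, 9, 4, 1)
  ev <- c(1, 1, 1, 0, 1, 1)
  got <- cox_regression(data.frame(x = x), tt, ev)
  beta_grid <- oracle_cox_beta(x, tt, ev)
  expect_equal(log(got$hr), beta_grid, tolerance = 1e-3)
  # duplicated covariate in multivariate mode: collinearity error
  expect_error(cox_regression(data.frame(a = x, b = x), tt, ev,
                              mode = "multivariate"), "collinear")
})

test_that("null and exponential two-group simulations recover known HRs", {
  set.seed(8)
  n <- 1000
  x0 <- rnorm(n)
  tt <- rexp(n, 0.02)
  ev <- rbinom(n, 1, 0.8)
  null_fit <- cox_regression(data.frame(x = x0), tt, ev)
  expect_lt(abs(null_fit$hr - 1), 0.15)

  grp <- rep(0:1, each = n / 2)
  tt2 <- rexp(n, 0.02 * 3^grp)
  fit2 <- cox_regression(data.frame(g = grp), tt2, rep(1, n))
  expect_lt(abs(fit2$hr - 3), 0.4)
  expect_lt(fit2$ci_lower, fit2$hr)
  expect_gt(fit2$ci_upper, fit2$hr)
})

test_that("concordance index matches exhaustive pair counting", {
  set.seed(5)
  s <- rnorm(10); tt <- rexp(10, 0.1); ev <- rbinom(10, 1, 0.7)
  ev[1] <- 1
  got <- concordance_index(s, tt, ev)
  expect_equal(got$c, oracle_cindex(s, tt, ev), tolerance = 1e-12)
  # perfect ordering
  o <- order(tt)
  expect_equal(concordance_index(-rank(tt), tt, rep(1, 10))$c, 1)
  # ties in score count one half
  expect_equal(concordance_index(rep(1, 10), tt, rep(1, 10))$c, 0.5)
})

test_that("time-dependent AUC integrates to sensible iAUC", {
  set.seed(12)
  n <- 150
  tt <- rexp(n, 0.02); ev <- rep(1, n)
  grid <- quantile(tt, seq(0.2, 0.8, 0.1))
  perfect <- time_dependent_auc(-tt, tt, ev, grid)
  expect_true(all(abs(perfect$auc - 1) < 1e-12))
  expect_equal(perfect$iauc, 1)
  anti <- time_dependent_auc(tt, tt, ev, grid)
  expect_equal(anti$iauc, 1 - perfect$iauc, tolerance = 1e-12)

  # dual-implementation cross-check of AUC(t) with censoring
  tab <- simulate_cohort(cohort_sim_params(
    n_patients = 200, beta = c(latent_1 = 1), censor_target = 0.25,
    seed = 3))
  g2 <- c(30, 60, 90)
  res <- time_dependent_auc(tab$true_eta, tab$dfs_months, tab$event, g2)
  for (k in seq_along(g2))
    expect_equal(res$auc[k],
                 oracle_ipcw_auc(tab$true_eta, tab$dfs_months, tab$event,
                                 g2[k]), tolerance = 1e-10)
})

test_that("nomogram points, survival maps and calibration behave", {
  tab <- simulate_cohort(cohort_sim_params(
    n_patients = 1000, beta = c(latent_1 = 0.9, tacs_1 = 0.7),
    censor_target = 0.25, seed = 17))
  nm <- build_nomogram(tab[, c("latent_1", "tacs_1")], tab$dfs_months,
                       tab$event, calibration_reps = 50, seed = 2)
  # widest covariate spans exactly 100 points
  expect_equal(max(nm$points$max_points), 100)
  # single binary covariate: point values are exactly {0, 100}
  nm1 <- build_nomogram(tab[, "tacs_1", drop = FALSE], tab$dfs_months,
                        tab$event, calibration_reps = 20, seed = 2)
  expect_equal(sort(unique(nm1$points$max_points)), 100)
  expect_equal(nm1$points$min, 0)
  expect_equal(nm1$points$max, 1)
  # survival maps decrease monotonically with total points
  for (mp in nm$survival_maps)
    expect_true(all(diff(mp$survival) <= 1e-12))
  # correctly specified model is well calibrated at 60 months
  expect_lte(nm$mace, 0.05)
  # horizon beyond follow-up is an error
  expect_error(build_nomogram(tab[, "latent_1", drop = FALSE],
                              tab$dfs_months, tab$event,
                              horizons = 1e5), "beyond")
})

test_that("score-to-DFS curves follow the Cox baseline", {
  tab <- simulate_cohort(cohort_sim_params(
    n_patients = 2000, beta = c(latent_1 = 1), censor_target = 0.2,
    admin_horizon_months = 300, seed = 19))
  s <- tab$true_eta
  cur <- score_to_dfs_curve(s, tab$dfs_months, tab$event, horizon = 60)
  expect_true(all(diff(cur$dfs_prob) <= 0))
  # at score 0 the prediction is the baseline survival
  at0 <- score_to_dfs_curve(s, tab$dfs_months, tab$event, horizon = 60,
                            score_grid = 0)
  expect_equal(at0$dfs_prob, attr(at0, "baseline_survival"),
               tolerance = 1e-12)
  # predicted S(60 | score) tracks the empirical KM within each decile
  dec <- cut(s, quantile(s, seq(0, 1, 0.1)), include.lowest = TRUE)
  pred <- score_to_dfs_curve(s, tab$dfs_months, tab$event, horizon = 60,
                             score_grid = tapply(s, dec, mean))
  for (k in c(2, 5, 9)) {
    i <- as.integer(dec) == k
    km <- survival::survfit(survival::Surv(tab$dfs_months[i],
                                           tab$event[i]) ~ 1)
    obs <- min(km$surv[km$time <= 60])
    expect_lt(abs(pred$dfs_prob[k] - obs), 0.05)
  }
})

test_that("subgroup report applies the machinery per stratum", {
  tab <- simulate_cohort(cohort_sim_params(
    n_patients = 400, beta = c(latent_1 = 1), censor_target = 0.2,
    admin_horizon_months = 300, seed = 23))
  tab$s <- tab$true_eta
  tab$grp <- "all"
  full <- subgroup_report(tab, "grp", "s", cutoffs = c(s = median(tab$s)))
  direct <- stratify_and_km(tab$s, median(tab$s), tab$dfs_months, tab$event)
  expect_equal(full$hr, direct$hr, tolerance = 1e-12)
  expect_equal(full$auc,
               roc_at_horizon(tab$s, tab$dfs_months, tab$event,
                              bootstrap_reps = 5, seed = 1)$auc,
               tolerance = 1e-10)
  # permutation invariance
  perm <- tab[sample(nrow(tab)), ]
  full2 <- subgroup_report(perm, "grp", "s", cutoffs = c(s = median(tab$s)))
  expect_equal(full2$hr, full$hr, tolerance = 1e-12)

  # effect present only in subgroup A
  wins <- 0
  for (s_ in 1:10) {
    t2 <- simulate_cohort(cohort_sim_params(
      n_patients = 500, beta = c(latent_1 = 1.2), censor_target = 0.2,
      admin_horizon_months = 300, seed = 900 + s_))
    half <- rep(c("A", "B"), length.out = nrow(t2))
    sc <- ifelse(half == "A", t2$true_eta, 0)
    set.seed(s_)
    t2$sub_score <- sc + rnorm(nrow(t2), 0, 0.05)
    t2$half <- half
    rep_ <- subgroup_report(t2, "half", "sub_score",
                            cutoffs = c(sub_score = 0))
    hrA <- rep_$hr[rep_$level == "A"]
    hrB <- rep_$hr[rep_$level == "B"]
    wins <- wins + (isTRUE(hrA > hrB))
  }
  expect_gte(wins, 9)
})

test_that("bootstrap CI width shrinks with sample size", {
  width <- function(n, seed) {
    tab <- simulate_cohort(cohort_sim_params(
      n_patients = n, beta = c(latent_1 = 0.8), censor_target = 0.2,
      admin_horizon_months = 300, seed = seed))
    r <- roc_at_horizon(tab$true_eta, tab$dfs_months, tab$event,
                        bootstrap_reps = 60, seed = 1)
    expect_true(r$ci_lower <= r$auc && r$auc <= r$ci_upper)
    r$ci_upper - r$ci_lower
  }
  expect_lt(width(2000, 3), width(200, 3))
})
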