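sim_feature_cohort <- function(n = 300, beta = c(f1 = 1, f2 = -0.9),
                               n_noise = 20, seed = 1, censor = 0.2) {
  simulate_cohort(cohort_sim_params(
    n_patients = n, beta = beta, n_noise_features = n_noise,
    censor_target = censor, admin_horizon_months = 300, seed = seed))
}

test_that("LASSO-Cox selection behaves along the penalty path", {
  tab <- sim_feature_cohort(seed = 21)
  X <- as.matrix(tab[, c("f1", "f2", paste0("noise_", 1:20))])
  # enormous penalty: nothing selected, score identically zero
  expect_warning(
    m0 <- fit_lasso_cox(X, tab$dfs_months, tab$event,
                        lambda_grid = c(20, 10), lambda_rule = "min",
                        seed = 1),
    "no features")
  expect_length(m0$features, 0)
  expect_equal(score(m0, tab), rep(0, nrow(tab)))

  # selection is monotone in the penalty
  sizes <- vapply(c(0.3, 0.1, 0.02), function(l)
    length(suppressWarnings(fit_lasso_cox(X, tab$dfs_months, tab$event,
                                          lambda_grid = c(l * 2, l),
                                          lambda_rule = "min",
                                          seed = 1))$features), numeric(1))
  expect_true(all(diff(sizes) >= 0))

  # the score is the plain dot product of selected features
  m <- fit_lasso_cox(X, tab$dfs_months, tab$event, seed = 2)
  s <- score(m, tab)
  manual <- as.matrix(tab[, m$features, drop = FALSE]) %*% m$coefficients
  expect_equal(s, drop(manual), tolerance = 1e-12)

  # seeded determinism
  m2 <- fit_lasso_cox(X, tab$dfs_months, tab$event, seed = 2)
  expect_identical(m$coefficients, m2$coefficients)
})

test_that("LASSO-Cox recovers planted signs at moderate n", {
  hits <- 0
  for (s in 1:10) {
    tab <- sim_feature_cohort(n = 1000, beta = c(f1 = 1, f2 = -0.9),
                              n_noise = 30, seed = 400 + s)
    X <- as.matrix(tab[, c("f1", "f2", paste0("noise_", 1:30))])
    m <- suppressWarnings(fit_lasso_cox(X, tab$dfs_months, tab$event,
                                        seed = s))
    ok <- all(c("f1", "f2") %in% m$features) &&
      m$coefficients[["f1"]] > 0 && m$coefficients[["f2"]] < 0
    hits <- hits + ok
  }
  expect_gte(hits, 9)
})

test_that("ridge-Cox keeps all TACS coefficients and shrinks with penalty", {
  tab <- simulate_cohort(cohort_sim_params(
    n_patients = 600, beta = c(tacs_3 = 1), censor_target = 0.2,
    admin_horizon_months = 300, seed = 31))
  X <- as.matrix(tab[, paste0("tacs_", 1:8)])
  m <- fit_ridge_cox(X, tab$dfs_months, tab$event, seed = 1)
  expect_length(m$coefficients, 8)
  expect_equal(names(which.max(abs(m$coefficients))), "tacs_3")

  # all-zero indicator patient scores 0
  expect_equal(score(m, as.data.frame(matrix(0, 1, 8,
    dimnames = list(NULL, paste0("tacs_", 1:8))))), 0)

  # penalty -> infinity drives all coefficients to 0
  mbig <- fit_ridge_cox(X, tab$dfs_months, tab$event, penalty = 1e6)
  expect_lt(max(abs(mbig$coefficients)), 1e-3)

  # constant column flagged
  Xc <- X; Xc[, 5] <- 0
  expect_warning(fit_ridge_cox(Xc, tab$dfs_months, tab$event, penalty = 0.1),
                 "constant")
})

test_that("TACS3-only risk puts the largest ridge coefficient on TACS3", {
  wins <- 0
  for (s in 1:20) {
    tab <- simulate_cohort(cohort_sim_params(
      n_patients = 400, beta = c(tacs_3 = 1), censor_target = 0.2,
      admin_horizon_months = 300, seed = 500 + s))
    m <- fit_ridge_cox(as.matrix(tab[, paste0("tacs_", 1:8)]),
                       tab$dfs_months, tab$event, seed = s)
    wins <- wins + (names(which.max(m$coefficients)) == "tacs_3")
  }
  expect_gte(wins, 18)
})

test_that("clinical Cox encodes covariates against fixed references", {
  set.seed(77)
  n <- 400
  tab <- data.frame(
    age_group = sample(c("<=50", ">50"), n, TRUE),
    subtype = sample(c("LuminalA", "LuminalB", "HER2", "TripleNegative"),
                     n, TRUE),
    tumor_size = sample(c("T1", "T2", "T3"), n, TRUE),
    nodal_status = sample(c("N0", "N1", "N2"), n, TRUE),
    grade = sample(c("G1", "G2", "G3"), n, TRUE),
    stage = sample(c("I", "II", "III"), n, TRUE),
    chemotherapy = sample(c("No", "Yes"), n, TRUE),
    radiation_therapy = sample(c("No", "Yes"), n, TRUE),
    stringsAsFactors = FALSE)
  lp <- 1.2 * (tab$nodal_status == "N2") + 0.8 * (tab$nodal_status == "N1")
  tt <- rexp(n, 0.02 * exp(lp))
  m <- fit_cli_cox(tab, tt, rep(1, n))
  # nodal coefficients dominate
  nod <- abs(m$coefficients[grep("nodal", m$features)])
  oth <- abs(m$coefficients[grep("nodal", m$features, invert = TRUE)])
  expect_gt(min(nod), max(oth))
  # scoring is row-order invariant
  s <- score(m, tab)
  perm <- sample(n)
  expect_equal(score(m, tab[perm, ]), s[perm], tolerance = 1e-12)
  # unknown level rejected
  bad <- tab; bad$grade[1] <- "G9"
  expect_error(score(m, bad), "unknown level")
  # identical covariates: constant (zero) score, flagged
  same <- tab[rep(1, 50), ]
  expect_warning(mc <- fit_cli_cox(same, tt[1:50], rep(1, 50)), "constant")
  expect_equal(score(mc, same), rep(0, 50))
})

test_that("score combination recovers generating weights", {
  tab <- simulate_cohort(cohort_sim_params(
    n_patients = 2000, beta = c(s1 = 1, s2 = 0.5), censor_target = 0.2,
    admin_horizon_months = 400, seed = 71))
  cmb <- combine_scores(tab, c("s1", "s2"), tab$dfs_months, tab$event)
  expect_equal(cmb$coefficients[["s1"]] / cmb$coefficients[["s2"]], 2,
               tolerance = 0.3)

  # pure-noise component gets (near) zero weight
  tabn <- simulate_cohort(cohort_sim_params(
    n_patients = 2000, beta = c(s1 = 1), n_noise_features = 1,
    censor_target = 0.2, admin_horizon_months = 400, seed = 72))
  cmb2 <- combine_scores(tabn, c("s1", "noise_1"), tabn$dfs_months,
                         tabn$event)
  expect_lt(abs(cmb2$coefficients[["noise_1"]]), 0.1)

  # single component: combined score is rank-identical to it
  cmb1 <- combine_scores(tab, "s1", tab$dfs_months, tab$event)
  s <- score(cmb1, tab)
  expect_equal(order(s), order(tab$s1 * sign(cmb1$coefficients[[1]])))
})

test_that("rank metrics are invariant under score translation", {
  tab <- sim_feature_cohort(n = 250, seed = 55)
  s <- tab$true_eta
  a1 <- roc_at_horizon(s, tab$dfs_months, tab$event, bootstrap_reps = 20,
                       seed = 1)
  a2 <- roc_at_horizon(s + 100, tab$dfs_months, tab$event,
                       bootstrap_reps = 20, seed = 1)
  expect_equal(a1$auc, a2$auc, tolerance = 1e-12)
  expect_equal(concordance_index(s, tab$dfs_months, tab$event)$c,
               concordance_index(s + 100, tab$dfs_months, tab$event)$c,
               tolerance = 1e-12)
  g1 <- stratify_and_km(s, quantile(s, 0.5), tab$dfs_months, tab$event)
  g2 <- stratify_and_km(s + 100, quantile(s + 100, 0.5), tab$dfs_months,
                        tab$event)
  expect_equal(g1$hr, g2$hr, tolerance = 1e-12)
})
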