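capi_fixture <- function(seed = 2, n_cand = 25, n_reg = 4) {
  s <- small_scenario(seed = seed, n_cand = n_cand, n_reg = n_reg)
  list(s = s, g = s$genomes[[1]],
       cands = regalign:::scenario_thetas(s),
       regimes = s$regimes,
       model = init_align_model(seed = seed))
}

test_that("reward is the weighted sum of predictions and linear in omega", {
  fx <- capi_fixture()
  omega <- stats::setNames(rep(0, 4), names(fx$regimes))
  expect_equal(reward(fx$cands[[1]], fx$g, fx$regimes, omega, fx$model), 0)
  one <- stats::setNames(1, names(fx$regimes)[1])
  expect_equal(reward(fx$cands[[2]], fx$g, fx$regimes[1], one, fx$model),
               predict_alignment(fx$cands[[2]], fx$regimes[[1]], fx$g,
                                 fx$model))
  withr::with_seed(3, {
    regimes6 <- lapply(1:6, function(j) make_regime(id = paste0("q", j)))
    w6 <- stats::setNames(runif(6), paste0("q", 1:6))
    th <- fx$cands[[3]]
    want <- sum(vapply(1:6, function(j)
      w6[[j]] * predict_alignment(th, regimes6[[j]], fx$g, fx$model), 0))
    expect_equal(reward(th, fx$g, regimes6, w6, fx$model), want,
                 tolerance = 1e-12)
    for (i in 1:15) {
      w1 <- stats::setNames(runif(4, 0, 0.5), names(fx$regimes))
      w2 <- stats::setNames(runif(4, 0, 0.5), names(fx$regimes))
      a <- runif(1, 0, 0.5); b <- runif(1, 0, 0.5)
      expect_equal(
        reward(th, fx$g, fx$regimes, a * w1 + b * w2, fx$model),
        a * reward(th, fx$g, fx$regimes, w1, fx$model) +
          b * reward(th, fx$g, fx$regimes, w2, fx$model),
        tolerance = 1e-10)
    }
  })
  expect_error(reward(fx$cands[[1]], fx$g, fx$regimes,
                      c(r01 = 1), fx$model), class = "missing_weight")
})

test_that("the feasible set equals a brute-force gate scan", {
  fx <- capi_fixture(seed = 5)
  open <- lapply(1:3, function(j) make_regime(id = paste0("o", j)))
  expect_equal(feasible_set(fx$g, fx$cands, open),
               seq_along(fx$cands))
  ban_all <- list(make_regime(id = "ban", exemptions = list(
    exemption_rule("hard_exclusion",
                   list(banned_ops = c("insertion", "deletion",
                                       "substitution"))))))
  expect_length(feasible_set(fx$g, fx$cands, ban_all), 0L)
  want <- which(vapply(fx$cands, function(th)
    all(vapply(fx$regimes, function(r)
      gate_oracle(th, r$exemptions) == 1L, TRUE)), TRUE))
  expect_equal(feasible_set(fx$g, fx$cands, fx$regimes), want)
})

test_that("edit selection maximises reward with stable tie-breaking", {
  fx <- capi_fixture(seed = 7)
  omega <- stats::setNames(runif(4), names(fx$regimes))
  feas <- feasible_set(fx$g, fx$cands, fx$regimes)
  J <- vapply(feas, function(i)
    reward(fx$cands[[i]], fx$g, fx$regimes, omega, fx$model), 0)
  sel <- select_edit(fx$g, fx$cands, fx$regimes, omega, fx$model)
  expect_equal(sel$index, feas[which.max(J)])
  expect_equal(sel$reward, max(J))
  ## single feasible candidate returns itself
  one <- select_edit(fx$g, fx$cands[feas[1]], fx$regimes, omega, fx$model)
  expect_equal(one$index, 1L)
  ## all candidates gated
  ban <- list(make_regime(id = "ban", exemptions = list(
    exemption_rule("hard_exclusion",
                   list(banned_ops = c("insertion", "deletion",
                                       "substitution"))))))
  expect_error(select_edit(fx$g, fx$cands, ban, c(ban = 1), fx$model),
               class = "empty_feasible_set")
  ## exact ties break by input position: duplicate the best candidate
  best <- fx$cands[[sel$index]]
  sel2 <- select_edit(fx$g, c(list(best), fx$cands), fx$regimes, omega,
                      fx$model)
  expect_equal(sel2$index, 1L)
})

test_that("drift fitting recovers analytic cases", {
  drift <- c(0.1, -0.2)
  series <- t(sapply(0:19, function(t) c(1, 2) + t * drift))
  dm <- fit_drift(series)
  expect_equal(dm$drift, drift, tolerance = 1e-12)
  expect_equal(max(abs(dm$Sigma)), 0, tolerance = 1e-12)
  const <- matrix(3, 10, 2)
  expect_equal(fit_drift(const)$drift, c(0, 0))
  expect_error(fit_drift(series[1:2, ]), class = "too_short_series")
})

test_that("drift steps are seeded, reproducible, and mean-unbiased", {
  dm <- structure(list(drift = c(0.3, -0.1),
                       Sigma = diag(c(0.04, 0.09))),
                  class = "drift_model")
  rho <- c(1, 1)
  expect_identical(drift_step(rho, dm, seed = 4),
                   drift_step(rho, dm, seed = 4))
  ## zero drift, zero covariance: unchanged
  dm0 <- structure(list(drift = c(0, 0), Sigma = diag(c(0, 0))),
                   class = "drift_model")
  expect_equal(drift_step(rho, dm0, seed = 1), rho)
  draws <- drift_sample(rho, dm, n = 2000, seed = 9)
  se <- sqrt(diag(dm$Sigma) / 2000)
  expect_true(all(abs(colMeans(draws) - (rho + dm$drift)) < 3 * se))
  bad <- structure(list(drift = 0, Sigma = matrix(-1, 1, 1)),
                   class = "drift_model")
  expect_error(drift_step(0, bad), class = "non_psd_covariance")
})

test_that("weight updates multiply by forecast means and stay in range", {
  omega <- c(a = 0.8, b = 0.5, c = 1)
  expect_equal(update_weights(omega, c(1, 1, 1)), omega)
  expect_equal(unname(update_weights(omega, c(0, 0, 0))), c(0, 0, 0))
  expect_equal(update_weights(omega, c(0.5, 1, 1))[["a"]], 0.4)
  expect_true(all(update_weights(omega, runif(3)) <= 1))
  ren <- update_weights(omega, c(0.5, 0.5, 0.5), renormalize = TRUE)
  expect_equal(max(ren), max(omega))
})

test_that("exemption features match the sliding-window oracle on both strands", {
  g <- genome("g", "ACGAC")
  th <- edit_spec(0, "AC", "substitution")
  x <- exemption_features(th, g)
  expect_equal(unname(x[["off_target_index"]]), 1)
  ## reverse-strand hit: donor AAC, genome carries GTT downstream
  g2 <- genome("g", "AACGGGTTG")
  th2 <- edit_spec(0, "AAC", "substitution")
  expect_equal(unname(exemption_features(th2, g2)[["off_target_index"]]), 1)
  ## donor absent elsewhere
  g3 <- genome("g", "AAAATTTT")
  th3 <- edit_spec(0, "AC", "insertion")
  expect_equal(unname(exemption_features(th3, g3)[["off_target_index"]]), 0)
  expect_equal(unname(exemption_features(th3, g3,
                                         natural_alleles = "AC")[[
                                           "natural_allele"]]), 1)
  withr::with_seed(51, {
    for (i in 1:30) {
      g4 <- genome("g", random_genome_seq(30))
      th4 <- random_edit(g4)
      expect_equal(off_target_index(th4, g4),
                   off_target_oracle(th4$donor, g4$sequence, th4$locus))
    }
  })
  ## origin codes follow the documented 0/1/2 convention
  th5 <- edit_spec(0, "AC", "insertion", donor_origin = "foreign")
  expect_equal(unname(exemption_features(th5, g3)[["donor_origin_code"]]), 2)
})

test_that("rejection risk is the classifier's ambiguity probability", {
  withr::with_seed(61, {
    X <- cbind(natural = rbinom(300, 1, 0.3),
               off_target = rpois(300, 0.7),
               origin = sample(0:2, 300, replace = TRUE))
    amb <- as.numeric(X[, 3] == 2 | (X[, 2] >= 1 & X[, 1] == 0))
  })
  clf <- fit_rejection_classifier(X, amb)
  g <- genome("g", "AAAACCCCGGGGTTTT")
  clear <- edit_spec(0, "AAAA", "substitution", donor_origin = "endogenous")
  risky <- edit_spec(0, "CATG", "substitution", donor_origin = "foreign")
  b_clear <- rejection_risk(clear, g, clf, natural_alleles = "AAAA")
  b_risky <- rejection_risk(risky, g, clf)
  expect_gte(b_clear, 0); expect_lte(b_clear, 1)
  expect_gt(b_risky, b_clear)
  expect_error(rejection_risk(clear, g, list()),
               class = "unfitted_classifier")
})

test_that("calibrated reward never exceeds the raw reward", {
  fx <- capi_fixture(seed = 11)
  omega <- stats::setNames(runif(4), names(fx$regimes))
  withr::with_seed(62, {
    X <- cbind(rbinom(200, 1, 0.3), rpois(200, 0.5),
               sample(0:2, 200, TRUE))
    clf <- fit_rejection_classifier(X, as.numeric(X[, 3] == 2))
  })
  for (i in 1:10) {
    th <- fx$cands[[i]]
    r_raw <- reward(th, fx$g, fx$regimes, omega, fx$model)
    r_cal <- calibrated_reward(th, fx$g, fx$regimes, omega, fx$model, clf,
                               fx$s$natural_alleles)
    expect_lte(r_cal, r_raw + 1e-12)
    ## without a classifier beta = 0 and the two coincide
    expect_equal(calibrated_reward(th, fx$g, fx$regimes, omega, fx$model),
                 r_raw)
    ## explicit triple-product oracle
    beta <- rejection_risk(th, fx$g, clf, fx$s$natural_alleles)
    want <- sum(vapply(seq_along(fx$regimes), function(j)
      omega[[j]] * predict_alignment(th, fx$regimes[[j]], fx$g, fx$model) *
        (1 - beta), 0))
    expect_equal(r_cal, want, tolerance = 1e-12)
  }
})

test_that("divergence follows the double-loop definition", {
  d <- divergence_stat(c(0.9, 0.5))
  expect_equal(d$d_var, 0.2)
  expect_equal(d$delta, matrix(c(0, 0.4, 0.4, 0), 2, 2))
  expect_equal(divergence_stat(rep(0.3, 5))$d_var, 0)
  withr::with_seed(71, {
    for (i in 1:100) {
      s <- runif(sample(2:8, 1))
      dv <- divergence_stat(s)$d_var
      expect_gte(dv, 0)
      expect_equal(divergence_stat(sample(s))$d_var, dv, tolerance = 1e-12)
      expect_equal(dv, mean(abs(outer(s, s, "-"))), tolerance = 1e-12)
    }
  })
})

test_that("the scalarised objective recombines its parts", {
  fx <- capi_fixture(seed = 13)
  omega <- stats::setNames(runif(4), names(fx$regimes))
  th <- fx$cands[[4]]
  ra <- calibrated_reward(th, fx$g, fx$regimes, omega, fx$model)
  dv <- divergence(th, fx$g, fx$regimes, fx$model)$d_var
  expect_equal(capi_objective(th, fx$g, fx$regimes, omega, fx$model,
                              lambda_var = 0.7), ra - 0.7 * dv,
               tolerance = 1e-12)
  expect_equal(capi_objective(th, fx$g, fx$regimes, omega, fx$model,
                              lambda_var = 0), ra)
})

test_that("projected ascent is deterministic, feasible, and monotone in accepted steps", {
  fx <- capi_fixture(seed = 17, n_cand = 40)
  omega <- stats::setNames(runif(4), names(fx$regimes))
  cfgc <- capi_config(seed = 5)
  o1 <- optimize_edit(fx$g, fx$cands, fx$regimes, omega, fx$model,
                      cfg = cfgc)
  o2 <- optimize_edit(fx$g, fx$cands, fx$regimes, omega, fx$model,
                      cfg = cfgc)
  expect_identical(o1$trajectory, o2$trajectory)
  expect_identical(o1$index, o2$index)
  feas <- feasible_set(fx$g, fx$cands, fx$regimes)
  expect_true(o1$index %in% feas)
  expect_true(all(diff(o1$trajectory$accepted) >= -1e-9))
  ## agreement with exhaustive enumeration on this pool
  objs <- vapply(feas, function(i)
    capi_objective(fx$cands[[i]], fx$g, fx$regimes, omega, fx$model,
                   lambda_var = cfgc$lambda_var), 0)
  expect_lt(max(objs) - o1$objective, 1e-6)
  ## starting at the enumerated optimum returns it
  o3 <- optimize_edit(fx$g, fx$cands, fx$regimes, omega, fx$model,
                      start = feas[which.max(objs)], cfg = cfgc)
  expect_equal(o3$objective, max(objs), tolerance = 1e-9)
  ban <- list(make_regime(id = "ban", exemptions = list(
    exemption_rule("hard_exclusion",
                   list(banned_ops = c("insertion", "deletion",
                                       "substitution"))))))
  expect_error(optimize_edit(fx$g, fx$cands, ban, c(ban = 1), fx$model),
               class = "empty_feasible_set")
})

test_that("influence weights combine covariates with clipping", {
  inputs <- data.frame(regime_id = c("a", "b", "c"),
                       gdp = c(0.3, 0.9, 2), trade = c(0, 0.5, 1),
                       reg_history = c(0, 0.2, 0.8),
                       zeta = c(1, 0, 1), xi = c(0, 0, 1),
                       delta = c(0, 0, 1))
  w <- influence_weights(inputs)
  expect_equal(unname(w), c(0.3, 0, 1))
  expect_named(w, c("a", "b", "c"))
  zero <- influence_weights(transform(inputs, zeta = 0, xi = 0, delta = 0))
  expect_equal(unname(zero), c(0, 0, 0))
})

test_that("drift series TSV round-trips at full precision", {
  withr::with_seed(81, {
    series <- list(r1 = matrix(rnorm(20), 5, 4),
                   r2 = matrix(rnorm(20), 5, 4))
  })
  path <- withr::local_tempfile(fileext = ".tsv")
  write_drift_tsv(series, path)
  back <- read_drift_tsv(path)
  expect_equal(back, series, tolerance = 0)
  writeLines("time\tbogus", path)
  expect_error(read_drift_tsv(path), class = "malformed_file")
})
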