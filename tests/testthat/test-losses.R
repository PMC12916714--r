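## A model with analytically controllable embeddings: the edit encoder's
## trainable layers are zeroed (so e = psi, a pure function of the locus)
## and the regulation encoder reduces to the SDN class table.
controlled_model <- function(d = 4L) {
  model <- init_align_model(d = d, k = d, h = 3L, L = 2L, q = 3L,
                            n_filters = 2L, kernel_sizes = c(3L), seed = 44)
  p <- regalign:::get_params(model)
  for (nm in c("W1", "W2", "W3", "b1", "b2", "b3", "E_ex")) {
    p[[nm]] <- p[[nm]] * 0
  }
  for (l in 1:2) {
    p[[paste0("A", l)]] <- p[[paste0("A", l)]] * 0
    p[[paste0("c", l)]] <- p[[paste0("c", l)]] * 0
    p[[paste0("B", l)]] <- p[[paste0("B", l)]] * 0
    p[[paste0("d0", l)]] <- p[[paste0("d0", l)]] * 0
  }
  regalign:::set_params(model, p)
}

test_that("contrastive loss hits its analytic hinge cases exactly", {
  model <- controlled_model()
  g <- genome("g", "ACGTACGTACGTACGTACGT")
  th <- edit_spec(5, "GG", "substitution")
  e <- encode_edit(th, g, model)
  tau <- 0.7
  ## r_pos at distance 0, r_neg at squared distance tau: hinge boundary -> 0
  model$reg$rho_table[1, ] <- e
  model$reg$rho_table[2, ] <- e + c(sqrt(tau), rep(0, 3))
  r_pos <- make_regime(id = "p", sdn = "SDN-1")
  r_neg <- make_regime(id = "n", sdn = "SDN-2")
  expect_equal(contrastive_loss(list(list(theta = th, g = g, r_pos = r_pos,
                                          r_neg = r_neg)), model, tau),
               0, tolerance = 1e-12)
  ## equal distances (identical descriptor classes) -> exactly tau per triple
  r_same <- make_regime(id = "s", sdn = "SDN-1")
  expect_equal(contrastive_loss(list(list(theta = th, g = g, r_pos = r_pos,
                                          r_neg = r_same)), model, tau),
               tau, tolerance = 1e-12)
  expect_equal(contrastive_loss(list(), model, tau), 0)
})

test_that("contrastive loss over a batch equals the explicit summation oracle", {
  model <- init_align_model(d = 8L, k = 8L, h = 4L, L = 2L, q = 4L,
                            n_filters = 3L, kernel_sizes = c(3L, 5L),
                            seed = 7)
  g <- genome("g", paste(rep("ACGT", 10), collapse = ""))
  withr::with_seed(19, {
    triples <- lapply(1:12, function(i)
      list(theta = random_edit(g), g = g,
           r_pos = make_regime(id = "p", sdn = sample(c("SDN-1", "SDN-2"), 1)),
           r_neg = make_regime(id = "n", sdn = "SDN-3",
                               atoms = list(predicate_atom(
                                 "bases_modified", "le", sample(1:5, 1))))))
  })
  tau <- 1.3
  want <- 0
  for (tr in triples) {
    e <- encode_edit(tr$theta, tr$g, model)
    dp <- sum((e - encode_regulation(tr$r_pos, model))^2)
    dn <- sum((e - encode_regulation(tr$r_neg, model))^2)
    want <- want + max(0, tau + dp - dn)
  }
  expect_equal(contrastive_loss(triples, model, tau), want,
               tolerance = 1e-12)
  expect_gte(contrastive_loss(triples, model, tau), 0)
})

test_that("smoothness loss is zero at zero variance and reproducible", {
  model <- init_align_model(seed = 3)
  g <- genome("g", paste(rep("ACGT", 15), collapse = ""))
  withr::with_seed(29, thetas <- lapply(1:5, function(i) random_edit(g)))
  expect_identical(smoothness_loss(thetas, list(g), model, sigma2 = 0), 0)
  l1 <- smoothness_loss(thetas, list(g), model, sigma2 = 0.02,
                        n_samples = 50, seed = 5)
  l2 <- smoothness_loss(thetas, list(g), model, sigma2 = 0.02,
                        n_samples = 50, seed = 5)
  expect_identical(l1, l2)
  expect_gte(l1, 0)
})

test_that("Monte-Carlo smoothness estimates stabilise across large runs", {
  model <- init_align_model(seed = 3)
  g <- genome("g", paste(rep("ACGT", 15), collapse = ""))
  withr::with_seed(30, thetas <- lapply(1:3, function(i) random_edit(g)))
  a <- smoothness_loss(thetas, list(g), model, sigma2 = 0.01,
                       n_samples = 10000, seed = 101)
  b <- smoothness_loss(thetas, list(g), model, sigma2 = 0.01,
                       n_samples = 10000, seed = 202)
  expect_lt(abs(a - b) / a, 0.05)
})

test_that("total loss reduces to an independent cross-entropy at zero lambdas", {
  model <- init_align_model(seed = 13)
  g <- genome("g", paste(rep("TGCA", 12), collapse = ""))
  withr::with_seed(37, {
    batch <- lapply(1:20, function(i) {
      r <- make_regime(id = sprintf("r%d", i %% 4),
                       exemptions = if (i %% 5 == 0) list(
                         exemption_rule("hard_exclusion",
                                        list(banned_ops = "deletion")))
                       else list())
      list(theta = random_edit(g), g = g, r = r, label = sample(0:1, 1))
    })
  })
  cfg0 <- loss_config(lambda1 = 0, lambda2 = 0)
  got <- total_loss(batch, model, cfg0)
  ## independent cross-entropy implementation
  yhat <- vapply(batch, function(b)
    predict_alignment(b$theta, b$r, b$g, model), 0)
  y <- vapply(batch, function(b) b$label, 0)
  p <- pmin(pmax(yhat, 1e-7), 1 - 1e-7)
  want <- -mean(y * log(p) + (1 - y) * log(1 - p))
  expect_equal(got$total, want, tolerance = 1e-10)
  expect_equal(got$align, want, tolerance = 1e-10)
  expect_identical(got$proj, 0)
  expect_identical(got$smooth, 0)
})

test_that("total loss decomposes into its separately computed terms", {
  model <- init_align_model(seed = 13)
  g <- genome("g", paste(rep("TGCA", 12), collapse = ""))
  withr::with_seed(41, {
    edits <- lapply(1:6, function(i) random_edit(g))
    regimes <- lapply(1:3, function(j) make_regime(
      id = paste0("r", j),
      atoms = list(predicate_atom("bases_modified", "le", j + 1))))
    batch <- list()
    for (th in edits) for (r in regimes) {
      batch[[length(batch) + 1]] <- list(
        theta = th, g = g, r = r,
        label = as.numeric(isTRUE(compliance_map(g, th, r))))
    }
  })
  cfg <- loss_config(lambda1 = 0.4, lambda2 = 0.2, sigma2 = 0.01,
                     n_perturb = 3, seed = 77)
  got <- total_loss(batch, model, cfg)
  proj <- contrastive_loss(regalign:::batch_triples(batch), model,
                           cfg$margin)
  smooth <- smoothness_loss(lapply(batch, `[[`, "theta"),
                            lapply(batch, `[[`, "g"), model, cfg$sigma2,
                            cfg$n_perturb, cfg$seed)
  expect_equal(got$total, got$align + 0.4 * proj + 0.2 * smooth,
               tolerance = 1e-12)
  expect_equal(got$proj, proj)
  expect_equal(got$smooth, smooth)
})

test_that("gated pairs with zero labels give a near-zero confident BCE", {
  model <- init_align_model(seed = 2)
  g <- genome("g", "ACGTACGTACGTACGT")
  ban <- make_regime(id = "b", exemptions = list(
    exemption_rule("hard_exclusion",
                   list(banned_ops = c("insertion", "deletion",
                                       "substitution")))))
  batch <- list(list(theta = edit_spec(0, "A", "insertion"), g = g, r = ban,
                     label = 0),
                list(theta = edit_spec(1, "C", "substitution"), g = g,
                     r = ban, label = 0))
  got <- total_loss(batch, model, loss_config(lambda1 = 0, lambda2 = 0))
  expect_lte(got$total, 1e-6)
})

test_that("labels outside 0/1 are rejected", {
  model <- init_align_model(seed = 2)
  g <- genome("g", "ACGTACGT")
  batch <- list(list(theta = edit_spec(0, "A", "insertion"), g = g,
                     r = make_regime(id = "r"), label = 2))
  expect_error(total_loss(batch, model), class = "invalid_label")
})

test_that("analytic batch gradients match numerical differentiation", {
  s <- small_scenario(seed = 3, n_cand = 10)
  model <- init_align_model(d = 6L, k = 6L, h = 4L, L = 2L, q = 5L,
                            n_filters = 3L, kernel_sizes = c(3L, 5L),
                            seed = 2)
  thetas <- regalign:::scenario_thetas(s)
  cache <- regalign:::build_edit_cache(thetas, s$candidates$genome_id,
                                       s$genomes, model)
  ci <- match(s$labels$edit_id, s$candidates$edit_id)
  ri <- match(s$labels$regime_id, names(s$regimes))
  y <- as.numeric(s$labels$compliant)
  G <- regalign:::build_gate_matrix(thetas, s$regimes)
  gate <- G[cbind(ci, ri)]
  idx <- 1:15
  cfg <- loss_config(lambda1 = 0.3, lambda2 = 0.2, sigma2 = 0.01,
                     n_perturb = 2, seed = 5)
  posneg <- lapply(seq_len(cache$n), function(i)
    list(pos = ri[ci == i & y == 1], neg = ri[ci == i & y == 0]))

  loss_fn <- function(model) {
    set.seed(99)
    rf <- regalign:::regime_forward_all(model, s$regimes)
    uc <- unique(ci[idx]); li <- match(ci[idx], uc)
    ef <- regalign:::encode_edits_matrix(model, cache$Z[uc, , drop = FALSE],
                                         cache$Psi[uc, , drop = FALSE],
                                         cache$op[uc])
    X <- cbind(ef$E[li, , drop = FALSE], rf$Rho[ri[idx], , drop = FALSE])
    TT <- tanh(sweep(X %*% t(model$compat$Wa), 2, model$compat$ba, "+"))
    sv <- regalign:::sigmoid(as.numeric(TT %*% model$compat$u))
    L <- regalign:::bce_loss(sv * gate[idx], y[idx])
    triples <- list()
    for (t in seq_along(uc)) {
      pn <- posneg[[uc[t]]]
      if (length(pn$pos) && length(pn$neg)) {
        jp <- pn$pos[sample.int(length(pn$pos), 1)]
        jn <- pn$neg[sample.int(length(pn$neg), 1)]
        triples[[length(triples) + 1]] <- c(t, jp, jn)
      }
    }
    if (length(triples)) {
      acc <- 0
      for (tr in triples) {
        e <- ef$E[tr[1], ]
        dp <- sum((e - rf$Rho[tr[2], ])^2)
        dn <- sum((e - rf$Rho[tr[3], ])^2)
        acc <- acc + max(0, cfg$margin + dp - dn)
      }
      L <- L + cfg$lambda1 * acc / length(triples)
    }
    sdv <- sqrt(cfg$sigma2); acc <- 0
    for (t in seq_along(uc)) {
      o <- cache$op[uc[t]]; z <- cache$Z[uc[t], ]
      for (sdx in 1:cfg$n_perturb) {
        ez <- rnorm(model$dims$m, 0, sdv)
        ep <- rnorm(model$dims$n_pe, 0, sdv)
        thp <- tanh(as.numeric(model$edit$W[[o]] %*% (z + ez)) +
                      model$edit$b[[o]])
        delta <- (thp - ef$Th[t, ]) +
          as.numeric(model$edit$P_psi %*% ep)
        acc <- acc + sum(delta^2)
      }
    }
    L + cfg$lambda2 * acc / (length(uc) * cfg$n_perturb)
  }

  set.seed(99)
  rf <- regalign:::regime_forward_all(model, s$regimes)
  bg <- regalign:::batch_gradients(model, cache, rf, ci[idx], ri[idx],
                                   y[idx], gate[idx], cfg, posneg)
  p0 <- regalign:::get_params(model)
  eps <- 1e-6
  withr::with_seed(55, {
    for (nm in names(p0)) {
      pick <- if (length(p0[[nm]]) > 4) sample(seq_along(p0[[nm]]), 4)
              else seq_along(p0[[nm]])
      for (ii in pick) {
        pp <- p0; pp[[nm]][ii] <- pp[[nm]][ii] + eps
        lp <- loss_fn(regalign:::set_params(model, pp))
        pp[[nm]][ii] <- pp[[nm]][ii] - 2 * eps
        lm <- loss_fn(regalign:::set_params(model, pp))
        gn <- (lp - lm) / (2 * eps)
        expect_equal(bg$grads[[nm]][ii], gn, tolerance = 1e-5)
      }
    }
  })
})
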