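## Constraint-Aware Policy Induction: selecting and optimising edits under
## heterogeneous, drifting regulatory regimes. Reward is the policy-weighted
## sum of gated alignment scores; a risk-calibrated variant downweights edits
## a rejection classifier flags as legally ambiguous; a divergence penalty
## favours edits scored consistently across jurisdictions.

#' CAPI configuration
#'
#' @param lambda_var divergence penalty weight, >= 0.
#' @param alpha ascent step size, > 0.
#' @param max_iter maximum ascent iterations per start.
#' @param tol convergence tolerance on the objective.
#' @param n_drift Monte-Carlo sample count for drift forecasts.
#' @param n_starts random restarts of the projected ascent.
#' @param knn neighbourhood size of the final candidate polish.
#' @param seed integer seed.
#' @export
capi_config <- function(lambda_var = 0.5, alpha = 0.5, max_iter = 200L,
                        tol = 1e-8, n_drift = 100L, n_starts = 12L,
                        knn = 40L, seed = 1L) {
  stopifnot(lambda_var >= 0, alpha > 0, max_iter >= 1, tol > 0, n_drift >= 1,
            n_starts >= 1, knn >= 1)
  structure(list(lambda_var = lambda_var, alpha = alpha,
                 max_iter = as.integer(max_iter), tol = tol,
                 n_drift = as.integer(n_drift),
                 n_starts = as.integer(n_starts), knn = as.integer(knn),
                 seed = seed),
            class = "capi_config")
}

#' Multi-jurisdictional reward
#'
#' \code{J(theta) = sum_r omega(r) * yhat_{theta,r}}; linear in the policy
#' weights.
#'
#' @param theta an \code{\link{edit_spec}}.
#' @param g the target genome.
#' @param regimes list of regulatory descriptors.
#' @param omega policy weights in [0,1], named by regime id or in regime
#'   order.
#' @param model fitted alignment model.
#' @return scalar reward.
#' @export
reward <- function(theta, g, regimes, omega, model) {
  w <- resolve_weights(omega, regimes)
  yhat <- vapply(regimes, function(r)
    predict_alignment(theta, r, g, model), 0)
  sum(w * yhat)
}

#' Feasible candidate set
#'
#' Candidates whose symbolic gate is open under every regime's exemption
#' context: the edits structurally compliant across all policy descriptors.
#'
#' @param g the target genome.
#' @param candidates list of \code{\link{edit_spec}} objects.
#' @param regimes list of regulatory descriptors.
#' @return integer vector of candidate indices.
#' @export
feasible_set <- function(g, candidates, regimes) {
  keep <- vapply(candidates, function(th)
    all(vapply(regimes, function(r)
      symbolic_gate(th, r$exemptions) == 1L, TRUE)), TRUE)
  which(keep)
}

#' Select the reward-maximising feasible edit
#'
#' Exhaustive argmax of the reward \code{J} over the feasible set; ties are
#' broken by earliest input position.
#'
#' @inheritParams feasible_set
#' @param omega policy weights.
#' @param model fitted alignment model.
#' @return list with \code{index} (into \code{candidates}), \code{edit},
#'   \code{reward}.
#' @export
select_edit <- function(g, candidates, regimes, omega, model) {
  feas <- feasible_set(g, candidates, regimes)
  if (!length(feas)) {
    stop_regalign("empty_feasible_set", "no candidate passes every gate")
  }
  J <- vapply(feas, function(i) reward(candidates[[i]], g, regimes, omega,
                                       model), 0)
  best <- feas[which.max(J)]
  list(index = best, edit = candidates[[best]], reward = max(J))
}

## ---- regulatory drift -------------------------------------------------------

#' Fit a linear drift model to a regime embedding time series
#'
#' Drift is the mean first difference; the residual covariance is the sample
#' covariance of the de-drifted differences.
#'
#' @param series numeric matrix, one row per time point, one column per
#'   embedding dimension (length >= 3 rows).
#' @return An object of class \code{drift_model} with fields \code{drift}
#'   (length k) and \code{Sigma} (k x k).
#' @export
fit_drift <- function(series) {
  series <- as.matrix(series)
  if (nrow(series) < 3L) {
    stop_regalign("too_short_series",
                  "drift estimation needs >= 3 time points, got %d",
                  nrow(series))
  }
  diffs <- diff(series)
  drift <- colMeans(diffs)
  resid <- sweep(diffs, 2L, drift)
  Sigma <- stats::cov(resid)
  structure(list(drift = drift, Sigma = Sigma), class = "drift_model")
}

check_psd <- function(Sigma) {
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -1e-10)) {
    stop_regalign("non_psd_covariance",
                  "residual covariance is not positive semi-definite")
  }
  invisible(TRUE)
}

#' Sample drifted regime embeddings
#'
#' Draws \code{rho + drift + eps} with \code{eps ~ N(0, Sigma)}; seeded and
#' reproducible.
#'
#' @param rho current embedding.
#' @param dm a \code{\link{fit_drift}} model.
#' @param n number of draws.
#' @param seed integer seed.
#' @return matrix with \code{n} rows.
#' @export
drift_sample <- function(rho, dm, n = 1L, seed = 1L) {
  stopifnot(length(rho) == length(dm$drift))
  check_psd(dm$Sigma)
  with_seed(derive_seed(seed, 23L), {
    eps <- MASS::mvrnorm(n, mu = rep(0, length(rho)), Sigma = dm$Sigma,
                         tol = 1e-8)
    if (n == 1L) eps <- matrix(eps, nrow = 1L)
    sweep(eps, 2L, rho + dm$drift, "+")
  })
}

#' One stochastic drift step
#'
#' @inheritParams drift_sample
#' @return drifted embedding vector.
#' @export
drift_step <- function(rho, dm, seed = 1L) {
  drift_sample(rho, dm, n = 1L, seed = seed)[1, ]
}

#' Forecast mean alignment under regulatory drift
#'
#' Monte-Carlo mean of the gated alignment score of one edit against each
#' regime's drifted embedding.
#'
#' @param theta an edit.
#' @param g the target genome.
#' @param regimes list of descriptors.
#' @param model fitted alignment model.
#' @param drift_models list of \code{drift_model} objects, one per regime.
#' @param n Monte-Carlo sample count.
#' @param seed integer seed.
#' @return numeric vector of forecast means, one per regime.
#' @export
forecast_alignment <- function(theta, g, regimes, model, drift_models,
                               n = 100L, seed = 1L) {
  e <- encode_edit(theta, g, model)
  vapply(seq_along(regimes), function(j) {
    r <- regimes[[j]]
    if (symbolic_gate(theta, r$exemptions) == 0L) return(0)
    rho <- encode_regulation(r, model)
    draws <- drift_sample(rho, drift_models[[j]], n = n,
                          seed = derive_seed(seed, j))
    mean(vapply(seq_len(n), function(s)
      alignment_score(e, draws[s, ], model$compat), 0))
  }, 0)
}

#' Update policy weights by forecast alignment
#'
#' \code{omega' = omega * E[yhat under drift]}, clipped to [0, 1]. The
#' product with a probability can only shrink the weights; optional
#' renormalisation to the previous maximum is off by default.
#'
#' @param omega current weights (named or positional).
#' @param forecast_means per-regime forecast means (from
#'   \code{\link{forecast_alignment}}).
#' @param renormalize rescale so the largest updated weight equals the
#'   largest previous weight.
#' @return updated weights, same names.
#' @export
update_weights <- function(omega, forecast_means, renormalize = FALSE) {
  stopifnot(length(omega) == length(forecast_means))
  out <- clip01(omega * forecast_means)
  if (renormalize && max(out) > 0) {
    out <- clip01(out * max(omega) / max(out))
  }
  out
}

## ---- exemption features and rejection risk ---------------------------------

#' Off-target index of a donor sequence
#'
#' Exact-match occurrence count of the donor (either strand) in the genome at
#' windows disjoint from the edited interval \code{[locus, locus + |donor|)}.
#' A deterministic, cheap stand-in for off-target risk.
#'
#' @param theta an edit.
#' @param g the genome.
#' @return non-negative integer.
#' @export
off_target_index <- function(theta, g) {
  s <- g$sequence
  d <- theta$donor
  L <- nchar(d)
  n <- nchar(s)
  if (L > n) return(0L)
  rc <- revcomp(d)
  count <- 0L
  for (p in 0:(n - L)) {
    if (p < theta$locus + L && p + L > theta$locus) next  # overlaps edit site
    w <- substr(s, p + 1L, p + L)
    if (w == d || w == rc) count <- count + 1L
  }
  count
}

#' Exemption feature vector
#'
#' \code{X(theta) = [I(donor in natural alleles), off-target index,
#' donor-origin code]} with origin coded 0 = endogenous, 1 = natural variant,
#' 2 = foreign.
#'
#' @param theta an edit.
#' @param g the genome.
#' @param natural_alleles character vector of natural allele sequences.
#' @return named numeric vector of length 3.
#' @export
exemption_features <- function(theta, g, natural_alleles = character()) {
  origin <- theta$donor_origin %||%
    infer_donor_origin(g, theta$donor, natural_alleles)
  c(natural_allele = as.numeric(theta$donor %in% natural_alleles),
    off_target_index = as.numeric(off_target_index(theta, g)),
    donor_origin_code = as.numeric(match(origin, DONOR_ORIGINS) - 1L))
}

#' Fit the rejection-risk classifier
#'
#' Regularised-by-default logistic model of the probability that an edit is
#' legally ambiguous, trained on exemption feature vectors and the
#' scenario's ambiguity labels.
#'
#' @param X matrix of \code{\link{exemption_features}} rows.
#' @param ambiguous 0/1 labels.
#' @return An object of class \code{rejection_classifier}.
#' @export
fit_rejection_classifier <- function(X, ambiguous) {
  df <- data.frame(natural_allele = X[, 1],
                   off_target_index = X[, 2],
                   origin_nat = as.numeric(X[, 3] == 1),
                   origin_foreign = as.numeric(X[, 3] == 2),
                   y = as.numeric(ambiguous))
  fit <- suppressWarnings(stats::glm(y ~ natural_allele + off_target_index +
                                       origin_nat + origin_foreign,
                                     family = stats::binomial(), data = df))
  structure(list(fit = fit), class = "rejection_classifier")
}

#' Estimated rejection risk
#'
#' \code{beta = 1 - P(clear | X(theta))}: the classifier's probability that
#' the edit is legally ambiguous.
#'
#' @param theta an edit.
#' @param g the genome.
#' @param classifier a fitted \code{\link{fit_rejection_classifier}}.
#' @param natural_alleles natural allele pool.
#' @return probability in [0, 1].
#' @export
rejection_risk <- function(theta, g, classifier,
                           natural_alleles = character()) {
  if (!inherits(classifier, "rejection_classifier")) {
    stop_regalign("unfitted_classifier",
                  "classifier must be fitted by fit_rejection_classifier()")
  }
  x <- exemption_features(theta, g, natural_alleles)
  nd <- data.frame(natural_allele = x[1], off_target_index = x[2],
                   origin_nat = as.numeric(x[3] == 1),
                   origin_foreign = as.numeric(x[3] == 2))
  as.numeric(stats::predict(classifier$fit, newdata = nd, type = "response"))
}

#' Risk-calibrated reward surface
#'
#' \code{R_align = sum_r omega(r) * yhat_{theta,r} * (1 - beta(theta))};
#' never exceeds the raw reward since \code{1 - beta} lies in [0, 1].
#'
#' @inheritParams reward
#' @param classifier optional rejection classifier; without one beta = 0 and
#'   the calibrated reward equals the reward.
#' @param natural_alleles natural allele pool.
#' @return scalar.
#' @export
calibrated_reward <- function(theta, g, regimes, omega, model,
                              classifier = NULL,
                              natural_alleles = character()) {
  beta <- if (is.null(classifier)) 0 else
    rejection_risk(theta, g, classifier, natural_alleles)
  w <- resolve_weights(omega, regimes)
  yhat <- vapply(regimes, function(r)
    predict_alignment(theta, r, g, model), 0)
  sum(w * yhat * (1 - beta))
}

#' Jurisdictional divergence of a score vector
#'
#' \code{D_var = (1/|R|^2) sum_{j,k} |s_j - s_k|}, both orderings and the
#' zero diagonal included: non-negative, zero iff all scores are equal, and
#' invariant under permutation of the regimes.
#'
#' @param scores per-regime alignment scores.
#' @return list with \code{delta} (pairwise absolute-difference matrix) and
#'   \code{d_var}.
#' @export
divergence_stat <- function(scores) {
  delta <- abs(outer(scores, scores, "-"))
  list(delta = delta, d_var = mean(delta))
}

#' Jurisdictional divergence of one edit
#'
#' @inheritParams reward
#' @return list with \code{delta} and \code{d_var}.
#' @export
divergence <- function(theta, g, regimes, model) {
  divergence_stat(vapply(regimes, function(r)
    predict_alignment(theta, r, g, model), 0))
}

#' Scalarised CAPI objective
#'
#' \code{O = R_align - lambda_var * D_var}: risk-calibrated reward balanced
#' against cross-jurisdiction divergence.
#'
#' @inheritParams calibrated_reward
#' @param lambda_var divergence penalty weight, >= 0.
#' @return scalar.
#' @export
capi_objective <- function(theta, g, regimes, omega, model,
                           classifier = NULL, natural_alleles = character(),
                           lambda_var = 0.5) {
  stopifnot(lambda_var >= 0)
  calibrated_reward(theta, g, regimes, omega, model, classifier,
                    natural_alleles) -
    lambda_var * divergence(theta, g, regimes, model)$d_var
}

## Objective evaluated from a precomputed latent point and per-candidate
## rejection risk -- the workhorse of the projected ascent.
objective_from_scores <- function(s, w, beta, lambda_var) {
  sum(w * s * (1 - beta)) - lambda_var * mean(abs(outer(s, s, "-")))
}

#' Projected ascent over the candidate pool
#'
#' Ascends the CAPI objective in a continuous relaxation of the edit: the
#' discrete candidate is relaxed to its continuous encoder inputs (donor
#' feature vector, positional encoding, soft op-type weights), the analytic
#' gradient of the objective is backpropagated through the alignment
#' network's edit encoder and compatibility head, and every step is
#' projected back onto the feasible candidate pool by nearest Euclidean
#' distance in that feature space. Random restarts and a nearest-neighbour
#' polish on the candidate graph guard against local optima; the returned
#' accepted objective sequence is non-decreasing and the final edit is
#' always feasible.
#'
#' @param g the target genome.
#' @param candidates list of \code{\link{edit_spec}} objects.
#' @param regimes list of regulatory descriptors.
#' @param omega policy weights.
#' @param model fitted alignment model.
#' @param start index of the initial candidate (defaults to the first
#'   feasible one).
#' @param cfg a \code{\link{capi_config}}.
#' @param classifier optional rejection classifier.
#' @param natural_alleles natural allele pool.
#' @return list with \code{index}, \code{edit}, \code{objective}, and
#'   \code{trajectory} (data.frame: iteration, candidate, objective,
#'   accepted objective).
#' @export
optimize_edit <- function(g, candidates, regimes, omega, model,
                          start = NULL, cfg = capi_config(),
                          classifier = NULL,
                          natural_alleles = character()) {
  feas <- feasible_set(g, candidates, regimes)
  if (!length(feas)) {
    stop_regalign("empty_feasible_set", "no candidate passes every gate")
  }
  w <- resolve_weights(omega, regimes)
  nf <- length(feas)
  d <- model$dims$d
  m <- model$dims$m
  n_pe <- model$dims$n_pe

  ## continuous relaxation coordinates of each feasible candidate: donor
  ## feature vector, positional encoding, one-hot op-type
  Zc <- t(vapply(feas, function(i)
    donor_conv_features(candidates[[i]]$donor, model), numeric(m)))
  Pc <- t(vapply(feas, function(i)
    pos_encoding(candidates[[i]]$locus / nchar(g$sequence)), numeric(n_pe)))
  Oc <- t(vapply(feas, function(i) {
    v <- rep(0, 3); v[op_index(candidates[[i]]$op_type)] <- 1; v
  }, numeric(3)))
  Xc <- cbind(Zc, Pc, Oc)

  Rho <- t(vapply(regimes, function(r)
    encode_regulation(r, model), numeric(model$dims$k)))
  beta <- vapply(feas, function(i) {
    if (is.null(classifier)) 0 else
      rejection_risk(candidates[[i]], g, classifier, natural_alleles)
  }, 0)

  embed_relaxed <- function(x) {
    z <- x[seq_len(m)]
    pe <- x[m + seq_len(n_pe)]
    opw <- x[m + n_pe + 1:3]
    th <- lapply(1:3, function(o)
      tanh(as.numeric(model$edit$W[[o]] %*% z) + model$edit$b[[o]]))
    e <- as.numeric(model$edit$P_psi %*% pe)
    for (o in 1:3) e <- e + opw[o] * th[[o]]
    list(e = e, th = th, z = z, opw = opw)
  }

  score_at <- function(e) {
    vapply(seq_along(regimes), function(j)
      alignment_score(e, Rho[j, ], model$compat), 0)
  }
  ## lazy, memoised objective over the candidate pool: the search only ever
  ## pays for candidates it actually visits
  obj_memo <- rep(NA_real_, nf)
  obj_at <- function(t) {
    if (is.na(obj_memo[t])) {
      emb <- embed_relaxed(Xc[t, ])
      obj_memo[t] <<- objective_from_scores(score_at(emb$e), w, beta[t],
                                            cfg$lambda_var)
    }
    obj_memo[t]
  }

  ## analytic gradient of the objective through the compatibility head and
  ## the edit encoder, with respect to the relaxation coordinates
  grad_at <- function(x, beta_here) {
    emb <- embed_relaxed(x)
    s <- score_at(emb$e)
    dO_ds <- w * (1 - beta_here) -
      cfg$lambda_var * (2 / length(s)^2) *
        rowSums(sign(outer(s, s, "-")))
    de <- rep(0, d)
    for (j in seq_along(s)) {
      xcat <- c(emb$e, Rho[j, ])
      t_h <- tanh(as.numeric(model$compat$Wa %*% xcat) + model$compat$ba)
      dv <- model$compat$u * (1 - t_h^2)
      de <- de + dO_ds[j] * s[j] * (1 - s[j]) *
        as.numeric(crossprod(model$compat$Wa[, seq_len(d), drop = FALSE],
                             dv))
    }
    dz <- rep(0, m)
    dop <- numeric(3)
    for (o in 1:3) {
      dop[o] <- sum(emb$th[[o]] * de)
      dz <- dz + emb$opw[o] *
        as.numeric(crossprod(model$edit$W[[o]], de * (1 - emb$th[[o]]^2)))
    }
    dpe <- as.numeric(crossprod(model$edit$P_psi, de))
    c(dz, dpe, dop)
  }

  nearest <- function(x) which.min(rowSums(sweep(Xc, 2L, x)^2))

  start_local <- if (is.null(start)) 1L else match(start, feas)
  if (is.na(start_local)) {
    stop_regalign("empty_feasible_set", "start candidate %d is not feasible",
                  start)
  }

  ## greedy hill-climb over the knn-neighbourhood graph of the pool
  polish <- function(t0) {
    t_cur <- t0
    repeat {
      dist2 <- rowSums(sweep(Xc, 2L, Xc[t_cur, ])^2)
      nb <- order(dist2)[seq_len(min(cfg$knn + 1L, nf))]
      objs <- vapply(nb, obj_at, 0)
      cand <- nb[which.max(objs)]
      if (obj_at(cand) > obj_at(t_cur) + cfg$tol) t_cur <- cand else break
    }
    t_cur
  }

  traj <- list()
  best_t <- start_local
  best_obj <- obj_at(start_local)
  iter_count <- 0L

  with_seed(derive_seed(cfg$seed, 13L), {
    starts <- unique(c(start_local,
                       sample.int(nf, min(nf, cfg$n_starts))))
    for (st in starts) {
      x <- Xc[st, ]
      prev_obj <- obj_at(st)
      if (prev_obj > best_obj) { best_obj <- prev_obj; best_t <- st }
      end_t <- st
      for (it in seq_len(cfg$max_iter)) {
        iter_count <- iter_count + 1L
        gvec <- grad_at(x, beta[end_t])
        if (!all(is.finite(gvec))) {
          stop_regalign("non_finite_gradient",
                        "objective gradient is not finite")
        }
        x <- x + cfg$alpha * gvec
        t_proj <- nearest(x)
        o_proj <- obj_at(t_proj)
        end_t <- t_proj
        if (o_proj > best_obj) { best_obj <- o_proj; best_t <- t_proj }
        traj[[length(traj) + 1L]] <- data.frame(
          iteration = iter_count, candidate = feas[t_proj],
          objective = o_proj, accepted = best_obj)
        if (abs(o_proj - prev_obj) < cfg$tol) break
        prev_obj <- o_proj
      }
      ## polish the ascent endpoint on the candidate graph
      pt <- polish(end_t)
      if (obj_at(pt) > best_obj) { best_obj <- obj_at(pt); best_t <- pt }
    }
  })
  best_t <- polish(best_t)
  best_obj <- obj_at(best_t)

  trajectory <- if (length(traj)) do.call(rbind, traj) else
    data.frame(iteration = integer(), candidate = integer(),
               objective = numeric(), accepted = numeric())
  list(index = feas[best_t], edit = candidates[[feas[best_t]]],
       objective = best_obj, trajectory = trajectory)
}

#' Influence-derived policy weights
#'
#' \code{omega_r = zeta_r * GDP_r + xi_r * Trade_r + delta_r * RegHistory_r},
#' clipped to [0, 1].
#'
#' @param inputs data.frame with columns \code{regime_id}, \code{gdp},
#'   \code{trade}, \code{reg_history}, \code{zeta}, \code{xi}, \code{delta}.
#' @return named numeric vector of weights in [0, 1].
#' @export
influence_weights <- function(inputs) {
  stopifnot(all(c("regime_id", "gdp", "trade", "reg_history", "zeta", "xi",
                  "delta") %in% names(inputs)),
            all(is.finite(inputs$gdp)), all(inputs$gdp >= 0),
            all(is.finite(inputs$trade)), all(inputs$trade >= 0),
            all(is.finite(inputs$reg_history)))
  w <- clip01(inputs$zeta * inputs$gdp + inputs$xi * inputs$trade +
                inputs$delta * inputs$reg_history)
  stats::setNames(w, inputs$regime_id)
}

#' Scenario-level CAPI report
#'
#' Per-candidate reward, calibrated reward, divergence, objective and gate
#' status, the reward-based selection, the ascent-based selection, and an
#' enumeration cross-check flag when the pool is small enough to enumerate.
#'
#' @inheritParams optimize_edit
#' @param enum_limit run the exhaustive cross-check when the pool size is at
#'   most this.
#' @return list (JSON-ready) with \code{candidates}, \code{selection},
#'   \code{optimize}, \code{enumeration_checked}, \code{feasible_count}.
#' @export
capi_report <- function(g, candidates, regimes, omega, model,
                        cfg = capi_config(), classifier = NULL,
                        natural_alleles = character(), enum_limit = 200L) {
  w <- resolve_weights(omega, regimes)
  feas <- feasible_set(g, candidates, regimes)
  per <- lapply(seq_along(candidates), function(i) {
    th <- candidates[[i]]
    yhat <- vapply(regimes, function(r)
      predict_alignment(th, r, g, model), 0)
    beta <- if (is.null(classifier)) 0 else
      rejection_risk(th, g, classifier, natural_alleles)
    dv <- divergence_stat(yhat)$d_var
    J <- sum(w * yhat)
    Ra <- sum(w * yhat * (1 - beta))
    list(candidate = i, gate_feasible = i %in% feas, J = J, R_align = Ra,
         D_var = dv, objective = Ra - cfg$lambda_var * dv)
  })
  if (!length(feas)) {
    return(list(status = "empty_feasible_set", candidates = per,
                feasible_count = 0L))
  }
  sel <- select_edit(g, candidates, regimes, omega, model)
  opt <- optimize_edit(g, candidates, regimes, omega, model, cfg = cfg,
                       classifier = classifier,
                       natural_alleles = natural_alleles)
  enum_ok <- NA
  if (length(candidates) <= enum_limit) {
    objs <- vapply(per, function(x)
      if (x$gate_feasible) x$objective else -Inf, 0)
    enum_ok <- abs(max(objs) - opt$objective) <= 1e-6
  }
  list(status = "ok", feasible_count = length(feas), candidates = per,
       selection = list(index = sel$index, reward = sel$reward),
       optimize = list(index = opt$index, objective = opt$objective),
       enumeration_checked = enum_ok)
}

## ---- drift series I/O -------------------------------------------------------

#' Write regime embedding time series to TSV
#'
#' Long format: \code{time}, \code{regime_id}, then one column per embedding
#' dimension, at full double precision.
#'
#' @param series named list of matrices (rows = time points).
#' @param path output file.
#' @export
write_drift_tsv <- function(series, path) {
  rows <- lapply(names(series), function(id) {
    m <- series[[id]]
    df <- data.frame(time = seq_len(nrow(m)), regime_id = id)
    cbind(df, as.data.frame(matrix(sprintf("%.17g", m), nrow(m))))
  })
  out <- do.call(rbind, rows)
  names(out) <- c("time", "regime_id",
                  paste0("dim", seq_len(ncol(out) - 2L)))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read regime embedding time series from TSV
#'
#' @param path file written by \code{\link{write_drift_tsv}}.
#' @return named list of matrices.
#' @export
read_drift_tsv <- function(path) {
  df <- tryCatch(utils::read.delim(path, colClasses = "character"),
                 error = function(e) stop_regalign(
                   "malformed_file", "cannot parse drift TSV %s: %s", path,
                   conditionMessage(e)))
  if (!all(c("time", "regime_id") %in% names(df))) {
    stop_regalign("malformed_file",
                  "drift TSV %s lacks time/regime_id columns", path)
  }
  dims <- setdiff(names(df), c("time", "regime_id"))
  out <- lapply(split(df, df$regime_id), function(s) {
    s <- s[order(as.integer(s$time)), , drop = FALSE]
    m <- as.matrix(s[, dims, drop = FALSE])
    matrix(as.numeric(m), nrow(m), dimnames = NULL)
  })
  out[unique(df$regime_id)]
}
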