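## Supervised training of the alignment network on labeled (edit, regime)
## pairs, with minibatch AdamW, hand-derived backpropagation, early stopping
## on validation loss, and best-checkpoint restoration.

## ---- parameter flattening for the optimiser -------------------------------

get_params <- function(model) {
  out <- list(W1 = model$edit$W[[1]], W2 = model$edit$W[[2]],
              W3 = model$edit$W[[3]], b1 = model$edit$b[[1]],
              b2 = model$edit$b[[2]], b3 = model$edit$b[[3]],
              rho_table = model$reg$rho_table, E_ex = model$reg$E_ex,
              a_ex = model$reg$a_ex, attn = model$reg$attn,
              Wa = model$compat$Wa, ba = model$compat$ba, u = model$compat$u)
  for (l in seq_along(model$reg$mlps)) {
    m <- model$reg$mlps[[l]]
    out[[paste0("A", l)]] <- m$A
    out[[paste0("c", l)]] <- m$c
    out[[paste0("B", l)]] <- m$B
    out[[paste0("d0", l)]] <- m$d0
  }
  out
}

set_params <- function(model, p) {
  model$edit$W <- list(p$W1, p$W2, p$W3)
  model$edit$b <- list(p$b1, p$b2, p$b3)
  model$reg$rho_table <- p$rho_table
  model$reg$E_ex <- p$E_ex
  model$reg$a_ex <- p$a_ex
  model$reg$attn <- p$attn
  model$compat$Wa <- p$Wa
  model$compat$ba <- p$ba
  model$compat$u <- p$u
  for (l in seq_along(model$reg$mlps)) {
    model$reg$mlps[[l]] <- list(A = p[[paste0("A", l)]],
                                c = p[[paste0("c", l)]],
                                B = p[[paste0("B", l)]],
                                d0 = p[[paste0("d0", l)]])
  }
  model
}

zero_like <- function(p) lapply(p, function(x) x * 0)

## ---- caches ----------------------------------------------------------------

scenario_thetas <- function(scenario) {
  lapply(seq_len(nrow(scenario$candidates)), function(i) {
    row <- scenario$candidates[i, ]
    edit_spec(row$locus, row$donor, row$op_type, row$donor_origin)
  })
}

build_edit_cache <- function(thetas, genome_ids, genomes, model) {
  n <- length(thetas)
  Z <- matrix(0, n, model$dims$m)
  Psi <- matrix(0, n, model$dims$d)
  op <- integer(n)
  for (i in seq_len(n)) {
    th <- thetas[[i]]
    g <- genomes[[genome_ids[i]]]
    Z[i, ] <- donor_conv_features(th$donor, model)
    Psi[i, ] <- as.numeric(model$edit$P_psi %*%
                             pos_encoding(th$locus / nchar(g$sequence)))
    op[i] <- op_index(th$op_type)
  }
  list(Z = Z, Psi = Psi, op = op, n = n)
}

build_gate_matrix <- function(thetas, regimes) {
  G <- matrix(1L, length(thetas), length(regimes))
  for (j in seq_along(regimes)) {
    ex <- regimes[[j]]$exemptions
    G[, j] <- vapply(thetas, symbolic_gate, 0L, exemptions = ex)
  }
  G
}

## Forward pass of the edit encoder over cached rows; returns embeddings and
## the tanh activations needed for backprop.
encode_edits_matrix <- function(model, Z, Psi, op) {
  n <- nrow(Z)
  d <- model$dims$d
  E <- matrix(0, n, d)
  Th <- matrix(0, n, d)
  for (o in 1:3) {
    idx <- which(op == o)
    if (!length(idx)) next
    pre <- Z[idx, , drop = FALSE] %*% t(model$edit$W[[o]])
    pre <- sweep(pre, 2L, model$edit$b[[o]], "+")
    Th[idx, ] <- tanh(pre)
    E[idx, ] <- Th[idx, , drop = FALSE] + Psi[idx, , drop = FALSE]
  }
  list(E = E, Th = Th)
}

regime_forward_all <- function(model, regimes) {
  rf <- lapply(regimes, encode_regulation_full, model = model)
  Rho <- do.call(rbind, lapply(rf, `[[`, "rho"))
  list(rf = rf, Rho = Rho)
}

## Accumulate regulation-encoder gradients for one regime given the upstream
## gradient on its embedding.
accumulate_reg_grads <- function(gr, model, f, dr) {
  gr$rho_table[f$sdn, ] <- gr$rho_table[f$sdn, ] + dr
  if (length(f$kidx)) {
    dalpha_e <- numeric(length(f$kidx))
    for (t in seq_along(f$kidx)) {
      gr$E_ex[f$kidx[t], ] <- gr$E_ex[f$kidx[t], ] + f$alpha_e[t] * dr
      dalpha_e[t] <- sum(model$reg$E_ex[f$kidx[t], ] * dr)
    }
    gr$a_ex[f$kidx] <- gr$a_ex[f$kidx] +
      f$alpha_e * (dalpha_e - sum(f$alpha_e * dalpha_e))
  }
  dalpha <- numeric(model$dims$L)
  for (l in seq_len(model$dims$L)) {
    dout <- f$alpha[l] * dr
    gr[[paste0("B", l)]] <- gr[[paste0("B", l)]] + outer(dout, f$H[[l]])
    gr[[paste0("d0", l)]] <- gr[[paste0("d0", l)]] + dout
    dH <- as.numeric(crossprod(model$reg$mlps[[l]]$B, dout)) *
      (1 - f$H[[l]]^2)
    gr[[paste0("A", l)]] <- gr[[paste0("A", l)]] + outer(dH, f$fpi)
    gr[[paste0("c", l)]] <- gr[[paste0("c", l)]] + dH
    dalpha[l] <- sum(f$outs[l, ] * dr)
  }
  gr$attn <- gr$attn + f$alpha * (dalpha - sum(f$alpha * dalpha))
  gr
}

## One minibatch: forward, loss, analytic gradients for every trainable
## bundle. Returns the gradient list and the batch alignment loss.
batch_gradients <- function(model, cache, reg_fwd, ci, ri, y, gate, cfg,
                            posneg) {
  d <- model$dims$d; k <- model$dims$k
  B <- length(ci)
  gr <- zero_like(get_params(model))

  uc <- unique(ci)
  li <- match(ci, uc)
  Zu <- cache$Z[uc, , drop = FALSE]
  Psiu <- cache$Psi[uc, , drop = FALSE]
  opu <- cache$op[uc]
  ef <- encode_edits_matrix(model, Zu, Psiu, opu)
  Rho <- reg_fwd$Rho

  X <- cbind(ef$E[li, , drop = FALSE], Rho[ri, , drop = FALSE])
  TT <- tanh(sweep(X %*% t(model$compat$Wa), 2L, model$compat$ba, "+"))
  s <- sigmoid(as.numeric(TT %*% model$compat$u))
  yhat <- s * gate
  loss_align <- bce_loss(yhat, y)

  dlogit <- ifelse(gate == 1L, s - y, 0) / B
  dTT <- (dlogit %o% model$compat$u) * (1 - TT^2)
  gr$Wa <- gr$Wa + t(dTT) %*% X
  gr$ba <- gr$ba + colSums(dTT)
  gr$u <- gr$u + as.numeric(crossprod(TT, dlogit))
  dX <- dTT %*% model$compat$Wa
  dE_pairs <- dX[, seq_len(d), drop = FALSE]
  dRho_pairs <- dX[, d + seq_len(k), drop = FALSE]

  dEu <- matrix(0, length(uc), d)
  tmp <- rowsum(dE_pairs, li)
  dEu[as.integer(rownames(tmp)), ] <- tmp
  dRho <- matrix(0, nrow(Rho), k)
  tmp <- rowsum(dRho_pairs, ri)
  dRho[as.integer(rownames(tmp)), ] <- tmp

  ## contrastive projection: one sampled (positive, negative) descriptor pair
  ## per distinct edit in the batch that has both.
  if (cfg$lambda1 > 0) {
    triples <- list()
    for (t in seq_along(uc)) {
      pn <- posneg[[uc[t]]]
      if (length(pn$pos) && length(pn$neg)) {
        jp <- pn$pos[sample.int(length(pn$pos), 1L)]
        jn <- pn$neg[sample.int(length(pn$neg), 1L)]
        triples[[length(triples) + 1L]] <- c(t, jp, jn)
      }
    }
    if (length(triples)) {
      sc <- cfg$lambda1 / length(triples)
      for (tr in triples) {
        e <- ef$E[tr[1], ]; rp <- Rho[tr[2], ]; rn <- Rho[tr[3], ]
        hinge <- cfg$margin + sum((e - rp)^2) - sum((e - rn)^2)
        if (hinge > 0) {
          dEu[tr[1], ] <- dEu[tr[1], ] + sc * 2 * (rn - rp)
          dRho[tr[2], ] <- dRho[tr[2], ] - sc * 2 * (e - rp)
          dRho[tr[3], ] <- dRho[tr[3], ] + sc * 2 * (e - rn)
        }
      }
    }
  }

  ## smoothness: Monte-Carlo perturbation of the continuous encoder inputs.
  if (cfg$lambda2 > 0 && cfg$sigma2 > 0) {
    sdv <- sqrt(cfg$sigma2)
    sc <- cfg$lambda2 / (length(uc) * cfg$n_perturb)
    for (t in seq_along(uc)) {
      o <- opu[t]
      z <- Zu[t, ]
      th_base <- ef$Th[t, ]
      for (sdx in seq_len(cfg$n_perturb)) {
        eps_z <- stats::rnorm(model$dims$m, 0, sdv)
        eps_p <- stats::rnorm(model$dims$n_pe, 0, sdv)
        th_pert <- tanh(as.numeric(model$edit$W[[o]] %*% (z + eps_z)) +
                          model$edit$b[[o]])
        delta <- (th_pert - th_base) +
          as.numeric(model$edit$P_psi %*% eps_p)
        common <- 2 * delta * sc
        gp <- common * (1 - th_pert^2)
        gb <- common * (1 - th_base^2)
        wn <- paste0("W", o); bn <- paste0("b", o)
        gr[[wn]] <- gr[[wn]] + outer(gp, z + eps_z) - outer(gb, z)
        gr[[bn]] <- gr[[bn]] + gp - gb
      }
    }
  }

  ## edit encoder backprop
  dPre <- dEu * (1 - ef$Th^2)
  for (o in 1:3) {
    idx <- which(opu == o)
    if (!length(idx)) next
    wn <- paste0("W", o); bn <- paste0("b", o)
    gr[[wn]] <- gr[[wn]] + t(dPre[idx, , drop = FALSE]) %*%
      Zu[idx, , drop = FALSE]
    gr[[bn]] <- gr[[bn]] + colSums(dPre[idx, , drop = FALSE])
  }

  ## regulation encoder backprop
  for (j in seq_len(nrow(Rho))) {
    if (any(dRho[j, ] != 0)) {
      gr <- accumulate_reg_grads(gr, model, reg_fwd$rf[[j]], dRho[j, ])
    }
  }

  list(grads = gr, loss_align = loss_align)
}

adamw_step <- function(params, grads, state, lr, wd, beta1 = 0.9,
                       beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    step <- (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
    params[[nm]] <- params[[nm]] - lr * (step + wd * params[[nm]])
  }
  list(params = params, state = state)
}

## ---- public training / evaluation interface --------------------------------

#' Train the alignment network on a scenario
#'
#' Minibatch AdamW on the total loss over the scenario's labeled
#' (edit, regime) pairs, with a seeded 70/15/15 train/validation/test split,
#' early stopping on validation loss, and restoration of the
#' best-validation checkpoint. Fully deterministic given \code{cfg$seed}.
#'
#' @param scenario a \code{\link{generate_scenario}} object (or anything with
#'   the same fields).
#' @param cfg a \code{\link{loss_config}}.
#' @param d,k,h,L latent dimensions passed to \code{\link{init_align_model}}.
#' @param use_gate set FALSE to train and evaluate with the symbolic gate
#'   ablated.
#' @param model optional pre-initialised model (overrides \code{d,k,h,L}).
#' @param verbose print per-epoch progress.
#' @return An object of class \code{align_fit}: fields \code{model},
#'   \code{log} (per-epoch data.frame), \code{metrics} (held-out test
#'   metrics), \code{split}, \code{cfg}.
#' @export
train_align <- function(scenario, cfg = loss_config(), d = 32L, k = 32L,
                        h = 32L, L = 3L, use_gate = TRUE, model = NULL,
                        verbose = FALSE) {
  model <- model %||% init_align_model(d = d, k = k, h = h, L = L,
                                       seed = cfg$seed)
  thetas <- scenario_thetas(scenario)
  cache <- build_edit_cache(thetas, scenario$candidates$genome_id,
                            scenario$genomes, model)
  regimes <- scenario$regimes
  rid <- vapply(regimes, function(r) r$id, "")
  G <- build_gate_matrix(thetas, regimes)

  ci <- match(scenario$labels$edit_id, scenario$candidates$edit_id)
  ri <- match(scenario$labels$regime_id, rid)
  stopifnot(!anyNA(ci), !anyNA(ri))
  y <- as.numeric(scenario$labels$compliant)
  gate <- if (use_gate) G[cbind(ci, ri)] else rep(1L, length(ci))
  np <- length(ci)

  split <- with_seed(derive_seed(cfg$seed, 5L), {
    perm <- sample.int(np)
    n_test <- floor(cfg$test_frac * np)
    n_val <- floor(cfg$val_frac * np)
    list(test = sort(perm[seq_len(n_test)]),
         val = sort(perm[n_test + seq_len(n_val)]),
         train = sort(perm[-seq_len(n_test + n_val)]))
  })
  if (length(unique(y[split$train])) < 2L) {
    warning("training labels are single-class; training proceeds")
  }

  ## per-candidate compliant / non-compliant regime lists over training pairs
  posneg <- vector("list", cache$n)
  for (i in seq_len(cache$n)) posneg[[i]] <- list(pos = integer(),
                                                  neg = integer())
  for (t in split$train) {
    if (y[t] == 1) posneg[[ci[t]]]$pos <- c(posneg[[ci[t]]]$pos, ri[t])
    else posneg[[ci[t]]]$neg <- c(posneg[[ci[t]]]$neg, ri[t])
  }

  params <- get_params(model)
  state <- list(t = 0L, m = zero_like(params), v = zero_like(params))
  best <- list(loss = Inf, params = params, epoch = 0L)
  log <- data.frame(epoch = integer(), train_loss = numeric(),
                    val_loss = numeric(), val_accuracy = numeric())
  wait <- 0L

  eval_split <- function(model, idx) {
    ef <- encode_edits_matrix(model, cache$Z, cache$Psi, cache$op)
    Rho <- regime_forward_all(model, regimes)$Rho
    X <- cbind(ef$E[ci[idx], , drop = FALSE], Rho[ri[idx], , drop = FALSE])
    TT <- tanh(sweep(X %*% t(model$compat$Wa), 2L, model$compat$ba, "+"))
    s <- sigmoid(as.numeric(TT %*% model$compat$u))
    yhat <- s * gate[idx]
    list(loss = bce_loss(yhat, y[idx]),
         acc = mean((yhat >= 0.5) == (y[idx] == 1)))
  }

  with_seed(derive_seed(cfg$seed, 9L), {
    for (epoch in seq_len(cfg$epochs)) {
      order_idx <- split$train[sample.int(length(split$train))]
      nb <- ceiling(length(order_idx) / cfg$batch_size)
      epoch_loss <- 0
      for (b in seq_len(nb)) {
        pb <- order_idx[((b - 1L) * cfg$batch_size + 1L):
                          min(b * cfg$batch_size, length(order_idx))]
        reg_fwd <- regime_forward_all(model, regimes)
        bg <- batch_gradients(model, cache, reg_fwd, ci[pb], ri[pb], y[pb],
                              gate[pb], cfg, posneg)
        upd <- adamw_step(params, bg$grads, state, cfg$lr, cfg$weight_decay)
        params <- upd$params
        state <- upd$state
        model <- set_params(model, params)
        epoch_loss <- epoch_loss + bg$loss_align * length(pb)
      }
      ev <- eval_split(model, split$val)
      log <- rbind(log, data.frame(epoch = epoch,
                                   train_loss = epoch_loss /
                                     length(order_idx),
                                   val_loss = ev$loss,
                                   val_accuracy = ev$acc))
      if (verbose) {
        message(sprintf("epoch %3d train %.4f val %.4f acc %.3f",
                        epoch, log$train_loss[epoch], ev$loss, ev$acc))
      }
      if (ev$loss < best$loss - 1e-6) {
        best <- list(loss = ev$loss, params = params, epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= cfg$patience) break
      }
    }
  })

  model <- set_params(model, best$params)
  test_ev <- evaluate_pairs_cached(model, cache, regimes, ci, ri, y, gate,
                                   split$test)
  structure(list(model = model, log = log, metrics = test_ev$metrics,
                 split = split, cfg = cfg, use_gate = use_gate,
                 best_epoch = best$epoch),
            class = "align_fit")
}

#' @export
print.align_fit <- function(x, ...) {
  cat(sprintf("<align_fit> %d epochs (best %d); test accuracy %.3f\n",
              nrow(x$log), x$best_epoch, x$metrics$accuracy))
  invisible(x)
}

evaluate_pairs_cached <- function(model, cache, regimes, ci, ri, y, gate,
                                  idx = seq_along(ci)) {
  ef <- encode_edits_matrix(model, cache$Z, cache$Psi, cache$op)
  Rho <- regime_forward_all(model, regimes)$Rho
  X <- cbind(ef$E[ci[idx], , drop = FALSE], Rho[ri[idx], , drop = FALSE])
  TT <- tanh(sweep(X %*% t(model$compat$Wa), 2L, model$compat$ba, "+"))
  yhat <- sigmoid(as.numeric(TT %*% model$compat$u)) * gate[idx]
  list(yhat = yhat, metrics = metrics_binary(y[idx], yhat))
}

#' Binary classification metrics
#'
#' Accuracy, positive-class recall, micro- and positive-class F1, and AUC
#' (via pROC) on a binary task at threshold 0.5. Micro-averaged F1 over both
#' classes of a single-label binary task coincides with accuracy and is
#' reported under \code{f1_micro}; \code{f1} is the compliant-class F1.
#'
#' @param y 0/1 labels.
#' @param yhat predicted probabilities.
#' @return list with \code{accuracy}, \code{recall}, \code{f1},
#'   \code{f1_micro}, \code{auc}.
#' @export
metrics_binary <- function(y, yhat) {
  pred <- as.numeric(yhat >= 0.5)
  tp <- sum(pred == 1 & y == 1)
  fp <- sum(pred == 1 & y == 0)
  fn <- sum(pred == 0 & y == 1)
  acc <- mean(pred == y)
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  f1 <- if (!is.na(prec) && !is.na(recall) && prec + recall > 0) {
    2 * prec * recall / (prec + recall)
  } else NA_real_
  auc <- if (length(unique(y)) == 2L) {
    as.numeric(pROC::auc(pROC::roc(y, yhat, quiet = TRUE,
                                   direction = "<", levels = c(0, 1))))
  } else NA_real_
  list(accuracy = acc, recall = recall, f1 = f1, f1_micro = acc, auc = auc)
}

#' Predict compliance for every labeled pair of a scenario
#'
#' @param model a fitted alignment model.
#' @param scenario a scenario.
#' @param use_gate set FALSE to ablate the symbolic gate.
#' @return data.frame with \code{edit_id}, \code{regime_id}, \code{label},
#'   \code{yhat}, \code{gate}.
#' @export
predict_scenario <- function(model, scenario, use_gate = TRUE) {
  thetas <- scenario_thetas(scenario)
  cache <- build_edit_cache(thetas, scenario$candidates$genome_id,
                            scenario$genomes, model)
  regimes <- scenario$regimes
  rid <- vapply(regimes, function(r) r$id, "")
  G <- build_gate_matrix(thetas, regimes)
  ci <- match(scenario$labels$edit_id, scenario$candidates$edit_id)
  ri <- match(scenario$labels$regime_id, rid)
  gate <- if (use_gate) G[cbind(ci, ri)] else rep(1L, length(ci))
  ev <- evaluate_pairs_cached(model, cache, regimes, ci, ri,
                              as.numeric(scenario$labels$compliant), gate)
  data.frame(edit_id = scenario$labels$edit_id,
             regime_id = scenario$labels$regime_id,
             label = as.numeric(scenario$labels$compliant),
             yhat = ev$yhat, gate = gate)
}
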