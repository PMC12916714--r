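## Loss surface of the alignment network: binary cross-entropy on the gated
## prediction, a contrastive projection term pulling edit embeddings toward
## compliant regulation embeddings, and a Monte-Carlo smoothness penalty.

#' Loss and training configuration
#'
#' Training defaults follow a standard desk-scale protocol: AdamW with weight
#' decay 0.01, 70/15/15 train/validation/test split, at most 100 epochs with
#' early stopping after 10 epochs without validation improvement.
#'
#' @param margin contrastive margin tau, > 0.
#' @param lambda1 weight of the contrastive projection term, >= 0.
#' @param lambda2 weight of the smoothness term, >= 0.
#' @param sigma2 perturbation variance of the smoothness term, >= 0.
#' @param n_perturb Monte-Carlo samples per edit for the smoothness term.
#' @param batch_size minibatch size.
#' @param epochs maximum training epochs.
#' @param patience early-stopping patience (epochs without validation
#'   improvement).
#' @param lr AdamW learning rate.
#' @param weight_decay AdamW decoupled weight decay.
#' @param val_frac,test_frac split fractions (train gets the remainder).
#' @param seed integer seed controlling splits, shuffling, and perturbations.
#' @return An object of class \code{loss_config}.
#' @export
loss_config <- function(margin = 1, lambda1 = 0.1, lambda2 = 0.01,
                        sigma2 = 0.01, n_perturb = 2L, batch_size = 32L,
                        epochs = 100L, patience = 10L, lr = 1e-2,
                        weight_decay = 0.01, val_frac = 0.15,
                        test_frac = 0.15, seed = 1L) {
  stopifnot(margin > 0, lambda1 >= 0, lambda2 >= 0, sigma2 >= 0,
            n_perturb >= 1, batch_size >= 1, epochs >= 1, lr > 0,
            val_frac >= 0, test_frac >= 0, val_frac + test_frac < 1)
  structure(list(margin = margin, lambda1 = lambda1, lambda2 = lambda2,
                 sigma2 = sigma2, n_perturb = as.integer(n_perturb),
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), patience = as.integer(patience),
                 lr = lr, weight_decay = weight_decay, val_frac = val_frac,
                 test_frac = test_frac, seed = seed),
            class = "loss_config")
}

bce_loss <- function(yhat, y) {
  p <- clip_prob(yhat)
  mean(-(y * log(p) + (1 - y) * log(1 - p)))
}

#' Contrastive projection loss
#'
#' Sum over triples of \code{max(0, margin + ||F_e - F_r+||^2 -
#' ||F_e - F_r-||^2)}: zero once every compliant descriptor is closer than
#' every non-compliant one by the margin. The empty batch gives 0.
#'
#' @param triples list of lists with fields \code{theta}, \code{g},
#'   \code{r_pos} (a compliant descriptor), \code{r_neg} (a non-compliant
#'   one).
#' @param model an alignment model.
#' @param margin margin tau > 0.
#' @return non-negative scalar.
#' @export
contrastive_loss <- function(triples, model, margin = 1) {
  if (!length(triples)) return(0)
  total <- 0
  for (tr in triples) {
    e <- encode_edit(tr$theta, tr$g, model)
    dp <- sum((e - encode_regulation(tr$r_pos, model))^2)
    dn <- sum((e - encode_regulation(tr$r_neg, model))^2)
    total <- total + max(0, margin + dp - dn)
  }
  total
}

## Perturb the continuous encoder inputs (donor conv features and the
## sinusoidal positional vector) of one edit and return the squared embedding
## displacement. Shared by the loss and its gradient.
smooth_displacement <- function(z, pe, oi, model, eps_z, eps_p) {
  W <- model$edit$W[[oi]]; b <- model$edit$b[[oi]]
  base <- tanh(as.numeric(W %*% z) + b)
  pert <- tanh(as.numeric(W %*% (z + eps_z)) + b)
  delta <- (pert - base) + as.numeric(model$edit$P_psi %*% eps_p)
  sum(delta^2)
}

#' Smoothness loss
#'
#' Monte-Carlo estimate of the expected squared displacement of the edit
#' embedding under Gaussian perturbation of the continuous encoder inputs
#' (the donor encoder output and the positional encoding). Exactly 0 when
#' \code{sigma2 = 0}; seeded and reproducible.
#'
#' @param thetas list of \code{\link{edit_spec}} objects.
#' @param gs list of matching \code{\link{genome}} objects (recycled if
#'   length 1).
#' @param model an alignment model.
#' @param sigma2 perturbation variance, >= 0.
#' @param n_samples Monte-Carlo samples per edit.
#' @param seed integer seed.
#' @return non-negative scalar.
#' @export
smoothness_loss <- function(thetas, gs, model, sigma2 = 0.01,
                            n_samples = 10L, seed = 1L) {
  stopifnot(sigma2 >= 0)
  if (sigma2 == 0 || !length(thetas)) return(0)
  if (length(gs) == 1L) gs <- rep(gs, length(thetas))
  sdv <- sqrt(sigma2)
  m <- model$dims$m; n_pe <- model$dims$n_pe
  with_seed(derive_seed(seed, 71L), {
    acc <- 0
    for (i in seq_along(thetas)) {
      z <- donor_conv_features(thetas[[i]]$donor, model)
      pe <- pos_encoding(thetas[[i]]$locus / nchar(gs[[i]]$sequence))
      oi <- op_index(thetas[[i]]$op_type)
      for (s in seq_len(n_samples)) {
        acc <- acc + smooth_displacement(
          z, pe, oi, model,
          stats::rnorm(m, 0, sdv), stats::rnorm(n_pe, 0, sdv))
      }
    }
    acc / (length(thetas) * n_samples)
  })
}

## Deterministic triple construction from a labeled batch: for every distinct
## edit with at least one compliant and one non-compliant regime in the batch,
## all (positive, negative) descriptor combinations.
batch_triples <- function(batch) {
  keys <- vapply(batch, function(b)
    paste(b$g$id, b$theta$locus, b$theta$donor, b$theta$op_type), "")
  triples <- list()
  for (key in unique(keys)) {
    idx <- which(keys == key)
    pos <- idx[vapply(batch[idx], function(b) b$label == 1, TRUE)]
    neg <- setdiff(idx, pos)
    for (i in pos) for (j in neg) {
      triples[[length(triples) + 1L]] <- list(
        theta = batch[[i]]$theta, g = batch[[i]]$g,
        r_pos = batch[[i]]$r, r_neg = batch[[j]]$r)
    }
  }
  triples
}

#' Total training loss
#'
#' \code{L_align + lambda1 * L_proj + lambda2 * L_smooth} where
#' \code{L_align} is the mean binary cross-entropy between the gated
#' prediction and the compliance label. With \code{lambda1 = lambda2 = 0}
#' this reduces exactly to the cross-entropy term.
#'
#' @param batch list of lists with fields \code{theta}, \code{g}, \code{r},
#'   \code{label} (0 or 1).
#' @param model an alignment model.
#' @param cfg a \code{\link{loss_config}}.
#' @param use_gate set FALSE to ablate the symbolic gate.
#' @return list with \code{total}, \code{align}, \code{proj}, \code{smooth}.
#' @export
total_loss <- function(batch, model, cfg = loss_config(), use_gate = TRUE) {
  labels <- vapply(batch, function(b) b$label, 0)
  if (!all(labels %in% c(0, 1))) {
    stop_regalign("invalid_label", "labels must be 0 or 1")
  }
  yhat <- vapply(batch, function(b)
    predict_alignment(b$theta, b$r, b$g, model, use_gate), 0)
  align <- bce_loss(yhat, labels)
  proj <- if (cfg$lambda1 > 0) {
    contrastive_loss(batch_triples(batch), model, cfg$margin)
  } else 0
  smooth <- if (cfg$lambda2 > 0) {
    smoothness_loss(lapply(batch, `[[`, "theta"), lapply(batch, `[[`, "g"),
                    model, cfg$sigma2, cfg$n_perturb, cfg$seed)
  } else 0
  list(total = align + cfg$lambda1 * proj + cfg$lambda2 * smooth,
       align = align, proj = proj, smooth = smooth)
}
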