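## The regulation-aware alignment network: an edit encoder and a regulation
## encoder projecting into a shared latent space, a compatibility head giving
## an alignment likelihood, and a symbolic gate that zeroes predictions for
## edits conflicting with hard exclusions.

#' Initialise an alignment model
#'
#' Builds all parameter bundles. The donor sequence encoder is a bank of 1-D
#' convolutions over the one-hot donor (kernel sizes 5/7/11, 16 filters each,
#' global max-pool) plus two summary scalars (length/10, GC fraction); the
#' filter bank and the sinusoidal positional projection are drawn once from
#' the seed and held fixed, while the op-type layers, regulation encoder and
#' compatibility head are trainable.
#'
#' @param d edit embedding dimension.
#' @param k regulation embedding dimension.
#' @param h compatibility head hidden width.
#' @param L number of predicate approximators.
#' @param q hidden width of each predicate approximator.
#' @param n_filters convolution filters per kernel size.
#' @param kernel_sizes convolution kernel sizes.
#' @param conv_scale down-weighting of the convolutional donor features
#'   relative to the donor summary scalars.
#' @param seed integer seed for parameter initialisation.
#' @return An object of class \code{align_model}.
#' @export
init_align_model <- function(d = 32L, k = 32L, h = 32L, L = 3L, q = 16L,
                             n_filters = 16L, kernel_sizes = c(5L, 7L, 11L),
                             conv_scale = 0.1, seed = 1L) {
  p <- length(predicate_features(predicate_rule()))
  m <- length(kernel_sizes) * n_filters + 2L
  n_pe <- 13L
  with_seed(derive_seed(seed, 11L), {
    rmat <- function(nr, nc, sd) matrix(stats::rnorm(nr * nc, 0, sd), nr, nc)
    model <- list(
      dims = list(d = d, k = k, h = h, L = L, q = q, m = m, p = p,
                  n_pe = n_pe, n_filters = n_filters,
                  kernel_sizes = kernel_sizes, conv_scale = conv_scale),
      seed = seed,
      edit = list(
        filters = lapply(kernel_sizes, function(ks)
          array(stats::rnorm(4 * ks * n_filters, 0, 1 / sqrt(4 * ks)),
                dim = c(4L, ks, n_filters))),
        W = lapply(1:3, function(i) rmat(d, m, 1 / sqrt(m))),
        b = lapply(1:3, function(i) rep(0, d)),
        P_psi = rmat(d, n_pe, 0.3 / sqrt(n_pe))
      ),
      reg = list(
        rho_table = rmat(3L, k, 0.1),
        E_ex = rmat(3L, k, 0.1),
        a_ex = rep(0, 3L),
        attn = rep(0, L),
        mlps = lapply(seq_len(L), function(l) list(
          A = rmat(q, p, 1 / sqrt(p)), c = rep(0, q),
          B = rmat(k, q, 1 / sqrt(q)), d0 = rep(0, k)))
      ),
      compat = list(
        Wa = rmat(h, d + k, 1 / sqrt(d + k)),
        ba = rep(0, h),
        u = rmat(h, 1L, 1 / sqrt(h))[, 1]
      )
    )
    class(model) <- "align_model"
    model
  })
}

#' @export
print.align_model <- function(x, ...) {
  cat(sprintf("<align_model> d=%d k=%d h=%d L=%d (seed %s)\n",
              x$dims$d, x$dims$k, x$dims$h, x$dims$L, format(x$seed)))
  invisible(x)
}

onehot_dna <- function(s) {
  idx <- match(strsplit(s, "", fixed = TRUE)[[1]], c("A", "C", "G", "T"))
  X <- matrix(0, 4L, length(idx))
  X[cbind(idx, seq_along(idx))] <- 1
  X
}

## Donor sequence encoder phi_delta: conv filter banks over the one-hot donor
## with global max-pooling, plus scaled length and GC fraction. The conv block
## is down-weighted (conv_scale) relative to the interpretable summary
## scalars so the high-dimensional random filter responses cannot drown out
## the length/composition signal. Output length m.
donor_conv_features <- function(donor, model) {
  X <- onehot_dna(donor)
  out <- numeric(0)
  for (fi in seq_along(model$dims$kernel_sizes)) {
    ks <- model$dims$kernel_sizes[fi]
    filt <- model$edit$filters[[fi]]
    Xp <- if (ncol(X) < ks) cbind(X, matrix(0, 4L, ks - ncol(X))) else X
    npos <- ncol(Xp) - ks + 1L
    acts <- matrix(0, npos, model$dims$n_filters)
    for (pos in seq_len(npos)) {
      win <- Xp[, pos:(pos + ks - 1L), drop = FALSE]
      acts[pos, ] <- vapply(seq_len(model$dims$n_filters),
                            function(f) sum(win * filt[, , f]), 0)
    }
    out <- c(out, apply(acts, 2L, max))
  }
  c(out * model$dims$conv_scale, nchar(donor) / 10, gc_fraction(donor))
}

## Sinusoidal encoding of the relative locus x = l / |g|, projected to d by
## the fixed matrix P_psi. The raw scalar is kept as the first component so
## positional thresholds stay linearly recoverable.
pos_encoding <- function(x) {
  freqs <- 2^(0:5)
  c(x, sin(pi * x * freqs), cos(pi * x * freqs))
}

## Core structured composition of the edit encoder: tanh(W z + b) + psi.
encode_edit_core <- function(z, psi, W, b) {
  as.numeric(tanh(W %*% z + b)) + psi
}

op_index <- function(op_type) match(op_type, OP_TYPES)

#' Encode an edit into the latent space
#'
#' Structured composition \code{tanh(W_op phi_delta(donor) + b_op) + psi(l)}
#' with op-type specific weights, a convolutional donor encoder and a fixed
#' sinusoidal positional term. Deterministic given the parameters.
#'
#' @param theta an \code{\link{edit_spec}}.
#' @param g the target \code{\link{genome}}.
#' @param model an \code{\link{init_align_model}} object.
#' @return numeric vector of length \code{d}.
#' @export
encode_edit <- function(theta, g, model) {
  check_edit_bounds(g, theta)
  z <- donor_conv_features(theta$donor, model)
  oi <- op_index(theta$op_type)
  if (ncol(model$edit$W[[oi]]) != length(z)) {
    stop_regalign("dimension_mismatch",
                  "edit encoder expects input length %d, got %d",
                  ncol(model$edit$W[[oi]]), length(z))
  }
  psi <- as.numeric(model$edit$P_psi %*%
                      pos_encoding(theta$locus / nchar(g$sequence)))
  encode_edit_core(z, psi, model$edit$W[[oi]], model$edit$b[[oi]])
}

## Regulation encoder with intermediates retained for backpropagation.
encode_regulation_full <- function(r, model) {
  k <- model$dims$k
  fpi <- predicate_features(r$predicate)
  alpha <- softmax(model$reg$attn)
  H <- vector("list", model$dims$L)
  outs <- matrix(0, model$dims$L, k)
  for (l in seq_len(model$dims$L)) {
    mlp <- model$reg$mlps[[l]]
    H[[l]] <- tanh(as.numeric(mlp$A %*% fpi + mlp$c))
    outs[l, ] <- as.numeric(mlp$B %*% H[[l]] + mlp$d0)
  }
  nu <- as.numeric(crossprod(outs, alpha))
  kinds <- unique(vapply(r$exemptions, function(e) e$kind, ""))
  kidx <- match(kinds, EXEMPTION_KINDS)
  if (length(kidx)) {
    alpha_e <- softmax(model$reg$a_ex[kidx])
    eta <- as.numeric(crossprod(model$reg$E_ex[kidx, , drop = FALSE], alpha_e))
  } else {
    alpha_e <- numeric(0)
    eta <- rep(0, k)  # masked attention over nothing
  }
  sdn <- match(r$sdn_class, SDN_CLASSES)
  list(rho = model$reg$rho_table[sdn, ] + eta + nu,
       fpi = fpi, alpha = alpha, H = H, outs = outs, kidx = kidx,
       alpha_e = alpha_e, sdn = sdn)
}

#' Encode a regulatory descriptor into the latent space
#'
#' Sum of the SDN class embedding, an exemption-aware masked-attention vector
#' (zero for an empty exemption context), and an attention-weighted mixture of
#' small feed-forward predicate approximators applied to the serialized
#' predicate features.
#'
#' @param r a \code{\link{regulatory_descriptor}}.
#' @param model an \code{\link{init_align_model}} object.
#' @return numeric vector of length \code{k}.
#' @export
encode_regulation <- function(r, model) {
  encode_regulation_full(r, model)$rho
}

#' Attention weights of the regulation encoder
#'
#' @inheritParams encode_regulation
#' @return list with \code{predicate} (length L, sums to 1) and
#'   \code{exemption} (one weight per exemption kind present).
#' @export
regulation_attention_weights <- function(r, model) {
  f <- encode_regulation_full(r, model)
  list(predicate = f$alpha, exemption = f$alpha_e)
}

#' Compatibility score between latent edit and regulation vectors
#'
#' \code{sigmoid(u' tanh(Wa [e || rho] + ba))}, strictly inside (0, 1).
#'
#' @param e edit embedding, length d.
#' @param rho_r regulation embedding, length k.
#' @param params the model's \code{compat} bundle (Wa, ba, u).
#' @return probability in (0, 1).
#' @export
alignment_score <- function(e, rho_r, params) {
  x <- c(e, rho_r)
  if (length(x) != ncol(params$Wa)) {
    stop_regalign("dimension_mismatch",
                  "compatibility head expects input length %d, got %d",
                  ncol(params$Wa), length(x))
  }
  t_h <- tanh(as.numeric(params$Wa %*% x) + params$ba)
  sigmoid(sum(params$u * t_h))
}

#' Symbolic exclusion gate
#'
#' Returns 0 iff any \code{hard_exclusion} rule in the exemption context is
#' triggered by the edit (banned operation type, donor length above the cap,
#' or banned donor origin); 1 otherwise. Non-exclusion exemption kinds are
#' never consulted.
#'
#' @param theta an \code{\link{edit_spec}}.
#' @param exemptions list of \code{\link{exemption_rule}} objects.
#' @return integer 0 or 1.
#' @export
symbolic_gate <- function(theta, exemptions) {
  for (e in exemptions) {
    if (e$kind != "hard_exclusion") next
    p <- e$params
    if (!is.null(p$banned_ops) && theta$op_type %in% p$banned_ops) return(0L)
    if (!is.null(p$max_donor_length) &&
        nchar(theta$donor) > p$max_donor_length) return(0L)
    if (!is.null(p$banned_origins) && !is.null(theta$donor_origin) &&
        theta$donor_origin %in% p$banned_origins) return(0L)
  }
  1L
}

#' Gated compliance prediction
#'
#' Final prediction \code{gate * alignment_score}: exactly zero whenever the
#' symbolic gate blocks the edit, the compatibility score otherwise.
#'
#' @inheritParams encode_edit
#' @param r a \code{\link{regulatory_descriptor}}.
#' @param use_gate set FALSE to ablate the symbolic gate.
#' @return probability in [0, 1].
#' @export
predict_alignment <- function(theta, r, g, model, use_gate = TRUE) {
  gate <- if (use_gate) symbolic_gate(theta, r$exemptions) else 1L
  if (gate == 0L) return(0)
  alignment_score(encode_edit(theta, g, model), encode_regulation(r, model),
                  model$compat)
}

#' Probabilistic compliance score
#'
#' When the jurisdiction's predicate is determinate the score is exactly 1 or
#' 0; for Indeterminate predicates the model's compatibility score is
#' returned as the soft compliance probability.
#'
#' @inheritParams predict_alignment
#' @return probability in [0, 1].
#' @export
uncertainty_score <- function(g, theta, r, model) {
  v <- evaluate_predicate(r$predicate, apply_edit(g, theta), theta, g)
  if (!is.na(v)) return(as.numeric(v))
  alignment_score(encode_edit(theta, g, model), encode_regulation(r, model),
                  model$compat)
}

#' Rank candidate edits by weighted alignment
#'
#' \code{Score(theta) = sum_r w_r * yhat_{theta,r}}, sorted descending with
#' ties broken by candidate input order (stable sort).
#'
#' @param candidates list of \code{\link{edit_spec}} objects.
#' @param g the target genome.
#' @param regimes list of regulatory descriptors.
#' @param weights numeric policy-prior weights named by regime id (or in
#'   regime order).
#' @param model fitted alignment model.
#' @param use_gate set FALSE to ablate the symbolic gate.
#' @return data.frame with columns \code{candidate} (input index) and
#'   \code{score}, in rank order.
#' @export
rank_edits <- function(candidates, g, regimes, weights, model,
                       use_gate = TRUE) {
  w <- resolve_weights(weights, regimes)
  scores <- vapply(candidates, function(th)
    sum(w * vapply(regimes, function(r)
      predict_alignment(th, r, g, model, use_gate), 0)), 0)
  ord <- order(-scores, seq_along(scores))
  data.frame(candidate = ord, score = scores[ord])
}

resolve_weights <- function(weights, regimes) {
  ids <- vapply(regimes, function(r) r$id, "")
  if (!is.null(names(weights)) && all(nzchar(names(weights)))) {
    if (!all(ids %in% names(weights))) {
      stop_regalign("missing_weight", "no policy weight for regime(s): %s",
                    paste(setdiff(ids, names(weights)), collapse = ", "))
    }
    return(as.numeric(weights[ids]))
  }
  if (length(weights) != length(regimes)) {
    stop_regalign("missing_weight",
                  "got %d unnamed weights for %d regimes",
                  length(weights), length(regimes))
  }
  as.numeric(weights)
}

#' Embed (edit, regime) pairs onto the latent compliance manifold
#'
#' One latent point per pair: the edit embedding, the regulation embedding,
#' and the gated prediction, concatenated to a row of length d + k + 1.
#'
#' @param pairs list of lists with fields \code{theta}, \code{r}, \code{g}.
#' @param model fitted alignment model.
#' @param use_gate set FALSE to ablate the symbolic gate.
#' @return data.frame with columns \code{e1..ed}, \code{r1..rk}, \code{yhat}.
#' @export
embed_manifold <- function(pairs, model, use_gate = TRUE) {
  d <- model$dims$d; k <- model$dims$k
  out <- matrix(0, length(pairs), d + k + 1L)
  for (i in seq_along(pairs)) {
    pr <- pairs[[i]]
    e <- encode_edit(pr$theta, pr$g, model)
    rho <- encode_regulation(pr$r, model)
    gate <- if (use_gate) symbolic_gate(pr$theta, pr$r$exemptions) else 1L
    yhat <- if (gate == 0L) 0 else alignment_score(e, rho, model$compat)
    out[i, ] <- c(e, rho, yhat)
  }
  df <- as.data.frame(out)
  names(df) <- c(paste0("e", seq_len(d)), paste0("r", seq_len(k)), "yhat")
  df
}

## ---- checkpoint serialization ---------------------------------------------

serialize_param <- function(x) {
  if (is.matrix(x)) list(dim = dim(x), data = as.numeric(x))
  else if (is.array(x)) list(dim = dim(x), data = as.numeric(x))
  else x
}

deserialize_param <- function(x) {
  if (is.list(x) && !is.null(x$dim)) {
    array(as.numeric(unlist(x$data)), dim = as.integer(unlist(x$dim)))
  } else if (is.list(x)) {
    as.numeric(unlist(x))
  } else x
}

#' Write a model checkpoint
#'
#' Self-describing JSON container with dimensions, seed, package version and
#' all parameter bundles at full double precision.
#'
#' @param model an \code{align_model}.
#' @param path output file.
#' @export
write_model_json <- function(model, path) {
  payload <- list(
    format = "regalign_checkpoint",
    version = as.character(utils::packageVersion("regalign")),
    dims = model$dims, seed = model$seed,
    edit = list(filters = lapply(model$edit$filters, serialize_param),
                W = lapply(model$edit$W, serialize_param),
                b = model$edit$b,
                P_psi = serialize_param(model$edit$P_psi)),
    reg = list(rho_table = serialize_param(model$reg$rho_table),
               E_ex = serialize_param(model$reg$E_ex),
               a_ex = model$reg$a_ex, attn = model$reg$attn,
               mlps = lapply(model$reg$mlps, function(m)
                 list(A = serialize_param(m$A), c = m$c,
                      B = serialize_param(m$B), d0 = m$d0))),
    compat = list(Wa = serialize_param(model$compat$Wa),
                  ba = model$compat$ba, u = model$compat$u)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a model checkpoint
#'
#' @param path checkpoint written by \code{\link{write_model_json}}.
#' @return an \code{align_model}.
#' @export
read_model_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(x$format, "regalign_checkpoint")) {
    stop_regalign("malformed_file", "%s is not a regalign checkpoint", path)
  }
  int_dims <- c("d", "k", "h", "L", "q", "m", "p", "n_pe", "n_filters",
                "kernel_sizes")
  dims <- lapply(stats::setNames(names(x$dims), names(x$dims)), function(nm) {
    v <- unlist(x$dims[[nm]])
    if (nm %in% int_dims) as.integer(v) else v
  })
  model <- list(
    dims = dims, seed = x$seed,
    edit = list(filters = lapply(x$edit$filters, deserialize_param),
                W = lapply(x$edit$W, function(w) as.matrix(deserialize_param(w))),
                b = lapply(x$edit$b, function(b) as.numeric(unlist(b))),
                P_psi = as.matrix(deserialize_param(x$edit$P_psi))),
    reg = list(rho_table = as.matrix(deserialize_param(x$reg$rho_table)),
               E_ex = as.matrix(deserialize_param(x$reg$E_ex)),
               a_ex = as.numeric(unlist(x$reg$a_ex)),
               attn = as.numeric(unlist(x$reg$attn)),
               mlps = lapply(x$reg$mlps, function(m)
                 list(A = as.matrix(deserialize_param(m$A)),
                      c = as.numeric(unlist(m$c)),
                      B = as.matrix(deserialize_param(m$B)),
                      d0 = as.numeric(unlist(m$d0))))),
    compat = list(Wa = as.matrix(deserialize_param(x$compat$Wa)),
                  ba = as.numeric(unlist(x$compat$ba)),
                  u = as.numeric(unlist(x$compat$u)))
  )
  class(model) <- "align_model"
  model
}
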