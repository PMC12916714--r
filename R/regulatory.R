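## Jurisdictional descriptors and the conjunctive rule DSL: compliance
## predicates, exemption contexts, static regulation embeddings, and the
## jurisdiction drift graph.

SDN_CLASSES <- c("SDN-1", "SDN-2", "SDN-3")
EXEMPTION_KINDS <- c("natural_variant", "mutagenesis_analog", "hard_exclusion")
PREDICATE_CMPS <- c("le", "ge", "eq", "in")

## Features a predicate atom may reference: the numeric edit features plus the
## two categorical ones. Unknown names never crash evaluation -- they make the
## predicate Indeterminate by contract.
predicate_feature_names <- function() {
  c(edit_feature_names(), "op_type", "donor_origin")
}

#' Construct a predicate atom
#'
#' One atomic condition of a compliance predicate: a named edit feature, a
#' comparator, and a threshold (or allowed set for \code{"in"}).
#'
#' @param feature feature name (see \code{\link{edit_feature_names}}, plus
#'   \code{"op_type"} and \code{"donor_origin"}). Unknown names are legal and
#'   evaluate to Indeterminate.
#' @param cmp one of \code{"le"}, \code{"ge"}, \code{"eq"}, \code{"in"}.
#' @param value numeric threshold, or a vector of allowed values for
#'   \code{"in"}.
#' @export
predicate_atom <- function(feature, cmp, value) {
  cmp <- match.arg(cmp, PREDICATE_CMPS)
  stopifnot(is.character(feature), length(feature) == 1L)
  structure(list(feature = feature, cmp = cmp, value = value),
            class = "predicate_atom")
}

#' Construct a compliance predicate
#'
#' A conjunction of atoms. The empty conjunction is vacuously true.
#'
#' @param atoms list of \code{\link{predicate_atom}} objects.
#' @export
predicate_rule <- function(atoms = list()) {
  stopifnot(all(vapply(atoms, inherits, TRUE, "predicate_atom")))
  structure(list(atoms = atoms), class = "predicate_rule")
}

#' Construct an exemption rule
#'
#' \code{natural_variant} and \code{mutagenesis_analog} rules describe
#' exemption context consumed by the regulation encoder;
#' \code{hard_exclusion} rules are the only ones consulted by the symbolic
#' gate's conflict check. Recognised params for hard exclusions:
#' \code{banned_ops} (character), \code{max_donor_length} (numeric),
#' \code{banned_origins} (character).
#'
#' @param kind one of \code{"natural_variant"}, \code{"mutagenesis_analog"},
#'   \code{"hard_exclusion"}.
#' @param params named list of thresholds.
#' @export
exemption_rule <- function(kind, params = list()) {
  kind <- match.arg(kind, EXEMPTION_KINDS)
  structure(list(kind = kind, params = params), class = "exemption_rule")
}

#' Construct a regulatory descriptor
#'
#' One jurisdiction's rule set: a compliance predicate, an SDN intervention
#' class, an exemption context, and a static embedding of length \code{k}
#' shared across all regimes (built by \code{\link{static_regime_embedding}}
#' when not supplied).
#'
#' @param id descriptor id.
#' @param jurisdiction jurisdiction label.
#' @param sdn_class one of \code{"SDN-1"}, \code{"SDN-2"}, \code{"SDN-3"}.
#' @param predicate a \code{\link{predicate_rule}}.
#' @param exemptions list of \code{\link{exemption_rule}} objects.
#' @param static_embedding numeric vector of length \code{k}, or NULL to
#'   derive it from the rules.
#' @param k embedding length.
#' @export
regulatory_descriptor <- function(id, jurisdiction, sdn_class,
                                  predicate = predicate_rule(),
                                  exemptions = list(),
                                  static_embedding = NULL, k = 32L) {
  sdn_class <- match.arg(sdn_class, SDN_CLASSES)
  stopifnot(inherits(predicate, "predicate_rule"),
            all(vapply(exemptions, inherits, TRUE, "exemption_rule")))
  r <- structure(list(id = id, jurisdiction = jurisdiction,
                      sdn_class = sdn_class, predicate = predicate,
                      exemptions = exemptions, static_embedding = NULL),
                 class = "regulatory_descriptor")
  r$static_embedding <- static_embedding %||% static_regime_embedding(r, k)
  stopifnot(is.numeric(r$static_embedding))
  r
}

#' @export
print.regulatory_descriptor <- function(x, ...) {
  cat(sprintf("<regulatory_descriptor> %s (%s, %s): %d atom(s), %d exemption(s)\n",
              x$id, x$jurisdiction, x$sdn_class,
              length(x$predicate$atoms), length(x$exemptions)))
  invisible(x)
}

eval_atom <- function(atom, feats, op_type, donor_origin) {
  f <- atom$feature
  if (f == "op_type") {
    x <- op_type
  } else if (f == "donor_origin") {
    if (is.null(donor_origin)) return(NA)
    x <- donor_origin
  } else if (f %in% names(feats)) {
    x <- feats[[f]]
  } else {
    return(NA)  # unknown feature: Indeterminate, never a crash
  }
  switch(atom$cmp,
    le = is.numeric(x) && x <= atom$value,
    ge = is.numeric(x) && x >= atom$value,
    eq = isTRUE(all.equal(x, atom$value)) || identical(x, atom$value),
    `in` = x %in% atom$value)
}

#' Evaluate a compliance predicate
#'
#' Three-valued conjunction over the atoms: \code{TRUE}, \code{FALSE}, or
#' \code{NA} (Indeterminate). Any Indeterminate atom makes the conjunction
#' Indeterminate unless another atom is already \code{FALSE}. The empty atom
#' list returns \code{TRUE}.
#'
#' @param predicate a \code{\link{predicate_rule}}.
#' @param g_prime edited genome (unused by the feature-based DSL but part of
#'   the evaluation contract; features are recomputed from \code{g, theta}).
#' @param theta the \code{\link{edit_spec}}.
#' @param g the original \code{\link{genome}}.
#' @return logical scalar, possibly \code{NA}.
#' @export
evaluate_predicate <- function(predicate, g_prime, theta, g) {
  if (length(predicate$atoms) == 0L) return(TRUE)
  feats <- featurize_edit(g, theta)
  vals <- vapply(predicate$atoms, eval_atom, NA,
                 feats = as.list(feats), op_type = theta$op_type,
                 donor_origin = theta$donor_origin)
  if (any(vals %in% FALSE)) return(FALSE)
  if (anyNA(vals)) return(NA)
  TRUE
}

#' Compliance mapping
#'
#' Applies the edit and evaluates the jurisdiction's predicate on the result:
#' identical by construction to composing \code{\link{apply_edit}} with
#' \code{\link{evaluate_predicate}}. An Indeterminate predicate is escalated
#' to the model's soft compliance probability thresholded at 0.5 when a
#' fitted model is supplied, and is \code{NA} otherwise.
#'
#' @inheritParams evaluate_predicate
#' @param r a \code{\link{regulatory_descriptor}}.
#' @param model optional fitted alignment model used to resolve Indeterminate
#'   predicates.
#' @return logical scalar.
#' @export
compliance_map <- function(g, theta, r, model = NULL) {
  gp <- apply_edit(g, theta)
  v <- evaluate_predicate(r$predicate, gp, theta, g)
  if (is.na(v)) {
    if (is.null(model)) return(NA)
    return(alignment_score(encode_edit(theta, g, model),
                           encode_regulation(r, model), model$compat) >= 0.5)
  }
  v
}

#' Regulatory alignment space
#'
#' The set of (task, regime) pairs whose compliance mapping is TRUE: a subset
#' of the Cartesian product of tasks and regimes.
#'
#' @param tasks list of \code{\link{edit_task}} objects.
#' @param regimes list of \code{\link{regulatory_descriptor}} objects.
#' @param genomes named list of \code{\link{genome}} objects resolving the
#'   tasks' genome references.
#' @param model optional model for Indeterminate resolution.
#' @return data.frame with columns \code{task}, \code{regime},
#'   \code{compliant}, restricted to compliant pairs.
#' @export
alignment_space <- function(tasks, regimes, genomes, model = NULL) {
  rows <- list()
  for (i in seq_along(tasks)) {
    tk <- tasks[[i]]
    g <- genomes[[tk$genome_ref]]
    if (is.null(g)) {
      stop_regalign("unknown_genome", "task %d references unknown genome %s",
                    i, tk$genome_ref)
    }
    for (j in seq_along(regimes)) {
      ok <- compliance_map(g, tk$edit, regimes[[j]], model)
      if (isTRUE(ok)) {
        rows[[length(rows) + 1L]] <- data.frame(
          task = i, regime = regimes[[j]]$id, compliant = TRUE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(task = integer(), regime = character(),
                      compliant = logical()))
  }
  do.call(rbind, rows)
}

#' Feasibility constraints over edit features
#'
#' Closed per-feature intervals (edit sparsity, off-target style bounds)
#' checked by \code{\link{consistency_score}}.
#'
#' @param bounds named list mapping feature names to \code{c(lower, upper)}.
#' @export
feasibility_constraints <- function(bounds = list()) {
  for (nm in names(bounds)) {
    b <- bounds[[nm]]
    stopifnot(is.numeric(b), length(b) == 2L, b[1] <= b[2])
  }
  structure(list(bounds = bounds), class = "feasibility_constraints")
}

#' Regulatory consistency score
#'
#' Counts the regimes whose compliance mapping is TRUE, provided the edit's
#' feature vector lies inside the feasibility box; returns \code{NA} (with
#' attribute \code{infeasible = TRUE}) when any bound is violated.
#'
#' @inheritParams compliance_map
#' @param regimes list of regulatory descriptors.
#' @param constraints a \code{\link{feasibility_constraints}} object.
#' @return integer count, or \code{NA_integer_} flagged infeasible.
#' @export
consistency_score <- function(g, theta, regimes,
                              constraints = feasibility_constraints(),
                              model = NULL) {
  feats <- featurize_edit(g, theta)
  for (nm in names(constraints$bounds)) {
    if (!nm %in% names(feats)) next
    b <- constraints$bounds[[nm]]
    if (feats[[nm]] < b[1] || feats[[nm]] > b[2]) {
      return(structure(NA_integer_, infeasible = TRUE))
    }
  }
  sum(vapply(regimes, function(r) isTRUE(compliance_map(g, theta, r, model)),
             TRUE))
}

## ---- static embedding ------------------------------------------------------

## Serialized predicate thresholds: per scalar feature a (lower, upper) bound
## pair extracted from the atoms, length-like features rescaled by 1/10 so all
## entries live on a comparable O(1) scale; plus an op-type allowed mask and
## an atom count.
PRED_SCALAR_FEATURES <- c("bases_modified", "levenshtein_distance",
                          "homology_length", "relative_locus",
                          "donor_gc_fraction")
PRED_FEATURE_SCALE <- c(bases_modified = 10, levenshtein_distance = 10,
                        homology_length = 10, relative_locus = 1,
                        donor_gc_fraction = 1)

#' Serialized predicate feature vector
#'
#' The fixed-length numeric encoding of a compliance predicate fed to both
#' the static regime embedding and the neural predicate approximators.
#'
#' @param predicate a \code{\link{predicate_rule}}.
#' @return numeric vector of length 14.
#' @export
predicate_features <- function(predicate) {
  lo <- stats::setNames(rep(0, length(PRED_SCALAR_FEATURES)),
                        PRED_SCALAR_FEATURES)
  hi <- stats::setNames(rep(1, length(PRED_SCALAR_FEATURES)),
                        PRED_SCALAR_FEATURES)
  ops <- stats::setNames(rep(1, 3), OP_TYPES)
  for (a in predicate$atoms) {
    f <- a$feature
    if (f %in% PRED_SCALAR_FEATURES && is.numeric(a$value)) {
      v <- a$value / PRED_FEATURE_SCALE[[f]]
      if (a$cmp == "le") hi[f] <- min(hi[f], v)
      if (a$cmp == "ge") lo[f] <- max(lo[f], v)
      if (a$cmp == "eq") { lo[f] <- max(lo[f], v); hi[f] <- min(hi[f], v) }
    } else if (f == "op_type" && a$cmp %in% c("in", "eq")) {
      ops[] <- as.numeric(OP_TYPES %in% a$value)
    }
  }
  unname(c(rbind(lo, hi), ops, length(predicate$atoms) / 4))
}

#' Static regulation embedding
#'
#' Deterministic k-vector for a descriptor: one-hot SDN class block,
#' serialized predicate thresholds, and an exemption-count scalar, zero-padded
#' to length \code{k}.
#'
#' @param r a \code{\link{regulatory_descriptor}}.
#' @param k output length (at least 18).
#' @return numeric vector of length \code{k}.
#' @export
static_regime_embedding <- function(r, k = 32L) {
  core <- c(as.numeric(SDN_CLASSES == r$sdn_class),
            predicate_features(r$predicate),
            length(r$exemptions) / 4)
  if (k < length(core)) {
    stop_regalign("dimension_mismatch",
                  "embedding length k=%d below minimum %d", k, length(core))
  }
  c(core, rep(0, k - length(core)))
}

## ---- jurisdiction drift graph ---------------------------------------------

#' Construct a jurisdiction graph
#'
#' Directed graph over regime ids whose edges carry affine drift morphisms
#' (matrix and offset, conforming k x k / k) mapping one jurisdiction's
#' embedding onto another's interpretation.
#'
#' @param nodes character vector of regime ids.
#' @param edges list of lists with fields \code{from}, \code{to},
#'   \code{matrix} (k x k), \code{offset} (length k).
#' @export
jurisdiction_graph <- function(nodes, edges = list()) {
  for (e in edges) {
    stopifnot(e$from %in% nodes, e$to %in% nodes, is.matrix(e$matrix),
              nrow(e$matrix) == ncol(e$matrix),
              length(e$offset) == nrow(e$matrix))
  }
  structure(list(nodes = nodes, edges = edges), class = "jurisdiction_graph")
}

#' Apply a drift morphism between jurisdictions
#'
#' Affine transport of a regime embedding along a graph edge:
#' \code{matrix \%*\% rho + offset}.
#'
#' @param graph a \code{\link{jurisdiction_graph}}.
#' @param from_id,to_id edge endpoints.
#' @param rho embedding vector of the source regime.
#' @return transformed embedding, same length.
#' @export
drift_transform <- function(graph, from_id, to_id, rho) {
  for (e in graph$edges) {
    if (e$from == from_id && e$to == to_id) {
      stopifnot(length(rho) == ncol(e$matrix))
      return(as.numeric(e$matrix %*% rho + e$offset))
    }
  }
  stop_regalign("missing_edge", "no edge %s -> %s in jurisdiction graph",
                from_id, to_id)
}

## ---- JSON serialization ----------------------------------------------------

descriptor_to_list <- function(r) {
  list(
    id = r$id, jurisdiction = r$jurisdiction, sdn_class = r$sdn_class,
    predicate = lapply(r$predicate$atoms, function(a)
      list(feature = a$feature, cmp = a$cmp, value = a$value)),
    exemptions = lapply(r$exemptions, function(e)
      list(kind = e$kind, params = e$params)),
    static_embedding = r$static_embedding
  )
}

descriptor_from_list <- function(x) {
  atoms <- lapply(x$predicate, function(a)
    predicate_atom(a$feature, a$cmp, unlist(a$value)))
  exems <- lapply(x$exemptions, function(e) {
    params <- lapply(e$params, unlist)
    exemption_rule(e$kind, params)
  })
  regulatory_descriptor(x$id, x$jurisdiction, x$sdn_class,
                        predicate_rule(atoms), exems,
                        static_embedding = as.numeric(unlist(x$static_embedding)))
}

#' Write regulatory descriptors to JSON
#'
#' @param regimes list of \code{\link{regulatory_descriptor}} objects.
#' @param path output file.
#' @export
write_regimes_json <- function(regimes, path) {
  jsonlite::write_json(lapply(regimes, descriptor_to_list), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read regulatory descriptors from JSON
#'
#' @param path JSON file written by \code{\link{write_regimes_json}}.
#' @return named list of descriptors.
#' @export
read_regimes_json <- function(path) {
  raw <- tryCatch(jsonlite::read_json(path),
                  error = function(e) stop_regalign(
                    "malformed_file", "cannot parse regimes JSON %s: %s",
                    path, conditionMessage(e)))
  out <- lapply(raw, descriptor_from_list)
  names(out) <- vapply(out, function(r) r$id, "")
  out
}
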