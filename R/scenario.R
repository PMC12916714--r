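## Synthetic scenario generator: genomes, candidate edits, regimes built from
## random conjunctive predicates, rule-derived compliance labels with
## controllable flip noise, ambiguity labels planted in exemption-feature
## space, and regime drift series with planted linear trends. Every label is
## recoverable from the stored rules, so planted structure is testable.

#' Scenario generation configuration
#'
#' Defaults describe the canonical study conditions: four 300 bp genomes with
#' 125 candidate edits each against four regimes (2000 labeled pairs),
#' two-atom conjunctive predicates with thresholds drawn from central feature
#' quantiles so every rule bites, a quarter of regimes carrying a hard
#' exclusion, noise-free labels, and 50-step drift series with increments of
#' at most 0.2 per dimension and residual noise sd 0.01.
#'
#' @param n_genomes number of genomes.
#' @param genome_length genome length in bp.
#' @param n_candidates_per_genome candidate edits per genome.
#' @param n_regimes number of regulatory regimes.
#' @param atoms_per_predicate atoms in each compliance predicate (0 gives a
#'   vacuously true predicate).
#' @param rule_features feature pool predicates draw from.
#' @param hard_exclusion_rate probability a regime carries a hard exclusion.
#' @param exclusion_kinds which exclusion families may be drawn:
#'   \code{"origin"} (foreign donors), \code{"op"} (one banned operation),
#'   \code{"donor_length"} (length cap).
#' @param label_noise independent label flip probability in [0, 1).
#' @param natural_allele_pool size of the natural allele pool.
#' @param drift_T drift series length (>= 3).
#' @param drift_magnitude planted per-dimension drift is uniform on
#'   [-magnitude, magnitude].
#' @param drift_noise_sd residual noise sd of the drift series.
#' @param drift_dim dimensionality of the drift embedding series.
#' @param ambiguity_noise flip probability of the planted ambiguity labels.
#' @param seed master seed; the scenario is a pure function of this config.
#' @export
scenario_config <- function(n_genomes = 4L, genome_length = 300L,
                            n_candidates_per_genome = 125L, n_regimes = 4L,
                            atoms_per_predicate = 2L,
                            rule_features = c("bases_modified",
                                              "relative_locus",
                                              "donor_gc_fraction",
                                              "op_type"),
                            hard_exclusion_rate = 0.25,
                            exclusion_kinds = c("origin", "op",
                                                "donor_length"),
                            label_noise = 0, natural_allele_pool = 20L,
                            drift_T = 50L, drift_magnitude = 0.15,
                            drift_noise_sd = 0.01, drift_dim = 8L,
                            ambiguity_noise = 0.05, seed = 1L) {
  stopifnot(n_genomes >= 1, genome_length >= 30,
            n_candidates_per_genome >= 1, n_regimes >= 1,
            atoms_per_predicate >= 0, label_noise >= 0, label_noise < 1,
            hard_exclusion_rate >= 0, hard_exclusion_rate <= 1,
            natural_allele_pool >= 1, drift_T >= 3, drift_magnitude >= 0,
            drift_noise_sd >= 0, drift_dim >= 1,
            ambiguity_noise >= 0, ambiguity_noise < 1,
            all(exclusion_kinds %in% c("origin", "op", "donor_length")))
  structure(list(n_genomes = as.integer(n_genomes),
                 genome_length = as.integer(genome_length),
                 n_candidates_per_genome = as.integer(n_candidates_per_genome),
                 n_regimes = as.integer(n_regimes),
                 atoms_per_predicate = as.integer(atoms_per_predicate),
                 rule_features = rule_features,
                 hard_exclusion_rate = hard_exclusion_rate,
                 exclusion_kinds = exclusion_kinds,
                 label_noise = label_noise,
                 natural_allele_pool = as.integer(natural_allele_pool),
                 drift_T = as.integer(drift_T),
                 drift_magnitude = drift_magnitude,
                 drift_noise_sd = drift_noise_sd,
                 drift_dim = as.integer(drift_dim),
                 ambiguity_noise = ambiguity_noise,
                 seed = seed),
            class = "scenario_config")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

random_substring <- function(s, len) {
  start <- sample.int(nchar(s) - len + 1L, 1L)
  substr(s, start, start + len - 1L)
}

sample_candidate <- function(g, pool) {
  n <- nchar(g$sequence)
  op <- sample(OP_TYPES, 1L)
  if (op == "deletion") {
    len <- sample.int(6L, 1L)
    locus <- sample.int(n - len + 1L, 1L) - 1L
    donor <- substr(g$sequence, locus + 1L, locus + len)
  } else {
    src <- sample(c("pool", "genome", "novel"), 1L,
                  prob = c(0.35, 0.25, 0.40))
    donor <- switch(src,
      pool = pool[sample.int(length(pool), 1L)],
      genome = random_substring(g$sequence, sample.int(12L, 1L)),
      novel = random_dna(sample.int(12L, 1L)))
    len <- nchar(donor)
    locus <- if (op == "insertion") sample.int(n + 1L, 1L) - 1L
             else sample.int(n - len + 1L, 1L) - 1L
  }
  edit_spec(locus, donor, op, infer_donor_origin(g, donor, pool))
}

sample_regime <- function(idx, cfg, feat_mat, donor_lengths) {
  n_atoms <- cfg$atoms_per_predicate
  atoms <- list()
  if (n_atoms > 0) {
    feats <- sample(cfg$rule_features, min(n_atoms, length(cfg$rule_features)))
    for (f in feats) {
      if (f == "op_type") {
        allowed <- sample(OP_TYPES, sample(1:2, 1L))
        atoms[[length(atoms) + 1L]] <- predicate_atom("op_type", "in", allowed)
      } else {
        q <- stats::quantile(feat_mat[, f], stats::runif(1, 0.3, 0.7),
                             names = FALSE)
        cmp <- sample(c("le", "ge"), 1L)
        atoms[[length(atoms) + 1L]] <- predicate_atom(f, cmp, q)
      }
    }
  }
  exems <- list()
  if (stats::runif(1) < cfg$hard_exclusion_rate) {
    kind <- sample(cfg$exclusion_kinds, 1L)
    params <- switch(kind,
      origin = list(banned_origins = "foreign"),
      op = list(banned_ops = sample(OP_TYPES, 1L)),
      donor_length = list(max_donor_length =
                            stats::quantile(donor_lengths, 0.7,
                                            names = FALSE)))
    exems[[length(exems) + 1L]] <- exemption_rule("hard_exclusion", params)
  }
  if (stats::runif(1) < 0.5) {
    exems[[length(exems) + 1L]] <- exemption_rule(
      sample(c("natural_variant", "mutagenesis_analog"), 1L),
      list(max_donor_length = sample(4:10, 1L)))
  }
  regulatory_descriptor(sprintf("r%02d", idx), sprintf("jurisdiction_%02d", idx),
                        sample(SDN_CLASSES, 1L), predicate_rule(atoms), exems)
}

rule_label <- function(g, theta, r) {
  isTRUE(compliance_map(g, theta, r)) &&
    symbolic_gate(theta, r$exemptions) == 1L
}

#' Generate per-regime drift series with planted linear trends
#'
#' \code{rho_{t+1} = rho_t + drift + eps} with the planted drift stored for
#' recovery tests.
#'
#' @param cfg a \code{\link{scenario_config}} (fields \code{n_regimes},
#'   \code{drift_T}, \code{drift_magnitude}, \code{drift_noise_sd},
#'   \code{drift_dim}, \code{seed} are used).
#' @return list with \code{series} (named list of T x dim matrices) and
#'   \code{planted} (named list of drift vectors).
#' @export
generate_drift_series <- function(cfg) {
  with_seed(derive_seed(cfg$seed, 37L), {
    ids <- sprintf("r%02d", seq_len(cfg$n_regimes))
    series <- list()
    planted <- list()
    for (id in ids) {
      drift <- stats::runif(cfg$drift_dim, -cfg$drift_magnitude,
                            cfg$drift_magnitude)
      rho <- stats::rnorm(cfg$drift_dim)
      m <- matrix(0, cfg$drift_T, cfg$drift_dim)
      m[1, ] <- rho
      for (t in seq_len(cfg$drift_T - 1L)) {
        m[t + 1L, ] <- m[t, ] + drift +
          stats::rnorm(cfg$drift_dim, 0, cfg$drift_noise_sd)
      }
      series[[id]] <- m
      planted[[id]] <- drift
    }
    list(series = series, planted = planted)
  })
}

#' Generate a fully labeled synthetic scenario
#'
#' Genomes are uniform over \{A,C,G,T\}; candidate edits carry valid loci and
#' mixed donor provenance; regimes are random conjunctive predicates with
#' thresholds at central quantiles of the realised feature distribution plus
#' optional hard exclusions; compliance labels are the rule evaluation
#' (predicate AND open gate) flipped independently with the configured noise;
#' ambiguity labels are planted in exemption-feature space. Regimes are
#' resampled (bounded retries) until the compliant fraction lies in
#' [0.2, 0.8]. The result is a pure function of the config, including its
#' seed.
#'
#' @param cfg a \code{\link{scenario_config}}.
#' @return An object of class \code{scenario}.
#' @export
generate_scenario <- function(cfg = scenario_config()) {
  with_seed(derive_seed(cfg$seed, 2L), {
    genomes <- list()
    for (i in seq_len(cfg$n_genomes)) {
      id <- sprintf("g%02d", i)
      genomes[[id]] <- genome(id, random_dna(cfg$genome_length))
    }
    pool <- unique(c(
      vapply(seq_len(ceiling(cfg$natural_allele_pool / 2)), function(i)
        random_dna(sample(2:8, 1L)), ""),
      vapply(seq_len(floor(cfg$natural_allele_pool / 2)), function(i)
        random_substring(genomes[[sample.int(length(genomes), 1L)]]$sequence,
                         sample(2:8, 1L)), "")))

    cand_rows <- list()
    thetas <- list()
    gid_of <- character()
    idx <- 0L
    for (gid in names(genomes)) {
      for (j in seq_len(cfg$n_candidates_per_genome)) {
        idx <- idx + 1L
        th <- sample_candidate(genomes[[gid]], pool)
        thetas[[idx]] <- th
        gid_of[idx] <- gid
        cand_rows[[idx]] <- data.frame(
          edit_id = sprintf("e%05d", idx), genome_id = gid,
          locus = th$locus, donor = th$donor, op_type = th$op_type,
          donor_origin = th$donor_origin, stringsAsFactors = FALSE)
      }
    }
    candidates <- do.call(rbind, cand_rows)

    feat_mat <- t(vapply(seq_along(thetas), function(i)
      featurize_edit(genomes[[gid_of[i]]], thetas[[i]]),
      numeric(length(edit_feature_names()))))
    colnames(feat_mat) <- edit_feature_names()
    donor_lengths <- nchar(candidates$donor)

    regimes <- NULL
    rule_mat <- NULL
    for (attempt in seq_len(20L)) {
      trial <- lapply(seq_len(cfg$n_regimes), sample_regime, cfg = cfg,
                      feat_mat = feat_mat, donor_lengths = donor_lengths)
      rm_trial <- vapply(trial, function(r)
        vapply(seq_along(thetas), function(i)
          rule_label(genomes[[gid_of[i]]], thetas[[i]], r), TRUE),
        logical(length(thetas)))
      frac <- mean(rm_trial)
      if (frac >= 0.2 && frac <= 0.8) {
        regimes <- trial
        rule_mat <- rm_trial
        break
      }
    }
    if (is.null(regimes)) {
      stop_regalign("generation_failure",
                    "could not reach label balance in [0.2, 0.8] after 20 regime resamples")
    }
    names(regimes) <- vapply(regimes, function(r) r$id, "")

    labels <- expand.grid(regime_id = names(regimes),
                          edit_id = candidates$edit_id,
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    labels <- labels[, c("edit_id", "regime_id")]
    labels <- labels[order(match(labels$edit_id, candidates$edit_id),
                           match(labels$regime_id, names(regimes))), ]
    rownames(labels) <- NULL
    rule_vec <- as.integer(t(rule_mat))  # candidate-major, regime-minor
    flips <- if (cfg$label_noise > 0) {
      stats::runif(length(rule_vec)) < cfg$label_noise
    } else rep(FALSE, length(rule_vec))
    labels$compliant <- as.integer(xor(rule_vec == 1L, flips))

    X <- t(vapply(seq_along(thetas), function(i)
      exemption_features(thetas[[i]], genomes[[gid_of[i]]], pool),
      numeric(3)))
    amb_rule <- (X[, 3] == 2) | (X[, 2] >= 1 & X[, 1] == 0)
    amb_flip <- if (cfg$ambiguity_noise > 0) {
      stats::runif(length(amb_rule)) < cfg$ambiguity_noise
    } else rep(FALSE, length(amb_rule))
    ambiguity <- data.frame(edit_id = candidates$edit_id,
                            ambiguous = as.integer(xor(amb_rule, amb_flip)))

    drift <- generate_drift_series(cfg)

    structure(list(
      genomes = genomes, candidates = candidates, regimes = regimes,
      labels = labels, ambiguity = ambiguity, natural_alleles = pool,
      drift = drift$series,
      meta = list(config = unclass(cfg), seed = cfg$seed,
                  planted_drift = drift$planted,
                  rule_balance = mean(rule_mat),
                  generator_version = "1")),
      class = "scenario")
  })
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf(
    "<scenario> %d genome(s), %d candidate(s), %d regime(s), %d labels (%.0f%% compliant)\n",
    length(x$genomes), nrow(x$candidates), length(x$regimes),
    nrow(x$labels), 100 * mean(x$labels$compliant)))
  invisible(x)
}

## ---- serialization ----------------------------------------------------------

#' Write a scenario to a directory
#'
#' FASTA for genomes, TSV for edits / labels / ambiguity / drift series, JSON
#' for regimes, and \code{scenario.meta.json} carrying the config, seed,
#' planted drift and allele pool. \code{read_scenario(write_scenario(s))} is
#' the identity.
#'
#' @param scenario a \code{scenario}.
#' @param dir output directory (created if missing).
#' @export
write_scenario <- function(scenario, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genomes_fasta(scenario$genomes, file.path(dir, "genomes.fasta"))
  write_edits_tsv(scenario$candidates, file.path(dir, "edits.tsv"))
  utils::write.table(scenario$labels, file.path(dir, "labels.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(scenario$ambiguity, file.path(dir, "ambiguity.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_regimes_json(scenario$regimes, file.path(dir, "regimes.json"))
  write_drift_tsv(scenario$drift, file.path(dir, "drift.tsv"))
  jsonlite::write_json(
    list(config = scenario$meta$config,
         seed = scenario$meta$seed,
         planted_drift = scenario$meta$planted_drift,
         rule_balance = scenario$meta$rule_balance,
         natural_alleles = scenario$natural_alleles,
         generator_version = scenario$meta$generator_version),
    file.path(dir, "scenario.meta.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(dir)
}

read_tsv_checked <- function(path, required, validate = NULL) {
  df <- tryCatch(utils::read.delim(path, stringsAsFactors = FALSE),
                 error = function(e) stop_regalign(
                   "malformed_file", "cannot parse %s: %s", path,
                   conditionMessage(e)))
  if (!all(required %in% names(df))) {
    stop_regalign("malformed_file", "%s must have columns %s", path,
                  paste(required, collapse = ", "))
  }
  if (!is.null(validate)) {
    bad <- validate(df)
    if (length(bad)) {
      stop_regalign("malformed_file", "%s: invalid record at data line %d",
                    path, bad[1])
    }
  }
  df
}

#' Read a scenario from a directory
#'
#' Inverse of \code{\link{write_scenario}}; donor origins and edit ids are
#' reconstructed deterministically from the genomes and the stored allele
#' pool.
#'
#' @param dir directory written by \code{\link{write_scenario}}.
#' @return a \code{scenario}.
#' @export
read_scenario <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "scenario.meta.json"),
                              simplifyVector = TRUE)
  cfg_args <- meta$config
  cfg <- do.call(scenario_config, cfg_args)
  genomes <- read_genomes_fasta(file.path(dir, "genomes.fasta"))
  edits <- read_edits_tsv(file.path(dir, "edits.tsv"))
  pool <- as.character(meta$natural_alleles)
  edits$edit_id <- sprintf("e%05d", seq_len(nrow(edits)))
  edits$donor_origin <- vapply(seq_len(nrow(edits)), function(i)
    infer_donor_origin(genomes[[edits$genome_id[i]]], edits$donor[i], pool),
    "")
  candidates <- edits[, c("edit_id", "genome_id", "locus", "donor",
                          "op_type", "donor_origin")]
  labels <- read_tsv_checked(
    file.path(dir, "labels.tsv"), c("edit_id", "regime_id", "compliant"),
    function(df) which(!df$compliant %in% c(0L, 1L)))
  ambiguity <- read_tsv_checked(
    file.path(dir, "ambiguity.tsv"), c("edit_id", "ambiguous"),
    function(df) which(!df$ambiguous %in% c(0L, 1L)))
  regimes <- read_regimes_json(file.path(dir, "regimes.json"))
  drift <- read_drift_tsv(file.path(dir, "drift.tsv"))
  planted <- lapply(meta$planted_drift, as.numeric)
  structure(list(genomes = genomes, candidates = candidates,
                 regimes = regimes, labels = labels, ambiguity = ambiguity,
                 natural_alleles = pool, drift = drift,
                 meta = list(config = unclass(cfg), seed = cfg$seed,
                             planted_drift = planted,
                             rule_balance = meta$rule_balance,
                             generator_version =
                               as.character(meta$generator_version))),
            class = "scenario")
}
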