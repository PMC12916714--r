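## Independent oracles and small fixture builders shared across test files.
## Oracles are deliberately naive (dynamic programming, exhaustive loops) and
## never call the code paths they check.

## Textbook dynamic-programming Levenshtein distance.
lev_oracle <- function(a, b) {
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  prev <- 0:length(bv)
  for (i in seq_along(av)) {
    cur <- numeric(length(bv) + 1)
    cur[1] <- i
    for (j in seq_along(bv)) {
      cur[j + 1] <- min(prev[j + 1] + 1, cur[j] + 1,
                        prev[j] + (av[i] != bv[j]))
    }
    prev <- cur
  }
  prev[length(bv) + 1]
}

## Naive both-strand substring scan with edited-interval exclusion.
off_target_oracle <- function(donor, seq, locus) {
  L <- nchar(donor)
  rc <- revcomp(donor)
  n <- nchar(seq)
  cnt <- 0L
  if (L > n) return(0L)
  for (p in 0:(n - L)) {
    if (p < locus + L && p + L > locus) next
    w <- substr(seq, p + 1, p + L)
    if (w == donor || w == rc) cnt <- cnt + 1L
  }
  cnt
}

## Naive hard-exclusion scan mirroring the gate contract.
gate_oracle <- function(theta, exemptions) {
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

random_genome_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

random_edit <- function(g, origin = NULL) {
  if (length(origin) && is.na(origin)) origin <- NULL
  n <- nchar(g$sequence)
  op <- sample(c("insertion", "deletion", "substitution"), 1)
  if (op == "deletion") {
    len <- sample(1:4, 1)
    locus <- sample(0:(n - len), 1)
    donor <- substr(g$sequence, locus + 1, locus + len)
  } else {
    donor <- random_genome_seq(sample(1:6, 1))
    locus <- if (op == "insertion") sample(0:n, 1) else
      sample(0:(n - nchar(donor)), 1)
  }
  edit_spec(locus, donor, op, origin)
}

make_regime <- function(id = "r1", atoms = list(), exemptions = list(),
                        sdn = "SDN-1") {
  regulatory_descriptor(id, paste0("j_", id), sdn, predicate_rule(atoms),
                        exemptions)
}

small_scenario <- function(seed = 3, n_cand = 30, n_reg = 3, ...) {
  generate_scenario(scenario_config(
    n_genomes = 1, genome_length = 150, n_candidates_per_genome = n_cand,
    n_regimes = n_reg, seed = seed, ...))
}
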