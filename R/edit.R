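## Edit calculus: one genomic intervention theta = (locus, donor, op_type)
## applied to a genome, and its interpretable featurization.

OP_TYPES <- c("insertion", "deletion", "substitution")

#' Construct an edit specification
#'
#' Coordinates are 0-based with half-open intervals. An insertion places the
#' donor before index \code{locus} (so \code{locus == nchar(genome)} appends).
#' For deletions the donor encodes the reference segment to be removed and
#' must match the genome at the locus; this makes insertion/deletion a
#' round trip and allows validation.
#'
#' @param locus non-negative integer, 0-based position.
#' @param donor non-empty string over A/C/G/T (the inserted, substituted, or
#'   removed segment).
#' @param op_type one of \code{"insertion"}, \code{"deletion"},
#'   \code{"substitution"}.
#' @param donor_origin optional provenance label for the donor, one of
#'   \code{"endogenous"}, \code{"natural_variant"}, \code{"foreign"}; consulted
#'   by origin-based exclusion rules and the exemption feature vector.
#' @return An object of class \code{edit_spec}.
#' @examples
#' edit_spec(2, "G", "substitution")
#' @export
edit_spec <- function(locus, donor, op_type, donor_origin = NULL) {
  stopifnot(is.numeric(locus), length(locus) == 1L, locus >= 0,
            locus == floor(locus))
  check_dna(donor, "donor")
  op_type <- match.arg(op_type, OP_TYPES)
  if (!is.null(donor_origin)) {
    donor_origin <- match.arg(donor_origin, DONOR_ORIGINS)
  }
  structure(list(locus = as.integer(locus), donor = donor, op_type = op_type,
                 donor_origin = donor_origin),
            class = "edit_spec")
}

DONOR_ORIGINS <- c("endogenous", "natural_variant", "foreign")

#' @export
print.edit_spec <- function(x, ...) {
  cat(sprintf("<edit_spec> %s of %s at locus %d%s\n", x$op_type, x$donor,
              x$locus,
              if (is.null(x$donor_origin)) "" else
                paste0(" (", x$donor_origin, ")")))
  invisible(x)
}

#' Construct an edit task
#'
#' Pairs a genome reference with an edit specification.
#'
#' @param genome_ref id of a genome in the active scenario.
#' @param edit an \code{\link{edit_spec}}.
#' @export
edit_task <- function(genome_ref, edit) {
  stopifnot(is.character(genome_ref), length(genome_ref) == 1L,
            inherits(edit, "edit_spec"))
  structure(list(genome_ref = genome_ref, edit = edit), class = "edit_task")
}

check_edit_bounds <- function(g, theta) {
  n <- nchar(g$sequence)
  dl <- nchar(theta$donor)
  if (theta$op_type == "insertion") {
    if (theta$locus > n) {
      stop_regalign("locus_out_of_bounds",
                    "insertion locus %d outside [0, %d]", theta$locus, n)
    }
  } else {
    if (theta$locus + dl > n) {
      stop_regalign("locus_out_of_bounds",
                    "%s at locus %d with donor length %d exceeds genome length %d",
                    theta$op_type, theta$locus, dl, n)
    }
  }
  if (theta$op_type == "deletion") {
    ref <- substr(g$sequence, theta$locus + 1L, theta$locus + dl)
    if (ref != theta$donor) {
      stop_regalign("deletion_reference_mismatch",
                    "deletion donor %s does not match reference segment %s at locus %d",
                    theta$donor, ref, theta$locus)
    }
  }
  invisible(TRUE)
}

#' Apply an edit to a genome
#'
#' Returns the edited genome; the input is untouched. Length accounting:
#' insertion adds \code{nchar(donor)}, deletion removes it, substitution
#' preserves length.
#'
#' @param g a \code{\link{genome}}.
#' @param theta an \code{\link{edit_spec}}.
#' @return A new \code{genome} whose id is suffixed with \code{"_edit"}.
#' @examples
#' apply_edit(genome("g", "AAAA"), edit_spec(2, "G", "substitution"))
#' @export
apply_edit <- function(g, theta) {
  stopifnot(inherits(g, "genome"), inherits(theta, "edit_spec"))
  check_edit_bounds(g, theta)
  s <- g$sequence
  l <- theta$locus
  dl <- nchar(theta$donor)
  new_seq <- switch(theta$op_type,
    insertion    = paste0(substr(s, 1L, l), theta$donor,
                          substr(s, l + 1L, nchar(s))),
    deletion     = paste0(substr(s, 1L, l), substr(s, l + dl + 1L, nchar(s))),
    substitution = paste0(substr(s, 1L, l), theta$donor,
                          substr(s, l + dl + 1L, nchar(s)))
  )
  genome(paste0(g$id, "_edit"), new_seq)
}

#' Feature names of the edit featurization
#'
#' The fixed, documented feature set: number of bases modified, Levenshtein
#' distance between original and edited genome, homology length of the donor
#' against the flanks at the locus, a one-hot operation-type block, the
#' relative locus, and the donor GC fraction.
#' @return character vector of length 8.
#' @export
edit_feature_names <- function() {
  c("bases_modified", "levenshtein_distance", "homology_length",
    "op_insertion", "op_deletion", "op_substitution",
    "relative_locus", "donor_gc_fraction")
}

gc_fraction <- function(s) {
  n <- nchar(s)
  if (n == 0L) return(0)
  (n - nchar(gsub("[GC]", "", s))) / n
}

## Longest exact match of the donor against the reference flanks at the locus:
## max over (longest common prefix of donor with the right flank, longest
## common suffix of donor with the left flank).
homology_length <- function(g, theta) {
  s <- g$sequence
  l <- theta$locus
  d <- theta$donor
  right <- substr(s, l + 1L, nchar(s))
  left <- substr(s, 1L, l)
  lcp <- 0L
  kmax <- min(nchar(d), nchar(right))
  while (lcp < kmax &&
         substr(d, lcp + 1L, lcp + 1L) == substr(right, lcp + 1L, lcp + 1L)) {
    lcp <- lcp + 1L
  }
  lcs <- 0L
  kmax <- min(nchar(d), nchar(left))
  while (lcs < kmax &&
         substr(d, nchar(d) - lcs, nchar(d) - lcs) ==
         substr(left, nchar(left) - lcs, nchar(left) - lcs)) {
    lcs <- lcs + 1L
  }
  max(lcp, lcs)
}

#' Featurize an edit
#'
#' Maps an edit applied to a genome to a fixed-dimension, biologically and
#' legally interpretable feature vector (see \code{\link{edit_feature_names}}).
#' Deterministic: identical inputs give identical vectors.
#'
#' @inheritParams apply_edit
#' @return Named numeric vector of length 8.
#' @export
featurize_edit <- function(g, theta) {
  gp <- apply_edit(g, theta)
  v <- c(
    bases_modified = nchar(theta$donor),
    levenshtein_distance =
      as.numeric(utils::adist(g$sequence, gp$sequence)[1, 1]),
    homology_length = as.numeric(homology_length(g, theta)),
    op_insertion = as.numeric(theta$op_type == "insertion"),
    op_deletion = as.numeric(theta$op_type == "deletion"),
    op_substitution = as.numeric(theta$op_type == "substitution"),
    relative_locus = theta$locus / nchar(g$sequence),
    donor_gc_fraction = gc_fraction(theta$donor)
  )
  stopifnot(identical(names(v), edit_feature_names()))
  v
}

#' Infer the provenance of a donor sequence
#'
#' A donor drawn from the natural-allele pool is a \code{natural_variant};
#' one occurring verbatim in the genome is \code{endogenous}; anything else is
#' \code{foreign}.
#'
#' @param g a \code{\link{genome}}.
#' @param donor donor string.
#' @param natural_alleles character vector of known natural allele sequences.
#' @return one of \code{"endogenous"}, \code{"natural_variant"},
#'   \code{"foreign"}.
#' @export
infer_donor_origin <- function(g, donor, natural_alleles = character()) {
  if (donor %in% natural_alleles) return("natural_variant")
  if (grepl(donor, g$sequence, fixed = TRUE)) return("endogenous")
  "foreign"
}

#' Read candidate edits from a TSV file
#'
#' Schema (header required): \code{genome_id}, \code{locus}, \code{donor},
#' \code{op_type}. Loci are 0-based.
#'
#' @param path TSV file.
#' @return data.frame with the four schema columns.
#' @export
read_edits_tsv <- function(path) {
  df <- tryCatch(
    utils::read.delim(path, colClasses = c("character", "integer",
                                           "character", "character")),
    error = function(e) stop_regalign("malformed_file",
                                      "cannot parse edits TSV %s: %s",
                                      path, conditionMessage(e)))
  required <- c("genome_id", "locus", "donor", "op_type")
  if (!identical(names(df), required)) {
    stop_regalign("malformed_file",
                  "edits TSV %s must have header columns %s", path,
                  paste(required, collapse = ", "))
  }
  bad <- which(!df$op_type %in% OP_TYPES | is.na(df$locus) |
                 !nzchar(df$donor) | grepl("[^ACGT]", df$donor))
  if (length(bad)) {
    stop_regalign("malformed_file",
                  "edits TSV %s: invalid record at data line %d", path, bad[1])
  }
  df
}

#' Write candidate edits to a TSV file
#'
#' @param edits data.frame with columns \code{genome_id}, \code{locus},
#'   \code{donor}, \code{op_type}.
#' @param path output file.
#' @export
write_edits_tsv <- function(edits, path) {
  utils::write.table(edits[, c("genome_id", "locus", "donor", "op_type")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
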