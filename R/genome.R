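#' Construct a genome
#'
#' A genome is a named nucleotide sequence over the strict alphabet
#' \{A, C, G, T\}. Ambiguity codes are rejected: the edit calculus is defined
#' over the four-letter alphabet only.
#'
#' @param id character label.
#' @param sequence character scalar over A/C/G/T, non-empty.
#' @return An object of class \code{genome} with fields \code{id} and
#'   \code{sequence}.
#' @examples
#' g <- genome("chr1", "ACGTACGT")
#' @export
genome <- function(id, sequence) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  check_dna(sequence)
  structure(list(id = id, sequence = sequence), class = "genome")
}

check_dna <- function(sequence, what = "sequence") {
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence) ||
      grepl("[^ACGT]", sequence)) {
    stop_regalign("invalid_alphabet",
                  "%s must be a non-empty string over {A,C,G,T}", what)
  }
  invisible(sequence)
}

#' @export
print.genome <- function(x, ...) {
  cat(sprintf("<genome> %s (%d bp)\n", x$id, nchar(x$sequence)))
  invisible(x)
}

#' @export
length.genome <- function(x) nchar(x$sequence)

#' Read genomes from a FASTA file
#'
#' @param path FASTA file (single- or multi-record).
#' @return Named list of \code{genome} objects, keyed by record id.
#' @export
read_genomes_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  out <- lapply(seq_along(set), function(i) {
    genome(names(set)[i], as.character(set[[i]]))
  })
  names(out) <- names(set)
  out
}

#' Write genomes to a FASTA file
#'
#' @param genomes list of \code{genome} objects.
#' @param path output file.
#' @export
write_genomes_fasta <- function(genomes, path) {
  seqs <- Biostrings::DNAStringSet(vapply(genomes, function(g) g$sequence, ""))
  names(seqs) <- vapply(genomes, function(g) g$id, "")
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
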