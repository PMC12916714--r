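#' @keywords internal
"_PACKAGE"

## Numerical helpers shared across modules.

sigmoid <- function(x) 1 / (1 + exp(-x))

softmax <- function(x) {
  z <- exp(x - max(x))
  z / sum(z)
}

## Probabilities are clipped before log() so binary cross-entropy stays finite.
clip_prob <- function(p, eps = 1e-7) pmin(pmax(p, eps), 1 - eps)

clip01 <- function(x) pmin(pmax(x, 0), 1)

#' Reverse complement of a DNA string
#'
#' Strict {A,C,G,T} alphabet; used by the off-target index scan.
#' @param x character scalar over A/C/G/T.
#' @return character scalar.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  paste(rev(strsplit(chartr("ACGT", "TGCA", x), "", fixed = TRUE)[[1]]),
        collapse = "")
}

## Run code under a temporary RNG state so library calls never perturb the
## caller's stream. All stochastic entry points funnel through this.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

## Classed conditions so callers (and tests) can distinguish failure modes.
stop_regalign <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "regalign_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Deterministic sub-seed derivation: keeps every stream independent while a
## single master seed reproduces the whole run. Kept below 2^31 - 1.
derive_seed <- function(seed, salt) {
  (as.numeric(seed) * 48271 + salt * 1299721) %% 2147483647
}
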