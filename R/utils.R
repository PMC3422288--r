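DNA_BASES <- c("A", "C", "G", "T")

## sequence <-> integer codes (1=A, 2=C, 3=G, 4=T)
seq_to_int <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  codes <- match(strsplit(x, "", fixed = TRUE)[[1L]], DNA_BASES)
  if (anyNA(codes)) {
    stop("sequence contains characters outside {A,C,G,T}", call. = FALSE)
  }
  codes
}

int_to_seq <- function(codes) {
  paste0(DNA_BASES[codes], collapse = "")
}

random_dna <- function(n) {
  int_to_seq(sample.int(4L, n, replace = TRUE))
}

#' Reverse complement of a DNA string
#'
#' Thin character-level wrapper around [Biostrings::reverseComplement()].
#'
#' @param x character vector of DNA sequences over \{A,C,G,T\}.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## Derive a vector of stage seeds from one master seed.  Documented scheme:
## seed the generator with `master` and draw `n` integers in [1, 2^31 - 2];
## each stage then calls set.seed() on its own derived seed, so stages are
## insensitive to how much randomness earlier stages consumed.
seed_split <- function(master, n) {
  stopifnot(length(master) == 1L, is.finite(master))
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      suppressWarnings(rm(".Random.seed", envir = globalenv()))
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(master))
  sample.int(.Machine$integer.max - 1L, n)
}

## Count-safe samplers: molecule counts exceed .Machine$integer.max in
## realistic protocols, where R's exact samplers fail.  Above the exact
## range the distributions are replaced by their asymptotic equivalents,
## whose error is negligible at that scale.

safe_rbinom <- function(size, prob) {
  if (size < 2^31 - 1) return(rbinom(1L, size, prob))
  mu <- size * prob
  round(max(0, min(size, stats::rnorm(1L, mu, sqrt(mu * (1 - prob))))))
}

## number of marked items in a without-replacement sample of k from m
## marked + n unmarked; k is always small here, so the with-replacement
## binomial is an excellent approximation when the population is huge
safe_rhyper <- function(m, n, k) {
  if (m + n < 2^31 - 1) return(rhyper(1L, m, n, k))
  rbinom(1L, k, m / (m + n))
}

safe_rpois <- function(lambda) {
  if (lambda < 1e9) return(rpois(1L, lambda))
  round(max(0, stats::rnorm(1L, lambda, sqrt(lambda))))
}

## classed error helpers -----------------------------------------------------

ngsam_error <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "ngsam_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

protocol_failure <- function(stage) {
  ngsam_error("ngsam_protocol_failure",
              sprintf("protocol failed: %s", stage), stage = stage)
}

assembly_failure <- function(msg) {
  ngsam_error("ngsam_assembly_failure", msg, stage = "assembly")
}

strandedness_failure <- function(msg) {
  ngsam_error("ngsam_strandedness_failure", msg, stage = "strandedness")
}
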