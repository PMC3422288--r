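#' Fragment-length model
#'
#' Sequencing libraries are made by random fragmentation; fragment lengths
#' are log-normal.  The log-normal is parameterized by its natural-scale
#' arithmetic mean and coefficient of variation: with
#' `sigma^2 = log(1 + cv^2)` and `mu = log(mean) - sigma^2 / 2` the
#' distribution has exactly the requested mean and CV.  The defaults (mean
#' 400 bp, CV 0.055) give, with 101-bp paired reads, a mean insert of
#' 400 - 2*101 = 198 bp.
#'
#' @param mean_length arithmetic mean fragment length in bp (default 400).
#' @param cv natural-scale coefficient of variation (default 0.055).
#' @return object of class `ngsam_fragment_model` with the derived
#'   log-scale `mu` and `sigma`.
#' @export
fragment_model <- function(mean_length = 400, cv = 0.055) {
  stopifnot(mean_length > 0, cv > 0)
  sigma2 <- log(1 + cv^2)
  structure(list(mean_length = mean_length, cv = cv,
                 mu = log(mean_length) - sigma2 / 2,
                 sigma = sqrt(sigma2)),
            class = "ngsam_fragment_model")
}

#' Mean insert size implied by a fragment model
#'
#' The insert is the unsequenced interior of a fragment in paired-end
#' sequencing: fragment length minus the two read lengths.
#'
#' @param model an [fragment_model()].
#' @param read_length read length in bp (default 101).
#' @return mean insert size in bp.
#' @export
mean_insert_size <- function(model, read_length = 101L) {
  model$mean_length - 2 * read_length
}

#' Sequencing error model
#'
#' A simple per-base substitution error model standing in for a full
#' platform intensity model.  `"ramp"` (the default) increases the error
#' rate linearly from `rate_start` at the first sequenced base to
#' `rate_end` at the last, mimicking the quality decay along short reads;
#' `"flat"` uses `rate_start` everywhere.  Base qualities written to FASTQ
#' are the Phred encoding of the position's true error probability.
#'
#' @param type `"ramp"` or `"flat"`.
#' @param rate_start error probability at read position 1.
#' @param rate_end error probability at the last position (ramp only).
#' @return object of class `ngsam_error_model`.
#' @export
error_model <- function(type = c("ramp", "flat"),
                        rate_start = 0.001, rate_end = 0.01) {
  type <- match.arg(type)
  stopifnot(rate_start >= 0, rate_start <= 0.75,
            rate_end >= 0, rate_end <= 0.75)
  structure(list(type = type, rate_start = rate_start, rate_end = rate_end),
            class = "ngsam_error_model")
}

error_rates <- function(em, read_length) {
  if (em$type == "flat") {
    rep(em$rate_start, read_length)
  } else {
    em$rate_start + (em$rate_end - em$rate_start) *
      (seq_len(read_length) - 1) / max(1L, read_length - 1L)
  }
}

phred_string <- function(rates) {
  q <- pmin(41L, pmax(2L, as.integer(round(-10 * log10(pmax(rates, 1e-5))))))
  intToUtf8(q + 33L)
}

#' Allocate sequencing coverage across mutant types
#'
#' Splits the fragment budget implied by a total coverage across the pool
#' entries proportionally to their final-PCR descendant weights, so that
#' the expected number of sequenced bases is
#' `total_coverage * target_length`.  At the default 4000x total coverage
#' with on the order of twenty mutant types this provides roughly 200x per
#' type.  Rounding uses largest remainders, so the allocation is
#' deterministic given the weights.
#'
#' @param pool data.frame with columns `sequence` and `weight` (as produced
#'   by [run_protocol()]).
#' @param total_coverage total fold coverage of the target (default 4000).
#' @param target_length length of the target region in bp.
#' @param read_length read length (default 101; each fragment yields two
#'   reads).
#' @return integer vector of fragment counts, one per pool entry.
#' @export
allocate_coverage <- function(pool, total_coverage = 4000, target_length,
                              read_length = 101L) {
  if (NROW(pool) == 0L) stop("empty mutant pool", call. = FALSE)
  stopifnot(total_coverage > 0, target_length > 0)
  total_frags <- total_coverage * target_length / (2 * read_length)
  share <- pool$weight / sum(pool$weight)
  exact <- total_frags * share
  n <- floor(exact)
  rem <- round(total_frags) - sum(n)
  if (rem > 0) {
    top <- order(exact - n, decreasing = TRUE)[seq_len(rem)]
    n[top] <- n[top] + 1
  }
  as.integer(n)
}

#' Fragment the pool and simulate paired-end reads
#'
#' For each mutant type, draws fragments with log-normal lengths and
#' uniform start positions on a uniformly chosen strand, rejects and
#' redraws fragments shorter than the read length (or longer than the
#' molecule), then sequences `read_length` bases inward from both fragment
#' ends: read 1 from the fragment's 5' end, read 2 reverse-complemented
#' from its 3' end.  Per-base substitution errors follow the error model.
#'
#' @param pool data.frame with `sequence` and `weight` columns.
#' @param n_fragments integer vector of fragment counts per pool entry,
#'   e.g. from [allocate_coverage()].
#' @param frag_model an [fragment_model()].
#' @param read_length read length in bp (default 101).
#' @param err an [error_model()].
#' @return object of class `ngsam_read_pairs`: list with `read1`, `read2`
#'   ([Biostrings::DNAStringSet]), `qual1`, `qual2` (character), and
#'   `provenance` (data.frame: `read_id`, `mutant`, `start`, `end` 0-based
#'   half-open fragment interval on the mutant, `strand`).
#' @export
fragment_and_sequence <- function(pool, n_fragments,
                                  frag_model = fragment_model(),
                                  read_length = 101L,
                                  err = error_model()) {
  stopifnot(NROW(pool) >= 1L, length(n_fragments) == NROW(pool))
  lens <- nchar(pool$sequence)
  if (any(lens[n_fragments > 0] < read_length)) {
    stop("mutant sequences shorter than the read length cannot be sequenced",
         call. = FALSE)
  }
  frag_list <- vector("list", NROW(pool))
  prov_list <- vector("list", NROW(pool))
  for (i in seq_len(NROW(pool))) {
    n <- n_fragments[i]
    if (n == 0L) next
    L <- lens[i]
    flen <- integer(0)
    while (length(flen) < n) {          # rejection sampling of lengths
      cand <- round(rlnorm(n, frag_model$mu, frag_model$sigma))
      cand <- cand[cand >= read_length & cand <= L]
      flen <- c(flen, cand)
    }
    flen <- flen[seq_len(n)]
    start <- floor(runif(n, 0, L - flen + 1))  # 0-based
    strand <- sample(c("+", "-"), n, replace = TRUE)
    frag <- substring(pool$sequence[i], start + 1, start + flen)
    rev <- strand == "-"
    if (any(rev)) frag[rev] <- revcomp(frag[rev])
    frag_list[[i]] <- frag
    prov_list[[i]] <- data.frame(mutant = i, start = start,
                                 end = start + flen, strand = strand,
                                 stringsAsFactors = FALSE)
  }
  frag <- unlist(frag_list)
  prov <- do.call(rbind, prov_list)
  if (is.null(frag) || length(frag) == 0L) {
    stop("no fragments to sequence", call. = FALSE)
  }
  prov$read_id <- sprintf("frag%06d", seq_along(frag))
  prov <- prov[c("read_id", "mutant", "start", "end", "strand")]

  flen <- nchar(frag)
  r1 <- substring(frag, 1L, read_length)
  r2 <- revcomp(substring(frag, flen - read_length + 1L, flen))
  rates <- error_rates(err, read_length)
  r1 <- Biostrings::DNAStringSet(apply_read_errors(r1, rates))
  r2 <- Biostrings::DNAStringSet(apply_read_errors(r2, rates))
  names(r1) <- paste0(prov$read_id, "/1")
  names(r2) <- paste0(prov$read_id, "/2")
  q <- phred_string(rates)
  structure(list(read1 = r1, read2 = r2,
                 qual1 = rep(q, length(r1)), qual2 = rep(q, length(r2)),
                 read_length = as.integer(read_length),
                 provenance = prov),
            class = "ngsam_read_pairs")
}

## per-position substitution errors on equal-width reads (character
## vector); sparse per-position sampling keeps this linear in the number
## of realized errors
apply_read_errors <- function(reads, rates) {
  n <- length(reads)
  if (n == 0L || all(rates == 0)) return(reads)
  for (p in seq_along(rates)) {
    n_err <- rbinom(1L, n, rates[p])
    if (n_err == 0L) next
    rows <- sample.int(n, n_err)
    s <- reads[rows]
    orig <- match(substr(s, p, p), DNA_BASES)
    subs <- DNA_BASES[((orig - 1L + sample.int(3L, n_err, replace = TRUE)) %% 4L) + 1L]
    substr(s, p, p) <- subs
    reads[rows] <- s
  }
  reads
}

#' @export
print.ngsam_read_pairs <- function(x, ...) {
  cat(sprintf("<ngsam_read_pairs> %d pairs of %d-bp reads from %d mutants\n",
              length(x$read1), x$read_length,
              length(unique(x$provenance$mutant))))
  invisible(x)
}

#' Write read pairs as paired FASTQ
#'
#' Standard 4-line records, Phred+33 qualities, mate files synchronized by
#' record index.
#'
#' @param pairs an `ngsam_read_pairs`.
#' @param path1,path2 output FASTQ paths for read 1 and read 2.
#' @return invisibly, the two paths.
#' @export
write_fastq <- function(pairs, path1, path2) {
  write_one <- function(reads, quals, path) {
    q <- Biostrings::PhredQuality(quals)
    x <- Biostrings::QualityScaledDNAStringSet(reads, q)
    tryCatch(
      Biostrings::writeQualityScaledXStringSet(x, path),
      error = function(e) stop(sprintf("failed writing FASTQ '%s': %s",
                                       path, conditionMessage(e)),
                               call. = FALSE))
  }
  write_one(pairs$read1, pairs$qual1, path1)
  write_one(pairs$read2, pairs$qual2, path2)
  invisible(c(path1, path2))
}

#' Write the read provenance table as TSV
#'
#' @param pairs an `ngsam_read_pairs`.
#' @param path output path.
#' @export
write_provenance <- function(pairs, path) {
  utils::write.table(pairs$provenance, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
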