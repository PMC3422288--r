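## shared nucleotide scoring for all alignment steps (orientation, MSA
## seeding, evaluation): match +5 / mismatch -4, affine gaps
ngsam_submat <- function() {
  Biostrings::nucleotideSubstitutionMatrix(match = 5, mismatch = -4,
                                           baseOnly = TRUE)
}

#' Alignment parameters
#'
#' Scoring used by contig orientation and consensus evaluation: match +5,
#' mismatch -4, affine gap penalties.  `min_score` is the local-alignment
#' score a contig must reach against the reference to be considered
#' related at all; the default is the score of a 50-bp perfect match,
#' which random sequence essentially never reaches.
#'
#' @param gap_opening,gap_extension affine gap penalties (positive costs).
#' @param min_score orientation/evaluation acceptance threshold.
#' @return list of class `ngsam_align_params`.
#' @export
align_params <- function(gap_opening = 10, gap_extension = 4,
                         min_score = 50 * 5) {
  structure(list(gap_opening = gap_opening, gap_extension = gap_extension,
                 min_score = min_score),
            class = "ngsam_align_params")
}

local_align <- function(a, b, ap) {
  Biostrings::pairwiseAlignment(a, b, type = "local",
                                substitutionMatrix = ngsam_submat(),
                                gapOpening = ap$gap_opening,
                                gapExtension = ap$gap_extension)
}

#' Orient contigs against the longest contig
#'
#' Aligns every contig locally to the longest one in both orientations and
#' expresses it on the longest contig's strand.  A contig whose better
#' orientation does not reach `min_score` cannot be placed on either
#' strand; since every contig is supposed to be a mutated copy of the same
#' target, that is treated as a failed experiment (the historical dominant
#' failure mode), not as a droppable contig.
#'
#' @param contigs an `ngsam_contigs` or named character vector.
#' @param ap an [align_params()].
#' @return object of class `ngsam_oriented`: list with `contigs` (character,
#'   all on the longest contig's strand), `flipped` (logical) and `score`
#'   (alignment score against the longest; `NA` for the longest itself).
#' @section Failure: signals `ngsam_strandedness_failure` if any contig
#'   fails both orientations.
#' @export
orient_contigs <- function(contigs, ap = align_params()) {
  seqs <- if (inherits(contigs, "ngsam_contigs")) contigs$contigs else contigs
  if (length(seqs) == 0L) stop("no contigs to orient", call. = FALSE)
  if (is.null(names(seqs))) names(seqs) <- paste0("contig", seq_along(seqs))
  ref_i <- which.max(nchar(seqs))
  ref <- seqs[[ref_i]]
  flipped <- rep(FALSE, length(seqs))
  score <- rep(NA_real_, length(seqs))
  for (i in seq_along(seqs)) {
    if (i == ref_i) next
    fwd <- Biostrings::score(local_align(ref, seqs[[i]], ap))
    rev <- Biostrings::score(local_align(ref, revcomp(seqs[[i]]), ap))
    best <- max(fwd, rev)
    if (best < ap$min_score) {
      strandedness_failure(sprintf(
        "contig '%s' could not be oriented (best score %.0f < %.0f)",
        names(seqs)[i], best, ap$min_score))
    }
    if (rev > fwd) {
      seqs[[i]] <- revcomp(seqs[[i]])
      flipped[i] <- TRUE
    }
    score[i] <- best
  }
  structure(list(contigs = seqs, flipped = flipped, score = score,
                 reference = names(seqs)[ref_i]),
            class = "ngsam_oriented")
}

#' Multiple alignment of oriented contigs
#'
#' The builtin backend is a center-star progressive alignment seeded on the
#' longest contig: every other contig is aligned pairwise to the center
#' with free end gaps, and the pairwise alignments are merged
#' column-by-column under the usual "once a gap, always a gap" rule (each
#' inter-column junction of the center receives the maximum number of
#' insertion columns required by any contig).  This is entirely adequate
#' for rows that are all mutated copies of one template.  A `"mafft"`
#' backend shells out to MAFFT when it is available for cross-checking.
#'
#' @param oriented an `ngsam_oriented` (or named character vector already
#'   on one strand).
#' @param backend `"builtin"` or `"mafft"`.
#' @param ap an [align_params()] (builtin backend).
#' @return object of class `ngsam_msa`: list with `rows` (equal-length
#'   gapped character vector, names preserved) and `backend`.  Degapping
#'   any row recovers the corresponding input contig.
#' @export
msa <- function(oriented, backend = c("builtin", "mafft"),
                ap = align_params()) {
  backend <- match.arg(backend)
  seqs <- if (inherits(oriented, "ngsam_oriented")) oriented$contigs
          else oriented
  if (length(seqs) == 0L) stop("no contigs to align", call. = FALSE)
  if (is.null(names(seqs))) names(seqs) <- paste0("contig", seq_along(seqs))
  if (length(seqs) == 1L) {
    return(structure(list(rows = seqs, backend = backend),
                     class = "ngsam_msa"))
  }
  if (backend == "mafft") {
    return(msa_mafft(seqs))
  }
  msa_center_star(seqs, ap)
}

msa_center_star <- function(seqs, ap) {
  center_i <- which.max(nchar(seqs))
  center <- seqs[[center_i]]
  L <- nchar(center)
  others <- setdiff(seq_along(seqs), center_i)

  ## per contig: subject chars at each center position (NA outside the
  ## aligned span, "-" at deletions) and insertions at each junction
  pos_char <- list()
  ins_chars <- list()
  ins_len <- matrix(0L, nrow = length(seqs), ncol = L + 1L)
  for (i in others) {
    al <- Biostrings::pairwiseAlignment(
      center, seqs[[i]], type = "overlap",
      substitutionMatrix = ngsam_submat(),
      gapOpening = ap$gap_opening, gapExtension = ap$gap_extension)
    p <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1L]]
    s <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1L]]
    pstart <- Biostrings::start(Biostrings::pattern(al))
    pend <- Biostrings::end(Biostrings::pattern(al))
    sstart <- Biostrings::start(Biostrings::subject(al))
    send <- Biostrings::end(Biostrings::subject(al))
    chars <- rep(NA_character_, L)
    inserts <- vector("list", L + 1L)
    ## subject ends hanging past the aligned span become insertions at the
    ## nearest junction, so degapping a row always recovers the contig
    if (sstart > 1L) {
      inserts[[pstart]] <- strsplit(substring(seqs[[i]], 1L, sstart - 1L),
                                    "")[[1L]]
    }
    if (send < nchar(seqs[[i]])) {
      inserts[[pend + 1L]] <- strsplit(
        substring(seqs[[i]], send + 1L, nchar(seqs[[i]])), "")[[1L]]
    }
    cpos <- pstart - 1L          # center position just consumed
    for (j in seq_along(p)) {
      if (p[j] == "-") {
        inserts[[cpos + 1L]] <- c(inserts[[cpos + 1L]], s[j])
      } else {
        cpos <- cpos + 1L
        chars[cpos] <- s[j]
      }
    }
    pos_char[[as.character(i)]] <- chars
    ins_chars[[as.character(i)]] <- inserts
    ins_len[i, ] <- vapply(inserts, length, integer(1))
  }
  master_ins <- apply(ins_len, 2L, max)

  build_row <- function(chars, inserts) {
    parts <- character(2L * L + 1L)
    for (j in 0:L) {
      gap_here <- master_ins[j + 1L]
      if (gap_here > 0L) {
        ins <- if (is.null(inserts)) character(0) else inserts[[j + 1L]]
        parts[2L * j + 1L] <- paste0(
          paste(ins, collapse = ""),
          strrep("-", gap_here - length(ins)))
      }
      if (j < L) {
        ch <- if (is.null(chars)) substr(center, j + 1L, j + 1L)
              else if (is.na(chars[j + 1L])) "-" else chars[j + 1L]
        parts[2L * j + 2L] <- ch
      }
    }
    paste(parts, collapse = "")
  }

  rows <- character(length(seqs))
  rows[center_i] <- build_row(NULL, NULL)
  for (i in others) {
    rows[i] <- build_row(pos_char[[as.character(i)]],
                         ins_chars[[as.character(i)]])
  }
  names(rows) <- names(seqs)
  structure(list(rows = rows, backend = "builtin"), class = "ngsam_msa")
}

msa_mafft <- function(seqs) {
  mafft <- Sys.which("mafft")
  if (mafft == "") {
    stop("mafft backend requested but mafft not found on PATH",
         call. = FALSE)
  }
  inp <- tempfile(fileext = ".fa")
  out <- tempfile(fileext = ".fa")
  on.exit(unlink(c(inp, out)))
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, inp)
  system2(mafft, c("--retree", "1", "--quiet", inp), stdout = out)
  aln <- Biostrings::readDNAStringSet(out)
  rows <- toupper(as.character(aln))[names(seqs)]
  structure(list(rows = rows, backend = "mafft"), class = "ngsam_msa")
}

#' @export
print.ngsam_msa <- function(x, ...) {
  cat(sprintf("<ngsam_msa> %d rows x %d columns (%s)\n",
              length(x$rows), nchar(x$rows[1L]), x$backend))
  invisible(x)
}

#' Majority-vote consensus of a multiple alignment
#'
#' Per column, the most frequent symbol among A, C, G, T and gap wins;
#' columns won by the gap are removed from the output.  Ties are broken
#' deterministically by the fixed order A < C < G < T < gap, and tied
#' columns are reported in the `"ties"` attribute so runs can log them.
#'
#' @param alignment an `ngsam_msa` (or gapped character vector of equal
#'   lengths).
#' @return consensus DNA string (attribute `"ties"`: 1-based alignment
#'   columns whose vote was tied).
#' @export
majority_consensus <- function(alignment) {
  rows <- if (inherits(alignment, "ngsam_msa")) alignment$rows else alignment
  stopifnot(length(rows) >= 1L, length(unique(nchar(rows))) == 1L)
  m <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  symbols <- c(DNA_BASES, "-")
  counts <- vapply(symbols, function(s) colSums(m == s),
                   numeric(ncol(m)))
  if (ncol(m) == 1L) counts <- matrix(counts, nrow = 1L)
  win <- apply(counts, 1L, which.max)       # first max = fixed tie order
  tie <- vapply(seq_len(nrow(counts)), function(j) {
    sum(counts[j, ] == counts[j, win[j]]) > 1L
  }, logical(1))
  keep <- win != 5L
  out <- paste(symbols[win[keep]], collapse = "")
  attr(out, "ties") <- which(tie)
  out
}

#' Write a multiple alignment as aligned FASTA
#'
#' @param alignment an `ngsam_msa`.
#' @param path output path.
#' @export
write_msa <- function(alignment, path) {
  x <- Biostrings::BStringSet(alignment$rows)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
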