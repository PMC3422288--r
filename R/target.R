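#' Repetitive target sequences
#'
#' A target is a perfectly (or near-perfectly) repetitive DNA region built by
#' concatenating `unit_count` copies of a single repeat unit, with no linker
#' sequence between units.  Identical (or near-identical) repeat units are
#' what makes such regions impossible to assemble from short reads directly,
#' and are therefore the ground truth against which reconstructions are
#' scored.
#'
#' All coordinates are 0-based and half-open: unit `i` occupies
#' `[boundaries$start[i], boundaries$end[i])` of the sequence.
#'
#' @param unit_length length of the repeat unit in bp (>= 1).
#' @param unit_count number of concatenated copies (>= 1).
#' @return An object of class `ngsam_target`: a list with elements
#'   `sequence` (character scalar over \{A,C,G,T\}), `unit_boundaries`
#'   (data.frame with 0-based half-open `start`, `end`), `tracking`
#'   (data.frame with 0-based `unit` index and `offset` within the unit;
#'   zero rows if no tracking mutations), `unit_length`, `unit_count` and
#'   `mode` (`"random_units"` or `"tandem_unit"`).
#'
#' @details `generate_random_target()` draws ONE uniform random unit and
#' copies it `unit_count` times, so all units are byte-identical; this is the
#' repeat structure that defeats ordinary short-read assembly.
#' `generate_tandem_target()` instead concatenates copies of a user-supplied
#' unit (for example a duplicated gene) and can place a single "tracking"
#' substitution at an independent random position in every copy; tracking
#' mutations are ignored by the reconstruction machinery and exist only so
#' that unit order and orientation can be audited afterwards.
#'
#' Both generators consume the session RNG; call [set.seed()] (or use the
#' grid drivers, which derive per-replicate seeds) for reproducibility.
#'
#' @examples
#' set.seed(1)
#' t1 <- generate_random_target(10, 4)
#' nchar(t1$sequence)  # 40
#' t2 <- generate_tandem_target("ACGT", 3)
#' t2$sequence         # "ACGTACGTACGT"
#' @export
generate_random_target <- function(unit_length, unit_count) {
  if (unit_length < 1 || unit_count < 1) {
    stop("unit_length and unit_count must be >= 1", call. = FALSE)
  }
  unit <- random_dna(unit_length)
  new_target(strrep(unit, unit_count), unit_length, unit_count,
             mode = "random_units",
             tracking = data.frame(unit = integer(), offset = integer()))
}

#' @rdname generate_random_target
#' @param unit_sequence character scalar, the repeat unit (over \{A,C,G,T\}).
#' @param copies number of tandem copies (>= 1).
#' @param tracking if `TRUE`, substitute one random position per copy with a
#'   different base (positions drawn independently per copy).
#' @export
generate_tandem_target <- function(unit_sequence, copies, tracking = FALSE) {
  stopifnot(is.character(unit_sequence), length(unit_sequence) == 1L)
  if (copies < 1) stop("copies must be >= 1", call. = FALSE)
  if (nchar(unit_sequence) == 0L) stop("unit_sequence is empty", call. = FALSE)
  codes <- seq_to_int(unit_sequence)  # errors on ambiguity codes
  L <- length(codes)
  track <- data.frame(unit = integer(), offset = integer())
  units <- vector("list", copies)
  for (i in seq_len(copies)) {
    u <- codes
    if (tracking) {
      pos <- sample.int(L, 1L)
      u[pos] <- sample(setdiff(1:4, u[pos]), 1L)
      track <- rbind(track, data.frame(unit = i - 1L, offset = pos - 1L))
    }
    units[[i]] <- u
  }
  new_target(paste(vapply(units, int_to_seq, character(1)), collapse = ""),
             L, copies, mode = "tandem_unit", tracking = track)
}

new_target <- function(sequence, unit_length, unit_count, mode, tracking) {
  structure(list(
    sequence = sequence,
    unit_boundaries = data.frame(
      start = (seq_len(unit_count) - 1L) * unit_length,
      end   = seq_len(unit_count) * unit_length
    ),
    tracking = tracking,
    unit_length = as.integer(unit_length),
    unit_count = as.integer(unit_count),
    mode = mode
  ), class = "ngsam_target")
}

#' @export
print.ngsam_target <- function(x, ...) {
  cat(sprintf("<ngsam_target> %d x %d bp units (%s), total %d bp, %d tracking positions\n",
              x$unit_count, x$unit_length, x$mode,
              nchar(x$sequence), nrow(x$tracking)))
  invisible(x)
}

#' Enumerate target specifications for an experiment grid
#'
#' Builds the (unit length, unit count) grid over which reconstruction
#' success is mapped.  Ranges advance from their start by their step while
#' the value stays at or below the stated maximum, and a cell enters the
#' grid only if its total length `unit_length * unit_count` does not exceed
#' `max_total_bp`.  Each retained cell is replicated `replicates` times with
#' distinct seeds (every replicate re-randomizes both the unit sequence and
#' all downstream stochastic stages).
#'
#' @param unit_lengths integer vector of unit lengths; default
#'   `seq(4, 4000, by = 5)`.
#' @param unit_counts integer vector of unit counts; default
#'   `seq(4, 100, by = 4)`.
#' @param max_total_bp retain only cells with total length at or below this
#'   bound (default 30000).
#' @param replicates targets generated per retained cell (default 5).
#' @param seed master seed from which per-replicate seeds are derived.
#' @return data.frame with columns `unit_length`, `unit_count`, `replicate`,
#'   `seed`; one row per target to simulate.
#' @export
grid_specs <- function(unit_lengths = seq(4L, 4000L, by = 5L),
                       unit_counts = seq(4L, 100L, by = 4L),
                       max_total_bp = 30000,
                       replicates = 5L,
                       seed = 1L) {
  stopifnot(length(unit_lengths) >= 1L, length(unit_counts) >= 1L,
            replicates >= 1L)
  cells <- expand.grid(unit_length = as.integer(unit_lengths),
                       unit_count = as.integer(unit_counts))
  cells <- cells[cells$unit_length * cells$unit_count <= max_total_bp, ,
                 drop = FALSE]
  n <- nrow(cells)
  if (n == 0L) {
    return(data.frame(unit_length = integer(), unit_count = integer(),
                      replicate = integer(), seed = integer()))
  }
  out <- cells[rep(seq_len(n), each = replicates), , drop = FALSE]
  out$replicate <- rep(seq_len(replicates), n)
  out$seed <- seed_split(seed, nrow(out))
  rownames(out) <- NULL
  out
}

#' Write a target and its annotation to disk
#'
#' Writes the sequence as FASTA plus a tab-separated sidecar with the
#' 0-based half-open unit boundaries and any tracking-mutation positions.
#'
#' @param target an `ngsam_target`.
#' @param fasta_path,annot_path output paths.
#' @param name FASTA record name.
#' @return invisibly, the two paths.
#' @export
write_target <- function(target, fasta_path, annot_path, name = "target") {
  seqs <- Biostrings::DNAStringSet(target$sequence)
  names(seqs) <- name
  Biostrings::writeXStringSet(seqs, fasta_path)
  b <- target$unit_boundaries
  annot <- data.frame(
    record = "unit", index = seq_len(nrow(b)) - 1L,
    start = b$start, end = b$end
  )
  if (nrow(target$tracking) > 0L) {
    tr <- target$tracking
    annot <- rbind(annot, data.frame(
      record = "tracking", index = tr$unit,
      start = target$unit_boundaries$start[tr$unit + 1L] + tr$offset,
      end = target$unit_boundaries$start[tr$unit + 1L] + tr$offset + 1L
    ))
  }
  utils::write.table(annot, annot_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(fasta_path, annot_path))
}
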