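#' Score a reconstructed consensus against its target
#'
#' Locally aligns the consensus to the target with the same affine scoring
#' used for contig orientation, in both orientations.  The reconstruction
#' is accepted as unambiguous only when the best orientation's score is at
#' least `min_score` and beats the opposite orientation by the
#' `margin` ratio; otherwise the experiment is recorded as
#' `alignment_ambiguous`.  For an accepted alignment:
#'
#' * `pct_identity` — percent of aligned columns that match (identity of
#'   the aligned portion);
#' * `pct_length` — percent of the target length spanned by the alignment;
#' * `pct_correct` — their product / 100, the percentage of correctly
#'   reconstructed bases.
#'
#' @param consensus,target character scalars.
#' @param ap an [align_params()].
#' @param margin best-to-runner-up score ratio required to call the
#'   alignment unambiguous (default 1.1).
#' @return list with `success`, `failure_stage` (`"none"` or
#'   `"alignment_ambiguous"`), `pct_identity`, `pct_length`, `pct_correct`
#'   (all `NA` on failure).
#' @export
evaluate <- function(consensus, target, ap = align_params(), margin = 1.1) {
  if (inherits(target, "ngsam_target")) target <- target$sequence
  stopifnot(nchar(consensus) > 0, nchar(target) > 0)
  fwd <- local_align(target, consensus, ap)
  rev <- local_align(target, revcomp(consensus), ap)
  s_fwd <- Biostrings::score(fwd)
  s_rev <- Biostrings::score(rev)
  best <- if (s_fwd >= s_rev) fwd else rev
  s1 <- max(s_fwd, s_rev)
  s2 <- min(s_fwd, s_rev)
  ambiguous <- s1 < ap$min_score || (s2 > 0 && s1 / s2 < margin)
  if (ambiguous) {
    return(list(success = FALSE, failure_stage = "alignment_ambiguous",
                pct_identity = NA_real_, pct_length = NA_real_,
                pct_correct = NA_real_))
  }
  n_cols <- Biostrings::nchar(best)         # aligned columns incl. gaps
  pct_id <- 100 * Biostrings::nmatch(best) / n_cols
  span <- Biostrings::end(Biostrings::pattern(best)) -
    Biostrings::start(Biostrings::pattern(best)) + 1
  pct_len <- 100 * span / nchar(target)
  list(success = TRUE, failure_stage = "none",
       pct_identity = pct_id, pct_length = pct_len,
       pct_correct = pct_id * pct_len / 100)
}

#' Run one complete simulated experiment
#'
#' Chains all stages for a single target: the mutagenesis-and-dilution
#' protocol, coverage allocation, paired-end read simulation, assembly,
#' contig orientation, multiple alignment, majority-vote consensus and
#' evaluation against the target.  Stage failures (empty sample after a
#' dilution, no surviving contig, unorientable contig, ambiguous final
#' alignment) are caught and recorded, never re-thrown.
#'
#' Each stage reseeds the RNG from a seed derived from `seed`, so a run is
#' reproducible from its master seed alone.
#'
#' @param target an `ngsam_target`.
#' @param params an [protocol_params()].
#' @param model a calibrated `ngsam_model`.
#' @param seed master seed for this experiment.
#' @param total_coverage total sequencing coverage (default 4000).
#' @param read_length read length (default 101).
#' @param frag_model an [fragment_model()].
#' @param err an [error_model()].
#' @param k,min_contig,max_divergence assembly settings (see [assemble()]).
#' @param ap an [align_params()].
#' @param margin evaluation ambiguity margin (see [evaluate()]).
#' @return one-row data.frame: `success`, `failure_stage` (`none`,
#'   `empty_sample`, `assembly`, `strandedness`, `alignment_ambiguous`),
#'   `pct_identity`, `pct_length`, `pct_correct`, `n_mutant_types` (the
#'   post-second-dilution molecule count; `NA` if that stage failed),
#'   `n_contigs`, `seed`.
#' @export
run_experiment <- function(target, params = protocol_params(),
                           model, seed,
                           total_coverage = 4000, read_length = 101L,
                           frag_model = fragment_model(),
                           err = error_model(),
                           k = 90L, min_contig = 400L, max_divergence = 0.1,
                           ap = align_params(), margin = 1.1) {
  seeds <- seed_split(seed, 4L)
  row <- data.frame(success = FALSE, failure_stage = "none",
                    pct_identity = NA_real_, pct_length = NA_real_,
                    pct_correct = NA_real_, n_mutant_types = NA_integer_,
                    n_contigs = NA_integer_, seed = seed,
                    stringsAsFactors = FALSE)
  fail <- function(stage) {
    row$failure_stage <- stage
    row
  }

  set.seed(seeds[1L])
  run <- tryCatch(run_protocol(target, params, model),
                  ngsam_protocol_failure = function(e) e)
  if (inherits(run, "ngsam_protocol_failure")) return(fail(run$stage))
  row$n_mutant_types <- as.integer(run$n_mutant_types)

  set.seed(seeds[2L])
  nf <- allocate_coverage(run$pool, total_coverage,
                          nchar(target$sequence), read_length)
  pairs <- fragment_and_sequence(run$pool, nf, frag_model, read_length, err)

  set.seed(seeds[3L])
  contigs <- tryCatch(
    assemble(pairs, k = k, min_contig = min_contig,
             max_divergence = max_divergence),
    ngsam_assembly_failure = function(e) e)
  if (inherits(contigs, "ngsam_assembly_failure")) return(fail("assembly"))
  row$n_contigs <- length(contigs$contigs)

  oriented <- tryCatch(orient_contigs(contigs, ap),
                       ngsam_strandedness_failure = function(e) e)
  if (inherits(oriented, "ngsam_strandedness_failure")) {
    return(fail("strandedness"))
  }

  set.seed(seeds[4L])
  aln <- msa(oriented, ap = ap)
  cons <- majority_consensus(aln)
  ev <- evaluate(cons, target, ap, margin)
  row$success <- ev$success
  row$failure_stage <- ev$failure_stage
  row$pct_identity <- ev$pct_identity
  row$pct_length <- ev$pct_length
  row$pct_correct <- ev$pct_correct
  row
}

#' Simulation setting 1: unit length x unit count grid
#'
#' Runs independent experiments over a grid of repetitive target
#' structures under one fixed protocol, the question being which repeat
#' structures a single tuned protocol can reconstruct.  Each grid row
#' (from [grid_specs()]) generates its own random target and runs one full
#' experiment; failures are recorded per row and never abort the grid.
#'
#' @param specs data.frame from [grid_specs()].
#' @param params an [protocol_params()].
#' @param model a calibrated `ngsam_model`.
#' @param ... further arguments passed to [run_experiment()].
#' @return data.frame with one row per experiment: the [grid_specs()]
#'   columns plus the [run_experiment()] columns.
#' @export
run_setting1 <- function(specs, params = protocol_params(), model, ...) {
  stopifnot(nrow(specs) >= 1L)
  res <- lapply(seq_len(nrow(specs)), function(i) {
    sd <- seed_split(specs$seed[i], 2L)
    set.seed(sd[1L])
    target <- generate_random_target(specs$unit_length[i],
                                     specs$unit_count[i])
    cbind(specs[i, c("unit_length", "unit_count", "replicate")],
          run_experiment(target, params, model, seed = sd[2L], ...))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Simulation setting 2: dilution-factor grid
#'
#' Probes robustness to the two dilution factors, the parameters a wetlab
#' run can least control: a fixed tandem-duplication target is run through
#' the protocol for every (d1, d2) combination, with all other parameters
#' unchanged.  The default target is three tandem copies of a random
#' 3,813-bp unit (an eater-gene-sized duplication) with one tracking
#' mutation per copy.
#'
#' @param d1_values,d2_values dilution factors to combine.
#' @param target an `ngsam_target`; `NULL` builds the default tandem
#'   target.
#' @param params baseline [protocol_params()]; its `d1`, `d2` are
#'   overridden per cell.
#' @param model a calibrated `ngsam_model`.
#' @param replicates experiments per (d1, d2) cell (default 5).
#' @param seed master seed.
#' @param ... further arguments passed to [run_experiment()].
#' @return data.frame with one row per experiment: `d1`, `d2`, `replicate`
#'   plus the [run_experiment()] columns.
#' @export
run_setting2 <- function(d1_values, d2_values, target = NULL,
                         params = protocol_params(), model,
                         replicates = 5L, seed = 1L, ...) {
  if (is.null(target)) {
    set.seed(seed_split(seed, 1L))
    unit <- random_dna(3813L)
    target <- generate_tandem_target(unit, 3L, tracking = TRUE)
  }
  cells <- expand.grid(d1 = d1_values, d2 = d2_values)
  cells <- cells[rep(seq_len(nrow(cells)), each = replicates), ]
  cells$replicate <- rep(seq_len(replicates), length.out = nrow(cells))
  cells$seed <- seed_split(seed + 1, nrow(cells))
  res <- lapply(seq_len(nrow(cells)), function(i) {
    p <- params
    p$d1 <- cells$d1[i]
    p$d2 <- cells$d2[i]
    cbind(cells[i, c("d1", "d2", "replicate")],
          run_experiment(target, p, model, seed = cells$seed[i], ...))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Summarize an experiment grid per cell
#'
#' @param results data.frame from [run_setting1()] or [run_setting2()].
#' @param by names of the cell-identifying columns (guessed when `NULL`).
#' @return data.frame with one row per cell: `n`, `pct_success`,
#'   `mean_pct_correct` (over successes), `mean_mutant_types`, and the
#'   count of each failure stage.
#' @export
summarize_grid <- function(results, by = NULL) {
  if (is.null(by)) {
    by <- intersect(c("unit_length", "unit_count", "d1", "d2"),
                    names(results))
  }
  key <- interaction(results[by], drop = TRUE)
  rows <- lapply(split(results, key), function(d) {
    cbind(d[1L, by, drop = FALSE], data.frame(
      n = nrow(d),
      pct_success = 100 * mean(d$success),
      mean_pct_correct = mean(d$pct_correct[d$success]),
      mean_mutant_types = mean(d$n_mutant_types, na.rm = TRUE),
      n_empty_sample = sum(d$failure_stage == "empty_sample"),
      n_assembly = sum(d$failure_stage == "assembly"),
      n_strandedness = sum(d$failure_stage == "strandedness"),
      n_ambiguous = sum(d$failure_stage == "alignment_ambiguous")))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write grid results or summaries as TSV
#'
#' @param results data.frame.
#' @param path output path.
#' @export
write_results <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
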