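#' Protocol parameters
#'
#' The full mutagenesis-and-dilution protocol: a mutagenic PCR of `n1`
#' cycles from `S0` template molecules, a first dilution by `d1`, a
#' mutation-free cleanup PCR of `n2` cycles, a second dilution by `d2`
#' (down to a handful of molecules), and a final PCR of `n3` cycles that
#' provides material for sequencing.  Defaults are the tuned operating
#' point of the simulation study: `S0 = 5000`, `n1 = n2 = 20`, `n3 = 30`,
#' `d1 = 70000`, `d2 = 16e6`, efficiency 0.75 shared by all three PCRs.
#'
#' @param s0 number of initial template molecules.
#' @param n1,n2,n3 cycle counts of the mutagenic, cleanup and final PCRs.
#' @param d1,d2 dilution factors (>= 1) of the two dilution steps.
#' @param efficiency per-cycle PCR efficiency shared by the three PCRs.
#' @param genealogy_sample_cap upper bound on the mutagenic-genealogy
#'   sample size (a guard: the post-dilution molecule count should be far
#'   below it; exceeding it raises an error rather than truncating).
#' @return object of class `ngsam_protocol_params`.
#' @export
protocol_params <- function(s0 = 5000, n1 = 20L, d1 = 70000,
                            n2 = 20L, d2 = 16e6, n3 = 30L,
                            efficiency = 0.75,
                            genealogy_sample_cap = 200L) {
  stopifnot(s0 >= 1, d1 >= 1, d2 >= 1, n1 >= 0, n2 >= 0, n3 >= 0,
            efficiency >= 0, efficiency <= 1, genealogy_sample_cap >= 1)
  structure(list(s0 = as.numeric(s0), n1 = as.integer(n1),
                 d1 = as.numeric(d1), n2 = as.integer(n2),
                 d2 = as.numeric(d2), n3 = as.integer(n3),
                 efficiency = efficiency,
                 genealogy_sample_cap = as.integer(genealogy_sample_cap)),
            class = "ngsam_protocol_params")
}

#' Sample a molecule count after dilution
#'
#' Dilution and sub-sampling of a well-mixed solution is Poisson: the
#' number of molecules carried over has mean `count / factor`.
#'
#' @param count molecule count before dilution (>= 0).
#' @param factor dilution factor (>= 1).  A factor of exactly 1 means the
#'   whole volume is carried over, so the count is returned unchanged.
#' @return sampled molecule count (non-negative; zero is a meaningful
#'   outcome that downstream steps treat as protocol failure).
#' @export
dilute <- function(count, factor) {
  stopifnot(count >= 0, factor >= 1)
  if (factor == 1) return(count)
  safe_rpois(count / factor)
}

#' Deterministic expected counts through the protocol
#'
#' Propagates expectations instead of simulating: `S1 = S0 (1+e)^n1`,
#' `S2 = S1/d1`, `S3 = S2 (1+e)^n2`, `S4 = S3/d2`,
#' `S5 = S4 (1+e)^n3`.  This is the approximation used to tune the
#' dilution factors towards a desired number of mutant types.
#'
#' @param params an [protocol_params()] object.
#' @return named numeric vector `S0..S5` of expected counts.
#' @export
expected_stage_counts <- function(params) {
  g <- function(n) (1 + params$efficiency)^n
  s1 <- params$s0 * g(params$n1)
  s2 <- s1 / params$d1
  s3 <- s2 * g(params$n2)
  s4 <- s3 / params$d2
  c(S0 = params$s0, S1 = s1, S2 = s2, S3 = s3, S4 = s4,
    S5 = s4 * g(params$n3))
}

#' Simulate the molecule-count chain of the protocol
#'
#' Counts-only simulation (no genealogies, no sequences): branching-process
#' PCR counts and Poisson dilutions.  Useful for studying the distribution
#' of the number of mutant types `S4` cheaply.
#'
#' @inheritParams expected_stage_counts
#' @return named numeric vector with realized `S0..S4` (`S4` is the number
#'   of molecules, i.e. mutant types, entering sequencing; it can be 0).
#' @export
simulate_stage_counts <- function(params) {
  s1 <- tail(simulate_counts(pcr_params(params$s0, params$efficiency,
                                        params$n1)), 1L)
  s2 <- dilute(s1, params$d1)
  if (s2 == 0) {
    return(c(S0 = params$s0, S1 = s1, S2 = 0, S3 = 0, S4 = 0))
  }
  s3 <- tail(simulate_counts(pcr_params(s2, params$efficiency,
                                        params$n2)), 1L)
  s4 <- dilute(s3, params$d2)
  c(S0 = params$s0, S1 = s1, S2 = s2, S3 = s3, S4 = s4)
}

#' Run the mutagenesis-and-dilution protocol on a target
#'
#' Simulates the whole molecular protocol for one target sequence and
#' returns the pool of mutant molecules entering sequencing:
#'
#' 1. mutagenic-PCR molecule counts (`S1`);
#' 2. first dilution (`S2`), Poisson;
#' 3. cleanup-PCR counts (`S3`);
#' 4. second dilution (`S4`), Poisson;
#' 5. the `S4` molecules are traced backward through the cleanup PCR (whose
#'    cycles introduce no mutations, so only the founder assignment
#'    matters) to find their distinct first-dilution ancestors;
#' 6. the mutagenic-PCR genealogy is sampled for those ancestors only and
#'    mutations are placed on its branches under the calibrated UNREST
#'    model — restricting the genealogy to the few sampled lineages is what
#'    keeps the simulation tractable;
#' 7. each of the `S4` molecules is amplified through an independent final
#'    PCR branching process to obtain its descendant count, which later
#'    sets its share of sequencing coverage.
#'
#' Molecules sampled after the second dilution that share a first-dilution
#' ancestor are identical by descent and form a single mutant type entry
#' with multiplicity > 1.
#'
#' @param target an `ngsam_target` (or a plain character sequence).
#' @param params an [protocol_params()] object.
#' @param model a calibrated `ngsam_model`.
#' @return list of class `ngsam_protocol_run` with elements `pool` (a
#'   data.frame with `sequence`, `founder` — the first-dilution ancestor id
#'   — `multiplicity` and `weight`, the final-PCR descendant count summed
#'   over the type's molecules), `counts` (named vector `S0..S5`),
#'   `n_mutant_types` (`S4`) and `genealogy` (the mutagenic-PCR genealogy).
#' @section Failure: signals a classed error (`ngsam_protocol_failure`,
#'   stage `"empty_sample"`) when either dilution leaves zero molecules.
#' @export
run_protocol <- function(target, params, model) {
  template <- if (inherits(target, "ngsam_target")) target$sequence else target
  stopifnot(is.character(template), nchar(template) > 0)

  par1 <- pcr_params(params$s0, params$efficiency, params$n1)
  traj1 <- simulate_counts(par1)
  s1 <- tail(traj1, 1L)

  s2 <- dilute(s1, params$d1)
  if (s2 == 0) protocol_failure("empty_sample")

  par2 <- pcr_params(s2, params$efficiency, params$n2)
  traj2 <- simulate_counts(par2)
  s3 <- tail(traj2, 1L)

  s4 <- dilute(s3, params$d2)
  if (s4 == 0) protocol_failure("empty_sample")
  if (s4 > params$genealogy_sample_cap) {
    ngsam_error("ngsam_config_error", sprintf(
      "post-dilution sample (%.0f) exceeds genealogy_sample_cap (%d); raise the cap",
      s4, params$genealogy_sample_cap))
  }

  ## backward through the mutation-free cleanup PCR: only the founder
  ## (first-dilution ancestor) of each sampled molecule matters
  g2 <- sample_genealogy(par2, s4, traj2)
  anc <- g2$leaf_founder
  distinct_anc <- unique(anc)
  m <- length(distinct_anc)

  ## mutagenic genealogy restricted to the surviving ancestors
  g1 <- sample_genealogy(par1, m, traj1)
  anc_seq <- mutate_pool(g1, template, model)  # one sequence per ancestor

  ## final PCR per sampled molecule: descendant counts -> coverage weights
  w <- vapply(seq_len(s4), function(i) {
    tail(simulate_counts(pcr_params(1, params$efficiency, params$n3)), 1L)
  }, numeric(1))

  type_of <- match(anc, distinct_anc)
  pool <- data.frame(
    sequence = unname(anc_seq[seq_len(m)]),
    founder = distinct_anc,
    multiplicity = as.integer(tabulate(type_of, m)),
    weight = as.numeric(tapply(w, factor(type_of, levels = seq_len(m)), sum)),
    stringsAsFactors = FALSE
  )
  counts <- c(S0 = params$s0, S1 = s1, S2 = s2, S3 = s3, S4 = s4,
              S5 = sum(w))
  structure(list(pool = pool, counts = counts, n_mutant_types = s4,
                 genealogy = g1),
            class = "ngsam_protocol_run")
}

#' @export
print.ngsam_protocol_run <- function(x, ...) {
  cat(sprintf("<ngsam_protocol_run> %d molecules after second dilution, %d distinct lineages\n",
              x$n_mutant_types, nrow(x$pool)))
  print(x$counts)
  invisible(x)
}

#' Write realized stage counts as JSON
#'
#' @param run an `ngsam_protocol_run` (or a named `S0..S4` vector).
#' @param path output path.
#' @export
write_stage_counts <- function(run, path) {
  counts <- if (inherits(run, "ngsam_protocol_run")) run$counts else run
  jsonlite::write_json(as.list(counts), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
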