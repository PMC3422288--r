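#' Mutation spectrum of the error-prone PCR
#'
#' A spectrum is a set of 12 non-negative relative weights, one per ordered
#' substitution X->Y (X != Y over A,C,G,T).  Only the ratios matter; the
#' overall mutation intensity is set separately by the branch-length scaling
#' factor (see [calibrate_scaling()]).
#'
#' `default_spectrum()` ships a transition-biased approximation to the
#' spectrum of mutagenic base-analogue PCR: nucleoside analogues such as
#' dPTP predominantly induce A:T->G:C and G:C->A:T transitions, with
#' 8-oxo-dGTP contributing G:C->T:A transversions.  It is a synthetic
#' stand-in with the qualitative shape of published error-prone PCR
#' spectra, not a transcription of any measured data set; supply your own
#' weights to match a particular protocol.
#'
#' @param weights named numeric vector; names are `"X>Y"` pairs such as
#'   `"A>G"`.  Missing pairs default to 0.  At least one weight must be
#'   positive.
#' @return named numeric vector of length 12 (class `ngsam_spectrum`).
#' @export
mutation_spectrum <- function(weights) {
  pairs <- spectrum_pairs()
  w <- setNames(numeric(12L), pairs)
  if (is.null(names(weights)) || !all(names(weights) %in% pairs)) {
    stop("weights must be named with ordered pairs like 'A>G'", call. = FALSE)
  }
  w[names(weights)] <- weights
  if (any(w < 0) || all(w == 0)) {
    stop("spectrum weights must be non-negative with at least one positive",
         call. = FALSE)
  }
  structure(w, class = "ngsam_spectrum")
}

spectrum_pairs <- function() {
  g <- expand.grid(to = DNA_BASES, from = DNA_BASES)
  g <- g[g$from != g$to, ]
  paste0(g$from, ">", g$to)
}

#' @rdname mutation_spectrum
#' @export
default_spectrum <- function() {
  mutation_spectrum(c(
    "A>G" = 0.28, "T>C" = 0.28,   # dPTP-type transitions
    "G>A" = 0.12, "C>T" = 0.12,
    "G>T" = 0.05, "C>A" = 0.05,   # 8-oxo-dG-type transversions
    "A>C" = 0.02, "T>G" = 0.02,
    "A>T" = 0.02, "T>A" = 0.02,
    "G>C" = 0.01, "C>G" = 0.01
  ))
}

#' Build a general non-reversible (UNREST) substitution model
#'
#' Constructs the 4x4 rate matrix Q whose off-diagonal entries are
#' proportional to the spectrum weights, with diagonals set so rows sum to
#' zero.  No reversibility or symmetry is imposed: an error-prone PCR
#' spectrum has no reason to satisfy detailed balance, which is why the
#' fully general model is used.  Q is normalized so that the mean
#' substitution rate from a uniform base composition is 1 per unit time;
#' branch "time" is the replication count multiplied by the scaling factor
#' `beta`, so after calibration `beta` is approximately the expected number
#' of substitutions per site per replication.
#'
#' @param spectrum an [mutation_spectrum()] (default [default_spectrum()]).
#' @param beta initial branch-length scaling factor (default 1; see
#'   [calibrate_scaling()]).
#' @return An object of class `ngsam_model`: list with `Q` (4x4, rows/cols
#'   A,C,G,T), `beta` and `spectrum`.
#' @export
build_unrest <- function(spectrum = default_spectrum(), beta = 1) {
  if (!inherits(spectrum, "ngsam_spectrum")) {
    spectrum <- mutation_spectrum(spectrum)
  }
  Q <- matrix(0, 4L, 4L, dimnames = list(DNA_BASES, DNA_BASES))
  for (p in names(spectrum)) {
    ft <- strsplit(p, ">", fixed = TRUE)[[1L]]
    Q[ft[1L], ft[2L]] <- spectrum[[p]]
  }
  diag(Q) <- -rowSums(Q)
  Q <- Q / mean(-diag(Q))  # mean rate 1 at uniform composition
  structure(list(Q = Q, beta = as.numeric(beta), spectrum = spectrum),
            class = "ngsam_model")
}

#' @export
print.ngsam_model <- function(x, ...) {
  cat(sprintf("<ngsam_model> UNREST, beta = %.6g\n", x$beta))
  print(round(x$Q, 4))
  invisible(x)
}

#' Transition probabilities over a branch
#'
#' `P(t) = expm(t * beta * Q)`, the per-site substitution probabilities
#' after `t` replication events under the scaled model.
#'
#' @param model an `ngsam_model`.
#' @param t branch length in replication events (>= 0).
#' @return 4x4 row-stochastic matrix.
#' @export
transition_matrix <- function(model, t) {
  stopifnot(t >= 0)
  P <- as.matrix(Matrix::expm(t * model$beta * model$Q))
  P[P < 0] <- 0
  P / rowSums(P)
}

#' Mutate a sequence along a genealogy branch
#'
#' Evolves every site independently under the scaled UNREST process for a
#' branch of `replication_count` replication events, by exact sampling from
#' the transition matrix `expm(replication_count * beta * Q)`.
#'
#' @param sequence character scalar over \{A,C,G,T\}.
#' @param replication_count integer branch length (>= 0).
#' @param model an `ngsam_model`.
#' @return mutated sequence (character scalar, same length).
#' @export
simulate_branch_mutations <- function(sequence, replication_count, model) {
  if (replication_count < 0) {
    stop("replication_count must be >= 0", call. = FALSE)
  }
  if (replication_count == 0 || model$beta == 0) return(sequence)
  codes <- seq_to_int(sequence)
  P <- transition_matrix(model, replication_count)
  out <- codes
  for (b in 1:4) {
    idx <- which(codes == b)
    if (length(idx)) {
      out[idx] <- sample.int(4L, length(idx), replace = TRUE, prob = P[b, ])
    }
  }
  int_to_seq(out)
}

#' Calibrate the branch-length scaling factor
#'
#' Chooses `beta` so that molecules sampled from a simulated mutagenic PCR
#' of `n_cycles` cycles carry, on average, `target_fraction` mutated sites.
#' The genealogy part is Monte Carlo: several mutagenic-PCR genealogies are
#' simulated and the root-to-leaf replication counts collected.  Given
#' those depths the expected mutated-site fraction is available in closed
#' form, `f(beta) = mean_d (1 - sum_b w_b P_bb(d * beta))` with `w` the
#' template base composition, and `f` is continuous and increasing in
#' `beta`, so `beta` is found by monotone bisection.  The procedure assumes
#' the cleanup PCR introduces no mutations, so the calibrated load is
#' entirely attributed to the mutagenic cycles.
#'
#' @param model an `ngsam_model` (its `beta` is ignored and replaced).
#' @param target_fraction desired mean fraction of mutated sites (default
#'   0.05, the reported load after 10 mutagenic cycles).
#' @param n_cycles mutagenic cycles used for calibration (default 10).
#' @param efficiency per-cycle PCR efficiency (default 0.75).
#' @param n_start template molecules in the calibration PCR (default 5000).
#' @param sample_size molecules sampled per simulated genealogy (default
#'   100).
#' @param n_genealogies genealogies simulated to estimate the depth
#'   distribution (default 20).
#' @param template character scalar used for the base composition weights;
#'   `NULL` means uniform composition (the calibration template of the
#'   original protocol is not published, so composition is configurable).
#' @param tolerance bisection tolerance on the mutated-site fraction
#'   (default 1e-5).
#' @return the model with `beta` set; attribute `"calibration"` records the
#'   achieved fraction and the depth sample size.
#' @export
calibrate_scaling <- function(model,
                              target_fraction = 0.05,
                              n_cycles = 10L,
                              efficiency = 0.75,
                              n_start = 5000,
                              sample_size = 100L,
                              n_genealogies = 20L,
                              template = NULL,
                              tolerance = 1e-5) {
  stopifnot(target_fraction > 0, target_fraction < 1, n_cycles >= 1)
  par <- pcr_params(n_start, efficiency, n_cycles)
  depths <- unlist(lapply(seq_len(n_genealogies), function(i) {
    leaf_depths(sample_genealogy(par, sample_size))
  }))
  w <- if (is.null(template)) {
    rep(0.25, 4)
  } else {
    tabulate(seq_to_int(template), 4L) / nchar(template)
  }
  ## expected mutated-site fraction at scaling beta, averaged over depths
  f <- function(beta) {
    m <- build_unrest(model$spectrum, beta = beta)
    ut <- sort(unique(depths))
    frac <- vapply(ut, function(d) {
      1 - sum(w * diag(transition_matrix(m, d)))
    }, numeric(1))
    mean(frac[match(depths, ut)])
  }
  lo <- 0
  hi <- 0.1
  while (f(hi) < target_fraction) {
    hi <- hi * 2
    if (hi > 1e3) {
      ngsam_error("ngsam_calibration_error",
                  "could not bracket target_fraction; check the spectrum")
    }
  }
  while (hi - lo > tolerance * max(1, hi)) {
    mid <- (lo + hi) / 2
    if (f(mid) < target_fraction) lo <- mid else hi <- mid
  }
  beta <- (lo + hi) / 2
  out <- build_unrest(model$spectrum, beta = beta)
  attr(out, "calibration") <- list(
    target_fraction = target_fraction,
    achieved_fraction = f(beta),
    n_cycles = n_cycles,
    n_depths = length(depths)
  )
  out
}

#' Mutate a pool of molecules along their genealogy
#'
#' Applies [simulate_branch_mutations()] along every branch of a sampled
#' genealogy, starting from the unmutated template at each founder.
#' Mutations on shared branches are inherited by all descendant leaves
#' (identity by descent), which is exactly the relatedness the coalescent
#' genealogy is there to capture.
#'
#' @param genealogy an `ngsam_genealogy`.
#' @param template character scalar, the unmutated molecule.
#' @param model an `ngsam_model`.
#' @return character vector of mutated sequences, one per genealogy leaf
#'   (in leaf order), with the per-leaf founder ids as names.
#' @export
mutate_pool <- function(genealogy, template, model) {
  g <- genealogy
  n <- length(g$parent)
  children <- split(seq_len(n), g$parent)
  seqs <- character(n)
  ## preorder from each root
  for (r in g$roots) {
    stack <- r
    seqs[r] <- simulate_branch_mutations(template, g$brlen[r], model)
    while (length(stack)) {
      v <- stack[[1L]]
      stack <- stack[-1L]
      kids <- children[[as.character(v)]]
      for (u in kids) {
        seqs[u] <- simulate_branch_mutations(seqs[v], g$brlen[u], model)
        stack <- c(stack, u)
      }
    }
  }
  setNames(seqs[g$leaves], g$leaf_founder)
}

#' Read and write mutation spectra as JSON config files
#'
#' The on-disk form is a flat JSON object mapping ordered pairs (`"A>G"`)
#' to relative weights, so protocol-specific spectra can be shipped
#' alongside run configs.
#'
#' @param spectrum an [mutation_spectrum()].
#' @param path file path.
#' @return `write_spectrum()` returns the path invisibly;
#'   `read_spectrum()` returns an `ngsam_spectrum`.
#' @export
write_spectrum <- function(spectrum, path) {
  jsonlite::write_json(as.list(unclass(spectrum)), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_spectrum
#' @export
read_spectrum <- function(path) {
  mutation_spectrum(unlist(jsonlite::read_json(path, simplifyVector = TRUE)))
}

#' Dump a model's rate matrix as TSV
#'
#' @param model an `ngsam_model`.
#' @param path output path.
#' @export
write_model <- function(model, path) {
  utils::write.table(cbind(data.frame(from = rownames(model$Q)), model$Q),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
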