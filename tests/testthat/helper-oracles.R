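## Brute-force forward PCR simulation tracking every parent-child link.
## Only usable for tiny instances; serves as the distributional oracle for
## the backward coalescent sampler.
forward_pcr_sample <- function(s0, lambda, n_cycles, sample_size) {
  parent <- rep(NA_integer_, s0)
  n <- s0
  for (cycle in seq_len(n_cycles)) {
    dup <- which(runif(n) < lambda)
    if (length(dup)) {
      parent <- c(parent, dup)
      n <- n + length(dup)
    }
  }
  if (sample_size > n) return(NULL)  # infeasible this rep
  sampled <- sample.int(n, sample_size)
  chains <- lapply(sampled, function(x) {
    ch <- integer(0)
    while (!is.na(parent[x])) {
      ch <- c(ch, x)
      x <- parent[x]
    }
    attr(ch, "founder") <- x
    ch
  })
  list(
    n_founders = length(unique(vapply(chains, attr, 0L, "founder"))),
    depths = lengths(chains),
    ## every product molecule on the union of lineage paths is one
    ## replication event of the sample's genealogy
    total_events = length(unique(unlist(chains)))
  )
}

## summary statistics of the backward sampler on the same instance
backward_pcr_sample <- function(s0, lambda, n_cycles, sample_size) {
  par <- pcr_params(s0, lambda, n_cycles)
  traj <- simulate_counts(par)
  if (sample_size > tail(as.numeric(traj), 1)) return(NULL)
  g <- sample_genealogy(par, sample_size, traj)
  list(
    n_founders = length(g$roots),
    depths = ngsam:::leaf_depths(g),
    total_events = sum(g$brlen)
  )
}

## calibrated model shared across tests (calibration is itself under test
## elsewhere; here it is just a fixture)
calibrate_quiet <- local({
  cached <- NULL
  function() {
    if (is.null(cached)) {
      set.seed(424242)
      cached <<- calibrate_scaling(build_unrest())
    }
    cached
  }
})

## deterministic tiny genealogy builder for hand-checked mutagenesis tests:
## a single tree ((leaf1, leaf2) internal) with given branch lengths
hand_genealogy <- function(brlen_leaf1, brlen_leaf2, brlen_root,
                           founder = 1) {
  structure(list(
    parent = c(3L, 3L, NA_integer_),
    brlen = as.integer(c(brlen_leaf1, brlen_leaf2, brlen_root)),
    leaves = 1:2,
    roots = 3L,
    founder = rep(founder, 3),
    leaf_founder = rep(founder, 2),
    n_start = 1,
    n_cycles = max(brlen_leaf1, brlen_leaf2) + brlen_root,
    trajectory = NULL
  ), class = "ngsam_genealogy")
}

## fraction of differing sites between equal-length sequences
site_diff <- function(a, b) {
  mean(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

## error-free reads tiling a sequence at a fixed step, both strands
tiling_reads <- function(seq, read_length = 101, step = 7) {
  L <- nchar(seq)
  starts <- seq(1, L - read_length + 1, by = step)
  fwd <- substring(seq, starts, starts + read_length - 1)
  c(fwd, revcomp(fwd))
}

## cheap pool data.frame for read-simulation tests
toy_pool <- function(seqs, weights = rep(1, length(seqs))) {
  data.frame(sequence = seqs, founder = seq_along(seqs),
             multiplicity = 1L, weight = weights,
             stringsAsFactors = FALSE)
}
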