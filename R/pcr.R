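#' PCR parameters
#'
#' Describes one PCR: the number of template molecules at cycle 0, the
#' per-cycle efficiency (the probability that any given molecule is
#' duplicated during a cycle, so the expected growth factor per cycle is
#' `1 + efficiency`) and the number of cycles.  Efficiency may be given as a
#' scalar (shared by all cycles, the usual case) or as a per-cycle vector.
#'
#' @param n_start number of starting molecules (>= 1).
#' @param efficiency per-cycle duplication probability in `[0, 1]`; scalar
#'   or vector of length `n_cycles`.  Default 0.75, a typical empirical
#'   estimate for efficient PCR.
#' @param n_cycles number of cycles (>= 0).
#' @return An object of class `ngsam_pcr_params`.
#' @export
pcr_params <- function(n_start, efficiency = 0.75, n_cycles) {
  stopifnot(n_start >= 1, n_cycles >= 0,
            all(efficiency >= 0), all(efficiency <= 1))
  if (length(efficiency) == 1L) {
    efficiency <- rep(efficiency, n_cycles)
  }
  if (length(efficiency) != n_cycles) {
    stop("efficiency must be scalar or of length n_cycles", call. = FALSE)
  }
  structure(list(n_start = as.numeric(n_start),
                 efficiency = as.numeric(efficiency),
                 n_cycles = as.integer(n_cycles)),
            class = "ngsam_pcr_params")
}

#' Simulate a PCR molecule-count trajectory
#'
#' The molecule count follows a discrete branching process: during cycle
#' `i`, each of the `N[i-1]` molecules is duplicated independently with the
#' cycle's efficiency, so `N[i] = N[i-1] + Binomial(N[i-1], efficiency[i])`.
#'
#' @param params an [pcr_params()] object.
#' @return numeric vector `N[0..n_cycles]` of molecule counts per cycle
#'   (class `ngsam_trajectory`).
#' @examples
#' set.seed(1)
#' simulate_counts(pcr_params(5, 1, 3))  # 5 10 20 40
#' @export
simulate_counts <- function(params) {
  stopifnot(inherits(params, "ngsam_pcr_params"))
  counts <- numeric(params$n_cycles + 1L)
  counts[1L] <- params$n_start
  for (i in seq_len(params$n_cycles)) {
    counts[i + 1L] <- counts[i] + safe_rbinom(counts[i], params$efficiency[i])
  }
  structure(counts, class = "ngsam_trajectory")
}

#' Expected molecule count after amplification
#'
#' Deterministic branching-process expectation
#' `n_start * prod(1 + efficiency)`, i.e. `n_start * (1 + lambda)^n` for
#' constant efficiency `lambda`.  This is the quantity used to tune dilution
#' factors without simulating.
#'
#' @inheritParams simulate_counts
#' @return expected final molecule count (numeric scalar).
#' @export
expected_final_count <- function(params) {
  stopifnot(inherits(params, "ngsam_pcr_params"))
  params$n_start * prod(1 + params$efficiency)
}

#' Sample the coalescent genealogy of molecules from a PCR pool
#'
#' Draws the shared ancestry of `sample_size` molecules taken from the final
#' pool of a PCR, conditional on the per-cycle molecule counts, using a
#' backward (coalescent) pass instead of tracking every replication.  Going
#' from the last cycle towards the first, each sampled lineage is a product
#' of the current cycle with probability `(N[i] - N[i-1]) / N[i]` (drawn
#' jointly without replacement, i.e. hypergeometrically across lineages);
#' each product accrues one replication event on its branch and descends
#' from a template chosen uniformly among the previous cycle's molecules,
#' with distinct templates across the cycle's products because a molecule is
#' duplicated at most once per cycle.  When a product's template is another
#' tracked lineage the two coalesce.  Lineages surviving to cycle 0 are
#' assigned distinct founder molecules.
#'
#' Branch lengths count replication events, which is the clock on which
#' PCR-induced mutations accrue.
#'
#' @inheritParams simulate_counts
#' @param sample_size number of distinct molecules sampled from the final
#'   pool; must not exceed the final count of the trajectory.
#' @param trajectory a trajectory from [simulate_counts()]; simulated afresh
#'   when `NULL`.
#' @return An object of class `ngsam_genealogy`: a list with `parent`
#'   (integer vector, `NA` at roots), `brlen` (integer replication counts
#'   per branch), `leaves` (node ids of the sampled molecules, in sample
#'   order), `roots`, `founder` (per-node founder id in `1..n_start`, `NA`
#'   for internal positions except as propagated), `leaf_founder` (founder
#'   id per leaf) and the `trajectory`.
#' @export
sample_genealogy <- function(params, sample_size, trajectory = NULL) {
  stopifnot(inherits(params, "ngsam_pcr_params"), sample_size >= 1)
  if (is.null(trajectory)) trajectory <- simulate_counts(params)
  counts <- as.numeric(trajectory)
  n <- params$n_cycles
  if (sample_size > counts[n + 1L]) {
    ngsam_error("ngsam_infeasible_sample",
                sprintf("sample_size %.0f exceeds final pool size %g",
                        sample_size, counts[n + 1L]))
  }

  ## growable node store
  parent <- rep(NA_integer_, 2L * sample_size)
  brlen <- integer(2L * sample_size)
  n_nodes <- sample_size
  active_node <- seq_len(sample_size)   # current lineage -> node id

  for (i in rev(seq_len(n))) {
    Nprev <- counts[i]
    Ncur <- counts[i + 1L]
    P <- Ncur - Nprev
    k <- length(active_node)
    ## how many of the k tracked (distinct) molecules are this cycle's products
    npr <- safe_rhyper(m = P, n = Nprev, k = k)
    is_prod <- rep(FALSE, k)
    if (npr > 0L) is_prod[sample.int(k, npr)] <- TRUE
    brlen[active_node[is_prod]] <- brlen[active_node[is_prod]] + 1L
    ## identities at cycle i-1: non-products are distinct survivors,
    ## products map to distinct templates; overlaps are coalescences
    labels <- numeric(k)
    labels[!is_prod] <- sample_distinct(Nprev, k - npr)
    labels[is_prod] <- sample_distinct(Nprev, npr)
    dup <- duplicated(labels)
    if (any(dup)) {
      for (lab in unique(labels[dup])) {
        idx <- which(labels == lab)       # exactly 2: one product, one survivor
        n_nodes <- n_nodes + 1L
        if (n_nodes > length(parent)) {   # grow storage
          parent <- c(parent, rep(NA_integer_, n_nodes))
          brlen <- c(brlen, integer(n_nodes))
        }
        parent[active_node[idx]] <- n_nodes
        active_node[idx[1L]] <- n_nodes
      }
      keep <- !dup
      active_node <- active_node[keep]
    }
  }

  ## surviving lineages at cycle 0 are distinct founder molecules
  founders <- sample_distinct(params$n_start, length(active_node))
  parent <- parent[seq_len(n_nodes)]
  brlen <- brlen[seq_len(n_nodes)]
  founder <- rep(NA_real_, n_nodes)
  founder[active_node] <- founders

  ## propagate founder ids down to every node
  for (v in seq_len(n_nodes)) {
    u <- v
    while (is.na(founder[u]) && !is.na(parent[u])) u <- parent[u]
    founder[v] <- founder[u]
  }

  structure(list(
    parent = parent,
    brlen = brlen,
    leaves = seq_len(sample_size),
    roots = active_node,
    founder = founder,
    leaf_founder = founder[seq_len(sample_size)],
    n_start = params$n_start,
    n_cycles = n,
    trajectory = counts
  ), class = "ngsam_genealogy")
}

## uniform sample of k distinct labels from 1..n (n may be huge, stays exact
## because sample.int hashes); returns numeric for arithmetic safety
sample_distinct <- function(n, k) {
  if (k == 0L) return(numeric())
  as.numeric(sample.int(n, k, useHash = (n > 1e7 && n < 2^31 - 1)))
}

#' @export
print.ngsam_genealogy <- function(x, ...) {
  cat(sprintf("<ngsam_genealogy> %d leaves, %d trees, %d replication events\n",
              length(x$leaves), length(x$roots), sum(x$brlen)))
  invisible(x)
}

## per-leaf total replication count from root to leaf
leaf_depths <- function(g) {
  vapply(g$leaves, function(v) {
    d <- 0L
    while (!is.na(v)) {
      d <- d + g$brlen[v]
      v <- g$parent[v]
    }
    d
  }, integer(1))
}

#' Export a genealogy as Newick
#'
#' One Newick string per tree in the forest, with integer branch lengths
#' (replication events).  Leaves are named `m<i>` after their sample order;
#' roots carry their founder id as `f<id>`.
#'
#' @param g an `ngsam_genealogy`.
#' @return character vector of Newick strings.
#' @export
genealogy_newick <- function(g) {
  children <- split(seq_along(g$parent), g$parent)
  rec <- function(v) {
    kids <- children[[as.character(v)]]
    lab <- if (v %in% g$leaves) {
      paste0("m", v)
    } else if (v %in% g$roots) {
      paste0("f", g$founder[v])
    } else {
      ""
    }
    if (is.null(kids)) {
      sprintf("%s:%d", lab, g$brlen[v])
    } else {
      sprintf("(%s)%s:%d", paste(vapply(kids, rec, character(1)),
                                 collapse = ","),
              lab, g$brlen[v])
    }
  }
  vapply(g$roots, function(r) paste0(rec(r), ";"), character(1))
}

#' Convert genealogy trees to ape phylo objects
#'
#' Trees with at least two leaves become [ape::phylo] objects (singleton
#' lineages cannot be represented by `phylo` and are returned as `NULL`).
#'
#' @param g an `ngsam_genealogy`.
#' @return list of `phylo` objects (or `NULL` for single-leaf trees), one
#'   per root.
#' @export
genealogy_phylo <- function(g) {
  nwk <- genealogy_newick(g)
  lapply(seq_along(nwk), function(i) {
    ## count leaves under this root
    n_tips <- sum(g$founder[g$leaves] == g$founder[g$roots[i]])
    if (n_tips < 2L) return(NULL)
    ape::read.tree(text = nwk[i])
  })
}

#' Write a trajectory as TSV
#'
#' @param trajectory result of [simulate_counts()].
#' @param path output path.
#' @export
write_trajectory <- function(trajectory, path) {
  utils::write.table(
    data.frame(cycle = seq_along(trajectory) - 1L,
               molecules = as.numeric(trajectory)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
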