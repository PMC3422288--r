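test_that("count trajectories obey the branching-process bounds", {
  set.seed(1)
  expect_equal(as.numeric(simulate_counts(pcr_params(5, 1, 3))),
               c(5, 10, 20, 40))
  expect_equal(as.numeric(simulate_counts(pcr_params(5000, 0, 20))),
               rep(5000, 21))
  for (i in 1:20) {
    tr <- as.numeric(simulate_counts(pcr_params(7, 0.6, 12)))
    inc <- diff(tr)
    expect_true(all(inc >= 0 & inc <= head(tr, -1)))
  }
})

test_that("mean final count matches the closed-form expectation", {
  expect_equal(expected_final_count(pcr_params(1, 1, 10)), 1024)
  expect_equal(expected_final_count(pcr_params(5000, 0.75, 20)),
               5000 * 1.75^20)
  expect_equal(expected_final_count(pcr_params(7, 0.5, 0)), 7)

  set.seed(42)
  finals <- replicate(1000, tail(as.numeric(
    simulate_counts(pcr_params(50, 0.75, 8))), 1))
  mu <- 50 * 1.75^8
  expect_lt(abs(mean(finals) - mu) / (sd(finals) / sqrt(1000)), 4)
})

test_that("efficiency is stochastically monotone in the final count", {
  set.seed(8)
  lo <- replicate(300, tail(as.numeric(simulate_counts(
    pcr_params(20, 0.4, 10))), 1))
  hi <- replicate(300, tail(as.numeric(simulate_counts(
    pcr_params(20, 0.8, 10))), 1))
  expect_gt(mean(hi), mean(lo))
})

test_that("genealogy invariants hold across random instances", {
  set.seed(21)
  for (i in 1:30) {
    s0 <- sample(1:5, 1)
    ncyc <- sample(0:8, 1)
    par <- pcr_params(s0, runif(1), ncyc)
    traj <- simulate_counts(par)
    smax <- tail(as.numeric(traj), 1)
    k <- sample.int(min(smax, 6), 1)
    g <- sample_genealogy(par, k, traj)
    expect_length(g$leaves, k)
    expect_lte(length(g$roots), min(k, s0))
    expect_true(all(ngsam:::leaf_depths(g) <= ncyc))
    expect_true(all(g$brlen >= 0))
    ## founder ids are distinct across trees and within 1..s0
    f <- g$founder[g$roots]
    expect_length(unique(f), length(f))
    expect_true(all(f >= 1 & f <= s0))
  }
})

test_that("degenerate genealogies are exact", {
  set.seed(3)
  ## single founder: every sample shares the one root
  g <- sample_genealogy(pcr_params(1, 0.9, 6), 2)
  expect_length(g$roots, 1L)
  ## zero efficiency: no replications ever, all singletons
  g0 <- sample_genealogy(pcr_params(5, 0, 10), 4)
  expect_length(g0$roots, 4L)
  expect_true(all(g0$brlen == 0))
  ## infeasible sample
  expect_error(sample_genealogy(pcr_params(2, 0, 3), 5),
               class = "ngsam_infeasible_sample")
})

test_that("backward sampler matches the forward parent-tracking oracle", {
  set.seed(1234)
  n_rep <- 4000
  fwd <- list()
  bwd <- list()
  for (i in seq_len(n_rep)) {
    fwd[[i]] <- forward_pcr_sample(2, 0.5, 4, 3)
    bwd[[i]] <- backward_pcr_sample(2, 0.5, 4, 3)
  }
  fwd <- fwd[!vapply(fwd, is.null, TRUE)]
  bwd <- bwd[!vapply(bwd, is.null, TRUE)]
  stat <- function(x, f) vapply(x, f, 0)

  ## founder-count distribution (1 or 2 founders)
  p1_f <- mean(stat(fwd, function(r) r$n_founders) == 1)
  p1_b <- mean(stat(bwd, function(r) r$n_founders) == 1)
  expect_lt(abs(p1_f - p1_b), 0.04)

  ## mean replication depth per sampled molecule
  d_f <- mean(unlist(lapply(fwd, `[[`, "depths")))
  d_b <- mean(unlist(lapply(bwd, `[[`, "depths")))
  expect_lt(abs(d_f - d_b), 0.1)

  ## mean total replication events in the sample genealogy
  t_f <- mean(stat(fwd, function(r) r$total_events))
  t_b <- mean(stat(bwd, function(r) r$total_events))
  expect_lt(abs(t_f - t_b), 0.15)
})

test_that("newick export round-trips through ape for multi-leaf trees", {
  set.seed(17)
  g <- sample_genealogy(pcr_params(2, 0.9, 5), 4)
  nwk <- genealogy_newick(g)
  expect_length(nwk, length(g$roots))
  phy <- genealogy_phylo(g)
  multi <- !vapply(phy, is.null, TRUE)
  for (p in phy[multi]) {
    expect_s3_class(p, "phylo")
    ## integer branch lengths bounded by the cycle count
    expect_true(all(p$edge.length == round(p$edge.length)))
    expect_true(all(p$edge.length <= 5))
  }
  ## leaf count across trees equals the sample size
  n_tips <- sum(vapply(phy, function(p) if (is.null(p)) 1L else
    length(p$tip.label), 1L))
  expect_equal(n_tips, 4L)
})
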