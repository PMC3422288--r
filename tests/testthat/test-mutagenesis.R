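test_that("UNREST construction honours the spectrum", {
  ## uniform spectrum -> all off-diagonals equal, rows sum to zero
  uni <- mutation_spectrum(setNames(rep(1, 12), ngsam:::spectrum_pairs()))
  m <- build_unrest(uni)
  off <- m$Q[row(m$Q) != col(m$Q)]
  expect_equal(max(off), min(off))
  expect_equal(rowSums(m$Q), rep(0, 4), ignore_attr = TRUE)

  ## single-entry spectrum -> one non-zero off-diagonal
  m1 <- build_unrest(mutation_spectrum(c("A>G" = 2)))
  off1 <- m1$Q[row(m1$Q) != col(m1$Q)]
  expect_equal(sum(off1 > 0), 1L)
  expect_gt(m1$Q["A", "G"], 0)

  ## the default is non-reversible: no symmetry constraint satisfied
  d <- build_unrest()
  expect_false(isTRUE(all.equal(d$Q, t(d$Q))))
  expect_error(build_unrest(mutation_spectrum(c("A>G" = 0))), "positive")
})

test_that("one-step substitution counts recover the spectrum ratios", {
  set.seed(31)
  spec <- default_spectrum()
  m <- build_unrest(spec, beta = 0.02)
  tpl <- paste(rep(c("A", "C", "G", "T"), each = 50000), collapse = "")
  out <- simulate_branch_mutations(tpl, 1, m)
  a <- strsplit(tpl, "")[[1]]
  b <- strsplit(out, "")[[1]]
  ch <- which(a != b)
  obs <- table(factor(paste0(a[ch], ">", b[ch]),
                      levels = ngsam:::spectrum_pairs()))
  keep <- spec > 0.015  # rare categories have too few counts at this size
  expected <- as.numeric(spec[keep]) / sum(spec[keep])
  pval <- suppressWarnings(
    chisq.test(as.numeric(obs[names(spec)[keep]]), p = expected)$p.value)
  expect_gt(pval, 1e-4)
})

test_that("branch mutation respects the zero-rate identities", {
  m <- build_unrest(beta = 0.05)
  tpl <- strrep("ACGT", 25)
  expect_identical(simulate_branch_mutations(tpl, 0, m), tpl)
  m0 <- build_unrest(beta = 0)
  expect_identical(simulate_branch_mutations(tpl, 7, m0), tpl)
  expect_error(simulate_branch_mutations(tpl, -1, m), ">= 0")
})

test_that("mutated-site fraction matches the transition-matrix diagonal", {
  set.seed(77)
  m <- build_unrest(beta = 0.01)
  p_same <- diag(transition_matrix(m, 5))[["A"]]
  out <- simulate_branch_mutations(strrep("A", 20000), 5, m)
  frac <- mean(strsplit(out, "")[[1]] != "A")
  se <- sqrt(p_same * (1 - p_same) / 20000)
  expect_lt(abs(frac - (1 - p_same)), 4 * se)
})

test_that("calibration reproduces the target mutation load independently", {
  set.seed(19)
  cal <- calibrate_scaling(build_unrest(), target_fraction = 0.05,
                           n_cycles = 10)
  expect_gt(cal$beta, 0)
  sim_frac <- function(ncyc, nrep) {
    mean(replicate(nrep, {
      g <- sample_genealogy(pcr_params(5000, 0.75, ncyc), 20)
      tpl <- paste(sample(c("A", "C", "G", "T"), 600, TRUE), collapse = "")
      pool <- mutate_pool(g, tpl, cal)
      mean(vapply(pool, site_diff, 0, b = tpl))
    }))
  }
  f10 <- sim_frac(10, 15)
  expect_lt(abs(f10 - 0.05), 0.005)
  ## the same scaling extrapolated to the 20-cycle mutagenic PCR
  f20 <- sim_frac(20, 15)
  expect_lt(abs(f20 - 0.10), 0.015)
})

test_that("calibration limit: vanishing target load gives vanishing beta", {
  set.seed(4)
  tiny <- calibrate_scaling(build_unrest(), target_fraction = 1e-4,
                            n_cycles = 10, n_genealogies = 3,
                            sample_size = 20)
  small <- calibrate_scaling(build_unrest(), target_fraction = 0.05,
                             n_cycles = 10, n_genealogies = 3,
                             sample_size = 20)
  expect_lt(tiny$beta, small$beta / 50)
})

test_that("pool mutation shares ancestral mutations and honours beta = 0", {
  tpl <- strrep("ACGTTGCA", 40)
  ## zero scaling: identical template copies whatever the genealogy
  set.seed(55)
  g <- sample_genealogy(pcr_params(3, 0.8, 6), 5)
  pool0 <- mutate_pool(g, tpl, build_unrest(beta = 0))
  expect_true(all(pool0 == tpl))

  ## star genealogy with zero branches: exact copies
  star <- sample_genealogy(pcr_params(10, 0, 4), 6)
  pool_star <- mutate_pool(star, tpl, build_unrest(beta = 0.05))
  expect_true(all(pool_star == tpl))

  ## hand-built tree: leaves at distance 0 from a mutated ancestor are
  ## identical to each other (identity by descent)
  set.seed(56)
  h <- hand_genealogy(0, 0, 5)
  pool_h <- mutate_pool(h, tpl, build_unrest(beta = 0.05))
  expect_identical(pool_h[[1]], pool_h[[2]])
  expect_gt(site_diff(pool_h[[1]], tpl), 0)  # root branch did mutate
})

test_that("spectrum JSON config round-trips and rebuilds the same model", {
  sp <- default_spectrum()
  p <- tempfile(fileext = ".json")
  write_spectrum(sp, p)
  back <- read_spectrum(p)
  expect_equal(unclass(back), unclass(sp))
  expect_equal(build_unrest(back)$Q, build_unrest(sp)$Q)
})

test_that("model rate matrix TSV dump is readable and consistent", {
  m <- build_unrest()
  path <- tempfile(fileext = ".tsv")
  write_model(m, path)
  q <- read.delim(path)
  expect_equal(q$from, c("A", "C", "G", "T"))
  expect_equal(as.matrix(q[, -1]), m$Q, ignore_attr = TRUE)
})
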