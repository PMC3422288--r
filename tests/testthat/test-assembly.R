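test_that("a single mutant is reconstructed from error-free tiling reads", {
  set.seed(111)
  src <- paste(sample(c("A", "C", "G", "T"), 1000, TRUE), collapse = "")
  ctg <- assemble(tiling_reads(src), k = 31, min_contig = 400)
  expect_s3_class(ctg, "ngsam_contigs")
  best <- ctg$contigs[[1]]
  if (best %in% c(src, revcomp(src))) {
    expect_gte(nchar(best), 0.95 * 1000)
  } else {
    al <- Biostrings::pairwiseAlignment(
      src, best, type = "local",
      substitutionMatrix = ngsam:::ngsam_submat())
    expect_gte(Biostrings::nmatch(al), 0.95 * 1000)
  }
})

test_that("mutants diverged beyond max_divergence stay separate contigs", {
  set.seed(112)
  a <- paste(sample(c("A", "C", "G", "T"), 900, TRUE), collapse = "")
  b_codes <- ngsam:::seq_to_int(a)
  flip <- sample(900, 90)  # ~10% divergence
  b_codes[flip] <- ((b_codes[flip] + sample(1:3, 90, TRUE) - 1) %% 4) + 1
  b <- ngsam:::int_to_seq(b_codes)
  ctg <- assemble(c(tiling_reads(a), tiling_reads(b)),
                  k = 31, min_contig = 400, max_divergence = 0.1)
  expect_gte(length(ctg$contigs), 2L)
  ## each source has at least one contig matching it better
  score_vs <- function(contig, src) {
    max(Biostrings::score(ngsam:::local_align(src, contig, align_params())),
        Biostrings::score(ngsam:::local_align(src, revcomp(contig),
                                              align_params())))
  }
  sa <- vapply(ctg$contigs, score_vs, 0, src = a)
  sb <- vapply(ctg$contigs, score_vs, 0, src = b)
  expect_true(any(sa > sb))
  expect_true(any(sb > sa))
})

test_that("assembly failures are signalled as classed conditions", {
  expect_error(assemble(character(0)), class = "ngsam_assembly_failure")
  set.seed(113)
  short <- paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = "")
  expect_error(assemble(tiling_reads(short, read_length = 60), k = 31,
                        min_contig = 400),
               class = "ngsam_assembly_failure")
})

test_that("low-coverage error k-mers are filtered by the auto cutoff", {
  set.seed(114)
  src <- paste(sample(c("A", "C", "G", "T"), 800, TRUE), collapse = "")
  reads <- rep(tiling_reads(src, step = 3), 4)  # deep clean coverage
  ## corrupt a handful of reads with isolated errors
  bad <- reads[1:5]
  substr(bad, 50, 50) <- "A"
  ctg <- assemble(c(reads, bad), k = 31, min_contig = 400)
  ## errors leave no extra contigs, and the survivor is an exact stretch of
  ## the source (coverage ramps at the ends may trim a few terminal bases)
  expect_length(ctg$contigs, 1L)
  c1 <- ctg$contigs[[1]]
  expect_true(grepl(c1, src, fixed = TRUE) ||
                grepl(revcomp(c1), src, fixed = TRUE))
  expect_gte(nchar(c1), 0.95 * nchar(src))
})

test_that("contig orientation flips reverse-complemented contigs", {
  set.seed(115)
  long <- paste(sample(c("A", "C", "G", "T"), 800, TRUE), collapse = "")
  short <- substring(long, 101, 700)
  ## single contig: identity orientation
  o1 <- orient_contigs(c(x = long))
  expect_false(any(o1$flipped))

  o2 <- orient_contigs(c(a = long, b = revcomp(short)))
  expect_true(o2$flipped[2])
  expect_equal(o2$contigs[["b"]], short)

  ## flipping the input leaves the oriented result invariant
  o3 <- orient_contigs(c(a = long, b = short))
  expect_equal(o3$contigs[["b"]], o2$contigs[["b"]])

  ## unrelated random sequence cannot be oriented
  set.seed(116)
  junk <- paste(sample(c("A", "C", "G", "T"), 600, TRUE), collapse = "")
  expect_error(orient_contigs(c(a = long, b = junk)),
               class = "ngsam_strandedness_failure")
})

test_that("orientation-randomized contig sets give identical consensus", {
  set.seed(117)
  src <- paste(sample(c("A", "C", "G", "T"), 700, TRUE), collapse = "")
  mutate_copy <- function(s, n_mut) {
    codes <- ngsam:::seq_to_int(s)
    i <- sample(length(codes), n_mut)
    codes[i] <- ((codes[i] + sample(1:3, n_mut, TRUE) - 1) %% 4) + 1
    ngsam:::int_to_seq(codes)
  }
  contigs <- c(src, replicate(4, mutate_copy(src, 70)))
  names(contigs) <- paste0("c", 1:5)
  cons_of <- function(seqs) {
    majority_consensus(msa(orient_contigs(seqs)))
  }
  ref <- cons_of(contigs)
  flipped <- contigs
  flipped[c(2, 4)] <- revcomp(flipped[c(2, 4)])
  expect_equal(as.character(cons_of(flipped)), as.character(ref))
})
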