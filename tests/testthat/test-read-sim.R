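test_that("log-normal parameterization reproduces the requested mean and CV", {
  fm <- fragment_model(400, 0.055)
  set.seed(61)
  draws <- rlnorm(40000, fm$mu, fm$sigma)
  expect_lt(abs(mean(draws) - 400), 1.5)
  expect_lt(abs(sd(draws) / mean(draws) - 0.055), 0.003)
  expect_equal(mean_insert_size(fm, 101), 198)
})

test_that("coverage allocation conserves bases and follows weights", {
  pool <- toy_pool(strrep("ACGT", 300))
  n <- allocate_coverage(pool, total_coverage = 4000, target_length = 1000,
                         read_length = 101)
  expect_equal(n * 2 * 101, 4000 * 1000, tolerance = 1e-3)

  pool2 <- toy_pool(rep(strrep("ACGT", 300), 2), weights = c(3, 1))
  n2 <- allocate_coverage(pool2, 4000, 1000)
  expect_equal(n2[1] / n2[2], 3, tolerance = 0.01)

  pool20 <- toy_pool(rep(strrep("ACGT", 300), 20))
  n20 <- allocate_coverage(pool20, 4000, 1200)
  per_type_cov <- n20 * 2 * 101 / 1200
  expect_true(all(abs(per_type_cov - 200) < 2))

  empty <- data.frame(sequence = character(0), weight = numeric(0))
  expect_error(allocate_coverage(empty, 4000, 100), "empty")
})

test_that("error-free reads are exact substrings with correct mate geometry", {
  set.seed(71)
  mutant <- paste(sample(c("A", "C", "G", "T"), 1500, TRUE), collapse = "")
  pool <- toy_pool(mutant)
  pairs <- fragment_and_sequence(pool, 400L,
                                 err = error_model("flat", 0))
  r1 <- unname(as.character(pairs$read1))
  r2 <- unname(as.character(pairs$read2))
  prov <- pairs$provenance
  expect_true(all(nchar(r1) == 101 & nchar(r2) == 101))
  for (i in sample(length(r1), 40)) {
    frag <- substring(mutant, prov$start[i] + 1, prov$end[i])
    if (prov$strand[i] == "-") frag <- revcomp(frag)
    ## read1 is the fragment 5' end; read2 reverse-complements the 3' end
    expect_equal(r1[i], substring(frag, 1, 101))
    expect_equal(r2[i], revcomp(substring(frag, nchar(frag) - 100,
                                          nchar(frag))))
  }
  ## fragments shorter than a read were redrawn; mean length matches model
  flen <- prov$end - prov$start
  expect_true(all(flen >= 101))
  expect_lt(abs(mean(flen) - 400), 4)
})

test_that("ramped error model realizes the per-position error rates", {
  set.seed(81)
  mutant <- strrep("A", 2000)
  pairs <- fragment_and_sequence(toy_pool(mutant), 3000L,
                                 err = error_model("ramp", 0.001, 0.02))
  ## reads from "-" strand fragments read the complement; keep "+" only
  plus <- pairs$provenance$strand == "+"
  m <- do.call(rbind, strsplit(as.character(pairs$read1)[plus], ""))
  per_pos <- colMeans(m != "A")
  expect_lt(abs(mean(per_pos[1:10]) - 0.002), 0.002)
  expect_lt(abs(mean(per_pos[92:101]) - 0.019), 0.004)
  ## qualities encode the position-specific error probability
  q <- utf8ToInt(pairs$qual1[1]) - 33
  expect_equal(q[1], 30)               # -10 log10(0.001)
  expect_lt(q[101], q[1])
})

test_that("FASTQ output round-trips and keeps mates synchronized", {
  set.seed(91)
  pool <- toy_pool(paste(sample(c("A", "C", "G", "T"), 600, TRUE),
                         collapse = ""))
  pairs <- fragment_and_sequence(pool, 25L)
  f1 <- tempfile(fileext = ".fq")
  f2 <- tempfile(fileext = ".fq")
  write_fastq(pairs, f1, f2)
  expect_equal(length(readLines(f1)), 100L)  # 25 records x 4 lines
  b1 <- Biostrings::readDNAStringSet(f1, format = "fastq")
  b2 <- Biostrings::readDNAStringSet(f2, format = "fastq")
  expect_equal(as.character(b1), as.character(pairs$read1),
               ignore_attr = TRUE)
  expect_equal(as.character(b2), as.character(pairs$read2),
               ignore_attr = TRUE)
  expect_equal(sub("/1$", "", names(b1)), sub("/2$", "", names(b2)))
})

test_that("a molecule shorter than the read length is rejected", {
  expect_error(
    fragment_and_sequence(toy_pool("ACGTACGT"), 5L, read_length = 101L),
    "shorter than the read length")
})
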