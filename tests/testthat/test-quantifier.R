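# Read masking and K2P divergence estimation.

test_that("kimura2p matches its closed form and an independent implementation", {
  expect_equal(kimura2p(0, 0), 0)
  expect_equal(kimura2p(0.1, 0.05), 0.1702, tolerance = 1e-3)
  # independent cross-check: build a 200-bp pair with exactly 20
  # transitions and 10 transversions and compare against ape's K80
  skip_if_not_installed("ape")
  withr::local_seed(101)
  s1 <- strsplit(random_seq(200), "")[[1]]
  s2 <- s1
  pos <- sample(200, 30)
  ts_map <- c(A = "G", G = "A", C = "T", T = "C")
  tv_map <- c(A = "C", G = "T", C = "A", T = "G")
  s2[pos[1:20]] <- ts_map[s1[pos[1:20]]]
  s2[pos[21:30]] <- tv_map[s1[pos[21:30]]]
  bin <- ape::as.DNAbin(matrix(tolower(c(s1, s2)), nrow = 2, byrow = TRUE))
  expect_equal(kimura2p(20 / 200, 10 / 200),
               as.numeric(ape::dist.dna(bin, model = "K80")),
               tolerance = 1e-10)
})

test_that("kimura2p is monotone and dominates the p-distance", {
  withr::local_seed(7)
  for (i in 1:20) {
    P <- stats::runif(1, 0, 0.2)
    Q <- stats::runif(1, 0, 0.15)
    d <- kimura2p(P, Q)
    expect_gte(d, P + Q)
    expect_gte(kimura2p(P + 0.01, Q), d)
    expect_gte(kimura2p(P, Q + 0.01), d)
  }
  # small-divergence limit: d approaches the p-distance
  expect_equal(kimura2p(2e-4, 1e-4) / 3e-4, 1, tolerance = 1e-3)
})

test_that("kimura2p signals saturation", {
  expect_error(kimura2p(0.5, 0.1), class = "satmapper_error_saturation")
  expect_error(kimura2p(0.1, 0.5), class = "satmapper_error_saturation")
  expect_error(kimura2p(-0.1, 0.1))
})

test_that("an exact read substring aligns with P = Q = 0", {
  mono <- random_monomer(141, seed = 50)
  lib <- build_search_library(sat_families(mono, family = "famA"))
  read <- substr(lib$sequence, 30, 130)
  h <- align_read_to_library(read, lib, 70)
  expect_equal(nrow(h), 1)
  expect_equal(h$family, "famA")
  expect_equal(h$masked_bp, 101L)
  expect_equal(h$transitions, 0L)
  expect_equal(h$transversions, 0L)
  expect_equal(h$identity, 100)
  expect_equal(h$k2p, 0)
})

test_that("planted substitutions are classified as transitions/transversions", {
  mono <- random_monomer(141, seed = 51)
  lib <- build_search_library(sat_families(mono, family = "famA"))
  b <- strsplit(mono, "")[[1]]
  ts_map <- c(A = "G", G = "A", C = "T", T = "C")
  tv_map <- c(A = "C", G = "T", C = "A", T = "G")
  withr::local_seed(52)
  pos <- sample(10:130, 9)  # interior, so local alignment keeps the ends
  b[pos[1:6]] <- ts_map[b[pos[1:6]]]
  b[pos[7:9]] <- tv_map[b[pos[7:9]]]
  read <- paste(b, collapse = "")
  h <- align_read_to_library(read, lib, 70)
  expect_equal(h$aligned_columns, 141L)
  expect_equal(h$transitions, 6L)
  expect_equal(h$transversions, 3L)
  expect_equal(h$k2p, kimura2p(6 / 141, 3 / 141))
  # the reverse-complement read gives the same counts on the minus strand
  h_rc <- align_read_to_library(reverse_complement(read), lib, 70)
  expect_equal(h_rc$strand, "-")
  expect_equal(h_rc$transitions, 6L)
  expect_equal(h_rc$transversions, 3L)
})

test_that("random reads do not mask against a satDNA library", {
  withr::local_seed(53)
  lib <- build_search_library(sat_families(random_monomer(141), family = "famA"))
  reads <- vapply(1:50, function(i) random_seq(101), character(1))
  h <- align_read_to_library(reads, lib, 80)
  expect_equal(nrow(h), 0)
  mq <- mask_and_quantify(reads, sat_families(random_monomer(141), family = "famA"),
                          min_identity = 80)
  expect_equal(mq$abundance_percent, 0)
  expect_equal(mq$masked_bp, 0L)
})

test_that("abundance and divergence are recovered from simulated reads", {
  mono <- random_monomer(141, seed = 54)
  fam <- sat_families(mono, family = "famA")
  plan <- dplyr::bind_rows(lapply(0:2, function(i)
    plant_plan("famA", "chr1", 20000 + i * 60000, 50, divergence = 0.07)))
  syn <- plant_arrays(plan, fam, c(chr1 = 200000), seed = 55)
  planted_frac <- sum(syn$truth$end - syn$truth$start) / 200000
  reads <- simulate_reads(syn$genome, coverage = 2, seed = 56)
  mq <- mask_and_quantify(reads, fam, 70)
  se <- sqrt(planted_frac * (1 - planted_frac) / length(reads))
  expect_lt(abs(mq$abundance_percent / 100 - planted_frac), 3 * se)
  expect_lt(abs(mq$divergence_percent - 7), 1.5)
  # masking partition: masked bp never exceeds read bp
  expect_lte(sum(mq$masked_bp), sum(Biostrings::width(reads)))
})

test_that("the abundance estimator is unbiased over seeded replicates", {
  mono <- random_monomer(120, seed = 57)
  fam <- sat_families(mono, family = "famA")
  plan <- plant_plan("famA", "chr1", 20000, 50, divergence = 0.05)
  ests <- vapply(1:10, function(r) {
    syn <- plant_arrays(plan, fam, c(chr1 = 60000), seed = 600 + r)
    reads <- simulate_reads(syn$genome, coverage = 2, seed = 700 + r)
    mask_and_quantify(reads, fam, 70)$abundance_percent / 100
  }, numeric(1))
  planted <- 50 * 120 / 60000
  se_mean <- stats::sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests) - planted), 2 * se_mean + 1e-4)
})

test_that("each read bp is assigned to at most one family", {
  monoA <- random_monomer(141, seed = 58)
  monoB <- random_monomer(141, seed = 59)
  fams <- sat_families(c(monoA, monoB), family = c("famA", "famB"))
  plan <- dplyr::bind_rows(
    plant_plan("famA", "chr1", 5000, 40, divergence = 0.05),
    plant_plan("famB", "chr1", 30000, 40, divergence = 0.05)
  )
  syn <- plant_arrays(plan, fams, c(chr1 = 60000), seed = 60)
  reads <- simulate_reads(syn$genome, coverage = 2, seed = 61)
  mq <- mask_and_quantify(reads, fams, 70)
  hits <- attr(mq, "hits")
  expect_equal(anyDuplicated(hits$read), 0)
  expect_lte(sum(mq$masked_bp), sum(Biostrings::width(reads)))
  expect_equal(sum(hits$masked_bp), sum(mq$masked_bp))
})

test_that("the repeat landscape conserves per-family abundance", {
  mono <- random_monomer(141, seed = 62)
  fam <- sat_families(mono, family = "famA")
  plan <- plant_plan("famA", "chr1", 10000, 60, divergence = 0.06)
  syn <- plant_arrays(plan, fam, c(chr1 = 80000), seed = 63)
  reads <- simulate_reads(syn$genome, coverage = 2, seed = 64)
  mq <- mask_and_quantify(reads, fam, 70)
  ls <- repeat_landscape(mq, bin_width = 1)
  expect_equal(sum(ls$abundance_percent), mq$abundance_percent, tolerance = 1e-10)
  # all mass at divergence zero collapses into the first bin
  reads0 <- substr(strrep(mono, 3), 50, 150)
  mq0 <- mask_and_quantify(reads0, fam, 70)
  ls0 <- repeat_landscape(mq0)
  expect_equal(ls0$bin_lower, 0)
  expect_equal(ls0$abundance_percent, 100)
})
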