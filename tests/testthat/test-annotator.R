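# Chromosome annotation: the semi-global monomer scan, overlap
# resolution, array merging and density binning.

test_that("a perfect tandem array is tiled exactly by monomer hits", {
  mono <- random_monomer(141, seed = 42)
  fx <- flanked_array(mono, 10, flank = 5000, seed = 42)
  h <- find_monomer_hits(fx$seq, mono, 70)
  expect_equal(nrow(h), 10)
  expect_equal(h$start, seq(fx$start, fx$end - 141, by = 141))
  expect_equal(h$end - h$start, rep(141L, 10))
  expect_equal(h$identity, rep(100, 10))
  expect_equal(h$strand, rep("+", 10))
  expect_equal(h$transitions + h$transversions + h$indel_columns, rep(0L, 10))
})

test_that("a reverse-complemented array yields mirrored minus-strand hits", {
  mono <- random_monomer(141, seed = 42)
  fx <- flanked_array(mono, 10, flank = 5000, seed = 42)
  arr <- substr(fx$seq, fx$start + 1, fx$end)
  seq_rc <- paste0(substr(fx$seq, 1, fx$start), reverse_complement(arr),
                   substr(fx$seq, fx$end + 1, nchar(fx$seq)))
  h <- find_monomer_hits(seq_rc, mono, 70)
  expect_equal(h$start, seq(fx$start, fx$end - 141, by = 141))
  expect_equal(h$strand, rep("-", 10))
  expect_equal(h$identity, rep(100, 10))
})

test_that("random background yields no monomer-scale hits at 70%", {
  mono <- random_monomer(141, seed = 8)
  h <- find_monomer_hits(random_seq(10000, seed = 9), mono, 70)
  expect_equal(nrow(h), 0)
})

test_that("fast scan agrees with the brute-force per-offset oracle", {
  withr::local_seed(13)
  mono <- random_monomer(90)
  copies <- vapply(1:8, function(i) mutate_to_divergence(mono, 0.10, 2), "")
  chrom <- paste0(random_seq(1500), paste(copies, collapse = ""),
                  random_seq(1000),
                  strrep(mono, 3), random_seq(500))
  both <- scan_both_routes(mono, chrom, 70)
  expect_equal(nrow(both$fast), nrow(both$ref))
  expect_equal(both$fast$start, both$ref$start)
  # equal-scoring gapped alignments may shift an end by a base or two
  expect_lte(max(abs(both$fast$end - both$ref$end)), 3)
  expect_equal(both$fast$identity, both$ref$identity, tolerance = 1e-8)
})

test_that("hits at a higher threshold are a subset of those at a lower one", {
  withr::local_seed(21)
  mono <- random_monomer(100)
  copies <- vapply(1:12, function(i)
    mutate_to_divergence(mono, stats::runif(1, 0, 0.18), 2), "")
  chrom <- paste0(random_seq(2000), paste(copies, collapse = ""),
                  random_seq(2000))
  h70 <- find_monomer_hits(chrom, mono, 70)
  h85 <- find_monomer_hits(chrom, mono, 85)
  key <- function(h) paste(h$start, h$end, h$strand)
  expect_true(all(key(h85) %in% key(h70)))
  expect_gte(nrow(h70), nrow(h85))
})

test_that("strand symmetry: annotating the reverse complement mirrors coordinates", {
  withr::local_seed(33)
  mono <- random_monomer(80)
  chrom <- paste0(random_seq(1500),
                  paste(vapply(1:6, function(i) mutate_to_divergence(mono, 0.08, 2), ""),
                        collapse = ""),
                  random_seq(1500))
  fam <- sat_families(mono, family = "famA")
  a_fwd <- annotate_assembly(fam, c(chr1 = chrom), 70)
  a_rev <- annotate_assembly(fam, c(chr1 = reverse_complement(chrom)), 70)
  L <- nchar(chrom)
  expect_equal(sort(L - a_rev$end), sort(a_fwd$start))
  expect_equal(sort(L - a_rev$start), sort(a_fwd$end))
  flip <- c(`+` = "-", `-` = "+")
  expect_equal(sort(unname(flip[a_rev$strand])), sort(a_fwd$strand))
})

test_that("min_identity outside (0, 100] is rejected", {
  expect_error(find_monomer_hits("ACGT", "ACGT", 0))
  expect_error(find_monomer_hits("ACGT", "ACGT", 101))
})

test_that("short monomers are annotated by exact tandem-run detection", {
  run <- strrep("TTAGG", 6)
  chrom <- paste0(random_seq(300, seed = 14), run, random_seq(300, seed = 15),
                  strrep("TTAGG", 3), random_seq(200, seed = 16))
  h <- find_monomer_hits(chrom, "TTAGG", 70)
  # the 6-copy run is reported copy by copy; the 3-copy run is below the
  # 4-copy floor
  expect_equal(nrow(h), 6)
  expect_equal(h$start, seq(300, 325, by = 5))
  expect_equal(h$identity, rep(100, 6))
  # minus-strand run found via the reverse complement
  chrom_rc <- paste0(random_seq(200, seed = 17), strrep("CCTAA", 5),
                     random_seq(200, seed = 18))
  h_rc <- find_monomer_hits(chrom_rc, "TTAGG", 70)
  expect_equal(nrow(h_rc), 5)
  expect_equal(unique(h_rc$strand), "-")
})

test_that("merge_hits_into_arrays applies the gap rule", {
  expect_equal(nrow(merge_hits_into_arrays(satmapper:::empty_hits(), 100)), 0)
  mono <- random_monomer(141, seed = 19)
  # two perfect single copies separated by 3 x rul of random sequence
  chrom <- paste0(random_seq(1000, seed = 20), mono,
                  random_seq(3 * 141, seed = 21), mono,
                  random_seq(1000, seed = 22))
  h <- find_monomer_hits(chrom, mono, 70)
  expect_equal(nrow(h), 2)
  two <- merge_hits_into_arrays(h, max_gap = 141)
  expect_equal(nrow(two), 2)
  expect_equal(two$n_monomers, c(1L, 1L))
  # contiguous hits merge into one array
  fx <- flanked_array(mono, 10, flank = 500, seed = 23)
  one <- merge_hits_into_arrays(find_monomer_hits(fx$seq, mono, 70), max_gap = 141)
  expect_equal(nrow(one), 1)
  expect_equal(one$n_monomers, 10L)
  expect_equal(one$start, fx$start)
  expect_equal(one$end, fx$end)
  # unsorted input is an error
  expect_error(merge_hits_into_arrays(h[c(2, 1), ], max_gap = 141), "sorted")
})

test_that("annotate_assembly recovers families on their own chromosomes only", {
  monoA <- random_monomer(120, seed = 24)
  monoB <- random_monomer(150, seed = 25)
  fams <- sat_families(c(monoA, monoB), family = c("famA", "famB"))
  plan <- dplyr::bind_rows(
    plant_plan("famA", "chr1", 2000, 8, divergence = 0.05),
    plant_plan("famB", "chr2", 3000, 6, divergence = 0.05)
  )
  syn <- plant_arrays(plan, fams, c(chr1 = 15000, chr2 = 15000), seed = 26)
  ann <- annotate_assembly(fams, syn$genome, 70)
  expect_setequal(unique(ann$chrom[ann$family == "famA"]), "chr1")
  expect_setequal(unique(ann$chrom[ann$family == "famB"]), "chr2")
  expect_gte(covered_fraction(ann, syn$truth, c(chr1 = 15000, chr2 = 15000)), 0.95)
  # a family with no planted copies gets no arrays
  famC <- sat_families(random_monomer(110, seed = 27), family = "famC")
  annC <- annotate_assembly(famC, syn$genome, 70)
  expect_equal(nrow(annC), 0)
  expect_error(annotate_assembly(fams, character(0)))
})

test_that("interleaved families are both recovered with interleaved intervals", {
  monoA <- random_monomer(100, seed = 28)
  monoB <- random_monomer(100, seed = 29)
  fams <- sat_families(c(monoA, monoB), family = c("famA", "famB"))
  # famB block planted inside famA's block
  plan <- dplyr::bind_rows(
    plant_plan("famA", "chr1", 2000, 5),
    plant_plan("famB", "chr1", 2500, 5, interleaved = TRUE),
    plant_plan("famA", "chr1", 3000, 5, interleaved = TRUE)
  )
  syn <- plant_arrays(plan, fams, c(chr1 = 10000), seed = 30)
  ann <- annotate_assembly(fams, syn$genome, 70, max_gap_factor = 1)
  a <- ann[ann$family == "famA", ]
  b <- ann[ann$family == "famB", ]
  expect_equal(sum(a$end - a$start), 1000)
  expect_equal(b$start, 2500)
  expect_equal(b$end, 3000)
})

test_that("binned_density conserves bp and splits straddling arrays", {
  arrays <- tibble::tibble(
    family = "famA", chrom = "chr1", start = 150L, end = 250L,
    strand = "+", n_monomers = 1L, mean_identity = 100
  )
  d <- binned_density(arrays, c(chr1 = 1000), bin_size = 100)
  expect_equal(d$bin_start, c(100, 200))
  expect_equal(d$bp, c(50, 50))
  # an array covering bins 2-3 exactly leaves other bins empty
  arr2 <- dplyr::mutate(arrays, start = 200L, end = 400L)
  d2 <- binned_density(arr2, c(chr1 = 1000), bin_size = 100)
  expect_equal(d2$bin_start, c(200, 300))
  expect_equal(sum(d2$bp), 200)
  # conservation on random arrays
  withr::local_seed(31)
  for (i in 1:5) {
    st <- sort(sample(0:9000, 10))
    en <- st + sample(50:900, 10, replace = TRUE)
    en <- pmin(en, 10000)
    ok <- c(TRUE, st[-1] >= cummax(en)[-10])  # keep non-overlapping subset
    ra <- tibble::tibble(family = "f", chrom = "chr1", start = st[ok],
                         end = en[ok], strand = "+", n_monomers = 1L,
                         mean_identity = 100)
    dd <- binned_density(ra, c(chr1 = 10000), bin_size = 512)
    expect_equal(sum(dd$bp), sum(ra$end - ra$start))
  }
})
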