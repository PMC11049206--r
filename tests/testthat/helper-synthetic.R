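# Shared generators for test fixtures; everything is built in code under
# fixed seeds.

random_monomer <- function(n, seed = NULL, at = 0.6) {
  if (!is.null(seed)) withr::local_seed(seed)
  paste(sample(c("A", "T", "C", "G"), n, replace = TRUE,
               prob = c(at / 2, at / 2, (1 - at) / 2, (1 - at) / 2)),
        collapse = "")
}

random_seq <- function(n, seed = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# chromosome with one perfect tandem array embedded between two random
# flanks; returns the sequence and the planted interval
flanked_array <- function(monomer, n_copies, flank = 5000, seed = 1) {
  withr::local_seed(seed)
  left <- random_seq(flank)
  right <- random_seq(flank)
  list(
    seq = paste0(left, strrep(monomer, n_copies), right),
    start = flank,
    end = flank + n_copies * nchar(monomer)
  )
}

# fraction of planted truth bp covered by reported arrays
covered_fraction <- function(arrays, truth, chrom_lengths) {
  tot <- 0
  cov <- 0
  for (ch in names(chrom_lengths)) {
    t_mask <- rep(FALSE, chrom_lengths[[ch]])
    a_mask <- rep(FALSE, chrom_lengths[[ch]])
    t_ch <- truth[truth$chrom == ch, ]
    a_ch <- arrays[arrays$chrom == ch, ]
    for (i in seq_len(nrow(t_ch))) t_mask[(t_ch$start[i] + 1):t_ch$end[i]] <- TRUE
    for (i in seq_len(nrow(a_ch))) a_mask[(a_ch$start[i] + 1):a_ch$end[i]] <- TRUE
    tot <- tot + sum(t_mask)
    cov <- cov + sum(t_mask & a_mask)
  }
  cov / tot
}

# run both scan routes on one strand and resolve overlaps identically
scan_both_routes <- function(monomer, chrom_seq, min_identity = 70) {
  fast <- satmapper:::resolve_overlaps(satmapper:::hit_tibble(
    satmapper:::scan_semiglobal_cpp(monomer, chrom_seq, min_identity),
    "fam", "chr", "+"))
  ref <- satmapper:::resolve_overlaps(satmapper:::hit_tibble(
    satmapper:::scan_reference_cpp(monomer, chrom_seq, min_identity),
    "fam", "chr", "+"))
  list(fast = fast, ref = ref)
}
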