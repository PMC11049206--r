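# Read masking against family search libraries: per-family genome
# abundance and K2P divergence estimated from sequencing reads.

as_reads <- function(reads) {
  if (is.character(reads) && length(reads) == 1 && file.exists(reads)) {
    fmt <- if (grepl("\\.f(ast)?q(\\.gz)?$", reads)) "fastq" else "fasta"
    reads <- Biostrings::readDNAStringSet(reads, format = fmt)
  } else if (is.character(reads)) {
    reads <- Biostrings::DNAStringSet(toupper(reads))
  }
  if (!methods::is(reads, "DNAStringSet")) {
    abort("`reads` must be a DNAStringSet, a character vector or a FASTA/FASTQ path")
  }
  if (is.null(names(reads))) names(reads) <- paste0("read", seq_along(reads))
  reads
}

sub_matrix <- function() {
  bases <- c("A", "C", "G", "T", "N")
  m <- matrix(-1, 5, 5, dimnames = list(bases, bases))
  diag(m) <- 1
  m["N", ] <- -1
  m[, "N"] <- -1
  m
}

# One vectorized pass of local alignment of all reads against one library
# sequence on one strand; returns per-read alignment statistics.
align_reads_one <- function(reads, lib_seq, strand) {
  subject <- Biostrings::DNAString(if (strand == "+") lib_seq else reverse_complement(lib_seq))
  pwa <- Biostrings::pairwiseAlignment(
    pattern = reads, subject = subject, type = "local",
    substitutionMatrix = sub_matrix(), gapOpening = 2, gapExtension = 1
  )
  nmat <- Biostrings::nmatch(pwa)
  nmis <- Biostrings::nmismatch(pwa)
  cols <- Biostrings::nchar(pwa)
  # classify substitutions; exclude pairs involving N from ts/tv
  mt <- Biostrings::mismatchTable(pwa)
  ts <- tv <- nn <- integer(length(reads))
  if (nrow(mt) > 0) {
    a <- as.character(mt$PatternSubstring)
    b <- as.character(mt$SubjectSubstring)
    is_n <- a == "N" | b == "N"
    is_ts <- !is_n & paste0(pmin(a, b), pmax(a, b)) %in% c("AG", "CT")
    id <- factor(mt$PatternId, levels = seq_along(reads))
    ts <- as.integer(tapply(is_ts, id, sum, default = 0))
    tv <- as.integer(tapply(!is_ts & !is_n, id, sum, default = 0))
    nn <- as.integer(tapply(is_n, id, sum, default = 0))
  }
  p <- Biostrings::pattern(pwa)  # aligned part of each read
  tibble(
    read = seq_along(reads),
    strand = strand,
    score = Biostrings::score(pwa),
    masked_bp = Biostrings::end(p) - Biostrings::start(p) + 1L,
    matches = nmat,
    aligned_columns = nmat + nmis - nn,
    transitions = ts,
    transversions = tv,
    columns = cols,
    identity = 100 * nmat / cols
  )
}

#' Align reads to the family search libraries
#'
#' Best local alignment of each read across all library sequences and both
#' strands (match +1, mismatch -1, gap open 2, gap extension 1 - the same
#' scoring as the chromosome annotator). A read is reported only if its
#' best alignment reaches `min_identity` percent identity and covers at
#' least half of the read; substitution columns are classified as
#' transitions (A<->G, C<->T) or transversions for K2P estimation.
#' Multi-matching reads are assigned by highest identity, ties by longer
#' aligned interval, then by lower family rank (library order).
#'
#' @param reads Reads as `DNAStringSet`, character vector, or FASTA/FASTQ
#'   path (qualities ignored).
#' @param library Search-library tibble from [build_search_library()].
#' @param min_identity Identity threshold in percent (default 70).
#' @param min_read_cov Minimum fraction of the read that must align
#'   (default 0.5); guards against short chance local matches.
#' @return A tibble with one row per masked read: `read`, `family`,
#'   `strand`, `masked_bp`, `aligned_columns`, `transitions`,
#'   `transversions`, `identity`, `k2p` (`NA` when saturated).
#' @export
align_read_to_library <- function(reads, library, min_identity = 70,
                                  min_read_cov = 0.5) {
  reads <- as_reads(reads)
  if (length(reads) == 0) abort("empty read set")
  hits <- purrr::map_dfr(seq_len(nrow(library)), function(i) {
    dplyr::bind_rows(
      align_reads_one(reads, library$sequence[i], "+"),
      align_reads_one(reads, library$sequence[i], "-")
    ) |>
      mutate(family = library$family[i], family_rank = i)
  })
  read_len <- Biostrings::width(reads)
  hits |>
    mutate(read_length = read_len[.data$read]) |>
    filter(.data$identity >= min_identity,
           .data$masked_bp >= min_read_cov * .data$read_length) |>
    group_by(.data$read) |>
    arrange(desc(.data$identity), desc(.data$masked_bp), .data$family_rank,
            .by_group = TRUE) |>
    dplyr::slice(1) |>
    ungroup() |>
    mutate(k2p = kimura2p_safe(.data$transitions / .data$aligned_columns,
                               .data$transversions / .data$aligned_columns)) |>
    select("read", "family", "strand", "masked_bp", "aligned_columns",
           "transitions", "transversions", "identity", "k2p")
}

#' Mask reads and quantify satDNA family abundance and divergence
#'
#' Reproduces library-based repeat quantification from reads: each read bp
#' is assigned to at most one family (best alignment wins), per-family
#' abundance is the masked fraction of total read bp, and per-family
#' divergence is the aligned-bp-weighted mean K2P across read hits. Hits
#' whose K2P is saturated are counted as masked bp but excluded from the
#' divergence mean, with a warning.
#'
#' @inheritParams align_read_to_library
#' @param families Family tibble with consensus monomers (search libraries
#'   are built with [build_search_library()]).
#' @return A `masking_result` tibble: `family`, `n_reads`, `masked_bp`,
#'   `abundance_percent`, `divergence_percent`; per-hit records are kept in
#'   the `"hits"` attribute for landscape plotting.
#' @export
mask_and_quantify <- function(reads, families, min_identity = 70,
                              min_read_cov = 0.5) {
  reads <- as_reads(reads)
  if (length(reads) == 0) abort("empty read set")
  library <- build_search_library(families)
  total_bp <- sum(Biostrings::width(reads))
  hits <- align_read_to_library(reads, library, min_identity = min_identity,
                                min_read_cov = min_read_cov)
  if (any(is.na(hits$k2p))) {
    warn(sprintf("%d read hit(s) with saturated K2P excluded from divergence means",
                 sum(is.na(hits$k2p))))
  }
  per_family <- hits |>
    group_by(.data$family) |>
    summarise(
      n_reads = n(),
      masked_bp = sum(.data$masked_bp),
      divergence_percent = 100 * stats::weighted.mean(
        .data$k2p, .data$aligned_columns, na.rm = TRUE),
      .groups = "drop"
    )
  out <- tibble(family = families$family) |>
    left_join(per_family, by = "family") |>
    mutate(
      n_reads = dplyr::coalesce(.data$n_reads, 0L),
      masked_bp = dplyr::coalesce(.data$masked_bp, 0L),
      abundance_percent = 100 * .data$masked_bp / total_bp,
      divergence_percent = ifelse(is.nan(.data$divergence_percent),
                                  NA_real_, .data$divergence_percent)
    ) |>
    select("family", "n_reads", "masked_bp", "abundance_percent",
           "divergence_percent")
  structure(out,
            hits = hits, total_read_bp = total_bp,
            params = list(min_identity = min_identity,
                          min_read_cov = min_read_cov),
            class = c("masking_result", class(out)))
}

#' @export
glance.masking_result <- function(x, ...) {
  tibble(
    n_families = nrow(x),
    total_read_bp = attr(x, "total_read_bp"),
    masked_bp = sum(x$masked_bp),
    masked_percent = 100 * sum(x$masked_bp) / attr(x, "total_read_bp"),
    min_identity = attr(x, "params")$min_identity
  )
}

#' @export
tidy.masking_result <- function(x, ...) {
  out <- as_tibble(x)
  attr(out, "hits") <- NULL
  attr(out, "total_read_bp") <- NULL
  attr(out, "params") <- NULL
  out
}

#' Repeat landscape: abundance by divergence bin
#'
#' Histograms each family's abundance over K2P divergence bins (percent
#' scale). Recently amplified or homogenized families show up as
#' low-divergence peaks. Per-family bin masses sum to the family's
#' abundance attributable to hits with a defined K2P (divergences beyond
#' `max_divergence` are clamped into the top bin so mass is conserved).
#'
#' @param result A `masking_result` from [mask_and_quantify()].
#' @param bin_width Bin width in percent divergence (default 1).
#' @param max_divergence Upper edge of the landscape in percent (default 30).
#' @return A `sat_landscape` tibble: `family`, `bin_lower`, `bin_upper`,
#'   `abundance_percent`.
#' @export
repeat_landscape <- function(result, bin_width = 1, max_divergence = 30) {
  stopifnot(bin_width > 0)
  hits <- attr(result, "hits")
  total_bp <- attr(result, "total_read_bp")
  if (is.null(hits) || is.null(total_bp)) {
    abort("`result` must come from mask_and_quantify()")
  }
  hits <- filter(hits, !is.na(.data$k2p))
  out <- hits |>
    mutate(
      div = pmin(100 * .data$k2p, max_divergence - bin_width / 2),
      bin_lower = floor(.data$div / bin_width) * bin_width
    ) |>
    group_by(.data$family, .data$bin_lower) |>
    summarise(abundance_percent = 100 * sum(.data$masked_bp) / total_bp,
              .groups = "drop") |>
    mutate(bin_upper = .data$bin_lower + bin_width) |>
    select("family", "bin_lower", "bin_upper", "abundance_percent")
  structure(out,
            bin_width = bin_width, max_divergence = max_divergence,
            class = c("sat_landscape", class(out)))
}
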