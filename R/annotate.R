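# Chromosome in silico mapping: locate satDNA consensus monomers on
# assembled chromosomes, merge monomer hits into tandem arrays.

as_assembly <- function(assembly) {
  if (is.character(assembly)) {
    if (is.null(names(assembly))) {
      names(assembly) <- paste0("chr", seq_along(assembly))
    }
    assembly <- Biostrings::DNAStringSet(toupper(assembly))
  }
  if (!methods::is(assembly, "DNAStringSet")) {
    abort("`assembly` must be a named character vector, a DNAStringSet or a FASTA path")
  }
  if (length(assembly) == 0) abort("empty assembly")
  if (anyDuplicated(names(assembly))) abort("chromosome ids must be unique")
  assembly
}

#' Read an assembly from FASTA
#'
#' @param path FASTA file of assembled chromosomes.
#' @return A `DNAStringSet`, ids truncated at the first whitespace.
#' @export
read_assembly <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  as_assembly(x)
}

hit_tibble <- function(df, family, chrom, strand) {
  tibble(
    family = family, chrom = chrom,
    start = as.integer(df$start), end = as.integer(df$end),
    strand = strand,
    identity = as.numeric(df$identity),
    score = as.numeric(df$score),
    matches = as.integer(df$matches),
    transitions = as.integer(df$transitions),
    transversions = as.integer(df$transversions),
    indel_columns = as.integer(df$indel_columns),
    columns = as.integer(df$columns)
  )
}

empty_hits <- function() {
  hit_tibble(list(start = integer(), end = integer(), identity = numeric(),
                  score = numeric(), matches = integer(),
                  transitions = integer(), transversions = integer(),
                  indel_columns = integer(), columns = integer()),
             character(), character(), character())
}

# Greedy overlap resolution within one family on one chromosome: keep the
# higher-identity hit; ties go to the leftmost, then to the plus strand.
resolve_overlaps <- function(hits) {
  if (nrow(hits) <= 1) return(hits)
  ord <- order(-hits$identity, hits$start, hits$strand != "+", hits$end)
  lo <- min(hits$start)
  covered <- logical(max(hits$end) - lo)
  keep <- logical(nrow(hits))
  for (k in ord) {
    span <- (hits$start[k] + 1):hits$end[k] - lo
    if (!any(covered[span])) {
      covered[span] <- TRUE
      keep[k] <- TRUE
    }
  }
  dplyr::arrange(hits[keep, ], .data$start, .data$end)
}

# Exact tandem-run detection for very short monomers, where percent
# identity over a handful of columns is meaninglessly permissive: report
# runs of >= min_copies exact head-to-tail copies, one hit per copy.
exact_tandem_hits <- function(monomer, chrom_seq, chrom = "chr",
                              family = "family1", min_copies = 4) {
  rul <- nchar(monomer)
  subject <- Biostrings::DNAString(chrom_seq)
  out <- list()
  for (strand in c("+", "-")) {
    pat <- if (strand == "+") monomer else reverse_complement(monomer)
    starts <- Biostrings::start(Biostrings::matchPattern(pat, subject)) - 1L
    if (length(starts) == 0) next
    starts <- sort(starts)
    # chain occurrences spaced exactly one repeat unit apart
    prev <- match(starts - rul, starts)
    run_id <- integer(length(starts))
    nid <- 0L
    for (i in seq_along(starts)) {
      if (is.na(prev[i])) {
        nid <- nid + 1L
        run_id[i] <- nid
      } else {
        run_id[i] <- run_id[prev[i]]
      }
    }
    len <- table(run_id)
    ok <- run_id %in% as.integer(names(len)[len >= min_copies])
    if (!any(ok)) next
    s <- starts[ok]
    out[[strand]] <- hit_tibble(
      list(start = s, end = s + rul,
           identity = rep(100, length(s)), score = rep(rul, length(s)),
           matches = rep(rul, length(s)),
           transitions = integer(length(s)), transversions = integer(length(s)),
           indel_columns = integer(length(s)), columns = rep(rul, length(s))),
      family, chrom, strand)
  }
  hits <- dplyr::bind_rows(out)
  if (nrow(hits) == 0) return(empty_hits())
  resolve_overlaps(hits)
}

#' Find monomer-scale hits of one satDNA family on a chromosome
#'
#' Scans both strands of a chromosome with the family consensus monomer
#' using a semi-global alignment at every subject offset (query end to end,
#' free subject window; match +1, mismatch -1, gap open 2, gap extension 1)
#' and keeps every maximal match whose identity (matches / alignment
#' columns, indel columns counting against) reaches `min_identity`.
#' Overlapping same-family candidates are resolved to the higher-identity
#' one (ties: leftmost). Monomers shorter than 20 bp are annotated by exact
#' tandem-run detection of at least four consecutive copies instead of
#' scored alignment.
#'
#' @param chrom_seq Chromosome sequence (single string or `DNAString`).
#' @param monomer Family consensus monomer.
#' @param min_identity Identity threshold in percent, in (0, 100].
#' @param family,chrom Labels carried into the output.
#' @param min_copies_exact Minimum run length for the exact short-monomer
#'   path.
#' @return A tibble of hits sorted by (start, end) with 0-based half-open
#'   coordinates, strand, identity, and substitution/indel column counts.
#' @export
find_monomer_hits <- function(chrom_seq, monomer, min_identity = 70,
                              family = "family1", chrom = "chr",
                              min_copies_exact = 4) {
  if (!is.numeric(min_identity) || min_identity <= 0 || min_identity > 100) {
    abort("`min_identity` must be in (0, 100]")
  }
  chrom_seq <- toupper(as.character(chrom_seq))
  monomer <- toupper(as.character(monomer))
  check_dna(monomer, "monomer")
  check_dna(chrom_seq, "chrom_seq")
  if (nchar(monomer) == 0 || nchar(chrom_seq) == 0) {
    abort("`monomer` and `chrom_seq` must be non-empty")
  }
  if (nchar(monomer) < 20) {
    return(exact_tandem_hits(monomer, chrom_seq, chrom = chrom,
                             family = family, min_copies = min_copies_exact))
  }
  fwd <- scan_semiglobal_cpp(monomer, chrom_seq, min_identity)
  rev <- scan_semiglobal_cpp(reverse_complement(monomer), chrom_seq, min_identity)
  hits <- dplyr::bind_rows(
    hit_tibble(fwd, family, chrom, rep("+", nrow(fwd))),
    hit_tibble(rev, family, chrom, rep("-", nrow(rev)))
  )
  if (nrow(hits) == 0) return(empty_hits())
  resolve_overlaps(hits)
}

#' Merge monomer hits into tandem arrays
#'
#' Consecutive same-strand hits of one family on one chromosome whose
#' inter-hit gap is at most `max_gap` are merged into a single array, the
#' unit drawn on chromosome distribution maps.
#'
#' @param hits Hit tibble from [find_monomer_hits()], sorted by start
#'   within each chromosome (unsorted input is an error).
#' @param max_gap Maximum tolerated gap in bp between consecutive hits;
#'   one repeat unit length is the conventional default, applied by
#'   [annotate_assembly()].
#' @return A tibble of arrays: `family`, `chrom`, `start`, `end`, `strand`,
#'   `n_monomers`, `mean_identity`.
#' @export
merge_hits_into_arrays <- function(hits, max_gap) {
  stopifnot(is.numeric(max_gap), max_gap >= 0)
  cols <- c("family", "chrom", "start", "end", "strand", "identity")
  if (!all(cols %in% names(hits))) {
    abort("`hits` must be a hit tibble (see find_monomer_hits())")
  }
  if (nrow(hits) == 0) {
    return(tibble(family = character(), chrom = character(),
                  start = integer(), end = integer(), strand = character(),
                  n_monomers = integer(), mean_identity = numeric()))
  }
  sorted <- hits |>
    group_by(.data$family, .data$chrom) |>
    summarise(ok = !is.unsorted(.data$start), .groups = "drop")
  if (!all(sorted$ok)) {
    abort("`hits` must be sorted by start within each chromosome")
  }
  hits |>
    group_by(.data$family, .data$chrom, .data$strand) |>
    arrange(.data$start, .by_group = TRUE) |>
    mutate(
      gap = .data$start - lag(.data$end, default = dplyr::first(.data$start)),
      array_id = cumsum(.data$gap > max_gap)
    ) |>
    group_by(.data$family, .data$chrom, .data$strand, .data$array_id) |>
    summarise(
      start = min(.data$start), end = max(.data$end),
      n_monomers = n(), mean_identity = mean(.data$identity),
      .groups = "drop"
    ) |>
    select("family", "chrom", "start", "end", "strand",
           "n_monomers", "mean_identity") |>
    arrange(.data$family, .data$chrom, .data$start)
}

#' Annotate a whole assembly with a satDNA family library
#'
#' Runs [find_monomer_hits()] and [merge_hits_into_arrays()] for every
#' family on every chromosome. Deterministic given its inputs.
#'
#' @param families Family tibble with `family`, `monomer`, `rul` columns.
#' @param assembly Named character vector or `DNAStringSet` of chromosomes.
#' @param min_identity Identity threshold in percent (default 70).
#' @param max_gap_factor Merge gap in repeat units (default 1: hits closer
#'   than one repeat unit length join one array).
#' @return A `sat_annotation` tibble of arrays across all families and
#'   chromosomes, with chromosome lengths and parameters attached as
#'   attributes.
#' @export
annotate_assembly <- function(families, assembly, min_identity = 70,
                              max_gap_factor = 1) {
  assembly <- as_assembly(assembly)
  if (anyDuplicated(families$family)) abort("family names must be unique")
  chrom_seqs <- as.character(assembly)
  arrays <- purrr::map_dfr(seq_len(nrow(families)), function(i) {
    purrr::map_dfr(names(chrom_seqs), function(ch) {
      hits <- find_monomer_hits(
        chrom_seqs[[ch]], families$monomer[i], min_identity = min_identity,
        family = families$family[i], chrom = ch
      )
      merge_hits_into_arrays(hits, max_gap = max_gap_factor * families$rul[i])
    })
  })
  if (nrow(arrays) == 0) {
    arrays <- merge_hits_into_arrays(empty_hits(), max_gap = 0)
  }
  structure(
    arrays,
    chrom_lengths = stats::setNames(Biostrings::width(assembly), names(assembly)),
    params = list(min_identity = min_identity, max_gap_factor = max_gap_factor),
    class = c("sat_annotation", class(arrays))
  )
}

#' @export
tidy.sat_annotation <- function(x, ...) {
  as_tibble(unclass_annotation(x))
}

unclass_annotation <- function(x) {
  attr(x, "chrom_lengths") <- NULL
  attr(x, "params") <- NULL
  class(x) <- setdiff(class(x), "sat_annotation")
  x
}

#' @export
glance.sat_annotation <- function(x, ...) {
  tibble(
    n_families = dplyr::n_distinct(x$family),
    n_arrays = nrow(x),
    total_bp = sum(x$end - x$start),
    min_identity = attr(x, "params")$min_identity,
    max_gap_factor = attr(x, "params")$max_gap_factor
  )
}

#' Per-bin occupied base pairs along a chromosome
#'
#' Splits array bp into fixed-width bins (an array straddling a bin
#' boundary contributes proportionally to both bins), for density tracks.
#' Total bp is conserved: the per-bin values of one family on one
#' chromosome sum to its total annotated bp there.
#'
#' @param arrays Array tibble (one chromosome's worth, or more; binning is
#'   per `chrom`).
#' @param chrom_lengths Named vector of chromosome lengths in bp.
#' @param bin_size Bin width in bp (default 100 kb; the last bin may be
#'   short).
#' @return A tibble `chrom`, `family`, `bin_start`, `bin_end`, `bp`.
#' @export
binned_density <- function(arrays, chrom_lengths, bin_size = 1e5) {
  stopifnot(bin_size >= 1)
  if (nrow(arrays) == 0) {
    return(tibble(chrom = character(), family = character(),
                  bin_start = numeric(), bin_end = numeric(), bp = numeric()))
  }
  if (!all(arrays$chrom %in% names(chrom_lengths))) {
    abort("arrays reference chromosomes absent from `chrom_lengths`")
  }
  purrr::map_dfr(seq_len(nrow(arrays)), function(i) {
    a <- arrays[i, ]
    L <- chrom_lengths[[a$chrom]]
    first_bin <- floor(a$start / bin_size)
    last_bin <- floor((a$end - 1) / bin_size)
    bs <- (first_bin:last_bin) * bin_size
    tibble(
      chrom = a$chrom, family = a$family,
      bin_start = bs, bin_end = pmin(bs + bin_size, L),
      bp = pmin(a$end, bs + bin_size) - pmax(a$start, bs)
    )
  }) |>
    group_by(.data$chrom, .data$family, .data$bin_start, .data$bin_end) |>
    summarise(bp = sum(.data$bp), .groups = "drop")
}
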