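# Satellitome summary statistics: ranking, naming, and the aggregate
# numbers of a family table (count, total fraction, divergence range and
# mean, repeat-unit-length range and histogram).

#' Load a satellitome family table
#'
#' Reads a tab-separated family table with the header
#' `family  genome_percent  divergence_k2p  rul_bp  at_percent`. The
#' packaged table for the *Chrysolina americana* satellitome (165
#' families) ships at
#' `system.file("extdata", "camericana_satellitome.tsv", package = "satmapper")`.
#'
#' Family ids are preserved verbatim (including suffixes such as `-tel`
#' marking the telomeric repeat); the repeat unit length comes from the
#' numeric column, not the name.
#'
#' @param path Path to the TSV file.
#' @return A family tibble: `family`, `rank`, `abundance_percent`,
#'   `divergence_percent`, `rul`, `at_percent`, `telomeric`.
#' @export
load_table_fixture <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  header <- strsplit(readLines(path, n = 1), "\t", fixed = TRUE)[[1]]
  expected <- c("family", "genome_percent", "divergence_k2p", "rul_bp", "at_percent")
  if (!identical(header, expected)) {
    abort(paste0("bad header; expected: ", paste(expected, collapse = ", ")),
          class = "satmapper_error_table")
  }
  raw <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = "character", quote = "",
                           comment.char = "")
  if (nrow(raw) == 0) abort("family table has no data rows",
                            class = "satmapper_error_table")
  num <- function(x, col) {
    v <- suppressWarnings(as.numeric(x))
    if (any(is.na(v))) {
      abort(sprintf("malformed value in column %s, row %d", col, which(is.na(v))[1]),
            class = "satmapper_error_table")
    }
    v
  }
  rul <- num(raw$rul_bp, "rul_bp")
  if (any(rul != floor(rul) | rul < 1)) {
    abort(sprintf("malformed value in column rul_bp, row %d",
                  which(rul != floor(rul) | rul < 1)[1]),
          class = "satmapper_error_table")
  }
  tibble(
    family = raw$family,
    rank = seq_len(nrow(raw)),
    abundance_percent = num(raw$genome_percent, "genome_percent"),
    divergence_percent = num(raw$divergence_k2p, "divergence_k2p"),
    rul = as.integer(rul),
    at_percent = num(raw$at_percent, "at_percent"),
    telomeric = grepl("-tel$", raw$family)
  )
}

#' Rank families by abundance and apply the naming convention
#'
#' Orders families by descending abundance (ties: descending masked bp if
#' present, then input order - deterministic under re-runs), assigns
#' 1-based ranks and regenerates names with [name_family()].
#'
#' @param families Family tibble with `abundance_percent` (and optionally
#'   `masked_bp`) columns.
#' @param genus,species Scientific name used for the convention names.
#' @return The family tibble reordered, with `rank` and `family` replaced.
#' @export
rank_and_name <- function(families, genus, species) {
  if (!"abundance_percent" %in% names(families) ||
      any(is.na(families$abundance_percent))) {
    abort("all families need an `abundance_percent` for ranking")
  }
  mb <- families[["masked_bp"]] %||% rep(0, nrow(families))
  ord <- order(-families$abundance_percent, -mb, seq_len(nrow(families)))
  out <- families[ord, ]
  out$rank <- seq_len(nrow(out))
  out$family <- name_family(genus, species, out$rank, out$rul)
  stopifnot(!anyDuplicated(out$family))
  out
}

#' Summarize a satellitome
#'
#' Aggregate statistics over a family table: family count, total genome
#' fraction, combined abundance of the top `k` families, the divergence
#' range (over non-telomeric satDNA families - the telomeric repeat is a
#' simple-sequence array, not a satDNA family proper) and unweighted mean
#' divergence (over all families), the repeat-unit-length range, and a
#' 100-bp-binned RUL histogram.
#'
#' @param families Family tibble as from [load_table_fixture()] or
#'   [rank_and_name()]; `abundance_percent`, `divergence_percent` and
#'   `rul` are required.
#' @param k Number of top families for `top_k_percent` (default 3).
#' @return A `satellitome_summary` list with the aggregate fields and a
#'   `rul_histogram` tibble; see also [glance.satellitome_summary()].
#' @export
summarize_satellitome <- function(families, k = 3) {
  if (nrow(families) == 0) abort("empty family table")
  need <- c("family", "abundance_percent", "divergence_percent", "rul")
  if (!all(need %in% names(families))) {
    abort(paste0("`families` must have columns: ", paste(need, collapse = ", ")))
  }
  tel <- families[["telomeric"]] %||% grepl("-tel$", families$family)
  div <- families$divergence_percent
  div_rng <- div
  div_rng[tel] <- NA
  top <- sort(families$abundance_percent, decreasing = TRUE)
  hist <- families |>
    mutate(bin_lower = pmax(1, floor((.data$rul - 1) / 100) * 100 + 1)) |>
    group_by(.data$bin_lower) |>
    summarise(n = n(), .groups = "drop") |>
    mutate(bin_upper = .data$bin_lower + 99) |>
    select("bin_lower", "bin_upper", "n") |>
    arrange(.data$bin_lower)
  i_rng <- function(v, f) families$family[which(v == f(v, na.rm = TRUE))[1]]
  structure(list(
    n_families = nrow(families),
    total_percent = sum(families$abundance_percent),
    top_k = min(k, nrow(families)),
    top_k_percent = sum(top[seq_len(min(k, nrow(families)))]),
    min_divergence = min(div_rng, na.rm = TRUE),
    min_divergence_family = i_rng(div_rng, min),
    max_divergence = max(div_rng, na.rm = TRUE),
    max_divergence_family = i_rng(div_rng, max),
    mean_divergence = mean(div),
    min_rul = min(families$rul),
    min_rul_family = families$family[which.min(families$rul)],
    max_rul = max(families$rul),
    max_rul_family = families$family[which.max(families$rul)],
    rul_histogram = hist
  ), class = "satellitome_summary")
}

#' @export
print.satellitome_summary <- function(x, ...) {
  cat(sprintf("Satellitome of %d satDNA families\n", x$n_families))
  cat(sprintf("  total genome fraction: %.2f%% (top %d: %.4f%%)\n",
              x$total_percent, x$top_k, x$top_k_percent))
  cat(sprintf("  K2P divergence: %.2f-%.2f%% (%s to %s), mean %.2f%%\n",
              x$min_divergence, x$max_divergence,
              x$min_divergence_family, x$max_divergence_family,
              x$mean_divergence))
  cat(sprintf("  repeat unit length: %d bp (%s) to %d bp (%s)\n",
              x$min_rul, x$min_rul_family, x$max_rul, x$max_rul_family))
  invisible(x)
}

#' One-row summary of a satellitome
#'
#' @param x A `satellitome_summary` from [summarize_satellitome()].
#' @param ... Unused.
#' @return A one-row tibble of the scalar aggregates.
#' @export
glance.satellitome_summary <- function(x, ...) {
  as_tibble(x[c("n_families", "total_percent", "top_k_percent",
                "min_divergence", "max_divergence", "mean_divergence",
                "min_rul", "max_rul")])
}

#' @export
tidy.satellitome_summary <- function(x, ...) {
  x$rul_histogram
}
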