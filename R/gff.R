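# GFF3 / BED serialization of tandem-array annotations. Internal
# coordinates are 0-based half-open; GFF3 is 1-based inclusive.

arrays_to_granges <- function(arrays) {
  gr <- GenomicRanges::GRanges(
    seqnames = arrays$chrom,
    ranges = IRanges::IRanges(start = arrays$start + 1L, end = arrays$end),
    strand = arrays$strand
  )
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    source = rep("chrismapp", nrow(arrays)),
    type = rep("satellite_DNA", nrow(arrays)),
    ID = sprintf("array%05d", seq_len(nrow(arrays))),
    family = arrays$family,
    n_monomers = arrays$n_monomers,
    mean_identity = arrays$mean_identity
  )
  gr
}

#' Write tandem-array annotations to GFF3
#'
#' Writes one `satellite_DNA` feature per array (source `chrismapp`),
#' 1-based inclusive coordinates, with the family id, monomer count and
#' mean identity carried in the attributes column. [read_gff3()] inverts
#' the writer.
#'
#' @param arrays Array tibble (see [merge_hits_into_arrays()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(arrays, path) {
  arrays <- as_tibble(arrays)
  if (nrow(arrays) == 0) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  gr <- arrays_to_granges(arrays)
  rtracklayer::export.gff3(gr, path)
  # drop the date stamp so identical runs yield identical bytes
  lines <- readLines(path)
  writeLines(lines[!grepl("^##date", lines)], path)
  invisible(path)
}

#' Read tandem-array annotations from GFF3
#'
#' @param path A GFF3 file written by [write_gff3()] (or compatible).
#' @return An array tibble with 0-based half-open coordinates.
#' @export
read_gff3 <- function(path) {
  lines <- readLines(path)
  body <- !grepl("^#", lines) & nzchar(lines)
  nfield <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nfield != 9)) {
    bad <- which(body)[which(nfield != 9)[1]]
    abort(sprintf("malformed GFF3: line %d does not have 9 tab-separated fields", bad),
          class = "satmapper_error_gff3")
  }
  gr <- rtracklayer::import(path, format = "gff3")
  md <- S4Vectors::mcols(gr)
  tibble(
    family = as.character(md$family),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    n_monomers = as.integer(md$n_monomers),
    mean_identity = as.numeric(md$mean_identity)
  )
}

#' Write tandem-array annotations to BED6
#'
#' 0-based half-open coordinates; the score column is the array mean
#' identity times 10 (0-1000 scale).
#'
#' @inheritParams write_gff3
#' @return `path`, invisibly.
#' @export
write_bed <- function(arrays, path) {
  arrays <- as_tibble(arrays)
  df <- data.frame(
    chrom = arrays$chrom,
    start = format(arrays$start, scientific = FALSE, trim = TRUE),
    end = format(arrays$end, scientific = FALSE, trim = TRUE),
    name = arrays$family,
    score = round(arrays$mean_identity * 10),
    strand = arrays$strand
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
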