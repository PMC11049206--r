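# End-to-end orchestration: annotate -> quantify -> landscape -> summarize
# -> plot, with file artifacts and a structured run log.

pipeline_defaults <- function() {
  list(min_identity = 70, max_gap_factor = 1, top_k = 5, seed = 1,
       bin_width = 1, genus = "Genus", species = "species",
       figure_format = "svg")
}

#' Run the full satellitome pipeline
#'
#' Executes annotation of the assembly, read masking and quantification
#' (when reads are given), families re-ranked and renamed by estimated
#' abundance, repeat landscape, satellitome summary, and the chromosome
#' distribution map. Artifacts are written under `out_dir`:
#' `annotation.gff3`, `annotation.bed`, `quantification.tsv`,
#' `landscape.tsv`, `summary.tsv`, `chromosome_maps.svg` (or `.pdf`) and
#' `run_log.txt`. Re-running with the same inputs and seed reproduces the
#' GFF3 and TSV files byte for byte.
#'
#' @param config A named list, or a path to a YAML file with the same
#'   keys. Required: `assembly` (FASTA path or named sequences), `library`
#'   (consensus FASTA path or family tibble), `out_dir`. Optional: `reads`
#'   (FASTA/FASTQ path or sequences), `min_identity` (70), `max_gap_factor`
#'   (1), `top_k` (5), `seed` (1), `bin_width` (1), `genus`, `species`,
#'   `figure_format` ("svg" or "pdf").
#' @return Invisibly, a list with the in-memory results (`annotation`,
#'   `quantification`, `landscape`, `summary`, `paths`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) abort("`config` must be a list or a YAML path")
  for (key in c("assembly", "library", "out_dir")) {
    if (is.null(config[[key]])) {
      abort(sprintf("config is missing required key `%s`", key))
    }
  }
  cfg <- utils::modifyList(pipeline_defaults(), config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    gff3 = file.path(cfg$out_dir, "annotation.gff3"),
    bed = file.path(cfg$out_dir, "annotation.bed"),
    quant = file.path(cfg$out_dir, "quantification.tsv"),
    landscape = file.path(cfg$out_dir, "landscape.tsv"),
    summary = file.path(cfg$out_dir, "summary.tsv"),
    figure = file.path(cfg$out_dir,
                       paste0("chromosome_maps.", cfg$figure_format)),
    log = file.path(cfg$out_dir, "run_log.txt")
  )
  log_lines <- c(
    sprintf("satmapper %s", as.character(utils::packageVersion("satmapper"))),
    sprintf("R %s", getRversion()),
    sprintf("seed: %d", as.integer(cfg$seed)),
    sprintf("min_identity: %s", cfg$min_identity),
    sprintf("max_gap_factor: %s", cfg$max_gap_factor),
    sprintf("top_k: %s", cfg$top_k)
  )
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
            parent = e)
    })
  }
  set.seed(as.integer(cfg$seed))

  families <- stage("load_library", {
    if (is.character(cfg$library)) read_consensus_library(cfg$library)
    else cfg$library
  })
  assembly <- stage("load_assembly", {
    if (is.character(cfg$assembly) && length(cfg$assembly) == 1 &&
        file.exists(cfg$assembly)) read_assembly(cfg$assembly)
    else as_assembly(cfg$assembly)
  })

  ann <- stage("annotate", annotate_assembly(
    families, assembly, min_identity = cfg$min_identity,
    max_gap_factor = cfg$max_gap_factor))
  stage("write_annotation", {
    write_gff3(ann, paths$gff3)
    write_bed(ann, paths$bed)
  })
  log_lines <- c(log_lines,
                 sprintf("arrays: %d on %d chromosome(s)", nrow(ann),
                         length(attr(ann, "chrom_lengths"))))

  quant <- landscape <- NULL
  if (!is.null(cfg$reads)) {
    quant <- stage("quantify", mask_and_quantify(
      cfg$reads, families, min_identity = cfg$min_identity))
    families <- stage("rank", {
      ranked <- families |>
        select(-dplyr::any_of(c("abundance_percent", "divergence_percent"))) |>
        left_join(tidy(quant) |>
                    select("family", "masked_bp", "abundance_percent",
                           "divergence_percent"),
                  by = "family")
      rank_and_name(ranked, cfg$genus, cfg$species)
    })
    stage("write_quant", {
      out <- tidy(quant) |>
        select("family", "masked_bp",
               genome_percent = "abundance_percent",
               divergence_k2p = "divergence_percent")
      readr::write_tsv(out, paths$quant)
    })
    landscape <- stage("landscape", repeat_landscape(
      quant, bin_width = cfg$bin_width))
    stage("write_landscape", {
      wide <- landscape |>
        as_tibble() |>
        select("family", "bin_lower", "abundance_percent") |>
        tidyr::pivot_wider(names_from = "bin_lower", names_prefix = "div_",
                           values_from = "abundance_percent", values_fill = 0)
      readr::write_tsv(wide, paths$landscape)
    })
    summ <- stage("summarize", summarize_satellitome(
      families |> mutate(divergence_percent = .data$divergence_percent),
      k = min(cfg$top_k, nrow(families))))
    stage("write_summary", readr::write_tsv(glance(summ), paths$summary))
    log_lines <- c(log_lines,
                   sprintf("masked: %.3f%% of read bp",
                           glance(quant)$masked_percent))
  } else {
    summ <- NULL
  }

  fig <- stage("plot", plot_chromosome_maps(
    ann, top_k = cfg$top_k,
    family_order = if (!is.null(quant)) {
      dplyr::arrange(tidy(quant), desc(.data$abundance_percent))$family
    } else NULL))
  stage("write_figure", save_vector_plot(fig, paths$figure))

  writeLines(log_lines, paths$log)
  invisible(list(annotation = ann, quantification = quant,
                 landscape = landscape, summary = summ,
                 families = families, paths = paths))
}
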