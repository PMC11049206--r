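# Synthetic genomes with planted satDNA arrays and simulated reads: known
# truth for validating the annotator and the read quantifier.

TRANSITION <- c(A = "G", G = "A", C = "T", T = "C")
TRANSVERSIONS <- list(A = c("C", "T"), G = c("C", "T"),
                      C = c("A", "G"), T = c("A", "G"))

random_dna <- function(n, at = 0.642) {
  p <- c(A = at / 2, T = at / 2, C = (1 - at) / 2, G = (1 - at) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

#' Mutate a monomer to a target K2P divergence
#'
#' Each site substitutes independently with a probability calibrated so
#' the expected K2P divergence of the copy against the consensus equals
#' `d_target`; substitutions are transitions with odds `tstv_ratio` : 1
#' over transversions. Optionally, short indels are introduced at rate
#' `indel_rate` per site (length 1-3, insertion or deletion equiprobable).
#' Mirrors a stochastic substitution process: individual copies scatter
#' around the target, families average to it.
#'
#' @param monomer Consensus monomer sequence.
#' @param d_target Target K2P divergence (proportion scale, e.g. 0.07).
#' @param tstv_ratio Transition:transversion odds (default 2).
#' @param indel_rate Per-site indel probability (default 0: substitutions
#'   only).
#' @param seed Optional integer seed; otherwise the global RNG stream is
#'   used.
#' @return The mutated copy as a single string.
#' @export
mutate_to_divergence <- function(monomer, d_target, tstv_ratio = 2,
                                 indel_rate = 0, seed = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  monomer <- toupper(monomer)
  check_dna(monomer, "monomer")
  stopifnot(d_target >= 0, tstv_ratio > 0, indel_rate >= 0)
  bases <- strsplit(monomer, "")[[1]]
  p <- k2p_site_probability(d_target, tstv_ratio)
  hit <- stats::runif(length(bases)) < p
  for (i in which(hit & bases != "N")) {
    if (stats::runif(1) < tstv_ratio / (tstv_ratio + 1)) {
      bases[i] <- TRANSITION[[bases[i]]]
    } else {
      bases[i] <- sample(TRANSVERSIONS[[bases[i]]], 1)
    }
  }
  if (indel_rate > 0) {
    ind <- which(stats::runif(length(bases)) < indel_rate)
    for (i in rev(ind)) {  # right to left so indices stay valid
      len <- sample(1:3, 1)
      if (stats::runif(1) < 0.5) {
        bases <- bases[-(i:min(i + len - 1, length(bases)))]
      } else {
        ins <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
        bases <- append(bases, ins, after = i)
      }
    }
  }
  paste(bases, collapse = "")
}

#' Build a planting plan
#'
#' Convenience constructor for the tibble consumed by [plant_arrays()].
#'
#' @param family Family name (must exist in the family table passed to
#'   [plant_arrays()]).
#' @param chrom Chromosome id.
#' @param start 0-based start of the planted array.
#' @param n_copies Number of monomer copies.
#' @param divergence Per-copy target K2P divergence (proportion).
#' @param tstv_ratio Transition:transversion odds.
#' @param strand `"+"` or `"-"`.
#' @param interleaved Set `TRUE` on rows deliberately planted inside
#'   another family's block; overlap checking then skips them.
#' @return A plan tibble.
#' @export
plant_plan <- function(family, chrom, start, n_copies, divergence = 0,
                       tstv_ratio = 2, strand = "+", interleaved = FALSE) {
  tibble(family = family, chrom = chrom, start = as.integer(start),
         n_copies = as.integer(n_copies), divergence = divergence,
         tstv_ratio = tstv_ratio, strand = strand,
         interleaved = interleaved)
}

#' Plant satDNA arrays in a synthetic genome
#'
#' Generates i.i.d. background chromosomes at a given A+T content (default
#' 64.2%, an insect-like composition) and overwrites the planned intervals
#' with tandem arrays of independently mutated monomer copies. Fully
#' reproducible from the seed.
#'
#' @param plan Plan tibble from [plant_plan()] (rows may be concatenated
#'   with `bind_rows()`).
#' @param families Family tibble carrying the consensus monomers.
#' @param chrom_lengths Named vector of chromosome lengths in bp.
#' @param background_at Background A+T fraction (default 0.642).
#' @param seed Optional integer seed.
#' @return A `sat_synthesis` list: `genome` (`DNAStringSet`), `truth`
#'   (array tibble with planted coordinates and `n_monomers`), and
#'   `substitutions` (per-copy transition/transversion counts).
#' @export
plant_arrays <- function(plan, families, chrom_lengths,
                         background_at = 0.642, seed = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  if (nrow(plan) > 0 && !all(plan$family %in% families$family)) {
    abort("plan references families absent from `families`")
  }
  rul <- stats::setNames(families$rul, families$family)
  if (nrow(plan) > 0) {
    plan$end <- plan$start + plan$n_copies * rul[plan$family]
    if (!all(plan$chrom %in% names(chrom_lengths))) {
      abort("plan references chromosomes absent from `chrom_lengths`")
    }
    if (any(plan$start < 0 | plan$end > chrom_lengths[plan$chrom])) {
      abort("planted intervals must lie within chromosome bounds")
    }
    strict <- plan[!plan$interleaved, ]
    for (ch in unique(strict$chrom)) {
      p <- strict[strict$chrom == ch, ]
      p <- p[order(p$start), ]
      if (nrow(p) > 1 && any(p$start[-1] < p$end[-nrow(p)])) {
        abort("planted intervals overlap (flag `interleaved` to allow)",
              class = "satmapper_error_overlap")
      }
    }
  }
  chroms <- lapply(chrom_lengths, random_dna, at = background_at)
  subs <- list()
  if (nrow(plan) > 0) {
    for (i in seq_len(nrow(plan))) {
      pr <- plan[i, ]
      monomer <- families$monomer[families$family == pr$family]
      copies <- vapply(seq_len(pr$n_copies), function(j) {
        mutate_to_divergence(monomer, pr$divergence, pr$tstv_ratio)
      }, character(1))
      arr <- paste(copies, collapse = "")
      if (pr$strand == "-") arr <- reverse_complement(arr)
      s <- chroms[[pr$chrom]]
      chroms[[pr$chrom]] <- paste0(
        substr(s, 1, pr$start), arr, substr(s, pr$start + nchar(arr) + 1, nchar(s))
      )
      subs[[i]] <- tibble(
        family = pr$family, chrom = pr$chrom, copy = seq_len(pr$n_copies),
        n_sub = vapply(copies, function(cp) {
          sum(strsplit(cp, "")[[1]] != strsplit(monomer, "")[[1]])
        }, numeric(1), USE.NAMES = FALSE)
      )
    }
  }
  truth <- if (nrow(plan) == 0) {
    tibble(family = character(), chrom = character(), start = integer(),
           end = integer(), strand = character(), n_monomers = integer(),
           divergence = numeric())
  } else {
    tibble(family = plan$family, chrom = plan$chrom, start = plan$start,
           end = as.integer(plan$end), strand = plan$strand,
           n_monomers = plan$n_copies, divergence = plan$divergence)
  }
  structure(list(
    genome = Biostrings::DNAStringSet(unlist(chroms)),
    truth = truth,
    substitutions = dplyr::bind_rows(subs)
  ), class = "sat_synthesis")
}

#' Simulate shotgun reads from a genome
#'
#' Uniform start positions (chromosomes weighted by the number of valid
#' start positions), both strands equiprobable; the read count is
#' `round(coverage * genome_bp / read_length)`. Error-free in the base
#' model; an optional uniform substitution error rate can be applied.
#'
#' @param genome `DNAStringSet` (e.g. `plant_arrays()$genome`) or named
#'   character vector.
#' @param read_length Read length in bp (default 101).
#' @param coverage Mean sequencing depth.
#' @param seed Optional integer seed.
#' @param paired If `TRUE`, reads are drawn as outer ends of 350-bp
#'   fragments (mate pairs occupy consecutive entries).
#' @param error_rate Per-base substitution error probability (default 0).
#' @return A `DNAStringSet` of reads; the origin of each read (chromosome,
#'   0-based start, strand) is attached as the `"origins"` attribute.
#' @export
simulate_reads <- function(genome, read_length = 101, coverage = 5,
                           seed = NULL, paired = FALSE, error_rate = 0) {
  if (!is.null(seed)) withr::local_seed(seed)
  genome <- as_assembly(genome)
  stopifnot(coverage > 0)
  if (read_length > min(Biostrings::width(genome))) {
    abort("`read_length` exceeds the shortest chromosome")
  }
  lens <- Biostrings::width(genome)
  n <- round(coverage * sum(lens) / read_length)
  if (paired) n <- 2 * floor(n / 2)
  seqs <- as.character(genome)
  if (paired) {
    insert <- 350L
    npair <- n %/% 2
    valid <- pmax(lens - insert + 1, 0)
    ch <- sample(seq_along(lens), npair, replace = TRUE, prob = valid)
    st <- floor(stats::runif(npair) * valid[ch])
    r1 <- substr(seqs[ch], st + 1, st + read_length)
    r2 <- reverse_complement(substr(seqs[ch], st + insert - read_length + 1,
                                    st + insert))
    reads <- as.vector(rbind(r1, r2))
    origins <- tibble(
      read = seq_len(n),
      chrom = rep(names(genome)[ch], each = 2),
      start = as.integer(as.vector(rbind(st, st + insert - read_length))),
      strand = rep(c("+", "-"), npair)
    )
  } else {
    valid <- lens - read_length + 1
    ch <- sample(seq_along(lens), n, replace = TRUE, prob = valid)
    st <- floor(stats::runif(n) * valid[ch])
    reads <- substr(seqs[ch], st + 1, st + read_length)
    rc <- stats::runif(n) < 0.5
    reads[rc] <- reverse_complement(reads[rc])
    origins <- tibble(read = seq_len(n), chrom = names(genome)[ch],
                      start = as.integer(st),
                      strand = ifelse(rc, "-", "+"))
  }
  if (error_rate > 0) {
    reads <- vapply(reads, function(r) {
      b <- strsplit(r, "")[[1]]
      e <- which(stats::runif(length(b)) < error_rate & b != "N")
      for (i in e) b[i] <- sample(setdiff(c("A", "C", "G", "T"), b[i]), 1)
      paste(b, collapse = "")
    }, character(1), USE.NAMES = FALSE)
  }
  out <- Biostrings::DNAStringSet(reads)
  names(out) <- sprintf("read%06d", seq_along(out))
  attr(out, "origins") <- origins
  out
}
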