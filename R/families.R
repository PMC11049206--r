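# Domain model: satDNA families, the naming convention, sequence utilities,
# and construction of per-family search libraries.

VALID_BASES_RE <- "^[ACGTN]*$"
FAMILY_NAME_RE <- "^[A-Z][a-z]{3}Sat\\d{3}-\\d+"

check_dna <- function(seq, arg = "seq") {
  if (any(is.na(seq)) || !all(grepl(VALID_BASES_RE, seq))) {
    abort(
      paste0("`", arg, "` must contain only A, C, G, T or N ",
             "(ambiguity codes other than N are rejected)"),
      class = "satmapper_error_bad_sequence"
    )
  }
  invisible(seq)
}

#' A+T content of a DNA sequence
#'
#' Percentage of A+T among the unambiguous bases of a sequence. `N` bases
#' carry no compositional information and are excluded from both the
#' numerator and the denominator.
#'
#' @param seq Character vector of DNA sequences (A, C, G, T, N).
#' @return Numeric vector: `100 * (A + T) / (A + C + G + T)` per sequence.
#' @examples
#' at_content("GACTTGTCCC")  # 40
#' @export
at_content <- function(seq) {
  seq <- toupper(seq)
  check_dna(seq)
  at <- stringr::str_count(seq, "[AT]")
  acgt <- stringr::str_count(seq, "[ACGT]")
  if (any(acgt == 0)) {
    abort("A+T content is undefined for an empty or all-N sequence",
          class = "satmapper_error_bad_sequence")
  }
  100 * at / acgt
}

#' Name a satDNA family
#'
#' Builds the conventional satellitome family name: the capitalized first
#' letter of the genus, the first three letters of the species (lower
#' case), `"Sat"`, the abundance rank zero-padded to three digits, a dash,
#' and the repeat unit length in bp (e.g. `CameSat001-141`).
#'
#' @param genus,species Scientific name parts (species needs >= 3 letters).
#' @param rank Abundance rank, 1-based; at most 999.
#' @param rul Repeat unit length in bp.
#' @return Character vector of family names.
#' @examples
#' name_family("Chrysolina", "americana", 1, 141)
#' @export
name_family <- function(genus, species, rank, rul) {
  stopifnot(nchar(genus) >= 1, nchar(species) >= 3)
  if (any(rank < 1) || any(rank != floor(rank))) {
    abort("`rank` must be a positive integer")
  }
  if (any(rank > 999)) {
    abort("`rank` > 999 overflows the three-digit padding",
          class = "satmapper_error_rank_overflow")
  }
  if (any(rul < 1)) abort("`rul` must be a positive integer")
  paste0(
    toupper(substr(genus, 1, 1)), tolower(substr(species, 1, 3)),
    "Sat", sprintf("%03d", as.integer(rank)), "-", as.integer(rul)
  )
}

#' Reverse complement
#'
#' @param seq Character vector of DNA sequences over A, C, G, T, N.
#' @return Character vector of Watson-Crick reverse complements.
#' @examples
#' reverse_complement("TTAGG")  # "CCTAA"
#' @export
reverse_complement <- function(seq) {
  seq <- toupper(seq)
  check_dna(seq)
  out <- character(length(seq))
  nonempty <- nchar(seq) > 0
  if (any(nonempty)) {
    out[nonempty] <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(seq[nonempty]))
    )
  }
  out
}

#' Canonical rotation of a tandem-repeat monomer
#'
#' Tandem monomers have an arbitrary phase and strand relative to any
#' chosen consensus start. The canonical rotation is the lexicographically
#' smallest string among all cyclic rotations of the monomer and of its
#' reverse complement; it is invariant under rotation and strand flip and
#' therefore serves as a phase-free family identity.
#'
#' @param monomer Non-empty DNA string.
#' @return The canonical rotation, a single string.
#' @examples
#' canonical_rotation("AAAA")
#' @export
canonical_rotation <- function(monomer) {
  if (length(monomer) != 1 || nchar(monomer) == 0) {
    abort("`monomer` must be a single non-empty string")
  }
  monomer <- toupper(monomer)
  check_dna(monomer, "monomer")
  k <- nchar(monomer)
  rots <- function(s) {
    doubled <- paste0(s, s)
    vapply(seq_len(k), function(i) substr(doubled, i, i + k - 1), character(1))
  }
  min(c(rots(monomer), rots(reverse_complement(monomer))))
}

#' Assemble a satDNA family table
#'
#' Builds the tibble of satDNA families used throughout the package, one
#' row per family, from consensus monomer sequences.
#'
#' @param monomer Character vector of consensus monomers (A, C, G, T, N).
#' @param family Optional family names; defaults to `family1`, `family2`, ...
#'   until [rank_and_name()] assigns convention names.
#' @param abundance_percent,divergence_percent Optional per-family
#'   estimates (percent of genome; mean K2P x 100).
#' @return A tibble with columns `family`, `rank`, `monomer`, `rul`,
#'   `at_percent`, `abundance_percent`, `divergence_percent`.
#' @export
sat_families <- function(monomer, family = NULL, abundance_percent = NA_real_,
                         divergence_percent = NA_real_) {
  monomer <- toupper(monomer)
  check_dna(monomer, "monomer")
  if (any(nchar(monomer) == 0)) abort("monomers must be non-empty")
  family <- family %||% paste0("family", seq_along(monomer))
  if (anyDuplicated(family)) abort("family names must be unique")
  tibble(
    family = unname(as.character(family)),
    rank = seq_along(monomer),
    monomer = unname(monomer),
    rul = unname(nchar(monomer)),
    at_percent = unname(at_content(monomer)),
    abundance_percent = as.numeric(abundance_percent),
    divergence_percent = as.numeric(divergence_percent)
  )
}

#' Read a consensus monomer library from FASTA
#'
#' One record per family. Record ids matching the family naming pattern
#' (`[A-Z][a-z]{3}Sat\\d{3}-\\d+`) are kept as family names; otherwise
#' records keep their FASTA id and can be renamed after abundance ranking
#' with [rank_and_name()].
#'
#' @param path Path to a FASTA file of consensus monomers.
#' @return A family tibble as from [sat_families()].
#' @export
read_consensus_library <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0) abort("no records in consensus library")
  ids <- sub("\\s.*$", "", names(seqs))
  sat_families(as.character(seqs), family = ids)
}

#' Number of monomer copies in a search-library concatemer
#'
#' Families with repeat units longer than 100 bp are searched as dimers;
#' shorter families as the smallest head-to-tail concatemer of at least
#' 200 bp. The dimer branch also covers a repeat unit of exactly 100 bp
#' (its dimer already reaches 200 bp).
#'
#' @param rul Repeat unit length(s) in bp.
#' @return Integer vector of copy counts.
#' @export
concatemer_copies <- function(rul) {
  if (any(rul < 1)) abort("`rul` must be positive")
  ifelse(rul >= 100, 2L, as.integer(ceiling(200 / rul)))
}

#' Build per-family search libraries
#'
#' Concatenates each consensus monomer head-to-tail into the search
#' sequence used for read masking and quantification: a dimer for repeat
#' units above 100 bp, or enough copies to reach at least 200 bp for
#' shorter units, so that any 101-bp read window of a tandem array fits
#' inside the library sequence at every phase.
#'
#' @param families Family tibble (see [sat_families()]); `monomer` required.
#' @return A tibble with columns `family`, `sequence`, `copies`, `rul`.
#' @export
build_search_library <- function(families) {
  if (!all(c("family", "monomer", "rul") %in% names(families))) {
    abort("`families` must have columns family, monomer, rul")
  }
  if (any(is.na(families$monomer) | nchar(families$monomer) == 0)) {
    abort("all families need a consensus monomer")
  }
  copies <- concatemer_copies(families$rul)
  tibble(
    family = families$family,
    sequence = vapply(seq_len(nrow(families)), function(i) {
      strrep(families$monomer[i], copies[i])
    }, character(1)),
    copies = copies,
    rul = families$rul
  )
}
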