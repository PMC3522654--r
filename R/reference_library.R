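# Reference intron library: nucleotide FASTA + protein FASTA + metadata TSV,
# modelled on the group II intron database layout (name, ribozyme group,
# ORF class, ORF coordinates, EBS motifs, functional flag).

#' Read a reference group II intron library
#'
#' @param nt_fasta FASTA of full intron nucleotide sequences.
#' @param aa_fasta FASTA of the proteins encoded by the intron ORFs; record
#'   ids must match the nucleotide records.
#' @param metadata Path to a tab-separated table (or a data frame) with
#'   columns `name`, `ribozyme_group` (IIA/IIB/IIC), `orf_class` (A..F, CL1,
#'   CL2, ML, C), `orf_start`, `orf_end`, `ebs1`, `ebs2`, `ebs3`,
#'   `functional`.  Class C entries must have an empty `ebs2` (they carry
#'   only EBS1 and EBS3).
#' @return A tibble with one row per reference intron, including `seq` and
#'   `protein` columns.
#' @export
read_intron_library <- function(nt_fasta, aa_fasta, metadata) {
  nt <- Biostrings::readDNAStringSet(nt_fasta)
  aa <- Biostrings::readAAStringSet(aa_fasta)
  meta <- if (is.data.frame(metadata)) {
    tibble::as_tibble(metadata)
  } else {
    readr::read_tsv(metadata, show_col_types = FALSE)
  }
  nt_ids <- sub("\\s.*$", "", names(nt))
  aa_ids <- sub("\\s.*$", "", names(aa))
  lib <- meta |>
    dplyr::mutate(
      seq = clean_dna(as.character(nt)[match(.data$name, nt_ids)]),
      protein = toupper(as.character(aa)[match(.data$name, aa_ids)])
    )
  validate_intron_library(lib)
}

validate_intron_library <- function(lib) {
  lib <- tibble::as_tibble(lib)
  stopifnot(all(c("name", "ribozyme_group", "orf_class", "orf_start",
                  "orf_end", "ebs1", "ebs3", "functional", "seq",
                  "protein") %in% names(lib)))
  if (!"ebs2" %in% names(lib)) lib$ebs2 <- NA_character_
  if (any(is.na(lib$seq))) stop("reference sequence missing for some entries")
  bad <- lib$orf_end > nchar(lib$seq) | lib$orf_start < 1
  if (any(bad)) stop("ORF interval outside reference sequence")
  cc <- lib$orf_class == "C"
  if (any(cc & !(is.na(lib$ebs2) | lib$ebs2 == ""))) {
    stop("class C introns carry only EBS1 and EBS3; ebs2 must be empty")
  }
  lib
}
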