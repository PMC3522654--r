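# Genome input/output: multi-FASTA + manifest in, GFF3 feature tables out.
# Internal coordinates are 1-based closed intervals (the IRanges/GFF3
# convention), so no conversion happens at the GFF3 boundary.

#' Read bacterial genomes from FASTA plus a replicon manifest
#'
#' Every FASTA record becomes one replicon row.  Sequences are uppercased and
#' any non-ACGT letter (IUPAC ambiguity codes included) is collapsed to `N`;
#' `N` never matches a consensus base in downstream scans.
#'
#' @param fasta Path(s) to multi-record FASTA file(s).
#' @param manifest Path to a tab-separated table with columns `record_id`,
#'   `strain`, `genus_complex`, `kind` (`chromosome`/`plasmid`) and
#'   `topology` (`linear`/`circular`), or a data frame with those columns.
#' @return A tibble with one row per replicon: `genome`, `genus_complex`,
#'   `replicon`, `kind`, `topology`, `length`, `seq`.
#' @export
read_genomes <- function(fasta, manifest) {
  seqs <- do.call(c, lapply(fasta, Biostrings::readDNAStringSet))
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA record id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  man <- if (is.data.frame(manifest)) {
    tibble::as_tibble(manifest)
  } else {
    readr::read_tsv(manifest, show_col_types = FALSE)
  }
  needed <- c("record_id", "strain", "genus_complex", "kind", "topology")
  missing_cols <- setdiff(needed, names(man))
  if (length(missing_cols)) {
    stop("manifest lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  absent <- setdiff(ids, man$record_id)
  if (length(absent)) {
    stop("FASTA record(s) absent from manifest: ",
         paste(absent, collapse = ", "))
  }
  tibble::tibble(
    record_id = ids,
    seq = unname(clean_dna(as.character(seqs)))
  ) |>
    dplyr::inner_join(man, by = "record_id") |>
    dplyr::transmute(
      genome = .data$strain,
      genus_complex = .data$genus_complex,
      replicon = .data$record_id,
      kind = tolower(.data$kind),
      topology = tolower(.data$topology),
      length = nchar(.data$seq),
      seq = .data$seq
    ) |>
    validate_genomes()
}

validate_genomes <- function(genomes) {
  stopifnot(all(nchar(genomes$seq) > 0))
  stopifnot(all(genomes$kind %in% c("chromosome", "plasmid")))
  stopifnot(all(genomes$topology %in% c("linear", "circular")))
  stopifnot(all(genomes$genus_complex != ""))
  if (anyDuplicated(genomes$replicon)) stop("duplicate replicon ids")
  genomes
}

#' Write detected intron copies and homing sites as GFF3
#'
#' Copies are emitted with type `group_II_intron` and sites with type
#' `homing_site`; attributes carry the assigned name, completeness and
#' availability state.
#'
#' @param copies Tibble of intron copies (as from [detect_introns()]); may be
#'   empty.
#' @param sites Tibble of site occurrences (as from [mark_occupancy()]); may
#'   be empty.
#' @param genomes Replicon tibble from [read_genomes()] (used to validate
#'   coordinates against replicon lengths).
#' @param path Output GFF3 path.
#' @return `path`, invisibly.
#' @export
write_features <- function(copies, sites, genomes, path) {
  lens <- setNames(genomes$length, genomes$replicon)
  gr_list <- list()
  check_bounds <- function(df, what) {
    if (nrow(df) == 0) return(invisible(NULL))
    bad <- df$end > lens[df$replicon] | df$start < 1
    if (any(is.na(bad)) || any(bad)) {
      stop(what, " interval outside replicon bounds")
    }
  }
  if (!is.null(copies) && nrow(copies)) {
    check_bounds(copies, "copy")
    gr_list$copies <- GenomicRanges::GRanges(
      seqnames = copies$replicon,
      ranges = IRanges::IRanges(copies$start, copies$end),
      strand = copies$strand,
      type = "group_II_intron",
      Name = copies$assigned_name,
      completeness = tolower(copies$completeness)
    )
  }
  if (!is.null(sites) && nrow(sites)) {
    check_bounds(sites, "site")
    gr_list$sites <- GenomicRanges::GRanges(
      seqnames = sites$replicon,
      ranges = IRanges::IRanges(sites$start, sites$end),
      strand = sites$strand,
      type = "homing_site",
      Name = sites$intron,
      state = tolower(sites$state)
    )
  }
  if (length(gr_list)) {
    gr <- suppressWarnings(do.call(c, unname(gr_list)))
    rtracklayer::export(gr, path, format = "gff3")
  } else {
    writeLines("##gff-version 3", path)
  }
  invisible(path)
}
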