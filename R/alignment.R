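# Seed-and-extend local alignment search.  Exact k-mer seeds select subject
# windows; a full affine-gap Smith-Waterman with iterative masking is then
# run inside each window, so every local alignment containing at least one
# exact seed k-mer is recovered together with its identity statistics.
# E-value statistics are deliberately out of scope: the detection contract
# is identity-over-length.

#' Detection search parameters
#'
#' Defaults: nucleotide scoring +1/-2 with affine gaps -5/-2, raw acceptance
#' at identity >= 0.60 over >= 50 bp (before the 100 bp / 75% detection
#' filters), seed k-mer 12 nt (4 aa for the protein search), protein scoring
#' BLOSUM62 with gaps -11/-1.
#'
#' @param k,k_aa Seed k-mer length for the nucleotide / protein search.
#' @param match,mismatch,gap_open,gap_ext Nucleotide scoring.
#' @param aa_gap_open,aa_gap_ext Protein gap scoring (BLOSUM62 substitution).
#' @param min_identity_raw,min_raw_length Raw hit acceptance contract.
#' @param min_score_nt,min_score_aa Stop thresholds for the iterative
#'   masking search.
#' @param min_length,min_similarity Detection filters: genomic footprint
#'   shorter than `min_length` is discarded; nucleotide hits below
#'   `min_similarity` are discarded (protein hits are exempt).
#' @param edge_slack Maximal distance (bp) from a reference extremity for a
#'   copy to count as covering that extremity.
#' @param locus_merge_gap Hits of one reference closer than this are merged
#'   into one copy locus.
#' @param name_divergence Copies more divergent than this from their
#'   reference receive a new systematic name.
#' @return A named list of parameters.
#' @export
detection_params <- function(k = 12, k_aa = 4, match = 1, mismatch = -2,
                             gap_open = -5, gap_ext = -2,
                             aa_gap_open = -11, aa_gap_ext = -1,
                             min_identity_raw = 0.60, min_raw_length = 50,
                             min_score_nt = 20, min_score_aa = 40,
                             min_length = 100, min_similarity = 0.75,
                             edge_slack = 15, locus_merge_gap = 50,
                             name_divergence = 0.10) {
  as.list(environment())
}

empty_hits <- function() {
  tibble::tibble(
    genome = character(), replicon = character(),
    start = integer(), end = integer(), strand = character(),
    ref_name = character(), ref_start = integer(), ref_end = integer(),
    identical = integer(), aligned = integer(), similarity = double(),
    score = integer(), level = character()
  )
}

# Search one query against one subject strand-pair; returns raw hit rows in
# genomic coordinates.  `subject` is the forward-strand replicon sequence.
search_nt_query <- function(qname, qseq, subject, params) {
  qlen <- nchar(qseq)
  margin <- qlen + 50L
  out <- list()
  for (str in c("+", "-")) {
    q <- if (str == "+") qseq else revcomp(qseq)
    win <- cpp_seed_windows(q, subject, params$k, margin)
    if (nrow(win) == 0) next
    for (w in seq_len(nrow(win))) {
      ws <- win[w, 1]; we <- win[w, 2]
      hits <- cpp_sw_hits_nt(q, substr(subject, ws, we), params$match,
                             params$mismatch, params$gap_open,
                             params$gap_ext, params$min_score_nt)
      if (nrow(hits) == 0) next
      hits <- tibble::as_tibble(hits)
      rs <- if (str == "+") hits$q_start else qlen - hits$q_end + 1L
      re <- if (str == "+") hits$q_end else qlen - hits$q_start + 1L
      out[[length(out) + 1]] <- tibble::tibble(
        start = hits$s_start + ws - 1L, end = hits$s_end + ws - 1L,
        strand = str, ref_name = qname, ref_start = rs, ref_end = re,
        identical = hits$identical, aligned = hits$aligned,
        similarity = hits$identical / hits$aligned, score = hits$score,
        level = "nt"
      )
    }
  }
  dplyr::bind_rows(out)
}

blosum62_table <- local({
  env <- new.env()
  function() {
    if (is.null(env$m)) {
      utils::data("BLOSUM62", package = "Biostrings", envir = env)
      env$m <- env$BLOSUM62
    }
    env$m
  }
})

# Protein search: 6-frame translation of the replicon, BLOSUM62 local
# alignment against the reference protein, coordinates mapped back to the
# genome (aa identity is reported; footprint is the genomic span in bp).
search_aa_query <- function(qname, qprot, subject, params) {
  b62 <- blosum62_table()
  alpha <- paste(rownames(b62), collapse = "")
  slen <- nchar(subject)
  out <- list()
  for (str in c("+", "-")) {
    sseq <- if (str == "+") subject else revcomp(subject)
    for (f in 1:3) {
      frame_seq <- substr(sseq, f, slen)
      frame_seq <- substr(frame_seq, 1, (nchar(frame_seq) %/% 3) * 3)
      if (nchar(frame_seq) < 3) next
      prot <- suppressWarnings(as.character(Biostrings::translate(
        Biostrings::DNAString(gsub("N", "A", frame_seq)),
        if.fuzzy.codon = "solve")))
      win <- cpp_seed_windows_aa(qprot, prot, params$k_aa, nchar(qprot) + 20L)
      if (nrow(win) == 0) next
      for (w in seq_len(nrow(win))) {
        ws <- win[w, 1]; we <- win[w, 2]
        hits <- cpp_sw_hits_matrix(qprot, substr(prot, ws, we),
                                   b62, alpha, params$aa_gap_open,
                                   params$aa_gap_ext, params$min_score_aa)
        if (nrow(hits) == 0) next
        hits <- tibble::as_tibble(hits)
        aa_s <- hits$s_start + ws - 1L
        aa_e <- hits$s_end + ws - 1L
        nt_s <- f + 3L * (aa_s - 1L)
        nt_e <- f + 3L * aa_e - 1L
        gs <- if (str == "+") nt_s else slen - nt_e + 1L
        ge <- if (str == "+") nt_e else slen - nt_s + 1L
        out[[length(out) + 1]] <- tibble::tibble(
          start = gs, end = ge, strand = str, ref_name = qname,
          ref_start = hits$q_start, ref_end = hits$q_end,
          identical = hits$identical, aligned = hits$aligned,
          similarity = hits$identical / hits$aligned, score = hits$score,
          level = "aa"
        )
      }
    }
  }
  dplyr::bind_rows(out)
}

#' Seed-and-extend search of a reference library against genomes
#'
#' Runs the nucleotide search for every library sequence (both strands) and,
#' when the library carries proteins, the 6-frame translated protein search,
#' and returns every raw local alignment meeting the raw identity/length
#' contract.
#'
#' @param genomes Replicon tibble from [read_genomes()].
#' @param library Reference library tibble ([read_intron_library()]), or any
#'   tibble with `name` and `seq` columns (optionally `protein`) to use as
#'   queries.
#' @param params [detection_params()].
#' @param level `"both"`, `"nt"` or `"aa"`.
#' @return A raw-hit tibble (one row per local alignment) with genomic and
#'   reference coordinates, identical/aligned counts, similarity and score.
#' @export
seed_extend_search <- function(genomes, library, params = detection_params(),
                               level = "both") {
  stopifnot(nrow(library) > 0, params$k >= 8)
  do_aa <- level %in% c("both", "aa") && "protein" %in% names(library)
  do_nt <- level %in% c("both", "nt")
  res <- purrr::pmap(
    list(genomes$genome, genomes$replicon, genomes$seq),
    function(gname, rid, subject) {
      rows <- list()
      for (qi in seq_len(nrow(library))) {
        if (do_nt) {
          rows[[length(rows) + 1]] <- search_nt_query(
            library$name[qi], library$seq[qi], subject, params)
        }
        if (do_aa && !is.na(library$protein[qi]) &&
            nzchar(library$protein[qi])) {
          rows[[length(rows) + 1]] <- search_aa_query(
            library$name[qi], library$protein[qi], subject, params)
        }
      }
      hits <- dplyr::bind_rows(rows)
      if (nrow(hits) == 0) return(NULL)
      hits$genome <- gname
      hits$replicon <- rid
      hits
    })
  hits <- dplyr::bind_rows(res)
  if (nrow(hits) == 0) return(empty_hits())
  hits |>
    dplyr::filter(
      .data$similarity >= params$min_identity_raw,
      .data$end - .data$start + 1L >= params$min_raw_length
    ) |>
    dplyr::select(dplyr::all_of(names(empty_hits()))) |>
    dplyr::arrange(.data$replicon, .data$start, .data$end, .data$ref_name)
}
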