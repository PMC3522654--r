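# Detection of group II intron copies: raw hits from the seed-and-extend
# search are overlap-filtered (best evidence per locus), passed through the
# 100 bp / 75% detection filters, complemented by a second search round that
# uses round-1 copies as queries to catch more divergent copies, and finally
# condensed into named, classified intron copies.

#' Filter overlapping raw hits, keeping the best evidence per locus
#'
#' Hits are clustered by single-linkage genomic overlap (>= 1 bp,
#' strand-agnostic, per replicon).  Within each cluster the hit with the most
#' identical sites is retained (ties: higher similarity, then leftmost start,
#' then smallest end); hits overlapping the retained one are removed and the
#' rule recurses on the remainder of the cluster.
#'
#' @param hits Raw-hit tibble from [seed_extend_search()].
#' @return A tibble of pairwise non-overlapping hits (a subset of the input).
#' @export
filter_overlapping_hits <- function(hits) {
  if (nrow(hits) == 0) return(hits)
  keep <- hits |>
    dplyr::group_split(.data$replicon) |>
    purrr::map(function(h) {
      h <- dplyr::arrange(h, dplyr::desc(.data$identical),
                          dplyr::desc(.data$similarity), .data$start,
                          .data$end, .data$ref_name, .data$level)
      kept <- h[0, ]
      while (nrow(h) > 0) {
        best <- h[1, ]
        kept <- dplyr::bind_rows(kept, best)
        ov <- h$start <= best$end & h$end >= best$start
        h <- h[!ov, , drop = FALSE]
      }
      kept
    }) |>
    dplyr::bind_rows()
  dplyr::arrange(keep, .data$replicon, .data$start, .data$end)
}

#' Apply the detection length and similarity filters
#'
#' Hits with a genomic footprint shorter than `min_length` are discarded;
#' nucleotide-level hits with similarity below `min_similarity` are also
#' discarded.  Protein-level hits are exempt from the similarity filter.
#' Both thresholds are strict ("shorter than" / "less than"), so a 100 bp
#' hit at exactly 75% similarity is retained.
#'
#' @param hits Raw-hit tibble.
#' @param min_length Minimal genomic footprint in bp (default 100).
#' @param min_similarity Minimal similarity for nucleotide hits (default
#'   0.75).
#' @return Filtered tibble.
#' @export
apply_detection_thresholds <- function(hits, min_length = 100,
                                       min_similarity = 0.75) {
  if (nrow(hits) == 0) return(hits)
  dplyr::filter(
    hits,
    .data$end - .data$start + 1L >= min_length,
    .data$level != "nt" | .data$similarity >= min_similarity
  )
}

# Extract the genomic sequence of a hit/copy row, strand-corrected.
extract_feature_seq <- function(genomes, replicon, start, end, strand) {
  seqs <- setNames(genomes$seq, genomes$replicon)
  s <- substr(seqs[replicon], start, end)
  ifelse(strand == "-", revcomp(s), s)
}

#' Second-round search using detected copies as queries
#'
#' Round-1 copy sequences (full-length and fragments) are re-searched against
#' the genomes to catch copies too divergent from the original references.
#' Genomic stretches already covered by round-1 hits are masked before
#' seeding, so only new loci are reported; round-2 hits inherit the
#' reference name of the copy that found them.
#'
#' @param genomes Replicon tibble.
#' @param round1_hits Filtered round-1 hit tibble.
#' @param params [detection_params()].
#' @return Combined, re-filtered hit tibble (round 1 plus new round-2 hits).
#' @export
second_round_search <- function(genomes, round1_hits,
                                params = detection_params()) {
  if (nrow(round1_hits) == 0) return(round1_hits)
  nt1 <- dplyr::filter(round1_hits, .data$level == "nt")
  queries <- nt1 |>
    dplyr::mutate(seq = extract_feature_seq(genomes, .data$replicon,
                                            .data$start, .data$end,
                                            .data$strand)) |>
    dplyr::distinct(.data$seq, .keep_all = TRUE) |>
    dplyr::transmute(name = .data$ref_name, seq = .data$seq)
  if (nrow(queries) == 0) return(round1_hits)
  masked <- genomes
  for (i in seq_len(nrow(round1_hits))) {
    r <- round1_hits[i, ]
    j <- match(r$replicon, masked$replicon)
    substr(masked$seq[j], r$start, r$end) <- strrep("X", r$end - r$start + 1L)
  }
  new_hits <- seed_extend_search(masked, queries, params, level = "nt")
  if (nrow(new_hits)) {
    # drop any residue contained in an already-detected locus
    contained <- purrr::map_lgl(seq_len(nrow(new_hits)), function(i) {
      r <- new_hits[i, ]
      any(round1_hits$replicon == r$replicon &
            round1_hits$start <= r$start & round1_hits$end >= r$end)
    })
    new_hits <- new_hits[!contained, , drop = FALSE]
  }
  dplyr::bind_rows(round1_hits, new_hits) |>
    filter_overlapping_hits() |>
    apply_detection_thresholds(params$min_length, params$min_similarity)
}

#' Classify copy completeness from merged reference coverage
#'
#' A locus is `full_length` when the merged alignment of its hits reaches
#' within `edge_slack` bp of both reference extremities, or when both intron
#' boundaries are confirmed by flanking evidence (an intron-free homologous
#' locus or another copy's flanks aligning contiguously across the insertion
#' point); otherwise it is a `fragment`.
#'
#' @param ref_intervals Matrix-like two-column data (start, end) of the
#'   locus hits' reference coordinates.
#' @param ref_length Reference intron length.
#' @param edge_slack Allowed distance from each extremity (default 15).
#' @param boundary_evidence Optional logical: both boundaries externally
#'   confirmed (flank comparison), overriding partial coverage.
#' @return `"full_length"` or `"fragment"`.
#' @export
classify_completeness <- function(ref_intervals, ref_length, edge_slack = 15,
                                  boundary_evidence = FALSE) {
  rs <- min(ref_intervals[, 1])
  re <- max(ref_intervals[, 2])
  covered <- rs <= edge_slack + 1L && re >= ref_length - edge_slack
  if (covered || isTRUE(boundary_evidence)) "full_length" else "fragment"
}

#' Assign intron names by the nomenclature rule
#'
#' A copy diverging by more than `name_divergence` (default 10%) from its
#' reference receives a new systematic name `<genome>.I<n>` (counter per
#' genome, in coordinate order); otherwise it keeps the reference name.
#' Deterministic and idempotent for a fixed copy table.
#'
#' @param copies Copy tibble with `genome`, `replicon`, `start`, `ref_name`,
#'   `identity` columns.
#' @param name_divergence Strict divergence threshold (default 0.10:
#'   divergence of exactly 0.10 keeps the reference name).
#' @return The tibble with an `assigned_name` column.
#' @export
assign_intron_names <- function(copies, name_divergence = 0.10) {
  if (nrow(copies) == 0) {
    copies$assigned_name <- character(0)
    return(copies)
  }
  copies |>
    dplyr::arrange(.data$genome, .data$replicon, .data$start) |>
    dplyr::group_by(.data$genome) |>
    dplyr::mutate(
      new_name = 1 - .data$identity > name_divergence,
      assigned_name = ifelse(
        .data$new_name,
        paste0(.data$genome, ".I", cumsum(.data$new_name)),
        .data$ref_name
      )
    ) |>
    dplyr::ungroup() |>
    dplyr::select(-"new_name")
}

# All uninterrupted ORFs (start ATG/GTG/TTG to in-frame stop) in the three
# forward frames of `seq`; returns tibble of 1-based [start, end] including
# the stop codon.
find_orfs <- function(seq) {
  n <- nchar(seq)
  ch <- seq_chars(seq)
  out <- list()
  starts_codons <- c("ATG", "GTG", "TTG")
  stops <- c("TAA", "TAG", "TGA")
  for (f in 1:3) {
    pos <- seq(f, n - 2, by = 3)
    if (length(pos) == 0) next
    cod <- paste0(ch[pos], ch[pos + 1], ch[pos + 2])
    stop_idx <- which(cod %in% stops)
    start_idx <- which(cod %in% starts_codons)
    prev_stop <- 0L
    for (si in stop_idx) {
      cand <- start_idx[start_idx > prev_stop & start_idx < si]
      if (length(cand)) {
        out[[length(out) + 1]] <- tibble::tibble(
          start = pos[cand[1]], end = pos[si] + 2L
        )
      }
      prev_stop <- si
    }
  }
  dplyr::bind_rows(out) %||%
    tibble::tibble(start = integer(), end = integer())
}

#' Assess whether a full-length copy retains an intact ORF
#'
#' True when the copy contains an uninterrupted open reading frame (ATG, GTG
#' or TTG start to stop, one frame) overlapping at least 90% of the
#' reference ORF interval projected on the copy and reaching at least 90% of
#' the reference ORF length.  Frameshifts and premature stops therefore
#' yield `FALSE`.
#'
#' @param copy_seq Strand-corrected copy sequence (full-length copies only).
#' @param orf_start,orf_end Reference ORF interval (1-based on the
#'   reference; projected 1:1 on the copy).
#' @param completeness The copy's completeness call; calling this on a
#'   fragment is an error.
#' @param min_fraction Overlap/length fraction (default 0.9).
#' @return Logical.
#' @export
assess_orf <- function(copy_seq, orf_start, orf_end,
                       completeness = "full_length", min_fraction = 0.9) {
  if (!identical(completeness, "full_length")) {
    stop("assess_orf() is defined for full-length copies only")
  }
  ref_len <- orf_end - orf_start + 1L
  orfs <- find_orfs(copy_seq)
  if (nrow(orfs) == 0) return(FALSE)
  ov <- pmin(orfs$end, orf_end) - pmax(orfs$start, orf_start) + 1L
  any(ov >= min_fraction * ref_len &
        (orfs$end - orfs$start + 1L) >= min_fraction * ref_len)
}

#' Detect group II intron copies in genomes
#'
#' Full two-round detection: seed-and-extend search of the nucleotide and
#' protein libraries, overlap filtering, 100 bp / 75% thresholds, a second
#' nucleotide round seeded with round-1 copies, locus merging, completeness
#' classification, ORF assessment and naming.
#'
#' @param genomes Replicon tibble from [read_genomes()].
#' @param library Reference library tibble.
#' @param params [detection_params()].
#' @return A copy tibble: `copy_id`, `genome`, `genus_complex`, `replicon`,
#'   `container`, `start`, `end`, `strand`, `ref_name`, `assigned_name`,
#'   `completeness`, `identity`, `orf_intact`, `level`.
#' @export
detect_introns <- function(genomes, library, params = detection_params()) {
  hits <- seed_extend_search(genomes, library, params) |>
    filter_overlapping_hits() |>
    apply_detection_thresholds(params$min_length, params$min_similarity)
  hits <- second_round_search(genomes, hits, params)
  copies_from_hits(hits, genomes, library, params)
}

# Merge filtered hits into copy loci and classify them.
copies_from_hits <- function(hits, genomes, library, params) {
  empty <- tibble::tibble(
    copy_id = character(), genome = character(), genus_complex = character(),
    replicon = character(), container = character(), start = integer(),
    end = integer(), strand = character(), ref_name = character(),
    assigned_name = character(), completeness = character(),
    identity = double(), orf_intact = logical(), level = character()
  )
  if (nrow(hits) == 0) return(empty)
  ginfo <- dplyr::select(genomes, "genome", "genus_complex", "replicon",
                         "kind")
  loci <- hits |>
    dplyr::arrange(.data$replicon, .data$start) |>
    dplyr::group_by(.data$replicon, .data$ref_name, .data$strand) |>
    dplyr::mutate(
      new_locus = .data$start - dplyr::lag(.data$end, default = -1e9) >
        params$locus_merge_gap,
      locus = cumsum(.data$new_locus)
    ) |>
    dplyr::group_by(.data$replicon, .data$ref_name, .data$strand,
                    .data$locus) |>
    dplyr::summarise(
      genome = .data$genome[1],
      start = min(.data$start), end = max(.data$end),
      ref_start = min(.data$ref_start), ref_end = max(.data$ref_end),
      identical = sum(.data$identical), aligned = sum(.data$aligned),
      level = if (any(.data$level == "nt")) "nt" else "aa",
      .groups = "drop"
    )
  lib_len <- setNames(nchar(library$seq), library$name)
  lib_pl <- if ("protein" %in% names(library)) {
    setNames(nchar(library$protein), library$name)
  } else {
    setNames(rep(NA_integer_, nrow(library)), library$name)
  }
  copies <- loci |>
    dplyr::left_join(ginfo, by = c("genome", "replicon")) |>
    dplyr::mutate(
      ref_length = ifelse(
        .data$level == "nt",
        lib_len[.data$ref_name],
        # protein-only loci: reference coords are in aa
        lib_pl[.data$ref_name]
      ),
      identity = .data$identical / .data$aligned,
      completeness = purrr::pmap_chr(
        list(.data$ref_start, .data$ref_end, .data$ref_length),
        function(rs, re, rl) {
          if (is.na(rl)) return("fragment")
          classify_completeness(cbind(rs, re), rl, params$edge_slack)
        }
      ),
      container = toupper(.data$kind)
    )
  # second-round copies may reference other copies rather than library
  # entries; treat those with unknown reference length as fragments unless
  # their own reference (the round-1 copy) is fully covered
  orf_lookup <- library |>
    dplyr::select("name", "orf_start", "orf_end")
  copies <- copies |>
    dplyr::left_join(orf_lookup, by = c(ref_name = "name")) |>
    dplyr::mutate(
      seq = extract_feature_seq(genomes, .data$replicon, .data$start,
                                .data$end, .data$strand),
      orf_intact = purrr::pmap_lgl(
        list(.data$seq, .data$orf_start, .data$orf_end, .data$completeness),
        function(s, os, oe, comp) {
          if (comp != "full_length" || is.na(os)) return(NA)
          assess_orf(s, os, oe, comp)
        }
      )
    ) |>
    assign_intron_names(params$name_divergence) |>
    dplyr::arrange(.data$genome, .data$replicon, .data$start) |>
    dplyr::mutate(copy_id = sprintf("%s:%s:%d-%d", .data$genome,
                                    .data$replicon, .data$start, .data$end))
  dplyr::select(copies, dplyr::all_of(names(empty)))
}
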