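# Summary statistics over copies, distinct sets and marked sites:
# per-intron/per-genome occupancy proportions, the per-genus abundance
# table, the strains-vs-abundance chi-square, and intra-genus MLST
# third-codon-position divergence.

#' Occupancy proportion in integer percent
#'
#' `round-half-up(100 * occupied / (occupied + available))`; both counts
#' zero gives `NA` (undefined, the "/" table cells).  Rounding is half-up:
#' 12.5 rounds to 13.
#'
#' @param occupied,available Non-negative integer vectors.
#' @return Integer percent vector (`NA` where undefined).
#' @export
#' @examples
#' occupancy_proportion(26, 17) # 60
#' occupancy_proportion(1, 7)   # 13
occupancy_proportion <- function(occupied, available) {
  stopifnot(all(occupied >= 0), all(available >= 0))
  tot <- occupied + available
  ifelse(tot > 0,
         round_half_up(100 * occupied / tot),
         NA_integer_)
}

#' Per-intron, per-genome occupancy table
#'
#' Counts OCCUPIED and AVAILABLE occurrences in a marked site tibble and
#' derives the occupancy percentage.
#'
#' @param sites Marked site tibble from [mark_occupancy()].
#' @return Tibble `intron`, `genome`, `occupied`, `available`,
#'   `proportion_pct`.
#' @export
occupancy_table <- function(sites) {
  sites |>
    dplyr::group_by(.data$intron, .data$genome) |>
    dplyr::summarise(
      occupied = sum(.data$state == "OCCUPIED"),
      available = sum(.data$state == "AVAILABLE"),
      .groups = "drop"
    ) |>
    dplyr::mutate(proportion_pct = occupancy_proportion(
      .data$occupied, .data$available))
}

#' Per-genus abundance of copies and distinct elements
#'
#' One row per genus/complex: number of strains, total copies, distinct
#' elements (orthologues collapsed), and the split of distinct elements
#' into full-length and fragments.  A distinct element counts as
#' full-length when ANY of its member copies is full-length.  A totals row
#' is appended.
#'
#' @param copies Copy tibble.
#' @param distinct_sets Output of [collapse_distinct()].
#' @param genomes Replicon tibble (strain counts come from here, so genera
#'   without any copy still appear).
#' @return Tibble `genus_complex`, `n_strains`, `n_copies`, `n_distinct`,
#'   `n_distinct_full_length`, `n_distinct_fragments`.
#' @export
genus_abundance_table <- function(copies, distinct_sets, genomes) {
  strains <- genomes |>
    dplyr::distinct(.data$genus_complex, .data$genome) |>
    dplyr::count(.data$genus_complex, name = "n_strains")
  per_set <- distinct_sets |>
    dplyr::left_join(dplyr::select(copies, "copy_id", "completeness"),
                     by = "copy_id") |>
    dplyr::group_by(.data$genus_complex, .data$set_id) |>
    dplyr::summarise(
      full_length = any(.data$completeness == "full_length"),
      .groups = "drop"
    )
  counts <- dplyr::left_join(
    dplyr::count(dplyr::left_join(
      copies, dplyr::select(distinct_sets, "copy_id", "set_id"),
      by = "copy_id"), .data$genus_complex, name = "n_copies"),
    per_set |>
      dplyr::group_by(.data$genus_complex) |>
      dplyr::summarise(
        n_distinct = dplyr::n(),
        n_distinct_full_length = sum(.data$full_length),
        n_distinct_fragments = sum(!.data$full_length)
      ),
    by = "genus_complex")
  tab <- strains |>
    dplyr::left_join(counts, by = "genus_complex") |>
    dplyr::mutate(dplyr::across(dplyr::where(is.numeric),
                                \(x) tidyr::replace_na(x, 0L))) |>
    dplyr::arrange(dplyr::desc(.data$n_distinct), .data$genus_complex)
  totals <- tab |>
    dplyr::summarise(
      genus_complex = "TOTAL",
      dplyr::across(dplyr::where(is.numeric), sum))
  dplyr::bind_rows(tab, totals)
}

#' Chi-square test of intron abundance against sequenced-strain counts
#'
#' Goodness-of-fit of observed copy (or distinct-element) counts per
#' genus/complex against expectation proportional to the number of
#' sequenced strains.  Genera with zero expected count are dropped with a
#' warning.
#'
#' @param abundance Abundance tibble ([genus_abundance_table()]) without a
#'   totals row, or any tibble with `genus_complex`, `n_strains` and the
#'   count column.
#' @param use_distinct Test distinct elements instead of raw copy counts.
#' @return A one-row tibble `statistic`, `df`, `p_value`, `n_genera`.
#' @export
abundance_vs_strains_test <- function(abundance, use_distinct = FALSE) {
  tab <- dplyr::filter(abundance, .data$genus_complex != "TOTAL")
  obs <- if (use_distinct) tab$n_distinct else tab$n_copies
  keep <- tab$n_strains > 0
  if (any(!keep)) {
    warning("dropping ", sum(!keep), " genus(era) with zero strains")
  }
  obs <- obs[keep]
  strains <- tab$n_strains[keep]
  stopifnot(length(obs) >= 2)
  ht <- suppressWarnings(stats::chisq.test(obs, p = strains / sum(strains)))
  tibble::tibble(statistic = unname(ht$statistic),
                 df = unname(ht$parameter),
                 p_value = unname(ht$p.value),
                 n_genera = length(obs))
}

#' Intra-genus mean nucleotide divergence at third codon positions
#'
#' Takes per-strain in-frame aligned (concatenated MLST gene) sequences,
#' keeps every third column, and averages the pairwise p-distance over all
#' unordered strain pairs; columns with a gap in either sequence of a pair
#' are skipped (complete pairwise deletion).
#'
#' @param alignment Named character vector (or tibble with `strain`, `seq`)
#'   of equal-length aligned sequences; length divisible by 3.
#' @param exclusions Strain names to exclude (outgroups).
#' @return A one-row tibble `mean_p_distance_pos3`, `n_genomes_used`,
#'   `n_pairs`, `excluded`.
#' @export
mlst_third_position_divergence <- function(alignment, exclusions = NULL) {
  if (is.data.frame(alignment)) {
    alignment <- setNames(alignment$seq, alignment$strain)
  }
  alignment <- alignment[!names(alignment) %in% exclusions]
  n <- length(alignment)
  stopifnot(n >= 2)
  len <- unique(nchar(alignment))
  if (length(len) != 1) stop("aligned sequences must have equal length")
  if (len %% 3 != 0) stop("alignment length must be divisible by 3")
  third <- do.call(rbind, strsplit(toupper(unname(
    as.character(alignment))), ""))[, seq(3, len, by = 3), drop = FALSE]
  real <- third %in% c("A", "C", "G", "T")
  dim(real) <- dim(third)
  pd <- utils::combn(n, 2, FUN = function(ij) {
    i <- ij[1]; j <- ij[2]
    ok <- real[i, ] & real[j, ]
    if (!any(ok)) return(NA_real_)
    mean(third[i, ok] != third[j, ok])
  })
  tibble::tibble(
    mean_p_distance_pos3 = mean(pd, na.rm = TRUE),
    n_genomes_used = n,
    n_pairs = length(pd),
    excluded = paste(exclusions %||% character(0), collapse = ",")
  )
}
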