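# Orthology and insertion-pattern classification.  Each detected copy's
# immediate 3 kb flanks are compared against the other genomes of the same
# genus/complex: contiguous flanks in a subject genome indicate retrohoming
# in the query genome; flanks matching the flanks of a subject copy of the
# same intron indicate orthology.  Orthologous copies are collapsed into
# distinct elements by connected components.

#' Orthology comparison parameters
#'
#' @param width Flank width in bp (default 3000).
#' @param min_flank_identity Minimal identity of a flank alignment (0.80).
#' @param min_flank_span Minimal aligned span in bp (500).
#' @param max_adjacency_gap Maximal gap (bp) between the two flank hits for
#'   a retrohoming call, and tolerance for flank/copy abutment (20;
#'   accommodates target-site duplications).
#' @return Named list.
#' @export
orthology_params <- function(width = 3000, min_flank_identity = 0.80,
                             min_flank_span = 500, max_adjacency_gap = 20) {
  as.list(environment())
}

#' Extract the immediate flanking sequences of intron copies
#'
#' Upstream is the `width` bases ending just before the copy start,
#' downstream the `width` bases starting just after the copy end (genomic
#' forward orientation).  Circular replicons wrap across the origin; linear
#' replicons truncate at their ends.
#'
#' @param copies Copy tibble.
#' @param genomes Replicon tibble.
#' @param width Flank width (default 3000).
#' @return Tibble `copy_id`, `upstream`, `downstream`.
#' @export
extract_flanks <- function(copies, genomes, width = 3000) {
  info <- genomes[match(copies$replicon, genomes$replicon), ]
  up <- character(nrow(copies))
  dn <- character(nrow(copies))
  for (i in seq_len(nrow(copies))) {
    L <- info$length[i]
    circ <- info$topology[i] == "circular"
    s <- copies$start[i]; e <- copies$end[i]
    seqi <- info$seq[i]
    if (circ) {
      dbl <- paste0(seqi, seqi)
      us <- s - width; ue <- s - 1
      up[i] <- substr(dbl, ((us - 1) %% L) + 1,
                      ((us - 1) %% L) + (ue - us + 1))
      ds <- e + 1; de <- e + width
      dn[i] <- substr(dbl, ((ds - 1) %% L) + 1,
                      ((ds - 1) %% L) + (de - ds + 1))
      # a flank can never be longer than the replicon minus the copy
      maxw <- max(0L, L - (e - s + 1L))
      if (nchar(up[i]) > maxw) up[i] <- substr(up[i], nchar(up[i]) - maxw + 1,
                                               nchar(up[i]))
      if (nchar(dn[i]) > maxw) dn[i] <- substr(dn[i], 1, maxw)
    } else {
      up[i] <- substr(seqi, max(1, s - width), s - 1)
      dn[i] <- substr(seqi, e + 1, min(L, e + width))
    }
  }
  tibble::tibble(copy_id = copies$copy_id, upstream = up, downstream = dn)
}

# Diagonal-tight seed windows: exact k-mer matches are clustered by
# alignment diagonal so the Smith-Waterman window hugs the candidate
# alignment instead of spanning margin-sized stretches of the subject.
seed_diag_windows <- function(query, subject, k = 16, drift = 80) {
  sp <- cpp_seed_positions(query, subject, k)
  if (nrow(sp) == 0) return(NULL)
  m <- nchar(query)
  n <- nchar(subject)
  d <- sort(unique(sp[, 3]))
  grp <- cumsum(c(1, diff(d) > drift))
  w <- do.call(rbind, lapply(split(d, grp), function(ds) {
    c(max(1L, min(ds) + 1L - drift), min(n, max(ds) + m + drift))
  }))
  w <- w[order(w[, 1]), , drop = FALSE]
  merged <- list()
  for (i in seq_len(nrow(w))) {
    last <- length(merged)
    if (last > 0 && w[i, 1] <= merged[[last]][2] + 1L) {
      merged[[last]][2] <- max(merged[[last]][2], w[i, 2])
    } else {
      merged[[last + 1L]] <- w[i, ]
    }
  }
  do.call(rbind, merged)
}

# Align one flank against one subject replicon; returns qualifying hits
# (subject coordinates plus strand).
flank_hits <- function(flank, subject_seq, params, cache = NULL,
                       cache_key = NULL) {
  if (nchar(flank) < params$min_flank_span) return(NULL)
  if (!is.null(cache) && !is.null(cache_key)) {
    key <- paste0(cache_key, "|", flank)
    hit <- cache[[key]]
    if (!is.null(hit)) return(if (identical(hit, "none")) NULL else hit)
  }
  min_score <- max(50L, as.integer(params$min_flank_span * 0.3))
  out <- list()
  for (str in c("+", "-")) {
    q <- if (str == "+") flank else revcomp(flank)
    win <- seed_diag_windows(q, subject_seq)
    if (is.null(win)) next
    for (w in seq_len(nrow(win))) {
      hits <- cpp_sw_hits_nt(q, substr(subject_seq, win[w, 1], win[w, 2]),
                             1L, -2L, -5L, -2L, min_score, max_hits = 2L)
      if (nrow(hits) == 0) next
      hits <- tibble::as_tibble(hits)
      out[[length(out) + 1]] <- tibble::tibble(
        start = hits$s_start + win[w, 1] - 1L,
        end = hits$s_end + win[w, 1] - 1L,
        strand = str,
        identical = hits$identical, aligned = hits$aligned
      )
    }
  }
  h <- if (length(out) == 0) NULL else {
    hh <- dplyr::bind_rows(out) |>
      dplyr::filter(
        .data$identical / .data$aligned >= params$min_flank_identity,
        .data$end - .data$start + 1L >= params$min_flank_span)
    if (nrow(hh) == 0) NULL else hh
  }
  if (!is.null(cache) && !is.null(cache_key)) {
    cache[[paste0(cache_key, "|", flank)]] <- if (is.null(h)) "none" else h
  }
  h
}

#' Classify the insertion pattern of one copy against one subject genome
#'
#' @param flank_row One row of [extract_flanks()].
#' @param copy_row The corresponding copy row.
#' @param subject_genomes Replicon tibble restricted to the subject genome.
#' @param subject_copies Copy tibble restricted to the subject genome.
#' @param params [orthology_params()].
#' @return A one-row tibble: `copy_id`, `subject_genome`, `classification`
#'   (`RETROHOMED`, `ORTHOLOGOUS` or `UNRESOLVED`), `partner_copy_id`,
#'   `adjacency_gap`.
#' @export
classify_insertion <- function(flank_row, copy_row, subject_genomes,
                               subject_copies,
                               params = orthology_params(), cache = NULL) {
  res <- function(cls, partner = NA_character_, gap = NA_integer_) {
    tibble::tibble(copy_id = flank_row$copy_id,
                   subject_genome = subject_genomes$genome[1],
                   classification = cls, partner_copy_id = partner,
                   adjacency_gap = gap)
  }
  same_intron <- subject_copies[
    subject_copies$ref_name == copy_row$ref_name, , drop = FALSE]
  for (ri in seq_len(nrow(subject_genomes))) {
    sseq <- subject_genomes$seq[ri]
    rid <- subject_genomes$replicon[ri]
    uh <- flank_hits(flank_row$upstream, sseq, params, cache, rid)
    dh <- flank_hits(flank_row$downstream, sseq, params, cache, rid)
    tol <- params$max_adjacency_gap
    # orthology: a flank hit abutting a subject copy of the same intron
    sc <- same_intron[same_intron$replicon == rid, , drop = FALSE]
    if (nrow(sc)) {
      for (h in list(uh, dh)) {
        if (is.null(h)) next
        for (k in seq_len(nrow(h))) {
          hit <- h[k, ]
          ab <- abs(hit$end - (sc$start - 1L)) <= tol |
            abs(hit$start - (sc$end + 1L)) <= tol
          if (any(ab)) {
            return(res("ORTHOLOGOUS", partner = sc$copy_id[which(ab)[1]]))
          }
        }
      }
    }
    # retrohoming: both flanks adjacent, same orientation, no copy between
    if (!is.null(uh) && !is.null(dh)) {
      for (ku in seq_len(nrow(uh))) {
        for (kd in seq_len(nrow(dh))) {
          u <- uh[ku, ]; d <- dh[kd, ]
          if (u$strand != d$strand) next
          gap <- if (u$strand == "+") d$start - u$end - 1L
                 else u$start - d$end - 1L
          if (abs(gap) > tol) next
          lo <- min(u$end, d$start); hi <- max(u$end, d$start)
          blocked <- any(subject_copies$replicon == rid &
                           subject_copies$start <= hi &
                           subject_copies$end >= lo)
          if (!blocked) return(res("RETROHOMED", gap = gap))
        }
      }
    }
  }
  res("UNRESOLVED")
}

#' Classify insertion patterns for all copies within each genus/complex
#'
#' Runs [classify_insertion()] for every (copy, other genome of the same
#' genus/complex) pair.
#'
#' @param copies Copy tibble.
#' @param genomes Replicon tibble.
#' @param params [orthology_params()].
#' @return Insertion-call tibble, one row per (copy, subject genome).
#' @export
classify_insertions <- function(copies, genomes,
                                params = orthology_params()) {
  empty <- tibble::tibble(copy_id = character(), subject_genome = character(),
                          classification = character(),
                          partner_copy_id = character(),
                          adjacency_gap = integer())
  if (nrow(copies) == 0) return(empty)
  flanks <- extract_flanks(copies, genomes, params$width)
  cache <- new.env(parent = emptyenv())
  ginfo <- dplyr::distinct(genomes, .data$genome, .data$genus_complex)
  copies <- dplyr::left_join(
    copies, dplyr::select(ginfo, "genome", gc2 = "genus_complex"),
    by = "genome")
  out <- list()
  for (i in seq_len(nrow(copies))) {
    cp <- copies[i, ]
    others <- ginfo$genome[ginfo$genus_complex == cp$gc2 &
                             ginfo$genome != cp$genome]
    for (sg in others) {
      out[[length(out) + 1]] <- classify_insertion(
        flanks[i, ], cp,
        genomes[genomes$genome == sg, , drop = FALSE],
        copies[copies$genome == sg, , drop = FALSE],
        params, cache = cache)
    }
  }
  if (length(out) == 0) return(empty)
  dplyr::bind_rows(out)
}

#' Apply manual MGE overrides to insertion calls
#'
#' Copies carried by mobile genetic elements (genomic islands, prophages)
#' that inserted independently at different loci are not true orthologues;
#' the override table reclassifies the listed (copy, subject genome) pairs
#' as `DISTINCT_MGE`.  All other calls are unchanged.
#'
#' @param calls Insertion-call tibble.
#' @param overrides Data frame with columns `copy_id`, `subject_genome` (or
#'   `NULL`/empty for no overrides).
#' @return The modified call tibble.
#' @export
apply_mge_overrides <- function(calls, overrides = NULL) {
  if (is.null(overrides) || nrow(overrides) == 0) return(calls)
  miss <- !paste(overrides$copy_id, overrides$subject_genome) %in%
    paste(calls$copy_id, calls$subject_genome)
  if (any(miss)) {
    stop("override row(s) reference non-existent calls: ",
         paste(overrides$copy_id[miss], collapse = ", "))
  }
  hit <- paste(calls$copy_id, calls$subject_genome) %in%
    paste(overrides$copy_id, overrides$subject_genome)
  calls$classification[hit] <- "DISTINCT_MGE"
  calls$partner_copy_id[hit] <- NA_character_
  calls
}

#' Collapse orthologous copies into distinct elements
#'
#' Connected components of the ORTHOLOGOUS relation (after overrides) within
#' each genus/complex; copies without any orthology call form singleton
#' sets, so the sets partition the copy set.
#'
#' @param copies Copy tibble.
#' @param calls Insertion-call tibble (after [apply_mge_overrides()]).
#' @return Tibble `copy_id`, `set_id`, `representative`, `genus_complex`;
#'   one row per copy.
#' @export
collapse_distinct <- function(copies, calls) {
  if (nrow(copies) == 0) {
    return(tibble::tibble(copy_id = character(), set_id = character(),
                          representative = character(),
                          genus_complex = character()))
  }
  edges <- calls |>
    dplyr::filter(.data$classification == "ORTHOLOGOUS",
                  !is.na(.data$partner_copy_id))
  g <- igraph::graph_from_data_frame(
    d = edges[, c("copy_id", "partner_copy_id")],
    directed = FALSE,
    vertices = data.frame(name = sort(unique(copies$copy_id))))
  comp <- igraph::components(g)$membership
  tibble::tibble(copy_id = names(comp), comp = comp) |>
    dplyr::left_join(dplyr::select(copies, "copy_id", "genus_complex"),
                     by = "copy_id") |>
    dplyr::group_by(.data$comp) |>
    dplyr::mutate(representative = min(.data$copy_id)) |>
    dplyr::ungroup() |>
    dplyr::mutate(set_id = paste0("D", dplyr::dense_rank(
      .data$representative))) |>
    dplyr::select("copy_id", "set_id", "representative", "genus_complex") |>
    dplyr::arrange(.data$set_id, .data$copy_id)
}
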