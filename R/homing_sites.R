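# Homing-site inference.  Four schemes produce a scanning model per intron:
#   flank_similarity      - 90 bp context around known integration sites,
#                           searched by local alignment (IS-targeting introns)
#   ebs_consensus         - IBS consensus from EBS base-pairing (Watson-Crick
#                           plus G:U wobble) over windows around full-length
#                           copies, optionally extended by bases identical
#                           across all windows and a reference flank
#   classc_terminator     - EBS1/EBS3 consensus gated by Rho-independent
#                           transcription terminators (class C introns)
#   conservation_consensus- per-column conservation over >= 5 windows
# Genomic occurrences of a model are marked AVAILABLE or OCCUPIED.

insertion_offset <- function(window) -window[1]

#' Construct a homing-site model
#'
#' @param intron Intron name the model belongs to.
#' @param scheme One of `"flank_similarity"`, `"ebs_consensus"`,
#'   `"classc_terminator"`, `"conservation_consensus"`.
#' @param consensus Consensus string over A/C/G/T/N; `N` matches any real
#'   base but never a genomic `N`.
#' @param offset Index of the consensus position immediately 5' of the
#'   insertion point.
#' @param window Two integers, the window relative to the insertion site
#'   (default `c(-25, 10)`).
#' @param requires_terminator Whether occurrences must lie just downstream
#'   of a Rho-independent terminator (class C).
#' @param context Optional 90 bp context sequence (flank-similarity scheme;
#'   insertion point after position 45).
#' @param ibs1_len Length of the IBS1 motif (used for terminator gating).
#' @return An object of class `homing_site_model`.
#' @export
homing_site_model <- function(intron, scheme, consensus, offset,
                              window = c(-25L, 10L),
                              requires_terminator = identical(
                                scheme, "classc_terminator"),
                              context = NULL, ibs1_len = 6L) {
  scheme <- match.arg(scheme, c("flank_similarity", "ebs_consensus",
                                "classc_terminator",
                                "conservation_consensus"))
  if (scheme == "classc_terminator") requires_terminator <- TRUE
  stopifnot(offset >= 1, offset <= nchar(consensus))
  structure(list(intron = intron, scheme = scheme, consensus = consensus,
                 offset = as.integer(offset), window = as.integer(window),
                 requires_terminator = requires_terminator,
                 context = context, ibs1_len = as.integer(ibs1_len)),
            class = "homing_site_model")
}

#' @export
print.homing_site_model <- function(x, ...) {
  cat("<homing_site_model>", x$intron, "scheme:", x$scheme, "\n")
  cat(" consensus:", x$consensus, "(insertion after position", x$offset,
      ")\n")
  if (x$requires_terminator) cat(" requires Rho-independent terminator\n")
  invisible(x)
}

# target bases compatible with an EBS base: Watson-Crick plus G:U wobble
# (EBS G pairs target T as well as C; EBS T/U pairs target G as well as A)
ebs_compatible <- function(ebs_base) {
  switch(ebs_base,
         A = "T", C = "G", G = c("C", "T"), T = c("A", "G"),
         U = c("A", "G"), character(0))
}

#' Build an IBS consensus from EBS motifs and flanking windows
#'
#' IBS2 (reverse complement of EBS2, when present) sits immediately 5' of
#' IBS1 (reverse complement of EBS1), which ends at the base just before
#' the insertion point; IBS3 (complement of EBS3) is the first base after
#' it.  Each EBS-covered position takes the most frequent wobble-consistent
#' base across the windows (ties or no consistent observation under several
#' windows fall back to the Watson-Crick complement; ties between observed
#' bases give `N`).  When `reference_flank` is supplied, positions identical
#' across all windows and the reference are fixed to that base.  All other
#' positions are `N`.
#'
#' @param ebs_motifs Named list/character with `EBS1`, optionally `EBS2`,
#'   and `EBS3` (class C introns have no EBS2).
#' @param flank_windows Character vector of window sequences aligned at the
#'   insertion point, each spanning `window`.
#' @param reference_flank Optional window around a reference copy.
#' @param window Window relative to the insertion site.
#' @param intron Intron name.
#' @param classc Whether to stamp the class C (terminator-gated) scheme.
#' @return A [homing_site_model()].
#' @export
build_consensus_from_ebs <- function(ebs_motifs, flank_windows,
                                     reference_flank = NULL,
                                     window = c(-25L, 10L), intron = "intron",
                                     classc = FALSE) {
  width <- -window[1] + window[2]
  stopifnot(length(flank_windows) >= 1)
  if (length(unique(nchar(flank_windows))) != 1 ||
      nchar(flank_windows[1]) != width) {
    stop("flank windows must all span the stated window (", width, " bases)")
  }
  if (!is.null(reference_flank) && nchar(reference_flank) != width) {
    stop("reference flank must span the stated window")
  }
  off <- insertion_offset(window)
  cons <- rep("N", width)
  has_motif <- function(x) {
    !is.null(x) && length(x) == 1 && !is.na(x) && nzchar(x)
  }
  ebs1 <- ebs_motifs[["EBS1"]]
  ebs2 <- ebs_motifs[["EBS2"]]
  ebs3 <- ebs_motifs[["EBS3"]]
  if (!has_motif(ebs1)) stop("EBS1 motif is required")
  ebs1 <- toupper(ebs1)
  wmat <- do.call(rbind, strsplit(flank_windows, ""))
  fix_ebs <- function(cons_pos, ebs_base) {
    wc <- chartr("ACGTU", "TGCAA", ebs_base)
    allowed <- ebs_compatible(ebs_base)
    obs <- wmat[, cons_pos]
    obs <- obs[obs %in% allowed]
    if (length(obs) == 0) return(wc)
    tab <- sort(table(obs), decreasing = TRUE)
    if (length(tab) > 1 && tab[1] == tab[2]) return("N")
    names(tab)[1]
  }
  # IBS1: ends at the insertion point (consensus positions off-L1+1 .. off)
  l1 <- nchar(ebs1)
  for (j in seq_len(l1)) {
    cons_pos <- off - l1 + j
    if (cons_pos >= 1) cons[cons_pos] <- fix_ebs(cons_pos, substr(
      ebs1, l1 - j + 1, l1 - j + 1))
  }
  if (!classc && has_motif(ebs2)) {
    ebs2 <- toupper(ebs2)
    l2 <- nchar(ebs2)
    for (j in seq_len(l2)) {
      cons_pos <- off - l1 - l2 + j
      if (cons_pos >= 1) cons[cons_pos] <- fix_ebs(cons_pos, substr(
        ebs2, l2 - j + 1, l2 - j + 1))
    }
  }
  # IBS3: first base after the insertion point; complement (not reverse)
  if (has_motif(ebs3) && off + 1 <= width) {
    cons[off + 1] <- fix_ebs(off + 1, toupper(ebs3))
  }
  # extension: bases identical across all windows and the reference
  if (!is.null(reference_flank)) {
    rch <- seq_chars(toupper(reference_flank))
    same <- vapply(seq_len(width), function(i) {
      all(wmat[, i] == rch[i]) && rch[i] %in% c("A", "C", "G", "T")
    }, logical(1))
    cons[same] <- rch[same]
  }
  homing_site_model(
    intron, if (classc) "classc_terminator" else "ebs_consensus",
    paste(cons, collapse = ""), off, window, ibs1_len = nchar(ebs1))
}

#' Build a conservation consensus from flanking windows
#'
#' Per column, the modal base is fixed when its frequency reaches
#' `threshold`; otherwise the column is `N`.
#'
#' @param flank_windows At least 5 window sequences aligned at the insertion
#'   point.
#' @param window Window relative to the insertion site.
#' @param threshold Modal-base frequency needed to fix a column (0.8).
#' @param intron Intron name.
#' @return A [homing_site_model()] with the conservation scheme.
#' @export
build_consensus_from_conservation <- function(flank_windows,
                                              window = c(-25L, 10L),
                                              threshold = 0.8,
                                              intron = "intron") {
  stopifnot(length(flank_windows) >= 5)
  width <- -window[1] + window[2]
  if (length(unique(nchar(flank_windows))) != 1 ||
      nchar(flank_windows[1]) != width) {
    stop("flank windows must all span the stated window")
  }
  wmat <- do.call(rbind, strsplit(toupper(flank_windows), ""))
  cons <- apply(wmat, 2, function(col) {
    col <- col[col %in% c("A", "C", "G", "T")]
    if (length(col) == 0) return("N")
    tab <- sort(table(col), decreasing = TRUE)
    if (tab[1] / nrow(wmat) >= threshold) names(tab)[1] else "N"
  })
  homing_site_model(intron, "conservation_consensus",
                    paste(cons, collapse = ""), insertion_offset(window),
                    window)
}

#' Terminator scan parameters
#'
#' @param min_stem,max_stem Stem length bounds in bp (5-18).
#' @param min_loop,max_loop Loop length bounds in nt (3-10).
#' @param max_mismatch Maximal non-paired (non-Watson-Crick, non-G:U)
#'   positions in the stem (1).
#' @param tail_gap_max The U-tract must start within this many nt of the 3'
#'   stem arm (3).
#' @param tail_window,tail_min_t At least `tail_min_t` of the `tail_window`
#'   bases after the stem must be T (5 of 8).
#' @return Named list.
#' @export
terminator_params <- function(min_stem = 5, max_stem = 18, min_loop = 3,
                              max_loop = 10, max_mismatch = 1,
                              tail_gap_max = 3, tail_window = 8,
                              tail_min_t = 5) {
  as.list(environment())
}

#' Find Rho-independent transcription terminators
#'
#' Scans both strands of each replicon for inverted repeats (stem-loops,
#' G:U pairs allowed, at most one other mismatch) followed within a few nt
#' by a U-rich tract.  Hits are maximal: no hit strictly contained in
#' another on the same strand.  Circular replicons wrap across the origin.
#' User-supplied terminator intervals can be appended downstream to
#' supplement the detector.
#'
#' @param genomes Replicon tibble (or any tibble with `replicon`, `seq`,
#'   `topology` columns).
#' @param params [terminator_params()].
#' @return Tibble `replicon`, `start`, `end`, `strand`, `stem_len`,
#'   `loop_len`, `mismatches`, `u_tail_score`.
#' @export
find_rho_independent_terminators <- function(genomes,
                                             params = terminator_params()) {
  span <- 2 * params$max_stem + params$max_loop + params$tail_gap_max +
    params$tail_window
  out <- purrr::pmap(
    list(genomes$replicon, genomes$seq,
         genomes$topology %||% rep("linear", nrow(genomes))),
    function(rid, seqi, topo) {
      L <- nchar(seqi)
      scan_seq <- if (identical(topo, "circular")) {
        wrap_sequence(seqi, span - 1L)
      } else {
        seqi
      }
      fw <- tibble::as_tibble(cpp_find_terminators(
        scan_seq, params$min_stem, params$max_stem, params$min_loop,
        params$max_loop, params$max_mismatch, params$tail_gap_max,
        params$tail_window, params$tail_min_t))
      fw$strand <- "+"
      rc <- tibble::as_tibble(cpp_find_terminators(
        revcomp(scan_seq), params$min_stem, params$max_stem,
        params$min_loop, params$max_loop, params$max_mismatch,
        params$tail_gap_max, params$tail_window, params$tail_min_t))
      if (nrow(rc)) {
        SL <- nchar(scan_seq)
        tmp <- rc
        rc$start <- SL - tmp$end + 1L
        rc$end <- SL - tmp$start + 1L
      }
      rc$strand <- "-"
      h <- dplyr::bind_rows(fw, rc)
      if (identical(topo, "circular") && nrow(h)) {
        h <- h[h$start <= L, , drop = FALSE]
      }
      if (nrow(h)) h$replicon <- rid
      h
    })
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) {
    return(tibble::tibble(replicon = character(), start = integer(),
                          end = integer(), strand = character(),
                          stem_len = integer(), loop_len = integer(),
                          mismatches = integer(), u_tail_score = double()))
  }
  dplyr::select(res, "replicon", "start", "end", "strand", "stem_len",
                "loop_len", "mismatches", "u_tail_score") |>
    dplyr::arrange(.data$replicon, .data$start, .data$end, .data$strand)
}

empty_sites <- function() {
  tibble::tibble(genome = character(), replicon = character(),
                 start = integer(), end = integer(), pos = integer(),
                 strand = character(), intron = character(),
                 scheme = character(), state = character(),
                 occupied_by = character())
}

# vectorized exact consensus match on one strand of one sequence; returns
# 1-based start positions
match_consensus <- function(chars, cons_chars, L_seq) {
  w <- length(cons_chars)
  n <- L_seq - w + 1L
  if (n < 1) return(integer(0))
  ok <- rep(TRUE, n)
  for (i in seq_len(w)) {
    b <- cons_chars[i]
    seg <- chars[i:(i + n - 1L)]
    if (b == "N") {
      ok <- ok & seg != "N"
    } else {
      ok <- ok & seg == b
    }
  }
  which(ok)
}

#' Scan genomes for perfect matches to a consensus model
#'
#' Reports every position (both strands; circular replicons wrap) where all
#' non-N consensus positions match exactly.  `N` consensus positions match
#' any real base but not a genomic `N`.
#'
#' @param genomes Replicon tibble.
#' @param model A [homing_site_model()] with at least one non-N position.
#' @return Site tibble (state `AVAILABLE`, pending [mark_occupancy()]):
#'   `genome`, `replicon`, `start`, `end`, `pos` (base immediately left of
#'   the insertion point in genomic coordinates), `strand`, `intron`,
#'   `scheme`, `state`, `occupied_by`.
#' @export
scan_perfect_match <- function(genomes, model) {
  cons <- model$consensus
  if (!grepl("[ACGT]", cons)) {
    stop("consensus must contain at least one non-N position")
  }
  w <- nchar(cons)
  off <- model$offset
  out <- purrr::pmap(
    list(genomes$genome, genomes$replicon, genomes$seq,
         genomes$topology %||% rep("linear", nrow(genomes))),
    function(gname, rid, seqi, topo) {
      L <- nchar(seqi)
      scan_seq <- if (identical(topo, "circular")) {
        wrap_sequence(seqi, w - 1L)
      } else {
        seqi
      }
      chars <- seq_chars(scan_seq)
      Ls <- length(chars)
      fw <- match_consensus(chars, seq_chars(cons), Ls)
      rc <- match_consensus(chars, seq_chars(revcomp(cons)), Ls)
      rows <- dplyr::bind_rows(
        tibble::tibble(start = fw, strand = "+"),
        tibble::tibble(start = rc, strand = "-")
      )
      if (nrow(rows) == 0) return(NULL)
      rows$end <- rows$start + w - 1L
      rows <- rows[rows$start <= L, , drop = FALSE]
      if (nrow(rows) == 0) return(NULL)
      rows$pos <- ifelse(rows$strand == "+", rows$start + off - 1L,
                         rows$end - off)
      rows$genome <- gname
      rows$replicon <- rid
      rows
    })
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) return(empty_sites())
  res$intron <- model$intron
  res$scheme <- model$scheme
  res$state <- "AVAILABLE"
  res$occupied_by <- NA_character_
  dplyr::select(res, dplyr::all_of(names(empty_sites()))) |>
    dplyr::arrange(.data$replicon, .data$start, .data$strand)
}

#' Scan genomes by 90 bp flank similarity
#'
#' Local-alignment search of the model's 90 bp context (insertion point
#' after position 45): hits with identity at or above `min_identity` over at
#' least `min_span` bases that cover the integration site are reported as
#' candidate homing sites.
#'
#' @param genomes Replicon tibble.
#' @param model A [homing_site_model()] carrying a `context` sequence.
#' @param min_identity Identity threshold (0.90).
#' @param min_span Minimal aligned span in bp (72, i.e. 80% of 90).
#' @return Site tibble as in [scan_perfect_match()].
#' @export
scan_flank_similarity <- function(genomes, model, min_identity = 0.90,
                                  min_span = 72) {
  stopifnot(!is.null(model$context), nchar(model$context) == 90)
  ctx_off <- 45L
  p <- detection_params(min_score_nt = 30L)
  out <- purrr::pmap(
    list(genomes$genome, genomes$replicon, genomes$seq),
    function(gname, rid, seqi) {
      h <- search_nt_query(model$intron, model$context, seqi, p)
      if (is.null(h) || nrow(h) == 0) return(NULL)
      h <- dplyr::filter(
        h,
        .data$identical / .data$aligned >= min_identity,
        .data$end - .data$start + 1L >= min_span,
        .data$ref_start <= ctx_off, .data$ref_end >= ctx_off + 1L
      )
      if (nrow(h) == 0) return(NULL)
      tibble::tibble(
        genome = gname, replicon = rid, start = h$start, end = h$end,
        pos = ifelse(h$strand == "+",
                     h$start + (ctx_off - h$ref_start),
                     h$end - (ctx_off - h$ref_start) - 1L),
        strand = h$strand
      )
    })
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) return(empty_sites())
  res$intron <- model$intron
  res$scheme <- model$scheme
  res$state <- "AVAILABLE"
  res$occupied_by <- NA_character_
  dplyr::select(res, dplyr::all_of(names(empty_sites()))) |>
    dplyr::arrange(.data$replicon, .data$start, .data$strand)
}

#' Keep only sites directly downstream of a terminator
#'
#' For class C models: a site survives when its IBS1 motif starts at most
#' `max_gap` nt 3' of a terminator stem-loop end on the same strand of the
#' same replicon.
#'
#' @param sites Site tibble from a class C model scan.
#' @param terminators Terminator tibble
#'   ([find_rho_independent_terminators()]), or user-supplied intervals
#'   with the same columns.
#' @param max_gap Maximal distance in nt (20).
#' @param ibs1_len IBS1 motif length (from the model; default 6).
#' @return The filtered site tibble (a subset of the input).
#' @export
restrict_to_terminator_downstream <- function(sites, terminators,
                                              max_gap = 20, ibs1_len = 6) {
  if (nrow(sites) == 0) return(sites)
  keep <- vapply(seq_len(nrow(sites)), function(i) {
    s <- sites[i, ]
    tt <- terminators[terminators$replicon == s$replicon &
                        terminators$strand == s$strand, , drop = FALSE]
    if (nrow(tt) == 0) return(FALSE)
    if (s$strand == "+") {
      ibs1_start <- s$pos - ibs1_len + 1L
      any(ibs1_start - tt$end >= 0 & ibs1_start - tt$end <= max_gap)
    } else {
      ibs1_start <- s$pos + ibs1_len
      any(tt$start - ibs1_start >= 0 & tt$start - ibs1_start <= max_gap)
    }
  }, logical(1))
  sites[keep, , drop = FALSE]
}

#' Mark homing-site occurrences as occupied or available
#'
#' Every copy of the model's intron contributes an OCCUPIED occurrence at
#' its insertion point; scanned candidate sites whose insertion point abuts
#' such a copy are merged into it.  Candidate sites falling strictly inside
#' any intron copy (uninterrupted copies do not offer targets) are removed;
#' the rest stay AVAILABLE.
#'
#' @param sites Candidate site tibble from a scan (state `AVAILABLE`).
#' @param copies Copy tibble for the same genome(s).
#' @param intron Intron name of the model; defaults to the sites' model
#'   name.
#' @param completeness Which copies occupy sites (`"full_length"`,
#'   `"fragment"` or both; default both).
#' @return Site tibble with `state` set (`OCCUPIED` rows carry
#'   `occupied_by`).
#' @export
mark_occupancy <- function(sites, copies, intron = NULL,
                           completeness = c("full_length", "fragment")) {
  intron <- intron %||% (if (nrow(sites)) sites$intron[1] else NA_character_)
  scheme <- if (nrow(sites)) sites$scheme[1] else NA_character_
  own <- copies[copies$ref_name %in% intron &
                  copies$completeness %in% completeness, , drop = FALSE]
  # candidate available sites must not fall inside any copy interval
  if (nrow(sites)) {
    inside <- vapply(seq_len(nrow(sites)), function(i) {
      s <- sites[i, ]
      any(copies$replicon == s$replicon & copies$start <= s$pos &
            copies$end >= s$pos + 1L)
    }, logical(1))
    abuts <- vapply(seq_len(nrow(sites)), function(i) {
      s <- sites[i, ]
      any(own$replicon == s$replicon &
            (abs(own$start - (s$pos + 1L)) <= 1L |
               abs(own$end - s$pos) <= 1L))
    }, logical(1))
    sites <- sites[!inside & !abuts, , drop = FALSE]
  }
  occ <- if (nrow(own)) {
    tibble::tibble(
      genome = own$genome, replicon = own$replicon, start = own$start,
      end = own$end, pos = own$start - 1L, strand = own$strand,
      intron = intron, scheme = scheme, state = "OCCUPIED",
      occupied_by = own$copy_id
    )
  } else {
    empty_sites()
  }
  dplyr::bind_rows(occ, sites) |>
    dplyr::arrange(.data$replicon, .data$start, .data$strand)
}
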