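# Independent oracles: straightforward exhaustive implementations used to
# validate the package's optimised search code.  They share only the
# declared scoring/tie-break conventions, never the seeded/windowed code
# paths.

# Full-matrix affine-gap local alignment (Gotoh) with iterative masking.
# Tie-breaks: best score, then smallest subject end, then smallest query
# end; traceback prefers diagonal, then gap-in-query, then gap-in-subject;
# gap states prefer opening.  Identity counts exact character matches
# (never N).  One strand; the caller handles reverse complements.
oracle_sw_hits <- function(query, subject, match = 1, mismatch = -2,
                           gap_open = -5, gap_ext = -2, min_score = 20) {
  qc <- strsplit(query, "")[[1]]
  sc <- strsplit(subject, "")[[1]]
  m <- length(qc)
  n <- length(sc)
  NEG <- -1e6
  masked <- rep(FALSE, n)
  hits <- list()
  repeat {
    H <- matrix(0, m + 1, n + 1)
    E <- matrix(NEG, m + 1, n + 1)
    F <- matrix(NEG, m + 1, n + 1)
    best <- 0; bi <- -1; bj <- -1
    for (i in 1:m) {
      for (j in 1:n) {
        e <- max(H[i + 1, j] + gap_open + gap_ext, E[i + 1, j] + gap_ext)
        f <- max(H[i, j + 1] + gap_open + gap_ext, F[i, j + 1] + gap_ext)
        sub <- if (masked[j] || qc[i] == "N" || sc[j] == "N") {
          if (masked[j]) NEG else mismatch
        } else if (qc[i] == sc[j]) match else mismatch
        d <- H[i, j] + sub
        h <- max(0, d, e, f)
        E[i + 1, j + 1] <- e
        F[i + 1, j + 1] <- f
        H[i + 1, j + 1] <- h
        if (h > best) { best <- h; bi <- i; bj <- j }
        else if (h == best && h > 0 &&
                 (j < bj || (j == bj && i < bi))) { bi <- i; bj <- j }
      }
    }
    if (best < min_score) break
    # traceback
    i <- bi; j <- bj; state <- "H"
    identical <- 0L; aligned <- 0L
    while (i > 0 && j > 0) {
      if (state == "H") {
        h <- H[i + 1, j + 1]
        if (h == 0) break
        sub <- if (masked[j] || qc[i] == "N" || sc[j] == "N") {
          if (masked[j]) NEG else mismatch
        } else if (qc[i] == sc[j]) match else mismatch
        if (h == H[i, j] + sub) {
          aligned <- aligned + 1L
          if (qc[i] == sc[j] && qc[i] != "N") identical <- identical + 1L
          i <- i - 1; j <- j - 1
        } else if (h == E[i + 1, j + 1]) {
          state <- "E"
        } else {
          state <- "F"
        }
      } else if (state == "E") {
        aligned <- aligned + 1L
        state <- if (E[i + 1, j + 1] ==
                     H[i + 1, j] + gap_open + gap_ext) "H" else "E"
        j <- j - 1
      } else {
        aligned <- aligned + 1L
        state <- if (F[i + 1, j + 1] ==
                     H[i, j + 1] + gap_open + gap_ext) "H" else "F"
        i <- i - 1
      }
    }
    hits[[length(hits) + 1]] <- data.frame(
      q_start = i + 1L, q_end = bi, s_start = j + 1L, s_end = bj,
      identical = identical, aligned = aligned, score = best)
    masked[(j + 1):bj] <- TRUE
  }
  if (length(hits) == 0) {
    return(data.frame(q_start = integer(), q_end = integer(),
                      s_start = integer(), s_end = integer(),
                      identical = integer(), aligned = integer(),
                      score = integer()))
  }
  do.call(rbind, hits)
}

# Both-strand oracle matching the seed_extend_search reporting convention
# (hits in subject coordinates; reference coordinates flipped on "-").
oracle_search <- function(query, subject, min_identity = 0.60,
                          min_length = 50, min_score = 20) {
  qlen <- nchar(query)
  out <- list()
  for (str in c("+", "-")) {
    q <- if (str == "+") query else intronscout::revcomp(query)
    h <- oracle_sw_hits(q, subject, min_score = min_score)
    if (nrow(h)) {
      h$strand <- str
      rs <- if (str == "+") h$q_start else qlen - h$q_end + 1L
      re <- if (str == "+") h$q_end else qlen - h$q_start + 1L
      h$ref_start <- rs
      h$ref_end <- re
      out[[length(out) + 1]] <- h
    }
  }
  h <- if (length(out)) do.call(rbind, out) else
    data.frame(q_start = integer(), q_end = integer(), s_start = integer(),
               s_end = integer(), identical = integer(),
               aligned = integer(), score = integer(), strand = character(),
               ref_start = integer(), ref_end = integer())
  h <- h[h$identical / h$aligned >= min_identity &
           (h$s_end - h$s_start + 1) >= min_length, , drop = FALSE]
  h[order(h$s_start, h$s_end, h$strand), , drop = FALSE]
}

# Exhaustive sliding-window consensus scan on one strand.
oracle_scan_one <- function(seq, consensus) {
  n <- nchar(seq)
  w <- nchar(consensus)
  cc <- strsplit(consensus, "")[[1]]
  starts <- integer(0)
  if (n < w) return(starts)
  for (p in 1:(n - w + 1)) {
    win <- strsplit(substr(seq, p, p + w - 1), "")[[1]]
    ok <- TRUE
    for (i in seq_len(w)) {
      if (cc[i] == "N") {
        if (win[i] == "N") { ok <- FALSE; break }
      } else if (win[i] != cc[i]) { ok <- FALSE; break }
    }
    if (ok) starts <- c(starts, p)
  }
  starts
}

oracle_scan <- function(seq, consensus) {
  fw <- oracle_scan_one(seq, consensus)
  rc <- oracle_scan_one(seq, intronscout::revcomp(consensus))
  rbind(
    if (length(fw)) data.frame(start = fw, strand = "+"),
    if (length(rc)) data.frame(start = rc, strand = "-")
  )
}

# Exhaustive stem/loop/tail enumerator for Rho-independent terminators on
# one strand, vectorised over sequence positions.
oracle_terminators_one <- function(seq, min_stem = 5, max_stem = 18,
                                   min_loop = 3, max_loop = 10,
                                   max_mismatch = 1, tail_gap_max = 3,
                                   tail_window = 8, tail_min_t = 5) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  tcum <- c(0L, cumsum(ch == "T"))
  pair_ok <- function(a, b) {
    (a == "A" & b == "T") | (a == "T" & b == "A") |
      (a == "G" & b == "C") | (a == "C" & b == "G") |
      (a == "G" & b == "T") | (a == "T" & b == "G")
  }
  rows <- list()
  for (s in min_stem:max_stem) {
    for (l in min_loop:max_loop) {
      span <- 2 * s + l
      n_pos <- n - span + 1
      if (n_pos < 1) next
      a <- seq_len(n_pos) # 1-based left arm start
      mm <- integer(n_pos)
      closed <- rep(TRUE, n_pos)
      for (jj in 0:(s - 1)) {
        x <- ch[a + jj]
        y <- ch[a + span - 1 - jj]
        bad <- !pair_ok(x, y) | x == "N" | y == "N"
        if (jj == 0 || jj == s - 1) {
          closed <- closed & !bad # boundary pairs must be real pairs
        } else {
          mm <- mm + as.integer(bad)
        }
      }
      # best T count over allowed tail gaps
      bestt <- rep(-1L, n_pos)
      for (g in 0:tail_gap_max) {
        lo <- a + span + g
        hi <- lo + tail_window - 1
        valid <- hi <= n
        ct <- ifelse(valid, tcum[pmin(hi, n) + 1] - tcum[pmin(lo, n + 1)],
                     -1L)
        bestt <- pmax(bestt, ct)
      }
      keep <- closed & mm <= max_mismatch & bestt >= tail_min_t
      if (any(keep)) {
        rows[[length(rows) + 1]] <- data.frame(
          start = a[keep], end = a[keep] + span - 1, stem_len = s,
          loop_len = l, mismatches = mm[keep],
          u_tail_score = bestt[keep] / tail_window)
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(start = integer(), end = integer(),
                      stem_len = integer(), loop_len = integer(),
                      mismatches = integer(), u_tail_score = double()))
  }
  h <- do.call(rbind, rows)
  # one hit per (start, end): fewest mismatches, longest stem, best tail
  h <- h[order(h$start, h$end, h$mismatches, -h$stem_len,
               -h$u_tail_score), , drop = FALSE]
  h <- h[!duplicated(h[, c("start", "end")]), , drop = FALSE]
  # drop hits strictly contained in a longer hit
  keep <- vapply(seq_len(nrow(h)), function(i) {
    !any(h$start <= h$start[i] & h$end >= h$end[i] &
           (h$end - h$start) > (h$end[i] - h$start[i]))
  }, logical(1))
  h[keep, , drop = FALSE]
}

oracle_terminators <- function(seq) {
  fw <- oracle_terminators_one(seq)
  if (nrow(fw)) fw$strand <- "+"
  rcseq <- intronscout::revcomp(seq)
  rc <- oracle_terminators_one(rcseq)
  if (nrow(rc)) {
    L <- nchar(seq)
    tmp <- rc
    rc$start <- L - tmp$end + 1L
    rc$end <- L - tmp$start + 1L
    rc$strand <- "-"
  }
  h <- rbind(fw, if (nrow(rc)) rc)
  h[order(h$start, h$end, h$strand), , drop = FALSE]
}

# Simple replicon tibble around raw sequences.
make_genome <- function(..., genome = "g1", genus = "GenusA",
                        kind = "chromosome", topology = "linear") {
  seqs <- c(...)
  ids <- if (is.null(names(seqs)) || any(names(seqs) == "")) {
    paste0(genome, "_r", seq_along(seqs))
  } else {
    names(seqs)
  }
  tibble::tibble(
    genome = genome, genus_complex = genus, replicon = ids,
    kind = kind, topology = topology, length = nchar(seqs),
    seq = unname(seqs))
}

rand_dna <- function(n, seed = NULL) {
  draw <- function() paste(sample(c("A", "C", "G", "T"), n, TRUE),
                           collapse = "")
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}
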