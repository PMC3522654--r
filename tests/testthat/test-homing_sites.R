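test_that("EBS consensus is the reverse complement of EBS1 under perfect
          Watson-Crick pairing", {
  # window -25..+10; IBS1 occupies positions 20..25 of the consensus
  win <- strrep("A", 35)
  ibs1 <- revcomp("GAAAGC") # GCTTTC
  substr(win, 20, 25) <- ibs1
  m <- build_consensus_from_ebs(list(EBS1 = "GAAAGC", EBS3 = NULL),
                                flank_windows = win)
  expect_s3_class(m, "homing_site_model")
  expect_equal(substr(m$consensus, 20, 25), ibs1)
  expect_equal(gsub("N", "", m$consensus), ibs1)
  expect_equal(m$offset, 25L)
})

test_that("G:U wobble pairings are accepted in the consensus", {
  # EBS base G pairs target T (wobble) as well as C
  win <- strrep("A", 35)
  substr(win, 25, 25) <- "T" # target T against EBS1 base G
  m <- build_consensus_from_ebs(list(EBS1 = "GAAAAG", EBS3 = NULL),
                                flank_windows = win)
  # EBS1 = G A A A A G -> IBS1 position 25 pairs the EBS 5' G
  expect_equal(substr(m$consensus, 25, 25), "T")
  # and EBS U/T pairs target G
  win2 <- strrep("A", 35)
  substr(win2, 25, 25) <- "G"
  m2 <- build_consensus_from_ebs(list(EBS1 = "TAAAAT", EBS3 = NULL),
                                 flank_windows = win2)
  expect_equal(substr(m2$consensus, 25, 25), "G")
})

test_that("identical bases across windows and reference extend the
          consensus", {
  withr::local_seed(31)
  base <- rand_dna(35)
  w1 <- base; w2 <- base
  # degrade all but 9 chosen non-EBS positions in window 2
  keep <- c(1, 3, 5, 7, 9, 11, 28, 30, 32)
  ch <- strsplit(w2, "")[[1]]
  for (i in setdiff(1:35, c(keep, 14:26))) {
    ch[i] <- setdiff(c("A", "C", "G", "T"), ch[i])[1]
  }
  w2 <- paste(ch, collapse = "")
  m <- build_consensus_from_ebs(list(EBS1 = "ACGTAC", EBS3 = NULL),
                                flank_windows = c(w1, w2),
                                reference_flank = base)
  cons <- strsplit(m$consensus, "")[[1]]
  bch <- strsplit(base, "")[[1]]
  expect_equal(cons[keep], bch[keep])
  out <- setdiff(1:13, keep)
  expect_true(all(cons[out] == "N"))
  expect_error(
    build_consensus_from_ebs(list(EBS1 = "ACGTAC", EBS3 = NULL),
                             flank_windows = c(w1, substr(w2, 1, 30))),
    "window")
})

test_that("conservation consensus fixes columns at the 0.8 threshold", {
  wins <- rep(strrep("A", 35), 26)
  m <- build_consensus_from_conservation(wins)
  expect_equal(m$consensus, strrep("A", 35))
  # a 50/50 column stays N
  half <- c(rep(paste0("C", strrep("A", 34)), 5),
            rep(paste0("G", strrep("A", 34)), 5))
  m2 <- build_consensus_from_conservation(half)
  expect_equal(substr(m2$consensus, 1, 1), "N")
  expect_equal(substr(m2$consensus, 2, 2), "A")
  expect_error(build_consensus_from_conservation(rep(strrep("A", 35), 4)),
               ">= 5")
})

test_that("conservation consensus recovers a generator consensus under
          noise", {
  withr::local_seed(32)
  truth <- rand_dna(35)
  wins <- vapply(1:10, function(i) {
    ch <- strsplit(truth, "")[[1]]
    flip <- which(stats::runif(35) < 0.10)
    for (p in flip) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
    paste(ch, collapse = "")
  }, character(1))
  m <- build_consensus_from_conservation(wins, threshold = 0.8)
  wmat <- do.call(rbind, strsplit(wins, ""))
  tch <- strsplit(truth, "")[[1]]
  for (i in 1:35) {
    modal <- max(table(wmat[, i])) / 10
    got <- substr(m$consensus, i, i)
    if (modal >= 0.8) expect_equal(got, names(which.max(table(wmat[, i]))))
    else expect_equal(got, "N")
  }
})

test_that("a canonical stem-loop with a poly-U tail is one clean hit", {
  # C-only flanks cannot pair with the stem or the U-tract, so the planted
  # hairpin is the exact maximal hit
  seq <- paste0(strrep("C", 30), "CCGGCC", "AAAA", "GGCCGG",
                strrep("T", 8), strrep("C", 30))
  g <- make_genome(chr1 = seq)
  h <- find_rho_independent_terminators(g)
  plus <- h[h$strand == "+" & h$start == 31 & h$end == 46, ]
  expect_equal(nrow(plus), 1)
  expect_equal(plus$mismatches, 0L)
  expect_equal(plus$stem_len, 6L)
  expect_equal(plus$u_tail_score, 1)
  # the same stem-loop without the U-tract is silent
  seq2 <- paste0(strrep("C", 30), "CCGGCC", "AAAA", "GGCCGG",
                 "ACACACAC", strrep("C", 30))
  h2 <- find_rho_independent_terminators(make_genome(chr1 = seq2))
  expect_equal(nrow(h2[h2$strand == "+" & h2$start == 31, ]), 0)
})

test_that("terminator detection is strand-symmetric", {
  withr::local_seed(35)
  seq <- rand_dna(4000)
  g1 <- make_genome(chr1 = seq)
  g2 <- make_genome(chr1 = revcomp(seq))
  h1 <- find_rho_independent_terminators(g1)
  h2 <- find_rho_independent_terminators(g2)
  L <- nchar(seq)
  mirrored <- tibble::tibble(
    start = L - h2$end + 1L, end = L - h2$start + 1L,
    strand = ifelse(h2$strand == "+", "-", "+"),
    stem_len = h2$stem_len, loop_len = h2$loop_len,
    mismatches = h2$mismatches, u_tail_score = h2$u_tail_score) |>
    dplyr::arrange(start, end, strand)
  expect_equal(dplyr::arrange(h1[, names(mirrored)], start, end, strand),
               mirrored)
})

test_that("terminator hits equal the exhaustive enumerator", {
  for (seed in 1:6) {
    withr::local_seed(400 + seed)
    seq <- rand_dna(3000)
    h <- find_rho_independent_terminators(make_genome(chr1 = seq))
    o <- oracle_terminators(seq)
    hh <- dplyr::arrange(as.data.frame(h[, c("start", "end", "strand",
                                             "stem_len", "loop_len",
                                             "mismatches")]),
                         start, end, strand)
    oo <- dplyr::arrange(o[, c("start", "end", "strand", "stem_len",
                               "loop_len", "mismatches")],
                         start, end, strand)
    rownames(hh) <- rownames(oo) <- NULL
    expect_equal(hh, oo)
  }
})

test_that("perfect-match scanning honours N semantics and both strands", {
  g <- make_genome(chr1 = "AGGTCCAGCT")
  m <- homing_site_model("I1", "ebs_consensus", "ANNT", 2L,
                         window = c(-2L, 2L))
  s <- scan_perfect_match(g, m)
  plus <- s[s$strand == "+", ]
  expect_equal(plus$start, c(1L, 7L))
  # all-N consensus is rejected
  mN <- homing_site_model("I1", "ebs_consensus", "NNNN", 2L,
                          window = c(-2L, 2L))
  expect_error(scan_perfect_match(g, mN), "non-N")
  # genomic N never matches a consensus N
  gN <- make_genome(chr1 = "AGNTCC")
  expect_equal(nrow(scan_perfect_match(gN, m)), 0)
  # a site planted as reverse complement is reported once on "-"
  withr::local_seed(36)
  cons <- "ACGTTGCA"
  bg <- paste0(rand_dna(50), revcomp(cons), rand_dna(50))
  g2 <- make_genome(chr1 = bg)
  m2 <- homing_site_model("I1", "ebs_consensus", cons, 4L,
                          window = c(-4L, 4L))
  s2 <- scan_perfect_match(g2, m2)
  s2 <- s2[s2$start == 51, ]
  expect_equal(nrow(s2), 1)
  expect_equal(s2$strand, "-")
})

test_that("perfect-match scanning equals the exhaustive window scan", {
  for (seed in 1:8) {
    withr::local_seed(500 + seed)
    seq <- rand_dna(4000)
    cons <- paste(sample(c("A", "C", "G", "T", "N"), 12, TRUE,
                         prob = c(.15, .15, .15, .15, .4)), collapse = "")
    if (!grepl("[ACGT]", cons)) cons <- paste0("A", substr(cons, 2, 12))
    m <- homing_site_model("I1", "ebs_consensus", cons, 6L,
                           window = c(-6L, 6L))
    s <- scan_perfect_match(make_genome(chr1 = seq), m)
    o <- oracle_scan(seq, cons)
    got <- paste(s$start, s$strand)
    want <- if (is.null(o)) character(0) else paste(o$start, o$strand)
    expect_setequal(got, want)
  }
})

test_that("flank-similarity scanning enforces identity, span and the
          integration point", {
  withr::local_seed(37)
  ctx <- rand_dna(90)
  bg <- function(insert) paste0(rand_dna(300), insert, rand_dna(300))
  m <- homing_site_model("I1", "flank_similarity", ctx, 45L,
                         window = c(-45L, 45L), context = ctx)
  s <- scan_flank_similarity(make_genome(chr1 = bg(ctx)), m)
  expect_equal(nrow(s), 1)
  expect_equal(s$pos, 345L)
  # 12 evenly spread mismatches: identity 86.7% < 90% in every window
  dch <- strsplit(ctx, "")[[1]]
  for (p in round(seq(5, 86, length.out = 12))) {
    dch[p] <- setdiff(c("A", "C", "G", "T"), dch[p])[1]
  }
  dirty <- paste(dch, collapse = "")
  expect_equal(nrow(scan_flank_similarity(make_genome(chr1 = bg(dirty)),
                                          m)), 0)
  # first 40 bases only: the integration point is missing
  expect_equal(nrow(scan_flank_similarity(
    make_genome(chr1 = bg(substr(ctx, 1, 40))), m)), 0)
})

test_that("terminator gating keeps only close same-strand downstream
          sites", {
  term <- tibble::tibble(replicon = "chr1", start = 100L, end = 130L,
                         strand = "+", stem_len = 6L, loop_len = 4L,
                         mismatches = 0L, u_tail_score = 1)
  site <- function(pos, strand = "+") tibble::tibble(
    genome = "g1", replicon = "chr1", start = pos - 24L, end = pos + 10L,
    pos = pos, strand = strand, intron = "I1",
    scheme = "classc_terminator", state = "AVAILABLE",
    occupied_by = NA_character_)
  # IBS1 start = pos - 5; kept iff 0 <= (pos - 5) - 130 <= 20
  expect_equal(nrow(restrict_to_terminator_downstream(site(139L), term)), 1)
  expect_equal(nrow(restrict_to_terminator_downstream(site(90L), term)), 0)
  expect_equal(nrow(restrict_to_terminator_downstream(site(139L, "-"),
                                                      term)), 0)
  expect_equal(nrow(restrict_to_terminator_downstream(site(160L), term)), 0)
  # subset property
  s <- dplyr::bind_rows(site(139L), site(150L), site(90L))
  out <- restrict_to_terminator_downstream(s, term)
  expect_true(all(out$pos %in% s$pos))
})

test_that("occupancy marking counts copies as occupied and prunes sites
          inside copies", {
  pop <- pop_occupancy()
  occ <- pop$survey$occupancy_full_length
  cha <- occ[occ$intron == "cHa.I1", ]
  expect_equal(cha$occupied, 26L)
  expect_equal(cha$available, 17L)
  expect_equal(cha$proportion_pct, 60)
  # a candidate site inside an intron copy interval is dropped
  copies <- tibble::tibble(
    copy_id = "c1", genome = "g1", genus_complex = "G", replicon = "chr1",
    container = "CHROMOSOME", start = 100L, end = 1200L, strand = "+",
    ref_name = "I1", assigned_name = "I1", completeness = "full_length",
    identity = 1, orf_intact = TRUE, level = "nt")
  inside <- tibble::tibble(
    genome = "g1", replicon = "chr1", start = 476L, end = 510L, pos = 500L,
    strand = "+", intron = "I1", scheme = "ebs_consensus",
    state = "AVAILABLE", occupied_by = NA_character_)
  marked <- mark_occupancy(inside, copies, intron = "I1")
  expect_equal(sum(marked$state == "AVAILABLE"), 0)
  expect_equal(sum(marked$state == "OCCUPIED"), 1)
  # no copies at all: candidate sites stay available
  marked2 <- mark_occupancy(inside, copies[0, ], intron = "I1")
  expect_equal(sum(marked2$state == "AVAILABLE"), 1)
  expect_equal(sum(marked2$state == "OCCUPIED"), 0)
})
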