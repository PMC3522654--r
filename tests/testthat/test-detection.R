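mk_hit <- function(start, end, identical, aligned = identical,
                   ref = "R1", level = "nt", strand = "+") {
  tibble::tibble(
    genome = "g1", replicon = "chr1", start = start, end = end,
    strand = strand, ref_name = ref, ref_start = 1L,
    ref_end = end - start + 1L, identical = identical, aligned = aligned,
    similarity = identical / aligned, score = identical, level = level)
}

test_that("overlap filtering keeps the hit with most identical sites", {
  h <- dplyr::bind_rows(mk_hit(101L, 400L, 250L, 300L),
                        mk_hit(301L, 600L, 180L, 300L))
  out <- filter_overlapping_hits(h)
  expect_equal(nrow(out), 1)
  expect_equal(out$start, 101L)
  # disjoint hits are both retained
  h2 <- dplyr::bind_rows(mk_hit(1L, 100L, 80L, 100L),
                         mk_hit(201L, 300L, 60L, 100L))
  expect_equal(nrow(filter_overlapping_hits(h2)), 2)
})

test_that("overlap filtering output is non-overlapping and recursion keeps
          secondary non-overlapping hits", {
  # chain: A overlaps B, B overlaps C, A and C disjoint; A best, C second
  h <- dplyr::bind_rows(mk_hit(1L, 200L, 190L, 200L),
                        mk_hit(150L, 350L, 150L, 200L),
                        mk_hit(301L, 500L, 170L, 200L))
  out <- filter_overlapping_hits(h)
  expect_equal(sort(out$start), c(1L, 301L))
  # ties on identical sites: higher similarity, then leftmost start
  t1 <- dplyr::bind_rows(mk_hit(1L, 200L, 150L, 200L),
                         mk_hit(100L, 250L, 150L, 180L))
  expect_equal(filter_overlapping_hits(t1)$start, 100L) # higher similarity
  t2 <- dplyr::bind_rows(mk_hit(100L, 250L, 150L, 200L),
                         mk_hit(1L, 200L, 150L, 200L))
  expect_equal(filter_overlapping_hits(t2)$start, 1L) # leftmost on full tie
})

test_that("overlap filtering matches greedy enumeration on small sets", {
  greedy <- function(h) {
    kept <- h[0, ]
    h <- dplyr::arrange(h, dplyr::desc(identical), dplyr::desc(similarity),
                        start, end)
    while (nrow(h) > 0) {
      kept <- dplyr::bind_rows(kept, h[1, ])
      h <- h[!(h$start <= kept$end[nrow(kept)] &
                 h$end >= kept$start[nrow(kept)]), ]
    }
    dplyr::arrange(kept, start)
  }
  for (seed in 1:10) {
    withr::local_seed(seed)
    n <- sample(3:6, 1)
    h <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
      s <- sample(1:500, 1)
      len <- sample(50:200, 1)
      al <- len
      id <- sample(round(0.6 * al):al, 1)
      mk_hit(s, s + len - 1L, id, al)
    }))
    expect_equal(filter_overlapping_hits(h)$start, greedy(h)$start)
  }
})

test_that("detection thresholds are strict and nucleotide-only for similarity", {
  short_hit <- mk_hit(1L, 99L, 98L, 99L)         # 99 bp, 99% similar
  low_sim <- mk_hit(1L, 150L, 111L, 150L)        # 150 bp, 74% similar
  low_sim_aa <- mk_hit(1L, 150L, 111L, 150L, level = "aa")
  boundary <- mk_hit(1L, 100L, 75L, 100L)        # exactly 100 bp, 75%
  h <- dplyr::bind_rows(short_hit, low_sim, low_sim_aa, boundary)
  out <- apply_detection_thresholds(h)
  expect_equal(nrow(out), 2)
  expect_true(all(out$start == 1 & out$end %in% c(150L, 100L)))
  expect_setequal(out$level, c("aa", "nt"))
  expect_equal(out$similarity[out$level == "nt"], 0.75)
})

test_that("a second search round recovers copies too divergent for round 1", {
  withr::local_seed(77)
  ref <- rand_dna(800)
  near <- mutate_sequence(ref, 0.08, seed = 1, protect_ends = 20)
  far <- mutate_sequence(near, 0.08, seed = 2, protect_ends = 20)
  # far is ~8% from near but ~15%+ from ref; shrink ref similarity further
  far2 <- mutate_sequence(far, 0.12, seed = 3, protect_ends = 20)
  g <- make_genome(chr1 = paste0(rand_dna(400), near, rand_dna(400), far2,
                                 rand_dna(400)))
  lib <- tibble::tibble(name = "R1", seq = ref)
  p <- detection_params()
  r1 <- seed_extend_search(g, lib, p, level = "nt") |>
    filter_overlapping_hits() |>
    apply_detection_thresholds(p$min_length, p$min_similarity)
  # far2 is ~26% diverged from the reference: below the 75% filter
  expect_equal(nrow(r1), 1)
  r2 <- second_round_search(g, r1, p)
  expect_equal(nrow(r2), 2)
  expect_true(any(r2$start > 1600))
})

test_that("second round without any round-1 copies returns its input", {
  h <- mk_hit(1L, 100L, 100L)[0, ]
  g <- make_genome(chr1 = rand_dna(500, seed = 5))
  expect_equal(nrow(second_round_search(g, h)), 0)
})

test_that("completeness follows reference coverage within edge slack", {
  expect_equal(classify_completeness(cbind(3L, 698L), 700L), "full_length")
  expect_equal(classify_completeness(cbind(200L, 450L), 700L), "fragment")
  expect_equal(classify_completeness(cbind(200L, 450L), 700L,
                                     boundary_evidence = TRUE),
               "full_length")
  # slack boundary: start within edge_slack + 1 counts as covered
  expect_equal(classify_completeness(cbind(16L, 700L), 700L), "full_length")
  expect_equal(classify_completeness(cbind(17L, 700L), 700L), "fragment")
})

test_that("completeness calls on a synthetic population match the truth", {
  pop <- pop_small()
  cp <- pop$survey$copies
  man <- pop$manifest$copies
  expect_equal(nrow(cp), nrow(man))
  for (i in seq_len(nrow(man))) {
    hit <- cp[cp$genome == man$strain[i] &
                abs(cp$start - man$start[i]) <= 5, ]
    expect_equal(nrow(hit), 1)
    expect_equal(hit$completeness, man$completeness[i])
  }
})

test_that("naming is by the >10% divergence rule, deterministic and
          idempotent", {
  cp <- tibble::tibble(
    genome = "g1", replicon = "chr1", start = c(10L, 500L, 900L),
    ref_name = "Zb.I1", identity = c(1, 0.89, 0.90))
  named <- assign_intron_names(cp)
  expect_equal(named$assigned_name, c("Zb.I1", "g1.I1", "Zb.I1"))
  expect_equal(assign_intron_names(named[, names(cp)])$assigned_name,
               named$assigned_name)
})

test_that("ORF assessment detects frameshifts and premature stops", {
  ref <- generate_reference_intron("R1", 900, seed = 4)
  expect_true(assess_orf(ref$seq, ref$orf_start, ref$orf_end))
  # single-base deletion inside the ORF: frameshift
  mid <- ref$orf_start + 150L
  fs <- paste0(substr(ref$seq, 1, mid - 1),
               substr(ref$seq, mid + 1, nchar(ref$seq)))
  expect_false(assess_orf(fs, ref$orf_start, ref$orf_end))
  # premature stop
  ps <- ref$seq
  stop_at <- ref$orf_start + 3L * 50L
  substr(ps, stop_at, stop_at + 2L) <- "TAA"
  expect_false(assess_orf(ps, ref$orf_start, ref$orf_end))
  expect_error(assess_orf(ref$seq, ref$orf_start, ref$orf_end,
                          completeness = "fragment"), "full-length")
})

test_that("planted ORF disruptions are recovered in copy calls", {
  pop <- pop_small()
  cp <- pop$survey$copies
  man <- pop$manifest$copies
  j <- dplyr::inner_join(cp, man,
                         by = c(genome = "strain", "replicon", "start"))
  full <- j[j$completeness.x == "full_length", ]
  expect_gt(nrow(full), 0)
  expect_equal(full$orf_intact.x, full$orf_intact.y)
})

test_that("no copies are reported in intron-free random genomes", {
  cfg <- sim_config(
    n_strains = 1, chromosome_length = 400000,
    intron_specs = list(intron_spec("FP.I1", length = 1500,
                                    scheme = "ebs_consensus")),
    seed = 42)
  pop <- generate_population(cfg)
  cp <- detect_introns(pop$genomes, pop$library)
  expect_equal(nrow(cp), 0)
})
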