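mk_copy <- function(id, genome, replicon, start, end, strand = "+",
                    ref = "R1", genus = "GenusA") {
  tibble::tibble(
    copy_id = id, genome = genome, genus_complex = genus,
    replicon = replicon, container = "CHROMOSOME", start = start,
    end = end, strand = strand, ref_name = ref, assigned_name = ref,
    completeness = "full_length", identity = 1, orf_intact = TRUE,
    level = "nt")
}

test_that("flank extraction handles interior, edge and circular cases", {
  seq20k <- rand_dna(20000, seed = 8)
  g <- make_genome(chr1 = seq20k)
  cp <- mk_copy("c1", "g1", "chr1", 5001L, 6000L)
  fl <- extract_flanks(cp, g)
  expect_equal(fl$upstream, substr(seq20k, 2001, 5000))
  expect_equal(fl$downstream, substr(seq20k, 6001, 9000))
  # near the start of a linear replicon the upstream flank truncates
  cp2 <- mk_copy("c2", "g1", "chr1", 101L, 800L)
  fl2 <- extract_flanks(cp2, g)
  expect_equal(nchar(fl2$upstream), 100L)
  expect_equal(fl2$upstream, substr(seq20k, 1, 100))
  # circular replicons wrap across the origin
  gc <- make_genome(chr1 = seq20k, topology = "circular")
  cp3 <- mk_copy("c3", "g1", "chr1", 1001L, 1500L)
  fl3 <- extract_flanks(cp3, gc)
  expect_equal(nchar(fl3$upstream), 3000L)
  expect_equal(fl3$upstream,
               paste0(substr(seq20k, 18001, 20000), substr(seq20k, 1, 1000)))
})

test_that("contiguous flanks in a subject genome mean retrohoming", {
  withr::local_seed(12)
  fu <- rand_dna(3000); fd <- rand_dna(3000); intron <- rand_dna(1000)
  qg <- make_genome(chr1 = paste0(rand_dna(800), fu, intron, fd,
                                  rand_dna(800)),
                    genome = "gq")
  sg <- make_genome(chr1 = paste0(rand_dna(1200), fu, fd, rand_dna(600)),
                    genome = "gs")
  cp <- mk_copy("c1", "gq", "gq_r1", 3801L, 4800L)
  cp$replicon <- qg$replicon
  fl <- extract_flanks(cp, qg)
  call <- classify_insertion(fl[1, ], cp[1, ], sg, cp[0, ])
  expect_equal(call$classification, "RETROHOMED")
  expect_lte(abs(call$adjacency_gap), 20)
})

test_that("flanks matching a subject copy's flanks mean orthology", {
  withr::local_seed(13)
  fu <- rand_dna(3000); fd <- rand_dna(3000); intron <- rand_dna(1000)
  cass <- paste0(fu, intron, fd)
  qg <- make_genome(chr1 = paste0(rand_dna(700), cass, rand_dna(500)),
                    genome = "gq")
  sg <- make_genome(chr1 = paste0(rand_dna(1500), cass, rand_dna(900)),
                    genome = "gs")
  cpq <- mk_copy("cq", "gq", qg$replicon, 3701L, 4700L)
  cps <- mk_copy("cs", "gs", sg$replicon, 4501L, 5500L)
  fl <- extract_flanks(cpq, qg)
  call <- classify_insertion(fl[1, ], cpq[1, ], sg, cps)
  expect_equal(call$classification, "ORTHOLOGOUS")
  expect_equal(call$partner_copy_id, "cs")
})

test_that("absent flanks leave the call unresolved", {
  withr::local_seed(14)
  qg <- make_genome(chr1 = rand_dna(8000), genome = "gq")
  sg <- make_genome(chr1 = rand_dna(8000), genome = "gs")
  cp <- mk_copy("c1", "gq", qg$replicon, 3001L, 4000L)
  fl <- extract_flanks(cp, qg)
  call <- classify_insertion(fl[1, ], cp[1, ], sg, cp[0, ])
  expect_equal(call$classification, "UNRESOLVED")
})

test_that("MGE overrides reclassify listed pairs only", {
  calls <- tibble::tibble(
    copy_id = c("a", "b", "c"), subject_genome = c("g2", "g3", "g2"),
    classification = c("ORTHOLOGOUS", "ORTHOLOGOUS", "UNRESOLVED"),
    partner_copy_id = c("x", "y", NA), adjacency_gap = NA_integer_)
  ov <- tibble::tibble(copy_id = c("a", "c"), subject_genome = c("g2", "g2"))
  out <- apply_mge_overrides(calls, ov)
  expect_equal(out$classification, c("DISTINCT_MGE", "ORTHOLOGOUS",
                                     "DISTINCT_MGE"))
  # empty override table is the identity
  expect_equal(apply_mge_overrides(calls, NULL), calls)
  expect_equal(apply_mge_overrides(calls, ov[0, ]), calls)
  # rows pointing at non-existent calls are an error
  bad <- tibble::tibble(copy_id = "zz", subject_genome = "g9")
  expect_error(apply_mge_overrides(calls, bad), "non-existent")
})

test_that("distinct collapsing is the transitive closure of orthology", {
  copies <- dplyr::bind_rows(lapply(letters[1:5], function(x) {
    mk_copy(x, paste0("g", x), "chr", 1L, 10L)
  }))
  calls <- tibble::tibble(
    copy_id = c("a", "b", "d"), subject_genome = "s",
    classification = "ORTHOLOGOUS", partner_copy_id = c("b", "c", "e"),
    adjacency_gap = NA_integer_)
  ds <- collapse_distinct(copies, calls)
  expect_equal(length(unique(ds$set_id)), 2)
  grp <- split(ds$copy_id, ds$set_id)
  expect_setequal(vapply(grp, function(g) paste(sort(g), collapse = ""),
                         character(1)), c("abc", "de"))
  # no calls: every copy is its own element
  ds2 <- collapse_distinct(copies, calls[0, ])
  expect_equal(length(unique(ds2$set_id)), 5)
  # partition: every copy in exactly one set
  expect_setequal(ds$copy_id, copies$copy_id)
  expect_equal(anyDuplicated(ds$copy_id), 0L)
  # invariant to input order
  ds3 <- collapse_distinct(copies[5:1, ], calls[c(3, 1, 2), ])
  expect_equal(dplyr::arrange(ds3, copy_id)$set_id,
               dplyr::arrange(ds, copy_id)$set_id)
})

test_that("recovered orthology groups match the planted truth", {
  pop <- pop_orthology()
  sv <- pop$survey
  ov <- truth_overrides(pop$manifest, sv$copies)
  calls <- apply_mge_overrides(sv$calls, ov)
  ds <- collapse_distinct(sv$copies, calls)
  man <- pop$manifest$copies
  # map detected copies to manifest rows by coordinates
  key <- function(g, s) paste(g, round(s / 10))
  man$copy_id <- vapply(seq_len(nrow(man)), function(i) {
    hit <- sv$copies[sv$copies$genome == man$strain[i] &
                       abs(sv$copies$start - man$start[i]) <= 5, ]
    hit$copy_id[1]
  }, character(1))
  expect_false(any(is.na(man$copy_id)))
  truth_groups <- split(man$copy_id, ifelse(is.na(man$ortho_group),
                                            man$copy_id, man$ortho_group))
  found_groups <- split(ds$copy_id, ds$set_id)
  norm <- function(gs) sort(vapply(gs, function(g)
    paste(sort(g), collapse = "|"), character(1)), method = "radix")
  expect_equal(unname(norm(found_groups)), unname(norm(truth_groups)))
  expect_equal(length(unique(ds$set_id)), length(truth_groups))
})

test_that("insertion calls reproduce the planted scenario classes", {
  pop <- pop_orthology()
  sv <- pop$survey
  ov <- truth_overrides(pop$manifest, sv$copies)
  calls <- apply_mge_overrides(sv$calls, ov)
  man <- pop$manifest$copies
  find_id <- function(strain, start) {
    hit <- sv$copies[sv$copies$genome == strain &
                       abs(sv$copies$start - start) <= 5, ]
    hit$copy_id[1]
  }
  # retrohoming: the source copy is RETROHOMED against every strain whose
  # matched locus is intron-free
  rl <- pop$manifest$retro_loci
  for (i in seq_len(nrow(rl))) {
    src <- man[man$strain == rl$source_strain[i], ]
    src <- src[is.na(src$ortho_group) & !src$mge, ]
    ids <- vapply(seq_len(nrow(src)), function(k)
      find_id(src$strain[k], src$start[k]), character(1))
    cc <- calls[calls$copy_id %in% ids &
                  calls$subject_genome == rl$strain[i], ]
    expect_true(any(cc$classification == "RETROHOMED"))
  }
  # orthology: each group member is ORTHOLOGOUS against strains carrying
  # another member
  ogs <- man[!is.na(man$ortho_group), ]
  for (g in unique(ogs$ortho_group)) {
    mem <- ogs[ogs$ortho_group == g, ]
    ids <- vapply(seq_len(nrow(mem)), function(k)
      find_id(mem$strain[k], mem$start[k]), character(1))
    for (k in seq_len(nrow(mem))) {
      others <- setdiff(mem$strain, mem$strain[k])
      cc <- calls[calls$copy_id == ids[k] &
                    calls$subject_genome %in% others, ]
      expect_true(all(cc$classification == "ORTHOLOGOUS"))
    }
  }
  # the MGE pair ends up DISTINCT_MGE after the override
  expect_equal(sum(calls$classification == "DISTINCT_MGE"), 2)
})
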