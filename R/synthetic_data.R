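# Synthetic bacterial populations with planted group II introns, homing
# sites, terminators, orthologues and MGE transfers -- with full ground
# truth -- so that every pipeline stage can be exercised without external
# data.  Planting is cassette-based: per-strain random backgrounds receive
# non-overlapping cassettes (site templates, site+intron, shared-flank
# loci); all coordinates are recorded in a truth manifest.
#
# Background sequence is i.i.d. with configured GC content and is scrubbed
# of chance occurrences of each intron's fixed site motif, so that the
# number of consensus matches in a generated genome is exactly the number
# of planted sites.  Divergence is substitution-only (exact identity
# arithmetic); planted elements always sit on the forward strand (strand
# symmetry of the scanners is exercised by dedicated unit tests).

comp_base <- function(b) chartr("ACGTU", "TGCAA", b)

#' Substitute a fixed number of positions in a sequence
#'
#' Exactly `round(divergence * nchar(seq))` distinct positions are replaced
#' by a different base (uniform choice); deterministic under `seed`.
#' `protect_ends` keeps that many bases at each extremity untouched so the
#' realised local-alignment identity of a planted copy equals
#' `1 - divergence` exactly (no end trimming).
#'
#' @param seq DNA string.
#' @param divergence Fraction in \[0, 0.5\].
#' @param seed Integer seed.
#' @param protect_ends Bases spared at each end (default 0).
#' @return The mutated sequence.
#' @export
mutate_sequence <- function(seq, divergence, seed, protect_ends = 0) {
  stopifnot(divergence >= 0, divergence <= 0.5)
  n <- nchar(seq)
  k <- round(divergence * n)
  if (k == 0) return(seq)
  withr::with_seed(seed, {
    shielded <- if (protect_ends > 0) {
      c(seq_len(protect_ends), seq(n - protect_ends + 1L, n))
    } else {
      integer(0)
    }
    eligible <- setdiff(seq_len(n), shielded)
    pos <- sample(eligible, k)
    ch <- seq_chars(seq)
    for (p in pos) {
      ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
    }
    paste(ch, collapse = "")
  })
}

#' Generate a reference group II intron
#'
#' A random ribozyme body with an embedded uninterrupted ORF (ATG start,
#' stop-free codons, terminal stop) and recorded EBS motifs.  Class C
#' entries carry only EBS1 and EBS3.
#'
#' @param name Intron name.
#' @param length Total length in bp (>= 400).
#' @param orf_class ORF class; `"C"` marks bacterial class C.
#' @param gc GC content of the non-ORF body.
#' @param seed Integer seed (deterministic output).
#' @return One-row reference library tibble (see [read_intron_library()]).
#' @export
generate_reference_intron <- function(name = "ref.I1", length = 1500,
                                      orf_class = "ML", gc = 0.5, seed = 1) {
  stopifnot(length >= 400)
  withr::with_seed(seed, {
    body <- random_dna(length, gc)
    orf_start <- 400L
    n_codons <- max(20L, ((length - orf_start - 60L) %/% 3L))
    orf_end <- orf_start + 3L * n_codons - 1L
    stopifnot(orf_end <= length)
    codons <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                                c("A", "C", "G", "T")), 1, paste,
                    collapse = "")
    sense <- setdiff(codons, c("TAA", "TAG", "TGA"))
    orf <- c("ATG", sample(sense, n_codons - 2L, replace = TRUE), "TAA")
    seqv <- seq_chars(body)
    seqv[orf_start:orf_end] <- unlist(strsplit(orf, ""))
    ebs1 <- random_dna(6, 0.5)
    ebs2 <- if (orf_class == "C") NA_character_ else random_dna(6, 0.5)
    ebs3 <- random_dna(1, 0.5)
    # junction guard: the first intron base must differ from the IBS3 base,
    # so an occupied locus can never look like a free site
    if (seqv[1] == comp_base(ebs3)) {
      seqv[1] <- setdiff(c("A", "C", "G", "T"), comp_base(ebs3))[1]
    }
    seq <- paste(seqv, collapse = "")
    prot <- as.character(Biostrings::translate(Biostrings::DNAString(
      substr(seq, orf_start, orf_end - 3L))))
    tibble::tibble(
      name = name,
      ribozyme_group = if (orf_class == "C") "IIC" else "IIB",
      orf_class = orf_class,
      orf_start = orf_start, orf_end = orf_end,
      ebs1 = ebs1, ebs2 = ebs2, ebs3 = ebs3,
      functional = TRUE, seq = seq, protein = prot
    )
  })
}

#' Planting plan for one intron in a synthetic population
#'
#' @param name Intron name.
#' @param length Reference length in bp.
#' @param orf_class ORF class (`"C"` for terminator-targeting class C).
#' @param scheme Homing-site scheme the intron is surveyed with.
#' @param n_full Full-length copies planted in the target strain.
#' @param n_fragment Truncated (internal-slice) copies planted there.
#' @param n_free Free (unoccupied) homing sites planted there.
#' @param divergence Substitution divergence of full copies from the
#'   reference.
#' @param fragment_divergence,fragment_fraction Divergence and relative
#'   length of fragments.
#' @param n_orf_disrupted How many full copies receive a premature stop.
#' @param custom_fragments Optional data frame (`length`, `divergence`) of
#'   additional non-ORF-region fragments (threshold boundary material).
#' @param ortho_groups Number of orthologous groups: one identical copy with
#'   shared 3 kb flanks planted in each of `ortho_group_size` strains.
#' @param ortho_group_size Strains per orthologous group (default 2).
#' @param retro_loci Retrohoming-testable loci: a copy in the target strain
#'   whose flanked site exists intron-free in every other strain.
#' @param mge_transfer Plant one shared-flank cassette at different loci in
#'   strains 1 and 2 (to be reclassified `DISTINCT_MGE` via override).
#' @param noise_positions Window columns receiving cycling per-site noise
#'   (conservation-scheme testing).
#' @param target_strain Strain index receiving the per-strain plants.
#' @return A list of class `intron_spec`.
#' @export
intron_spec <- function(name, length = 1500, orf_class = "ML",
                        scheme = c("ebs_consensus", "classc_terminator",
                                   "conservation_consensus",
                                   "flank_similarity"),
                        n_full = 0, n_fragment = 0, n_free = 0,
                        divergence = 0, fragment_divergence = 0,
                        fragment_fraction = 0.4, n_orf_disrupted = 0,
                        custom_fragments = NULL, ortho_groups = 0,
                        ortho_group_size = 2, retro_loci = 0,
                        mge_transfer = FALSE, noise_positions = 0,
                        target_strain = 1) {
  scheme <- match.arg(scheme)
  if (orf_class == "C" && scheme == "ebs_consensus") {
    scheme <- "classc_terminator"
  }
  structure(as.list(environment()), class = "intron_spec")
}

#' Configuration of a synthetic population
#'
#' @param n_strains Number of strains.
#' @param genus_complex Grouping label shared by all strains.
#' @param strain_prefix Strain names are `<prefix><i>`.
#' @param chromosome_length Background chromosome length in bp.
#' @param n_plasmids,plasmid_length Plain background plasmids per strain.
#' @param gc Background GC content.
#' @param topology Chromosome topology (`"linear"` or `"circular"`).
#' @param intron_specs List of [intron_spec()] plans.
#' @param seed Master seed; identical configs give byte-identical output.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_strains = 1, genus_complex = "SimGenus",
                       strain_prefix = "strain",
                       chromosome_length = 100000L, n_plasmids = 0,
                       plasmid_length = 20000L, gc = 0.5,
                       topology = "linear", intron_specs = list(),
                       seed = 1) {
  stopifnot(n_strains >= 1, chromosome_length >= 20000)
  structure(as.list(environment()), class = "sim_config")
}

# Replace chance occurrences of `pattern` (and its reverse complement) in a
# background sequence by mutating the middle base of each occurrence.
scrub_pattern <- function(bg, pattern) {
  pats <- unique(c(pattern, revcomp(pattern)))
  for (iter in 1:5) {
    found <- FALSE
    for (p in pats) {
      m <- gregexpr(p, bg, fixed = TRUE)[[1]]
      if (m[1] == -1) next
      found <- TRUE
      ch <- seq_chars(bg)
      for (s in as.integer(m)) {
        mid <- s + nchar(p) %/% 2
        ch[mid] <- setdiff(c("A", "C", "G", "T"), ch[mid])[1]
      }
      bg <- paste(ch, collapse = "")
    }
    if (!found) break
  }
  bg
}

# Remove site-motif occurrences from an intron sequence without creating a
# stop codon inside its ORF.
scrub_intron <- function(seq, pattern, orf_start, orf_end) {
  pats <- unique(c(pattern, revcomp(pattern)))
  for (iter in 1:5) {
    hit <- FALSE
    for (p in pats) {
      m <- gregexpr(p, seq, fixed = TRUE)[[1]]
      if (m[1] == -1) next
      hit <- TRUE
      ch <- seq_chars(seq)
      for (s in as.integer(m)) {
        mid <- s + nchar(p) %/% 2
        for (cand in setdiff(c("A", "C", "G", "T"), ch[mid])) {
          ch2 <- ch
          ch2[mid] <- cand
          if (mid >= orf_start && mid <= orf_end) {
            cstart <- orf_start + 3 * ((mid - orf_start) %/% 3)
            codon <- paste(ch2[cstart:(cstart + 2)], collapse = "")
            if (codon %in% c("TAA", "TAG", "TGA")) next
          }
          ch <- ch2
          break
        }
      }
      seq <- paste(ch, collapse = "")
    }
    if (!hit) break
  }
  seq
}

# Build the per-intron site machinery: the window template, the cassette
# builders and the fixed scan motif to scrub from backgrounds.
make_site_kit <- function(ref, spec) {
  off <- 25L
  width <- 35L
  ibs1 <- revcomp(ref$ebs1)
  ibs3 <- comp_base(ref$ebs3)
  if (spec$scheme == "classc_terminator") {
    stem_left <- random_dna(6, 0.8)
    loop <- random_dna(4, 0.5)
    pre <- random_dna(5, 0.5)
    spacer0 <- random_dna(4, 0.5)
    # guard: spacer must not extend the stem pairing into the U-tract side
    head_seq <- paste0(pre, stem_left, loop, revcomp(stem_left),
                       strrep("T", 8), spacer0)
    tmpl_free <- paste0(head_seq, ibs1, ibs3, random_dna(9, 0.5))
    ins_at <- nchar(head_seq) + 6L # base immediately 5' of insertion
    list(
      scheme = spec$scheme,
      scrub = paste0(ibs1, ibs3),
      free_cassette = tmpl_free,
      ins_at = ins_at,
      window_start = ins_at - 25L + 1L,
      term_start = nchar(pre) + 1L,
      term_end = nchar(pre) + 16L,
      occupied_cassette = function(copy_seq) {
        paste0(substr(tmpl_free, 1, ins_at), copy_seq,
               substr(tmpl_free, ins_at + 1L, nchar(tmpl_free)))
      }
    )
  } else if (spec$scheme == "flank_similarity") {
    ctx <- random_dna(90, 0.5)
    ch <- seq_chars(ctx)
    ch[34:39] <- seq_chars(revcomp(ref$ebs2))
    ch[40:45] <- seq_chars(ibs1)
    ch[46] <- ibs3
    ctx <- paste(ch, collapse = "")
    list(
      scheme = spec$scheme,
      scrub = substr(ctx, 34, 46),
      free_cassette = ctx,
      ins_at = 45L,
      window_start = 45L - 25L + 1L,
      term_start = NA_integer_, term_end = NA_integer_,
      occupied_cassette = function(copy_seq) {
        paste0(substr(ctx, 1, 45), copy_seq, substr(ctx, 46, 90))
      }
    )
  } else {
    tmpl <- random_dna(width, 0.5)
    ch <- seq_chars(tmpl)
    if (spec$scheme == "ebs_consensus") {
      ch[14:19] <- seq_chars(revcomp(ref$ebs2))
      ch[20:25] <- seq_chars(ibs1)
      ch[26] <- ibs3
    }
    tmpl <- paste(ch, collapse = "")
    noise_cols <- integer(0)
    if (spec$noise_positions > 0) {
      noise_cols <- sample(setdiff(seq_len(width), 14:26),
                           spec$noise_positions)
    }
    scrub <- if (spec$scheme == "ebs_consensus") {
      substr(tmpl, 14, 26)
    } else {
      tmpl # conservation: the full fixed window
    }
    counter <- new.env()
    counter$i <- 0L
    vary <- function() {
      if (length(noise_cols) == 0) return(tmpl)
      counter$i <- counter$i + 1L
      ch <- seq_chars(tmpl)
      ch[noise_cols] <- c("A", "C", "G", "T")[
        ((counter$i + seq_along(noise_cols)) %% 4L) + 1L]
      paste(ch, collapse = "")
    }
    list(
      scheme = spec$scheme,
      scrub = scrub,
      free_cassette = NULL, # drawn fresh per site when noise is on
      draw_free = vary,
      ins_at = off,
      window_start = 1L,
      term_start = NA_integer_, term_end = NA_integer_,
      occupied_cassette = function(copy_seq) {
        t <- vary()
        paste0(substr(t, 1, off), copy_seq, substr(t, off + 1L, width))
      }
    )
  }
}

kit_free_cassette <- function(kit) {
  if (!is.null(kit$free_cassette)) kit$free_cassette else kit$draw_free()
}

#' Generate a synthetic strain population with ground truth
#'
#' Emits per-strain genomes (chromosome plus optional plasmids) carrying the
#' planted intron copies, free homing sites, terminators, orthologous loci
#' and MGE-transfer scenarios requested by the configuration, together with
#' a truth manifest recording every planted feature.
#'
#' @param config A [sim_config()].
#' @return A list: `genomes` (replicon tibble as from [read_genomes()]),
#'   `library` (reference library tibble with a `scheme` column),
#'   `manifest` (list of tibbles: `copies`, `free_sites`, `terminators`,
#'   `retro_loci`, `mge_pairs`), and `config`.
#' @export
generate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, generate_population_impl(config))
}

generate_population_impl <- function(config) {
  ns <- config$n_strains
  strains <- paste0(config$strain_prefix, seq_len(ns))
  # reference library + site kits
  lib <- list()
  kits <- list()
  for (i in seq_along(config$intron_specs)) {
    spec <- config$intron_specs[[i]]
    ref <- generate_reference_intron(spec$name, spec$length, spec$orf_class,
                                     config$gc,
                                     seed = config$seed * 1000L + i)
    kit <- make_site_kit(ref, spec)
    ref$seq <- scrub_intron(ref$seq, kit$scrub, ref$orf_start, ref$orf_end)
    ref$scheme <- spec$scheme
    lib[[i]] <- ref
    kits[[i]] <- kit
  }
  library_tbl <- dplyr::bind_rows(lib)

  # per-strain cassette plans
  plans <- lapply(seq_len(ns), function(i) list())
  add <- function(strain_idx, cassette, meta) {
    meta$cassette <- cassette
    plans[[strain_idx]][[length(plans[[strain_idx]]) + 1L]] <<- meta
  }
  copy_counter <- 0L
  new_copy_meta <- function(intron, completeness, divergence, orf_intact,
                            intron_off, intron_len, kit, ortho_group = NA,
                            mge = FALSE, record_site = TRUE) {
    copy_counter <<- copy_counter + 1L
    list(kind = "copy", intron = intron, completeness = completeness,
         divergence = divergence, orf_intact = orf_intact,
         intron_off = intron_off, intron_len = intron_len,
         kit = kit, ortho_group = ortho_group, mge = mge,
         record_site = record_site, uid = copy_counter)
  }

  for (i in seq_along(config$intron_specs)) {
    spec <- config$intron_specs[[i]]
    ref <- lib[[i]]
    kit <- kits[[i]]
    ts <- spec$target_strain
    full_seq <- function(div, seed_off, disrupted = FALSE) {
      s <- if (div > 0) {
        mutate_sequence(ref$seq, div, config$seed * 10000L + seed_off,
                        protect_ends = 25)
      } else {
        ref$seq
      }
      if (disrupted) {
        mid_codon <- ref$orf_start +
          3L * (((ref$orf_end - ref$orf_start + 1L) %/% 6L))
        substr(s, mid_codon, mid_codon + 2L) <- "TAA"
      }
      s
    }
    # plain full-length copies
    for (k in seq_len(spec$n_full)) {
      disrupted <- k <= spec$n_orf_disrupted
      cs <- full_seq(spec$divergence, i * 100L + k, disrupted)
      cass <- kit$occupied_cassette(cs)
      add(ts, cass, new_copy_meta(
        spec$name, "full_length", spec$divergence, !disrupted,
        intron_off = kit$ins_at, intron_len = nchar(cs), kit = kit))
    }
    # fragments (internal ribozyme slice downstream of position 30)
    for (k in seq_len(spec$n_fragment)) {
      flen <- max(120L, round(spec$fragment_fraction * spec$length))
      fstart <- max(30L, round(0.3 * spec$length))
      frag <- substr(ref$seq, fstart, fstart + flen - 1L)
      if (spec$fragment_divergence > 0) {
        frag <- mutate_sequence(frag, spec$fragment_divergence,
                                config$seed * 20000L + i * 100L + k,
                                protect_ends = 20)
      }
      cass <- kit$occupied_cassette(frag)
      add(ts, cass, new_copy_meta(
        spec$name, "fragment", spec$fragment_divergence, NA,
        intron_off = kit$ins_at, intron_len = nchar(frag), kit = kit))
    }
    # threshold-boundary fragments from the non-ORF 5' region
    if (!is.null(spec$custom_fragments)) {
      for (k in seq_len(nrow(spec$custom_fragments))) {
        cf <- spec$custom_fragments[k, ]
        frag <- substr(ref$seq, 10L, 10L + cf$length - 1L)
        if (cf$divergence > 0) {
          frag <- mutate_sequence(frag, cf$divergence,
                                  config$seed * 30000L + i * 100L + k,
                                  protect_ends = 12)
        }
        add(ts, frag, list(kind = "boundary", intron = spec$name,
                           length = cf$length, divergence = cf$divergence))
      }
    }
    # free sites
    for (k in seq_len(spec$n_free)) {
      add(ts, kit_free_cassette(kit),
          list(kind = "free", intron = spec$name, kit = kit))
    }
    # orthologous groups: identical copy + shared 3 kb flanks in several
    # strains
    for (g in seq_len(spec$ortho_groups)) {
      members <- ((ts - 1L + seq_len(min(spec$ortho_group_size, ns)) - 1L)
                  %% ns) + 1L
      fu <- random_dna(3000, config$gc)
      fd <- random_dna(3000, config$gc)
      core <- kit$occupied_cassette(ref$seq)
      gid <- paste0(spec$name, ".og", g)
      for (m in members) {
        add(m, paste0(fu, core, fd), new_copy_meta(
          spec$name, "full_length", 0, TRUE,
          intron_off = 3000L + kit$ins_at, intron_len = nchar(ref$seq),
          kit = kit, ortho_group = gid))
      }
    }
    # retrohoming loci: copy in the target strain, intron-free flanked
    # locus in every other strain
    for (r in seq_len(spec$retro_loci)) {
      fu <- random_dna(3000, config$gc)
      fd <- random_dna(3000, config$gc)
      free_core <- kit_free_cassette(kit)
      occ_core <- kit$occupied_cassette(ref$seq)
      add(ts, paste0(fu, occ_core, fd), new_copy_meta(
        spec$name, "full_length", 0, TRUE,
        intron_off = 3000L + kit$ins_at, intron_len = nchar(ref$seq),
        kit = kit))
      for (m in setdiff(seq_len(ns), ts)) {
        add(m, paste0(fu, free_core, fd),
            list(kind = "retro_free", intron = spec$name, kit = kit,
                 source_strain = strains[ts]))
      }
    }
    # MGE transfer: same island, different chromosomal locus in strains 1/2
    if (isTRUE(spec$mge_transfer) && ns >= 2) {
      fu <- random_dna(3000, config$gc)
      fd <- random_dna(3000, config$gc)
      core <- kit$occupied_cassette(ref$seq)
      for (m in 1:2) {
        add(m, paste0(fu, core, fd), new_copy_meta(
          spec$name, "full_length", 0, TRUE,
          intron_off = 3000L + kit$ins_at, intron_len = nchar(ref$seq),
          kit = kit, mge = TRUE))
      }
    }
  }

  # assemble strains
  genomes <- list()
  man_copies <- list()
  man_free <- list()
  man_term <- list()
  man_retro <- list()
  mge_rows <- list()
  for (si in seq_len(ns)) {
    bg <- random_dna(config$chromosome_length, config$gc)
    for (kit in kits) bg <- scrub_pattern(bg, kit$scrub)
    plan <- plans[[si]]
    n_cass <- length(plan)
    rid <- paste0(strains[si], "_chr")
    if (n_cass > 0) {
      total_len <- sum(vapply(plan, function(p) nchar(p$cassette),
                              numeric(1)))
      usable <- config$chromosome_length - 12000L
      min_gap <- 600L
      if (n_cass * min_gap > usable) {
        stop("infeasible packing: too many cassettes for the chromosome")
      }
      if (total_len + config$chromosome_length > 60e6) {
        stop("infeasible packing: planted bases exceed practical bounds")
      }
      extra <- usable - n_cass * min_gap
      cuts <- sort(stats::runif(n_cass))
      anchors <- 6000L + round(cuts * extra) +
        min_gap * seq_len(n_cass) - min_gap %/% 2L
      anchors <- sort(anchors)
      ord <- sample(n_cass) # shuffle cassette order along the chromosome
      plan <- plan[ord]
      shift <- 0L
      pieces <- character(0)
      prev <- 0L
      for (ci in seq_len(n_cass)) {
        a <- anchors[ci]
        pieces <- c(pieces, substr(bg, prev + 1L, a))
        cstart <- a + shift + 1L # absolute start of the cassette
        p <- plan[[ci]]
        record_feature(p, cstart, strains[si], rid,
                       env = environment())
        pieces <- c(pieces, p$cassette)
        shift <- shift + nchar(p$cassette)
        prev <- a
      }
      pieces <- c(pieces, substr(bg, prev + 1L, nchar(bg)))
      chr_seq <- paste(pieces, collapse = "")
    } else {
      chr_seq <- bg
    }
    genomes[[length(genomes) + 1L]] <- tibble::tibble(
      genome = strains[si], genus_complex = config$genus_complex,
      replicon = rid, kind = "chromosome", topology = config$topology,
      length = nchar(chr_seq), seq = chr_seq)
    for (pl in seq_len(config$n_plasmids)) {
      pseq <- random_dna(config$plasmid_length, config$gc)
      for (kit in kits) pseq <- scrub_pattern(pseq, kit$scrub)
      genomes[[length(genomes) + 1L]] <- tibble::tibble(
        genome = strains[si], genus_complex = config$genus_complex,
        replicon = paste0(strains[si], "_p", pl), kind = "plasmid",
        topology = "circular", length = nchar(pseq), seq = pseq)
    }
  }
  genomes <- dplyr::bind_rows(genomes)

  manifest <- list(
    copies = dplyr::bind_rows(man_copies) %||% tibble::tibble(),
    free_sites = dplyr::bind_rows(man_free) %||% tibble::tibble(),
    terminators = dplyr::bind_rows(man_term) %||% tibble::tibble(),
    retro_loci = dplyr::bind_rows(man_retro) %||% tibble::tibble(),
    mge_pairs = mge_pairs_from(dplyr::bind_rows(man_copies)),
    schemes = setNames(vapply(config$intron_specs, function(s) s$scheme,
                              character(1)),
                       vapply(config$intron_specs, function(s) s$name,
                              character(1)))
  )
  list(genomes = genomes, library = library_tbl, manifest = manifest,
       config = config)
}

# Append manifest rows for one cassette placed at absolute position
# `cstart` (records into the caller's collector lists).
record_feature <- function(p, cstart, strain, rid, env) {
  if (p$kind == "copy") {
    istart <- cstart + p$intron_off
    iend <- istart + p$intron_len - 1L
    env$man_copies[[length(env$man_copies) + 1L]] <- tibble::tibble(
      strain = strain, replicon = rid, start = istart, end = iend,
      strand = "+", intron = p$intron, completeness = p$completeness,
      divergence = p$divergence, orf_intact = p$orf_intact,
      ortho_group = p$ortho_group %||% NA_character_, mge = p$mge,
      uid = p$uid)
    if (!is.na(p$kit$term_start)) {
      env$man_term[[length(env$man_term) + 1L]] <- tibble::tibble(
        strain = strain, replicon = rid,
        start = cstart + p$kit$term_start - 1L,
        end = cstart + p$kit$term_end - 1L, strand = "+")
    }
  } else if (p$kind == "free" || p$kind == "retro_free") {
    off <- if (p$kind == "retro_free") 3000L else 0L
    pos <- cstart + off + p$kit$ins_at - 1L
    env$man_free[[length(env$man_free) + 1L]] <- tibble::tibble(
      strain = strain, replicon = rid, pos = pos, strand = "+",
      intron = p$intron, scheme = p$kit$scheme)
    if (!is.na(p$kit$term_start)) {
      env$man_term[[length(env$man_term) + 1L]] <- tibble::tibble(
        strain = strain, replicon = rid,
        start = cstart + off + p$kit$term_start - 1L,
        end = cstart + off + p$kit$term_end - 1L, strand = "+")
    }
    if (p$kind == "retro_free") {
      env$man_retro[[length(env$man_retro) + 1L]] <- tibble::tibble(
        strain = strain, replicon = rid, pos = pos,
        source_strain = p$source_strain, intron = p$intron)
    }
  } else if (p$kind == "boundary") {
    env$man_copies[[length(env$man_copies) + 1L]] <- tibble::tibble(
      strain = strain, replicon = rid, start = cstart,
      end = cstart + nchar(p$cassette) - 1L, strand = "+",
      intron = p$intron, completeness = "boundary",
      divergence = p$divergence, orf_intact = NA, ortho_group = NA_character_,
      mge = FALSE, uid = NA_integer_)
  }
  invisible(NULL)
}

mge_pairs_from <- function(copies) {
  if (is.null(copies) || nrow(copies) == 0 || !any(copies$mge)) {
    return(tibble::tibble(intron = character(), strain_a = character(),
                          start_a = integer(), strain_b = character(),
                          start_b = integer()))
  }
  m <- copies[copies$mge, , drop = FALSE]
  out <- list()
  for (intr in unique(m$intron)) {
    mi <- m[m$intron == intr, , drop = FALSE]
    if (nrow(mi) >= 2) {
      out[[length(out) + 1L]] <- tibble::tibble(
        intron = intr, strain_a = mi$strain[1], start_a = mi$start[1],
        strain_b = mi$strain[2], start_b = mi$start[2])
    }
  }
  dplyr::bind_rows(out)
}

#' Build an MGE override table from a truth manifest and detected copies
#'
#' Matches the manifest's MGE-transfer pairs to detected copies by
#' coordinates and returns the (copy, subject genome) rows to feed
#' [apply_mge_overrides()], in both directions.
#'
#' @param manifest Truth manifest from [generate_population()].
#' @param copies Detected copy tibble.
#' @return Override tibble (`copy_id`, `subject_genome`).
#' @export
truth_overrides <- function(manifest, copies) {
  mp <- manifest$mge_pairs
  if (nrow(mp) == 0) {
    return(tibble::tibble(copy_id = character(),
                          subject_genome = character()))
  }
  find_copy <- function(strain, start) {
    hit <- copies[copies$genome == strain &
                    abs(copies$start - start) <= 25, , drop = FALSE]
    if (nrow(hit) == 0) NA_character_ else hit$copy_id[1]
  }
  out <- list()
  for (i in seq_len(nrow(mp))) {
    ca <- find_copy(mp$strain_a[i], mp$start_a[i])
    cb <- find_copy(mp$strain_b[i], mp$start_b[i])
    out[[length(out) + 1L]] <- tibble::tibble(
      copy_id = c(ca, cb),
      subject_genome = c(mp$strain_b[i], mp$strain_a[i]))
  }
  dplyr::bind_rows(out) |> dplyr::filter(!is.na(.data$copy_id))
}
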