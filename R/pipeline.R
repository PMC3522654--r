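# End-to-end survey: detection -> orthology -> homing-site models -> site
# scans -> occupancy tables, with report files mirroring the survey's
# standard layouts (per-genus abundance; full-length and fragment occupancy).

# -25..+10 windows around the insertion points of full-length copies,
# strand-corrected so the window reads 5'->3' in the intron's orientation.
copy_windows <- function(copies, genomes, window = c(-25L, 10L)) {
  seqs <- setNames(genomes$seq, genomes$replicon)
  lens <- setNames(genomes$length, genomes$replicon)
  up_w <- -window[1]
  dn_w <- window[2]
  out <- character(0)
  for (i in seq_len(nrow(copies))) {
    cp <- copies[i, ]
    L <- lens[cp$replicon]
    s <- seqs[cp$replicon]
    if (cp$strand == "+") {
      if (cp$start - up_w < 1 || cp$end + dn_w > L) next
      w <- paste0(substr(s, cp$start - up_w, cp$start - 1L),
                  substr(s, cp$end + 1L, cp$end + dn_w))
    } else {
      if (cp$end + up_w > L || cp$start - dn_w < 1) next
      w <- paste0(revcomp(substr(s, cp$end + 1L, cp$end + up_w)),
                  revcomp(substr(s, cp$start - dn_w, cp$start - 1L)))
    }
    out <- c(out, w)
  }
  out
}

# 90 bp flank-similarity context from one full-length copy (45 bp each side
# of the insertion point).
copy_context <- function(copy, genomes) {
  seqs <- setNames(genomes$seq, genomes$replicon)
  lens <- setNames(genomes$length, genomes$replicon)
  s <- seqs[copy$replicon]
  L <- lens[copy$replicon]
  if (copy$strand == "+") {
    if (copy$start - 45 < 1 || copy$end + 45 > L) return(NULL)
    paste0(substr(s, copy$start - 45L, copy$start - 1L),
           substr(s, copy$end + 1L, copy$end + 45L))
  } else {
    if (copy$end + 45 > L || copy$start - 45 < 1) return(NULL)
    paste0(revcomp(substr(s, copy$end + 1L, copy$end + 45L)),
           revcomp(substr(s, copy$start - 45L, copy$start - 1L)))
  }
}

default_scheme <- function(lib_row) {
  if (!is.null(lib_row$scheme) && !is.na(lib_row$scheme)) {
    return(lib_row$scheme)
  }
  if (lib_row$orf_class == "C") return("classc_terminator")
  if (!is.na(lib_row$ebs1) && nzchar(lib_row$ebs1)) return("ebs_consensus")
  "conservation_consensus"
}

#' Build homing-site models for every intron with full-length copies
#'
#' Chooses the scheme per intron (a `scheme` column in the library, else
#' class C introns get the terminator scheme, introns with EBS motifs the
#' EBS consensus, and the rest the conservation consensus), collects the
#' -25..+10 windows around the detected full-length copies and builds the
#' corresponding [homing_site_model()].
#'
#' @param copies Detected copy tibble.
#' @param genomes Replicon tibble.
#' @param library Reference library tibble.
#' @param window Window relative to the insertion site.
#' @param conservation_threshold Column conservation needed to fix a base.
#' @param min_conservation_windows Minimal windows for the conservation
#'   scheme (5).
#' @return Named list of models (introns without a buildable model are
#'   omitted).
#' @export
build_site_models <- function(copies, genomes, library,
                              window = c(-25L, 10L),
                              conservation_threshold = 0.8,
                              min_conservation_windows = 5) {
  models <- list()
  for (i in seq_len(nrow(library))) {
    lr <- library[i, ]
    scheme <- default_scheme(lr)
    full <- copies[copies$ref_name == lr$name &
                     copies$completeness == "full_length", , drop = FALSE]
    if (nrow(full) == 0) next
    if (scheme == "flank_similarity") {
      ctx <- NULL
      for (k in seq_len(nrow(full))) {
        ctx <- copy_context(full[k, ], genomes)
        if (!is.null(ctx)) break
      }
      if (is.null(ctx)) next
      ibs1_len <- if (is.na(lr$ebs1) || !nzchar(lr$ebs1)) 6L
                  else nchar(lr$ebs1)
      models[[lr$name]] <- homing_site_model(
        lr$name, "flank_similarity", consensus = ctx, offset = 45L,
        window = c(-45L, 45L), context = ctx, ibs1_len = ibs1_len)
      next
    }
    wins <- copy_windows(full, genomes, window)
    if (length(wins) == 0) next
    if (scheme == "conservation_consensus") {
      if (length(wins) < min_conservation_windows) next
      models[[lr$name]] <- build_consensus_from_conservation(
        wins, window, conservation_threshold, intron = lr$name)
    } else {
      ebs <- list(EBS1 = lr$ebs1, EBS2 = lr$ebs2, EBS3 = lr$ebs3)
      models[[lr$name]] <- build_consensus_from_ebs(
        ebs, wins, reference_flank = NULL, window = window,
        intron = lr$name, classc = scheme == "classc_terminator")
    }
  }
  models
}

#' Run the full survey on a set of genomes
#'
#' Chains detection, orthology classification (with optional MGE
#' overrides), distinct-element collapsing, homing-site model building,
#' site scanning (terminator-gated for class C models) and occupancy
#' accounting.
#'
#' @param genomes Replicon tibble from [read_genomes()] or
#'   [generate_population()].
#' @param library Reference library tibble.
#' @param overrides Optional MGE override table (`copy_id`,
#'   `subject_genome`).
#' @param det_params,orth_params,term_params Stage parameter lists.
#' @param window Consensus window relative to the insertion site.
#' @return An object of class `intron_survey`: a list with `copies`,
#'   `calls`, `distinct_sets`, `abundance`, `models`, `terminators`,
#'   `sites`, `occupancy_full_length`, `occupancy_fragments` and
#'   `genome_info`.
#' @export
survey_population <- function(genomes, library, overrides = NULL,
                              det_params = detection_params(),
                              orth_params = orthology_params(),
                              term_params = terminator_params(),
                              window = c(-25L, 10L)) {
  copies <- detect_introns(genomes, library, det_params)
  calls <- classify_insertions(copies, genomes, orth_params)
  calls <- apply_mge_overrides(calls, overrides)
  dsets <- collapse_distinct(copies, calls)
  abundance <- genus_abundance_table(copies, dsets, genomes)
  models <- build_site_models(copies, genomes, library, window)
  needs_term <- any(vapply(models, function(m) m$requires_terminator,
                           logical(1)))
  terms <- if (needs_term) {
    find_rho_independent_terminators(genomes, term_params)
  } else {
    empty_term_tbl()
  }
  sites <- list()
  for (m in models) {
    raw <- if (m$scheme == "flank_similarity") {
      scan_flank_similarity(genomes, m)
    } else {
      scan_perfect_match(genomes, m)
    }
    if (m$requires_terminator) {
      raw <- restrict_to_terminator_downstream(raw, terms, max_gap = 20,
                                               ibs1_len = m$ibs1_len)
    }
    for (g in unique(genomes$genome)) {
      sites[[length(sites) + 1L]] <- mark_occupancy(
        raw[raw$genome == g, , drop = FALSE],
        copies[copies$genome == g, , drop = FALSE],
        intron = m$intron, completeness = "full_length")
    }
  }
  sites <- dplyr::bind_rows(sites) %||% empty_sites()
  if (nrow(sites) == 0) sites <- empty_sites()
  occ_full <- occupancy_table(sites)
  occ_frag <- fragment_occupancy_table(sites, copies, names(models))
  structure(list(
    genome_info = dplyr::select(genomes, -"seq"),
    copies = copies, calls = calls, distinct_sets = dsets,
    abundance = abundance, models = models, terminators = terms,
    sites = sites, occupancy_full_length = occ_full,
    occupancy_fragments = occ_frag,
    params = list(detection = det_params, orthology = orth_params,
                  terminator = term_params, window = window)
  ), class = "intron_survey")
}

empty_term_tbl <- function() {
  tibble::tibble(replicon = character(), start = integer(),
                 end = integer(), strand = character(),
                 stem_len = integer(), loop_len = integer(),
                 mismatches = integer(), u_tail_score = double())
}

# Fragment occupancy (the "expected time of fragment acquisition" view):
# occupied = fragment copies of the intron; available = currently free
# sites plus the sites now occupied by full-length copies.
fragment_occupancy_table <- function(sites, copies, modeled_introns) {
  if (length(modeled_introns) == 0) {
    return(tibble::tibble(intron = character(), genome = character(),
                          occupied = integer(), available = integer(),
                          proportion_pct = integer()))
  }
  counts <- sites |>
    dplyr::group_by(.data$intron, .data$genome) |>
    dplyr::summarise(
      n_avail_now = sum(.data$state == "AVAILABLE"),
      .groups = "drop")
  per_copy <- copies |>
    dplyr::filter(.data$ref_name %in% modeled_introns) |>
    dplyr::group_by(intron = .data$ref_name, .data$genome) |>
    dplyr::summarise(
      n_frag = sum(.data$completeness == "fragment"),
      n_full = sum(.data$completeness == "full_length"),
      .groups = "drop")
  dplyr::full_join(counts, per_copy, by = c("intron", "genome")) |>
    dplyr::mutate(dplyr::across(dplyr::where(is.numeric),
                                \(x) tidyr::replace_na(x, 0L))) |>
    dplyr::transmute(
      .data$intron, .data$genome,
      occupied = .data$n_frag,
      available = .data$n_avail_now + .data$n_full,
      proportion_pct = occupancy_proportion(.data$occupied,
                                            .data$available))
}

#' @export
print.intron_survey <- function(x, ...) {
  g <- glance(x)
  cat("<intron_survey>", g$n_genomes, "genome(s),", g$n_copies,
      "intron copies (", g$n_full_length, "full-length ),",
      g$n_distinct, "distinct elements\n")
  invisible(x)
}

#' @rdname survey_population
#' @param x An `intron_survey` object.
#' @param ... Unused.
#' @export
tidy.intron_survey <- function(x, ...) {
  x$copies
}

#' @rdname survey_population
#' @export
glance.intron_survey <- function(x, ...) {
  n_gen <- length(unique(x$genome_info$genome))
  colonized <- length(unique(x$copies$genome))
  tibble::tibble(
    n_genomes = n_gen,
    n_copies = nrow(x$copies),
    n_full_length = sum(x$copies$completeness == "full_length"),
    n_fragments = sum(x$copies$completeness == "fragment"),
    n_distinct = length(unique(x$distinct_sets$set_id)),
    copies_per_genome = round(nrow(x$copies) / n_gen, 1),
    pct_genomes_colonized = occupancy_proportion(colonized,
                                                 n_gen - colonized)
  )
}

#' Run the survey from files and write the report bundle
#'
#' Thin orchestration over [read_genomes()], [read_intron_library()] and
#' [survey_population()], writing `copies.tsv`, `insertion_calls.tsv`,
#' `distinct_report.tsv`, `occupancy_full_length.tsv`,
#' `occupancy_fragments.tsv`, `sites.gff3` and `run.log` to `out_dir`.
#'
#' @param genomes Replicon tibble, or FASTA path(s) (then `manifest` is
#'   required).
#' @param library Library tibble, or a list with `nt`, `aa`, `meta` paths.
#' @param out_dir Output directory (created if absent).
#' @param manifest Manifest path when `genomes` is a FASTA path.
#' @param overrides Optional override table or TSV path.
#' @param ... Passed to [survey_population()].
#' @return The `intron_survey` object, invisibly.
#' @export
run_survey <- function(genomes, library, out_dir, manifest = NULL,
                       overrides = NULL, ...) {
  t0 <- Sys.time()
  if (is.character(genomes)) {
    genomes <- read_genomes(genomes, manifest)
  }
  if (!is.data.frame(library)) {
    library <- read_intron_library(library$nt, library$aa, library$meta)
  }
  if (is.character(overrides)) {
    overrides <- readr::read_tsv(overrides, show_col_types = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sv <- survey_population(genomes, library, overrides = overrides, ...)
  wr <- function(df, name) {
    readr::write_tsv(df, file.path(out_dir, name))
  }
  wr(sv$copies, "copies.tsv")
  wr(sv$calls, "insertion_calls.tsv")
  distinct_report <- sv$abundance
  wr(distinct_report, "distinct_report.tsv")
  wr(sv$occupancy_full_length, "occupancy_full_length.tsv")
  wr(sv$occupancy_fragments, "occupancy_fragments.tsv")
  write_features(sv$copies, sv$sites, genomes,
                 file.path(out_dir, "sites.gff3"))
  elapsed <- round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 2)
  log_lines <- c(
    paste0("intronscout survey @ ", format(t0)),
    paste0("genomes: ", length(unique(genomes$genome)),
           " replicons: ", nrow(genomes)),
    paste0("library entries: ", nrow(library)),
    paste0("copies detected: ", nrow(sv$copies)),
    paste0("distinct elements: ", length(unique(sv$distinct_sets$set_id))),
    paste0("parameters: ", paste(names(sv$params$detection),
                                 unlist(sv$params$detection),
                                 sep = "=", collapse = " ")),
    paste0("elapsed_sec: ", elapsed)
  )
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(sv)
}
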