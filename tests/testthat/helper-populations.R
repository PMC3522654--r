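# Shared synthetic populations, built once per test run.

.pop_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.pop_cache[[key]])) .pop_cache[[key]] <- force(expr)
  .pop_cache[[key]]
}

# Small mixed population: full-length, fragments, a disrupted ORF and free
# sites for one EBS-modelled intron.
pop_small <- function() {
  cached("small", {
    cfg <- sim_config(
      n_strains = 1, chromosome_length = 60000,
      intron_specs = list(
        intron_spec("Sm.I1", length = 900, scheme = "ebs_consensus",
                    n_full = 4, n_fragment = 2, n_free = 3,
                    n_orf_disrupted = 1)),
      seed = 101)
    pop <- generate_population(cfg)
    pop$survey <- survey_population(pop$genomes, pop$library)
    pop
  })
}

# The occupancy-structure population: one intron with 26 full-length copies
# and 17 free EBS-consensus sites, plus a class C intron with 2 copies and
# 17 terminator-gated free sites, in a single strain.
pop_occupancy <- function(seed = 11) {
  cached(paste0("occupancy", seed), {
    cfg <- sim_config(
      n_strains = 1, chromosome_length = 120000,
      intron_specs = list(
        intron_spec("cHa.I1", length = 1200, scheme = "ebs_consensus",
                    n_full = 26, n_free = 17),
        intron_spec("Cc.I1", length = 1000, orf_class = "C",
                    scheme = "classc_terminator", n_full = 2, n_free = 17)),
      seed = seed)
    pop <- generate_population(cfg)
    pop$survey <- survey_population(pop$genomes, pop$library)
    pop
  })
}

# Six-strain population with orthologous groups, retrohoming loci and one
# MGE transfer.
pop_orthology <- function(seed = 3) {
  cached(paste0("orthology", seed), {
    cfg <- sim_config(
      n_strains = 6, chromosome_length = 60000,
      intron_specs = list(
        intron_spec("Og.I1", length = 1000, scheme = "ebs_consensus",
                    ortho_groups = 4, ortho_group_size = 3, retro_loci = 3,
                    mge_transfer = TRUE)),
      seed = seed)
    pop <- generate_population(cfg)
    pop$survey <- survey_population(pop$genomes, pop$library)
    pop
  })
}
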