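# Shared small simulation configs used across test files.

tiny_family_config <- function(seed = 1L, ...) {
  sim_config(seed = seed, n_species = 3L, n_families = 2L,
             genes_per_family = 4L, codons_per_gene = 100L,
             target_ks = c(0.15, 0.7),
             event_types = c("species_specific", "lineage_specific"), ...)
}

# Checks one simulated dataset against its planted events: exactly one
# species-specific and one lineage-specific call, each covering precisely
# the planted family's genes.
clade_calls_match_truth <- function(sim, calls) {
  tg <- sim$truth$genes
  ss <- paste(sort(tg$gene_id[tg$event == "species_specific"]), collapse = ";")
  ls <- paste(sort(tg$gene_id[tg$event == "lineage_specific"]), collapse = ";")
  nrow(calls) == 2 &&
    any(calls$call == "species_specific" & calls$genes == ss) &&
    any(calls$call == "lineage_specific" & calls$genes == ls)
}

resistant_split_recovered <- function(groups,
                                      early = c("R_0h", "R_3h", "R_6h", "R_9h", "R_12h"),
                                      late = c("R_24h", "R_48h", "R_72h")) {
  length(unique(groups[early])) == 1 &&
    length(unique(groups[late])) == 1 &&
    groups[early][1] != groups[late][1]
}
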