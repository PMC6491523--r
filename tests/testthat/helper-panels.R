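# shared fixture builders

# tiny deterministic panel from explicit dosages
toy_panel <- function(dosage, groups = NULL, colour = NULL) {
  gm <- genotype_matrix(dosage)
  if (!is.null(groups)) gm$passport$subspecies <- groups
  if (!is.null(colour)) gm$passport$colour_class <- colour
  gm
}

# two-group Balding-Nichols panel under study-like conditions
two_group_panel <- function(n_per_group = 60, n_markers = 500, F = 0.5,
                            selfing = 4, n_dup = 0, missing = 0.05,
                            seed = 1) {
  cfg <- panel_config(
    n_markers = n_markers, n_chromosomes = 12,
    groups = data.frame(group = c("A", "B"),
                        n = c(n_per_group, n_per_group), F = c(F, F)),
    selfing_generations = selfing, n_duplicates = n_dup,
    missing_rate = missing, rng_seed = seed)
  simulate_panel(cfg)
}

# canonical string form of a cluster partition, for exact comparison
canonical_clusters <- function(cl) {
  sort(vapply(cl, function(s) paste(sort(s), collapse = "|"), character(1)))
}
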