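# Small configurations reused across tests.

# Two-condition, two-group design for differential testing: `frac_diff` of
# elements are open in group B only; effect = 0 gives a null dataset.
two_group_config <- function(seed, n_elements = 1000, effect = 3,
                             dispersion = 0.2, frac_diff = 0,
                             n_replicates = 3, baseline = 50) {
  prof <- rbind(flat = c(0, 0), open_in_B = c(0, 1))
  w <- if (frac_diff > 0) c(1 - frac_diff, frac_diff) else c(1, 0)
  sim_config(
    seed = seed, n_elements = n_elements, n_planted_patterns = 2,
    cell_types = data.frame(name = c("A", "B"),
                            regime = c("shared", "shared")),
    conditions = data.frame(cell_type = c("A", "B"), day = c(5, 5),
                            sag_nM = c(0, 0)),
    n_replicates = n_replicates, baseline_mean = baseline,
    effect_log2fc = effect, nb_dispersion = dispersion,
    pattern_profile = prof, pattern_weights = w,
    frac_low_quality = 0)
}

# Differential-test sensitivity/FDR under the standard selection rule for a
# two-group planted simulation.
da_recovery <- function(seed, n_elements = 2000, effect = 3,
                        frac_diff = 0.1) {
  cfg <- two_group_config(seed, n_elements, effect, frac_diff = frac_diff)
  sim <- simulate_accessibility(cfg)
  sf <- size_factors(sim$counts)
  grp <- split(sim$samples$sample_id, sim$samples$cell_type)
  disp <- estimate_dispersion(sim$counts, sf, grp)
  res <- wald_test(sim$counts, sf, grp$A, grp$B, disp)
  sel <- select_differential(res)
  truth_diff <- names(sim$truth$element_pattern)[sim$truth$element_pattern == 2]
  list(sensitivity = length(intersect(sel, truth_diff)) /
         max(1, length(truth_diff)),
       fdr = if (length(sel)) length(setdiff(sel, truth_diff)) / length(sel)
             else 0,
       n_selected = length(sel))
}

# Full accessibility pipeline through clustering on the default design.
clustered_simulation <- function(seed, n_elements = 900, k1 = 30,
                                 k_final = 9, cluster_seed = seed + 100) {
  cfg <- sim_config(seed = seed, n_elements = n_elements)
  sim <- simulate_accessibility(cfg)
  sf <- size_factors(sim$counts)
  nm <- vst(sim$counts, sf)
  plan <- build_plan(sim$samples)
  res <- run_plan(sim$counts, sf, plan)
  sel <- sort(unique(unlist(lapply(res, select_differential))))
  prof <- build_profiles(nm, sim$samples, sel)
  model <- label_clusters(two_stage_cluster(prof, k1, k_final,
                                            seed = cluster_seed),
                          sim$samples)
  list(cfg = cfg, sim = sim, sf = sf, norm = nm, profiles = prof,
       model = model,
       truth_pattern = sim$truth$element_pattern[rownames(prof)])
}

# Brute-force O(n*m) interval overlap oracle (half-open coordinates).
overlap_oracle <- function(query, reference, min_bp = 1) {
  out <- logical(nrow(query))
  for (i in seq_len(nrow(query))) {
    for (j in seq_len(nrow(reference))) {
      if (query$chrom[i] != reference$chrom[j]) next
      ov <- min(query$end[i], reference$end[j]) -
        max(query$start[i], reference$start[j])
      if (ov >= min_bp) { out[i] <- TRUE; break }
    }
  }
  setNames(out, query$id)
}

random_peaks <- function(n, chroms = c("chr1", "chr2"), span = 10000,
                         max_width = 300) {
  start <- sample.int(span, n, replace = TRUE)
  peak_set(chrom = sample(chroms, n, replace = TRUE), start = start,
           end = start + sample.int(max_width, n, replace = TRUE),
           id = sprintf("iv%04d", seq_len(n)))
}
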