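#' Simulation configuration
#'
#' Bundles every parameter of the synthetic-data generator. Defaults
#' emulate the study design the package targets: a day-3 neuromesodermal
#' progenitor (NMP) condition followed by four neural progenitor types
#' (p0-1, p2, pMN, p3) sampled at days 4-6, three replicates each, with
#' negative-binomial fragment counts over nine planted accessibility
#' patterns. The p3 type is planted with a private ("unique-regime")
#' accessibility program; p0-1, p2 and pMN share their open chromatin and
#' differ only in planted footprint scores ("shared regime").
#'
#' @param seed integer RNG seed; all generator functions are deterministic
#'   given the config.
#' @param n_elements number of consensus elements.
#' @param n_planted_patterns number of accessibility patterns (>= 2); the
#'   first `n_planted_patterns` rows of `pattern_profile` are used.
#' @param cell_types data frame with columns `name` and
#'   `regime` (`"shared"` or `"unique"`).
#' @param conditions data frame with columns `cell_type`, `day`, `sag_nM`.
#' @param n_replicates replicates per condition (>= 2).
#' @param baseline_mean expected fragment count of a closed element at unit
#'   library factor.
#' @param effect_log2fc accessibility difference (log2) between open and
#'   closed states; default 3.
#' @param nb_dispersion negative-binomial dispersion `alpha` with
#'   `variance = mu + alpha * mu^2`; must be positive.
#' @param pattern_profile optional 0/1 matrix, patterns x conditions; the
#'   default nine patterns are built by [default_patterns()].
#' @param pattern_weights optional per-pattern assignment proportions
#'   (default equal).
#' @param frac_low_quality fraction of elements planted to fail the
#'   consensus q-value filter.
#' @param n_motifs,n_archetypes motif/archetype counts for the footprint
#'   generator.
#' @param n_decoys decoy TFs per archetype.
#' @param driver_correlation planted Pearson correlation between each
#'   archetype score and its driver TF's expression, in `[-1, 1]`.
#' @param motif_noise_sd sd of motif-level noise around archetype scores.
#' @param image list of section-image parameters: `n_sections`, `n_nuclei`,
#'   `size` (square image side, px), `radius_px`, `noise_sd`,
#'   `n_background` (far NKX2.2+ background-binding nuclei per section),
#'   `sep_margin` (extra center separation beyond twice the radius, px),
#'   `class_probs` (named p3/V3/other), `tdtom_prob`, `channel_high`,
#'   `channel_low` (mean intensities of on/off markers), `dapi_mean`,
#'   `domain_frac` (radius of the central domain as a fraction of `size`).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       n_elements = 1800,
                       n_planted_patterns = 9,
                       cell_types = default_cell_types(),
                       conditions = default_conditions(),
                       n_replicates = 3,
                       baseline_mean = 50,
                       effect_log2fc = 3,
                       nb_dispersion = 0.2,
                       pattern_profile = NULL,
                       pattern_weights = NULL,
                       frac_low_quality = 0.05,
                       n_motifs = 40,
                       n_archetypes = 4,
                       n_decoys = 5,
                       driver_correlation = 0.9,
                       motif_noise_sd = 0.1,
                       image = list()) {
  img <- utils::modifyList(list(
    n_sections = 6, n_nuclei = 20, size = 192, radius_px = 6,
    sep_margin = 7, noise_sd = 0, n_background = 0,
    class_probs = c(p3 = 0.4, V3 = 0.3, other = 0.3),
    tdtom_prob = 0.5, channel_high = 180, channel_low = 20,
    dapi_mean = 200, domain_frac = 0.3), image)
  cfg <- list(seed = as.integer(seed), n_elements = n_elements,
              n_planted_patterns = n_planted_patterns,
              cell_types = as.data.frame(cell_types),
              conditions = as.data.frame(conditions),
              n_replicates = n_replicates, baseline_mean = baseline_mean,
              effect_log2fc = effect_log2fc, nb_dispersion = nb_dispersion,
              pattern_profile = pattern_profile,
              pattern_weights = pattern_weights,
              frac_low_quality = frac_low_quality,
              n_motifs = n_motifs, n_archetypes = n_archetypes,
              n_decoys = n_decoys, driver_correlation = driver_correlation,
              motif_noise_sd = motif_noise_sd, image = img)
  class(cfg) <- "sim_config"
  validate_config(cfg)
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config: ", x$n_elements, " elements, ",
      nrow(x$conditions), " conditions x ", x$n_replicates,
      " replicates, ", x$n_planted_patterns, " patterns, seed ",
      x$seed, "\n", sep = "")
  invisible(x)
}

validate_config <- function(cfg) {
  chk <- function(ok, field, why)
    if (!ok) stop("invalid sim_config field '", field, "': ", why)
  chk(cfg$n_planted_patterns >= 2, "n_planted_patterns", "must be >= 2")
  chk(cfg$n_replicates >= 2, "n_replicates", "must be >= 2")
  chk(cfg$nb_dispersion > 0, "nb_dispersion", "must be > 0")
  chk(cfg$baseline_mean > 0, "baseline_mean", "must be > 0")
  chk(cfg$n_elements >= cfg$n_planted_patterns, "n_elements",
      "need at least one element per pattern")
  chk(abs(cfg$driver_correlation) <= 1, "driver_correlation",
      "must lie in [-1, 1]")
  chk(all(c("cell_type", "day", "sag_nM") %in% names(cfg$conditions)),
      "conditions", "needs columns cell_type, day, sag_nM")
  chk(all(c("name", "regime") %in% names(cfg$cell_types)),
      "cell_types", "needs columns name, regime")
  chk(all(cfg$cell_types$regime %in% c("shared", "unique")),
      "cell_types", "regime must be 'shared' or 'unique'")
  chk(cfg$image$channel_high >= 0 && cfg$image$channel_low >= 0 &&
        cfg$image$dapi_mean >= 0, "image", "channel means must be >= 0")
  if (!is.null(cfg$pattern_profile))
    chk(nrow(cfg$pattern_profile) >= cfg$n_planted_patterns &&
          ncol(cfg$pattern_profile) == nrow(cfg$conditions),
        "pattern_profile", "must be patterns x conditions")
  invisible(cfg)
}

#' Default cell types of the simulated design
#' @return Data frame with columns `name` and `regime`.
#' @export
default_cell_types <- function() {
  data.frame(name = c("NMP", "p0-1", "p2", "pMN", "p3"),
             regime = c("unique", "shared", "shared", "shared", "unique"),
             stringsAsFactors = FALSE)
}

#' Default condition table of the simulated design
#'
#' One NMP condition at day 3 and the four neural progenitor types at days
#' 4-6, each at the SAG dose that generates it.
#' @return Data frame with columns `cell_type`, `day`, `sag_nM`.
#' @export
default_conditions <- function() {
  neural <- expand.grid(cell_type = c("p0-1", "p2", "pMN", "p3"),
                        day = 4:6, stringsAsFactors = FALSE)
  neural$sag_nM <- c(`p0-1` = 10, p2 = 100, pMN = 100, p3 = 500)[neural$cell_type]
  rbind(data.frame(cell_type = "NMP", day = 3, sag_nM = 0),
        neural[order(neural$day, neural$cell_type), ])
}

#' Default planted accessibility patterns
#'
#' Nine 0/1 open/closed profiles over the conditions, emulating the cluster
#' dynamics the pipeline is designed to recover: an NMP-only program that is
#' decommissioned, a pan-neural program, p3-private programs (the
#' unique-regime landscape), stage-dependent programs shared across cell
#' types, and a program shared by the shared-regime types only.
#'
#' @param conditions a condition data frame (see [default_conditions()]).
#' @return 0/1 matrix, 9 x `nrow(conditions)`.
#' @export
default_patterns <- function(conditions) {
  ct <- conditions$cell_type; day <- conditions$day
  shared <- c("p0-1", "p2", "pMN")
  p <- rbind(
    nmp_only      = as.integer(ct == "NMP"),
    pan_neural    = as.integer(ct != "NMP"),
    p3_all        = as.integer(ct == "p3"),
    p3_late       = as.integer(ct == "p3" & day >= 5),
    neural_late   = as.integer(ct != "NMP" & day >= 5),
    early         = as.integer(day <= 4),
    day4_only     = as.integer(day == 4),
    shared_open   = as.integer(ct %in% shared),
    nmp_and_p3    = as.integer(ct == "NMP" | ct == "p3"))
  colnames(p) <- paste(ct, paste0("d", day), paste0("sag", conditions$sag_nM),
                       sep = "_")
  p
}

element_intervals <- function(n_elements) {
  start <- (seq_len(n_elements) - 1L) * 2000L
  peak_set(chrom = rep("chrS", n_elements), start = start,
           end = start + 500L,
           id = sprintf("elem_%05d", seq_len(n_elements)))
}

#' Simulate a cell-type-resolved accessibility experiment
#'
#' Draws a fragment-count matrix with planted pattern structure. Element
#' `i` carries pattern `g(i)`; its expected count in sample `j` is
#' `baseline_mean * 2^(effect_log2fc * open[g(i), cond(j)]) * lib[j]`
#' with library factors `lib` drawn log-uniform in `[0.5, 2]`, and counts
#' are negative binomial with `variance = mu + alpha * mu^2`. Per-sample
#' MACS-style q-values are attached to the peaks so the consensus filter
#' can be exercised: a planted fraction of elements fails it.
#'
#' @param config a [sim_config()].
#' @return List with components `peaks` ([peak_set()] with q-values),
#'   `counts` ([count_matrix()] with `library_total` implying a planted
#'   FRiP), `samples` ([sample_table()]) and `truth` (list with
#'   `element_pattern`, `pattern_profile`, `lib_factors`, `frip`,
#'   `open_matrix`).
#' @export
simulate_accessibility <- function(config) {
  validate_config(config)
  set.seed(config$seed)
  cond <- config$conditions
  n_cond <- nrow(cond)
  k <- config$n_planted_patterns
  prof <- config$pattern_profile
  if (is.null(prof)) prof <- default_patterns(cond)
  if (nrow(prof) < k)
    stop("pattern_profile has fewer rows than n_planted_patterns")
  prof <- prof[seq_len(k), , drop = FALSE]
  if (is.null(rownames(prof))) rownames(prof) <- paste0("pattern", seq_len(k))
  if (is.null(colnames(prof)))     # columns follow the condition table order
    colnames(prof) <- paste(cond$cell_type, paste0("d", cond$day),
                            paste0("sag", cond$sag_nM), sep = "_")

  samples <- do.call(rbind, lapply(seq_len(n_cond), function(ci) {
    data.frame(sample_id = paste0(cond$cell_type[ci], "_d", cond$day[ci],
                                  "_sag", cond$sag_nM[ci], "_r",
                                  seq_len(config$n_replicates)),
               cell_type = cond$cell_type[ci], sag_nM = cond$sag_nM[ci],
               day = cond$day[ci], replicate = seq_len(config$n_replicates),
               stringsAsFactors = FALSE)
  }))
  samples <- sample_table(samples)
  n_samp <- nrow(samples)
  cond_of_sample <- condition_id(samples)

  w <- config$pattern_weights
  if (is.null(w)) w <- rep(1 / k, k)
  if (length(w) != k) stop("pattern_weights must have one entry per pattern")
  n_per <- diff(round(cumsum(c(0, w / sum(w))) * config$n_elements))
  pattern <- rep(seq_len(k), n_per)
  pattern <- rep_len(pattern, config$n_elements)
  pattern <- sample(pattern)                      # decouple pattern from position

  peaks <- element_intervals(config$n_elements)
  ids <- sprintf("elem_%05d", seq_len(config$n_elements))
  names(pattern) <- ids

  lib <- exp(runif(n_samp, log(0.5), log(2)))
  names(lib) <- samples$sample_id
  open <- prof[pattern, match(cond_of_sample, colnames(prof)), drop = FALSE]
  dimnames(open) <- list(ids, samples$sample_id)
  mu <- config$baseline_mean * 2^(config$effect_log2fc * open)
  mu <- sweep(mu, 2L, lib, "*")
  counts <- if (config$nb_dispersion < 1e-10) {
    matrix(rpois(length(mu), mu), nrow = nrow(mu))
  } else {
    matrix(rnbinom(length(mu), mu = mu, size = 1 / config$nb_dispersion),
           nrow = nrow(mu))
  }
  dimnames(counts) <- dimnames(mu)

  # q-values: open samples (or one random sample for flat elements) pass the
  # consensus cutoff; a planted fraction of elements never passes.
  qv <- matrix(10^-runif(length(mu), 0, 3), nrow = nrow(mu),
               dimnames = dimnames(mu))
  low_q <- seq_len(config$n_elements) %in%
    sample.int(config$n_elements, round(config$frac_low_quality *
                                          config$n_elements))
  for (i in which(!low_q)) {
    js <- which(open[i, ] == 1)
    if (!length(js)) js <- sample.int(n_samp, 1L)
    qv[i, js] <- 10^-runif(length(js), 6, 12)
  }

  frip_planted <- runif(n_samp, 0.5, 0.9)
  names(frip_planted) <- samples$sample_id
  lib_total <- ceiling(colSums(counts) / frip_planted)
  lib_total[lib_total == 0] <- 1L

  attr(peaks, "qval") <- qv[peaks$id, , drop = FALSE]
  truth <- list(element_pattern = pattern, pattern_profile = prof,
                lib_factors = lib, frip = frip_planted,
                low_quality = setNames(low_q, ids), open_matrix = open)
  list(peaks = peaks,
       counts = count_matrix(counts, lib_total),
       samples = samples, truth = truth)
}

#' Simulate a ChIP peak set enriched in one planted pattern
#'
#' Emits peaks overlapping approximately a fraction `enrichment` of the
#' elements carrying `target_pattern` and a fraction `background` of all
#' other elements.
#'
#' @param config a [sim_config()].
#' @param truth ground truth from [simulate_accessibility()].
#' @param target_pattern row name (or index) of the planted pattern.
#' @param enrichment fraction of target elements overlapped, in `[0, 1]`.
#' @param background fraction of non-target elements overlapped.
#' @return A [peak_set()] of ChIP peaks.
#' @export
simulate_chip <- function(config, truth, target_pattern, enrichment,
                          background = 0.05) {
  stopifnot(enrichment >= 0, enrichment <= 1,
            background >= 0, background <= 1)
  pat_names <- rownames(truth$pattern_profile)
  if (is.numeric(target_pattern)) target_pattern <- pat_names[target_pattern]
  if (is.na(target_pattern) || !target_pattern %in% pat_names)
    stop("unknown pattern_id: ", target_pattern)
  set.seed(config$seed + 7717L + match(target_pattern, pat_names))
  is_target <- pat_names[truth$element_pattern] == target_pattern
  hit <- ifelse(is_target, rbinom(length(is_target), 1L, enrichment),
                rbinom(length(is_target), 1L, background)) == 1L
  idx <- which(hit)
  if (!length(idx))
    return(peak_set(character(), integer(), integer()))
  start <- (idx - 1L) * 2000L + 100L
  peak_set(chrom = rep("chrS", length(idx)), start = start, end = start + 300L,
           id = paste0("chip_", sprintf("%05d", idx)))
}

#' Write a simulated accessibility experiment to disk
#'
#' Writes the peaks (BED), counts and sample table (TSV) and the ground
#' truth plus a config echo (JSON) into a directory.
#'
#' @param sim result of [simulate_accessibility()].
#' @param dir output directory (created if needed).
#' @param config the generating [sim_config()], echoed into the JSON.
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir, config = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_peaks(sim$peaks, file.path(dir, "peaks.bed"))
  write_counts(sim$counts, file.path(dir, "counts.tsv"), peaks = sim$peaks)
  write_samples(sim$samples, file.path(dir, "samples.tsv"))
  truth <- sim$truth
  truth$open_matrix <- NULL                     # large and reconstructible
  payload <- list(truth = truth)
  if (!is.null(config))
    payload$config <- config[setdiff(names(config),
                                     c("pattern_profile", "conditions",
                                       "cell_types"))]
  jsonlite::write_json(payload, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
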