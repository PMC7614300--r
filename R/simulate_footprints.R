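#' Simulate footprint scores, motifs, archetypes and RNA expression
#'
#' Generates the inputs of the footprint/driver-TF stage with planted
#' ground truth. Each archetype gets a per-condition score vector; member
#' motifs are the archetype score plus small independent noise, and their
#' PWMs are offset or reverse-complement variants of one seed PWM. One
#' planted driver gene per archetype has RNA expression correlated with the
#' archetype score at expectation `driver_correlation`; decoy genes are
#' independent. The first archetype is planted as the "pioneer" archetype:
#' its score is elevated exactly in the conditions of the unique-regime
#' cell type, mirroring a pioneer factor driving a private accessibility
#' program.
#'
#' @param config a [sim_config()] (needs at least 3 conditions).
#' @param truth ground truth list from [simulate_accessibility()]; extended
#'   and returned.
#' @return List with `footprints` (motif x condition matrix),
#'   `motifs` (list of PWMs, see [read_pfm()]), `archetype_map`
#'   (list with `motif_to_archetype`, `archetype_members`),
#'   `rna` (gene x condition matrix) and the extended `truth`
#'   (adds `driver_tf`, `pioneer_archetype`, `archetype_scores`).
#' @export
simulate_footprints <- function(config, truth) {
  validate_config(config)
  cond <- config$conditions
  n_cond <- nrow(cond)
  if (n_cond < 3)
    stop("need at least 3 conditions for footprint/RNA correlation")
  set.seed(config$seed + 1L)
  cond_ids <- paste(cond$cell_type, paste0("d", cond$day),
                    paste0("sag", cond$sag_nM), sep = "_")
  n_arch <- config$n_archetypes
  arch_ids <- paste0("archetype", seq_len(n_arch))

  unique_ct <- config$cell_types$name[config$cell_types$regime == "unique"]
  unique_ct <- setdiff(unique_ct, "NMP")
  pioneer_profile <- as.numeric(cond$cell_type %in% unique_ct)

  arch_scores <- matrix(rnorm(n_arch * n_cond), n_arch, n_cond,
                        dimnames = list(arch_ids, cond_ids))
  # the pioneer archetype carries a strong planted signal (amplitude 1.8 in
  # units of the decoy-archetype sd) so it dominates the variability ranking
  if (length(unique_ct) && sd(pioneer_profile) > 0)
    arch_scores[1, ] <- 1.8 * as.numeric(scale(pioneer_profile)) +
      rnorm(n_cond, sd = 0.15)

  arch_of_motif <- rep_len(seq_len(n_arch), config$n_motifs)
  motif_names <- paste0(arch_ids[arch_of_motif], "_m",
                        stats::ave(arch_of_motif, arch_of_motif,
                                   FUN = seq_along))
  fp <- arch_scores[arch_of_motif, , drop = FALSE] +
    matrix(rnorm(config$n_motifs * n_cond, sd = config$motif_noise_sd),
           config$n_motifs, n_cond)
  rownames(fp) <- motif_names

  motifs <- vector("list", config$n_motifs)
  seed_pwms <- lapply(seq_len(n_arch), function(a) {
    m <- matrix(rgamma(4 * 10, shape = 0.5), 4, 10)
    sweep(m, 2L, colSums(m), "/")
  })
  for (i in seq_len(config$n_motifs)) {
    a <- arch_of_motif[i]
    variant <- (match(i, which(arch_of_motif == a)) - 1L) %% 4L
    m <- seed_pwms[[a]]
    if (variant %in% c(1L, 3L)) m <- reverse_complement_pwm(m)
    if (variant >= 2L)                       # offset by 2 columns
      m <- cbind(matrix(0.25, 4, 2), m[, 1:(ncol(m) - 2), drop = FALSE])
    motifs[[i]] <- pwm(m, name = motif_names[i])
  }
  names(motifs) <- motif_names

  r <- config$driver_correlation
  genes <- character(0); rna <- NULL
  driver_tf <- setNames(character(n_arch), arch_ids)
  members <- setNames(vector("list", n_arch), arch_ids)
  for (a in seq_len(n_arch)) {
    s <- as.numeric(scale(arch_scores[a, ]))
    driver <- paste0("Tf", a, "d")
    decoys <- paste0("Tf", a, "x", seq_len(config$n_decoys))
    noise <- if (abs(r) < 1) rnorm(n_cond) else rep(0, n_cond)
    drv_expr <- 5 + 2 * (r * s + sqrt(max(0, 1 - r^2)) * noise)
    dec_expr <- matrix(5 + 2 * rnorm(config$n_decoys * n_cond),
                       config$n_decoys, n_cond)
    block <- rbind(drv_expr, dec_expr)
    rownames(block) <- c(driver, decoys)
    rna <- rbind(rna, block)
    driver_tf[a] <- driver
    members[[a]] <- c(driver, decoys)
  }
  colnames(rna) <- cond_ids

  truth$driver_tf <- driver_tf
  truth$pioneer_archetype <- if (length(unique_ct)) arch_ids[1] else NA_character_
  truth$archetype_scores <- arch_scores
  list(footprints = fp, motifs = motifs,
       archetype_map = list(
         motif_to_archetype = setNames(arch_ids[arch_of_motif], motif_names),
         archetype_members = members),
       rna = rna, truth = truth)
}
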