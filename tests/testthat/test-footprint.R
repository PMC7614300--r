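random_pwm <- function(L = 10, name = "m") {
  m <- matrix(rgamma(4 * L, 0.5), 4, L)
  pwm(sweep(m, 2, colSums(m), "/"), name = name)
}

test_that("PFM reading normalizes counts and round-trips", {
  tmp <- tempfile(fileext = ".pfm")
  writeLines(c(">MA0001 testA",
               "A [ 10 20 70  0 50 25 ]",
               "C [ 30 20 10 90 10 25 ]",
               "G [ 40 30 10  5 20 25 ]",
               "T [ 20 30 10  5 20 25 ]",
               ">plainB",
               "0.25 0.1 0.9 0.3",
               "0.25 0.2 0.05 0.3",
               "0.25 0.3 0.03 0.2",
               "0.25 0.4 0.02 0.2"), tmp)
  ms <- read_pfm(tmp)
  expect_equal(names(ms), c("MA0001", "plainB"))
  expect_equal(unname(colSums(ms$MA0001$mat)), rep(1, 6), tolerance = 1e-9)
  expect_equal(unname(ms$MA0001$mat["A", 3]), 0.7)
  expect_equal(unname(ms$plainB$mat["G", 2]), 0.3)  # probabilities pass through

  out <- tempfile(fileext = ".pfm")
  write_pfm(ms, out)
  ms2 <- read_pfm(out)
  expect_equal(ms2$MA0001$mat, ms$MA0001$mat, tolerance = 1e-6)

  writeLines(c(">ragged", "1 2 3", "1 2", "1 2 3", "1 2 3"), tmp)
  expect_error(read_pfm(tmp), "ragged")
})

test_that("footprint score measures flank-over-center depletion", {
  expect_equal(footprint_score(rep(5, 40), 10, 10), 0)        # flat
  prof <- rep(7, 40); prof[16:25] <- 0
  expect_equal(footprint_score(prof, 10, 10), log2(8))        # closed form
  # deeper planted depletion gives a strictly larger score
  scores <- vapply(seq(0, 6, by = 1), function(depth) {
    p <- rep(8, 40); p[16:25] <- 8 - depth
    footprint_score(p, 10, 10)
  }, 0)
  expect_true(all(diff(scores) > 0))
  # with c -> 0 the score is exactly scale-invariant
  p <- rep(10, 40); p[16:25] <- 2
  s1 <- footprint_score(p, 10, 10, pseudocount = 1e-12)
  s2 <- footprint_score(p * 7, 10, 10, pseudocount = 1e-12)
  expect_equal(s1, s2, tolerance = 1e-9)
  expect_error(footprint_score(rep(1, 20), 10, 10), "shorter")
  expect_error(footprint_score(c(-1, rep(1, 39)), 10, 10), ">= 0")
})

test_that("differential footprints z-score against the motif background", {
  set.seed(73)
  fp <- matrix(rnorm(60), 20, 3,
               dimnames = list(sprintf("m%02d", 1:20), c("a", "b", "c")))
  d <- differential_footprints(fp, "a", "b")
  expect_equal(d$delta, unname(fp[, "b"] - fp[, "a"]))
  # antisymmetry under condition swap
  d2 <- differential_footprints(fp, "b", "a")
  expect_equal(d2$delta, -d$delta)
  expect_equal(d2$z, -d$z)
  # all deltas equal: z = 0, p = 1 everywhere
  fp_eq <- fp; fp_eq[, "b"] <- fp_eq[, "a"]
  deq <- differential_footprints(fp_eq, "a", "b")
  expect_true(all(deq$z == 0))
  expect_true(all(deq$pvalue == 1))
  # one motif far above the background is extreme
  fp_out <- fp_eq; fp_out["m01", "b"] <- fp_out["m01", "a"] + 50
  dout <- differential_footprints(fp_out, "a", "b")
  expect_lt(dout$pvalue[dout$motif == "m01"], 1e-6)
  expect_error(differential_footprints(fp[1:5, ], "a", "b"), "10 motifs")
})

test_that("variable-motif selection takes the top-percent union", {
  set.seed(79)
  d <- data.frame(motif = sprintf("m%03d", 1:100),
                  delta = rnorm(100), z = rnorm(100),
                  pvalue = runif(100))
  sel <- select_variable_motifs(list(d), top_pct = 5)
  expect_gte(length(sel), 5L)   # at least ceiling(5) from either rule
  expect_lte(length(sel), 10L)  # at most the union of both
  # monotone in top_pct
  sel10 <- select_variable_motifs(list(d), top_pct = 10)
  expect_true(all(sel %in% sel10))
  # ties: identical |delta| and p give the deterministic ceiling set
  dt <- data.frame(motif = sprintf("m%03d", 1:40), delta = 1, z = 0,
                   pvalue = 0.5)
  st <- select_variable_motifs(list(dt), top_pct = 5)
  expect_equal(st, sprintf("m%03d", 1:2))   # ceiling(0.05 * 40) = 2, by name
  # a planted divergent motif is always selected
  for (s in 1:20) {
    set.seed(s)
    dp <- data.frame(motif = sprintf("m%03d", 1:60), delta = rnorm(60),
                     z = 0, pvalue = runif(60, 0.1, 1))
    dp$delta[7] <- 25; dp$pvalue[7] <- 1e-12
    expect_true("m007" %in% select_variable_motifs(list(dp)))
  }
})

test_that("PWM archetype clustering respects identity and reverse complement", {
  set.seed(83)
  a <- random_pwm(name = "a")
  expect_equal(regland:::pwm_similarity(a, a), 1, tolerance = 1e-12)
  rc <- pwm(a$mat[4:1, ncol(a$mat):1], name = "a_rc")
  expect_equal(regland:::pwm_similarity(a, rc), 1, tolerance = 1e-12)
  cl <- cluster_archetypes(list(a, rc), similarity_min = 0.8)
  expect_equal(unname(cl$motif_to_archetype["a"]),
               unname(cl$motif_to_archetype["a_rc"]))
  # independent random PWMs land in different archetypes most of the time
  apart <- 0L
  for (s in 1:40) {
    set.seed(100 + s)
    x <- random_pwm(name = "x"); y <- random_pwm(name = "y")
    cl2 <- cluster_archetypes(list(x, y))
    apart <- apart + (cl2$motif_to_archetype[["x"]] !=
                        cl2$motif_to_archetype[["y"]])
  }
  expect_gte(apart, 38L)   # >= 95% of draws
  # the map is a partition: every motif appears exactly once
  ms <- lapply(1:6, function(i) random_pwm(name = paste0("p", i)))
  cl3 <- cluster_archetypes(ms)
  expect_equal(sort(unlist(cl3$archetype_members, use.names = FALSE)),
               sort(vapply(ms, function(m) m$name, "")))
  expect_equal(length(cl3$motif_to_archetype), 6L)
})

test_that("archetype scores are member means ranked by variability", {
  fp <- rbind(a_m1 = c(1, 2, 3), a_m2 = c(3, 4, 5), b_m1 = c(0, 10, 0))
  colnames(fp) <- c("c1", "c2", "c3")
  map <- list(motif_to_archetype = c(a_m1 = "A", a_m2 = "A", b_m1 = "B"))
  sc <- archetype_scores(fp, map)
  expect_equal(unname(sc["A", ]), c(2, 3, 4))      # group mean
  expect_equal(unname(sc["B", ]), c(0, 10, 0))     # singleton equals its row
  expect_equal(rownames(sc)[1], "B")               # higher variance first
  # identical member rows: mean equals either row
  fp2 <- rbind(x_m1 = c(1, 5, 2), x_m2 = c(1, 5, 2))
  colnames(fp2) <- colnames(fp)
  sc2 <- archetype_scores(fp2, list(motif_to_archetype =
                                      c(x_m1 = "X", x_m2 = "X")))
  expect_equal(unname(sc2["X", ]), c(1, 5, 2))
  # brute-force oracle on random input
  set.seed(89)
  fpr <- matrix(rnorm(40), 8, 5,
                dimnames = list(sprintf("r%d", 1:8), sprintf("c%d", 1:5)))
  grp <- setNames(rep(c("G1", "G2"), 4), rownames(fpr))
  scr <- archetype_scores(fpr, list(motif_to_archetype = grp))
  for (g in c("G1", "G2"))
    expect_equal(unname(scr[g, ]),
                 unname(colMeans(fpr[names(grp)[grp == g], ])))
  expect_error(archetype_scores(fpr, list(motif_to_archetype = grp[-1])),
               "unmapped")
})

test_that("candidate TF ranking orders genes by footprint-RNA correlation", {
  sc <- matrix(c(1, 2, 3, 4, 5, 6), 1, 6,
               dimnames = list("arch1", paste0("c", 1:6)))
  rna <- rbind(perfect = 10 + 3 * sc[1, ],
               anti = 10 - 2 * sc[1, ],
               flat = rep(4, 6),
               noisy = c(2, 1, 4, 3, 6, 5))
  colnames(rna) <- colnames(sc)
  cand <- rank_candidate_tfs(sc, rna,
                             list(arch1 = c("perfect", "anti", "flat",
                                            "noisy", "absent")))
  expect_equal(cand$gene[cand$rank == 1], "perfect")
  expect_equal(cand$pearson_r[cand$rank == 1], 1)
  expect_equal(cand$pearson_r[cand$gene == "anti"], -1)
  defined <- cand[is.finite(cand$pearson_r), ]
  expect_equal(defined$gene[which.max(defined$rank)], "anti")  # last defined
  # zero-variance gene is flagged NA and ranked last
  expect_true(is.na(cand$pearson_r[cand$gene == "flat"]))
  expect_equal(cand$rank[cand$gene == "flat"], max(cand$rank))
  expect_false("absent" %in% cand$gene)   # missing genes skipped
  expect_error(rank_candidate_tfs(sc[, 1:2, drop = FALSE], rna,
                                  list(arch1 = "perfect")), "3 shared")
})

test_that("planted pioneer driver tops its archetype end to end", {
  cfg <- sim_config(seed = 97, n_elements = 60)
  tr <- simulate_accessibility(cfg)$truth
  fx <- simulate_footprints(cfg, tr)
  sc <- archetype_scores(fx$footprints, fx$archetype_map)
  # the pioneer archetype is the most variable one
  expect_equal(rownames(sc)[1], fx$truth$pioneer_archetype)
  cand <- rank_candidate_tfs(sc, fx$rna, fx$archetype_map$archetype_members)
  top <- cand[cand$archetype == fx$truth$pioneer_archetype &
                cand$rank == 1, ]
  expect_equal(top$gene, unname(fx$truth$driver_tf[
    fx$truth$pioneer_archetype]))
})
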