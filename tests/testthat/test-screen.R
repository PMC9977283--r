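test_that("dynamic correlation matches the definitional average-rank oracle", {
  prot <- list(timepoints = 1:5, values = c(0, -0.6, -1, -0.7, -0.2))
  base <- c(0.1, 0.2, 0.3, 0.5, 0.9)
  perms <- as.matrix(expand.grid(rep(list(1:5), 5)))
  perms <- perms[apply(perms, 1, function(p) all(sort(p) == 1:5)), ]
  vals <- t(apply(perms, 1, function(p) base[p]))
  tc <- make_timecourse(vals, timepoints = 1:5)
  rhos <- compute_dynamic_correlation(tc, prot)
  expected <- apply(vals, 1, spearman_oracle, y = prot$values)
  expect_equal(unname(rhos), unname(expected), tolerance = 1e-12)
})

test_that("dynamic correlation handles ties with average ranks", {
  prot <- list(timepoints = 1:4, values = c(0.0, 0.2, 0.5, 0.8))
  tc <- make_timecourse(matrix(c(0.1, 0.1, 0.4, 0.9), nrow = 1),
                        timepoints = 1:4)
  # frozen from the definitional oracle: ranks (1.5, 1.5, 3, 4) vs (1, 2, 3, 4)
  expect_equal(unname(compute_dynamic_correlation(tc, prot)),
               0.948683298050514, tolerance = 1e-12)
})

test_that("comonotone and antitone series give rho of exactly +/-1", {
  prot <- list(timepoints = 1:5, values = c(0, -0.6, -1, -0.7, -0.2))
  tc <- make_timecourse(rbind(prot$values, -prot$values), timepoints = 1:5)
  expect_equal(unname(compute_dynamic_correlation(tc, prot)), c(1, -1))
})

test_that("rho is invariant under strictly monotone transforms", {
  set.seed(31)
  prot <- list(timepoints = 1:7, values = rnorm(7))
  for (i in 1:10) {
    g <- rnorm(7)
    tc1 <- make_timecourse(matrix(g, 1), timepoints = 1:7)
    tc2 <- make_timecourse(matrix(exp(2 * g) - 3, 1), timepoints = 1:7)
    r1 <- compute_dynamic_correlation(tc1, prot)
    r2 <- compute_dynamic_correlation(tc2, prot)
    expect_equal(unname(r1), unname(r2), tolerance = 1e-12)
    # monotone transform of the protein side too
    prot3 <- list(timepoints = 1:7, values = prot$values^3 + prot$values)
    expect_equal(unname(compute_dynamic_correlation(tc1, prot3)),
                 unname(r1), tolerance = 1e-12)
  }
})

test_that("constant series yield undefined (NA) correlation, never 0", {
  prot <- list(timepoints = 1:4, values = c(0, -1, -0.5, -0.2))
  tc <- make_timecourse(rbind(rep(0.3, 4), c(1, 2, 3, 4)), timepoints = 1:4)
  rhos <- compute_dynamic_correlation(tc, prot)
  expect_true(is.na(rhos[1]))
  expect_false(is.na(rhos[2]))
  expect_identical(select_correlated(rhos, 0.1), "g2")
})

test_that("axis mismatches and short series are rejected", {
  tc <- make_timecourse(matrix(rnorm(8), 2), timepoints = 1:4)
  expect_error(compute_dynamic_correlation(
    tc, list(timepoints = 2:5, values = rnorm(4))), "axes")
  tc2 <- make_timecourse(matrix(rnorm(4), 2), timepoints = 1:2)
  expect_error(compute_dynamic_correlation(
    tc2, list(timepoints = 1:2, values = rnorm(2))), "3 timepoints")
})

test_that("correlation selection uses a strict absolute-value threshold", {
  rhos <- c(a = 0.76, b = -0.80, c = 0.75, d = -0.75, e = NA, f = 0.2)
  expect_setequal(select_correlated(rhos), c("a", "b"))
  expect_setequal(select_correlated(rhos, threshold = 0.1),
                  c("a", "b", "c", "d", "f"))
})

test_that("pLI filter is strict and drops unknown genes with a warning", {
  tab <- data.frame(gene = c("a", "b", "c"), pli = c(0.95, 0.90, 0.1))
  expect_identical(filter_by_constraint(c("a", "b", "c"), tab), "a")
  expect_warning(out <- filter_by_constraint(c("a", "zz"), tab), "zz")
  expect_identical(out, "a")
})

test_that("cross-study tally counts significance, testing and concordance", {
  mk <- function(id, mc, l2fc, padj) list(
    study_id = id, model_class = mc,
    table = data.frame(gene = "Gdf11", log2fc = l2fc, padj = padj))
  panel <- c(
    lapply(1:19, function(i) mk(paste0("s", i), "LOF", -1, 0.01)),
    list(mk("s20", "GOF", 1, 0.5)))
  t1 <- tally_cross_study("Gdf11", panel)
  expect_equal(t1$n_significant, 19)
  expect_equal(t1$n_tested, 20)
  expect_equal(t1$n_concordant, 19)

  # boundary: padj exactly at alpha is not significant ("below" is strict)
  t2 <- tally_cross_study("Gdf11", list(mk("s", "LOF", -1, 0.1)))
  expect_equal(t2$n_significant, 0)

  # discordant direction: significant but wrong sign for the model class
  t3 <- tally_cross_study("Gdf11", list(mk("s", "LOF", 1.0, 0.01)))
  expect_equal(t3$n_significant, 1)
  expect_equal(t3$n_concordant, 0)

  # missing padj or missing gene counts as untested
  panel4 <- list(mk("s1", "LOF", -1, NA),
                 list(study_id = "s2", model_class = "GOF",
                      table = data.frame(gene = "Other", log2fc = 1,
                                         padj = 0.01)))
  t4 <- tally_cross_study("Gdf11", panel4)
  expect_equal(t4$n_tested, 0)
  expect_setequal(t4$calls$status, "untested")
})

test_that("tally is invariant to study order and obeys count nesting", {
  set.seed(17)
  for (i in 1:10) {
    panel <- lapply(1:8, function(j) list(
      study_id = paste0("s", j),
      model_class = sample(c("LOF", "GOF"), 1),
      table = data.frame(gene = "g", log2fc = rnorm(1),
                         padj = sample(c(runif(1), NA), 1))))
    t1 <- tally_cross_study("g", panel)
    t2 <- tally_cross_study("g", sample(panel))
    expect_equal(t1[c("n_significant", "n_tested", "n_concordant")],
                 t2[c("n_significant", "n_tested", "n_concordant")])
    expect_lte(t1$n_concordant, t1$n_significant)
    expect_lte(t1$n_significant, t1$n_tested)
  }
})

test_that("candidate ranking is a deterministic total order", {
  rep <- data.frame(gene = c("b", "a", "c", "d"),
                    rho = c(0.80, 0.92, 0.92, -0.95),
                    n_significant = c(12, 19, 19, 12),
                    n_concordant = c(12, 19, 19, 12))
  out <- rank_candidates(rep)
  expect_identical(out$gene, c("a", "c", "d", "b"))
  expect_identical(out$rank, 1:4)
  # fully identical stats fall back to lexicographic gene order
  rep2 <- data.frame(gene = c("z", "m"), rho = 0.8,
                     n_significant = 5, n_concordant = 5)
  expect_identical(rank_candidates(rep2)$gene, c("m", "z"))
})

test_that("the assembled screen recovers planted tracking genes", {
  sim <- simulate_timecourse(n_genes = 100, n_tracking = 6, noise_sd = 0.1,
                             seed = 7)
  panel <- simulate_study_panel(seed = 7)$panel
  scr <- dosage_screen(sim$timecourse, sim$protein, sim$constraint, panel)
  expect_s3_class(scr, "dosage_screen")
  expect_true(all(names(sim$truth$tracking_genes) %in% scr$candidates$gene))
  expect_true(all(scr$candidates$n_concordant <= scr$candidates$n_significant))
  expect_output(print(scr), "candidates")
  s <- summary(scr)
  expect_equal(unname(s["n_genes"]), 100)
})
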