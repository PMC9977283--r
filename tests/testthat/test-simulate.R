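test_that("generators are deterministic under a fixed seed", {
  a <- simulate_timecourse(50, 4, seed = 9)
  b <- simulate_timecourse(50, 4, seed = 9)
  expect_identical(a, b)

  a <- simulate_study_panel(n_studies = 6, model_classes = rep("LOF", 6),
                            seed = 9)
  b <- simulate_study_panel(n_studies = 6, model_classes = rep("LOF", 6),
                            seed = 9)
  expect_identical(a, b)

  a <- simulate_cells(c(neuron_ex = 100, neuron_in = 80), seed = 9)
  b <- simulate_cells(c(neuron_ex = 100, neuron_in = 80), seed = 9)
  expect_identical(a, b)

  w <- list(list(chrom = "chr1", start = 1000, end = 8000, id = "w1"))
  a <- simulate_fragments(w, seed = 9)
  b <- simulate_fragments(w, seed = 9)
  expect_identical(a, b)

  a <- simulate_sections(5000, seed = 9)
  b <- simulate_sections(5000, seed = 9)
  expect_identical(a, b)
})

test_that("generators never emit non-finite values", {
  for (seed in 1:3) {
    s <- simulate_timecourse(40, 5, seed = seed)
    expect_true(all(is.finite(s$timecourse$values)))
    expect_true(all(is.finite(s$protein$values)))
    p <- simulate_study_panel(n_studies = 4,
                              model_classes = c("LOF", "GOF", "LOF", "GOF"),
                              seed = seed)
    for (st in p$panel) expect_true(all(is.finite(st$table$log2fc)) &&
                                      all(is.finite(st$table$padj)))
    cc <- simulate_cells(c(neuron_ex = 50, astrocyte = 50), seed = seed)
    expect_true(all(is.finite(cc$counts$counts)))
  }
})

test_that("time-course planting honors the requested structure", {
  # no tracking genes requested
  s0 <- simulate_timecourse(100, 0, seed = 2)
  expect_length(s0$truth$tracking_genes, 0)

  # zero noise, unit slope magnitude: tracking series equal the protein
  # series up to the recorded signed slope, exactly
  s1 <- simulate_timecourse(20, 5, slope_range = c(1, 1), noise_sd = 0,
                            seed = 3)
  for (g in names(s1$truth$tracking_genes)) {
    expect_equal(unname(s1$timecourse$values[g, ]),
                 s1$truth$tracking_genes[[g]] * s1$protein$values)
  }
  # planted ids exist in the dataset and carry high pLI
  expect_true(all(names(s1$truth$tracking_genes) %in% s1$timecourse$gene_ids))
  pli <- s1$constraint$pli[match(names(s1$truth$tracking_genes),
                                 s1$constraint$gene)]
  expect_true(all(pli > 0.9))

  # protein curve drops monotonically to a nadir then recovers monotonically
  pv <- s1$protein$values
  nadir <- which.min(pv)
  expect_true(all(diff(pv[1:nadir]) < 0))
  expect_true(all(diff(pv[nadir:length(pv)]) > 0))

  expect_error(simulate_timecourse(0, 0, seed = 1), "positive")
  expect_error(simulate_timecourse(10, 2, timepoints = c(1, 2, 2, 4),
                                   seed = 1), "duplicate")
})

test_that("study panel planting follows the model-class sign convention", {
  # near-zero standard error: the planted gene is significant everywhere
  # and its sign matches LOF down / GOF up
  s <- simulate_study_panel(n_studies = 10,
                            model_classes = rep(c("LOF", "GOF"), 5),
                            target_effect = 1, se = 1e-6, seed = 4)
  t <- tally_cross_study(s$truth$robust_gene, s$panel)
  expect_equal(t$n_significant, 10)
  expect_equal(t$n_concordant, 10)
  expect_error(simulate_study_panel(n_studies = 0, model_classes = character(0)),
               "non-empty")
})

test_that("cell simulation hits the target rank correlation", {
  # null coupling at 5000 cells
  s0 <- simulate_cells(c(neuron_in = 5000), target_rho = 0, seed = 5)
  r0 <- correlate_pair(s0$counts, "Gdf11", "Mecp2",
                       setNames(s0$annotation$class, s0$annotation$cell_id))
  expect_lt(abs(r0$rho[r0$group == "all"]), 0.05)

  # comonotone coupling: identical quantiles give rho 1 despite ties
  s1 <- simulate_cells(c(neuron_in = 5000), target_rho = 1, seed = 5)
  r1 <- correlate_pair(s1$counts, "Gdf11", "Mecp2",
                       setNames(s1$annotation$class, s1$annotation$cell_id))
  expect_gte(r1$rho[r1$group == "all"], 0.99)

  expect_error(simulate_cells(c(a = 10), nb_dispersion = -1), "dispersion")
})

test_that("fragment simulation plants enrichment and rejects ambiguity", {
  w <- list(list(chrom = "chr1", start = 1e5, end = 1e5 + 7000, id = "w1"),
            list(chrom = "chr1", start = 5e5, end = 5e5 + 7000, id = "w2"))
  s <- simulate_fragments(w, c("WT", "KO"), 2, background_rate = 5,
                          enrichment = list(WT = c(8, 8), KO = c(8, 0)),
                          seed = 6)
  tab <- count_fragments(s$fragments, w)
  ko <- grep("KO", tab$samples)
  # complete loss of binding: (near) zero KO counts in the silenced window;
  # only boundary-straddling background can contribute
  expect_lt(max(tab$counts["w2", ko]), 5)
  expect_gt(min(tab$counts["w1", ko]), 100)

  over <- list(list(chrom = "chr1", start = 100, end = 300, id = "a"),
               list(chrom = "chr1", start = 200, end = 400, id = "b"))
  expect_error(simulate_fragments(over, seed = 1), "overlapping")
})

test_that("section simulation supports exhaustive and empty limits", {
  # exhaustive sampling: every cell of the hemisphere is counted and the
  # bilateral estimate doubles it
  s <- simulate_sections(10000, n_sections_total = 30, ssf = 1, t = 40,
                         h = 40, asf = 1, seed = 7)
  expect_equal(sum(s$sections$Q), 5000)
  expect_equal(estimate_total_cells(s$sections), 10000)

  s0 <- simulate_sections(0, seed = 8)
  expect_true(all(s0$sections$Q == 0))
  expect_equal(estimate_total_cells(s0$sections), 0)

  expect_error(simulate_sections(100, ssf = 0.3, seed = 1), "1/k")
})
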