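#' Simulate a knockdown-recovery time-course with planted tracking genes
#'
#' Generates the inputs of the dynamic-correlation stage with known truth.
#' The regulator-protein trajectory is a piecewise-linear knockdown-recovery
#' curve: log2 fold-change 0 at the first timepoint, a monotone drop to
#' `nadir_depth` at a fraction `nadir_frac` of the time span, then a monotone
#' return toward `recovery_level`. A random subset of `n_tracking` genes
#' tracks the protein: `geneFC(t) = slope * proteinFC(t) + N(0, noise_sd)`
#' with a signed slope drawn from `slope_range`; the remaining genes are
#' i.i.d. `N(0, noise_sd)` at every timepoint. A constraint (pLI) table is
#' generated alongside: planted genes draw pLI from (0.95, 1), null genes
#' uniform on (0, 1), so the full correlate-select-filter screen can be
#' exercised on the synthetic data.
#'
#' @param n_genes Number of genes (> 0).
#' @param n_tracking Number of planted protein-tracking genes
#'   (`<= n_genes`).
#' @param timepoints Ordered ages in weeks (no duplicates, >= 4 required).
#' @param slope_range Interval for the magnitude of the tracking slope
#'   (log2FC per log2FC); the sign is random per gene.
#' @param noise_sd Gaussian noise sd in log2FC units (>= 0).
#' @param nadir_depth,nadir_frac,recovery_level Shape of the protein curve:
#'   lowest log2FC, its position as a fraction of the span, and the final
#'   level.
#' @param seed Integer seed; identical arguments reproduce identical output.
#' @return List with `timecourse` (gene_ids, timepoints, values matrix),
#'   `protein` (timepoints, values), `constraint` (data.frame gene, pli) and
#'   `truth` (list with `tracking_genes`, a named vector of planted slopes).
#' @export
simulate_timecourse <- function(n_genes, n_tracking,
                                timepoints = seq(4, 18, by = 2),
                                slope_range = c(0.8, 1.2), noise_sd = 0.1,
                                nadir_depth = -1, nadir_frac = 0.35,
                                recovery_level = -0.1, seed = 1) {
  if (n_genes <= 0) stop("n_genes must be positive")
  if (anyDuplicated(timepoints)) stop("duplicate timepoints")
  stopifnot(n_tracking <= n_genes, n_tracking >= 0,
            length(timepoints) >= 4L, noise_sd >= 0, nadir_depth < 0)
  timepoints <- sort(as.numeric(timepoints))
  set.seed(seed)
  span <- range(timepoints)
  t_nadir <- span[1] + nadir_frac * diff(span)
  prot <- ifelse(timepoints <= t_nadir,
                 nadir_depth * (timepoints - span[1]) / (t_nadir - span[1]),
                 nadir_depth + (recovery_level - nadir_depth) *
                   (timepoints - t_nadir) / (span[2] - t_nadir))
  gene_ids <- sprintf("gene%04d", seq_len(n_genes))
  tracking <- sort(sample(gene_ids, n_tracking))
  slopes <- setNames(runif(n_tracking, slope_range[1], slope_range[2]) *
                       sample(c(-1, 1), n_tracking, replace = TRUE), tracking)
  vals <- matrix(rnorm(n_genes * length(timepoints), 0, noise_sd),
                 nrow = n_genes, dimnames = list(gene_ids, timepoints))
  for (g in tracking) vals[g, ] <- slopes[[g]] * prot + vals[g, ]
  pli <- runif(n_genes)
  pli[match(tracking, gene_ids)] <- runif(n_tracking, 0.95, 1)
  list(timecourse = list(gene_ids = gene_ids, timepoints = timepoints,
                         values = vals),
       protein = list(timepoints = timepoints, values = prot),
       constraint = data.frame(gene = gene_ids, pli = pli,
                               stringsAsFactors = FALSE),
       truth = list(tracking_genes = slopes))
}

#' Simulate a cross-study differential-expression panel
#'
#' Generates summary-level DE tables for a panel of studies, each tagged with
#' a model class (LOF or GOF), with one planted dosage-sensitive gene. Per
#' study, the planted gene's estimated log2 fold-change is
#' `N(-target_effect, se)` in LOF studies and `N(+target_effect, se)` in GOF
#' studies (a target positively regulated by the perturbed factor); null
#' genes are `N(0, se)`. Two-sided normal p-values from `estimate / se` are
#' adjusted by Benjamini-Hochberg within each study.
#'
#' @param n_studies Number of studies; must equal `length(model_classes)`.
#' @param model_classes Character vector of "LOF"/"GOF" per study.
#' @param target_effect Planted |log2FC| (>= 0).
#' @param se Standard error of the log2FC estimates.
#' @param n_genes Genes per study table (includes the planted gene).
#' @param alpha_gen Adjusted-p cutoff recorded in the truth for reference.
#' @param seed Integer seed.
#' @return List with `panel` (list of study results: `study_id`,
#'   `model_class`, `table` with gene/log2fc/padj) and `truth`
#'   (`robust_gene`, `alpha`).
#' @export
simulate_study_panel <- function(n_studies = 20,
                                 model_classes = rep(c("LOF", "GOF"),
                                                     length.out = n_studies),
                                 target_effect = 1, se = 0.2, n_genes = 100,
                                 alpha_gen = 0.1, seed = 1) {
  if (length(model_classes) == 0L) stop("model_classes must be non-empty")
  stopifnot(n_studies == length(model_classes),
            all(model_classes %in% c("LOF", "GOF")),
            target_effect >= 0, se > 0)
  set.seed(seed)
  gene_ids <- sprintf("gene%04d", seq_len(n_genes))
  robust <- gene_ids[1]
  panel <- lapply(seq_len(n_studies), function(i) {
    mc <- model_classes[i]
    mu <- rep(0, n_genes)
    mu[1] <- if (mc == "LOF") -target_effect else target_effect
    l2fc <- rnorm(n_genes, mu, se)
    p <- 2 * pnorm(-abs(l2fc / se))
    list(study_id = sprintf("study%02d", i), model_class = mc,
         table = data.frame(gene = gene_ids, log2fc = l2fc,
                            padj = p.adjust(p, method = "BH"),
                            stringsAsFactors = FALSE))
  })
  list(panel = panel, truth = list(robust_gene = robust, alpha = alpha_gen))
}

#' Simulate single-cell counts for two coupled genes with a marker split
#'
#' Generates per-class counts for two focal genes with negative-binomial
#' marginals coupled through a Gaussian copula calibrated to a target
#' Spearman correlation via the closed relation
#' `r_latent = 2 sin(pi rho_S / 6)`; the realized rank correlation carries a
#' small residual attenuation from count discretization. Cells of the
#' designated excitatory class draw marker counts as
#' `min_count + NB(marker_mu)` (always at or above the split threshold);
#' all other cells draw marker counts truncated strictly below the
#' threshold, so the planted excitatory set is exactly recoverable by
#' [split_neurons()]. Both neuron subclasses are annotated "neuron"; other
#' classes keep their own labels.
#'
#' @param n_cells_per_class Named integer vector class -> cell count; class
#'   names may include `excitatory_class` and `inhibitory_class`.
#' @param target_rho Target Spearman correlation in \[-1, 1\]; scalar or a
#'   named vector per class.
#' @param geneA,geneB Ids of the two focal genes.
#' @param marker_gene Marker gene id used for the neuron split.
#' @param min_count Inclusive marker threshold defining excitatory cells.
#' @param marker_mu Mean of the NB excess marker count in excitatory cells.
#' @param nb_mean,nb_dispersion NB marginal mean and dispersion (variance
#'   `mu + dispersion * mu^2`; dispersion >= 0) of the two focal genes.
#' @param excitatory_class,inhibitory_class Class names annotated as
#'   "neuron" and split by the marker.
#' @param seed Integer seed.
#' @return List with `counts` (gene_ids, cell_ids, counts matrix),
#'   `annotation` (data.frame cell_id, class) and `truth` (`planted_rho`
#'   per class, `excitatory_cells`).
#' @export
simulate_cells <- function(n_cells_per_class, target_rho = 0.7,
                           geneA = "Gdf11", geneB = "Mecp2",
                           marker_gene = "Slc17a7", min_count = 5,
                           marker_mu = 15, nb_mean = 8, nb_dispersion = 0.2,
                           excitatory_class = "neuron_ex",
                           inhibitory_class = "neuron_in", seed = 1) {
  stopifnot(length(n_cells_per_class) >= 1L, all(n_cells_per_class > 0))
  if (nb_dispersion < 0) stop("negative dispersion")
  classes <- names(n_cells_per_class)
  rho_by_class <- if (length(target_rho) == 1L)
    setNames(rep(target_rho, length(classes)), classes) else target_rho[classes]
  if (any(is.na(rho_by_class)) || any(abs(rho_by_class) > 1))
    stop("target_rho must cover every class and lie in [-1, 1]")
  set.seed(seed)
  size <- if (nb_dispersion == 0) Inf else 1 / nb_dispersion
  cells <- list(); ann <- list(); xs <- list(); ys <- list(); mks <- list()
  for (cl in classes) {
    n <- n_cells_per_class[[cl]]
    r <- 2 * sin(pi * rho_by_class[[cl]] / 6)
    z1 <- rnorm(n); z2 <- r * z1 + sqrt(1 - r^2) * rnorm(n)
    xs[[cl]] <- qnbinom(pnorm(z1), mu = nb_mean, size = size)
    ys[[cl]] <- qnbinom(pnorm(z2), mu = nb_mean, size = size)
    mks[[cl]] <- if (cl == excitatory_class) {
      min_count + rnbinom(n, mu = marker_mu, size = 2)
    } else if (min_count == 0) {
      integer(n)  # threshold 0: every neuron is excitatory by the rule
    } else {
      pmin(rnbinom(n, mu = 0.5, size = 1), min_count - 1L)
    }
    ids <- sprintf("%s_%04d", cl, seq_len(n))
    cells[[cl]] <- ids
    ann[[cl]] <- data.frame(
      cell_id = ids,
      class = if (cl %in% c(excitatory_class, inhibitory_class)) "neuron" else cl,
      stringsAsFactors = FALSE)
  }
  cell_ids <- unlist(cells, use.names = FALSE)
  counts <- rbind(unlist(xs, use.names = FALSE),
                  unlist(ys, use.names = FALSE),
                  unlist(mks, use.names = FALSE))
  dimnames(counts) <- list(c(geneA, geneB, marker_gene), cell_ids)
  list(counts = list(gene_ids = rownames(counts), cell_ids = cell_ids,
                     counts = counts),
       annotation = do.call(rbind, c(ann, list(make.row.names = FALSE))),
       truth = list(planted_rho = rho_by_class,
                    excitatory_cells = cells[[excitatory_class]]))
}

#' Simulate spike-in CUT&RUN fragment data with planted window enrichment
#'
#' Generates primary-genome fragments whose counts follow
#' `Poisson(background_rate * width_kb * enrichment)` inside each
#' quantification window and `Poisson(background_rate * length_kb)` in the
#' inter-window background, plus `Poisson(spike_mean)` spike-genome fragments
#' per sample. Fragment lengths are uniform on `len_range` (default 120-180
#' bp, a mononucleosomal CUT&RUN range; irrelevant to >= 1 bp overlap
#' counting) and fragments are placed fully inside their window or background
#' gap so the planted truth is unambiguous. Windows must not overlap.
#'
#' @param windows List of windows (`chrom`, `start`, `end`, `id`), all on one
#'   chromosome.
#' @param genotypes Character vector of genotype labels (subset of
#'   WT/KO/TG).
#' @param n_samples_per_genotype Replicates per genotype; samples are named
#'   `<genotype>_<i>`.
#' @param background_rate Background fragments per kb per sample.
#' @param enrichment Fold enrichment per window per genotype: named list
#'   genotype -> numeric vector over windows (recycled); > 0, or 0 for
#'   complete loss of binding.
#' @param spike_mean Mean spike-genome fragments per sample (> 0).
#' @param chrom_length Length of the simulated chromosome (bp).
#' @param len_range Fragment length range (bp).
#' @param seed Integer seed.
#' @return List with `fragments` (data.frame chrom/start/end/sample/genome),
#'   `genotype_of` (named vector sample -> genotype), `libs` (per-sample
#'   libraries) and `truth` (`enrichment` windows x genotypes matrix).
#' @export
simulate_fragments <- function(windows, genotypes = c("WT", "KO"),
                               n_samples_per_genotype = 3,
                               background_rate = 5, enrichment = list(),
                               spike_mean = 500, chrom_length = 1e6,
                               len_range = c(120, 180), seed = 1) {
  stopifnot(length(windows) >= 1L, spike_mean > 0, background_rate >= 0)
  chrom <- windows[[1]]$chrom
  ord <- order(vapply(windows, `[[`, 0, "start"))
  ws <- vapply(windows, `[[`, 0, "start")[ord]
  we <- vapply(windows, `[[`, 0, "end")[ord]
  if (any(ws[-1] < we[-length(we)]))
    stop("overlapping windows: planted truth would be ambiguous")
  set.seed(seed)
  enr <- sapply(genotypes, function(g) {
    e <- if (is.null(enrichment[[g]])) 1 else enrichment[[g]]
    if (any(e < 0)) stop("enrichment must be >= 0")
    rep_len(e, length(windows))
  })
  enr <- matrix(enr, nrow = length(windows), ncol = length(genotypes),
                dimnames = list(vapply(windows, `[[`, "", "id"), genotypes))
  gaps_s <- c(0, we); gaps_e <- c(ws, chrom_length)
  frag_block <- function(n, lo, hi, sample, genome) {
    if (n == 0L) return(NULL)
    len <- round(runif(n, len_range[1], len_range[2]))
    start <- floor(runif(n, lo, pmax(lo + 1, hi - len)))
    data.frame(chrom = if (genome == "primary") chrom else "spike_chr",
               start = start, end = start + len, sample = sample,
               genome = genome, stringsAsFactors = FALSE)
  }
  out <- list()
  for (g in genotypes) for (i in seq_len(n_samples_per_genotype)) {
    smp <- sprintf("%s_%d", g, i)
    for (w in seq_along(windows)) {
      lam <- background_rate * (we[w] - ws[w]) / 1000 * enr[w, g]
      out[[length(out) + 1L]] <-
        frag_block(rpois(1, lam), ws[w], we[w], smp, "primary")
    }
    for (k in seq_along(gaps_s)) {
      glen <- gaps_e[k] - gaps_s[k]
      if (glen < len_range[2] + 1) next
      out[[length(out) + 1L]] <-
        frag_block(rpois(1, background_rate * glen / 1000),
                   gaps_s[k], gaps_e[k], smp, "primary")
    }
    out[[length(out) + 1L]] <-
      frag_block(rpois(1, spike_mean), 0, 1e5, smp, "spike")
  }
  fragments <- do.call(rbind, out)
  rownames(fragments) <- NULL
  genotype_of <- setNames(
    rep(genotypes, each = n_samples_per_genotype),
    unlist(lapply(genotypes, function(g)
      sprintf("%s_%d", g, seq_len(n_samples_per_genotype)))))
  libs <- tabulate_libraries(fragments, genotype_of)
  list(fragments = fragments, genotype_of = genotype_of, libs = libs,
       truth = list(enrichment = enr))
}

#' Simulate stereology section counts with a known total
#'
#' Distributes half of `true_total` cells (one hemisphere) uniformly
#' (multinomially) across `n_sections_total` sections, takes a systematic
#' 1-in-`1/ssf` sample of sections with a random start, and thins each
#' sampled section's count binomially with probability `(h/t) * asf` (the
#' within-section height and area sampling). The optical-fractionator
#' estimator applied to the output is unbiased for `true_total`.
#'
#' @param true_total Planted total cell number for the bilateral brain
#'   (>= 0).
#' @param n_sections_total Sections in the sectioned hemisphere.
#' @param ssf Section sampling fraction; must be `1/k` for integer `k`.
#' @param t,h Section thickness and dissector height (um, `0 < h <= t`).
#' @param asf Area sampling fraction in (0, 1].
#' @param section_area Per-section area (um^2), carried for density.
#' @param seed Integer seed.
#' @return List with `sections` (Q, t, h, asf, ssf, bilateral_factor,
#'   section_ids, areas) and `truth` (`true_total`).
#' @export
simulate_sections <- function(true_total, n_sections_total = 60, ssf = 1/6,
                              t = 40, h = 40, asf = 1, section_area = 9e4,
                              seed = 1) {
  stopifnot(true_total >= 0, n_sections_total >= 1, t > 0, h > 0, h <= t,
            asf > 0, asf <= 1, ssf > 0, ssf <= 1)
  k <- 1 / ssf
  if (abs(k - round(k)) > 1e-9)
    stop("ssf must be of the form 1/k for integer k (systematic sampling)")
  k <- as.integer(round(k))
  set.seed(seed)
  hemi <- round(true_total / 2)
  per_section <- as.integer(rmultinom(1, hemi,
                                      rep(1, n_sections_total)))
  start <- sample.int(k, 1)
  sampled <- seq(start, n_sections_total, by = k)
  Q <- rbinom(length(sampled), per_section[sampled], (h / t) * asf)
  list(sections = list(Q = Q, t = t, h = h, asf = asf, ssf = ssf,
                       bilateral_factor = 2, section_ids = sampled,
                       areas = rep(section_area, length(sampled))),
       truth = list(true_total = true_total))
}
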