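#' Expand a peak to a symmetric quantification window
#'
#' Builds the fixed-width window used for occupancy quantification: the
#' midpoint of the peak (floor of the coordinate mean, 0-based half-open)
#' extended by `halfwidth` on both sides and clipped at position 0. The
#' default halfwidth of 3500 bp gives the conventional +/-3.5 kb region
#' around a called binding peak.
#'
#' @param peak List or one-row data.frame with `chrom`, `start`, `end`
#'   (0-based half-open, `start < end`).
#' @param halfwidth Window half-width in bp (>= 1).
#' @param id Optional window id; defaults to "chrom:start-end" of the peak.
#' @return List with `chrom`, `start`, `end`, `id`, `provenance = "peak-derived"`.
#' @export
expand_peak <- function(peak, halfwidth = 3500, id = NULL) {
  stopifnot(halfwidth >= 1)
  s <- as.numeric(peak$start); e <- as.numeric(peak$end)
  if (!is.finite(s) || !is.finite(e) || s >= e) stop("invalid peak interval")
  center <- floor((s + e) / 2)
  list(chrom = as.character(peak$chrom),
       start = max(0, center - halfwidth),
       end = center + halfwidth,
       id = if (is.null(id)) sprintf("%s:%.0f-%.0f", peak$chrom, s, e) else id,
       provenance = "peak-derived")
}

#' Spike-in scale factor for one sample
#'
#' The per-sample calibration factor `C / spike_count`: multiplying a
#' sample's raw primary-genome signal by this factor expresses it per fixed
#' quantity of exogenous spike-in material, making occupancy comparable
#' across libraries of different depth or amplification. `C` is an arbitrary
#' display constant (default 10000) that cancels in any between-sample ratio.
#'
#' @param lib Sample library: list with at least `sample` and `spike_count`.
#' @param C Calibration constant (> 0).
#' @return Numeric scale factor.
#' @export
spike_scale_factor <- function(lib, C = 10000) {
  stopifnot(C > 0)
  if (is.null(lib$spike_count) || lib$spike_count < 1)
    stop(sprintf("sample '%s' has no spike-in fragments; cannot normalize",
                 lib$sample))
  C / lib$spike_count
}

#' Count primary-genome fragments per window per sample
#'
#' A fragment is counted in a window iff it overlaps it by at least 1 bp
#' under 0-based half-open arithmetic (`frag_start < win_end` and
#' `frag_end > win_start` on the same chromosome). A fragment overlapping two
#' windows counts in both (per-window independent counting). Only records
#' with `genome == "primary"` contribute.
#'
#' @param fragments data.frame with columns `chrom`, `start`, `end`,
#'   `sample`, `genome` ("primary" or "spike").
#' @param windows List of windows (each with `chrom`, `start`, `end`, `id`).
#' @param samples Optional character vector fixing the sample columns;
#'   defaults to the sorted samples present in `fragments`.
#' @return Occupancy table: list with `counts` (windows x samples integer
#'   matrix), `window_ids`, `samples`.
#' @export
count_fragments <- function(fragments, windows, samples = NULL) {
  if (length(windows) == 0L) stop("window list is empty")
  validate_fragments(fragments)
  if (is.null(samples)) samples <- sort(unique(fragments$sample))
  prim <- fragments[fragments$genome == "primary", , drop = FALSE]
  wid <- vapply(windows, `[[`, "", "id")
  counts <- matrix(0L, nrow = length(windows), ncol = length(samples),
                   dimnames = list(wid, samples))
  si <- match(prim$sample, samples)
  for (w in seq_along(windows)) {
    win <- windows[[w]]
    hit <- prim$chrom == win$chrom & prim$start < win$end & prim$end > win$start
    if (any(hit)) {
      tab <- table(factor(si[hit], levels = seq_along(samples)))
      counts[w, ] <- counts[w, ] + as.integer(tab)
    }
  }
  list(counts = counts, window_ids = wid, samples = samples)
}

#' Summarize per-sample libraries from a fragment set
#'
#' Tallies total primary and spike-genome fragments per sample and attaches
#' genotypes, producing the library metadata consumed by
#' [spike_scale_factor()] and [differential_occupancy()].
#'
#' @param fragments Fragment data.frame (see [count_fragments()]).
#' @param genotypes Named character vector sample -> genotype ("WT", "KO",
#'   "TG").
#' @param antibody Antibody label attached to every library.
#' @return List of library lists (`sample`, `genotype`, `antibody`,
#'   `primary_count`, `spike_count`).
#' @export
tabulate_libraries <- function(fragments, genotypes, antibody = "unknown") {
  validate_fragments(fragments)
  samples <- sort(unique(fragments$sample))
  lapply(samples, function(s) {
    f <- fragments[fragments$sample == s, , drop = FALSE]
    list(sample = s,
         genotype = unname(genotypes[[s]]),
         antibody = antibody,
         primary_count = sum(f$genome == "primary"),
         spike_count = sum(f$genome == "spike"))
  })
}

#' Spike-calibrated window signal
#'
#' Multiplies each sample's raw window counts by its spike scale factor
#' `C / spike_count`, giving occupancy per fixed spike-in mass.
#'
#' @param table Occupancy table from [count_fragments()].
#' @param libs List of sample libraries covering `table$samples`.
#' @param C Calibration constant.
#' @return Windows x samples numeric matrix of calibrated signal.
#' @export
normalize_occupancy <- function(table, libs, C = 10000) {
  names(libs) <- vapply(libs, `[[`, "", "sample")
  if (!all(table$samples %in% names(libs)))
    stop("libraries missing for some samples in the occupancy table")
  for (s in table$samples) spike_scale_factor(libs[[s]], C)  # validates spikes
  spikes <- vapply(table$samples, function(s) as.numeric(libs[[s]]$spike_count), 0)
  # multiply before dividing: integer counts times C are exact, so k-fold
  # duplication of a sample (counts and spikes both scaled by k) reproduces
  # the normalized signal bit-for-bit
  sweep(table$counts * C, 2L, spikes, `/`)
}

#' Differential occupancy between genotypes with spike-in normalization
#'
#' Tests each window for a difference in spike-calibrated occupancy between a
#' perturbed genotype and wild-type. Raw counts are divided by per-sample
#' normalization factors `spike_count / geometric_mean(spike_counts)` (the
#' spike-in analogue of sequencing-depth size factors). Per window the test
#' is a Wald test on the difference of log group means under a
#' negative-binomial variance model: the dispersion is a per-window pooled
#' method-of-moments estimate floored at 0 (Poisson when underdispersed),
#'
#' \deqn{\hat\alpha = \max\!\left(0, \frac{SS - \sum_g (n_g-1)\bar y_g}
#'   {\sum_g (n_g-1)\bar y_g^2}\right)}
#'
#' with `SS` the pooled within-group sum of squared residuals; the statistic
#' is `(log(m_p + c0) - log(m_w + c0)) / se` with
#' `se^2 = sum_g (m_g + alpha m_g^2) / (n_g (m_g + c0)^2)` and pseudo-count
#' `c0 = 0.5`, referred two-sided to a t distribution with `n_p + n_w - 1`
#' degrees of freedom (calibrated against null simulation; the zero floor on
#' the dispersion makes the naive `n - 2` reference conservative).
#'
#' @param table Occupancy table from [count_fragments()].
#' @param libs List of sample libraries with `genotype` and `spike_count`.
#' @param contrast Length-2 character vector `c(perturbed, reference)`,
#'   e.g. `c("KO", "WT")`.
#' @param c0 Pseudo-count added inside the log fold-change (default 0.5).
#' @return Object of class `occupancy_test`: data.frame with columns
#'   `window`, `log2fc` (perturbed vs reference), `se`, `p`,
#'   `mean_perturbed`, `mean_reference` (normalized), plus attributes
#'   `contrast` and `size_factors`.
#' @export
differential_occupancy <- function(table, libs, contrast, c0 = 0.5) {
  stopifnot(length(contrast) == 2L)
  names(libs) <- vapply(libs, `[[`, "", "sample")
  geno <- vapply(table$samples, function(s) {
    if (is.null(libs[[s]])) stop(sprintf("no library for sample '%s'", s))
    libs[[s]]$genotype
  }, "")
  use <- geno %in% contrast
  pert <- table$samples[use & geno == contrast[1]]
  ref <- table$samples[use & geno == contrast[2]]
  if (length(pert) < 2L || length(ref) < 2L)
    stop("at least 2 samples per group are required for dispersion estimation")
  spikes <- vapply(c(pert, ref), function(s) {
    sc <- libs[[s]]$spike_count
    if (is.null(sc) || sc < 1)
      stop(sprintf("sample '%s' has no spike-in fragments", s))
    as.numeric(sc)
  }, 0)
  sf <- spikes / exp(mean(log(spikes)))
  norm <- sweep(table$counts[, c(pert, ref), drop = FALSE], 2L, sf, `/`)
  ip <- seq_along(pert); ir <- length(pert) + seq_along(ref)
  n1 <- length(pert); n2 <- length(ref)
  res <- t(apply(norm, 1L, function(y) {
    y1 <- y[ip]; y2 <- y[ir]
    m1 <- mean(y1); m2 <- mean(y2)
    SS <- sum((y1 - m1)^2) + sum((y2 - m2)^2)
    den <- (n1 - 1) * m1^2 + (n2 - 1) * m2^2
    alpha <- if (den > 0) max(0, (SS - (n1 - 1) * m1 - (n2 - 1) * m2) / den) else 0
    se2 <- (m1 + alpha * m1^2) / (n1 * (m1 + c0)^2) +
           (m2 + alpha * m2^2) / (n2 * (m2 + c0)^2)
    lfc <- log2((m1 + c0) / (m2 + c0))
    if (se2 <= 0) {
      # both groups exactly zero (or identical constants): no evidence
      return(c(lfc, 0, 1, m1, m2))
    }
    se <- sqrt(se2)
    z <- (log(m1 + c0) - log(m2 + c0)) / se
    p <- 2 * pt(-abs(z), df = n1 + n2 - 1)
    c(lfc, se / log(2), p, m1, m2)
  }))
  out <- data.frame(window = table$window_ids,
                    log2fc = res[, 1], se = res[, 2], p = res[, 3],
                    mean_perturbed = res[, 4], mean_reference = res[, 5],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "contrast") <- contrast
  attr(out, "size_factors") <- setNames(sf, c(pert, ref))
  class(out) <- c("occupancy_test", "data.frame")
  out
}

#' @method print occupancy_test
#' @export
print.occupancy_test <- function(x, ...) {
  ct <- attr(x, "contrast")
  cat(sprintf("Differential occupancy: %s vs %s (%d window%s)\n",
              ct[1], ct[2], nrow(x), if (nrow(x) == 1) "" else "s"))
  print.data.frame(x, row.names = FALSE, digits = 3)
  invisible(x)
}

validate_fragments <- function(fragments) {
  need <- c("chrom", "start", "end", "sample", "genome")
  stopifnot(is.data.frame(fragments), all(need %in% names(fragments)))
  if (any(fragments$start >= fragments$end))
    stop("fragment records with start >= end")
  if (!all(fragments$genome %in% c("primary", "spike")))
    stop("fragment genome must be 'primary' or 'spike'")
  invisible(fragments)
}
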