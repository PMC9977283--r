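#' Optical-fractionator estimate of total cell number
#'
#' Design-based stereology estimator: the objects counted in a systematic
#' sample of sections are scaled up by the inverses of the three sampling
#' fractions — section sampling fraction (ssf), area sampling fraction (asf)
#' and height sampling fraction (h/t, dissector height over section
#' thickness) — and doubled when only one hemisphere was sectioned:
#'
#' \deqn{N = \left[\sum Q \cdot \frac{t}{h} \cdot \frac{1}{asf} \cdot
#'   \frac{1}{ssf}\right] \cdot b}
#'
#' @param s Section counts: list with `Q` (integer counts per sampled
#'   section), `t` (section thickness, um), `h` (dissector height, um,
#'   `0 < h <= t`), `asf` and `ssf` (fractions in (0, 1\]), and
#'   `bilateral_factor` (default 2: one hemisphere sectioned).
#' @return Estimated total cell number (real-valued; rounding is the
#'   caller's choice).
#' @examples
#' estimate_total_cells(list(Q = rep(1, 10), t = 40, h = 40,
#'                           asf = 1, ssf = 1/6))  # 120
#' @export
estimate_total_cells <- function(s) {
  if (is.null(s$bilateral_factor)) s$bilateral_factor <- 2
  stopifnot(all(s$Q >= 0), s$h > 0, s$h <= s$t,
            s$asf > 0, s$asf <= 1, s$ssf > 0, s$ssf <= 1)
  sum(s$Q) * (s$t / s$h) * (1 / s$asf) * (1 / s$ssf) * s$bilateral_factor
}

#' Cell density from a fractionator estimate and sampled section areas
#'
#' Divides the estimated total cell number by a Cavalieri-style reference
#' volume built from the sampled sections: `V = (sum(area) * t) / ssf`,
#' i.e. each sampled section contributes a slab `area x t` and the slabs are
#' scaled up by the section sampling fraction. Areas are in um^2, thickness
#' in um; the result is cells per mm^3.
#'
#' @param N Estimated total cells (e.g. from [estimate_total_cells()]).
#' @param sampled_areas Numeric vector of per-section areas (um^2, > 0).
#' @param t Section thickness (um).
#' @param ssf Section sampling fraction in (0, 1].
#' @return Density in cells per mm^3.
#' @export
cell_density <- function(N, sampled_areas, t, ssf) {
  stopifnot(all(sampled_areas > 0), t > 0, ssf > 0, ssf <= 1)
  v_um3 <- sum(sampled_areas) * t / ssf
  if (v_um3 <= 0) stop("reference volume is zero")
  N / (v_um3 * 1e-9)  # 1 mm^3 = 1e9 um^3
}

#' Relative expression by the delta-delta-Ct method
#'
#' Livak 2^(-ddCt) quantification: per sample, the Ct of the target and the
#' reference gene are each averaged over technical replicates; `dCt = Ct_target
#' - Ct_reference`; `ddCt = dCt - mean(dCt over the control group)`; relative
#' expression is `2^(-ddCt)`. Centering on the control-group mean dCt forces
#' the geometric mean of control relative expression to 1 exactly. Samples in
#' which the target was not detected are reported with `detected = FALSE` and
#' `rel_expr = NA` (never 0); samples in which the reference was not detected
#' cannot be normalized and are excluded with a warning.
#'
#' @param table Ct table: data.frame with columns `gene`, `sample`, `group`,
#'   `ct` (one row per technical replicate) and `detected` (logical; `ct`
#'   ignored when `FALSE`).
#' @param target Target gene id.
#' @param reference Reference (housekeeping) gene id, e.g. Ppia.
#' @param control_group Label of the control group used for centering.
#' @return data.frame with columns `sample`, `group`, `dct`, `ddct`,
#'   `rel_expr`, `detected`.
#' @export
ddct_relative_expression <- function(table, target, reference,
                                     control_group = "control") {
  need <- c("gene", "sample", "group", "ct", "detected")
  stopifnot(is.data.frame(table), all(need %in% names(table)))
  samples <- unique(table$sample[table$gene == target])
  mean_ct <- function(gene, smp) {
    r <- table[table$gene == gene & table$sample == smp, , drop = FALSE]
    if (nrow(r) == 0L || !any(r$detected)) return(NA_real_)
    mean(r$ct[r$detected])
  }
  rows <- lapply(samples, function(smp) {
    grp <- unique(table$group[table$sample == smp])[1]
    ct_t <- mean_ct(target, smp)
    ct_r <- mean_ct(reference, smp)
    if (is.na(ct_r)) {
      warning(sprintf("reference '%s' not detected in sample '%s'; excluded",
                      reference, smp))
      return(NULL)
    }
    data.frame(sample = smp, group = grp,
               dct = ct_t - ct_r, detected = !is.na(ct_t),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  ctrl <- out$dct[out$group == control_group & out$detected]
  if (length(ctrl) == 0L) stop("empty control group (or no detected control samples)")
  out$ddct <- out$dct - mean(ctrl)
  out$rel_expr <- 2^(-out$ddct)
  out[c("sample", "group", "dct", "ddct", "rel_expr", "detected")]
}
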