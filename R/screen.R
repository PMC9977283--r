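#' Spearman correlation of each gene's fold-change series with a protein trajectory
#'
#' For every gene in a time-course fold-change matrix, computes the Spearman
#' rank correlation (average ranks for ties) between the gene's log2
#' fold-change series and the regulator-protein log2 fold-change trajectory
#' measured on the same timepoints. This is the "dynamic correlation" stage of
#' the dosage screen: a gene whose expression tracks regulator dosage rises and
#' falls with the protein as the knockdown takes hold and washes out.
#'
#' Genes whose series is constant (all tied ranks), or paired with a constant
#' protein series, have no defined rank correlation; they are returned as `NA`
#' rather than silently assigned 0.
#'
#' @param tc A time-course fold-change object as returned by
#'   [read_fold_change_matrix()] or [simulate_timecourse()]: a list with
#'   `gene_ids`, `timepoints` (strictly increasing ages) and `values`
#'   (genes x timepoints numeric matrix of log2 fold-changes).
#' @param prot A protein trajectory: list with `timepoints` (identical axis to
#'   `tc`, same order) and `values` (log2 fold-change of the protein).
#' @return Named numeric vector of Spearman's rho, one per gene; `NA` where
#'   undefined (constant series).
#' @seealso [select_correlated()], [dosage_screen()]
#' @export
compute_dynamic_correlation <- function(tc, prot) {
  validate_timecourse(tc)
  if (!identical(as.numeric(tc$timepoints), as.numeric(prot$timepoints)))
    stop("timepoint axes of the fold-change matrix and protein trajectory differ")
  if (length(tc$timepoints) < 3L)
    stop("at least 3 timepoints are required for a rank correlation")
  pv <- as.numeric(prot$values)
  if (!all(is.finite(pv))) stop("protein trajectory contains non-finite values")
  prot_const <- length(unique(pv)) == 1L
  pr <- rank(pv)  # average ranks
  rhos <- apply(tc$values, 1L, function(g) {
    if (prot_const || length(unique(g)) == 1L) return(NA_real_)
    cor(rank(g), pr)
  })
  setNames(as.numeric(rhos), tc$gene_ids)
}

#' Select genes whose dynamic correlation exceeds a threshold in magnitude
#'
#' Keeps genes with `|rho|` strictly greater than `threshold` (default 0.75,
#' the conventional "highly correlated" cut for this screen). Genes with
#' undefined (`NA`) correlation are never selected.
#'
#' @param rhos Named numeric vector of Spearman coefficients (from
#'   [compute_dynamic_correlation()]).
#' @param threshold Magnitude cutoff in (0, 1]; strict inequality.
#' @return Character vector of selected gene ids.
#' @export
select_correlated <- function(rhos, threshold = 0.75) {
  stopifnot(is.numeric(threshold), length(threshold) == 1L,
            threshold > 0, threshold <= 1)
  names(rhos)[!is.na(rhos) & abs(rhos) > threshold]
}

#' Filter a gene set by loss-of-function intolerance (pLI)
#'
#' Retains genes whose pLI is strictly greater than `pli_min` (default 0.9,
#' the usual "loss intolerant" cut). Genes absent from the constraint table
#' cannot be assessed and are dropped with a warning.
#'
#' @param genes Character vector of gene ids.
#' @param table Constraint table: data.frame with columns `gene` and `pli`
#'   (pLI in \[0, 1\], one row per gene).
#' @param pli_min pLI cutoff in \[0, 1\]; strict inequality.
#' @return Character vector of retained gene ids, in input order.
#' @export
filter_by_constraint <- function(genes, table, pli_min = 0.9) {
  stopifnot(is.numeric(pli_min), length(pli_min) == 1L,
            pli_min >= 0, pli_min <= 1)
  validate_constraint_table(table)
  idx <- match(genes, table$gene)
  missing <- genes[is.na(idx)]
  if (length(missing))
    warning(sprintf("%d gene(s) absent from the constraint table were dropped: %s",
                    length(missing), paste(missing, collapse = ", ")))
  keep <- !is.na(idx) & table$pli[idx] > pli_min
  genes[keep]
}

#' Tally cross-study significance and direction concordance for one gene
#'
#' Counts, over a panel of per-study differential-expression results, how many
#' studies call the gene significant (adjusted p strictly below `alpha`), how
#' many tested it at all, and how many of the significant calls are
#' direction-concordant with the study's model class under the
#' positive-regulation convention: a target of a positive regulator should go
#' down in loss-of-function (LOF) models and up in gain-of-function (GOF)
#' models. Studies lacking the gene, or reporting it without an adjusted p,
#' count toward neither tally and are listed as untested/indeterminate.
#'
#' @param gene Gene id.
#' @param panel List of study results; each element a list with `study_id`,
#'   `model_class` ("LOF" or "GOF") and `table` (data.frame with columns
#'   `gene`, `log2fc`, `padj`).
#' @param alpha Adjusted-p cutoff in (0, 1); strict inequality ("below").
#' @return List with `n_significant`, `n_tested`, `n_concordant` and `calls`,
#'   a data.frame of per-study calls (`study_id`, `model_class`, `log2fc`,
#'   `padj`, `status` in significant/not_significant/untested, `concordant`).
#' @export
tally_cross_study <- function(gene, panel, alpha = 0.1) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha > 0, alpha < 1)
  if (length(panel) == 0L) stop("empty study panel")
  rows <- lapply(panel, function(st) {
    stopifnot(st$model_class %in% c("LOF", "GOF"))
    i <- match(gene, st$table$gene)
    l2fc <- if (is.na(i)) NA_real_ else st$table$log2fc[i]
    padj <- if (is.na(i)) NA_real_ else st$table$padj[i]
    untested <- is.na(i) || is.na(padj)
    sig <- !untested && padj < alpha
    conc <- sig && !is.na(l2fc) &&
      sign(l2fc) == if (st$model_class == "LOF") -1 else 1
    data.frame(study_id = st$study_id, model_class = st$model_class,
               log2fc = l2fc, padj = padj,
               status = if (untested) "untested"
                        else if (sig) "significant" else "not_significant",
               concordant = conc, stringsAsFactors = FALSE)
  })
  calls <- do.call(rbind, rows)
  list(n_significant = sum(calls$status == "significant"),
       n_tested = sum(calls$status != "untested"),
       n_concordant = sum(calls$concordant),
       calls = calls)
}

#' Rank candidate genes deterministically
#'
#' Orders candidate reports by replication strength: number of significant
#' studies (descending), then direction-concordant count (descending), then
#' `|rho|` (descending), then gene id (lexicographic) so the order is total.
#'
#' @param reports data.frame with columns `gene`, `rho`, `n_significant`,
#'   `n_concordant` (and any others, carried through).
#' @return The same data.frame reordered, with a `rank` column (1 = best).
#' @export
rank_candidates <- function(reports) {
  stopifnot(is.data.frame(reports))
  if (nrow(reports) == 0L) {
    reports$rank <- integer(0)
    return(reports)
  }
  o <- order(-reports$n_significant, -reports$n_concordant,
             -abs(reports$rho), reports$gene)
  out <- reports[o, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Run the full dosage-sensitivity screen
#'
#' Composes the three screening stages: (1) dynamic Spearman correlation of
#' each gene's time-course fold-changes against the regulator-protein
#' trajectory; (2) selection of genes with `|rho|` above `rho_threshold` and
#' pLI above `pli_min`; (3) a cross-study replication tally of each surviving
#' candidate over a panel of differential-expression results, counting studies
#' with adjusted p below `alpha` and, separately, those whose fold-change
#' direction matches the model class (down in LOF, up in GOF). Candidates are
#' ranked by replication strength.
#'
#' @param timecourse Time-course fold-change object (see
#'   [compute_dynamic_correlation()]).
#' @param protein Protein trajectory on the same timepoint axis.
#' @param constraint Constraint table (`gene`, `pli`).
#' @param panel Optional list of study results (see [tally_cross_study()]);
#'   when `NULL` the tally columns are zero and `n_tested` is `NA`.
#' @param rho_threshold,pli_min,alpha Stage thresholds; defaults 0.75, 0.9,
#'   0.1.
#' @return An object of class `dosage_screen`: list with `candidates` (ranked
#'   report data.frame with columns gene, rho, pli, n_significant, n_tested,
#'   n_concordant, rank), `rhos` (all genes), `selected` (post-correlation
#'   gene set), `dropped_missing_pli`, and the `params` used.
#' @examples
#' sim <- simulate_timecourse(n_genes = 50, n_tracking = 4, seed = 1)
#' scr <- dosage_screen(sim$timecourse, sim$protein, sim$constraint)
#' print(scr)
#' @export
dosage_screen <- function(timecourse, protein, constraint, panel = NULL,
                          rho_threshold = 0.75, pli_min = 0.9, alpha = 0.1) {
  rhos <- compute_dynamic_correlation(timecourse, protein)
  sel <- select_correlated(rhos, rho_threshold)
  dropped <- setdiff(sel, constraint$gene)
  cand <- withCallingHandlers(
    filter_by_constraint(sel, constraint, pli_min),
    warning = function(w) invokeRestart("muffleWarning"))
  pli <- constraint$pli[match(cand, constraint$gene)]
  if (length(cand)) {
    if (!is.null(panel)) {
      tallies <- lapply(cand, tally_cross_study, panel = panel, alpha = alpha)
      rep_df <- data.frame(
        gene = cand, rho = unname(rhos[cand]), pli = pli,
        n_significant = vapply(tallies, `[[`, 0L, "n_significant"),
        n_tested = vapply(tallies, `[[`, 0L, "n_tested"),
        n_concordant = vapply(tallies, `[[`, 0L, "n_concordant"),
        stringsAsFactors = FALSE)
    } else {
      rep_df <- data.frame(gene = cand, rho = unname(rhos[cand]), pli = pli,
                           n_significant = 0L, n_tested = NA_integer_,
                           n_concordant = 0L, stringsAsFactors = FALSE)
    }
    rep_df <- rank_candidates(rep_df)
  } else {
    rep_df <- data.frame(gene = character(0), rho = numeric(0),
                         pli = numeric(0), n_significant = integer(0),
                         n_tested = integer(0), n_concordant = integer(0),
                         rank = integer(0), stringsAsFactors = FALSE)
  }
  structure(list(candidates = rep_df, rhos = rhos, selected = sel,
                 dropped_missing_pli = dropped,
                 params = list(rho_threshold = rho_threshold,
                               pli_min = pli_min, alpha = alpha)),
            class = "dosage_screen")
}

#' @method print dosage_screen
#' @export
print.dosage_screen <- function(x, ...) {
  p <- x$params
  cat("Dosage-sensitivity screen\n")
  cat(sprintf("  %d genes correlated; %d with |rho| > %.2f; %d candidates after pLI > %.2f\n",
              length(x$rhos), length(x$selected), p$rho_threshold,
              nrow(x$candidates), p$pli_min))
  if (length(x$dropped_missing_pli))
    cat(sprintf("  dropped (no pLI): %s\n",
                paste(x$dropped_missing_pli, collapse = ", ")))
  if (nrow(x$candidates)) {
    cat("Ranked candidates:\n")
    print(x$candidates, row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' @method summary dosage_screen
#' @export
summary.dosage_screen <- function(object, ...) {
  c(n_genes = length(object$rhos),
    n_correlated = length(object$selected),
    n_candidates = nrow(object$candidates),
    n_undefined_rho = sum(is.na(object$rhos)))
}

# --- internal validators -----------------------------------------------------

validate_timecourse <- function(tc) {
  stopifnot(is.list(tc), !is.null(tc$gene_ids), !is.null(tc$timepoints),
            is.matrix(tc$values))
  if (anyDuplicated(tc$gene_ids)) stop("duplicate gene ids")
  if (is.unsorted(tc$timepoints, strictly = TRUE))
    stop("timepoints must be strictly increasing")
  if (!all(is.finite(tc$values))) stop("fold-change matrix contains non-finite values")
  if (nrow(tc$values) != length(tc$gene_ids) ||
      ncol(tc$values) != length(tc$timepoints))
    stop("fold-change matrix dimensions do not match gene/timepoint labels")
  invisible(tc)
}

validate_constraint_table <- function(table) {
  stopifnot(is.data.frame(table), all(c("gene", "pli") %in% names(table)))
  if (anyDuplicated(table$gene)) stop("constraint table has duplicate genes")
  ok <- !is.na(table$pli) & table$pli >= 0 & table$pli <= 1
  if (!all(ok)) stop("pLI values must lie in [0, 1]")
  invisible(table)
}
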