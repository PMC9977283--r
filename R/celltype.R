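#' Split neurons into excitatory and inhibitory by a marker threshold
#'
#' Coarsely partitions a set of neuronal cells on the raw count of a single
#' excitatory marker (Slc17a7/Vglut1 in mouse brain): cells with marker count
#' at or above `min_count` are labeled excitatory, all remaining neurons
#' inhibitory. The partition is exhaustive and disjoint over `neurons`.
#'
#' @param counts Cell counts object: list with `gene_ids`, `cell_ids` and
#'   `counts` (genes x cells matrix of non-negative integers; may be a sparse
#'   `Matrix`).
#' @param neurons Character vector of cell ids annotated as neurons.
#' @param rule Marker rule: list with `marker_gene` and `min_count`
#'   (inclusive threshold, default convention >= 5 counts).
#' @return Named character vector mapping each neuron to "excitatory" or
#'   "inhibitory".
#' @export
split_neurons <- function(counts, neurons, rule) {
  stopifnot(is.list(rule), !is.null(rule$marker_gene), rule$min_count >= 0)
  gi <- match(rule$marker_gene, counts$gene_ids)
  if (is.na(gi)) stop(sprintf("marker gene '%s' absent from the count matrix",
                              rule$marker_gene))
  ci <- match(neurons, counts$cell_ids)
  if (anyNA(ci)) stop("some neuron cell ids are absent from the count matrix")
  mk <- as.numeric(counts$counts[gi, ci])
  setNames(ifelse(mk >= rule$min_count, "excitatory", "inhibitory"), neurons)
}

#' Per-group Spearman correlation between two genes across cells
#'
#' Within each cell group, computes the Spearman rank correlation (average
#' ranks for ties) between the raw counts of `geneA` and `geneB` across that
#' group's cells, plus a pooled "all" value across every grouped cell. Raw
#' counts are used: Spearman's rank basis makes per-gene monotone scalings
#' (library-size or other normalizations applied per gene) irrelevant, and no
#' cell filtering is applied — all-zero cells carry rank information as ties.
#' A group in which either gene is constant has no defined rank correlation
#' and is reported with `rho = NA`.
#'
#' @param counts Cell counts object (see [split_neurons()]).
#' @param geneA,geneB Gene ids present in the matrix.
#' @param groups Named character vector mapping cell id to group label; cells
#'   not in the count matrix are an error, cells of the matrix absent from
#'   `groups` are ignored (unannotated).
#' @return data.frame with columns `group`, `n_cells`, `rho`, `defined`;
#'   one row per group label plus a final "all" row for the pooled cells.
#' @export
correlate_pair <- function(counts, geneA, geneB, groups) {
  ia <- match(geneA, counts$gene_ids); ib <- match(geneB, counts$gene_ids)
  if (is.na(ia) || is.na(ib))
    stop("both genes must be present in the count matrix")
  cells <- names(groups)
  ci <- match(cells, counts$cell_ids)
  if (anyNA(ci)) stop("annotated cells missing from the count matrix")
  a <- as.numeric(counts$counts[ia, ci])
  b <- as.numeric(counts$counts[ib, ci])
  one <- function(idx) {
    if (length(idx) == 0L) stop("empty cell group")
    x <- a[idx]; y <- b[idx]
    if (length(unique(x)) == 1L || length(unique(y)) == 1L)
      return(c(n = length(idx), rho = NA_real_))
    c(n = length(idx), rho = cor(rank(x), rank(y)))
  }
  labs <- sort(unique(unname(groups)))
  res <- lapply(labs, function(l) one(which(unname(groups) == l)))
  res <- c(res, list(one(seq_along(a))))
  data.frame(group = c(labs, "all"),
             n_cells = vapply(res, `[[`, 0, "n"),
             rho = vapply(res, `[[`, 0, "rho"),
             defined = !is.na(vapply(res, `[[`, 0, "rho")),
             stringsAsFactors = FALSE)
}
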