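# Shared TSV/BED/MTX readers and writers. All genomic coordinates are
# 0-based half-open (BED convention); numeric columns are written with 17
# significant digits so write-then-read round trips are exact.

read_tsv_checked <- function(path, required, what = "table") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   check.names = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(sprintf("%s '%s' is missing required column(s): %s",
                 what, path, paste(missing, collapse = ", ")))
  df
}

write_tsv <- function(df, path) {
  out <- df
  for (j in seq_along(out))
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a genes x timepoints log2 fold-change matrix
#'
#' TSV with a `gene` column and one numeric column per timepoint (column
#' names are the ages).
#'
#' @param path File path.
#' @return Time-course object (list: `gene_ids`, `timepoints`, `values`).
#' @export
read_fold_change_matrix <- function(path) {
  df <- read_tsv_checked(path, "gene", "fold-change matrix")
  tp <- as.numeric(names(df)[-1])
  if (anyNA(tp)) stop("fold-change matrix column names must be numeric timepoints")
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df$gene
  tc <- list(gene_ids = df$gene, timepoints = tp, values = m)
  validate_timecourse(tc)
}

#' @rdname read_fold_change_matrix
#' @param tc Time-course object.
#' @export
write_fold_change_matrix <- function(tc, path) {
  df <- data.frame(gene = tc$gene_ids, tc$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[-1] <- as.character(tc$timepoints)
  write_tsv(df, path)
}

#' Read / write a protein log2 fold-change trajectory
#'
#' TSV with columns `timepoint` and `log2fc`.
#' @param path File path.
#' @return Protein trajectory (list: `timepoints`, `values`).
#' @export
read_protein_trajectory <- function(path) {
  df <- read_tsv_checked(path, c("timepoint", "log2fc"), "protein trajectory")
  list(timepoints = as.numeric(df$timepoint), values = as.numeric(df$log2fc))
}

#' @rdname read_protein_trajectory
#' @param prot Protein trajectory.
#' @export
write_protein_trajectory <- function(prot, path) {
  write_tsv(data.frame(timepoint = prot$timepoints, log2fc = prot$values),
            path)
}

#' Read / write a gene constraint (pLI) table
#'
#' TSV with columns `gene` and `pli`.
#' @param path File path.
#' @return data.frame (`gene`, `pli`).
#' @export
read_constraint_table <- function(path) {
  df <- read_tsv_checked(path, c("gene", "pli"), "constraint table")
  validate_constraint_table(df[c("gene", "pli")])
}

#' @rdname read_constraint_table
#' @param table Constraint data.frame.
#' @export
write_constraint_table <- function(table, path) write_tsv(table, path)

#' Read one study's differential-expression table
#'
#' TSV with columns `gene`, `log2fc` (alias `log2FoldChange` accepted) and
#' `padj`; `padj` may contain NA for untested genes.
#' @param path File path.
#' @return data.frame (`gene`, `log2fc`, `padj`).
#' @export
read_de_table <- function(path) {
  df <- read_tsv_checked(path, "gene", "DE table")
  if (!"log2fc" %in% names(df) && "log2FoldChange" %in% names(df))
    names(df)[names(df) == "log2FoldChange"] <- "log2fc"
  missing <- setdiff(c("log2fc", "padj"), names(df))
  if (length(missing))
    stop(sprintf("DE table '%s' is missing required column(s): %s",
                 path, paste(missing, collapse = ", ")))
  ok <- is.na(df$padj) | (df$padj >= 0 & df$padj <= 1)
  if (!all(ok)) stop("padj values outside [0, 1]")
  df[c("gene", "log2fc", "padj")]
}

#' @rdname read_de_table
#' @param table DE data.frame.
#' @export
write_de_table <- function(table, path) write_tsv(table, path)

#' Read a study-panel manifest (YAML)
#'
#' YAML list of studies, each with `study_id`, `model_class` ("LOF"/"GOF"),
#' optional `tissue`, and `path` to the study's DE table (relative paths are
#' resolved against the manifest's directory).
#' @param path Manifest path.
#' @return List of study results ready for [tally_cross_study()].
#' @export
read_panel_manifest <- function(path) {
  man <- yaml::read_yaml(path)
  base <- dirname(path)
  lapply(man, function(st) {
    stopifnot(!is.null(st$study_id), st$model_class %in% c("LOF", "GOF"),
              !is.null(st$path))
    p <- if (startsWith(st$path, "/")) st$path else file.path(base, st$path)
    list(study_id = st$study_id, model_class = st$model_class,
         tissue = st$tissue %||% NA_character_, table = read_de_table(p))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read / write BED3 intervals
#'
#' Headerless, tab-separated, 0-based half-open; `start < end` enforced with
#' the offending line number.
#' @param path File path.
#' @return data.frame (`chrom`, `start`, `end`).
#' @export
read_bed3 <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- read.delim(path, header = FALSE, sep = "\t",
                   stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop(sprintf("BED file '%s' has fewer than 3 columns", path))
  df <- df[, 1:3]
  names(df) <- c("chrom", "start", "end")
  bad <- which(!is.finite(df$start) | !is.finite(df$end) |
                 df$start >= df$end | df$start < 0)
  if (length(bad))
    stop(sprintf("BED '%s': invalid interval at line %d (start >= end or negative)",
                 path, bad[1]))
  df
}

#' @rdname read_bed3
#' @param bed data.frame with chrom/start/end.
#' @export
write_bed3 <- function(bed, path) {
  write.table(bed[c("chrom", "start", "end")], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write a fragment BED-like TSV
#'
#' Headerless 5 columns: chrom, start, end, sample, genome
#' ("primary"/"spike"); coordinates 0-based half-open.
#' @param path File path.
#' @return Validated fragment data.frame.
#' @export
read_fragments <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- read.delim(path, header = FALSE, sep = "\t",
                   stringsAsFactors = FALSE)
  if (ncol(df) != 5L)
    stop(sprintf("fragment BED '%s' must have 5 columns (chrom, start, end, sample, genome)", path))
  names(df) <- c("chrom", "start", "end", "sample", "genome")
  bad <- which(df$start >= df$end)
  if (length(bad))
    stop(sprintf("fragment BED '%s': start >= end at line %d", path, bad[1]))
  validate_fragments(df)
}

#' @rdname read_fragments
#' @param fragments Fragment data.frame.
#' @export
write_fragments <- function(fragments, path) {
  write.table(fragments[c("chrom", "start", "end", "sample", "genome")],
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read / write single-cell counts (Matrix Market + row/col TSVs)
#'
#' `prefix.mtx` holds the sparse genes x cells matrix, `prefix.genes.tsv`
#' and `prefix.cells.tsv` the row and column ids (one per line, no header).
#' @param prefix Path prefix.
#' @return Cell counts object (list: `gene_ids`, `cell_ids`, `counts`).
#' @export
read_counts_mtx <- function(prefix) {
  m <- Matrix::readMM(paste0(prefix, ".mtx"))
  genes <- readLines(paste0(prefix, ".genes.tsv"))
  cells <- readLines(paste0(prefix, ".cells.tsv"))
  if (nrow(m) != length(genes) || ncol(m) != length(cells))
    stop("MTX dimensions do not match gene/cell id files")
  m <- as.matrix(m)
  dimnames(m) <- list(genes, cells)
  list(gene_ids = genes, cell_ids = cells, counts = m)
}

#' @rdname read_counts_mtx
#' @param counts Cell counts object.
#' @export
write_counts_mtx <- function(counts, prefix) {
  Matrix::writeMM(Matrix::Matrix(counts$counts, sparse = TRUE),
                  paste0(prefix, ".mtx"))
  writeLines(counts$gene_ids, paste0(prefix, ".genes.tsv"))
  writeLines(counts$cell_ids, paste0(prefix, ".cells.tsv"))
  invisible(prefix)
}

#' Read / write a cell annotation table
#'
#' TSV with columns `cell_id` and `class`.
#' @param path File path.
#' @return data.frame (`cell_id`, `class`).
#' @export
read_annotation <- function(path)
  read_tsv_checked(path, c("cell_id", "class"), "annotation")

#' @rdname read_annotation
#' @param ann Annotation data.frame.
#' @export
write_annotation <- function(ann, path) write_tsv(ann, path)

#' Read / write a qPCR Ct table
#'
#' TSV with columns `gene`, `sample`, `group`, `ct`, `detected`
#' (TRUE/FALSE); one row per technical replicate.
#' @param path File path.
#' @return data.frame.
#' @export
read_ct_table <- function(path) {
  df <- read_tsv_checked(path, c("gene", "sample", "group", "ct", "detected"),
                         "Ct table")
  df$detected <- as.logical(df$detected)
  bad <- df$detected & (!is.finite(df$ct) | df$ct <= 0)
  if (any(bad)) stop("detected wells must have positive finite Ct")
  df
}

#' @rdname read_ct_table
#' @param table Ct data.frame.
#' @export
write_ct_table <- function(table, path) write_tsv(table, path)

#' Read / write a stereology sections table
#'
#' TSV with columns `section_id`, `Q`, `area`, `t`, `h`, `asf`, `ssf`
#' (sampling parameters repeated per row).
#' @param path File path.
#' @return Section counts object for [estimate_total_cells()].
#' @export
read_sections <- function(path) {
  df <- read_tsv_checked(path, c("section_id", "Q", "area", "t", "h",
                                 "asf", "ssf"), "sections table")
  list(Q = as.numeric(df$Q), t = df$t[1], h = df$h[1], asf = df$asf[1],
       ssf = df$ssf[1], bilateral_factor = 2,
       section_ids = df$section_id, areas = as.numeric(df$area))
}

#' @rdname read_sections
#' @param s Section counts object.
#' @export
write_sections <- function(s, path) {
  write_tsv(data.frame(section_id = s$section_ids, Q = s$Q, area = s$areas,
                       t = s$t, h = s$h, asf = s$asf, ssf = s$ssf), path)
}
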