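# Config-driven orchestration of the full screen. A single global seed is
# fanned out to per-stage child seeds with a fixed affine splitting scheme so
# each stage is reproducible independently of which other stages run.

PIPELINE_STAGES <- c("simulate", "screen", "celltype", "cutrun",
                     "stereology", "qpcr")

DEFAULT_THRESHOLDS <- list(rho_threshold = 0.75, pli_min = 0.9, alpha = 0.1,
                           halfwidth = 3500, marker_min = 5,
                           spike_constant = 10000, pseudo_count = 0.5)

#' Derive a per-stage child seed from the global seed
#'
#' Fixed affine split `(seed * 131 + 7 * stage_index) mod (2^31 - 1)`;
#' documented so external tooling can reproduce any single stage.
#' @param seed Global integer seed.
#' @param stage_index 1-based index of the stage in the canonical order.
#' @return Integer child seed.
#' @export
child_seed <- function(seed, stage_index) {
  as.integer((as.numeric(seed) * 131 + 7 * stage_index) %% (2^31 - 1))
}

#' Validate a pipeline run configuration
#'
#' Checks stage names, threshold ranges and key spelling; unknown keys are
#' rejected. Raises a condition of class `dosagescreen_validation_error`
#' naming the offending field.
#'
#' @param config Configuration list (see [run_pipeline()]).
#' @return The config with defaults filled in, invisibly usable.
#' @export
validate_config <- function(config) {
  fail <- function(msg) stop(structure(
    class = c("dosagescreen_validation_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))))
  known <- c("seed", "out_dir", "stages", "thresholds", "inputs", "simulate")
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    fail(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  if (is.null(config$out_dir)) fail("config field 'out_dir' is required")
  if (is.null(config$seed)) config$seed <- 1L
  if (is.null(config$stages)) config$stages <- PIPELINE_STAGES
  bad <- setdiff(config$stages, PIPELINE_STAGES)
  if (length(bad)) fail(sprintf("unknown stage(s): %s", paste(bad, collapse = ", ")))
  th <- modifyList(DEFAULT_THRESHOLDS, config$thresholds %||% list())
  extra <- setdiff(names(th), names(DEFAULT_THRESHOLDS))
  if (length(extra))
    fail(sprintf("unknown threshold(s): %s", paste(extra, collapse = ", ")))
  rng <- list(rho_threshold = c(0, 1), pli_min = c(0, 1), alpha = c(0, 1),
              halfwidth = c(1, Inf), marker_min = c(0, Inf),
              spike_constant = c(0, Inf), pseudo_count = c(0, Inf))
  for (k in names(rng)) {
    v <- th[[k]]
    if (!is.numeric(v) || length(v) != 1L || v < rng[[k]][1] || v > rng[[k]][2])
      fail(sprintf("threshold '%s' = %s is outside its valid range [%s, %s]",
                   k, format(v), rng[[k]][1], rng[[k]][2]))
  }
  config$thresholds <- th
  config
}

#' Run the configured screening pipeline
#'
#' Executes the requested stages in dependency order (simulate, screen,
#' celltype, cutrun, stereology, qpcr), writing every stage's outputs under
#' `out_dir` plus a machine-readable `run_report.json`. Explicit input paths
#' in `config$inputs` take precedence; otherwise stages read the files the
#' simulate stage wrote. Re-running with an identical config and seed
#' reproduces byte-identical outputs. On error, files created by the failing
#' run are removed.
#'
#' @param config Configuration list or path to a YAML file with fields
#'   `seed`, `out_dir`, `stages`, `thresholds` (rho_threshold, pli_min,
#'   alpha, halfwidth, marker_min, spike_constant, pseudo_count), `inputs`
#'   (per-stage file paths and labels) and `simulate` (per-dataset generator
#'   parameters).
#' @return Run report (list), invisibly; also serialized to
#'   `out_dir/run_report.json`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- validate_config(config)
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  th <- config$thresholds
  created <- character(0)
  reg <- function(...) {
    p <- file.path(out_dir, ...)
    created <<- c(created, p)
    p
  }
  report <- list(version = as.character(utils::packageVersion("dosagescreen")),
                 seed = config$seed, parameters = th, stages = list())
  sim_paths <- list()
  run_stage <- function(name, fun) {
    warnings <- character(0)
    res <- withCallingHandlers(fun(), warning = function(w) {
      warnings <<- c(warnings, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
    report$stages[[name]] <<- c(list(status = "ok", warnings = warnings), res)
  }
  inp <- function(key, default = NULL) config$inputs[[key]] %||%
    sim_paths[[key]] %||% default

  tryCatch({
    for (stage in intersect(PIPELINE_STAGES, config$stages)) {
      si <- match(stage, PIPELINE_STAGES)
      seed_s <- child_seed(config$seed, si)
      if (stage == "simulate") run_stage("simulate", function() {
        sim_dir <- file.path(out_dir, "sim")
        dir.create(sim_dir, showWarnings = FALSE)
        sp <- config$simulate %||% list()
        n_out <- 0L
        if (!is.null(sp$timecourse)) {
          s <- do.call(simulate_timecourse,
                       modifyList(sp$timecourse, list(seed = seed_s)))
          write_fold_change_matrix(s$timecourse, reg("sim", "timecourse.tsv"))
          write_protein_trajectory(s$protein, reg("sim", "protein.tsv"))
          write_constraint_table(s$constraint, reg("sim", "pli.tsv"))
          jsonlite::write_json(s$truth, reg("sim", "truth_timecourse.json"),
                               auto_unbox = TRUE, digits = NA)
          sim_paths$timecourse <<- file.path(sim_dir, "timecourse.tsv")
          sim_paths$protein <<- file.path(sim_dir, "protein.tsv")
          sim_paths$pli <<- file.path(sim_dir, "pli.tsv")
          n_out <- n_out + 4L
        }
        if (!is.null(sp$panel)) {
          s <- do.call(simulate_study_panel,
                       modifyList(sp$panel, list(seed = seed_s + 1L)))
          pdir <- file.path(sim_dir, "panel")
          dir.create(pdir, showWarnings = FALSE)
          man <- lapply(s$panel, function(st) {
            f <- paste0(st$study_id, ".tsv")
            write_de_table(st$table, reg("sim", "panel", f))
            list(study_id = st$study_id, model_class = st$model_class,
                 path = f)
          })
          yaml::write_yaml(man, reg("sim", "panel", "manifest.yaml"))
          jsonlite::write_json(s$truth, reg("sim", "truth_panel.json"),
                               auto_unbox = TRUE, digits = NA)
          sim_paths$panel_manifest <<- file.path(pdir, "manifest.yaml")
          n_out <- n_out + length(man) + 2L
        }
        if (!is.null(sp$cells)) {
          args <- sp$cells
          args$n_cells_per_class <- unlist(args$n_cells_per_class)
          s <- do.call(simulate_cells, modifyList(args, list(seed = seed_s + 2L)))
          write_counts_mtx(s$counts, file.path(sim_dir, "cells"))
          created <<- c(created, file.path(sim_dir, paste0("cells",
                        c(".mtx", ".genes.tsv", ".cells.tsv"))))
          write_annotation(s$annotation, reg("sim", "annotation.tsv"))
          jsonlite::write_json(s$truth, reg("sim", "truth_cells.json"),
                               auto_unbox = TRUE, digits = NA)
          sim_paths$counts_prefix <<- file.path(sim_dir, "cells")
          sim_paths$annotation <<- file.path(sim_dir, "annotation.tsv")
          n_out <- n_out + 5L
        }
        if (!is.null(sp$fragments)) {
          args <- sp$fragments
          if (is.null(args$windows)) {
            n_w <- args$n_windows %||% 5L
            centers <- seq(1e5, 9e5, length.out = n_w)
            args$windows <- lapply(seq_len(n_w), function(i) list(
              chrom = "chr1", start = centers[i] - 100, end = centers[i] + 100,
              id = sprintf("peak%02d", i)))
          }
          args$n_windows <- NULL
          peaks <- data.frame(
            chrom = vapply(args$windows, `[[`, "", "chrom"),
            start = vapply(args$windows, function(w) as.numeric(w$start), 0),
            end = vapply(args$windows, function(w) as.numeric(w$end), 0))
          hw <- th$halfwidth
          args$windows <- lapply(args$windows, expand_peak, halfwidth = hw)
          s <- do.call(simulate_fragments,
                       modifyList(args, list(seed = seed_s + 3L)))
          write_fragments(s$fragments, reg("sim", "fragments.bed"))
          write_bed3(peaks, reg("sim", "peaks.bed"))
          jsonlite::write_json(
            list(genotype_of = as.list(s$genotype_of),
                 enrichment = as.data.frame(s$truth$enrichment)),
            reg("sim", "truth_fragments.json"), auto_unbox = TRUE, digits = NA)
          sim_paths$fragments <<- file.path(sim_dir, "fragments.bed")
          sim_paths$peaks <<- file.path(sim_dir, "peaks.bed")
          sim_paths$genotypes <<- as.list(s$genotype_of)
          n_out <- n_out + 3L
        }
        if (!is.null(sp$sections)) {
          s <- do.call(simulate_sections,
                       modifyList(sp$sections, list(seed = seed_s + 4L)))
          write_sections(s$sections, reg("sim", "sections.tsv"))
          jsonlite::write_json(s$truth, reg("sim", "truth_sections.json"),
                               auto_unbox = TRUE, digits = NA)
          sim_paths$sections <<- file.path(sim_dir, "sections.tsv")
          n_out <- n_out + 2L
        }
        list(files_out = n_out)
      })
      if (stage == "screen") run_stage("screen", function() {
        tc <- read_fold_change_matrix(inp("timecourse"))
        prot <- read_protein_trajectory(inp("protein"))
        constraint <- read_constraint_table(inp("pli"))
        panel <- if (!is.null(inp("panel_manifest")))
          read_panel_manifest(inp("panel_manifest")) else NULL
        scr <- dosage_screen(tc, prot, constraint, panel,
                             rho_threshold = th$rho_threshold,
                             pli_min = th$pli_min, alpha = th$alpha)
        write_tsv(scr$candidates, reg("candidates.tsv"))
        jsonlite::write_json(
          list(summary = as.list(summary(scr)),
               dropped_missing_pli = scr$dropped_missing_pli),
          reg("screen_summary.json"), auto_unbox = TRUE, digits = NA)
        list(rows_in = length(tc$gene_ids), rows_out = nrow(scr$candidates),
             dropped = scr$dropped_missing_pli)
      })
      if (stage == "celltype") run_stage("celltype", function() {
        cc <- read_counts_mtx(inp("counts_prefix"))
        ann <- read_annotation(inp("annotation"))
        pars <- config$inputs$celltype %||% list()
        ga <- pars$gene_a %||% "Gdf11"; gb <- pars$gene_b %||% "Mecp2"
        marker <- pars$marker %||% "Slc17a7"
        groups <- setNames(ann$class, ann$cell_id)
        neurons <- ann$cell_id[ann$class == "neuron"]
        if (length(neurons)) {
          split <- split_neurons(cc, neurons,
                                 list(marker_gene = marker,
                                      min_count = th$marker_min))
          groups[names(split)] <- paste0("neuron_", split)
        }
        res <- correlate_pair(cc, ga, gb, groups)
        write_tsv(res, reg("celltype_corr.tsv"))
        list(rows_in = length(cc$cell_ids), rows_out = nrow(res))
      })
      if (stage == "cutrun") run_stage("cutrun", function() {
        frags <- read_fragments(inp("fragments"))
        peaks <- read_bed3(inp("peaks"))
        windows <- lapply(seq_len(nrow(peaks)), function(i)
          expand_peak(peaks[i, ], halfwidth = th$halfwidth))
        genos <- unlist(inp("genotypes"))
        libs <- tabulate_libraries(frags, genos)
        tab <- count_fragments(frags, windows)
        norm <- normalize_occupancy(tab, libs, C = th$spike_constant)
        occ <- data.frame(window = tab$window_ids, tab$counts,
                          check.names = FALSE)
        names(occ)[-1] <- paste0("raw_", tab$samples)
        occ <- cbind(occ, setNames(as.data.frame(norm),
                                   paste0("norm_", tab$samples)))
        write_tsv(occ, reg("occupancy.tsv"))
        contrast <- unlist(config$inputs$contrast %||% c("KO", "WT"))
        diff <- differential_occupancy(tab, libs, contrast,
                                       c0 = th$pseudo_count)
        write_tsv(as.data.frame(diff), reg("differential.tsv"))
        list(rows_in = nrow(frags), rows_out = nrow(diff),
             contrast = contrast)
      })
      if (stage == "stereology") run_stage("stereology", function() {
        s <- read_sections(inp("sections"))
        N <- estimate_total_cells(s)
        dens <- cell_density(N, s$areas, s$t, s$ssf)
        write_tsv(data.frame(total_cells = N, density_per_mm3 = dens),
                  reg("stereology.tsv"))
        list(rows_in = length(s$Q), rows_out = 1L)
      })
      if (stage == "qpcr") run_stage("qpcr", function() {
        ct <- read_ct_table(inp("ct_table"))
        pars <- config$inputs$qpcr %||% list()
        res <- ddct_relative_expression(
          ct, target = pars$target %||% "Gdf11",
          reference = pars$reference %||% "Ppia",
          control_group = pars$control_group %||% "control")
        write_tsv(res, reg("qpcr.tsv"))
        list(rows_in = nrow(ct), rows_out = nrow(res))
      })
    }
  }, error = function(e) {
    unlink(created)
    stop(e)
  })
  jsonlite::write_json(report, file.path(out_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
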