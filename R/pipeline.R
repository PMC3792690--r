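# End-to-end orchestration: filter -> replicate consensus -> control screen
# -> gene assignment -> TSS profile -> DE summary -> overlap enrichment.

#' Pipeline configuration
#'
#' @param repA,repB Paths to the two treatment-replicate peak files
#'   (narrowPeak or BED6).
#' @param controls Character vector of negative-control peak file paths.
#' @param gtf Path to the gene annotation (GTF).
#' @param de_table Path to the differential-expression TSV.
#' @param outdir Output directory.
#' @param thresholds A [chirp_thresholds()] object.
#' @param window_mode Replication-window semantics, `"gap"` or `"summit"`.
#' @param representative Consensus interval, `"anchor"` or `"union"`.
#' @param exclude_control_proximal Use only the control-specific subset for
#'   gene assignment and enrichment (default TRUE).
#' @param gene_dist_mode `"gene_body"` or `"midpoint_tss"` (see
#'   [assign_closest_gene()]).
#' @param yates Apply the Yates continuity correction to the chi-squared
#'   test.
#' @param check_paths Verify that the input paths exist (default TRUE).
#' @return An object of class `PipelineConfig`.
#' @export
pipeline_config <- function(repA, repB, controls, gtf, de_table,
                            outdir = "chirpflow_out",
                            thresholds = chirp_thresholds(),
                            window_mode = c("gap", "summit"),
                            representative = c("anchor", "union"),
                            exclude_control_proximal = TRUE,
                            gene_dist_mode = c("gene_body", "midpoint_tss"),
                            yates = FALSE, check_paths = TRUE) {
  cfg <- list(repA = repA, repB = repB, controls = controls, gtf = gtf,
              de_table = de_table, outdir = outdir,
              thresholds = thresholds,
              window_mode = match.arg(window_mode),
              representative = match.arg(representative),
              exclude_control_proximal = isTRUE(exclude_control_proximal),
              gene_dist_mode = match.arg(gene_dist_mode),
              yates = isTRUE(yates))
  if (!inherits(thresholds, "chirp_thresholds")) {
    stop("thresholds must be a chirp_thresholds() object", call. = FALSE)
  }
  if (!length(controls)) stop("at least one control peak file is required",
                              call. = FALSE)
  if (check_paths) {
    paths <- c(repA, repB, controls, gtf, de_table)
    miss <- paths[!file.exists(paths)]
    if (length(miss)) {
      stop("input path(s) not found: ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
  }
  structure(cfg, class = "PipelineConfig")
}

#' Read a pipeline configuration from JSON
#'
#' Expects the layout written by [write_synthetic_dataset()] /
#' [chirp_cli()]: paths `repA`, `repB`, `controls`, `gtf`, `de_table`,
#' `outdir` plus an optional flat `thresholds` block and mode flags.
#'
#' @param path JSON file path.
#' @return A `PipelineConfig`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  th <- do.call(chirp_thresholds, as.list(j$thresholds))
  # relative paths are resolved against the config file's directory
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base, p))
  }
  pipeline_config(
    repA = resolve(j$repA), repB = resolve(j$repB),
    controls = resolve(unlist(j$controls)),
    gtf = resolve(j$gtf), de_table = resolve(j$de_table),
    outdir = resolve(if (is.null(j$outdir)) "chirpflow_out" else j$outdir),
    thresholds = th,
    window_mode = if (is.null(j$window_mode)) "gap" else j$window_mode,
    representative = if (is.null(j$representative)) "anchor" else j$representative,
    exclude_control_proximal = is.null(j$exclude_control_proximal) ||
      isTRUE(j$exclude_control_proximal),
    gene_dist_mode = if (is.null(j$gene_dist_mode)) "gene_body" else j$gene_dist_mode,
    yates = isTRUE(j$yates))
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the ChIRP downstream analysis on in-memory objects
#'
#' The stage order is: quality-filter every sample, find peaks replicated
#' between the two treatment replicates within the replication window,
#' flag consensus peaks near pooled control peaks, assign the remaining
#' (by default control-specific) peaks to their closest gene within the
#' gene window, profile peak positions relative to TSSs, summarize the DE
#' table, and test ChIRP-gene / DE-gene overlap with a chi-squared test
#' over the universe of annotated genes that were tested for differential
#' expression.
#'
#' @param repA,repB `PeakSet`s of the treatment replicates.
#' @param controls List of control `PeakSet`s.
#' @param annotation A `GeneAnnotation`.
#' @param de DE data frame (`gene_id`, `log2fc`, `qvalue`).
#' @param thresholds A [chirp_thresholds()] object.
#' @param window_mode,representative,exclude_control_proximal,gene_dist_mode,yates
#'   See [pipeline_config()].
#' @return List of stage results: `filtered` (named list of `PeakSet`s),
#'   `consensus` (`ConsensusResult`), `used_peaks`, `assignments`,
#'   `gene_set`, `tss_profile`, `de_summary`, `universe`, `contingency`,
#'   `enrichment`, `overlap`, and the machine-readable `report` list.
#' @export
run_chirp_analysis <- function(repA, repB, controls, annotation, de,
                               thresholds = chirp_thresholds(),
                               window_mode = "gap",
                               representative = "anchor",
                               exclude_control_proximal = TRUE,
                               gene_dist_mode = "gene_body",
                               yates = FALSE) {
  samples <- c(list(repA, repB), controls)
  filtered <- .stage("filter_peaks",
                     lapply(samples, filter_peaks, thresholds = thresholds))
  names(filtered) <- vapply(samples, function(s) s$label, character(1))
  for (i in seq_along(samples)) {
    message(sprintf("filter_peaks[%s]: %d -> %d peaks",
                    samples[[i]]$label, n_peaks(samples[[i]]),
                    n_peaks(filtered[[i]])))
  }
  fA <- filtered[[1]]; fB <- filtered[[2]]
  fCtrl <- filtered[-(1:2)]
  cons <- .stage("replicate_consensus",
                 replicate_consensus(fA, fB,
                                     window = thresholds$replication_window,
                                     mode = window_mode,
                                     representative = representative))
  message(sprintf("replicate_consensus: %d replicated peaks",
                  cons$n_replicated))
  cons <- .stage("flag_control_proximity",
                 flag_control_proximity(cons, fCtrl,
                                        window = thresholds$control_window))
  message(sprintf("flag_control_proximity: %d control-proximal, %d specific",
                  cons$n_control_proximal,
                  cons$n_replicated - cons$n_control_proximal))
  used <- if (exclude_control_proximal) specific_peaks(cons) else cons$consensus
  assign <- .stage("assign_closest_gene",
                   assign_closest_gene(used, annotation,
                                       max_dist = thresholds$gene_max_dist,
                                       mode = gene_dist_mode))
  gene_set <- chirp_gene_set(assign)
  message(sprintf("assign_closest_gene: %d/%d peaks assigned, %d genes",
                  sum(!is.na(assign$gene_id)), nrow(assign),
                  length(gene_set)))
  profile <- .stage("tss_distance_profile",
                    tss_distance_profile(used, annotation))
  des <- .stage("de_summary", de_summary(de, alpha = thresholds$de_alpha))
  message(sprintf("de_summary: %d/%d significant (%.1f%% up)",
                  des$n_significant, des$n_tested,
                  ifelse(des$frac_up_defined, des$frac_up, NA)))
  universe <- .stage("overlap_counts",
                     intersect(annotation$genes$gene_id, de$gene_id))
  chirp_in_universe <- intersect(gene_set, universe)
  sig_in_universe <- intersect(des$significant_genes, universe)
  tab <- .stage("overlap_counts",
                overlap_counts(chirp_in_universe, sig_in_universe, universe))
  enr <- .stage("chi_squared_2x2", chi_squared_2x2(tab, correct = yates))
  ovl <- if (length(chirp_in_universe) > 0) {
    overlap_percentage(tab$a, length(chirp_in_universe))
  } else list(percent = NA_real_, rounded = NA_real_)
  message(sprintf(
    "enrichment: a=%d chi2=%.3g p=%.3g; overlap %.1f%% of ChIRP genes",
    tab$a, enr$chi2, enr$pvalue, ovl$percent))
  report <- list(
    version = as.character(utils::packageVersion("chirpflow")),
    thresholds = unclass(thresholds),
    options = list(window_mode = window_mode,
                   representative = representative,
                   exclude_control_proximal = exclude_control_proximal,
                   gene_dist_mode = gene_dist_mode, yates = yates),
    samples = lapply(seq_along(samples), function(i) list(
      label = samples[[i]]$label, role = samples[[i]]$role,
      n_in = n_peaks(samples[[i]]), n_after_filter = n_peaks(filtered[[i]]))),
    n_replicated = cons$n_replicated,
    n_control_proximal = cons$n_control_proximal,
    n_specific = cons$n_replicated - cons$n_control_proximal,
    n_controls_within_window = cons$n_controls_within_window,
    n_peaks_used = nrow(used),
    n_genes_assigned = sum(!is.na(assign$gene_id)),
    n_chirp_genes = length(gene_set),
    tss_profile = list(bins = profile$bins,
                       counts = unname(profile$counts),
                       n_total = profile$n_total,
                       n_excluded = profile$n_excluded),
    de_summary = list(n_tested = des$n_tested,
                      n_significant = des$n_significant,
                      n_up = des$n_up, n_down = des$n_down,
                      n_zero = des$n_zero, frac_up = des$frac_up),
    universe = list(size = length(universe),
                    n_chirp_in_universe = length(chirp_in_universe),
                    n_chirp_outside_universe =
                      length(gene_set) - length(chirp_in_universe)),
    contingency = list(a = tab$a, b = tab$b, c = tab$c, d = tab$d),
    enrichment = list(chi2 = enr$chi2, df = enr$df, pvalue = enr$pvalue,
                      odds_ratio = enr$odds_ratio,
                      low_expected_warning = enr$low_expected_warning),
    overlap_percentage = ovl$percent,
    overlap_percentage_rounded = ovl$rounded
  )
  list(filtered = filtered, consensus = cons, used_peaks = used,
       assignments = assign, gene_set = gene_set, tss_profile = profile,
       de_summary = des, universe = universe, contingency = tab,
       enrichment = enr, overlap = ovl, report = report)
}

#' Run the full pipeline from files
#'
#' Reads the inputs named in `config`, runs [run_chirp_analysis()], and
#' writes `consensus.bed`, `specific.bed`, `peak_gene.tsv`,
#' `chirp_genes.txt`, `tss_profile.tsv`, `de_summary.json`,
#' `enrichment.json` and `report.json` into `config$outdir`. The report
#' carries no timestamps, so repeated runs on identical inputs produce
#' identical files.
#'
#' @param config A `PipelineConfig` (see [pipeline_config()] /
#'   [read_pipeline_config()]).
#' @return The report list, invisibly.
#' @export
run_pipeline <- function(config) {
  repA <- .stage("read_peaks", read_narrowpeak(config$repA, label = "repA"))
  repB <- .stage("read_peaks", read_narrowpeak(config$repB, label = "repB"))
  controls <- .stage("read_peaks", lapply(seq_along(config$controls),
    function(i) read_narrowpeak(config$controls[i],
                                label = paste0("ctrl", i), role = "control")))
  annotation <- .stage("read_gtf", read_gtf(config$gtf))
  de <- .stage("read_de_table", read_de_table(config$de_table))
  res <- run_chirp_analysis(
    repA, repB, controls, annotation, de,
    thresholds = config$thresholds,
    window_mode = config$window_mode,
    representative = config$representative,
    exclude_control_proximal = config$exclude_control_proximal,
    gene_dist_mode = config$gene_dist_mode,
    yates = config$yates)
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_bed(res$consensus$consensus, file.path(outdir, "consensus.bed"))
  write_bed(specific_peaks(res$consensus), file.path(outdir, "specific.bed"))
  utils::write.table(res$assignments, file.path(outdir, "peak_gene.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(res$gene_set, file.path(outdir, "chirp_genes.txt"))
  write_tss_profile(res$tss_profile, file.path(outdir, "tss_profile.tsv"))
  jsonlite::write_json(res$report$de_summary,
                       file.path(outdir, "de_summary.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  jsonlite::write_json(c(res$report$contingency, res$report$enrichment),
                       file.path(outdir, "enrichment.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  jsonlite::write_json(res$report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  invisible(res$report)
}
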