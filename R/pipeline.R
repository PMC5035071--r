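#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end run.  Defaults are the standard
#' operating point: k = 5, LMR length filter 200 bp-3 kb, RP cutoff grid
#' around 0.95, LN cutoff 0.15, 5-fold CV, 5% coverage cap, 2 kb windows
#' stepped every 500 bp, TPM rule 1 kb, TSS rule 2.5 kb.
#'
#' @param k,canonical K-mer encoding parameters.
#' @param min_len,max_len Inclusive LMR length filter in bp.
#' @param delta_grid RP-cutoff grid for model selection.
#' @param ln_quantile LN cutoff.
#' @param weight_grid List of [wsvm_weights()].
#' @param folds CV folds.
#' @param coverage_cap Proxy-coverage cap (0.05 default; 0.10 / 0.15 are
#'   looser presets).
#' @param tie_tol F-score tie tolerance in model selection.
#' @param window,step Scan geometry in bp.
#' @param tpm_bp,tss_bp,tss_exclusion_bp Validation distance thresholds.
#' @param proxy_chrom Coverage proxy chromosome (default: first in genome).
#' @param var_explained PCA variance kept when fitting the anchor density.
#' @param svm_tol SVM stopping tolerance.
#' @param max_tries Rejection-sampling cap for negative placement.
#' @param split_at_negative Split merged enhancers at negative windows.
#' @param seed Master seed; stage seeds are derived from it.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(k = 5, canonical = FALSE, min_len = 200,
                            max_len = 3000,
                            delta_grid = c(0.90, 0.95, 0.99),
                            ln_quantile = 0.15,
                            weight_grid = default_weight_grid(),
                            folds = 5, coverage_cap = 0.05,
                            tie_tol = 0.005, window = 2000, step = 500,
                            tpm_bp = 1000, tss_bp = 2500,
                            tss_exclusion_bp = 1000, proxy_chrom = NULL,
                            var_explained = 0.95, svm_tol = 1e-6,
                            max_tries = 2000, split_at_negative = TRUE,
                            seed = 1L) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full enhancer-prediction pipeline
#'
#' Chains every stage: length-filter the LMRs, find the validated-enhancer
#' anchors among them, encode in k-mer space, fit the anchor density and
#' rank all LMRs, shuffle out a background (RN) set, select the partition
#' cutoff and SVM weights by cross-validation under the coverage cap, scan
#' the genome, merge positive windows into enhancers, and validate the
#' representative windows against the marker, CAGE-enhancer and
#' conservation tracks.
#'
#' @param inputs A [simulate_enhancer_genome()] result, a
#'   [read_simulation()] list, or any list with `genome`, `lmrs`, `vista`,
#'   `exons`, `tss`, `dhs`, `p300`, `tf` and optionally `fantom`,
#'   `conserved`, `truth`.
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory: predictions, reports and a run
#'   manifest are written there.
#' @return An `lmr_pipeline` list with the ranked LMRs, negatives,
#'   selection, scored windows, enhancers, validation and a `report` tibble
#'   of headline numbers.
#' @export
run_pipeline <- function(inputs, config = pipeline_config(),
                         out_dir = NULL) {
  genome <- inputs$genome
  proxy <- config$proxy_chrom %||% names(genome)[1]

  lmrs <- filter_by_length(inputs$lmrs, config$min_len, config$max_len)
  x_lmr <- encode_kmers(extract_sequences(genome, lmrs), k = config$k,
                        canonical = config$canonical)
  valid <- attr(x_lmr, "valid")
  if (!all(valid)) {
    warn(paste0(sum(!valid), " LMR(s) had no valid k-mer; dropped"))
    lmrs <- lmrs[valid, , drop = FALSE]
    x_lmr <- x_lmr[valid, , drop = FALSE]
  }

  anchor_rows <- overlap_select(
    dplyr::mutate(lmrs, .row = dplyr::row_number()), inputs$vista,
    min_bp = 1)
  if (nrow(anchor_rows) < 5)
    abort("fewer than 5 LMRs overlap the validated-enhancer track")
  dens <- fit_kmer_density(x_lmr[anchor_rows$.row, , drop = FALSE],
                           var_explained = config$var_explained)
  ranked <- rank_by_density(dens, lmrs, x_lmr)

  negatives <- generate_negatives(
    lmrs, genome,
    exclusions = dplyr::bind_rows(
      inputs$exons[c("chrom", "start", "end")],
      lmrs[c("chrom", "start", "end")]),
    seed = config$seed + 1L, max_tries = config$max_tries)
  rn_x <- encode_kmers(extract_sequences(genome, negatives), k = config$k,
                       canonical = config$canonical)

  sel <- select_wsvm(ranked, x_lmr, rn_x, genome, proxy,
                     delta_grid = config$delta_grid,
                     weight_grid = config$weight_grid,
                     ln_quantile = config$ln_quantile,
                     folds = config$folds,
                     coverage_cap = config$coverage_cap,
                     tie_tol = config$tie_tol, window = config$window,
                     step = config$step, k = config$k,
                     canonical = config$canonical, tol = config$svm_tol,
                     seed = config$seed + 2L)

  windows <- scan_genome(sel$model, genome, window = config$window,
                         step = config$step, k = config$k,
                         canonical = config$canonical)
  enhancers <- merge_windows(windows,
                             split_at_negative = config$split_at_negative)
  reps <- representatives(enhancers)

  tpm <- build_tpm(inputs$dhs, inputs$p300, inputs$tf, inputs$tss,
                   tss_exclusion_bp = config$tss_exclusion_bp)
  validation <- categorize_enhancers(reps, tpm$tpm, inputs$tss,
                                     tpm_bp = config$tpm_bp,
                                     tss_bp = config$tss_bp)
  vw <- validation$windows
  states <- if (any(vw$category == "validated"))
    marker_states(vw[vw$category == "validated", , drop = FALSE],
                  tpm$dhs, tpm$p300, tpm$tf, tpm_bp = config$tpm_bp)
  else factor(character(), levels = c("p300+/-DHS", "DHS only", "TF+DHS",
                                      "TF only", "TF+p300", "p300+DHS+TF"))

  fantom_rate <- if (!is.null(inputs$fantom))
    fantom_overlap_rate(reps, inputs$fantom) else NA_real_
  conserved_rate <- if (!is.null(inputs$conserved))
    conserved_midpoint_rate(reps, inputs$conserved, inputs$exons)
  else NA_real_

  recovery <- if (!is.null(inputs$truth) && nrow(inputs$truth) > 0)
    recovery_metrics(reps, inputs$truth) else NULL

  coverage <- genome_coverage_fraction(enhancers, genome)
  gc_summary <- tibble(
    track = c("lmr", "negative", "predicted"),
    median_gc = c(stats::median(gc_content(extract_sequences(genome, lmrs))),
                  stats::median(gc_content(extract_sequences(genome,
                                                             negatives))),
                  if (nrow(reps) > 0)
                    stats::median(gc_content(extract_sequences(genome,
                                                               reps)))
                  else NA_real_))

  pct <- function(cat) {
    i <- validation$summary$category == cat
    if (any(i)) validation$summary$pct[i] else 0
  }
  report <- tibble(
    n_lmrs = nrow(lmrs), n_anchors = nrow(anchor_rows),
    delta = sel$delta, cv_f = sel$metrics$f,
    cv_precision = sel$metrics$precision,
    n_enhancer_windows = sum(windows$score > 0),
    n_enhancers = nrow(enhancers),
    genomic_coverage = coverage,
    validated_pct = pct("validated"),
    misclassified_pct = pct("misclassified"),
    unknown_pct = pct("unknown"),
    fantom_overlap_pct = 100 * fantom_rate,
    conserved_pct = 100 * conserved_rate,
    recovery_f = if (!is.null(recovery)) recovery$f else NA_real_)

  out <- structure(
    list(lmrs = lmrs, ranked = ranked, negatives = negatives,
         selection = sel, windows = windows, enhancers = enhancers,
         representatives = reps, tpm = tpm, validation = validation,
         states = states, recovery = recovery, gc_summary = gc_summary,
         report = report, config = config),
    class = "lmr_pipeline")
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir, inputs)
  out
}

#' Recovery of planted enhancers by representative windows
#'
#' Precision is the fraction of representative windows overlapping a true
#' enhancer by >= 1 bp; recall is the fraction of true enhancers overlapped
#' by some representative window.
#'
#' @param reps Representative windows.
#' @param truth True enhancer intervals.
#' @return One-row tibble: `tp`, `n_pred`, `n_truth`, `precision`,
#'   `recall`, `f`.
#' @export
recovery_metrics <- function(reps, truth) {
  n_pred <- nrow(reps); n_truth <- nrow(truth)
  if (n_pred == 0 || n_truth == 0)
    return(tibble(tp = 0, n_pred = n_pred, n_truth = n_truth,
                  precision = 0, recall = 0, f = 0))
  tp_pred <- nrow(overlap_select(reps, truth))
  tp_truth <- nrow(overlap_select(truth, reps))
  precision <- tp_pred / n_pred
  recall <- tp_truth / n_truth
  f <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  tibble(tp = tp_pred, n_pred = n_pred, n_truth = n_truth,
         precision = precision, recall = recall, f = f)
}

genome_coverage_fraction <- function(enhancers, genome) {
  if (nrow(enhancers) == 0) return(0)
  sum(enhancers$end - enhancers$start) / sum(Biostrings::width(genome))
}

#' @export
print.lmr_pipeline <- function(x, ...) {
  cat("Enhancer-prediction pipeline run\n")
  print(as.data.frame(x$report), row.names = FALSE)
  invisible(x)
}

write_pipeline_outputs <- function(res, out_dir, inputs) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)

  sw <- res$windows[is.finite(res$windows$score), , drop = FALSE]
  write_bed(tibble(chrom = sw$chrom, start = sw$start, end = sw$end,
                   name = ".", score = sw$score), p("scored_windows.bed"))
  if (nrow(res$enhancers) > 0) {
    write_bed(tibble(chrom = res$enhancers$chrom,
                     start = res$enhancers$start,
                     end = res$enhancers$end,
                     name = paste0("enh", seq_len(nrow(res$enhancers))),
                     score = res$enhancers$score), p("enhancers.bed"))
    write_bed(tibble(chrom = res$representatives$chrom,
                     start = res$representatives$start,
                     end = res$representatives$end,
                     name = paste0("enh", seq_len(nrow(res$enhancers))),
                     score = res$representatives$score),
              p("representatives.bed"))
  }
  utils::write.table(
    dplyr::select(as_tibble(res$ranked), -dplyr::any_of("members")),
    p("ranked_lmrs.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(res$selection$report, p("selection_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  report <- c(as.list(res$report),
              list(states = as.list(table(res$states))))
  jsonlite::write_json(report, p("report.json"), auto_unbox = TRUE,
                       digits = NA)

  cfg <- res$config
  cfg$weight_grid <- lapply(cfg$weight_grid, unclass)
  jsonlite::write_json(unclass(cfg), p("run_config.json"),
                       auto_unbox = TRUE, digits = NA)
  written <- c("scored_windows.bed", "enhancers.bed",
               "representatives.bed", "ranked_lmrs.tsv",
               "selection_report.tsv", "report.json", "run_config.json")
  written <- written[file.exists(file.path(out_dir, written))]
  manifest <- list(
    package_version = as.character(utils::packageVersion("lmrsvm")),
    seed = res$config$seed,
    config_md5 = unname(tools::md5sum(p("run_config.json"))),
    outputs = as.list(tools::md5sum(file.path(out_dir, written))))
  names(manifest$outputs) <- written
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(out_dir)
}
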