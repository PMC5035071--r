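#' Build the true-positive-marker (TPM) set
#'
#' DHS, p300 and enhancer-associated TF peaks are only trusted as enhancer
#' evidence away from promoters: a site is retained iff its nearest-TSS edge
#' distance exceeds `tss_exclusion_bp` (sites on chromosomes with no TSS are
#' retained).  The TPM track is the union of the three filtered lists.
#'
#' @param dhs,p300,tf Interval tibbles of marker peaks.
#' @param tss Interval tibble of TSS points (1 bp).
#' @param tss_exclusion_bp Minimum TSS distance in bp (default 1000).
#' @return List with the filtered `dhs`, `p300`, `tf`, the combined `tpm`
#'   track, and a `retention` summary tibble.
#' @export
build_tpm <- function(dhs, p300, tf, tss, tss_exclusion_bp = 1000) {
  if (nrow(tss) == 0) abort("tss must be non-empty")
  keep_far <- function(ivs) {
    ivs <- validate_intervals(ivs)
    if (nrow(ivs) == 0) return(ivs)
    ivs[nearest_distance(ivs, tss, mode = "edge") > tss_exclusion_bp, ,
        drop = FALSE]
  }
  fd <- keep_far(dhs); fp <- keep_far(p300); ft <- keep_far(tf)
  list(dhs = fd, p300 = fp, tf = ft,
       tpm = dplyr::bind_rows(fd[c("chrom", "start", "end")],
                              fp[c("chrom", "start", "end")],
                              ft[c("chrom", "start", "end")]),
       retention = tibble(
         track = c("dhs", "p300", "tf"),
         n_in = c(nrow(dhs), nrow(p300), nrow(tf)),
         n_kept = c(nrow(fd), nrow(fp), nrow(ft))))
}

#' Categorize predicted enhancers as validated / misclassified / unknown
#'
#' Rules are applied in order to each representative window, using edge
#' distances (overlap counts as 0, thresholds inclusive):
#' 1. a TPM within `tpm_bp` makes it **validated**;
#' 2. otherwise a TSS within `tss_bp` makes it **misclassified**
#'    (promoter-proximal with no marker support);
#' 3. otherwise it is **unknown**.
#'
#' @param windows Representative windows (one per enhancer).
#' @param tpm TPM interval tibble (see [build_tpm()]).
#' @param tss TSS interval tibble.
#' @param tpm_bp,tss_bp Distance thresholds in bp (defaults 1000 and 2500).
#' @param mode Distance mode for both rules: `"edge"` (default) or
#'   `"center"`.
#' @return A `enhancer_validation` list: `windows` (input plus `category`
#'   column), `summary` (counts and percentages per category).
#' @export
categorize_enhancers <- function(windows, tpm, tss, tpm_bp = 1000,
                                 tss_bp = 2500, mode = "edge") {
  windows <- validate_intervals(windows, "window")
  d_tpm <- if (nrow(tpm) > 0)
    nearest_distance(windows, tpm, mode = mode) else rep(Inf, nrow(windows))
  d_tss <- if (nrow(tss) > 0)
    nearest_distance(windows, tss, mode = mode) else rep(Inf, nrow(windows))
  category <- ifelse(d_tpm <= tpm_bp, "validated",
                     ifelse(d_tss <= tss_bp, "misclassified", "unknown"))
  out <- windows
  out$category <- factor(category,
                         levels = c("validated", "misclassified", "unknown"))
  n_total <- nrow(out)
  counts <- table(out$category)
  summary <- tibble(category = names(counts),
                    n = as.integer(counts),
                    pct = if (n_total > 0) 100 * as.integer(counts) / n_total
                          else rep(0, length(counts)))
  structure(list(windows = out, summary = summary, n = n_total),
            class = "enhancer_validation")
}

#' @export
print.enhancer_validation <- function(x, ...) {
  cat("Validation of", x$n, "predicted enhancers\n")
  print(x$summary)
  invisible(x)
}

#' Marker states of validated enhancers
#'
#' Each validated window is assigned one of six mutually exclusive states
#' from its within-`tpm_bp` marker memberships (p300, DHS, TF):
#' `p300+/-DHS` (p300 without TF, with or without DHS), `DHS only`,
#' `TF+DHS`, `TF only`, `TF+p300`, and `p300+DHS+TF`.
#'
#' @param windows Validated representative windows.
#' @param dhs,p300,tf Filtered marker tracks (see [build_tpm()]).
#' @param tpm_bp Distance threshold in bp.
#' @param mode Distance mode, as in [categorize_enhancers()].
#' @return Factor of states, one per window.  A window near none of the
#'   three tracks contradicts its validated status and raises an error.
#' @export
marker_states <- function(windows, dhs, p300, tf, tpm_bp = 1000,
                          mode = "edge") {
  windows <- validate_intervals(windows, "window")
  near <- function(track) {
    if (nrow(track) == 0) return(rep(FALSE, nrow(windows)))
    nearest_distance(windows, track, mode = mode) <= tpm_bp
  }
  hp <- near(p300); hd <- near(dhs); ht <- near(tf)
  if (any(!hp & !hd & !ht))
    abort("window with no nearby marker passed as validated")
  state <- dplyr::case_when(
    hp & !ht ~ "p300+/-DHS",
    !hp & hd & !ht ~ "DHS only",
    !hp & hd & ht ~ "TF+DHS",
    !hp & !hd & ht ~ "TF only",
    hp & !hd & ht ~ "TF+p300",
    hp & hd & ht ~ "p300+DHS+TF")
  factor(state, levels = c("p300+/-DHS", "DHS only", "TF+DHS", "TF only",
                           "TF+p300", "p300+DHS+TF"))
}

#' Fraction of windows overlapping a CAGE-enhancer track
#'
#' @param windows Interval tibble of predicted windows.
#' @param fantom Interval tibble of CAGE-defined (FANTOM-style) enhancers.
#' @param min_bp Minimum overlap (default 1 bp).
#' @return Fraction in `[0, 1]`; 0 when either input is empty.
#' @export
fantom_overlap_rate <- function(windows, fantom, min_bp = 1) {
  windows <- validate_intervals(windows, "window")
  if (nrow(windows) == 0 || nrow(fantom) == 0) return(0)
  nrow(overlap_select(windows, fantom, min_bp = min_bp)) / nrow(windows)
}

#' Conservation rate of predicted enhancers by the midpoint rule
#'
#' Because conserved segments are dense, a 2 kb window can hit one by
#' chance; each enhancer is therefore reduced to its 1 bp midpoint, and
#' enhancers overlapping exons are removed first.  An enhancer counts as
#' conserved iff its midpoint lies inside a conserved segment.
#'
#' @param enhancers Interval tibble of predicted enhancers (or windows).
#' @param conserved Interval tibble of conserved segments.
#' @param exons Interval tibble of exons to exclude.
#' @return Conserved / retained fraction; `NA` (with a warning) when every
#'   enhancer overlaps an exon.
#' @export
conserved_midpoint_rate <- function(enhancers, conserved, exons) {
  enhancers <- validate_intervals(enhancers, "enhancer")
  if (nrow(enhancers) == 0) return(NA_real_)
  if (nrow(exons) > 0) {
    drop <- overlap_select(enhancers, exons, min_bp = 1)
    keep <- !paste(enhancers$chrom, enhancers$start, enhancers$end) %in%
      paste(drop$chrom, drop$start, drop$end)
    enhancers <- enhancers[keep, , drop = FALSE]
  }
  if (nrow(enhancers) == 0) {
    warn("every enhancer overlaps an exon; conservation rate undefined")
    return(NA_real_)
  }
  mids <- midpoints(enhancers)
  if (nrow(conserved) == 0) return(0)
  nrow(overlap_select(mids, conserved, min_bp = 1)) / nrow(enhancers)
}

#' Two-proportion z-test with pooled variance
#'
#' @param x1,n1 Successes and trials in group 1.
#' @param x2,n2 Successes and trials in group 2.
#' @param alternative `"two.sided"`, `"greater"` or `"less"` (of p1 - p2).
#' @return One-row tibble: `estimate1`, `estimate2`, `z`, `p_value`.  Zero
#'   pooled variance (all successes or all failures) yields `NA` statistics.
#' @export
two_proportion_ztest <- function(x1, n1, x2, n2,
                                 alternative = c("two.sided", "greater",
                                                 "less")) {
  alternative <- match.arg(alternative)
  stopifnot(n1 > 0, n2 > 0, x1 >= 0, x2 >= 0, x1 <= n1, x2 <= n2)
  p1 <- x1 / n1; p2 <- x2 / n2
  pool <- (x1 + x2) / (n1 + n2)
  se <- sqrt(pool * (1 - pool) * (1 / n1 + 1 / n2))
  if (se == 0) {
    warn("zero pooled variance; z undefined")
    return(tibble(estimate1 = p1, estimate2 = p2, z = NA_real_,
                  p_value = NA_real_))
  }
  z <- (p1 - p2) / se
  p <- switch(alternative,
              two.sided = 2 * pnorm(-abs(z)),
              greater = pnorm(z, lower.tail = FALSE),
              less = pnorm(z))
  tibble(estimate1 = p1, estimate2 = p2, z = z, p_value = p)
}

#' Plot a validation result
#'
#' Bar chart of the validated / misclassified / unknown percentages.
#'
#' @param object A [categorize_enhancers()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.enhancer_validation <- function(object, ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(x = .data$category, y = .data$pct,
                               fill = .data$category)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = "% of predicted enhancers") +
    ggplot2::theme_minimal()
}
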