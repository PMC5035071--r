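#' Four-set penalty weights for the weighted SVM
#'
#' One misclassification cost per training set.  Confidence ordering is
#' enforced: RP sequences carry at least the LP penalty (`c_rp >= c_lp`) and
#' RN at least the LN penalty (`c_rn >= c_ln`).
#'
#' @param c_rp,c_lp Positive penalties for reliable/likely positives.
#' @param c_ln,c_rn Positive penalties for likely/reliable negatives.
#' @return A `wsvm_weights` list.
#' @export
wsvm_weights <- function(c_rp = 10, c_lp = 1, c_ln = 1, c_rn = 10) {
  if (any(c(c_rp, c_lp, c_ln, c_rn) <= 0)) abort("weights must be positive")
  if (c_rp < c_lp) abort("need c_rp >= c_lp")
  if (c_rn < c_ln) abort("need c_rn >= c_ln")
  structure(list(c_rp = c_rp, c_lp = c_lp, c_ln = c_ln, c_rn = c_rn),
            class = "wsvm_weights")
}

weights_for_sets <- function(weights, set) {
  unname(c(RP = weights$c_rp, LP = weights$c_lp,
           LN = weights$c_ln, RN = weights$c_rn)[as.character(set)])
}

#' Train the weighted soft-margin linear SVM
#'
#' Solves the per-sample-cost soft-margin problem
#' \deqn{\min_{w,b,\xi} \tfrac12\|w\|^2 + \sum_i C_i \xi_i
#'       \quad \mathrm{s.t.}\quad y_i(w^\top x_i + b) \ge 1 - \xi_i,\
#'       \xi_i \ge 0,}
#' where sample \eqn{i}'s cost \eqn{C_i} is the penalty of its set (RP, LP,
#' LN or RN).  The dual is optimized by sequential minimal optimization with
#' maximal-violating-pair working sets; at return every sample's KKT
#' residual is at most `tol`.
#'
#' @param training A `wsvm_training` (see [build_training()]), or any list
#'   with elements `x`, `y` and `set`.
#' @param weights A [wsvm_weights()] object.
#' @param tol Stopping tolerance on the maximal KKT violation.
#' @param max_iter Iteration cap for the optimizer.
#' @return A `wsvm_model` with the weight vector `w`, bias `b`, duals
#'   `alpha`, slacks `xi` and the primal objective.
#' @export
wsvm <- function(training, weights = wsvm_weights(), tol = 1e-8,
                 max_iter = 1e6L) {
  x <- as.matrix(training$x)
  y <- as.numeric(training$y)
  if (length(unique(y)) < 2)
    abort("training data must contain both classes")
  C <- weights_for_sets(weights, training$set)
  fit <- wsvm_smo(x, y, C, tol, as.integer(max_iter))
  if (!fit$converged)
    warn(paste0("optimizer stopped at max_iter with KKT gap ",
                signif(fit$gap, 3)))
  w <- drop(fit$w)
  names(w) <- colnames(x)
  f <- drop(x %*% w) + fit$b
  xi <- pmax(0, 1 - y * f)
  structure(list(w = w, b = fit$b, weights = weights,
                 alpha = drop(fit$alpha), xi = xi,
                 objective = 0.5 * sum(w^2) + sum(C * xi),
                 iterations = fit$iterations, gap = fit$gap,
                 converged = fit$converged, n = nrow(x),
                 n_sv = sum(fit$alpha > 1e-12),
                 set_sizes = table(training$set)),
            class = "wsvm_model")
}

#' @export
print.wsvm_model <- function(x, ...) {
  cat("Weighted linear SVM:", length(x$w), "features,", x$n, "samples,",
      x$n_sv, "support vectors\n")
  cat("  penalties C(RP, LP, LN, RN) =",
      paste(unlist(x$weights), collapse = ", "), "\n")
  cat("  objective", signif(x$objective, 6), "| KKT gap",
      signif(x$gap, 3), "\n")
  invisible(x)
}

#' Decision values for new data
#'
#' @param object A `wsvm_model`.
#' @param newdata Numeric matrix of encoded sequences (columns must match
#'   the training features).
#' @param ... Unused.
#' @return Numeric vector `w . x + b`; positive means predicted enhancer.
#' @export
predict.wsvm_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$w))
    abort("newdata does not match the model's feature dimension")
  drop(newdata %*% object$w) + object$b
}

#' @exportS3Method generics::tidy
tidy.wsvm_model <- function(x, ...) {
  tibble(term = names(x$w) %||% paste0("f", seq_along(x$w)),
         estimate = unname(x$w))
}

#' @exportS3Method generics::glance
glance.wsvm_model <- function(x, ...) {
  tibble(n = x$n, n_sv = x$n_sv, b = x$b, objective = x$objective,
         iterations = x$iterations, kkt_gap = x$gap,
         converged = x$converged)
}

#' Recall, precision and F-score from pooled counts
#'
#' In the positive-unlabeled protocol, `tp` and `fn` count RP/LP sequences
#' predicted positive and negative, while `pp` counts *all* sequences
#' predicted positive (so false positives from LN/RN lower precision).
#' All three statistics are 0 whenever their denominator vanishes.
#'
#' @param tp,fn,pp Non-negative counts.
#' @return One-row tibble with `tp`, `fn`, `pp`, `recall`, `precision`, `f`.
#' @export
prf_metrics <- function(tp, fn, pp) {
  stopifnot(tp >= 0, fn >= 0, pp >= 0)
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  precision <- if (pp > 0) tp / pp else 0
  f <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  tibble(tp = tp, fn = fn, pp = pp, recall = recall,
         precision = precision, f = f)
}

#' Genomic coverage of a model's predictions on a proxy chromosome
#'
#' Scans one chromosome with sliding windows, merges positive windows into
#' enhancers, and returns covered bp / chromosome bp.  A single chromosome
#' stands proxy for the genome during model selection.
#'
#' @param model A `wsvm_model`.
#' @param genome Named [Biostrings::DNAStringSet].
#' @param proxy_chrom Chromosome name to scan.
#' @param window,step Scan geometry in bp.
#' @param k,canonical Encoding parameters (must match training).
#' @return Fraction in `[0, 1]`.
#' @export
genomic_coverage <- function(model, genome, proxy_chrom, window = 2000,
                             step = 500, k = 5, canonical = FALSE) {
  if (!proxy_chrom %in% names(genome))
    abort(paste0("proxy chromosome ", proxy_chrom, " not in genome"))
  sw <- scan_genome(model, genome, window = window, step = step,
                    chroms = proxy_chrom, k = k, canonical = canonical)
  enh <- merge_windows(sw)
  L <- Biostrings::width(genome)[match(proxy_chrom, names(genome))]
  if (nrow(enh) == 0) return(0)
  sum(enh$end - enh$start) / L
}

#' Cross-validated grid selection of the partition cutoff and SVM weights
#'
#' For every `(delta, weights)` pair: partition the ranked LMRs, attach the
#' RN set, and run stratified k-fold cross-validation of the weighted SVM;
#' held-out counts are pooled over folds into a single recall / precision /
#' F-score.  Candidates whose fully retrained model covers more than
#' `coverage_cap` of the proxy chromosome are discarded.  Among survivors,
#' the candidates within `tie_tol` of the best F-score form the top group
#' and the one with the highest precision wins (remaining ties go to the
#' lexicographically smallest grid point).  The winner is retrained on all
#' data.
#'
#' @param ranked An [rank_by_density()] result (carries `quantile` and the
#'   original row index `idx`).
#' @param lmr_x Encoded LMR matrix in the *pre-ranking* row order (the same
#'   matrix passed to [rank_by_density()]).
#' @param rn_x Encoded RN matrix.
#' @param genome Named [Biostrings::DNAStringSet] (for the coverage proxy).
#' @param proxy_chrom Chromosome used as the genomic-coverage proxy.
#' @param delta_grid Numeric vector of RP cutoffs.
#' @param weight_grid List of [wsvm_weights()] (or a data frame with columns
#'   `c_rp`, `c_lp`, `c_ln`, `c_rn`).
#' @param ln_quantile LN cutoff (fixed during selection).
#' @param folds Number of CV folds (default 5).
#' @param coverage_cap Maximum allowed proxy coverage (default 0.05; 0.10
#'   and 0.15 are the usual alternative operating points).
#' @param tie_tol Absolute F-score tolerance defining the top group.
#' @param window,step,k,canonical Scan geometry and encoding parameters.
#' @param tol SVM stopping tolerance.
#' @param seed Seed for the fold assignment.
#' @return A `wsvm_selection` list: `model` (final refit), `delta`,
#'   `weights`, `metrics` (CV metrics of the winner) and `report` (one row
#'   per grid point).
#' @export
select_wsvm <- function(ranked, lmr_x, rn_x, genome, proxy_chrom,
                        delta_grid = c(0.90, 0.95, 0.99),
                        weight_grid = default_weight_grid(),
                        ln_quantile = 0.15, folds = 5, coverage_cap = 0.05,
                        tie_tol = 0.005, window = 2000, step = 500, k = 5,
                        canonical = FALSE, tol = 1e-6, seed = 1L) {
  if (is.data.frame(weight_grid))
    weight_grid <- purrr::pmap(weight_grid,
                               function(c_rp, c_lp, c_ln, c_rn, ...)
                                 wsvm_weights(c_rp, c_lp, c_ln, c_rn))
  if (length(delta_grid) == 0 || length(weight_grid) == 0)
    abort("grids must be non-empty")
  if (!"idx" %in% names(ranked))
    abort("ranked lacks the original-row index column idx")
  x_lmr <- as.matrix(lmr_x)[ranked$idx, , drop = FALSE]
  rn_x <- as.matrix(rn_x)
  n_lmr <- nrow(x_lmr)
  x_all <- rbind(x_lmr, rn_x)

  grid <- tidyr::expand_grid(di = seq_along(delta_grid),
                             wi = seq_along(weight_grid))
  rows <- vector("list", nrow(grid))
  fits <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    delta <- delta_grid[grid$di[g]]
    wts <- weight_grid[[grid$wi[g]]]
    part <- partition_lmrs(ranked, delta = delta, ln_quantile = ln_quantile)
    set <- factor(c(as.character(part$set), rep("RN", nrow(rn_x))),
                  levels = c("RP", "LP", "LN", "RN"))
    y <- ifelse(set %in% c("RP", "LP"), 1, -1)
    train <- list(x = x_all, y = y, set = set)

    fold_id <- stratified_folds(set, folds, seed = seed)
    pred <- rep(NA, length(y))
    for (fd in seq_len(folds)) {
      hold <- fold_id == fd
      sub <- list(x = x_all[!hold, , drop = FALSE], y = y[!hold],
                  set = set[!hold])
      m <- wsvm(sub, wts, tol = tol)
      pred[hold] <- predict(m, x_all[hold, , drop = FALSE]) > 0
    }
    pos <- set %in% c("RP", "LP")
    met <- prf_metrics(tp = sum(pred & pos), fn = sum(!pred & pos),
                       pp = sum(pred))

    full <- wsvm(train, wts, tol = tol)
    cov <- genomic_coverage(full, genome, proxy_chrom, window = window,
                            step = step, k = k, canonical = canonical)
    fits[[g]] <- full
    rows[[g]] <- dplyr::bind_cols(
      tibble(delta = delta, c_rp = wts$c_rp, c_lp = wts$c_lp,
             c_ln = wts$c_ln, c_rn = wts$c_rn),
      met, tibble(coverage = cov))
  }
  report <- dplyr::bind_rows(rows)
  report$excluded <- report$coverage > coverage_cap
  keep <- which(!report$excluded)
  if (length(keep) == 0)
    abort("every grid point exceeded the coverage cap; no model selected")
  fmax <- max(report$f[keep])
  group <- keep[report$f[keep] >= fmax - tie_tol]
  best_prec <- max(report$precision[group])
  cand <- group[report$precision[group] == best_prec]
  ord <- order(report$delta[cand], report$c_rp[cand], report$c_lp[cand],
               report$c_ln[cand], report$c_rn[cand])
  win <- cand[ord[1]]
  report$selected <- seq_len(nrow(report)) == win
  structure(list(model = fits[[win]], delta = report$delta[win],
                 ln_quantile = ln_quantile,
                 weights = wsvm_weights(report$c_rp[win], report$c_lp[win],
                                        report$c_ln[win], report$c_rn[win]),
                 metrics = report[win, c("tp", "fn", "pp", "recall",
                                         "precision", "f", "coverage")],
                 report = report),
            class = "wsvm_selection")
}

#' Default weight grid
#'
#' Three confidence profiles respecting `c_rp >= c_lp` and `c_rn >= c_ln`:
#' mild, moderate and strong emphasis on the reliable sets.
#'
#' @return A list of [wsvm_weights()].
#' @export
default_weight_grid <- function() {
  list(wsvm_weights(10, 1, 1, 10),
       wsvm_weights(50, 5, 1, 25),
       wsvm_weights(100, 10, 5, 50))
}

stratified_folds <- function(set, folds, seed) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  id <- integer(length(set))
  for (lv in levels(set)) {
    i <- which(set == lv)
    id[i] <- sample(rep_len(seq_len(folds), length(i)))
  }
  id
}

#' @export
print.wsvm_selection <- function(x, ...) {
  cat("wSVM model selection over", nrow(x$report), "grid points\n")
  cat("  selected delta =", x$delta, "; C =",
      paste(unlist(x$weights), collapse = ", "), "\n")
  cat(sprintf("  CV F = %.3f, precision = %.3f, proxy coverage = %.3f\n",
              x$metrics$f, x$metrics$precision, x$metrics$coverage))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.wsvm_selection <- function(x, ...) x$report

#' @exportS3Method generics::glance
glance.wsvm_selection <- function(x, ...) {
  dplyr::bind_cols(tibble(delta = x$delta, ln_quantile = x$ln_quantile),
                   x$metrics)
}

#' Plot a model-selection report
#'
#' CV F-score against proxy coverage for every grid point; excluded points
#' are crossed out and the winner highlighted.
#'
#' @param object A `wsvm_selection`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.wsvm_selection <- function(object, ...) {
  rep <- object$report
  rep$status <- ifelse(rep$selected, "selected",
                       ifelse(rep$excluded, "excluded", "candidate"))
  ggplot2::ggplot(rep, ggplot2::aes(x = .data$coverage, y = .data$f,
                                    colour = .data$status,
                                    shape = factor(.data$delta))) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::labs(x = "proxy genomic coverage", y = "cross-validated F",
                  shape = "delta") +
    ggplot2::theme_minimal()
}
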