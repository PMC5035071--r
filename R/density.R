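#' Fit a kernel density model on anchor k-mer vectors
#'
#' LMRs that overlap validated enhancers act as anchors: a nonparametric
#' density fitted on their k-mer vectors defines "resemblance to a validated
#' enhancer".  Raw k-mer space (4^k dimensions) is far too wide for a kernel
#' density estimate on ~100 anchors, so the anchors are first projected onto
#' their leading principal components (enough to explain `var_explained` of
#' the variance) and a product-Gaussian KDE with a per-dimension Silverman
#' bandwidth is fitted in that space.  Queries are mapped through the stored
#' projection, so ranking is well defined for any vector of matching width.
#'
#' @param anchors Numeric matrix of anchor vectors (rows = anchors); at
#'   least 5 rows.
#' @param var_explained Fraction of variance the retained principal
#'   components must explain (default 0.95).
#' @param max_dim Optional cap on the number of retained components.
#' @param bw_scale Multiplier on the Silverman bandwidths (tuning knob;
#'   default 1).
#' @return An object of class `kmer_density` recording the projection
#'   (center + rotation), retained dimension, per-dimension bandwidths and
#'   the projected anchors.
#' @export
fit_kmer_density <- function(anchors, var_explained = 0.95, max_dim = NULL,
                             bw_scale = 1) {
  anchors <- as.matrix(anchors)
  m <- nrow(anchors)
  if (m < 5) abort("at least 5 anchor vectors are required")
  pc <- prcomp(anchors, center = TRUE, scale. = FALSE)
  v <- pc$sdev^2
  if (sum(v) <= 0) {
    # all anchors identical: degenerate 1-dim model with floored bandwidth
    warn("anchors have zero variance; bandwidth floored")
    p <- 1L
  } else {
    p <- which(cumsum(v) / sum(v) >= var_explained)[1]
  }
  if (!is.null(max_dim)) p <- min(p, as.integer(max_dim))
  p <- max(1L, min(p, ncol(pc$rotation)))
  proj <- pc$x[, seq_len(p), drop = FALSE]
  sds <- apply(proj, 2, sd)
  # multivariate Silverman rule per retained dimension
  h <- sds * (4 / ((p + 2) * m))^(1 / (p + 4)) * bw_scale
  floor_h <- 1e-8 * max(1, max(sds))
  h <- pmax(h, floor_h)
  structure(list(center = pc$center,
                 rotation = pc$rotation[, seq_len(p), drop = FALSE],
                 dim = p, bandwidth = h, anchors = proj, m = m,
                 var_explained = var_explained),
            class = "kmer_density")
}

#' @export
print.kmer_density <- function(x, ...) {
  cat("Anchor k-mer density model\n")
  cat("  anchors:   ", x$m, "\n")
  cat("  dimensions:", x$dim, "(PCA, >=", x$var_explained, "variance)\n")
  cat("  bandwidths:", paste(signif(x$bandwidth, 3), collapse = " "), "\n")
  invisible(x)
}

#' Evaluate the anchor density at query vectors
#'
#' @param model A [fit_kmer_density()] model.
#' @param x Numeric matrix of query vectors in the original feature space.
#' @return Strictly positive, finite densities (one per row), computed with
#'   a log-sum-exp accumulation for stability.
#' @export
density_values <- function(model, x) {
  x <- as.matrix(x)
  if (ncol(x) != length(model$center))
    abort("query vectors do not match the model's feature dimension")
  q <- sweep(x, 2, model$center) %*% model$rotation
  m <- model$m; h <- model$bandwidth
  logs <- matrix(0, nrow(q), m)
  for (j in seq_len(model$dim)) {
    d <- outer(q[, j], model$anchors[, j], "-") / h[j]
    logs <- logs - 0.5 * d^2 - log(h[j])
  }
  logs <- logs - model$dim / 2 * log(2 * pi) - log(m)
  mx <- apply(logs, 1, max)
  dens <- exp(mx) * rowSums(exp(logs - mx))
  pmax(dens, .Machine$double.xmin)
}

#' Rank LMRs by anchor density
#'
#' Each LMR is scored under the anchor density and ranked ascending (rank 1 =
#' lowest density); the normalized rank `rank / n` is its quantile, so high
#' quantiles mean strong resemblance to the validated-enhancer anchors.
#' Ties are broken deterministically by `(density, chrom, start)`.
#'
#' @param model A [fit_kmer_density()] model.
#' @param lmrs Interval tibble of LMRs.
#' @param x Encoded k-mer matrix, one row per row of `lmrs`.
#' @return `lmrs` with columns `density`, `rank` and `quantile`, ordered by
#'   rank; class `lmr_ranking`.
#' @export
rank_by_density <- function(model, lmrs, x) {
  lmrs <- validate_intervals(lmrs, "LMR")
  x <- as.matrix(x)
  if (nrow(x) != nrow(lmrs)) abort("lmrs and x must have the same rows")
  out <- lmrs
  out$density <- density_values(model, x)
  ord <- order(out$density, out$chrom, out$start)
  out <- out[ord, , drop = FALSE]
  out$idx <- ord  # original row index, so callers can realign companions
  out$rank <- seq_len(nrow(out))
  out$quantile <- out$rank / nrow(out)
  class(out) <- c("lmr_ranking", class(out))
  out
}

#' Plot an LMR density ranking
#'
#' Density (log scale) against quantile, colored by partition label when a
#' `set` column is present.
#'
#' @param object An [rank_by_density()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.lmr_ranking <- function(object, ...) {
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data$quantile, y = .data$density))
  if ("set" %in% names(object))
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data$set), size = 0.8)
  else p <- p + ggplot2::geom_point(size = 0.8)
  p + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "density quantile (rank / n)",
                  y = "anchor KDE density") +
    ggplot2::theme_minimal()
}
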