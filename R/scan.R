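#' Scan a genome with scored sliding windows
#'
#' Tiles each chromosome with fixed windows starting at 0, `step`,
#' `2 * step`, ... (a trailing partial window is not emitted), encodes each
#' window and scores it with the model.  Windows with no valid k-mer (e.g.
#' assembly-gap deserts of N) are scored `-Inf` and flagged non-callable
#' rather than treated as confident negatives.
#'
#' @param model A `wsvm_model`.
#' @param genome Named [Biostrings::DNAStringSet].
#' @param window Window size in bp (default 2000).
#' @param step Step between window starts in bp (default 500).
#' @param chroms Optional subset of chromosomes to scan.
#' @param k,canonical Encoding parameters (must match training).
#' @return Tibble of scored windows: `chrom`, `start`, `end`, `score`,
#'   `callable`; class `scored_windows`.
#' @export
scan_genome <- function(model, genome, window = 2000, step = 500,
                        chroms = NULL, k = 5, canonical = FALSE) {
  stopifnot(window >= k, step >= 1)
  chroms <- chroms %||% names(genome)
  unknown <- setdiff(chroms, names(genome))
  if (length(unknown) > 0)
    abort(paste0("chromosome(s) not in genome: ",
                 paste(unknown, collapse = ", ")))
  out <- vector("list", length(chroms))
  for (ci in seq_along(chroms)) {
    cm <- chroms[ci]
    L <- Biostrings::width(genome)[match(cm, names(genome))]
    if (L < window) {
      warn(paste0(cm, " (", L, " bp) is shorter than the window; skipped"))
      out[[ci]] <- NULL
      next
    }
    starts <- seq(0, L - window, by = step)
    v <- Biostrings::Views(genome[[cm]], start = starts + 1, width = window)
    x <- encode_kmers(Biostrings::DNAStringSet(v), k = k,
                      canonical = canonical)
    score <- predict(model, x)
    callable <- attr(x, "valid")
    score[!callable] <- -Inf
    out[[ci]] <- tibble(chrom = cm, start = starts, end = starts + window,
                        score = score, callable = callable)
  }
  res <- dplyr::bind_rows(out)
  class(res) <- c("scored_windows", class(res))
  res
}

#' Merge positive windows into enhancers
#'
#' Positive-scored windows are grouped into connected components under
#' overlap-or-adjacency; each component's union span is one enhancer.  When
#' `split_at_negative` is `TRUE`, a component is additionally cut between
#' two consecutive positive members when a negative-scored callable window
#' lies between them and no positive member spans the midpoint of that
#' negative window (a situation the sliding geometry can produce).
#'
#' @param windows A [scan_genome()] tibble (any interval tibble with a
#'   `score` column works; rows are sorted internally).
#' @param split_at_negative Apply the negative-window cut rule.
#' @return Tibble of enhancers: `chrom`, `start`, `end`, `n_windows`,
#'   representative window coordinates (`rep_start`, `rep_end`) and score
#'   (`score`), plus a list-column `members` holding each enhancer's
#'   windows; class `enhancer_set`.
#' @export
merge_windows <- function(windows, split_at_negative = TRUE) {
  windows <- dplyr::arrange(as_tibble(windows), .data$chrom, .data$start)
  pos <- windows[windows$score > 0, , drop = FALSE]
  empty <- tibble(chrom = character(), start = numeric(), end = numeric(),
                  n_windows = integer(), rep_start = numeric(),
                  rep_end = numeric(), score = numeric(),
                  members = list())
  class(empty) <- c("enhancer_set", class(empty))
  if (nrow(pos) == 0) return(empty)
  neg <- windows[windows$score <= 0 &
                   (windows$callable %||% TRUE), , drop = FALSE]
  out <- vector("list", 0)
  for (cm in unique(pos$chrom)) {
    p <- pos[pos$chrom == cm, , drop = FALSE]
    ng <- neg[neg$chrom == cm, , drop = FALSE]
    comp <- integer(nrow(p)); comp[1] <- 1L
    if (nrow(p) > 1) {
      for (i in 2:nrow(p)) {
        linked <- p$start[i] <= max(p$end[seq_len(i - 1)])
        if (linked && split_at_negative && nrow(ng) > 0) {
          between <- ng$start > p$start[i - 1] & ng$start < p$start[i]
          if (any(between)) {
            mids <- (ng$start[between] + ng$end[between]) / 2
            spanned <- vapply(mids, function(m)
              any(p$start < m & p$end > m), logical(1))
            if (any(!spanned)) linked <- FALSE
          }
        }
        comp[i] <- if (linked) comp[i - 1] else comp[i - 1] + 1L
      }
    }
    sp <- split(seq_len(nrow(p)), comp)
    out <- c(out, lapply(sp, function(i) {
      mem <- p[i, , drop = FALSE]
      ri <- which(mem$score == max(mem$score))[1]  # leftmost on ties
      tibble(chrom = cm, start = min(mem$start), end = max(mem$end),
             n_windows = nrow(mem), rep_start = mem$start[ri],
             rep_end = mem$end[ri], score = mem$score[ri],
             members = list(mem))
    }))
  }
  res <- dplyr::arrange(dplyr::bind_rows(out), .data$chrom, .data$start)
  class(res) <- c("enhancer_set", class(res))
  res
}

#' Representative windows of merged enhancers
#'
#' One window per enhancer: the member with the highest decision score
#' (leftmost on ties).  Representative windows, not full concatenated
#' spans, are what validation statistics are computed on, because long
#' concatenated enhancers trivially hit nearby markers.
#'
#' @param enhancers A [merge_windows()] result.
#' @return Tibble of windows: `chrom`, `start`, `end`, `score`.
#' @export
representatives <- function(enhancers) {
  tibble(chrom = enhancers$chrom, start = enhancers$rep_start,
         end = enhancers$rep_end, score = enhancers$score)
}

#' Plot a score track
#'
#' Decision scores of scanned windows along one chromosome, with the
#' positive (predicted-enhancer) windows highlighted.
#'
#' @param windows A [scan_genome()] tibble.
#' @param chrom Chromosome to display (default: the first present).
#' @return A ggplot object.
#' @export
plot_score_track <- function(windows, chrom = NULL) {
  chrom <- chrom %||% windows$chrom[1]
  w <- windows[windows$chrom == chrom & is.finite(windows$score), ,
               drop = FALSE]
  ggplot2::ggplot(w, ggplot2::aes(x = (.data$start + .data$end) / 2,
                                  y = .data$score,
                                  colour = .data$score > 0)) +
    ggplot2::geom_point(size = 0.6, show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = paste0(chrom, " position (bp)"),
                  y = "SVM decision score") +
    ggplot2::theme_minimal()
}
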