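#' Partition ranked LMRs into RP / LP / LN by density quantile
#'
#' LMRs in the top `delta` quantiles of the anchor density become the
#' reliable-positive (RP) set, those below `ln_quantile` the likely-negative
#' (LN) set, and the remainder the likely-positive (LP) set.  Boundaries are
#' inclusive on the RP side (`quantile >= delta`) and exclusive on the LN
#' side (`quantile < ln_quantile`).
#'
#' @param ranked An [rank_by_density()] result (needs a `quantile` column).
#' @param delta RP cutoff in (0, 1); 0.95 by default (the cutoff learned for
#'   both reference cell types).
#' @param ln_quantile LN cutoff in (0, 1), strictly below `delta`; 0.15 by
#'   default (the H1 setting; 0.11 for IMR90-like data).
#' @return `ranked` with a `set` factor column (`RP`, `LP`, `LN`).
#' @export
partition_lmrs <- function(ranked, delta = 0.95, ln_quantile = 0.15) {
  if (!"quantile" %in% names(ranked)) abort("ranked lacks a quantile column")
  if (!(ln_quantile < delta)) abort("ln_quantile must be < delta")
  if (delta <= 0 || delta >= 1 || ln_quantile <= 0)
    abort("cutoffs must lie in (0, 1)")
  set <- ifelse(ranked$quantile >= delta, "RP",
                ifelse(ranked$quantile < ln_quantile, "LN", "LP"))
  out <- ranked
  out$set <- factor(set, levels = c("RP", "LP", "LN"))
  out
}

#' Shuffle intervals into exclusion-aware random background loci
#'
#' Builds the reliable-negative (RN) set: one random locus per template
#' interval, on the same chromosome and of identical length, placed
#' uniformly by rejection sampling so that it (i) does not overlap any
#' exclusion interval (typically exons plus the LMRs themselves), (ii) does
#' not overlap previously placed negatives, and (iii) contains no N.  This
#' preserves the per-chromosome count and length distribution of the
#' template, mirroring a coordinate shuffle with exclusions.
#'
#' @param template Interval tibble whose per-chromosome length multiset is
#'   reproduced.
#' @param genome Named [Biostrings::DNAStringSet].
#' @param exclusions Interval tibble of forbidden regions.
#' @param seed Integer seed; the sampler uses a private RNG stream.
#' @param max_tries Rejection-sampling attempts per interval before erroring.
#' @param allow_self_overlap If `TRUE`, placed negatives may overlap each
#'   other (closer to a plain coordinate shuffle).
#' @return Interval tibble of negatives, same row count as `template`.
#' @export
generate_negatives <- function(template, genome, exclusions = NULL,
                               seed = 1L, max_tries = 1000L,
                               allow_self_overlap = FALSE) {
  template <- validate_intervals(template, "template")
  check_in_genome(template, genome)
  if (!is.null(exclusions) && nrow(exclusions) > 0)
    exclusions <- validate_intervals(exclusions, "exclusion")
  else exclusions <- NULL

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  res_start <- numeric(nrow(template))
  for (cm in unique(template$chrom)) {
    rows <- which(template$chrom == cm)
    L <- Biostrings::width(genome)[match(cm, names(genome))]
    ex_s <- ex_e <- numeric(0)
    if (!is.null(exclusions)) {
      e <- exclusions[exclusions$chrom == cm, , drop = FALSE]
      ex_s <- e$start; ex_e <- e$end
    }
    placed_s <- placed_e <- numeric(0)
    chrom_seq <- genome[[cm]]
    for (r in rows) {
      len <- template$end[r] - template$start[r]
      if (len > L)
        abort(paste0("interval of ", len, " bp cannot fit on ", cm))
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        s <- floor(runif(1, 0, L - len + 1))
        e <- s + len
        if (length(ex_s) > 0 && any(ex_s < e & ex_e > s)) next
        if (!allow_self_overlap && length(placed_s) > 0 &&
            any(placed_s < e & placed_e > s)) next
        sq <- Biostrings::subseq(chrom_seq, s + 1, e)
        if (Biostrings::countPattern("N", sq) > 0) next
        ok <- TRUE
        break
      }
      if (!ok)
        abort(paste0("could not place a ", len, " bp negative on ", cm,
                     " after ", max_tries, " tries"))
      res_start[r] <- s
      placed_s <- c(placed_s, s); placed_e <- c(placed_e, e)
    }
  }
  tibble(chrom = template$chrom, start = res_start,
         end = res_start + (template$end - template$start))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Assemble the labeled training set
#'
#' Encodes LMRs and background negatives and attaches the four set labels:
#' RP and LP rows get class `y = +1`, LN and RN rows `y = -1`.  Rows whose
#' sequence has no valid k-mer are dropped with a warning.
#'
#' @param partitioned A [partition_lmrs()] result (`set` column over RP, LP,
#'   LN).
#' @param negatives Interval tibble of RN loci (e.g. from
#'   [generate_negatives()]).
#' @param genome Named [Biostrings::DNAStringSet].
#' @param k K-mer length.
#' @param canonical Passed to [encode_kmers()].
#' @return A `wsvm_training` list: `x` (feature matrix), `set` (factor over
#'   RP, LP, LN, RN), `y` (+1/-1), `info` (interval tibble of all rows).
#' @export
build_training <- function(partitioned, negatives, genome, k = 5,
                           canonical = FALSE) {
  if (!"set" %in% names(partitioned)) abort("partitioned lacks a set column")
  negatives <- validate_intervals(negatives, "negative")
  info <- dplyr::bind_rows(
    tibble(chrom = partitioned$chrom, start = partitioned$start,
           end = partitioned$end, set = as.character(partitioned$set)),
    tibble(chrom = negatives$chrom, start = negatives$start,
           end = negatives$end, set = "RN"))
  x <- encode_kmers(extract_sequences(genome, info), k = k,
                    canonical = canonical)
  valid <- attr(x, "valid")
  if (!all(valid)) {
    warn(paste0(sum(!valid), " sequence(s) had no valid k-mer; dropped"))
    x <- x[valid, , drop = FALSE]
    info <- info[valid, , drop = FALSE]
  }
  new_wsvm_training(x, info)
}

new_wsvm_training <- function(x, info) {
  set <- factor(info$set, levels = c("RP", "LP", "LN", "RN"))
  structure(list(x = x, set = set,
                 y = ifelse(set %in% c("RP", "LP"), 1, -1),
                 info = as_tibble(info[c("chrom", "start", "end")])),
            class = "wsvm_training")
}

#' @export
print.wsvm_training <- function(x, ...) {
  cat("wSVM training set:", nrow(x$x), "sequences x", ncol(x$x), "features\n")
  print(table(x$set))
  invisible(x)
}
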