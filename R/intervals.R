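#' Build and validate an interval tibble
#'
#' Genomic locations throughout the package are plain tibbles with columns
#' `chrom`, `start`, `end` and optionally `name` and `score`.  Coordinates
#' follow the BED convention: 0-based, half-open `[start, end)`, so touching
#' intervals never overlap and `end - start` is the length in bp.
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end Integer-valued coordinates, `0 <= start < end`.
#' @param name Optional character vector of feature names.
#' @param score Optional numeric vector of scores.
#' @return A tibble with one row per interval.
#' @examples
#' intervals("chr1", 100, 600)
#' @export
intervals <- function(chrom, start, end, name = NULL, score = NULL) {
  out <- tibble(chrom = as.character(chrom),
                start = as.numeric(start), end = as.numeric(end))
  if (!is.null(name)) out$name <- as.character(name)
  if (!is.null(score)) out$score <- as.numeric(score)
  validate_intervals(out)
}

validate_intervals <- function(ivs, what = "interval") {
  stopifnot(is.data.frame(ivs))
  need <- c("chrom", "start", "end")
  miss <- setdiff(need, names(ivs))
  if (length(miss) > 0)
    abort(paste0(what, " table lacks column(s): ", paste(miss, collapse = ", ")))
  if (nrow(ivs) == 0) return(as_tibble(ivs))
  bad_int <- which(ivs$start != floor(ivs$start) | ivs$end != floor(ivs$end))
  if (length(bad_int) > 0)
    abort(paste0("non-integer coordinates at row(s) ",
                 paste(head(bad_int, 5), collapse = ", ")))
  bad <- which(!(ivs$start >= 0 & ivs$start < ivs$end))
  if (length(bad) > 0)
    abort(paste0("invalid ", what, " (need 0 <= start < end) at row(s) ",
                 paste(head(bad, 5), collapse = ", ")))
  as_tibble(ivs)
}

# interval tibble -> GRanges (1-based closed); internal.  A shared seqlevel
# set keeps findOverlaps quiet when the two tracks cover different chromosomes.
ivs_to_gr <- function(ivs, levels = unique(ivs$chrom)) {
  GenomicRanges::GRanges(
    seqnames = factor(ivs$chrom, levels = levels),
    ranges = IRanges::IRanges(start = ivs$start + 1L, end = ivs$end)
  )
}

#' Read a BED file into an interval tibble
#'
#' Accepts BED3 and wider; column 4 becomes `name` and column 5 `score` when
#' present.  Lines starting with `#`, `track` or `browser` are skipped.
#' Malformed lines (fewer than three fields, non-integer coordinates,
#' `start >= end`) raise an error naming the offending line number.
#'
#' @param path Path to a tab-separated BED file.
#' @return Interval tibble in file order.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0)
    return(tibble(chrom = character(), start = numeric(), end = numeric()))
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3))
    abort(paste0("line ", idx[which(nf < 3)[1]], ": fewer than 3 columns"))
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end) |
                 start != floor(start) | end != floor(end))
  if (length(bad) > 0)
    abort(paste0("line ", idx[bad[1]], ": non-integer coordinates"))
  bad <- which(start >= end | start < 0)
  if (length(bad) > 0)
    abort(paste0("line ", idx[bad[1]], ": invalid interval (start >= end)"))
  out <- tibble(chrom = chrom, start = start, end = end)
  if (all(nf >= 4)) out$name <- vapply(fields, `[[`, "", 4L)
  if (all(nf >= 5))
    out$score <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 5L)))
  out
}

#' Write an interval tibble as BED
#'
#' Emits BED3, BED4 or BED5 depending on which of `name`/`score` are present
#' (a `name` column of "." is synthesised when only `score` exists).
#'
#' @param ivs Interval tibble.
#' @param path Output path.
#' @param digits Decimal digits for the score column.
#' @return `path`, invisibly.
#' @export
write_bed <- function(ivs, path, digits = 6) {
  ivs <- validate_intervals(ivs)
  cols <- list(ivs$chrom, format_coord(ivs$start), format_coord(ivs$end))
  has <- function(col) col %in% names(ivs)
  if (has("score") && !has("name")) ivs$name <- rep(".", nrow(ivs))
  if (has("name")) cols <- c(cols, list(ivs$name))
  if (has("score"))
    cols <- c(cols, list(formatC(ivs$score, format = "f", digits = digits)))
  writeLines(do.call(paste, c(cols, sep = "\t")), path)
  invisible(path)
}

format_coord <- function(x) format(x, scientific = FALSE, trim = TRUE)

#' Read a FASTA genome
#'
#' @param path Multi-record FASTA (wrapped or unwrapped).  Soft-masked
#'   lowercase bases are uppercased.
#' @return A named [Biostrings::DNAStringSet] keyed by chromosome.
#' @export
read_genome <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' Write a genome as FASTA
#' @param genome Named [Biostrings::DNAStringSet].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path, width = 70L)
  invisible(path)
}

check_in_genome <- function(ivs, genome) {
  unknown <- setdiff(unique(ivs$chrom), names(genome))
  if (length(unknown) > 0)
    abort(paste0("chromosome(s) not in genome: ", paste(unknown, collapse = ", ")))
  len <- Biostrings::width(genome)[match(ivs$chrom, names(genome))]
  bad <- which(ivs$end > len)
  if (length(bad) > 0)
    abort(paste0("interval beyond chromosome end at row(s) ",
                 paste(head(bad, 5), collapse = ", ")))
  invisible(ivs)
}

#' Extract plus-strand sequences for intervals
#'
#' @param genome Named [Biostrings::DNAStringSet].
#' @param ivs Interval tibble; every interval must lie within its chromosome.
#' @return Character vector of uppercase sequences, one per row of `ivs`.
#' @export
extract_sequences <- function(genome, ivs) {
  ivs <- validate_intervals(ivs)
  if (nrow(ivs) == 0) return(character())
  check_in_genome(ivs, genome)
  out <- character(nrow(ivs))
  for (cm in unique(ivs$chrom)) {
    i <- which(ivs$chrom == cm)
    v <- Biostrings::Views(genome[[cm]], start = ivs$start[i] + 1L,
                           end = ivs$end[i])
    out[i] <- toupper(as.character(v))
  }
  out
}

#' Filter intervals by length
#'
#' Candidate regulatory regions far shorter or longer than a typical enhancer
#' carry little usable sequence signal; the default bounds keep LMRs between
#' 200 bp and 3 kb inclusive.
#'
#' @param ivs Interval tibble.
#' @param min_bp,max_bp Inclusive length bounds in bp.
#' @return The rows of `ivs` with `min_bp <= end - start <= max_bp`, order
#'   preserved.
#' @export
filter_by_length <- function(ivs, min_bp = 200, max_bp = 3000) {
  stopifnot(min_bp <= max_bp)
  ivs <- validate_intervals(ivs)
  len <- ivs$end - ivs$start
  ivs[len >= min_bp & len <= max_bp, , drop = FALSE]
}

#' Select intervals overlapping another set
#'
#' An interval of `a` is kept iff it overlaps some interval of `b` on the
#' same chromosome by at least `min_bp` bases.  Half-open semantics: touching
#' intervals share zero bases and are never selected at `min_bp = 1`.
#'
#' @param a,b Interval tibbles.
#' @param min_bp Minimum overlap in bp.
#' @return The selected rows of `a`, order preserved.
#' @export
overlap_select <- function(a, b, min_bp = 1) {
  a <- validate_intervals(a); b <- validate_intervals(b)
  if (nrow(a) == 0 || nrow(b) == 0) return(a[integer(0), , drop = FALSE])
  lv <- union(unique(a$chrom), unique(b$chrom))
  hits <- GenomicRanges::findOverlaps(ivs_to_gr(a, lv), ivs_to_gr(b, lv),
                                      minoverlap = as.integer(min_bp))
  a[sort(unique(S4Vectors::queryHits(hits))), , drop = FALSE]
}

#' Distance from each interval to its nearest anchor
#'
#' `mode = "edge"` measures the gap between closest edges (0 for overlapping
#' or touching intervals); `mode = "center"` measures the absolute difference
#' of the floored midpoints `floor((start + end) / 2)`.  Intervals with no
#' same-chromosome anchor get `Inf`.
#'
#' @param ivs Interval tibble of query features.
#' @param anchors Interval tibble of anchors (e.g. TSS points).
#' @param mode `"edge"` or `"center"`.
#' @return Numeric vector of distances, one per row of `ivs`.
#' @export
nearest_distance <- function(ivs, anchors, mode = c("edge", "center")) {
  mode <- match.arg(mode)
  ivs <- validate_intervals(ivs); anchors <- validate_intervals(anchors)
  if (nrow(ivs) == 0) return(numeric())
  out <- rep(Inf, nrow(ivs))
  if (nrow(anchors) == 0) return(out)
  for (cm in intersect(unique(ivs$chrom), unique(anchors$chrom))) {
    i <- which(ivs$chrom == cm)
    j <- which(anchors$chrom == cm)
    if (mode == "center") {
      qm <- floor((ivs$start[i] + ivs$end[i]) / 2)
      am <- sort(floor((anchors$start[j] + anchors$end[j]) / 2))
      pos <- findInterval(qm, am)
      lo <- pmax(pos, 1L); hi <- pmin(pos + 1L, length(am))
      out[i] <- pmin(abs(qm - am[lo]), abs(qm - am[hi]))
    } else {
      q <- IRanges::IRanges(ivs$start[i] + 1L, ivs$end[i])
      s <- IRanges::IRanges(anchors$start[j] + 1L, anchors$end[j])
      hit <- IRanges::distanceToNearest(q, s)
      d <- rep(Inf, length(i))
      d[S4Vectors::queryHits(hit)] <- S4Vectors::mcols(hit)$distance
      out[i] <- d
    }
  }
  out
}

#' Interval midpoints as 1 bp point intervals
#'
#' The midpoint base is `floor((start + end) / 2)` in 0-based coordinates.
#'
#' @param ivs Interval tibble.
#' @return Interval tibble of 1 bp points.
#' @export
midpoints <- function(ivs) {
  ivs <- validate_intervals(ivs)
  m <- floor((ivs$start + ivs$end) / 2)
  out <- ivs
  out$start <- m
  out$end <- m + 1
  out
}
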