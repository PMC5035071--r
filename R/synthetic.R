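#' Configuration for the toy-genome simulator
#'
#' The simulator emulates the inputs of the enhancer-prediction pipeline at
#' desk scale: a background genome of i.i.d. bases at a genomic GC level,
#' planted enhancers whose sequences are seeded with short GC-rich motif
#' words (giving them a learnable k-mer profile, the premise of sequence-
#' based enhancer prediction), LMR calls that are a mix of enhancer-covering
#' and background intervals, a validated-anchor track covering a subset of
#' planted enhancers, and companion exon / TSS / marker / CAGE-enhancer /
#' conservation tracks with configurable on-enhancer and background rates.
#'
#' @param seed Integer seed; all randomness flows from it.
#' @param chrom_lengths Named vector of chromosome lengths in bp.
#' @param background_gc Background GC fraction (0.41, the human genomic
#'   level).
#' @param n_enhancers Number of planted enhancers.
#' @param enhancer_length Min/max planted-enhancer length in bp.
#' @param enhancer_margin Minimum separation between planted enhancers.
#' @param motifs Motif words planted inside enhancers.
#' @param motif_spacing One planting opportunity every this many bp.
#' @param motif_rate Probability an opportunity receives a motif.
#' @param n_lmrs Number of simulated LMR calls.
#' @param lmr_on_enhancer_frac Fraction of LMRs centred on enhancers.
#' @param lmr_length_meanlog,lmr_length_sdlog Log-normal LMR length
#'   parameters (median ~500 bp).
#' @param lmr_length_range Clipping bounds for LMR lengths.
#' @param vista_frac Fraction of planted enhancers emitted as validated
#'   anchors (with `vista_flank` bp primer-like flanks).
#' @param vista_flank Flank added to each anchor fragment.
#' @param n_exons,exon_length Exon count and length range.
#' @param n_tss Number of TSS points.
#' @param tss_margin Minimum TSS distance from any planted enhancer.
#' @param dhs_rate,p300_rate,tf_rate Per-enhancer probability of carrying
#'   each marker.
#' @param n_background_markers Background (off-enhancer) peaks per marker
#'   track.
#' @param marker_length Marker peak length range.
#' @param fantom_frac Fraction of enhancers with a CAGE-style interval.
#' @param n_background_fantom Background CAGE intervals.
#' @param conserved_rate Fraction of enhancers carrying a conserved segment
#'   at their centre.
#' @param n_background_conserved Background conserved segments (dense, as
#'   genome-wide conservation tracks are).
#' @param n_gap_bp Length of one assembly-gap N run placed on the last
#'   chromosome (0 disables it).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       chrom_lengths = c(chrS1 = 4e5, chrS2 = 4e5,
                                         chrS3 = 4e5),
                       background_gc = 0.41,
                       n_enhancers = 15,
                       enhancer_length = c(1200, 2000),
                       enhancer_margin = 4000,
                       motifs = c("GGCGCC", "CACGTG", "GGGCGG", "GCCACG"),
                       motif_spacing = 20,
                       motif_rate = 0.8,
                       n_lmrs = 240,
                       lmr_on_enhancer_frac = 0.25,
                       lmr_length_meanlog = log(650),
                       lmr_length_sdlog = 0.35,
                       lmr_length_range = c(300, 2200),
                       vista_frac = 0.4,
                       vista_flank = 200,
                       n_exons = 90,
                       exon_length = c(120, 300),
                       n_tss = 90,
                       tss_margin = 3000,
                       dhs_rate = 0.9,
                       p300_rate = 0.6,
                       tf_rate = 0.5,
                       n_background_markers = 30,
                       marker_length = c(150, 400),
                       fantom_frac = 0.6,
                       n_background_fantom = 30,
                       conserved_rate = 0.8,
                       n_background_conserved = 400,
                       n_gap_bp = 3000) {
  cfg <- as.list(environment())
  rates <- c(cfg$motif_rate, cfg$lmr_on_enhancer_frac, cfg$vista_frac,
             cfg$dhs_rate, cfg$p300_rate, cfg$tf_rate, cfg$fantom_frac,
             cfg$conserved_rate, cfg$background_gc)
  if (any(rates < 0 | rates > 1)) abort("rates must lie in [0, 1]")
  structure(cfg, class = "sim_config")
}

# uniform integer in [lo, hi]
runif_int <- function(n, lo, hi) floor(runif(n, lo, hi + 1))

# place n non-overlapping intervals of the given lengths on one chromosome,
# keeping `margin` bp apart from the `avoid` intervals and each other
place_apart <- function(n, lens, L, avoid_s, avoid_e, margin,
                        self_margin = margin, max_tries = 5000) {
  s_out <- numeric(0); e_out <- numeric(0)
  for (i in seq_len(n)) {
    for (try in seq_len(max_tries)) {
      s <- runif_int(1, 0, L - lens[i])
      e <- s + lens[i]
      if (length(avoid_s) > 0 &&
          any(avoid_s - margin < e & avoid_e + margin > s)) next
      if (length(s_out) > 0 &&
          any(s_out - self_margin < e & e_out + self_margin > s)) next
      s_out <- c(s_out, s); e_out <- c(e_out, e)
      break
    }
    if (length(s_out) < i)
      abort("could not place simulated intervals; relax the configuration")
  }
  list(start = s_out, end = e_out)
}

#' Simulate a toy genome with planted enhancers and companion tracks
#'
#' See [sim_config()] for what is emulated.  Identical configurations
#' (including the seed) give byte-identical genomes and tracks.
#'
#' @param cfg A [sim_config()].
#' @return A `sim_data` list: `genome` ([Biostrings::DNAStringSet]) and
#'   interval tibbles `truth`, `lmrs`, `vista`, `exons`, `tss`, `dhs`,
#'   `p300`, `tf`, `fantom`, `conserved`, plus `planted` (per-enhancer motif
#'   counts and opportunities) and the `config`.
#' @export
simulate_enhancer_genome <- function(cfg = sim_config()) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(cfg$seed)

  chroms <- names(cfg$chrom_lengths)
  gc <- cfg$background_gc
  base_prob <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seqs <- lapply(cfg$chrom_lengths, function(L)
    sample(names(base_prob), L, replace = TRUE, prob = base_prob))

  # assembly-gap N run on the last chromosome
  gaps <- tibble(chrom = character(), start = numeric(), end = numeric())
  if (cfg$n_gap_bp > 0) {
    cm <- chroms[length(chroms)]
    L <- cfg$chrom_lengths[[cm]]
    gs <- runif_int(1, round(L * 0.3), round(L * 0.7))
    seqs[[cm]][(gs + 1):(gs + cfg$n_gap_bp)] <- "N"
    gaps <- tibble(chrom = cm, start = gs, end = gs + cfg$n_gap_bp)
  }

  # planted enhancers, spread over chromosomes proportionally to length
  n_per <- diff(round(seq(0, cfg$n_enhancers, length.out =
                            length(chroms) + 1)))
  truth <- list(); planted <- list()
  for (ci in seq_along(chroms)) {
    cm <- chroms[ci]
    if (n_per[ci] == 0) next
    lens <- runif_int(n_per[ci], cfg$enhancer_length[1],
                      cfg$enhancer_length[2])
    g <- gaps[gaps$chrom == cm, , drop = FALSE]
    pl <- place_apart(n_per[ci], lens, cfg$chrom_lengths[[ci]],
                      g$start, g$end, cfg$enhancer_margin)
    truth[[cm]] <- tibble(chrom = cm, start = pl$start, end = pl$end)
    # motif planting: one opportunity every motif_spacing bp
    mlen <- nchar(cfg$motifs[1])
    for (i in seq_along(pl$start)) {
      opp <- seq(pl$start[i], pl$end[i] - mlen, by = cfg$motif_spacing)
      hit <- runif(length(opp)) < cfg$motif_rate
      words <- sample(cfg$motifs, sum(hit), replace = TRUE)
      for (j in seq_along(words)) {
        at <- opp[hit][j]
        seqs[[cm]][(at + 1):(at + mlen)] <-
          strsplit(words[j], "")[[1]]
      }
      planted[[length(planted) + 1]] <-
        tibble(chrom = cm, start = pl$start[i], end = pl$end[i],
               opportunities = length(opp), motifs_planted = sum(hit))
    }
  }
  truth <- if (length(truth) > 0) dplyr::bind_rows(truth) else
    tibble(chrom = character(), start = numeric(), end = numeric())
  planted <- if (length(planted) > 0) dplyr::bind_rows(planted) else
    tibble(chrom = character(), start = numeric(), end = numeric(),
           opportunities = integer(), motifs_planted = integer())

  genome <- Biostrings::DNAStringSet(
    setNames(vapply(seqs, paste, "", collapse = ""), chroms))

  clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  # LMRs: a mix of enhancer-covering and background intervals
  n_on <- round(cfg$n_lmrs * cfg$lmr_on_enhancer_frac)
  n_on <- min(n_on, ifelse(nrow(truth) > 0, n_on, 0))
  n_bg <- cfg$n_lmrs - n_on
  lmr_len <- function(n) clip(round(stats::rlnorm(n, cfg$lmr_length_meanlog,
                                                  cfg$lmr_length_sdlog)),
                              cfg$lmr_length_range[1],
                              cfg$lmr_length_range[2])
  lmrs <- list()
  if (n_on > 0 && nrow(truth) > 0) {
    pick <- sample(nrow(truth), n_on, replace = TRUE)
    lens <- lmr_len(n_on)
    # centre inside the central half of the host enhancer
    tlen <- truth$end[pick] - truth$start[pick]
    centre <- truth$start[pick] +
      runif_int(n_on, round(tlen * 0.25), round(tlen * 0.75))
    L <- cfg$chrom_lengths[match(truth$chrom[pick], chroms)]
    s <- clip(centre - floor(lens / 2), 0, L - lens)
    lmrs$on <- tibble(chrom = truth$chrom[pick], start = s, end = s + lens)
  }
  if (n_bg > 0) {
    per <- table(factor(sample(chroms, n_bg, replace = TRUE,
                               prob = cfg$chrom_lengths), levels = chroms))
    bg <- list()
    for (cm in chroms) {
      if (per[[cm]] == 0) next
      tv <- truth[truth$chrom == cm, , drop = FALSE]
      g <- gaps[gaps$chrom == cm, , drop = FALSE]
      pl <- place_apart(per[[cm]], lmr_len(per[[cm]]),
                        cfg$chrom_lengths[[cm]],
                        c(tv$start, g$start), c(tv$end, g$end),
                        margin = 1000)
      bg[[cm]] <- tibble(chrom = cm, start = pl$start, end = pl$end)
    }
    lmrs$bg <- dplyr::bind_rows(bg)
  }
  lmrs <- dplyr::arrange(dplyr::bind_rows(lmrs), .data$chrom, .data$start)

  # validated-anchor (VISTA-like) fragments over a subset of enhancers;
  # in a null (0-enhancer) configuration, random LMRs stand in so the
  # ranking stage still runs and learns nothing
  if (nrow(truth) > 0) {
    nv <- max(1, round(nrow(truth) * cfg$vista_frac))
    pick <- sort(sample(nrow(truth), nv))
    L <- cfg$chrom_lengths[match(truth$chrom[pick], chroms)]
    vista <- tibble(chrom = truth$chrom[pick],
                    start = pmax(truth$start[pick] - cfg$vista_flank, 0),
                    end = pmin(truth$end[pick] + cfg$vista_flank, L))
  } else {
    pick <- sort(sample(nrow(lmrs), max(5, round(nrow(lmrs) *
                                                   cfg$vista_frac / 2))))
    vista <- lmrs[pick, , drop = FALSE]
  }

  # exons and TSSs away from enhancers
  exons <- list(); tss <- list()
  per_e <- table(factor(sample(chroms, cfg$n_exons, replace = TRUE,
                               prob = cfg$chrom_lengths), levels = chroms))
  per_t <- table(factor(sample(chroms, cfg$n_tss, replace = TRUE,
                               prob = cfg$chrom_lengths), levels = chroms))
  for (cm in chroms) {
    tv <- truth[truth$chrom == cm, , drop = FALSE]
    g <- gaps[gaps$chrom == cm, , drop = FALSE]
    if (per_e[[cm]] > 0) {
      pl <- place_apart(per_e[[cm]],
                        runif_int(per_e[[cm]], cfg$exon_length[1],
                                  cfg$exon_length[2]),
                        cfg$chrom_lengths[[cm]],
                        c(tv$start, g$start), c(tv$end, g$end), margin = 500)
      exons[[cm]] <- tibble(chrom = cm, start = pl$start, end = pl$end)
    }
    if (per_t[[cm]] > 0) {
      pl <- place_apart(per_t[[cm]], rep(1, per_t[[cm]]),
                        cfg$chrom_lengths[[cm]],
                        c(tv$start, g$start), c(tv$end, g$end),
                        margin = cfg$tss_margin, self_margin = 100)
      tss[[cm]] <- tibble(chrom = cm, start = pl$start, end = pl$end)
    }
  }
  exons <- dplyr::bind_rows(exons); tss <- dplyr::bind_rows(tss)

  # marker tracks: on-enhancer at the per-track rate, plus uniform noise
  on_enhancer_track <- function(rate) {
    if (nrow(truth) == 0 || rate == 0)
      return(tibble(chrom = character(), start = numeric(),
                    end = numeric()))
    hit <- which(runif(nrow(truth)) < rate)
    lens <- runif_int(length(hit), cfg$marker_length[1],
                      cfg$marker_length[2])
    centre <- floor((truth$start[hit] + truth$end[hit]) / 2) +
      runif_int(length(hit), -200, 200)
    L <- cfg$chrom_lengths[match(truth$chrom[hit], chroms)]
    s <- clip(centre - floor(lens / 2), 0, L - lens)
    tibble(chrom = truth$chrom[hit], start = s, end = s + lens)
  }
  background_track <- function(n, len_range) {
    if (n == 0) return(tibble(chrom = character(), start = numeric(),
                              end = numeric()))
    cm <- sample(chroms, n, replace = TRUE, prob = cfg$chrom_lengths)
    lens <- runif_int(n, len_range[1], len_range[2])
    L <- cfg$chrom_lengths[match(cm, chroms)]
    s <- runif_int(n, 0, L - lens)
    tibble(chrom = cm, start = s, end = s + lens)
  }
  mk <- function(rate) dplyr::arrange(
    dplyr::bind_rows(on_enhancer_track(rate),
                     background_track(cfg$n_background_markers,
                                      cfg$marker_length)),
    .data$chrom, .data$start)
  dhs <- mk(cfg$dhs_rate); p300 <- mk(cfg$p300_rate); tf <- mk(cfg$tf_rate)

  fantom <- dplyr::arrange(dplyr::bind_rows(
    { hit <- which(runif(nrow(truth)) < cfg$fantom_frac)
      if (length(hit) > 0) {
        centre <- floor((truth$start[hit] + truth$end[hit]) / 2)
        tibble(chrom = truth$chrom[hit], start = pmax(centre - 250, 0),
               end = centre + 250)
      } else tibble(chrom = character(), start = numeric(),
                    end = numeric()) },
    background_track(cfg$n_background_fantom, c(400, 600))),
    .data$chrom, .data$start)

  conserved <- dplyr::arrange(dplyr::bind_rows(
    { hit <- which(runif(nrow(truth)) < cfg$conserved_rate)
      if (length(hit) > 0) {
        lens <- runif_int(length(hit), 100, 300)
        centre <- floor((truth$start[hit] + truth$end[hit]) / 2)
        tibble(chrom = truth$chrom[hit],
               start = pmax(centre - floor(lens / 2), 0),
               end = pmax(centre - floor(lens / 2), 0) + lens)
      } else tibble(chrom = character(), start = numeric(),
                    end = numeric()) },
    background_track(cfg$n_background_conserved, c(50, 200))),
    .data$chrom, .data$start)

  structure(list(genome = genome, truth = truth, lmrs = lmrs,
                 vista = vista, exons = exons, tss = tss, dhs = dhs,
                 p300 = p300, tf = tf, fantom = fantom,
                 conserved = conserved, planted = planted, config = cfg),
            class = "sim_data")
}

#' @export
print.sim_data <- function(x, ...) {
  cat("Simulated genome:", length(x$genome), "chromosomes,",
      sum(Biostrings::width(x$genome)), "bp\n")
  cat("  planted enhancers:", nrow(x$truth), "| LMRs:", nrow(x$lmrs),
      "| anchors:", nrow(x$vista), "\n")
  invisible(x)
}

#' Write a simulation to disk in pipeline formats
#'
#' Emits `genome.fa` plus one BED per track and the configuration as JSON.
#'
#' @param sim A [simulate_enhancer_genome()] result.
#' @param dir Target directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_genome(sim$genome, file.path(dir, "genome.fa"))
  for (tr in c("truth", "lmrs", "vista", "exons", "tss", "dhs", "p300",
               "tf", "fantom", "conserved")) {
    if (nrow(sim[[tr]]) > 0)
      write_bed(sim[[tr]], file.path(dir, paste0(tr, ".bed")))
    else writeLines(character(), file.path(dir, paste0(tr, ".bed")))
  }
  cfg <- sim$config
  cfg$chrom_lengths <- as.list(cfg$chrom_lengths)
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a simulation directory back into pipeline inputs
#'
#' @param dir A directory written by [write_simulation()] (or hand-built
#'   with the same file names).
#' @return A list with `genome` and the interval tracks present.
#' @export
read_simulation <- function(dir) {
  out <- list(genome = read_genome(file.path(dir, "genome.fa")))
  for (tr in c("truth", "lmrs", "vista", "exons", "tss", "dhs", "p300",
               "tf", "fantom", "conserved")) {
    p <- file.path(dir, paste0(tr, ".bed"))
    if (file.exists(p)) out[[tr]] <- read_bed(p)
  }
  out
}
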