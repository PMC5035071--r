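test_that("window tiling follows floor((L - window)/step) + 1", {
  g <- make_random_genome(c(c10k = 10000, tiny = 1999), seed = 81)
  m <- constant_model(b = 1)
  expect_warning(sw <- scan_genome(m, g, window = 2000, step = 500),
                 "shorter than the window")
  expect_equal(nrow(sw), 17)
  expect_equal(max(sw$start), 8000)
  expect_equal(unique(sw$end - sw$start), 2000)
  expect_equal(unique(diff(sw$start)), 500)
})

test_that("window scores equal the recomputed dot product", {
  sim <- simulate_enhancer_genome(small_sim_config(seed = 82))
  tr_seqs <- extract_sequences(sim$genome,
                               filter_by_length(sim$lmrs)[1:40, ])
  x <- encode_kmers(tr_seqs)
  withr::with_seed(82, {
    w <- rnorm(1024, sd = 0.1)
  })
  m <- structure(list(w = setNames(w, kmer_words(5)), b = 0.02),
                 class = "wsvm_model")
  sw <- scan_genome(m, sim$genome, window = 2000, step = 500,
                    chroms = "chrP1")
  pick <- c(1, 17, nrow(sw))
  seqs <- extract_sequences(sim$genome, sw[pick, c("chrom", "start", "end")])
  expected <- drop(encode_kmers(seqs) %*% w) + 0.02
  expect_equal(sw$score[pick], expected, tolerance = 1e-12)
})

test_that("all-N windows are flagged non-callable, not negative", {
  seq <- paste0(paste(rep("A", 4000), collapse = ""),
                paste(rep("N", 4000), collapse = ""),
                paste(rep("A", 4000), collapse = ""))
  g <- Biostrings::DNAStringSet(c(gap = seq))
  sw <- scan_genome(constant_model(b = 1), g)
  inner <- sw$start >= 4000 & sw$end <= 8000
  expect_true(all(!sw$callable[inner]))
  expect_true(all(sw$score[inner] == -Inf))
  expect_true(all(sw$callable[!inner]))  # boundary windows keep A runs
})

test_that("overlapping positive windows merge into one span", {
  w <- tibble::tibble(chrom = "c1", start = c(0, 500),
                      end = c(2000, 2500), score = c(0.4, 0.2),
                      callable = TRUE)
  enh <- merge_windows(w)
  expect_equal(nrow(enh), 1)
  expect_equal(c(enh$start, enh$end), c(0, 2500))
  expect_equal(enh$n_windows, 2)
})

test_that("negative stretches separate enhancers", {
  w <- tibble::tibble(chrom = "c1",
                      start = c(0, 500, 4000, 4500),
                      end = c(2000, 2500, 6000, 6500),
                      score = c(1, 0.5, -0.2, 0.8),
                      callable = TRUE)
  # windows 3 overlaps 2 and 4, but it is negative: two enhancers
  enh <- merge_windows(w)
  expect_equal(nrow(enh), 2)
  expect_equal(enh$start, c(0, 4500))
})

test_that("the negative-window cut applies only when no positive spans it", {
  # positives overlap each other and a negative window sits between their
  # starts, but is spanned by the first positive: stay merged
  w <- tibble::tibble(chrom = "c1",
                      start = c(0, 500, 1000),
                      end = c(2000, 2500, 3000),
                      score = c(1, -1, 1),
                      callable = TRUE)
  expect_equal(nrow(merge_windows(w)), 1)

  # adjacency-linked positives with a fully-negative window between whose
  # midpoint neither positive covers: split (only the sliding geometry can
  # produce this: e.g. positives at 0 and 2000, negative window at 1000)
  w2 <- tibble::tibble(chrom = "c1",
                       start = c(0, 1000, 2000),
                       end = c(2000, 3000, 4000),
                       score = c(1, -1, 1),
                       callable = TRUE)
  expect_equal(nrow(merge_windows(w2, split_at_negative = TRUE)), 2)
  expect_equal(nrow(merge_windows(w2, split_at_negative = FALSE)), 1)
})

test_that("merge components equal the union-find oracle on random tracks", {
  withr::with_seed(83, {
    for (rep in 1:8) {
      n <- 40
      starts <- sort(sample(0:20000, n)) * 1L
      w <- tibble::tibble(chrom = sample(c("cA", "cB"), n, replace = TRUE),
                          start = starts, end = starts + 800,
                          score = rnorm(n), callable = TRUE)
      got <- merge_windows(w, split_at_negative = FALSE)
      want <- bf_merge_components(w)
      expect_equal(got$chrom, want$chrom)
      expect_equal(got$start, want$start)
      expect_equal(got$end, want$end)
    }
  })
})

test_that("representatives take the max score, leftmost on ties", {
  w <- tibble::tibble(chrom = "c1", start = c(0, 500, 1000),
                      end = c(2000, 2500, 3000),
                      score = c(0.2, 0.9, 0.4), callable = TRUE)
  enh <- merge_windows(w)
  rep1 <- representatives(enh)
  expect_equal(rep1$start, 500)
  expect_equal(rep1$score, 0.9)

  w$score <- c(0.7, 0.3, 0.7)  # tie between first and last
  rep2 <- representatives(merge_windows(w))
  expect_equal(rep2$start, 0)
  expect_equal(nrow(rep2), nrow(merge_windows(w)))
})

test_that("merge is idempotent on its own spans", {
  withr::with_seed(84, {
    n <- 60
    starts <- sort(sample(0:30000, n)) * 1L
    w <- tibble::tibble(chrom = "c1", start = starts, end = starts + 1000,
                        score = rnorm(n, 0.2), callable = TRUE)
    enh <- merge_windows(w, split_at_negative = FALSE)
    again <- merge_windows(
      tibble::tibble(chrom = enh$chrom, start = enh$start, end = enh$end,
                     score = enh$score, callable = TRUE),
      split_at_negative = FALSE)
    expect_equal(again$start, enh$start)
    expect_equal(again$end, enh$end)
  })
})

test_that("every positive base is covered by exactly one enhancer", {
  withr::with_seed(85, {
    n <- 50
    starts <- sort(sample(0:15000, n)) * 1L
    w <- tibble::tibble(chrom = "c1", start = starts, end = starts + 600,
                        score = rnorm(n), callable = TRUE)
    enh <- merge_windows(w, split_at_negative = FALSE)
    pos <- w[w$score > 0, ]
    for (i in seq_len(nrow(pos))) {
      holders <- sum(enh$start <= pos$start[i] & enh$end >= pos$end[i])
      expect_equal(holders, 1)
    }
    # enhancers never overlap each other
    if (nrow(enh) > 1)
      expect_true(all(enh$start[-1] > enh$end[-nrow(enh)]))
  })
})

test_that("coverage equals merged span over chromosome length (cross-module)", {
  sim <- simulate_enhancer_genome(small_sim_config(seed = 86))
  m <- gc_block_model(b = -0.0005)  # positive on G-homopolymer-rich windows
  cov <- genomic_coverage(m, sim$genome, "chrP1")
  sw <- scan_genome(m, sim$genome, chroms = "chrP1")
  enh <- merge_windows(sw)
  span <- if (nrow(enh) > 0) sum(enh$end - enh$start) else 0
  expect_equal(cov, span / Biostrings::width(sim$genome)[1])
})
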