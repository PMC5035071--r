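test_that("TPM building removes promoter-proximal markers", {
  tss <- intervals("c1", 10000, 10001)
  near <- intervals("c1", 10002, 11001)    # edge distance 1 <= 1000
  at999 <- intervals("c1", 11000, 11500)   # edge distance 999
  at1001 <- intervals("c1", 11002, 11500)  # edge distance 1001
  other <- intervals("c2", 0, 500)         # no TSS on c2 -> retained
  tpm <- build_tpm(dhs = dplyr::bind_rows(near, at1001),
                   p300 = at999, tf = other, tss = tss)
  expect_equal(nrow(tpm$dhs), 1)
  expect_equal(tpm$dhs$start, 11002)
  expect_equal(nrow(tpm$p300), 0)
  expect_equal(nrow(tpm$tf), 1)
  expect_equal(nrow(tpm$tpm), 2)
  expect_equal(tpm$retention$n_kept, c(1L, 0L, 1L))
})

test_that("TPM retention matches the brute-force distance filter", {
  withr::with_seed(91, {
    tss <- rand_intervals(30, min_len = 1, max_len = 1)
    mk <- rand_intervals(80, min_len = 100, max_len = 400)
    tpm <- build_tpm(dhs = mk, p300 = mk[0, ], tf = mk[0, ], tss = tss)
    keep <- bf_nearest(mk, tss, "edge") > 1000
    expect_equal(tpm$dhs, mk[keep, ])
  })
})

test_that("categorize applies validated -> misclassified -> unknown in order", {
  win <- intervals("c1", c(10000, 30000, 50000),
                   c(12000, 32000, 52000))
  tpm <- intervals("c1", c(12800), c(13000))       # 800 bp from window 1
  tss <- intervals("c1", c(34000, 55000), c(34001, 55001))
  # window 2: TPM far, TSS edge distance 2000 -> misclassified
  # window 3: TPM far, TSS 3000 -> unknown
  val <- categorize_enhancers(win, tpm, tss)
  expect_equal(as.character(val$windows$category),
               c("validated", "misclassified", "unknown"))
  expect_equal(sum(val$summary$n), 3)
  expect_equal(sum(val$summary$pct), 100)
})

test_that("threshold boundaries are inclusive", {
  win <- intervals("c1", 10000, 12000)
  exactly1k <- intervals("c1", 13000, 13200)   # edge distance exactly 1000
  val <- categorize_enhancers(win, exactly1k, intervals("c1", 0, 1))
  expect_equal(as.character(val$windows$category), "validated")
  tss2500 <- intervals("c1", 14500, 14501)     # edge distance exactly 2500
  val2 <- categorize_enhancers(win, exactly1k[0, ], tss2500)
  expect_equal(as.character(val2$windows$category), "misclassified")
})

test_that("marker states follow the six-way exclusive mapping", {
  win <- intervals("c1", 10000, 12000)
  hit <- intervals("c1", 11000, 11200)
  far <- intervals("c1", 90000, 90200)
  st <- function(p300, dhs, tf)
    as.character(marker_states(win, dhs = dhs, p300 = p300, tf = tf))
  expect_equal(st(hit, far, far), "p300+/-DHS")   # p300 only
  expect_equal(st(hit, hit, far), "p300+/-DHS")   # p300 + DHS absorbed
  expect_equal(st(far, hit, far), "DHS only")
  expect_equal(st(far, hit, hit), "TF+DHS")
  expect_equal(st(far, far, hit), "TF only")
  expect_equal(st(hit, far, hit), "TF+p300")
  expect_equal(st(hit, hit, hit), "p300+DHS+TF")
  expect_error(st(far, far, far), "no nearby marker")
})

test_that("CAGE-enhancer overlap rate counts >= 1 bp overlaps", {
  win <- intervals("c1", c(0, 5000), c(2000, 7000))
  expect_equal(fantom_overlap_rate(win, win[0, ]), 0)
  giant <- intervals("c1", 0, 10000)
  expect_equal(fantom_overlap_rate(win, giant), 1)
  touch <- intervals("c1", 2000, 2500)  # touches window 1 only (0 bp)
  expect_equal(fantom_overlap_rate(win, touch), 0)
  withr::with_seed(92, {
    w <- rand_intervals(100, min_len = 500, max_len = 2000)
    f <- rand_intervals(40, min_len = 200, max_len = 600)
    expect_equal(fantom_overlap_rate(w, f),
                 length(bf_overlap_rows(w, f)) / 100)
  })
})

test_that("conservation uses exon-filtered midpoints", {
  enh <- intervals("c1", c(1000, 5000, 9000), c(3000, 7000, 11000))
  conserved <- intervals("c1", 1990, 2010)   # contains midpoint 2000
  exons <- intervals("c1", 6900, 7100)       # overlaps enhancer 2
  r <- conserved_midpoint_rate(enh, conserved, exons)
  expect_equal(r, 1 / 2)  # enhancer 2 dropped; 1 of remaining 2 conserved
  # midpoint just outside the segment does not count
  expect_equal(conserved_midpoint_rate(intervals("c1", 1000, 3000),
                                       intervals("c1", 2001, 2100),
                                       exons[0, ]), 0)
  expect_warning(
    r2 <- conserved_midpoint_rate(enh[2, ], conserved, exons),
    "undefined")
  expect_true(is.na(r2))
})

test_that("rate statistics are invariant under input shuffling", {
  withr::with_seed(93, {
    w <- rand_intervals(60, min_len = 500, max_len = 2000)
    f <- rand_intervals(30, min_len = 200, max_len = 800)
    ex <- rand_intervals(20, min_len = 100, max_len = 300)
    perm <- sample(nrow(w))
    expect_equal(fantom_overlap_rate(w, f),
                 fantom_overlap_rate(w[perm, ], f))
    expect_equal(conserved_midpoint_rate(w, f, ex),
                 conserved_midpoint_rate(w[perm, ], f[sample(nrow(f)), ],
                                         ex))
  })
})

test_that("two-proportion z-test matches the pooled formula", {
  eq <- two_proportion_ztest(30, 100, 15, 50)
  expect_equal(eq$z, 0)
  expect_equal(eq$p_value, 1)

  zt <- two_proportion_ztest(90, 100, 50, 100)
  p_pool <- 140 / 200
  z_hand <- (0.9 - 0.5) / sqrt(p_pool * (1 - p_pool) * (1 / 100 + 1 / 100))
  expect_equal(zt$z, z_hand)
  expect_equal(zt$p_value, 2 * pnorm(-abs(z_hand)))

  # antisymmetry
  sw <- two_proportion_ztest(50, 100, 90, 100)
  expect_equal(sw$z, -zt$z)
  expect_equal(sw$p_value, zt$p_value)

  # agreement with the chi-square equivalence (z^2 = X^2, no correction)
  pt <- prop.test(c(90, 50), c(100, 100), correct = FALSE)
  expect_equal(zt$z^2, unname(pt$statistic))

  expect_warning(und <- two_proportion_ztest(0, 10, 0, 20), "pooled")
  expect_true(is.na(und$z))
})

test_that("categories and states partition their inputs on a full run", {
  sim <- simulate_enhancer_genome(small_sim_config(seed = 94))
  tpm <- build_tpm(sim$dhs, sim$p300, sim$tf, sim$tss)
  withr::with_seed(94, {
    win <- rand_intervals(40, chroms = names(sim$genome), L = 195000,
                          min_len = 2000, max_len = 2000)
  })
  val <- categorize_enhancers(win, tpm$tpm, sim$tss)
  expect_equal(sum(val$summary$n), nrow(win))
  expect_equal(sum(val$summary$pct), 100)
  vw <- val$windows[val$windows$category == "validated", ]
  if (nrow(vw) > 0) {
    st <- marker_states(vw, tpm$dhs, tpm$p300, tpm$tf)
    expect_equal(length(st), nrow(vw))
    expect_false(anyNA(st))
    expect_equal(sum(table(st)), nrow(vw))
  }
})
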