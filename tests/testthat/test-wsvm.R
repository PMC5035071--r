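test_that("weight constructor enforces the confidence ordering", {
  expect_error(wsvm_weights(1, 10, 1, 10), "c_rp >= c_lp")
  expect_error(wsvm_weights(10, 1, 10, 1), "c_rn >= c_ln")
  expect_error(wsvm_weights(-1, -1, 1, 1), "positive")
  w <- wsvm_weights(10, 1, 2, 20)
  expect_equal(weights_for_sets(w, factor(c("RP", "RN", "LP", "LN"))),
               c(10, 20, 1, 2))
})

test_that("symmetric separable 1-D problem has the analytic optimum", {
  tr <- list(x = matrix(c(-1, 1), 2, 1), y = c(-1, 1),
             set = factor(c("RN", "RP"), levels = c("RP", "LP", "LN", "RN")))
  m <- wsvm(tr, wsvm_weights(1e6, 1e6, 1e6, 1e6), tol = 1e-10)
  expect_equal(unname(m$w), 1, tolerance = 1e-8)
  expect_equal(m$b, 0, tolerance = 1e-8)
  expect_equal(max(m$xi), 0, tolerance = 1e-8)
})

test_that("equal weights reduce to a standard C-SVM (libsvm cross-check)", {
  skip_if_not_installed("e1071")
  tr <- make_training(n = 80, d = 10, sep = 0.8, seed = 61)
  m <- wsvm(tr, wsvm_weights(3, 3, 3, 3), tol = 1e-12)
  em <- e1071::svm(tr$x, factor(tr$y), kernel = "linear", cost = 3,
                   scale = FALSE, tolerance = 1e-10)
  dv <- attr(predict(em, tr$x, decision.values = TRUE), "decision.values")
  sgn <- if (colnames(dv)[1] == "1/-1") 1 else -1
  # libsvm converges to ~1e-5 in its decision values; the exact-QP
  # comparison at 1e-6 lives in the acceptance suite
  expect_equal(predict(m, tr$x), sgn * dv[, 1], tolerance = 1e-4,
               ignore_attr = TRUE)
})

test_that("unequal weights match the sample-replication libsvm oracle", {
  skip_if_not_installed("e1071")
  tr <- make_training(n = 60, d = 6, sep = 0.6, seed = 62)
  m <- wsvm(tr, wsvm_weights(6, 2, 2, 4), tol = 1e-12)
  # integer cost ratios: replicating a row r times multiplies its C by r
  reps <- c(RP = 3, LP = 1, LN = 1, RN = 2)[as.character(tr$set)]
  xr <- tr$x[rep(seq_len(60), reps), ]
  yr <- tr$y[rep(seq_len(60), reps)]
  er <- e1071::svm(xr, factor(yr), kernel = "linear", cost = 2,
                   scale = FALSE, tolerance = 1e-10)
  dv <- attr(predict(er, tr$x, decision.values = TRUE), "decision.values")
  sgn <- if (colnames(dv)[1] == "1/-1") 1 else -1
  expect_equal(predict(m, tr$x), sgn * dv[, 1], tolerance = 1e-4,
               ignore_attr = TRUE)
})

test_that("the optimum is KKT-certified and matches the dual QP oracle", {
  skip_if_not_installed("kernlab")
  tr <- make_training(n = 50, d = 5, sep = 0.5, seed = 63)
  ws <- wsvm_weights(8, 2, 1, 5)
  m <- wsvm(tr, ws, tol = 1e-10)
  C <- weights_for_sets(ws, tr$set)
  expect_lt(kkt_residual(m, tr$x, tr$y, C), 1e-8)
  orac <- qp_svm_oracle(tr$x, tr$y, C)
  expect_equal(m$objective, orac$objective, tolerance = 1e-6)
  expect_true(all(m$xi >= 0))
})

test_that("scaling all weights leaves a separable hyperplane unchanged", {
  tr <- make_training(n = 40, d = 4, sep = 4, seed = 64)  # wide margin
  m1 <- wsvm(tr, wsvm_weights(100, 100, 100, 100), tol = 1e-10)
  m2 <- wsvm(tr, wsvm_weights(1000, 1000, 1000, 1000), tol = 1e-10)
  expect_equal(m1$w, m2$w, tolerance = 1e-6)
  expect_equal(m1$b, m2$b, tolerance = 1e-6)
  expect_equal(max(m1$xi), 0, tolerance = 1e-8)
})

test_that("single-class input is rejected", {
  tr <- list(x = matrix(rnorm(20), 10, 2), y = rep(1, 10),
             set = factor(rep("RP", 10), levels = c("RP", "LP", "LN", "RN")))
  expect_error(wsvm(tr), "both classes")
})

test_that("prf_metrics implements the pooled recall/precision/F rules", {
  m <- prf_metrics(50, 50, 100)
  expect_equal(c(m$recall, m$precision, m$f), c(0.5, 0.5, 0.5))
  expect_equal(prf_metrics(0, 10, 5)$f, 0)
  expect_equal(prf_metrics(0, 0, 0)$f, 0)
  withr::with_seed(65, {
    for (i in 1:20) {
      tp <- sample(0:50, 1); fn <- sample(0:50, 1); pp <- sample(0:80, 1)
      m <- prf_metrics(tp, fn, pp)
      r <- if (tp + fn > 0) tp / (tp + fn) else 0
      p <- if (pp > 0) tp / pp else 0
      expect_equal(m$f, if (p + r > 0) 2 * p * r / (p + r) else 0)
    }
  })
})

test_that("genomic coverage reflects the scanned merged span", {
  g <- make_random_genome(c(cP = 50000), seed = 66)
  always <- constant_model(b = 1)
  expect_equal(genomic_coverage(always, g, "cP"), 1)
  never <- constant_model(b = -1)
  expect_equal(genomic_coverage(never, g, "cP"), 0)
})

test_that("a planted high-scoring block yields ~block/chromosome coverage", {
  block <- paste(rep("G", 10000), collapse = "")
  withr::with_seed(67, {
    left <- random_dna(45000, letters = c("A", "T"))
    right <- random_dna(45000, letters = c("A", "T"))
  })
  g <- Biostrings::DNAStringSet(c(cB = paste0(left, block, right)))
  m <- gc_block_model(b = -0.5)
  cov <- genomic_coverage(m, g, "cB")
  expect_lt(abs(cov - 0.1), 2000 / 100000 + 1e-9)
})

test_that("select_wsvm returns the single grid point when the grid is 1x1", {
  sim <- simulate_enhancer_genome(small_sim_config(seed = 71))
  lmrs <- filter_by_length(sim$lmrs)
  x <- encode_kmers(extract_sequences(sim$genome, lmrs))
  anchors <- overlap_select(dplyr::mutate(lmrs,
                                          .row = dplyr::row_number()),
                            sim$vista)
  dens <- fit_kmer_density(x[anchors$.row, , drop = FALSE])
  ranked <- rank_by_density(dens, lmrs, x)
  neg <- generate_negatives(lmrs, sim$genome, exclusions = lmrs, seed = 72)
  rx <- encode_kmers(extract_sequences(sim$genome, neg))
  sel <- select_wsvm(ranked, x, rx, sim$genome, "chrP1",
                     delta_grid = 0.95,
                     weight_grid = list(wsvm_weights(100, 10, 5, 50)),
                     coverage_cap = 1, seed = 73)
  expect_equal(nrow(sel$report), 1)
  expect_true(sel$report$selected)
  expect_equal(sel$delta, 0.95)
  expect_equal(unlist(sel$weights), c(c_rp = 100, c_lp = 10, c_ln = 5,
                                      c_rn = 50))
  # deterministic given the seed
  sel2 <- select_wsvm(ranked, x, rx, sim$genome, "chrP1",
                      delta_grid = 0.95,
                      weight_grid = list(wsvm_weights(100, 10, 5, 50)),
                      coverage_cap = 1, seed = 73)
  expect_equal(sel$report, sel2$report)
  expect_equal(sel$model$w, sel2$model$w)

  # an impossible coverage cap excludes everything
  expect_error(select_wsvm(ranked, x, rx, sim$genome, "chrP1",
                           delta_grid = 0.95,
                           weight_grid = list(wsvm_weights(100, 10, 5, 50)),
                           coverage_cap = -1, seed = 73),
               "coverage cap")
})

test_that("tidy and glance expose coefficients and fit diagnostics", {
  tr <- make_training(n = 30, d = 4, sep = 1, seed = 68)
  m <- wsvm(tr, wsvm_weights(5, 1, 1, 5), tol = 1e-8)
  td <- generics::tidy(m)
  expect_equal(nrow(td), 4)
  expect_named(td, c("term", "estimate"))
  gl <- generics::glance(m)
  expect_true(gl$converged)
  expect_lt(gl$kkt_gap, 1e-8)
})
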