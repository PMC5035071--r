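# Brute-force oracles and fixture builders shared across the suite.
# Oracles are deliberately naive (quadratic scans, dictionary counting,
# generic QP) and independent of the package's implementation paths.

rand_intervals <- function(n, chroms = c("c1", "c2"), L = 1e5,
                           min_len = 50, max_len = 2000) {
  len <- sample(min_len:max_len, n, replace = TRUE)
  start <- vapply(len, function(l) sample(0:(L - l), 1), numeric(1))
  tibble::tibble(chrom = sample(chroms, n, replace = TRUE),
                 start = start, end = start + len)
}

# quadratic overlap oracle: which rows of a overlap any row of b by >= min_bp
bf_overlap_rows <- function(a, b, min_bp = 1) {
  hit <- logical(nrow(a))
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] != b$chrom[j]) next
      ov <- min(a$end[i], b$end[j]) - max(a$start[i], b$start[j])
      if (ov >= min_bp) { hit[i] <- TRUE; break }
    }
  }
  which(hit)
}

bf_nearest <- function(ivs, anchors, mode = "edge") {
  out <- rep(Inf, nrow(ivs))
  for (i in seq_len(nrow(ivs))) {
    for (j in seq_len(nrow(anchors))) {
      if (ivs$chrom[i] != anchors$chrom[j]) next
      d <- if (mode == "edge") {
        max(0, max(ivs$start[i], anchors$start[j]) -
              min(ivs$end[i], anchors$end[j]))
      } else {
        abs(floor((ivs$start[i] + ivs$end[i]) / 2) -
              floor((anchors$start[j] + anchors$end[j]) / 2))
      }
      out[i] <- min(out[i], d)
    }
  }
  out
}

# dictionary-counting k-mer oracle: normalized counts over valid windows
bf_kmer_encode <- function(seq, k) {
  words <- lmrsvm::kmer_words(k)
  v <- setNames(numeric(length(words)), words)
  n <- nchar(seq)
  if (n >= k) {
    wins <- substring(seq, 1:(n - k + 1), k:n)
    wins <- wins[!grepl("[^ACGT]", wins)]
    if (length(wins) > 0) {
      tab <- table(wins)
      v[names(tab)] <- as.numeric(tab)
    }
  }
  if (sum(v) > 0) v / sum(v) else v
}

random_dna <- function(n, letters = c("A", "C", "G", "T")) {
  paste(sample(letters, n, replace = TRUE), collapse = "")
}

make_random_genome <- function(lengths, seed = 1, gc = 0.45) {
  withr::with_seed(seed, {
    p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    Biostrings::DNAStringSet(setNames(vapply(lengths, function(L)
      paste(sample(names(p), L, replace = TRUE, prob = p), collapse = ""),
      ""), names(lengths)))
  })
}

# union-find connected components of positive windows under
# overlap-or-adjacency (the no-split merge semantics)
bf_merge_components <- function(windows) {
  pos <- windows[windows$score > 0, , drop = FALSE]
  pos <- pos[order(pos$chrom, pos$start), , drop = FALSE]
  n <- nrow(pos)
  if (n == 0) return(pos[0, c("chrom", "start", "end")])
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j || pos$chrom[i] != pos$chrom[j]) next
    if (pos$start[j] <= pos$end[i] && pos$start[i] <= pos$end[j]) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  sp <- split(seq_len(n), root)
  out <- do.call(rbind, lapply(sp, function(ix)
    data.frame(chrom = pos$chrom[ix[1]], start = min(pos$start[ix]),
               end = max(pos$end[ix]))))
  out[order(out$chrom, out$start), , drop = FALSE]
}

# exact C-SVM / weighted-SVM reference: dual QP via kernlab's interior-point
# solver, bias recovered from free support vectors
qp_svm_oracle <- function(x, y, C, sigf = 10) {
  n <- nrow(x)
  Q <- (y %*% t(y)) * (x %*% t(x))
  sol <- NULL
  for (s in unique(c(sigf, 8, 7))) {  # interior point can hit singular
    sol <- try(kernlab::ipop(c = rep(-1, n), H = Q, A = t(y), b = 0,
                             l = rep(0, n), u = unname(C), r = 0,
                             sigf = s, maxiter = 400), silent = TRUE)
    if (!inherits(sol, "try-error")) break
  }
  if (inherits(sol, "try-error")) return(NULL)
  alpha <- kernlab::primal(sol)
  w <- drop(t(x) %*% (alpha * y))
  free <- alpha > 1e-5 * C & alpha < C * (1 - 1e-5)
  b <- if (any(free)) mean(y[free] - (x %*% w)[free]) else 0
  xi <- pmax(0, 1 - y * (drop(x %*% w) + b))
  list(alpha = alpha, w = w, b = b,
       objective = 0.5 * sum(w^2) + sum(C * xi))
}

kkt_residual <- function(model, x, y, C) {
  yf <- y * predict(model, x)
  a <- model$alpha
  max(pmax(ifelse(a < 1e-8 * C, 1 - yf,
                  ifelse(a > C * (1 - 1e-8), yf - 1, abs(yf - 1))), 0))
}

# hand-built linear model (bypasses training) for scan/merge mechanics
constant_model <- function(b, k = 5) {
  w <- setNames(numeric(4^k), lmrsvm::kmer_words(k))
  structure(list(w = w, b = b, alpha = numeric(0)), class = "wsvm_model")
}

gc_block_model <- function(k = 5, b = -0.5) {
  # scores + iff more than half the k-mers are the G homopolymer
  w <- setNames(numeric(4^k), lmrsvm::kmer_words(k))
  w[paste(rep("G", k), collapse = "")] <- 1
  structure(list(w = w, b = b, alpha = numeric(0)), class = "wsvm_model")
}

# small four-set training fixture with controllable separation
make_training <- function(n = 80, d = 8, sep = 1, seed = 1) {
  withr::with_seed(seed, {
    y <- rep(c(1, -1), each = n / 2)
    x <- matrix(rnorm(n * d), n, d) + outer(y, rep(sep / 2, d))
    set <- factor(ifelse(y > 0,
                         sample(c("RP", "LP"), n, replace = TRUE),
                         sample(c("LN", "RN"), n, replace = TRUE)),
                  levels = c("RP", "LP", "LN", "RN"))
    list(x = x, y = y, set = set)
  })
}

small_sim_config <- function(seed = 1) {
  sim_config(seed = seed,
             chrom_lengths = c(chrP1 = 2e5, chrP2 = 2e5),
             n_enhancers = 6, vista_frac = 0.7, n_lmrs = 120, n_exons = 40, n_tss = 40,
             n_background_markers = 15, n_background_fantom = 15,
             n_background_conserved = 150, n_gap_bp = 2000)
}
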