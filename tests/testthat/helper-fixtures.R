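# Shared fixtures and independent oracles. The oracles deliberately use
# brute-force enumeration or direct arithmetic, never the package's (or
# stats') routines they are checking against.

tiny_registry <- function() {
  class_registry(superclasses = c("1", "2", "3"),
                 classes = c("1.1", "1.2", "2.1", "2.2", "2.3", "3.1"))
}

# Minimal annotation corpus with controllable fields.
make_records <- function(n = 4, codes = rep("1.1", n), labels = "unlabeled",
                         pfam = NULL, ...) {
  tf_records(tf_id = sprintf("T%03d", seq_len(n)), tfclass_code = codes,
             pfam_counts = pfam, label = labels, ...)
}

# Small separable corpus for training tests: class is essentially
# determined by the TFClass code plus a near-exclusive marker domain.
separable_sim <- function(seed = 1) {
  cfg <- simulation_config(
    seed = seed,
    n_per_class = c(P = 20L, S = 20L, `M+` = 20L, `M-` = 20L),
    class_tfclass_counts = matrix(
      diag(4), 4, 4,
      dimnames = list(c("1.1", "2.1", "3.1", "4.1"),
                      c("P", "S", "M+", "M-"))),
    class_pfam_rates = matrix(
      c(0.95, 0.02, 0.02, 0.02,
        0.02, 0.95, 0.02, 0.02,
        0.02, 0.02, 0.95, 0.02,
        0.02, 0.02, 0.02, 0.95), 4, byrow = TRUE,
      dimnames = list(c("dP", "dS", "dM", "dN"),
                      c("P", "S", "M+", "M-"))))
  generate_tf_table(cfg)
}

# Block-structured binary feature matrix for model-selection tests:
# `informative` block separates y, `noise` blocks are Bernoulli(1/2).
make_block_features <- function(y, n_informative = 4, n_noise_blocks = 2,
                                block_size = 4, flip = 0) {
  n <- length(y)
  info <- vapply(seq_len(n_informative), function(j) {
    bit <- as.integer(y)
    swap <- runif(n) < flip
    ifelse(swap, 1L - bit, bit)
  }, integer(n))
  noise <- matrix(rbinom(n * n_noise_blocks * block_size, 1, 0.5), n)
  x <- cbind(info, noise)
  colnames(x) <- paste0("b", seq_len(ncol(x)))
  lens <- c(INFO = n_informative, rep(block_size, n_noise_blocks))
  names(lens)[-1] <- paste0("NOISE", seq_len(n_noise_blocks))
  ends <- cumsum(lens)
  structure(x,
            blocks = stats::setNames(
              lapply(seq_along(lens),
                     function(i) (ends[i] - lens[i] + 1L):ends[i]),
              names(lens)),
            class = c("tf_features", class(x)))
}

# Two-sided Fisher exact p by full enumeration of tables with the observed
# margins: sum the point hypergeometric probabilities of every table as or
# less probable than the observed one.
oracle_fisher_two_sided <- function(a, b, c, d) {
  r1 <- a + b
  r2 <- c + d
  c1 <- a + c
  n <- r1 + r2
  xs <- max(0, c1 - r2):min(r1, c1)
  point <- function(x) {
    exp(lchoose(r1, x) + lchoose(r2, c1 - x) - lchoose(n, c1))
  }
  probs <- vapply(xs, point, 0)
  p_obs <- probs[xs == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# AUC as the explicit O(n^2) positive-negative pair count.
oracle_auc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + (p > q) + 0.5 * (p == q)
  }
  total / (length(pos) * length(neg))
}

# Exact two-sided signed-rank p by enumeration of all 2^n sign
# assignments of the ranks of |d| (no zeros, no tied magnitudes).
oracle_signed_rank <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(FALSE, TRUE)), n))
  w_all <- apply(signs, 1, function(s) sum(r[as.logical(s)]))
  centre <- n * (n + 1) / 4
  p <- if (w_obs > centre) 2 * mean(w_all >= w_obs) else
    2 * mean(w_all <= w_obs)
  min(1, p)
}

# Benjamini-Hochberg by the literal step-up formula.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  for (i in (n - 1):1) adj[i] <- min(adj[i], adj[i + 1])
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# Nearest-centroid classifier used as a sanity oracle for separable tasks.
oracle_nearest_centroid <- function(x_train, y_train, x_new) {
  mu_pos <- colMeans(x_train[y_train == "pos", , drop = FALSE])
  mu_neg <- colMeans(x_train[y_train == "neg", , drop = FALSE])
  d_pos <- rowSums(sweep(x_new, 2, mu_pos)^2)
  d_neg <- rowSums(sweep(x_new, 2, mu_neg)^2)
  ifelse(d_pos < d_neg, "pos", "neg")
}
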