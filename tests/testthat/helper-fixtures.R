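# small in-code fixtures shared across tests

# k well-separated Gaussian blobs in d dimensions
make_blobs <- function(n_per = 50, k = 4, d = 5, sep = 10, sd = 1, seed = 1) {
  set.seed(seed)
  # centers on orthonormal directions: all pairwise distances sep * sqrt(2)
  mu <- qr.Q(qr(matrix(stats::rnorm(d * d), d, d)))[seq_len(k), ] * sep
  x <- do.call(rbind, lapply(seq_len(k), function(i) {
    matrix(stats::rnorm(n_per * d, sd = sd), n_per, d) +
      matrix(mu[i, ], n_per, d, byrow = TRUE)
  }))
  list(x = x, labels = rep(seq_len(k), each = n_per))
}

# feature table with a planted cluster structure (fast stand-in for images)
make_planted_table <- function(n = 120, p = 30, k = 4, sep = 4, seed = 1) {
  set.seed(seed)
  mu <- matrix(stats::rnorm(k * p, sd = sep), k, p)
  g <- rep(seq_len(k), length.out = n)
  x <- mu[g, ] + matrix(stats::rnorm(n * p), n, p)
  colnames(x) <- paste0("f", seq_len(p))
  list(table = as.data.frame(x), labels = g)
}

make_disc <- function(lv) {
  structure(list(levels = lv, ng = max(lv, na.rm = TRUE), bin_width = 1,
                 mask = !is.na(lv)), class = "oct_disc")
}
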