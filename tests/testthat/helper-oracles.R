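# Independent, deliberately naive implementations used as oracles.
# Everything here is written with explicit loops and textbook formulas, on a
# separate code path from the package internals.

naive_mean <- function(x) sum(x) / length(x)

naive_sd <- function(x) {
  m <- naive_mean(x)
  sqrt(sum((x - m)^2) / (length(x) - 1))
}

naive_correlation <- function(X) {
  n <- ncol(X)
  r <- matrix(NA_real_, n, n)
  for (k in seq_len(n)) {
    for (l in seq_len(n)) {
      xk <- X[, k] - naive_mean(X[, k])
      xl <- X[, l] - naive_mean(X[, l])
      r[k, l] <- sum(xk * xl) / (sqrt(sum(xk^2)) * sqrt(sum(xl^2)))
    }
  }
  r
}

# full CRITIC chain: standardize, contrast, conflict, information, weights
naive_critic_weights <- function(X, convention = "table", magnitude = "abs") {
  m <- nrow(X); n <- ncol(X)
  std <- X
  v <- numeric(n)
  for (j in seq_len(n)) {
    mu <- naive_mean(X[, j])
    s <- naive_sd(X[, j])
    std[, j] <- (X[, j] - mu) / s
    v[j] <- if (convention == "table") mu / s else s / mu
  }
  r <- naive_correlation(std)
  eta <- numeric(n)
  for (j in seq_len(n)) {
    for (k in seq_len(n)) eta[j] <- eta[j] + (1 - abs(r[k, j]))
  }
  fv <- if (magnitude == "abs") abs(v) else v
  d <- fv * eta
  d / sum(d)
}

# one subject-phase record on legal grids, for pairing tests
make_record <- function(subject_id = "A", phase = "pre", va = 0.5,
                        brbp_right = 5, brbp_left = 3, pep_h = 1.1,
                        pep_v = NA_real_, stereo = 2) {
  tibble::tibble(
    subject_id = subject_id, phase = phase, va_logmar = va,
    pep_h_deg = pep_h, pep_v_deg = pep_v,
    brbp_right = brbp_right, brbp_left = brbp_left, stereo_level = stereo
  )
}

# small random difference-score matrix with named indicator columns
random_indicator_matrix <- function(m = 8, n = 4) {
  x <- matrix(stats::rnorm(m * n, mean = stats::runif(1, -2, 2)), m, n)
  colnames(x) <- paste0("ind", seq_len(n))
  x
}
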