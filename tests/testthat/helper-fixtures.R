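# Shared fixtures: everything is generated in code at test time.

# Small, fast cohort for structural and IO tests.
tiny_config <- function(seed = 1, ...) {
  synthetic_config(n_patients = 2, n_controls = 2,
                   freq_start = 0.10, freq_stop = 0.40, freq_step = 0.10,
                   seed = seed, ...)
}

# Mid-sized cohort: big enough for meaningful LOO, still sub-second.
small_config <- function(seed = 1, ...) {
  synthetic_config(n_patients = 6, n_controls = 6,
                   freq_start = 0.10, freq_stop = 1.00, freq_step = 0.10,
                   seed = seed, ...)
}

# Random complex matrix helper.
rcplx <- function(n, m = NULL, sd = 1) {
  k <- if (is.null(m)) n else n * m
  z <- complex(real = stats::rnorm(k, sd = sd),
               imaginary = stats::rnorm(k, sd = sd))
  if (is.null(m)) z else matrix(z, n, m)
}

# Brute-force AUC oracle: Mann-Whitney pair counting, ties count one half.
pair_count_auc <- function(scores, labels) {
  pos <- scores[labels == "cSDH"]
  neg <- scores[labels == "HC"]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + (p > q) + 0.5 * (p == q)
  }
  total / (length(pos) * length(neg))
}

# Brute-force least-squares projection of x onto the column span of X.
ls_projection <- function(X, x) {
  X %*% solve(Conj(t(X)) %*% X, Conj(t(X)) %*% x)
}

# Power iteration for the leading eigenvector of the Hermitian matrix A.
power_leading_eigvec <- function(A, iters = 2000) {
  v <- complex(real = seq_len(nrow(A)), imaginary = rev(seq_len(nrow(A))))
  v <- v / sqrt(sum(Mod(v)^2))
  for (i in seq_len(iters)) {
    v <- A %*% v
    v <- v / sqrt(sum(Mod(v)^2))
  }
  as.vector(v)
}
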