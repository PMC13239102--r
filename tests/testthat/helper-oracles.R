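# Independent oracles, deliberately written against different code paths
# than the production kernels they check.

# Brute-force sample entropy by explicit template counting with full
# Chebyshev distance matrices (O(N^2 m) memory/work).
oracle_sampen <- function(x, m = 3L, r_frac = 0.6) {
  N <- length(x)
  r <- r_frac * sqrt(mean((x - mean(x))^2))
  nt <- N - m
  cheb_count <- function(len) {
    D <- matrix(0, nt, nt)
    for (k in 0:(len - 1)) {
      v <- x[seq_len(nt) + k]
      D <- pmax(D, abs(outer(v, v, "-")))
    }
    (sum(D <= r) - nt) / 2  # unordered pairs, self-matches excluded
  }
  B <- cheb_count(m)
  A <- cheb_count(m + 1L)
  if (A == 0 || B == 0) return(NA_real_)
  -log(A / B)
}

# Least-squares residuals via the normal equations (not QR).
oracle_resid <- function(y, X) {
  beta <- solve(t(X) %*% X, t(X) %*% y)
  y - X %*% beta
}

# Amplitude of the component of `x` at frequency f (Hz), via the DFT bin
# nearest to f.
fft_amplitude <- function(x, f, tr) {
  n <- length(x)
  bin <- round(f * n * tr) + 1L
  2 * Mod(fft(x))[bin] / n
}

# Scalar paired t by the textbook formula.
oracle_paired_t <- function(a, b) {
  d <- a - b
  n <- length(d)
  tval <- mean(d) / (sd(d) / sqrt(n))
  list(t = tval, df = n - 1, p = 2 * pt(-abs(tval), n - 1))
}

# t -> z through numerical quadrature of the t density (independent of pt).
oracle_t_to_z <- function(t, df) {
  dens <- function(u) dt(u, df)
  if (t <= 0) {
    p <- integrate(dens, -Inf, t, rel.tol = 1e-12)$value
    qnorm(p)
  } else {
    p_upper <- integrate(dens, t, Inf, rel.tol = 1e-12)$value
    -qnorm(p_upper)
  }
}

# Small cohort spec used across pipeline tests.
tiny_spec <- function(n_subjects = 4, seed = 11, grid = c(10L, 10L, 4L),
                      n_volumes = 64L) {
  cohort_spec(n_subjects = n_subjects, grid_shape = grid,
              n_volumes = n_volumes, seed = seed)
}

# Preprocessing config matched to short tiny_spec runs.
tiny_preproc <- function() preproc_config(n_discard = 4, tr = 2)
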