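# Independent brute-force oracles used to validate the package kernels.

# quadratic-time sample-entropy template counter, written directly from the
# definition (Chebyshev distance, self-matches excluded, templates over the
# first N - m positions)
sampen_counts_oracle <- function(x, m, r) {
  n <- length(x)
  nt <- n - m
  A <- 0; B <- 0
  for (i in seq_len(nt - 1)) {
    for (j in (i + 1):nt) {
      if (max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)])) <= r) {
        B <- B + 1
        if (abs(x[i + m] - x[j + m]) <= r) A <- A + 1
      }
    }
  }
  c(A, B)
}

sampen_oracle <- function(x, m, r) {
  ab <- sampen_counts_oracle(x, m, r)
  if (ab[1] == 0 || ab[2] == 0) return(NA_real_)
  -log(ab[1] / ab[2])
}

# cubic-time natural-visibility edge enumeration straight from the strict
# inequality: c blocks (a, b) when it lies on or above the connecting line
nvg_edges_oracle <- function(t, y) {
  n <- length(y)
  edges <- matrix(0L, 0, 2)
  for (a in seq_len(n - 1)) {
    for (b in (a + 1):n) {
      visible <- TRUE
      if (b > a + 1) {
        for (cc in (a + 1):(b - 1)) {
          bound <- y[b] + (y[a] - y[b]) * (t[b] - t[cc]) / (t[b] - t[a])
          if (y[cc] >= bound) { visible <- FALSE; break }
        }
      }
      if (visible) edges <- rbind(edges, c(a, b))
    }
  }
  edges
}

# spectrally synthesized 1/f (pink) noise: Hermitian spectrum with
# amplitude 1/sqrt(f) and random phases
pink_noise <- function(n) {
  k <- 0:(n - 1)
  fa <- pmin(k, n - k)
  amp <- ifelse(fa == 0, 0, 1 / sqrt(fa))
  S <- complex(modulus = amp, argument = stats::runif(n, 0, 2 * pi))
  idx <- 2:ceiling(n / 2)
  S[n + 2 - idx] <- Conj(S[idx])
  if (n %% 2 == 0) S[n / 2 + 1] <- complex(modulus = amp[n / 2 + 1],
                                           argument = 0)
  Re(stats::fft(S, inverse = TRUE))
}

# beats on a uniform grid with a prescribed tachogram function rr_ms(t)
synthetic_beats <- function(duration_s, rr_fun) {
  t <- 0; ts <- numeric(0); rrs <- numeric(0)
  repeat {
    rr <- rr_fun(t)
    t <- t + rr / 1000
    if (t > duration_s) break
    ts <- c(ts, t); rrs <- c(rrs, rr)
  }
  list(t = ts, rr = rrs)
}
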