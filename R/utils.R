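# Physical constants (CODATA 2018) used throughout.
.const <- list(
  h  = 6.62607015e-34,   # Planck, J s
  m0 = 9.1093837015e-31, # electron rest mass, kg
  e  = 1.602176634e-19,  # elementary charge, C
  c  = 299792458         # speed of light, m/s
)

#' @keywords internal
stop_domain <- function(...) stop(..., call. = FALSE)

assert_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) == 0L || any(!is.finite(x)) || any(x <= 0)) {
    stop_domain(sprintf("`%s` must be a positive finite number", name))
  }
  invisible(x)
}

assert_nonneg <- function(x, name) {
  if (!is.numeric(x) || length(x) == 0L || any(!is.finite(x)) || any(x < 0)) {
    stop_domain(sprintf("`%s` must be a non-negative finite number", name))
  }
  invisible(x)
}

# Centered <-> FFT-ordered index helpers. Convention: on an even grid of side
# n the DC pixel of a centered array sits at 0-based index n/2 (R index
# n/2 + 1); fftshift moves FFT order (DC first) to centered order.
fftshift2 <- function(m) {
  n1 <- nrow(m); n2 <- ncol(m)
  s1 <- floor(n1 / 2); s2 <- floor(n2 / 2)
  m[c((s1 + 1):n1, seq_len(s1)), c((s2 + 1):n2, seq_len(s2)), drop = FALSE]
}

ifftshift2 <- function(m) {
  n1 <- nrow(m); n2 <- ncol(m)
  s1 <- ceiling(n1 / 2); s2 <- ceiling(n2 / 2)
  m[c((s1 + 1):n1, seq_len(s1)), c((s2 + 1):n2, seq_len(s2)), drop = FALSE]
}

# Signed FFT frequency indices (cycles per grid) for side n, FFT order.
fft_freq_index <- function(n) {
  k <- 0:(n - 1)
  k[k >= ceiling(n / 2)] <- k[k >= ceiling(n / 2)] - n
  k
}

# Centered pixel coordinate (0-based index minus n/2) for side n.
centered_coord <- function(n) (0:(n - 1)) - floor(n / 2)
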