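# Independent oracles used across the suite. These never call the code
# paths they check.

# trapezoidal quadrature of an analytic function on a fine grid
oracle_quad <- function(f, lo, hi, step = 0.01) {
  x <- seq(lo, hi, by = step)
  y <- f(x)
  sum((y[-1] + y[-length(y)]) / 2) * step
}

# brute-force channel response for analytic S, E, R
oracle_response <- function(Sf, Ef, Rf, lo, hi, step = 0.01) {
  oracle_quad(function(x) Sf(x) * Ef(x) * Rf(x), lo, hi, step)
}

# exact two-sided Wilcoxon rank-sum p by full enumeration of the group
# assignments (no ties assumed); feasible for small n
oracle_wilcoxon_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combos <- utils::combn(nx + ny, nx)
  w_all <- apply(combos, 2, function(idx) sum(r[idx]) - nx * (nx + 1) / 2)
  mu <- nx * ny / 2
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-12)
}

# flat-field test camera: visible profile with exposure standardised once
test_visible_camera <- local({
  cam <- NULL
  function() {
    if (is.null(cam)) cam <<- standardise_exposure(synthetic_visible_profile())
    cam
  }
})

test_uv_camera <- local({
  cam <- NULL
  function() {
    if (is.null(cam)) cam <<- standardise_exposure(synthetic_uv_profile())
    cam
  }
})

# gaussian helper for analytic spectra
gauss <- function(a, b, c) function(x) a * exp(-((x - b) / c)^2)
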