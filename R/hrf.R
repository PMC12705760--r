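#' Canonical double-gamma hemodynamic response function
#'
#' The conventional canonical HRF: a gamma density peaking near 5 s
#' minus a later undershoot gamma scaled by `ratio`, evaluated over a
#' 32 s support.  Parameters are in seconds; dispersions of 1 give the
#' standard shape.
#'
#' @param t time points in seconds.
#' @param peak_delay,peak_disp delay / dispersion of the response gamma.
#' @param under_delay,under_disp delay / dispersion of the undershoot.
#' @param ratio response : undershoot amplitude ratio (default 1/6).
#' @return numeric vector, zero outside `[0, 32]` seconds.
#' @export
canonical_hrf <- function(t, peak_delay = 6, peak_disp = 1,
                          under_delay = 16, under_disp = 1, ratio = 1 / 6) {
  h <- stats::dgamma(t, shape = peak_delay / peak_disp, scale = peak_disp) -
    ratio * stats::dgamma(t, shape = under_delay / under_disp, scale = under_disp)
  h[t < 0 | t > 32] <- 0
  h
}

## Convolve boxcar events with the canonical HRF on an oversampled time
## grid (oversample bins per TR) and sample at volume midpoints
## t = (v - 1/2) * tr.  The unit-sum kernel makes the plateau response
## to a long block equal to 1.  Sub-TR onsets are honoured at the
## resolution of the oversampling grid (tr / oversample seconds).
convolve_events <- function(onsets, durations, n_vols, tr, oversample = 16,
                            hrf = list()) {
  stopifnot(length(onsets) == length(durations))
  dt <- tr / oversample
  ng <- n_vols * oversample
  tgrid <- (seq_len(ng) - 1) * dt
  u <- numeric(ng)
  for (e in seq_along(onsets)) {
    u[tgrid >= onsets[e] - dt / 2 & tgrid < onsets[e] + durations[e] - dt / 2] <- 1
  }
  kern <- do.call(canonical_hrf, c(list(t = seq(0, 32, by = dt)), hrf))
  kern <- kern / sum(kern)
  x <- stats::convolve(u, rev(kern), type = "open")[seq_len(ng)]
  idx <- (seq_len(n_vols) - 0.5) * oversample + 1
  x[idx]
}
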