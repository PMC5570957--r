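# Independent oracles the tests check package code against. These are
# deliberately written in the most literal (slow) style possible so they
# share no code path with the package implementations.

# exhaustive double-loop zero-normalized cross-correlation: slides the
# template over every admissible top-left offset of the image and scores
# each window from the textbook definition. Returns 0-based x/y of the
# first maximum in (y, x) lexicographic order plus the full score grid.
oracle_zncc <- function(image, template) {
  th <- nrow(template); tw <- ncol(template)
  tc <- template - mean(template)
  tn <- sqrt(sum(tc^2))
  ys <- 0:(nrow(image) - th)
  xs <- 0:(ncol(image) - tw)
  best <- list(score = -Inf, x = NA, y = NA)
  scores <- matrix(NA_real_, length(ys), length(xs))
  for (iy in seq_along(ys)) {
    for (ix in seq_along(xs)) {
      win <- image[(ys[iy] + 1):(ys[iy] + th), (xs[ix] + 1):(xs[ix] + tw)]
      wc <- win - mean(win)
      wn <- sqrt(sum(wc^2))
      s <- if (wn * tn > 0) sum(wc * tc) / (wn * tn) else 0
      scores[iy, ix] <- s
      if (s > best$score) best <- list(score = s, x = xs[ix], y = ys[iy])
    }
  }
  best$scores <- scores
  best
}

# closed-form peak percent change of the saturating-exponential transient
oracle_peak_pct <- function(A, tau_rise, t_on, t_off) {
  100 * A * (1 - exp(-(t_off - t_on) / tau_rise))
}

# build a noise-free fret_trace directly from the transient equations with
# optional per-channel exponential bleaching -- no package generator involved
oracle_trace <- function(A = 0.3, R0 = 1.5, tau_rise = 5, tau_decay = 8,
                         t_on = 40, t_off = 70, n = 90, dt = 1,
                         lam_d = 0, lam_a = 0, donor0 = 400) {
  t <- (seq_len(n) - 1) * dt
  r <- numeric(n)
  for (i in seq_len(n)) {
    r[i] <- if (t[i] < t_on) R0
    else if (t[i] <= t_off)
      R0 * (1 + A * (1 - exp(-(t[i] - t_on) / tau_rise)))
    else {
      r_off <- R0 * (1 + A * (1 - exp(-(t_off - t_on) / tau_rise)))
      R0 + (r_off - R0) * exp(-(t[i] - t_off) / tau_decay)
    }
  }
  donor <- donor0 * exp(-lam_d * t)
  acceptor <- donor0 * r * exp(-lam_a * t)
  fret_trace(t, donor, acceptor, stim_window = c(t_on, t_off))
}

# deterministic noise-free in-focus rendering of a scene for single-frame
# detection tests
ideal_frame <- function(scene, channel = "acceptor") {
  render_frame(scene, z_offset = 0, noise = noise_config(FALSE))[[channel]]
}
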