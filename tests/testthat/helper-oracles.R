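# Independent oracles used across test files.

# Brute-force representative-window search: partitions the classified range
# series into spring-onset..next-spring-onset periods with plain loops and
# scans every candidate for the minimum score. Independent of the internals
# of select_tide_window (which assembles the same quantities vectorised).
brute_force_window <- function(signal, min_sep_s = 8 * 3600) {
  cls <- classify_tidal_ranges(extract_tidal_ranges(signal, min_sep_s))
  sp_mean <- mean(cls$range_m[cls$phase == "SPRING"])
  np_mean <- mean(cls$range_m[cls$phase == "NEAP"])
  onsets <- c()
  for (k in seq_len(nrow(cls))) {
    if (cls$phase[k] == "SPRING" && (k == 1 || cls$phase[k - 1] != "SPRING"))
      onsets <- c(onsets, k)
  }
  if (length(onsets) < 2) stop("too short")
  best <- NULL
  best_score <- Inf
  for (p in seq_len(length(onsets) - 1)) {
    i0 <- onsets[p]; i1 <- onsets[p + 1]
    sp <- c(); np <- c()
    for (k in seq_len(nrow(cls))) {
      if (cls$time_s[k] >= cls$time_s[i0] && cls$time_s[k] < cls$time_s[i1]) {
        if (cls$phase[k] == "SPRING") sp <- c(sp, cls$range_m[k])
        if (cls$phase[k] == "NEAP") np <- c(np, cls$range_m[k])
      }
    }
    if (length(sp) == 0 || length(np) == 0) next
    score <- abs(mean(sp) - sp_mean) + abs(mean(np) - np_mean)
    if (score < best_score - 1e-12) {
      best_score <- score
      best <- cls$time_s[i0]
    }
  }
  list(t_start = best, score = best_score)
}

# Dense grid search for the settling-velocity fit (fixed or profiled c_s0).
grid_search_ws <- function(series, h, c_s0 = NULL,
                           ws_grid = exp(seq(log(1e-7), log(1e-2),
                                             length.out = 4000))) {
  t <- series$time_s; conc <- series$conc_kg_m3
  best_ws <- NA; best_sse <- Inf
  for (ws in ws_grid) {
    decay <- exp(-t * ws / h)
    c0 <- if (is.null(c_s0)) sum(conc * decay) / sum(decay^2) else c_s0
    sse <- sum((conc - c0 * decay)^2)
    if (sse < best_sse) { best_sse <- sse; best_ws <- ws }
  }
  best_ws
}

# random constituent set for property tests: M2/S2 core plus optional
# randomised minor constituents and phases
random_constituents <- function(seed) {
  set.seed(seed)
  spring <- runif(1, 2.2, 3.0)
  neap <- runif(1, 1.2, spring - 0.4)
  minors <- NULL
  if (runif(1) < 0.7) {
    minors <- data.frame(
      name = c("N2", "K1"),
      amplitude_m = runif(2, 0.02, 0.20),
      phase_deg = runif(2, 0, 360),
      omega_rad_s = c(2 * pi / (12.65834751 * 3600),
                      2 * pi / (23.93447213 * 3600)))
  }
  gen_constituents(spring, neap, minors = minors, seed = seed,
                   random_phases = TRUE)
}
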