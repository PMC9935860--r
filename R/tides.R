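# Tidal harmonic synthesis and spring-neap window selection.
#
# Water level is the harmonic sum eta(t) = sum_i A_i cos(omega_i t - phi_i).
# Spring/neap classification follows the quartile rule: tidal ranges below
# the empirical Q25 are neap, above Q75 spring, the remainder mid-cycle.

#' Build a tidal constituent set
#'
#' @param name Constituent names (e.g. "M2", "S2").
#' @param amplitude_m Amplitudes, m (>= 0).
#' @param phase_deg Phases, degrees.
#' @param omega_rad_s Angular frequencies, rad s^-1 (> 0, distinct).
#' @return A `tide_constituents` data frame.
#' @export
tide_constituents <- function(name, amplitude_m, phase_deg, omega_rad_s) {
  stopifnot(length(name) == length(amplitude_m),
            length(name) == length(phase_deg),
            length(name) == length(omega_rad_s),
            all(amplitude_m >= 0), all(omega_rad_s > 0),
            !anyDuplicated(omega_rad_s))
  structure(data.frame(name = as.character(name),
                       amplitude_m = amplitude_m,
                       phase_deg = phase_deg,
                       omega_rad_s = omega_rad_s,
                       stringsAsFactors = FALSE),
            class = c("tide_constituents", "data.frame"))
}

#' Read / write a constituent table
#'
#' Delimited text with header `name,amplitude_m,phase_deg,omega_rad_s`.
#'
#' @param path File path.
#' @return [read_constituents()] returns a `tide_constituents` object.
#' @export
read_constituents <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "amplitude_m", "phase_deg", "omega_rad_s")
  if (!all(need %in% names(df)))
    stop("constituent table must have columns: ", paste(need, collapse = ", "))
  tide_constituents(df$name, df$amplitude_m, df$phase_deg, df$omega_rad_s)
}

#' @rdname read_constituents
#' @param constituents A `tide_constituents` object.
#' @export
write_constituents <- function(constituents, path) {
  utils::write.csv(as.data.frame(constituents), path, row.names = FALSE)
  invisible(path)
}

#' Synthesize a water-level signal from harmonic constituents
#'
#' @param constituents A `tide_constituents` object.
#' @param t_start,t_end Start and end times, s.
#' @param dt Sampling step, s; must resolve the fastest constituent with at
#'   least 20 samples per period.
#' @return A `tide_signal` data frame with columns `time_s` and `level_m`.
#' @export
synthesize_tide <- function(constituents, t_start, t_end, dt) {
  stopifnot(inherits(constituents, "tide_constituents"),
            t_end > t_start, dt > 0)
  t_fast <- 2 * pi / max(constituents$omega_rad_s)
  if (dt > t_fast / 20)
    stop(sprintf("dt = %g s undersamples the fastest constituent (period %.1f s); need dt <= %.1f s",
                 dt, t_fast, t_fast / 20))
  tt <- seq(t_start, t_end, by = dt)
  phi <- constituents$phase_deg * pi / 180
  lev <- rep(0, length(tt))
  for (i in seq_len(nrow(constituents)))
    lev <- lev + constituents$amplitude_m[i] *
      cos(constituents$omega_rad_s[i] * tt - phi[i])
  structure(data.frame(time_s = tt, level_m = lev),
            class = c("tide_signal", "data.frame"))
}

#' Evaluate the harmonic sum at arbitrary times
#'
#' Exact (non-gridded) evaluation, used for solver boundary forcing.
#' @inheritParams synthesize_tide
#' @param times Times, s.
#' @return Water levels, m AMSL.
#' @export
eval_tide <- function(constituents, times) {
  phi <- constituents$phase_deg * pi / 180
  lev <- rep(0, length(times))
  for (i in seq_len(nrow(constituents)))
    lev <- lev + constituents$amplitude_m[i] *
      cos(constituents$omega_rad_s[i] * times - phi[i])
  lev
}

# Local extrema of a sampled signal. The minimum separation applies to
# extrema of the same kind (peak-to-peak / trough-to-trough): adjacent
# opposite-kind pairs closer than half the separation are treated as noise
# wiggles and removed pairwise, which preserves alternation. Returns indices
# and kind (+1 max, -1 min), alternating.
.find_extrema <- function(level, min_sep) {
  d <- diff(level)
  s <- sign(d)
  for (i in seq_along(s)) if (s[i] == 0 && i > 1) s[i] <- s[i - 1]
  turn <- which(diff(s) != 0) + 1  # index into level
  if (!length(turn)) return(list(index = integer(0), kind = integer(0)))
  kind <- ifelse(s[turn] < s[turn - 1], 1L, -1L)  # falling after rising = max
  pair_gap <- max(1, min_sep / 2)
  repeat {
    if (length(turn) < 2) break
    gaps <- diff(turn)
    j <- which.min(gaps)
    if (gaps[j] >= pair_gap) break
    turn <- turn[-c(j, j + 1)]
    kind <- kind[-c(j, j + 1)]
  }
  # collapse any residual same-kind neighbours to the more extreme one
  keep <- rep(TRUE, length(turn))
  for (j in seq_along(turn)[-1]) {
    prev <- max(which(keep[seq_len(j - 1)]))
    if (kind[j] == kind[prev]) {
      better <- if (kind[j] > 0) level[turn[j]] > level[turn[prev]]
                else level[turn[j]] < level[turn[prev]]
      if (better) keep[prev] <- FALSE else keep[j] <- FALSE
    }
  }
  list(index = turn[keep], kind = kind[keep])
}

#' Extract tidal ranges from a water-level signal
#'
#' Pairs each local low with the following local high; the range is
#' high minus low. Extrema closer than `min_sep_s` (default 8 h) are treated
#' as noise.
#'
#' @param signal A `tide_signal` data frame (`time_s`, `level_m`).
#' @param min_sep_s Minimum separation between retained extrema, s.
#' @return A `tidal_ranges` data frame with columns `time_s` (time of the
#'   high), `low_m`, `high_m`, `range_m`.
#' @export
extract_tidal_ranges <- function(signal, min_sep_s = 8 * 3600) {
  stopifnot(is.data.frame(signal), nrow(signal) > 2)
  dt <- signal$time_s[2] - signal$time_s[1]
  ex <- .find_extrema(signal$level_m, max(1L, floor(min_sep_s / dt)))
  if (length(ex$index) < 2)
    stop("no alternating extrema found; signal must span at least two tidal cycles")
  lows <- which(ex$kind < 0)
  out <- data.frame(time_s = numeric(0), low_m = numeric(0),
                    high_m = numeric(0), range_m = numeric(0))
  for (j in lows) {
    if (j + 1 <= length(ex$index) && ex$kind[j + 1] > 0) {
      lo <- signal$level_m[ex$index[j]]
      hi <- signal$level_m[ex$index[j + 1]]
      out <- rbind(out, data.frame(time_s = signal$time_s[ex$index[j + 1]],
                                   low_m = lo, high_m = hi,
                                   range_m = hi - lo))
    }
  }
  if (nrow(out) == 0) stop("no low-to-high pairs found")
  structure(out, class = c("tidal_ranges", "data.frame"))
}

#' Classify tidal ranges into neap / spring / mid phases
#'
#' Ranges strictly below the empirical 25th percentile are `NEAP`, strictly
#' above the 75th percentile `SPRING`, all others `MID`. Percentiles use
#' linear interpolation between order statistics (`type = 7`), configurable.
#'
#' @param ranges A `tidal_ranges` data frame (>= 4 ranges).
#' @param type Quantile estimator type passed to [stats::quantile()].
#' @return The input with a `phase` factor column and attributes `q25`,
#'   `q75`.
#' @export
classify_tidal_ranges <- function(ranges, type = 7) {
  stopifnot(is.data.frame(ranges), nrow(ranges) >= 4)
  q <- stats::quantile(ranges$range_m, c(0.25, 0.75), type = type, names = FALSE)
  phase <- rep("MID", nrow(ranges))
  phase[ranges$range_m < q[1]] <- "NEAP"
  phase[ranges$range_m > q[2]] <- "SPRING"
  ranges$phase <- factor(phase, levels = c("NEAP", "MID", "SPRING"))
  attr(ranges, "q25") <- q[1]
  attr(ranges, "q75") <- q[2]
  ranges
}

#' Select the most representative spring-neap window
#'
#' Partitions the record into consecutive periods running from one spring
#' onset to the next (a period thus contains one spring phase and the
#' following neap phase). For each period the mean spring range and mean
#' neap range are compared with the record-wide mean spring and neap ranges;
#' the period minimising the sum of the two absolute differences holds the
#' most representative spring and neap tides. Ties are broken by the
#' earliest start. Periods lacking either phase are excluded (and listed).
#'
#' @param signal A `tide_signal` spanning at least two spring-neap cycles.
#' @param period_length_s Length of the returned simulation window, s
#'   (default 16 days). The window starts at the selected period's start.
#' @param min_sep_s Passed to [extract_tidal_ranges()].
#' @return A list with `t_start`, `t_end` (= t_start + period_length_s),
#'   `score`, `periods` (data frame of candidate periods with their scores),
#'   and `excluded` (row indices of periods lacking a phase).
#' @export
select_tide_window <- function(signal, period_length_s = 16 * 86400,
                               min_sep_s = 8 * 3600) {
  stopifnot(signal$time_s[nrow(signal)] - signal$time_s[1] >= 2 * period_length_s)
  cls <- classify_tidal_ranges(extract_tidal_ranges(signal, min_sep_s))
  spring_mean <- mean(cls$range_m[cls$phase == "SPRING"])
  neap_mean <- mean(cls$range_m[cls$phase == "NEAP"])

  is_spring <- cls$phase == "SPRING"
  onset <- which(is_spring & !c(FALSE, is_spring[-length(is_spring)]))
  if (length(onset) < 2)
    stop("record too short: need at least two spring onsets")
  periods <- data.frame(t_start = cls$time_s[onset[-length(onset)]],
                        t_next = cls$time_s[onset[-1]])
  periods$mean_spring <- NA_real_
  periods$mean_neap <- NA_real_
  for (k in seq_len(nrow(periods))) {
    idx <- cls$time_s >= periods$t_start[k] & cls$time_s < periods$t_next[k]
    sp <- cls$range_m[idx & cls$phase == "SPRING"]
    np <- cls$range_m[idx & cls$phase == "NEAP"]
    if (length(sp)) periods$mean_spring[k] <- mean(sp)
    if (length(np)) periods$mean_neap[k] <- mean(np)
  }
  periods$score <- abs(periods$mean_spring - spring_mean) +
    abs(periods$mean_neap - neap_mean)
  excluded <- which(is.na(periods$score))
  ok <- which(!is.na(periods$score))
  if (!length(ok)) stop("no period contains both a spring and a neap phase")
  best <- ok[which.min(periods$score[ok])]  # which.min takes the first = earliest
  list(t_start = periods$t_start[best],
       t_end = periods$t_start[best] + period_length_s,
       score = periods$score[best],
       periods = periods, excluded = excluded)
}
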