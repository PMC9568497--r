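# Independent reference implementations used as oracles. These are literal,
# loop-based restatements of the rules, kept deliberately free of the
# package's vectorized code paths.

# per-sample moving-average derivative, direct summation
ref_velocity <- function(trace, window = 5) {
  x <- trace$x_deg; y <- trace$y_deg
  n <- length(x)
  dt_s <- 1 / trace$sample_rate_hz
  k <- (window - 1) %/% 2
  d1 <- function(p) {
    v <- numeric(n)
    for (i in seq_len(n)) {
      kk <- min(k, i - 1L, n - i)
      if (kk >= 1L) {
        fwd <- 0; bwd <- 0
        for (j in seq_len(kk)) {
          fwd <- fwd + p[i + j]
          bwd <- bwd + p[i - j]
        }
        v[i] <- (fwd - bwd) / (kk * (kk + 1) * dt_s)
      } else if (i == 1L) {
        v[i] <- (p[2] - p[1]) / dt_s
      } else {
        v[i] <- (p[n] - p[n - 1]) / dt_s
      }
    }
    v
  }
  vx <- d1(x); vy <- d1(y)
  speed <- sqrt(vx^2 + vy^2)
  accel <- numeric(n)
  for (i in seq_len(n)) {
    if (i == 1L) accel[i] <- (speed[2] - speed[1]) / dt_s
    else if (i == n) accel[i] <- (speed[n] - speed[n - 1]) / dt_s
    else accel[i] <- (speed[i + 1] - speed[i - 1]) / (2 * dt_s)
  }
  list(vx = vx, vy = vy, speed = speed, accel = accel)
}

# literal per-sample microsaccade detector applying the same rules as
# detect_microsaccades: elliptical lambda-sigma criterion, invalid-pupil
# masking, min duration, merging, classification
ref_detect_microsaccades <- function(trace, params = detector_params()) {
  vel <- ref_velocity(trace, params$velocity_window_samples)
  n <- length(trace$t_ms)
  dt_ms <- 1000 / trace$sample_rate_hz
  med <- function(v) stats::median(v)
  sx <- sqrt(max(med(vel$vx^2) - med(vel$vx)^2, 0))
  sy <- sqrt(max(med(vel$vy^2) - med(vel$vy)^2, 0))
  if (sx <= 0 || sy <= 0) return(NULL)
  ex <- params$lambda * sx
  ey <- params$lambda * sy
  k <- (params$velocity_window_samples - 1) %/% 2
  cand <- logical(n)
  for (i in seq_len(n)) {
    near_bad <- FALSE
    for (j in max(1, i - k):min(n, i + k)) {
      if (!trace$pupil_valid[j]) near_bad <- TRUE
    }
    cand[i] <- !near_bad &&
      (vel$vx[i] / ex)^2 + (vel$vy[i] / ey)^2 > 1
  }
  # runs
  runs <- list()
  i <- 1L
  while (i <= n) {
    if (cand[i]) {
      j <- i
      while (j < n && cand[j + 1L]) j <- j + 1L
      runs[[length(runs) + 1L]] <- c(i, j)
      i <- j + 1L
    } else i <- i + 1L
  }
  # duration filter
  runs <- Filter(function(r) (r[2] - r[1]) * dt_ms >= params$min_duration_ms,
                 runs)
  # merge
  gap_samples <- ceiling(params$merge_gap_ms / dt_ms)
  merged <- list()
  for (r in runs) {
    m <- length(merged)
    if (m > 0 && r[1] - merged[[m]][2] - 1L < gap_samples) {
      merged[[m]][2] <- r[2]
    } else {
      merged[[length(merged) + 1L]] <- r
    }
  }
  if (!length(merged)) return(data.frame())
  rows <- lapply(merged, function(r) {
    i0 <- r[1]; i1 <- r[2]
    kind <- "microsaccade"
    if (any(!trace$pupil_valid[i0:i1])) {
      kind <- "blink"
    } else {
      pk_v <- max(vel$speed[i0:i1])
      pk_a <- max(abs(vel$accel[i0:i1]))
      if (pk_v > params$saccade_velocity_deg_s &&
          pk_a > params$saccade_accel_deg_s2) kind <- "saccade"
    }
    dx <- trace$x_deg[i1] - trace$x_deg[i0]
    dy <- trace$y_deg[i1] - trace$y_deg[i0]
    data.frame(trial = trace$trial_id, kind = kind,
               onset_ms = trace$t_ms[i0], offset_ms = trace$t_ms[i1],
               dx_deg = dx, dy_deg = dy,
               amplitude_deg = sqrt(dx^2 + dy^2),
               direction_rad = atan2(dy, dx),
               peak_velocity_deg_s = max(vel$speed[i0:i1]))
  })
  do.call(rbind, rows)
}

# brute-force Benjamini-Hochberg step-up from its definition
ref_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  # enforce monotone non-decreasing from the largest down
  for (i in (m - 1):1) {
    if (m == 1) break
    q[i] <- min(q[i], q[i + 1])
  }
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# convenience: simulated trace with a random configuration
random_trace <- function(seed, blink_prob = 0.1) {
  set.seed(seed)
  cfg <- trace_sim_config(
    ms_rate_hz = stats::runif(1, 0.8, 2.5),
    amp_median_deg = stats::runif(1, 0.15, 0.4),
    noise_sd_deg = stats::runif(1, 2e-4, 1.5e-3),
    blink_prob_per_trial = blink_prob)
  tl <- make_timeline(sample(c(200, 500), 1))
  simulate_trace(cfg, tl, sample(c("left", "right"), 1),
                 trial_id = sprintf("t%04d", seed))
}
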