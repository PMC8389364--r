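# Independent brute-force oracles used across the suite. These deliberately
# take the naive single-pass route (explicit loops, no shared helpers with
# the package) so that agreement with the package implementations is a
# genuine cross-check.

make_track <- function(x, y, dt = 0.1, arena = arena_geometry(),
                       fly_id = "fixture") {
  structure(
    data.frame(t_s = (seq_along(x) - 1) * dt, x_mm = x, y_mm = y),
    arena = arena, sampling_rate = 1 / dt, fly_id = fly_id,
    class = c("fly_track", "data.frame")
  )
}

# random wandering track confined to the platform
random_track <- function(n_frames, dt = 0.1, arena = arena_geometry(),
                         p_rest = 0.3, step_max = 3) {
  x <- y <- numeric(n_frames)
  heading <- stats::runif(1, 0, 2 * pi)
  for (i in 2:n_frames) {
    if (stats::runif(1) < p_rest) {
      x[i] <- x[i - 1]; y[i] <- y[i - 1]
    } else {
      heading <- heading + stats::rnorm(1, 0, 0.6)
      step <- stats::runif(1, 0, step_max)
      nx <- x[i - 1] + step * cos(heading)
      ny <- y[i - 1] + step * sin(heading)
      if (sqrt(nx^2 + ny^2) > arena$platform_radius * 0.95) {
        heading <- heading + pi
        nx <- x[i - 1]; ny <- y[i - 1]
      }
      x[i] <- nx; y[i] <- ny
    }
  }
  make_track(x, y, dt, arena)
}

oracle_pauses <- function(track, pause_threshold = 1, eps = 0.1) {
  dt <- 1 / attr(track, "sampling_rate")
  n <- nrow(track)
  segs <- list()
  run_start <- NA
  run_len <- 0
  for (i in 1:(n - 1)) {
    d <- sqrt((track$x_mm[i + 1] - track$x_mm[i])^2 +
              (track$y_mm[i + 1] - track$y_mm[i])^2)
    if (d <= eps) {
      if (run_len == 0) run_start <- i
      run_len <- run_len + 1
    }
    if (d > eps || i == n - 1) {
      if (run_len > 0 && run_len * dt > pause_threshold)
        segs[[length(segs) + 1]] <- c(start = track$t_s[run_start],
                                      end = track$t_s[run_start + run_len],
                                      duration = run_len * dt)
      if (d > eps) run_len <- 0
    }
  }
  if (length(segs) == 0)
    return(data.frame(start = numeric(0), end = numeric(0),
                      duration = numeric(0)))
  as.data.frame(do.call(rbind, segs))
}

oracle_metrics <- function(track, arena = attr(track, "arena"),
                           pause_threshold = 1, eps = 0.1,
                           jump_threshold = 50, zone_half_angle = pi / 6,
                           zone_depth = 0.2) {
  dt <- 1 / attr(track, "sampling_rate")
  n <- nrow(track)
  total_t <- track$t_s[n] - track$t_s[1]
  pauses <- oracle_pauses(track, pause_threshold, eps)

  dist <- 0
  speeds <- c()
  devs <- c()
  meanders <- c()
  prev_v <- NULL
  for (i in 1:(n - 1)) {
    vx <- track$x_mm[i + 1] - track$x_mm[i]
    vy <- track$y_mm[i + 1] - track$y_mm[i]
    d <- sqrt(vx^2 + vy^2)
    dist <- dist + d
    moving <- d > eps
    if (moving) {
      sp <- d / dt
      if (sp <= jump_threshold) speeds <- c(speeds, sp)
      angs <- sapply(1:2, function(j) {
        sx <- arena$stripe_distance * cos(arena$stripe_bearings[j]) -
          track$x_mm[i]
        sy <- arena$stripe_distance * sin(arena$stripe_bearings[j]) -
          track$y_mm[i]
        acos(min(1, max(-1, (vx * sx + vy * sy) /
                            (sqrt(vx^2 + vy^2) * sqrt(sx^2 + sy^2)))))
      })
      devs <- c(devs, min(angs) * 180 / pi)
      if (!is.null(prev_v)) {
        turn <- acos(min(1, max(-1,
          (prev_v[1] * vx + prev_v[2] * vy) /
            (sqrt(prev_v[1]^2 + prev_v[2]^2) * sqrt(vx^2 + vy^2))))) *
          180 / pi
        meanders <- c(meanders, turn / (d / dt))
      }
      prev_v <- c(vx, vy)
    } else {
      prev_v <- NULL
    }
  }

  # walks: alternating entries into the two stripe-approach zones
  zones <- integer(0)
  for (i in 1:n) {
    r <- sqrt(track$x_mm[i]^2 + track$y_mm[i]^2)
    th <- atan2(track$y_mm[i], track$x_mm[i])
    z <- 0
    if (r >= (1 - zone_depth) * arena$platform_radius) {
      for (j in 1:2) {
        dd <- abs(((th - arena$stripe_bearings[j] + pi) %% (2 * pi)) - pi)
        if (dd <= zone_half_angle) z <- j
      }
    }
    if (z > 0) zones <- c(zones, z)
  }
  walks <- if (length(zones) < 2) 0 else sum(diff(zones) != 0)

  list(
    activity_time_per_min = (total_t - sum(pauses$duration)) / total_t * 60,
    pauses_per_min = nrow(pauses) * 60 / total_t,
    distance_traveled = dist,
    median_speed = if (length(speeds)) median(speeds) else NA_real_,
    pause_duration = if (nrow(pauses)) median(pauses$duration) else NA_real_,
    walks_per_min = walks * 60 / total_t,
    stripe_deviation = if (length(devs)) median(devs) else NA_real_,
    meander = if (length(meanders)) median(meanders) else NA_real_
  )
}

# Kruskal-Wallis via the alternative rank-ANOVA identity
# H = (N - 1) * SS_between(ranks) / SS_total(ranks), which absorbs the tie
# correction automatically.
oracle_kw <- function(values, groups) {
  r <- rank(values)
  g <- factor(groups)
  rbar <- mean(r)
  ssb <- sum(tapply(r, g, function(ri) length(ri) * (mean(ri) - rbar)^2))
  sst <- sum((r - rbar)^2)
  (length(r) - 1) * ssb / sst
}

# Dunn z via the sample variance of the pooled mid-ranks (equals the
# textbook tie-corrected variance N(N+1)/12 - sum(t^3 - t)/(12(N-1)))
oracle_dunn_z <- function(values, groups, g1, g2) {
  r <- rank(values)
  g <- as.character(groups)
  v <- stats::var(r)
  n1 <- sum(g == g1); n2 <- sum(g == g2)
  (mean(r[g == g1]) - mean(r[g == g2])) / sqrt(v * (1 / n1 + 1 / n2))
}

total_variation <- function(p, q) 0.5 * sum(abs(p - q))
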