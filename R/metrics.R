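# Eight walking metrics for Buridan trajectories. All operate on fixed-rate
# planar tracks (t_s, x_mm, y_mm); "movement" in a frame means an
# inter-frame displacement exceeding movement_epsilon (default 0.1 mm,
# i.e. 1 mm/s at 10 Hz — below plausible tracking noise).

track_dt <- function(track) {
  sr <- attr(track, "sampling_rate")
  if (!is.null(sr)) return(1 / sr)
  stats::median(diff(track$t_s))
}

track_displacements <- function(track) {
  n <- nrow(track)
  if (n < 2) stop("trajectory needs at least 2 samples")
  sqrt(diff(track$x_mm)^2 + diff(track$y_mm)^2)
}

#' Detect pauses in a walking trajectory
#'
#' A pause is a maximal run of consecutive frames without movement whose
#' total span exceeds `pause_threshold` (default 1 s); shorter rests count
#' as activity.
#'
#' @param track A `fly_track` (or data frame with `t_s`, `x_mm`, `y_mm`).
#' @param pause_threshold Minimum rest span, in seconds, to count as a
#'   pause (strictly exceeded; default 1).
#' @param movement_epsilon Displacement at or below which a frame counts as
#'   "no movement", in mm (default 0.1).
#' @return A data frame with columns `start`, `end`, `duration` (seconds),
#'   non-overlapping and ordered; zero rows when the fly never pauses.
#' @export
segment_pauses <- function(track, pause_threshold = 1,
                           movement_epsilon = 0.1) {
  d <- track_displacements(track)
  dt <- track_dt(track)
  still <- d <= movement_epsilon
  runs <- rle(still)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values & runs$lengths * dt > pause_threshold
  out <- data.frame(
    start = track$t_s[starts[keep]],
    end = track$t_s[ends[keep] + 1L],
    duration = runs$lengths[keep] * dt
  )
  out[order(out$start), , drop = FALSE]
}

#' Activity time per minute
#'
#' Seconds of activity per minute of experiment: everything that is not a
#' detected pause counts as active, so activity time and pause time
#' partition the experiment exactly.
#'
#' @inheritParams segment_pauses
#' @param pauses Optional precomputed [segment_pauses()] output.
#' @return Activity in s/min, in `[0, 60]`.
#' @export
activity_time_per_min <- function(track, pauses = NULL, pause_threshold = 1,
                                  movement_epsilon = 0.1) {
  if (is.null(pauses))
    pauses <- segment_pauses(track, pause_threshold, movement_epsilon)
  total <- track$t_s[nrow(track)] - track$t_s[1]
  (total - sum(pauses$duration)) / total * 60
}

#' Pause rate and median pause duration
#'
#' @inheritParams activity_time_per_min
#' @return `pauses_per_min()`: pauses per minute of experiment.
#'   `pause_duration_median()`: the median pause duration in seconds, `NA`
#'   when the fly never paused (missing, not zero, so rank tests stay
#'   honest).
#' @export
pauses_per_min <- function(track, pauses = NULL, pause_threshold = 1,
                           movement_epsilon = 0.1) {
  if (is.null(pauses))
    pauses <- segment_pauses(track, pause_threshold, movement_epsilon)
  total <- track$t_s[nrow(track)] - track$t_s[1]
  nrow(pauses) * 60 / total
}

#' @rdname pauses_per_min
#' @export
pause_duration_median <- function(track, pauses = NULL, pause_threshold = 1,
                                  movement_epsilon = 0.1) {
  if (is.null(pauses))
    pauses <- segment_pauses(track, pause_threshold, movement_epsilon)
  if (nrow(pauses) == 0) return(NA_real_)
  stats::median(pauses$duration)
}

#' Total distance traveled
#'
#' Sum of all inter-frame displacement lengths. Jump frames are *not*
#' excluded here; the 50 mm/s jump filter applies only to the median speed.
#'
#' @inheritParams segment_pauses
#' @return Distance in mm.
#' @export
total_distance <- function(track) sum(track_displacements(track))

#' Median walking speed
#'
#' Instantaneous speed per moving frame (displacement divided by the
#' sampling interval); frames faster than `jump_threshold` are treated as
#' jumps and excluded from the median.
#'
#' @inheritParams segment_pauses
#' @param jump_threshold Speed in mm/s above which a frame is a jump
#'   (default 50).
#' @return Median speed in mm/s; `NA` if no frame qualifies.
#' @export
median_speed <- function(track, jump_threshold = 50,
                         movement_epsilon = 0.1) {
  d <- track_displacements(track)
  dt <- track_dt(track)
  speeds <- d[d > movement_epsilon] / dt
  speeds <- speeds[speeds <= jump_threshold]
  if (length(speeds) == 0) return(NA_real_)
  stats::median(speeds)
}

#' Walks between the two stripes per minute
#'
#' Counts the number of times the fly walked from one stripe to the other:
#' an entry into the approach zone of one stripe after the most recent zone
#' entry was the opposite stripe. A zone is the sector within
#' `zone_half_angle` of a stripe bearing intersected with the outer
#' `zone_depth` fraction of the platform (a stripe-to-stripe walk must end
#' near the edge facing a stripe). Re-entering the same zone does not
#' count.
#'
#' @inheritParams segment_pauses
#' @param arena An [arena_geometry()]; defaults to the track's own.
#' @param zone_half_angle Half-width of the approach sector, radians
#'   (default pi/6, i.e. 30 degrees).
#' @param zone_depth Radial depth of the zone as a fraction of the platform
#'   radius (default 0.2: the outer 20 percent annulus).
#' @return Walks per minute.
#' @export
walks_per_min <- function(track, arena = attr(track, "arena"),
                          zone_half_angle = pi / 6, zone_depth = 0.2) {
  if (is.null(arena)) stop("no arena geometry available for this track")
  r <- sqrt(track$x_mm^2 + track$y_mm^2)
  theta <- atan2(track$y_mm, track$x_mm)
  in_annulus <- r >= (1 - zone_depth) * arena$platform_radius
  zone <- integer(nrow(track))
  for (j in 1:2) {
    dang <- abs(angle_diff(theta, arena$stripe_bearings[j]))
    zone[in_annulus & dang <= zone_half_angle] <- j
  }
  # count alternating zone entries: a walk ends when the fly enters the
  # zone opposite to the one it last visited
  visited <- zone[zone != 0L]
  walks <- sum(diff(visited) != 0L)
  total <- track$t_s[nrow(track)] - track$t_s[1]
  walks * 60 / total
}

angle_diff <- function(a, b) {
  d <- (a - b) %% (2 * pi)
  ifelse(d > pi, d - 2 * pi, d)
}

#' Stripe deviation (landmark fixation)
#'
#' For each moving frame, the angle between the velocity vector and the
#' vector from the fly to each stripe centre is computed and the smaller of
#' the two (the stripe most in front of the animal) is kept. The median
#' over moving frames, in degrees, is reported; lower values mean stronger
#' landmark fixation.
#'
#' @inheritParams walks_per_min
#' @inheritParams segment_pauses
#' @return Median deviation in degrees, in `[0, 180]`; `NA` if the fly
#'   never moved.
#' @export
stripe_deviation <- function(track, arena = attr(track, "arena"),
                             movement_epsilon = 0.1) {
  if (is.null(arena)) stop("no arena geometry available for this track")
  n <- nrow(track)
  vx <- diff(track$x_mm); vy <- diff(track$y_mm)
  d <- sqrt(vx^2 + vy^2)
  moving <- d > movement_epsilon
  if (!any(moving)) return(NA_real_)
  px <- track$x_mm[-n]; py <- track$y_mm[-n]
  dev <- rep(Inf, n - 1L)
  for (j in 1:2) {
    sx <- arena$stripe_distance * cos(arena$stripe_bearings[j]) - px
    sy <- arena$stripe_distance * sin(arena$stripe_bearings[j]) - py
    ang <- vector_angle(vx, vy, sx, sy)
    dev <- pmin(dev, ang)
  }
  stats::median(dev[moving]) * 180 / pi
}

vector_angle <- function(ax, ay, bx, by) {
  cosang <- (ax * bx + ay * by) / (sqrt(ax^2 + ay^2) * sqrt(bx^2 + by^2))
  acos(pmin(1, pmax(-1, cosang)))
}

#' Meander (path tortuosity)
#'
#' The unsigned turning angle between two consecutive velocity vectors,
#' divided by the instantaneous speed, median over all pairs of
#' consecutive moving frames. Units: degrees * s / mm. Higher values mean
#' a more tortuous path.
#'
#' @inheritParams segment_pauses
#' @return Median meander; `NA` when there are no consecutive moving
#'   frames.
#' @export
meander <- function(track, movement_epsilon = 0.1) {
  n <- nrow(track)
  if (n < 3) stop("trajectory needs at least 3 samples")
  vx <- diff(track$x_mm); vy <- diff(track$y_mm)
  d <- sqrt(vx^2 + vy^2)
  dt <- track_dt(track)
  m <- length(d)
  ok <- d[-m] > movement_epsilon & d[-1] > movement_epsilon
  if (!any(ok)) return(NA_real_)
  turn <- vector_angle(vx[-m], vy[-m], vx[-1], vy[-1]) * 180 / pi
  speed <- d[-1] / dt
  stats::median((turn / speed)[ok])
}

#' Compute all eight Buridan metrics for one trajectory
#'
#' One record per fly with the eight standard Buridan walking metrics:
#' activity time per minute, pauses per minute, total distance, median
#' speed, median pause duration, walks between the stripes per minute,
#' stripe deviation and meander. Metrics that are undefined for a track
#' (a fly that never pauses, or never moves) come back as `NA`, never as
#' zero.
#'
#' @inheritParams walks_per_min
#' @inheritParams median_speed
#' @param pause_threshold Minimum rest span in seconds counting as a pause.
#' @return A one-row data frame with `fly_id` plus the eight metric
#'   columns.
#' @examples
#' fly <- sample_flies(population_model("spontaneity"), 1, seed = 1)
#' trk <- simulate_buridan(fly, params = buridan_params(duration = 60), seed = 2)
#' buridan_metrics(trk)
#' @export
buridan_metrics <- function(track, arena = attr(track, "arena"),
                            pause_threshold = 1, movement_epsilon = 0.1,
                            jump_threshold = 50, zone_half_angle = pi / 6,
                            zone_depth = 0.2) {
  pauses <- segment_pauses(track, pause_threshold, movement_epsilon)
  data.frame(
    fly_id = attr(track, "fly_id") %||% NA_character_,
    activity_time_per_min = activity_time_per_min(track, pauses),
    pauses_per_min = pauses_per_min(track, pauses),
    distance_traveled = total_distance(track),
    median_speed = median_speed(track, jump_threshold, movement_epsilon),
    pause_duration = pause_duration_median(track, pauses),
    walks_per_min = walks_per_min(track, arena, zone_half_angle, zone_depth),
    stripe_deviation = stripe_deviation(track, arena, movement_epsilon),
    meander = meander(track, movement_epsilon),
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Compute metrics for a set of trajectory files or tracks
#'
#' @param tracks A list of `fly_track` objects, or a character vector of
#'   track CSV paths (read with [read_track()]). Malformed files are
#'   skipped with a warning; the run continues.
#' @param ... Passed to [buridan_metrics()].
#' @return A data frame with one metrics row per readable track.
#' @export
metrics_table <- function(tracks, ...) {
  if (is.character(tracks)) {
    paths <- tracks
    tracks <- lapply(paths, function(p) tryCatch(read_track(p),
      error = function(e) {
        warning("skipping unreadable track ", p, ": ", conditionMessage(e))
        NULL
      }))
    names(tracks) <- paths
  }
  rows <- lapply(tracks, function(trk) {
    if (is.null(trk)) return(NULL)
    tryCatch(buridan_metrics(trk, ...), error = function(e) {
      warning("skipping track: ", conditionMessage(e))
      NULL
    })
  })
  do.call(rbind, rows)
}
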