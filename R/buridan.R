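#' Buridan arena geometry
#'
#' The arena is a round walking platform surrounded by a water moat, with
#' two opposing vertical black stripes on the surrounding cylinder that the
#' fly can see but never reach. Defaults follow the standard apparatus:
#' 117 mm platform (radius 58.5 mm), stripes 30 mm wide at bearings 0 and
#' pi, 148.5 mm from the platform centre.
#'
#' @param platform_radius Platform radius in mm (> 0).
#' @param stripe_bearings Two stripe bearings in radians, ideally pi apart.
#' @param stripe_distance Distance from platform centre to stripe centre in
#'   mm (> `platform_radius`).
#' @param stripe_width Stripe width in mm.
#' @return An object of class `arena_geometry`.
#' @export
arena_geometry <- function(platform_radius = 58.5,
                           stripe_bearings = c(0, pi),
                           stripe_distance = 148.5,
                           stripe_width = 30) {
  if (platform_radius <= 0) stop("'platform_radius' must be positive")
  if (stripe_distance <= platform_radius)
    stop("'stripe_distance' must exceed 'platform_radius'")
  if (length(stripe_bearings) != 2L)
    stop("exactly two stripe bearings are required")
  structure(
    list(platform_radius = platform_radius,
         stripe_bearings = as.numeric(stripe_bearings),
         stripe_distance = stripe_distance,
         stripe_width = stripe_width),
    class = "arena_geometry"
  )
}

#' @export
print.arena_geometry <- function(x, ...) {
  cat(sprintf(paste0("Buridan arena: platform radius %.1f mm, stripes at ",
                     "%.2f / %.2f rad, %.1f mm away (%.0f mm wide)\n"),
              x$platform_radius, x$stripe_bearings[1], x$stripe_bearings[2],
              x$stripe_distance, x$stripe_width))
  invisible(x)
}

#' Buridan simulation parameters
#'
#' @param duration Experiment duration in seconds (default 900).
#' @param sampling_rate Sampling rate in Hz (default 10).
#' @param base_speed Walking speed in mm/s of a fly with activity 1
#'   (default 15, a typical wild-type walking speed).
#' @param pause_rate Expected pause initiations per minute of activity
#'   (default 4).
#' @param pause_duration_mean Mean pause duration in seconds (default 3).
#' @param heading_noise Standard deviation (radians) of per-frame heading
#'   jitter around the bearing towards the current target stripe
#'   (default 0.3).
#' @return An object of class `buridan_params`.
#' @export
buridan_params <- function(duration = 900, sampling_rate = 10,
                           base_speed = 15, pause_rate = 4,
                           pause_duration_mean = 3, heading_noise = 0.3) {
  if (duration <= 0 || sampling_rate <= 0)
    stop("'duration' and 'sampling_rate' must be positive")
  if (base_speed < 0 || pause_rate < 0 || pause_duration_mean < 0 ||
      heading_noise < 0)
    stop("rate and dispersion parameters must be non-negative")
  structure(
    list(duration = duration, sampling_rate = sampling_rate,
         base_speed = base_speed, pause_rate = pause_rate,
         pause_duration_mean = pause_duration_mean,
         heading_noise = heading_noise),
    class = "buridan_params"
  )
}

#' Simulate one Buridan walking trajectory
#'
#' Discrete-time kinematics on the sampling grid: the fly alternates
#' directed walks towards the two stripes, switching target when it reaches
#' the platform edge, interrupted by pauses whose initiation rate and mean
#' duration are configurable. The per-frame step length is
#' `base_speed * activity / sampling_rate`, so expected speed (and total
#' path length) scale linearly with the fly's activity trait; a fly with
#' activity 0 never moves.
#'
#' @param fly One row of a [sample_flies()] data frame (or any list with
#'   `fly_id` and `activity`).
#' @param arena An [arena_geometry()].
#' @param params A [buridan_params()].
#' @param seed Optional integer seed.
#' @return A `fly_track`: a data frame with columns `t_s`, `x_mm`, `y_mm`
#'   and attributes `arena`, `sampling_rate`, `fly_id`.
#' @examples
#' fly <- sample_flies(population_model("spontaneity"), 1, seed = 1)
#' trk <- simulate_buridan(fly, params = buridan_params(duration = 60), seed = 2)
#' total_distance(trk)
#' @export
simulate_buridan <- function(fly, arena = arena_geometry(),
                             params = buridan_params(), seed = NULL) {
  stopifnot(inherits(arena, "arena_geometry"),
            inherits(params, "buridan_params"))
  activity <- if (is.data.frame(fly)) fly$activity[1] else fly$activity
  fly_id <- if (is.data.frame(fly)) fly$fly_id[1] else fly$fly_id
  if (is.null(activity) || is.na(activity) || activity < 0)
    stop("'fly' must carry a non-negative 'activity' trait")
  if (!is.null(seed)) set.seed(seed)

  dt <- 1 / params$sampling_rate
  n_frames <- floor(params$duration * params$sampling_rate) + 1L
  step <- params$base_speed * activity * dt
  r_max <- arena$platform_radius
  # pause initiation probability per active frame
  p_pause <- min(1, params$pause_rate / 60 * dt)

  x <- y <- numeric(n_frames)
  target <- 1L  # index into stripe_bearings
  pause_left <- 0
  for (i in seq_len(n_frames - 1L)) {
    if (pause_left > 0) {
      pause_left <- pause_left - 1L
      x[i + 1L] <- x[i]; y[i + 1L] <- y[i]
      next
    }
    if (step > 0 && p_pause > 0 && stats::runif(1) < p_pause) {
      pause_left <- max(1L, round(stats::rexp(1, 1 / params$pause_duration_mean) /
                                    dt))
      x[i + 1L] <- x[i]; y[i + 1L] <- y[i]
      next
    }
    bearing <- arena$stripe_bearings[target]
    tx <- arena$stripe_distance * cos(bearing)
    ty <- arena$stripe_distance * sin(bearing)
    heading <- atan2(ty - y[i], tx - x[i])
    if (params$heading_noise > 0)
      heading <- heading + stats::rnorm(1, 0, params$heading_noise)
    nx <- x[i] + step * cos(heading)
    ny <- y[i] + step * sin(heading)
    if (sqrt(nx^2 + ny^2) >= r_max) {
      # clamp to the platform edge and turn back towards the other stripe
      r <- sqrt(nx^2 + ny^2)
      nx <- nx * r_max / r; ny <- ny * r_max / r
      target <- 3L - target
    }
    x[i + 1L] <- nx; y[i + 1L] <- ny
  }
  new_fly_track(data.frame(t_s = (seq_len(n_frames) - 1L) * dt,
                           x_mm = x, y_mm = y),
                arena = arena, sampling_rate = params$sampling_rate,
                fly_id = fly_id)
}

new_fly_track <- function(df, arena, sampling_rate, fly_id = NA_character_) {
  structure(df, arena = arena, sampling_rate = sampling_rate,
            fly_id = fly_id, class = c("fly_track", "data.frame"))
}

#' Write / read a trajectory as CSV plus a JSON sidecar
#'
#' The track itself is written as plain CSV (`t_s`, `x_mm`, `y_mm`); the
#' arena geometry, sampling rate and fly id travel in a JSON sidecar next
#' to it (same path with extension `.json`), so a track file round-trips
#' losslessly.
#'
#' @param track A `fly_track` from [simulate_buridan()] or [read_track()].
#' @param path CSV file path.
#' @return `write_track` returns `path` invisibly; `read_track` returns a
#'   `fly_track`.
#' @export
write_track <- function(track, path) {
  stopifnot(inherits(track, "fly_track"))
  utils::write.csv(as.data.frame(track)[c("t_s", "x_mm", "y_mm")], path,
                   row.names = FALSE)
  arena <- attr(track, "arena")
  sidecar <- list(
    fly_id = attr(track, "fly_id"),
    sampling_rate = attr(track, "sampling_rate"),
    arena = unclass(arena)
  )
  jsonlite::write_json(sidecar, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_track
#' @export
read_track <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("t_s", "x_mm", "y_mm") %in% names(df)))
    stop("track CSV must have columns t_s, x_mm, y_mm")
  sp <- sidecar_path(path)
  if (file.exists(sp)) {
    meta <- jsonlite::read_json(sp, simplifyVector = TRUE)
    arena <- do.call(arena_geometry, meta$arena)
    new_fly_track(df, arena = arena, sampling_rate = meta$sampling_rate,
                  fly_id = meta$fly_id)
  } else {
    dt <- stats::median(diff(df$t_s))
    new_fly_track(df, arena = arena_geometry(), sampling_rate = 1 / dt)
  }
}

sidecar_path <- function(path) sub("\\.[^.]*$", ".json", path)
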