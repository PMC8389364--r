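#' Simulate one light/dark T-maze session
#'
#' Each fly is abstracted to a single choice: with probability
#' `elevator_capture_prob` it fails to leave the elevator within the choice
#' period (independently of its preference); otherwise it enters the bright
#' arm with probability `p_light` and the dark arm otherwise.
#'
#' @param flies Trait data frame from [sample_flies()] (or any data frame
#'   with `fly_id` and `p_light`).
#' @param elevator_capture_prob Probability of being caught in the elevator
#'   (default 0.05).
#' @param seed Optional integer seed.
#' @param session_id Optional identifier.
#' @return An object of class `tmaze_session`: a list with `outcomes` (the
#'   trait rows plus an `outcome` factor with levels bright/dark/elevator)
#'   and the session metadata. Convert to counts with [as_tmaze_counts()].
#' @examples
#' flies <- sample_flies(population_model("spontaneity", p_mean = 0.7), 80, seed = 1)
#' s <- simulate_tmaze(flies, seed = 2)
#' choice_index(s)
#' @export
simulate_tmaze <- function(flies, elevator_capture_prob = 0.05, seed = NULL,
                           session_id = NA_character_) {
  check_flies(flies)
  if (elevator_capture_prob < 0 || elevator_capture_prob > 1)
    stop("'elevator_capture_prob' must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(flies)
  caught <- stats::runif(n) < elevator_capture_prob
  bright <- stats::runif(n) < flies$p_light
  outcome <- ifelse(caught, "elevator", ifelse(bright, "bright", "dark"))
  out <- flies
  out$outcome <- factor(outcome, levels = c("bright", "dark", "elevator"))
  structure(
    list(outcomes = out, session_id = session_id,
         elevator_capture_prob = elevator_capture_prob),
    class = "tmaze_session"
  )
}

#' @export
print.tmaze_session <- function(x, ...) {
  print(as_tmaze_counts(x))
  invisible(x)
}

#' @describeIn simulate_tmaze Collapse a simulated session to compartment
#'   counts.
#' @param x A `tmaze_session`.
#' @export
as_tmaze_counts <- function(x) {
  stopifnot(inherits(x, "tmaze_session"))
  tab <- table(x$outcomes$outcome)
  tmaze_counts(n_bright = as.integer(tab[["bright"]]),
               n_dark = as.integer(tab[["dark"]]),
               n_elevator = as.integer(tab[["elevator"]]),
               n_total = nrow(x$outcomes),
               session_id = x$session_id)
}

#' Simulate one countercurrent phototaxis session
#'
#' Each fly makes `n_choices` independent walk/stay decisions; its tube
#' index is the number of times it walked towards the light. Under the
#' default link the per-choice walk probability is the fly's `p_light`;
#' with `walk_link = "activity"` it is `p_light * min(activity /
#' activity_mean, 1)`, a saturating attenuation reflecting that walking
#' towards the light (unlike a symmetric T-maze choice) also requires the
#' inclination to walk at all.
#'
#' @inheritParams simulate_tmaze
#' @param n_choices Choices per session (default 5, giving six tubes).
#' @param walk_link `"preference"` (default) or `"activity"`.
#' @param activity_mean Reference activity for the saturating link.
#' @return An object of class `cpp_session`: `outcomes` holds the trait rows
#'   plus `tube` and the choice sequence matrix is in `sequences` (flies x
#'   choices, 0 = stay, 1 = walk). Convert to tube counts with
#'   [as_cpp_counts()].
#' @examples
#' flies <- sample_flies(population_model("individuality", alpha = 1, beta = 1),
#'                       80, seed = 1)
#' s <- simulate_cpp(flies, seed = 2)
#' performance_index(s)
#' @export
simulate_cpp <- function(flies, n_choices = 5,
                         walk_link = c("preference", "activity"),
                         activity_mean = 1, seed = NULL,
                         session_id = NA_character_) {
  check_flies(flies)
  walk_link <- match.arg(walk_link)
  if (n_choices < 1) stop("'n_choices' must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  p_walk <- switch(walk_link,
    preference = flies$p_light,
    activity = flies$p_light * pmin(flies$activity / activity_mean, 1)
  )
  n <- nrow(flies)
  seqs <- matrix(stats::runif(n * n_choices) < rep(p_walk, n_choices),
                 nrow = n, ncol = n_choices) * 1L
  out <- flies
  out$tube <- as.integer(rowSums(seqs))
  structure(
    list(outcomes = out, sequences = seqs, n_choices = as.integer(n_choices),
         walk_link = walk_link, session_id = session_id),
    class = "cpp_session"
  )
}

#' @export
print.cpp_session <- function(x, ...) {
  print(as_cpp_counts(x))
  invisible(x)
}

#' @describeIn simulate_cpp Collapse a simulated session to tube counts.
#' @param x A `cpp_session`.
#' @export
as_cpp_counts <- function(x) {
  stopifnot(inherits(x, "cpp_session"))
  counts <- tabulate(x$outcomes$tube + 1L, nbins = x$n_choices + 1L)
  cpp_counts(counts, n_total = nrow(x$outcomes), session_id = x$session_id)
}

#' Simulate a split/pool/retest protocol
#'
#' Runs `replicates` first sessions on fresh groups drawn from `model`,
#' splits the flies by their first-session outcome, pools the subgroups
#' according to the standard rules ([pool_subgroups()] /
#' [pool_cpp_subgroups()]), and runs a second session on every pool with
#' the *same* fly traits. Because traits persist across sessions, the
#' second-session indices reveal whether choices carry information about
#' the individual (individuality) or not (spontaneity).
#'
#' @param model A [population_model()].
#' @param paradigm `"tmaze"` or `"cpp"`.
#' @param replicates Number of first sessions (default 8 for the T-maze,
#'   24 for the countercurrent paradigm, which yields roughly eight
#'   40-fly second-session pools per tube under a uniform preference
#'   distribution).
#' @param n_flies Flies per first session (default 80).
#' @param minimum Minimum pool size for a second session (default 40).
#' @param seed Integer seed governing the whole protocol.
#' @param ... Passed on to [simulate_tmaze()] / [simulate_cpp()].
#' @return A list with `first_sessions` (list of session objects), `pools`,
#'   and `retest`, a data frame with one row per pool: `source`, `tube`
#'   (CPP only, `NA` for T-maze), `n`, `meets_minimum`, and the
#'   second-session `index` (CI or PI). Pools below the minimum are
#'   retested anyway but flagged.
#' @examples
#' r <- simulate_retest(population_model("individuality", alpha = 1, beta = 1),
#'                      paradigm = "cpp", replicates = 6, seed = 1)
#' aggregate(index ~ tube, r$retest, mean)
#' @export
simulate_retest <- function(model, paradigm = c("tmaze", "cpp"),
                            replicates = NULL, n_flies = 80, minimum = 40,
                            seed = NULL, ...) {
  paradigm <- match.arg(paradigm)
  if (is.null(replicates)) replicates <- if (paradigm == "tmaze") 8L else 24L
  if (replicates < 1) stop("'replicates' must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  sessions <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    flies <- sample_flies(model, n_flies)
    sessions[[r]] <- if (paradigm == "tmaze") {
      simulate_tmaze(flies, session_id = paste0("rep", r), ...)
    } else {
      simulate_cpp(flies, session_id = paste0("rep", r), ...)
    }
  }
  pools <- if (paradigm == "tmaze") pool_subgroups(sessions, minimum)
           else pool_cpp_subgroups(sessions, minimum)
  retest <- lapply(pools, function(pool) {
    if (pool$n == 0) return(NULL)
    second <- if (paradigm == "tmaze") {
      choice_index(simulate_tmaze(pool$flies[names(pool$flies) !=
                                               "outcome"], ...))
    } else {
      performance_index(simulate_cpp(pool$flies[names(pool$flies) !=
                                                  "tube"], ...))
    }
    data.frame(source = pool$source,
               tube = if (is.null(pool$tube)) NA_integer_ else pool$tube,
               n = pool$n, meets_minimum = pool$meets_minimum,
               index = second, stringsAsFactors = FALSE)
  })
  retest <- do.call(rbind, retest)
  if (any(!retest$meets_minimum))
    attr(retest, "short_pools") <- sum(!retest$meets_minimum)
  list(first_sessions = sessions, pools = pools, retest = retest)
}

check_flies <- function(flies) {
  if (!is.data.frame(flies) || nrow(flies) == 0)
    stop("'flies' must be a non-empty data frame of fly traits")
  if (!all(c("fly_id", "p_light") %in% names(flies)))
    stop("'flies' must have columns 'fly_id' and 'p_light'")
  if (any(flies$p_light < 0 | flies$p_light > 1))
    stop("'p_light' must lie in [0, 1]")
  invisible(flies)
}
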