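#' Elevator correction factor for the T-maze Choice Index
#'
#' The dark transfer chamber (the "elevator") adds a small extra volume of
#' darkness to the dark arm of the T-maze. Flies found there at scoring time
#' are counted with the dark side, down-weighted by one minus the volume
#' proportion the elevator represents.
#'
#' @param elevator_proportion Fraction of the dark volume contributed by the
#'   elevator, in `[0, 1)`. Default 0.036, giving the standard 0.964
#'   multiplier.
#' @return The multiplier `1 - elevator_proportion`.
#' @examples
#' correction_factor()      # 0.964
#' correction_factor(0)     # uncorrected index
#' @export
correction_factor <- function(elevator_proportion = 0.036) {
  if (!is.numeric(elevator_proportion) || length(elevator_proportion) != 1L ||
      elevator_proportion < 0 || elevator_proportion >= 1)
    stop("'elevator_proportion' must lie in [0, 1)")
  1 - elevator_proportion
}

#' Construct a T-maze session from compartment counts
#'
#' @param n_bright Flies found in the transparent (bright) tube.
#' @param n_dark Flies found in the opaque (dark) tube.
#' @param n_elevator Flies still in the elevator at scoring time.
#' @param n_total Nominal number of flies loaded; defaults to the sum of the
#'   three compartments. Flies may be lost, so the compartment sum may fall
#'   short of `n_total`, never exceed it.
#' @param session_id Optional identifier.
#' @return An object of class `tmaze_counts`.
#' @export
tmaze_counts <- function(n_bright, n_dark, n_elevator = 0,
                         n_total = n_bright + n_dark + n_elevator,
                         session_id = NA_character_) {
  counts <- c(n_bright, n_dark, n_elevator, n_total)
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be non-negative numbers")
  if (n_bright + n_dark + n_elevator > n_total)
    stop("compartment counts exceed 'n_total'")
  structure(
    list(n_bright = n_bright, n_dark = n_dark, n_elevator = n_elevator,
         n_total = n_total, session_id = session_id),
    class = "tmaze_counts"
  )
}

#' @export
print.tmaze_counts <- function(x, ...) {
  cat(sprintf("T-maze session%s: bright %d, dark %d, elevator %d (of %d)\n",
              if (is.na(x$session_id)) "" else paste0(" ", x$session_id),
              x$n_bright, x$n_dark, x$n_elevator, x$n_total))
  cat(sprintf("  Choice Index = %.4f\n", choice_index(x)))
  invisible(x)
}

#' Elevator-corrected Choice Index for T-maze sessions
#'
#' The Choice Index is
#' \deqn{CI = \frac{\#F_L - 0.964 (\#F_D + \#F_E)}{\#F_T}}
#' where \eqn{\#F_L}, \eqn{\#F_D}, \eqn{\#F_E} count flies in the bright
#' tube, dark tube and elevator and \eqn{\#F_T} is the total. A CI of 1
#' means every fly chose the bright arm; -0.964 means every fly preferred
#' the dark side. The 0.964 factor compensates for the extra dark volume of
#' the elevator; set `elevator_proportion = 0` for the classic uncorrected
#' preference index.
#'
#' @param x A [tmaze_counts()], a [simulate_tmaze()] session, or a data
#'   frame with columns `n_bright`, `n_dark`, `n_elevator`, `n_total` (one
#'   session per row).
#' @param elevator_proportion Passed to [correction_factor()].
#' @param denominator `"found"` (default) divides by the flies actually
#'   recovered in the three compartments; `"nominal"` divides by `n_total`
#'   as loaded, counting lost flies in the denominator.
#' @param ... Unused.
#' @return Numeric CI (vector for data-frame input), in
#'   `[-(1 - elevator_proportion), 1]`.
#' @examples
#' choice_index(tmaze_counts(80, 0, 0))   #  1
#' choice_index(tmaze_counts(0, 80, 0))   # -0.964
#' @export
choice_index <- function(x, ...) UseMethod("choice_index")

#' @rdname choice_index
#' @export
choice_index.tmaze_counts <- function(x, elevator_proportion = 0.036,
                                      denominator = c("found", "nominal"),
                                      ...) {
  ci_from_counts(x$n_bright, x$n_dark, x$n_elevator, x$n_total,
                 elevator_proportion, match.arg(denominator))
}

#' @rdname choice_index
#' @export
choice_index.data.frame <- function(x, elevator_proportion = 0.036,
                                    denominator = c("found", "nominal"),
                                    ...) {
  need <- c("n_bright", "n_dark", "n_elevator", "n_total")
  if (!all(need %in% names(x)))
    stop("data frame must have columns ", paste(need, collapse = ", "))
  ci_from_counts(x$n_bright, x$n_dark, x$n_elevator, x$n_total,
                 elevator_proportion, match.arg(denominator))
}

#' @rdname choice_index
#' @export
choice_index.tmaze_session <- function(x, elevator_proportion = 0.036,
                                       denominator = c("found", "nominal"),
                                       ...) {
  choice_index(as_tmaze_counts(x), elevator_proportion,
               match.arg(denominator))
}

ci_from_counts <- function(n_bright, n_dark, n_elevator, n_total,
                           elevator_proportion, denominator) {
  if (any(c(n_bright, n_dark, n_elevator) < 0))
    stop("counts must be non-negative")
  denom <- if (denominator == "nominal") n_total
           else n_bright + n_dark + n_elevator
  if (any(denom <= 0)) stop("Choice Index undefined: no flies in session")
  f <- correction_factor(elevator_proportion)
  (n_bright - f * (n_dark + n_elevator)) / denom
}

#' Construct a countercurrent session from tube occupancy counts
#'
#' @param counts Non-negative counts for tubes `0..n_choices` (default six
#'   tubes); tube `k` holds flies that walked towards the light `k` times.
#' @param n_total Nominal total; defaults to `sum(counts)`.
#' @param session_id Optional identifier.
#' @return An object of class `cpp_counts`.
#' @export
cpp_counts <- function(counts, n_total = sum(counts),
                       session_id = NA_character_) {
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("tube counts must be non-negative numbers")
  if (sum(counts) > n_total) stop("tube counts exceed 'n_total'")
  structure(
    list(counts = as.numeric(counts), n_choices = length(counts) - 1L,
         n_total = n_total, session_id = session_id),
    class = "cpp_counts"
  )
}

#' @export
print.cpp_counts <- function(x, ...) {
  cat(sprintf("Countercurrent session%s (%d tubes, %g flies)\n",
              if (is.na(x$session_id)) "" else paste0(" ", x$session_id),
              x$n_choices + 1L, x$n_total))
  names(x$counts) <- paste0("tube_", 0:x$n_choices)
  print(x$counts)
  cat(sprintf("  Performance Index = %.4f\n", performance_index(x)))
  invisible(x)
}

#' Performance Index for countercurrent phototaxis sessions
#'
#' The Performance Index is the occupancy-weighted mean tube index,
#' \deqn{PI = \sum_k k\,\#F_k / \#F_T,}
#' ranging from 0 (no fly ever walked towards the light) to the number of
#' choices (default 5; every fly walked every time). When per-fly tube
#' assignments are available the PI equals their unweighted mean.
#'
#' @param x A [cpp_counts()], a [simulate_cpp()] session, a bare numeric
#'   vector of tube counts (tube 0 first), or a data frame with columns
#'   `tube_0 ... tube_k` plus `n_total`.
#' @param denominator `"found"` (default) or `"nominal"`, as for
#'   [choice_index()].
#' @param ... Unused.
#' @return Numeric PI in `[0, n_choices]`.
#' @examples
#' performance_index(c(0, 0, 10, 10, 10, 50))  # 4.25
#' @export
performance_index <- function(x, ...) UseMethod("performance_index")

#' @rdname performance_index
#' @export
performance_index.cpp_counts <- function(x,
                                         denominator = c("found", "nominal"),
                                         ...) {
  denom <- if (match.arg(denominator) == "nominal") x$n_total
           else sum(x$counts)
  if (denom <= 0) stop("Performance Index undefined: no flies in session")
  sum(x$counts * (0:x$n_choices)) / denom
}

#' @rdname performance_index
#' @export
performance_index.numeric <- function(x, ...) {
  performance_index(cpp_counts(x), ...)
}

#' @rdname performance_index
#' @export
performance_index.cpp_session <- function(x, ...) {
  performance_index(as_cpp_counts(x), ...)
}

#' @rdname performance_index
#' @export
performance_index.data.frame <- function(x, ...) {
  tube_cols <- grep("^tube_[0-9]+$", names(x), value = TRUE)
  if (length(tube_cols) < 2) stop("data frame must have tube_0..tube_k columns")
  tube_cols <- tube_cols[order(as.integer(sub("tube_", "", tube_cols)))]
  vapply(seq_len(nrow(x)), function(i)
    performance_index(as.numeric(x[i, tube_cols]), ...), numeric(1))
}

#' Pool T-maze subgroups for a second choice session
#'
#' After a first T-maze session the bright subgroup of each replicate is
#' usually large enough to re-test on its own, but the dark subgroup is not.
#' Following the standard protocol, flies from the elevator are first added
#' to the dark tube (the elevator is also dark), and dark+elevator subgroups
#' from successive replicates are then merged until the pool reaches the
#' minimum size for a second session (default 40 flies, half of the standard
#' 80-fly group). Pools that cannot reach the minimum are returned flagged,
#' never dropped.
#'
#' @param sessions A list of [simulate_tmaze()] sessions (they carry per-fly
#'   outcomes).
#' @param minimum Minimum pool size for a second session (default 40).
#' @param shuffle If `TRUE`, replicates are merged in a seeded random order
#'   instead of input order (random combination of dark+elevator subgroups).
#' @param seed Seed for `shuffle`.
#' @return A list of subgroup pools, each a list with elements `source`
#'   (`"bright"` or `"dark_plus_elevator"`), `flies` (trait rows of the
#'   member flies), `n`, `meets_minimum` and `members` (contributing session
#'   ids).
#' @export
pool_subgroups <- function(sessions, minimum = 40, shuffle = FALSE,
                           seed = NULL) {
  if (length(sessions) == 0) stop("'sessions' must be non-empty")
  stopifnot(all(vapply(sessions, inherits, logical(1), "tmaze_session")))
  order_idx <- seq_along(sessions)
  if (shuffle) {
    if (!is.null(seed)) set.seed(seed)
    order_idx <- sample(order_idx)
  }
  pools <- list()
  # bright subgroup: one pool per replicate
  for (i in order_idx) {
    s <- sessions[[i]]
    bright <- s$outcomes[s$outcomes$outcome == "bright", , drop = FALSE]
    pools[[length(pools) + 1L]] <- list(
      source = "bright", flies = bright, n = nrow(bright),
      meets_minimum = nrow(bright) >= minimum, members = s$session_id
    )
  }
  # dark + elevator: accumulate across replicates until the minimum is met
  acc <- NULL; acc_members <- character(0)
  flush_pool <- function(acc, members, pools) {
    pools[[length(pools) + 1L]] <- list(
      source = "dark_plus_elevator", flies = acc, n = nrow(acc),
      meets_minimum = nrow(acc) >= minimum, members = members
    )
    pools
  }
  for (i in order_idx) {
    s <- sessions[[i]]
    dk <- s$outcomes[s$outcomes$outcome %in% c("dark", "elevator"), ,
                     drop = FALSE]
    acc <- if (is.null(acc)) dk else rbind(acc, dk)
    acc_members <- c(acc_members, s$session_id)
    if (nrow(acc) >= minimum) {
      pools <- flush_pool(acc, acc_members, pools)
      acc <- NULL; acc_members <- character(0)
    }
  }
  if (!is.null(acc) && nrow(acc) > 0)
    pools <- flush_pool(acc, acc_members, pools)  # short pool, flagged
  pools
}

#' Pool countercurrent tube subgroups for a second session
#'
#' Flies that made the same number of light choices in independent first
#' sessions are merged, tube by tube, until each pool reaches the minimum
#' size for a second session. Mirrors [pool_subgroups()] for the six-tube
#' fractionation.
#'
#' @param sessions A list of [simulate_cpp()] sessions.
#' @inheritParams pool_subgroups
#' @return A list of pools with elements `source` (`"tube_k"`), `tube`,
#'   `flies`, `n`, `meets_minimum`, `members`.
#' @export
pool_cpp_subgroups <- function(sessions, minimum = 40, shuffle = FALSE,
                               seed = NULL) {
  if (length(sessions) == 0) stop("'sessions' must be non-empty")
  stopifnot(all(vapply(sessions, inherits, logical(1), "cpp_session")))
  order_idx <- seq_along(sessions)
  if (shuffle) {
    if (!is.null(seed)) set.seed(seed)
    order_idx <- sample(order_idx)
  }
  n_choices <- sessions[[1L]]$n_choices
  pools <- list()
  for (k in 0:n_choices) {
    acc <- NULL; acc_members <- character(0)
    for (i in order_idx) {
      s <- sessions[[i]]
      sub <- s$outcomes[s$outcomes$tube == k, , drop = FALSE]
      if (nrow(sub) == 0 && is.null(acc)) next
      acc <- if (is.null(acc)) sub else rbind(acc, sub)
      acc_members <- c(acc_members, s$session_id)
      if (nrow(acc) >= minimum) {
        pools[[length(pools) + 1L]] <- list(
          source = paste0("tube_", k), tube = k, flies = acc, n = nrow(acc),
          meets_minimum = TRUE, members = acc_members
        )
        acc <- NULL; acc_members <- character(0)
      }
    }
    if (!is.null(acc) && nrow(acc) > 0)
      pools[[length(pools) + 1L]] <- list(
        source = paste0("tube_", k), tube = k, flies = acc, n = nrow(acc),
        meets_minimum = FALSE, members = acc_members
      )
  }
  pools
}
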