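#' Define a generative population model for fly photopreference
#'
#' A population model describes how individual flies acquire their latent
#' light preference `p_light` and their locomotor activity level. Two kinds
#' are available, formalising the two competing accounts of choice
#' variability:
#'
#' * `"spontaneity"`: every fly shares the same choice probability
#'   `p_mean`; successive choices are independent coin flips, so subgroups
#'   selected on a first choice behave like the original population on a
#'   retest.
#' * `"individuality"`: each fly draws a stable `p_light` from a
#'   Beta(`alpha`, `beta`) distribution; between-fly heterogeneity makes
#'   choice history informative about future choices.
#'
#' Activity is drawn from a normal distribution truncated at zero, and a
#' Gaussian copula induces correlation `rho` between `p_light` and activity
#' (only meaningful under the individuality model, where `p_light` varies).
#'
#' @param kind `"individuality"` or `"spontaneity"`.
#' @param p_mean Mean light preference in `[0, 1]`. For the individuality
#'   model this is derived from `alpha / (alpha + beta)` when shapes are
#'   supplied; defaults to 0.7, the canonical bright/dark split observed in
#'   wild-type T-maze groups.
#' @param alpha,beta Beta shape parameters (individuality only, both > 0).
#'   Defaults give mean 0.7 with concentration `alpha + beta = 4`, a broad
#'   preference distribution.
#' @param activity_mean,activity_sd Parameters of the (pre-truncation)
#'   normal activity distribution. Activity is a dimensionless multiplier on
#'   locomotor output with population mean near 1.
#' @param rho Gaussian-copula correlation in `[-1, 1]` between `p_light`
#'   and activity. Default 0.6: more photopositive flies are more active.
#' @return An object of class `population_model`.
#' @seealso [sample_flies()]
#' @examples
#' population_model("spontaneity", p_mean = 0.7)
#' population_model("individuality", alpha = 2, beta = 2)
#' @export
population_model <- function(kind = c("individuality", "spontaneity"),
                             p_mean = NULL, alpha = NULL, beta = NULL,
                             activity_mean = 1, activity_sd = 0.3,
                             rho = 0.6) {
  kind <- match.arg(kind)
  if (kind == "spontaneity") {
    if (is.null(p_mean)) p_mean <- 0.7
    if (!is.null(alpha) || !is.null(beta))
      stop("shape parameters apply only to the individuality model")
    alpha <- beta <- NA_real_
  } else {
    if (is.null(alpha) && is.null(beta)) {
      if (is.null(p_mean)) p_mean <- 0.7
      # default concentration 4: broad but unimodal-ish preference spread
      alpha <- 4 * p_mean
      beta <- 4 * (1 - p_mean)
    }
    if (is.null(alpha) || is.null(beta))
      stop("supply both 'alpha' and 'beta', or neither")
    if (!is.numeric(alpha) || !is.numeric(beta) || alpha <= 0 || beta <= 0)
      stop("'alpha' and 'beta' must be positive")
    p_mean <- alpha / (alpha + beta)
  }
  if (!is.numeric(p_mean) || p_mean < 0 || p_mean > 1)
    stop("'p_mean' must lie in [0, 1]")
  if (activity_mean < 0 || activity_sd < 0)
    stop("'activity_mean' and 'activity_sd' must be non-negative")
  if (abs(rho) > 1) stop("'rho' must lie in [-1, 1]")
  structure(
    list(kind = kind, p_mean = p_mean, alpha = alpha, beta = beta,
         activity_mean = activity_mean, activity_sd = activity_sd,
         rho = rho),
    class = "population_model"
  )
}

#' @export
print.population_model <- function(x, ...) {
  cat("Population model:", x$kind, "\n")
  if (x$kind == "individuality")
    cat(sprintf("  p_light ~ Beta(%.3g, %.3g)  (mean %.3f)\n",
                x$alpha, x$beta, x$p_mean))
  else
    cat(sprintf("  p_light = %.3f for every fly\n", x$p_mean))
  cat(sprintf("  activity ~ N(%.3g, %.3g) truncated at 0, copula rho = %.2f\n",
              x$activity_mean, x$activity_sd, x$rho))
  invisible(x)
}

#' Sample a population of flies from a generative model
#'
#' Draws `n` flies, each with a stable latent light preference and activity
#' level. Traits are fixed for the lifetime of the fly object: repeated
#' sessions simulated on the same data frame reuse the same `p_light`, which
#' is what makes the individuality model history-dependent.
#'
#' @param model A [population_model()].
#' @param n Number of flies (> 0).
#' @param seed Optional integer seed; identical `(model, n, seed)` give
#'   identical populations.
#' @return A data frame with columns `fly_id`, `p_light`, `activity`.
#' @examples
#' flies <- sample_flies(population_model("individuality", alpha = 2, beta = 2),
#'                       n = 10, seed = 1)
#' mean(flies$p_light)
#' @export
sample_flies <- function(model, n, seed = NULL) {
  stopifnot(inherits(model, "population_model"))
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop("'n' must be a positive integer")
  n <- as.integer(n)
  if (!is.null(seed)) set.seed(seed)
  # Gaussian copula: z1 drives preference, z2 (correlated) drives activity
  z1 <- stats::rnorm(n)
  z2 <- model$rho * z1 + sqrt(1 - model$rho^2) * stats::rnorm(n)
  p_light <- if (model$kind == "spontaneity") {
    rep(model$p_mean, n)
  } else {
    stats::qbeta(stats::pnorm(z1), model$alpha, model$beta)
  }
  activity <- rtruncnorm_probit(z2, model$activity_mean, model$activity_sd)
  data.frame(
    fly_id = sprintf("fly_%04d", seq_len(n)),
    p_light = p_light,
    activity = activity,
    stringsAsFactors = FALSE
  )
}

# Map standard-normal draws through the truncated-at-zero normal quantile
# function, preserving the copula dependence carried by z.
rtruncnorm_probit <- function(z, mean, sd) {
  if (sd == 0) return(rep(max(mean, 0), length(z)))
  p0 <- stats::pnorm(0, mean, sd)
  stats::qnorm(p0 + stats::pnorm(z) * (1 - p0), mean, sd)
}
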