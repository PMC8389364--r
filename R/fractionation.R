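#' Tube index of a countercurrent choice sequence
#'
#' In the countercurrent apparatus a fly's final tube equals the number of
#' times it walked towards the light, irrespective of the order of its
#' choices: five walks land it in tube 5, five stays leave it in tube 0.
#'
#' @param seq Binary vector (0 = stay, 1 = walk), or a matrix with one
#'   sequence per row.
#' @return Integer tube index (vector for matrix input).
#' @examples
#' tube_assignment(c(1, 0, 1, 0, 1))  # 3
#' @export
tube_assignment <- function(seq) {
  if (is.matrix(seq)) return(apply(seq, 1L, tube_assignment))
  if (length(seq) == 0 || !all(seq %in% c(0, 1)))
    stop("'seq' must be a non-empty binary (0/1) sequence")
  as.integer(sum(seq))
}

#' Closed-form tube occupancy distributions
#'
#' Under the spontaneity model every fly walks with the same probability
#' `p` at each choice, so tube occupancy follows Binomial(`n_choices`, `p`).
#' Under the individuality model each fly's walk probability is drawn from
#' Beta(`alpha`, `beta`), giving the beta-binomial mixture; as
#' `alpha, beta` grow with their ratio fixed, it concentrates back onto the
#' binomial.
#'
#' @param p Shared walk probability in `[0, 1]`.
#' @param alpha,beta Positive beta shape parameters.
#' @param n_choices Choices per session (default 5).
#' @return An object of class `tube_dist`: probabilities over tubes
#'   `0..n_choices` plus the model label and parameters.
#' @examples
#' tube_dist_binomial(0.5)           # (1,5,10,10,5,1)/32
#' tube_dist_betabinomial(1, 1)      # uniform 1/6
#' @export
tube_dist_binomial <- function(p, n_choices = 5) {
  if (!is.numeric(p) || length(p) != 1L || p < 0 || p > 1)
    stop("'p' must lie in [0, 1]")
  new_tube_dist(stats::dbinom(0:n_choices, n_choices, p),
                model = "binomial", params = c(p = p),
                n_choices = n_choices)
}

#' @rdname tube_dist_binomial
#' @export
tube_dist_betabinomial <- function(alpha, beta, n_choices = 5) {
  if (!is.numeric(alpha) || !is.numeric(beta) || alpha <= 0 || beta <= 0)
    stop("'alpha' and 'beta' must be positive")
  new_tube_dist(dbetabinom(0:n_choices, n_choices, alpha, beta),
                model = "betabinomial", params = c(alpha = alpha, beta = beta),
                n_choices = n_choices)
}

new_tube_dist <- function(probs, model, params, n_choices) {
  names(probs) <- paste0("tube_", 0:n_choices)
  structure(list(probs = probs, model = model, params = params,
                 n_choices = as.integer(n_choices)),
            class = "tube_dist")
}

#' @export
print.tube_dist <- function(x, digits = 4, ...) {
  cat(sprintf("Tube occupancy distribution (%s; %s)\n", x$model,
              paste(names(x$params), signif(x$params, 4),
                    sep = " = ", collapse = ", ")))
  print(round(x$probs, digits))
  invisible(x)
}

#' Beta-binomial probability mass function
#'
#' @param k Number of successes.
#' @param n Number of trials.
#' @param alpha,beta Positive shape parameters of the mixing beta.
#' @param log Return log probabilities?
#' @return `P(K = k)` for `K ~ BetaBinomial(n, alpha, beta)`.
#' @export
dbetabinom <- function(k, n, alpha, beta, log = FALSE) {
  lp <- lchoose(n, k) + lbeta(k + alpha, n - k + beta) - lbeta(alpha, beta)
  lp[k < 0 | k > n | k != round(k)] <- -Inf
  if (log) lp else exp(lp)
}

#' Fit a fractionation model to tube occupancy counts
#'
#' Fits the spontaneity (binomial, one parameter `p`) or individuality
#' (beta-binomial, shapes `alpha`, `beta`) model to observed tube counts by
#' maximum likelihood under a multinomial likelihood (flies independent,
#' conditioned on flies recovered in tubes). The binomial MLE is the
#' closed-form weighted mean `PI / n_choices`; the beta-binomial likelihood
#' is maximised over log-shapes from the fixed start `alpha = beta = 1`
#' with convergence tolerance 1e-8, so fits are deterministic.
#'
#' Comparing the two fits by AIC formalises the chance-vs-necessity
#' question: if flies share one walk probability the binomial should win;
#' stable between-fly heterogeneity (e.g. a near-uniform preference
#' distribution, which the binomial cannot produce) favours the
#' beta-binomial.
#'
#' @param counts A [cpp_counts()] object, a `cpp_session`, or a bare
#'   numeric vector of tube counts (tube 0 first).
#' @param model `"binomial"` or `"betabinomial"`.
#' @return An object of class `tube_fit` with components `model`,
#'   `coefficients`, `logLik`, `aic`, `fitted` (expected tube proportions),
#'   `observed`, `n`, `n_choices`, `convergence`, `boundary`.
#' @seealso [predict.tube_fit()] for posterior-predictive retest curves.
#' @examples
#' counts <- c(13, 13, 14, 13, 14, 13)          # near-uniform occupancy
#' fb <- fit_tube_model(counts, "binomial")
#' fbb <- fit_tube_model(counts, "betabinomial")
#' AIC(fb, fbb)                                  # beta-binomial wins
#' @export
fit_tube_model <- function(counts, model = c("binomial", "betabinomial")) {
  model <- match.arg(model)
  if (inherits(counts, "cpp_session")) counts <- as_cpp_counts(counts)
  if (inherits(counts, "cpp_counts")) counts <- counts$counts
  counts <- as.numeric(counts)
  if (any(counts < 0) || sum(counts) <= 0)
    stop("'counts' must be non-negative with a positive total")
  n_choices <- length(counts) - 1L
  k <- 0:n_choices
  n <- sum(counts)
  boundary <- sum(counts > 0) == 1L
  loglik_const <- lgamma(n + 1) - sum(lgamma(counts + 1))

  if (model == "binomial") {
    p_hat <- sum(counts * k) / (n * n_choices)
    probs <- stats::dbinom(k, n_choices, p_hat)
    ll <- loglik_const + sum(counts[counts > 0] * log(probs[counts > 0]))
    coefs <- c(p = p_hat)
    convergence <- TRUE
  } else {
    nll <- function(theta) {
      # cap the log-shapes: beyond ~exp(30) the likelihood is flat at the
      # binomial limit and lbeta differences lose all precision
      if (any(abs(theta) > 30)) return(.Machine$double.xmax / 2)
      lp <- dbetabinom(k, n_choices, exp(theta[1]), exp(theta[2]), log = TRUE)
      val <- -sum(counts * lp)
      if (!is.finite(val)) return(.Machine$double.xmax / 2)
      val
    }
    opt <- stats::optim(c(0, 0), nll, method = "Nelder-Mead",
                        control = list(reltol = 1e-8, maxit = 2000))
    coefs <- c(alpha = exp(opt$par[1]), beta = exp(opt$par[2]))
    probs <- dbetabinom(k, n_choices, coefs[["alpha"]], coefs[["beta"]])
    ll <- loglik_const - opt$value
    convergence <- opt$convergence == 0
    # degenerate data push the shapes to the edge of the parameter space
    if (any(coefs > 1e6) || any(coefs < 1e-6)) boundary <- TRUE
  }
  structure(
    list(model = model, coefficients = coefs,
         logLik = ll, aic = 2 * length(coefs) - 2 * ll,
         fitted = probs, observed = counts, n = n,
         n_choices = n_choices, convergence = convergence,
         boundary = boundary),
    class = "tube_fit"
  )
}

#' @export
print.tube_fit <- function(x, ...) {
  cat(sprintf("Fractionation model fit: %s (%g flies, %d choices)\n",
              x$model, x$n, x$n_choices))
  cat("  ", paste(names(x$coefficients), signif(x$coefficients, 4),
                  sep = " = ", collapse = ", "), "\n", sep = "")
  cat(sprintf("  logLik = %.3f, AIC = %.3f\n", x$logLik, x$aic))
  if (x$boundary) cat("  (boundary fit: data degenerate or shapes extreme)\n")
  if (!x$convergence) cat("  (optimizer did not converge)\n")
  invisible(x)
}

#' @export
summary.tube_fit <- function(object, ...) {
  print(object)
  cat("\nObserved vs fitted tube occupancy:\n")
  tab <- rbind(observed = object$observed,
               fitted = object$fitted * object$n)
  colnames(tab) <- paste0("tube_", 0:object$n_choices)
  print(round(tab, 2))
  cat("\nPearson residuals:\n")
  print(round(residuals(object), 3))
  invisible(object)
}

#' @export
coef.tube_fit <- function(object, ...) object$coefficients

#' @export
logLik.tube_fit <- function(object, ...) {
  structure(object$logLik, df = length(object$coefficients),
            nobs = object$n, class = "logLik")
}

#' @export
residuals.tube_fit <- function(object, ...) {
  expected <- object$fitted * object$n
  r <- (object$observed - expected) / sqrt(pmax(expected, .Machine$double.eps))
  names(r) <- paste0("tube_", 0:object$n_choices)
  r
}

#' Posterior-predictive retest curve for a fitted fractionation model
#'
#' Given a fly's first-session tube `k`, predicts its second-session tube
#' distribution and expected Performance Index. Under the beta-binomial
#' model the posterior over the fly's walk probability after observing `k`
#' walks in `n_choices` trials is Beta(`alpha + k`, `beta + n_choices - k`),
#' so the predicted mean PI, `n_choices * (alpha + k) / (alpha + beta +
#' n_choices)`, increases strictly with `k` — the fractionation signature.
#' Under the binomial model the prediction is the same for every `k`.
#'
#' @param object A [fit_tube_model()] fit.
#' @param first_tube First-session tube indices (default all of
#'   `0..n_choices`).
#' @param ... Unused.
#' @return A data frame with one row per `first_tube`: the predicted mean
#'   second-session PI (`mean_pi`) and the predictive tube probabilities
#'   (`tube_0 ...`).
#' @examples
#' fit <- fit_tube_model(c(10, 10, 10, 10, 10, 10), "betabinomial")
#' predict(fit)   # mean PI rises with first-session tube
#' @export
predict.tube_fit <- function(object, first_tube = 0:object$n_choices, ...) {
  nc <- object$n_choices
  if (any(first_tube < 0 | first_tube > nc | first_tube != round(first_tube)))
    stop("'first_tube' must be integers in 0..n_choices")
  k2 <- 0:nc
  rows <- lapply(first_tube, function(k) {
    if (object$model == "binomial") {
      p <- object$coefficients[["p"]]
      probs <- stats::dbinom(k2, nc, p)
      mean_pi <- nc * p
    } else {
      a <- object$coefficients[["alpha"]] + k
      b <- object$coefficients[["beta"]] + nc - k
      probs <- dbetabinom(k2, nc, a, b)
      mean_pi <- nc * a / (a + b)
    }
    c(first_tube = k, mean_pi = mean_pi, stats::setNames(probs,
      paste0("tube_", k2)))
  })
  as.data.frame(do.call(rbind, rows))
}

#' Simulate tube counts from a fitted fractionation model
#'
#' @param object A [fit_tube_model()] fit.
#' @param nsim Number of simulated sessions.
#' @param seed Optional integer seed.
#' @param n_flies Flies per simulated session (default: the fitted total).
#' @param ... Unused.
#' @return A matrix with `nsim` rows of tube counts.
#' @export
simulate.tube_fit <- function(object, nsim = 1, seed = NULL,
                              n_flies = object$n, ...) {
  if (!is.null(seed)) set.seed(seed)
  out <- t(stats::rmultinom(nsim, n_flies, object$fitted))
  colnames(out) <- paste0("tube_", 0:object$n_choices)
  out
}

#' @export
plot.tube_fit <- function(x, ...) {
  tab <- rbind(observed = x$observed / x$n, fitted = x$fitted)
  graphics::barplot(tab, beside = TRUE, legend.text = TRUE,
                    names.arg = paste0("tube ", 0:x$n_choices),
                    ylab = "proportion of flies",
                    main = sprintf("Tube occupancy: %s fit", x$model), ...)
  invisible(x)
}

#' Likelihood-ratio comparison of binomial and beta-binomial fits
#'
#' AIC is the primary comparison ([fit_tube_model()] reports it); this
#' helper additionally gives the likelihood-ratio statistic against the
#' 1-df chi-square reference. The binomial sits on the boundary of the
#' beta-binomial parameter space, so the reference distribution is
#' approximate there (anti-conservative); the p-value is flagged as such.
#'
#' @param fit_binomial,fit_betabinomial Fits from [fit_tube_model()] on the
#'   same counts.
#' @return A list with `lr` (statistic), `df`, `p_value` (approximate),
#'   `delta_aic` (binomial AIC minus beta-binomial AIC; positive favours
#'   the beta-binomial) and `preferred` by AIC.
#' @export
compare_tube_models <- function(fit_binomial, fit_betabinomial) {
  stopifnot(inherits(fit_binomial, "tube_fit"),
            inherits(fit_betabinomial, "tube_fit"),
            fit_binomial$model == "binomial",
            fit_betabinomial$model == "betabinomial")
  lr <- max(0, 2 * (fit_betabinomial$logLik - fit_binomial$logLik))
  list(lr = lr, df = 1L,
       p_value = stats::pchisq(lr, df = 1, lower.tail = FALSE),
       p_value_note = "approximate: binomial lies on the boundary",
       delta_aic = fit_binomial$aic - fit_betabinomial$aic,
       preferred = if (fit_binomial$aic <= fit_betabinomial$aic)
         "binomial" else "betabinomial")
}
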