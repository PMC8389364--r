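# Nonparametric statistics layer. The omnibus and post-hoc rank tests are
# implemented from the rank formulas (tie-corrected); Levene and
# Shapiro-Wilk delegate to car and stats. The significance threshold
# defaults to 0.005 throughout.

#' Kruskal-Wallis rank-sum test
#'
#' Tie-corrected H statistic on mid-ranks with a chi-square reference on
#' `k - 1` degrees of freedom. Being rank-based, the statistic is invariant
#' under any strictly monotone transform of the data.
#'
#' @param values Numeric vector of observations (`NA`s dropped and
#'   counted).
#' @param groups Group labels, same length as `values` (>= 2 groups, each
#'   with at least one value).
#' @param threshold Significance threshold (default 0.005).
#' @return A `test_report` list: `test`, `statistic`, `df`, `p_value`,
#'   `significant`, `n`, `n_missing`.
#' @examples
#' kruskal_wallis(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
#' @export
kruskal_wallis <- function(values, groups, threshold = 0.005) {
  d <- drop_missing(values, groups)
  g <- factor(d$groups)
  if (nlevels(g) < 2) stop("need at least 2 groups")
  if (any(table(g) < 1)) stop("every group needs at least one value")
  n <- length(d$values)
  r <- rank(d$values)
  rbar <- tapply(r, g, mean)
  ni <- tabulate(g)
  h <- 12 / (n * (n + 1)) * sum(ni * (rbar - (n + 1) / 2)^2)
  ties <- table(d$values)
  tie_corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  if (tie_corr > 0) h <- h / tie_corr
  df <- nlevels(g) - 1L
  p <- stats::pchisq(h, df, lower.tail = FALSE)
  test_report("Kruskal-Wallis", statistic = h, df = df, p_value = p,
              threshold = threshold, n = n, n_missing = d$n_missing)
}

#' Dunn's post-hoc test on joint ranks
#'
#' Pairwise z statistics from the pooled mid-ranks with tie correction, the
#' standard companion to a significant Kruskal-Wallis omnibus test.
#' Unadjusted and Bonferroni-adjusted p-values are both reported.
#'
#' @inheritParams kruskal_wallis
#' @return A data frame with one row per group pair: `group1`, `group2`,
#'   `z`, `p_value`, `p_bonferroni`, `significant` (on the adjusted
#'   p-value).
#' @export
dunn_posthoc <- function(values, groups, threshold = 0.005) {
  d <- drop_missing(values, groups)
  g <- factor(d$groups)
  if (nlevels(g) < 2) stop("need at least 2 groups")
  n <- length(d$values)
  r <- rank(d$values)
  rbar <- tapply(r, g, mean)
  ni <- tabulate(g)
  ties <- table(d$values)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  sig2 <- n * (n + 1) / 12 - tie_term
  lev <- levels(g)
  pairs <- utils::combn(seq_along(lev), 2)
  out <- apply(pairs, 2, function(ij) {
    i <- ij[1]; j <- ij[2]
    se <- sqrt(sig2 * (1 / ni[i] + 1 / ni[j]))
    z <- (rbar[i] - rbar[j]) / se
    p <- 2 * stats::pnorm(abs(z), lower.tail = FALSE)
    data.frame(group1 = lev[i], group2 = lev[j], z = as.numeric(z),
               p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out$p_bonferroni <- pmin(1, out$p_value * nrow(out))
  out$significant <- out$p_bonferroni < threshold
  out
}

#' Levene / Brown-Forsythe test for homogeneity of variance
#'
#' Delegates to [car::leveneTest()]; centering defaults to the median (the
#' robust Brown-Forsythe variant), with the classical mean centering
#' available.
#'
#' @inheritParams kruskal_wallis
#' @param center `"median"` (default) or `"mean"`.
#' @return A `test_report` with the F statistic and both degrees of
#'   freedom.
#' @export
levene_test <- function(values, groups, center = c("median", "mean"),
                        threshold = 0.005) {
  center <- match.arg(center)
  d <- drop_missing(values, groups)
  g <- factor(d$groups)
  if (nlevels(g) < 2) stop("need at least 2 groups")
  tab <- car::leveneTest(d$values, g,
                         center = if (center == "median") stats::median
                                  else mean)
  test_report("Levene", statistic = tab[1, "F value"],
              df = c(tab[1, "Df"], tab[2, "Df"]),
              p_value = tab[1, "Pr(>F)"], threshold = threshold,
              n = length(d$values), n_missing = d$n_missing)
}

#' Shapiro-Wilk normality test
#'
#' Thin wrapper around [stats::shapiro.test()] returning the package's
#' uniform `test_report` structure.
#'
#' @param values Numeric vector (3 to 5000 non-missing values).
#' @param threshold Significance threshold (default 0.005).
#' @return A `test_report`.
#' @export
shapiro_test <- function(values, threshold = 0.005) {
  values <- values[!is.na(values)]
  res <- stats::shapiro.test(values)
  test_report("Shapiro-Wilk", statistic = unname(res$statistic), df = NA,
              p_value = res$p.value, threshold = threshold,
              n = length(values), n_missing = 0L)
}

test_report <- function(test, statistic, df, p_value, threshold, n,
                        n_missing = 0L) {
  structure(
    list(test = test, statistic = unname(statistic), df = unname(df),
         p_value = unname(p_value), threshold = threshold,
         significant = p_value < threshold, n = n, n_missing = n_missing),
    class = "test_report"
  )
}

#' @export
print.test_report <- function(x, ...) {
  dfs <- if (all(is.na(x$df))) "" else
    sprintf(" (df = %s)", paste(x$df, collapse = ", "))
  cat(sprintf("%s: statistic = %.4g%s, p = %.4g [%s at %.3g]\n",
              x$test, x$statistic, dfs, x$p_value,
              if (x$significant) "significant" else "not significant",
              x$threshold))
  if (x$n_missing > 0)
    cat(sprintf("  (%d missing values excluded, n = %d)\n",
                x$n_missing, x$n))
  invisible(x)
}

drop_missing <- function(values, groups) {
  if (length(values) != length(groups))
    stop("'values' and 'groups' must have the same length")
  ok <- !is.na(values) & !is.na(groups)
  list(values = values[ok], groups = groups[ok], n_missing = sum(!ok))
}

#' Principal component analysis on the correlation matrix
#'
#' Standardises every variable to zero mean and unit variance, performs an
#' eigendecomposition of the correlation matrix, and retains the components
#' with eigenvalue at least 1 (the Kaiser rule). Loadings are reported in
#' the correlation convention, eigenvector times the square root of the
#' eigenvalue, so a loading is the correlation of the variable with the
#' component; the raw eigenvectors are also returned. The sign of each
#' component is fixed by making its largest-magnitude loading positive.
#'
#' @param x A numeric matrix or data frame (samples in rows, variables in
#'   columns). Constant columns are rejected by name.
#' @param min_eigenvalue Retention threshold (default 1).
#' @return An object of class `pca_cor`: `eigenvalues`, `retained`,
#'   `loadings` (variables x retained components), `eigenvectors`, `scores`
#'   (standardised samples projected on retained components),
#'   `proportion_variance`.
#' @examples
#' x <- matrix(rnorm(200), 50, 4)
#' pca_correlation(x)
#' @export
pca_correlation <- function(x, min_eigenvalue = 1) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("'x' must be numeric")
  if (ncol(x) < 2) stop("need at least 2 variables")
  ok <- stats::complete.cases(x)
  x <- x[ok, , drop = FALSE]
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    stop("constant variable(s): ",
         paste(colnames(x)[sds == 0], collapse = ", "))
  z <- scale(x)
  r <- stats::cor(x)
  e <- eigen(r, symmetric = TRUE)
  ev <- e$values
  vec <- e$vectors
  rownames(vec) <- colnames(x)
  # deterministic sign: largest-magnitude loading positive per component
  for (j in seq_len(ncol(vec))) {
    lead <- which.max(abs(vec[, j]))
    if (vec[lead, j] < 0) vec[, j] <- -vec[, j]
  }
  retained <- which(ev >= min_eigenvalue)
  loadings <- sweep(vec[, retained, drop = FALSE], 2,
                    sqrt(ev[retained]), `*`)
  colnames(loadings) <- paste0("PC", retained)
  scores <- z %*% vec[, retained, drop = FALSE]
  colnames(scores) <- paste0("PC", retained)
  structure(
    list(eigenvalues = ev, retained = length(retained),
         loadings = loadings,
         eigenvectors = vec,
         scores = scores,
         proportion_variance = ev / length(ev),
         n = nrow(x)),
    class = "pca_cor"
  )
}

#' @export
print.pca_cor <- function(x, digits = 3, ...) {
  cat(sprintf("Correlation-matrix PCA: %d variables, %d samples, %d component(s) retained (eigenvalue >= 1)\n",
              length(x$eigenvalues), x$n, x$retained))
  cat("Eigenvalues:", paste(round(x$eigenvalues, digits), collapse = ", "),
      "\n")
  cat("Proportion of variance:",
      paste(round(x$proportion_variance, digits), collapse = ", "), "\n\n")
  cat("Loadings (correlation convention):\n")
  print(round(x$loadings, digits))
  invisible(x)
}

#' @export
plot.pca_cor <- function(x, components = c(1, 2), ...) {
  if (x$retained < 2) stop("need at least 2 retained components to biplot")
  sc <- x$scores[, components]
  ld <- x$loadings[, components]
  graphics::plot(sc, xlab = colnames(sc)[1], ylab = colnames(sc)[2],
                 pch = 19, col = grDevices::adjustcolor("grey40", 0.6), ...)
  scale_f <- max(abs(sc)) * 0.9
  graphics::arrows(0, 0, ld[, 1] * scale_f, ld[, 2] * scale_f,
                   length = 0.08, col = "red3")
  graphics::text(ld[, 1] * scale_f * 1.08, ld[, 2] * scale_f * 1.08,
                 rownames(ld), col = "red3", cex = 0.8)
  invisible(x)
}
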