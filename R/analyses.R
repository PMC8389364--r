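#' Run the full synthetic analysis battery
#'
#' Reproduces, on synthetic populations, the structure of the standard
#' photopreference analysis battery:
#'
#' 1. **Group size** — T-maze Choice Index for groups of 20..100 flies,
#'    compared by Kruskal-Wallis, with Levene's test on CI variability.
#' 2. **Repeated days** — the same groups re-tested on four consecutive
#'    days (traits fixed), compared by Kruskal-Wallis.
#' 3. **T-maze retest** — bright and dark+elevator subgroups pooled and
#'    re-tested; second-session CIs compared across subgroups.
#' 4. **Countercurrent retest** — six tube subgroups pooled to 40-fly
#'    second-session groups; second-session PI versus first-session tube,
#'    with the Kruskal-Wallis omnibus test and Dunn post-hoc.
#' 5. **Model comparison** — binomial and beta-binomial fits to the pooled
#'    first-session tube counts, compared by AIC, plus the fitted
#'    posterior-predictive retest curve.
#' 6. **Buridan metrics** — individual flies sampled per tube walk in the
#'    simulated arena; all eight metrics compared across tubes.
#' 7. **PCA** — correlation-matrix PCA of the number of light choices plus
#'    the eight metrics, eigenvalue-1 retention.
#'
#' @param model A [population_model()] (default: the individuality model
#'   with the canonical 70/30 mean preference and activity correlation
#'   0.6).
#' @param seed Integer seed governing the whole battery.
#' @param group_sizes Group sizes for stage 1.
#' @param replicates_per_size Sessions per group size (default 15).
#' @param n_days Consecutive test days for stage 2 (default 4).
#' @param tmaze_replicates,cpp_replicates First sessions for the retest
#'   protocols (defaults 8 and 24).
#' @param flies_per_tube Flies sampled per tube for Buridan testing
#'   (default 13).
#' @param buridan_duration Arena experiment duration in seconds (default
#'   900).
#' @param threshold Significance threshold (default 0.005).
#' @param out_dir Optional directory: tables are written as CSV, fit
#'   reports and the resolved configuration (including the seed) as JSON,
#'   making the run self-describing and exactly re-runnable.
#' @return A list of class `flychoice_report` with the per-stage tables,
#'   test reports, model fits and the PCA.
#' @examples
#' \donttest{
#' rep <- reproduce_analyses(seed = 1, buridan_duration = 120,
#'                           flies_per_tube = 5)
#' rep$model_comparison$preferred
#' }
#' @export
reproduce_analyses <- function(model = population_model("individuality"),
                               seed = 1,
                               group_sizes = c(20, 40, 60, 80, 100),
                               replicates_per_size = 15,
                               n_days = 4,
                               tmaze_replicates = 8,
                               cpp_replicates = 24,
                               flies_per_tube = 13,
                               buridan_duration = 900,
                               threshold = 0.005,
                               out_dir = NULL) {
  stopifnot(inherits(model, "population_model"))
  set.seed(seed)

  ## 1. group size: CI distributions and their variability
  size_rows <- do.call(rbind, lapply(group_sizes, function(n) {
    ci <- replicate(replicates_per_size, {
      choice_index(simulate_tmaze(sample_flies(model, n)))
    })
    data.frame(group_size = n, replicate = seq_along(ci), ci = ci)
  }))
  group_size <- list(
    table = size_rows,
    kruskal = kruskal_wallis(size_rows$ci, size_rows$group_size, threshold),
    levene = levene_test(size_rows$ci, size_rows$group_size,
                         threshold = threshold),
    variances = stats::aggregate(ci ~ group_size, size_rows, stats::var)
  )

  ## 2. repeated days: same trait groups tested n_days times
  day_rows <- do.call(rbind, lapply(seq_len(replicates_per_size),
    function(r) {
      flies <- sample_flies(model, 80)
      data.frame(group = r, day = seq_len(n_days),
                 ci = vapply(seq_len(n_days), function(d)
                   choice_index(simulate_tmaze(flies)), numeric(1)))
    }))
  repeated_days <- list(
    table = day_rows,
    kruskal = kruskal_wallis(day_rows$ci, day_rows$day, threshold)
  )

  ## 3. T-maze subgroup retest
  tm <- simulate_retest(model, "tmaze", replicates = tmaze_replicates)
  tm_first <- vapply(tm$first_sessions, choice_index, numeric(1))
  tm_tab <- rbind(
    data.frame(source = "original", index = tm_first),
    tm$retest[c("source", "index")]
  )
  tmaze_retest <- list(
    table = tm_tab,
    kruskal = kruskal_wallis(tm_tab$index, tm_tab$source, threshold)
  )

  ## 4. countercurrent subgroup retest
  cp <- simulate_retest(model, "cpp", replicates = cpp_replicates)
  cpp_kw <- kruskal_wallis(cp$retest$index, cp$retest$tube, threshold)
  cpp_retest <- list(
    table = cp$retest,
    mean_pi_by_tube = stats::aggregate(index ~ tube, cp$retest, mean),
    kruskal = cpp_kw,
    dunn = dunn_posthoc(cp$retest$index, cp$retest$tube, threshold)
  )

  ## 5. model comparison on the pooled first-session tube counts
  tube_counts <- Reduce(`+`, lapply(cp$first_sessions,
                                    function(s) as_cpp_counts(s)$counts))
  fit_bin <- fit_tube_model(tube_counts, "binomial")
  fit_bb <- fit_tube_model(tube_counts, "betabinomial")
  model_comparison <- c(
    compare_tube_models(fit_bin, fit_bb),
    list(fit_binomial = fit_bin, fit_betabinomial = fit_bb,
         predicted_retest = predict(
           if (fit_bin$aic <= fit_bb$aic) fit_bin else fit_bb))
  )

  ## 6. Buridan metrics for individual flies per tube
  pool <- sample_flies(model, flies_per_tube * 40)
  first <- simulate_cpp(pool)
  bp <- buridan_params(duration = buridan_duration)
  met_rows <- list()
  for (k in 0:first$n_choices) {
    sub <- first$outcomes[first$outcomes$tube == k, , drop = FALSE]
    sub <- utils::head(sub, flies_per_tube)
    for (i in seq_len(nrow(sub))) {
      trk <- simulate_buridan(sub[i, ], params = bp)
      m <- buridan_metrics(trk)
      m$tube <- k
      met_rows[[length(met_rows) + 1L]] <- m
    }
  }
  metrics <- do.call(rbind, met_rows)
  metric_cols <- setdiff(names(metrics), c("fly_id", "tube"))
  buridan <- list(
    table = metrics,
    kruskal = lapply(stats::setNames(metric_cols, metric_cols), function(mc) {
      ok <- !is.na(metrics[[mc]])
      if (length(unique(metrics$tube[ok])) < 2) return(NULL)
      kruskal_wallis(metrics[[mc]][ok], metrics$tube[ok], threshold)
    })
  )

  ## 7. PCA: light choices + the eight metrics
  pca_mat <- cbind(light_choices = metrics$tube,
                   metrics[metric_cols])
  # keep variables observed in most flies (pause metrics can be missing),
  # then complete cases over what remains
  keep <- vapply(pca_mat, function(v) mean(!is.na(v)) >= 0.8, logical(1))
  pca_mat <- pca_mat[keep]
  pca_mat <- pca_mat[stats::complete.cases(pca_mat), , drop = FALSE]
  nondeg <- vapply(pca_mat, function(v) stats::sd(v) > 0, logical(1))
  pca <- if (nrow(pca_mat) >= 3 && sum(nondeg) >= 2)
    pca_correlation(pca_mat[nondeg]) else NULL

  report <- structure(
    list(model = model, seed = seed, threshold = threshold,
         group_size = group_size, repeated_days = repeated_days,
         tmaze_retest = tmaze_retest, cpp_retest = cpp_retest,
         model_comparison = model_comparison, buridan = buridan,
         pca = pca),
    class = "flychoice_report"
  )
  if (!is.null(out_dir)) write_report(report, out_dir,
    config = list(model = unclass(model), seed = seed,
                  group_sizes = group_sizes,
                  replicates_per_size = replicates_per_size,
                  n_days = n_days, tmaze_replicates = tmaze_replicates,
                  cpp_replicates = cpp_replicates,
                  flies_per_tube = flies_per_tube,
                  buridan_duration = buridan_duration,
                  threshold = threshold))
  report
}

write_report <- function(report, out_dir, config) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(config, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  w <- function(df, name) utils::write.csv(df,
    file.path(out_dir, paste0(name, ".csv")), row.names = FALSE)
  w(report$group_size$table, "group_size_ci")
  w(report$repeated_days$table, "repeated_days_ci")
  w(report$tmaze_retest$table, "tmaze_retest")
  w(report$cpp_retest$table, "cpp_retest")
  w(report$buridan$table, "buridan_metrics")
  w(report$model_comparison$predicted_retest, "predicted_retest")
  fits <- lapply(report$model_comparison[c("fit_binomial",
                                           "fit_betabinomial")],
                 function(f) list(model = f$model,
                                  parameters = as.list(f$coefficients),
                                  loglik = f$logLik, aic = f$aic,
                                  convergence = f$convergence,
                                  boundary = f$boundary))
  fits$delta_aic <- report$model_comparison$delta_aic
  fits$preferred <- report$model_comparison$preferred
  jsonlite::write_json(fits, file.path(out_dir, "tube_model_fits.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.flychoice_report <- function(x, ...) {
  cat("Synthetic photopreference analysis battery\n")
  cat(sprintf("  population model: %s; seed %d; threshold p < %g\n\n",
              x$model$kind, x$seed, x$threshold))
  cat("Group size (CI):        "); print(x$group_size$kruskal)
  cat("CI variability (Levene):"); print(x$group_size$levene)
  cat("Repeated days (CI):     "); print(x$repeated_days$kruskal)
  cat("T-maze retest:          "); print(x$tmaze_retest$kruskal)
  cat("Countercurrent retest:  "); print(x$cpp_retest$kruskal)
  cat("\nMean second-session PI by first-session tube:\n")
  print(x$cpp_retest$mean_pi_by_tube, row.names = FALSE)
  cat(sprintf("\nTube model comparison: %s preferred (delta AIC = %.2f)\n",
              x$model_comparison$preferred, x$model_comparison$delta_aic))
  sig <- vapply(x$buridan$kruskal,
                function(k) !is.null(k) && k$significant, logical(1))
  cat(sprintf("\nBuridan metrics across tubes: %d of %d significant (%s)\n",
              sum(sig), length(sig),
              paste(names(sig)[sig], collapse = ", ")))
  if (!is.null(x$pca))
    cat(sprintf("\nPCA: %d component(s) retained; light-choice loading on PC1 = %.2f\n",
                x$pca$retained, x$pca$loadings["light_choices", 1]))
  invisible(x)
}
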