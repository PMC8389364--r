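test_that("tube assignment counts walks and ignores order", {
  expect_identical(tube_assignment(c(1, 1, 1, 1, 1)), 5L)
  expect_identical(tube_assignment(c(0, 0, 0, 0, 0)), 0L)
  expect_identical(tube_assignment(c(1, 0, 1, 0, 1)), 3L)
  # exhaustive: all 32 sequences, six distinct outputs, order-invariant
  seqs <- as.matrix(expand.grid(rep(list(0:1), 5)))
  tubes <- tube_assignment(seqs)
  expect_setequal(unique(tubes), 0:5)
  expect_identical(tubes, as.integer(rowSums(seqs)))
  for (i in sample(nrow(seqs), 10))
    expect_identical(tube_assignment(sample(seqs[i, ])), tubes[i])
  expect_error(tube_assignment(c(1, 2, 0)), "binary")
})

test_that("binomial tube distribution matches the mass function", {
  expect_equal(tube_dist_binomial(0.5)$probs,
               choose(5, 0:5) / 32, ignore_attr = TRUE)
  expect_equal(unname(tube_dist_binomial(1)$probs[6]), 1)
  expect_equal(unname(tube_dist_binomial(0)$probs[1]), 1)
  expect_error(tube_dist_binomial(1.2), "\\[0, 1\\]")
})

test_that("beta-binomial distribution: uniform prior, normalization, binomial limit", {
  expect_equal(tube_dist_betabinomial(1, 1)$probs, rep(1 / 6, 6),
               ignore_attr = TRUE)
  # numeric integration of Binomial(5, p) over the mixing beta
  for (sh in list(c(1, 1), c(2, 5), c(0.5, 0.5))) {
    bb <- tube_dist_betabinomial(sh[1], sh[2])$probs
    by_quad <- vapply(0:5, function(k)
      integrate(function(p) dbinom(k, 5, p) * dbeta(p, sh[1], sh[2]),
                0, 1, rel.tol = 1e-10)$value, numeric(1))
    expect_equal(bb, by_quad, tolerance = 1e-6, ignore_attr = TRUE)
    expect_equal(sum(bb), 1, tolerance = 1e-12)
  }
  tv <- total_variation(tube_dist_betabinomial(1000, 1000)$probs,
                        tube_dist_binomial(0.5)$probs)
  expect_lt(tv, 1e-3)
  expect_error(tube_dist_betabinomial(0, 1), "positive")
})

test_that("binomial MLE recovers p from noiseless expected counts", {
  counts <- dbinom(0:5, 5, 0.7) * 3200
  fit <- fit_tube_model(counts, "binomial")
  expect_equal(unname(coef(fit)), 0.7, tolerance = 0.01)
  expect_true(fit$convergence)
})

test_that("uniform counts are fit by beta-binomial(1,1), beating the binomial", {
  counts <- rep(50, 6)
  bb <- fit_tube_model(counts, "betabinomial")
  expect_equal(unname(coef(bb)), c(1, 1), tolerance = 0.05)
  bin <- fit_tube_model(counts, "binomial")
  expect_lt(bb$aic, bin$aic)
  cmp <- compare_tube_models(bin, bb)
  expect_identical(cmp$preferred, "betabinomial")
  expect_gt(cmp$delta_aic, 0)
})

test_that("AIC formula and logLik bookkeeping are consistent", {
  counts <- c(5, 10, 20, 25, 15, 5)
  for (m in c("binomial", "betabinomial")) {
    fit <- fit_tube_model(counts, m)
    k <- length(coef(fit))
    expect_equal(fit$aic, 2 * k - 2 * fit$logLik)
    expect_equal(AIC(fit), fit$aic)
    expect_equal(attr(logLik(fit), "df"), k)
  }
})

test_that("model recovery: binomial wins AIC on shared-p data", {
  set.seed(301)
  wins <- 0L
  for (r in 1:200) {
    counts <- as.vector(rmultinom(1, 480, dbinom(0:5, 5, 0.7)))
    cmp <- compare_tube_models(fit_tube_model(counts, "binomial"),
                               fit_tube_model(counts, "betabinomial"))
    wins <- wins + (cmp$preferred == "binomial")
  }
  expect_gte(wins / 200, 0.9)
})

test_that("degenerate single-tube data give a flagged boundary fit, not an error", {
  fit <- fit_tube_model(c(0, 0, 0, 0, 0, 80), "betabinomial")
  expect_true(fit$boundary)
  fitb <- fit_tube_model(c(80, 0, 0, 0, 0, 0), "binomial")
  expect_true(fitb$boundary)
  expect_equal(unname(coef(fitb)), 0)
})

test_that("posterior-predictive retest means follow the closed form", {
  fit <- fit_tube_model(rep(10, 6), "betabinomial")  # alpha = beta = 1
  pr <- predict(fit)
  expect_equal(pr$mean_pi, 5 * (1 + 0:5) / 7, tolerance = 0.02)
  expect_equal(pr$mean_pi[6], 30 / 7, tolerance = 0.02)
  expect_equal(pr$mean_pi[1], 5 / 7, tolerance = 0.02)
  # strictly increasing in first-session tube for finite shapes
  expect_true(all(diff(pr$mean_pi) > 0))
  # predictive rows are distributions
  probs <- as.matrix(pr[paste0("tube_", 0:5)])
  expect_equal(rowSums(probs), rep(1, 6), tolerance = 1e-9)
  expect_error(predict(fit, first_tube = 6), "0..n_choices")
})

test_that("binomial retest prediction is flat in the first-session tube", {
  fit <- fit_tube_model(dbinom(0:5, 5, 0.6) * 800, "binomial")
  pr <- predict(fit)
  expect_equal(diff(pr$mean_pi), rep(0, 5))
  expect_equal(pr$mean_pi[1], 3, tolerance = 1e-6)
})

test_that("simulated CPP occupancies match the closed-form distributions", {
  # shared p: binomial
  flies <- sample_flies(population_model("spontaneity", p_mean = 0.7),
                        10000, seed = 12)
  emp <- as_cpp_counts(simulate_cpp(flies, seed = 13))$counts / 10000
  expect_lt(total_variation(emp, tube_dist_binomial(0.7)$probs), 0.02)
  # heterogeneous p: beta-binomial
  flies2 <- sample_flies(population_model("individuality", alpha = 2,
                                          beta = 2), 10000, seed = 14)
  emp2 <- as_cpp_counts(simulate_cpp(flies2, seed = 15))$counts / 10000
  expect_lt(total_variation(emp2, tube_dist_betabinomial(2, 2)$probs), 0.02)
})

test_that("two sessions with fixed traits compose to a 10-choice beta-binomial", {
  flies <- sample_flies(population_model("individuality", alpha = 2,
                                         beta = 2), 5000, seed = 16)
  s1 <- simulate_cpp(flies, seed = 17)
  s2 <- simulate_cpp(flies, seed = 18)
  total <- s1$outcomes$tube + s2$outcomes$tube
  emp <- tabulate(total + 1L, nbins = 11L) / 5000
  expect_lt(total_variation(emp, dbetabinom(0:10, 10, 2, 2)), 0.03)
})

test_that("parameter recovery holds for most seeded replicates", {
  set.seed(302)
  hits <- 0L
  for (r in 1:40) {
    counts <- as.vector(rmultinom(1, 2000, dbetabinom(0:5, 5, 2, 2)))
    est <- coef(fit_tube_model(counts, "betabinomial"))
    if (all(abs(est - 2) / 2 <= 0.25)) hits <- hits + 1L
  }
  expect_gte(hits / 40, 0.8)
})
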