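test_that("multiplicative prediction and k-term error propagation", {
  subs <- c("A1G", "C2D", "E3F")
  genos <- c("WT", enumerate_intermediates(subs), "A1G+C2D+E3F")
  ls <- fitness_landscape(subs, data.frame(
    genotype = genos,
    mean_fold = c(1, 2, 3, 1, 6, 2, 3, 6),
    sd = c(0, 0.2, 0.3, 0.1, 0.5, 0.2, 0.3, 0.6), n = 4))
  # k = 1 reduces to the single measurement
  p1 <- predict_multiplicative(ls, "A1G")
  expect_equal(p1$predicted, 2)
  expect_equal(p1$delta_predicted, 0.2)
  # X = 2 +/- 0.2, Y = 3 +/- 0.3, Z = 1 +/- 0.1: R = 6, dR = 6 sqrt(0.03)
  p3 <- predict_multiplicative(ls, "A1G+C2D+E3F")
  expect_equal(p3$predicted, 6)
  expect_equal(p3$delta_predicted, 6 * sqrt(0.1^2 + 0.1^2 + 0.1^2))
  # order invariance in the genotype string
  p3b <- predict_multiplicative(ls, "E3F+C2D+A1G")
  expect_equal(p3b$predicted, p3$predicted)
  expect_equal(p3b$delta_predicted, p3$delta_predicted)
  # missing single-substitution measurement is named
  ls_gap <- fitness_landscape(subs, data.frame(
    genotype = c("WT", "A1G", "A1G+C2D"), mean_fold = c(1, 2, 3), sd = 0, n = 2))
  expect_error(predict_multiplicative(ls_gap, "A1G+C2D"), "C2D")
  expect_error(predict_multiplicative(ls, "WT"), "wild type")
})

test_that("propagated error matches Monte-Carlo resampling and scales linearly", {
  X <- c(2, 3, 1.5); dX <- c(0.08, 0.12, 0.05)  # small CVs
  subs <- c("A1G", "C2D", "E3F")
  # canonical order: WT, the three singles, the three pairs, the triple
  genos <- c("WT", enumerate_intermediates(subs), "A1G+C2D+E3F")
  folds <- c(1, X, X[1] * X[2], X[1] * X[3], X[2] * X[3], prod(X))
  sds <- c(0, dX, 0, 0, 0, 0)
  ls <- fitness_landscape(subs, data.frame(genotype = genos, mean_fold = folds,
                                           sd = sds, n = 4))
  p <- predict_multiplicative(ls, "A1G+C2D+E3F")
  set.seed(7)
  draws <- rnorm(1e5, X[1], dX[1]) * rnorm(1e5, X[2], dX[2]) * rnorm(1e5, X[3], dX[3])
  expect_lt(abs(p$delta_predicted - sd(draws)) / sd(draws), 0.05)
  # dR is linear under uniform scaling of all dX
  ls2 <- fitness_landscape(subs, data.frame(genotype = genos, mean_fold = folds,
                                            sd = 2 * sds, n = 4))
  p2 <- predict_multiplicative(ls2, "A1G+C2D+E3F")
  expect_equal(p2$delta_predicted, 2 * p$delta_predicted)
})

test_that("epistasis score is the log observed/predicted ratio", {
  expect_equal(epistasis_score(6, 6), 0)
  expect_equal(epistasis_score(12, 6), log(2))
  expect_error(epistasis_score(-1, 6), "positive")
  # a noise-free multiplicative landscape scores 0 everywhere
  ls <- multiplicative_landscape(c(A1G = 1.5, C2D = 0.8, E3F = 2.2))
  et <- epistasis_table(ls)
  expect_lt(max(abs(et$epsilon)), 1e-12)
  # an injected interaction term is recovered exactly at zero noise
  spec <- landscape_spec(labels = c("A1G", "C2D", "E3F"),
                         effects = c(A1G = log(1.5), C2D = log(1.3), E3F = log(1.1)),
                         interactions = data.frame(members = "A1G+C2D",
                                                   log_term = log(2)),
                         gate = NULL, masking = 1, replicates = 1, cv = 0)
  sim <- simulate_landscape(spec, seed = 1)
  p <- predict_multiplicative(sim$landscape, "A1G+C2D")
  expect_equal(epistasis_score(p), log(2), tolerance = 1e-12)
})

test_that("pairwise epistasis classification", {
  expect_equal(classify_pair(1, 1.5, 1.2, 1.5 * 1.2), "none")
  # within tolerance: still none
  expect_equal(classify_pair(1, 1.5, 1.2, 1.5 * 1.2 * 1.04), "none")
  # magnitude: strong deviation, no direction change
  expect_equal(classify_pair(1, 1.5, 1.2, 3.6), "magnitude")
  # both effects beneficial alone and reversed in the double: reciprocal
  expect_equal(classify_pair(1, 1.5, 1.2, 1.0), "reciprocal_sign")
  # reciprocal sign: both deleterious alone, beneficial jointly
  expect_equal(classify_pair(1, 0.8, 0.8, 2.0), "reciprocal_sign")
  expect_error(classify_pair(2, 1.5, 1.2, 1.8), "f_wt must be 1")
  # every pair of a multiplicative landscape is "none"
  ls <- multiplicative_landscape(c(A1G = 1.5, C2D = 0.7, E3F = 2.0))
  f <- setNames(ls$data$mean_fold, ls$data$genotype)
  pairs <- list(c("A1G", "C2D"), c("A1G", "E3F"), c("C2D", "E3F"))
  for (pr in pairs) {
    ab <- paste(pr, collapse = "+")
    expect_equal(classify_pair(1, f[[pr[1]]], f[[pr[2]]], f[[ab]]), "none")
  }
})

test_that("sign classification matches a hand-derived two-substitution truth table", {
  # rows: f_a, f_b, f_ab, expected label (tolerance 0.05 on the log scale)
  cases <- list(
    list(1.4, 1.4, 1.96, "none"),            # exactly multiplicative
    list(1.4, 1.4, 3.50, "magnitude"),       # synergy, both still beneficial
    list(1.4, 1.4, 0.90, "reciprocal_sign"), # both flip to deleterious
    list(1.4, 0.9, 1.80, "sign"),            # only b flips: deleterious alone, 1.8/1.4 > 1 with a
    list(0.7, 0.7, 1.30, "reciprocal_sign"),
    list(1.6, 1.1, 1.10, "sign")             # b's effect flips: 1.1 alone vs 1.1/1.6 < 1
  )
  for (cs in cases) {
    expect_equal(classify_pair(1, cs[[1]], cs[[2]], cs[[3]]), cs[[4]],
                 info = paste(unlist(cs), collapse = " "))
  }
})

test_that("summary-statistic t-test agrees with stats::t.test on raw data", {
  set.seed(21)
  for (i in 1:10) {
    x <- rnorm(sample(3:8, 1), mean = runif(1, 0, 5), sd = runif(1, 0.2, 2))
    y <- rnorm(sample(3:8, 1), mean = runif(1, 0, 5), sd = runif(1, 0.2, 2))
    ours <- unpaired_t_test(mean(x), sd(x), length(x), mean(y), sd(y), length(y),
                            method = "pooled")
    ref <- t.test(x, y, var.equal = TRUE)
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(ours$p.value, ref$p.value, tolerance = 1e-10)
    oursw <- unpaired_t_test(mean(x), sd(x), length(x), mean(y), sd(y), length(y),
                             method = "welch")
    refw <- t.test(x, y)
    expect_equal(oursw$statistic, unname(refw$statistic), tolerance = 1e-10)
    expect_equal(oursw$df, unname(refw$parameter), tolerance = 1e-10)
    expect_equal(oursw$p.value, refw$p.value, tolerance = 1e-10)
  }
})

test_that("t-test edge cases and extremes", {
  deg <- unpaired_t_test(2, 0, 4, 2, 0, 4)
  expect_equal(deg$statistic, 0)
  expect_equal(deg$p.value, 1)
  far <- unpaired_t_test(10, 1, 4, 0, 1, 4)  # 10 sigma apart
  expect_lt(far$p.value, 0.001)
  expect_equal(far$stars, "***")
  expect_error(unpaired_t_test(1, 0.1, 1, 2, 0.1, 4), "at least 2")
})

test_that("compare_genotypes runs the test on stored summaries", {
  ls <- toy_landscape(c("A1G", "C2D"),
                      c("A1G" = 4, "C2D" = 1.05, "A1G+C2D" = 4.2),
                      sd = 0.3, n = 5)
  res <- compare_genotypes(ls, "A1G", "C2D")
  ref <- unpaired_t_test(4, 0.3, 5, 1.05, 0.3, 5)
  expect_equal(res$statistic, ref$statistic)
  expect_equal(res$p.value, ref$p.value)
})

test_that("significance stars follow the printed thresholds with <= comparisons", {
  expect_equal(significance_stars(0.0005), "***")
  expect_equal(significance_stars(0.001), "***")
  expect_equal(significance_stars(0.0011), "**")
  expect_equal(significance_stars(0.01), "**")
  expect_equal(significance_stars(0.03), "*")
  expect_equal(significance_stars(0.05), "*")
  expect_equal(significance_stars(0.2), "ns")
  expect_error(significance_stars(1.2), "\\[0, 1\\]")
})
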