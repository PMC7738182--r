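#' Multiplicative null prediction for a combination of substitutions
#'
#' Under the multiplicative null, the expected fold-improvement of a genotype
#' carrying substitutions with individual folds \eqn{X_1, ..., X_k} is
#' \eqn{R = \prod_i X_i}, and its error propagates as
#' \eqn{\delta R = R \sqrt{\sum_i (\delta X_i / X_i)^2}}
#' (the k-term generalisation of the usual three-variable product rule; the
#' wild-type error is not entered as an extra term since every fold is
#' already expressed relative to wild type).
#'
#' @param landscape A [fitness_landscape()] containing all single-substitution
#'   genotypes of `genotype`.
#' @param genotype Genotype string (k >= 1 substitutions).
#' @return Object of class `epistasis_prediction`: list with `genotype`,
#'   `predicted` (R), `delta_predicted` (dR), `components` (data frame
#'   `substitution`, `fold`, `sd`), and `observed` (one-row data frame or
#'   `NULL` if the genotype itself is not measured).
#' @export
predict_multiplicative <- function(landscape, genotype) {
  stopifnot(inherits(landscape, "fitness_landscape"))
  subs <- landscape$substitutions
  cg <- canonicalise_genotype(genotype, subs)
  mask <- attr(cg, "mask")
  if (mask == 0L) stopf("the wild type has no substitutions to predict from")
  n <- nrow(subs)
  bits <- bitwShiftL(1L, seq_len(n) - 1L)
  idx <- which(bitwAnd(mask, bits) != 0L)
  comp <- lapply(idx, function(i) {
    j <- match(bits[i], landscape$mask)
    if (is.na(j)) stopf("single-substitution genotype '%s' is not measured", subs$label[i])
    data.frame(substitution = subs$label[i],
               fold = landscape$data$mean_fold[j],
               sd = landscape$data$sd[j], stringsAsFactors = FALSE)
  })
  comp <- do.call(rbind, comp)
  R <- prod(comp$fold)
  dR <- R * sqrt(sum((comp$sd / comp$fold)^2))
  obs <- if (mask %in% landscape$mask) {
    landscape$data[match(mask, landscape$mask), , drop = FALSE]
  } else NULL
  structure(list(genotype = as.character(cg), predicted = R,
                 delta_predicted = dR, components = comp, observed = obs),
            class = "epistasis_prediction")
}

#' @export
print.epistasis_prediction <- function(x, ...) {
  cat(sprintf("Multiplicative prediction for %s: %.3g +/- %.3g\n",
              x$genotype, x$predicted, x$delta_predicted))
  if (!is.null(x$observed)) {
    eps <- epistasis_score(x$observed$mean_fold, x$predicted)
    cat(sprintf("observed: %.3g +/- %.3g (n = %d); epistasis score ln(obs/pred) = %+.3f\n",
                x$observed$mean_fold, x$observed$sd, x$observed$n, eps))
  }
  invisible(x)
}

#' Epistasis score
#'
#' The log-ratio of observed fitness to the multiplicative prediction,
#' \eqn{\epsilon = \ln(\mathrm{observed}/R)}. Zero under exact
#' multiplicativity; positive/negative values indicate positive/negative
#' epistasis.
#'
#' @param observed Observed mean fold (positive), or an
#'   `epistasis_prediction` with an observed measurement.
#' @param predicted Predicted fold R (positive); ignored when `observed` is a
#'   prediction object.
#' @return Numeric epistasis score(s).
#' @export
epistasis_score <- function(observed, predicted = NULL) {
  if (inherits(observed, "epistasis_prediction")) {
    if (is.null(observed$observed)) stopf("prediction carries no observed measurement")
    return(log(observed$observed$mean_fold / observed$predicted))
  }
  if (any(!is.finite(observed) | observed <= 0) ||
      any(!is.finite(predicted) | predicted <= 0)) {
    stopf("observed and predicted folds must be positive")
  }
  log(observed / predicted)
}

#' Epistasis table for all multi-substitution genotypes
#'
#' Applies [predict_multiplicative()] and [epistasis_score()] to every
#' measured genotype with at least two substitutions.
#'
#' @param landscape A [fitness_landscape()] with all single-substitution
#'   genotypes measured.
#' @return Data frame with columns `genotype`, `k`, `predicted`,
#'   `delta_predicted`, `observed`, `sd`, `n`, `epsilon`.
#' @export
epistasis_table <- function(landscape) {
  stopifnot(inherits(landscape, "fitness_landscape"))
  sel <- which(popcount(landscape$mask) >= 2L)
  rows <- lapply(sel, function(i) {
    p <- predict_multiplicative(landscape, landscape$data$genotype[i])
    data.frame(genotype = p$genotype, k = popcount(landscape$mask[i]),
               predicted = p$predicted, delta_predicted = p$delta_predicted,
               observed = p$observed$mean_fold, sd = p$observed$sd,
               n = p$observed$n,
               epsilon = epistasis_score(p$observed$mean_fold, p$predicted),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Classify pairwise epistasis
#'
#' Given the fitness of wild type (normalised to 1), both single mutants and
#' the double mutant, classifies the pair against the multiplicative
#' expectation `f_a * f_b`:
#' \describe{
#'   \item{none}{deviation within tolerance (`|ln(f_ab / (f_a f_b))| <= tol`)}
#'   \item{magnitude}{deviation beyond tolerance, but neither substitution's
#'     effect changes direction across backgrounds}
#'   \item{sign}{exactly one substitution's effect changes direction
#'     (beneficial in one background, deleterious in the other)}
#'   \item{reciprocal_sign}{both substitutions change direction}
#' }
#'
#' @param f_wt Wild-type fitness, must be 1 (the fold scale's reference).
#' @param f_a,f_b,f_ab Positive fold values of the singles and the double.
#' @param tol Log-scale deviation tolerance for "none" (default 0.05).
#' @return One of `"none"`, `"magnitude"`, `"sign"`, `"reciprocal_sign"`.
#' @export
#' @examples
#' classify_pair(1, 1.5, 1.2, 1.5 * 1.2)   # "none"
#' classify_pair(1, 0.8, 0.8, 2.0)          # "reciprocal_sign"
classify_pair <- function(f_wt = 1, f_a, f_b, f_ab, tol = 0.05) {
  vals <- c(f_wt, f_a, f_b, f_ab)
  if (any(!is.finite(vals) | vals <= 0)) stopf("all fitness values must be positive")
  if (abs(log(f_wt)) > 1e-9) stopf("f_wt must be 1 (fold scale is relative to wild type)")
  eps <- log(f_ab) - log(f_a) - log(f_b)
  if (abs(eps) <= tol) return("none")
  # effect of a: in the wild-type background log(f_a); in the b background
  # log(f_ab / f_b); a sign change in that effect is sign epistasis for a
  flip_a <- sign(log(f_a)) * sign(log(f_ab) - log(f_b)) < 0
  flip_b <- sign(log(f_b)) * sign(log(f_ab) - log(f_a)) < 0
  if (flip_a && flip_b) "reciprocal_sign" else if (flip_a || flip_b) "sign" else "magnitude"
}

#' Unpaired two-sample t-test from summary statistics
#'
#' Student's unpaired t-test (pooled variance, the default) or Welch's
#' variant, computed from group means, standard deviations and sizes. The
#' two-sided p-value comes from the t distribution. The degenerate case of
#' two identical constant groups (both sds zero, equal means) returns t = 0,
#' p = 1 by convention.
#'
#' @param mean1,sd1,n1 Summary statistics of group 1 (`n1 >= 2`, `sd1 >= 0`).
#' @param mean2,sd2,n2 Summary statistics of group 2.
#' @param method `"pooled"` (Student, default) or `"welch"`.
#' @return Object of class `ttest_summary`: list with `statistic`, `df`,
#'   `p.value`, `method`, `stars`.
#' @export
unpaired_t_test <- function(mean1, sd1, n1, mean2, sd2, n2,
                            method = c("pooled", "welch")) {
  method <- match.arg(method)
  if (n1 < 2 || n2 < 2) stopf("both groups need at least 2 observations")
  if (sd1 < 0 || sd2 < 0) stopf("standard deviations must be nonnegative")
  if (sd1 == 0 && sd2 == 0 && mean1 == mean2) {
    t <- 0
    df <- if (method == "pooled") n1 + n2 - 2 else n1 + n2 - 2
    p <- 1
  } else if (method == "pooled") {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    if (se == 0) stopf("zero pooled variance with unequal means")
    t <- (mean1 - mean2) / se
    df <- n1 + n2 - 2
    p <- 2 * stats::pt(-abs(t), df)
  } else {
    v1 <- sd1^2 / n1; v2 <- sd2^2 / n2
    se <- sqrt(v1 + v2)
    if (se == 0) stopf("zero variance with unequal means")
    t <- (mean1 - mean2) / se
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
    p <- 2 * stats::pt(-abs(t), df)
  }
  structure(list(statistic = t, df = df, p.value = p, method = method,
                 stars = significance_stars(p)),
            class = "ttest_summary")
}

#' @export
print.ttest_summary <- function(x, ...) {
  cat(sprintf("Unpaired t-test (%s): t = %.4g, df = %.4g, p = %.4g %s\n",
              if (x$method == "pooled") "Student, pooled variance" else "Welch",
              x$statistic, x$df, x$p.value, x$stars))
  invisible(x)
}

#' Compare the measured fitness of two genotypes
#'
#' Runs [unpaired_t_test()] on the stored summary statistics of two
#' genotypes of a landscape.
#'
#' @param landscape A [fitness_landscape()].
#' @param genotype1,genotype2 Genotype strings.
#' @inheritParams unpaired_t_test
#' @return A `ttest_summary` object.
#' @export
compare_genotypes <- function(landscape, genotype1, genotype2,
                              method = c("pooled", "welch")) {
  a <- landscape_fitness(landscape, genotype1)
  b <- landscape_fitness(landscape, genotype2)
  unpaired_t_test(a$mean_fold, a$sd, a$n, b$mean_fold, b$sd, b$n, method = method)
}

#' Significance star labels
#'
#' `"***"` for p <= 0.001, `"**"` for p <= 0.01, `"*"` for p <= 0.05, else
#' `"ns"`.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Character vector of labels.
#' @export
significance_stars <- function(p) {
  if (any(!is.finite(p) | p < 0 | p > 1)) stopf("p-values must lie in [0, 1]")
  ifelse(p <= 0.001, "***", ifelse(p <= 0.01, "**", ifelse(p <= 0.05, "*", "ns")))
}
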