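#' Percentage growth inhibition
#'
#' From the growth (increase in OD600 between pre-challenge and 4 h
#' post-challenge) of a drug-challenged well relative to its unchallenged
#' control: `100 * (1 - delta_od_challenged / delta_od_control)`. Equal
#' growth gives 0% inhibition; no growth in the challenged well gives 100%.
#'
#' @param delta_od_challenged OD600 increase of the challenged well(s).
#' @param delta_od_control OD600 increase of the matched control well(s);
#'   must be positive (a non-growing control is an assay failure).
#' @return Percentage inhibition (can exceed 100 if the challenged well
#'   shrank, or be negative if it outgrew the control).
#' @export
#' @examples
#' percent_inhibition(0.2, 0.4)  # 50
percent_inhibition <- function(delta_od_challenged, delta_od_control) {
  if (any(!is.finite(delta_od_control) | delta_od_control <= 0)) {
    stopf("control growth must be positive (assay failure otherwise)")
  }
  100 * (1 - delta_od_challenged / delta_od_control)
}

# Four-parameter variable-slope dose-response inhibition curve, the common
# log10 "variable slope" convention.
fourpl <- function(x, bottom, top, logEC50, hill) {
  bottom + (top - bottom) / (1 + 10^((logEC50 - log10(x)) * hill))
}

#' Fit a four-parameter variable-slope dose-response curve
#'
#' Least-squares fit of
#' `response = bottom + (top - bottom) / (1 + 10^((logEC50 - log10(conc)) * hill))`
#' to a concentration/response series, the four-parameter variable-slope
#' model commonly used for EC50 estimation from growth-inhibition data.
#' Initialisation is deterministic: `top` = max response, `bottom` = min
#' response, `hill` = 1 and `logEC50` = log10 of the concentration whose
#' response is closest to `(top + bottom)/2`; the fit itself uses
#' Levenberg-Marquardt least squares ([minpack.lm::nlsLM]).
#'
#' Non-convergence, or a fitted EC50 outside the tested concentration range,
#' is flagged on the returned object (and warned about), never silently
#' dropped.
#'
#' @param conc Positive concentrations (µM); at least 5 distinct values.
#' @param response Percent-inhibition responses, same length.
#' @param constrain Constrain `bottom >= 0` and `top <= 100` (default FALSE,
#'   i.e. unconstrained).
#' @return An object of class `fit4pl` with components `coefficients`
#'   (`bottom`, `top`, `logEC50`, `hill`), `ec50` (µM), `rss`, `converged`,
#'   `extrapolated`, `data`. Methods: `print`, `coef`, `predict`, `fitted`,
#'   `residuals`, `plot`.
#' @export
#' @examples
#' x <- 5 * 1.5^(-6:6)
#' y <- 100 / (1 + 10^((log10(5) - log10(x)) * 1.2))
#' fit <- fit_4pl(x, y)
#' fit$ec50  # ~5
fit_4pl <- function(conc, response, constrain = FALSE) {
  if (length(conc) != length(response)) stopf("conc and response must have equal length")
  if (any(!is.finite(conc) | conc <= 0)) stopf("concentrations must be positive")
  if (any(!is.finite(response))) stopf("responses must be finite")
  if (length(unique(conc)) < 5L) stopf("at least 5 distinct concentrations are required")
  ord <- order(conc)
  conc <- conc[ord]; response <- response[ord]
  top0 <- max(response); bottom0 <- min(response)
  mid <- (top0 + bottom0) / 2
  log_ec50_0 <- log10(conc[which.min(abs(response - mid))])
  start <- list(bottom = bottom0, top = top0, logEC50 = log_ec50_0, hill = 1)
  df <- data.frame(x = conc, y = response)
  lower <- c(bottom = if (constrain) 0 else -Inf, top = -Inf, logEC50 = -Inf, hill = -Inf)
  upper <- c(bottom = Inf, top = if (constrain) 100 else Inf, logEC50 = Inf, hill = Inf)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ bottom + (top - bottom) / (1 + 10^((logEC50 - log10(x)) * hill)),
                      data = df, start = start, lower = lower, upper = upper,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    warning(sprintf("4PL fit did not converge: %s", conditionMessage(fit)), call. = FALSE)
    out <- list(coefficients = unlist(start) * NA_real_, ec50 = NA_real_,
                rss = NA_real_, converged = FALSE, extrapolated = NA,
                data = df)
    class(out) <- "fit4pl"
    return(out)
  }
  cf <- stats::coef(fit)
  ec50 <- 10^cf[["logEC50"]]
  extrapolated <- ec50 < min(conc) || ec50 > max(conc)
  converged <- isTRUE(fit$convInfo$isConv)
  if (extrapolated) {
    warning(sprintf("fitted EC50 (%.3g) lies outside the tested range [%.3g, %.3g]",
                    ec50, min(conc), max(conc)), call. = FALSE)
  }
  out <- list(coefficients = cf, ec50 = ec50,
              rss = sum(stats::resid(fit)^2), converged = converged,
              extrapolated = extrapolated, data = df)
  class(out) <- "fit4pl"
  out
}

#' @export
print.fit4pl <- function(x, ...) {
  cat("Four-parameter variable-slope dose-response fit\n")
  if (!x$converged) {
    cat("  (did not converge)\n")
  } else {
    cf <- x$coefficients
    cat(sprintf("  EC50 = %.4g uM%s  hill = %.3g\n", x$ec50,
                if (isTRUE(x$extrapolated)) " [extrapolated!]" else "", cf[["hill"]]))
    cat(sprintf("  bottom = %.3g%%, top = %.3g%%, RSS = %.4g (n = %d)\n",
                cf[["bottom"]], cf[["top"]], x$rss, nrow(x$data)))
  }
  invisible(x)
}

#' @export
#' @method coef fit4pl
coef.fit4pl <- function(object, ...) object$coefficients

#' @export
predict.fit4pl <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data$x else {
    if (is.data.frame(newdata)) newdata$x else newdata
  }
  cf <- object$coefficients
  fourpl(x, cf[["bottom"]], cf[["top"]], cf[["logEC50"]], cf[["hill"]])
}

#' @export
fitted.fit4pl <- function(object, ...) predict(object)

#' @export
#' @method residuals fit4pl
residuals.fit4pl <- function(object, ...) object$data$y - fitted(object)

#' @export
#' @method plot fit4pl
plot.fit4pl <- function(x, ...) {
  graphics::plot(x$data$x, x$data$y, log = "x",
                 xlab = "concentration (uM)", ylab = "% inhibition", ...)
  xs <- exp(seq(log(min(x$data$x)), log(max(x$data$x)), length.out = 200))
  graphics::lines(xs, predict(x, xs))
  if (x$converged) graphics::abline(v = x$ec50, lty = 2)
  invisible(x)
}

#' Summarise per-replicate EC50 fits into fitness-measurement inputs
#'
#' Technical replicates are averaged first within each biological replicate;
#' biological-replicate EC50s are then averaged to the final mean, with the
#' sample standard deviation and replicate count over biological replicates.
#' A genotype with a single biological replicate gets sd 0 and `n = 1`.
#'
#' @param fits Data frame with columns `genotype`, `bio_rep`, `ec50_uM` and
#'   optionally `tech_rep`.
#' @return Data frame `genotype`, `mean_ec50_uM`, `sd`, `n` (one row per
#'   genotype).
#' @export
ec50_summary <- function(fits) {
  need <- c("genotype", "bio_rep", "ec50_uM")
  if (!all(need %in% names(fits))) stopf("fits must have columns %s",
                                         paste(need, collapse = ", "))
  # technical-first averaging
  bio <- stats::aggregate(ec50_uM ~ genotype + bio_rep, data = fits, FUN = mean)
  out <- do.call(rbind, lapply(split(bio, bio$genotype), function(d) {
    data.frame(genotype = d$genotype[1], mean_ec50_uM = mean(d$ec50_uM),
               sd = sd_or_zero(d$ec50_uM), n = nrow(d), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Fit EC50s for a whole plate table
#'
#' Takes raw plate data (`genotype, bio_rep, tech_rep, conc_uM, od_pre,
#' od_4h, is_control`), computes percent inhibition per well against the
#' matched unchallenged control of the same genotype/replicate, fits one 4PL
#' curve per technical replicate and returns the per-fit EC50 table suitable
#' for [ec50_summary()].
#'
#' @param plate Data frame in the plate CSV layout above (`is_control`
#'   logical or 0/1; control rows supply the unchallenged OD increase).
#' @param constrain Passed to [fit_4pl()].
#' @return Data frame `genotype`, `bio_rep`, `tech_rep`, `ec50_uM`,
#'   `converged`, `extrapolated`.
#' @export
fit_plate <- function(plate, constrain = FALSE) {
  need <- c("genotype", "bio_rep", "tech_rep", "conc_uM", "od_pre", "od_4h", "is_control")
  if (!all(need %in% names(plate))) stopf("plate table must have columns %s",
                                          paste(need, collapse = ", "))
  plate$is_control <- as.logical(plate$is_control)
  plate$delta <- plate$od_4h - plate$od_pre
  key <- interaction(plate$genotype, plate$bio_rep, plate$tech_rep, drop = TRUE)
  rows <- lapply(split(plate, key), function(d) {
    ctrl <- d$delta[d$is_control]
    if (length(ctrl) == 0L) stopf("no control well for %s bio %s tech %s",
                                  d$genotype[1], d$bio_rep[1], d$tech_rep[1])
    inh <- percent_inhibition(d$delta[!d$is_control], mean(ctrl))
    f <- suppressWarnings(fit_4pl(d$conc_uM[!d$is_control], inh, constrain = constrain))
    data.frame(genotype = d$genotype[1], bio_rep = d$bio_rep[1],
               tech_rep = d$tech_rep[1], ec50_uM = f$ec50,
               converged = f$converged, extrapolated = f$extrapolated,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
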