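#' Specification for a synthetic fitness landscape
#'
#' Defines the generative model for a combinatorial landscape with known
#' ground truth: per-substitution log-fold effects, optional pairwise
#' log-interaction terms, an optional *gating* substitution whose absence
#' masks the other substitutions' effects, a replicate count and a
#' measurement CV.
#'
#' The default specification emulates the study conditions of a
#' seven-substitution active-site landscape (128 genotypes): fold
#' improvements spanning roughly 0.2-10x, four replicates per genotype, a
#' measurement CV of 0.16 (the average relative EC50 error), and a gating
#' substitution at position 225 that must be acquired before the other
#' substitutions' benefits manifest (masking strength 0.15, i.e. only 15% of
#' the other log-effects are expressed while the gate is absent).
#'
#' @param labels Substitution labels (ordered by residue position on
#'   construction).
#' @param effects Named numeric vector of log-fold single effects, names
#'   matching `labels`.
#' @param interactions Optional data frame `members`, `log_term`: a
#'   log-interaction term added whenever all of its member substitutions
#'   (a `"+"`-joined label set, e.g. `"S41Y+T219Y"`) are present. Pairs give
#'   pairwise epistasis; larger member sets give higher-order terms.
#' @param gate Label of the gating substitution, or `NULL` for none.
#' @param masking Fraction (0-1) of the non-gating single effects expressed
#'   while the gate is absent; 0 = full masking, 1 = no gating behaviour.
#' @param replicates Replicates per genotype (>= 1).
#' @param cv Measurement coefficient of variation (>= 0) of replicate folds.
#' @return Object of class `landscape_spec`.
#' @export
landscape_spec <- function(labels = c("S41Y", "H215C", "T219Y", "K222V",
                                      "S224R", "R225V", "F227G"),
                           effects = c(S41Y = log(1.9), H215C = log(0.9),
                                       T219Y = log(1.4), K222V = log(0.85),
                                       S224R = log(1.2), R225V = log(2.9),
                                       F227G = log(1.3)),
                           interactions = data.frame(
                             members = c("H215C+K222V", "H215C+K222V+S224R"),
                             log_term = c(log(0.3), -log(0.3))),
                           gate = "R225V", masking = 0.15,
                           replicates = 4, cv = 0.16) {
  subs <- order_substitutions(labels)
  if (!setequal(names(effects), subs$label)) {
    stopf("effects must be named by the substitution labels")
  }
  effects <- effects[subs$label]
  if (!is.null(interactions) && nrow(interactions)) {
    need <- c("members", "log_term")
    if (!all(need %in% names(interactions))) {
      stopf("interactions must have columns members, log_term")
    }
    for (m in interactions$members) {
      toks <- strsplit(m, "+", fixed = TRUE)[[1]]
      if (length(toks) < 2L || !all(toks %in% subs$label) || anyDuplicated(toks)) {
        stopf("interaction members '%s' must name >= 2 distinct landscape substitutions", m)
      }
    }
  } else {
    interactions <- data.frame(members = character(0), log_term = numeric(0))
  }
  if (!is.null(gate)) {
    gate <- toupper(trimws(gate))
    if (!gate %in% subs$label) stopf("gate '%s' is not one of the substitutions", gate)
  }
  if (!is.numeric(masking) || length(masking) != 1L || masking < 0 || masking > 1) {
    stopf("masking must lie in [0, 1]")
  }
  if (!is_count(replicates) || replicates < 1) stopf("replicates must be a positive integer")
  if (!is.numeric(cv) || length(cv) != 1L || cv < 0) stopf("cv must be >= 0")
  structure(list(substitutions = subs, effects = effects,
                 interactions = interactions, gate = gate, masking = masking,
                 replicates = as.integer(replicates), cv = cv),
            class = "landscape_spec")
}

# True fold of every subset mask under the generative model:
# log fold = sum of expressed single effects + sum of active interactions,
# with non-gate effects scaled by `masking` while the gate is absent.
true_fold_by_mask <- function(spec) {
  subs <- spec$substitutions
  n <- nrow(subs)
  bits <- bitwShiftL(1L, seq_len(n) - 1L)
  gate_bit <- if (is.null(spec$gate)) 0L else bits[match(spec$gate, subs$label)]
  ia <- spec$interactions
  ia_bits <- if (nrow(ia)) {
    vapply(strsplit(ia$members, "+", fixed = TRUE), function(toks) {
      as.integer(sum(bits[match(toks, subs$label)]))
    }, integer(1))
  } else integer(0)
  vapply(0:(2^n - 1L), function(m) {
    present <- bitwAnd(m, bits) != 0L
    scale <- rep(1, n)
    if (gate_bit != 0L && bitwAnd(m, gate_bit) == 0L) {
      scale[bits != gate_bit] <- spec$masking
    }
    lf <- sum(spec$effects[present] * scale[present])
    if (length(ia_bits)) {
      active <- bitwAnd(m, ia_bits) == ia_bits
      lf <- lf + sum(ia$log_term[active])
    }
    exp(lf)
  }, numeric(1))
}

#' Simulate a replicate-level fitness landscape with known ground truth
#'
#' Draws `replicates` i.i.d. fold measurements per genotype from a lognormal
#' distribution around the genotype's true fold with the specified CV (the
#' lognormal is mean-preserving: the expected replicate fold equals the true
#' fold and the coefficient of variation equals `cv` exactly). The wild type
#' is the reference of the fold scale and is fixed at 1 without noise (its
#' measurement error is part of every variant's fold ratio). Identical seeds
#' give identical output.
#'
#' @param spec A [landscape_spec()].
#' @param seed Integer seed (the caller's RNG state is left untouched).
#' @return List with elements
#'   \describe{
#'     \item{landscape}{[fitness_landscape()] aggregated from the replicates}
#'     \item{replicates}{long data frame `genotype`, `replicate`, `fold`}
#'     \item{truth}{list: `fold` (named true fold per genotype), `effects`
#'       (true single log effects), `interactions`, `spec`}
#'   }
#' @export
simulate_landscape <- function(spec = landscape_spec(), seed = 1) {
  stopifnot(inherits(spec, "landscape_spec"))
  subs <- spec$substitutions
  n <- nrow(subs)
  truth <- true_fold_by_mask(spec)
  genos <- vapply(0:(2^n - 1L), mask_to_genotype, "", subs = subs)
  sdlog <- sqrt(log1p(spec$cv^2))
  reps <- with_seed(seed, {
    do.call(rbind, lapply(seq_along(genos), function(i) {
      if (genos[i] == "WT") {
        fold <- rep(1, spec$replicates)  # reference of the fold scale
      } else {
        meanlog <- log(truth[i]) - sdlog^2 / 2
        fold <- stats::rlnorm(spec$replicates, meanlog = meanlog, sdlog = sdlog)
      }
      data.frame(genotype = genos[i], replicate = seq_len(spec$replicates),
                 fold = fold, stringsAsFactors = FALSE)
    }))
  })
  agg <- do.call(rbind, lapply(split(reps, reps$genotype), function(d) {
    data.frame(genotype = d$genotype[1], mean_fold = mean(d$fold),
               sd = sd_or_zero(d$fold), n = nrow(d), stringsAsFactors = FALSE)
  }))
  agg$mean_fold[agg$genotype == "WT"] <- 1  # exact by construction
  agg$sd[agg$genotype == "WT"] <- 0
  ls <- fitness_landscape(subs$label, agg, name = "simulated", replicates = reps)
  list(landscape = ls, replicates = reps,
       truth = list(fold = setNames(truth, genos), effects = spec$effects,
                    interactions = spec$interactions, spec = spec))
}

#' Simulate a dose-response curve from a known EC50
#'
#' Generates percent-inhibition responses from the four-parameter
#' variable-slope model plus multiplicative (mean-preserving lognormal)
#' noise. The default concentration series is a 1.5-fold dilution series of
#' 13 concentrations centred on the true EC50, and the default hill slope is
#' 2: growth-inhibition endpoints collapse sharply around the effective
#' concentration, and a steep slope is also what lets the dilution series
#' sample both plateaus, keeping the EC50 identifiable in an unconstrained
#' four-parameter fit.
#'
#' @param true_ec50 True EC50 (µM, > 0).
#' @param concentrations Optional explicit concentration vector (µM);
#'   otherwise built from `n_conc` and `dilution`.
#' @param n_conc Number of concentrations in the default series.
#' @param dilution Dilution factor of the default series.
#' @param hill,top,bottom Curve parameters (defaults 2, 100, 0).
#' @param cv Multiplicative response noise CV (0 = noiseless).
#' @param seed Integer seed.
#' @return Data frame `conc_uM`, `response`, plus the true parameters as
#'   attributes.
#' @export
simulate_dose_response <- function(true_ec50, concentrations = NULL,
                                   n_conc = 13, dilution = 1.5,
                                   hill = 2, top = 100, bottom = 0,
                                   cv = 0, seed = 1) {
  if (!is.numeric(true_ec50) || length(true_ec50) != 1L || true_ec50 <= 0) {
    stopf("true_ec50 must be a single positive number")
  }
  if (is.null(concentrations)) {
    half <- (n_conc - 1) / 2
    concentrations <- true_ec50 * dilution^(seq_len(n_conc) - 1 - half)
  }
  if (any(concentrations <= 0)) stopf("concentrations must be positive")
  mu <- fourpl(concentrations, bottom, top, log10(true_ec50), hill)
  resp <- if (cv > 0) {
    sdlog <- sqrt(log1p(cv^2))
    with_seed(seed, mu * stats::rlnorm(length(mu), meanlog = -sdlog^2 / 2, sdlog = sdlog))
  } else mu
  structure(data.frame(conc_uM = concentrations, response = resp),
            true_ec50 = true_ec50, hill = hill, top = top, bottom = bottom)
}

#' Recover generative parameters from a simulated landscape
#'
#' Estimates the single-substitution log effects from the single-substitution
#' genotype means, and the pairwise epistasis scores
#' \eqn{\epsilon_{ab} = \ln f_{ab} - \ln f_a - \ln f_b} from the double
#' mutants, and tabulates them against the ground truth (the truth
#' \eqn{\epsilon} is computed from the true folds, so gating-induced
#' epistasis is part of the truth, not an error).
#'
#' @param sim Result of [simulate_landscape()].
#' @return List of two data frames: `singles` (`substitution`, `truth`,
#'   `estimate`, `se` of the replicate-mean log effect) and `pairs` (`a`,
#'   `b`, `truth`, `estimate`).
#' @export
recover_parameters <- function(sim) {
  if (!is.list(sim) || is.null(sim$landscape) || is.null(sim$truth)) {
    stopf("sim must be the result of simulate_landscape()")
  }
  ls <- sim$landscape
  subs <- ls$substitutions
  n <- nrow(subs)
  true_fold <- sim$truth$fold
  singles <- do.call(rbind, lapply(seq_len(n), function(i) {
    lab <- subs$label[i]
    m <- landscape_fitness(ls, lab)
    data.frame(substitution = lab,
               truth = log(true_fold[[lab]]),
               estimate = log(m$mean_fold),
               se = (m$sd / m$mean_fold) / sqrt(m$n),
               stringsAsFactors = FALSE)
  }))
  pairs <- do.call(rbind, apply(utils::combn(n, 2), 2, function(ij) {
    a <- subs$label[ij[1]]; b <- subs$label[ij[2]]
    ab <- paste(a, b, sep = "+")
    est <- log(landscape_fitness(ls, ab)$mean_fold) -
      log(landscape_fitness(ls, a)$mean_fold) -
      log(landscape_fitness(ls, b)$mean_fold)
    tru <- log(true_fold[[ab]]) - log(true_fold[[a]]) - log(true_fold[[b]])
    data.frame(a = a, b = b, truth = tru, estimate = est, stringsAsFactors = FALSE)
  }))
  rownames(singles) <- rownames(pairs) <- NULL
  list(singles = singles, pairs = pairs)
}
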