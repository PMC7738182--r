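# Independent oracles and small fixtures used across the test files.

# Brute-force accessible-trajectory count: walks every permutation explicitly
# and re-checks each step straight from the landscape table, independently of
# the subset-lattice dynamic program in count_accessible().
bf_count_accessible <- function(landscape, threshold = 0.16) {
  subs <- landscape$substitutions$label
  n <- length(subs)
  folds <- setNames(landscape$data$mean_fold, landscape$data$genotype)
  canon <- function(labels) {
    if (length(labels) == 0) return("WT")
    pos <- as.integer(gsub("[^0-9]", "", labels))
    paste(labels[order(pos)], collapse = "+")
  }
  perms <- collect_trajectories(n)
  acc <- 0L
  for (r in seq_len(nrow(perms))) {
    ok <- TRUE
    f_prev <- folds[["WT"]]
    for (k in seq_len(n)) {
      g <- canon(subs[perms[r, seq_len(k)]])
      f_now <- folds[[g]]
      if (!(f_now > f_prev * (1 + threshold))) { ok <- FALSE; break }
      f_prev <- f_now
    }
    if (ok) acc <- acc + 1L
  }
  acc
}

# Monte-Carlo oracle for expected distinct variants: samples transformants
# from the per-variant probability distribution by enumerating the variants.
mc_expected_distinct <- function(design, L, reps = 1e4) {
  code <- fitscape::standard_genetic_code()
  site_prob <- lapply(seq_len(nrow(design)), function(i) {
    rep <- amino_acid_repertoire(design$codon[i], code)
    rep <- rep[setdiff(names(rep), "*")]
    rep / sum(rep)
  })
  # enumerate all protein variants and their probabilities
  probs <- Reduce(function(p, q) as.numeric(outer(p, q)), site_prob)
  draws <- vapply(seq_len(reps), function(r) {
    length(unique(sample.int(length(probs), L, replace = TRUE, prob = probs)))
  }, numeric(1))
  list(mean = mean(draws), se = sd(draws) / sqrt(reps))
}

# Build a small complete landscape directly from a named fold vector
# (names are canonical genotype strings incl. "WT").
toy_landscape <- function(substitutions, folds, sd = 0, n = 4) {
  fitness_landscape(substitutions, data.frame(
    genotype = names(folds), mean_fold = as.numeric(folds),
    sd = sd, n = n, stringsAsFactors = FALSE))
}

# Complete multiplicative landscape from per-substitution fold effects.
multiplicative_landscape <- function(effects, sd = 0) {
  subs <- names(effects)
  n <- length(subs)
  pos <- as.integer(gsub("[^0-9]", "", subs))
  ord <- order(pos)
  genos <- "WT"; vals <- 1
  for (m in seq_len(2^n - 1)) {
    sel <- ord[bitwAnd(m, bitwShiftL(1L, seq_len(n) - 1L)) != 0L]
    sel <- sel[order(pos[sel])]
    genos <- c(genos, paste(subs[sel], collapse = "+"))
    vals <- c(vals, prod(effects[sel]))
  }
  toy_landscape(subs, setNames(vals, genos), sd = sd)
}

nfsa_design <- function() {
  library_design(
    position  = c(41, 43, 215, 219, 222, 224, 225, 227),
    wild_type = c("S", "L", "H", "T", "K", "S", "R", "F"),
    codon     = c("NDT", "NDT", "NDT", "NHT", "VNG", "NDT", "NDT", "NDT"))
}
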