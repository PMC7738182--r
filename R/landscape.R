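#' Amino-acid substitutions and genotypes
#'
#' A substitution is written `wt + position + mut`, e.g. `"S41Y"`. A genotype
#' is a subset of a landscape's substitutions, written as the `"+"`-joined
#' labels sorted by ascending residue position (`"S41Y+R225V"`); the empty
#' subset (wild type) is written `"WT"`.
#'
#' @param x Character vector of substitution labels.
#' @return `parse_substitution()` returns a data frame with columns `label`,
#'   `wild_type`, `position`, `mutant`.
#' @export
#' @examples
#' parse_substitution("S41Y")
parse_substitution <- function(x) {
  x <- toupper(trimws(x))
  m <- regmatches(x, regexec("^([A-Z])([0-9]+)([A-Z*])$", x))
  bad <- vapply(m, length, integer(1)) != 4L
  if (any(bad)) stopf("cannot parse substitution '%s' (expected e.g. 'S41Y')", x[bad][1])
  wt <- vapply(m, `[`, "", 2L)
  pos <- as.integer(vapply(m, `[`, "", 3L))
  mut <- vapply(m, `[`, "", 4L)
  if (any(!wt %in% AMINO_ACIDS)) stopf("wild-type residue must be a standard amino acid in '%s'",
                                       x[!wt %in% AMINO_ACIDS][1])
  if (any(wt == mut)) stopf("substitution '%s' does not change the residue", x[wt == mut][1])
  data.frame(label = paste0(wt, pos, mut), wild_type = wt, position = pos,
             mutant = mut, stringsAsFactors = FALSE)
}

# Order substitution labels by ascending residue position; reject duplicates.
order_substitutions <- function(labels) {
  info <- parse_substitution(labels)
  if (anyDuplicated(info$position)) {
    dup <- info$position[duplicated(info$position)][1]
    stopf("more than one substitution at position %d", dup)
  }
  info[order(info$position), , drop = FALSE]
}

# Canonicalise a genotype string against an ordered substitution table.
# Returns the canonical string; attr "mask" holds the subset bitmask
# (bit i set <=> i-th substitution, ascending position, present).
canonicalise_genotype <- function(g, subs) {
  g <- toupper(trimws(g))
  if (g %in% c("", "WT")) {
    return(structure("WT", mask = 0L))
  }
  toks <- strsplit(g, "+", fixed = TRUE)[[1]]
  toks <- toupper(trimws(toks))
  idx <- match(toks, subs$label)
  if (anyNA(idx)) stopf("unknown substitution '%s' in genotype '%s'", toks[is.na(idx)][1], g)
  pos <- subs$position[idx]
  if (anyDuplicated(pos)) {
    stopf("genotype '%s' carries two substitutions at position %d",
          g, pos[duplicated(pos)][1])
  }
  idx <- sort(idx)
  structure(paste(subs$label[idx], collapse = "+"),
            mask = as.integer(sum(bitwShiftL(1L, idx - 1L))))
}

mask_to_genotype <- function(mask, subs) {
  if (mask == 0L) return("WT")
  idx <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(nrow(subs)) - 1L)) != 0L)
  paste(subs$label[idx], collapse = "+")
}

popcount <- function(mask) {
  vapply(mask, function(m) sum(bitwAnd(m, bitwShiftL(1L, 0:30)) != 0L), integer(1))
}

#' Canonical bitstring form of a genotype
#'
#' One bit per landscape substitution, ordered by ascending residue position
#' (leftmost bit = lowest position); `1` marks a present substitution.
#'
#' @param genotype Genotype string (see [parse_substitution()]).
#' @param substitutions Character vector of the landscape's substitutions.
#' @return A string of `0`/`1` characters.
#' @export
#' @examples
#' genotype_bitstring("S41Y+R225V", c("S41Y", "T219Y", "R225V"))  # "101"
genotype_bitstring <- function(genotype, substitutions) {
  subs <- order_substitutions(substitutions)
  mask <- attr(canonicalise_genotype(genotype, subs), "mask")
  paste(ifelse(bitwAnd(mask, bitwShiftL(1L, seq_len(nrow(subs)) - 1L)) != 0L, "1", "0"),
        collapse = "")
}

#' Combinatorial genotype-fitness landscape
#'
#' A fitness landscape maps every measured subset of `n` amino-acid
#' substitutions to a fitness measurement: the mean fold-improvement in EC50
#' relative to wild type, its standard deviation, and the replicate count.
#' The wild type (empty genotype, fold 1 by definition) is always present; a
#' landscape is *complete* when all `2^n` subsets are measured.
#'
#' @param substitutions Character vector of the `n` substitution labels.
#' @param data Data frame with columns `genotype`, `mean_fold`, `sd`, `n`.
#'   Genotype `""` or `"WT"` denotes wild type; if absent it is inserted with
#'   fold 1.
#' @param name Landscape name.
#' @param replicates Optional long-format data frame of per-replicate fold
#'   values (columns `genotype`, `replicate`, `fold`), kept as an attribute.
#' @return An object of class `fitness_landscape`.
#' @export
fitness_landscape <- function(substitutions, data, name = "landscape",
                              replicates = NULL) {
  subs <- order_substitutions(substitutions)
  n <- nrow(subs)
  if (n > 20L) stopf("landscapes with more than 20 substitutions are not supported")
  need <- c("genotype", "mean_fold", "sd", "n")
  if (!all(need %in% names(data))) {
    stopf("landscape data must have columns %s", paste(need, collapse = ", "))
  }
  canon <- character(nrow(data))
  mask <- integer(nrow(data))
  for (i in seq_len(nrow(data))) {
    cg <- tryCatch(canonicalise_genotype(data$genotype[i], subs),
                   error = function(e) stopf("row %d: %s", i, conditionMessage(e)))
    canon[i] <- cg
    mask[i] <- attr(cg, "mask")
  }
  if (anyDuplicated(mask)) {
    stopf("duplicate genotype '%s'", canon[duplicated(mask)][1])
  }
  mean_fold <- as.numeric(data$mean_fold)
  sdv <- as.numeric(data$sd)
  nrep <- as.integer(data$n)
  bad <- which(!is.finite(mean_fold) | mean_fold <= 0)
  if (length(bad)) stopf("row %d: fitness must be positive (genotype '%s')", bad[1], canon[bad[1]])
  if (any(!is.finite(sdv) | sdv < 0)) stopf("sd must be nonnegative")
  if (any(is.na(nrep) | nrep < 1L)) stopf("replicate count n must be >= 1")
  if (0L %in% mask) {
    wt_mean <- mean_fold[mask == 0L]
    if (abs(wt_mean - 1) > 1e-8) {
      stopf("wild-type fold must be 1 on the fold-improvement scale (got %g)", wt_mean)
    }
  } else {
    canon <- c(canon, "WT"); mask <- c(mask, 0L)
    mean_fold <- c(mean_fold, 1); sdv <- c(sdv, 0); nrep <- c(nrep, 1L)
  }
  df <- data.frame(genotype = canon, mean_fold = mean_fold, sd = sdv, n = nrep,
                   stringsAsFactors = FALSE)
  ord <- order(popcount(mask), canon)
  df <- df[ord, , drop = FALSE]
  mask <- mask[ord]
  rownames(df) <- NULL
  fold_by_mask <- rep(NA_real_, 2^n)
  fold_by_mask[mask + 1L] <- df$mean_fold
  structure(list(name = name, substitutions = subs, data = df, mask = mask,
                 fold_by_mask = fold_by_mask,
                 complete = nrow(df) == 2^n,
                 replicates = replicates),
            class = "fitness_landscape")
}

#' @export
print.fitness_landscape <- function(x, ...) {
  cat(sprintf("Fitness landscape '%s': %d substitutions (%s)\n", x$name,
              nrow(x$substitutions), paste(x$substitutions$label, collapse = ", ")))
  cat(sprintf("%d of %d genotypes measured (%s)\n", nrow(x$data),
              2^nrow(x$substitutions), if (x$complete) "complete" else "incomplete"))
  rng <- range(x$data$mean_fold)
  cat(sprintf("fold-improvement range: %.3g - %.3g\n", rng[1], rng[2]))
  invisible(x)
}

#' Number of substitutions of a landscape
#' @param landscape A [fitness_landscape()].
#' @return Integer `n`.
#' @export
n_substitutions <- function(landscape) {
  stopifnot(inherits(landscape, "fitness_landscape"))
  nrow(landscape$substitutions)
}

# Mean fold of one or more genotypes given by subset mask (0-based).
fold_at_mask <- function(landscape, mask) landscape$fold_by_mask[mask + 1L]

#' Look up the fitness of a genotype
#'
#' @param landscape A [fitness_landscape()].
#' @param genotype Genotype string.
#' @return One-row data frame (`genotype`, `mean_fold`, `sd`, `n`), or an
#'   error if the genotype is not measured.
#' @export
landscape_fitness <- function(landscape, genotype) {
  stopifnot(inherits(landscape, "fitness_landscape"))
  cg <- canonicalise_genotype(genotype, landscape$substitutions)
  i <- match(attr(cg, "mask"), landscape$mask)
  if (is.na(i)) stopf("genotype '%s' is not measured in landscape '%s'", cg, landscape$name)
  landscape$data[i, , drop = FALSE]
}

require_complete <- function(landscape, allow_incomplete = FALSE) {
  if (landscape$complete) return(invisible(TRUE))
  if (allow_incomplete) {
    warning(sprintf("landscape '%s' is incomplete; missing genotypes are skipped",
                    landscape$name), call. = FALSE)
    return(invisible(FALSE))
  }
  stopf("landscape '%s' is incomplete (%d of %d genotypes); pass allow_incomplete = TRUE to proceed",
        landscape$name, nrow(landscape$data), 2^n_substitutions(landscape))
}

#' Read / write a landscape CSV
#'
#' The canonical on-disk format is a UTF-8 CSV with header
#' `genotype,mean_fold,sd,n`; genotype `""` or `"WT"` denotes wild type and
#' all other genotypes are `"+"`-joined substitution labels.
#' `write_landscape()` emits genotypes in canonical order (by substitution
#' count, then alphabetically), so `write` then `read` is the identity on
#' canonical files.
#'
#' @param path File path.
#' @param substitutions Optional declared substitution list; inferred from
#'   the file's genotype tokens when `NULL`.
#' @param name Landscape name (defaults to the file name).
#' @return `read_landscape()` returns a [fitness_landscape()];
#'   `write_landscape()` invisibly returns `path`.
#' @export
read_landscape <- function(path, substitutions = NULL, name = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = c(genotype = "character"))
  need <- c("genotype", "mean_fold", "sd", "n")
  if (!all(need %in% names(df))) {
    stopf("landscape file must have columns %s", paste(need, collapse = ", "))
  }
  if (is.null(substitutions)) {
    toks <- unlist(strsplit(setdiff(toupper(trimws(df$genotype)), c("", "WT")), "+", fixed = TRUE))
    substitutions <- unique(trimws(toks))
    if (length(substitutions) == 0L) stopf("no substitutions found in '%s'", path)
  }
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  fitness_landscape(substitutions, df, name = name)
}

#' @rdname read_landscape
#' @param landscape A [fitness_landscape()].
#' @export
write_landscape <- function(landscape, path) {
  stopifnot(inherits(landscape, "fitness_landscape"))
  utils::write.csv(landscape$data, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Enumerate intermediate genotypes
#'
#' All genotypes strictly between wild type and the full `n`-substitution
#' variant on the subset lattice; there are `2^n - 2` of them. Order is
#' deterministic: by substitution count, then alphabetically by canonical
#' string.
#'
#' @param x A [fitness_landscape()] or a character vector of substitution
#'   labels.
#' @return Character vector of genotype strings.
#' @export
#' @examples
#' length(enumerate_intermediates(c("S41Y", "T219Y", "R225V")))  # 6
enumerate_intermediates <- function(x) {
  subs <- if (inherits(x, "fitness_landscape")) x$substitutions else order_substitutions(x)
  n <- nrow(subs)
  masks <- seq_len(max(2^n - 2L, 0L))
  if (length(masks) == 0L) return(character(0))
  g <- vapply(masks, mask_to_genotype, "", subs = subs)
  g[order(popcount(masks), g)]
}

#' Fold improvement in EC50 over wild type
#'
#' @param variant_ec50,wt_ec50 Positive EC50 values in the same units.
#' @return `variant_ec50 / wt_ec50`.
#' @export
fold_improvement <- function(variant_ec50, wt_ec50) {
  if (any(!is.finite(variant_ec50) | variant_ec50 <= 0) ||
      any(!is.finite(wt_ec50) | wt_ec50 <= 0)) {
    stopf("EC50 values must be positive and finite")
  }
  variant_ec50 / wt_ec50
}

#' Fold improvement from replicate EC50 measurements
#'
#' When replicate EC50s carry batch identifiers pairing each variant
#' measurement with a wild-type control measured alongside it, the fold is
#' computed per batch and the batch ratios averaged. Without batch structure
#' the ratio of grand means is used, with the SD propagated from the two
#' groups' relative errors.
#'
#' @param variant_ec50 Numeric vector of variant EC50 replicates.
#' @param wt_ec50 Numeric vector of wild-type EC50 replicates.
#' @param batch Optional vector of batch identifiers, parallel to
#'   `variant_ec50`; `wt_batch` parallel to `wt_ec50`. Each variant batch must
#'   have a wild-type measurement (batch wild-type replicates are averaged).
#' @param wt_batch See `batch`.
#' @return A one-row data frame `mean_fold`, `sd`, `n`.
#' @export
fold_from_ec50 <- function(variant_ec50, wt_ec50, batch = NULL, wt_batch = NULL) {
  if (any(variant_ec50 <= 0) || any(wt_ec50 <= 0)) stopf("EC50 values must be positive")
  if (is.null(batch)) {
    mv <- mean(variant_ec50); mw <- mean(wt_ec50)
    r <- mv / mw
    rel <- sqrt((sd_or_zero(variant_ec50) / mv)^2 + (sd_or_zero(wt_ec50) / mw)^2)
    return(data.frame(mean_fold = r, sd = r * rel, n = length(variant_ec50)))
  }
  if (is.null(wt_batch)) stopf("wt_batch is required when batch is given")
  wt_by_batch <- tapply(wt_ec50, wt_batch, mean)
  missing <- setdiff(unique(as.character(batch)), names(wt_by_batch))
  if (length(missing)) stopf("no wild-type measurement for batch '%s'", missing[1])
  ratios <- variant_ec50 / as.numeric(wt_by_batch[as.character(batch)])
  data.frame(mean_fold = mean(ratios), sd = sd_or_zero(ratios), n = length(ratios))
}

sd_or_zero <- function(x) if (length(x) < 2L) 0 else stats::sd(x)

#' Build a landscape from a long-format replicate EC50 table
#'
#' Ingests per-replicate EC50 measurements (`genotype, replicate, batch,
#' ec50_uM`; genotype `"WT"` marks the wild-type control) and converts them to
#' the fold-improvement scale, pairing each measurement with the wild-type
#' control of its batch.
#'
#' @param df Data frame with columns `genotype`, `replicate`, `batch`,
#'   `ec50_uM`.
#' @param substitutions Optional declared substitution list (inferred
#'   otherwise).
#' @param name Landscape name.
#' @return A [fitness_landscape()] whose `replicates` attribute holds the
#'   per-replicate folds.
#' @export
landscape_from_ec50 <- function(df, substitutions = NULL, name = "landscape") {
  need <- c("genotype", "replicate", "batch", "ec50_uM")
  if (!all(need %in% names(df))) stopf("replicate table must have columns %s",
                                       paste(need, collapse = ", "))
  if (any(df$ec50_uM <= 0)) stopf("EC50 values must be positive")
  g <- toupper(trimws(df$genotype))
  is_wt <- g %in% c("", "WT")
  if (!any(is_wt)) stopf("replicate table must contain wild-type ('WT') control rows")
  wt_by_batch <- tapply(df$ec50_uM[is_wt], df$batch[is_wt], mean)
  missing <- setdiff(unique(as.character(df$batch)), names(wt_by_batch))
  if (length(missing)) stopf("no wild-type measurement for batch '%s'", missing[1])
  fold <- df$ec50_uM / as.numeric(wt_by_batch[as.character(df$batch)])
  var_rows <- !is_wt
  reps <- data.frame(genotype = g[var_rows], replicate = df$replicate[var_rows],
                     fold = fold[var_rows], stringsAsFactors = FALSE)
  agg_mean <- tapply(reps$fold, reps$genotype, mean)
  agg_sd <- tapply(reps$fold, reps$genotype, sd_or_zero)
  agg_n <- tapply(reps$fold, reps$genotype, length)
  data <- data.frame(genotype = names(agg_mean), mean_fold = as.numeric(agg_mean),
                     sd = as.numeric(agg_sd), n = as.integer(agg_n),
                     stringsAsFactors = FALSE)
  if (is.null(substitutions)) {
    toks <- unlist(strsplit(setdiff(data$genotype, c("", "WT")), "+", fixed = TRUE))
    substitutions <- unique(trimws(toks))
  }
  fitness_landscape(substitutions, data, name = name, replicates = reps)
}

#' Fitness summary over the presence/absence partition of a substitution
#'
#' Splits all measured genotypes into those containing the given substitution
#' and those lacking it (wild type counts as lacking) and reports the mean
#' and sample standard deviation of the genotype mean folds in each group.
#' This is the statistic behind statements like "variants containing the
#' gating substitution tolerated on average 4.0 +/- 2.4 fold higher drug
#' concentrations, versus 1.0 +/- 0.5 for those retaining the native residue".
#'
#' @param landscape A [fitness_landscape()].
#' @param substitution One of the landscape's substitution labels.
#' @return Data frame with rows `with` and `without` and columns `group`,
#'   `mean`, `sd`, `n_genotypes`.
#' @export
partition_summary <- function(landscape, substitution) {
  stopifnot(inherits(landscape, "fitness_landscape"))
  subs <- landscape$substitutions
  i <- match(toupper(trimws(substitution)), subs$label)
  if (is.na(i)) stopf("substitution '%s' is not part of landscape '%s'",
                      substitution, landscape$name)
  bit <- bitwShiftL(1L, i - 1L)
  has <- bitwAnd(landscape$mask, bit) != 0L
  grp <- function(sel) {
    x <- landscape$data$mean_fold[sel]
    c(mean = mean(x), sd = sd_or_zero(x), n = length(x))
  }
  w <- grp(has); wo <- grp(!has)
  data.frame(group = c("with", "without"),
             mean = c(w["mean"], wo["mean"]),
             sd = c(w["sd"], wo["sd"]),
             n_genotypes = c(w["n"], wo["n"]),
             row.names = c("with", "without"))
}
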