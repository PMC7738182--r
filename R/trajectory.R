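#' Iterate over all stepwise evolutionary trajectories
#'
#' A trajectory is an order in which the `n` substitutions are acquired one
#' at a time, i.e. a permutation; there are `n!` of them. The iterator yields
#' permutations of `1:n` in lexicographic order without materialising the
#' full list, so `n = 10` remains feasible.
#'
#' @param n Number of substitutions (1 to 12; the factorial guard).
#' @return A function: each call returns the next permutation as an integer
#'   vector, or `NULL` when exhausted.
#' @export
#' @examples
#' it <- enumerate_trajectories(3)
#' it()  # 1 2 3
#' it()  # 1 3 2
enumerate_trajectories <- function(n) {
  if (!is_count(n) || n < 1 || n > 12) {
    stopf("n must be an integer in 1..12 (%s! trajectories would be intractable)", n)
  }
  n <- as.integer(n)
  state <- NULL
  function() {
    if (is.null(state)) {
      state <<- seq_len(n)
      return(state)
    }
    nxt <- next_permutation(state)
    if (is.null(nxt)) return(NULL)
    state <<- nxt
    state
  }
}

# Classic next-lexicographic-permutation; NULL after the last one.
next_permutation <- function(p) {
  n <- length(p)
  i <- n - 1L
  while (i >= 1L && p[i] >= p[i + 1L]) i <- i - 1L
  if (i < 1L) return(NULL)
  j <- n
  while (p[j] <= p[i]) j <- j - 1L
  tmp <- p[i]; p[i] <- p[j]; p[j] <- tmp
  p[(i + 1L):n] <- rev(p[(i + 1L):n])
  p
}

#' Collect all trajectories into a matrix
#'
#' Convenience wrapper around [enumerate_trajectories()]; materialises all
#' `n!` permutations, so it is restricted to `n <= 8`.
#'
#' @inheritParams enumerate_trajectories
#' @return Integer matrix with `n!` rows.
#' @export
collect_trajectories <- function(n) {
  if (!is_count(n) || n < 1 || n > 8) stopf("collect_trajectories is limited to n <= 8")
  it <- enumerate_trajectories(n)
  out <- matrix(0L, nrow = factorial(n), ncol = n)
  k <- 0L
  while (!is.null(p <- it())) {
    k <- k + 1L
    out[k, ] <- p
  }
  out
}

#' Is a mutational step an improvement?
#'
#' A step from fitness `f_from` to `f_to` counts as improving when the
#' relative gain strictly exceeds the threshold: `f_to > f_from * (1 +
#' threshold)`. The default threshold of 0.16 treats a gain within the
#' average EC50 measurement error (16%) as no improvement; the inequality is
#' strict, so a gain of exactly 16% does not qualify.
#'
#' @param f_from,f_to Positive fold-improvement values.
#' @param threshold Relative improvement threshold (>= 0), default 0.16.
#' @return Logical vector.
#' @export
#' @examples
#' classify_step(1.0, 1.20)  # TRUE
#' classify_step(1.0, 1.16)  # FALSE (boundary, strict)
classify_step <- function(f_from, f_to, threshold = 0.16) {
  if (any(!is.finite(f_from) | f_from <= 0) || any(!is.finite(f_to) | f_to <= 0)) {
    stopf("fitness values must be positive and finite")
  }
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold < 0) {
    stopf("threshold must be a single nonnegative number")
  }
  f_to > f_from * (1 + threshold)
}

#' Count accessible evolutionary trajectories
#'
#' A trajectory is accessible when every one of its `n` steps is improving
#' under [classify_step()]. The count is computed by a dynamic program over
#' the subset lattice (number of monotone paths from the empty to the full
#' genotype using only improving edges), which is exact and avoids visiting
#' all `n!` orderings; the accessible orderings themselves are only
#' materialised when `list_accessible = TRUE`.
#'
#' @param landscape A complete [fitness_landscape()].
#' @param threshold Step rule threshold, see [classify_step()].
#' @param list_accessible Also return the accessible permutations (as a list
#'   of substitution-label vectors).
#' @return An object of class `trajectory_report`: list with `n`, `total`
#'   (`n!`), `accessible`, `fraction`, `threshold`, `greedy` (the greedy
#'   most-plausible path, see [greedy_plausible_path()]) and optionally
#'   `accessible_paths`.
#' @export
count_accessible <- function(landscape, threshold = 0.16, list_accessible = FALSE) {
  stopifnot(inherits(landscape, "fitness_landscape"))
  require_complete(landscape)
  n <- n_substitutions(landscape)
  fold <- landscape$fold_by_mask
  n_states <- 2^n
  bits <- bitwShiftL(1L, seq_len(n) - 1L)
  # paths[m + 1] = number of all-improving orderings reaching subset mask m
  paths <- numeric(n_states)
  paths[1] <- 1
  masks <- order(popcount(seq_len(n_states) - 1L))[-1] - 1L  # nonzero masks by popcount
  for (m in masks) {
    present <- which(bitwAnd(m, bits) != 0L)
    for (i in present) {
      prev <- bitwXor(m, bits[i])
      if (paths[prev + 1L] > 0 && classify_step(fold[prev + 1L], fold[m + 1L], threshold)) {
        paths[m + 1L] <- paths[m + 1L] + paths[prev + 1L]
      }
    }
  }
  acc <- paths[n_states]
  out <- list(n = n, total = factorial(n), accessible = acc,
              fraction = acc / factorial(n), threshold = threshold,
              greedy = greedy_plausible_path(landscape))
  if (list_accessible) {
    out$accessible_paths <- accessible_path_list(landscape, threshold)
  }
  structure(out, class = "trajectory_report")
}

# Depth-first enumeration of accessible orderings (label vectors).
accessible_path_list <- function(landscape, threshold) {
  n <- n_substitutions(landscape)
  fold <- landscape$fold_by_mask
  bits <- bitwShiftL(1L, seq_len(n) - 1L)
  labels <- landscape$substitutions$label
  paths <- list()
  recurse <- function(mask, order_idx) {
    if (length(order_idx) == n) {
      paths[[length(paths) + 1L]] <<- labels[order_idx]
      return(invisible(NULL))
    }
    for (i in setdiff(seq_len(n), order_idx)) {
      nxt <- bitwOr(mask, bits[i])
      if (classify_step(fold[mask + 1L], fold[nxt + 1L], threshold)) {
        recurse(nxt, c(order_idx, i))
      }
    }
  }
  recurse(0L, integer(0))
  paths
}

#' @export
print.trajectory_report <- function(x, ...) {
  cat(sprintf("Trajectory accessibility (n = %d, step rule: > %.0f%% gain)\n",
              x$n, 100 * x$threshold))
  cat(sprintf("accessible: %s of %s orderings (%.2f%%)\n",
              format(x$accessible, big.mark = ","),
              format(x$total, big.mark = ","), 100 * x$fraction))
  cat("greedy most-plausible path:\n")
  print(x$greedy, row.names = FALSE)
  invisible(x)
}

#' Greedy most-plausible evolutionary path
#'
#' Starting from wild type, repeatedly adds the remaining substitution whose
#' addition yields the highest mean fold-improvement of the resulting
#' genotype. This single rule covers both regimes: when some substitution
#' improves fitness the largest improvement is taken, and when none does the
#' smallest decrease is taken. Ties in resulting fitness are broken by the
#' lowest residue position.
#'
#' @param landscape A complete [fitness_landscape()].
#' @return Data frame with one row per step: `step`, `substitution`,
#'   `genotype`, `fold` (the fold of the genotype reached).
#' @export
greedy_plausible_path <- function(landscape) {
  stopifnot(inherits(landscape, "fitness_landscape"))
  require_complete(landscape)
  n <- n_substitutions(landscape)
  subs <- landscape$substitutions
  bits <- bitwShiftL(1L, seq_len(n) - 1L)
  fold <- landscape$fold_by_mask
  mask <- 0L
  remaining <- seq_len(n)
  steps <- data.frame(step = integer(0), substitution = character(0),
                      genotype = character(0), fold = numeric(0))
  for (s in seq_len(n)) {
    cand_fold <- fold[bitwOr(mask, bits[remaining]) + 1L]
    # which.max takes the first maximum; `remaining` is in ascending-position
    # order, so ties resolve to the lowest residue position
    pick <- remaining[which.max(cand_fold)]
    mask <- bitwOr(mask, bits[pick])
    remaining <- setdiff(remaining, pick)
    steps <- rbind(steps, data.frame(step = s, substitution = subs$label[pick],
                                     genotype = mask_to_genotype(mask, subs),
                                     fold = fold[mask + 1L]))
  }
  steps
}

#' Build the mutation network of a landscape
#'
#' The Hasse diagram of the subset lattice as a directed igraph: one node per
#' genotype (`2^n` nodes) and one edge for every single-substitution gain
#' (`n * 2^(n-1)` edges). Node attributes: `name` (canonical genotype),
#' `layer` (substitution count) and `fold`; edge attributes: `improving`
#' (from [classify_step()]), `delta` (fold difference) and `on_greedy_path`.
#'
#' @param landscape A complete [fitness_landscape()].
#' @param threshold Step rule threshold.
#' @param greedy Greedy path to flag; defaults to
#'   [greedy_plausible_path()] of the landscape. Must be a path over this
#'   landscape's substitutions.
#' @return An `igraph` directed graph.
#' @export
build_network <- function(landscape, threshold = 0.16, greedy = NULL) {
  stopifnot(inherits(landscape, "fitness_landscape"))
  require_complete(landscape)
  if (is.null(greedy)) greedy <- greedy_plausible_path(landscape)
  if (!is.data.frame(greedy) || !all(c("substitution", "genotype") %in% names(greedy)) ||
      nrow(greedy) != n_substitutions(landscape) ||
      !all(greedy$substitution %in% landscape$substitutions$label)) {
    stopf("greedy path does not belong to this landscape")
  }
  n <- n_substitutions(landscape)
  subs <- landscape$substitutions
  bits <- bitwShiftL(1L, seq_len(n) - 1L)
  fold <- landscape$fold_by_mask
  all_masks <- 0:(2^n - 1L)
  nodes <- vapply(all_masks, mask_to_genotype, "", subs = subs)
  from <- integer(0); to <- integer(0)
  for (m in all_masks) {
    absent <- which(bitwAnd(m, bits) == 0L)
    if (length(absent)) {
      from <- c(from, rep.int(m, length(absent)))
      to <- c(to, bitwOr(m, bits[absent]))
    }
  }
  improving <- classify_step(fold[from + 1L], fold[to + 1L], threshold)
  delta <- fold[to + 1L] - fold[from + 1L]
  # greedy chain of masks: WT, then each row's genotype
  greedy_masks <- c(0L, vapply(greedy$genotype, function(g) {
    attr(canonicalise_genotype(g, subs), "mask")
  }, integer(1)))
  greedy_edge <- paste(greedy_masks[-length(greedy_masks)], greedy_masks[-1])
  on_greedy <- paste(from, to) %in% greedy_edge
  g <- igraph::graph_from_data_frame(
    data.frame(from = nodes[from + 1L], to = nodes[to + 1L],
               delta = delta, improving = improving, on_greedy_path = on_greedy),
    directed = TRUE,
    vertices = data.frame(name = nodes, layer = popcount(all_masks),
                          fold = fold)
  )
  g
}

#' Export / import a mutation network
#'
#' Writes a mutation network (see [build_network()]) to GraphML or DOT (via
#' igraph's writers) or to a flat edge CSV with header
#' `from,to,delta,improving,on_greedy_path`. The edge CSV can be re-imported
#' with `import_edge_csv()`, reproducing the topology and the edge
#' attributes.
#'
#' @param network An `igraph` graph from [build_network()].
#' @param path Output file.
#' @param format One of `"graphml"`, `"dot"`, `"edge-csv"`.
#' @return Invisibly, `path`.
#' @export
export_network <- function(network, path, format = c("graphml", "dot", "edge-csv")) {
  stopifnot(igraph::is_igraph(network))
  format <- match.arg(format)
  if (format == "edge-csv") {
    el <- igraph::as_data_frame(network, what = "edges")
    need <- c("from", "to", "delta", "improving", "on_greedy_path")
    if (!all(need %in% names(el))) stopf("network lacks required edge attributes")
    utils::write.csv(el[, need], path, row.names = FALSE, quote = FALSE)
  } else {
    suppressWarnings(igraph::write_graph(network, path, format = format))
  }
  invisible(path)
}

#' @rdname export_network
#' @export
import_edge_csv <- function(path) {
  el <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(from = "character", to = "character"))
  need <- c("from", "to", "delta", "improving", "on_greedy_path")
  if (!all(need %in% names(el))) stopf("edge CSV must have columns %s",
                                       paste(need, collapse = ", "))
  el$improving <- as.logical(el$improving)
  el$on_greedy_path <- as.logical(el$on_greedy_path)
  igraph::graph_from_data_frame(el, directed = TRUE)
}
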