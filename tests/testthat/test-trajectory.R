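test_that("trajectory iterator yields n! distinct permutations in lexicographic order", {
  it <- enumerate_trajectories(3)
  expect_equal(it(), c(1, 2, 3))
  expect_equal(it(), c(1, 3, 2))
  expect_equal(it(), c(2, 1, 3))
  perms <- collect_trajectories(4)
  expect_equal(nrow(perms), 24)
  expect_equal(anyDuplicated(perms), 0L)
  one <- enumerate_trajectories(1)
  expect_equal(one(), 1L)
  expect_null(one())
  expect_error(enumerate_trajectories(0), "1..12")
  expect_error(enumerate_trajectories(13), "1..12")
})

test_that("step classification applies a strict relative threshold", {
  expect_true(classify_step(1.0, 1.20, 0.16))
  expect_false(classify_step(1.0, 1.16, 0.16))   # boundary, strict
  expect_true(classify_step(2.0, 2.40, 0.16))    # relative, not absolute
  expect_false(classify_step(2.0, 2.30, 0.16))
  expect_error(classify_step(0, 1), "positive")
  expect_error(classify_step(1, 1.5, -0.1), "nonnegative")
})

test_that("accessible-path count matches exhaustive brute force for n <= 5", {
  set.seed(101)
  for (n in 2:5) {
    labs <- paste0("A", seq_len(n) * 10, "G")
    genos <- c("WT", enumerate_intermediates(labs),
               paste(labs, collapse = "+"))
    for (rep in 1:3) {
      folds <- setNames(exp(rnorm(2^n, 0, 0.6)), genos)
      folds[["WT"]] <- 1
      ls <- toy_landscape(labs, folds)
      expect_equal(count_accessible(ls)$accessible, bf_count_accessible(ls),
                   info = sprintf("n=%d rep=%d", n, rep))
    }
  }
})

test_that("a multiplicative landscape with strong single effects is fully accessible", {
  ls <- multiplicative_landscape(c(A1G = 1.5, C2D = 1.5, E3F = 1.5, G4H = 1.5))
  rep <- count_accessible(ls)
  expect_equal(rep$accessible, factorial(4))
  expect_equal(rep$fraction, 1)
})

test_that("accessible trajectories start with the gating substitution", {
  spec <- landscape_spec(labels = paste0("A", (1:5) * 10, "G"),
                         effects = setNames(rep(log(1.5), 5), paste0("A", (1:5) * 10, "G")),
                         interactions = NULL, gate = "A30G", masking = 0,
                         replicates = 1, cv = 0)
  sim <- simulate_landscape(spec, seed = 1)
  rep <- count_accessible(sim$landscape, list_accessible = TRUE)
  expect_gt(rep$accessible, 0)
  expect_equal(length(rep$accessible_paths), rep$accessible)
  firsts <- vapply(rep$accessible_paths, `[`, "", 1L)
  expect_true(all(firsts == "A30G"))
})

test_that("greedy path maximises next-state fitness and handles downhill starts", {
  # multiplicative: substitutions picked in descending single-effect order
  ls <- multiplicative_landscape(c(A1G = 1.2, C2D = 2.0, E3F = 1.5))
  g <- greedy_plausible_path(ls)
  expect_equal(g$substitution, c("C2D", "E3F", "A1G"))
  expect_equal(g$fold, c(2.0, 3.0, 3.6))
  # no first step improves: start with the least-deleterious substitution
  subs <- c("A1G", "C2D", "E3F")
  genos <- c("WT", enumerate_intermediates(subs), "A1G+C2D+E3F")
  folds <- setNames(c(1, 0.5, 0.9, 0.7, 2.0, 1.5, 0.8, 3.0), genos)
  ls2 <- toy_landscape(subs, folds)
  g2 <- greedy_plausible_path(ls2)
  expect_equal(g2$substitution[1], "C2D")  # fold 0.9, the smallest decrease
  # ties broken by lowest residue position
  ls3 <- multiplicative_landscape(c(A1G = 1.5, C2D = 1.5))
  expect_equal(greedy_plausible_path(ls3)$substitution[1], "A1G")
})

test_that("greedy path is invariant to input row order", {
  sim <- simulate_landscape(landscape_spec(), seed = 5)
  df <- sim$landscape$data
  set.seed(9)
  shuffled <- df[sample(nrow(df)), ]
  ls2 <- fitness_landscape(sim$landscape$substitutions$label, shuffled)
  expect_equal(greedy_plausible_path(ls2), greedy_plausible_path(sim$landscape))
})

test_that("incomplete landscapes are rejected by lattice operations", {
  df <- data.frame(genotype = c("WT", "A1G", "C2D"), mean_fold = c(1, 2, 3),
                   sd = 0, n = 1)
  ls <- fitness_landscape(c("A1G", "C2D"), df)
  expect_false(ls$complete)
  expect_error(count_accessible(ls), "incomplete")
  expect_error(greedy_plausible_path(ls), "incomplete")
})

test_that("mutation network has the lattice node and edge structure", {
  sim <- simulate_landscape(landscape_spec(), seed = 2)
  net <- build_network(sim$landscape)
  expect_equal(igraph::vcount(net), 128)           # 2^7
  expect_equal(igraph::ecount(net), 7 * 2^6)       # n * 2^(n-1) = 448
  expect_equal(sum(igraph::E(net)$on_greedy_path), 7)
  expect_setequal(unique(igraph::V(net)$layer), 0:7)
  # improving flags agree with classify_step recomputed from the landscape
  el <- igraph::as_data_frame(net, "edges")
  f <- setNames(sim$landscape$data$mean_fold, sim$landscape$data$genotype)
  expect_equal(el$improving, unname(classify_step(f[el$from], f[el$to])))
  # a foreign greedy path is rejected
  other <- greedy_plausible_path(multiplicative_landscape(c(A1G = 2, C2D = 3)))
  expect_error(build_network(sim$landscape, greedy = other), "does not belong")
})

test_that("network exports round-trip through graphml and edge CSV", {
  sim <- simulate_landscape(landscape_spec(labels = paste0("A", (1:4) * 10, "G"),
                                           effects = setNames(log(c(1.5, 0.9, 2, 1.2)),
                                                              paste0("A", (1:4) * 10, "G")),
                                           interactions = NULL, gate = NULL,
                                           masking = 1, replicates = 2, cv = 0.1),
                            seed = 4)
  net <- build_network(sim$landscape)
  gml <- tempfile(fileext = ".graphml")
  export_network(net, gml, "graphml")
  back <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(back), igraph::vcount(net))
  expect_equal(igraph::ecount(back), igraph::ecount(net))
  expect_equal(sort(igraph::V(back)$fold), sort(igraph::V(net)$fold))
  expect_equal(sum(igraph::E(back)$improving), sum(igraph::E(net)$improving))

  csv <- tempfile(fileext = ".csv")
  export_network(net, csv, "edge-csv")
  back2 <- import_edge_csv(csv)
  expect_equal(igraph::vcount(back2), igraph::vcount(net))
  expect_equal(igraph::ecount(back2), igraph::ecount(net))
  el0 <- igraph::as_data_frame(net, "edges")
  el1 <- igraph::as_data_frame(back2, "edges")
  key0 <- order(el0$from, el0$to); key1 <- order(el1$from, el1$to)
  expect_equal(el1$improving[key1], el0$improving[key0])
  expect_equal(el1$on_greedy_path[key1], el0$on_greedy_path[key0])
  expect_equal(el1$delta[key1], el0$delta[key0])

  dot <- tempfile(fileext = ".dot")
  export_network(net, dot, "dot")
  lines <- readLines(dot)
  expect_equal(sum(grepl("^  [0-9]+ \\[$", lines)), igraph::vcount(net))
  expect_error(export_network(net, tempfile(), "gexf"))
})
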