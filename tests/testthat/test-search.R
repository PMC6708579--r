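# Heuristic searches, rearrangement neighbourhoods, resampling.

test_that("neighbour joining recovers additive trees exactly", {
  skip_if_not_installed("phangorn")
  set.seed(50)
  for (i in 1:20) {
    tr <- random_topology(paste0("s", 1:12), seed = 900 + i)
    tr$edge.length <- runif(nrow(tr$edge), 0.2, 2)
    d <- ape::cophenetic.phylo(tr)
    rec <- nj_tree(d)
    expect_equal(phangorn::RF.dist(rec, tr), 0)
  }
  # 3 taxa: the unique topology with three-point branch lengths
  d3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
               dimnames = list(LETTERS[1:3], LETTERS[1:3]))
  t3 <- nj_tree(d3)
  expect_equal(sort(t3$edge.length), c(1, 2, 3))
  expect_error(nj_tree(matrix(c(0, NA, NA, 0), 2, 2)), "NA")
})

test_that("rearrangement neighbourhoods have the expected structure", {
  tr <- random_topology(paste0("s", 1:6), seed = 3)
  nni <- nni_neighbours(tr)
  expect_length(nni, 2L * 3L)                    # 2 per internal edge
  for (nb in nni) expect_equal(robinson_foulds(nb, tr), 2L)
  spr <- spr_neighbours(tr)
  tbr <- tbr_neighbours(tr)
  expect_gte(length(spr), length(nni))
  expect_gte(length(tbr), length(spr))
  # every NNI topology occurs among the SPR topologies
  spr_keys <- vapply(spr, write_sorted_splits, "")
  for (nb in nni) expect_true(write_sorted_splits(nb) %in% spr_keys)
  # no neighbour equals the original tree
  expect_false(write_sorted_splits(tr) %in% vapply(tbr, write_sorted_splits, ""))
})

test_that("random addition is reproducible and exact at 3 species", {
  d <- random_dataset(5, 4, seed = 51, names_prefix = "s")
  scorer <- criterion_scorer(d, "scp")
  t1 <- random_addition_tree(d, scorer, seed = 5)
  t2 <- random_addition_tree(d, scorer, seed = 5)
  expect_equal(robinson_foulds(t1, t2), 0L)
  d3 <- random_dataset(3, 4, seed = 52, names_prefix = "s")
  t3a <- random_addition_tree(d3, criterion_scorer(d3, "scp"), seed = 1)
  t3b <- random_addition_tree(d3, criterion_scorer(d3, "scp"), seed = 99)
  expect_equal(robinson_foulds(t3a, t3b), 0L)
})

test_that("hill climbing is monotone and stops at local optima", {
  st <- signal_study(6, 10, seed = 53)
  scorer <- criterion_scorer(st$shapes, "scp")
  # exhaustive optimum over all 105 topologies
  topos <- all_topologies(st$tree$tip.label)
  vals <- vapply(topos, scorer, 0)
  opt <- min(vals)
  res <- swap_search(random_addition_tree(st$shapes, scorer, seed = 2),
                     scorer, move_set = "NNI", seed = 2)
  expect_true(all(diff(res$trace) < 0))
  # starting at the optimum leaves the tree unchanged
  best_tree <- topos[[which.min(vals)]]
  res2 <- swap_search(best_tree, scorer, move_set = "NNI", seed = 3)
  expect_equal(res2$value, opt, tolerance = 1e-12)
  expect_equal(robinson_foulds(res2$tree, best_tree), 0L)
  # one NNI away from the optimum, the climb recovers it
  near <- nni_neighbours(best_tree)[[1]]
  res3 <- swap_search(near, scorer, move_set = "NNI", seed = 4)
  expect_equal(res3$value, opt, tolerance = 1e-9)
})

test_that("criterion searches find the exhaustive optimum on 6 taxa", {
  st <- signal_study(6, 10, seed = 54)
  topos <- all_topologies(st$tree$tip.label)
  # squared-change parsimony
  sc <- criterion_scorer(st$shapes, "scp")
  expect_equal(scp_search(st$shapes, search_settings(3, seed = 1))$value,
               min(vapply(topos, sc, 0)), tolerance = 1e-9)
  # linear parsimony with TBR
  sl <- criterion_scorer(st$shapes, "lp")
  expect_equal(lp_search(st$shapes, search_settings(3, "TBR", seed = 1))$value,
               min(vapply(topos, sl, 0)), tolerance = 1e-9)
  # spatial parsimony (gpa mode)
  g <- grid_spec(2, 1, 1)
  sg <- criterion_scorer(st$shapes, "laup", grid = g)
  got <- laup_search(st$shapes, "gpa",
                     search_settings(2, "TBR", seed = 1, grid = g))
  expect_equal(got$value, min(vapply(topos, sg, 0)), tolerance = 1e-9)
  # providing the true tree as a start never worsens the result
  with_start <- laup_search(st$shapes, "gpa",
                            search_settings(2, "TBR", seed = 1, grid = g),
                            start_tree = st$tree)
  expect_lte(with_start$value, got$value + 1e-9)
})

test_that("search degenerates gracefully on zero-variance data", {
  d <- landmark_dataset("flat", lapply(setNames(1:4, paste0("s", 1:4)),
                                       function(i) matrix(1, 3, 3)))
  res <- scp_search(d, search_settings(2, seed = 1))
  expect_equal(res$value, 0)
  expect_equal(lp_search(d, search_settings(2, "NNI", seed = 1))$value, 0)
})

test_that("searches are reproducible under a seed", {
  st <- signal_study(6, 8, seed = 55)
  a <- scp_search(st$shapes, search_settings(2, seed = 42))
  b <- scp_search(st$shapes, search_settings(2, seed = 42))
  expect_equal(robinson_foulds(a$tree, b$tree), 0L)
  expect_equal(a$value, b$value)
})

test_that("landmark resampling has the declared statistical structure", {
  d <- random_dataset(4, 5, seed = 56)
  spec_b <- resampling_spec("bootstrap", replicates = 3, seed = 7)
  r1 <- resample_landmarks(d, spec_b, 1)
  r1b <- resample_landmarks(d, spec_b, 1)
  expect_identical(attr(r1, "landmark_index"), attr(r1b, "landmark_index"))
  expect_equal(r1$n_landmarks, d$n_landmarks)
  expect_equal(r1$species, d$species)
  expect_equal(r1$dims, d$dims)
  # symmetric mode: expected fraction of weight-1 landmarks is 1 - p
  p <- 0.33
  spec_s <- resampling_spec("symmetric", change_probability = p, seed = 8)
  big <- random_dataset(3, 200, seed = 57)
  frac1 <- vapply(1:50, function(b) {
    idx <- attr(resample_landmarks(big, spec_s, b), "landmark_index")
    mean(tabulate(idx, 200) == 1L)
  }, 0)
  n_total <- 200 * 50
  se <- sqrt(p * (1 - p) / n_total)
  expect_lt(abs(mean(frac1) - (1 - p)), 3 * se + 0.01)
})

test_that("bootstrap support separates signal from noise", {
  st <- signal_study(6, 20, seed = 58)
  light_search <- function(dat, seed) {
    scorer <- criterion_scorer(dat, "scp")
    swap_search(random_addition_tree(dat, scorer, seed = seed), scorer,
                move_set = "NNI", seed = seed)$tree
  }
  bs <- bootstrap_support(st$shapes, light_search,
                          resampling_spec("bootstrap", replicates = 20, seed = 9))
  sup <- attr(tree_splits(bs$consensus), "support")
  expect_true(all(sup >= 0 & sup <= 100))
  # strong signal: every true split at (essentially) full support
  expect_equal(robinson_foulds(bs$consensus, st$tree), 0L)
  expect_true(all(sup >= 95))
  # pure noise: the consensus collapses towards a star
  noise <- random_dataset(6, 20, seed = 59, names_prefix = "t")
  bs2 <- bootstrap_support(noise, light_search,
                           resampling_spec("bootstrap", replicates = 20, seed = 10))
  expect_lte(bs2$consensus$Nnode, 3L)
})
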