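# Criterion scoring: squared-change parsimony, linear parsimony, spatial
# landmark parsimony, Brownian maximum likelihood.

test_that("squared-change parsimony reproduces the hand-solved instances", {
  star <- parse_newick("(A,B,C);")
  s <- scp_score(star, toy_1d_dataset(list(A = 0, B = 3, C = 6)))
  expect_equal(s$value, 18)
  expect_equal(unname(s$ancestral_states[1, 1]), 3)
  quartet <- parse_newick("((A,B),(C,D));")
  s2 <- scp_score(quartet, toy_1d_dataset(list(A = 0, B = 2, C = 6, D = 8)))
  expect_equal(s2$value, 22)
  expect_equal(sort(s2$ancestral_states[, 1]), c(2.5, 5.5))
  # identical tips
  same <- toy_1d_dataset(list(A = 1, B = 1, C = 1, D = 1))
  expect_equal(scp_score(quartet, same)$value, 0)
  # reconstruction re-sums to the reported value
  expect_equal(sum(s2$branch_lengths), s2$value, tolerance = 1e-8)
})

test_that("squared-change parsimony matches a numeric-optimisation oracle", {
  set.seed(20)
  for (i in 1:25) {
    tr <- random_topology(paste0("s", 1:8), seed = 400 + i)
    d <- random_dataset(8, 5, seed = 500 + i, names_prefix = "s")
    expect_equal(scp_score(tr, d)$value, scp_oracle(tr, d), tolerance = 1e-6)
  }
})

test_that("linear parsimony reproduces the worked examples and the DP oracle", {
  star <- parse_newick("(A,B,C);")
  expect_equal(linear_parsimony_score(star, toy_1d_dataset(list(A = 0, B = 3, C = 6)))$value, 6)
  quartet <- parse_newick("((A,B),(C,D));")
  expect_equal(linear_parsimony_score(quartet,
    toy_1d_dataset(list(A = 0, B = 2, C = 6, D = 8)))$value, 8)
  expect_equal(linear_parsimony_score(quartet,
    toy_1d_dataset(list(A = 1, B = 1, C = 1, D = 1)))$value, 0)
  # 6-taxon integer instances against exhaustive enumeration
  set.seed(21)
  for (i in 1:10) {
    tr <- random_topology(paste0("s", 1:6), seed = 600 + i)
    vals <- sample(0:6, 6, replace = TRUE)
    d <- toy_1d_dataset(setNames(as.list(vals), paste0("s", 1:6)))
    expect_equal(linear_parsimony_score(tr, d)$value, lp_bruteforce_1d(tr, vals))
  }
})

test_that("linear parsimony interval and state-set routes agree on polytomies", {
  # a multifurcating tree goes down the Sankoff route; resolving it can only
  # lower the score, and on a star the score equals distance to the median
  star5 <- parse_newick("(A,B,C,D,E);")
  vals <- c(A = 0, B = 1, C = 5, D = 7, E = 10)
  d <- toy_1d_dataset(as.list(vals))
  expect_equal(linear_parsimony_score(star5, d)$value,
               sum(abs(vals - median(vals))))
})

test_that("spatial parsimony handles the boundary geometries exactly", {
  mk <- function(v) matrix(c(v, 0, 0), 1, 3)
  # two taxa: exact distance regardless of the grid
  d2 <- landmark_dataset("d2", list(A = mk(0), B = mk(2)))
  expect_equal(laup_score(parse_newick("(A,B);"), d2, grid_spec(3, 1, 1))$value, 2)
  # collinear 3-point star: middle point is the geometric median
  d3 <- landmark_dataset("d3", list(A = mk(0), B = mk(1), C = mk(2)))
  expect_equal(laup_score(parse_newick("(A,B,C);"), d3, grid_spec(2, 1, 1))$value, 2)
  # identical configurations score zero
  d0 <- landmark_dataset("d0", list(A = mk(1), B = mk(1), C = mk(1)))
  expect_equal(laup_score(parse_newick("(A,B,C);"), d0, grid_spec(4, 2, 1))$value, 0)
})

test_that("spatial parsimony converges from above to the continuous optimum", {
  set.seed(22)
  pts <- matrix(rnorm(9), 3, 3)
  d <- landmark_dataset("tri", list(A = pts[1, , drop = FALSE],
                                    B = pts[2, , drop = FALSE],
                                    C = pts[3, , drop = FALSE]))
  star <- parse_newick("(A,B,C);")
  opt <- sum_dist(pts, geometric_median(pts))
  scores <- vapply(c(2, 4, 8, 16, 32), function(g)
    laup_score(star, d, grid_spec(g, 1, 1))$value, 0)
  expect_true(all(diff(scores) <= 1e-9))         # monotone decreasing envelope
  expect_true(all(scores >= opt - 1e-9))         # bounded below by the optimum
  expect_lt(scores[5] - opt, 0.05)
  # nesting refines towards the same optimum and never increases the score
  s1 <- laup_score(star, d, grid_spec(4, 1, 1))$value
  s2 <- laup_score(star, d, grid_spec(4, 2, 1))$value
  s3 <- laup_score(star, d, grid_spec(4, 3, 1))$value
  expect_lte(s2, s1)
  expect_lte(s3, s2)
})

test_that("criterion scores are invariant to species and landmark permutation", {
  set.seed(23)
  d <- random_dataset(6, 4, seed = 99, names_prefix = "s")
  tr <- random_topology(paste0("s", 1:6), seed = 7)
  perm_sp <- landmark_dataset("p", d$data[sample(d$species), , , drop = FALSE])
  perm_lm <- landmark_dataset("q", d$data[, sample(d$n_landmarks), , drop = FALSE])
  for (f in list(function(x) scp_score(tr, x)$value,
                 function(x) linear_parsimony_score(tr, x)$value,
                 function(x) laup_score(tr, x, grid_spec(3, 1, 1))$value)) {
    expect_equal(f(perm_sp), f(d), tolerance = 1e-9)
    expect_equal(f(perm_lm), f(d), tolerance = 1e-9)
  }
})

test_that("Brownian ML matches the two-taxon closed form", {
  set.seed(24)
  XA <- matrix(rnorm(15), 5, 3); XB <- matrix(rnorm(15), 5, 3)
  d <- landmark_dataset("two", list(A = XA, B = XB))
  fit <- brownian_ml(parse_newick("(A,B);"), d)
  k <- 15
  vhat <- sum((XA - XB)^2) / k
  expect_equal(fit$branch_lengths, vhat, tolerance = 1e-8)
  expect_equal(fit$value, -0.5 * (k * log(2 * pi * vhat) + k), tolerance = 1e-8)
})

test_that("Brownian ML collapses branches between identical tips", {
  set.seed(25)
  X <- matrix(rnorm(12), 4, 3)
  d <- landmark_dataset("dup", list(A = X, B = X,
                                    C = matrix(rnorm(12), 4, 3),
                                    D = matrix(rnorm(12), 4, 3)))
  fit <- brownian_ml(parse_newick("((A,B),(C,D));"), d)
  expect_lt(min(fit$branch_lengths), 1e-6)
  expect_error(brownian_ml(parse_newick("(A,B,C,D);"), d), "binary")
})

test_that("true topology outscores random topologies under strong signal", {
  wins <- 0L; total <- 0L
  for (rep in 1:3) {
    st <- signal_study(8, 12, seed = 30 + rep)
    ll_true <- brownian_ml(st$tree, st$shapes)$value
    for (i in 1:15) {
      rt <- random_topology(st$tree$tip.label, seed = 800 + 20 * rep + i)
      if (robinson_foulds(rt, st$tree) == 0L) next
      total <- total + 1L
      if (ll_true >= brownian_ml(rt, st$shapes)$value) wins <- wins + 1L
    }
  }
  expect_gte(wins / total, 0.95)
})

test_that("dynamic alignment undoes a known rotation and never worsens the score", {
  # identical shapes on every tip, one terminal rotated: the reconstruction
  # pins the ancestors, so realignment must undo the rotation
  set.seed(40)
  tr <- ape::unroot(ape::rtree(5)); tr$edge.length <- rep(1, nrow(tr$edge))
  shape <- matrix(rnorm(30), 10, 3)
  shapes <- landmark_dataset("same", setNames(replicate(5, shape, simplify = FALSE),
                                              tr$tip.label))
  data <- shapes$data
  set.seed(41)
  R <- rand_rot()
  sp1 <- tr$tip.label[1]
  data[sp1, , ] <- matrix(data[sp1, , ], 10, 3) %*% R
  rotated <- landmark_dataset("rot", data)
  g <- grid_spec(4, 3, 1)
  before <- laup_score(tr, rotated, g)$value
  al <- dynamic_align(rotated, tr, g)
  expect_true(all(diff(al$trace) <= 0))
  expect_lte(al$score$value, before)
  # the realigned terminal is back on the common shape (up to residual grid error)
  resid <- opa_residual(matrix(al$dataset$data[sp1, , ], 10, 3), shape)
  expect_lt(resid, 1e-4)
  # re-aligning an already converged alignment changes nothing
  al0 <- dynamic_align(al$dataset, tr, g)
  expect_equal(al0$score$value, al$score$value, tolerance = 1e-6)
})
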