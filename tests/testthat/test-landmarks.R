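# Landmark processing: GPA, symmetrisation, repair, dataset assembly.

test_that("GPA is invariant to similarity transforms of the inputs", {
  set.seed(1)
  cfg <- matrix(rnorm(30), 10, 3)
  R <- rand_rot()
  sup <- gpa(list(cfg, cfg %*% R * 2 + 5, cfg %*% t(R) * 0.5 - 3))
  expect_lt(sup$total_variance, 1e-12)
  # invariants: centred members, unit centroid size, consensus = mean
  for (m in sup$members) {
    expect_lt(max(abs(colMeans(m))), 1e-9)
    expect_equal(sqrt(sum(scale(m, scale = FALSE)^2)), 1, tolerance = 1e-9)
  }
  expect_equal(sup$consensus, Reduce(`+`, sup$members) / 3, tolerance = 1e-12)
})

test_that("two-shape GPA residual matches the pairwise Procrustes oracle", {
  skip_if_not_installed("vegan")
  set.seed(2)
  for (i in 1:5) {
    a <- matrix(rnorm(24), 8, 3)
    # b is a rotated, perturbed copy of a so that the optimal orthogonal
    # alignment is a proper rotation (vegan also allows reflections)
    b <- (a + matrix(rnorm(24, sd = 0.1), 8, 3)) %*% rand_rot()
    sup <- gpa(list(a, b))
    resid <- sum((sup$members[[1]] - sup$members[[2]])^2)
    # vegan's symmetric Procrustes statistic on unit-size centred shapes
    ac <- scale(a, scale = FALSE); ac <- ac / sqrt(sum(ac^2))
    bc <- scale(b, scale = FALSE); bc <- bc / sqrt(sum(bc^2))
    ora <- vegan::procrustes(ac, bc, scale = FALSE, symmetric = FALSE)
    expect_equal(resid, ora$ss, tolerance = 1e-6)
  }
})

test_that("GPA consensus does not depend on input order", {
  set.seed(3)
  configs <- lapply(1:5, function(i) matrix(rnorm(18), 6, 3))
  s1 <- gpa(configs)
  s2 <- gpa(rev(configs))
  expect_lt(opa_residual(s1$consensus, s2$consensus), 1e-16)
})

test_that("replicate consensus recovers the true shape as noise shrinks", {
  set.seed(4)
  true_shape <- matrix(rnorm(36), 12, 3)
  errs <- vapply(c(1e-2, 1e-4), function(noise) {
    reps <- lapply(1:2, function(i) {
      x <- true_shape + matrix(rnorm(36, sd = noise), 12, 3)
      specimen_config("s", "sp", "carapace", c("a", "b")[i], x %*% rand_rot() + 3)
    })
    cons <- consensus_of_replicates(reps)
    opa_residual(cons$coords, true_shape)
  }, 0)
  expect_lt(errs[2], errs[1])
  expect_lt(errs[2], 1e-6)
  # identical replicates -> consensus equals either
  reps <- lapply(c("a", "b"), function(tg)
    specimen_config("s", "sp", "carapace", tg, true_shape))
  expect_lt(opa_residual(consensus_of_replicates(reps)$coords, true_shape), 1e-12)
  expect_warning(consensus_of_replicates(reps[1]), "single replicate")
})

# small bilateral definition table: 4 right, 4 left, 2 medial
small_defs <- function() {
  landmark_defs(data.frame(
    index = 1:10, name = paste0("lm", 1:10),
    side = c(rep("right", 4), rep("left", 4), "medial", "medial"),
    lobe = "none",
    pair_index = c(5:8, 1:4, NA, NA), excluded = FALSE))
}

# perfectly symmetric configuration about the x = 0 plane
symmetric_config <- function(seed = 5) {
  set.seed(seed)
  right <- cbind(abs(rnorm(4)) + 0.5, rnorm(4), rnorm(4))
  left <- right; left[, 1] <- -left[, 1]
  med <- cbind(0, rnorm(2), rnorm(2))
  specimen_config("sym", "sp", "carapace", "none", rbind(right, left, med))
}

test_that("symmetrising a symmetric shape returns its right side exactly", {
  cfg <- symmetric_config()
  out <- symmetrise(cfg, small_defs())
  expect_equal(nrow(out$coords), 6L)
  expect_equal(out$coords, cfg$coords[c(1:4, 9:10), ], tolerance = 1e-9)
})

test_that("symmetrisation removes injected asymmetry", {
  cfg <- symmetric_config()
  bumped <- cfg$coords
  bumped[5, ] <- bumped[5, ] + c(0.05, -0.03, 0.02)   # perturb one left landmark
  out <- symmetrise(specimen_config("s", "sp", "carapace", "none", bumped),
                    small_defs())
  ref <- symmetrise(cfg, small_defs())
  # averaging halves the perturbation of the paired landmark
  expect_lt(max(abs(out$coords - ref$coords)), 0.05)
  expect_gt(max(abs(out$coords - ref$coords)), 0)
})

test_that("built-in definition tables give the published landmark counts", {
  car <- builtin_definitions("carapace")
  pla <- builtin_definitions("plastron")
  expect_equal(nrow(car), 152L)
  expect_equal(nrow(pla), 52L)
  expect_length(retained_indices(car), 77L)
  expect_length(retained_indices(pla), 25L)
})

test_that("abnormality repair restores a displaced landmark", {
  cfg <- symmetric_config()
  broken <- cfg$coords
  broken[2, ] <- broken[2, ] + c(0.5, 0.5, -0.4)
  rep_cfg <- repair_abnormalities(
    specimen_config("s", "sp", "carapace", "none", broken), small_defs(),
    dont_use = 2L)
  expect_lt(max(abs(rep_cfg$coords[2, ] - cfg$coords[2, ])), 1e-9)
  # empty repair table is the identity
  same <- repair_abnormalities(cfg, small_defs(), integer(0))
  expect_identical(same$coords, cfg$coords)
  # flagged landmark on a symmetric shape maps to itself
  fixed <- repair_abnormalities(cfg, small_defs(), dont_use = 3L)
  expect_lt(max(abs(fixed$coords - cfg$coords)), 1e-9)
})

test_that("lobe splitting partitions a symmetrised plastron per the definitions", {
  pla <- builtin_definitions("plastron")
  set.seed(6)
  # synthetic symmetric plastron over the full 52-landmark layout
  coords <- matrix(rnorm(52 * 3), 52, 3)
  right <- pla$index[pla$side == "right"]
  for (i in right) {
    j <- pla$pair_index[pla$index == i]
    coords[j, ] <- coords[i, ] * c(-1, 1, 1)
  }
  coords[pla$index[pla$side == "medial"], 1] <- 0
  coords[pla$side == "right", 1] <- abs(coords[pla$side == "right", 1]) + 0.2
  for (i in right) {
    j <- pla$pair_index[pla$index == i]
    coords[j, ] <- coords[i, ] * c(-1, 1, 1)
  }
  cfg <- specimen_config("p1", "sp", "plastron", "none", coords)
  sym <- symmetrise(cfg, pla)
  expect_equal(nrow(sym$coords), 25L)
  lobes <- split_lobes(sym, pla)
  expect_equal(nrow(lobes$anterior$coords), 14L)
  expect_equal(nrow(lobes$posterior$coords), 11L)
  # landmark 1 (medial, anterior) goes to the anterior lobe
  expect_true(1L %in% attr(lobes$anterior, "retained"))
})

test_that("dataset assembly concatenates blocks on the species intersection", {
  set.seed(7)
  mk_block <- function(spp, p) {
    out <- lapply(spp, function(s) matrix(rnorm(p * 3), p, 3))
    names(out) <- spp
    out
  }
  car <- mk_block(c("A", "B", "C"), 77)
  ant <- mk_block(c("B", "C", "D"), 14)
  post <- mk_block(c("B", "C", "D"), 11)
  plastron <- assemble_dataset("plastron", list(anterior_lobe = ant,
                                                posterior_lobe = post))
  expect_equal(plastron$n_landmarks, 25L)
  shell <- assemble_dataset("shell", list(carapace = car, anterior_lobe = ant,
                                          posterior_lobe = post))
  expect_equal(shell$n_landmarks, 102L)
  expect_equal(shell$species, c("B", "C"))
  expect_error(assemble_dataset("x", list(a = mk_block("A", 3), b = mk_block("B", 3))),
               "empty species intersection")
})

test_that("Procrustes distances and total variance behave as defined", {
  set.seed(8)
  base <- matrix(rnorm(15), 5, 3)
  shifted <- base; shifted[1, 1] <- shifted[1, 1] + 0.25
  d <- landmark_dataset("toy", list(A = base, B = base, C = shifted))
  dm <- procrustes_distance_matrix(d)
  expect_equal(dm["A", "B"], 0)
  expect_equal(dm["A", "C"], 0.25)
  expect_equal(dm, t(dm))
  expect_equal(diag(dm), c(A = 0, B = 0, C = 0))
  # brute-force agreement
  flat <- t(vapply(d$species, function(s) as.vector(t(d$data[s, , ])), numeric(15)))
  expect_equal(unname(dm), unname(as.matrix(dist(flat))), tolerance = 1e-12)
  # variance: identical species -> 0
  d0 <- landmark_dataset("same", list(A = base, B = base))
  expect_equal(total_variance(d0), 0)
  expect_error(total_variance(landmark_dataset("one", list(A = base))),
               "at least 2")
})

test_that("species consensus error shrinks with sample size", {
  set.seed(9)
  true_shape <- matrix(rnorm(24), 8, 3)
  cons_err <- vapply(c(2L, 16L), function(ns) {
    cfgs <- lapply(seq_len(ns), function(i)
      specimen_config(paste0("s", i), "sp", "carapace", "none",
                      (true_shape + matrix(rnorm(24, sd = 0.05), 8, 3)) %*% rand_rot()))
    opa_residual(species_consensus(cfgs)$sp, true_shape)
  }, 0)
  expect_lt(cons_err[2], cons_err[1])
})

test_that("dataset CSV export round-trips exactly", {
  set.seed(10)
  d <- random_dataset(4, 6)
  path <- withr::local_tempfile(fileext = ".csv")
  write_dataset_csv(d, path)
  back <- read_dataset_csv(path)
  expect_identical(unname(back$data), unname(d$data))
  expect_equal(back$species, d$species)
})
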