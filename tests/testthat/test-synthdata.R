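# Brownian study generator: moments, determinism, file round-trips.

test_that("Brownian simulation has the right first and second moments", {
  # two sister tips at equal depth v: E[(x_a - x_b)^2] = 2 * rate * v
  tr <- parse_newick("(A:0.5,B:0.5);")
  tr$edge.length <- c(0.5, 0.5)
  rate <- 1.3
  nrep <- 3000
  sq <- vapply(seq_len(nrep), function(i) {
    spec <- simulation_spec(tr, n_landmarks = 3, rate = rate,
                            replicate_noise_sd = 0, seed = 5000 + i)
    sh <- simulate_species_shapes(spec)
    mean((sh$data["A", , ] - sh$data["B", , ])^2)
  }, 0)
  expected <- 2 * rate * 0.5
  se <- sd(sq) / sqrt(nrep)
  expect_lt(abs(mean(sq) - expected), 3 * se)
})

test_that("shared history induces covariance proportional to shared path", {
  # ((A,B),C): A and B share the root-to-MRCA path, C splits at the root
  tr <- ape::read.tree(text = "((A:0.2,B:0.2):0.8,C:1.0);")
  nrep <- 2000
  diffs <- t(vapply(seq_len(nrep), function(i) {
    spec <- simulation_spec(tr, n_landmarks = 3, rate = 1,
                            replicate_noise_sd = 0, seed = 7000 + i)
    sh <- simulate_species_shapes(spec)
    c(ab = mean((sh$data["A", , ] - sh$data["B", , ])^2),
      ac = mean((sh$data["A", , ] - sh$data["C", , ])^2))
  }, c(ab = 0, ac = 0)))
  # E[d_ab^2] = 2*0.2 = 0.4; E[d_ac^2] = 0.2 + 1.0 + 0.8 = 2.0
  expect_lt(abs(mean(diffs[, "ab"]) - 0.4), 3 * sd(diffs[, "ab"]) / sqrt(nrep))
  expect_lt(abs(mean(diffs[, "ac"]) - 2.0), 3 * sd(diffs[, "ac"]) / sqrt(nrep))
})

test_that("rate zero collapses every species onto the root shape", {
  tr <- ape::rtree(5); tr$edge.length <- tr$edge.length + 0.2
  spec <- simulation_spec(tr, n_landmarks = 8, rate = 1e-12,
                          replicate_noise_sd = 0, seed = 8)
  sh <- simulate_species_shapes(spec)
  flat <- vapply(sh$species, function(s) as.vector(sh$data[s, , ]), numeric(24))
  expect_lt(max(apply(flat, 1, sd)), 1e-5)
})

test_that("contrast-based rate estimation recovers the simulated rate", {
  set.seed(96)
  tr <- ape::rtree(20); tr$edge.length <- tr$edge.length + 0.3
  rate <- 2.5
  spec <- simulation_spec(tr, n_landmarks = 30, rate = rate,
                          replicate_noise_sd = 0, seed = 97)
  sh <- simulate_species_shapes(spec)
  # standard PIC estimator per coordinate, averaged over 90 coordinates
  est <- mean(vapply(seq_len(30 * 3), function(j) {
    lm <- (j - 1) %/% 3 + 1; ax <- (j - 1) %% 3 + 1
    mean(ape::pic(sh$data[tr$tip.label, lm, ax], tr)^2)
  }, 0))
  expect_lt(abs(est - rate) / rate, 0.15)
})

test_that("studies regenerate bit for bit from their manifest", {
  tr <- ape::rtree(4); tr$edge.length <- tr$edge.length + 0.2
  spec <- simulation_spec(tr, n_landmarks = 6, bilateral = TRUE, seed = 99)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  s1 <- emit_study(spec, d1)
  man <- jsonlite::read_json(s1$paths$manifest)
  tr2 <- parse_newick(man$tree)
  # newick branch lengths are rounded on output; the manifest carries them
  # at full precision in edge order
  tr2$edge.length <- as.numeric(unlist(man$edge_lengths))
  spec2 <- simulation_spec(tr2, n_landmarks = man$n_landmarks,
                           dims = man$dims, rate = man$rate,
                           replicate_noise_sd = man$replicate_noise_sd,
                           n_specimens_per_species = man$n_specimens_per_species,
                           n_replicates_per_specimen = man$n_replicates_per_specimen,
                           bilateral = man$bilateral, n_medial = man$n_medial,
                           asymmetry_sd = man$asymmetry_sd, seed = man$seed)
  s2 <- emit_study(spec2, d2)
  expect_identical(readLines(s1$paths$tps), readLines(s2$paths$tps))
  expect_identical(readLines(s1$paths$defs), readLines(s2$paths$defs))
  # file inventory: specimens x replicates records in the TPS
  n_rec <- length(grep("^LM", readLines(s1$paths$tps)))
  expect_equal(n_rec, 4L * spec$n_specimens_per_species *
                 spec$n_replicates_per_specimen)
})

test_that("the full bilateral pipeline recovers the simulated shapes", {
  set.seed(98)
  tr <- ape::rtree(5); tr$edge.length <- tr$edge.length + 0.5
  spec <- simulation_spec(tr, n_landmarks = 12, rate = 1,
                          replicate_noise_sd = 0, bilateral = TRUE, seed = 13)
  study <- emit_study(spec, withr::local_tempdir())
  configs <- read_tps(study$paths$tps, structure = "synthetic",
                      species = morphotree:::specimen_species_map(study$specimens$configs))
  ds <- morphotree:::process_bilateral(configs, study$specimens$defs)
  err0 <- max(vapply(ds$species, function(s)
    opa_residual(matrix(ds$data[s, , ], 12, 3),
                 matrix(study$shapes$data[s, , ], 12, 3)), 0))
  expect_lt(err0, 1e-8)
  # with replicate noise the residual grows but stays O(noise)
  spec_n <- simulation_spec(tr, n_landmarks = 12, rate = 1,
                            replicate_noise_sd = 0.02, bilateral = TRUE, seed = 13)
  study_n <- emit_study(spec_n, withr::local_tempdir())
  cfg_n <- read_tps(study_n$paths$tps, structure = "synthetic",
                    species = morphotree:::specimen_species_map(study_n$specimens$configs))
  ds_n <- morphotree:::process_bilateral(cfg_n, study_n$specimens$defs)
  err_n <- max(vapply(ds_n$species, function(s)
    opa_residual(matrix(ds_n$data[s, , ], 12, 3),
                 matrix(study_n$shapes$data[s, , ], 12, 3)), 0))
  expect_gt(err_n, err0)
  expect_lt(err_n, 0.02)
})

test_that("an injected abnormality is fixed by reflection repair", {
  set.seed(100)
  tr <- ape::rtree(4); tr$edge.length <- tr$edge.length + 0.5
  ab <- list(list(specimen = paste0(tr$tip.label[1], "_s1"),
                  landmark = 2L, offset = c(0.6, -0.4, 0.5)))
  spec <- simulation_spec(tr, n_landmarks = 10, rate = 1,
                          replicate_noise_sd = 0.005, bilateral = TRUE,
                          abnormalities = ab, seed = 101)
  shapes <- simulate_species_shapes(spec)
  made <- make_specimens(shapes, spec)
  sp1 <- tr$tip.label[1]
  run_pipe <- function(repairs) {
    cons <- morphotree:::replicate_consensus_all(made$configs)
    cons <- lapply(cons, function(cfg) {
      fix <- repairs[[cfg$specimen_id]]
      if (!is.null(fix)) repair_abnormalities(cfg, made$defs, fix) else cfg
    })
    sym <- lapply(cons, symmetrise, defs = made$defs)
    spp <- species_consensus(sym)
    opa_residual(spp[[sp1]], matrix(shapes$data[sp1, , ], 10, 3))
  }
  err_raw <- run_pipe(list())
  err_fixed <- run_pipe(setNames(list(2L), paste0(sp1, "_s1")))
  expect_lt(err_fixed, err_raw)
})

test_that("convergent shifts shared by distant clades mislead inference", {
  set.seed(102)
  tr <- ape::unroot(ape::rtree(10)); tr$edge.length <- tr$edge.length + 0.4
  tips <- tr$tip.label
  base <- simulation_spec(tr, n_landmarks = 15, rate = 0.3,
                          replicate_noise_sd = 0, seed = 103)
  shift <- rnorm(15 * 3, sd = 1.2)
  conv <- simulation_spec(tr, n_landmarks = 15, rate = 0.3,
                          replicate_noise_sd = 0, seed = 103,
                          convergence = list(list(tips = tips[c(1, 2, 9, 10)],
                                                  shift = shift)))
  ta_of <- function(spec) {
    sh <- simulate_species_shapes(spec)
    fit <- scp_search(sh, search_settings(2, seed = 5))
    obs <- quartet_conflict(tr, fit$tree)
    nulls <- vapply(1:100, function(i)
      quartet_conflict(tr, random_topology(tips, seed = 6000 + i)), 0)
    (median(nulls) - obs) / median(nulls)
  }
  expect_lt(ta_of(conv), ta_of(base))
})
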