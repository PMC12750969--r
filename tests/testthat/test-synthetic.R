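test_that("pure-birth trees are normalized, reproducible, ultrametric", {
  t3 <- simulate_tree(3, seed = 91)
  expect_equal(ape::Ntip(t3), 3L)
  expect_equal(max(ape::node.depth.edgelength(t3)), 1, tolerance = 1e-12)

  a <- ape::write.tree(simulate_tree(12, seed = 92))
  b <- ape::write.tree(simulate_tree(12, seed = 92))
  expect_identical(a, b)

  big <- simulate_tree(1000, seed = 93)
  depths <- ape::node.depth.edgelength(big)[seq_len(1000)]
  expect_lt(max(abs(depths - 1)), 1e-9)
})

test_that("a zero-variance simulation collapses to one shape after GPA", {
  truth <- simulation_truth(n_species = 8, positions = "CF", seed = 94,
                            sigma_bm = 0, sigma_noise = 0,
                            speed_effect = 0, hunting_effect = 0)
  sim <- simulate_dataset(truth, seed = 95)
  blk <- generalized_procrustes(subset_position(sim$dataset, "CF"))
  n <- dim(blk$aligned)[3]
  for (i in seq_len(n - 1))
    expect_lt(procrustes_distance(blk$aligned[, , i], blk$aligned[, , n],
                                  tol = 1e-6), 1e-9)
})

test_that("generated files are re-readable with identical coordinates", {
  truth <- simulation_truth(n_species = 6, positions = c("CF", "LF"),
                            seed = 96)
  dir <- withr::local_tempdir()
  sim <- simulate_dataset(truth, n_specimens_per_species = c(1, 2),
                          seed = 97, dir = dir)
  expect_true(all(file.exists(sim$files)))
  back <- read_morphologika(sim$files[["landmarks"]])
  expect_length(back, length(sim$dataset))
  for (i in seq_len(length(back)))
    expect_identical(back$configurations[[i]]$coords,
                     sim$dataset$configurations[[i]]$coords)
  eco <- read_ecology_table(sim$files[["ecology"]])
  expect_equal(eco$species, sim$ecology$species)
  tree <- read_newick(sim$files[["tree"]])
  expect_equal(sort(tree$tip.label), sort(truth$species))
  truth_json <- jsonlite::read_json(sim$files[["truth"]])
  expect_equal(truth_json$sigma_bm, truth$sigma_bm)
})

test_that("effect vectors are pure shape displacements", {
  truth <- simulation_truth(n_species = 6, positions = "LF", seed = 98)
  base <- truth$base_shapes[["LF"]]
  p <- nrow(base)
  for (vec in c(truth$effects$LF$speed, truth$effects$LF$hunting)) {
    m <- matrix(vec, ncol = 3)
    expect_lt(max(abs(colSums(m))), 1e-9)           # no translation
    expect_lt(abs(sum(vec * as.vector(base))), 1e-9) # no scale at base shape
  }
  for (vec in truth$effects$LF$speed)
    expect_equal(sqrt(sum(vec^2)), truth$speed_effect, tolerance = 1e-9)
  for (vec in truth$effects$LF$hunting)
    expect_equal(sqrt(sum(vec^2)), truth$hunting_effect, tolerance = 1e-9)
})

test_that("a noiseless pseudo-fossil is assigned to its own group", {
  truth <- simulation_truth(n_species = 18, positions = "LF", seed = 99,
                            sigma_bm = 0.01, sigma_noise = 0.002,
                            speed_effect = 0.08)
  sim <- simulate_dataset(truth, seed = 100)
  blk <- species_mean_shapes(
    generalized_procrustes(subset_position(sim$dataset, "LF")))
  sp <- fit_pca(blk)
  grp <- factor(sim$ecology$speed[match(blk$specimen_ids,
                                        sim$ecology$species)])
  model <- cva_from_space(sp, grp)
  fossil <- make_pseudofossil(truth, "slow", "LF", sigma_noise = 0,
                              seed = 101)
  pred <- membership_probabilities(model, project_external(model, fossil),
                                   position = "LF", category_set = "speed")
  expect_equal(pred$predicted, "slow")
  expect_equal(which.min(pred$mahalanobis_d2),
               which.max(pred$probability))
  expect_error(make_pseudofossil(truth, "arboreal"), "unknown group")
})

test_that("posterior for the true group decays with fossil noise", {
  truth <- simulation_truth(n_species = 18, positions = "LF", seed = 102,
                            sigma_bm = 0.01, sigma_noise = 0.002,
                            speed_effect = 0.08)
  sim <- simulate_dataset(truth, seed = 103)
  blk <- species_mean_shapes(
    generalized_procrustes(subset_position(sim$dataset, "LF")))
  sp <- fit_pca(blk)
  grp <- factor(sim$ecology$speed[match(blk$specimen_ids,
                                        sim$ecology$species)])
  model <- cva_from_space(sp, grp)
  med_post <- vapply(c(0, 0.01, 0.05), function(ns) {
    post <- vapply(1:100, function(s) {
      f <- make_pseudofossil(truth, "fast", "LF", sigma_noise = ns,
                             seed = 200 + s)
      pr <- membership_probabilities(model, project_external(model, f))
      unname(pr$probability[model$group_labels == "fast"])
    }, numeric(1))
    stats::median(post)
  }, numeric(1))
  expect_true(all(diff(med_post) <= 1e-9))
})

test_that("speed signal dominates when only speed effects are simulated", {
  wins <- 0L
  for (rep in 1:12) {
    truth <- simulation_truth(n_species = 15, positions = "TM",
                              seed = 300 + rep,
                              sigma_bm = 0.02, sigma_noise = 0.005,
                              speed_effect = 0.1, hunting_effect = 0)
    sim <- simulate_dataset(truth, seed = 400 + rep)
    blk <- species_mean_shapes(
      generalized_procrustes(subset_position(sim$dataset, "TM")))
    Y <- t(sapply(seq_len(dim(blk$aligned)[3]),
                  function(i) as.vector(blk$aligned[, , i])))
    rownames(Y) <- blk$specimen_ids
    C <- bm_covariance(truth$tree, blk$specimen_ids)
    r2s <- pgls_fit(Y, factor(truth$speed[blk$specimen_ids]), C,
                    n_perm = 0)$r_squared
    r2h <- pgls_fit(Y, factor(truth$hunting[blk$specimen_ids]), C,
                    n_perm = 0)$r_squared
    if (r2s > r2h) wins <- wins + 1L
  }
  expect_gte(wins, 11L)
})
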