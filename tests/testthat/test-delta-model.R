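test_that("descriptors vanish without neighbours and beyond the cutoff", {
  lone <- atoms("O", matrix(0, 1, 3))
  expect_equal(max(abs(featurize(lone))), 0)
  far <- atoms(c("O", "O"), rbind(c(0, 0, 0), c(4.5, 0, 0)))
  expect_equal(max(abs(featurize(far))), 0)
  near <- atoms(c("O", "O"), rbind(c(0, 0, 0), c(3.0, 0, 0)))
  expect_gt(max(abs(featurize(near))), 0)
})

test_that("descriptors are rotation and permutation invariant", {
  cl <- rand_cluster(6, seed = 14)
  G <- featurize(cl)
  withr::with_seed(15, {
    for (k in 1:3) {
      R <- rand_rotation()
      rot <- atoms(cl$elements, t(R %*% t(cl$positions)))
      expect_equal(featurize(rot), G, tolerance = 1e-10)
    }
  })
  # permuting atoms permutes rows but leaves per-element sums unchanged
  perm <- withr::with_seed(16, sample(length(cl$elements)))
  shuf <- atoms(cl$elements[perm], cl$positions[perm, ])
  Gs <- featurize(shuf)
  o1 <- cl$elements == "O"; o2 <- shuf$elements == "O"
  expect_equal(colSums(Gs[o2, ]), colSums(G[o1, ]), tolerance = 1e-10)
  expect_equal(colSums(Gs[!o2, ]), colSums(G[!o1, ]), tolerance = 1e-10)
})

test_that("zero labels give a zero model", {
  ds <- build_cluster_dataset(source126(),
    carve_spec(radii = c(2.5, 3.5), counts = c(30, 30), seed = 9))
  ds$labels <- rep(0, length(ds))
  m <- delta_fit(ds)
  expect_equal(max(abs(m$coefficients)), 0, tolerance = 1e-12)
  expect_equal(m$report$rmse_per_mol_val, 0, tolerance = 1e-12)
  f <- source126()$frames[[10]]
  pr <- predict(m, f)
  expect_equal(pr$energy, 0, tolerance = 1e-12)
  expect_equal(max(abs(pr$forces)), 0)
})

test_that("a planted linear law is recovered essentially exactly", {
  ds <- build_cluster_dataset(source126(),
    carve_spec(radii = c(2.5, 3.5), counts = c(120, 120), seed = 10))
  desc <- descriptor_spec()
  X <- t(vapply(ds$clusters, deltamd:::.design_row,
                numeric(2 * deltamd:::.n_feat(desc) + 1), spec = desc))
  w_true <- withr::with_seed(17, rnorm(ncol(X), sd = 0.01))
  ds$labels <- drop(X %*% w_true) + 0.3
  m <- delta_fit(ds, desc, lambda = 1e-10)
  expect_lt(m$report$rmse_per_mol_val, 1e-8)
  # prediction reproduces the planted law on an unseen cluster
  cl <- carve_cluster(source126()$frames[[149]], 60, 3.5)
  x_new <- deltamd:::.design_row(cl, desc)
  expect_equal(predict(m, cl)$energy, sum(x_new * w_true) + 0.3,
               tolerance = 1e-6)
})

test_that("angular channels capture the three-body content radial ones miss", {
  ds <- subset_dataset(dataset55(), 3.5)
  m_full <- delta_fit(ds)
  m_rad <- delta_fit(ds, descriptor_spec(zeta = numeric(0),
                                         lambda = numeric(0),
                                         eta = numeric(0)))
  expect_lt(m_full$report$rmse_per_mol_val, m_rad$report$rmse_per_mol_val)
})

test_that("lambda = 0 on a singular system suggests regularisation", {
  ds <- build_cluster_dataset(source126(),
    carve_spec(radii = 2.5, counts = 8, seed = 12))
  ds$labels <- rnorm(8)
  expect_error(delta_fit(ds, lambda = 0), "lambda")
})

test_that("model forces are the exact gradient, on clusters and in the box", {
  m <- model55()
  cl <- rand_cluster(8, seed = 19, spread = 3.5)
  res <- predict(m, cl)
  expect_lt(fd_force_error(cl, function(c) predict(m, c)$energy,
                           res$forces, h = 1e-4), 1e-5)
  fr <- source126()$frames[[120]]
  resb <- predict(m, fr)
  expect_lt(fd_force_error(fr, function(c) predict(m, c)$energy,
                           resb$forces, h = 1e-4, n_atoms = 4), 1e-5)
  expect_lt(max(abs(colSums(resb$forces))), 1e-8)
})

test_that("predictions are local: a remote molecule adds only itself", {
  # beyond the cutoff, a new molecule contributes only its per-molecule
  # constant and its own (zero-neighbour) features: E(joint) - E(cluster)
  # equals E(monomer) minus the model's global offset
  m <- model55()
  cl <- rand_cluster(5, seed = 20, spread = 3)
  e0 <- predict(m, cl)$energy
  far_pos <- ideal_monomer()$positions + rep(c(40, 0, 0), each = 3)
  joint <- atoms(c(cl$elements, "O", "H", "H"), rbind(cl$positions, far_pos))
  mono <- atoms(c("O", "H", "H"), far_pos)
  expect_equal(predict(m, joint)$energy - e0,
               predict(m, mono)$energy - m$econst0, tolerance = 1e-9)
})

test_that("permuting atoms leaves the predicted energy unchanged", {
  m <- model35()
  cl <- rand_cluster(7, seed = 21)
  e0 <- predict(m, cl)$energy
  perm <- withr::with_seed(22, sample(length(cl$elements)))
  shuf <- atoms(cl$elements[perm], cl$positions[perm, ])
  expect_equal(predict(m, shuf)$energy, e0, tolerance = 1e-10)
})

test_that("models survive JSON serialisation", {
  m <- model55()
  f <- tempfile(fileext = ".json")
  write_delta_model(m, f)
  m2 <- read_delta_model(f)
  fr <- source126()$frames[[60]]
  expect_equal(predict(m2, fr)$energy, predict(m, fr)$energy,
               tolerance = 1e-10)
  expect_equal(m2$vO, m$vO, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("unknown elements are rejected", {
  m <- model35()
  ar <- atoms("Ar", matrix(0, 1, 3))
  expect_error(predict(m, ar))
})

test_that("the model transfers from clusters to the periodic bulk", {
  # the delta-learning premise: a model trained only on open clusters (up
  # to 5.5 A cumulative) reproduces the periodic bulk correction
  m <- model55()
  th <- two_level_theory()
  frames <- source126()$frames[round(seq(11, 151, length.out = 20))]
  pred <- vapply(frames, function(f) predict(m, f)$energy, 0)
  truth <- vapply(frames, function(f)
    evaluate_potential(th, f, "delta")$energy, 0)
  expect_lt(sqrt(mean((pred - truth)^2)), 0.10 * sd(truth))
  expect_gt(cor(pred, truth), 0.99)
})
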