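test_that("carving keeps whole molecules by the centre-O inclusion rule", {
  # hand-built 2-molecule box with O-O distance 3.0 A
  dim <- water_dimer(3.0, cell = 13.0)
  expect_equal(carve_cluster(dim, 1, 2.9)$info$n_mol, 1)
  expect_equal(carve_cluster(dim, 1, 3.1)$info$n_mol, 2)
  # a radius below the nearest O-O distance returns just the centre
  wb <- water_box(72, seed = 2)
  cl <- carve_cluster(wb, 5, 1.5)
  expect_equal(cl$info$n_mol, 1)
  expect_false(cl$periodic)
  # centre O at the origin
  expect_equal(cl$positions[1, ], c(0, 0, 0))
})

test_that("carved clusters match brute-force neighbour counting", {
  src <- source126()
  frames <- src$frames[seq(5, 150, by = 5)]
  withr::with_seed(33, {
    cases <- data.frame(f = sample(length(frames), 100, replace = TRUE),
                        c = sample(126, 100, replace = TRUE),
                        r = runif(100, 1.5, 5.5))
  })
  for (k in seq_len(nrow(cases))) {
    fr <- frames[[cases$f[k]]]
    topo <- identify_molecules(fr)
    cl <- carve_cluster(fr, cases$c[k], cases$r[k], topology = topo)
    # brute force: minimum-image O-O distances
    po <- fr$positions[topo$o_index, ]
    d <- minimum_image(sweep(po, 2, po[cases$c[k], ]), fr$cell)
    expect_equal(cl$info$n_mol, sum(sqrt(rowSums(d^2)) <= cases$r[k]))
    # whole molecules, neutral composition
    expect_equal(length(cl$elements) %% 3, 0)
    expect_equal(sum(cl$elements == "H"), 2 * sum(cl$elements == "O"))
  }
})

test_that("clusters are nested under growing radii", {
  fr <- source126()$frames[[50]]
  topo <- identify_molecules(fr)
  mols_at <- function(r) {
    po <- fr$positions[topo$o_index, ]
    d <- minimum_image(sweep(po, 2, po[7, ]), fr$cell)
    which(sqrt(rowSums(d^2)) <= r)
  }
  for (r in c(2.0, 3.0, 4.0)) {
    expect_true(all(mols_at(r) %in% mols_at(r + 1.0)))
  }
})

test_that("carved molecules stay intact across the periodic boundary", {
  fr <- source126()$frames[[80]]
  cl <- carve_cluster(fr, 3, 3.5)
  topo <- identify_molecules(cl) # open boundary: would fail if split
  expect_equal(topo$n_mol, cl$info$n_mol)
  # O-H distances near the bond length
  for (m in seq_len(topo$n_mol)) {
    o <- cl$positions[topo$o_index[m], ]
    for (h in topo$h_index[m, ]) {
      expect_lt(abs(sqrt(sum((cl$positions[h, ] - o)^2)) - 0.9572), 0.25)
    }
  }
})

test_that("dataset construction is deterministic and bookkeeps counts", {
  src <- source126()
  spec <- carve_spec(radii = c(2.5, 3.5), counts = c(40, 25), seed = 7)
  ds1 <- build_cluster_dataset(src, spec)
  ds2 <- build_cluster_dataset(src, spec)
  expect_equal(length(ds1), 65)
  expect_identical(ds1$manifest, ds2$manifest)
  expect_identical(ds1$clusters[[13]]$positions, ds2$clusters[[13]]$positions)
  ds3 <- build_cluster_dataset(src, carve_spec(radii = c(2.5, 3.5),
                                               counts = c(40, 25), seed = 8))
  expect_false(identical(ds1$manifest$frame, ds3$manifest$frame))
  expect_equal(table(ds1$manifest$radius),
               table(factor(c(rep(2.5, 40), rep(3.5, 25)))),
               ignore_attr = TRUE)
  # validation split is stratified at the configured fraction
  spl <- tapply(ds1$manifest$split == "val", ds1$manifest$radius, sum)
  expect_equal(as.vector(spl), c(4, 2))
})

test_that("a cumulative subset equals the prefix-built dataset", {
  src <- source126()
  full <- build_cluster_dataset(src, carve_spec(radii = c(2.5, 3.5),
                                                counts = c(20, 10), seed = 6))
  pre <- build_cluster_dataset(src, carve_spec(radii = 2.5, counts = 20,
                                               seed = 6))
  sub <- subset_dataset(full, 2.5)
  expect_identical(sub$manifest[, c("radius", "frame", "center")],
                   pre$manifest[, c("radius", "frame", "center")])
  expect_identical(sub$clusters[[7]]$positions, pre$clusters[[7]]$positions)
})

test_that("impossible requests fail loudly", {
  src <- source126()
  expect_error(build_cluster_dataset(src,
    carve_spec(radii = 2.5, counts = 10^7, seed = 1)), "insufficient")
  fr <- src$frames[[1]]
  expect_error(carve_cluster(fr, 1, 7.0), "too large")
})

test_that("labels equal the two-level energy difference", {
  th <- two_level_theory()
  src <- source126()
  ds <- build_cluster_dataset(src, carve_spec(radii = 3.0, counts = 12, seed = 3))
  ds <- label_delta(ds, th)
  for (i in c(1, 5, 12)) {
    cl <- ds$clusters[[i]]
    expect_equal(ds$labels[i],
                 evaluate_potential(th, cl, "HL")$energy -
                   evaluate_potential(th, cl, "LL")$energy,
                 tolerance = 1e-12)
  }
  # degenerate theory (HL == LL) labels vanish identically
  th0 <- two_level_theory(d_eps = 0, lambda3 = 0)
  ds0 <- label_delta(ds, th0)
  expect_identical(ds0$labels, rep(0, length(ds0)))
  # an isolated monomer cluster carries a zero label
  mono <- build_cluster_dataset(src, carve_spec(radii = 1.2, counts = 3,
                                                seed = 4, margin = 2))
  expect_identical(label_delta(mono, th)$labels, rep(0, 3))
})

test_that("datasets round-trip through extended-XYZ plus manifest", {
  th <- two_level_theory()
  ds <- label_delta(build_cluster_dataset(source126(),
    carve_spec(radii = 2.8, counts = 6, seed = 5)), th)
  xyz <- tempfile(fileext = ".xyz"); man <- tempfile(fileext = ".csv")
  write_dataset(ds, xyz, man)
  back <- read_extxyz(xyz)
  expect_length(back$frames, 6)
  expect_equal(vapply(back$frames, function(f) f$info$delta_energy, 0),
               ds$labels, tolerance = 1e-9)
  m <- read.csv(man)
  expect_equal(nrow(m), 6)
  expect_true(all(c("radius", "frame", "center", "split") %in% names(m)))
})

test_that("cluster occupancy approaches the ideal-density estimate", {
  # mean molecule count at radius r on equilibrated boxes ~ rho_N 4/3 pi r^3
  src <- source126()
  frames <- src$frames[seq(51, 151, by = 20)]
  r <- 4.5
  counts <- unlist(lapply(frames, function(fr) {
    topo <- identify_molecules(fr)
    po <- fr$positions[topo$o_index, ]
    vapply(1:126, function(cc) {
      d <- minimum_image(sweep(po, 2, po[cc, ]), fr$cell)
      sum(sqrt(rowSums(d^2)) <= r)
    }, 0)
  }))
  rho_n <- 126 / cell_edge(frames[[1]])^3
  expect_equal(mean(counts), rho_n * 4 / 3 * pi * r^3, tolerance = 0.15)
})
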