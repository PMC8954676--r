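# Scoring model: architecture shapes, forward-pass closed forms, Boltzmann
# ensemble, training behavior, screening contracts.

two_ch <- channel_scheme("other")  # 2 channels keeps micro-models tiny

test_that("default architecture matches the hand-computed shape chain", {
  m <- build_model(default_architecture(), grid_spec(n = 30), rng_seed = 1)
  s <- summary(m)
  # 30 -conv3-> 28 -conv3-> 26 -pool-> 13 -conv3-> 11 -conv3-> 9 -pool-> 4
  # -conv2-> 3 ; flatten 64*3^3 = 1728 -> 256 -> 1
  expect_equal(s$out_dim, c(32 * 28^3, 64 * 26^3, 64 * 13^3, 64 * 11^3,
                            64 * 9^3, 64 * 4^3, 64 * 3^3, 1728, 256, 1))
  expect_equal(dim(m$params[[9]]$W), c(256L, 1728L))
  expect_equal(dim(m$params[[1]]$W), c(32L, 14L * 27L))
  # printed filter sequence is the published one
  convs <- Filter(function(l) l$kind == "conv3d", m$layers)
  expect_equal(vapply(convs, `[[`, 0L, "filters"), c(32L, 64L, 64L, 64L, 64L))
  expect_equal(vapply(convs, `[[`, 0L, "kernel"), c(3L, 3L, 3L, 3L, 2L))
  expect_equal(m$layers[[9]]$units, 256L)
})

test_that("incompatible shape chains fail at build with the layer named", {
  expect_error(build_model(list(conv3d_layer(4, 3), flatten_layer(),
                                dense_layer(1, "linear")),
                           grid_spec(n = 8, scheme = two_ch)), NA)
  expect_error(
    build_model(list(maxpool_layer(2), maxpool_layer(2), conv3d_layer(4, 3)),
                grid_spec(n = 8, scheme = two_ch)),
    "layer 3")
  expect_error(
    build_model(list(flatten_layer(), dense_layer(4)),
                grid_spec(n = 8, scheme = two_ch)),
    "single scalar")
})

test_that("initialization is deterministic given the seed", {
  a <- build_model(default_architecture(), grid_spec(n = 20), rng_seed = 7)
  b <- build_model(default_architecture(), grid_spec(n = 20), rng_seed = 7)
  d <- build_model(default_architecture(), grid_spec(n = 20), rng_seed = 8)
  expect_identical(a$params, b$params)
  expect_false(identical(a$params, d$params))
})

test_that("forward pass matches hand-computed affine values", {
  spec <- grid_spec(n = 8, scheme = two_ch)
  # pure linear readout with hand-set weights: score = sum(W[occupied]) + b
  m <- build_model(list(flatten_layer(), dense_layer(1, "linear")), spec, 1)
  w <- seq_len(2 * 8^3) / 1000
  m$params[[2]]$W <- matrix(w, 1)
  m$params[[2]]$b <- 0.25
  g <- list(values = array(0, c(2, 8, 8, 8)), spec = spec, origin = rep(-4, 3))
  class(g) <- "voxel_grid"
  g$values[1, 3, 5, 2] <- 1
  g$values[2, 8, 1, 7] <- 1
  i1 <- 1 + 2 * ((3 - 1) + 8 * ((5 - 1) + 8 * (2 - 1)))
  i2 <- 2 + 2 * ((8 - 1) + 8 * ((1 - 1) + 8 * (7 - 1)))
  expect_equal(predict_pose(m, g), w[i1] + w[i2] + 0.25, tolerance = 1e-12)

  # one-filter linear conv with all-ones kernel counts occupied voxels per
  # window; with a summing dense head the score is (# windows covering the
  # occupied voxel) * 1 + b = 27 for an interior voxel
  mc <- build_model(list(conv3d_layer(1, 3, activation = "linear"),
                         flatten_layer(), dense_layer(1, "linear")), spec, 1)
  mc$params[[1]]$W <- matrix(1, 1, 2 * 27)
  mc$params[[1]]$b <- 0
  mc$params[[3]]$W <- matrix(1, 1, 6^3)
  mc$params[[3]]$b <- -1
  g2 <- list(values = array(0, c(2, 8, 8, 8)), spec = spec, origin = rep(-4, 3))
  class(g2) <- "voxel_grid"
  g2$values[1, 4, 4, 4] <- 1  # interior: covered by 3^3 windows
  expect_equal(predict_pose(mc, g2), 27 - 1, tolerance = 1e-12)

  # all-zero grid exercises the bias pathway only
  g0 <- list(values = array(0, c(2, 8, 8, 8)), spec = spec, origin = rep(-4, 3))
  class(g0) <- "voxel_grid"
  expect_equal(predict_pose(mc, g0), -1, tolerance = 1e-12)
  # identical grids give identical scores
  expect_identical(predict_pose(mc, g2), predict_pose(mc, g2))
})

test_that("ensemble_score has the stated closed forms and properties", {
  expect_equal(ensemble_score(c(2, 2, 2), 7), 2, tolerance = 1e-12)
  expect_equal(ensemble_score(c(1, 3), 0), 2, tolerance = 1e-12)
  expect_equal(ensemble_score(c(1, 3), 50), 3, tolerance = 1e-9)
  # overflow safety
  v <- ensemble_score(c(1000, 1001), 1)
  expect_true(is.finite(v) && v >= 1000 && v <= 1001)
  expect_error(ensemble_score(numeric(0)), "at least one")
  set.seed(31)
  for (k in 1:200) {
    sc <- rnorm(sample(1:6, 1), sd = 3)
    beta <- runif(1, 0, 5)
    s <- ensemble_score(sc, beta)
    expect_gte(s, min(sc)); expect_lte(s, max(sc))
    expect_equal(ensemble_score(sc, 0), mean(sc), tolerance = 1e-12)
    # shifting every score shifts the ensemble by the same amount
    d <- runif(1, -3, 3)
    expect_equal(ensemble_score(sc + d, beta), s + d, tolerance = 1e-9)
    # raising the maximum never decreases the ensemble (monotone in the
    # max; the weighted mean is deliberately not monotone in every input)
    sc2 <- sc; i <- which.max(sc); sc2[i] <- sc2[i] + runif(1, 0, 2)
    expect_gte(ensemble_score(sc2, beta), s - 1e-12)
  }
})

test_that("training is reproducible, inert at lr 0, and memorizes a tiny set", {
  spec <- grid_spec(n = 8, scheme = two_ch)
  arch <- list(conv3d_layer(4, 3), maxpool_layer(2), flatten_layer(),
               dense_layer(16), dense_layer(1, "linear"))
  set.seed(5)
  grids <- lapply(1:8, function(i) {
    v <- array(0, c(2, 8, 8, 8))
    v[sample(length(v), 20)] <- 1
    structure(list(values = v, spec = spec, origin = rep(-4, 3)),
              class = "voxel_grid")
  })
  labels <- runif(8, 3, 8)

  m0 <- build_model(arch, spec, rng_seed = 2)
  frozen <- train_model(m0, grids, labels,
                        train_config(8, 0, 5, rng_seed = 4))
  expect_identical(frozen$params, m0$params)
  expect_equal(length(frozen$history), 5L)
  expect_equal(diff(frozen$history), rep(0, 4))

  t1 <- train_model(m0, grids, labels, train_config(4, 1e-3, 6, rng_seed = 4))
  t2 <- train_model(m0, grids, labels, train_config(4, 1e-3, 6, rng_seed = 4))
  expect_identical(t1$history, t2$history)
  expect_identical(t1$params, t2$params)

  t3 <- train_model(m0, grids, labels,
                    train_config(8, 5e-3, 250, rng_seed = 4))
  expect_lt(min(t3$history), 0.01)
})

test_that("screening ranks deterministically with id tie-breaks and flags", {
  pk <- make_pocket(pocket_params(cavity_edge = 8))
  site <- flood_site(pk$structure, pk$seed)
  spec <- grid_spec(n = 12)
  arch <- list(conv3d_layer(4, 3), flatten_layer(), dense_layer(1, "linear"))
  m <- build_model(arch, spec, rng_seed = 3)
  ligs <- make_ligand_set(3, c(4, 6), rng_seed = 21)

  one <- screen_library(m, ligs[1], pk$structure, site, n_poses = 4,
                        rng_seed = 9)
  expect_equal(nrow(one), 1L)
  expect_equal(one$rank, 1L)

  # identical compound under two ids: identical scores, id-ordered
  twin <- ligs[[1]]
  a <- twin; a$id <- "aaa"
  b <- twin; b$id <- "aab"
  tw <- screen_library(m, list(aaa = a, aab = b), pk$structure, site,
                       n_poses = 4, rng_seed = 9)
  expect_equal(tw$score[1], tw$score[2], tolerance = 1e-12)
  expect_equal(tw$compound_id, c("aaa", "aab"))

  # bit-identical across runs, library order irrelevant
  r1 <- screen_library(m, ligs, pk$structure, site, n_poses = 4, rng_seed = 9)
  r2 <- screen_library(m, rev(ligs), pk$structure, site, n_poses = 4,
                       rng_seed = 9)
  expect_identical(r1, r2)

  # an unplaceable compound is ranked last and flagged, not dropped
  huge <- make_ligand_set(1, c(16, 16), rng_seed = 5)[[1]]
  huge$id <- "zzz_huge"
  tiny_site <- flood_site(tiny_pocket()$structure, c(0, 0, 0))
  mix <- screen_library(m, c(ligs[1], list(zzz_huge = huge)),
                        tiny_pocket()$structure, tiny_site,
                        n_poses = 2, rng_seed = 9)
  expect_equal(mix$compound_id[nrow(mix)], "zzz_huge")
  expect_equal(mix$flags[nrow(mix)], "no_placeable_pose")
  expect_equal(mix$n_poses_accepted[nrow(mix)], 0L)
})

test_that("model checkpoints round-trip through save_model/load_model", {
  spec <- grid_spec(n = 8, scheme = two_ch)
  arch <- list(conv3d_layer(2, 3), flatten_layer(), dense_layer(1, "linear"))
  m <- build_model(arch, spec, rng_seed = 6)
  path <- tempfile(fileext = ".rds")
  save_model(m, path)
  back <- load_model(path)
  expect_equal(back$params, m$params)
  g <- list(values = array(0, c(2, 8, 8, 8)), spec = spec, origin = rep(-4, 3))
  class(g) <- "voxel_grid"
  g$values[c(3, 77, 400)] <- 1
  expect_equal(predict_pose(back, g), predict_pose(m, g), tolerance = 1e-12)
})
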