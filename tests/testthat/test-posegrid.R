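# Pose sampling, rigid augmentation, rasterization and lattice rotations.

make_scene <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      pk <- make_pocket(pocket_params(cavity_edge = 10))
      site <- flood_site(pk$structure, pk$seed)
      ligs <- make_ligand_set(2, c(5, 8), rng_seed = 1)
      cache <<- list(pk = pk, site = site, ligs = ligs)
    }
    cache
  }
})

test_that("a point ligand with t_max = 0 lands exactly at the site center", {
  sc <- make_scene()
  point <- mol_graph("pt", "C", NULL, coords = matrix(c(9, 9, 9), 3, 1))
  pose <- sample_poses(sc$pk$structure, point, sc$site, n_poses = 1,
                       t_max = 0, rng_seed = 5)[[1]]
  expect_equal(as.numeric(pose$ligand_coords), unname(sc$site$center),
               tolerance = 1e-12)
  expect_true(pose$clash_free)
})

test_that("a ligand inside a dense slab has no placeable pose", {
  pk <- tiny_pocket()           # 3A cavity
  site <- flood_site(pk$structure, pk$seed)
  big <- make_ligand_set(1, c(14, 14), rng_seed = 2)[[1]]  # too big to fit
  expect_error(
    sample_poses(pk$structure, big, site, n_poses = 1, rng_seed = 3,
                 max_attempts = 50),
    "no placeable pose")
})

test_that("pose sampling is deterministic in its seed and order-invariant", {
  sc <- make_scene()
  lig <- sc$ligs[[1]]
  a <- sample_poses(sc$pk$structure, lig, sc$site, n_poses = 4, rng_seed = 11)
  b <- sample_poses(sc$pk$structure, lig, sc$site, n_poses = 4, rng_seed = 11)
  expect_identical(a, b)
  # permuting ligand atom order leaves acceptance/geometry decisions intact
  perm <- rev(seq_along(lig$atoms))
  lig2 <- mol_graph(lig$id, lig$atoms[perm], NULL, coords = lig$coords[, perm])
  d <- sample_poses(sc$pk$structure, lig2, sc$site, n_poses = 4, rng_seed = 11)
  for (k in seq_along(a)) {
    expect_equal(d[[k]]$ligand_coords[, perm], a[[k]]$ligand_coords,
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
  # accepted poses respect the clash rule
  prot <- sc$pk$structure$atoms
  for (p in a) {
    for (i in seq_len(ncol(p$ligand_coords))) {
      dmin <- sqrt((prot$x - p$ligand_coords[1, i])^2 +
                   (prot$y - p$ligand_coords[2, i])^2 +
                   (prot$z - p$ligand_coords[3, i])^2)
      thr <- 0.75 * (vdw_radius(prot$element) + vdw_radius(lig$atoms[i]))
      expect_true(all(dmin >= thr))
    }
  }
})

test_that("augment_complex is a joint rigid motion about the site center", {
  sc <- make_scene()
  pose <- sample_poses(sc$pk$structure, sc$ligs[[1]], sc$site, n_poses = 1,
                       rng_seed = 7)[[1]]
  all_xyz <- cbind(voxscreen:::struct_coords(sc$pk$structure),
                   pose$ligand_coords)
  d0 <- as.matrix(dist(t(all_xyz)))
  for (seed in 1:20) {
    out <- augment_complex(sc$pk$structure, pose, sc$site, rng_seed = seed)
    xyz2 <- cbind(voxscreen:::struct_coords(out$structure),
                  out$pose$ligand_coords)
    expect_equal(as.matrix(dist(t(xyz2))), d0, tolerance = 1e-9)
    # ligand centroid distance to center changes only by the drawn translation
    c0 <- rowMeans(pose$ligand_coords) - sc$site$center
    c1 <- rowMeans(out$pose$ligand_coords) -
      (sc$site$center + out$transform$translation)
    expect_equal(sqrt(sum(c1^2)), sqrt(sum(c0^2)), tolerance = 1e-9)
  }
})

test_that("rasterization places atoms in the documented voxels and channels", {
  sc <- make_scene()
  spec <- grid_spec(n = 30)
  lig <- mol_graph("one", "C", NULL,
                   coords = matrix(sc$site$center, 3, 1))
  pose <- structure(list(ligand_coords = lig$coords, clash_free = TRUE),
                    class = "vox_pose")
  # protein-free structure isolates the single ligand voxel
  empty <- sc$pk$structure
  empty$atoms <- empty$atoms[1, , drop = FALSE]
  empty$atoms$x <- 100; empty$atoms$y <- 100; empty$atoms$z <- 100
  g <- rasterize_complex(empty, lig, pose, sc$site, spec)
  expect_equal(sum(g$values), 1)
  ch <- atom_channel("C", "ligand")
  expect_equal(g$values[ch, 16, 16, 16], 1)  # voxel index floor(15)=15 (0-based)
  # atoms outside the box are ignored
  xyz <- cbind(matrix(rnorm(24, sd = 2), 3, 8),
               matrix(c(40, 40, 40, -40, 0, 0), 3, 2))
  lig10 <- mol_graph("ten", rep("C", 10), NULL, coords = xyz)
  pose10 <- structure(list(ligand_coords = xyz, clash_free = TRUE),
                      class = "vox_pose")
  g10 <- rasterize_complex(empty, lig10, pose10, sc$site, spec)
  # per-atom index oracle
  idx <- floor(sweep(t(xyz), 2, g10$origin))
  inb <- rowSums(idx >= 0 & idx <= 29) == 3
  expect_equal(sum(g10$values),
               nrow(unique(idx[inb, , drop = FALSE])))
  expect_equal(sum(inb), 8)
})

test_that("occupancy equals atom count when no same-channel atoms share a voxel", {
  sc <- make_scene()
  spec <- grid_spec(n = 20)
  lig <- sc$ligs[[2]]
  pose <- sample_poses(sc$pk$structure, lig, sc$site, n_poses = 1,
                       rng_seed = 9)[[1]]
  g <- rasterize_complex(sc$pk$structure, lig, pose, sc$site, spec)
  # count in-bounds atoms per channel and compare where collision-free
  idx <- floor(sweep(t(pose$ligand_coords), 2, g$origin))
  keys <- paste(atom_channel(lig$atoms, "ligand"), idx[, 1], idx[, 2], idx[, 3])
  if (!anyDuplicated(keys)) {
    lig_ch <- 8:14
    expect_equal(sum(g$values[lig_ch, , , ]), length(lig$atoms))
  }
  # empty structure -> all-zero grid
  empty <- sc$pk$structure
  empty$atoms <- empty$atoms[1, , drop = FALSE]
  empty$atoms$x <- 500; empty$atoms$y <- 500; empty$atoms$z <- 500
  g0 <- rasterize(empty, NULL, sc$site, spec)
  expect_equal(sum(g0$values), 0)
})

test_that("the 24 proper cube rotations act on grids as exact voxel permutations", {
  atoms <- data.frame(
    element = c("C", "N", "O", "C", "S"),
    x = c(1.2, -2.3, 0.7, 3.1, -0.4), y = c(0.4, 1.9, -3.2, 2.2, 1.1),
    z = c(-1.1, 0.3, 2.8, -2.7, 3.6),
    atom_name = "X", res_index = 1, res_name = "ALA", chain = "A",
    role = "protein", occupancy = 1, bfactor = 0)
  s <- vox_structure(atoms, "toy")
  site <- structure(list(center = c(0, 0, 0)), class = "binding_site")
  lig <- mol_graph("l", c("C", "O"), rbind(c(1, 2, 1)),
                   coords = cbind(c(0.6, -1.4, 2.1), c(-0.9, 1.1, -0.4)))
  pose <- structure(list(ligand_coords = lig$coords, clash_free = TRUE),
                    class = "vox_pose")
  spec <- grid_spec(n = 10)
  g <- rasterize_complex(s, lig, pose, site, spec)
  tab <- voxscreen:::cube_rotation_table()
  expect_length(tab, 24L)
  for (r in seq_along(tab)) {
    R <- tab[[r]]
    s2 <- s
    xyz <- R %*% voxscreen:::struct_coords(s)
    s2$atoms$x <- xyz[1, ]; s2$atoms$y <- xyz[2, ]; s2$atoms$z <- xyz[3, ]
    pose2 <- pose
    pose2$ligand_coords <- R %*% pose$ligand_coords
    expect_identical(rasterize_complex(s2, lig, pose2, site, spec)$values,
                     rotate_grid(g, r)$values, label = sprintf("rotation %d", r))
  }
  # augmentation carries labels unchanged and includes the identity
  aug <- augment_grid_rotations(list(g), 4.2, n_rotations = 4)
  expect_length(aug$grids, 4L)
  expect_equal(aug$labels, rep(4.2, 4))
  expect_identical(aug$grids[[1]]$values, g$values)
  for (k in 2:4) expect_equal(sum(aug$grids[[k]]$values), sum(g$values))
})
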