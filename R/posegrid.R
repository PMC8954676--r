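# Pose sampling, rigid augmentation and voxel-grid rasterization.
#
# Poses are rigid placements of a ligand in the flooded site: the ligand is
# centered at the site center, given a uniform random rotation (Shoemake's
# uniform-quaternion construction) and a translation uniform in a ball,
# then accepted iff no ligand-protein heavy-atom pair comes closer than
# clash_factor x (sum of the pair's Bondi vdW radii). Grids are binary
# per-channel occupancy tensors over an n^3 box centered on the site.

#' Rigid transform (rotation + translation)
#'
#' @param rotation 3 x 3 proper rotation matrix.
#' @param translation Numeric 3-vector, Angstrom.
#' @return Object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  stopifnot(all(dim(rotation) == c(3, 3)), length(translation) == 3)
  if (abs(det(rotation) - 1) > 1e-8 ||
      max(abs(crossprod(rotation) - diag(3))) > 1e-8)
    vs_stop("rotation must be a proper orthonormal matrix")
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "rigid_transform")
}

# Apply a rigid transform to a 3 x N coordinate matrix about a pivot point.
apply_transform <- function(xyz, tf, pivot = c(0, 0, 0)) {
  tf$rotation %*% (xyz - pivot) + pivot + tf$translation
}

# Uniform random rotation matrix (Shoemake 1992 uniform quaternion).
random_rotation <- function() {
  u <- runif(3)
  q <- c(sqrt(1 - u[1]) * sin(2 * pi * u[2]),
         sqrt(1 - u[1]) * cos(2 * pi * u[2]),
         sqrt(u[1]) * sin(2 * pi * u[3]),
         sqrt(u[1]) * cos(2 * pi * u[3]))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# Uniform random point in a ball of radius r (inverse-CDF on the radius).
random_in_ball <- function(r) {
  if (r <= 0) return(c(0, 0, 0))
  v <- rnorm(3)
  v <- v / sqrt(sum(v^2))
  v * r * runif(1)^(1 / 3)
}

# Minimum clash-free check: any ligand-protein pair closer than
# factor * (vdw_i + vdw_j)? Vectorized over the protein.
has_clash <- function(lig_xyz, lig_vdw, prot_xyz, prot_vdw, factor) {
  for (i in seq_len(ncol(lig_xyz))) {
    d <- sqrt(colSums((prot_xyz - lig_xyz[, i])^2))
    if (any(d < factor * (prot_vdw + lig_vdw[i]))) return(TRUE)
  }
  FALSE
}

#' Sample clash-free rigid poses of a ligand in a site
#'
#' Each candidate pose centers the ligand (heavy-atom centroid) at
#' `site$center`, applies a uniform random rotation and a translation drawn
#' uniformly from a ball of radius `t_max`, and is accepted iff no
#' ligand-protein heavy-atom pair is closer than
#' `clash_factor * (vdW_i + vdW_j)`. Sampling continues until `n_poses`
#' poses are accepted or `max_attempts` candidates have been tried.
#'
#' @param s A [vox_structure()] (protein atoms are the clash context).
#' @param lig A [mol_graph()] with 3D coordinates.
#' @param site A [flood_site()] result.
#' @param n_poses Number of poses wanted.
#' @param t_max Translation ball radius, Angstrom.
#' @param clash_factor Fraction of the vdW-sum below which a contact is a
#'   clash.
#' @param rng_seed Integer seed; the pose list is a pure function of it.
#' @param max_attempts Candidate budget (default `200 * n_poses`).
#' @return List of poses; each pose has `ligand_coords` (3 x N),
#'   `transform` ([rigid_transform()]) and `clash_free = TRUE`.
#' @export
sample_poses <- function(s, lig, site, n_poses = 16L, t_max = 4.0,
                         clash_factor = 0.75, rng_seed = 1L,
                         max_attempts = 200L * n_poses) {
  stopifnot(n_poses >= 1)
  if (is.null(lig$coords)) vs_stop("ligand '%s' has no 3D coordinates", lig$id)
  prot <- struct_coords(s, role = "protein")
  prot_vdw <- vdw_radius(s$atoms$element[s$atoms$role == "protein"])
  lig_vdw <- vdw_radius(lig$atoms)
  centered <- lig$coords - rowMeans(lig$coords)

  with_seed(rng_seed, {
    poses <- list()
    attempts <- 0L
    while (length(poses) < n_poses && attempts < max_attempts) {
      attempts <- attempts + 1L
      R <- random_rotation()
      tr <- random_in_ball(t_max)
      xyz <- R %*% centered + site$center + tr
      if (!has_clash(xyz, lig_vdw, prot, prot_vdw, clash_factor)) {
        poses[[length(poses) + 1L]] <- structure(
          list(ligand_coords = xyz,
               transform = rigid_transform(R, site$center + tr),
               clash_free = TRUE),
          class = "vox_pose")
      }
    }
    if (!length(poses))
      vs_stop("no placeable pose for ligand '%s' after %d attempts",
              lig$id, max_attempts)
    if (length(poses) < n_poses)
      vs_warn("ligand '%s': only %d of %d poses placeable",
              lig$id, length(poses), n_poses)
    poses
  })
}

#' Jointly rotate/translate a complex about the site center
#'
#' Training-time augmentation: one uniform random rotation plus a
#' translation uniform in a ball of radius `t_max` is applied to the protein
#' and the ligand pose together, about `site$center`. Internal geometry is
#' exactly preserved (one rigid motion).
#'
#' @param s A [vox_structure()].
#' @param pose A pose from [sample_poses()].
#' @param site A [flood_site()] result.
#' @param t_max Translation ball radius, Angstrom (default 2).
#' @param rng_seed Integer seed.
#' @return List with transformed `structure`, `pose` and the drawn
#'   `transform`.
#' @export
augment_complex <- function(s, pose, site, t_max = 2.0, rng_seed = 1L) {
  with_seed(rng_seed, {
    R <- random_rotation()
    tr <- random_in_ball(t_max)
    tf <- rigid_transform(R, tr)
    prot <- apply_transform(struct_coords(s), tf, pivot = site$center)
    s2 <- s
    s2$atoms$x <- prot[1, ]; s2$atoms$y <- prot[2, ]; s2$atoms$z <- prot[3, ]
    pose2 <- pose
    pose2$ligand_coords <- apply_transform(pose$ligand_coords, tf,
                                           pivot = site$center)
    list(structure = s2, pose = pose2, transform = tf)
  })
}

#' Voxel-grid specification
#'
#' @param n Voxels per edge (default 30).
#' @param spacing Angstrom per voxel (default 1).
#' @param scheme A [channel_scheme()] (default 14 channels).
#' @return Object of class `grid_spec`.
#' @export
grid_spec <- function(n = 30L, spacing = 1.0, scheme = channel_scheme()) {
  stopifnot(n >= 8, spacing > 0)
  structure(list(n = as.integer(n), spacing = spacing, scheme = scheme),
            class = "grid_spec")
}

#' Rasterize a protein-ligand pose into a binary occupancy grid
#'
#' The box is centered on `site$center`: its origin is
#' `center - n * spacing / 2` on each axis. Every heavy atom at position x
#' occupies the voxel `floor((x - origin) / spacing)` in its
#' [atom_channel()]; atoms falling outside the box are ignored. Occupancy is
#' binary — several atoms in one voxel+channel still give 1.
#'
#' @param s A [vox_structure()] (protein context; its ligand atoms, if any,
#'   are ignored in favor of `pose`).
#' @param pose A pose from [sample_poses()], or `NULL` for a protein-only
#'   grid.
#' @param site A [flood_site()] result (or any object with a `center`).
#' @param spec A [grid_spec()].
#' @return Object of class `voxel_grid`: `values` is a
#'   `channels x n x n x n` 0/1 array, plus `spec` and `origin`.
#' @export
rasterize <- function(s, pose, site, spec = grid_spec()) {
  n <- spec$n
  C <- spec$scheme$n_channels
  origin <- site$center - n * spec$spacing / 2
  values <- array(0, dim = c(C, n, n, n))

  put <- function(xyz, channels) {
    if (is.null(xyz) || ncol(xyz) == 0L) return()
    idx <- floor(sweep(t(xyz), 2, origin) / spec$spacing)
    inb <- rowSums(idx >= 0 & idx <= (n - 1)) == 3L
    if (!any(inb)) return()
    idx <- idx[inb, , drop = FALSE]
    ch <- channels[inb]
    lin <- ch + C * (idx[, 1] + n * (idx[, 2] + n * idx[, 3]))
    values[lin] <<- 1
  }

  prot_mask <- s$atoms$role == "protein"
  if (any(prot_mask)) {
    put(struct_coords(s, "protein"),
        atom_channel(s$atoms$element[prot_mask], "protein", spec$scheme))
  }
  if (!is.null(pose)) {
    lig_el <- attr(pose, "elements") %||% pose$elements
    if (is.null(lig_el))
      vs_stop("pose carries no element labels; use rasterize_complex()")
    put(pose$ligand_coords, atom_channel(lig_el, "ligand", spec$scheme))
  }
  structure(list(values = values, spec = spec, origin = origin),
            class = "voxel_grid")
}

#' Rasterize with explicit ligand graph
#'
#' Convenience wrapper attaching the ligand's element labels to the pose
#' before calling [rasterize()].
#'
#' @inheritParams rasterize
#' @param lig The [mol_graph()] the pose was sampled for.
#' @return A `voxel_grid`.
#' @export
rasterize_complex <- function(s, lig, pose, site, spec = grid_spec()) {
  pose$elements <- lig$atoms
  rasterize(s, pose, site, spec)
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid: %d channels x %d^3, %.2f A spacing, %d occupied voxels>\n",
              dim(x$values)[1], x$spec$n, x$spec$spacing, sum(x$values)))
  invisible(x)
}

# ---- Exact lattice rotations -------------------------------------------

# The 24 proper rotations of the cube, encoded as (axis permutation, axis
# sign flips) pairs with determinant +1. Applied to a voxel grid they are
# exact: rotating the rasterized grid equals rasterizing the rotated
# complex (rotation about the grid center).
cube_rotation_table <- function() {
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  out <- list()
  for (p in perms) for (s1 in c(1, -1)) for (s2 in c(1, -1)) for (s3 in c(1, -1)) {
    R <- matrix(0, 3, 3)
    sg <- c(s1, s2, s3)
    for (i in 1:3) R[i, p[i]] <- sg[i]
    if (abs(det(R) - 1) < 1e-9) out[[length(out) + 1L]] <- R
  }
  out
}

#' Rotate a voxel grid by a proper cube rotation
#'
#' Applies one of the 24 axis-aligned proper rotations to the spatial axes
#' of a grid (all channels together) — an exact voxel permutation,
#' equivalent to jointly rotating the protein-ligand complex about the grid
#' center before rasterizing.
#'
#' @param grid A `voxel_grid`.
#' @param rot Index 1..24 into [cube_rotation_table()].
#' @return The rotated `voxel_grid`.
#' @export
rotate_grid <- function(grid, rot) {
  R <- cube_rotation_table()[[rot]]
  v <- grid$values
  n <- dim(v)[2]
  # spatial axis j of the output draws from input axis perm[j], reversed
  # when the sign is negative
  perm <- apply(abs(R), 1, which.max)
  sgn <- R[cbind(1:3, perm)]
  v <- aperm(v, c(1, 1 + perm))
  # after aperm, output axis j holds input axis perm[j]; now flip negatives
  idx <- rep(list(quote(expr = )), 4)
  for (j in 1:3) if (sgn[j] < 0) idx[[j + 1]] <- n:1
  v <- do.call(`[`, c(list(v), idx, list(drop = FALSE)))
  out <- grid
  out$values <- v
  out
}

#' Augment grids with exact lattice rotations
#'
#' Training-time augmentation in the spirit of random complex rotation, but
#' restricted to exact 90-degree lattice rotations so no re-rasterization
#' (and no interpolation error) is involved: labels are carried over
#' unchanged because a joint rigid motion of the complex leaves the
#' affinity invariant.
#'
#' @param grids List of `voxel_grid` objects.
#' @param labels Numeric labels, one per grid.
#' @param n_rotations How many rotations per grid (1..24; the identity is
#'   always included first).
#' @return List with expanded `grids` and `labels`.
#' @export
augment_grid_rotations <- function(grids, labels, n_rotations = 4L) {
  stopifnot(length(grids) == length(labels), n_rotations >= 1, n_rotations <= 24)
  # fixed, spread-out selection: identity plus rotations stepping through
  # the table
  sel <- unique(c(1L, as.integer(round(seq(1, 24, length.out = n_rotations)))))
  sel <- sel[seq_len(min(n_rotations, length(sel)))]
  out_g <- vector("list", length(grids) * length(sel))
  out_l <- numeric(length(out_g))
  k <- 0L
  for (i in seq_along(grids)) for (r in sel) {
    k <- k + 1L
    out_g[[k]] <- if (r == 1L) grids[[i]] else rotate_grid(grids[[i]], r)
    out_l[k] <- labels[i]
  }
  list(grids = out_g, labels = out_l)
}
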