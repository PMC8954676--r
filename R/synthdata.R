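# Synthetic data with known ground truth.
#
# Everything here is a pure function of its seed. The generators provide:
# hollow pseudo-atom pockets (so flooding has a known answer), random rigid
# ligand clusters with valid geometry, a contact-count affinity model that
# a 3D occupancy CNN can in principle learn (labels are a near-linear
# function of the ligand occupancy pattern given a fixed pocket), grid/label
# training sets with a regeneration manifest, and SMILES screening libraries
# with planted triage-stage outcomes.

#' Pocket generator parameters
#'
#' @param cavity_edge Inner cavity edge length, Angstrom (>= 3).
#' @param wall_thickness Wall shell thickness, Angstrom.
#' @param wall_atom_spacing Lattice spacing of wall pseudo-atoms, Angstrom.
#' @param aperture Optional opening diameter in the +x wall, Angstrom
#'   (`NULL` = closed pocket, guaranteeing flood termination).
#' @param rng_seed Seed for wall-atom element assignment.
#' @return Object of class `pocket_params`.
#' @export
pocket_params <- function(cavity_edge = 10, wall_thickness = 2,
                          wall_atom_spacing = 1, aperture = NULL,
                          rng_seed = 1L) {
  stopifnot(cavity_edge >= 3, wall_thickness > 0, wall_atom_spacing > 0)
  structure(list(cavity_edge = cavity_edge, wall_thickness = wall_thickness,
                 wall_atom_spacing = wall_atom_spacing, aperture = aperture,
                 rng_seed = as.integer(rng_seed)),
            class = "pocket_params")
}

#' Build a hollow synthetic pocket
#'
#' A cuboid shell of pseudo-atoms (mixed C/N/O, seeded) enclosing an empty
#' cavity centered at `center`. Wall atoms sit on a lattice with L-infinity
#' distance from the center between `cavity_edge/2 + 1.5` and that plus
#' `wall_thickness`; the 1.5 A margin keeps lattice points just inside the
#' cavity boundary from being occluded at the default 2 A occlusion radius.
#' Atoms are grouped into pseudo-residues (8 atoms each, standard residue
#' names) so pocket-residue listing and clash attribution work unchanged.
#'
#' @param p A [pocket_params()].
#' @param center Cavity center, Angstrom.
#' @return List with `structure` (a [vox_structure()]) and `seed` (the
#'   cavity center, the natural flood seed).
#' @export
make_pocket <- function(p = pocket_params(), center = c(0, 0, 0)) {
  h <- p$cavity_edge / 2 + 1.5
  hmax <- h + p$wall_thickness
  g <- seq(-hmax, hmax, by = p$wall_atom_spacing)
  lattice <- as.matrix(expand.grid(x = g, y = g, z = g))
  linf <- pmax(abs(lattice[, 1]), abs(lattice[, 2]), abs(lattice[, 3]))
  keep <- linf >= h - 1e-9 & linf <= hmax + 1e-9
  if (!is.null(p$aperture)) {
    rad <- sqrt(lattice[, 2]^2 + lattice[, 3]^2)
    keep <- keep & !(lattice[, 1] > 0 & rad < p$aperture / 2)
  }
  pts <- lattice[keep, , drop = FALSE]
  n <- nrow(pts)
  el <- with_seed(p$rng_seed,
                  sample(c("C", "N", "O"), n, replace = TRUE,
                         prob = c(0.6, 0.2, 0.2)))
  res_index <- (seq_len(n) - 1L) %/% 8L + 1L
  res_pool <- names(.AA3TO1)
  res_name <- res_pool[(res_index - 1L) %% length(res_pool) + 1L]
  within <- stats::ave(seq_len(n), res_index, FUN = seq_along)
  atoms <- data.frame(
    element = el,
    x = pts[, 1] + center[1], y = pts[, 2] + center[2], z = pts[, 3] + center[3],
    atom_name = paste0(el, within),
    res_index = res_index, res_name = res_name, chain = "A",
    role = "protein", occupancy = 1, bfactor = 0,
    stringsAsFactors = FALSE)
  list(structure = vox_structure(atoms, id = "synthetic-pocket"),
       seed = as.numeric(center))
}

#' Generate a random rigid ligand set
#'
#' Random heavy-atom clusters grown atom by atom: each new atom bonds to a
#' random existing atom at 1.45-1.6 A, rejecting geometries with any
#' non-bonded pair closer than 1.2 A. Elements are drawn from C/N/O/S
#' (carbon-rich). Connectivity is the growth tree (single bonds).
#'
#' @param n Number of ligands.
#' @param size_range Heavy-atom count range, inclusive (default 4-20).
#' @param rng_seed Seed; the set is a pure function of it.
#' @return Named list of [mol_graph()] objects with 3D coordinates (ids
#'   `lig001`, ...).
#' @export
make_ligand_set <- function(n, size_range = c(4L, 20L), rng_seed = 1L) {
  stopifnot(n >= 1, size_range[1] >= 1, size_range[2] >= size_range[1])
  with_seed(rng_seed, {
    out <- vector("list", n)
    for (m in seq_len(n)) {
      sizes <- seq(size_range[1], size_range[2])
      sz <- sizes[sample.int(length(sizes), 1L)]
      el <- sample(c("C", "N", "O", "S"), sz, replace = TRUE,
                   prob = c(0.55, 0.2, 0.2, 0.05))
      xyz <- matrix(0, 3, sz)
      bonds <- NULL
      if (sz > 1) for (i in 2:sz) {
        repeat {
          anchor <- sample.int(i - 1L, 1L)
          dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
          cand <- xyz[, anchor] + dir * runif(1, 1.45, 1.6)
          d <- sqrt(colSums((xyz[, seq_len(i - 1L), drop = FALSE] - cand)^2))
          d[anchor] <- Inf  # bonded distance already constrained
          if (all(d >= 1.2)) break
        }
        xyz[, i] <- cand
        bonds <- rbind(bonds, c(anchor, i, 1L))
      }
      id <- sprintf("lig%03d", m)
      out[[m]] <- mol_graph(id, el, bonds, coords = xyz)
    }
    setNames(out, vapply(out, function(x) x$id, ""))
  })
}

#' Ground-truth affinity weights
#'
#' The synthetic label model: pK = `contact_gain` x (number of
#' ligand-heavy-atom / protein-N-or-O pairs within `contact_radius`)
#' - `clash_penalty` x (number of pairs closer than 0.75 x vdW sum)
#' + Gaussian noise.
#'
#' @param contact_gain pK per polar contact (> 0).
#' @param clash_penalty pK per clashing pair.
#' @param contact_radius Contact distance cutoff, Angstrom.
#' @param noise_sd Label noise standard deviation, pK.
#' @return Object of class `affinity_weights`.
#' @export
affinity_weights <- function(contact_gain = 0.15, clash_penalty = 0.5,
                             contact_radius = 4.0, noise_sd = 0.2) {
  stopifnot(contact_gain > 0, noise_sd >= 0, contact_radius > 0)
  structure(list(contact_gain = contact_gain, clash_penalty = clash_penalty,
                 contact_radius = contact_radius, noise_sd = noise_sd),
            class = "affinity_weights")
}

#' Ground-truth affinity of a placed pose
#'
#' @param s A [vox_structure()] (protein context).
#' @param pose A pose from [sample_poses()].
#' @param lig_elements Ligand element symbols (for the clash vdW radii).
#' @param w An [affinity_weights()].
#' @param rng_seed Seed for the noise draw (deterministic per seed).
#' @param clash_factor Clash threshold as a fraction of the vdW sum.
#' @return Scalar pK label.
#' @export
true_affinity <- function(s, pose, lig_elements, w = affinity_weights(),
                          rng_seed = 1L, clash_factor = 0.75) {
  prot <- s$atoms[s$atoms$role == "protein", , drop = FALSE]
  pxyz <- t(as.matrix(prot[, c("x", "y", "z")]))
  polar <- prot$element %in% c("N", "O")
  pvdw <- vdw_radius(prot$element)
  lvdw <- vdw_radius(lig_elements)
  contacts <- 0L; clashes <- 0L
  for (i in seq_len(ncol(pose$ligand_coords))) {
    d <- sqrt(colSums((pxyz - pose$ligand_coords[, i])^2))
    contacts <- contacts + sum(polar & d <= w$contact_radius)
    clashes <- clashes + sum(d < clash_factor * (pvdw + lvdw[i]))
  }
  noise <- if (w$noise_sd > 0) with_seed(rng_seed, rnorm(1, 0, w$noise_sd)) else 0
  w$contact_gain * contacts - w$clash_penalty * clashes + noise
}

#' Generate a labeled training set of grids
#'
#' Pipeline composition: pocket -> ligands -> pose sampling ->
#' ground-truth affinity -> rasterization. Each complex is one
#' (ligand, pose) pair; by default every ligand contributes two sampled
#' poses, which teaches a scorer the pose-dependence of the contact signal
#' rather than ligand identity alone. The returned manifest (master seed
#' plus every derived seed and all parameters) reproduces the set
#' bit-exactly.
#'
#' @param n_complexes Number of grid/label pairs.
#' @param pocket A [pocket_params()].
#' @param size_range Ligand heavy-atom range.
#' @param w An [affinity_weights()].
#' @param spec A [grid_spec()].
#' @param flood A [flood_params()].
#' @param t_max Pose translation radius, Angstrom.
#' @param poses_per_ligand Sampled poses contributed by each ligand.
#' @param rng_seed Master seed.
#' @return List: `grids`, `labels`, `site`, `structure`, `ligands`,
#'   `poses`, `manifest`.
#' @export
make_training_set <- function(n_complexes, pocket = pocket_params(),
                              size_range = c(4L, 14L),
                              w = affinity_weights(), spec = grid_spec(),
                              flood = flood_params(), t_max = 4.0,
                              poses_per_ligand = 2L, rng_seed = 1L) {
  stopifnot(poses_per_ligand >= 1)
  pk <- make_pocket(pocket)
  site <- flood_site(pk$structure, pk$seed, flood)
  n_lig <- ceiling(n_complexes / poses_per_ligand)
  grids <- list(); labels <- numeric(0); poses <- list(); ligs <- list()
  lig_seeds <- pose_seeds <- integer(n_lig)
  noise_seeds <- integer(0)
  for (li in seq_len(n_lig)) {
    pose_seeds[li] <- derive_seed(rng_seed, "pose", li)
    # a drawn ligand occasionally cannot be placed without clashes (too
    # extended for the cavity); redraw deterministically until one fits
    pl <- NULL
    for (try in 0:20) {
      lig_seeds[li] <- derive_seed(rng_seed, "ligand", li * 64L + try)
      lig <- make_ligand_set(1L, size_range, rng_seed = lig_seeds[li])[[1]]
      lig$id <- sprintf("cplx%04d", li)
      pl <- tryCatch(withCallingHandlers(
        sample_poses(pk$structure, lig, site, n_poses = poses_per_ligand,
                     t_max = t_max, rng_seed = pose_seeds[li]),
        warning = function(w) invokeRestart("muffleWarning")),
        error = function(e) NULL)
      if (!is.null(pl) && length(pl) == poses_per_ligand) break
      pl <- NULL
    }
    if (is.null(pl))
      vs_stop("ligand %d: not placeable after 20 redraws", li)
    ligs[[lig$id]] <- lig
    for (k in seq_len(poses_per_ligand)) {
      if (length(labels) >= n_complexes) break
      ns <- derive_seed(rng_seed, "noise", li * 64L + k)
      noise_seeds <- c(noise_seeds, ns)
      labels <- c(labels, true_affinity(pk$structure, pl[[k]], lig$atoms, w,
                                        rng_seed = ns))
      grids[[length(grids) + 1L]] <- rasterize_complex(pk$structure, lig,
                                                       pl[[k]], site, spec)
      poses[[length(poses) + 1L]] <- pl[[k]]
    }
  }
  manifest <- list(rng_seed = rng_seed, ligand_seeds = lig_seeds,
                   pose_seeds = pose_seeds, noise_seeds = noise_seeds,
                   pocket = unclass(pocket), size_range = size_range,
                   weights = unclass(w), t_max = t_max,
                   poses_per_ligand = as.integer(poses_per_ligand),
                   grid = list(n = spec$n, spacing = spec$spacing),
                   flood = unclass(flood))
  list(grids = grids, labels = labels, site = site, structure = pk$structure,
       ligands = ligs, poses = poses, manifest = manifest)
}

#' Oracle compound scores from the ground-truth affinity model
#'
#' Mirrors [screen_library()] — same per-compound pose streams — but scores
#' poses with [true_affinity()] (noise-free) instead of a network, giving
#' the ground-truth ranking that a trained model should recover.
#'
#' @param lib Named list of [mol_graph()] with coordinates.
#' @param s A [vox_structure()].
#' @param site A [flood_site()] result.
#' @param w An [affinity_weights()] (noise ignored).
#' @param n_poses,t_max,beta,rng_seed As in [screen_library()].
#' @return Named numeric vector of ground-truth compound scores.
#' @export
true_compound_scores <- function(lib, s, site, w = affinity_weights(),
                                 n_poses = 16L, t_max = 4.0, beta = 1.0,
                                 rng_seed = 1L) {
  w0 <- w; w0$noise_sd <- 0
  out <- vapply(lib, function(mol) {
    seed_i <- compound_pose_seed(rng_seed, mol)
    poses <- sample_poses(s, mol, site, n_poses = n_poses, t_max = t_max,
                          rng_seed = seed_i)
    sc <- vapply(poses, function(p)
      true_affinity(s, p, mol$atoms, w0, rng_seed = 0L), numeric(1))
    ensemble_score(sc, beta)
  }, numeric(1))
  setNames(out, names(lib))
}

# ---- Planted screening libraries ---------------------------------------

# Family archetypes: chemically distinct scaffold + repeat-unit chemistries
# so intra-family ECFP4 similarity stays above the Butina cutoff and
# inter-family similarity below it. `kind` drives the stage-5 traits.
.family_defs <- list(
  list(kind = "normal", r_ok = 3:7,
       make = function(r, cap = "O") paste0("c1ccc(", strrep("OCC", r), cap, ")cc1")),
  list(kind = "normal", r_ok = 2:4,
       make = function(r, cap = "") paste0("C1CCC(", strrep("CC(=O)NC", r), cap, ")CC1")),
  list(kind = "normal", r_ok = 3:5,
       make = function(r, cap = "O") paste0("c1cc(", strrep("OC(C)C", r), cap, ")cnc1")),
  list(kind = "normal", r_ok = 2:4,
       make = function(r, cap = "") paste0("C1CCOC(", strrep("COC(=O)C", r), "C", cap, ")C1")),
  list(kind = "normal", r_ok = 2:4,
       make = function(r, cap = "") paste0("COc1cc(OC)cc(", strrep("CCOC", r), "C", cap, ")c1")),
  list(kind = "pains", r_ok = 3:6,
       make = function(r, cap = "") paste0("Oc1ccc(", strrep("CCO", r), "C", cap, ")cc1O")),
  list(kind = "high_logp", r_ok = 8:12,
       make = function(r, cap = "") paste0("c1ccc(", strrep("CC", r), "C", cap, ")cc1")),
  list(kind = "mw_above", r_ok = 9:12,
       make = function(r, cap = "O") paste0("c1ccc2cc(", strrep("OCC(C)", r), cap, ")ccc2c1"))
)

.NITRO_CAP <- "[N+](=O)[O-]"

.small_pool <- c("CCO", "CCCO", "CCOCC", "CC(C)O", "CCCC", "COCC")

#' Build a planted screening-library plan
#'
#' One row per compound: its family, whether it ranks inside the top-K,
#' whether it is planted below the MW floor, whether it carries the
#' excluded (nitro) motif. Families 6-8 of the default archetypes carry
#' stage-5 traits (PAINS catechol core, cLogP > 5, MW > 500); traits are
#' family-uniform so the triage outcome is independent of which member
#' Butina picks as representative.
#'
#' @param n Library size.
#' @param top_k Rank cutoff the plan plants around.
#' @param frac_outside_topk,frac_below_mw,frac_excluded Planted fractions.
#' @param n_families Number of families used (2..8; the last three carry
#'   the stage-5 traits when included).
#' @param rng_seed Seed.
#' @return data.frame plan (one row per compound).
#' @export
make_screen_plan <- function(n = 1000L, top_k = 800L,
                             frac_outside_topk = NULL, frac_below_mw = 0.1,
                             frac_excluded = 0.1, n_families = 8L,
                             rng_seed = 1L) {
  stopifnot(n >= n_families, n_families >= 1, n_families <= length(.family_defs))
  with_seed(rng_seed, {
    fam <- sort(rep_len(seq_len(n_families), n))
    below <- rep(FALSE, n)
    n_below <- round(frac_below_mw * n)
    if (n_below > 0) below[sample.int(n, n_below)] <- TRUE
    excl <- rep(FALSE, n)
    cand <- which(!below)
    n_excl <- min(round(frac_excluded * n), length(cand))
    if (n_excl > 0) excl[sample(cand, n_excl)] <- TRUE
    ranks <- sample.int(n)  # ranks decoupled from family blocks
    data.frame(id = sprintf("cmp%05d", seq_len(n)), family = fam,
               rank = ranks, in_top_k = ranks <= top_k,
               below_mw = below, excluded_motif = excl,
               kind = vapply(.family_defs[fam], `[[`, "", "kind"),
               stringsAsFactors = FALSE)
  })
}

#' Generate a screening library with planted triage outcomes
#'
#' Emits SMILES per the plan and the exact expected survivor set of every
#' triage stage. Generation verifies its own plants — MW classes, planted
#' cLogP and PAINS traits, and (optionally) that ECFP4/Butina at the given
#' cutoff reproduces the family structure (all post-exclusion intra-family
#' similarities >= cutoff, inter-family < cutoff) — and raises a plan error
#' on any violation, so the returned truth is guaranteed, not assumed.
#'
#' @param plan From [make_screen_plan()].
#' @param rng_seed Seed for member-level variation.
#' @param butina_cutoff Clustering cutoff the truth is constructed for.
#' @param n_bits Fingerprint length.
#' @param mw_min,mw_max,logp_max The thresholds the plants are verified
#'   against.
#' @param verify_clusters Verify the family/cluster equivalence (O(n^2)
#'   fingerprint comparisons).
#' @return List: `smiles` (named), `mols`, `ranked` (screen-output-shaped
#'   data.frame), `plan`, `truth` (per-stage survivor counts and id sets).
#' @export
make_screen_library <- function(plan, rng_seed = 1L, butina_cutoff = 0.35,
                                n_bits = 2048L, mw_min = 200, mw_max = 500,
                                logp_max = 5, verify_clusters = TRUE) {
  n <- nrow(plan)
  smiles <- character(n)
  with_seed(rng_seed, {
    for (i in seq_len(n)) {
      if (plan$below_mw[i]) {
        smiles[i] <- sample(.small_pool, 1L)
      } else {
        fd <- .family_defs[[plan$family[i]]]
        r <- sample(fd$r_ok, 1L)
        # the excluded motif is planted as a nitro cap on the tail
        smiles[i] <- if (plan$excluded_motif[i]) fd$make(r, cap = .NITRO_CAP)
                     else fd$make(r)
      }
    }
  })
  names(smiles) <- plan$id
  parsed <- parse_smiles_set(smiles)
  if (nrow(parsed$rejects))
    vs_stop("plan error: generated SMILES failed to parse (%s)",
            paste(utils::head(parsed$rejects$id, 3), collapse = ", "))
  mols <- parsed$mols[plan$id]
  desc <- descriptor_table(mols)

  # verify plants against the real descriptor values
  mw <- desc[plan$id, "mw"]; lp <- desc[plan$id, "clogp"]
  bad <- (plan$below_mw & mw > mw_min) |
    (!plan$below_mw & mw <= mw_min) |
    (!plan$below_mw & plan$kind == "mw_above" & mw < mw_max) |
    (!plan$below_mw & plan$kind != "mw_above" & mw >= mw_max)
  if (any(bad)) vs_stop("plan error: MW class violated for %s",
                        paste(utils::head(plan$id[bad], 5), collapse = ", "))
  # mw_above families may be greasy too; they fail stage 5 on MW regardless
  badl <- (!plan$below_mw & plan$kind == "high_logp" & lp < logp_max) |
    (!plan$below_mw & !plan$kind %in% c("high_logp", "mw_above") &
       lp >= logp_max)
  if (any(badl)) vs_stop("plan error: cLogP trait violated for %s",
                         paste(utils::head(plan$id[badl], 5), collapse = ", "))
  pains_set <- default_pains_smarts()
  np <- pains_matches(mols, pains_set)
  badp <- (!plan$below_mw & plan$kind == "pains" & np == 0L) |
    (!plan$below_mw & plan$kind != "pains" & np > 0L)
  if (any(badp)) vs_stop("plan error: PAINS trait violated for %s",
                         paste(utils::head(plan$id[badp], 5), collapse = ", "))

  # truth cascade from the (verified) flags
  s1 <- plan$id[plan$in_top_k]
  s2 <- plan$id[plan$in_top_k & !plan$below_mw]
  s3 <- plan$id[plan$in_top_k & !plan$below_mw & !plan$excluded_motif]
  fam3 <- sort(unique(plan$family[plan$id %in% s3]))
  good_kind <- vapply(.family_defs[fam3], `[[`, "", "kind") == "normal"

  if (verify_clusters && length(s3) > 1) {
    fps <- lapply(mols[s3], ecfp4, n_bits = n_bits)
    fam_of <- plan$family[match(s3, plan$id)]
    for (i in seq_len(length(s3) - 1)) for (j in seq(i + 1, length(s3))) {
      sim <- tanimoto(fps[[i]], fps[[j]])
      same <- fam_of[i] == fam_of[j]
      if (same && sim < butina_cutoff)
        vs_stop("plan error: intra-family similarity %.2f < cutoff (%s vs %s)",
                sim, s3[i], s3[j])
      if (!same && sim >= butina_cutoff)
        vs_stop("plan error: inter-family similarity %.2f >= cutoff (%s vs %s)",
                sim, s3[i], s3[j])
    }
  }

  ranked <- data.frame(rank = plan$rank, compound_id = plan$id)
  ranked <- ranked[order(ranked$rank), ]
  rownames(ranked) <- NULL
  truth <- list(
    stage_counts = c(input = n, top_k = length(s1), mw_min = length(s2),
                     smarts = length(s3),
                     cluster_representatives = length(fam3),
                     final = sum(good_kind)),
    top_k = s1, mw_min = s2, smarts = s3,
    n_clusters = length(fam3), n_final = sum(good_kind))
  list(smiles = smiles, mols = mols, ranked = ranked, plan = plan,
       truth = truth)
}

#' Write a library as a SMILES file
#'
#' @param smiles Named character vector (`SMILES<TAB>id` lines).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_smiles <- function(smiles, path) {
  writeLines(paste(smiles, names(smiles), sep = "\t"), path)
  invisible(path)
}
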