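# Binding-site definition by flooding.
#
# The site is grown breadth-first from a seed point over a cubic lattice
# anchored at the seed. A lattice point is part of the site iff it is
#   open:   no protein heavy atom within `occlusion_radius` of its center,
#   buried: at least `burial_min_neighbors` protein heavy atoms within
#           `burial_radius` of its center (keeps the flood out of open
#           solvent), and
#   reachable from the seed through open+buried points within `max_radius`.
# The site center is the unweighted arithmetic mean of the flooded voxel
# centers; it becomes the grid origin reference for featurization.

#' Flooding parameters
#'
#' @param spacing Lattice spacing, Angstrom.
#' @param occlusion_radius A lattice point closer than this to any protein
#'   heavy atom is closed (Angstrom).
#' @param max_radius Maximum Euclidean distance of a flooded point from the
#'   seed (Angstrom).
#' @param burial_min_neighbors Minimum protein heavy atoms within
#'   `burial_radius` for a point to count as buried.
#' @param burial_radius Burial counting radius, Angstrom.
#' @param connectivity Lattice connectivity for the flood: 6 (faces) or 26.
#' @return An object of class `flood_params`.
#' @export
flood_params <- function(spacing = 1.0, occlusion_radius = 2.0,
                         max_radius = 12.0, burial_min_neighbors = 8L,
                         burial_radius = 8.0, connectivity = 6L) {
  stopifnot(spacing > 0, occlusion_radius > 0, max_radius >= spacing,
            burial_radius > 0, burial_min_neighbors >= 0,
            connectivity %in% c(6L, 26L))
  structure(list(spacing = spacing, occlusion_radius = occlusion_radius,
                 max_radius = max_radius,
                 burial_min_neighbors = as.integer(burial_min_neighbors),
                 burial_radius = burial_radius,
                 connectivity = as.integer(connectivity)),
            class = "flood_params")
}

.neighbor_offsets <- function(connectivity) {
  if (connectivity == 6L) {
    rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
          c(0, 0, 1), c(0, 0, -1))
  } else {
    g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
    g[rowSums(abs(g)) > 0, , drop = FALSE]
  }
}

#' Flood a binding site from a seed point
#'
#' Breadth-first region growing from `seed` over a lattice anchored at the
#' seed (the seed sits exactly on a lattice point). See [flood_params()] for
#' the open/buried/radius rules. If the flood keeps pressing against the
#' `max_radius` boundary in most directions, an "open-solvent" warning is
#' emitted (the site is still returned).
#'
#' @param s A [vox_structure()]; only protein heavy atoms occlude.
#' @param seed Numeric 3-vector, Angstrom.
#' @param params A [flood_params()].
#' @return An object of class `binding_site` with fields `seed`, `voxels`
#'   (integer offset triples from the seed, one row each), `origin`,
#'   `spacing`, `center`, `params` and (after [pocket_residues()]) the
#'   pocket residue list.
#' @export
flood_site <- function(s, seed, params = flood_params()) {
  stopifnot(inherits(s, "vox_structure"), length(seed) == 3)
  seed <- as.numeric(seed)
  p <- params
  prot <- struct_coords(s, role = "protein")
  if (ncol(prot) == 0L) vs_stop("structure has no protein atoms to flood against")

  occ2 <- p$occlusion_radius^2
  bur2 <- p$burial_radius^2
  # squared distances from one lattice point to all protein atoms
  open_and_buried <- function(pt) {
    d2 <- colSums((prot - pt)^2)
    if (any(d2 < occ2)) return(c(FALSE, FALSE))
    c(TRUE, sum(d2 <= bur2) >= p$burial_min_neighbors)
  }

  ob <- open_and_buried(seed)
  if (!ob[1]) vs_stop("seed point is occluded by a protein atom within %.2f A",
                      p$occlusion_radius)
  if (!ob[2]) vs_stop("seed point is not buried (%d+ protein atoms within %.1f A required)",
                      p$burial_min_neighbors, p$burial_radius)

  offsets <- .neighbor_offsets(p$connectivity)
  rmax_vox <- p$max_radius / p$spacing
  key <- function(v) paste(v[1], v[2], v[3])
  visited <- new.env(hash = TRUE, parent = emptyenv())
  assign(key(c(0, 0, 0)), TRUE, envir = visited)
  accepted <- list(c(0L, 0L, 0L))
  escaping <- new.env(hash = TRUE, parent = emptyenv())  # voxels pressing past the bound
  queue <- list(c(0L, 0L, 0L))
  qhead <- 1L

  while (qhead <= length(queue)) {
    v <- queue[[qhead]]; qhead <- qhead + 1L
    for (r in seq_len(nrow(offsets))) {
      w <- v + offsets[r, ]
      k <- key(w)
      if (!is.null(visited[[k]])) next
      if (sqrt(sum(w^2)) > rmax_vox) {
        # would the flood have continued here but for the radius bound?
        pt <- seed + w * p$spacing
        obw <- open_and_buried(pt)
        if (obw[1] && obw[2]) assign(key(v), TRUE, envir = escaping)
        next
      }
      assign(k, TRUE, envir = visited)
      pt <- seed + w * p$spacing
      obw <- open_and_buried(pt)
      if (obw[1] && obw[2]) {
        accepted[[length(accepted) + 1L]] <- as.integer(w)
        queue[[length(queue) + 1L]] <- as.integer(w)
      }
    }
  }

  vox <- do.call(rbind, accepted)
  colnames(vox) <- c("i", "j", "k")
  centers <- sweep(vox * p$spacing, 2, seed, `+`)
  center <- unname(colMeans(centers))
  # open-solvent diagnostic: of the flooded voxels touching the max_radius
  # boundary (outer shell), how many were still growing when the bound cut
  # them off? A closed pocket never reaches the shell; a leaking one mostly
  # does.
  shell <- sqrt(rowSums(vox^2)) > rmax_vox - 1
  n_shell <- sum(shell)
  n_escaping <- length(ls(escaping))
  frac <- if (n_shell == 0L) 0 else n_escaping / n_shell
  if (n_shell > 0L && frac > 0.5)
    vs_warn("open-solvent warning: %d of %d boundary voxels press past max_radius",
            n_escaping, n_shell)
  structure(list(seed = seed, voxels = vox, origin = seed,
                 spacing = p$spacing, center = center, params = p,
                 pocket_residues = NULL,
                 open_solvent_fraction = frac),
            class = "binding_site")
}

#' @export
print.binding_site <- function(x, ...) {
  cat(sprintf("<binding_site: %d voxels at %.2f A spacing, center (%.2f, %.2f, %.2f)>\n",
              nrow(x$voxels), x$spacing, x$center[1], x$center[2], x$center[3]))
  invisible(x)
}

# Absolute coordinates (N x 3) of a site's voxel centers.
site_voxel_centers <- function(site) {
  sweep(site$voxels * site$spacing, 2, site$seed, `+`)
}

#' Seed point from named residues
#'
#' Returns the centroid of all heavy atoms of the named protein residues —
#' the usual way to seed the flood when mutagenesis or template alignment
#' identifies the pocket residues rather than a bound ligand.
#'
#' @param s A [vox_structure()].
#' @param refs Residue references: a data.frame from
#'   [parse_residue_spec()] (columns `aa`, `res_index`).
#' @return Numeric 3-vector (Angstrom).
#' @export
seed_from_residues <- function(s, refs) {
  a <- s$atoms[s$atoms$role == "protein", , drop = FALSE]
  sel <- rep(FALSE, nrow(a))
  for (r in seq_len(nrow(refs))) {
    hit <- a$res_index == refs$res_index[r] &
      (.AA3TO1[a$res_name] %in% refs$aa[r] | a$res_name == refs$aa[r])
    if (!any(hit))
      vs_stop("residue %s%d not found in structure '%s'",
              refs$aa[r], refs$res_index[r], s$id)
    sel <- sel | hit
  }
  colMeans(a[sel, c("x", "y", "z")])
}

#' Pocket residues lining a binding site
#'
#' Protein residues with at least one heavy atom within `cutoff` of at least
#' one flooded voxel center, sorted by residue index and deduplicated.
#'
#' @param s A [vox_structure()].
#' @param site A [flood_site()] result.
#' @param cutoff Distance cutoff, Angstrom.
#' @return data.frame with columns `aa` (1-letter code) and `res_index`.
#' @export
pocket_residues <- function(s, site, cutoff = 4.5) {
  stopifnot(nrow(site$voxels) > 0)
  a <- s$atoms[s$atoms$role == "protein", , drop = FALSE]
  centers <- site_voxel_centers(site)
  near <- vapply(seq_len(nrow(a)), function(i) {
    d2 <- (centers[, 1] - a$x[i])^2 + (centers[, 2] - a$y[i])^2 +
      (centers[, 3] - a$z[i])^2
    any(d2 <= cutoff^2)
  }, logical(1))
  hit <- unique(a[near, c("res_name", "res_index", "chain")])
  hit <- hit[order(hit$res_index), , drop = FALSE]
  aa1 <- .AA3TO1[hit$res_name]
  aa1[is.na(aa1)] <- "X"
  data.frame(aa = unname(aa1), res_index = hit$res_index,
             stringsAsFactors = FALSE)
}

#' Export a binding site as JSON
#'
#' Serializes seed, spacing, flood parameters, voxel offsets, center and
#' pocket residues (as a residue-spec string) so a site can be reloaded or
#' inspected without the structure.
#'
#' @param site A [flood_site()] result.
#' @param path Output path.
#' @param residues Optional data.frame from [pocket_residues()].
#' @return `path`, invisibly.
#' @export
write_site_json <- function(site, path, residues = NULL) {
  obj <- list(seed = site$seed, spacing = site$spacing,
              params = unclass(site$params),
              center = site$center,
              voxels = unname(apply(site$voxels, 1, function(v) as.integer(v),
                                    simplify = FALSE)),
              pocket_residues = if (!is.null(residues))
                format_residue_spec(residues) else NULL)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Reload a binding site from JSON
#'
#' @param path Path written by [write_site_json()].
#' @return A `binding_site` object.
#' @export
read_site_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- do.call(flood_params, obj$params)
  vox <- if (is.matrix(obj$voxels)) obj$voxels
         else matrix(as.integer(unlist(obj$voxels)), ncol = 3, byrow = TRUE)
  storage.mode(vox) <- "integer"
  dimnames(vox) <- list(NULL, c("i", "j", "k"))
  res_spec <- obj$pocket_residues
  structure(list(seed = as.numeric(obj$seed), voxels = vox,
                 origin = as.numeric(obj$seed), spacing = obj$spacing,
                 center = as.numeric(obj$center), params = p,
                 pocket_residues = if (is.character(res_spec) &&
                                       length(res_spec) == 1L &&
                                       nzchar(res_spec))
                   parse_residue_spec(res_spec) else NULL,
                 open_solvent_fraction = NA_real_),
            class = "binding_site")
}
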