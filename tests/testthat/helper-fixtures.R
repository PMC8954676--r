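# Shared fixture builders. Everything is generated in code; no binary data.

# A minimal PDB text fixture with the given records.
write_fixture_pdb <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), path)
  path
}

pdb_atom_line <- function(serial, name, res_name, chain, res_index, x, y, z,
                          record = "ATOM  ", element = NULL, occ = 1, b = 0,
                          altloc = " ") {
  if (is.null(element)) element <- substr(trimws(name), 1, 1)
  name4 <- if (nchar(name) >= 4) substr(name, 1, 4) else sprintf(" %-3s", name)
  # wwPDB v3.3 columns: name 13-16, altLoc 17, resName 18-20, chainID 22,
  # resSeq 23-26, x from 31
  sprintf("%-6s%5d %s%s%-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name4, altloc, res_name, chain, res_index,
          x, y, z, occ, b, toupper(element))
}

# A tiny three-residue protein with full N/CA/C backbones.
toy_protein <- function(path = tempfile(fileext = ".pdb")) {
  lines <- c(
    pdb_atom_line(1, "N",  "ALA", "A", 1, 0.0, 0.0, 0.0),
    pdb_atom_line(2, "CA", "ALA", "A", 1, 1.5, 0.0, 0.0),
    pdb_atom_line(3, "C",  "ALA", "A", 1, 2.2, 1.3, 0.0),
    pdb_atom_line(4, "N",  "GLY", "A", 2, 3.5, 1.3, 0.2),
    pdb_atom_line(5, "CA", "GLY", "A", 2, 4.4, 2.4, 0.3),
    pdb_atom_line(6, "C",  "GLY", "A", 2, 5.8, 2.0, 0.6),
    pdb_atom_line(7, "N",  "SER", "A", 3, 6.7, 3.0, 0.6),
    pdb_atom_line(8, "CA", "SER", "A", 3, 8.1, 2.8, 0.9),
    pdb_atom_line(9, "C",  "SER", "A", 3, 8.9, 4.1, 1.0))
  write_fixture_pdb(lines, path)
}

# Closed cubic test pocket shared across sitefinder/synthdata tests:
# 3 A cavity whose flood at 1 A spacing is exactly the 27 center voxels.
tiny_pocket <- function() make_pocket(pocket_params(cavity_edge = 3))

# Independent breadth-first flood oracle: enumerate the full lattice,
# classify every point open/buried by brute force, then take the seed's
# connected component by BFS over the precomputed adjacency. Deliberately
# a different route from flood_site(), which classifies points on demand
# during the traversal.
flood_oracle <- function(s, seed, params) {
  p <- params
  prot <- t(as.matrix(s$atoms[s$atoms$role == "protein", c("x", "y", "z")]))
  rmax <- floor(p$max_radius / p$spacing)
  rng <- -rmax:rmax
  lat <- as.matrix(expand.grid(i = rng, j = rng, k = rng))
  lat <- lat[sqrt(rowSums(lat^2)) <= p$max_radius / p$spacing, , drop = FALSE]
  pts <- sweep(lat * p$spacing, 2, seed, `+`)
  keep <- logical(nrow(lat))
  for (r in seq_len(nrow(lat))) {
    d2 <- colSums((prot - pts[r, ])^2)
    keep[r] <- !any(d2 < p$occlusion_radius^2) &&
      sum(d2 <= p$burial_radius^2) >= p$burial_min_neighbors
  }
  lat <- lat[keep, , drop = FALSE]
  key <- paste(lat[, 1], lat[, 2], lat[, 3], sep = ",")
  idx <- stats::setNames(seq_len(nrow(lat)), key)
  offs <- if (p$connectivity == 6L) {
    rbind(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1))
  } else {
    g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
    g[rowSums(abs(g)) > 0, , drop = FALSE]
  }
  start <- idx[["0,0,0"]]
  if (is.na(start)) stop("oracle: seed voxel not open/buried")
  seen <- logical(nrow(lat)); seen[start] <- TRUE
  queue <- start
  while (length(queue)) {
    v <- queue[[1]]; queue <- queue[-1]
    for (o in seq_len(nrow(offs))) {
      w <- lat[v, ] + offs[o, ]
      wi <- idx[paste(w[1], w[2], w[3], sep = ",")]
      if (!is.na(wi) && !seen[wi]) { seen[wi] <- TRUE; queue <- c(queue, wi) }
    }
  }
  out <- lat[seen, , drop = FALSE]
  out[order(out[, 1], out[, 2], out[, 3]), , drop = FALSE]
}

sorted_voxels <- function(site) {
  v <- site$voxels
  v <- v[order(v[, 1], v[, 2], v[, 3]), , drop = FALSE]
  dimnames(v) <- NULL
  v
}

# Random occupancy maze: scatter pseudo-atoms in a box, pick an open+buried
# seed on the lattice. Used for flood equivalence property tests.
random_maze <- function(seed, n_atoms = 220, box = 9) {
  set.seed(seed)
  atoms <- data.frame(
    element = sample(c("C", "N", "O"), n_atoms, TRUE),
    x = runif(n_atoms, -box, box), y = runif(n_atoms, -box, box),
    z = runif(n_atoms, -box, box),
    atom_name = "X", res_index = rep(seq_len(ceiling(n_atoms / 8)),
                                     each = 8)[seq_len(n_atoms)],
    res_name = "ALA", chain = "A", role = "protein",
    occupancy = 1, bfactor = 0)
  s <- vox_structure(atoms, sprintf("maze%d", seed))
  p <- flood_params(max_radius = 6, occlusion_radius = 1.5,
                    burial_min_neighbors = 4, burial_radius = 6)
  prot <- t(as.matrix(atoms[, c("x", "y", "z")]))
  for (try in 1:200) {
    cand <- runif(3, -3, 3)
    d2 <- colSums((prot - cand)^2)
    if (!any(d2 < p$occlusion_radius^2) &&
        sum(d2 <= p$burial_radius^2) >= p$burial_min_neighbors)
      return(list(structure = s, seed = cand, params = p))
  }
  NULL
}

# Reference Butina implementation: a literal transcription of the published
# procedure over a full similarity matrix. Kept independent of
# butina_cluster()'s neighbor-list code path.
butina_oracle <- function(fps, cutoff) {
  ids <- names(fps)
  n <- length(fps)
  simmat <- matrix(1, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    simmat[i, j] <- tanimoto(fps[[i]], fps[[j]])
  nb <- simmat >= cutoff
  diag(nb) <- FALSE
  counts <- rowSums(nb)
  remaining <- rep(TRUE, n)
  assign <- rep(NA_integer_, n)
  cl <- 0L
  while (any(remaining)) {
    cand <- which(remaining)
    cand <- cand[order(-counts[cand], ids[cand])]
    rep_i <- cand[1]
    cl <- cl + 1L
    members <- c(rep_i, which(nb[rep_i, ] & remaining))
    members <- unique(members)
    assign[members] <- cl
    remaining[members] <- FALSE
  }
  stats::setNames(assign, ids)
}

# Random sparse fingerprints for property tests.
random_fp <- function(n_bits = 64, density = 0.2) {
  bits <- sort(sample(0:(n_bits - 1), max(1, rbinom(1, n_bits, density))))
  structure(unique(bits), n_bits = as.integer(n_bits), class = "ecfp")
}

# Canonical partition signature (cluster labels up to renumbering).
partition_signature <- function(assign) {
  ids <- sort(names(assign))
  a <- assign[ids]
  match(a, unique(a))
}
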