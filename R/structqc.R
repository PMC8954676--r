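# Structure-model quality checks: least-squares superposition (Kabsch),
# backbone RMSD between paired structures, ligand steric-clash detection,
# and pLDDT confidence banding.

#' Optimal rigid superposition (Kabsch algorithm)
#'
#' Finds the proper rotation + translation minimizing the RMSD of `B` onto
#' `A` (correspondence by column index), via SVD of the cross-covariance
#' with the usual determinant correction so reflections are never returned.
#'
#' @param A,B 3 x N coordinate matrices, N >= 3.
#' @return List with `transform` ([rigid_transform()] mapping B onto A),
#'   `rmsd` (Angstrom) and `n_atoms`.
#' @export
kabsch_superpose <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (nrow(A) != 3 || nrow(B) != 3 || ncol(A) != ncol(B))
    vs_stop("A and B must be 3 x N matrices of equal N")
  n <- ncol(A)
  if (n < 3) vs_stop("superposition needs at least 3 paired atoms")
  ca <- rowMeans(A); cb <- rowMeans(B)
  A0 <- A - ca; B0 <- B - cb
  H <- B0 %*% t(A0)
  sv <- svd(H)
  if (sv$d[2] < 1e-10 * max(sv$d[1], 1))
    vs_stop("degenerate (collinear) coordinates: superposition ill-conditioned")
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  Bfit <- R %*% B0 + ca
  rmsd <- sqrt(mean(colSums((Bfit - A)^2)))
  list(transform = rigid_transform(R, ca - R %*% cb),
       rmsd = rmsd, n_atoms = n)
}

#' Backbone RMSD between two structures
#'
#' Pairs residues by index (optionally shifted by `offset` on `b`), collects
#' the requested backbone atoms from each paired residue, and delegates to
#' [kabsch_superpose()].
#'
#' @param a,b [vox_structure()] objects.
#' @param atom_names Backbone atom set (default `c("N", "CA", "C")`;
#'   `"CA"`-only is the common alternative).
#' @param offset Added to `b`'s residue indices before pairing.
#' @return The [kabsch_superpose()] result (fields `transform`, `rmsd`,
#'   `n_atoms`).
#' @export
backbone_rmsd <- function(a, b, atom_names = c("N", "CA", "C"), offset = 0L) {
  pa <- a$atoms[a$atoms$role == "protein" & a$atoms$atom_name %in% atom_names, ]
  pb <- b$atoms[b$atoms$role == "protein" & b$atoms$atom_name %in% atom_names, ]
  pb$res_index <- pb$res_index + as.integer(offset)
  shared <- intersect(unique(pa$res_index), unique(pb$res_index))
  if (!length(shared)) vs_stop("no paired residues between '%s' and '%s'", a$id, b$id)
  keyA <- paste(pa$res_index, pa$atom_name)
  keyB <- paste(pb$res_index, pb$atom_name)
  offenders <- character(0)
  coordsA <- NULL; coordsB <- NULL
  for (ri in shared) {
    for (an in atom_names) {
      iA <- which(keyA == paste(ri, an))
      iB <- which(keyB == paste(ri, an))
      if (length(iA) != 1L || length(iB) != 1L) {
        offenders <- c(offenders, paste0(an, "@", ri))
        next
      }
      coordsA <- cbind(coordsA, c(pa$x[iA], pa$y[iA], pa$z[iA]))
      coordsB <- cbind(coordsB, c(pb$x[iB], pb$y[iB], pb$z[iB]))
    }
  }
  if (length(offenders))
    vs_stop("unpaired backbone atoms: %s",
            paste(utils::head(offenders, 10), collapse = ", "))
  kabsch_superpose(coordsA, coordsB)
}

#' Detect steric clashes between placed ligand coordinates and a protein
#'
#' A ligand-protein heavy-atom pair clashes iff its distance is below
#' `factor * (vdW_lig + vdW_prot)` (Bondi radii). Matches the clash rule
#' used by pose sampling, so a pose accepted by [sample_poses()] yields an
#' empty report at the same factor.
#'
#' @param lig_coords 3 x N matrix of ligand heavy-atom coordinates.
#' @param lig_elements Element symbols for the ligand atoms.
#' @param s A [vox_structure()].
#' @param factor Fraction of the vdW sum (default 0.75).
#' @return data.frame with one row per clashing pair: `lig_atom`, `aa`,
#'   `res_index`, `res_name`, `atom_name`, `distance`, `threshold`.
#' @export
detect_clashes <- function(lig_coords, lig_elements, s, factor = 0.75) {
  prot <- s$atoms[s$atoms$role == "protein", , drop = FALSE]
  pxyz <- t(as.matrix(prot[, c("x", "y", "z")]))
  pvdw <- vdw_radius(prot$element)
  lvdw <- vdw_radius(lig_elements)
  out <- list()
  for (i in seq_len(ncol(lig_coords))) {
    d <- sqrt(colSums((pxyz - lig_coords[, i])^2))
    thr <- factor * (pvdw + lvdw[i])
    hit <- which(d < thr)
    for (h in hit) {
      aa1 <- .AA3TO1[prot$res_name[h]]
      out[[length(out) + 1L]] <- data.frame(
        lig_atom = i, aa = if (is.na(aa1)) "X" else unname(aa1),
        res_index = prot$res_index[h], res_name = prot$res_name[h],
        atom_name = prot$atom_name[h],
        distance = d[h], threshold = thr[h])
    }
  }
  if (!length(out))
    return(data.frame(lig_atom = integer(), aa = character(),
                      res_index = integer(), res_name = character(),
                      atom_name = character(), distance = numeric(),
                      threshold = numeric()))
  do.call(rbind, out)
}

#' Confidence bands for per-residue pLDDT scores
#'
#' Default edges follow the AlphaFold DB convention: >= 90 very_high,
#' 70-90 confident, 50-70 low, < 50 very_low; boundaries are inclusive at
#' the lower edge of the higher band (a score of exactly 90 is very_high).
#'
#' @param edges Strictly decreasing numeric edges.
#' @param labels One more label than edges, best first.
#' @return Object of class `confidence_bands`.
#' @export
confidence_bands <- function(edges = c(90, 70, 50),
                             labels = c("very_high", "confident", "low", "very_low")) {
  stopifnot(length(labels) == length(edges) + 1L, all(diff(edges) < 0))
  structure(list(edges = edges, labels = labels), class = "confidence_bands")
}

#' Band per-residue pLDDT scores and summarize regions
#'
#' @param plddt Named numeric vector of per-residue scores in \[0, 100\]
#'   (names = residue indices).
#' @param bands A [confidence_bands()].
#' @param regions Optional named list of residue-index vectors; each region
#'   is summarized by the band of its mean score.
#' @return List with `residue_labels` (named character vector) and
#'   `regions` (data.frame with `region`, `mean_plddt`, `label`).
#' @export
band_confidence <- function(plddt, bands = confidence_bands(), regions = NULL) {
  if (any(!is.finite(plddt)) || any(plddt < 0 | plddt > 100))
    vs_stop("pLDDT scores must lie in [0, 100]")
  lab1 <- function(x) bands$labels[sum(x < bands$edges) + 1L]
  res_lab <- vapply(plddt, lab1, "")
  reg <- NULL
  if (!is.null(regions)) {
    reg <- do.call(rbind, lapply(names(regions), function(nm) {
      idx <- as.character(regions[[nm]])
      m <- mean(plddt[idx])
      data.frame(region = nm, mean_plddt = m, label = lab1(m))
    }))
  }
  list(residue_labels = res_lab, regions = reg)
}

#' Read per-residue pLDDT from a PDB B-factor column or a two-column CSV
#'
#' AlphaFold DB deposits pLDDT in the B-factor field; alternatively a CSV
#' with columns `res_index`, `plddt` is accepted.
#'
#' @param path PDB or CSV file path.
#' @return Named numeric vector (names = residue indices).
#' @export
read_plddt <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    tab <- read.csv(path)
    return(setNames(as.numeric(tab$plddt), tab$res_index))
  }
  s <- read_pdb(path)
  a <- s$atoms[s$atoms$role == "protein", ]
  agg <- tapply(a$bfactor, a$res_index, function(v) v[1])
  setNames(as.numeric(agg), names(agg))
}
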