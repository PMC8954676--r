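# Small-molecule graphs: SMILES/SDF ingestion via ChemmineR/ChemmineOB
# (OpenBabel) and a light graph container the featurizer and descriptor
# code operate on.
#
# A mol_graph holds: id, smiles, atoms (element vector), bonds (matrix with
# columns i, j, order), charges, optional 3 x N coords, and (when the
# molecule came through OpenBabel) the ChemmineR SDF object, reused for
# property and SMARTS calls.

#' Construct a molecular graph
#'
#' @param id Text identifier.
#' @param atoms Character vector of element symbols (heavy atoms).
#' @param bonds Integer matrix with columns `i`, `j`, `order` (1-based atom
#'   indices; order 1/2/3, 4 = aromatic).
#' @param coords Optional 3 x N matrix of coordinates (Angstrom).
#' @param smiles Optional SMILES string.
#' @param charges Optional integer vector of formal charges (default 0).
#' @param sdf Optional ChemmineR `SDF` object backing this molecule.
#' @return An object of class `mol_graph`.
#' @export
mol_graph <- function(id, atoms, bonds, coords = NULL, smiles = NA_character_,
                      charges = NULL, sdf = NULL) {
  atoms <- normalize_element(atoms)
  n <- length(atoms)
  if (n == 0L) vs_stop("molecule '%s' has no heavy atoms", id)
  if (is.null(bonds)) bonds <- matrix(integer(), 0, 3)
  bonds <- matrix(as.integer(bonds), ncol = 3,
                  dimnames = list(NULL, c("i", "j", "order")))
  if (nrow(bonds) && (min(bonds[, 1:2]) < 1L || max(bonds[, 1:2]) > n))
    vs_stop("molecule '%s': bond endpoint out of range", id)
  if (!is.null(coords)) {
    coords <- as.matrix(coords)
    if (nrow(coords) != 3L || ncol(coords) != n)
      vs_stop("molecule '%s': coords must be 3 x %d", id, n)
  }
  if (is.null(charges)) charges <- integer(n)
  structure(list(id = as.character(id), atoms = atoms, bonds = bonds,
                 coords = coords, smiles = smiles,
                 charges = as.integer(charges), sdf = sdf),
            class = "mol_graph")
}

#' @export
print.mol_graph <- function(x, ...) {
  cat(sprintf("<mol_graph '%s': %d heavy atoms, %d bonds%s%s>\n", x$id,
              length(x$atoms), nrow(x$bonds),
              if (!is.null(x$coords)) ", 3D" else "",
              if (!is.na(x$smiles)) paste0(", ", x$smiles) else ""))
  invisible(x)
}

# MDL charge codes in SDF atom blocks: 1..7 -> +3,+2,+1,radical,-1,-2,-3
.mdl_charge <- function(code) {
  map <- c(0L, 3L, 2L, 1L, 0L, -1L, -2L, -3L)
  out <- map[as.integer(code) + 1L]
  out[is.na(out)] <- 0L
  out
}

# Convert one ChemmineR SDF object to a mol_graph, dropping explicit
# hydrogens and remapping bond indices.
sdf_to_molgraph <- function(sdf, id, smiles = NA_character_, use_coords = TRUE) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  el <- normalize_element(gsub("_.*$", "", rownames(ab)))
  heavy <- !(el %in% c("H", "D"))
  if (!any(heavy)) vs_stop("molecule '%s' has no heavy atoms", id)
  remap <- cumsum(heavy)
  bonds <- NULL
  if (!is.null(bb) && nrow(bb)) {
    bi <- as.integer(bb[, 1]); bj <- as.integer(bb[, 2])
    keep <- heavy[bi] & heavy[bj]
    bonds <- cbind(remap[bi[keep]], remap[bj[keep]], as.integer(bb[keep, 3]))
  }
  charges <- .mdl_charge(if (ncol(ab) >= 5) ab[heavy, 5] else 0)
  coords <- if (use_coords) t(as.matrix(ab[heavy, 1:3, drop = FALSE])) else NULL
  mol_graph(id, el[heavy], bonds, coords = coords, smiles = smiles,
            charges = charges, sdf = sdf)
}

# Light syntactic lint for SMILES records. OpenBabel silently coerces some
# truncated strings (e.g. "C(C" parses as ethane), so unbalanced
# parentheses/brackets and unpaired ring closures are rejected up front.
smiles_lint <- function(s) {
  if (!nzchar(s)) return("empty SMILES")
  chars <- strsplit(s, "")[[1]]
  if (sum(chars == "(") != sum(chars == ")")) return("unbalanced parentheses")
  if (sum(chars == "[") != sum(chars == "]")) return("unbalanced brackets")
  body <- gsub("\\[[^]]*\\]", "A", s)         # bracket atoms opaque
  body <- gsub("%[0-9]{2}", "~", body)        # two-digit ring closures
  digits <- gsub("[^0-9~]", "", body)
  counts <- table(strsplit(digits, "")[[1]])
  if (any(counts %% 2 != 0)) return("unpaired ring-bond closure")
  if (grepl("[^A-Za-z0-9@+%\\^\\-\\[\\]()=#$:/\\\\~.*]", s))
    return("invalid character")
  NA_character_
}

#' Read a ligand library from SMILES or SDF
#'
#' SMILES format: one record per line, `SMILES<TAB>id` (id optional; a
#' running index is used when absent). Lines starting with `#` are skipped.
#' Invalid records are collected in a rejects table, not silently dropped,
#' and do not abort the run. SDF (V2000) 3D coordinates are preserved.
#'
#' @param path File path.
#' @param format `"smiles"` or `"sdf"`.
#' @return A list with elements `mols` (named list of [mol_graph()]) and
#'   `rejects` (data.frame with columns `id`, `reason`).
#' @export
read_ligands <- function(path, format = c("smiles", "sdf")) {
  format <- match.arg(format)
  if (!file.exists(path)) vs_stop("cannot read ligand file: %s", path)
  if (format == "smiles") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
    parts <- strsplit(lines, "[\t ]+")
    smi <- vapply(parts, `[`, "", 1L)
    ids <- vapply(parts, function(p) if (length(p) >= 2) p[2] else NA_character_, "")
    ids[is.na(ids)] <- sprintf("mol%05d", which(is.na(ids)))
    parse_smiles_set(setNames(smi, ids))
  } else {
    sdfset <- ChemmineR::read.SDFset(path)
    ids <- ChemmineR::sdfid(sdfset)
    ids[!nzchar(ids)] <- sprintf("mol%05d", which(!nzchar(ids)))
    valid <- ChemmineR::validSDF(sdfset)
    mols <- list(); rejects <- list()
    for (k in seq_along(sdfset)) {
      if (!valid[k]) {
        rejects[[length(rejects) + 1L]] <- data.frame(
          id = ids[k], reason = "invalid SDF record")
        next
      }
      m <- tryCatch(sdf_to_molgraph(sdfset[[k]], ids[k]),
                    error = function(e) conditionMessage(e))
      if (is.character(m)) {
        rejects[[length(rejects) + 1L]] <- data.frame(id = ids[k], reason = m)
      } else mols[[ids[k]]] <- m
    }
    list(mols = mols,
         rejects = if (length(rejects)) do.call(rbind, rejects)
                   else data.frame(id = character(), reason = character()))
  }
}

# Parse a named vector of SMILES through OpenBabel, with lint-based
# rejection. Batch conversion, falling back to per-record on failure.
parse_smiles_set <- function(smiles) {
  ids <- names(smiles)
  if (is.null(ids) || any(!nzchar(ids)))
    ids <- names(smiles) <- sprintf("mol%05d", seq_along(smiles))
  if (anyDuplicated(ids)) vs_stop("duplicate ligand ids")
  lint <- vapply(smiles, smiles_lint, "")
  rejects <- data.frame(id = ids[!is.na(lint)], reason = lint[!is.na(lint)],
                        row.names = NULL)
  good <- smiles[is.na(lint)]
  mols <- list()
  if (length(good)) {
    sdfset <- tryCatch(ChemmineR::smiles2sdf(good), error = function(e) NULL)
    if (is.null(sdfset) || length(sdfset) != length(good)) {
      for (k in seq_along(good)) {
        s1 <- tryCatch(ChemmineR::smiles2sdf(good[k]), error = function(e) NULL)
        if (is.null(s1)) {
          rejects <- rbind(rejects, data.frame(id = names(good)[k],
                                               reason = "SMILES parse failure"))
        } else {
          mols[[names(good)[k]]] <- sdf_to_molgraph(
            s1[[1]], names(good)[k], smiles = unname(good[k]), use_coords = FALSE)
        }
      }
    } else {
      for (k in seq_along(sdfset)) {
        m <- tryCatch(
          sdf_to_molgraph(sdfset[[k]], names(good)[k],
                          smiles = unname(good[k]), use_coords = FALSE),
          error = function(e) conditionMessage(e))
        if (is.character(m)) {
          rejects <- rbind(rejects, data.frame(id = names(good)[k], reason = m))
        } else mols[[names(good)[k]]] <- m
      }
    }
  }
  list(mols = mols, rejects = rejects)
}

# Heavy-atom degree of every atom.
mol_degree <- function(mol) {
  deg <- integer(length(mol$atoms))
  if (nrow(mol$bonds)) {
    t1 <- tabulate(mol$bonds[, "i"], nbins = length(deg))
    t2 <- tabulate(mol$bonds[, "j"], nbins = length(deg))
    deg <- t1 + t2
  }
  deg
}

# Implicit hydrogen count per heavy atom from a standard valence model:
# nH = max(0, default_valence(element) + formal_charge - sum of bond orders),
# aromatic bonds (order 4) counted as 1.5 with the total rounded.
mol_nH <- function(mol) {
  val <- .DEFAULT_VALENCE[mol$atoms]
  val[is.na(val)] <- 0
  bsum <- numeric(length(mol$atoms))
  if (nrow(mol$bonds)) {
    ord <- ifelse(mol$bonds[, "order"] == 4L, 1.5, mol$bonds[, "order"])
    for (k in seq_len(nrow(mol$bonds))) {
      bsum[mol$bonds[k, "i"]] <- bsum[mol$bonds[k, "i"]] + ord[k]
      bsum[mol$bonds[k, "j"]] <- bsum[mol$bonds[k, "j"]] + ord[k]
    }
  }
  chg <- mol$charges
  adj <- ifelse(mol$atoms %in% c("N", "P"), chg,
         ifelse(mol$atoms %in% c("O", "S"), chg, 0))
  pmax(0L, as.integer(round(val + adj - bsum)))
}

# Logical vector: is bond k part of a ring? A bond is a ring bond iff its
# endpoints stay connected after removing it.
mol_ring_bonds <- function(mol) {
  nb <- nrow(mol$bonds)
  if (!nb) return(logical(0))
  n <- length(mol$atoms)
  adj <- vector("list", n)
  for (k in seq_len(nb)) {
    i <- mol$bonds[k, "i"]; j <- mol$bonds[k, "j"]
    adj[[i]] <- c(adj[[i]], k); adj[[j]] <- c(adj[[j]], k)
  }
  other <- function(k, a) {
    b <- mol$bonds[k, c("i", "j")]
    if (b[1] == a) b[2] else b[1]
  }
  vapply(seq_len(nb), function(k) {
    src <- mol$bonds[k, "i"]; dst <- mol$bonds[k, "j"]
    seen <- logical(n); seen[src] <- TRUE
    queue <- src
    while (length(queue)) {
      a <- queue[1]; queue <- queue[-1]
      for (kb in adj[[a]]) {
        if (kb == k) next
        b <- other(kb, a)
        if (b == dst) return(TRUE)
        if (!seen[b]) { seen[b] <- TRUE; queue <- c(queue, b) }
      }
    }
    FALSE
  }, logical(1))
}

# Build a minimal ChemmineR SDF object from a mol_graph (used for SDF export
# of transformed poses and synthetic ligands).
molgraph_to_sdf <- function(mol, coords = NULL) {
  n <- length(mol$atoms)
  xyz <- coords %||% mol$coords %||% matrix(0, 3, n)
  ab <- cbind(t(xyz), matrix(0, n, 12))
  rownames(ab) <- paste(mol$atoms, seq_len(n), sep = "_")
  colnames(ab) <- c("C1", "C2", "C3", paste0("C", 5:16))
  bb <- mol$bonds
  if (!nrow(bb)) bb <- matrix(0L, 0, 3)
  bb <- cbind(bb, matrix(0, nrow(bb), 4))
  colnames(bb) <- paste0("C", 1:7)
  rownames(bb) <- if (nrow(bb)) seq_len(nrow(bb)) else NULL
  methods::new("SDF",
               header = c(Molecule_Name = mol$id, Source = "voxscreen",
                          Comment = "", Counts_Line = sprintf(
                            "%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nrow(mol$bonds))),
               atomblock = ab, bondblock = bb,
               datablock = character(0))
}

#' Write poses or molecules to an SDF file
#'
#' @param mols List of [mol_graph()] objects (with coordinates).
#' @param path Output path.
#' @param coords Optional list of 3 x N matrices overriding each molecule's
#'   own coordinates (e.g. transformed pose coordinates).
#' @return `path`, invisibly.
#' @export
write_ligands_sdf <- function(mols, path, coords = NULL) {
  sdfs <- lapply(seq_along(mols), function(k)
    molgraph_to_sdf(mols[[k]],
                    coords = if (is.null(coords)) NULL else coords[[k]]))
  set <- methods::new("SDFset", SDF = sdfs,
                      ID = vapply(mols, function(m) m$id, ""))
  ChemmineR::write.SDF(set, file = path)
  invisible(path)
}
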