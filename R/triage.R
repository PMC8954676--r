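# Post-screen compound triage.
#
# Stage order follows the published cascade: (1) top-K by rank, (2) MW >
# mw_min, (3) SMARTS exclusion, (4) ECFP4 + Butina clustering keeping
# representatives, (5) property/PAINS filters (MW < mw_max, cLogP <
# logp_max, PAINS pass, optional external tox score).
#
# Descriptors: MW, Wildman-Crippen cLogP and Ertl TPSA come from OpenBabel
# (ChemmineOB); HBA (Lipinski N+O count), HBD (N-H plus O-H bond count) and
# rotatable bonds are computed on the molecular graph. The rotatable-bond
# rule is the standard strict one: non-ring single bonds between
# non-terminal heavy atoms, excluding amide and ester acyl C-N / C-O bonds.

#' Physicochemical descriptors of a molecule
#'
#' @param mol A [mol_graph()] (needs its OpenBabel backing for cLogP/TPSA,
#'   i.e. molecules read from SMILES/SDF).
#' @return data.frame with one row: `mw` (Da), `clogp`, `hba`, `hbd`,
#'   `n_rot`, `tpsa` (A^2).
#' @export
descriptors <- function(mol) {
  if (is.null(mol$sdf))
    vs_stop("molecule '%s' has no chemistry backing (built from raw coordinates?); descriptors need SMILES/SDF input", mol$id)
  p <- ChemmineR::propOB(methods::new("SDFset", SDF = list(mol$sdf), ID = mol$id))
  nH <- mol_nH(mol)
  data.frame(mw = p$MW, clogp = p$logP,
             hba = sum(mol$atoms %in% c("N", "O")),
             hbd = sum(nH[mol$atoms %in% c("N", "O")]),
             n_rot = count_rotatable(mol),
             tpsa = p$TPSA)
}

#' Descriptors for a set of molecules (batched)
#'
#' @param mols Named list of [mol_graph()] objects.
#' @return data.frame with one row per molecule, rownames = ids.
#' @export
descriptor_table <- function(mols) {
  has_sdf <- vapply(mols, function(m) !is.null(m$sdf), TRUE)
  if (!all(has_sdf))
    vs_stop("molecules without chemistry backing: %s",
            paste(names(mols)[!has_sdf], collapse = ", "))
  set <- methods::new("SDFset", SDF = lapply(mols, function(m) m$sdf),
                      ID = vapply(mols, function(m) m$id, ""))
  p <- ChemmineR::propOB(set)
  out <- data.frame(
    mw = p$MW, clogp = p$logP,
    hba = vapply(mols, function(m) sum(m$atoms %in% c("N", "O")), 0L),
    hbd = vapply(mols, function(m) {
      nH <- mol_nH(m); sum(nH[m$atoms %in% c("N", "O")])
    }, 0L),
    n_rot = vapply(mols, count_rotatable, 0L),
    tpsa = p$TPSA)
  rownames(out) <- vapply(mols, function(m) m$id, "")
  out
}

# Strict rotatable-bond count: single, non-ring, both endpoints of heavy
# degree >= 2, excluding acyl C-N (amide) and acyl C-O (ester) bonds.
count_rotatable <- function(mol) {
  b <- mol$bonds
  if (!nrow(b)) return(0L)
  deg <- mol_degree(mol)
  ring <- mol_ring_bonds(mol)
  # atoms that are carbonyl carbons: C with a double bond to O
  carbonyl <- rep(FALSE, length(mol$atoms))
  dbl <- b[b[, "order"] == 2L, , drop = FALSE]
  if (nrow(dbl)) {
    for (r in seq_len(nrow(dbl))) {
      i <- dbl[r, "i"]; j <- dbl[r, "j"]
      if (mol$atoms[i] == "C" && mol$atoms[j] == "O") carbonyl[i] <- TRUE
      if (mol$atoms[j] == "C" && mol$atoms[i] == "O") carbonyl[j] <- TRUE
    }
  }
  n <- 0L
  for (r in seq_len(nrow(b))) {
    if (b[r, "order"] != 1L || ring[r]) next
    i <- b[r, "i"]; j <- b[r, "j"]
    if (deg[i] < 2L || deg[j] < 2L) next
    acyl <- (carbonyl[i] && mol$atoms[j] %in% c("N", "O")) ||
            (carbonyl[j] && mol$atoms[i] %in% c("N", "O"))
    if (acyl) next
    n <- n + 1L
  }
  n
}

#' Lipinski rule-of-five violations
#'
#' Checks the four strict inequalities as printed: MW < 500, cLogP < 5,
#' HBA < 10, HBD < 5. Returns the names of the failed rules (empty =
#' compliant).
#'
#' @param d One-row data.frame (or list) with `mw`, `clogp`, `hba`, `hbd`.
#' @return Character vector of violated rule names.
#' @export
lipinski_violations <- function(d) {
  v <- character(0)
  if (!(d$mw < 500)) v <- c(v, "mw")
  if (!(d$clogp < 5)) v <- c(v, "clogp")
  if (!(d$hba < 10)) v <- c(v, "hba")
  if (!(d$hbd < 5)) v <- c(v, "hbd")
  v
}

#' Veber rule violations
#'
#' Checks, exactly as printed: rotatable bonds <= 10, HBA + HBD < 12,
#' TPSA <= 140 A^2.
#'
#' @param d One-row data.frame (or list) with `n_rot`, `hba`, `hbd`, `tpsa`.
#' @return Character vector of violated rule names.
#' @export
veber_violations <- function(d) {
  v <- character(0)
  if (!(d$n_rot <= 10)) v <- c(v, "n_rot")
  if (!(d$hba + d$hbd < 12)) v <- c(v, "hb_atoms")
  if (!(d$tpsa <= 140)) v <- c(v, "tpsa")
  v
}

# ---- ECFP4 fingerprints -------------------------------------------------

# Initial atom invariant: element number proxy, heavy degree, implicit H
# count, formal charge, ring membership. Hashed to 32 bits.
ecfp_init_invariants <- function(mol) {
  deg <- mol_degree(mol)
  nH <- mol_nH(mol)
  ring_b <- mol_ring_bonds(mol)
  in_ring <- rep(FALSE, length(mol$atoms))
  if (any(ring_b)) in_ring[unique(as.vector(mol$bonds[ring_b, c("i", "j")]))] <- TRUE
  el_code <- match(mol$atoms, names(.ELEMENT_MASS))
  el_code[is.na(el_code)] <- 99L
  vapply(seq_along(mol$atoms), function(i)
    hash_ints(c(el_code[i], deg[i], nH[i], mol$charges[i], as.integer(in_ring[i]))),
    numeric(1))
}

#' ECFP4 circular fingerprint
#'
#' Extended-connectivity fingerprint of radius 2: atom invariants are
#' iteratively refined over bonded neighbors (with bond orders) for two
#' rounds; every intermediate identifier is hashed onto a fixed-length bit
#' set. Identical molecular graphs give identical fingerprints regardless
#' of atom ordering.
#'
#' @param mol A [mol_graph()].
#' @param n_bits Fingerprint length (default 2048).
#' @return Object of class `ecfp`: sorted integer vector of on bits
#'   (0-based) with attribute `n_bits`.
#' @export
ecfp4 <- function(mol, n_bits = 2048L) {
  radius <- 2L
  n <- length(mol$atoms)
  inv <- ecfp_init_invariants(mol)
  nbrs <- vector("list", n)
  b <- mol$bonds
  if (nrow(b)) for (r in seq_len(nrow(b))) {
    i <- b[r, "i"]; j <- b[r, "j"]; o <- b[r, "order"]
    nbrs[[i]] <- rbind(nbrs[[i]], c(j, o))
    nbrs[[j]] <- rbind(nbrs[[j]], c(i, o))
  }
  ids <- inv
  all_ids <- inv
  for (it in seq_len(radius)) {
    new_ids <- numeric(n)
    for (i in seq_len(n)) {
      nb <- nbrs[[i]]
      if (is.null(nb)) {
        new_ids[i] <- hash_ints(c(it, ids[i]))
      } else {
        # order-independent: sort neighbor (bond order, id) pairs
        mat <- cbind(nb[, 2], ids[nb[, 1]])
        o <- order(mat[, 1], mat[, 2])
        pairs <- as.vector(t(mat[o, , drop = FALSE]))
        new_ids[i] <- hash_ints(c(it, ids[i], pairs))
      }
    }
    ids <- new_ids
    all_ids <- c(all_ids, new_ids)
  }
  bits <- sort(unique(as.integer(all_ids %% n_bits)))
  structure(bits, n_bits = as.integer(n_bits), class = "ecfp")
}

#' Tanimoto similarity of two fingerprints
#'
#' `|A intersect B| / |A union B|`; defined as 1 when both are empty.
#'
#' @param a,b `ecfp` fingerprints of equal length.
#' @return Similarity in \[0, 1\].
#' @export
tanimoto <- function(a, b) {
  if (!identical(attr(a, "n_bits"), attr(b, "n_bits")))
    vs_stop("fingerprint length mismatch (%d vs %d bits)",
            attr(a, "n_bits"), attr(b, "n_bits"))
  ai <- as.integer(a); bi <- as.integer(b)
  u <- length(union(ai, bi))
  if (u == 0L) return(1.0)
  length(intersect(ai, bi)) / u
}

#' Butina clustering of fingerprints
#'
#' Greedy sphere-exclusion clustering: compounds are neighbors when their
#' Tanimoto similarity is >= `cutoff`; ids are sorted by descending
#' neighbor count (ties broken lexicographically by id); the highest
#' unassigned id becomes a cluster representative and claims all its
#' unassigned neighbors; repeat until everything is assigned.
#'
#' @param fps Named list of `ecfp` fingerprints.
#' @param cutoff Tanimoto similarity threshold for neighborhood.
#' @return Object of class `cluster_set`: list with `clusters` (list of
#'   `list(representative, members)`) and `assignment` (named integer
#'   vector).
#' @export
butina_cluster <- function(fps, cutoff = 0.35) {
  # cutoff > 1 is allowed: nothing can be a neighbor, every compound
  # becomes a singleton cluster (the permissive no-op convention)
  stopifnot(length(fps) >= 1, cutoff >= 0)
  ids <- names(fps)
  if (is.null(ids) || anyDuplicated(ids)) vs_stop("fps must be uniquely named")
  n <- length(fps)
  neigh <- vector("list", n)
  for (i in seq_len(n)) neigh[[i]] <- integer(0)
  if (n > 1) for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    if (tanimoto(fps[[i]], fps[[j]]) >= cutoff) {
      neigh[[i]] <- c(neigh[[i]], j)
      neigh[[j]] <- c(neigh[[j]], i)
    }
  }
  counts <- lengths(neigh)
  ord <- order(-counts, ids)
  assigned <- rep(NA_integer_, n)
  clusters <- list()
  for (i in ord) {
    if (!is.na(assigned[i])) next
    cl <- length(clusters) + 1L
    members <- c(i, neigh[[i]][is.na(assigned[neigh[[i]]])])
    assigned[members] <- cl
    clusters[[cl]] <- list(representative = ids[i],
                           members = sort(ids[members]))
  }
  structure(list(clusters = clusters, assignment = setNames(assigned, ids)),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  sizes <- lengths(lapply(x$clusters, `[[`, "members"))
  cat(sprintf("<cluster_set: %d clusters over %d compounds (largest %d, singletons %d)>\n",
              length(x$clusters), length(x$assignment), max(sizes),
              sum(sizes == 1L)))
  invisible(x)
}

# ---- SMARTS filters -----------------------------------------------------

# Match counts of one SMARTS against a list of mol_graphs (via OpenBabel).
smarts_match_counts <- function(mols, pattern) {
  has_sdf <- vapply(mols, function(m) !is.null(m$sdf), TRUE)
  if (!all(has_sdf)) vs_stop("SMARTS matching needs SMILES/SDF-backed molecules")
  set <- methods::new("SDFset", SDF = lapply(mols, function(m) m$sdf),
                      ID = vapply(mols, function(m) m$id, ""))
  as.integer(ChemmineR::smartsSearchOB(set, pattern, uniqueMatches = FALSE))
}

validate_smarts <- function(patterns) {
  probe <- parse_smiles_set(c(probe = "CCO"))$mols
  for (p in patterns) {
    ok <- tryCatch({
      smarts_match_counts(probe, p); TRUE
    }, error = function(e) FALSE)
    if (!ok) vs_stop("invalid SMARTS pattern: %s", p)
  }
  invisible(patterns)
}

#' Read a SMARTS pattern file
#'
#' One pattern per line, optional whitespace-separated name; `#` comments
#' and blank lines ignored. Patterns are validated at load time.
#'
#' @param path File path.
#' @return Named character vector of SMARTS.
#' @export
read_smarts_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  # '#' opens a comment only at line start or after whitespace; bare '#'
  # inside a SMARTS (triple bond, [#6]) must survive
  lines <- sub("^#.*$", "", lines)
  lines <- sub("\\s#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "[\t ]+")
  pat <- vapply(parts, `[`, "", 1L)
  nm <- vapply(parts, function(p) if (length(p) >= 2)
    paste(p[-1], collapse = "_") else NA_character_, "")
  nm[is.na(nm)] <- pat[is.na(nm)]
  validate_smarts(setNames(pat, nm))
}

#' Default exclusion SMARTS (undesired moieties)
#'
#' A small editable public list of reactive/undesirable groups standing in
#' for proprietary exclusion sets; see
#' `system.file("extdata/exclusion_smarts.txt", package = "voxscreen")`.
#'
#' @return Named character vector of SMARTS.
#' @export
default_exclusion_smarts <- function() {
  read_smarts_file(system.file("extdata", "exclusion_smarts.txt",
                               package = "voxscreen"))
}

#' Default PAINS substructure set
#'
#' A curated subset of well-known public pan-assay-interference motifs
#' (catechol, quinone, rhodanine, azo, hydroxyphenyl-hydrazone, ...);
#' editable, and any fuller pattern file can be passed to
#' [pains_matches()] instead.
#'
#' @return Named character vector of SMARTS.
#' @export
default_pains_smarts <- function() {
  read_smarts_file(system.file("extdata", "pains_smarts.txt",
                               package = "voxscreen"))
}

#' Exclude molecules matching any SMARTS pattern
#'
#' @param mols Named list of [mol_graph()] objects.
#' @param patterns Named character vector of SMARTS.
#' @return List with `retained` (list of mol_graph) and `excluded`
#'   (data.frame `id`, `pattern` = name of the first matching pattern).
#' @export
smarts_filter <- function(mols, patterns) {
  if (!length(patterns) || !length(mols))
    return(list(retained = mols,
                excluded = data.frame(id = character(), pattern = character())))
  validate_smarts(patterns)
  first_hit <- rep(NA_character_, length(mols))
  for (k in seq_along(patterns)) {
    todo <- is.na(first_hit)
    if (!any(todo)) break
    cnt <- smarts_match_counts(mols[todo], patterns[k])
    hit <- cnt > 0L
    first_hit[which(todo)[hit]] <- names(patterns)[k] %||% patterns[k]
  }
  excl <- !is.na(first_hit)
  list(retained = mols[!excl],
       excluded = data.frame(id = names(mols)[excl],
                             pattern = first_hit[excl], row.names = NULL))
}

#' Count PAINS pattern matches
#'
#' Number of distinct PAINS patterns matching a molecule as substructure;
#' the default triage pass requires 0 matches.
#'
#' @param mol A [mol_graph()] (or named list of them).
#' @param pains_set Named character vector of SMARTS (default
#'   [default_pains_smarts()]).
#' @return Integer match count (vector if `mol` is a list).
#' @export
pains_matches <- function(mol, pains_set = default_pains_smarts()) {
  mols <- if (inherits(mol, "mol_graph")) list(mol) else mol
  if (!length(pains_set)) return(integer(length(mols)))
  hits <- matrix(0L, length(mols), length(pains_set))
  for (k in seq_along(pains_set))
    hits[, k] <- as.integer(smarts_match_counts(mols, pains_set[k]) > 0L)
  out <- rowSums(hits)
  if (inherits(mol, "mol_graph")) as.integer(out) else
    setNames(as.integer(out), names(mols))
}

# ---- Triage cascade -----------------------------------------------------

#' Triage configuration
#'
#' Defaults follow the published cascade: top 30,000 by rank, MW > 200 Da
#' (strict), SMARTS exclusion, Butina clustering at Tanimoto 0.35, then
#' MW < 500 Da, cLogP < 5 (strict) and PAINS pass (0 matches) on the
#' cluster representatives. An external toxicology score column can be
#' supplied to the pipeline; compounds with `tox >= tox_max` fail stage 5
#' (no tox model ships with the package).
#'
#' @param top_k Compounds taken from the top of the ranking.
#' @param mw_min Stage-2 molecular-weight floor (strict >), Da.
#' @param smarts_patterns Exclusion SMARTS (named character vector).
#' @param butina_cutoff Tanimoto similarity cutoff for clustering.
#' @param mw_max Stage-5 molecular-weight cap (strict <), Da.
#' @param logp_max Stage-5 cLogP cap (strict <).
#' @param pains_max_matches Maximum allowed PAINS matches (default 0).
#' @param pains_set PAINS SMARTS set.
#' @param tox_max Cap for an optional external tox score column (strict <).
#' @param n_bits Fingerprint length.
#' @return Object of class `triage_config`.
#' @export
triage_config <- function(top_k = 30000L, mw_min = 200, smarts_patterns = NULL,
                          butina_cutoff = 0.35, mw_max = 500, logp_max = 5,
                          pains_max_matches = 0L, pains_set = NULL,
                          tox_max = 2.0, n_bits = 2048L) {
  stopifnot(top_k >= 1, butina_cutoff >= 0, butina_cutoff <= 1.01)
  structure(list(top_k = as.integer(top_k), mw_min = mw_min,
                 smarts_patterns = smarts_patterns,
                 butina_cutoff = butina_cutoff, mw_max = mw_max,
                 logp_max = logp_max,
                 pains_max_matches = as.integer(pains_max_matches),
                 pains_set = pains_set, tox_max = tox_max,
                 n_bits = as.integer(n_bits)),
            class = "triage_config")
}

#' Run the post-screen triage cascade
#'
#' Stages, in order: (1) top-K by rank; (2) MW > `mw_min`; (3) SMARTS
#' exclusion; (4) ECFP4 + Butina clustering, keep representatives; (5)
#' MW < `mw_max`, cLogP < `logp_max`, PAINS pass, optional tox cap.
#' Every compound keeps a full audit trail of the stage that removed it.
#'
#' @param ranked [screen_library()]-style data.frame (`rank`,
#'   `compound_id`) or any data.frame with those columns.
#' @param mols Named list of [mol_graph()] covering all ranked ids.
#' @param cfg A [triage_config()].
#' @param tox Optional named numeric vector of external tox scores.
#' @return Object of class `triage_report`: `stage_counts` (named integer
#'   vector), `survivors` (character), `audit` (per-compound data.frame),
#'   `clusters` (the stage-4 `cluster_set`).
#' @export
triage_pipeline <- function(ranked, mols, cfg = triage_config(), tox = NULL) {
  ids <- as.character(ranked$compound_id[order(ranked$rank)])
  if (!all(ids %in% names(mols)))
    vs_stop("ranked ids missing from the molecule set: %s",
            paste(utils::head(setdiff(ids, names(mols)), 5), collapse = ", "))
  audit <- data.frame(id = ids, rank = sort(ranked$rank),
                      stage_removed = NA_character_, detail = "",
                      cluster = NA_integer_, stringsAsFactors = FALSE)
  rownames(audit) <- ids

  # stage 1: top-K
  s1 <- ids[seq_len(min(cfg$top_k, length(ids)))]
  audit$stage_removed[!(ids %in% s1)] <- "top_k"

  # stage 2: MW floor
  desc <- descriptor_table(mols[s1])
  keep2 <- desc$mw > cfg$mw_min
  audit[s1[!keep2], "stage_removed"] <- "mw_min"
  audit[s1[!keep2], "detail"] <- sprintf("mw=%.1f", desc$mw[!keep2])
  s2 <- s1[keep2]

  # stage 3: SMARTS exclusion
  if (length(cfg$smarts_patterns) && length(s2)) {
    sf <- smarts_filter(mols[s2], cfg$smarts_patterns)
    if (nrow(sf$excluded)) {
      audit[sf$excluded$id, "stage_removed"] <- "smarts"
      audit[sf$excluded$id, "detail"] <- sf$excluded$pattern
    }
    s3 <- names(sf$retained)
  } else s3 <- s2

  # stage 4: cluster, keep representatives
  clusters <- NULL
  if (length(s3)) {
    fps <- lapply(mols[s3], ecfp4, n_bits = cfg$n_bits)
    clusters <- butina_cluster(fps, cutoff = cfg$butina_cutoff)
    audit[s3, "cluster"] <- clusters$assignment[s3]
    reps <- vapply(clusters$clusters, `[[`, "", "representative")
    non_rep <- setdiff(s3, reps)
    audit[non_rep, "stage_removed"] <- "cluster_member"
    audit[non_rep, "detail"] <- sprintf("cluster=%d", clusters$assignment[non_rep])
    s4 <- reps[order(match(reps, s3))]  # keep rank order
  } else s4 <- character(0)

  # stage 5: final property / PAINS / tox filters
  if (length(s4)) {
    d5 <- desc[s4, , drop = FALSE]
    pains_set <- cfg$pains_set %||% default_pains_smarts()
    np <- pains_matches(mols[s4], pains_set)
    why <- character(length(s4))
    why[!(d5$mw < cfg$mw_max)] <- "mw_max"
    why[why == "" & !(d5$clogp < cfg$logp_max)] <- "logp"
    why[why == "" & np > cfg$pains_max_matches] <- "pains"
    if (!is.null(tox)) {
      tx <- tox[s4]
      why[why == "" & !is.na(tx) & !(tx < cfg$tox_max)] <- "tox"
    }
    fail5 <- why != ""
    audit[s4[fail5], "stage_removed"] <- "final_filters"
    audit[s4[fail5], "detail"] <- why[fail5]
    s5 <- s4[!fail5]
  } else s5 <- character(0)

  counts <- c(input = length(ids), top_k = length(s1), mw_min = length(s2),
              smarts = length(s3), cluster_representatives = length(s4),
              final = length(s5))
  structure(list(stage_counts = counts, survivors = s5, audit = audit,
                 clusters = clusters),
            class = "triage_report")
}

#' @export
print.triage_report <- function(x, ...) {
  cat("Triage cascade:\n")
  for (nm in names(x$stage_counts))
    cat(sprintf("  %-24s %d\n", nm, x$stage_counts[[nm]]))
  invisible(x)
}

#' Write a triage report (CSV audit + JSON stage summary)
#'
#' @param report A [triage_pipeline()] result.
#' @param csv_path,json_path Output paths (either may be `NULL`).
#' @return Invisibly, the report.
#' @export
write_triage_report <- function(report, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path)) {
    out <- report$audit
    out$survivor <- is.na(out$stage_removed)
    write.csv(out, csv_path, row.names = FALSE, quote = FALSE)
  }
  if (!is.null(json_path))
    jsonlite::write_json(as.list(report$stage_counts), json_path,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
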