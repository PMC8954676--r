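# Compound triage: descriptors, drug-likeness rules, fingerprints,
# clustering, SMARTS/PAINS filters and the cascade.

mols_of <- function(smiles) voxscreen:::parse_smiles_set(smiles)$mols

test_that("descriptors reproduce the classic small-molecule values", {
  m <- mols_of(c(benzene = "c1ccccc1", ethanol = "CCO"))
  db <- descriptors(m$benzene)
  expect_equal(db$hba, 0L); expect_equal(db$hbd, 0L)
  expect_equal(db$tpsa, 0); expect_equal(db$n_rot, 0L)
  de <- descriptors(m$ethanol)
  expect_equal(de$hba, 1L); expect_equal(de$hbd, 1L)
  expect_equal(de$mw, 46.07, tolerance = 0.01)
  expect_equal(de$tpsa, 20.23, tolerance = 0.01)
})

test_that("descriptors agree with the frozen toolkit panel", {
  tab <- read.csv(test_path("panel_descriptors.csv"))
  expect_equal(nrow(tab), 50L)
  m <- mols_of(setNames(tab$smiles, sprintf("m%02d", seq_len(nrow(tab)))))
  d <- descriptor_table(m)
  expect_equal(d$mw, tab$mw, tolerance = 0.01)
  expect_equal(d$clogp, tab$clogp, tolerance = 0.01)
  expect_equal(d$tpsa, tab$tpsa, tolerance = 0.01)
  expect_equal(d$hba, tab$hba)
  expect_equal(d$hbd, tab$hbd)
  expect_equal(d$n_rot, tab$n_rot)
})

test_that("rule engines follow the printed inequalities on the reported rows", {
  # descriptor rows as printed for the four compounds
  t1a <- list(clogp = 5.05, mw = 430, hba = 5, hbd = 0, n_rot = 6, tpsa = 34.17)
  t2a <- list(clogp = 4.67, mw = 405, hba = 5, hbd = 1, n_rot = 9, tpsa = 48.95)
  t1  <- list(clogp = 3.07, mw = 350, hba = 4, hbd = 1, n_rot = 7, tpsa = 35.58)
  t2  <- list(clogp = 1.64, mw = 343, hba = 6, hbd = 1, n_rot = 5, tpsa = 54.04)
  expect_equal(lipinski_violations(t1), character(0))
  expect_equal(lipinski_violations(t2), character(0))
  # 1a's printed cLogP of 5.05 violates the strict "< 5" reading
  expect_equal(lipinski_violations(t1a), "clogp")
  expect_equal(lipinski_violations(t2a), character(0))
  for (d in list(t1a, t2a, t1, t2))
    expect_equal(veber_violations(d), character(0))
  # boundary behavior
  expect_equal(veber_violations(list(n_rot = 11, hba = 3, hbd = 2, tpsa = 100)),
               "n_rot")
  expect_equal(veber_violations(list(n_rot = 10, hba = 6, hbd = 6, tpsa = 140)),
               "hb_atoms")
  expect_equal(lipinski_violations(list(mw = 500, clogp = 2, hba = 10, hbd = 5)),
               c("mw", "hba", "hbd"))
})

test_that("ecfp4 is canonical, discriminating and non-empty", {
  m <- mols_of(c(a = "c1ccccc1", b = "C1CCCCC1", e = "CCO",
                 a2 = "c1ccccc1"))
  f <- lapply(m, ecfp4)
  expect_identical(f$a, f$a2)               # same molecule, same bits
  expect_false(identical(f$a, f$b))         # benzene vs cyclohexane differ
  expect_gte(length(f$e), 1L)               # popcount >= 1
  # atom-order independence: parse a permuted SMILES of the same molecule
  m2 <- mols_of(c(x = "OCC"))
  expect_identical(ecfp4(m2$x), f$e)
})

test_that("tanimoto satisfies its closed forms and properties", {
  fp <- function(bits, n = 16L) structure(as.integer(bits), n_bits = n,
                                          class = "ecfp")
  expect_equal(tanimoto(fp(c(1, 2, 3)), fp(c(2, 3, 4))), 0.5)
  expect_equal(tanimoto(fp(1:5), fp(1:5)), 1)
  expect_equal(tanimoto(fp(1:3), fp(8:10)), 0)
  expect_equal(tanimoto(fp(integer(0)), fp(integer(0))), 1)
  expect_error(tanimoto(fp(1), fp(1, n = 32L)), "mismatch")
  set.seed(77)
  for (k in 1:1000) {
    a <- random_fp(); b <- random_fp()
    expect_equal(tanimoto(a, b), tanimoto(b, a))
    expect_equal(tanimoto(a, a), 1)
    s <- tanimoto(a, b)
    expect_true(s >= 0 && s <= 1)
  }
})

test_that("butina_cluster handles its edge cases and always partitions", {
  fp <- function(bits, n = 16L) structure(as.integer(bits), n_bits = n,
                                          class = "ecfp")
  # all dissimilar -> singletons
  fps <- list(a = fp(c(0, 1)), b = fp(c(4, 5)), c = fp(c(8, 9)))
  cs <- butina_cluster(fps, 0.35)
  expect_length(cs$clusters, 3L)
  # two identical + one disjoint -> {A,B} and {C}
  fps2 <- list(A = fp(1:4), B = fp(1:4), C = fp(9:12))
  cs2 <- butina_cluster(fps2, 0.35)
  sizes <- sort(lengths(lapply(cs2$clusters, `[[`, "members")))
  expect_equal(sizes, c(1L, 2L))
  expect_true(all(cs2$assignment[c("A", "B")] ==
                  cs2$assignment[["A"]]))
  # representatives are members; clusters partition the ids
  all_members <- unlist(lapply(cs2$clusters, `[[`, "members"))
  expect_setequal(all_members, names(fps2))
  expect_false(anyDuplicated(all_members) > 0)
})

test_that("butina_cluster matches the reference procedure on random sets", {
  set.seed(123)
  for (k in 1:100) {
    fps <- setNames(lapply(1:8, function(i) random_fp(n_bits = 32,
                                                      density = 0.3)),
                    sprintf("c%02d", 1:8))
    cutoff <- sample(c(0.2, 0.35, 0.5, 0.7), 1)
    got <- butina_cluster(fps, cutoff)
    want <- butina_oracle(fps, cutoff)
    expect_equal(partition_signature(got$assignment),
                 partition_signature(want),
                 info = sprintf("set %d cutoff %.2f", k, cutoff))
  }
})

test_that("smarts_filter excludes matches and records the first pattern", {
  m <- mols_of(c(nb = "c1ccccc1[N+](=O)[O-]", bz = "c1ccccc1"))
  out <- smarts_filter(m, c(nitro = "[N+](=O)[O-]"))
  expect_equal(names(out$retained), "bz")
  expect_equal(out$excluded$id, "nb")
  expect_equal(out$excluded$pattern, "nitro")
  # empty pattern list retains everything
  out2 <- smarts_filter(m, character(0))
  expect_equal(names(out2$retained), names(m))
  expect_error(validate_smarts <- voxscreen:::validate_smarts("C(("),
               "invalid SMARTS")
})

test_that("pains_matches counts distinct matching motifs", {
  m <- mols_of(c(bz = "c1ccccc1", cat = "Oc1ccccc1O",
                 catlong = "Oc1ccc(CCOCC)cc1O"))
  expect_equal(unname(pains_matches(m["bz"])), 0L)
  expect_gte(pains_matches(m$cat), 1L)
  expect_gte(pains_matches(m$catlong), 1L)
  expect_equal(pains_matches(m$cat, character(0)), 0L)
})

test_that("triage_pipeline follows the stage order on a small planted library", {
  plan <- make_screen_plan(n = 60, top_k = 48, frac_below_mw = 0.15,
                           frac_excluded = 0.15, rng_seed = 41)
  lib <- make_screen_library(plan, rng_seed = 42)
  cfg <- triage_config(top_k = 48,
                       smarts_patterns = c(nitro = "[N+](=O)[O-]"))
  rep <- triage_pipeline(lib$ranked, lib$mols, cfg)
  expect_equal(unname(rep$stage_counts), unname(lib$truth$stage_counts))
  # counts are non-increasing along the cascade
  expect_true(all(diff(rep$stage_counts) <= 0))
  # audit covers every compound exactly once
  expect_equal(sort(rep$audit$id), sort(lib$plan$id))
  expect_equal(sum(is.na(rep$audit$stage_removed)), rep$stage_counts[["final"]])
})

test_that("permissive settings make the cascade a no-op and top_k=1 works", {
  plan <- make_screen_plan(n = 12, top_k = 12, frac_below_mw = 0,
                           frac_excluded = 0, n_families = 4, rng_seed = 9)
  lib <- make_screen_library(plan, rng_seed = 10)
  cfg <- triage_config(top_k = 12, mw_min = 0, butina_cutoff = 1.01,
                       mw_max = Inf, logp_max = Inf,
                       pains_set = character(0))
  rep <- triage_pipeline(lib$ranked, lib$mols, cfg)
  expect_equal(rep$stage_counts[["final"]], 12L)
  expect_length(rep$survivors, 12L)

  cfg1 <- triage_config(top_k = 1, mw_min = 0, butina_cutoff = 1.01,
                        mw_max = Inf, logp_max = Inf,
                        pains_set = character(0))
  rep1 <- triage_pipeline(lib$ranked, lib$mols, cfg1)
  expect_lte(rep1$stage_counts[["final"]], 1L)

  # external tox hook: a score >= the cap removes the compound in stage 5
  tox <- setNames(rep(0, 12), lib$plan$id)
  tox[rep$survivors[1]] <- 5
  rep_tox <- triage_pipeline(lib$ranked, lib$mols, cfg, tox = tox)
  expect_equal(rep_tox$stage_counts[["final"]], 11L)
  expect_false(rep$survivors[1] %in% rep_tox$survivors)
})

test_that("shipped SMARTS files load, validate and match their motifs", {
  excl <- default_exclusion_smarts()
  pains <- default_pains_smarts()
  expect_gte(length(excl), 10L)
  expect_gte(length(pains), 10L)
  m <- mols_of(c(epox = "CCC1OC1", quin = "O=C1C=CC(=O)C=C1"))
  expect_gte(voxscreen:::smarts_match_counts(m["epox"], excl[["epoxide"]]), 1L)
  expect_gte(pains_matches(m$quin, pains), 1L)
})
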