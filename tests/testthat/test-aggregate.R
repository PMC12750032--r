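# Assembly selection, mapped rescoring, aggregation, common subsets.

test_that("weighted ligand mean uses heavy atoms and stays bounded", {
  pl <- list(list(ligand_ref = "a", lddt_pli = 0.8, heavy_atoms = 10L),
             list(ligand_ref = "b", lddt_pli = 0.0, heavy_atoms = 1L))
  expect_equal(weighted_pli(pl), 8 / 11)
  # equal atom counts reduce to the arithmetic mean
  pl2 <- list(list(ligand_ref = "a", lddt_pli = 0.4, heavy_atoms = 5L),
              list(ligand_ref = "b", lddt_pli = 0.8, heavy_atoms = 5L))
  expect_equal(weighted_pli(pl2), 0.6)
  expect_equal(weighted_pli(pl2[1]), 0.4)
  # undefined scores are skipped, never treated as zero
  pl3 <- c(pl2, list(list(ligand_ref = "c", lddt_pli = NA_real_,
                          heavy_atoms = 100L)))
  expect_equal(weighted_pli(pl3), 0.6)
  expect_true(is.na(weighted_pli(pl3[3])))
  # bounded by the defined scores
  set.seed(21)
  for (k in 1:20) {
    s <- runif(sample(1:6, 1)); w <- sample(1:30, length(s), replace = TRUE)
    pl4 <- Map(function(si, wi) list(ligand_ref = "x", lddt_pli = si,
                                     heavy_atoms = wi), s, w)
    m <- weighted_pli(pl4)
    expect_gte(m, min(s)); expect_lte(m, max(s))
  }
})

test_that("success fractions use a strict cutoff over all reference ligands", {
  pose <- function(r) list(ligand_ref = "x", bisy_rmsd = r, lddt_pli = 0.5,
                           heavy_atoms = 3L)
  pl <- lapply(c(0.5, 1.5, 2.5), pose)
  expect_equal(success_fraction(pl, 3, 2), 2 / 3)
  # unpredicted copies count as failures through the denominator
  pl2 <- lapply(c(1.0, 1.0), pose)
  expect_equal(success_fraction(pl2, 4, 2), 0.5)
  # strict "<": exactly 2.0 fails at 2 A
  expect_equal(success_fraction(list(pose(1.999)), 1, 2), 1)
  expect_equal(success_fraction(list(pose(2.0)), 1, 2), 0)
  expect_true(is.na(success_fraction(list(), 0, 2)))
  # monotone non-decreasing across 1/2/5 A on random pose sets
  set.seed(31)
  for (k in 1:20) {
    r <- c(runif(sample(1:8, 1), 0, 7), rep(NA_real_, sample(0:2, 1)))
    pl3 <- lapply(r, pose)
    f <- vapply(c(1, 2, 5), function(th)
      success_fraction(pl3, length(r), th), 1)
    expect_true(all(diff(f) >= 0))
    expect_true(all(f >= 0 & f <= 1))
  }
})

test_that("best pose per entity keeps the lowest RMSD copy", {
  pose <- function(id, r, s) list(ligand_ref = id, bisy_rmsd = r,
                                  lddt_pli = s, heavy_atoms = 3L)
  ent <- c(l1 = "e1", l2 = "e1", l3 = "e2", l4 = "e3")
  pl <- list(pose("l1", 1.5, 0.7), pose("l2", 3.0, 0.9),
             pose("l3", 0.4, 0.8), pose("l4", NA_real_, NA_real_))
  best <- best_pose_per_entity(pl, ent)
  expect_length(best, 2)                       # e3 has no scored copy
  expect_equal(best[["e1"]]$bisy_rmsd, 1.5)
  expect_equal(best[["e2"]]$ligand_ref, "l3")
  # RMSD ties resolve by the higher LDDT-PLI
  tie <- best_pose_per_entity(list(pose("l1", 1.0, 0.2),
                                   pose("l2", 1.0, 0.9)),
                              c(l1 = "e1", l2 = "e1"))
  expect_equal(tie[["e1"]]$ligand_ref, "l2")
  expect_length(best_pose_per_entity(list(), ent), 0)
})

test_that("assembly selection follows the documented tie-break cascade", {
  mk <- function(lddt, n, pli, bisy)
    list(lddt = lddt, n_ligands_scored = n, sum_pli = pli, sum_bisy = bisy)
  one <- select_assembly(list(a1 = mk(0.7, 1L, 0.5, 1)))
  expect_equal(one$polymer_assembly, "a1")
  expect_equal(one$rationale, "only assembly")
  # polymers: highest LDDT; ligands: most ligands scored
  ch <- select_assembly(list(a1 = mk(0.8, 3L, 1.0, 2),
                             a2 = mk(0.6, 2L, 2.0, 1)))
  expect_equal(ch$polymer_assembly, "a1")
  expect_equal(ch$ligand_assembly, "a1")
  # ligand count tie -> higher sum of LDDT-PLI
  ch2 <- select_assembly(list(a1 = mk(0.5, 2L, 1.4, 2),
                              a2 = mk(0.5, 2L, 1.6, 5)))
  expect_equal(ch2$ligand_assembly, "a2")
  # full tie on count and PLI -> lower sum of BiSyRMSD
  ch3 <- select_assembly(list(a1 = mk(0.5, 2L, 1.5, 5),
                              a2 = mk(0.5, 2L, 1.5, 3)))
  expect_equal(ch3$ligand_assembly, "a2")
  # complete tie -> lowest assembly id, deterministically
  ch4 <- select_assembly(list(a2 = mk(0.5, 2L, 1.5, 3),
                              a1 = mk(0.5, 2L, 1.5, 3)))
  expect_equal(ch4$polymer_assembly, "a1")
  expect_equal(ch4$ligand_assembly, "a1")
})

test_that("mapped scores drop the missing-chain penalty", {
  fx <- make_complex(fixture_spec(seed = 25, copies_per_entity = 2,
                                  chain_length = 20))
  m <- make_model(fx$reference, list(type = "drop_chain", k = 1))
  cm <- map_chains(m, fx$reference)
  full <- lddt(m, fx$reference, cm)$score
  ms <- mapped_scores(m, fx$reference, cm)
  expect_lt(full, 1)
  expect_equal(ms$mapped_lddt, 1, tolerance = 1e-9)
  expect_true(is.na(ms$mapped_ilddt))   # single mapped chain: no interface
  # complete models: mapped equals unmapped
  m2 <- make_model(fx$reference)
  cm2 <- map_chains(m2, fx$reference)
  ms2 <- mapped_scores(m2, fx$reference, cm2)
  expect_equal(ms2$mapped_lddt, lddt(m2, fx$reference, cm2)$score)
  expect_equal(ms2$mapped_ilddt, ilddt(m2, fx$reference, cm2)$score)
  # empty mappings leave both undefined
  ms3 <- mapped_scores(m, fx$reference,
                       chain_mapping(character(), character(),
                                     c("A"), c("A", "B")))
  expect_true(is.na(ms3$mapped_lddt) && is.na(ms3$mapped_ilddt))
})

test_that("mapped >= stoichiometry-aware scores on random fixtures", {
  set.seed(41)
  for (k in 1:8) {
    fx <- make_complex(fixture_spec(seed = 600 + k,
                                    n_entities = sample(1:2, 1),
                                    copies_per_entity = sample(1:2, 2,
                                                               replace = TRUE),
                                    chain_length = 12))
    m <- make_model(fx$reference, random_perturbation(fx$reference))
    cm <- map_chains(m, fx$reference)
    if (!nrow(cm$pairs)) next
    ms <- mapped_scores(m, fx$reference, cm)
    l <- lddt(m, fx$reference, cm)$score
    il <- ilddt(m, fx$reference, cm)$score
    if (!is.na(ms$mapped_lddt)) expect_gte(ms$mapped_lddt + 1e-9, l)
    if (!is.na(il) && !is.na(ms$mapped_ilddt))
      expect_gte(ms$mapped_ilddt + 1e-9, il)
  }
})

test_that("score_complex assembles a coherent per-target report", {
  fx <- make_complex(fixture_spec(seed = 27, copies_per_entity = 2,
                                  chain_length = 30, ligands = "CCO"))
  rep <- score_complex(make_model(fx$reference), fx$reference, fx$target)
  expect_s3_class(rep, "score_report")
  expect_equal(rep$lddt, 1)
  expect_equal(rep$mapped_lddt, 1)
  expect_equal(rep$ilddt, 1)
  expect_equal(rep$tm, 1, tolerance = 1e-9)
  expect_equal(rep$lddt_pli_weighted, 1)
  expect_equal(rep$success_frac_2A, 1)
  expect_equal(rep$oligo_state_predicted, 2L)
  expect_equal(rep$oligo_state_reference, 2L)
  # undefined scores serialize as nulls, not zeros
  f <- tempfile(fileext = ".json")
  rep2 <- score_complex(make_model(fx$reference,
                                   list(type = "drop_chain", k = 1)),
                        fx$reference, fx$target)
  write_report_json(rep2, f)
  parsed <- jsonlite::read_json(f)
  expect_null(parsed$mapped_ilddt)
  expect_lt(parsed$lddt, 1)
  expect_equal(parsed$mapped_lddt, 1, tolerance = 1e-9)
})

test_that("two-assembly scoring reports against the better assembly", {
  fx <- make_complex(fixture_spec(seed = 29, copies_per_entity = 2,
                                  chain_length = 20, ligands = "CCO"))
  ref1 <- fx$reference
  ref2 <- make_model(fx$reference,
                     list(type = "rigid_shift", d = 12, chains = "B",
                          direction = c(0, 1, 0)))
  ref2$structure_id <- "synthetic"     # same entry, different assembly
  rep <- score_complex(make_model(ref1), list(`1` = ref1, `2` = ref2),
                       fx$target)
  expect_equal(rep$assembly_choice$polymer_assembly, "1")
  expect_equal(rep$lddt, 1)
})

test_that("common subsets intersect server target sets", {
  res <- list(
    s1 = data.frame(target_id = c("A", "B", "C"), lddt = c(0.9, 0.8, 0.7)),
    s2 = data.frame(target_id = c("B", "C"), lddt = c(0.6, 0.5)),
    s3 = data.frame(target_id = c("B", "C", "D"), lddt = c(0.4, 0.3, 0.2)))
  cs <- common_subset(res)
  expect_equal(cs$n, 2)
  expect_equal(cs$targets, c("B", "C"))
  m1 <- cs$summary$mean[cs$summary$server == "s1" & cs$summary$metric == "lddt"]
  expect_equal(m1, 0.75)
  # one server: all of its targets
  expect_equal(common_subset(res, "s1")$n, 3)
  # disjoint servers: empty summary with n = 0
  res2 <- list(x = data.frame(target_id = "A", lddt = 1),
               y = data.frame(target_id = "B", lddt = 1))
  cs2 <- common_subset(res2)
  expect_equal(cs2$n, 0)
  expect_equal(nrow(cs2$summary[cs2$summary$n_defined > 0, ]), 0)
})
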