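# LDDT family, TM-score, ligand pose scores.

id_map <- function(s) chain_mapping(complexeval:::polymer_chain_ids(s),
                                    complexeval:::polymer_chain_ids(s))

test_that("a model identical to its reference scores perfectly", {
  fx <- make_complex(fixture_spec(seed = 1, copies_per_entity = 2,
                                  chain_length = 20, ligands = "CCO"))
  m <- make_model(fx$reference)
  cm <- map_chains(m, fx$reference)
  expect_equal(lddt(m, fx$reference, cm)$score, 1)
  expect_equal(ilddt(m, fx$reference, cm)$score, 1)
  expect_equal(tm_score(m, fx$reference, cm)$score, 1, tolerance = 1e-9)
  pair <- list(model = "L1", reference = "L1")
  expect_equal(lddt_pli(m, fx$reference, pair, cm)$score, 1)
  expect_lt(bisy_rmsd(m, fx$reference, pair, cm)$rmsd, 1e-9)
})

test_that("the three-point worked example scores exactly 2/3", {
  ref <- point_chain_structure("ref", cbind(c(0, 4, 8), 0, 0))
  mod <- point_chain_structure("mod", cbind(c(0, 4, 9.5), 0, 0))
  res <- lddt(mod, ref, chain_mapping("A", "A"))
  # distance errors {0, 1.5, 1.5} -> per-distance fractions {1, 1/2, 1/2}
  expect_identical(res$score, 2 / 3)
  expect_equal(res$n_distances, 3L)
})

test_that("LDDT is invariant under rigid transforms of the model", {
  fx <- make_complex(fixture_spec(seed = 13, copies_per_entity = 2,
                                  chain_length = 15))
  m <- make_model(fx$reference, list(type = "per_atom_noise", sigma = 0.4,
                                     seed = 2))
  cm <- id_map(fx$reference)
  base <- lddt(m, fx$reference, cm)$score
  for (sd in 1:3) {
    mt <- rigid_transform(m, seed = sd)
    expect_equal(lddt(mt, fx$reference, cm)$score, base, tolerance = 1e-9)
  }
})

test_that("missing chains zero their distances; monotone under deletion", {
  fx <- make_complex(fixture_spec(seed = 5, copies_per_entity = 2,
                                  chain_length = 20))
  full <- make_model(fx$reference)
  cm <- id_map(fx$reference)
  half <- make_model(fx$reference, list(type = "drop_chain", k = 1))
  cm_half <- map_chains(half, fx$reference)
  l_full <- lddt(full, fx$reference, cm)$score
  l_half <- lddt(half, fx$reference, cm_half)$score
  expect_lt(l_half, l_full)
  expect_equal(ilddt(half, fx$reference, cm_half)$score, 0)
  # the surviving chain still carries its intra-chain distances
  expect_gt(l_half, 0)
})

test_that("interface LDDT is undefined for monomers and 0 for displaced chains", {
  fx1 <- make_complex(fixture_spec(seed = 7, chain_length = 15))
  m1 <- make_model(fx1$reference)
  expect_true(is.na(ilddt(m1, fx1$reference, chain_mapping("A", "A"))$score))
  fx2 <- make_complex(fixture_spec(seed = 7, copies_per_entity = 2,
                                   chain_length = 15))
  m2 <- make_model(fx2$reference,
                   list(type = "rigid_shift", d = 15, chains = "B",
                        direction = c(1, 0, 0)))
  expect_equal(ilddt(m2, fx2$reference, id_map(fx2$reference))$score, 0)
  expect_equal(ilddt(make_model(fx2$reference), fx2$reference,
                     id_map(fx2$reference))$score, 1)
})

test_that("stereochemistry filter removes clashing atoms before scoring", {
  ref <- point_chain_structure("ref", cbind(c(0, 4, 8), 0, 0))
  mod <- point_chain_structure("mod", cbind(c(0, 4, 4.6), 0, 0))
  # model residues 2 and 3 clash at 0.6 A: both atoms removed, all
  # distances touching them score zero
  res_on <- lddt(mod, ref, chain_mapping("A", "A"))
  res_off <- lddt(mod, ref, chain_mapping("A", "A"),
                  lddt_params(stereo_check = FALSE))
  expect_equal(res_on$score, 0)
  expect_gt(res_off$score, 0)
})

test_that("TM-score: superposition invariance and closed-form displacement", {
  fx <- make_complex(fixture_spec(seed = 11, chain_length = 150))
  cm <- chain_mapping("A", "A")
  m0 <- make_model(fx$reference)
  expect_equal(tm_score(rigid_transform(m0, 3), fx$reference, cm)$score, 1,
               tolerance = 1e-9)
  d0 <- complexeval:::tm_d0(150)
  for (d in c(1, 2, 5)) {
    m <- make_model(fx$reference, list(type = "uniform_displacement", d = d))
    expect_equal(tm_score(m, fx$reference, cm)$score, 1 / (1 + (d / d0)^2),
                 tolerance = 1e-6)
  }
})

test_that("TM-score normalises by reference length: deletions cap the score", {
  fx <- make_complex(fixture_spec(seed = 11, chain_length = 60))
  cm <- chain_mapping("A", "A")
  m <- make_model(fx$reference)
  # delete the second half of the model residues
  m$atoms <- m$atoms[m$atoms$resno <= 30, ]
  sc <- tm_score(m, fx$reference, cm)$score
  expect_equal(sc, 0.5, tolerance = 1e-9)
  expect_true(is.na(tm_score(make_model(fx$reference), fx$reference,
                             chain_mapping(character(), character(),
                                           "A", "A"))$score))
})

test_that("TM-score never increases as model residues are deleted", {
  fx <- make_complex(fixture_spec(seed = 17, chain_length = 40))
  cm <- chain_mapping("A", "A")
  m <- make_model(fx$reference, list(type = "per_atom_noise", sigma = 0.5,
                                     seed = 4))
  prev <- tm_score(m, fx$reference, cm)$score
  for (cut in c(35, 25, 15)) {
    m$atoms <- m$atoms[m$atoms$resno <= cut, ]
    cur <- tm_score(m, fx$reference, cm)$score
    expect_lte(cur, prev + 1e-9)
    prev <- cur
  }
})

test_that("LDDT-PLI: pocket displacement and symmetry handling", {
  fx <- make_complex(fixture_spec(seed = 19, chain_length = 30,
                                  ligands = "c1ccccc1"))
  ref <- fx$reference
  cm <- chain_mapping("A", "A")
  pair <- list(model = "L1", reference = "L1")
  autos <- ligand_automorphisms(ligand_graph("c1ccccc1"))
  # ligand translated out of the pocket, straight away from the chain:
  # every contact distance grows by far more than the largest threshold
  pol <- ref$atoms[ref$atoms$chain_id == "A", c("x", "y", "z")]
  lig <- ref$atoms[ref$atoms$chain_id == "L1", c("x", "y", "z")]
  away <- colMeans(lig) - colMeans(pol)
  away <- away / sqrt(sum(away^2))
  m <- make_model(ref, list(type = "rigid_shift", d = 15, chains = "L1",
                            direction = away))
  expect_equal(lddt_pli(m, ref, pair, cm, autos)$score, 0)
  # a symmetry-equivalent pose scores as the identity pose
  m2 <- make_model(ref)
  lig_rows <- which(m2$atoms$chain_id == "L1")
  perm <- c(2:6, 1)  # one ring rotation
  m2$atoms[lig_rows, c("x", "y", "z")] <-
    m2$atoms[lig_rows, c("x", "y", "z")][perm, ]
  expect_equal(lddt_pli(m2, ref, pair, cm, autos)$score, 1)
  # without symmetry correction the rotated pose scores below 1
  expect_lt(lddt_pli(m2, ref, pair, cm, list(1:6))$score, 1)
})

test_that("BiSyRMSD: translation equals RMSD; symmetry corrects rotations", {
  fx <- make_complex(fixture_spec(seed = 19, chain_length = 30,
                                  ligands = "c1ccccc1"))
  ref <- fx$reference
  cm <- chain_mapping("A", "A")
  pair <- list(model = "L1", reference = "L1")
  autos <- ligand_automorphisms(ligand_graph("c1ccccc1"))
  # rigid 2.5 A ligand translation with an identical site is exactly 2.5
  m <- make_model(ref, list(type = "rigid_shift", d = 2.5, chains = "L1",
                            direction = c(0, 0, 1)))
  r <- bisy_rmsd(m, ref, pair, cm, autos)
  expect_equal(r$rmsd, 2.5, tolerance = 1e-9)
  # success at 5 A, failure at 2 A (strict <)
  expect_true(r$rmsd < 5); expect_false(r$rmsd < 2)
  # benzene rotated by any automorphism in place gives 0
  for (perm in autos) {
    m2 <- make_model(ref)
    lig_rows <- which(m2$atoms$chain_id == "L1")
    m2$atoms[lig_rows, c("x", "y", "z")] <-
      m2$atoms[lig_rows, c("x", "y", "z")][perm, ]
    expect_lt(bisy_rmsd(m2, ref, pair, cm, autos)$rmsd, 1e-9)
  }
})

test_that("BiSyRMSD is bounded by the identity-correspondence RMSD", {
  fx <- make_complex(fixture_spec(seed = 23, chain_length = 30,
                                  ligands = "CCO"))
  cm <- chain_mapping("A", "A")
  pair <- list(model = "L1", reference = "L1")
  autos <- ligand_automorphisms(ligand_graph("CCO"))
  expect_length(autos, 1)   # asymmetric: identity only, bound is equality
  m <- make_model(fx$reference, list(type = "per_atom_noise", sigma = 0.5,
                                     seed = 12))
  with_sym <- bisy_rmsd(m, fx$reference, pair, cm, autos)$rmsd
  identity_only <- bisy_rmsd(m, fx$reference, pair, cm, list(1:3))$rmsd
  expect_equal(with_sym, identity_only)
})
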