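test_that("noh map of a hydrogen-free system is the identity selection", {
  top <- topology(data.frame(element = c("C", "N", "O")),
                  rbind(c(1L, 2L), c(2L, 3L)))
  map <- buildNohMap(top)
  expect_identical(heavyIndices(map), 1:3)
  expect_true(all(lengths(hydrogenSets(map)) == 0))
  x <- matrix(rnorm(9), 3, 3)
  f <- matrix(rnorm(9), 3, 3)
  cg <- aggregateForces(allAtomFrame(x, f), map)
  expect_identical(coords(cg), x)
  expect_identical(forces(cg), f)
})

test_that("capped alanine dipeptide maps 22 atoms to 10 beads", {
  top <- buildPeptideTopology("ALA", capped = TRUE)
  expect_equal(nAtoms(top), 22)
  map <- buildNohMap(top)
  expect_equal(nBeads(map), 10)
  # coordinates are a pure selection of the heavy rows
  x <- matrix(rnorm(22 * 3), 22, 3)
  cg <- mapCoordinates(allAtomFrame(x), map)
  expect_equal(coords(cg), x[heavyIndices(map), ])
  # translation passes through the selection
  t_ <- c(1.5, -2, 0.3)
  cgT <- mapCoordinates(allAtomFrame(sweep(x, 2, -t_)), map)
  expect_equal(coords(cgT), sweep(coords(cg), 2, -t_))
})

test_that("bead order, hydrogen partition and type assignment invariants", {
  top <- buildPeptideTopology("MKTW")
  map <- buildNohMap(top)
  expect_true(all(diff(heavyIndices(map)) > 0))
  nH <- sum(top@atoms$element == "H")
  hs <- unlist(hydrogenSets(map))
  expect_equal(sort(hs), which(top@atoms$element == "H"))
  expect_equal(length(hs), nH)
  expect_equal(nBeads(map), sum(top@atoms$element != "H"))
  # types are a pure function of (element, nH)
  tab <- standardBeadTypeTable()
  counts <- lengths(hydrogenSets(map))
  el <- top@atoms$element[heavyIndices(map)]
  expect_identical(beadTypes(map), beadTypeId(tab, el, counts))
})

test_that("force aggregation follows the per-bead hydrogen sums and conserves total force", {
  # a CH3 bead: f_C = (1,0,0), hydrogens (0,1,0), (0,0,1), (1,1,1)
  top <- oneBead("C", 3)
  map <- buildNohMap(top)
  f <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(1, 1, 1))
  x <- matrix(rnorm(12), 4, 3)
  cg <- aggregateForces(allAtomFrame(x, f), map)
  expect_equal(forces(cg)[1, ], c(2, 2, 2))
  # zero input stays zero
  cg0 <- aggregateForces(allAtomFrame(x, matrix(0, 4, 3)), map)
  expect_true(all(forces(cg0) == 0))
  # random frames on a peptide: brute-force oracle + conservation
  ptop <- buildPeptideTopology("GASP")
  pmap <- buildNohMap(ptop)
  set.seed(1)
  for (rep in 1:5) {
    f <- matrix(rnorm(nAtoms(ptop) * 3), nAtoms(ptop), 3)
    x <- matrix(rnorm(nAtoms(ptop) * 3), nAtoms(ptop), 3)
    cg <- aggregateForces(allAtomFrame(x, f), pmap)
    expect_equal(forces(cg), bruteAggregate(f, pmap))
    expect_equal(colSums(forces(cg)), colSums(f), tolerance = 1e-12)
  }
})

test_that("aggregation requires forces and rejects malformed topologies", {
  top <- oneBead("C", 3)
  map <- buildNohMap(top)
  expect_error(aggregateForces(allAtomFrame(matrix(0, 4, 3)), map),
               "no forces")
  # unbonded hydrogen
  bad <- data.frame(element = c("C", "H"))
  expect_error(buildNohMap(topology(bad)), "not bonded to exactly one")
  # hydrogen bonded to two heavy atoms
  bad2 <- topology(data.frame(element = c("C", "C", "H")),
                   rbind(c(1L, 3L), c(2L, 3L)))
  expect_error(buildNohMap(bad2), "not bonded to exactly one")
  # shape mismatch
  expect_error(mapCoordinates(allAtomFrame(matrix(0, 3, 3)), map),
               "expects")
})

test_that("strict typing rejects pairs outside the canonical table and non-strict extends it", {
  # oxygen with three hydrogens is not among the 12 protein classes
  odd <- oneBead("O", 3)
  expect_error(buildNohMap(odd, strict = TRUE), "O 3")
  map <- buildNohMap(odd, strict = FALSE)
  expect_equal(nBeads(map), 1)
  expect_gt(beadTypes(map)[1], 12)
})

test_that("permuting hydrogen order leaves CG outputs unchanged", {
  top <- buildPeptideTopology("AV")
  n <- nAtoms(top)
  hIdx <- which(top@atoms$element == "H")
  # reverse the hydrogen block while keeping heavy atoms in place
  perm <- seq_len(n)
  perm[hIdx] <- rev(hIdx)
  atoms2 <- top@atoms[order(perm), ]
  inv <- order(perm)        # original index -> permuted position
  bonds2 <- matrix(match(as.vector(top@bonds), inv), ncol = 2)
  top2 <- topology(atoms2, bonds2)
  map1 <- buildNohMap(top)
  map2 <- buildNohMap(top2)
  set.seed(7)
  x <- matrix(rnorm(3 * n), n, 3)
  f <- matrix(rnorm(3 * n), n, 3)
  cg1 <- aggregateForces(allAtomFrame(x, f), map1)
  cg2 <- aggregateForces(allAtomFrame(x[inv, ], f[inv, ]), map2)
  expect_equal(coords(cg1), coords(cg2))
  expect_equal(forces(cg1), forces(cg2))
  expect_identical(beadTypes(map1), beadTypes(map2))
})

test_that("bead-type enumeration yields 12 classes for standard residues and matches manual counts", {
  tab <- enumerateBeadTypes(lapply(standardResidues(), residueTopology))
  expect_equal(nrow(tab@entries), 12)
  key <- paste0(tab@entries$element, tab@entries$nH)
  expect_setequal(key, c("C0", "C1", "C2", "C3", "N0", "N1", "N2", "N3",
                         "O0", "O1", "S0", "S1"))
  # deterministic id assignment: sorted by element then hydrogen count
  expect_identical(tab@entries$id, order(key))
  # glycine alone: backbone only -> N1, C1(CA has 2H) wait: manual count
  gly <- enumerateBeadTypes(list(residueTopology("GLY")))
  expect_setequal(paste0(gly@entries$element, gly@entries$nH),
                  c("N1", "C2", "C0", "O0"))
  # vacuous enumeration
  empty <- enumerateBeadTypes(list())
  expect_equal(nrow(empty@entries), 0)
})

test_that("bead masses aggregate the element and hydrogen masses", {
  expect_equal(beadMasses(buildNohMap(oneBead("C", 0)))[1], 12.011)
  expect_equal(beadMasses(buildNohMap(oneBead("C", 3)))[1],
               12.011 + 3 * 1.008)
  expect_equal(beadMasses(buildNohMap(oneBead("N", 3)))[1],
               14.007 + 3 * 1.008)
})
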