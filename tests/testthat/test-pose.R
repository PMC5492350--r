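test_that("well-separated chains score zero contacts", {
  poses <- genPoseSet(n_decoys = 1, planted_contacts = 0, seed = 3)
  s <- contactScore(poses[[1]])  # planted pose with nothing planted
  expect_equal(s@contacts, 0L)
  expect_equal(nrow(s@per_pair), 21L)  # 7 x 3 key pairs
  sd2 <- contactScore(poses[[2]])
  expect_equal(sd2@contacts, 0L)
})

test_that("a constructed pose with three planted pairs scores exactly three", {
  poses <- genPoseSet(n_decoys = 1, planted_contacts = 3, seed = 9)
  s <- contactScore(poses[[1]])
  expect_equal(s@contacts, 3L)
  # verified by the independent all-pairs scan
  brute <- bruteMinPairDist(poses[[1]], cyp51KeyResidues(),
                            porKeyResidues())
  expect_equal(sum(unlist(brute) <= 5.0), 3)
})

test_that("per-pair distances equal an exhaustive double loop", {
  for (seed in c(1, 2)) {
    poses <- genPoseSet(n_decoys = 1, planted_contacts = 5, seed = seed)
    for (p in poses) {
      s <- contactScore(p)
      brute <- bruteMinPairDist(p, cyp51KeyResidues(), porKeyResidues())
      got <- setNames(s@per_pair$min_distance,
                      paste(s@per_pair$number_a, s@per_pair$number_b,
                            sep = "_"))
      expect_equal(got[names(brute)],
                   setNames(unlist(brute), names(brute)),
                   tolerance = 1e-9)
    }
  }
})

test_that("scores are invariant when both chains move rigidly together", {
  poses <- genPoseSet(n_decoys = 1, planted_contacts = 7, seed = 12)
  p <- poses[[1]]
  s1 <- contactScore(p)
  moved <- new("Pose", label = p@label,
               structure = applyRigidTransform(p@structure, testRotation(),
                                               c(5, 5, -8)),
               chain_a = p@chain_a, chain_b = p@chain_b)
  s2 <- contactScore(moved)
  expect_equal(s2@contacts, s1@contacts)
  expect_equal(s2@sum_min_distances, s1@sum_min_distances,
               tolerance = 1e-9)
})

test_that("ranking is deterministic with documented tie-breaks", {
  poses <- genPoseSet(n_decoys = 3, planted_contacts = 21, seed = 30)
  ranked <- rankPoses(poses)
  expect_equal(ranked[[1]]@label, "planted")
  expect_setequal(vapply(ranked, slot, "", "label"),
                  vapply(poses, slot, "", "label"))
  # single pose ranks first trivially
  one <- rankPoses(poses[2])
  expect_equal(one[[1]]@label, poses[[2]]@label)
  # equal contacts (all decoys have 0): smaller distance sum first, then label
  decoys <- ranked[-1]
  sums <- vapply(decoys, slot, numeric(1), "sum_min_distances")
  expect_true(!is.unsorted(sums) ||
              all(diff(order(sums, vapply(decoys, slot, "", "label"))) > 0))
  expect_true(all(diff(vapply(decoys, slot, numeric(1),
                              "sum_min_distances")) >= 0))
})

test_that("missing key residues raise a resolution error, name mismatches warn", {
  poses <- genPoseSet(n_decoys = 1, planted_contacts = 0, seed = 2)
  badSet <- keyResidueSet("A", c(127L, 999L))
  expect_error(contactScore(poses[[1]], set_a = badSet), "999")
  wrongName <- keyResidueSet("A",
                             cyp51KeyResidues()@residue_numbers,
                             c("W", "A", "K", "K", "K", "R", "N"))
  expect_warning(contactScore(poses[[1]], set_a = wrongName), "expected W")
})

test_that("the planted near-native pose ranks first across seeded decoy sets", {
  hits <- 0L
  for (seed in 1:20) {
    poses <- genPoseSet(n_decoys = 10, planted_contacts = 21, seed = seed)
    ranked <- rankPoses(poses)
    hits <- hits + (ranked[[1]]@label == "planted")
  }
  expect_gte(hits, 19L)
})
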