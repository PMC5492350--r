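test_that("the distance criterion is applied inclusively at the cut-off", {
  topo <- cyp51md:::newTopology(1:2, c("O1", "N"), c("LAN", "MET"),
                                c("L", "A"), c(1L, 384L), c("O", "N"))
  mk <- function(d) makeTraj(topo, list(rbind(c(0, 0, 0), c(d, 0, 0))))
  expect_true(hbondPresent(mk(2.0), 1, 2, 1))
  expect_true(hbondPresent(mk(2.4), 1, 2, 1))   # boundary, inclusive
  expect_false(hbondPresent(mk(2.41), 1, 2, 1))
  excl <- hbondCriterion(inclusive = FALSE)
  expect_false(hbondPresent(mk(2.4), 1, 2, 1, criterion = excl))
  expect_error(hbondPresent(mk(2.0), 1, 99, 1), "out of range")
  expect_error(hbondPresent(mk(2.0), 5, 2, 1), "out of range")
})

test_that("default partners are the backbone amide N/O of protein residues", {
  topo <- genTopologyTemplate(residue_numbers = c(384L, 385L, 383L),
                              residue_names = c("MET", "ILE", "ILE"))
  sel <- candidatePartners(topo)
  a <- atoms(topo)
  expect_length(selectionIndices(sel), 6L)  # N and O of each residue
  expect_true(all(a$atom_name[selectionIndices(sel)] %in% c("N", "O")))
  expect_true(all(a$chain_id[selectionIndices(sel)] == "A"))

  # an extra selection adds e.g. a ligand oxygen
  sel2 <- candidatePartners(topo, extra_spec = "atom_name=O1")
  expect_length(selectionIndices(sel2), 7L)

  # equals a brute-force filter
  want <- which(a$residue_name %in% cyp51md:::AA3 &
                a$atom_name %in% c("N", "O"))
  expect_equal(selectionIndices(sel), want)
})

test_that("occupancy equals the per-frame bond fraction on a constructed case", {
  topo <- genTopologyTemplate(residue_numbers = 384L, residue_names = "MET")
  a <- atoms(topo)
  nIdx <- which(a$atom_name == "N" & a$chain_id == "A")
  o1 <- which(a$atom_name == "O1")
  frames <- lapply(1:10, function(f) {
    xyz <- matrix(30, nrow = nAtoms(topo), ncol = 3)  # park everything far
    xyz[o1, ] <- 0
    xyz[nIdx, ] <- if (f %in% c(1, 3, 5, 7)) c(2.0, 0, 0) else c(6, 0, 0)
    xyz
  })
  traj <- makeTraj(topo, frames)
  tab <- occupancyTable(traj, "atom_name=O1", window = c(1L, 10L),
                        structure_label = "toy")
  e <- occupancyEntries(tab)
  expect_equal(nrow(e), 1L)
  expect_equal(e$occupancy_percent, 40.0)
  expect_equal(e$residue_number, 384L)
  expect_equal(tab@n_frames_analyzed, 10L)
})

test_that("a hydroxyl that never approaches any partner gives no entries", {
  sc <- hbondScenario(data.frame(residue_name = "MET",
                                 residue_number = 384L, prob = 0),
                      n_frames = 20L, seed = 2L)
  tab <- occupancyTable(genHbondTrajectory(sc), "atom_name=O1",
                        window = c(1L, 20L))
  expect_equal(nrow(occupancyEntries(tab)), 0L)
})

test_that("occupancyTable matches the brute-force oracle on random trajectories", {
  for (seed in 1:12) {
    traj <- randomSmallTraj(n_res = 3, n_frames = 6, seed = seed)
    o1 <- selectionIndices(selectAtoms(traj, "atom_name=O1"))
    part <- candidatePartners(traj)
    tab <- occupancyTable(traj, "atom_name=O1", partner_sel = part,
                          window = c(1L, 6L), keep_zero = TRUE)
    want <- bruteOccupancy(traj, o1, selectionIndices(part), 2.4,
                           window = c(1, 6))
    e <- occupancyEntries(tab)
    got <- setNames(e$occupancy_percent,
                    paste("A", e$residue_number, e$residue_name, sep = "|"))
    expect_equal(got[names(want)], setNames(want, names(want)),
                 tolerance = 1e-12)
  }
})

test_that("enlarging the cut-off never decreases any occupancy", {
  traj <- randomSmallTraj(n_res = 4, n_frames = 10, seed = 99)
  cuts <- c(1.5, 2.4, 3.5, 5.0)
  occ <- lapply(cuts, function(cc)
    occupancyEntries(occupancyTable(traj, "atom_name=O1",
                                    criterion = hbondCriterion(cc),
                                    window = c(1L, 10L), keep_zero = TRUE)))
  for (k in seq_len(length(cuts) - 1)) {
    a <- occ[[k]]; b <- occ[[k + 1]]
    m <- merge(a, b, by = c("residue_name", "residue_number"))
    expect_true(all(m$occupancy_percent.y >= m$occupancy_percent.x))
  }
})

test_that("hydrogen_acceptor mode measures from the hydroxyl hydrogen", {
  topo <- genTopologyTemplate(residue_numbers = 384L, residue_names = "MET")
  a <- atoms(topo)
  xyz <- matrix(30, nrow = nAtoms(topo), ncol = 3)
  xyz[a$atom_name == "O1", ] <- 0
  xyz[a$atom_name == "HO1", ] <- c(0.95, 0, 0)
  # partner N: 3.0 A from O1 but 2.05 A from HO1
  xyz[a$atom_name == "N", ] <- c(3.0, 0, 0)
  traj <- makeTraj(topo, list(xyz))
  donor <- occupancyTable(traj, "atom_name=O1", window = c(1L, 1L))
  hyd <- occupancyTable(traj, "atom_name=HO1",
                        criterion = hbondCriterion(mode = "hydrogen_acceptor"),
                        window = c(1L, 1L))
  expect_equal(nrow(occupancyEntries(donor)), 0L)
  expect_equal(occupancyEntries(hyd)$occupancy_percent, 100)
})

test_that("an empty or out-of-range window is rejected", {
  traj <- randomSmallTraj(seed = 1)
  expect_error(occupancyTable(traj, "atom_name=O1", window = c(5L, 2L)),
               "window")
  expect_error(occupancyTable(traj, "atom_name=O1", window = c(1L, 99L)),
               "window")
})
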