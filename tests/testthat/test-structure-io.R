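test_that("a single-model PDB yields a one-frame trajectory", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  FE  HEM H   1       0.000   0.000   0.000  1.00  0.00          FE",
    "ATOM      2  C30 LAN L   1       3.000   4.000   0.000  1.00  0.00           C",
    "END"), f)
  traj <- readMultimodelPDB(f)
  expect_equal(nFrames(traj), 1L)
  expect_equal(nAtoms(traj), 2L)
  expect_equal(atoms(traj)$atom_name, c("FE", "C30"))
  expect_equal(coords(traj)[1, 2, ], c(3, 4, 0))
})

test_that("PDB write/read round-trips coordinates at format precision", {
  sc <- hbondScenario(data.frame(residue_name = "MET",
                                 residue_number = 384L, prob = 0.5),
                      n_frames = 5L, seed = 11L)
  traj <- genHbondTrajectory(sc)
  f <- withr::local_tempfile(fileext = ".pdb")
  writeMultimodelPDB(traj, f)
  back <- readMultimodelPDB(f)
  expect_equal(nFrames(back), 5L)
  expect_equal(atoms(back)$residue_number, atoms(traj)$residue_number)
  expect_lt(max(abs(coords(back) - coords(traj))), 5e-4)
})

test_that("models with differing atom counts raise a structural error", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "MODEL        1",
    "ATOM      1  N   MET A 384       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  MET A 384       1.000   0.000   0.000  1.00  0.00           C",
    "ATOM      3  O   MET A 384       2.000   0.000   0.000  1.00  0.00           O",
    "ENDMDL",
    "MODEL        2",
    "ATOM      1  N   MET A 384       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  MET A 384       1.000   0.000   0.000  1.00  0.00           C",
    "ENDMDL", "END"), f)
  expect_error(readMultimodelPDB(f), "MODEL 2")
})

test_that("an empty PDB file is a parse error", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(character(0), f)
  expect_error(readMultimodelPDB(f), "parse error")
})

test_that("XYZ trajectories parse, round-trip, and report truncation", {
  topo <- cyp51md:::newTopology(1L, "X1", "LIG", "L", 1L, "C")
  f <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("1", "t=0.0", "X1 0.0 0.0 0.0"), f)
  traj <- readXYZTrajectory(f, topo)
  expect_equal(nFrames(traj), 1L)
  expect_equal(coords(traj)[1, 1, ], c(0, 0, 0))

  # round trip of a multi-frame trajectory at the declared precision
  sc <- hbondScenario(data.frame(residue_name = "ILE",
                                 residue_number = 385L, prob = 0.4),
                      n_frames = 4L, seed = 3L)
  gen <- genHbondTrajectory(sc)
  f2 <- withr::local_tempfile(fileext = ".xyz")
  writeXYZTrajectory(gen, f2, digits = 6)
  back <- readXYZTrajectory(f2, topology(gen))
  expect_equal(nFrames(back), nFrames(gen))
  expect_lt(max(abs(coords(back) - coords(gen))), 5e-7)
  expect_equal(timesPs(back), timesPs(gen))

  # truncated final frame carries the frame index
  writeLines(c("1", "t=0.0", "X1 0.0 0.0 0.0", "1", "t=1.0"), f)
  expect_error(readXYZTrajectory(f, topo), "frame 1")
  # atom-count mismatch is a structural error
  writeLines(c("2", "t=0.0", "X1 0 0 0", "X2 1 1 1"), f)
  expect_error(readXYZTrajectory(f, topo), "structural error")
})

test_that("energy CSV reading validates and round-trips exactly", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("frame,energy", "0,-100.0", "1,-101.0"), f)
  s <- readEnergyCSV(f)
  expect_equal(length(energyValues(s)), 2L)
  expect_equal(mean(energyValues(s)), -100.5)

  writeLines("frame,energy", f)
  expect_error(readEnergyCSV(f), "no data rows")

  writeLines(c("frame,energy", "0,-100.0", "1,oops"), f)
  expect_error(readEnergyCSV(f), "row 2")

  # bit-identical write/read round trip of an AR(1) draw
  ar1 <- genAR1Series(seriesScenario(mean = -100, sd = 5, ar1_phi = 0.5,
                                     n = 200, seed = 7))
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeEnergyCSV(ar1, f2)
  back <- readEnergyCSV(f2)
  expect_identical(energyValues(back), energyValues(ar1))
})
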