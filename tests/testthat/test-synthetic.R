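test_that("generators are seed-deterministic", {
  sc <- hbondScenario(data.frame(residue_name = "MET",
                                 residue_number = 384L, prob = 0.4),
                      n_frames = 50L, seed = 17L)
  expect_identical(coords(genHbondTrajectory(sc)),
                   coords(genHbondTrajectory(sc)))
  s <- seriesScenario(mean = -100, sd = 5, ar1_phi = 0.3, n = 100,
                      seed = 17L)
  expect_identical(energyValues(genAR1Series(s)),
                   energyValues(genAR1Series(s)))
  p1 <- genPoseSet(2, 4, seed = 17)
  p2 <- genPoseSet(2, 4, seed = 17)
  expect_identical(lapply(p1, function(p) coords(p@structure)),
                   lapply(p2, function(p) coords(p@structure)))
})

test_that("scenario validation rejects ill-posed inputs", {
  tg <- data.frame(residue_name = "MET", residue_number = 384L, prob = 0.5)
  expect_error(hbondScenario(transform(tg, prob = 1.5), 10), "\\[0, 1\\]")
  expect_error(hbondScenario(tg, 10, bonded_distance = 7), "smaller")
  expect_error(hbondScenario(tg, 10, persistence = 1), "persistence")
  expect_error(seriesScenario(0, sd = -1, n = 10), "sd")
  expect_error(seriesScenario(0, sd = 1, ar1_phi = 1, n = 10), "ar1_phi")
})

test_that("AR(1) series have the declared stationary moments", {
  # degenerate sd -> constant series at the mean
  s0 <- genAR1Series(seriesScenario(mean = -42, sd = 0, n = 20, seed = 1))
  expect_equal(energyValues(s0), rep(-42, 20))

  # white noise: sample sd within 5% of target at n = 10000
  sw <- genAR1Series(seriesScenario(mean = 0, sd = 3, ar1_phi = 0,
                                    n = 10000, seed = 8))
  expect_lt(abs(sd(energyValues(sw)) - 3) / 3, 0.05)

  # lag-1 autocorrelation within 0.05 of phi at n = 10000
  sa <- genAR1Series(seriesScenario(mean = 0, sd = 3, ar1_phi = 0.6,
                                    n = 10000, seed = 9))
  rho <- acf(energyValues(sa), lag.max = 1, plot = FALSE)$acf[2]
  expect_lt(abs(rho - 0.6), 0.05)
})

test_that("forced occupancy extremes behave exactly", {
  tgt <- data.frame(residue_name = "TRP", residue_number = 245L, prob = 1)
  tab <- occupancyTable(genHbondTrajectory(hbondScenario(tgt, 10L,
                                                         seed = 5L)),
                        "atom_name=O1", window = c(1L, 10L))
  expect_equal(occupancyEntries(tab)$occupancy_percent, 100)

  tgt0 <- transform(tgt, prob = 0)
  tab0 <- occupancyTable(genHbondTrajectory(hbondScenario(tgt0, 10L,
                                                          seed = 5L)),
                         "atom_name=O1", window = c(1L, 10L))
  expect_equal(nrow(occupancyEntries(tab0)), 0L)
})

test_that("generator and analyser close the loop on occupancy targets", {
  probs <- c(0.25, 0.65, 0.02)
  sc <- hbondScenario(data.frame(residue_name = c("MET", "ILE", "ILE"),
                                 residue_number = c(384L, 385L, 383L),
                                 prob = probs),
                      n_frames = 2000L, seed = 31L)
  tab <- occupancyTable(genHbondTrajectory(sc), "atom_name=O1",
                        window = c(1L, 2000L), keep_zero = TRUE)
  e <- occupancyEntries(tab)
  got <- e$occupancy_percent[match(c(384L, 385L, 383L),
                                   e$residue_number)] / 100
  bound <- 3 * sqrt(probs * (1 - probs) / 2000)
  expect_true(all(abs(got - probs) <= bound))
})

test_that("Markov persistence induces the configured autocorrelation", {
  sc <- hbondScenario(data.frame(residue_name = "MET",
                                 residue_number = 384L, prob = 0.5),
                      n_frames = 10000L, persistence = 0.7, seed = 13L)
  traj <- genHbondTrajectory(sc)
  d <- distanceSeries(traj, "atom_name=O1",
                      "atom_name=N and residue_number=384")
  bonded <- as.numeric(d@distances_angstrom < 2.4)
  rho <- acf(bonded, lag.max = 1, plot = FALSE)$acf[2]
  expect_lt(abs(rho - 0.7), 0.05)
  expect_lt(abs(mean(bonded) - 0.5), 3 * sqrt(0.25 / (10000 * 0.3 / 1.7)))
})

test_that("pose sets plant the requested contacts and keep decoys apart", {
  poses <- genPoseSet(n_decoys = 3, planted_contacts = 21, seed = 41)
  expect_equal(contactScore(poses[[1]])@contacts, 21L)
  for (p in poses[-1]) {
    a <- atoms(p@structure)
    xyz <- coords(p@structure)[1, , ]
    da <- xyz[a$chain_id == "A", , drop = FALSE]
    db <- xyz[a$chain_id == "B", , drop = FALSE]
    expect_gte(min(cyp51md:::crossDist(da, db)), 15)
  }
  expect_error(genPoseSet(1, 22), "planted_contacts")
})
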