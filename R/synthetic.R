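## Seed-deterministic generators emulating the statistical structure of the
## analysis inputs: intermittent ligand-hydroxyl hydrogen bonds with set
## occupancy targets, stationary autocorrelated energy/distance series with
## set means, and docking pose sets with one planted near-native pose. No
## physical realism (no force field, no sterics) is attempted: the targets
## are the statistics the analysis layer estimates.

AA1TO3 <- stats::setNames(names(AA3TO1), AA3TO1)

#' Hydrogen-bond scenario for the synthetic generator
#'
#' Describes a set of residues that intermittently hydrogen-bond to the
#' ligand hydroxyl. Each residue follows an independent two-state
#' (bonded/unbonded) Markov chain with stationary probability equal to its
#' occupancy target; \code{persistence} is the chain's lag-1 correlation
#' (0 = independent frames). When bonded, the residue's backbone amide
#' nitrogen sits at \code{bonded_distance} from the hydroxyl oxygen,
#' otherwise at \code{unbonded_distance}; the defaults bracket the 2.4
#' Angstrom criterion.
#'
#' @param targets \code{data.frame} with columns \code{residue_name}
#'   (3-letter), \code{residue_number}, \code{prob} (occupancy target in
#'   [0, 1]).
#' @param n_frames number of frames to generate.
#' @param bonded_distance,unbonded_distance hydroxyl-partner distances
#'   (Angstrom) in the two states; defaults 2.2 and 6.0.
#' @param persistence two-state Markov stay correlation in [0, 1);
#'   default 0.
#' @param seed integer seed; every generator is deterministic given its
#'   seed.
#' @return a validated scenario list.
#' @export
hbondScenario <- function(targets, n_frames, bonded_distance = 2.2,
                          unbonded_distance = 6.0, persistence = 0,
                          seed = 1L) {
  stopifnot(is.data.frame(targets),
            all(c("residue_name", "residue_number", "prob") %in%
                names(targets)))
  if (any(targets$prob < 0 | targets$prob > 1))
    stopf("occupancy targets must lie in [0, 1]")
  if (bonded_distance >= unbonded_distance)
    stopf("bonded_distance must be smaller than unbonded_distance")
  if (persistence < 0 || persistence >= 1)
    stopf("persistence must lie in [0, 1)")
  if (n_frames < 1L) stopf("n_frames must be positive")
  list(targets = targets, n_frames = as.integer(n_frames),
       bonded_distance = bonded_distance,
       unbonded_distance = unbonded_distance,
       persistence = persistence, seed = as.integer(seed))
}

#' Stationary AR(1) series scenario
#'
#' First-order autoregressive Gaussian process with stationary mean
#' \code{mean} and stationary standard deviation \code{sd}:
#' \eqn{x_t = \mu + \phi (x_{t-1} - \mu) + \epsilon_t} with
#' \eqn{\epsilon_t \sim N(0, \sigma^2 (1 - \phi^2))} and \eqn{x_1 = \mu}.
#' Used to emulate per-frame internal energies and slowly fluctuating
#' distances.
#'
#' @param mean stationary mean.
#' @param sd stationary standard deviation (> 0, or 0 for a constant
#'   series).
#' @param ar1_phi lag-1 autocorrelation in [0, 1); default 0.
#' @param n series length.
#' @param seed integer seed.
#' @return a validated scenario list.
#' @export
seriesScenario <- function(mean, sd, ar1_phi = 0, n, seed = 1L) {
  if (sd < 0) stopf("sd must be non-negative")
  if (ar1_phi < 0 || ar1_phi >= 1) stopf("ar1_phi must lie in [0, 1)")
  if (n < 1L) stopf("n must be positive")
  list(mean = mean, sd = sd, ar1_phi = ar1_phi, n = as.integer(n),
       seed = as.integer(seed))
}

#' Minimal topology template for hydrogen-bond scenarios
#'
#' One backbone (N, CA, C, O) per listed protein residue on chain A, a
#' lanosterol-like ligand (atoms C30, O1, HO1) on chain L, and a heme iron
#' (FE) on chain H.
#'
#' @param residue_numbers integer residue numbers.
#' @param residue_names matching 3-letter residue names.
#' @return an [MDTopology-class]
#' @export
genTopologyTemplate <- function(residue_numbers, residue_names) {
  stopifnot(length(residue_numbers) == length(residue_names))
  nres <- length(residue_numbers)
  bb <- c("N", "CA", "C", "O")
  el <- c("N", "C", "C", "O")
  atom_name <- c(rep(bb, nres), "C30", "O1", "HO1", "FE")
  element <- c(rep(el, nres), "C", "O", "H", "FE")
  residue_name <- c(rep(residue_names, each = 4L), "LAN", "LAN", "LAN",
                    "HEM")
  residue_number <- c(rep(residue_numbers, each = 4L), 1L, 1L, 1L, 1L)
  chain <- c(rep("A", 4L * nres), "L", "L", "L", "H")
  newTopology(seq_along(atom_name), atom_name, residue_name, chain,
              residue_number, element)
}

## per-residue unit direction vectors, well separated on the sphere
residueDirections <- function(n) {
  k <- seq_len(n)
  theta <- acos(1 - 2 * (k - 0.5) / n)
  phi <- pi * (1 + sqrt(5)) * k
  cbind(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))
}

#' Generate a trajectory with prescribed hydrogen-bond occupancies
#'
#' The ligand hydroxyl oxygen is fixed at the origin (its hydrogen at 0.95
#' Angstrom along x); per frame, each target residue's backbone amide
#' nitrogen sits at the bonded or unbonded distance along a residue-specific
#' direction according to its two-state Markov chain. The remaining backbone
#' atoms are placed further out so only the amide nitrogen can satisfy the
#' criterion. Deterministic given the scenario seed.
#'
#' @param scenario an [hbondScenario].
#' @param topology_template optional [MDTopology-class]; default built by
#'   [genTopologyTemplate] from the scenario targets. Must contain the
#'   ligand hydroxyl (\code{O1}) and one backbone \code{N} per target
#'   residue.
#' @return an [MDTrajectory-class] (1 ps per frame).
#' @export
genHbondTrajectory <- function(scenario, topology_template = NULL) {
  tg <- scenario$targets
  if (is.null(topology_template))
    topology_template <- genTopologyTemplate(tg$residue_number,
                                             tg$residue_name)
  a <- topology_template@atoms
  o1 <- which(a$atom_name == "O1")
  if (length(o1) != 1L)
    stopf("structural error: template must contain exactly one O1 atom")
  nres <- nrow(tg)
  nIdx <- vapply(seq_len(nres), function(i) {
    w <- which(a$atom_name == "N" & a$residue_number == tg$residue_number[i]
               & a$residue_name == tg$residue_name[i])
    if (length(w) != 1L)
      stopf("structural error: template lacks backbone N of %s%d",
            tg$residue_name[i], tg$residue_number[i])
    w
  }, 0L)
  nf <- scenario$n_frames
  set.seed(scenario$seed)
  lam <- scenario$persistence
  ## two-state Markov chain with stationary prob p and stay correlation lam
  states <- matrix(FALSE, nrow = nf, ncol = nres)
  for (i in seq_len(nres)) {
    p <- tg$prob[i]
    s <- logical(nf)
    s[1L] <- stats::runif(1) < p
    if (nf > 1L) {
      u <- stats::runif(nf - 1L)
      for (t in 2:nf) {
        pb <- if (s[t - 1L]) lam + (1 - lam) * p else (1 - lam) * p
        s[t] <- u[t - 1L] < pb
      }
    }
    states[, i] <- s
  }
  dirs <- residueDirections(nres)
  co <- array(0, dim = c(nf, nAtoms(topology_template), 3L))
  ## static atoms: hydroxyl at origin, ligand/heme anchors nearby
  ho1 <- which(a$atom_name == "HO1")
  c30 <- which(a$atom_name == "C30")
  fe <- which(a$atom_name == "FE")
  for (f in seq_len(nf)) {
    if (length(ho1)) co[f, ho1, ] <- c(0.95, 0, 0)
    if (length(c30)) co[f, c30, ] <- c(0, 0, -2.5)
    if (length(fe)) co[f, fe, ] <- c(0, 0, -8.5)
  }
  for (i in seq_len(nres)) {
    d <- ifelse(states[, i], scenario$bonded_distance,
                scenario$unbonded_distance)
    co[, nIdx[i], ] <- outer(d, dirs[i, ])
    ## park CA, C, O of the residue beyond any plausible cut-off
    others <- which(a$residue_number == tg$residue_number[i] &
                    a$residue_name == tg$residue_name[i] &
                    a$chain_id == "A" & a$atom_name != "N")
    for (k in seq_along(others))
      co[, others[k], ] <- matrix(rep((12 + 3 * k) * dirs[i, ], nf),
                                  ncol = 3L, byrow = TRUE)
  }
  newTrajectory(topology_template, co)
}

#' Generate a stationary AR(1) energy series
#'
#' @param scenario a [seriesScenario].
#' @param label,unit passed to [energySeries].
#' @return an [EnergySeries-class]
#' @export
genAR1Series <- function(scenario, label = "other", unit = "kcal/mol") {
  energySeries(genAR1Values(scenario), label = label, unit = unit)
}

## the raw AR(1) draw shared by energy and distance generators
genAR1Values <- function(scenario) {
  set.seed(scenario$seed)
  n <- scenario$n
  phi <- scenario$ar1_phi
  if (scenario$sd == 0) return(rep(scenario$mean, n))
  eps <- stats::rnorm(n - 1L, 0, scenario$sd * sqrt(1 - phi^2))
  dev <- stats::filter(c(0, eps), filter = phi, method = "recursive")
  scenario$mean + as.numeric(dev)
}

#' Generate a heme-Fe / ligand-carbon distance trajectory
#'
#' A two-atom trajectory (heme \code{FE} fixed at the origin, ligand
#' \code{C30} on the x axis) whose interatomic distance follows the AR(1)
#' scenario -- the synthetic stand-in for the heme-iron to C30 separation of
#' a simulated structure. Negative draws are clamped at 0 (never reached
#' with realistic means).
#'
#' @param scenario a [seriesScenario] (mean/sd in Angstrom).
#' @return an [MDTrajectory-class] (1 ps per frame).
#' @export
genDistanceTrajectory <- function(scenario) {
  d <- pmax(genAR1Values(scenario), 0)
  topo <- newTopology(1:2, c("FE", "C30"), c("HEM", "LAN"), c("H", "L"),
                      c(1L, 1L), c("FE", "C"))
  co <- array(0, dim = c(scenario$n, 2L, 3L))
  co[, 2L, 1L] <- d
  newTrajectory(topo, co)
}

#' Synthetic panel emulating the wild type and the three modelled variants
#'
#' Scenario presets for a qualitative end-to-end run over the four simulated
#' structures (WT, R277L, R431H, D152G). The targets encode the qualitative
#' picture the analyses are designed to resolve: for lanosterol binding the
#' wild type is most favourable followed by R277L, with R431H and D152G
#' markedly weaker; for POR binding the wild type is most favourable, R431H
#' close behind, R277L clearly weaker and D152G set to exactly zero (the
#' "almost zero binding enthalpy" case the near-zero flag should catch); the
#' heme-Fe to C30 distance means put R431H and D152G about 4 Angstrom above
#' the wild type. Energy series are AR(1) with sd 5 and lag-1 correlation
#' 0.5; distances AR(1) with sd 0.3.
#'
#' @param n frames per series (default 5000).
#' @param seed base seed; each series draws a distinct derived seed.
#' @return nested list: \code{lanosterol} and \code{por} map structure label
#'   to \code{list(cmplx, m1, m2)} [seriesScenario]s (component means -20
#'   and -80; complex mean = -100 + target E_b), \code{distances} maps
#'   label to a distance [seriesScenario], and \code{targets} records the
#'   ground-truth E_b and distance means.
#' @export
variantPanelScenarios <- function(n = 5000L, seed = 1L) {
  labs <- c("WT", "R277L", "R431H", "D152G")
  eb_lan <- c(WT = -50, R277L = -45, R431H = -25, D152G = -20)
  eb_por <- c(WT = -60, R277L = -30, R431H = -55, D152G = 0)
  dmean <- c(WT = 6.0, R277L = 6.3, R431H = 10.0, D152G = 10.2)
  m1 <- -20  # isolated ligand / partner
  m2 <- -80  # isolated protein
  k <- 0L
  nextSeed <- function() { k <<- k + 1L; seed + 1000L * k }
  mkTriple <- function(eb) list(
    cmplx = seriesScenario(m1 + m2 + eb, sd = 5, ar1_phi = 0.5, n = n,
                           seed = nextSeed()),
    m1 = seriesScenario(m1, sd = 5, ar1_phi = 0.5, n = n,
                        seed = nextSeed()),
    m2 = seriesScenario(m2, sd = 5, ar1_phi = 0.5, n = n,
                        seed = nextSeed()))
  list(lanosterol = stats::setNames(lapply(eb_lan[labs], mkTriple), labs),
       por = stats::setNames(lapply(eb_por[labs], mkTriple), labs),
       distances = stats::setNames(lapply(dmean[labs], function(m)
         seriesScenario(m, sd = 0.3, ar1_phi = 0.5, n = n,
                        seed = nextSeed())), labs),
       targets = list(eb_lanosterol = eb_lan, eb_por = eb_por,
                      distance_mean = dmean))
}

#' Binding-enthalpy results for a scenario panel
#'
#' Convenience wrapper: generates the three energy series of each structure
#' in a panel (see [variantPanelScenarios]) and runs [bindingEnthalpy].
#'
#' @param panel named list of \code{list(cmplx, m1, m2)} scenarios.
#' @return named list of [BindingEnergyResult-class].
#' @export
panelBindingResults <- function(panel) {
  lapply(panel, function(p)
    bindingEnthalpy(genAR1Series(p$cmplx, "complex"),
                    genAR1Series(p$m1, "component1"),
                    genAR1Series(p$m2, "component2")))
}

## Rodrigues rotation matrix about a random axis
randomRotation <- function() {
  ax <- stats::rnorm(3)
  ax <- ax / sqrt(sum(ax^2))
  th <- stats::runif(1, 0, 2 * pi)
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
              3, 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Apply a rigid transform to every frame of a trajectory
#'
#' @param traj an [MDTrajectory-class].
#' @param rotation 3x3 rotation matrix (default identity).
#' @param translation length-3 translation vector (default zero).
#' @return the transformed [MDTrajectory-class].
#' @export
applyRigidTransform <- function(traj, rotation = diag(3),
                                translation = c(0, 0, 0)) {
  stopifnot(is(traj, "MDTrajectory"))
  co <- traj@coords
  for (f in seq_len(dim(co)[1L]))
    co[f, , ] <- sweep(matrix(co[f, , ], ncol = 3L) %*% t(rotation), 2,
                       translation, "+")
  newTrajectory(traj@topology, co, traj@times_ps, traj@frame_indices)
}

## residue coordinate block: backbone + CB clustered around a base point
syntheticResidueAtoms <- function(base) {
  offs <- rbind(N = c(0, 0, 0), CA = c(1.5, 0, 0), C = c(2.4, 1.1, 0),
                O = c(2.4, 2.3, 0), CB = c(1.9, -0.8, 1.2))
  sweep(offs, 2, base, "+")
}

#' Generate a decoy pose set with one planted near-native pose
#'
#' Builds synthetic two-chain complexes over the key residue sets: the
#' planted pose places exactly \code{planted_contacts} cross-chain key
#' residue pairs within 4.5 Angstrom (extra side-chain atoms of the
#' B-chain residue are dropped next to the selected A-chain residues) while
#' all other pairs stay far apart; each decoy has chain B randomly rotated
#' and translated so that the minimum interface separation is at least 15
#' Angstrom. Deterministic given the seed.
#'
#' @param n_decoys number of decoys (>= 1).
#' @param planted_contacts contacts to plant, between 0 and
#'   \code{length(set_a) * length(set_b)}.
#' @param set_a,set_b [KeyResidueSet-class]; defaults [cyp51KeyResidues] /
#'   [porKeyResidues].
#' @param seed integer seed.
#' @param max_retries placement retries per decoy before a generation error
#'   (default 100).
#' @return a list of [Pose-class]: the planted pose (label
#'   \code{"planted"}) followed by decoys (\code{"decoy01"}, ...).
#' @export
genPoseSet <- function(n_decoys, planted_contacts,
                       set_a = cyp51KeyResidues(), set_b = porKeyResidues(),
                       seed = 1L, max_retries = 100L) {
  na <- length(set_a@residue_numbers)
  nb <- length(set_b@residue_numbers)
  if (n_decoys < 1L) stopf("n_decoys must be >= 1")
  if (planted_contacts < 0L || planted_contacts > na * nb)
    stopf("planted_contacts must lie in [0, %d]", na * nb)
  set.seed(seed)
  name3 <- function(set) {
    nm <- AA1TO3[set@residue_names]
    nm[is.na(nm)] <- "UNK"
    unname(nm)
  }
  namesA <- name3(set_a)
  namesB <- name3(set_b)
  basesA <- cbind(40 * seq_len(na), 0, 0)
  basesB <- cbind(40 * seq_len(nb), 200, 0)
  ## chain A is common to every pose
  atomsA <- do.call(rbind, lapply(seq_len(na), function(i)
    syntheticResidueAtoms(basesA[i, ])))
  bb <- rownames(syntheticResidueAtoms(c(0, 0, 0)))
  elA <- substr(bb, 1, 1)
  mkPose <- function(label, atomsB, namesBAtoms, resBAtoms) {
    nAa <- nrow(atomsA)
    nBa <- nrow(atomsB)
    topo <- newTopology(
      seq_len(nAa + nBa),
      c(rep(bb, na), namesBAtoms),
      c(rep(namesA, each = length(bb)), resBAtoms$name),
      c(rep(set_a@chain_id, nAa), rep(set_b@chain_id, nBa)),
      c(rep(set_a@residue_numbers, each = length(bb)), resBAtoms$number),
      c(rep(elA, na), substr(namesBAtoms, 1, 1)))
    co <- array(0, dim = c(1L, nAa + nBa, 3L))
    co[1, , ] <- rbind(atomsA, atomsB)
    new("Pose", label = label, structure = newTrajectory(topo, co),
        chain_a = set_a@chain_id, chain_b = set_b@chain_id)
  }
  ## planted pose: base chain B far away, plus one planted contact atom per
  ## selected (A residue, B residue) pair
  pairs <- expand.grid(i = seq_len(na), j = seq_len(nb))
  sel <- utils::head(seq_len(nrow(pairs)), planted_contacts)
  atomsB <- do.call(rbind, lapply(seq_len(nb), function(j)
    syntheticResidueAtoms(basesB[j, ])))
  namesBAtoms <- rep(bb, nb)
  resB <- list(name = rep(namesB, each = length(bb)),
               number = rep(set_b@residue_numbers, each = length(bb)))
  for (k in seq_along(sel)) {
    i <- pairs$i[sel[k]]
    j <- pairs$j[sel[k]]
    atomsB <- rbind(atomsB, basesA[i, ] + c(0, -3.5, 0))
    namesBAtoms <- c(namesBAtoms, sprintf("CX%d", k))
    resB$name <- c(resB$name, namesB[j])
    resB$number <- c(resB$number, set_b@residue_numbers[j])
  }
  poses <- list(mkPose("planted", atomsB, namesBAtoms, resB))
  ## decoys: plain chain B rigidly moved to >= 15 A interface separation
  atomsB0 <- do.call(rbind, lapply(seq_len(nb), function(j)
    syntheticResidueAtoms(basesB[j, ])))
  resB0 <- list(name = rep(namesB, each = length(bb)),
                number = rep(set_b@residue_numbers, each = length(bb)))
  for (d in seq_len(n_decoys)) {
    placed <- FALSE
    for (try in seq_len(max_retries)) {
      R <- randomRotation()
      centre <- colMeans(atomsB0)
      shift <- stats::rnorm(3)
      shift <- shift / sqrt(sum(shift^2)) * stats::runif(1, 60, 250)
      cand <- sweep(sweep(atomsB0, 2, centre) %*% t(R), 2, centre + shift,
                    "+")
      if (min(crossDist(atomsA, cand)) >= 15) { placed <- TRUE; break }
    }
    if (!placed)
      stopf("generation error: could not place decoy %d at >= 15 A", d)
    poses[[d + 1L]] <- mkPose(sprintf("decoy%02d", d), cand, rep(bb, nb),
                              resB0)
  }
  poses
}
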