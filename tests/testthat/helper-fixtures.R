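# Shared in-code fixtures and independent brute-force oracles.

# Trajectory with explicit per-frame coordinates for a template topology.
# coord_list: list of (n_atoms x 3) matrices.
makeTraj <- function(topology, coord_list) {
  co <- array(0, dim = c(length(coord_list), nAtoms(topology), 3))
  for (f in seq_along(coord_list)) co[f, , ] <- coord_list[[f]]
  cyp51md:::newTrajectory(topology, co)
}

# Random small protein+ligand trajectory for oracle comparisons: coordinates
# uniform in an 8 A box so hydroxyl-partner distances straddle the cut-off.
randomSmallTraj <- function(n_res = 3, n_frames = 6, seed = 1) {
  set.seed(seed)
  topo <- genTopologyTemplate(residue_numbers = seq(101, 100 + n_res),
                              residue_names = sample(
                                c("MET", "ILE", "TRP", "PHE", "ALA"),
                                n_res, replace = TRUE))
  co <- array(runif(n_frames * nAtoms(topo) * 3, -4, 4),
              dim = c(n_frames, nAtoms(topo), 3))
  cyp51md:::newTrajectory(topo, co)
}

# Brute-force occupancy oracle: plain per-frame, per-atom distance loops,
# independent of the vectorised implementation.
bruteOccupancy <- function(traj, hydroxyl_idx, partner_idx, cutoff,
                           inclusive = TRUE, window = NULL) {
  nf <- nFrames(traj)
  if (is.null(window)) window <- c(floor(nf / 2) + 1, nf)
  a <- atoms(traj)
  frames <- window[1]:window[2]
  key <- paste(a$chain_id[partner_idx], a$residue_number[partner_idx],
               a$residue_name[partner_idx], sep = "|")
  res <- unique(key)
  counts <- setNames(numeric(length(res)), res)
  for (f in frames) {
    bondedRes <- character(0)
    for (k in seq_along(partner_idx)) {
      d <- sqrt(sum((coords(traj)[f, partner_idx[k], ] -
                     coords(traj)[f, hydroxyl_idx, ])^2))
      hit <- if (inclusive) d <= cutoff else d < cutoff
      if (hit) bondedRes <- union(bondedRes, key[k])
    }
    counts[bondedRes] <- counts[bondedRes] + 1
  }
  100 * counts / length(frames)
}

# Brute-force per-pair minimum heavy-atom distance for a pose.
bruteMinPairDist <- function(pose, set_a, set_b) {
  a <- atoms(pose@structure)
  xyz <- coords(pose@structure)[1, , ]
  out <- list()
  for (na in set_a@residue_numbers) {
    ia <- which(a$chain_id == set_a@chain_id & a$residue_number == na &
                toupper(a$element) != "H")
    for (nb in set_b@residue_numbers) {
      ib <- which(a$chain_id == set_b@chain_id & a$residue_number == nb &
                  toupper(a$element) != "H")
      best <- Inf
      for (i in ia) for (j in ib) {
        d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
        if (d < best) best <- d
      }
      out[[paste(na, nb, sep = "_")]] <- best
    }
  }
  out
}

# Deterministic rotation matrix for invariance checks.
testRotation <- function(ax = c(1, 2, 3), theta = 0.7) {
  ax <- ax / sqrt(sum(ax^2))
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
              3, 3, byrow = TRUE)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

# Minimal two-atom trajectory with prescribed per-frame positions of atoms
# FE (HEM) and C30 (LAN).
feC30Traj <- function(pos_fe, pos_c30) {
  topo <- cyp51md:::newTopology(1:2, c("FE", "C30"), c("HEM", "LAN"),
                                c("H", "L"), c(1, 1), c("FE", "C"))
  nf <- nrow(pos_fe)
  co <- array(0, dim = c(nf, 2, 3))
  co[, 1, ] <- pos_fe
  co[, 2, ] <- pos_c30
  cyp51md:::newTrajectory(topo, co)
}
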