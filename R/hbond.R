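AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
         "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
         "TYR", "VAL")
AA3TO1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
            GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
            LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
            SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

## "M384"-style residue tag; falls back to the 3-letter name.
residueTag <- function(residue_name, residue_number) {
  one <- AA3TO1[residue_name]
  one[is.na(one)] <- residue_name[is.na(one)]
  paste0(one, residue_number)
}

#' Is a hydrogen bond present in one frame?
#'
#' Applies the distance criterion to a single atom pair in a single frame: a
#' bond is present iff the Euclidean distance between the hydroxyl probe atom
#' (the donor oxygen, or the hydroxyl hydrogen under
#' \code{"hydrogen_acceptor"} mode) and the partner atom is within the
#' cut-off.
#'
#' @param traj an [MDTrajectory-class].
#' @param frame 1-based frame position.
#' @param partner_index,hydroxyl_index 1-based atom positions.
#' @param criterion an [HBondCriterion-class]; default 2.4 Angstrom
#'   donor-acceptor, inclusive.
#' @return logical scalar.
#' @export
hbondPresent <- function(traj, frame, partner_index, hydroxyl_index,
                         criterion = hbondCriterion()) {
  stopifnot(is(traj, "MDTrajectory"), is(criterion, "HBondCriterion"))
  nf <- nFrames(traj)
  na <- nAtoms(traj)
  if (frame < 1L || frame > nf) stopf("frame %d out of range 1..%d", frame, nf)
  if (partner_index < 1L || partner_index > na ||
      hydroxyl_index < 1L || hydroxyl_index > na)
    stopf("atom index out of range 1..%d", na)
  d <- sqrt(sum((traj@coords[frame, partner_index, ] -
                 traj@coords[frame, hydroxyl_index, ])^2))
  if (criterion@inclusive) d <= criterion@cutoff_angstrom
  else d < criterion@cutoff_angstrom
}

#' Candidate hydrogen-bond partner atoms
#'
#' The default partner set for the occupancy analysis: the backbone amide
#' nitrogen and carbonyl oxygen (atom names \code{N} and \code{O}) of every
#' standard amino-acid residue, i.e. the groups the ligand hydroxyl
#' predominantly bonds to. An extra selection expression can add further
#' acceptors/donors (e.g. a side-chain indole nitrogen).
#'
#' @param topology an [MDTopology-class] (or trajectory).
#' @param extra_spec optional [selectAtoms] expression whose matches are
#'   added to the backbone set.
#' @return an [AtomSelection-class]
#' @export
candidatePartners <- function(topology, extra_spec = NULL) {
  if (is(topology, "MDTrajectory")) topology <- topology@topology
  a <- topology@atoms
  mask <- a$residue_name %in% AA3 & a$atom_name %in% c("N", "O")
  spec <- "backbone amide N/O of protein residues"
  if (!is.null(extra_spec)) {
    mask <- mask | evalSelection(a, extra_spec)
    spec <- paste0(spec, " plus (", extra_spec, ")")
  }
  new("AtomSelection", spec = spec, indices = as.integer(which(mask)))
}

#' Relative hydrogen-bond occupation times (tau_HB/tau_0)
#'
#' For each residue owning at least one partner atom, the percentage of
#' frames in the analysis window in which the ligand hydroxyl forms a
#' hydrogen bond (distance criterion, see [HBondCriterion-class]) with any
#' partner atom of that residue. Multiple bonded atoms of one residue in one
#' frame count once; tau_0 is the full window, so each occupancy lies in
#' [0, 100] but occupancies need not sum to 100 (the hydroxyl may be unbonded
#' or multiply bonded in a frame). Entries are sorted by descending
#' occupancy; residues never bonded are omitted unless \code{keep_zero}.
#'
#' @param traj an [MDTrajectory-class].
#' @param hydroxyl_sel selection (expression or [AtomSelection-class])
#'   resolving exactly one probe atom: the hydroxyl oxygen under
#'   \code{donor_acceptor} mode, the hydroxyl hydrogen under
#'   \code{hydrogen_acceptor} mode.
#' @param partner_sel selection of partner atoms; default
#'   [candidatePartners] (backbone amide N/O).
#' @param criterion an [HBondCriterion-class]; default 2.4 Angstrom
#'   donor-acceptor, inclusive.
#' @param window integer \code{c(start, end)}, 1-based inclusive frame
#'   positions; default the second half of the trajectory (the production
#'   window convention: the last half of the run is analysed).
#' @param structure_label label stored in the result (default "structure").
#' @param keep_zero also report residues with 0\% occupancy (default FALSE).
#' @return an [OccupancyTable-class]
#' @export
occupancyTable <- function(traj, hydroxyl_sel, partner_sel = NULL,
                           criterion = hbondCriterion(), window = NULL,
                           structure_label = "structure",
                           keep_zero = FALSE) {
  stopifnot(is(traj, "MDTrajectory"), is(criterion, "HBondCriterion"))
  nf <- nFrames(traj)
  if (is.null(window)) window <- c(floor(nf / 2) + 1L, nf)
  window <- as.integer(window)
  if (length(window) != 2L || window[1L] > window[2L] ||
      window[1L] < 1L || window[2L] > nf)
    stopf("invalid analysis window [%s]", paste(window, collapse = ", "))
  hi <- resolveSingleAtom(traj, hydroxyl_sel, "hydroxyl selection")
  if (is.null(partner_sel)) partner_sel <- candidatePartners(traj)
  pidx <- if (is(partner_sel, "AtomSelection")) partner_sel@indices
          else selectAtoms(traj, partner_sel)@indices
  frames <- window[1L]:window[2L]
  nw <- length(frames)
  a <- atoms(traj)

  entries <- data.frame(residue_name = character(0),
                        residue_number = integer(0),
                        occupancy_percent = numeric(0))
  if (length(pidx) > 0L) {
    ## per-frame distances hydroxyl -> each partner atom, vectorised
    dx <- traj@coords[frames, pidx, 1, drop = FALSE] -
          traj@coords[frames, hi, 1]
    dy <- traj@coords[frames, pidx, 2, drop = FALSE] -
          traj@coords[frames, hi, 2]
    dz <- traj@coords[frames, pidx, 3, drop = FALSE] -
          traj@coords[frames, hi, 3]
    d <- sqrt(dx^2 + dy^2 + dz^2)
    dim(d) <- c(nw, length(pidx))
    bonded <- if (criterion@inclusive) d <= criterion@cutoff_angstrom
              else d < criterion@cutoff_angstrom
    ## attribute to the residue owning the partner atom; count once per frame
    resKey <- paste(a$chain_id[pidx], a$residue_number[pidx],
                    a$residue_name[pidx], sep = "|")
    groups <- split(seq_along(pidx), resKey)
    occ <- vapply(groups, function(g) {
      anyBond <- rowSums(bonded[, g, drop = FALSE]) > 0L
      100 * sum(anyBond) / nw
    }, numeric(1))
    first <- vapply(groups, `[`, 0L, 1L)
    entries <- data.frame(
      residue_name = a$residue_name[pidx][first],
      residue_number = a$residue_number[pidx][first],
      occupancy_percent = unname(occ),
      stringsAsFactors = FALSE)
    if (!keep_zero) entries <- entries[entries$occupancy_percent > 0, ]
    ord <- order(-entries$occupancy_percent, entries$residue_number)
    entries <- entries[ord, , drop = FALSE]
    rownames(entries) <- NULL
  }
  new("OccupancyTable", structure_label = structure_label, entries = entries,
      n_frames_analyzed = nw, window = window)
}

#' Write occupancy tables as a TSV report
#'
#' Columns \code{structure_label}, \code{residue}, \code{occupancy_percent};
#' percentages are rounded to 1 decimal in the report (full precision is
#' retained in the objects).
#'
#' @param tables an [OccupancyTable-class] or list of them.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeOccupancyTSV <- function(tables, path) {
  if (is(tables, "OccupancyTable")) tables <- list(tables)
  rows <- do.call(rbind, lapply(tables, function(tab) {
    e <- tab@entries
    if (nrow(e) == 0L) return(NULL)
    data.frame(structure_label = tab@structure_label,
               residue = residueTag(e$residue_name, e$residue_number),
               occupancy_percent = sprintf("%.1f", e$occupancy_percent),
               stringsAsFactors = FALSE)
  }))
  if (is.null(rows))
    rows <- data.frame(structure_label = character(0), residue = character(0),
                       occupancy_percent = character(0))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
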