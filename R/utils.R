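## internal helpers shared across modules

## Construct an MDTopology from parallel vectors.
newTopology <- function(serial, atom_name, residue_name, chain_id,
                        residue_number, element) {
  new("MDTopology", atoms = data.frame(
    serial = as.integer(serial),
    atom_name = as.character(atom_name),
    residue_name = as.character(residue_name),
    chain_id = as.character(chain_id),
    residue_number = as.integer(residue_number),
    element = as.character(element),
    stringsAsFactors = FALSE))
}

## Construct an MDTrajectory from a coords array.
newTrajectory <- function(topology, coords, times_ps = NULL,
                          frame_indices = NULL) {
  nf <- dim(coords)[1L]
  if (is.null(times_ps)) times_ps <- as.numeric(seq_len(nf) - 1L)
  if (is.null(frame_indices)) frame_indices <- seq_len(nf) - 1L
  new("MDTrajectory", topology = topology, coords = coords,
      times_ps = as.numeric(times_ps),
      frame_indices = as.integer(frame_indices))
}

#' Create an energy series
#'
#' @param values numeric per-frame energies.
#' @param label series role: \code{"complex"}, \code{"component1"},
#'   \code{"component2"} or \code{"other"}.
#' @param frame_indices optional integer frame labels (default \code{0:(n-1)}).
#' @param unit energy unit string; metadata only, default \code{"kcal/mol"}.
#' @return an [EnergySeries-class]
#' @export
energySeries <- function(values, label = "other", frame_indices = NULL,
                         unit = "kcal/mol") {
  if (is.null(frame_indices)) frame_indices <- seq_along(values) - 1L
  new("EnergySeries", label = label, values = as.numeric(values),
      frame_indices = as.integer(frame_indices), unit = unit)
}

#' Hydrogen-bond distance criterion constructor
#'
#' @param cutoff_angstrom cut-off distance in Angstrom; default 2.4, the
#'   donor-acceptor criterion used throughout the occupancy analyses.
#' @param mode \code{"donor_acceptor"} (heavy-atom, default) or
#'   \code{"hydrogen_acceptor"}.
#' @param inclusive count a distance exactly at the cut-off as bonded
#'   (default \code{TRUE}).
#' @return an [HBondCriterion-class]
#' @export
hbondCriterion <- function(cutoff_angstrom = 2.4, mode = "donor_acceptor",
                           inclusive = TRUE) {
  new("HBondCriterion", cutoff_angstrom = cutoff_angstrom, mode = mode,
      inclusive = inclusive)
}

#' Key residue set constructor
#'
#' @param chain_id chain the residues live on.
#' @param residue_numbers positive residue numbers.
#' @param residue_names expected one-letter codes, \code{NA} for wildcard;
#'   recycled \code{NA} if omitted.
#' @return a [KeyResidueSet-class]
#' @export
keyResidueSet <- function(chain_id, residue_numbers, residue_names = NULL) {
  if (is.null(residue_names))
    residue_names <- rep(NA_character_, length(residue_numbers))
  new("KeyResidueSet", chain_id = chain_id,
      residue_numbers = as.integer(residue_numbers),
      residue_names = as.character(residue_names))
}

## Pairwise Euclidean distances between rows of two xyz matrices.
crossDist <- function(a, b) {
  ## |a_i - b_j|: outer sums of squares minus cross term
  a2 <- rowSums(a * a)
  b2 <- rowSums(b * b)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)
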