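#' @import methods
NULL

#' MDTopology: the atom list of a simulated system
#'
#' An ordered table of atom records whose order matches the coordinate order
#' of every frame of an [MDTrajectory-class]. Atom identities follow PDB
#' conventions: 1-based residue numbering, single-character chain identifiers,
#' coordinates in Angstrom downstream. The atom names carry the identities the
#' analyses rely on, e.g. the heme iron (\code{FE} of residue \code{HEM}) and
#' lanosterol's oxidation-centre methyl carbon (\code{C30}).
#'
#' @slot atoms a \code{data.frame} with columns \code{serial} (unique positive
#'   integer), \code{atom_name}, \code{residue_name}, \code{chain_id} (single
#'   character), \code{residue_number} (integer), \code{element}.
#' @aliases MDTopology
#' @exportClass MDTopology
setClass("MDTopology", slots = c(atoms = "data.frame"))

setValidity("MDTopology", function(object) {
  a <- object@atoms
  need <- c("serial", "atom_name", "residue_name", "chain_id",
            "residue_number", "element")
  if (!all(need %in% names(a)))
    return(paste("atoms must have columns:", paste(need, collapse = ", ")))
  if (nrow(a) == 0L) return("topology must contain at least one atom")
  if (anyDuplicated(a$serial)) return("atom serials must be unique")
  if (any(a$serial <= 0L)) return("atom serials must be positive")
  if (any(!nzchar(a$atom_name))) return("atom names must be non-empty")
  if (any(nchar(a$chain_id) != 1L)) return("chain_id must be one character")
  TRUE
})

#' MDTrajectory: ordered coordinate frames over a topology
#'
#' Frames are stored as a numeric array of dimension
#' \code{c(n_frames, n_atoms, 3)} (Angstrom); \code{times_ps} carries the
#' simulation-time axis in picoseconds and \code{frame_indices} the strictly
#' increasing frame numbers.
#'
#' @slot topology an [MDTopology-class].
#' @slot coords numeric array \code{[frame, atom, xyz]} in Angstrom.
#' @slot times_ps numeric vector, one non-negative time (ps) per frame.
#' @slot frame_indices strictly increasing integer frame labels.
#' @aliases MDTrajectory
#' @exportClass MDTrajectory
setClass("MDTrajectory",
         slots = c(topology = "MDTopology", coords = "array",
                   times_ps = "numeric", frame_indices = "integer"))

setValidity("MDTrajectory", function(object) {
  d <- dim(object@coords)
  if (length(d) != 3L || d[3L] != 3L)
    return("coords must be an [frame, atom, 3] array")
  if (d[2L] != nrow(object@topology@atoms))
    return("coords atom dimension must match topology length")
  if (d[1L] == 0L) return("trajectory must contain at least one frame")
  if (length(object@times_ps) != d[1L])
    return("times_ps length must equal frame count")
  if (length(object@frame_indices) != d[1L])
    return("frame_indices length must equal frame count")
  if (any(!is.finite(object@coords))) return("all coordinates must be finite")
  if (any(object@times_ps < 0)) return("times must be non-negative")
  if (d[1L] > 1L && any(diff(object@frame_indices) <= 0L))
    return("frame indices must be strictly increasing")
  TRUE
})

#' EnergySeries: per-frame internal energies from one simulation
#'
#' Holds one of the three terms of the binding-enthalpy difference: the
#' complex, or one of the isolated components, each computed in its own
#' simulation (so series lengths may differ between terms). The energy unit is
#' configuration metadata (default kcal/mol); all analyses are unit-agnostic.
#'
#' @slot label one of \code{"complex"}, \code{"component1"},
#'   \code{"component2"}, \code{"other"}.
#' @slot values finite numeric energies, one per frame.
#' @slot frame_indices matching integer frame labels.
#' @slot unit energy unit string (metadata only).
#' @aliases EnergySeries
#' @exportClass EnergySeries
setClass("EnergySeries",
         slots = c(label = "character", values = "numeric",
                   frame_indices = "integer", unit = "character"))

setValidity("EnergySeries", function(object) {
  if (!object@label %in% c("complex", "component1", "component2", "other"))
    return("label must be one of complex/component1/component2/other")
  if (length(object@values) == 0L) return("values must be non-empty")
  if (any(!is.finite(object@values))) return("values must be finite")
  if (length(object@frame_indices) != length(object@values))
    return("frame_indices must match values in length")
  TRUE
})

#' AtomSelection: a resolved atom selection
#'
#' The result of evaluating a selection expression (see [selectAtoms]) against
#' a topology: the expression string plus the 1-based positions of the
#' matching atoms in topology order.
#'
#' @slot spec the selection expression.
#' @slot indices integer positions of the selected atoms (may be empty).
#' @aliases AtomSelection
#' @exportClass AtomSelection
setClass("AtomSelection", slots = c(spec = "character", indices = "integer"))

#' HBondCriterion: the distance criterion for a hydrogen bond
#'
#' A hydrogen bond is scored present when the distance between the two probe
#' atoms is within the cut-off; the default is the 2.4 Angstrom donor-acceptor
#' heavy-atom criterion, applied inclusively. The alternative
#' \code{"hydrogen_acceptor"} mode measures from the hydroxyl hydrogen
#' instead, for workflows that read the same cut-off as a hydrogen-acceptor
#' distance. No angular term is applied.
#'
#' @slot cutoff_angstrom positive cut-off distance in Angstrom (default 2.4).
#' @slot mode \code{"donor_acceptor"} (default) or \code{"hydrogen_acceptor"}.
#' @slot inclusive logical; if \code{TRUE} (default) a distance exactly equal
#'   to the cut-off counts as bonded.
#' @aliases HBondCriterion
#' @exportClass HBondCriterion
setClass("HBondCriterion",
         slots = c(cutoff_angstrom = "numeric", mode = "character",
                   inclusive = "logical"),
         prototype = prototype(cutoff_angstrom = 2.4, mode = "donor_acceptor",
                               inclusive = TRUE))

setValidity("HBondCriterion", function(object) {
  if (length(object@cutoff_angstrom) != 1L || object@cutoff_angstrom <= 0)
    return("cutoff_angstrom must be a single positive number")
  if (!object@mode %in% c("donor_acceptor", "hydrogen_acceptor"))
    return("mode must be donor_acceptor or hydrogen_acceptor")
  TRUE
})

#' OccupancyTable: relative hydrogen-bond occupation times
#'
#' Per-residue relative occupation times tau_HB/tau_0 of the ligand hydroxyl
#' group, in percent of the analysed window, sorted by descending occupancy.
#' Occupancies need not sum to 100: the hydroxyl may be unbonded, or bonded to
#' more than one residue, in any given frame.
#'
#' @slot structure_label label of the simulated structure (e.g. "WT",
#'   "R277L").
#' @slot entries \code{data.frame} with columns \code{residue_name},
#'   \code{residue_number}, \code{occupancy_percent}, sorted by descending
#'   occupancy; residues never bonded are omitted.
#' @slot n_frames_analyzed number of frames in the analysis window.
#' @slot window integer \code{c(start, end)}, 1-based inclusive frame
#'   positions.
#' @aliases OccupancyTable
#' @exportClass OccupancyTable
setClass("OccupancyTable",
         slots = c(structure_label = "character", entries = "data.frame",
                   n_frames_analyzed = "integer", window = "integer"))

setValidity("OccupancyTable", function(object) {
  e <- object@entries
  need <- c("residue_name", "residue_number", "occupancy_percent")
  if (!all(need %in% names(e)))
    return(paste("entries must have columns:", paste(need, collapse = ", ")))
  if (nrow(e) > 0) {
    if (any(e$occupancy_percent < 0 | e$occupancy_percent > 100))
      return("occupancies must lie in [0, 100]")
    if (is.unsorted(rev(e$occupancy_percent)))
      return("entries must be sorted by descending occupancy")
  }
  if (length(object@window) != 2L)
    return("window must be c(start, end)")
  if (object@n_frames_analyzed != object@window[2L] - object@window[1L] + 1L)
    return("n_frames_analyzed must equal window end - start + 1")
  if (object@n_frames_analyzed <= 0L)
    return("analysis window must be non-empty")
  TRUE
})

#' DistanceSeries: an interatomic distance as a function of time
#'
#' Per-frame Euclidean distance between two selected atoms, e.g. the heme
#' iron and lanosterol's C30 methyl carbon whose separation proxies
#' catalytically competent substrate positioning.
#'
#' @slot structure_label label of the structure the series belongs to.
#' @slot times_ps simulation times in picoseconds.
#' @slot distances_angstrom non-negative distances in Angstrom.
#' @aliases DistanceSeries
#' @exportClass DistanceSeries
setClass("DistanceSeries",
         slots = c(structure_label = "character", times_ps = "numeric",
                   distances_angstrom = "numeric"))

setValidity("DistanceSeries", function(object) {
  if (length(object@times_ps) != length(object@distances_angstrom))
    return("times and distances must have equal length")
  if (any(object@distances_angstrom < 0)) return("distances must be >= 0")
  TRUE
})

#' BindingEnergyResult: a trajectory-average binding enthalpy
#'
#' The binding enthalpy E_b = <U_complex> - <U_component1> - <U_component2>,
#' where <.> is the average over each (separately simulated) trajectory, with
#' a standard error propagated from per-series block-averaged standard
#' errors. More negative E_b means more favourable binding.
#'
#' @slot e_b the enthalpy estimate (energy units of the input series).
#' @slot se non-negative propagated standard error.
#' @slot means named numeric(3): the three trajectory averages.
#' @slot ses named numeric(3): the three block standard errors.
#' @slot n_frames named integer(3): frames per series.
#' @slot n_blocks number of blocks requested for block averaging.
#' @slot unit energy unit string (metadata).
#' @aliases BindingEnergyResult
#' @exportClass BindingEnergyResult
setClass("BindingEnergyResult",
         slots = c(e_b = "numeric", se = "numeric", means = "numeric",
                   ses = "numeric", n_frames = "integer", n_blocks = "integer",
                   unit = "character"))

setValidity("BindingEnergyResult", function(object) {
  if (object@se < 0) return("se must be non-negative")
  if (length(object@n_frames) != 3L) return("n_frames must have length 3")
  if (any(object@n_frames <= 0L)) return("n_frames must be positive")
  TRUE
})

#' KeyResidueSet: interface residues expected to drive complex formation
#'
#' A chain plus the residue numbers (with optionally expected one-letter
#' residue names; \code{NA} means wildcard) whose cross-chain proximity is
#' scored when ranking docking poses. Defaults for the CYP51A1-POR system are
#' provided by [cyp51KeyResidues] and [porKeyResidues].
#'
#' @slot chain_id single chain character.
#' @slot residue_numbers positive integer residue numbers.
#' @slot residue_names expected one-letter residue codes, \code{NA} for
#'   wildcard; same length as \code{residue_numbers}.
#' @aliases KeyResidueSet
#' @exportClass KeyResidueSet
setClass("KeyResidueSet",
         slots = c(chain_id = "character", residue_numbers = "integer",
                   residue_names = "character"))

setValidity("KeyResidueSet", function(object) {
  if (length(object@residue_numbers) == 0L)
    return("residue set must be non-empty")
  if (any(object@residue_numbers <= 0L))
    return("residue numbers must be positive")
  if (length(object@residue_names) != length(object@residue_numbers))
    return("residue_names must match residue_numbers in length")
  TRUE
})

#' Pose: one candidate two-chain complex geometry
#'
#' A labelled single-frame structure containing the two chains of a docked
#' complex (e.g. CYP51A1 and POR as produced by rigid-body docking).
#'
#' @slot label pose label.
#' @slot structure an [MDTrajectory-class] with exactly one frame.
#' @slot chain_a,chain_b the two chain identifiers.
#' @aliases Pose
#' @exportClass Pose
setClass("Pose",
         slots = c(label = "character", structure = "MDTrajectory",
                   chain_a = "character", chain_b = "character"))

setValidity("Pose", function(object) {
  if (dim(object@structure@coords)[1L] != 1L)
    return("pose structure must contain exactly one frame")
  ch <- object@structure@topology@atoms$chain_id
  if (!object@chain_a %in% ch)
    return(paste0("chain ", object@chain_a, " not present in pose"))
  if (!object@chain_b %in% ch)
    return(paste0("chain ", object@chain_b, " not present in pose"))
  TRUE
})

#' PoseScore: key-residue contact score of one pose
#'
#' For every cross-chain pair of key residues, the minimum heavy-atom
#' distance; \code{contacts} counts the pairs within the contact cut-off and
#' \code{sum_min_distances} is the tie-breaking sum of the per-pair minima.
#'
#' @slot label label of the scored pose.
#' @slot contacts number of key-residue pairs in contact.
#' @slot sum_min_distances sum of per-pair minimum distances (Angstrom).
#' @slot per_pair \code{data.frame} with columns \code{residue_a},
#'   \code{number_a}, \code{residue_b}, \code{number_b}, \code{min_distance}.
#' @slot cutoff contact cut-off used (Angstrom).
#' @aliases PoseScore
#' @exportClass PoseScore
setClass("PoseScore",
         slots = c(label = "character", contacts = "integer",
                   sum_min_distances = "numeric", per_pair = "data.frame",
                   cutoff = "numeric"))

setValidity("PoseScore", function(object) {
  if (object@contacts < 0L) return("contacts must be non-negative")
  if (object@contacts > nrow(object@per_pair))
    return("contacts cannot exceed the number of residue pairs")
  TRUE
})
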