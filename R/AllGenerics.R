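#' @rdname MDTrajectory-class
#' @param x an object with frames
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname MDTopology-class
#' @param x an object with atoms
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' @rdname MDTopology-class
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))

#' @rdname MDTrajectory-class
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))

#' @rdname MDTrajectory-class
#' @export
setGeneric("timesPs", function(x) standardGeneric("timesPs"))

#' @rdname MDTrajectory-class
#' @export
setGeneric("topology", function(x) standardGeneric("topology"))

#' @rdname OccupancyTable-class
#' @param x an object with a structure label
#' @export
setGeneric("structureLabel", function(x) standardGeneric("structureLabel"))

#' @rdname OccupancyTable-class
#' @export
setGeneric("occupancyEntries", function(x) standardGeneric("occupancyEntries"))

#' @rdname EnergySeries-class
#' @param x an [EnergySeries-class]
#' @export
setGeneric("energyValues", function(x) standardGeneric("energyValues"))

#' @rdname AtomSelection-class
#' @param x an [AtomSelection-class]
#' @export
setGeneric("selectionIndices",
           function(x) standardGeneric("selectionIndices"))

setMethod("nFrames", "MDTrajectory", function(x) dim(x@coords)[1L])
setMethod("nAtoms", "MDTrajectory", function(x) dim(x@coords)[2L])
setMethod("nAtoms", "MDTopology", function(x) nrow(x@atoms))
setMethod("atoms", "MDTopology", function(x) x@atoms)
setMethod("atoms", "MDTrajectory", function(x) x@topology@atoms)
setMethod("coords", "MDTrajectory", function(x) x@coords)
setMethod("timesPs", "MDTrajectory", function(x) x@times_ps)
setMethod("topology", "MDTrajectory", function(x) x@topology)
setMethod("structureLabel", "OccupancyTable", function(x) x@structure_label)
setMethod("structureLabel", "DistanceSeries", function(x) x@structure_label)
setMethod("occupancyEntries", "OccupancyTable", function(x) x@entries)
setMethod("energyValues", "EnergySeries", function(x) x@values)
setMethod("selectionIndices", "AtomSelection", function(x) x@indices)
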