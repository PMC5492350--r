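setMethod("show", "MDTopology", function(object) {
  a <- object@atoms
  cat(sprintf("MDTopology: %d atoms, %d residues, chains: %s\n",
              nrow(a),
              length(unique(paste(a$chain_id, a$residue_number))),
              paste(unique(a$chain_id), collapse = " ")))
})

setMethod("show", "MDTrajectory", function(object) {
  cat(sprintf("MDTrajectory: %d frames x %d atoms, t = %.1f..%.1f ps\n",
              nFrames(object), nAtoms(object), min(object@times_ps),
              max(object@times_ps)))
})

setMethod("show", "EnergySeries", function(object) {
  cat(sprintf("EnergySeries '%s': %d frames, mean %.4g %s\n",
              object@label, length(object@values), mean(object@values),
              object@unit))
})

setMethod("show", "AtomSelection", function(object) {
  cat(sprintf("AtomSelection '%s': %d atoms\n", object@spec,
              length(object@indices)))
})

setMethod("show", "OccupancyTable", function(object) {
  cat(sprintf("OccupancyTable [%s]: %d residues over %d frames (%d..%d)\n",
              object@structure_label, nrow(object@entries),
              object@n_frames_analyzed, object@window[1L],
              object@window[2L]))
  if (nrow(object@entries)) {
    e <- object@entries
    cat(sprintf("  %s %5.1f%%\n",
                residueTag(e$residue_name, e$residue_number),
                e$occupancy_percent), sep = "")
  }
})

setMethod("show", "DistanceSeries", function(object) {
  s <- seriesSummary(object)
  cat(sprintf(
    "DistanceSeries [%s]: %d frames, mean %.2f A (sd %.2f, %.2f..%.2f)\n",
    object@structure_label, s$n, s$mean, s$sd, s$min, s$max))
})

setMethod("show", "BindingEnergyResult", function(object) {
  cat(sprintf("BindingEnergyResult: e_b = %.4g +/- %.2g %s\n", object@e_b,
              object@se, object@unit))
  cat(sprintf("  <U> complex %.6g, components %.6g / %.6g (n = %s)\n",
              object@means[1L], object@means[2L], object@means[3L],
              paste(object@n_frames, collapse = "/")))
})

setMethod("show", "KeyResidueSet", function(object) {
  nm <- ifelse(is.na(object@residue_names), "?", object@residue_names)
  cat(sprintf("KeyResidueSet chain %s: %s\n", object@chain_id,
              paste0(nm, object@residue_numbers, collapse = ", ")))
})

setMethod("show", "Pose", function(object) {
  cat(sprintf("Pose '%s': chains %s/%s, %d atoms\n", object@label,
              object@chain_a, object@chain_b, nAtoms(object@structure)))
})

setMethod("show", "PoseScore", function(object) {
  cat(sprintf(
    "PoseScore '%s': %d contacts (<= %.1f A), sum min dist %.1f A\n",
    object@label, object@contacts, object@cutoff,
    object@sum_min_distances))
})
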