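#' Key interface residues of the CYP51A1-POR complex
#'
#' The CYP51A1 residues expected to contact POR -- K127, A172, K175, K364,
#' K442, R452, N459 -- chosen by homology to CYP family members with known
#' reductase interfaces, and the corresponding POR-side residues E92, 93 and
#' 142 (the identities of 93 and 142 are not asserted, so they carry
#' wildcards).
#'
#' @param chain_id chain carrying the residues (default \code{"A"} for
#'   CYP51A1, \code{"B"} for POR).
#' @return a [KeyResidueSet-class]
#' @export
cyp51KeyResidues <- function(chain_id = "A") {
  keyResidueSet(chain_id,
                residue_numbers = c(127L, 172L, 175L, 364L, 442L, 452L, 459L),
                residue_names = c("K", "A", "K", "K", "K", "R", "N"))
}

#' @rdname cyp51KeyResidues
#' @export
porKeyResidues <- function(chain_id = "B") {
  keyResidueSet(chain_id, residue_numbers = c(92L, 93L, 142L),
                residue_names = c("E", NA, NA))
}

## Heavy-atom coordinate blocks of each key residue, frame 1 of the pose.
resolveKeyAtoms <- function(pose, set) {
  a <- atoms(pose@structure)
  lapply(seq_along(set@residue_numbers), function(i) {
    num <- set@residue_numbers[i]
    sel <- a$chain_id == set@chain_id & a$residue_number == num &
           toupper(a$element) != "H"
    if (!any(sel))
      stopf("resolution error: residue %d not found on chain %s",
            num, set@chain_id)
    rname <- a$residue_name[sel][1L]
    expected <- set@residue_names[i]
    if (!is.na(expected)) {
      found1 <- AA3TO1[rname]
      if (!is.na(found1) && found1 != expected)
        warnf("chain %s residue %d is %s, expected %s",
              set@chain_id, num, rname, expected)
    }
    list(name = rname, number = num,
         xyz = matrix(pose@structure@coords[1, sel, ], ncol = 3L))
  })
}

#' Key-residue contact score of a docking pose
#'
#' For every cross-chain pair of key residues, computes the minimum
#' heavy-atom distance in the pose, counts the pairs within the contact
#' cut-off and sums the per-pair minima. This positional score formalises
#' the pose-selection step of the docking protocol: among candidate rigid
#' poses, the one placing the known favourable interface residues closest
#' together is preferred.
#'
#' @param pose a [Pose-class].
#' @param set_a,set_b [KeyResidueSet-class] objects on the pose's two
#'   chains; defaults [cyp51KeyResidues] / [porKeyResidues].
#' @param contact_cutoff heavy-atom contact cut-off in Angstrom
#'   (default 5.0).
#' @return a [PoseScore-class]
#' @export
contactScore <- function(pose, set_a = cyp51KeyResidues(),
                         set_b = porKeyResidues(), contact_cutoff = 5.0) {
  stopifnot(is(pose, "Pose"), contact_cutoff > 0)
  ra <- resolveKeyAtoms(pose, set_a)
  rb <- resolveKeyAtoms(pose, set_b)
  grid <- expand.grid(i = seq_along(ra), j = seq_along(rb))
  mind <- mapply(function(i, j) min(crossDist(ra[[i]]$xyz, rb[[j]]$xyz)),
                 grid$i, grid$j)
  per_pair <- data.frame(
    residue_a = vapply(ra, `[[`, "", "name")[grid$i],
    number_a = vapply(ra, `[[`, 0L, "number")[grid$i],
    residue_b = vapply(rb, `[[`, "", "name")[grid$j],
    number_b = vapply(rb, `[[`, 0L, "number")[grid$j],
    min_distance = as.numeric(mind),
    stringsAsFactors = FALSE)
  new("PoseScore", label = pose@label,
      contacts = as.integer(sum(mind <= contact_cutoff)),
      sum_min_distances = sum(mind), per_pair = per_pair,
      cutoff = contact_cutoff)
}

#' Rank candidate poses by key-residue contacts
#'
#' Scores every pose with [contactScore] and sorts by contact count
#' (descending), breaking ties by the sum of per-pair minimum distances
#' (ascending) and then by label, so the ranking is deterministic.
#'
#' @inheritParams contactScore
#' @param poses a list of [Pose-class] objects (at least one).
#' @return a list of [PoseScore-class], best pose first.
#' @export
rankPoses <- function(poses, set_a = cyp51KeyResidues(),
                      set_b = porKeyResidues(), contact_cutoff = 5.0) {
  if (length(poses) == 0L) stopf("need at least one pose")
  scores <- lapply(poses, contactScore, set_a = set_a, set_b = set_b,
                   contact_cutoff = contact_cutoff)
  ord <- order(-vapply(scores, slot, 0L, "contacts"),
               vapply(scores, slot, numeric(1), "sum_min_distances"),
               vapply(scores, slot, "", "label"))
  scores[ord]
}

#' Read a two-chain pose from a PDB file
#'
#' @param path PDB file with (at least) the two declared chains.
#' @param label pose label; default the file name without extension.
#' @param chain_a,chain_b the two chain identifiers (defaults "A", "B").
#' @return a [Pose-class]
#' @export
readPosePDB <- function(path, label = NULL, chain_a = "A", chain_b = "B") {
  traj <- readMultimodelPDB(path)
  if (nFrames(traj) != 1L)
    stopf("pose file %s must contain exactly one model", path)
  if (is.null(label)) label <- sub("\\.[^.]*$", "", basename(path))
  new("Pose", label = label, structure = traj,
      chain_a = chain_a, chain_b = chain_b)
}

#' Write a pose ranking as TSV / per-pair distances as JSON
#'
#' @param scores list of [PoseScore-class] from [rankPoses].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeRankingTSV <- function(scores, path) {
  tab <- data.frame(
    label = vapply(scores, slot, "", "label"),
    contacts = vapply(scores, slot, 0L, "contacts"),
    sum_min_distances = vapply(scores, slot, numeric(1),
                               "sum_min_distances"),
    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeRankingTSV
#' @export
writePerPairJSON <- function(scores, path) {
  out <- lapply(scores, function(s) {
    pp <- s@per_pair
    list(label = s@label, contacts = s@contacts, cutoff = s@cutoff,
         pairs = lapply(seq_len(nrow(pp)), function(i) list(
           residue_a = paste0(pp$residue_a[i], pp$number_a[i]),
           residue_b = paste0(pp$residue_b[i], pp$number_b[i]),
           min_distance = pp$min_distance[i])))
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
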