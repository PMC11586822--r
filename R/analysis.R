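# Trajectory validation analytics: per-residue contact residence
# fractions, centre-of-mass displacement traces, and overlap between
# predicted and observed interacting residues.

#' Per-residue contact fractions along a trajectory
#'
#' A residue counts as contacting in a frame iff any of its heavy atoms
#' lies within `cutoff` of any cluster atom in that frame. Hydrogens are
#' excluded by default.
#'
#' @param frames list of cluster coordinate frames (`coords` n x 3), e.g.
#'   from [make_trajectory()] or [read_trajectory()].
#' @param protein_atoms static protein atom records.
#' @param cutoff contact distance (Angstrom, default 4.0).
#' @param include_hydrogens count protein hydrogens as well.
#' @return `contact_report` data.frame (chain_id, residue_id, residue_name,
#'   contact_fraction), sorted by fraction descending; metadata in
#'   attributes.
#' @export
contact_fractions <- function(frames, protein_atoms, cutoff = 4.0,
                              include_hydrogens = FALSE) {
  stopifnot(length(frames) >= 1)
  pa <- protein_atoms
  if (!include_hydrogens) pa <- pa[pa$element != "H", , drop = FALSE]
  prot_xyz <- as.matrix(pa[, c("x", "y", "z")])
  res_key <- paste(pa$chain_id, pa$residue_id)
  keys <- unique(res_key)
  counts <- stats::setNames(numeric(length(keys)), keys)
  n_atoms <- nrow(frames[[1]]$coords)
  for (fr in frames) {
    if (nrow(fr$coords) != n_atoms)
      stop("inconsistent atom count across frames")
    if (cutoff <= 0) next
    D <- cross_dist(fr$coords, prot_xyz)
    touched <- unique(res_key[apply(D <= cutoff, 2, any)])
    counts[touched] <- counts[touched] + 1
  }
  frac <- counts / length(frames)
  first <- match(keys, res_key)
  rep_df <- data.frame(chain_id = pa$chain_id[first],
                       residue_id = pa$residue_id[first],
                       residue_name = pa$residue_name[first],
                       contact_fraction = unname(frac),
                       stringsAsFactors = FALSE)
  rep_df <- rep_df[rep_df$contact_fraction > 0, , drop = FALSE]
  rep_df <- rep_df[order(-rep_df$contact_fraction, rep_df$chain_id,
                         rep_df$residue_id), , drop = FALSE]
  rownames(rep_df) <- NULL
  structure(rep_df, class = c("contact_report", "data.frame"),
            frames = length(frames), cutoff = cutoff, threshold = 0)
}

#' Filter a contact report by residence fraction
#'
#' Strict inequality: only residues with fraction > threshold are kept
#' (default: more than 40% of the frames).
#'
#' @param report a `contact_report`.
#' @param threshold residence-fraction threshold (default 0.40).
#' @return filtered `contact_report`.
#' @export
filter_report <- function(report, threshold = 0.40) {
  out <- report[report$contact_fraction > threshold, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("contact_report", "data.frame"),
            frames = attr(report, "frames"), cutoff = attr(report, "cutoff"),
            threshold = threshold)
}

#' Centre-of-mass displacement along a trajectory
#'
#' d_t = |COM_t - COM_0| per frame; the summary is the RMS of the d_t
#' (a root-mean-square displacement with respect to the initial centre of
#' mass).
#'
#' @param frames list of coordinate frames with `elements`.
#' @return list with `displacement` (per frame) and `rmsd` (summary).
#' @export
com_displacement <- function(frames) {
  coms <- t(vapply(frames, function(fr) {
    m <- atomic_mass(fr$elements)
    colSums(fr$coords * m) / sum(m)
  }, numeric(3)))
  d <- sqrt(rowSums(sweep(coms, 2, coms[1, ])^2))
  list(displacement = d, rmsd = sqrt(mean(d^2)))
}

#' Overlap between predicted site residues and an observed contact report
#'
#' @param predicted character vector of predicted residue keys
#'   ("chain residue_id") or a data.frame with chain_id/residue_id columns.
#' @param report a (filtered) `contact_report`.
#' @return list with `overlap_count`, `overlap_fraction` (of the predicted
#'   set) and the overlapping keys.
#' @export
compare_sites <- function(predicted, report) {
  pk <- if (is.data.frame(predicted))
    paste(predicted$chain_id, predicted$residue_id)
  else as.character(predicted)
  rk <- paste(report$chain_id, report$residue_id)
  ov <- intersect(pk, rk)
  list(overlap_count = length(ov),
       overlap_fraction = if (length(pk)) length(ov) / length(pk) else 0,
       overlapping = ov)
}

#' @export
print.contact_report <- function(x, ...) {
  cat(sprintf("Contact report: %d residue(s), %d frames, cutoff %.1f A",
              nrow(x), attr(x, "frames"), attr(x, "cutoff")))
  thr <- attr(x, "threshold")
  if (!is.null(thr) && thr > 0) cat(sprintf(", fraction > %.2f", thr))
  cat("\n")
  print.data.frame(utils::head(as.data.frame(x), 20))
  invisible(x)
}
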