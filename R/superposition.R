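# ---------------------------------------------------------------------------
# Anchor-based superposition onto the master structural frame, and the 0-10
# structure quality score. Anchors are the hinge, catalytic loop and xDFG
# slots; the fit uses backbone atoms only (side chains move with
# conformation, the backbone of these regions does not).
# ---------------------------------------------------------------------------

# paired backbone coordinate sets (mobile from the pocket, fixed from the
# master frame) for the given slots
paired_backbone <- function(pocket, frame, slots) {
  bb <- c("N", "CA", "C", "O")
  mob <- pocket$atoms |>
    dplyr::filter(.data$slot %in% slots, .data$elety %in% bb) |>
    dplyr::arrange(.data$slot, match(.data$elety, bb))
  fix <- frame |>
    dplyr::filter(.data$slot %in% slots, .data$elety %in% bb) |>
    dplyr::arrange(.data$slot, match(.data$elety, bb))
  key_m <- paste(mob$slot, mob$elety)
  key_f <- paste(fix$slot, fix$elety)
  common <- intersect(key_m, key_f)
  list(
    mobile = as.matrix(mob[match(common, key_m), c("x", "y", "z")]),
    fixed = as.matrix(fix[match(common, key_f), c("x", "y", "z")]),
    slots = unique(mob$slot[match(common, key_m)])
  )
}

#' Superpose a pocket onto the master frame
#'
#' Least-squares rigid (Kabsch) superposition on the backbone atoms (N,
#' C-alpha, C, O) of the anchor slots (hinge 46-48, catalytic loop 68-75,
#' xDFG 80-82). Reports the anchor RMSD and the RMSD over the backbone of
#' all mapped pocket slots after applying the fitted transform.
#'
#' @param pocket A `kp_pocket` with coordinates.
#' @param frame Master frame atom tibble; defaults to the bundled one.
#' @param anchors Anchor slot indices.
#' @return A `kp_superposition`: `rotation` (3x3, det +1), `translation`
#'   (length-3), `rmsd_anchor`, `rmsd_pocket`, `n_anchor_residues`.
#' @export
superpose <- function(pocket, frame = master_frame(),
                      anchors = anchor_slots()) {
  mapped_anchors <- anchors[!pocket$slots$gap[anchors]]
  pr <- paired_backbone(pocket, frame, mapped_anchors)
  if (length(pr$slots) < 3) {
    stop("insufficient anchors: need at least 3 mapped anchor residues",
         call. = FALSE)
  }
  fit <- kabsch(pr$mobile, pr$fixed)
  all_slots <- pocket$slots$index[!pocket$slots$gap]
  pk <- paired_backbone(pocket, frame, all_slots)
  rmsd_pocket <- rmsd_xyz(
    apply_rigid(pk$mobile, fit$rotation, fit$translation), pk$fixed)
  structure(list(
    rotation = fit$rotation, translation = fit$translation,
    rmsd_anchor = fit$rmsd, rmsd_pocket = rmsd_pocket,
    n_anchor_residues = length(pr$slots)
  ), class = "kp_superposition")
}

#' @export
print.kp_superposition <- function(x, ...) {
  cat(sprintf(
    "<kp_superposition> %d anchor residues: RMSD %.3f A (anchors), %.3f A (pocket)\n",
    x$n_anchor_residues, x$rmsd_anchor, x$rmsd_pocket))
  invisible(x)
}

#' @export
glance.kp_superposition <- function(x, ...) {
  tibble(rmsd_anchor = x$rmsd_anchor, rmsd_pocket = x$rmsd_pocket,
         n_anchor_residues = x$n_anchor_residues)
}

#' Apply a superposition to an atom table
#'
#' @param atoms Tibble with `x`, `y`, `z`.
#' @param sp A `kp_superposition`.
#' @return The atom tibble with transformed coordinates.
#' @export
transform_atoms <- function(atoms, sp) {
  xyz <- apply_rigid(as.matrix(atoms[, c("x", "y", "z")]),
                     sp$rotation, sp$translation)
  atoms$x <- xyz[, 1]; atoms$y <- xyz[, 2]; atoms$z <- xyz[, 3]
  atoms
}

#' Structure quality score
#'
#' Composite 0-10 score combining the superposition RMSDs with the number
#' of missing pocket residues and missing atoms:
#' `score = clamp(10 - w1 max(0, rmsd_anchor - r0) - w2 max(0, rmsd_pocket - r1)
#'   - w3 n_missing_residues - w4 n_missing_atoms, 0, 10)`.
#' 10 means flawless; the score never increases when any penalty input
#' grows.
#'
#' @param rmsd_anchor,rmsd_pocket Superposition RMSDs in Angstrom.
#' @param n_missing_residues,n_missing_atoms Non-negative counts.
#' @param weights Penalty weights `(w1, w2, w3, w4)`.
#' @param rmsd_floors Penalty-free allowances `(r0, r1)` for the anchor and
#'   pocket RMSD; typical well-processed structures sit near these values,
#'   so only the excess is penalised.
#' @return A `kp_quality`: list with `score` and the four penalty
#'   `components`.
#' @export
compute_quality_score <- function(rmsd_anchor, rmsd_pocket,
                                  n_missing_residues, n_missing_atoms,
                                  weights = c(4, 1, 0.4, 0.1),
                                  rmsd_floors = c(0.8, 2.2)) {
  vals <- c(rmsd_anchor, rmsd_pocket, n_missing_residues, n_missing_atoms)
  if (any(vals < 0)) stop("quality-score inputs must be non-negative",
                          call. = FALSE)
  comp <- c(
    anchor = weights[1] * max(0, rmsd_anchor - rmsd_floors[1]),
    pocket = weights[2] * max(0, rmsd_pocket - rmsd_floors[2]),
    missing_residues = weights[3] * n_missing_residues,
    missing_atoms = weights[4] * n_missing_atoms
  )
  structure(list(score = min(10, max(0, 10 - sum(comp))), components = comp),
            class = "kp_quality")
}

#' @export
print.kp_quality <- function(x, ...) {
  cat(sprintf("<kp_quality> score %.2f / 10\n", x$score))
  invisible(x)
}

#' @export
tidy.kp_quality <- function(x, ...) {
  tibble(component = names(x$components), penalty = unname(x$components))
}

#' @export
glance.kp_quality <- function(x, ...) tibble(score = x$score)
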