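#' Least-squares rigid-body superposition (Kabsch)
#'
#' Finds the rotation and translation that minimise the (optionally
#' weighted) RMSD of `mobile` onto `target` and returns the transformed
#' coordinates. The optimal rotation is obtained from the singular value
#' decomposition of the coordinate cross-covariance, with the usual
#' determinant correction that excludes reflections.
#'
#' @param mobile,target `n x 3` coordinate matrices over the same atoms.
#' @param weights Optional non-negative weights (e.g. masses); default
#'   uniform.
#' @return The superposed `n x 3` coordinates of `mobile`.
#' @export
kabsch_superpose <- function(mobile, target, weights = NULL) {
  stopifnot(is.matrix(mobile), is.matrix(target),
            ncol(mobile) == 3L, all(dim(mobile) == dim(target)))
  w <- weights %||% rep(1, nrow(mobile))
  w <- w / sum(w)
  cm <- colSums(mobile * w)
  ct <- colSums(target * w)
  P <- sweep(mobile, 2L, cm)
  Q <- sweep(target, 2L, ct)
  C <- crossprod(P * w, Q)
  sv <- svd(C)
  d <- sign(det(sv$u) * det(sv$v))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  sweep(P %*% R, 2L, ct, `+`)
}

coord_rmsd <- function(a, b) {
  sqrt(mean(rowSums((a - b)^2)))
}

#' RMSD time series relative to a reference frame
#'
#' Root-mean-square deviation of each frame from a reference frame of the
#' same trajectory, a standard conformational-stability readout. With
#' `superpose = TRUE` (default) every frame is first optimally rigid-body
#' superposed onto the reference, so the series is invariant to global
#' rigid motion and is zero at the reference frame.
#'
#' @param traj A [trajectory()].
#' @param reference Reference frame index (default 1).
#' @param selection `"calpha"` (protein C-alpha atoms, default) or
#'   `"all"`.
#' @param superpose Superpose each frame onto the reference first?
#' @return Numeric vector of per-frame RMSD (Angstrom) with attribute
#'   `time` (ns).
#' @export
rmsd_series <- function(traj, reference = 1L,
                        selection = c("calpha", "all"), superpose = TRUE) {
  stopifnot(inherits(traj, "trajectory"))
  selection <- match.arg(selection)
  if (reference < 1L || reference > n_frames(traj)) {
    stop("reference frame index out of range", call. = FALSE)
  }
  sel <- select_atoms(traj, selection)
  if (!any(sel)) stop("empty atom selection", call. = FALSE)
  ref <- frame_coords(traj, reference)[sel, , drop = FALSE]
  out <- vapply(seq_len(n_frames(traj)), function(f) {
    co <- frame_coords(traj, f)[sel, , drop = FALSE]
    if (superpose) co <- kabsch_superpose(co, ref)
    coord_rmsd(co, ref)
  }, numeric(1))
  structure(out, time = (seq_len(n_frames(traj)) - 1L) * traj$time_step)
}

resolve_window <- function(traj, window) {
  nf <- n_frames(traj)
  if (is.character(window)) {
    window <- match.arg(window, c("all", "last_third"))
    if (window == "all") return(seq_len(nf))
    return(seq.int(max(1L, floor(2 * nf / 3) + 1L), nf))
  }
  window <- as.integer(window)
  if (length(window) == 0L || any(window < 1L) || any(window > nf)) {
    stop("window must be a non-empty set of valid frame indices",
         call. = FALSE)
  }
  window
}

# C-alpha selection with a warning for residues lacking a CA atom.
calpha_index <- function(traj) {
  prot <- !traj$atoms$is_ligand
  ca <- select_atoms(traj, "calpha")
  res_all <- unique(traj$atoms$residue_index[prot])
  res_ca <- unique(traj$atoms$residue_index[ca])
  dropped <- setdiff(res_all, res_ca)
  if (length(dropped) > 0L) {
    warning("residue(s) without a C-alpha atom excluded: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  }
  idx <- which(ca)
  idx[order(traj$atoms$residue_index[idx])]
}

#' Per-residue C-alpha RMSF
#'
#' Root-mean-square fluctuation of each protein residue's C-alpha about its
#' mean position over a frame window, after superposing every frame onto
#' the window-mean structure (the mean is refined once: frames are aligned
#' to an initial frame, averaged, then re-aligned to that average).
#' Residues lacking a C-alpha atom are excluded with a warning.
#'
#' @param traj A [trajectory()].
#' @param window `"all"` (default), `"last_third"`, or an integer vector of
#'   frame indices.
#' @return Named numeric vector of per-residue RMSF (Angstrom), names =
#'   residue indices.
#' @export
rmsf_profile <- function(traj, window = "all") {
  stopifnot(inherits(traj, "trajectory"))
  window <- resolve_window(traj, window)
  idx <- calpha_index(traj)
  if (length(idx) == 0L) stop("no C-alpha atoms in trajectory",
                              call. = FALSE)
  frames <- lapply(window, function(f) {
    frame_coords(traj, f)[idx, , drop = FALSE]
  })
  aligned <- lapply(frames, kabsch_superpose, target = frames[[1L]])
  mstruct <- Reduce(`+`, aligned) / length(aligned)
  aligned <- lapply(frames, kabsch_superpose, target = mstruct)
  mstruct <- Reduce(`+`, aligned) / length(aligned)
  sq <- Reduce(`+`, lapply(aligned, function(co) {
    rowSums((co - mstruct)^2)
  })) / length(aligned)
  setNames(sqrt(sq), traj$atoms$residue_index[idx])
}

mass_com <- function(co, mass) {
  colSums(co * mass) / sum(mass)
}

#' Ligand-protein centre-of-mass distance series
#'
#' Per-frame Euclidean distance between the mass-weighted centre of mass of
#' the ligand and that of the protein (ligand excluded), the standard
#' dissociation readout: a ligand drifting out of the pocket shows a
#' rising series. A least-squares slope in Angstrom/ns over the full series
#' is attached as a dissociation indicator, together with the series mean.
#'
#' @param traj A [trajectory()] containing at least one ligand atom and one
#'   protein atom.
#' @return A list of class `com_distance_series`: `distance` (Angstrom per
#'   frame), `time` (ns), `slope` (Angstrom/ns), `mean`.
#' @export
com_distance_series <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  lig <- select_atoms(traj, "ligand")
  prot <- select_atoms(traj, "protein")
  if (!any(lig)) stop("trajectory has no ligand atoms", call. = FALSE)
  if (!any(prot)) stop("trajectory has no protein atoms", call. = FALSE)
  ml <- traj$atoms$mass[lig]
  mp <- traj$atoms$mass[prot]
  d <- vapply(seq_len(n_frames(traj)), function(f) {
    co <- frame_coords(traj, f)
    sqrt(sum((mass_com(co[lig, , drop = FALSE], ml) -
              mass_com(co[prot, , drop = FALSE], mp))^2))
  }, numeric(1))
  tm <- (seq_len(n_frames(traj)) - 1L) * traj$time_step
  slope <- if (length(d) > 1L) {
    unname(stats::coef(stats::lm(d ~ tm))[2L])
  } else {
    NA_real_
  }
  structure(list(distance = d, time = tm, slope = slope, mean = mean(d)),
            class = "com_distance_series")
}

#' @export
print.com_distance_series <- function(x, ...) {
  cat(sprintf(
    "COM distance series: %d frames, mean %.2f A, slope %.4g A/ns\n",
    length(x$distance), x$mean, x$slope))
  invisible(x)
}

#' Per-residue mean distance to the protein centre of mass
#'
#' For every protein residue, the time-average over a frame window of the
#' distance from its C-alpha atom to the protein's mass-weighted centre of
#' mass (ligand excluded). These d-values, computed for a ligand-bound and
#' a ligand-free simulation, feed [delta_d_profile()]. The default window
#' is the final third of the frames, taken as the equilibrated portion.
#'
#' @param traj A [trajectory()].
#' @param window `"last_third"` (default), `"all"`, or frame indices.
#' @param state Label for the trajectory state, e.g. `"ligand-bound"`.
#' @return A data.frame of class `residue_distance_profile` with columns
#'   `residue` and `d` (Angstrom); the state and window are attached as
#'   attributes.
#' @export
residue_distance_profile <- function(traj, window = "last_third",
                                     state = "unspecified") {
  stopifnot(inherits(traj, "trajectory"))
  window <- resolve_window(traj, window)
  idx <- calpha_index(traj)
  if (length(idx) == 0L) stop("no C-alpha atoms in trajectory",
                              call. = FALSE)
  prot <- select_atoms(traj, "protein")
  mp <- traj$atoms$mass[prot]
  dsum <- numeric(length(idx))
  for (f in window) {
    co <- frame_coords(traj, f)
    com <- mass_com(co[prot, , drop = FALSE], mp)
    dsum <- dsum + sqrt(rowSums(sweep(co[idx, , drop = FALSE], 2L, com)^2))
  }
  out <- data.frame(residue = traj$atoms$residue_index[idx],
                    d = dsum / length(window))
  attr(out, "state") <- state
  attr(out, "window") <- window
  class(out) <- c("residue_distance_profile", "data.frame")
  out
}

#' Per-residue bound-minus-free distance shift
#'
#' The conformational-shift profile `delta_d = d(n, bound) - d(n, free)`,
#' where `d(n, state)` is a residue's mean C-alpha distance to the protein
#' centre of mass in that state ([residue_distance_profile()]). A positive
#' value means the residue moved further from the protein centre upon
#' ligand binding, a negative one that it moved closer; shifts whose
#' magnitude exceeds the threshold (default 2 Angstrom, strict) are
#' classified `"further"`/`"closer"`, the rest `"unchanged"`.
#'
#' @param bound,free [residue_distance_profile()] objects covering the same
#'   residue set.
#' @param threshold Significance threshold in Angstrom (default 2.0).
#' @return A data.frame of class `delta_d_profile` with columns `residue`,
#'   `d_bound`, `d_free`, `delta_d`, `class`.
#' @export
delta_d_profile <- function(bound, free, threshold = 2.0) {
  stopifnot(inherits(bound, "residue_distance_profile"),
            inherits(free, "residue_distance_profile"))
  if (!setequal(bound$residue, free$residue)) {
    only_b <- setdiff(bound$residue, free$residue)
    only_f <- setdiff(free$residue, bound$residue)
    stop("residue sets differ; only in bound: ",
         paste(only_b, collapse = ", "), "; only in free: ",
         paste(only_f, collapse = ", "), call. = FALSE)
  }
  if (!is.numeric(threshold) || threshold < 0) {
    stop("threshold must be a non-negative number of Angstrom",
         call. = FALSE)
  }
  free <- free[match(bound$residue, free$residue), , drop = FALSE]
  delta <- bound$d - free$d
  cls <- ifelse(delta > threshold, "further",
                ifelse(delta < -threshold, "closer", "unchanged"))
  out <- data.frame(residue = bound$residue,
                    d_bound = bound$d,
                    d_free = free$d,
                    delta_d = delta,
                    class = cls,
                    stringsAsFactors = FALSE)
  attr(out, "threshold") <- threshold
  class(out) <- c("delta_d_profile", "data.frame")
  out
}
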