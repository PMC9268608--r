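element_masses <- function() {
  c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
    P = 30.974, F = 18.998, CL = 35.45, BR = 79.904, I = 126.904,
    ZN = 65.38, MG = 24.305, `NA` = 22.990, K = 39.098, CA = 40.078,
    FE = 55.845)
}

element_mass <- function(element) {
  masses <- element_masses()
  key <- toupper(trimws(element))
  m <- masses[key]
  if (anyNA(m)) {
    warning("unknown element(s) ",
            paste(unique(key[is.na(m)]), collapse = ", "),
            "; using 12.011 Da", call. = FALSE)
    m[is.na(m)] <- 12.011
  }
  unname(m)
}

#' Construct a trajectory
#'
#' A trajectory holds an ordered set of coordinate frames (Angstrom) over a
#' fixed atom list. Atom metadata carries a 1-based residue index, residue
#' name, atom name, mass (Da) and a ligand flag; protein/ligand selections
#' and mass-weighted centres of mass are derived from it.
#'
#' @param coords Numeric array `n_atoms x 3 x n_frames`, or a list of
#'   `n_atoms x 3` matrices (one per frame).
#' @param atoms data.frame with columns `residue_index`, `residue_name`,
#'   `atom_name`, `mass`, `is_ligand` (one row per atom, frame order).
#' @param time_step Time between consecutive frames, in ns.
#' @return A `trajectory` object.
#' @export
trajectory <- function(coords, atoms, time_step = 1) {
  if (is.list(coords) && !is.array(coords)) {
    nat <- unique(vapply(coords, nrow, integer(1)))
    if (length(nat) != 1L) {
      stop("all frames must have the same atom count", call. = FALSE)
    }
    coords <- array(unlist(coords), dim = c(nat, 3L, length(coords)))
  }
  if (!is.array(coords) || length(dim(coords)) != 3L || dim(coords)[2L] != 3L) {
    stop("coords must be an n_atoms x 3 x n_frames array", call. = FALSE)
  }
  if (dim(coords)[3L] < 1L) stop("trajectory needs >= 1 frame", call. = FALSE)
  if (anyNA(coords) || any(!is.finite(coords))) {
    stop("coordinates must be finite", call. = FALSE)
  }
  need <- c("residue_index", "residue_name", "atom_name", "mass", "is_ligand")
  missing <- setdiff(need, names(atoms))
  if (length(missing) > 0L) {
    stop("atom table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(atoms) != dim(coords)[1L]) {
    stop("atom table and coordinate array disagree on atom count",
         call. = FALSE)
  }
  if (!is.numeric(time_step) || time_step <= 0) {
    stop("time_step must be a positive number of ns", call. = FALSE)
  }
  structure(list(coords = coords, atoms = as.data.frame(atoms),
                 time_step = time_step),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d atoms (%d ligand), %d frames, %.4g ns/frame\n",
              n_atoms(x), sum(x$atoms$is_ligand), n_frames(x), x$time_step))
  invisible(x)
}

#' Trajectory dimensions and frame access
#'
#' @param traj A [trajectory()].
#' @param i Frame index.
#' @return `n_frames()`/`n_atoms()` return counts; `frame_coords()` the
#'   `n_atoms x 3` coordinate matrix of frame `i`.
#' @export
n_frames <- function(traj) dim(traj$coords)[3L]

#' @rdname n_frames
#' @export
n_atoms <- function(traj) dim(traj$coords)[1L]

#' @rdname n_frames
#' @export
frame_coords <- function(traj, i) traj$coords[, , i, drop = FALSE][, , 1L]

# Logical atom selection: "calpha" = protein C-alpha atoms, "protein",
# "ligand", or "all".
select_atoms <- function(traj, selection = c("calpha", "protein",
                                             "ligand", "all")) {
  selection <- match.arg(selection)
  a <- traj$atoms
  switch(selection,
         calpha = a$atom_name == "CA" & !a$is_ligand,
         protein = !a$is_ligand,
         ligand = a$is_ligand,
         all = rep(TRUE, nrow(a)))
}

#' Read a trajectory from multi-model PDB or XYZ
#'
#' Multi-model PDB files (frames delimited by `MODEL`/`ENDMDL`) are parsed
#' with `bio3d::read.pdb(multi = TRUE)`; plain xmol XYZ files (atom count,
#' comment line, then `element x y z` records per frame) with a built-in
#' reader. Atoms whose residue name (PDB) or element symbol (XYZ) equals
#' `ligand_selector` are flagged as ligand atoms. Masses come from a
#' standard element table, falling back to 12.011 Da with a warning for
#' unknown elements.
#'
#' @param path Input file.
#' @param format `"auto"` (by extension), `"pdb"` or `"xyz"`.
#' @param ligand_selector Residue name (PDB) or element symbol (XYZ)
#'   identifying ligand atoms. Default `"LIG"`.
#' @param time_step ns per frame (file formats do not carry it).
#' @return A [trajectory()].
#' @export
read_trajectory <- function(path, format = c("auto", "pdb", "xyz"),
                            ligand_selector = "LIG", time_step = 1) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.xyz$", path, ignore.case = TRUE)) "xyz" else "pdb"
  }
  if (format == "pdb") {
    read_trajectory_pdb(path, ligand_selector, time_step)
  } else {
    read_trajectory_xyz(path, ligand_selector, time_step)
  }
}

read_trajectory_pdb <- function(path, ligand_selector, time_step) {
  lines <- readLines(path)
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  model_starts <- grep("^MODEL", lines)
  if (length(model_starts) > 0L) {
    # count atom records per MODEL block so a malformed frame is reported
    # by index before handing the file to the parser
    model_ends <- grep("^ENDMDL", lines)
    if (length(model_ends) != length(model_starts)) {
      stop("unbalanced MODEL/ENDMDL records in ", path, call. = FALSE)
    }
    counts <- mapply(function(s, e) sum(is_atom[s:e]), model_starts,
                     model_ends)
    if (length(unique(counts)) != 1L) {
      bad <- which(counts != counts[1L])[1L]
      stop("inconsistent atom count in frame ", bad, " of ", path,
           " (", counts[bad], " vs ", counts[1L], ")", call. = FALSE)
    }
  }
  if (!any(is_atom)) stop("no atom records (zero frames) in ", path,
                          call. = FALSE)
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  xyz <- pdb$xyz                       # frames x 3*n_atoms
  nat <- ncol(xyz) / 3L
  nf <- nrow(xyz)
  coords <- array(NA_real_, dim = c(nat, 3L, nf))
  for (f in seq_len(nf)) {
    coords[, , f] <- matrix(xyz[f, ], ncol = 3L, byrow = TRUE)
  }
  at <- pdb$atom
  element <- at$elesy
  if (is.null(element) || all(!nzchar(trimws(element)))) {
    element <- substr(trimws(at$elety), 1L, 1L)
  }
  element <- ifelse(nzchar(trimws(element)), trimws(element),
                    substr(trimws(at$elety), 1L, 1L))
  atoms <- data.frame(residue_index = as.integer(at$resno),
                      residue_name = trimws(at$resid),
                      atom_name = trimws(at$elety),
                      mass = element_mass(element),
                      is_ligand = trimws(at$resid) == ligand_selector,
                      stringsAsFactors = FALSE)
  trajectory(coords, atoms, time_step = time_step)
}

read_trajectory_xyz <- function(path, ligand_selector, time_step) {
  lines <- readLines(path)
  lines <- lines[seq_len(max(which(nzchar(trimws(lines))), 0L))]
  if (length(lines) == 0L) stop("zero frames in ", path, call. = FALSE)
  frames <- list()
  atoms0 <- NULL
  pos <- 1L
  f <- 0L
  while (pos <= length(lines)) {
    nat <- suppressWarnings(as.integer(trimws(lines[pos])))
    f <- f + 1L
    if (is.na(nat) || nat < 1L || pos + 1L + nat > length(lines)) {
      stop("malformed XYZ frame ", f, " in ", path, call. = FALSE)
    }
    block <- lines[(pos + 2L):(pos + 1L + nat)]
    toks <- strsplit(trimws(block), "[[:space:]]+")
    if (any(vapply(toks, length, integer(1)) < 4L)) {
      stop("malformed XYZ frame ", f, " in ", path, call. = FALSE)
    }
    el <- vapply(toks, `[`, character(1), 1L)
    co <- matrix(as.numeric(unlist(lapply(toks, `[`, 2:4))),
                 ncol = 3L, byrow = TRUE)
    if (is.null(atoms0)) {
      atoms0 <- data.frame(residue_index = seq_len(nat),
                           residue_name = el,
                           atom_name = el,
                           mass = element_mass(el),
                           is_ligand = el == ligand_selector,
                           stringsAsFactors = FALSE)
    } else if (nat != nrow(atoms0)) {
      stop("inconsistent atom count in frame ", f, " of ", path,
           " (", nat, " vs ", nrow(atoms0), ")", call. = FALSE)
    }
    frames[[f]] <- co
    pos <- pos + 2L + nat
  }
  trajectory(frames, atoms0, time_step = time_step)
}

#' Write a trajectory
#'
#' Writes a multi-model PDB (one `MODEL`/`ENDMDL` block per frame; ligand
#' atoms as `HETATM`) or an xmol XYZ file (element taken from the first
#' character of the atom name). Round-trips through [read_trajectory()].
#'
#' @param traj A [trajectory()].
#' @param path Output file.
#' @param format `"pdb"` (default) or `"xyz"`.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, format = c("pdb", "xyz")) {
  stopifnot(inherits(traj, "trajectory"))
  format <- match.arg(format)
  a <- traj$atoms
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "pdb") {
    rec <- ifelse(a$is_ligand, "HETATM", "ATOM  ")
    name4 <- ifelse(nchar(a$atom_name) < 4L,
                    sprintf(" %-3s", a$atom_name), a$atom_name)
    for (f in seq_len(n_frames(traj))) {
      co <- frame_coords(traj, f)
      writeLines(sprintf("MODEL     %4d", f), con)
      writeLines(sprintf(
        "%s%5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        rec, seq_len(nrow(a)), name4, substr(a$residue_name, 1L, 3L), "A",
        a$residue_index, co[, 1L], co[, 2L], co[, 3L], 1, 0,
        toupper(substr(a$atom_name, 1L, 1L))), con)
      writeLines("ENDMDL", con)
    }
    writeLines("END", con)
  } else {
    el <- toupper(substr(a$atom_name, 1L, 1L))
    for (f in seq_len(n_frames(traj))) {
      co <- frame_coords(traj, f)
      writeLines(as.character(nrow(a)), con)
      writeLines(sprintf("frame %d", f), con)
      writeLines(sprintf("%-2s %12.6f %12.6f %12.6f", el,
                         co[, 1L], co[, 2L], co[, 3L]), con)
    }
  }
  invisible(path)
}
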