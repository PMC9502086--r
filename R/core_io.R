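# Trajectory container and multi-model PDB interchange.
#
# Coordinates are stored in nanometres (distance cutoffs in this field are
# quoted in nm) and times in picoseconds. The on-disk interchange format is
# multi-model PDB: one MODEL block per frame, Angstrom units.

#' Construct a trajectory object
#'
#' A trajectory is an ordered set of frames sharing one atom table. The atom
#' table is a data frame with columns `serial`, `name`, `resname`, `resno`,
#' `chain` and `element`; coordinates are held as an `n_frames x 3*n_atoms`
#' matrix in nm (bio3d xyz layout: x1, y1, z1, x2, ...).
#'
#' @param atoms Atom table (see above). `(chain, resno, name)` must be unique.
#' @param xyz Numeric matrix, `n_frames` rows, `3 * nrow(atoms)` columns, nm.
#' @param times Frame times in ps, strictly increasing. Default
#'   `(0:(n-1)) * frame_spacing`.
#' @param frame_spacing Frame spacing in ps (used when `times` is omitted).
#' @return An object of class `"trajectory"`.
#' @export
trajectory <- function(atoms, xyz, times = NULL, frame_spacing = 10) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  need <- c("name", "resname", "resno", "chain")
  missing_cols <- setdiff(need, names(atoms))
  if (length(missing_cols))
    stop("atom table lacks columns: ", paste(missing_cols, collapse = ", "))
  if (is.null(atoms$serial)) atoms$serial <- seq_len(nrow(atoms))
  if (is.null(atoms$element)) atoms$element <- .element_of(atoms$name)
  if (any(!nzchar(atoms$name))) stop("atom names must be non-empty")
  if (any(atoms$resno < 1)) stop("residue numbers must be >= 1")
  key <- paste(atoms$chain, atoms$resno, atoms$name)
  if (anyDuplicated(key))
    stop("duplicate (chain, resno, name) atom identity: ",
         key[duplicated(key)][1])
  xyz <- rbind(xyz)
  if (nrow(xyz) < 1L) stop("a trajectory needs at least one frame")
  if (ncol(xyz) != 3L * nrow(atoms))
    stop("coordinate count (", ncol(xyz), ") does not match atom count (",
         nrow(atoms), " atoms)")
  if (is.null(times)) times <- (seq_len(nrow(xyz)) - 1) * frame_spacing
  if (length(times) != nrow(xyz) || any(diff(times) <= 0) || any(times < 0))
    stop("frame times must be non-negative and strictly increasing")
  structure(list(atoms = atoms, xyz = xyz, times = as.numeric(times),
                 frame_spacing = frame_spacing),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("trajectory: ", n_frames(x), " frame(s), ", n_atoms(x), " atoms, ",
      length(unique(x$atoms$resno)), " residues, span ",
      x$times[1], "-", x$times[n_frames(x)], " ps\n", sep = "")
  invisible(x)
}

#' Number of frames / atoms in a trajectory
#' @param traj A trajectory.
#' @return Integer count.
#' @export
n_frames <- function(traj) nrow(traj$xyz)

#' @rdname n_frames
#' @export
n_atoms <- function(traj) nrow(traj$atoms)

#' Coordinates of one frame
#'
#' @param traj A trajectory.
#' @param i Frame index (1-based).
#' @param atoms Optional integer atom indices to extract.
#' @return `length(atoms) x 3` matrix, nm.
#' @export
frame_coords <- function(traj, i, atoms = NULL) {
  if (i < 1 || i > n_frames(traj)) stop("frame index out of range: ", i)
  m <- matrix(traj$xyz[i, ], ncol = 3L, byrow = TRUE)
  if (!is.null(atoms)) m <- m[atoms, , drop = FALSE]
  m
}

# ---- multi-model PDB ------------------------------------------------------

.validate_pdb_lines <- function(lines) {
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(is_atom)) stop("no ATOM records found")
  at <- which(is_atom)
  for (fld in list(c(31, 38), c(39, 46), c(47, 54))) {
    txt <- substr(lines[at], fld[1], fld[2])
    bad <- is.na(suppressWarnings(as.numeric(txt))) | !nzchar(trimws(txt))
    if (any(bad))
      stop("malformed ATOM record at line ", at[which(bad)[1]],
           ": unreadable coordinate field")
  }
  resno <- suppressWarnings(as.integer(substr(lines[at], 23, 26)))
  if (anyNA(resno))
    stop("malformed ATOM record at line ", at[which(is.na(resno))[1]],
         ": unreadable residue number")
  # per-model atom counts must agree
  model_starts <- grepl("^MODEL", lines)
  if (any(model_starts)) {
    blk <- cumsum(model_starts)[is_atom]
    counts <- table(blk)
    if (length(unique(as.integer(counts))) > 1L)
      stop("inconsistent atom count across MODEL blocks: ",
           paste(as.integer(counts), collapse = ", "))
  }
  invisible(TRUE)
}

#' Read a multi-model PDB file as a trajectory
#'
#' Each MODEL block becomes one frame (a bare ATOM block gives a single
#' frame). Coordinates are converted from Angstrom to nm. The atom table is
#' taken from the first model; all models must contain the same number of
#' atoms.
#'
#' @param path PDB file path.
#' @param frame_spacing Time between frames, ps (default 10, the
#'   conventional save interval for the trajectories this package analyses).
#' @return A [trajectory].
#' @export
read_multimodel_pdb <- function(path, frame_spacing = 10) {
  if (!file.exists(path)) stop("file not found: ", path)
  .validate_pdb_lines(readLines(path))
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  atoms <- data.frame(
    serial  = pdb$atom$eleno,
    name    = pdb$atom$elety,
    resname = pdb$atom$resid,
    resno   = pdb$atom$resno,
    chain   = ifelse(is.na(pdb$atom$chain), "A", pdb$atom$chain),
    element = .element_of(pdb$atom$elety),
    stringsAsFactors = FALSE)
  xyz <- rbind(pdb$xyz) / 10  # Angstrom -> nm
  trajectory(atoms, xyz, frame_spacing = frame_spacing)
}

#' Write a trajectory as a multi-model PDB file
#'
#' Inverse of [read_multimodel_pdb()]; coordinates are converted nm ->
#' Angstrom and written at standard PDB precision (0.001 Angstrom).
#'
#' @param traj A [trajectory].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_multimodel_pdb <- function(traj, path) {
  bio3d::write.pdb(file = path, xyz = traj$xyz * 10,
                   resno = traj$atoms$resno, resid = traj$atoms$resname,
                   eleno = traj$atoms$serial, elety = traj$atoms$name,
                   chain = traj$atoms$chain)
  invisible(path)
}

# ---- atom selection -------------------------------------------------------

#' Select atoms with a small expression language
#'
#' Clauses are joined with `and`; each clause is a keyword followed by one or
#' more values. Keywords: `resid`/`resno` (residue numbers, ranges as `30-40`),
#' `resname`, `name`/`elety` (atom names), `chain`, `element`. Example:
#' `"resid 236 and name CZ"`, `"resid 30 and name NE NH1 NH2"`.
#'
#' Resolution is a pure function of the atom table and the expression; atom
#' order follows the atom table.
#'
#' @param traj A [trajectory].
#' @param expr Selection expression.
#' @return Object of class `"selection"`: list with `expression` and `atoms`
#'   (integer indices into the atom table).
#' @export
select_atoms <- function(traj, expr) {
  atoms <- traj$atoms
  clauses <- strsplit(trimws(expr), "\\s+and\\s+")[[1]]
  if (!length(clauses) || any(!nzchar(clauses)))
    stop("empty selection expression")
  keep <- rep(TRUE, nrow(atoms))
  for (cl in clauses) {
    tok <- strsplit(trimws(cl), "\\s+")[[1]]
    kw <- tolower(tok[1])
    vals <- tok[-1]
    if (!length(vals)) stop("selection clause without values: '", cl, "'")
    keep <- keep & switch(kw,
      resid = , resno = atoms$resno %in% .expand_ranges(vals),
      resname = toupper(atoms$resname) %in% toupper(vals),
      name = , elety = atoms$name %in% vals,
      chain = atoms$chain %in% vals,
      element = toupper(atoms$element) %in% toupper(vals),
      stop("unknown selection keyword: '", kw, "'"))
  }
  idx <- which(keep)
  if (!length(idx)) stop("selection resolved to zero atoms: '", expr, "'")
  structure(list(expression = expr, atoms = idx), class = "selection")
}

.expand_ranges <- function(vals) {
  unlist(lapply(vals, function(v) {
    if (grepl("^[0-9]+[-:][0-9]+$", v)) {
      ab <- as.integer(strsplit(v, "[-:]")[[1]])
      seq(ab[1], ab[2])
    } else {
      n <- suppressWarnings(as.integer(v))
      if (is.na(n)) stop("bad residue number in selection: '", v, "'")
      n
    }
  }))
}

#' @export
print.selection <- function(x, ...) {
  cat("selection '", x$expression, "': ", length(x$atoms), " atom(s)\n",
      sep = "")
  invisible(x)
}

# ---- interaction labels ---------------------------------------------------

#' Format a residue-pair interaction label
#'
#' Labels follow the convention used in occupancy tables for this carrier:
#' one-letter residue code and number, with an atom-context suffix for
#' backbone atoms — `"(O)"` for the backbone carbonyl oxygen, `"(NH)"` for
#' the backbone amide — and no suffix for side-chain contacts. E.g.
#' `"V37(O):A40(NH)"`, `"R30:A141(O)"`, `"R236:E264"`.
#'
#' @param resname_a,resname_b Residue codes (1- or 3-letter).
#' @param resno_a,resno_b Residue numbers.
#' @param context_a,context_b `"sidechain"`, `"O"` or `"NH"`.
#' @return Label string.
#' @export
format_interaction_label <- function(resname_a, resno_a, context_a,
                                     resname_b, resno_b, context_b) {
  sfx <- function(ctx) switch(match.arg(ctx, c("sidechain", "O", "NH")),
                              sidechain = "", O = "(O)", NH = "(NH)")
  paste0(.aa_one(resname_a), resno_a, sfx(context_a), ":",
         .aa_one(resname_b), resno_b, sfx(context_b))
}
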