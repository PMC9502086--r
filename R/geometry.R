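# Geometry metrics: side-chain orientation angle series, per-residue RMSF
# after least-squares superposition, and minimum-distance time series.

#' Angle specification (three atoms, vertex at B)
#'
#' The default reproduces the side-chain orientation metric for the capping
#' arginine of domain 3: the angle at R236-Calpha between R236-Czeta and
#' T232-Calpha.
#'
#' @param a,b,c Selection expressions (see [select_atoms()]), each resolving
#'   to exactly one atom; `b` is the vertex.
#' @return Object of class `"angle_spec"`.
#' @export
angle_spec <- function(a = "resid 236 and name CZ",
                       b = "resid 236 and name CA",
                       c = "resid 232 and name CA") {
  if (length(unique(c(a, b, c))) != 3L)
    stop("an angle needs three distinct atoms")
  structure(list(a = a, b = b, c = c), class = "angle_spec")
}

.single_atom <- function(traj, expr) {
  sel <- select_atoms(traj, expr)
  if (length(sel$atoms) != 1L)
    stop("angle atom '", expr, "' resolves to ", length(sel$atoms),
         " atoms (need exactly 1)")
  sel$atoms
}

#' Angle time series
#'
#' Per frame, the angle (degrees, in `[0, 180]`) at the vertex atom between
#' the rays to the two flanking atoms.
#'
#' @param traj A [trajectory].
#' @param spec An [angle_spec()].
#' @return Data frame: `time_ps`, `value` (degrees); attribute
#'   `metric = "angle"`.
#' @export
angle_series <- function(traj, spec = angle_spec()) {
  ia <- .single_atom(traj, spec$a)
  ib <- .single_atom(traj, spec$b)
  ic <- .single_atom(traj, spec$c)
  col3 <- function(i) traj$xyz[, (i - 1L) * 3L + 1:3, drop = FALSE]
  u <- col3(ia) - col3(ib)
  v <- col3(ic) - col3(ib)
  cosang <- rowSums(u * v) /
    (sqrt(rowSums(u^2)) * sqrt(rowSums(v^2)))
  cosang <- pmin(1, pmax(-1, cosang))
  out <- data.frame(time_ps = traj$times, value = acos(cosang) * 180 / pi)
  attr(out, "metric") <- "angle"
  out
}

#' Per-residue RMSF after least-squares superposition
#'
#' Each frame is superposed onto the reference (optimal rotation and
#' translation over the fit selection's atoms), then
#' `RMSF_i = sqrt(mean_t ||x_i(t) - xbar_i||^2)` is computed per selected
#' residue's Calpha. Rigid-body motion therefore contributes nothing.
#'
#' @param traj A [trajectory] with at least 2 frames.
#' @param selection Selection expression for the reported atoms (default all
#'   Calpha).
#' @param reference `"first"` (default) or `"mean"`: superposition target.
#' @param fit Superpose before measuring (default TRUE).
#' @param fit_selection Selection expression for the fitting group (default:
#'   same as `selection`).
#' @return Data frame: `resno`, `resname`, `rmsf` (nm).
#' @export
rmsf <- function(traj, selection = "name CA",
                 reference = c("first", "mean"), fit = TRUE,
                 fit_selection = selection) {
  reference <- match.arg(reference)
  if (n_frames(traj) < 2L) stop("RMSF needs at least 2 frames")
  sel <- select_atoms(traj, selection)
  xyz <- traj$xyz
  if (fit) {
    fit_idx <- select_atoms(traj, fit_selection)$atoms
    cols <- as.vector(t(outer(fit_idx, 1:3, function(i, k) (i - 1L) * 3L + k)))
    fixed <- if (reference == "first") xyz[1, ] else colMeans(xyz)
    xyz <- bio3d::fit.xyz(fixed = fixed, mobile = xyz,
                          fixed.inds = cols, mobile.inds = cols)
  }
  out <- data.frame(resno = traj$atoms$resno[sel$atoms],
                    resname = traj$atoms$resname[sel$atoms],
                    rmsf = NA_real_)
  for (k in seq_along(sel$atoms)) {
    i <- sel$atoms[k]
    m <- xyz[, (i - 1L) * 3L + 1:3, drop = FALSE]
    mu <- colMeans(m)
    out$rmsf[k] <- sqrt(mean((m[, 1] - mu[1])^2 + (m[, 2] - mu[2])^2 +
                               (m[, 3] - mu[3])^2))
  }
  out
}

#' Minimum-distance time series between two residues
#'
#' @param traj A [trajectory].
#' @param res_a,res_b Residue numbers.
#' @param scope `"heavy"` (all heavy atoms) or `"sidechain"` (side-chain
#'   heavy atoms only).
#' @return Data frame: `time_ps`, `value` (nm); attribute
#'   `metric = "min_distance"`.
#' @export
distance_series <- function(traj, res_a, res_b,
                            scope = c("heavy", "sidechain")) {
  scope <- match.arg(scope)
  pick <- function(resno) {
    idx <- which(traj$atoms$resno == resno)
    if (!length(idx)) stop("residue ", resno, " not present in trajectory")
    idx <- idx[!.element_of(traj$atoms$name[idx]) %in% "H"]
    if (scope == "sidechain")
      idx <- idx[!traj$atoms$name[idx] %in% c("N", "CA", "C", "O")]
    if (!length(idx)) stop("residue ", resno, " has no atoms in scope ", scope)
    idx
  }
  out <- data.frame(time_ps = traj$times,
                    value = .pair_min_series(traj, pick(res_a), pick(res_b)))
  attr(out, "metric") <- "min_distance"
  out
}

#' Write a series as two-column TSV
#'
#' @param series Data frame with `time_ps` and `value`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_series <- function(series, path) {
  utils::write.table(series[, c("time_ps", "value")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
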