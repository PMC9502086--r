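# Polar contact enumeration, windowed occupancies, and the interaction
# taxonomy (intra-loop / loop-matrix-helix / inter-domain).
#
# A contact is counted when the minimum distance over the two atom sets is
# <= the cutoff (0.33 nm by default, inclusive). Occupancy is the percentage
# of analysed frames in contact, computed over a trailing window; retained
# interactions are those with average occupancy strictly above the
# threshold (25% by default, "higher than" being strict).

#' Minimum distance between two atom sets
#'
#' @param a,b Numeric matrices (`n x 3`) of coordinates in nm.
#' @return Minimum Euclidean distance over the Cartesian product, nm.
#' @export
min_distance <- function(a, b) {
  a <- rbind(a); b <- rbind(b)
  if (!nrow(a) || !nrow(b)) stop("empty atom set in min_distance")
  best <- Inf
  for (i in seq_len(nrow(a))) {
    d2 <- (b[, 1] - a[i, 1])^2 + (b[, 2] - a[i, 2])^2 + (b[, 3] - a[i, 3])^2
    best <- min(best, min(d2))
  }
  sqrt(best)
}

# atom indices of a residue's named atoms (error if any is absent)
.atom_indices <- function(traj, resno, atom_names) {
  idx <- which(traj$atoms$resno == resno & traj$atoms$name %in% atom_names)
  if (!length(idx))
    stop("no atoms ", paste(atom_names, collapse = "/"),
         " found for residue ", resno)
  idx
}

# per-frame minimum distance between two atom-index sets, vectorised over
# frames (loops over the small set product only)
.pair_min_series <- function(traj, idx_a, idx_b, frames = NULL) {
  if (is.null(frames)) frames <- seq_len(n_frames(traj))
  xyz <- traj$xyz
  best <- rep(Inf, length(frames))
  for (i in idx_a) {
    ca <- (i - 1L) * 3L
    for (j in idx_b) {
      cb <- (j - 1L) * 3L
      d2 <- (xyz[frames, cb + 1] - xyz[frames, ca + 1])^2 +
            (xyz[frames, cb + 2] - xyz[frames, ca + 2])^2 +
            (xyz[frames, cb + 3] - xyz[frames, ca + 3])^2
      best <- pmin(best, d2)
    }
  }
  sqrt(best)
}

#' Trailing analysis window
#'
#' The production analyses this package mirrors use the trailing 2 us
#' (2,000,000 ps) of each trajectory; short desk-scale fixtures degrade to a
#' trailing fraction.
#'
#' @param last_ps Trailing window length in ps, or `NULL`.
#' @param fraction Trailing fraction of frames in (0, 1], or `NULL`.
#' @return Object of class `"trailing_window"`.
#' @export
trailing_window <- function(last_ps = NULL, fraction = NULL) {
  if (!is.null(fraction) && (fraction <= 0 || fraction > 1))
    stop("window fraction must be in (0, 1]")
  structure(list(last_ps = last_ps, fraction = fraction),
            class = "trailing_window")
}

# resolve a window spec to frame indices
.window_frames <- function(traj, window) {
  nf <- n_frames(traj)
  if (is.null(window)) return(seq_len(nf))
  if (!inherits(window, "trailing_window"))
    stop("window must be NULL or a trailing_window()")
  if (!is.null(window$last_ps)) {
    t_end <- traj$times[nf]
    keep <- which(traj$times > t_end - window$last_ps)
    if (length(keep)) return(keep)
    stop("window selects no frames")
  }
  if (!is.null(window$fraction)) {
    n <- max(1L, floor(nf * window$fraction))
    return(seq(nf - n + 1L, nf))
  }
  seq_len(nf)
}

#' Default analysis window: trailing 2 us, or trailing 2/3 when shorter
#'
#' @param traj Trajectory the window will be applied to.
#' @return A [trailing_window()]; the fallback substitution is messaged.
#' @export
default_window <- function(traj) {
  span <- traj$times[n_frames(traj)] - traj$times[1]
  if (span >= 2e6) return(trailing_window(last_ps = 2e6))
  message("trajectory span ", span,
          " ps < 2,000,000 ps; using trailing 2/3 of frames instead")
  trailing_window(fraction = 2 / 3)
}

#' Occupancy of one residue-pair contact
#'
#' @param traj A [trajectory].
#' @param spec A contact-pair spec: one row of an [enumerate_pairs()] result,
#'   or a list with `resno_a`, `atoms_a`, `resno_b`, `atoms_b`.
#' @param cutoff Contact cutoff in nm (inclusive). Default 0.33.
#' @param window `NULL` (all frames) or a [trailing_window()].
#' @return Percentage of window frames in contact, in `[0, 100]`.
#' @export
occupancy <- function(traj, spec, cutoff = 0.33, window = NULL) {
  spec <- .as_pair_spec(spec)
  frames <- .window_frames(traj, window)
  if (!length(frames)) stop("empty analysis window")
  d <- .pair_min_series(traj,
                        .atom_indices(traj, spec$resno_a, spec$atoms_a),
                        .atom_indices(traj, spec$resno_b, spec$atoms_b),
                        frames)
  100 * sum(d <= cutoff) / length(d)
}

.as_pair_spec <- function(spec) {
  if (is.data.frame(spec)) {
    stopifnot(nrow(spec) == 1L)
    spec <- list(resno_a = spec$resno_a, atoms_a = spec$atoms_a[[1]],
                 resno_b = spec$resno_b, atoms_b = spec$atoms_b[[1]],
                 label = if ("label" %in% names(spec)) spec$label else NULL)
  }
  if (!length(spec$atoms_a) || !length(spec$atoms_b))
    stop("contact-pair spec with empty atom set")
  spec
}

# ---- pair enumeration -----------------------------------------------------

# polar atom contexts of one residue: backbone carbonyl (acceptor), backbone
# amide (donor; absent for proline), side chain (template table)
.residue_contexts <- function(resname, atom_names) {
  ctx <- list()
  if ("O" %in% atom_names)
    ctx$O <- list(atoms = "O", donor = FALSE, acceptor = TRUE)
  if ("N" %in% atom_names && toupper(resname) != "PRO")
    ctx$NH <- list(atoms = "N", donor = TRUE, acceptor = FALSE)
  don <- intersect(sidechain_polar_atoms(resname, "donor"), atom_names)
  acc <- intersect(sidechain_polar_atoms(resname, "acceptor"), atom_names)
  sc <- union(don, acc)
  if (length(sc))
    ctx$sidechain <- list(atoms = sc, donor = length(don) > 0,
                          acceptor = length(acc) > 0)
  ctx
}

.is_salt_bridge <- function(resname_a, atoms_a, resname_b, atoms_b) {
  sb <- function(rn, at, side) {
    set <- side[[toupper(rn)]]
    !is.null(set) && all(at %in% set)
  }
  (sb(resname_a, atoms_a, .saltbridge_basic) &&
     sb(resname_b, atoms_b, .saltbridge_acidic)) ||
  (sb(resname_a, atoms_a, .saltbridge_acidic) &&
     sb(resname_b, atoms_b, .saltbridge_basic))
}

#' Enumerate candidate polar contact pairs
#'
#' All donor/acceptor-bearing residue pairs falling in the screened regions
#' (within one matrix loop, between a loop and its domain's matrix helix, or
#' across a domain-domain interface) whose minimum heavy-atom distance in
#' any frame is within `max_residue_distance`. For each retained residue
#' pair, one spec per donor/acceptor context combination is emitted (backbone
#' carbonyl `O`, backbone amide `NH`, side-chain polar set). Self-pairs and
#' backbone-backbone specs of sequence neighbours (|i - j| <= 1) are
#' excluded.
#'
#' @param traj A [trajectory].
#' @param em An [element_map()].
#' @param max_residue_distance Prefilter distance in nm (default 0.6).
#' @return Data frame of contact-pair specs: `label`, `resno_a`, `resname_a`,
#'   `ctx_a`, `atoms_a` (list), likewise for `b`, `kind`, `category`,
#'   `interface`.
#' @export
enumerate_pairs <- function(traj, em, max_residue_distance = 0.6) {
  res <- unique(traj$atoms[, c("resno", "resname")])
  res <- res[order(res$resno), ]
  n <- nrow(res)
  out <- list()
  if (n < 2L) return(.empty_pair_table())
  heavy_idx <- lapply(res$resno, function(r)
    which(traj$atoms$resno == r & !.element_of(traj$atoms$name) %in% "H"))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      cls <- classify_residue_pair(res$resno[i], res$resno[j], em)
      if (cls$category == "other") next
      dmin <- min(.pair_min_series(traj, heavy_idx[[i]], heavy_idx[[j]]))
      if (dmin > max_residue_distance) next
      ctx_i <- .residue_contexts(res$resname[i],
                                 traj$atoms$name[heavy_idx[[i]]])
      ctx_j <- .residue_contexts(res$resname[j],
                                 traj$atoms$name[heavy_idx[[j]]])
      adjacent <- abs(res$resno[i] - res$resno[j]) <= 1L
      for (ca in names(ctx_i)) for (cb in names(ctx_j)) {
        A <- ctx_i[[ca]]; B <- ctx_j[[cb]]
        if (!((A$donor && B$acceptor) || (A$acceptor && B$donor))) next
        if (adjacent && ca != "sidechain" && cb != "sidechain") next
        kind <- if (.is_salt_bridge(res$resname[i], A$atoms,
                                    res$resname[j], B$atoms))
          "salt-bridge" else "H-bond"
        out[[length(out) + 1L]] <- data.frame(
          label = format_interaction_label(res$resname[i], res$resno[i], ca,
                                           res$resname[j], res$resno[j], cb),
          resno_a = res$resno[i], resname_a = res$resname[i], ctx_a = ca,
          resno_b = res$resno[j], resname_b = res$resname[j], ctx_b = cb,
          kind = kind, category = cls$category, interface = cls$interface,
          stringsAsFactors = FALSE)
        out[[length(out)]]$atoms_a <- list(A$atoms)
        out[[length(out)]]$atoms_b <- list(B$atoms)
      }
    }
  }
  if (!length(out)) return(.empty_pair_table())
  do.call(rbind, out)
}

.empty_pair_table <- function() {
  data.frame(label = character(0), resno_a = integer(0),
             resname_a = character(0), ctx_a = character(0),
             resno_b = integer(0), resname_b = character(0),
             ctx_b = character(0), kind = character(0),
             category = character(0), interface = character(0))
}

#' Classify a residue pair into the screening taxonomy
#'
#' Deterministic total rule: both residues within the same matrix loop gives
#' `intra-loop`; one in a matrix loop and the other in the same domain's
#' matrix helix gives `loop-helix`; residues in different domains give
#' `inter-domain` with interface `1-2`, `2-3` or `3-1`; everything else
#' (including residues not covered by the element map, with a warning) is
#' `other`.
#'
#' @param resno_a,resno_b Residue numbers.
#' @param em An [element_map()].
#' @return List: `category`, `interface` (NA unless inter-domain), `domain`
#'   (NA unless intra-domain).
#' @export
classify_residue_pair <- function(resno_a, resno_b, em) {
  if (resno_a == resno_b)
    return(list(category = "other", interface = NA_character_,
                domain = NA_integer_))
  da <- .domain_of(em, resno_a); db <- .domain_of(em, resno_b)
  if (is.na(da) || is.na(db)) {
    warning("residue ", if (is.na(da)) resno_a else resno_b,
            " not covered by the element map; classified 'other'")
    return(list(category = "other", interface = NA_character_,
                domain = NA_integer_))
  }
  if (da != db) {
    iface <- paste(sort(c(da, db)), collapse = "-")
    if (iface == "1-3") iface <- "3-1"
    return(list(category = "inter-domain", interface = iface,
                domain = NA_integer_))
  }
  ea <- .element_of_residue(em, resno_a)
  eb <- .element_of_residue(em, resno_b)
  is_loop <- function(e) !is.null(e) && grepl("^M", e$element)
  is_helix <- function(e) !is.null(e) && grepl("^h", e$element)
  if (is_loop(ea) && is_loop(eb) && ea$element == eb$element)
    return(list(category = "intra-loop", interface = NA_character_,
                domain = da))
  if ((is_loop(ea) && is_helix(eb)) || (is_helix(ea) && is_loop(eb)))
    return(list(category = "loop-helix", interface = NA_character_,
                domain = da))
  list(category = "other", interface = NA_character_, domain = da)
}

# ---- occupancy tables, filtering, summaries -------------------------------

#' Occupancies of contact-pair specs over one or more trajectories
#'
#' @param trajs A [trajectory] or list of (parallel) trajectories.
#' @param specs Spec table from [enumerate_pairs()].
#' @param cutoff Contact cutoff, nm (inclusive).
#' @param window `NULL`, a [trailing_window()], or `"default"` for the
#'   trailing-2-us rule of [default_window()].
#' @return `specs` with per-trajectory columns `occ_1..occ_k`, `average`
#'   (full precision) and `printed` (integer, round-half-up, the convention
#'   occupancy tables are printed in).
#' @export
occupancy_table <- function(trajs, specs, cutoff = 0.33, window = NULL) {
  if (inherits(trajs, "trajectory")) trajs <- list(trajs)
  occ <- matrix(NA_real_, nrow(specs), length(trajs))
  for (k in seq_along(trajs)) {
    w <- if (identical(window, "default")) default_window(trajs[[k]]) else window
    for (i in seq_len(nrow(specs)))
      occ[i, k] <- occupancy(trajs[[k]], specs[i, ], cutoff, w)
  }
  colnames(occ) <- paste0("occ_", seq_along(trajs))
  res <- cbind(specs, as.data.frame(occ))
  res$average <- rowMeans(occ)
  res$printed <- .round_half_up(res$average)
  res
}

#' Filter occupancies at the retention threshold and attach categories
#'
#' Retains records whose average occupancy is strictly above the threshold
#' ("higher than 25%"), and (re)classifies each retained pair.
#'
#' @param records Data frame with `resno_a`, `resno_b` and either an
#'   `average` column or per-trajectory `occ_*` columns.
#' @param threshold Retention threshold in percent (strict). Default 25.
#' @param em An [element_map()] (used to classify; optional if `records`
#'   already carries `category`/`interface`).
#' @return The retained records with `average`, `category`, `interface`.
#' @export
filter_and_classify <- function(records, threshold = 25, em = NULL) {
  if (!nrow(records)) return(records)
  if (!"average" %in% names(records)) {
    occ_cols <- grep("^occ(_|$)", names(records), value = TRUE)
    if (!length(occ_cols)) stop("records carry no occupancies")
    records$average <- rowMeans(records[, occ_cols, drop = FALSE])
  }
  if (any(records$average < 0 | records$average > 100))
    stop("occupancy outside [0, 100]")
  if (!is.null(em)) {
    cls <- lapply(seq_len(nrow(records)), function(i)
      classify_residue_pair(records$resno_a[i], records$resno_b[i], em))
    records$category <- vapply(cls, `[[`, "", "category")
    records$interface <- vapply(cls, `[[`, NA_character_, "interface")
  }
  if (!"category" %in% names(records))
    stop("no element map given and records carry no category")
  records[records$average > threshold, , drop = FALSE]
}

#' Per-category interaction strength summary
#'
#' Sums and counts of retained average occupancies per taxonomy cell:
#' intra-loop and loop-helix per domain, and the three domain-domain
#' interfaces. Cells with no records report zero. Row order is fixed.
#'
#' @param records Classified records ([filter_and_classify()] output). The
#'   per-domain cells require a `domain` column or an element map to
#'   recover it.
#' @param em Optional [element_map()] to derive the domain of intra-domain
#'   records.
#' @return Data frame: `category`, `unit` (domain or interface id),
#'   `total_occupancy`, `n`.
#' @export
interface_strength <- function(records, em = NULL) {
  cells <- rbind(
    data.frame(category = "intra-loop", unit = c("1", "2", "3")),
    data.frame(category = "loop-helix", unit = c("1", "2", "3")),
    data.frame(category = "inter-domain", unit = c("1-2", "2-3", "3-1")))
  cells$total_occupancy <- 0
  cells$n <- 0L
  if (!nrow(records)) return(cells)
  unit <- rep(NA_character_, nrow(records))
  inter <- records$category == "inter-domain"
  unit[inter] <- records$interface[inter]
  if (any(!inter)) {
    if ("domain" %in% names(records)) {
      unit[!inter] <- as.character(records$domain[!inter])
    } else if (!is.null(em)) {
      unit[!inter] <- vapply(which(!inter), function(i)
        as.character(.domain_of(em, records$resno_a[i])), character(1))
    }
  }
  for (i in seq_len(nrow(records))) {
    k <- which(cells$category == records$category[i] & cells$unit == unit[i])
    if (length(k) == 1L) {
      cells$total_occupancy[k] <- cells$total_occupancy[k] + records$average[i]
      cells$n[k] <- cells$n[k] + 1L
    }
  }
  cells
}

#' Write an occupancy table in the conventional layout
#'
#' Label, per-trajectory occupancies, average (printed as round-half-up
#' integers), kind and category.
#'
#' @param tab [occupancy_table()] (optionally filtered) output.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_occupancy_table <- function(tab, path) {
  occ_cols <- grep("^occ(_|$)", names(tab), value = TRUE)
  out <- data.frame(label = tab$label)
  for (cc in occ_cols) out[[cc]] <- .round_half_up(tab[[cc]])
  out$average <- .round_half_up(tab$average)
  for (cc in intersect(c("kind", "category", "interface"), names(tab)))
    out[[cc]] <- tab[[cc]]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
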