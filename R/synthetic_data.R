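# Synthetic inputs with known ground truth: telegraph-process contact
# trajectories, and tripartite/family sequences with planted MCF motifs.
#
# The contact model is a two-state Markov (telegraph) process per residue
# pair, with stationary bound probability p and lag-1 autocorrelation phi;
# phi = 0 recovers i.i.d. frames. Atom positions are real amino-acid
# templates so selection and donor/acceptor logic is exercised unchanged.

#' Telegraph (two-state Markov) state sequence
#'
#' Stationary `P(bound) = p`, lag-1 autocorrelation `phi`
#' (`P(1->1) = p + (1-p) phi`, `P(0->1) = p (1-phi)`); the first state is a
#' stationary draw. The effective sample size of an n-frame run is
#' `n (1-phi) / (1+phi)`.
#'
#' @param n Number of frames.
#' @param p Stationary bound probability in `[0, 1]`.
#' @param phi Lag-1 autocorrelation in `[0, 1)`.
#' @return Integer vector of 0/1 states. Consumes the current RNG stream.
#' @export
telegraph_states <- function(n, p, phi = 0) {
  if (p < 0 || p > 1) stop("p must be in [0, 1]")
  if (phi < 0 || phi >= 1) stop("phi must be in [0, 1)")
  s <- integer(n)
  u <- stats::runif(n)
  s[1] <- as.integer(u[1] < p)
  p11 <- p + (1 - p) * phi
  p01 <- p * (1 - phi)
  for (t in seq_len(n - 1L) + 1L)
    s[t] <- as.integer(u[t] < if (s[t - 1L] == 1L) p11 else p01)
  s
}

#' Contact scenario for the synthetic trajectory generator
#'
#' @param pairs Optional data frame with per-pair columns (`res_a`, `res_b`,
#'   `resno_a`, `resno_b`, `p`, `phi`, `bound`, `unbound`, `sigma`); scalars
#'   below fill in whatever is missing.
#' @param n_pairs Number of residue pairs when `pairs` is not given.
#' @param p Target occupancy (stationary bound probability), per pair.
#' @param phi Telegraph lag-1 autocorrelation, per pair.
#' @param bound,unbound Contact-atom distances in the bound / unbound state,
#'   nm. Defaults 0.25 / 0.45 sit well clear of the 0.33 nm cutoff.
#' @param sigma Isotropic Gaussian positional noise per axis, nm.
#' @param res_a,res_b Residue types (3-letter codes); the default Arg/Glu
#'   pair exercises the salt-bridge atom sets.
#' @param n_frames Frames per trajectory.
#' @param frame_spacing Frame spacing, ps.
#' @param cutoff Contact cutoff the scenario must be separable against.
#' @param seed Mandatory RNG seed.
#' @return Object of class `"contact_scenario"`.
#' @export
contact_scenario <- function(pairs = NULL, n_pairs = 1, p = 0.5, phi = 0,
                             bound = 0.25, unbound = 0.45, sigma = 0.01,
                             res_a = "ARG", res_b = "GLU",
                             n_frames = 1000, frame_spacing = 10,
                             cutoff = 0.33, seed) {
  if (missing(seed)) stop("a seed is mandatory for synthetic scenarios")
  if (is.null(pairs)) pairs <- data.frame(idx = seq_len(n_pairs))
  n <- nrow(pairs)
  fill <- function(col, val) if (is.null(pairs[[col]])) rep_len(val, n) else pairs[[col]]
  pairs <- data.frame(
    res_a = fill("res_a", res_a), res_b = fill("res_b", res_b),
    resno_a = fill("resno_a", 2L * seq_len(n) - 1L),
    resno_b = fill("resno_b", 2L * seq_len(n)),
    p = fill("p", p), phi = fill("phi", phi),
    bound = fill("bound", bound), unbound = fill("unbound", unbound),
    sigma = fill("sigma", sigma), stringsAsFactors = FALSE)
  bad <- pairs$bound + 3 * pairs$sigma >= cutoff |
    pairs$unbound - 3 * pairs$sigma <= cutoff
  if (any(bad))
    stop("scenario not separable: need bound + 3*sigma < cutoff < ",
         "unbound - 3*sigma (pair ", which(bad)[1], ")")
  if (anyDuplicated(c(pairs$resno_a, pairs$resno_b)))
    stop("pair residue numbers must be distinct")
  structure(list(pairs = pairs, n_frames = n_frames,
                 frame_spacing = frame_spacing, cutoff = cutoff,
                 seed = seed),
            class = "contact_scenario")
}

# designated contact atom of a residue type: first salt-bridge atom if
# charged, else first side-chain polar atom, else the backbone carbonyl
.contact_atom <- function(resname) {
  rn <- toupper(resname)
  if (!is.null(.saltbridge_basic[[rn]])) return(.saltbridge_basic[[rn]][1])
  if (!is.null(.saltbridge_acidic[[rn]])) return(.saltbridge_acidic[[rn]][1])
  sc <- sidechain_polar_atoms(rn)
  if (length(sc)) sc[1] else "O"
}

# the atom set used to measure the pair: the side-chain polar set when
# present (salt-bridge sets for charged residues), else backbone O
.interaction_set <- function(resname) {
  rn <- toupper(resname)
  if (!is.null(.saltbridge_basic[[rn]])) return(.saltbridge_basic[[rn]])
  if (!is.null(.saltbridge_acidic[[rn]])) return(.saltbridge_acidic[[rn]])
  sc <- sidechain_polar_atoms(rn)
  if (length(sc)) sc else "O"
}

#' Generate a synthetic contact trajectory
#'
#' Per pair, a telegraph state series sets the distance between the two
#' designated contact atoms to `bound` or `unbound`; every atom coordinate
#' additionally receives i.i.d. Gaussian noise of `sigma` per axis. Pairs
#' are placed 10 nm apart so they cannot touch each other. Fully
#' reproducible from the scenario seed.
#'
#' @param scenario A [contact_scenario()].
#' @return Object of class `"contact_sim"`: list with `trajectory`, and
#'   `truth` (per-frame `states` matrix, `realized_occupancy` percentages,
#'   `specs` — ready-made atom-set specs for [occupancy()] — and the
#'   scenario `pairs`).
#' @export
gen_contact_trajectory <- function(scenario) {
  stopifnot(inherits(scenario, "contact_scenario"))
  pr <- scenario$pairs
  nf <- scenario$n_frames
  withr::with_seed(scenario$seed, {
    states <- sapply(seq_len(nrow(pr)), function(k)
      telegraph_states(nf, pr$p[k], pr$phi[k]))
    states <- matrix(states, nrow = nf)

    atoms <- list(); base <- list()
    for (k in seq_len(nrow(pr))) {
      yk <- 10 * (k - 1)
      for (side in c("a", "b")) {
        rn <- toupper(pr[[paste0("res_", side)]][k])
        resno <- pr[[paste0("resno_", side)]][k]
        nm <- residue_atoms(rn)
        contact <- .contact_atom(rn)
        rest <- setdiff(nm, contact)
        off <- matrix(0, length(nm), 3,
                      dimnames = list(c(contact, rest), NULL))
        l <- seq_along(rest)
        off[rest, 1] <- 0.12 * l
        off[rest, 2] <- 0.03 * (l %% 3)
        off[rest, 3] <- 0.025 * (l %% 2)
        if (side == "a") off[, 1] <- -off[, 1]
        atoms[[length(atoms) + 1L]] <- data.frame(
          name = rownames(off), resname = rn, resno = resno, chain = "A",
          stringsAsFactors = FALSE)
        base[[length(base) + 1L]] <- list(off = off, y = yk, pair = k,
                                          side = side)
      }
    }
    atom_tab <- do.call(rbind, atoms)
    atom_tab$serial <- seq_len(nrow(atom_tab))
    natom <- nrow(atom_tab)
    xyz <- matrix(NA_real_, nf, 3L * natom)
    col0 <- 0L
    for (blk in base) {
      k <- blk$pair
      d <- ifelse(states[, k] == 1L, pr$bound[k], pr$unbound[k])
      shift_x <- if (blk$side == "b") d else rep(0, nf)
      for (j in seq_len(nrow(blk$off))) {
        s <- pr$sigma[k]
        xyz[, col0 + 1L] <- blk$off[j, 1] + shift_x + stats::rnorm(nf, 0, s)
        xyz[, col0 + 2L] <- blk$off[j, 2] + blk$y + stats::rnorm(nf, 0, s)
        xyz[, col0 + 3L] <- blk$off[j, 3] + stats::rnorm(nf, 0, s)
        col0 <- col0 + 3L
      }
    }
    traj <- trajectory(atom_tab, xyz, frame_spacing = scenario$frame_spacing)
    specs <- data.frame(
      resno_a = pr$resno_a, resname_a = pr$res_a,
      resno_b = pr$resno_b, resname_b = pr$res_b,
      label = mapply(format_interaction_label,
                     pr$res_a, pr$resno_a, "sidechain",
                     pr$res_b, pr$resno_b, "sidechain"),
      stringsAsFactors = FALSE)
    specs$atoms_a <- lapply(pr$res_a, .interaction_set)
    specs$atoms_b <- lapply(pr$res_b, .interaction_set)
    structure(list(
      trajectory = traj,
      truth = list(states = states,
                   realized_occupancy = 100 * colMeans(states),
                   specs = specs, pairs = pr),
      scenario = scenario), class = "contact_sim")
  })
}

# ---- sequence generation --------------------------------------------------

.FILLER <- c("L", "I", "V", "A", "T", "S", "M")

#' Sequence scenario for the tripartite generator
#'
#' Default within-domain layout (1-based offsets): the 12-residue
#' `Px[DE]xx[KR]xRxQxQ` block at 1, `[YF]xG` at 24 with `DCxx[RK]` at 29
#' (together matching `[YF]xGxxDCxx[RK]`), and the `[DE]G` pair at 38
#' followed by `[YWF][KR]G` at 44 (together matching
#' `[DE]Gxxxx[YWF][KR]G`). Filler residues are drawn from a small
#' hydrophobic/polar alphabet that cannot spawn spurious motif hits.
#'
#' @param domain_len Residues per domain (default 100, the approximate
#'   repeat length of the carrier fold).
#' @param deg_letters Length-3 character: the `[DE]G` first residue planted
#'   in each domain (default `c("D", "D", "E")`, the wild-type carrier
#'   arrangement).
#' @param offsets Named integer offsets of the planted motifs within each
#'   domain: `px`, `yxg`, `dcxxrk`, `deg`, `ywfkrg`.
#' @param indels Optional data frame (`domain`, `after`, `len`): insert
#'   `len` filler residues after within-domain position `after` of one
#'   domain (gap columns in the other two rows).
#' @param seed Mandatory RNG seed.
#' @return Object of class `"sequence_scenario"`.
#' @export
sequence_scenario <- function(domain_len = 100,
                              deg_letters = c("D", "D", "E"),
                              offsets = c(px = 1L, yxg = 24L, dcxxrk = 29L,
                                          deg = 38L, ywfkrg = 44L),
                              indels = NULL, seed) {
  if (missing(seed)) stop("a seed is mandatory for synthetic scenarios")
  stopifnot(length(deg_letters) == 3L, all(deg_letters %in% c("D", "E")))
  blocks <- rbind(
    data.frame(motif = "px", start = offsets[["px"]], len = 12L),
    data.frame(motif = "yxg", start = offsets[["yxg"]], len = 3L),
    data.frame(motif = "dcxxrk", start = offsets[["dcxxrk"]], len = 5L),
    data.frame(motif = "deg", start = offsets[["deg"]], len = 2L),
    data.frame(motif = "ywfkrg", start = offsets[["ywfkrg"]], len = 3L))
  blocks$end <- blocks$start + blocks$len - 1L
  if (any(blocks$start < 1L) || any(blocks$end > domain_len))
    stop("planted motifs fall outside the domain")
  o <- order(blocks$start)
  if (any(blocks$start[o][-1] <= blocks$end[o][-nrow(blocks)]))
    stop("planted motifs collide")
  if (!is.null(indels)) {
    indels <- as.data.frame(indels)
    stopifnot(all(c("domain", "after", "len") %in% names(indels)))
    inside <- vapply(indels$after, function(a)
      any(blocks$start <= a & blocks$end > a), logical(1))
    if (any(inside))
      stop("indel insertion point falls inside a planted motif")
  }
  structure(list(domain_len = domain_len, deg_letters = deg_letters,
                 offsets = offsets, blocks = blocks, indels = indels,
                 seed = seed),
            class = "sequence_scenario")
}

#' Generate a tripartite sequence with planted MCF motifs
#'
#' Three homologous domains are emitted as one consecutive-numbered
#' sequence, a three-row alignment, and a ground-truth annotation listing
#' every planted motif start, the `[DE]G` letters, and the element ranges
#' (loop and matrix helix) the plant implies.
#'
#' @param scenario A [sequence_scenario()].
#' @return Object of class `"tripartite_sim"`: list with `sequence`,
#'   `domains`, `alignment` (named aligned rows), and `truth`.
#' @export
gen_tripartite_sequence <- function(scenario) {
  stopifnot(inherits(scenario, "sequence_scenario"))
  L <- scenario$domain_len
  off <- scenario$offsets
  withr::with_seed(scenario$seed, {
    dom_chars <- list()
    for (d in 1:3) {
      ch <- sample(.FILLER, L, replace = TRUE)
      p0 <- off[["px"]]
      ch[p0] <- "P"
      ch[p0 + 2L] <- sample(c("D", "E"), 1)
      ch[p0 + 5L] <- sample(c("K", "R"), 1)
      ch[p0 + 7L] <- "R"
      ch[p0 + 9L] <- "Q"
      ch[p0 + 11L] <- "Q"
      y0 <- off[["yxg"]]
      ch[y0] <- sample(c("Y", "F"), 1)
      ch[y0 + 2L] <- "G"
      c0 <- off[["dcxxrk"]]
      ch[c0] <- "D"; ch[c0 + 1L] <- "C"
      ch[c0 + 4L] <- sample(c("R", "K"), 1)
      g0 <- off[["deg"]]
      ch[g0] <- scenario$deg_letters[d]
      ch[g0 + 1L] <- "G"
      w0 <- off[["ywfkrg"]]
      ch[w0] <- sample(c("Y", "W", "F"), 1)
      ch[w0 + 1L] <- sample(c("K", "R"), 1)
      ch[w0 + 2L] <- "G"
      dom_chars[[d]] <- ch
    }

    # apply indels: extra filler residues in one domain, gaps elsewhere
    ins <- scenario$indels
    aligned <- lapply(dom_chars, identity)  # start gap-free
    if (!is.null(ins) && nrow(ins)) {
      # column descriptors: original coordinate and per-domain content
      cols <- lapply(seq_len(L), function(i)
        list(orig = i, chars = c(dom_chars[[1]][i], dom_chars[[2]][i],
                                 dom_chars[[3]][i])))
      for (r in seq_len(nrow(ins))) {
        d <- ins$domain[r]; a <- ins$after[r]; len <- ins$len[r]
        pos <- max(which(vapply(cols, function(cc) cc$orig <= a &&
                                  cc$orig > 0, logical(1))))
        newcols <- lapply(seq_len(len), function(i) {
          ch <- c("-", "-", "-")
          ch[d] <- sample(.FILLER, 1)
          list(orig = 0L, chars = ch)
        })
        cols <- append(cols, newcols, after = pos)
      }
      aligned <- lapply(1:3, function(d)
        vapply(cols, function(cc) cc$chars[d], character(1)))
      dom_chars <- lapply(aligned, function(ch) ch[ch != "-"])
    }

    dom_seq <- vapply(dom_chars, paste, character(1), collapse = "")
    lens <- nchar(dom_seq)
    starts <- cumsum(c(1L, lens[-3]))

    # within-domain position after accounting for that domain's insertions
    shift <- function(d, pos) {
      if (is.null(ins)) return(pos)
      vapply(pos, function(p)
        p + sum(ins$len[ins$domain == d & ins$after < p]), numeric(1))
    }
    motifs <- do.call(rbind, lapply(1:3, function(d) {
      b <- scenario$blocks
      data.frame(motif = b$motif, domain = d,
                 start = as.integer(starts[d] + shift(d, b$start) - 1L),
                 end = as.integer(starts[d] + shift(d, b$end) - 1L),
                 stringsAsFactors = FALSE)
    }))
    deg_truth <- data.frame(
      domain = 1:3, letter = scenario$deg_letters,
      pos_de = motifs$start[motifs$motif == "deg"],
      pos_g = motifs$start[motifs$motif == "deg"] + 1L)
    elements <- do.call(rbind, lapply(1:3, function(d) {
      m <- motifs[motifs$domain == d, ]
      px <- m$start[m$motif == "px"]
      yxg <- m$start[m$motif == "yxg"]
      degg <- m$end[m$motif == "deg"]
      rbind(data.frame(element = paste0("M", d), domain = d,
                       start = px + 11L, end = yxg - 1L),
            data.frame(element = c("h12", "h34", "h56")[d], domain = d,
                       start = yxg, end = degg))
    }))
    anchor_triplets <- vapply(c("px", "yxg", "dcxxrk", "deg", "ywfkrg"),
                              function(m)
                                motifs$start[motifs$motif == m &
                                               motifs$domain == 1L],
                              integer(1))
    aligned_rows <- vapply(aligned, paste, character(1), collapse = "")
    names(aligned_rows) <- sprintf("domain%d/%d-%d", 1:3, starts,
                                   starts + lens - 1L)
    structure(list(
      sequence = paste(dom_seq, collapse = ""),
      domains = dom_seq,
      alignment = aligned_rows,
      truth = list(motifs = motifs, deg = deg_truth, elements = elements,
                   anchor_triplets = anchor_triplets,
                   domain_spans = data.frame(domain = 1:3, start = starts,
                                             end = starts + lens - 1L)),
      scenario = scenario), class = "tripartite_sim")
  })
}

#' Generate a synthetic carrier family
#'
#' `n` members drawn independently; the `[DE]G` first residue of domain `d`
#' is E with probability `p_e[d]`, else D. Member names may include the
#' standard exclusion-list names to exercise [apply_exclusions()].
#'
#' @param n Family size (default 53, the number of human mitochondrial
#'   carriers).
#' @param p_e Length-3 numeric: per-domain probability of E.
#' @param member_names Optional character vector of `n` names.
#' @param planted_exclusions Names (e.g. from [mc_exclusions()]) appended in
#'   place of the last generic names.
#' @param domain_len Residues per domain.
#' @param seed Mandatory RNG seed.
#' @return Object of class `"family_sim"`: list with `seqs` (named
#'   character), `truth` (data frame `name`, `d1`, `d2`, `d3`), `windows`
#'   (matrix-helix search windows, identical across members) and
#'   `domain_spans`.
#' @export
gen_family <- function(n = 53, p_e = c(0.5, 0.5, 0.5), member_names = NULL,
                       planted_exclusions = character(0), domain_len = 100,
                       seed) {
  if (missing(seed)) stop("a seed is mandatory for synthetic scenarios")
  stopifnot(n >= 1, length(p_e) == 3L)
  if (is.null(member_names))
    member_names <- sprintf("MC%03d", seq_len(n))
  if (length(planted_exclusions)) {
    k <- length(planted_exclusions)
    if (k > n) stop("more planted exclusion names than members")
    member_names[(n - k + 1L):n] <- planted_exclusions
  }
  if (length(member_names) != n) stop("need ", n, " member names")
  withr::with_seed(seed, {
    letters3 <- t(sapply(seq_len(n), function(i)
      ifelse(stats::runif(3) < p_e, "E", "D")))
    seqs <- character(n)
    windows <- NULL; spans <- NULL
    for (i in seq_len(n)) {
      sim <- gen_tripartite_sequence(sequence_scenario(
        domain_len = domain_len, deg_letters = letters3[i, ],
        seed = sample.int(2^31 - 1, 1)))
      seqs[i] <- sim$sequence
      if (is.null(windows)) {
        windows <- sim$truth$elements[grepl("^h", sim$truth$elements$element),
                                      c("domain", "start", "end")]
        spans <- sim$truth$domain_spans
      }
    }
    names(seqs) <- member_names
    structure(list(seqs = seqs,
                   truth = data.frame(name = member_names,
                                      d1 = letters3[, 1], d2 = letters3[, 2],
                                      d3 = letters3[, 3],
                                      stringsAsFactors = FALSE),
                   windows = windows, domain_spans = spans,
                   p_e = p_e, seed = seed),
              class = "family_sim")
  })
}

#' Write named sequences as FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), path)
  invisible(path)
}

#' Write aligned rows as FASTA
#'
#' @param alignment Named character vector of equal-length aligned rows.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(alignment, path) {
  write_fasta(alignment, path)
}
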