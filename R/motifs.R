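# MCF motif grammar: compile and scan residue-class patterns.
#
# Pattern language: literal one-letter residues, `x` for any residue,
# `[..]` for a residue class, and the small-residue symbol (Greek pi) for a
# configurable small-residue class. Scanning reports all (possibly
# overlapping) matches; anchor-based disambiguation happens only in
# annotate_mcf so that scanning stays a pure primitive.

.AA20 <- unname(.AA1)
.PI_SYMBOL <- "π"

#' Default small-residue class
#'
#' Membership of the small-residue symbol in motif patterns. The literature
#' defines it only as "a small residue"; the default is {G, A, S, C, T}.
#' @return Character vector of one-letter codes.
#' @export
small_residues <- function() c("G", "A", "S", "C", "T")

#' The conserved MCF motif grammar
#'
#' The matrix-side signature of the mitochondrial carrier family and the
#' cytoplasmic-side motifs, as pattern strings understood by
#' [compile_pattern()].
#'
#' @return Named character vector of pattern strings.
#' @export
mcf_motifs <- function() {
  c(px       = "Px[DE]xx[KR]xRxQxQ",
    deg_long = "[DE]Gxxxx[YWF][KR]G",
    helix    = "[YF]xGxxDCxx[RK]",
    yxg      = "[YF]xG",
    deg      = "[DE]G",
    dcxxrk   = "DCxx[RK]",
    ywfkrg   = "[YWF][KR]G",
    ydexxrk  = "[YF][DE]xx[RK]",
    gxxxg    = "GxxxG",
    pixxxpi  = paste0(.PI_SYMBOL, "xxx", .PI_SYMBOL))
}

#' Compile a motif pattern string
#'
#' @param spec Pattern string (see [mcf_motifs()] for examples).
#' @param small Small-residue class used for the pi symbol.
#' @return Object of class `"motif_pattern"`: list with `name` (the spec
#'   string), `tokens` (list of allowed-residue character vectors) and
#'   `types` (`"literal"`, `"any"`, `"small"` or `"class"`).
#' @export
compile_pattern <- function(spec, small = small_residues()) {
  chars <- strsplit(spec, "")[[1]]
  tokens <- list(); types <- character(0)
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i + 1L
      members <- character(0)
      while (j <= length(chars) && chars[j] != "]") {
        if (chars[j] == "[") stop("nested '[' in pattern: ", spec)
        members <- c(members, toupper(chars[j]))
        j <- j + 1L
      }
      if (j > length(chars)) stop("unbalanced '[' in pattern: ", spec)
      if (!length(members)) stop("empty residue class in pattern: ", spec)
      if (!all(members %in% .AA20))
        stop("non-standard residue in class: ",
             paste(setdiff(members, .AA20), collapse = ""))
      tokens <- c(tokens, list(members)); types <- c(types, "class")
      i <- j + 1L
    } else if (ch == "]") {
      stop("unbalanced ']' in pattern: ", spec)
    } else if (ch == "x") {
      tokens <- c(tokens, list(.AA20)); types <- c(types, "any")
      i <- i + 1L
    } else if (ch == .PI_SYMBOL) {
      tokens <- c(tokens, list(toupper(small))); types <- c(types, "small")
      i <- i + 1L
    } else if (toupper(ch) %in% .AA20) {
      tokens <- c(tokens, list(toupper(ch))); types <- c(types, "literal")
      i <- i + 1L
    } else {
      stop("unexpected character '", ch, "' in pattern: ", spec)
    }
  }
  if (!length(tokens)) stop("empty pattern")
  structure(list(name = spec, tokens = tokens, types = types),
            class = "motif_pattern")
}

#' Reconstruct the pattern string of a compiled pattern
#'
#' Inverse of [compile_pattern()]: `detokenize_pattern(compile_pattern(p))`
#' equals `p`.
#'
#' @param pattern A `"motif_pattern"`.
#' @return Pattern string.
#' @export
detokenize_pattern <- function(pattern) {
  paste(mapply(function(tok, type) {
    switch(type,
      any = "x",
      small = .PI_SYMBOL,
      literal = tok,
      class = paste0("[", paste(tok, collapse = ""), "]"))
  }, pattern$tokens, pattern$types), collapse = "")
}

#' @export
print.motif_pattern <- function(x, ...) {
  cat("motif_pattern '", x$name, "': ", length(x$tokens), " tokens\n",
      sep = "")
  invisible(x)
}

#' Scan a sequence for motif matches
#'
#' Exhaustive position-by-position matching; all (possibly overlapping)
#' matches are reported in ascending start order.
#'
#' @param seq Protein sequence (one-letter codes) as a single string.
#' @param pattern A `"motif_pattern"` or a pattern string.
#' @param window Optional `c(start, end)` interval (1-based, inclusive)
#'   restricting match *starts and ends* to lie inside it.
#' @return Data frame: `start`, `end`, `match` (matched subsequence).
#' @export
scan_motif <- function(seq, pattern, window = NULL) {
  if (is.character(pattern)) pattern <- compile_pattern(pattern)
  chars <- strsplit(toupper(seq), "")[[1]]
  L <- length(chars)
  m <- length(pattern$tokens)
  if (is.null(window)) window <- c(1L, L)
  if (window[1] < 1L || window[2] > L || window[1] > window[2])
    stop("window [", window[1], ", ", window[2],
         "] outside sequence of length ", L)
  reg <- window[1]:window[2]
  bad <- reg[!chars[reg] %in% .AA20]
  if (length(bad))
    stop("non-standard residue letter(s) at position(s): ",
         paste(bad, collapse = ", "))
  starts <- window[1]:(window[2] - m + 1L)
  if (window[2] - window[1] + 1L < m)
    return(data.frame(start = integer(0), end = integer(0),
                      match = character(0)))
  ok <- rep(TRUE, length(starts))
  for (j in seq_len(m))
    ok <- ok & chars[starts + j - 1L] %in% pattern$tokens[[j]]
  s <- starts[ok]
  data.frame(start = s, end = s + m - 1L,
             match = vapply(s, function(i)
               paste(chars[i:(i + m - 1L)], collapse = ""), character(1)),
             stringsAsFactors = FALSE)
}

# ---- per-domain annotation ------------------------------------------------

#' Default triplet anchors of the annotated MCF motifs
#'
#' Expected triplet positions (domain-1 numbering) of the motif starts used
#' for anchor-proximity disambiguation: the P of the P-motif at triplet 27,
#' the `[YF]xG` aromatic at 50, the D of `DCxx[RK]` at 55, the `[DE]` of
#' `[DE]G` at 64 and `[YWF][KR]G` at 70.
#'
#' @return Named integer vector.
#' @export
mcf_anchor_triplets <- function() {
  c(px = 27L, yxg = 50L, dcxxrk = 55L, deg = 64L, ywfkrg = 70L)
}

# prefix fallback for the long P-motif: real carrier domains often deviate
# from the consensus after the capping arginine
.PX_PREFIX <- "Px[DE]xx[KR]xR"

#' Annotate the MCF motifs of a tripartite sequence
#'
#' For each of the three domains, scans the domain's residue window for each
#' motif and keeps the hit whose start lies nearest the expected triplet
#' anchor. Ambiguities (two candidates equally near) are reported via
#' `n_candidates` and a warning, not silently resolved. A domain in which the
#' full `Px[DE]xx[KR]xRxQxQ` consensus does not occur is re-scanned with the
#' `Px[DE]xx[KR]xR` prefix and the hit is flagged `partial`. Motifs with no
#' candidate hit in a domain produce a warning and an `NA` row.
#'
#' @param x Either a single string whose character positions are the residue
#'   numbers (padded full-chain sequence), or a named list/vector of the
#'   three domain sequences with attributes taken from the triplet map spans.
#' @param map A [build_triplet_map()] result covering the three domains.
#' @param motifs Named patterns to annotate (default: P-motif, `[YF]xG`,
#'   `DCxx[RK]`, `[DE]G`, `[YWF][KR]G`).
#' @param anchors Named triplet anchors, as [mcf_anchor_triplets()].
#' @return Data frame: `motif`, `domain`, `start`, `end`, `match`,
#'   `partial`, `n_candidates`.
#' @export
annotate_mcf <- function(x, map,
                         motifs = mcf_motifs()[c("px", "yxg", "dcxxrk",
                                                 "deg", "ywfkrg")],
                         anchors = mcf_anchor_triplets()) {
  sp <- map$domain_spans
  domain_seq <- .domain_sequences(x, map)
  out <- list()
  for (nm in names(motifs)) {
    pat <- compile_pattern(motifs[[nm]])
    for (d in 1:3) {
      seq_d <- domain_seq$seq[[d]]
      off <- domain_seq$start[d] - 1L
      hits <- scan_motif(seq_d, pat)
      partial <- FALSE
      if (!nrow(hits) && nm == "px") {
        hits <- scan_motif(seq_d, .PX_PREFIX)
        partial <- TRUE
      }
      if (!nrow(hits)) {
        warning("no ", nm, " motif hit in domain ", d)
        out[[length(out) + 1L]] <- data.frame(
          motif = nm, domain = d, start = NA_integer_, end = NA_integer_,
          match = NA_character_, partial = NA, n_candidates = 0L)
        next
      }
      hits$start <- hits$start + off
      hits$end <- hits$end + off
      anchor_pos <- NA_integer_
      if (nm %in% names(anchors)) {
        anchor_pos <- tryCatch(
          as.integer(triplet_partners(map, anchors[[nm]])[d]),
          error = function(e) NA_integer_)
      }
      if (is.na(anchor_pos)) {
        pick <- 1L; ncand <- nrow(hits)
      } else {
        dist <- abs(hits$start - anchor_pos)
        pick <- which.min(dist)
        ncand <- sum(dist == min(dist))
        if (ncand > 1L)
          warning("ambiguous ", nm, " motif in domain ", d, ": ",
                  ncand, " hits equally near triplet ", anchors[[nm]])
      }
      out[[length(out) + 1L]] <- data.frame(
        motif = nm, domain = d, start = hits$start[pick],
        end = hits$end[pick], match = hits$match[pick],
        partial = partial, n_candidates = ncand,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

# Resolve the three numbered domain sequences from either a full-chain
# string (positions = residue numbers) or three explicit domain strings.
.domain_sequences <- function(x, map) {
  sp <- map$domain_spans
  if (is.character(x) && length(x) == 1L) {
    if (nchar(x) < max(sp$end))
      stop("sequence (length ", nchar(x),
           ") shorter than the aligned span end (", max(sp$end), ")")
    seqs <- lapply(1:3, function(d) substr(x, sp$start[d], sp$end[d]))
  } else if (length(x) == 3L) {
    seqs <- as.list(unname(unlist(x)))
    for (d in 1:3)
      if (nchar(seqs[[d]]) != sp$end[d] - sp$start[d] + 1L)
        stop("domain ", d, " sequence length (", nchar(seqs[[d]]),
             ") does not match its span (", sp$end[d] - sp$start[d] + 1L, ")")
  } else {
    stop("x must be one full-chain string or three domain sequences")
  }
  list(seq = seqs, start = sp$start)
}

#' Write a motif annotation table
#'
#' @param hits Data frame from [annotate_mcf()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_motif_table <- function(hits, path) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
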