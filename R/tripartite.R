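# Tripartite "triplet" mapping.
#
# The carrier fold is built from three homologous ~100-residue domains. A
# "triplet" is the group of residues occupying the same column of a
# three-domain alignment, indexed by the residue number of the domain-1
# member (e.g. triplet 38 = Q38/D143/Q240 in bovine AAC1). Columns where
# domain 1 is gapped carry no triplet number of their own; they are labelled
# "between t and t+1" and excluded from symmetry summaries.

#' Build a triplet map from a three-domain alignment
#'
#' @param alignment Path to an aligned FASTA file with exactly three rows
#'   (domains 1-3), or a character vector of three aligned sequences
#'   (gaps as `-`). FASTA headers of the form `name/start-end` supply the
#'   residue numbering of each row.
#' @param domain_starts Optional integer vector: first residue number of each
#'   row. Length 3, or length 1 (domain-1 start) when the three rows are
#'   consecutive stretches of one numbering, as in a gap-free internal-repeat
#'   alignment. Overrides header-derived starts.
#' @return Object of class `"triplet_map"`: list with `columns` (data frame:
#'   `column`, `triplet`, `gapped`, `label`, `res_d1`, `res_d2`, `res_d3`),
#'   `domain_spans`, and the aligned rows.
#' @export
build_triplet_map <- function(alignment, domain_starts = NULL) {
  rows <- .read_alignment_rows(alignment)
  if (length(rows$seq) != 3L)
    stop("a triplet map needs exactly 3 aligned rows, got ", length(rows$seq))
  width <- unique(nchar(rows$seq))
  if (length(width) != 1L)
    stop("aligned rows differ in length: ", paste(nchar(rows$seq), collapse = ", "))
  chars <- t(vapply(rows$seq, function(s) strsplit(s, "")[[1]],
                    character(width)))
  is_res <- chars != "-" & chars != "."
  nres <- rowSums(is_res)

  starts <- domain_starts
  if (is.null(starts)) starts <- rows$starts
  if (is.null(starts)) starts <- 1L
  if (length(starts) == 1L)
    starts <- cumsum(c(starts, nres[1], nres[2]))[1:3] -
      c(0L, 0L, 0L) # consecutive numbering: d2 starts after d1, d3 after d2
  if (length(starts) != 3L || anyNA(starts))
    stop("domain_starts must give 3 residue numbers (or 1 for consecutive numbering)")

  resno <- matrix(NA_integer_, 3L, width)
  for (d in 1:3) resno[d, is_res[d, ]] <- starts[d] + seq_len(nres[d]) - 1L

  spans <- data.frame(domain = 1:3, start = starts,
                      end = starts + nres - 1L)
  for (d in 1:2) for (e in (d + 1):3)
    if (spans$start[e] <= spans$end[d] && spans$end[e] >= spans$start[d])
      stop("domain residue-number ranges overlap (domains ", d, " and ", e,
           "): duplicate residue numbers are not allowed")

  # triplet number = domain-1 residue number; d1-gapped columns get interval labels
  triplet <- resno[1, ]
  gapped <- is.na(triplet)
  label <- as.character(triplet)
  if (any(gapped)) {
    prev <- cummax(ifelse(is.na(triplet), 0L, triplet))
    prev[prev == 0L] <- NA_integer_
    label[gapped] <- ifelse(is.na(prev[gapped]),
                            paste0("before ", starts[1]),
                            paste0("between ", prev[gapped], " and ",
                                   prev[gapped] + 1L))
  }
  columns <- data.frame(column = seq_len(width), triplet = triplet,
                        gapped = gapped, label = label,
                        res_d1 = resno[1, ], res_d2 = resno[2, ],
                        res_d3 = resno[3, ], stringsAsFactors = FALSE)
  structure(list(columns = columns, domain_spans = spans,
                 alignment = stats::setNames(rows$seq, rows$names)),
            class = "triplet_map")
}

.read_alignment_rows <- function(alignment) {
  if (is.character(alignment) && length(alignment) == 1L &&
      file.exists(alignment)) {
    ss <- Biostrings::readAAStringSet(alignment)
    nm <- names(ss)
    seqs <- as.character(ss)
  } else if (is.character(alignment)) {
    nm <- names(alignment)
    if (is.null(nm)) nm <- paste0("domain", seq_along(alignment))
    seqs <- unname(alignment)
  } else {
    stop("alignment must be a file path or a character vector of aligned rows")
  }
  starts <- suppressWarnings(
    as.integer(sub("^.*/([0-9]+)-[0-9]+\\s*$", "\\1", nm)))
  if (anyNA(starts)) starts <- NULL
  list(seq = toupper(seqs), names = nm, starts = starts)
}

#' @export
print.triplet_map <- function(x, ...) {
  cat("triplet_map: ", nrow(x$columns), " columns, ",
      sum(!x$columns$gapped), " triplets; domain spans ",
      paste(sprintf("%d-%d", x$domain_spans$start, x$domain_spans$end),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Map a residue number to its (domain, triplet) position
#'
#' Inverse of [triplet_partners()]. Residues sitting in columns where domain
#' 1 is gapped have no triplet number; they are returned with `triplet = NA`
#' and the interval label of their column.
#'
#' @param map A [build_triplet_map()] result.
#' @param residue_number Residue number (author numbering).
#' @return List: `domain`, `triplet` (NA if the column has no domain-1
#'   member), `gapped`, `label`.
#' @export
map_residue <- function(map, residue_number) {
  sp <- map$domain_spans
  d <- which(residue_number >= sp$start & residue_number <= sp$end)
  if (!length(d))
    stop("residue ", residue_number, " is outside the aligned span")
  col <- map$columns[[paste0("res_d", d)]]
  i <- which(col == residue_number)
  if (!length(i))
    stop("residue ", residue_number, " not covered by the alignment")
  r <- map$columns[i, ]
  list(domain = d, triplet = r$triplet, gapped = r$gapped, label = r$label)
}

#' Residues of one triplet
#'
#' @param map A [build_triplet_map()] result.
#' @param triplet Triplet number (a domain-1 residue number).
#' @return Named integer vector `c(d1=, d2=, d3=)`; `NA` where the domain is
#'   gapped in that column.
#' @export
triplet_partners <- function(map, triplet) {
  i <- which(map$columns$triplet == triplet)
  if (!length(i)) stop("unknown triplet: ", triplet)
  r <- map$columns[i, ]
  c(d1 = r$res_d1, d2 = r$res_d2, d3 = r$res_d3)
}

#' Export a triplet table
#'
#' @param map A triplet map.
#' @param path Output TSV path (columns: triplet, res_d1, res_d2, res_d3).
#' @return `path`, invisibly.
#' @export
write_triplet_table <- function(map, path) {
  tab <- map$columns[!map$columns$gapped,
                     c("triplet", "res_d1", "res_d2", "res_d3")]
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Reference triplet anchors for the ADP/ATP carrier
#'
#' The five landmark triplets of bovine AAC1 used to validate a supplied
#' three-domain alignment: the capping arginines (30), the hydrophobic plug
#' (37), the loop N-end (38), the `[YF]xG` aromatics (50) and the G of the
#' `[DE]G` motif (65).
#'
#' @return Data frame with columns `triplet`, `res_d1`, `res_d2`, `res_d3`.
#' @export
aac_triplet_anchors <- function() {
  data.frame(
    triplet = c(30L, 37L, 38L, 50L, 65L),
    res_d1  = c(30L, 37L, 38L, 50L, 65L),
    res_d2  = c(139L, 142L, 143L, 153L, 168L),
    res_d3  = c(236L, 239L, 240L, 250L, 265L))
}

#' Validate a triplet map against anchor triplets
#'
#' @param map A triplet map.
#' @param anchors Data frame as returned by [aac_triplet_anchors()].
#' @return `TRUE` invisibly; stops with the offending triplets otherwise.
#' @export
validate_triplet_anchors <- function(map, anchors = aac_triplet_anchors()) {
  bad <- character(0)
  for (i in seq_len(nrow(anchors))) {
    want <- unlist(anchors[i, c("res_d1", "res_d2", "res_d3")])
    got <- tryCatch(triplet_partners(map, anchors$triplet[i]),
                    error = function(e) rep(NA_integer_, 3))
    if (!identical(unname(as.integer(got)), unname(as.integer(want))))
      bad <- c(bad, sprintf("triplet %d: expected (%s), got (%s)",
                            anchors$triplet[i],
                            paste(want, collapse = ","),
                            paste(got, collapse = ",")))
  }
  if (length(bad))
    stop("alignment fails anchor validation:\n  ",
         paste(bad, collapse = "\n  "))
  invisible(TRUE)
}

# ---- structural elements --------------------------------------------------

#' Construct an element map
#'
#' An element map names the matrix loops (`M1`-`M3`) and short matrix helices
#' (`h12`, `h34`, `h56`) as inclusive residue intervals per domain, and
#' carries the domain residue spans used for inter-domain classification.
#'
#' @param elements Data frame: `element`, `domain`, `start`, `end`.
#' @param domain_spans Data frame: `domain`, `start`, `end`.
#' @return Object of class `"element_map"`.
#' @export
element_map <- function(elements, domain_spans) {
  elements <- as.data.frame(elements)
  for (d in unique(elements$domain)) {
    e <- elements[elements$domain == d, ]
    if (nrow(e) > 1) {
      o <- order(e$start)
      if (any(e$start[o][-1] <= e$end[o][-nrow(e)]))
        stop("overlapping element intervals in domain ", d)
    }
  }
  structure(list(elements = elements,
                 domain_spans = as.data.frame(domain_spans)),
            class = "element_map")
}

#' @export
print.element_map <- function(x, ...) {
  cat("element_map:\n")
  print(x$elements, row.names = FALSE)
  invisible(x)
}

#' Derive matrix-loop and matrix-helix ranges from motif anchors
#'
#' Per domain, the matrix loop runs from the residue after the hydrophobic
#' plug (triplet-37 equivalent, i.e. position 11 of the
#' `Px[DE]xx[KR]xRxQxQ` motif) to the residue before the `[YF]xG` aromatic,
#' and the short matrix helix from that aromatic to the G of the `[DE]G`
#' motif. Where a domain's own P-motif hit is partial or absent, the loop
#' start is obtained through the triplet map from a domain that has one.
#'
#' @param map A triplet map.
#' @param motif_hits Data frame from [annotate_mcf()] (columns `motif`,
#'   `domain`, `start`, `end`, `partial`).
#' @return An [element_map()].
#' @export
derive_elements <- function(map, motif_hits) {
  h <- motif_hits[!is.na(motif_hits$start), ]
  get_hit <- function(motif, d) h[h$motif == motif & h$domain == d, ]

  missing <- character(0)
  for (d in 1:3) {
    if (!nrow(get_hit("yxg", d))) missing <- c(missing, paste0("yxg/domain", d))
    if (!nrow(get_hit("deg", d))) missing <- c(missing, paste0("deg/domain", d))
  }
  if (length(missing))
    stop("cannot derive elements; missing anchor motifs: ",
         paste(missing, collapse = ", "))

  # loop-start triplet from any full (or prefix) P-motif hit: motif position
  # 12 is the triplet-38 equivalent
  px <- h[h$motif == "px", ]
  if (!nrow(px))
    stop("cannot derive elements; missing anchor motifs: px (all domains)")
  t_loop <- NA_integer_
  for (i in seq_len(nrow(px))) {
    tr <- tryCatch(map_residue(map, px$start[i])$triplet,
                   error = function(e) NA_integer_)
    if (!is.na(tr)) { t_loop <- tr + 11L; break }
  }
  if (is.na(t_loop))
    stop("cannot derive elements; P-motif hits not covered by the triplet map")
  loop_starts <- triplet_partners(map, t_loop)

  rows <- list()
  for (d in 1:3) {
    yxg <- get_hit("yxg", d); deg <- get_hit("deg", d)
    ls <- loop_starts[d]
    if (is.na(ls)) {
      pd <- get_hit("px", d)
      if (!nrow(pd))
        stop("cannot derive elements; missing anchor motifs: px/domain", d)
      ls <- pd$start[1] + 11L
    }
    rows[[length(rows) + 1L]] <- data.frame(
      element = paste0("M", d), domain = d,
      start = as.integer(ls), end = yxg$start[1] - 1L)
    rows[[length(rows) + 1L]] <- data.frame(
      element = c("h12", "h34", "h56")[d], domain = d,
      start = yxg$start[1], end = deg$end[1])
  }
  element_map(do.call(rbind, rows), map$domain_spans)
}

# domain / element membership helpers used by the interaction classifier
.domain_of <- function(em, resno) {
  sp <- em$domain_spans
  d <- sp$domain[resno >= sp$start & resno <= sp$end]
  if (length(d) != 1L) NA_integer_ else as.integer(d)
}

.element_of_residue <- function(em, resno) {
  e <- em$elements
  i <- which(resno >= e$start & resno <= e$end)
  if (!length(i)) return(NULL)
  e[i[1], ]
}
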