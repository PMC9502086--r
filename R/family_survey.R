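# Family-wide [DE]G survey and position-frequency (sequence-logo) matrices.
#
# For each carrier and each of its three homologous domains, the first
# residue of the [DE]G motif at the C-end of the short matrix helix is
# called (D, E, or other); carriers localising outside the inner
# mitochondrial membrane and carriers with an unexpected charged residue in
# the motif's second position are excluded before computing per-domain E
# frequencies.

#' Standard survey exclusion lists
#'
#' The human mitochondrial carriers conventionally excluded from the
#' family-wide `[DE]G` statistics: members reported to localise outside the
#' inner mitochondrial membrane, and members with an unexpected charged
#' residue in the second position of the `[DE]G` motif.
#'
#' @return List with `outside_imm` and `charged_second` name vectors.
#' @export
mc_exclusions <- function() {
  list(outside_imm = c("MTCH1", "MTCH2", "SLC25A46", "PM34"),
       charged_second = c("SLC25A47", "SLC25A51", "SLC25A52"))
}

#' Call the [DE]G first residue in each domain
#'
#' Within each domain window (normally the matrix-helix range), the
#' candidate is a G preceded by a charged residue; among candidates the one
#' nearest the window's C-end (the matrix-helix C-end anchor) is taken, and
#' the call is the residue preceding the G: `"D"`, `"E"`, or `"other"`
#' (flagged) for an unexpected charged first residue (K/R/H). A window with
#' no candidate yields `"other"` with a warning.
#'
#' @param seq Protein sequence (positions = residue numbers).
#' @param windows Data frame `domain`, `start`, `end` (three rows), e.g. the
#'   matrix-helix rows of an [element_map()] or a generator's truth windows.
#' @return Data frame: `domain`, `call`, `letter`, `position` (of the first
#'   residue), `flag`.
#' @export
locate_deg <- function(seq, windows) {
  windows <- as.data.frame(windows)
  stopifnot(nrow(windows) == 3L)
  chars <- strsplit(toupper(seq), "")[[1]]
  out <- lapply(seq_len(nrow(windows)), function(i) {
    d <- windows$domain[i]
    w <- c(windows$start[i], windows$end[i])
    idx <- (w[1] + 1L):w[2]
    cand <- idx[chars[idx] == "G" & chars[idx - 1L] %in%
                  c("D", "E", "K", "R", "H")]
    if (!length(cand)) {
      warning("no G-anchored [DE]G candidate in domain ", d,
              " window [", w[1], ", ", w[2], "]")
      return(data.frame(domain = d, call = "other", letter = NA_character_,
                        position = NA_integer_, flag = "no-candidate"))
    }
    g <- cand[which.min(w[2] - cand)]  # nearest the C-end anchor
    first <- chars[g - 1L]
    data.frame(domain = d,
               call = if (first %in% c("D", "E")) first else "other",
               letter = first, position = g - 1L,
               flag = if (first %in% c("D", "E")) "none" else
                 "charged-first-position",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Survey the [DE]G motif across a carrier family
#'
#' @param seqs Named character vector of sequences, or a FASTA path.
#' @param windows Per-domain search windows (see [locate_deg()]); the same
#'   windows are applied to every member (supply a config table per member
#'   via repeated calls if domains differ).
#' @param outside_imm,charged_second Exclusion name lists
#'   (defaults: [mc_exclusions()]).
#' @return Object of class `"carrier_survey"`: data frame `id`, `d1`, `d2`,
#'   `d3` (calls), `exclusion`.
#' @export
survey_family <- function(seqs, windows,
                          outside_imm = mc_exclusions()$outside_imm,
                          charged_second = mc_exclusions()$charged_second) {
  if (is.character(seqs) && length(seqs) == 1L && file.exists(seqs))
    seqs <- stats::setNames(as.character(Biostrings::readAAStringSet(seqs)),
                            names(Biostrings::readAAStringSet(seqs)))
  calls <- t(vapply(seqs, function(s) locate_deg(s, windows)$call,
                    character(3)))
  entries <- data.frame(id = names(seqs), d1 = calls[, 1], d2 = calls[, 2],
                        d3 = calls[, 3], stringsAsFactors = FALSE)
  entries <- apply_exclusions(entries, outside_imm, charged_second)
  class(entries) <- c("carrier_survey", class(entries))
  entries
}

#' Apply the survey exclusion lists
#'
#' Retained entries are the input minus the union of the two lists; an entry
#' on both lists is excluded once with both flags recorded. Listed names
#' absent from the input produce a warning, not an error. No entry is lost:
#' the returned table carries every input row with its exclusion flag.
#'
#' @param entries Data frame with an `id` column.
#' @param outside_imm,charged_second Name vectors.
#' @return `entries` with an `exclusion` column (`"none"`, `"outside-IMM"`,
#'   `"charged-second-position"`, or both joined with `";"`).
#' @export
apply_exclusions <- function(entries,
                             outside_imm = mc_exclusions()$outside_imm,
                             charged_second = mc_exclusions()$charged_second) {
  missing <- setdiff(c(outside_imm, charged_second), entries$id)
  if (length(missing))
    warning("exclusion-list name(s) absent from input: ",
            paste(missing, collapse = ", "))
  flag <- character(nrow(entries))
  for (i in seq_len(nrow(entries))) {
    f <- c(if (entries$id[i] %in% outside_imm) "outside-IMM",
           if (entries$id[i] %in% charged_second) "charged-second-position")
    flag[i] <- if (length(f)) paste(f, collapse = ";") else "none"
  }
  entries$exclusion <- flag
  entries
}

#' Retained entries of a survey
#'
#' @param entries [apply_exclusions()] / [survey_family()] output.
#' @return The rows with `exclusion == "none"`.
#' @export
retained_entries <- function(entries) {
  entries[entries$exclusion == "none", , drop = FALSE]
}

#' Per-domain frequency of E in the [DE]G motif
#'
#' @param entries Survey table; only rows with `exclusion == "none"` (if the
#'   column is present) are counted.
#' @param groups Optional factor/character of group labels (same length as
#'   the retained entries) for stratified frequencies.
#' @return Data frame: `group` (`"all"` if ungrouped), `domain`, `freq_e`,
#'   `n`.
#' @export
e_frequency <- function(entries, groups = NULL) {
  if ("exclusion" %in% names(entries)) entries <- retained_entries(entries)
  if (is.null(groups)) groups <- rep("all", nrow(entries))
  stopifnot(length(groups) == nrow(entries))
  out <- list()
  for (g in unique(groups)) {
    e <- entries[groups == g, , drop = FALSE]
    for (d in 1:3) {
      calls <- e[[paste0("d", d)]]
      out[[length(out) + 1L]] <- data.frame(
        group = g, domain = d,
        freq_e = if (nrow(e)) mean(calls == "E") else NA_real_,
        n = nrow(e), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

# ---- position-frequency matrices ------------------------------------------

#' Build a position-frequency matrix from aligned sequences
#'
#' Per column, counts over the 20 residues plus gap, and the information
#' content in bits: `IC = log2(20) - H` where `H` is the Shannon entropy of
#' the residue frequencies (gaps are excluded from the frequency
#' normalisation and counted separately).
#'
#' @param seqs Character vector of equal-length aligned sequences.
#' @return Object of class `"pfm"`: list with `counts` (21 x L matrix, rows
#'   the residues and `-`), `ic` (per-column bits) and `n` (sequence count).
#' @export
build_pfm <- function(seqs) {
  seqs <- toupper(seqs)
  L <- unique(nchar(seqs))
  if (length(L) != 1L)
    stop("ragged alignment: lengths ", paste(nchar(seqs), collapse = ", "))
  chars <- vapply(seqs, function(s) strsplit(s, "")[[1]], character(L))
  chars <- matrix(chars, nrow = L)
  chars[!chars %in% c(.AA20, "-")] <- "-"
  counts <- vapply(seq_len(L), function(j)
    table(factor(chars[j, ], levels = c(.AA20, "-"))), integer(21))
  rownames(counts) <- c(.AA20, "-")
  ic <- vapply(seq_len(L), function(j) {
    cj <- counts[.AA20, j]
    tot <- sum(cj)
    if (!tot) return(0)
    f <- cj[cj > 0] / tot
    log2(20) + sum(f * log2(f))
  }, numeric(1))
  structure(list(counts = counts, ic = ic, n = length(seqs)),
            class = "pfm")
}

#' @export
print.pfm <- function(x, ...) {
  cat("pfm: ", ncol(x$counts), " columns from ", x$n, " sequences; IC ",
      sprintf("%.2f", min(x$ic)), "-", sprintf("%.2f", max(x$ic)),
      " bits\n", sep = "")
  invisible(x)
}

#' Write a position-frequency matrix as TSV
#'
#' @param pfm A [build_pfm()] result.
#' @param path Output path. Rows: residues (+ gap + IC); columns: positions.
#' @return `path`, invisibly.
#' @export
write_pfm <- function(pfm, path) {
  m <- rbind(pfm$counts, IC = round(pfm$ic, 6))
  utils::write.table(m, path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}

#' Write a survey table as TSV
#'
#' @param entries Survey table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_survey_table <- function(entries, path) {
  utils::write.table(as.data.frame(entries), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
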