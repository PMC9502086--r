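# Shared fixtures and independent oracles for the test suite.

fixture_alignment <- function() loopscan_example("aac1_domains_synthetic.afa")

fixture_sequence <- function() {
  as.character(Biostrings::readAAStringSet(
    loopscan_example("aac1_synthetic.fasta")))[[1]]
}

aac_map <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_triplet_map(fixture_alignment())
    cache
  }
})

aac_elements <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      hits <- suppressWarnings(annotate_mcf(fixture_sequence(), aac_map()))
      cache <<- derive_elements(aac_map(), hits)
    }
    cache
  }
})

# independent overlapping-match oracle via the PCRE engine
regex_scan_oracle <- function(seq, pattern, small = c("G", "A", "S", "C", "T")) {
  chars <- strsplit(pattern, "")[[1]]
  rx <- character(0)
  i <- 1
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "[") {
      j <- which(chars[i:length(chars)] == "]")[1] + i - 1
      rx <- c(rx, paste(chars[i:j], collapse = ""))
      i <- j + 1
    } else if (ch == "x") {
      rx <- c(rx, "."); i <- i + 1
    } else if (ch == "π") {
      rx <- c(rx, paste0("[", paste(small, collapse = ""), "]")); i <- i + 1
    } else {
      rx <- c(rx, ch); i <- i + 1
    }
  }
  m <- gregexpr(paste0("(?=", paste(rx, collapse = ""), ")"), seq,
                perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m)
}

# exhaustive pairwise minimum distance
brute_min_distance <- function(a, b) {
  best <- Inf
  for (i in seq_len(nrow(a)))
    for (j in seq_len(nrow(b)))
      best <- min(best, sqrt(sum((a[i, ] - b[j, ])^2)))
  best
}

# a small trajectory with explicit atoms and per-frame coordinates;
# coords is a list of n_atoms x 3 matrices (nm)
make_traj <- function(atoms, coords, frame_spacing = 10) {
  xyz <- t(vapply(coords, function(m) as.vector(t(m)),
                  numeric(3L * nrow(atoms))))
  trajectory(atoms, xyz, frame_spacing = frame_spacing)
}

# non-collinear CA scaffold used by geometry tests
ca_scaffold <- function(n, seed = 1) {
  withr::with_seed(seed, cbind(stats::rnorm(n), stats::rnorm(n),
                               stats::rnorm(n)))
}

random_protein <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}
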