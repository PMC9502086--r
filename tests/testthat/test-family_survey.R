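# [DE]G survey: per-domain calls, exclusions, E frequencies, PFMs.

helix_windows <- function(em) {
  em$elements[grepl("^h", em$elements$element), c("domain", "start", "end")]
}

test_that("the carrier fixture yields the published [DE]G calls", {
  calls <- locate_deg(fixture_sequence(), helix_windows(aac_elements()))
  expect_identical(calls$call, c("D", "D", "E"))
  expect_equal(calls$position, c(64, 167, 264))  # D167 and E264
  expect_true(all(calls$flag == "none"))
})

test_that("windows without a candidate fall back to 'other' with a warning", {
  w <- testthat::capture_warnings(
    calls <- locate_deg(strrep("A", 60),
                        data.frame(domain = 1:3, start = c(1, 21, 41),
                                   end = c(20, 40, 60))))
  expect_length(w, 3)  # one per domain
  expect_match(w, "no G-anchored", all = TRUE)
  expect_true(all(calls$call == "other"))
})

test_that("synthetic family calls reproduce generator truth exactly", {
  fam <- gen_family(n = 40, p_e = c(0.8, 0.3, 0.9), seed = 19)
  sv <- survey_family(fam$seqs, fam$windows,
                      outside_imm = character(0),
                      charged_second = character(0))
  expect_identical(sv$d1, fam$truth$d1)
  expect_identical(sv$d2, fam$truth$d2)
  expect_identical(sv$d3, fam$truth$d3)
  # frequency recovery is exact counting
  ef <- e_frequency(sv)
  expect_equal(ef$freq_e,
               c(mean(fam$truth$d1 == "E"), mean(fam$truth$d2 == "E"),
                 mean(fam$truth$d3 == "E")))
})

test_that("exclusion lists partition the family without losing entries", {
  fam <- gen_family(n = 53, planted_exclusions = unlist(mc_exclusions()),
                    seed = 23)
  sv <- survey_family(fam$seqs, fam$windows)
  expect_equal(nrow(sv), 53)
  expect_equal(nrow(retained_entries(sv)), 46)
  expect_setequal(sv$id[sv$exclusion != "none"], unlist(mc_exclusions()))

  # empty lists are the identity
  ident <- apply_exclusions(data.frame(id = c("A", "B")),
                            outside_imm = character(0),
                            charged_second = character(0))
  expect_true(all(ident$exclusion == "none"))

  # an entry on both lists is excluded once with both flags
  both <- suppressWarnings(apply_exclusions(
    data.frame(id = c("X", "Y")),
    outside_imm = "X", charged_second = c("X", "Y")))
  expect_equal(both$exclusion[both$id == "X"],
               "outside-IMM;charged-second-position")
  expect_equal(nrow(both[both$exclusion == "none", ]), 0)

  # absent listed names warn, not error
  expect_warning(apply_exclusions(data.frame(id = "A"),
                                  outside_imm = "MISSING",
                                  charged_second = character(0)),
                 "absent")
})

test_that("E frequencies count retained entries per domain", {
  entries <- data.frame(id = c("a", "b"),
                        d1 = c("E", "E"), d2 = c("D", "E"),
                        d3 = c("E", "E"))
  ef <- e_frequency(entries)
  expect_equal(ef$freq_e, c(1.0, 0.5, 1.0))
  alld <- data.frame(id = "z", d1 = "D", d2 = "D", d3 = "D")
  expect_equal(e_frequency(alld)$freq_e, c(0, 0, 0))
  # groups stratify
  g <- e_frequency(entries, groups = c("g1", "g2"))
  expect_equal(nrow(g), 6)
  expect_equal(g$freq_e[g$group == "g1" & g$domain == 2], 0)
})

test_that("planted family frequencies fall within the binomial envelope", {
  n <- 500; p <- c(0.8, 0.3, 0.9)
  fam <- gen_family(n = n, p_e = p, seed = 29)
  ef <- e_frequency(survey_family(fam$seqs, fam$windows,
                                  outside_imm = character(0),
                                  charged_second = character(0)))
  for (d in 1:3)
    expect_lte(abs(ef$freq_e[d] - p[d]), 3 * sqrt(p[d] * (1 - p[d]) / n))
})

test_that("position-frequency matrices conserve counts and bound IC", {
  # zero-entropy column
  pfm1 <- build_pfm(rep("W", 10))
  expect_equal(pfm1$ic, log2(20), tolerance = 1e-12)
  # uniform column over the 20 residues
  pfm0 <- build_pfm(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])
  expect_equal(pfm0$ic, 0, tolerance = 1e-12)
  expect_error(build_pfm(c("ACD", "AC")), "ragged")

  withr::with_seed(41, {
    seqs <- replicate(30, random_protein(25))
    # a gappy column: gaps counted separately, excluded from frequencies
    substr(seqs[1:10], 3, 3) <- "-"
    pfm <- build_pfm(seqs)
    expect_true(all(colSums(pfm$counts) == 30))
    expect_equal(unname(pfm$counts["-", 3]), 10)
    expect_true(all(pfm$ic >= 0 & pfm$ic <= log2(20) + 1e-12))
    # independent entropy oracle
    for (j in seq_len(25)) {
      col <- substr(seqs, j, j)
      col <- col[col != "-"]
      f <- table(col) / length(col)
      oracle <- log2(20) + sum(f * log2(f))
      expect_equal(pfm$ic[j], oracle, tolerance = 1e-9)
    }
  })
})
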