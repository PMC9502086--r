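# Triplet mapping between symmetric positions of the three domains.

test_that("the packaged carrier alignment maps the landmark triplets", {
  map <- aac_map()
  expect_true(validate_triplet_anchors(map))
  expect_equal(unname(triplet_partners(map, 37)), c(37, 142, 239))
  expect_equal(unname(triplet_partners(map, 38)), c(38, 143, 240))
  expect_equal(unname(triplet_partners(map, 50)), c(50, 153, 250))
  expect_equal(unname(triplet_partners(map, 30)), c(30, 139, 236))
  expect_equal(unname(triplet_partners(map, 65)), c(65, 168, 265))

  r236 <- map_residue(map, 236)
  expect_equal(c(r236$domain, r236$triplet), c(3, 30))
  r167 <- map_residue(map, 167)
  expect_equal(c(r167$domain, r167$triplet), c(2, 64))
  r38 <- map_residue(map, 38)
  expect_equal(c(r38$domain, r38$triplet), c(1, 38))
})

test_that("a gap-free repeat alignment has constant offsets", {
  s <- "ACDEFGHIKL"
  map <- build_triplet_map(c(a = s, b = s, c = s), domain_starts = 1)
  for (t in 1:10)
    expect_equal(unname(triplet_partners(map, t)), c(t, t + 10, t + 20))
})

test_that("domain-1 gap columns are labelled as intervals, not triplets", {
  map <- aac_map()
  g <- map$columns[map$columns$gapped, ]
  expect_equal(nrow(g), 4)  # the insertion between triplets 27 and 28
  expect_true(all(g$label == "between 27 and 28"))
  r133 <- map_residue(map, 133)
  expect_equal(r133$domain, 2)
  expect_true(r133$gapped)
  expect_true(is.na(r133$triplet))
})

test_that("map_residue and triplet_partners are mutually inverse and injective", {
  sim <- gen_tripartite_sequence(sequence_scenario(
    domain_len = 60, indels = data.frame(domain = c(2, 1), after = c(15, 50),
                                         len = c(3, 2)), seed = 21))
  for (map in list(aac_map(), build_triplet_map(sim$alignment))) {
    cols <- map$columns
    # injectivity: every residue appears in exactly one column
    for (d in 1:3) {
      res <- cols[[paste0("res_d", d)]]
      expect_false(anyDuplicated(res[!is.na(res)]) > 0)
    }
    # round trip over all covered residues
    for (d in 1:3) {
      for (r in stats::na.omit(cols[[paste0("res_d", d)]])) {
        mr <- map_residue(map, r)
        expect_equal(mr$domain, d)
        if (!mr$gapped)
          expect_equal(unname(triplet_partners(map, mr$triplet)[d]), r)
      }
    }
  }
})

test_that("map_residue agrees with a brute-force column scan", {
  sim <- gen_tripartite_sequence(sequence_scenario(
    domain_len = 50, indels = data.frame(domain = 3, after = 20, len = 4),
    seed = 8))
  map <- build_triplet_map(sim$alignment)
  rows <- lapply(sim$alignment, function(s) strsplit(s, "")[[1]])
  starts <- map$domain_spans$start
  # brute force: walk each row, count residues, record the column's triplet
  for (d in 1:3) {
    resno <- starts[d] - 1L
    for (col in seq_along(rows[[d]])) {
      if (rows[[d]][col] == "-") next
      resno <- resno + 1L
      expected_triplet <- map$columns$triplet[col]
      got <- map_residue(map, resno)
      expect_equal(got$domain, d)
      expect_equal(got$triplet, expected_triplet)
    }
  }
})

test_that("malformed alignments are rejected", {
  expect_error(build_triplet_map(c("ACD", "ACD")), "exactly 3")
  expect_error(build_triplet_map(c("ACD", "AC", "ACD")), "differ in length")
  # overlapping residue numbering across domains
  expect_error(build_triplet_map(c("ACD", "ACD", "ACD"),
                                 domain_starts = c(1, 2, 10)),
               "overlap")
  expect_error(map_residue(aac_map(), 300), "outside the aligned span")
  expect_error(triplet_partners(aac_map(), 99), "unknown triplet")
})

test_that("element derivation reproduces the carrier's loop boundaries", {
  em <- aac_elements()
  e <- em$elements
  m1 <- e[e$element == "M1", ]
  expect_equal(c(m1$start, m1$end), c(38, 49))   # loop N-end at triplet 38
  h12 <- e[e$element == "h12", ]
  expect_equal(c(h12$start, h12$end), c(50, 65)) # Y50 beta-turn .. G of [DE]G
  m3 <- e[e$element == "M3", ]
  expect_equal(c(m3$start, m3$end), c(240, 249))
  h56 <- e[e$element == "h56", ]
  expect_equal(c(h56$start, h56$end), c(250, 265))
})

test_that("element derivation matches generator ground truth", {
  sim <- gen_tripartite_sequence(sequence_scenario(domain_len = 70, seed = 4))
  map <- build_triplet_map(sim$alignment)
  hits <- suppressWarnings(annotate_mcf(
    as.list(sim$domains), map, anchors = sim$truth$anchor_triplets))
  em <- derive_elements(map, hits)
  got <- em$elements[order(em$elements$domain, em$elements$start), ]
  want <- sim$truth$elements[order(sim$truth$elements$domain,
                                   sim$truth$elements$start), ]
  expect_equal(got$start, want$start)
  expect_equal(got$end, want$end)
  expect_equal(got$element, want$element)
})

test_that("missing anchor motifs abort element derivation with their names", {
  map <- aac_map()
  hits <- suppressWarnings(annotate_mcf(fixture_sequence(), map))
  expect_error(derive_elements(map, hits[hits$motif != "yxg", ]),
               "yxg/domain1")
})
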