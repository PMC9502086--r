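# Contact enumeration, occupancy, threshold filtering, taxonomy.

two_atom_traj <- function(dists) {
  atoms <- data.frame(name = c("N", "O"), resname = c("ALA", "ALA"),
                      resno = c(1, 3), chain = "A")
  make_traj(atoms, lapply(dists, function(d)
    rbind(c(0, 0, 0), c(0, 0, d))))
}

test_that("min_distance takes the minimum over the atom-set product", {
  expect_equal(min_distance(rbind(c(0, 0, 0)), rbind(c(0, 0, 0.3))), 0.3)
  expect_equal(min_distance(rbind(c(0, 0, 0)),
                            rbind(c(0, 0, 0.5), c(0, 0, 0.2))), 0.2)
  expect_error(min_distance(matrix(0, 0, 3), rbind(c(0, 0, 0))), "empty")
  withr::with_seed(5, {
    for (rep in 1:20) {
      a <- matrix(rnorm(15), 5, 3)
      b <- matrix(rnorm(21), 7, 3)
      expect_equal(min_distance(a, b), brute_min_distance(a, b))
    }
  })
})

test_that("occupancy counts window frames at the inclusive cutoff", {
  traj <- two_atom_traj(rep(c(0.30, 0.40), 5))
  spec <- list(resno_a = 1, atoms_a = "N", resno_b = 3, atoms_b = "O")
  expect_equal(occupancy(traj, spec), 50)
  expect_equal(occupancy(two_atom_traj(rep(0.33, 4)), spec), 100)  # boundary
  expect_equal(occupancy(two_atom_traj(rep(0.331, 4)), spec), 0)
  expect_error(occupancy(traj, spec, window = trailing_window(last_ps = 0)),
               "no frames")
  # trailing fraction
  traj2 <- two_atom_traj(c(0.4, 0.4, 0.3, 0.3))
  expect_equal(occupancy(traj2, spec,
                         window = trailing_window(fraction = 0.5)), 100)
})

test_that("occupancy is monotone in the cutoff and bounded", {
  withr::with_seed(11, {
    traj <- two_atom_traj(runif(50, 0.2, 0.5))
    spec <- list(resno_a = 1, atoms_a = "N", resno_b = 3, atoms_b = "O")
    occ <- vapply(seq(0.2, 0.5, by = 0.02), function(cut)
      occupancy(traj, spec, cutoff = cut), numeric(1))
    expect_true(all(diff(occ) >= 0))
    expect_true(all(occ >= 0 & occ <= 100))
    expect_equal(occupancy(traj, spec, cutoff = 0.51), 100)
  })
})

# independent frame-counting oracle: direct coordinate arithmetic per frame
count_contacts_oracle <- function(traj, resno_a, atoms_a, resno_b, atoms_b,
                                  cutoff) {
  ia <- which(traj$atoms$resno == resno_a & traj$atoms$name %in% atoms_a)
  ib <- which(traj$atoms$resno == resno_b & traj$atoms$name %in% atoms_b)
  hits <- 0L
  for (f in seq_len(n_frames(traj))) {
    m <- frame_coords(traj, f)
    if (brute_min_distance(m[ia, , drop = FALSE],
                           m[ib, , drop = FALSE]) <= cutoff)
      hits <- hits + 1L
  }
  hits
}

test_that("the occupancy estimator tracks the telegraph duty cycle", {
  grid <- expand.grid(p = c(0.25, 0.67), phi = c(0, 0.5))
  n <- 2000
  for (g in seq_len(nrow(grid))) {
    p <- grid$p[g]; phi <- grid$phi[g]
    errs <- numeric(5)
    for (s in 1:5) {
      sim <- gen_contact_trajectory(contact_scenario(
        p = p, phi = phi, n_frames = n, seed = 1000 * g + s))
      spec <- sim$truth$specs[1, ]
      occ <- occupancy(sim$trajectory, spec)
      errs[s] <- abs(occ / 100 - p)
      # exact agreement with the frame-counting oracle
      expect_equal(occ, 100 * count_contacts_oracle(
        sim$trajectory, spec$resno_a, spec$atoms_a[[1]],
        spec$resno_b, spec$atoms_b[[1]], 0.33) / n)
    }
    n_eff <- n * (1 - phi) / (1 + phi)
    expect_lte(mean(errs), 3 * sqrt(p * (1 - p) / n_eff))
  }
})

test_that("pair enumeration covers the screened regions with correct specs", {
  em <- aac_elements()
  # an Arg-30 / Ala-141 pair in range: side chain to backbone contact
  sim <- gen_contact_trajectory(contact_scenario(
    pairs = data.frame(res_a = "ARG", res_b = "ALA",
                       resno_a = 30, resno_b = 141, p = 1),
    n_frames = 3, seed = 2))
  specs <- enumerate_pairs(sim$trajectory, em)
  expect_true("R30:A141(O)" %in% specs$label)
  expect_true(all(specs$category == "inter-domain"))
  expect_true(all(specs$interface == "1-2"))

  # glycines offer only backbone donors/acceptors
  gsim <- gen_contact_trajectory(contact_scenario(
    pairs = data.frame(res_a = "GLY", res_b = "GLY",
                       resno_a = 144, resno_b = 148, p = 1),
    n_frames = 3, seed = 3))
  gspecs <- enumerate_pairs(gsim$trajectory, em)
  expect_gt(nrow(gspecs), 0)
  expect_true(all(gspecs$ctx_a %in% c("O", "NH")))
  expect_true(all(gspecs$ctx_b %in% c("O", "NH")))
  expect_true(all(gspecs$kind == "H-bond"))
})

test_that("pair enumeration equals a brute-force all-pairs oracle", {
  em <- aac_elements()
  # ten residues parked inside M3/h56 at mutual distances ~0.4 nm
  resnos <- 240:249
  resnames <- c("ARG", "GLU", "SER", "GLY", "LYS", "ASP", "GLN", "ALA",
                "THR", "ASN")
  atoms <- do.call(rbind, lapply(seq_along(resnos), function(i)
    data.frame(name = residue_atoms(resnames[i]), resname = resnames[i],
               resno = resnos[i], chain = "A")))
  withr::with_seed(17, {
    centers <- matrix(rnorm(length(resnos) * 3, sd = 0.15),
                      length(resnos), 3)
    coords <- do.call(rbind, lapply(seq_along(resnos), function(i) {
      k <- length(residue_atoms(resnames[i]))
      sweep(matrix(rnorm(k * 3, sd = 0.03), k, 3), 2, centers[i, ], `+`)
    }))
  })
  traj <- make_traj(atoms, list(coords))
  specs <- suppressWarnings(enumerate_pairs(traj, em,
                                            max_residue_distance = 0.5))
  # oracle: direct double loop over residues and contexts
  ctxs <- function(rn, resno) {
    out <- list()
    nm <- residue_atoms(rn)
    out$O <- list(atoms = "O", donor = FALSE, acceptor = TRUE)
    if (rn != "PRO") out$NH <- list(atoms = "N", donor = TRUE,
                                    acceptor = FALSE)
    don <- sidechain_polar_atoms(rn, "donor")
    acc <- sidechain_polar_atoms(rn, "acceptor")
    if (length(union(don, acc)))
      out$sidechain <- list(atoms = union(don, acc),
                            donor = length(don) > 0,
                            acceptor = length(acc) > 0)
    out
  }
  expected <- character(0)
  for (i in 1:9) for (j in (i + 1):10) {
    ia <- which(atoms$resno == resnos[i]); ib <- which(atoms$resno == resnos[j])
    if (brute_min_distance(coords[ia, , drop = FALSE],
                           coords[ib, , drop = FALSE]) > 0.5) next
    cls <- classify_residue_pair(resnos[i], resnos[j], em)
    if (cls$category == "other") next
    for (ca in names(ctxs(resnames[i]))) for (cb in names(ctxs(resnames[j]))) {
      A <- ctxs(resnames[i])[[ca]]; B <- ctxs(resnames[j])[[cb]]
      if (!((A$donor && B$acceptor) || (A$acceptor && B$donor))) next
      if (abs(resnos[i] - resnos[j]) <= 1 && ca != "sidechain" &&
          cb != "sidechain") next
      expected <- c(expected, format_interaction_label(
        resnames[i], resnos[i], ca, resnames[j], resnos[j], cb))
    }
  }
  expect_setequal(specs$label, expected)
})

test_that("the strict 25% threshold separates the published example rows", {
  records <- data.frame(
    label = c("V37(O):A40(NH)", "V37(O):S41(NH)"),
    resno_a = c(37, 37), resno_b = c(40, 41),
    occ_1 = c(76, 8), occ_2 = c(58, 14), occ_3 = c(66, 12),
    category = "other", stringsAsFactors = FALSE)
  kept <- filter_and_classify(records, threshold = 25)
  expect_identical(kept$label, "V37(O):A40(NH)")
  expect_equal(kept$average, (76 + 58 + 66) / 3)
  # printed averages use round-half-up: 66.67 -> 67, 11.33 -> 11
  tab <- records
  tab$average <- rowMeans(tab[, c("occ_1", "occ_2", "occ_3")])
  out <- withr::local_tempfile(fileext = ".tsv")
  write_occupancy_table(tab, out)
  printed <- utils::read.delim(out)
  expect_equal(printed$average, c(67, 11))
  # exactly at the threshold is rejected ("higher than" is strict)
  at25 <- records[1, ]; at25[, c("occ_1", "occ_2", "occ_3")] <- 25
  expect_equal(nrow(filter_and_classify(at25, threshold = 25)), 0)
})

test_that("classification is a total partition over the taxonomy", {
  em <- aac_elements()
  expect_equal(classify_residue_pair(167, 241, em)$interface, "2-3")
  expect_equal(classify_residue_pair(40, 45, em)$category, "intra-loop")
  expect_equal(classify_residue_pair(245, 255, em)$category, "loop-helix")
  expect_equal(classify_residue_pair(30, 250, em)$interface, "3-1")
  expect_equal(classify_residue_pair(30, 36, em)$category, "other")
  expect_warning(cls <- classify_residue_pair(30, 300, em), "not covered")
  expect_equal(cls$category, "other")
  withr::with_seed(9, {
    cats <- c("intra-loop", "loop-helix", "inter-domain", "other")
    for (rep in 1:50) {
      pair <- sample(27:265, 2)
      got <- suppressWarnings(classify_residue_pair(pair[1], pair[2], em))
      expect_true(got$category %in% cats)
      expect_length(got$category, 1)
    }
  })
})

test_that("interface strength totals are exhaustive and ordered", {
  empty <- interface_strength(data.frame())
  expect_equal(nrow(empty), 9)
  expect_true(all(empty$total_occupancy == 0) && all(empty$n == 0))

  one <- data.frame(resno_a = 167, resno_b = 241, average = 80,
                    category = "inter-domain", interface = "2-3")
  s <- interface_strength(one)
  cell <- s[s$category == "inter-domain" & s$unit == "2-3", ]
  expect_equal(cell$total_occupancy, 80)
  expect_equal(cell$n, 1)
  expect_equal(sum(s$n), 1)
})

test_that("planted interface asymmetry is recovered from a trajectory", {
  sim <- gen_tripartite_sequence(sequence_scenario(domain_len = 60,
                                                   seed = 11))
  map <- build_triplet_map(sim$alignment)
  hits <- suppressWarnings(annotate_mcf(as.list(sim$domains), map,
                                        anchors = sim$truth$anchor_triplets))
  em <- derive_elements(map, hits)
  pairs <- data.frame(res_a = c("ARG", "LYS", "ARG"),
                      res_b = c("GLU", "ASP", "GLU"),
                      resno_a = c(80, 22, 150), resno_b = c(140, 95, 30),
                      p = c(0.9, 0.35, 0.30), phi = 0.2)
  csim <- gen_contact_trajectory(contact_scenario(pairs = pairs,
                                                  n_frames = 800, seed = 77))
  specs <- enumerate_pairs(csim$trajectory, em)
  tab <- occupancy_table(csim$trajectory, specs)
  kept <- filter_and_classify(tab, 25, em)
  s <- interface_strength(kept, em)
  inter <- s[s$category == "inter-domain", ]
  t23 <- inter$total_occupancy[inter$unit == "2-3"]
  expect_true(all(t23 > inter$total_occupancy[inter$unit != "2-3"]))
})
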