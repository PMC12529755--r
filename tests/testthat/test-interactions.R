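chem <- residue_chemistry()

test_that("salt-bridge rule flips at 6 A and gates on a basic/acidic partnering", {
  lys_at <- function(x) res_view("LYS", NZ = c(x, 0, 0))
  glu <- res_view("GLU", OE1 = c(0, 0, 0), OE2 = c(0, -1.2, 0))
  expect_true(detect_salt_bridge(lys_at(5.9), glu, chem = chem))
  expect_true(detect_salt_bridge(lys_at(6.0), glu, chem = chem))   # inclusive
  expect_false(detect_salt_bridge(lys_at(6.1), glu, chem = chem))
  # order-independent
  expect_true(detect_salt_bridge(glu, lys_at(5.9), chem = chem))
  # two basic residues: no acidic partner
  arg <- res_view("ARG", NH1 = c(3, 0, 0))
  expect_false(detect_salt_bridge(lys_at(0), arg, chem = chem))
  # truncated side chain: named atoms missing
  bare_lys <- res_view("LYS", CB = c(0, 0, 0))
  expect_warning(ok <- detect_salt_bridge(bare_lys, glu, chem = chem),
                 "missing")
  expect_false(ok)
})

test_that("hydrogen-bond rule flips at 3.5 A and 30 degrees deviation", {
  # donor D at origin, H at (1,0,0); placing the acceptor at
  # H + r*(cos a, sin a, 0) makes the deviation from linearity exactly a
  hb <- function(dev_deg, r = 2.5) {
    a <- dev_deg * pi / 180
    ser <- res_view("SER", OG = c(0, 0, 0), HG = c(1, 0, 0))
    asn <- res_view("ASN", OD1 = c(1 + r * cos(a), r * sin(a), 0))
    detect_hbond(ser, asn, chem = chem)
  }
  expect_true(hb(20))                        # d = 3.46 A, dev 20
  expect_false(hb(35))                       # d = 3.37 A, dev 35: angle gate
  expect_true(hb(29.9))
  expect_false(hb(30.1))
  expect_false(hb(0, r = 2.6))               # d = 3.6 A: distance gate
  expect_true(hb(0, r = 2.4))                # d = 3.4 A, linear
  # donor without hydrogens is skipped with a warning
  ser_noH <- res_view("SER", OG = c(0, 0, 0))
  asn <- res_view("ASN", OD1 = c(3, 0, 0))
  expect_warning(ok <- detect_hbond(ser_noH, asn, chem = chem), "no hydrogens")
  expect_false(ok)
})

test_that("hydrophobic rule flips at 8 A on side-chain carbons; GLY never matches", {
  leu_at <- function(x) res_view("LEU", CD1 = c(x, 0, 0))
  val <- res_view("VAL", CG1 = c(0, 0, 0))
  expect_true(detect_hydrophobic(leu_at(7.9), val, chem = chem))
  expect_false(detect_hydrophobic(leu_at(8.1), val, chem = chem))
  gly <- res_view("GLY", CA = c(0, 0, 0))
  expect_false(detect_hydrophobic(gly, leu_at(1), chem = chem))
})

test_that("repulsion rule: like-charge within 12 A, else hydrophobic-polar, else none", {
  lys_at <- function(x) res_view("LYS", NZ = c(x, 0, 0), CB = c(x, 0, 1),
                                 CG = c(x, 0, 2), CD = c(x, 0, 3),
                                 CE = c(x, 0, 4))
  arg <- res_view("ARG", NH1 = c(0, 0, 0))
  expect_equal(detect_repulsion(lys_at(11), arg, chem = chem), "same_charge")
  expect_equal(detect_repulsion(lys_at(12.01), arg, chem = chem), "none")
  glu_at <- function(x) res_view("GLU", OE1 = c(x, 0, 0))
  asp <- res_view("ASP", OD1 = c(0, 0, 0))
  expect_equal(detect_repulsion(glu_at(12.5), asp, chem = chem), "none")
  expect_equal(detect_repulsion(glu_at(11.5), asp, chem = chem), "same_charge")
  leu_at <- function(x) res_view("LEU", CD1 = c(x, 0, 0))
  expect_equal(detect_repulsion(leu_at(10), lys_at(0), chem = chem),
               "hydrophobic_polar")
  expect_equal(detect_repulsion(leu_at(12.2), lys_at(0), chem = chem), "none")
  # same-charge takes precedence when both clauses hold
  expect_equal(detect_repulsion(lys_at(10), arg, chem = chem), "same_charge")
  # aromatic residues are not aliphatic for this clause
  phe <- res_view("PHE", CZ = c(10, 0, 0))
  expect_equal(detect_repulsion(phe, lys_at(0), chem = chem), "none")
})

test_that("vectorized frequency engine agrees frame-by-frame with the detectors", {
  traj <- generate_allatom_interface(ALL_MOTIFS, occupancy = 0.37,
                                     n_frames = 40, seed = 14)
  gt <- attr(traj, "ground_truth")
  pairs <- data.frame(res_i = gt$res_i, res_j = gt$res_j,
                      C = gt$sign, stringsAsFactors = FALSE)
  fq <- suppressWarnings(compute_frequencies(traj, pairs, all_types = TRUE))
  for (key in names(fq$per_frame)) {
    parts <- strsplit(key, "|", fixed = TRUE)[[1]]
    oracle <- vapply(seq_len(traj$n_frames), function(f) {
      ri <- residue_frame(traj, f, parts[1])
      rj <- residue_frame(traj, f, parts[2])
      switch(parts[3],
        salt_bridge = detect_salt_bridge(ri, rj, chem = chem),
        hydrogen_bond = detect_hbond(ri, rj, chem = chem),
        hydrophobic = detect_hydrophobic(ri, rj, chem = chem),
        repulsion_same_charge =
          detect_repulsion(ri, rj, chem = chem) == "same_charge",
        repulsion_hydrophobic_polar = {
          # clause (ii) evaluated on its own, as in the per-type map
          r <- covcontact:::series_repulsion_hp(
            traj$xyz[f, , drop = FALSE],
            covcontact:::pair_context(traj, parts[1], parts[2]),
            12, chem)
          r[1]
        })
    }, logical(1))
    expect_identical(unname(fq$per_frame[[key]]), oracle, label = key)
  }
})

test_that("occupancies: planted fractions are reported exactly, map holds the max", {
  traj <- generate_allatom_interface(ALL_MOTIFS, occupancy = 0.5,
                                     n_frames = 8000, seed = 2)
  gt <- attr(traj, "ground_truth")
  pairs <- data.frame(res_i = gt$res_i, res_j = gt$res_j, C = gt$sign,
                      stringsAsFactors = FALSE)
  fq <- compute_frequencies(traj, pairs)
  for (k in seq_len(nrow(gt))) {
    r <- fq$records[fq$records$res_i == gt$res_i[k] &
                    fq$records$itype == gt$itype[k], ]
    expect_equal(r$frequency_pct, 50.0)
    expect_equal(r$n_true, 4000L)
  }
  expect_true(all(fq$records$frequency_pct >= 0 &
                  fq$records$frequency_pct <= 100))
  expect_equal(fq$map$combined,
               Reduce(pmax, fq$map$per_type))
  # all-zero record rows stay in the records but not in the map
  zero <- fq$records[fq$records$frequency_pct == 0, ]
  expect_gt(nrow(zero), 0)
  for (k in seq_len(nrow(zero)))
    expect_equal(fq$map$per_type[[zero$itype[k]]][zero$res_i[k], zero$res_j[k]], 0)
})

test_that("extreme occupancies give exactly 0 and 100 percent", {
  traj <- generate_allatom_interface(c("salt_bridge", "hbond"),
                                     occupancy = c(1, 0), n_frames = 50,
                                     seed = 4)
  gt <- attr(traj, "ground_truth")
  pairs <- data.frame(res_i = gt$res_i, res_j = gt$res_j, C = gt$sign,
                      stringsAsFactors = FALSE)
  fq <- compute_frequencies(traj, pairs)
  sb <- fq$records[fq$records$itype == "salt_bridge" &
                   fq$records$res_i == gt$res_i[1], ]
  hb <- fq$records[fq$records$itype == "hydrogen_bond" &
                   fq$records$res_i == gt$res_i[2], ]
  expect_equal(sb$frequency_pct, 100.0)
  expect_equal(hb$frequency_pct, 0.0)
})

test_that("hbond frequency tracks a deviation ramp across frames", {
  devs <- seq(0, 60, length.out = 25)
  freq <- mean(vapply(devs, function(a) {
    rad <- a * pi / 180
    ser <- res_view("SER", OG = c(0, 0, 0), HG = c(1, 0, 0))
    asn <- res_view("ASN", OD1 = c(1 + 2.4 * cos(rad), 2.4 * sin(rad), 0))
    detect_hbond(ser, asn, chem = chem)
  }, logical(1)))
  expect_equal(freq, mean(devs <= 30))
})

test_that("enlarging any cutoff never decreases a frequency", {
  traj <- generate_allatom_interface(ALL_MOTIFS, occupancy = 0.6,
                                     n_frames = 60, seed = 6,
                                     wobble_sigma_A = 0.8,
                                     jitter_sigma_A = 0.3)
  gt <- attr(traj, "ground_truth")
  pairs <- data.frame(res_i = gt$res_i, res_j = gt$res_j, C = gt$sign,
                      stringsAsFactors = FALSE)
  base <- suppressWarnings(compute_frequencies(traj, pairs, all_types = TRUE))
  for (grow in c("salt_bridge_A", "hbond_dist_A", "hbond_angle_deg",
                 "hydrophobic_A", "repulsion_A")) {
    cu <- interaction_cutoffs()
    cu[[grow]] <- cu[[grow]] * 1.5
    big <- suppressWarnings(compute_frequencies(traj, pairs,
                                                cutoffs = cu,
                                                all_types = TRUE))
    expect_true(all(big$records$frequency_pct >= base$records$frequency_pct),
                label = grow)
  }
})

test_that("brute force contains the filtered workflow's detections exactly", {
  traj <- generate_allatom_interface(ALL_MOTIFS, occupancy = 0.5,
                                     n_frames = 100, seed = 10)
  ca <- select_representation(traj, "calpha")
  ncov <- normalize_covariance(compute_covariance(ca))
  ccm <- apply_close_contact_filter(ncov)
  pairs <- enumerate_contact_pairs(ccm)
  fq <- compute_frequencies(traj, pairs)
  bf <- brute_force_scan(traj)
  for (t in names(fq$map$per_type)) {
    m <- fq$map$per_type[[t]]
    nz <- which(m > 0, arr.ind = TRUE)
    if (!nrow(nz)) next
    expect_identical(m[nz], bf$map$per_type[[t]][nz], label = t)
  }
  # empty selection on one side: empty map, no error
  empty <- traj
  empty$atoms$protein_tag[empty$atoms$protein_tag == "protein2"] <- "protein1"
  bf0 <- brute_force_scan(empty)
  expect_equal(nrow(bf0$records), 0L)
})

test_that("missing residues and cross-sign gating are reported", {
  traj <- generate_allatom_interface("salt_bridge", n_frames = 10, seed = 1)
  bad <- data.frame(res_i = "A:9:LYS", res_j = "B:1:GLU", C = 1)
  expect_error(compute_frequencies(traj, bad), "A:9:LYS")
  gt <- attr(traj, "ground_truth")
  flip <- data.frame(res_i = gt$res_i, res_j = gt$res_j, C = -1)
  expect_warning(compute_frequencies(traj, flip, all_types = TRUE),
                 "opposite")
})
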