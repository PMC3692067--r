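# Structure I/O, backbone reconstruction and feature assignment

test_that("PDB round-trip preserves residues, order and coordinates", {
  s <- make_ideal_structure("mixed", 35, seed = 4)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(s, path)
  s2 <- read_pdb(path)
  expect_equal(n_residues(s2), n_residues(s))
  expect_equal(residue_letters(s2), residue_letters(s))
  expect_equal(s2$atoms$elety, s$atoms$elety)
  expect_equal(as.matrix(s2$atoms[, c("x", "y", "z")]),
               as.matrix(s$atoms[, c("x", "y", "z")]),
               tolerance = 1e-3, ignore_attr = TRUE)
})

test_that("scaffold length gate rejects 29 residues and accepts 30", {
  s30 <- make_ideal_structure("helix_bundle", 30, seed = 1)
  p30 <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(s30, p30)
  expect_equal(n_residues(read_pdb(p30)), 30L)

  bb <- profdesign:::build_backbone_from_torsions(rep(-62, 29), rep(-41, 29))
  s29 <- profdesign:::structure_from_backbone(bb, rep("A", 29))
  p29 <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(s29, p29)
  expect_error(read_pdb(p29), "too short")
})

test_that("hetero atoms are collected and waters excluded", {
  s <- make_ideal_structure("helix_bundle", 30, seed = 2)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(s, path)
  lines <- readLines(path)
  het <- c(
    "HETATM 9991 FE   HEM A 900      10.000  10.000  10.000  1.00  0.00          FE",
    "HETATM 9992 ZN   ZN  A 901      12.000  10.000  10.000  1.00  0.00          ZN",
    "HETATM 9993  O   HOH A 902      14.000  10.000  10.000  1.00  0.00           O")
  writeLines(append(lines, het, after = grep("^END", lines)[1] - 1), path)
  s2 <- read_pdb(path)
  expect_equal(nrow(s2$het), 2L)
})

test_that("CA-only detection follows the all-residues-complete rule", {
  full <- ideal_helix(20)
  expect_false(is_ca_only(full))
  expect_true(is_ca_only(ca_only_copy(full)))
  mixed <- full
  drop <- which(mixed$atoms$elety == "N" & mixed$atoms$res_idx == 5)
  mixed <- profdesign:::new_structure(mixed$atoms[-drop, ])
  expect_true(is_ca_only(mixed))
})

test_that("backbone reconstruction places ideal bonds and is idempotent", {
  ca <- ca_only_copy(ideal_helix(20))
  rec <- reconstruct_backbone(ca)
  expect_false(is_ca_only(rec))
  bb <- profdesign:::get_backbone(rec)
  n_ca <- sqrt(rowSums((bb$N - bb$CA)^2))
  expect_true(all(abs(n_ca - 1.46) < 0.1))
  expect_equal(bb$CA, profdesign:::get_ca(ca))
  # idempotent and identity on full-backbone input
  expect_identical(reconstruct_backbone(rec), rec)
  full <- ideal_helix(15)
  expect_identical(reconstruct_backbone(full), full)
  # too-short trace
  two <- ca_only_copy(ideal_helix(5))
  two$atoms <- two$atoms[1:2, ]; two$aa <- two$aa[1:2]
  two$resno <- two$resno[1:2]; two$icode <- two$icode[1:2]
  expect_error(reconstruct_backbone(two), "underdetermined")
})

test_that("helical structures are assigned mostly H, strand pairs E", {
  f <- assign_features(ideal_helix(20))
  expect_gte(mean(f$ss[2:19] == "H"), 0.8)
  sheet <- make_paired_strands(8)
  fs <- assign_features(sheet)
  expect_true(all(fs$ss[c(4:6, 12:14)] == "E"))
})

test_that("terminal torsions are undefined, interior ones near ideal", {
  f <- assign_features(ideal_helix(12))
  expect_true(is.na(f$phi[1]))
  expect_true(is.na(f$psi[12]))
  expect_equal(f$phi[5], -62, tolerance = 1)
  expect_equal(f$psi[5], -41, tolerance = 1)
})

test_that("features are invariant under rigid-body superposition", {
  s <- make_ideal_structure("mixed", 34, seed = 9)
  f1 <- assign_features(s)
  f2 <- assign_features(transform_structure(s))
  expect_identical(f1$ss, f2$ss)
  expect_equal(f1$rsa, f2$rsa, tolerance = 1e-6)
  expect_equal(f1$phi, f2$phi, tolerance = 1e-6)
  expect_equal(f1$psi, f2$psi, tolerance = 1e-6)
})

test_that("buried residues get lower relative accessibility than free termini", {
  sheet <- make_paired_strands(8)
  f <- assign_features(sheet)
  expect_lt(min(f$rsa[4:6]), f$rsa[1])
  expect_true(all(f$rsa >= 0 & f$rsa <= 1))
})

test_that("binding-site residues follow the any-atom distance rule", {
  s <- ideal_helix(20)
  ca <- profdesign:::get_ca(s)
  # hetero atom exactly 7.9 A from residue 1's CA along x, far from others?
  # place it 7.9 from residue 10 CA instead, then check inclusion/exclusion
  # radii around the stated 8 A boundary
  probe <- ca[10, ] + c(7.9, 0, 0)
  d_all <- apply(s$atoms[, c("x", "y", "z")], 1,
                 function(p) sqrt(sum((p - probe)^2)))
  s$het <- data.frame(elety = "FE", resid = "HEM",
                      x = probe[1], y = probe[2], z = probe[3])
  bs <- binding_site_residues(s, radius = 8)
  expect_true(10L %in% bs)
  included <- sort(unique(s$atoms$res_idx[d_all <= 8 + 1e-9]))
  expect_equal(sort(unname(bs)), included)
  # boundary: a residue whose closest atom sits beyond the radius is excluded
  min_d10 <- min(d_all[s$atoms$res_idx == 10])
  expect_false(10L %in% binding_site_residues(s, radius = min_d10 - 0.2))
  s$het <- profdesign:::empty_het()
  expect_length(binding_site_residues(s, radius = 8), 0L)
})
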