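test_that("virtual_cbeta has the ideal geometry and L-chirality", {
  n <- c(0, 0, 0)
  ca <- c(1.458, 0, 0)
  ang <- 111.2 * pi / 180
  c_pos <- ca + 1.525 * c(cos(pi - ang), sin(pi - ang), 0)
  cb <- virtual_cbeta(n, ca, c_pos)
  expect_equal(sqrt(sum((cb - ca)^2)), 1.522, tolerance = 1e-6)
  cosang <- sum((n - ca) * (cb - ca)) /
    (sqrt(sum((n - ca)^2)) * sqrt(sum((cb - ca)^2)))
  expect_equal(acos(cosang) * 180 / pi, 110.4, tolerance = 1e-6)
  # L-chirality: positive signed volume of (N-CA, C-CA, CB-CA)
  expect_gt(det(cbind(n - ca, c_pos - ca, cb - ca)), 0)
})

test_that("virtual_cbeta is rigid-equivariant and rejects degenerate frames", {
  set.seed(3)
  for (i in 1:10) {
    n <- rnorm(3); ca <- n + rnorm(3); c_pos <- ca + rnorm(3)
    if (vec_len <- sqrt(sum((c_pos - ca)^2)) < 0.5) next
    rigid <- random_rigid(i)
    cb <- virtual_cbeta(n, ca, c_pos)
    move <- function(p) as.numeric(rigid$rotation %*% p + rigid$translation)
    cb2 <- virtual_cbeta(move(n), move(ca), move(c_pos))
    expect_equal(cb2, move(cb), tolerance = 1e-9)
  }
  expect_error(virtual_cbeta(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)), "degenerate")
  expect_error(virtual_cbeta(c(1, 0, 0), c(1, 0, 0), c(2, 1, 0)), "degenerate")
})

test_that("mask_to_backbone virtualizes missing C-beta only where possible", {
  st <- make_toy_native(10, "helix", seed = 1)
  # strip all CBs, mark residue 4's N absent
  mask <- st$atom_mask
  mask[, "CB"] <- FALSE
  mask[4, "N"] <- FALSE
  coords <- st$coords
  coords[, "CB", ] <- NA_real_
  coords[4, "N", ] <- NA_real_
  bare <- protein_structure(coords, st$sequence, mask)
  bb <- mask_to_backbone(bare)
  expect_true(all(bb$atom_mask[-4, "CB"]))
  expect_false(bb$atom_mask[4, "CB"])    # cannot virtualize without N

  # an existing (experimental) CB is never overwritten
  st2 <- make_toy_native(8, "helix", seed = 2)
  st2$coords[3, "CB", ] <- st2$coords[3, "CB", ] + 0.3
  kept <- mask_to_backbone(st2)
  expect_equal(kept$coords[3, "CB", ], st2$coords[3, "CB", ])
})

test_that("glycines receive a C-beta", {
  st <- make_toy_native(9, "helix", seed = 5)
  st$sequence <- "GGGGGGGGG"
  mask <- st$atom_mask
  mask[, "CB"] <- FALSE
  coords <- st$coords
  coords[, "CB", ] <- NA_real_
  gly <- protein_structure(coords, st$sequence, mask)
  expect_true(all(mask_to_backbone(gly)$atom_mask[, "CB"]))
})

test_that("gap_sequence is one-hot at the gap token", {
  g <- gap_sequence(5)
  expect_equal(dim(g), c(5L, 22L))
  expect_equal(rowSums(g), rep(1, 5))
  expect_equal(sum(g), 5)                          # exactly L nonzeros
  expect_true(all(g[, "-"] == 1))
  expect_equal(asNamespace("decoyrank")$decode_onehot(g), "-----")
  expect_error(gap_sequence(0), ">= 1")
})

test_that("featurize_template masks termini and honours sequence modes", {
  st <- make_toy_native(8, "helix", seed = 1)
  f <- featurize_template(st)
  expect_s3_class(f, "template_features")
  expect_equal(f$cbeta_distance_matrix, t(f$cbeta_distance_matrix))
  expect_equal(diag(f$cbeta_distance_matrix), rep(0, 8))
  expect_false(f$torsion_mask[1, "phi"])
  expect_false(f$torsion_mask[1, "omega"])
  expect_false(f$torsion_mask[8, "psi"])
  expect_true(all(f$torsion_mask[2:7, ]))
  expect_false(any(f$sidechain_torsion_mask))
  # sin^2 + cos^2 = 1 wherever the torsion is defined
  r2 <- f$torsions[, , "sin"]^2 + f$torsions[, , "cos"]^2
  expect_equal(r2[f$torsion_mask], rep(1, sum(f$torsion_mask)),
               tolerance = 1e-9)
  expect_equal(f$aatype_onehot, gap_sequence(8))
  fn <- featurize_template(st, sequence_mode = "native")
  expect_equal(unname(fn$aatype_onehot[, 22]), rep(0, 8))
  expect_equal(asNamespace("decoyrank")$decode_onehot(fn$aatype_onehot),
               st$sequence)
})

test_that("helix torsions round-trip through build-then-measure", {
  st <- build_backbone(rep(-57, 10), rep(-47, 10))
  f <- featurize_template(st)
  ang <- atan2(f$torsions[, , "sin"], f$torsions[, , "cos"]) * 180 / pi
  expect_equal(ang[2:10, "phi"], rep(-57, 9), tolerance = 1e-3 * 180 / pi)
  expect_equal(ang[1:9, "psi"], rep(-47, 9), tolerance = 1e-3 * 180 / pi)
  expect_equal(abs(ang[2:10, "omega"]), rep(180, 9), tolerance = 1e-3 * 180 / pi)
})

test_that("features are invariant to rigid motion of the input", {
  st <- make_toy_native(12, "helix_hairpin", seed = 4)
  f1 <- featurize_template(st)
  f2 <- featurize_template(transform_structure(st, random_rigid(6)))
  expect_equal(f2$cbeta_distance_matrix, f1$cbeta_distance_matrix,
               tolerance = 1e-6)
  expect_equal(f2$torsions, f1$torsions, tolerance = 1e-6)
})

test_that("gap-mode features carry no amino-acid identity", {
  st <- make_toy_native(12, "random_compact", seed = 8)
  shuffled <- st
  shuffled$sequence <- paste(rev(seq_chars <- strsplit(st$sequence, "")[[1]]),
                             collapse = "")
  f1 <- featurize_template(st)
  f2 <- featurize_template(shuffled)
  expect_equal(f1$aatype_onehot, f2$aatype_onehot)
  expect_equal(f1$cbeta_distance_matrix, f2$cbeta_distance_matrix)
  expect_equal(f1$torsions, f2$torsions)
})

test_that("residues without a C-beta flag their pairs invalid", {
  st <- make_toy_native(8, "helix", seed = 1)
  mask <- st$atom_mask
  mask[3, c("N", "CB")] <- FALSE   # no CB and cannot virtualize
  coords <- st$coords
  coords[3, "N", ] <- NA_real_
  coords[3, "CB", ] <- NA_real_
  partial <- protein_structure(coords, st$sequence, mask)
  f <- featurize_template(partial)
  expect_false(any(f$pair_valid[3, ]))
  expect_true(all(is.na(f$cbeta_distance_matrix[3, ])))
  fb <- featurize_template(partial, ca_fallback = TRUE)
  expect_true(all(fb$pair_valid))
  expect_true(all(is.finite(fb$cbeta_distance_matrix[3, ])))
})

test_that("feature serialization round-trips bit-exactly", {
  st <- make_toy_native(9, "helix_hairpin", seed = 3)
  f <- featurize_template(st)
  dir <- withr::local_tempdir()
  write_template_features(f, dir)
  back <- read_template_features(dir)
  expect_equal(back$aatype_onehot, f$aatype_onehot, ignore_attr = TRUE)
  expect_equal(back$cbeta_distance_matrix, unname(f$cbeta_distance_matrix),
               tolerance = 1e-12)
  expect_equal(back$pair_valid, unname(f$pair_valid), ignore_attr = TRUE)
  expect_equal(back$torsion_mask, unname(f$torsion_mask), ignore_attr = TRUE)
  expect_equal(back$sequence_mode, "gap")
})
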