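test_that("kabsch recovers exact rigid motions", {
  set.seed(1)
  pts <- matrix(rnorm(30), 10, 3)
  s <- kabsch_superpose(pts, pts)
  expect_equal(s$rotation, diag(3), tolerance = 1e-10)
  expect_equal(s$translation, rep(0, 3), tolerance = 1e-10)
  expect_equal(s$rmsd, 0, tolerance = 1e-10)

  rot90z <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, byrow = TRUE)
  moved <- pts %*% t(rot90z) + matrix(c(5, 0, 0), 10, 3, byrow = TRUE)
  s2 <- kabsch_superpose(moved, pts)
  expect_lt(s2$rmsd, 1e-9)
  expect_equal(s2$rotation %*% rot90z, diag(3), tolerance = 1e-9)
  expect_equal(det(s2$rotation), 1, tolerance = 1e-9)
})

test_that("kabsch rmsd matches the quaternion oracle on random clouds", {
  for (i in 1:25) {
    set.seed(i)
    a <- matrix(rnorm(30, sd = 3), 10, 3)
    b <- matrix(rnorm(30, sd = 3), 10, 3)
    expect_equal(kabsch_superpose(a, b)$rmsd, quaternion_rmsd(a, b),
                 tolerance = 1e-9)
  }
})

test_that("kabsch rejects bad inputs", {
  expect_error(kabsch_superpose(matrix(0, 2, 3), matrix(0, 2, 3)),
               "at least 3")
  expect_error(kabsch_superpose(matrix(0, 3, 3), matrix(0, 4, 3)),
               "equal-size")
})

test_that("tm_score is exact on self and invariant to rigid motion", {
  st <- make_toy_native(20, "helix_hairpin", seed = 1)
  expect_equal(tm_score(st, st), 1.0)
  moved <- transform_structure(st, random_rigid(4))
  expect_equal(tm_score(moved, st), 1.0, tolerance = 1e-6)
})

test_that("tm_score matches the rotation-grid oracle on a toy pair", {
  native <- make_toy_native(8, "helix", seed = 2)
  decoy <- perturb_structure(native, 1.0, seed = 3)
  expect_equal(tm_score(decoy, native), tm_grid_oracle(decoy, native),
               tolerance = 1e-3)
})

test_that("tm_score normalization is asymmetric by design", {
  # same pair, different normalization lengths: scores must differ
  long <- make_toy_native(24, "helix_hairpin", seed = 1)
  short <- protein_structure(long$coords[1:18, , , drop = FALSE],
                             substr(long$sequence, 1, 18))
  ab <- tm_score(short, long)             # normalized by 24
  ba <- tm_score(long, short)             # normalized by 18
  expect_false(isTRUE(all.equal(ab, ba, tolerance = 1e-6)))
  expect_lt(ab, ba)  # missing residues penalized under reference length
})

test_that("tm_score d0 floors at 0.5 for short chains", {
  expect_equal(asNamespace("decoyrank")$tm_d0(8), 0.5)
  expect_gt(asNamespace("decoyrank")$tm_d0(100), 0.5)
})

test_that("gdt_ts fixed-frame mode reproduces the hand-counted toy", {
  ref <- make_toy_native(8, "helix", seed = 1)
  # displace 4 residues by 0.5/1.5/3.0/9.0 A; leave a 4-residue anchor is
  # not needed in fixed-frame mode; restrict to 4 residues
  ref4 <- protein_structure(ref$coords[1:4, , , drop = FALSE],
                            substr(ref$sequence, 1, 4))
  mod4 <- displaced_structure(ref4, c(0.5, 1.5, 3.0, 9.0))
  # thresholds 1/2/4/8: hits 1, 2, 3, 3 -> (1+2+3+3)/16
  expect_equal(gdt_ts(mod4, ref4, superpose = FALSE), 0.5625)
})

test_that("gdt_ts search mode dominates fixed-frame and is exact on self", {
  st <- make_toy_native(16, "helix_hairpin", seed = 2)
  expect_equal(gdt_ts(st, st), 1.0)
  for (seed in 1:5) {
    decoy <- transform_structure(perturb_structure(st, 1.5, seed = seed),
                                 random_rigid(seed))
    expect_gte(gdt_ts(decoy, st, superpose = TRUE),
               gdt_ts(decoy, st, superpose = FALSE))
  }
})

test_that("lddt is exact on self, matches brute force, ignores rigid motion", {
  st <- make_toy_native(14, "helix_hairpin", seed = 3)
  self <- lddt(st, st)
  expect_equal(self$global, 1.0)
  expect_true(all(self$per_residue[!is.na(self$per_residue)] == 1.0))

  decoy <- perturb_structure(st, 1.2, seed = 9)
  got <- lddt(decoy, st)
  want <- lddt_bruteforce(decoy, st)
  expect_equal(got$global, want$global, tolerance = 1e-12)
  expect_equal(got$per_residue, want$per_residue, tolerance = 1e-12)

  moved <- transform_structure(decoy, random_rigid(7))
  expect_equal(lddt(moved, st)$global, got$global, tolerance = 1e-9)
})

test_that("a single perturbed pair contributes its threshold fraction", {
  # 3 residues in a line, 5 A apart: only the (1,3) pair is scored
  coords <- array(NA_real_, c(3, 5, 3),
                  dimnames = list(NULL, c("N", "CA", "C", "O", "CB"),
                                  c("x", "y", "z")))
  for (i in 1:3) {
    coords[i, "CA", ] <- c(5 * (i - 1), 0, 0)
    coords[i, "N", ] <- c(5 * (i - 1) - 0.5, 1, 0)
    coords[i, "C", ] <- c(5 * (i - 1) + 0.5, 1, 0)
    coords[i, "O", ] <- c(5 * (i - 1) + 0.7, 2, 0)
    coords[i, "CB", ] <- c(5 * (i - 1), -1, 1)
  }
  ref <- protein_structure(coords, "AAA")
  coords2 <- coords
  coords2[3, , 1] <- coords2[3, , 1] + 1.5  # pair distance changes by 1.5 A
  mod <- protein_structure(coords2, "AAA")
  got <- lddt(mod, ref)
  expect_equal(got$global, 0.5)             # (0 + 0 + 1 + 1) / 4
  expect_equal(got$per_residue, c(0.5, NA, 0.5))
})

test_that("sequence recovery counts identities", {
  expect_equal(sequence_recovery("ACDEF", "ACDEF"), 1.0)
  expect_equal(sequence_recovery("ACDEF", "ACDFF"), 0.8)
  expect_error(sequence_recovery("ACD", "AC"), "equal length")
  # random pairs: expected identity 1/20
  set.seed(42)
  recov <- replicate(100, {
    a <- paste(sample(AA_ALPHABET, 1000, TRUE), collapse = "")
    b <- paste(sample(AA_ALPHABET, 1000, TRUE), collapse = "")
    sequence_recovery(a, b)
  })
  se <- sqrt(0.05 * 0.95 / 1000) / sqrt(100)
  expect_lt(abs(mean(recov) - 0.05), 3 * se)
})

test_that("spearman_rho handles monotone data, ties and degeneracy", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(spearman_rho(x, exp(x)), 1.0)
  expect_equal(spearman_rho(x, -x^3), -1.0)
  set.seed(8)
  xt <- c(3, 1, 4, 1, 5, 9)   # one tie
  yt <- rnorm(6)
  expect_equal(spearman_rho(xt, yt), spearman_bruteforce(xt, yt),
               tolerance = 1e-12)
  expect_error(spearman_rho(rep(1, 5), x), "constant")
  expect_error(spearman_rho(1, 2), "length")
})

test_that("metric identity and rigid invariance hold over random cases", {
  # property sweep over generated structures and rigid motions
  for (i in 1:25) {
    st <- make_toy_native(8 + (i %% 3) * 4, "random_compact", seed = i)
    rigid <- random_rigid(i + 100)
    moved <- transform_structure(st, rigid)
    expect_equal(tm_score(st, st), 1.0)
    expect_equal(lddt(st, st)$global, 1.0)
    expect_equal(tm_score(moved, st), 1.0, tolerance = 1e-6)
    expect_equal(lddt(moved, st)$global, 1.0, tolerance = 1e-6)
  }
})
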