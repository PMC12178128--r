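# Contract-conformance suite run against every shipped predictor, plus the
# behaviour specific to each mock.

make_test_predictors <- function(native) {
  list(
    "geometry-mock" = geometry_mock(),
    "oracle-mock" = oracle_mock(native),
    "sequence-match-mock" = sequence_match_mock(native, native$sequence),
    "planted-generator-mock" = planted_generator_mock(
      native, native$sequence))
}

test_that("every implementation satisfies the predictor contract", {
  native <- make_toy_native(12, "helix_hairpin", seed = 1)
  decoy <- perturb_structure(native, 1, seed = 2)
  template <- featurize_template(mask_to_backbone(decoy))
  for (nm in names(make_test_predictors(native))) {
    p <- make_test_predictors(native)[[nm]]
    tmpl <- if (isTRUE(p$requires_template) || nm != "planted-generator-mock")
      template else NULL
    out1 <- predict_structure(p, native$sequence, tmpl, seed = 7)
    out2 <- predict_structure(p, native$sequence, tmpl, seed = 7)
    # determinism under a fixed seed
    expect_equal(out1$structure$coords, out2$structure$coords, info = nm)
    expect_equal(out1$plddt, out2$plddt, info = nm)
    # invariants
    expect_true(all(out1$plddt >= 0 & out1$plddt <= 100), info = nm)
    expect_gte(out1$ptm, 0)
    expect_lte(out1$ptm, 1)
    sums <- apply(out1$distogram, c(1, 2), sum)
    expect_lt(max(abs(sums - 1)), 1e-6)
    # length preservation
    expect_equal(length(out1$structure), nchar(native$sequence), info = nm)
  }
})

test_that("predictor input contracts are enforced", {
  native <- make_toy_native(10, "helix", seed = 1)
  gm <- geometry_mock()
  expect_error(predict_structure(gm, "ACDB"), "20 amino-acid letters")
  short <- featurize_template(make_toy_native(8, "helix", seed = 1))
  expect_error(predict_structure(gm, native$sequence, short),
               "length must equal")
  om <- oracle_mock(native)
  expect_error(predict_structure(om, native$sequence, NULL),
               "requires a template")
})

test_that("geometry mock scores ideal geometry high and clashes low", {
  helix <- make_toy_native(20, "helix", seed = 1)
  conf <- geometry_mock_confidence(helix)
  expect_true(all(conf$plddt > 90))
  expect_gte(mean(conf$plddt), 90)

  out <- predict_structure(geometry_mock(), helix$sequence,
                           featurize_template(helix))
  expect_gte(mean(out$plddt), 90)

  # two CA atoms forced within 1 A at |i - j| > 2: clash penalty active
  clashed <- helix
  clashed$coords[8, , ] <- clashed$coords[8, , ] +
    matrix(helix$coords[1, "CA", ] + c(0.5, 0, 0) - helix$coords[8, "CA", ],
           5, 3, byrow = TRUE)
  cc <- geometry_mock_confidence(clashed)
  expect_lt(cc$ptm, conf$ptm)
  expect_lt(max(cc$plddt), 100)
})

test_that("geometry mock confidence decreases with jitter amplitude", {
  helix <- make_toy_native(20, "helix", seed = 1)
  mean_p <- function(sigma) {
    mean(vapply(1:25, function(s) {
      mean(geometry_mock_confidence(
        perturb_structure(helix, sigma, seed = s))$plddt)
    }, 0))
  }
  expect_lt(mean_p(2), mean_p(0.2))
})

test_that("oracle mock reports perfect confidence for the native template", {
  native <- make_toy_native(14, "helix_hairpin", seed = 2)
  om <- oracle_mock(native)
  out <- predict_structure(om, native$sequence,
                           featurize_template(mask_to_backbone(native)))
  expect_equal(out$ptm, 1.0, tolerance = 1e-6)
  expect_equal(out$plddt, rep(100, 14), tolerance = 1e-6)
})

test_that("oracle mock pTM orders scaled copies of the same noise", {
  native <- make_toy_native(14, "helix_hairpin", seed = 2)
  om <- oracle_mock(native)
  # one noise realization, applied at two scales in the same directions
  set.seed(11)
  direction <- matrix(rnorm(14 * 3), 14, 3)
  noised <- function(scale) {
    coords <- native$coords
    for (a in 1:5) coords[, a, ] <- coords[, a, ] + scale * direction
    protein_structure(coords, native$sequence)
  }
  ptm_of <- function(st) predict_structure(
    om, native$sequence, featurize_template(mask_to_backbone(st)))$ptm
  expect_gt(ptm_of(noised(0.3)), ptm_of(noised(1.5)))
})

test_that("oracle mock distogram argmax reconstructs native distances", {
  native <- make_toy_native(10, "helix", seed = 3)
  om <- oracle_mock(native)
  out <- predict_structure(om, native$sequence,
                           featurize_template(mask_to_backbone(native)))
  bins <- out$bins
  nb <- mask_to_backbone(native)
  cb <- nb$coords[, "CB", ]
  width <- bins$edges[2] - bins$edges[1]
  for (i in 1:9) {
    for (j in (i + 1):10) {
      true_d <- sqrt(sum((cb[i, ] - cb[j, ])^2))
      if (true_d >= max(bins$edges)) next
      k <- which.max(out$distogram[i, j, ])
      expect_lt(abs(bins$centers[k] - true_d), width)
    }
  }
})

test_that("distogram bin layout matches its definition", {
  bins <- distogram_bins()
  expect_equal(bins$n_bins, 64L)
  expect_equal(length(bins$edges), 63L)
  expect_equal(bins$edges[1], 2.3125)
  expect_equal(bins$edges[63], 21.6875)
  expect_equal(unique(round(diff(bins$edges), 10)), 0.3125)
  ns <- asNamespace("decoyrank")
  expect_equal(ns$distance_to_bin(c(1, 2.4, 21.7, 50), bins),
               c(1L, 2L, 64L, 64L))
})

test_that("geometry mock ranks a decoy ladder by noise level", {
  spec <- decoy_ladder_spec(native_length = 30, topology = "helix_hairpin",
                            sigmas = c(0.1, 0.25, 0.5, 0.75, 1, 1.5, 2,
                                       2.5, 3, 4),
                            n_per_sigma = 5, seed = 11)
  ladder <- make_decoy_ladder(spec)
  gm <- geometry_mock()
  conf <- vapply(ladder$decoys, function(d) {
    out <- predict_structure(gm, ladder$native$sequence,
                             featurize_template(mask_to_backbone(d)))
    as.numeric(composite_score(out, mask_to_backbone(d)))
  }, 0)
  expect_gte(spearman_rho(conf, -ladder$manifest$sigma), 0.8)
})
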