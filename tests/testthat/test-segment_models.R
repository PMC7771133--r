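p3 <- segment_partition(300, 700, 3)

test_that("brightness is an unweighted sum with half-open segments", {
  l1 <- flat_radiance(grid1)
  l5 <- flat_radiance(grid5)
  expect_equal(brightness(l1, 300, 700), 401) # both endpoints on full range
  expect_equal(brightness(l5, 300, 700), 81)
  # interior segment is half-open: [400, 500) has 100 samples at 1 nm
  expect_equal(brightness(l1, 400, 500), 100)
  # additivity: beta over the full range equals the sum over the 4 segments
  set.seed(11)
  r <- random_reflectance(grid1)
  l <- radiance(r, d65(grid1))
  segs <- vapply(1:4, function(i) {
    brightness(l, p3$boundaries[i], p3$boundaries[i + 1],
               include_right = (i == 4))
  }, numeric(1))
  expect_equal(sum(segs), brightness(l, 300, 700))
  expect_error(brightness(l1, 400.2, 400.8), "empty segment")
  expect_error(brightness(r, 300, 700), "radiance")
  expect_error(brightness(l1, 200, 400), "beyond")
})

test_that("white-standard brightness equals the illuminant's own brightness", {
  expect_equal(white_standard_brightness(flat_illuminant(grid1), p3), 401)
  d <- d65(grid5)
  white <- spectrum(grid5$wl, rep(1, 81), "reflectance")
  expect_equal(white_standard_brightness(d, p3),
               brightness(radiance(white, d), 300, 700))
})

test_that("relative segment brightnesses sum to 1 and match the tally oracle", {
  sb <- segment_relative_brightness(flat_radiance(grid1), p3)
  expect_equal(sum(sb$S), 1, tolerance = 1e-12)
  expect_named(sb$S, c("B", "G", "Y", "R"))
  # flat spectrum: equal up to boundary-sample assignment (last segment holds
  # one extra sample at 1 nm: 100,100,100,101 of 401)
  expect_equal(unname(sb$S), c(100, 100, 100, 101) / 401)

  # support only in the 4th segment
  v <- numeric(401); v[grid1$wl >= 650 & grid1$wl <= 660] <- 2
  sb4 <- segment_relative_brightness(spectrum(grid1$wl, v, "radiance"), p3)
  expect_equal(unname(sb4$S), c(0, 0, 0, 1))

  # step sigmoid with inflection exactly on the 500 nm boundary: half-open
  # convention puts the boundary sample in segment 3; oracle must agree
  stp <- generate_spectrum(spectrum_recipe("step", center = 500), grid5)
  lstp <- radiance(stp, flat_illuminant(grid5))
  sbs <- segment_relative_brightness(lstp, p3)
  expect_identical(unname(sbs$S), tally_relative_brightness(lstp, p3))

  # oracle equals vectorized computation exactly on random spectra
  set.seed(23)
  for (i in 1:20) {
    l <- radiance(random_reflectance(grid5), d65(grid5))
    sbr <- segment_relative_brightness(l, p3)
    expect_identical(unname(sbr$S), tally_relative_brightness(l, p3))
    expect_equal(sum(sbr$S), 1, tolerance = 1e-12)
  }

  zero <- spectrum(grid1$wl, rep(0, 401), "radiance")
  expect_error(segment_relative_brightness(zero, p3),
               "undefined chromatic coordinates")
})

test_that("Endler locus reproduces the three-branch arcsine arithmetic", {
  # branch R>=G, Y>=B
  el <- endler_locus(fake_sb(c(B = 0.1, G = 0.2, Y = 0.3, R = 0.4)))
  expect_equal(el$X1, sqrt(0.08), tolerance = 1e-12)
  expect_equal(el$X2, pi / 4, tolerance = 1e-12)
  expect_true(el$hue_defined)
  # branch R < G
  el3 <- endler_locus(fake_sb(c(B = 0.4, G = 0.3, Y = 0.2, R = 0.1)))
  expect_equal(el3$X2, pi + pi / 4, tolerance = 1e-12)
  # branch R >= G, Y < B
  el2 <- endler_locus(fake_sb(c(B = 0.3, G = 0.2, Y = 0.1, R = 0.4)))
  expect_equal(el2$X2, asin(-0.2 / el2$X1) + 2 * pi, tolerance = 1e-12)
  # achromatic point: zero chroma, conventional hue 0, flagged
  ela <- endler_locus(fake_sb(rep(0.25, 4), beta = 401))
  expect_equal(ela$X1, 0)
  expect_equal(ela$X2, 0)
  expect_false(ela$hue_defined)
  expect_equal(ela$X3, 401)
  # defined only for the trichromatic case
  expect_error(endler_locus(fake_sb(rep(0.2, 5))), "trichromatic")
})

test_that("Endler chromatic distance follows the law of cosines", {
  a <- endler_locus(fake_sb(c(0.1, 0.2, 0.3, 0.4)))
  expect_equal(endler_chromatic_distance(a, a), 0)
  # antipodal loci at equal chroma c are 2c apart
  b1 <- endler_locus(fake_sb(c(0.15, 0.15, 0.35, 0.35))) # Y-B=0.2, R-G=0.2
  b2 <- endler_locus(fake_sb(c(0.35, 0.35, 0.15, 0.15))) # both negated
  expect_equal(abs(b1$X2 - b2$X2), pi, tolerance = 1e-12)
  expect_equal(endler_chromatic_distance(b1, b2), 2 * b1$X1, tolerance = 1e-12)
  # achromatic distance is |X3 difference|
  expect_equal(endler_achromatic_distance(b1, b2), 0)
})

test_that("NSC locus matches worked arithmetic in both variants", {
  # white reflectance under flat illuminant: pure achromatic point up to the
  # boundary-sample asymmetry (401 samples cannot split into 4 equal
  # segments; the closed last segment carries one extra sample, so a
  # chromatic coordinate can be off by at most 1/401)
  white <- spectrum(grid1$wl, rep(1, 401), "reflectance")
  z <- nsc_locus(radiance(white, flat_illuminant(grid1)),
                 flat_illuminant(grid1), p3)
  expect_lte(max(abs(z$Z[1:2])), 1 / 401 + 1e-12)
  expect_equal(z$Z[3], 1, tolerance = 1e-12)

  # prescribed S = (0.1, 0.2, 0.3, 0.4), beta/beta_m = 0.5:
  sb <- fake_sb(c(0.1, 0.2, 0.3, 0.4), beta = 1, beta_m = 2)
  zs <- nscolor:::nsc_coordinates(sb, "standard")
  expect_equal(zs, c(0.2, 0.2, 0.5), tolerance = 1e-12)
  zn <- nscolor:::nsc_coordinates(sb, "normalized")
  # per-mechanism normalization: 2(Y-B)/(Y+B) = 1, 2(R-G)/(R+G) = 2/3
  expect_equal(zn, c(1, 2 / 3, 0.5), tolerance = 1e-12)

  # near-zero denominator guard names the coordinate
  sb0 <- fake_sb(c(0, 0.5, 0, 0.5), beta = 1, beta_m = 2)
  expect_error(nscolor:::nsc_coordinates(sb0, "normalized"), "Z1")
})

test_that("tetrachromatic NSC has 3 chromatic + 1 achromatic coordinates", {
  p4 <- segment_partition(300, 700, 4)
  set.seed(5)
  r <- random_reflectance(grid5)
  d <- d65(grid5)
  z4 <- nsc_locus(radiance(r, d), d, p4)
  expect_length(z4$Z, 4L)
  sb <- segment_relative_brightness(radiance(r, d), p4)
  expect_equal(z4$Z[1:3], unname(sb$S[3:5] - sb$S[1:3]), tolerance = 1e-14)
  # n = 3 reduces to the pairwise segment differences of the 4-segment case
  z3 <- nsc_locus(radiance(r, d), d, p3)
  sb3 <- segment_relative_brightness(radiance(r, d), p3)
  expect_equal(z3$Z[1:2], unname(sb3$S[3:4] - sb3$S[1:2]), tolerance = 1e-14)
})

test_that("chromatic coordinates are scale invariant; achromatic scales as c", {
  d <- d65(grid5)
  set.seed(31)
  for (i in 1:10) {
    r <- random_reflectance(grid5)
    c_ <- runif(1, 0.05, 1)
    rs <- spectrum(r$wl, c_ * r$values, "reflectance")
    for (variant in c("standard", "normalized")) {
      z <- nsc_locus(radiance(r, d), d, p3, variant)
      zs <- nsc_locus(radiance(rs, d), d, p3, variant)
      expect_equal(zs$Z[1:2], z$Z[1:2], tolerance = 1e-12)
      expect_equal(zs$Z[3], c_ * z$Z[3], tolerance = 1e-12)
    }
  }
})

test_that("coordinate bounds hold for physical reflectances", {
  d <- d65(grid5)
  set.seed(13)
  for (i in 1:50) {
    r <- random_reflectance(grid5)
    z <- nsc_locus(radiance(r, d), d, p3)
    expect_true(all(z$Z[1:2] >= -1 & z$Z[1:2] <= 1))
    expect_true(z$Z[3] > 0 && z$Z[3] <= 1)
    zn <- nsc_locus(radiance(r, d), d, p3, "normalized")
    expect_true(all(zn$Z[1:2] >= -2 & zn$Z[1:2] <= 2))
    el <- endler_locus(segment_relative_brightness(radiance(r, d), p3))
    expect_lte(el$X1, sqrt(2))
  }
})

test_that("nsc_distance applies the alpha weight and checks comparability", {
  d <- flat_illuminant(grid5)
  mk <- function(z) structure(list(Z = z, variant = "standard", partition = p3,
                                   illum_id = nscolor:::illum_fingerprint(d)),
                              class = "nsc_locus")
  a <- mk(c(0.2, 0.2, 0.9)); b <- mk(c(0.2, 0.2, 0.4))
  expect_equal(nsc_distance(a, b, alpha = 1), 0.5)
  expect_equal(nsc_distance(a, b, alpha = 0), 0)
  expect_equal(nsc_distance(a, b, alpha = 4), 1)  # doubles the length scale
  expect_equal(nsc_distance(a, a), 0)
  bad_var <- mk(c(0, 0, 1)); bad_var$variant <- "normalized"
  expect_error(nsc_distance(a, bad_var), "variant")
  bad_p <- mk(c(0, 0, 0, 1)); bad_p$partition <- segment_partition(300, 700, 4)
  expect_error(nsc_distance(a, bad_p), "partition")
  bad_il <- mk(c(0, 0, 1)); bad_il$illum_id <- "other"
  expect_error(nsc_distance(a, bad_il), "illuminant")
  expect_error(nsc_distance(a, b, alpha = -1), "alpha")
})

test_that("nsc distances satisfy metric axioms on random triples", {
  d <- d65(grid5)
  set.seed(17)
  for (i in 1:200) {
    zz <- lapply(1:3, function(j) nsc_locus(radiance(random_reflectance(grid5), d),
                                            d, p3))
    for (alpha in c(0, 0.5, 1, 4)) {
      dab <- nsc_distance(zz[[1]], zz[[2]], alpha)
      dba <- nsc_distance(zz[[2]], zz[[1]], alpha)
      dbc <- nsc_distance(zz[[2]], zz[[3]], alpha)
      dac <- nsc_distance(zz[[1]], zz[[3]], alpha)
      expect_identical(dab, dba)
      expect_lte(dac, dab + dbc + 1e-12)
    }
  }
})

test_that("pairwise distance matrix is symmetric with zero diagonal", {
  d <- d65(grid5)
  set.seed(3)
  loci <- lapply(1:4, function(i) nsc_locus(radiance(random_reflectance(grid5), d),
                                            d, p3))
  names(loci) <- paste0("s", 1:4)
  m <- nsc_distance_matrix(loci)
  expect_identical(m, t(m))
  expect_equal(diag(m), setNames(rep(0, 4), names(loci)))
})
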