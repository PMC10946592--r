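# Colour-space matrices, tristimulus integration, chromaticity and loci.

test_that("built-in matrices reproduce the printed columns exactly", {
  m <- cmf_matrix("RGB", "LMS", "10deg")
  expect_identical(unname(m %*% c(1, 0, 0)), cbind(c(2.846201, 0.168926, 0)))
  expect_identical(unname(m %*% c(0, 1, 0)),
                   cbind(c(11.092401, 8.265895, 0.010600)))
  expect_identical(unname(m %*% c(0, 0, 1)), cbind(c(1, 1, 1)))

  x2 <- cmf_matrix("LMS", "XYZ", "2deg")
  expect_identical(unname(x2 %*% c(1, 0, 0)),
                   cbind(c(1.94735469, 0.68990272, 0)))
  expect_identical(unname(x2 %*% c(0, 0, 1)),
                   cbind(c(0.36476327, 0, 1.93485343)))
  x10 <- cmf_matrix("LMS", "XYZ", "10deg")
  expect_identical(unname(x10 %*% c(0, 0, 1)),
                   cbind(c(0.43044935, 0, 2.14687945)))
  expect_identical(unname(x10 %*% c(0, 1, 0)),
                   cbind(c(-1.34664359, 0.34967567, 0)))

  # structural zeros
  expect_identical(x2[2, 3], 0)
  expect_identical(x2[3, 1], 0)
  expect_identical(x2[3, 2], 0)
  expect_identical(m[3, 1], 0)
  expect_error(cmf_matrix("RGB", "LMS", "2deg"), "10-deg")
})

test_that("matrix round trips are the identity to 1e-10", {
  set.seed(11)
  for (pair in list(c("RGB", "LMS"), c("LMS", "XYZ"))) {
    field <- if (pair[1] == "RGB") "10deg" else "2deg"
    fwd <- cmf_matrix(pair[1], pair[2], field)
    bwd <- cmf_matrix(pair[2], pair[1], field)
    for (i in 1:20) {
      t0 <- runif(3, -2, 5)
      expect_equal_tol(drop(bwd %*% (fwd %*% t0)), t0, 1e-10)
    }
  }
  # the inverse maps the printed L/M/S column back to a unit R tristimulus
  expect_equal_tol(drop(cmf_matrix("LMS", "RGB", "10deg") %*%
                          c(2.846201, 0.168926, 0)), c(1, 0, 0), 1e-10)
  expect_equal(drop(cmf_matrix("LMS", "RGB", "10deg") %*% c(0, 0, 0)),
               c(R = 0, G = 0, B = 0))
})

test_that("chromaticity projects onto the unit-sum plane", {
  expect_equal(unlist(chromaticity(tibble::tibble(L = 1, M = 1, S = 1))),
               c(l = 1 / 3, m = 1 / 3))
  expect_equal(unlist(chromaticity(tibble::tibble(L = 2, M = 0, S = 0))),
               c(l = 1, m = 0))
  # projective invariance under positive scaling
  set.seed(3)
  t0 <- tibble::tibble(X = runif(10, 0.1, 4), Y = runif(10, 0.1, 4),
                       Z = runif(10, 0.1, 4))
  for (k in c(0.25, 3, 17)) {
    expect_equal(chromaticity(dplyr::mutate(t0, X = k * X, Y = k * Y,
                                            Z = k * Z)),
                 chromaticity(t0))
  }
  expect_error(chromaticity(tibble::tibble(L = 0, M = 0, S = 0)), "zero")
  expect_error(chromaticity(tibble::tibble(L = 1, M = 1)), "three")
})

test_that("tristimulus integration is a sifting, linear rectangle rule", {
  cf <- cone_fundamentals(standard_observer("2deg"))
  # monochromatic unit impulse picks out the CMF row times the step
  p <- tibble::tibble(wavelength = 550, power = 1)
  tv <- tristimulus(p, cf)
  i <- match(550, cf$wavelength)
  expect_equal(unlist(tv), c(L = cf$L[i], M = cf$M[i], S = cf$S[i]) * 1)
  # linearity
  set.seed(5)
  grid <- cf$wavelength
  p1 <- tibble::tibble(wavelength = grid, power = runif(length(grid)))
  p2 <- tibble::tibble(wavelength = grid, power = runif(length(grid)))
  combo <- tibble::tibble(wavelength = grid,
                          power = 2 * p1$power + 0.5 * p2$power)
  expect_equal(unlist(tristimulus(combo, cf)),
               2 * unlist(tristimulus(p1, cf)) +
                 0.5 * unlist(tristimulus(p2, cf)))
  # zero spectrum
  z <- tibble::tibble(wavelength = grid, power = 0)
  expect_equal(unname(unlist(tristimulus(z, cf))), c(0, 0, 0))
  # unit mismatch
  qcf <- cone_fundamentals(standard_observer("2deg"), units = "quantal")
  expect_error(tristimulus(p1, qcf), "mismatch")
  expect_equal(unlist(tristimulus(p1, qcf, power_units = "quantal")),
               unlist(tristimulus(p1, qcf, power_units = "quantal")))
})

test_that("transformed CMFs keep the stated structure", {
  cf <- cone_fundamentals(standard_observer("2deg"))
  xyz <- transform_cmfs(cf, "XYZ")
  # y-bar is a nonnegative combination of l-bar and m-bar
  expect_true(all(xyz$Y >= 0))
  expect_equal(xyz$Y, 0.68990272 * cf$L + 0.34832189 * cf$M)
  # z-bar is a pure scaling of s-bar wherever s-bar is non-negligible
  sel <- cf$S > 1e-6
  ratio <- xyz$Z[sel] / cf$S[sel]
  expect_equal_tol(ratio, 1.93485343, 1e-12)
})

test_that("spectrum loci stay inside their admissible regions", {
  cf <- cone_fundamentals(standard_observer("10deg"))
  lm <- spectrum_locus(cf, "lm")
  expect_true(all(lm$l >= 0 & lm$m >= 0 & lm$l + lm$m <= 1))
  xy <- spectrum_locus(cf, "xy", field = "10deg")
  expect_true(all(is.finite(xy$x) & is.finite(xy$y)))
  # at the long-wave end S ~ 0, so y ~ Y/(X+Y) there
  tail_i <- nrow(cf)
  xyz <- transform_cmfs(cf, "XYZ", field = "10deg")
  expect_lt(xyz$Z[tail_i] / (xyz$X[tail_i] + xyz$Y[tail_i]), 1e-4)
  expect_equal(xy$y[tail_i],
               xyz$Y[tail_i] / (xyz$X[tail_i] + xyz$Y[tail_i] + xyz$Z[tail_i]))
  rg <- spectrum_locus(cf, "rg")
  expect_identical(names(rg), c("wavelength", "r", "g"))
  expect_error(spectrum_locus(cone_fundamentals(units = "quantal"), "lm"),
               "energy")
})

test_that("primary matrices are read off the fundamentals", {
  cf <- cone_fundamentals(standard_observer("10deg"))
  m <- primaries_matrix(cf, c(645, 526, 444))
  i <- match(c(645, 526, 444), cf$wavelength)
  expect_identical(unname(m[, "R"]), c(cf$L[i[1]], cf$M[i[1]], cf$S[i[1]]))
  expect_identical(unname(m[, "B"]), c(cf$L[i[3]], cf$M[i[3]], cf$S[i[3]]))
  # broadband impulse primaries reduce to the monochromatic case (x step)
  imp <- lapply(c(645, 526, 444), function(l0) {
    tibble::tibble(wavelength = l0, power = 1)
  })
  mb <- primaries_matrix(cf, imp)
  expect_equal(unname(mb), unname(m))
  expect_error(primaries_matrix(cf, c(645.5, 526, 444)), "grid")
})
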