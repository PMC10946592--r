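# Corneal cone fundamentals: self-screening, pre-receptoral filtering,
# unit conversion, normalization.

abs_tbl <- function(name, from = 390, to = 830, by = 1) {
  tabulate_template(builtin_template(name), from, to, by, value = "linear")
}

test_that("absorptance follows the self-screening closed form", {
  d <- tibble::tibble(wavelength = c(500, 550), value = c(0, 1))
  expect_equal(absorptance(d, 0.5)$value, c(0, 1 - 10^-0.5))
  expect_equal(absorptance(d, 0.4)$value[2], 0.60189, tolerance = 1e-5)
  expect_equal(absorptance(d, 0.5)$value[2], 0.68377, tolerance = 1e-5)
  # bounded by the peak absorptance
  a <- absorptance(abs_tbl("L"), 0.5)
  expect_true(all(a$value > 0 & a$value <= 1 - 10^-0.5))
  expect_error(absorptance(d, 0), "positive")
  expect_error(absorptance(d, -1), "positive")
})

test_that("self-screening broadens without moving the peak", {
  for (name in c("L", "M", "S")) {
    tab <- abs_tbl(name, 390, 830, 0.1)
    widths <- vapply(c(0.2, 0.4, 0.6, 1.0), function(od) {
      a <- absorptance(tab, od)
      fwhm(a$wavelength, a$value)
    }, numeric(1))
    expect_true(all(diff(widths) > 0))
    # argmax invariant under the monotone pointwise transform
    for (od in c(0.3, 0.5, 1.0)) {
      expect_identical(find_lambda_max(absorptance(tab, od), column = "value"),
                       find_lambda_max(tab, column = "value"))
    }
  }
})

test_that("pre-receptoral filtering only attenuates, and only below 660 nm", {
  a <- absorptance(abs_tbl("L"), 0.5)
  q <- corneal_quantal(a, filter_scaling(1, 1))
  expect_true(all(q$value <= a$value))
  over660 <- a$wavelength > 660
  expect_identical(q$value[over660], a$value[over660])
  # zero scaling is the identity
  q0 <- corneal_quantal(a, filter_scaling(0, 0))
  expect_identical(q0$value, a$value)
  # definition check at 460 nm against independently computed densities
  i <- match(460, a$wavelength)
  expect_equal(q$value[i],
               a$value[i] * 10^-(macular_density(460) + lens_density(460)))
})

test_that("energy conversion multiplies by wavelength and renormalizes", {
  const <- tibble::tibble(wavelength = 400:500, value = rep(0.5, 101))
  e <- to_energy_normalized(const)
  expect_equal(max(e$value), 1)
  expect_identical(which.max(e$value), 101L) # forced to the grid end
  expect_equal(e$value, (400:500) / 500)
  # peak shifts to longer wavelengths for each built-in cone
  for (name in c("L", "M", "S")) {
    q <- corneal_quantal(absorptance(abs_tbl(name), 0.5), filter_scaling())
    e <- to_energy_normalized(q)
    expect_gte(find_lambda_max(e, column = "value"),
               find_lambda_max(q, column = "value"))
  }
  expect_error(to_energy_normalized(tibble::tibble(wavelength = 1:3,
                                                   value = c(0, 0, 0))),
               "all-zero")
})

test_that("standard observer parameter sets are as defined", {
  o2 <- standard_observer("2deg")
  expect_identical(unname(o2$od), c(0.50, 0.50, 0.40))
  expect_identical(o2$scaling$k_mac, 1)
  expect_identical(o2$scaling$k_lens, 1)
  o10 <- standard_observer("10deg")
  expect_identical(unname(o10$od), c(0.38, 0.38, 0.30))
  expect_identical(o10$scaling$k_mac, 0.271)
  expect_identical(o10$scaling$k_lens, 1)
  expect_identical(standard_observer(10)$field, "10deg")
})

test_that("fundamentals are unit-peak, positive, and carry their metadata", {
  for (field in c("2deg", "10deg")) {
    for (units in c("energy", "quantal")) {
      cf <- cone_fundamentals(standard_observer(field), units = units)
      expect_identical(max(cf$L), 1)
      expect_identical(max(cf$M), 1)
      expect_identical(max(cf$S), 1)
      expect_true(all(cf$L > 0 & cf$M > 0 & cf$S > 0))
      expect_identical(attr(cf, "units"), units)
      expect_true(all(attr(cf, "alpha") > 0))
    }
  }
  cf <- cone_fundamentals(standard_observer("2deg"))
  expect_identical(nrow(cf), 441L)
  g <- glance(cf)
  expect_identical(g$field, "2deg")
  td <- tidy(cf)
  expect_identical(nrow(td), 3L * 441L)
  expect_setequal(unique(td$cone), c("L", "M", "S"))
})

test_that("energy conversion commutes with filtering up to normalization", {
  a <- absorptance(abs_tbl("M"), 0.5)
  sc <- filter_scaling(1, 1)
  after <- to_energy_normalized(corneal_quantal(a, sc))
  before <- corneal_quantal(to_energy_normalized(a), sc)
  before$value <- before$value / max(before$value)
  expect_equal(after$value, before$value, tolerance = 1e-12)
})

test_that("raising lens density depresses the S-cone short-wave limb", {
  s_limb <- function(k_lens) {
    obs <- observer(od = c(L = 0.5, M = 0.5, S = 0.4),
                    scaling = filter_scaling(k_mac = 1, k_lens = k_lens))
    cf <- cone_fundamentals(obs)
    mean(cf$S[cf$wavelength <= 500])
  }
  limbs <- vapply(c(0.5, 1, 1.5, 2), s_limb, numeric(1))
  expect_true(all(diff(limbs) < 0))
})

test_that("observer variants and shifts propagate into the fundamentals", {
  shifted <- observer(shift_nm = c(L = 0, M = 4, S = 0))
  cf0 <- cone_fundamentals(standard_observer("2deg"), by = 0.5)
  cf1 <- cone_fundamentals(shifted, by = 0.5)
  expect_gt(find_lambda_max(cf1, column = "M"),
            find_lambda_max(cf0, column = "M"))
  expect_identical(cf1$S, cf0$S)

  ser <- cone_fundamentals(observer(l_variant = "ser180"), by = 0.5)
  ala <- cone_fundamentals(observer(l_variant = "ala180"), by = 0.5)
  expect_gt(find_lambda_max(ser, column = "L"),
            find_lambda_max(ala, column = "L"))

  mixed <- cone_fundamentals(observer(l_variant = "mixture"), by = 0.5)
  expect_identical(max(mixed$L), 1)

  expect_error(cone_fundamentals(standard_observer(), from = 300), "Grid")
  expect_error(cone_fundamentals(observer(shift_nm = c(L = 0, M = 0, S = -40)),
                                 from = 360),
               "support")
})
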