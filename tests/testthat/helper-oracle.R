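# Independent brute-force oracle for template evaluation, plus small
# spectral helpers used across the tests. The oracle reads the raw
# coefficient JSON itself and sums the trigonometric series term by term
# with a plain loop, independent of the package's vectorized evaluator.

oracle_registry <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      path <- system.file("extdata", "templates.json", package = "conefund",
                          mustWork = TRUE)
      raw <- jsonlite::read_json(path, simplifyVector = FALSE)
      cache <<- setNames(raw$templates,
                         vapply(raw$templates, `[[`, "", "name"))
    }
    cache
  }
})

# term-by-term Fourier sum at an arbitrary angle
oracle_fourier <- function(name, theta) {
  t <- oracle_registry()[[name]]
  vapply(theta, function(th) {
    acc <- t$a0
    for (k in seq_len(t$order)) {
      acc <- acc + t$a[[k]] * cos(k * th) + t$b[[k]] * sin(k * th)
    }
    acc
  }, numeric(1))
}

oracle_eval <- function(name, lambda) {
  t <- oracle_registry()[[name]]
  if (t$axis == "log10_nm") {
    th <- pi * log10(lambda / t$lambda_lo) / log10(t$lambda_hi / t$lambda_lo)
    oracle_fourier(name, th) + t$post_scale
  } else {
    out <- numeric(length(lambda))
    inside <- lambda >= t$lambda_lo & lambda <= t$lambda_hi
    th <- pi * (lambda[inside] - t$lambda_lo) / (t$lambda_hi - t$lambda_lo)
    out[inside] <- pmax(oracle_fourier(name, th) * t$post_scale, 0)
    out
  }
}

# full width at half maximum by linear interpolation of the half-max crossings
fwhm <- function(wavelength, value) {
  half <- max(value) / 2
  above <- value >= half
  i1 <- which(above)[1]
  i2 <- rev(which(above))[1]
  cross <- function(ia, ib) {
    # interpolate between the bracketing samples
    wavelength[ia] + (half - value[ia]) *
      (wavelength[ib] - wavelength[ia]) / (value[ib] - value[ia])
  }
  lo <- if (i1 == 1) wavelength[1] else cross(i1 - 1, i1)
  hi <- if (i2 == length(value)) wavelength[i2] else cross(i2 + 1, i2)
  hi - lo
}

expect_equal_tol <- function(object, expected, tol) {
  expect_true(all(abs(object - expected) <= tol),
              label = sprintf("max |diff| = %g (tol %g)",
                              max(abs(object - expected)), tol))
}
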