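# Deterministic toy inputs for tests and demonstrations.

#' Generate deterministic test fixtures
#'
#' Writes small plain-text inputs exercising the I/O and comparison paths:
#' narrowband Gaussian power spectra (with their analytic parameters in the
#' header), random positive tristimulus triples, and a degraded copy of the
#' standard 2-deg table (5-nm step, truncated range) for MAE comparisons.
#' The same seed always yields byte-identical files.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed.
#' @return Named character vector of the written file paths, invisibly.
#' @export
make_fixtures <- function(dir, seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)

  # narrowband Gaussian power spectra; analytic area = amp * sd * sqrt(2*pi)
  centers <- round(stats::runif(3, 430, 640))
  sds <- round(stats::runif(3, 8, 25), 1)
  amps <- round(stats::runif(3, 0.5, 2), 3)
  grid <- seq(390, 830, by = 1)
  spectra <- purrr::pmap(list(centers, sds, amps), function(c0, s0, a0) {
    a0 * exp(-0.5 * ((grid - c0) / s0)^2)
  })
  gauss <- tibble(wavelength = grid)
  for (i in 1:3) gauss[[paste0("power", i)]] <- spectra[[i]]
  gauss_path <- file.path(dir, "gaussian_spectra.csv")
  writeLines(c(
    sprintf("# gaussian power spectra; center=%s sd=%s amp=%s",
            paste(centers, collapse = "/"), paste(sds, collapse = "/"),
            paste(amps, collapse = "/")),
    paste(names(gauss), collapse = ","),
    do.call(paste, c(purrr::map(gauss, ~ sprintf("%.8f", .x)), sep = ","))
  ), gauss_path)

  tri <- tibble(L = round(stats::runif(8, 0.1, 5), 6),
                M = round(stats::runif(8, 0.1, 5), 6),
                S = round(stats::runif(8, 0.1, 5), 6))
  tri_path <- file.path(dir, "tristimuli.csv")
  utils::write.csv(tri, tri_path, row.names = FALSE, quote = FALSE)

  # degraded standard table: 5-nm step, truncated to 400-700 nm
  cf <- cone_fundamentals(standard_observer("2deg"), from = 400, to = 700, by = 5)
  ref_path <- file.path(dir, "standard2_5nm_truncated.csv")
  write_cmf_table(cf, ref_path)

  invisible(c(gaussian = gauss_path, tristimuli = tri_path,
              reference = ref_path))
}
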