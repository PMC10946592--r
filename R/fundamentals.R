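# Assembly of corneal cone fundamentals: photopigment absorbance ->
# absorptance (self-screening) -> pre-receptoral filtering -> quantal or
# energy sensitivity, normalized to unit peak.

#' Observer parameters
#'
#' Describes the physiological parameters from which an observer's cone
#' fundamentals are generated: peak axial photopigment optical densities,
#' macular/lens density scalings, per-cone peak-wavelength shifts, and the
#' L-cone opsin variant.
#'
#' @param field Free-text label (e.g. `"2deg"`).
#' @param od Named numeric vector `c(L=, M=, S=)` of peak photopigment
#'   optical densities in log10 units, each in (0, 2].
#' @param scaling A [filter_scaling()].
#' @param shift_nm Named numeric `c(L=, M=, S=)` of signed peak shifts in nm
#'   applied to each cone's absorbance template.
#' @param l_variant L-cone template choice: `"mean"` (the population-mean
#'   template, itself the 0.44:0.56 ala/ser average), `"ser180"`,
#'   `"ala180"`, or `"mixture"` to re-mix the two polymorphic templates.
#' @param w_ser Serine-180 weight when `l_variant = "mixture"` (default
#'   0.56, the population proportion; the ala weight is `1 - w_ser`).
#' @return A `cone_observer` object.
#' @seealso [standard_observer()] for the CIE 2-deg and 10-deg parameter
#'   sets; [cone_fundamentals()] to generate the spectra.
#' @export
observer <- function(field = "custom",
                     od = c(L = 0.50, M = 0.50, S = 0.40),
                     scaling = filter_scaling(),
                     shift_nm = c(L = 0, M = 0, S = 0),
                     l_variant = c("mean", "ser180", "ala180", "mixture"),
                     w_ser = 0.56) {
  l_variant <- match.arg(l_variant)
  od <- od[c("L", "M", "S")]
  shift_nm <- shift_nm[c("L", "M", "S")]
  if (any(is.na(od)) || any(od <= 0) || any(od > 2)) {
    abort("Photopigment optical densities must be named L/M/S and lie in (0, 2]")
  }
  if (any(is.na(shift_nm))) abort("shift_nm must be a named L/M/S vector")
  if (w_ser < 0 || w_ser > 1) abort("w_ser must lie in [0, 1]")
  structure(
    list(field = field, od = od, scaling = scaling, shift_nm = shift_nm,
         l_variant = l_variant, w_ser = w_ser),
    class = "cone_observer"
  )
}

#' Standard observers
#'
#' The standard 2-deg observer uses peak photopigment optical densities
#' (0.50, 0.50, 0.40) for L, M, S with unit macular and lens scaling; the
#' 10-deg observer uses (0.38, 0.38, 0.30) with `k_mac = 0.271` (macular
#' pigment is largely absent over a 10-deg field) and `k_lens = 1`.
#'
#' @param field `"2deg"` or `"10deg"` (also accepts `2`/`10`).
#' @return A `cone_observer`.
#' @export
standard_observer <- function(field = c("2deg", "10deg")) {
  if (is.numeric(field)) field <- paste0(field, "deg")
  field <- match.arg(field)
  if (field == "2deg") {
    observer(field = "2deg", od = c(L = 0.50, M = 0.50, S = 0.40),
             scaling = filter_scaling(k_mac = 1, k_lens = 1))
  } else {
    observer(field = "10deg", od = c(L = 0.38, M = 0.38, S = 0.30),
             scaling = filter_scaling(k_mac = 0.271, k_lens = 1))
  }
}

#' @export
print.cone_observer <- function(x, ...) {
  cat("<cone_observer> ", x$field, "\n", sep = "")
  cat(sprintf("  OD: L %.2f, M %.2f, S %.2f; k_mac %.3f, k_lens %.3f\n",
              x$od["L"], x$od["M"], x$od["S"],
              x$scaling$k_mac, x$scaling$k_lens))
  if (any(x$shift_nm != 0)) {
    cat("  peak shifts (nm):", paste(names(x$shift_nm), x$shift_nm,
                                     sep = "=", collapse = " "), "\n")
  }
  cat("  L variant:", x$l_variant,
      if (x$l_variant == "mixture") sprintf("(w_ser %.2f)", x$w_ser), "\n")
  invisible(x)
}

# Absorbance templates for an observer, with variant selection and per-cone
# nm shifts converted to log10 units at each base template's own peak.
observer_templates <- function(obs) {
  l_base <- switch(obs$l_variant,
    mean = builtin_template("L"),
    ser180 = polymorphic_L("ser180"),
    ala180 = polymorphic_L("ala180"),
    mixture = mix_templates(
      list(polymorphic_L("ala180"), polymorphic_L("ser180")),
      c(1 - obs$w_ser, obs$w_ser))
  )
  tpl <- list(L = l_base, M = builtin_template("M"), S = builtin_template("S"))
  purrr::imap(tpl, function(t, cone) {
    dnm <- obs$shift_nm[[cone]]
    if (dnm == 0) return(t)
    ref <- find_lambda_max(t)
    shift_template(t, shift_nm_to_log10(dnm, ref))
  })
}

#' Photopigment absorptance from absorbance
#'
#' Converts a unit-peak linear absorbance spectrum into the absorptance of a
#' pigment layer with peak axial optical density `od`:
#' `1 - 10^(-od * A(lambda))`. Higher densities broaden the spectrum
#' (self-screening) without moving its peak.
#'
#' @param absorbance A tibble with columns `wavelength` and `value` holding
#'   linear absorbance in `[0, 1]`.
#' @param od Peak axial photopigment optical density (log10 units, > 0).
#' @return A tibble `wavelength`/`value` of absorptances in
#'   `(0, 1 - 10^-od]`.
#' @export
absorptance <- function(absorbance, od) {
  if (od <= 0) abort("Photopigment optical density must be positive")
  dplyr::mutate(absorbance, value = 1 - 10^(-od * .data$value))
}

#' Apply pre-receptoral filtering to an absorptance spectrum
#'
#' Multiplies pointwise by the transmittance of the combined lens and
#' macular pigments, `10^-(k_lens*lens + k_mac*mac)`, giving the quantal
#' corneal spectral sensitivity (up to normalization).
#'
#' @param absorptance_tbl A tibble `wavelength`/`value`.
#' @param scaling A [filter_scaling()].
#' @return A tibble `wavelength`/`value`.
#' @export
corneal_quantal <- function(absorptance_tbl, scaling = filter_scaling()) {
  d <- total_prereceptoral_density(absorptance_tbl$wavelength, scaling)
  dplyr::mutate(absorptance_tbl, value = .data$value * 10^(-d))
}

#' Convert a quantal sensitivity to energy units and normalize
#'
#' Photon energy is inversely proportional to wavelength, so an energy-unit
#' sensitivity is the quantal sensitivity multiplied by wavelength, here
#' rescaled to a unit peak on its grid. The multiplication shifts the peak
#' slightly toward longer wavelengths.
#'
#' @param quantal A tibble `wavelength`/`value` of quantal sensitivities.
#' @return A tibble `wavelength`/`value` with unit peak; the scaling
#'   constant is stored in the `alpha` attribute.
#' @export
to_energy_normalized <- function(quantal) {
  v <- quantal$value * quantal$wavelength
  m <- max(v)
  if (m <= 0) abort("Cannot normalize an all-zero sensitivity")
  out <- dplyr::mutate(quantal, value = v / m)
  attr(out, "alpha") <- 1 / m
  out
}

#' Generate corneal cone fundamentals
#'
#' Runs the full pipeline for each cone class: absorbance template
#' (selected and shifted per the observer) -> linear absorbance ->
#' absorptance at the observer's photopigment optical density ->
#' pre-receptoral (lens + macular) filtering -> quantal sensitivity, and
#' optionally energy units (multiplication by wavelength). Each returned
#' fundamental is normalized to peak at exactly 1 on the output grid, with
#' the scaling constants recorded.
#'
#' The default grid, 390-830 nm at 1 nm, is the standard tabulation range.
#' The templates extend over 360-850 nm and the full range can be requested,
#' but the extensions beyond 390-830 nm are extrapolations and should be
#' used with caution.
#'
#' @param obs A [observer()] or [standard_observer()].
#' @param from,to,by Output wavelength grid in nm.
#' @param units `"energy"` (default) or `"quantal"`.
#' @return A `cone_fundamentals` tibble with columns `wavelength`, `L`,
#'   `M`, `S`; attributes `observer`, `units`, `alpha` (named normalization
#'   constants) and `step`.
#' @examples
#' cf <- cone_fundamentals(standard_observer("2deg"))
#' glance(cf)
#' @export
cone_fundamentals <- function(obs = standard_observer("2deg"),
                              from = 390, to = 830, by = 1,
                              units = c("energy", "quantal")) {
  units <- match.arg(units)
  if (from < 360 || to > 850 || !(from < to) || by <= 0) {
    abort("Grid must satisfy 360 <= from < to <= 850 and by > 0")
  }
  tpl <- observer_templates(obs)
  grid <- round(seq(from, to, by = by), 10)
  alpha <- c(L = NA_real_, M = NA_real_, S = NA_real_)
  cols <- purrr::imap(tpl, function(t, cone) {
    sup <- template_support(t)
    if (grid[1] < sup[1] || grid[length(grid)] > sup[2]) {
      abort(sprintf(
        "Requested grid extends beyond the shifted %s template support [%.1f, %.1f] nm",
        cone, sup[1], sup[2]))
    }
    tibble(wavelength = grid,
           value = eval_template(t, grid, value = "linear")) |>
      absorptance(od = obs$od[[cone]]) |>
      corneal_quantal(scaling = obs$scaling)
  })
  if (units == "energy") {
    cols <- purrr::map(cols, to_energy_normalized)
    alpha[] <- purrr::map_dbl(cols, ~ attr(.x, "alpha"))
  } else {
    cols <- purrr::map(cols, function(x) {
      m <- max(x$value)
      out <- dplyr::mutate(x, value = .data$value / m)
      attr(out, "alpha") <- 1 / m
      out
    })
    alpha[] <- purrr::map_dbl(cols, ~ attr(.x, "alpha"))
  }
  out <- tibble(wavelength = grid,
                L = cols$L$value, M = cols$M$value, S = cols$S$value)
  structure(out,
            class = c("cone_fundamentals", class(out)),
            observer = obs, units = units, alpha = alpha, step = by,
            space = "LMS")
}

#' @export
print.cone_fundamentals <- function(x, ...) {
  obs <- attr(x, "observer")
  cat("Cone fundamentals (", attr(x, "units"), " units, ",
      obs$field, " observer)\n", sep = "")
  NextMethod()
}

#' @rdname cone_fundamentals
#' @param x A `cone_fundamentals` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
#' @export
tidy.cone_fundamentals <- function(x, ...) {
  tidyr::pivot_longer(as_tibble(x), cols = -"wavelength",
                      names_to = "cone", values_to = "sensitivity")
}

#' @rdname cone_fundamentals
#' @exportS3Method generics::glance
#' @export
glance.cone_fundamentals <- function(x, ...) {
  obs <- attr(x, "observer")
  tb <- as_tibble(x)
  tibble(
    field = obs$field,
    units = attr(x, "units"),
    n = nrow(tb),
    step = attr(x, "step"),
    lambda_min = min(tb$wavelength),
    lambda_max_grid = max(tb$wavelength),
    peak_L = find_lambda_max(tb, column = "L"),
    peak_M = find_lambda_max(tb, column = "M"),
    peak_S = find_lambda_max(tb, column = "S"),
    od_L = obs$od[["L"]], od_M = obs$od[["M"]], od_S = obs$od[["S"]],
    k_mac = obs$scaling$k_mac, k_lens = obs$scaling$k_lens
  )
}

#' Plot cone fundamentals
#'
#' @param object A `cone_fundamentals` object.
#' @param log10 Plot log10 sensitivities instead of linear.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.cone_fundamentals <- function(object, log10 = FALSE, ...) {
  d <- tidy(object)
  if (log10) d <- dplyr::filter(d, .data$sensitivity > 0) |>
      dplyr::mutate(sensitivity = base::log10(.data$sensitivity))
  ggplot2::ggplot(d, ggplot2::aes(.data$wavelength, .data$sensitivity,
                                  colour = .data$cone)) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_manual(values = c(L = "#c0392b", M = "#27ae60",
                                            S = "#2980b9")) +
    ggplot2::labs(x = "Wavelength (nm)",
                  y = if (log10) "log10 sensitivity" else "Relative sensitivity",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
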