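# Fourier-polynomial spectral templates: evaluation, registry, peak search.
#
# A template is the truncated Fourier series
#   F(theta) = a0 + sum_{k=1}^n [ a_k cos(k theta) + b_k sin(k theta) ]
# evaluated at an angle theta that sweeps 0..pi across the template's fitted
# wavelength range, either on a log10-wavelength axis (photopigment
# absorbances, 360-850 nm) or a linear axis (macular and lens densities).
# A per-template post-scale is then applied: an additive renormalization s
# for the log-absorbance templates (so the linear absorbance peaks at 1 to
# the nearest 0.1 nm), or a multiplicative factor d for the density
# templates (pinning the standard anchor densities).

.conefund <- new.env(parent = emptyenv())

template_registry <- function() {
  if (is.null(.conefund$registry)) {
    path <- system.file("extdata", "templates.json", package = "conefund",
                        mustWork = TRUE)
    raw <- jsonlite::read_json(path, simplifyVector = FALSE)
    reg <- lapply(raw$templates, function(t) {
      new_cone_template(
        name = t$name, order = t$order, a0 = t$a0,
        a = unlist(t$a), b = unlist(t$b),
        post_scale_kind = t$post_scale_kind, post_scale = t$post_scale,
        axis = t$axis, lambda_lo = t$lambda_lo, lambda_hi = t$lambda_hi,
        out_of_range = t$out_of_range, units = t$units
      )
    })
    names(reg) <- vapply(raw$templates, `[[`, "", "name")
    .conefund$registry <- reg
    .conefund$registry_version <- raw$version
  }
  .conefund$registry
}

new_cone_template <- function(name, order, a0, a, b, post_scale_kind,
                              post_scale, axis, lambda_lo, lambda_hi,
                              out_of_range, units, shift = 0) {
  stopifnot(length(a) == order, length(b) == order, lambda_lo < lambda_hi)
  structure(
    list(name = name, order = order, a0 = a0, a = a, b = b,
         post_scale_kind = match.arg(post_scale_kind,
                                     c("additive_s", "multiplicative_d")),
         post_scale = post_scale,
         axis = match.arg(axis, c("log10_nm", "linear_nm")),
         lambda_lo = lambda_lo, lambda_hi = lambda_hi,
         out_of_range = match.arg(out_of_range, c("error", "zero")),
         units = units, shift = shift),
    class = "cone_template"
  )
}

#' Built-in spectral templates
#'
#' Returns one of the packaged Fourier-polynomial templates: the L-, M- and
#' S-cone log10 photopigment absorbance spectra (the mean-observer set), the
#' polymorphic `L_ser180_poly` absorbance template, the shape-invariant
#' `L_common` template shared by all three cones, and the `macular` and
#' `lens` pigment optical density spectra.
#'
#' The absorbance templates are defined on a log10-wavelength axis over
#' 360-850 nm and evaluate to log10 absorbance (unit linear peak). The
#' density templates are defined on a linear wavelength axis (macular
#' 375-550 nm, lens 360-660 nm) and are zero outside their fitted support.
#'
#' @param name One of `"L"`, `"M"`, `"S"`, `"L_ser180_poly"`, `"L_common"`,
#'   `"macular"`, `"lens"`.
#' @return A `cone_template` object.
#' @examples
#' builtin_template("L")
#' find_lambda_max(builtin_template("M"))
#' @export
builtin_template <- function(name) {
  reg <- template_registry()
  if (!name %in% names(reg)) {
    abort(paste0("Unknown template '", name, "'. Available: ",
                 paste(names(reg), collapse = ", ")))
  }
  reg[[name]]
}

#' @export
print.cone_template <- function(x, ...) {
  cat("<cone_template> ", x$name,
      if (x$shift != 0) sprintf(" [shifted %+0.6f log10 nm]", x$shift), "\n",
      sep = "")
  cat("  order ", x$order, ", ", x$axis, " axis, ",
      x$lambda_lo, "-", x$lambda_hi, " nm, units: ", x$units, "\n", sep = "")
  invisible(x)
}

#' Map a wavelength to the template's Fourier angle
#'
#' The angle runs from 0 at the template's lower wavelength limit to pi at
#' its upper limit, linearly in log10(wavelength) for the absorbance
#' templates and linearly in wavelength for the density templates.
#'
#' @param lambda_nm Wavelength(s) in nm, within the template's fitted range.
#' @param template A `cone_template`.
#' @return Angle(s) in radians, in `[0, pi]`.
#' @export
map_theta <- function(lambda_nm, template) {
  bad <- lambda_nm < template$lambda_lo | lambda_nm > template$lambda_hi
  if (any(bad)) {
    abort(sprintf("Wavelength %g nm outside template domain [%g, %g] nm",
                  lambda_nm[bad][1], template$lambda_lo, template$lambda_hi))
  }
  if (template$axis == "log10_nm") {
    pi * log10(lambda_nm / template$lambda_lo) /
      log10(template$lambda_hi / template$lambda_lo)
  } else {
    pi * (lambda_nm - template$lambda_lo) /
      (template$lambda_hi - template$lambda_lo)
  }
}

fourier_sum <- function(template, theta) {
  k <- seq_len(template$order)
  # cos/sin term matrices: rows = theta, cols = harmonic
  kt <- outer(theta, k)
  drop(template$a0 + cos(kt) %*% template$a + sin(kt) %*% template$b)
}

#' Wavelength range over which a template can be evaluated
#'
#' For absorbance templates this is 360-850 nm contracted by any applied
#' log-wavelength shift; density templates evaluate (to zero) over all of
#' 360-850 nm.
#'
#' @param template A `cone_template` or template mixture.
#' @return Length-2 numeric `c(lo, hi)` in nm.
#' @export
template_support <- function(template) {
  UseMethod("template_support")
}

#' @export
template_support.cone_template <- function(template) {
  if (template$out_of_range == "zero") return(c(360, 850))
  f <- 10^template$shift
  c(max(360, template$lambda_lo * f), min(850, template$lambda_hi * f))
}

#' Evaluate a spectral template
#'
#' Computes the Fourier polynomial at the template's angle mapping and
#' applies its post-scale: the additive renormalization term for
#' log-absorbance templates, or the multiplicative factor for density
#' templates (which are additionally clamped at zero from below and are
#' exactly zero outside their fitted support). If the template carries a
#' log-wavelength shift, the value at `lambda` is the unshifted value at
#' `lambda * 10^(-shift)`.
#'
#' @param template A `cone_template` (or mixture from [mix_templates()]).
#' @param lambda_nm Wavelengths in nm.
#' @param value `"native"` for the template's own units (log10 absorbance or
#'   optical density), `"linear"` for linear absorbance (antilog; only
#'   meaningful for absorbance templates).
#' @param clamp Clamp density values at zero from below (default). Set to
#'   `FALSE` to inspect the raw fitted polynomial.
#' @return Numeric vector of template values at `lambda_nm`.
#' @examples
#' eval_template(builtin_template("macular"), 460)
#' eval_template(builtin_template("lens"), 400)
#' @export
eval_template <- function(template, lambda_nm, value = c("native", "linear"),
                          clamp = TRUE) {
  UseMethod("eval_template")
}

#' @export
eval_template.cone_template <- function(template, lambda_nm,
                                        value = c("native", "linear"),
                                        clamp = TRUE) {
  value <- match.arg(value)
  lam_eff <- lambda_nm * 10^(-template$shift)

  if (template$out_of_range == "zero") {
    if (any(lambda_nm < 360 | lambda_nm > 850)) {
      abort("Wavelength outside 360-850 nm")
    }
    out <- numeric(length(lam_eff))
    inside <- lam_eff >= template$lambda_lo & lam_eff <= template$lambda_hi
    if (any(inside)) {
      v <- fourier_sum(template, map_theta(lam_eff[inside], template))
      v <- v * template$post_scale
      if (clamp) v <- pmax(v, 0)
      out[inside] <- v
    }
    if (value == "linear") {
      abort("Linear absorbance is undefined for density templates")
    }
    return(out)
  }

  v <- fourier_sum(template, map_theta(lam_eff, template)) + template$post_scale
  if (value == "linear") 10^v else v
}

#' Wavelength of peak linear sensitivity
#'
#' Locates the maximum of the linear template value (or of a tabulated
#' spectral function) on a uniform grid at the requested resolution over the
#' searchable support; ties break toward the shorter wavelength, and the
#' result is reported at the grid resolution.
#'
#' @param x A `cone_template`, template mixture, or a data frame with a
#'   `wavelength` column and one value column.
#' @param resolution Search grid step in nm (default 0.1).
#' @param column For data frames with several value columns, which one to use.
#' @return Peak wavelength in nm.
#' @examples
#' find_lambda_max(builtin_template("L")) # 551.9
#' @export
find_lambda_max <- function(x, resolution = 0.1, column = NULL) {
  UseMethod("find_lambda_max")
}

#' @export
find_lambda_max.default <- function(x, resolution = 0.1, column = NULL) {
  sup <- template_support(x)
  if (sup[1] >= sup[2]) abort("Degenerate template support")
  grid <- peak_grid(sup, resolution)
  vals <- linear_value(x, grid)
  grid[which.max(vals)]
}

#' @export
find_lambda_max.data.frame <- function(x, resolution = 0.1, column = NULL) {
  if (!"wavelength" %in% names(x)) abort("Need a 'wavelength' column")
  vcols <- setdiff(names(x), c("wavelength"))
  col <- column %||% vcols[1]
  if (nrow(x) == 0) abort("Empty spectral function")
  x$wavelength[which.max(x[[col]])]
}

peak_grid <- function(sup, resolution) {
  # snap the grid to multiples of the resolution so reported peaks land on
  # the 0.1 nm lattice regardless of shift
  lo <- ceiling(sup[1] / resolution) * resolution
  hi <- floor(sup[2] / resolution) * resolution
  round(seq(lo, hi, by = resolution), 10)
}

linear_value <- function(x, lambda) {
  if (inherits(x, "cone_template") && x$units == "density") {
    eval_template(x, lambda)
  } else {
    eval_template(x, lambda, value = "linear")
  }
}

#' Tabulate a template on a uniform wavelength grid
#'
#' @inheritParams eval_template
#' @param from,to,by Grid range and step in nm; endpoints are included when
#'   `(to - from)` is a multiple of `by`.
#' @return A tibble with columns `wavelength` and `value`, with the value
#'   units recorded in the `units` attribute.
#' @examples
#' tabulate_template(builtin_template("lens"), 390, 830, 5)
#' @export
tabulate_template <- function(template, from, to, by = 1,
                              value = c("native", "linear")) {
  value <- match.arg(value)
  if (!(from < to) || by <= 0) abort("Need from < to and by > 0")
  grid <- round(seq(from, to, by = by), 10)
  out <- tibble(wavelength = grid,
                value = eval_template(template, grid, value = value))
  units <- if (inherits(template, "cone_template")) template$units else "linear_absorbance"
  if (value == "linear") units <- "linear_absorbance"
  attr(out, "units") <- units
  out
}
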