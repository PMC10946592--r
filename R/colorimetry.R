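# Tristimulus integration, chromaticity projection, and exact linear
# transformations between the LMS, Stiles-Burch RGB and XYZ colour-matching
# spaces.

space_channels <- function(space) {
  switch(toupper(space),
         LMS = c("L", "M", "S"),
         RGB = c("R", "G", "B"),
         XYZ = c("X", "Y", "Z"),
         abort(paste0("Unknown colour space '", space, "'")))
}

matrix_registry <- function() {
  if (is.null(.conefund$matrices)) {
    path <- system.file("extdata", "matrices.json", package = "conefund",
                        mustWork = TRUE)
    raw <- jsonlite::read_json(path, simplifyVector = FALSE)
    mats <- lapply(raw$matrices, function(m) {
      mat <- do.call(rbind, lapply(m$m, unlist))
      dimnames(mat) <- list(space_channels(m$to), space_channels(m$from))
      attr(mat, "field") <- m$field
      mat
    })
    names(mats) <- vapply(raw$matrices, `[[`, "", "name")
    .conefund$matrices <- mats
  }
  .conefund$matrices
}

#' Colour-space transformation matrices
#'
#' Returns the packaged 3x3 matrix mapping tristimulus values (or CMFs)
#' from one colour-matching space to another. The built-ins are the
#' Stiles-Burch 10-deg RGB to LMS matrix and the 2-deg and 10-deg LMS to
#' XYZ matrices; the reverse directions use the numerical inverses.
#'
#' @param from,to `"LMS"`, `"RGB"` or `"XYZ"`.
#' @param field `"2deg"` or `"10deg"`. RGB transformations exist only for
#'   the 10-deg Stiles-Burch primaries.
#' @return A 3x3 matrix with channel dimnames (rows = `to`, cols = `from`).
#' @examples
#' cmf_matrix("LMS", "XYZ", "2deg")
#' @export
cmf_matrix <- function(from, to, field = c("2deg", "10deg")) {
  field <- match.arg(field)
  from <- toupper(from); to <- toupper(to)
  mats <- matrix_registry()
  key <- paste(from, to, sep = "_")
  out <- switch(
    key,
    RGB_LMS = {
      if (field != "10deg") abort("RGB transformations are defined for the 10-deg Stiles-Burch primaries only")
      mats$rgb10_to_lms
    },
    LMS_RGB = {
      if (field != "10deg") abort("RGB transformations are defined for the 10-deg Stiles-Burch primaries only")
      inv_labeled(mats$rgb10_to_lms)
    },
    LMS_XYZ = if (field == "2deg") mats$lms_to_xyz_2deg else mats$lms_to_xyz_10deg,
    XYZ_LMS = inv_labeled(if (field == "2deg") mats$lms_to_xyz_2deg else mats$lms_to_xyz_10deg),
    LMS_LMS = diag3("LMS"),
    RGB_RGB = diag3("RGB"),
    XYZ_XYZ = diag3("XYZ"),
    abort(paste0("No transformation from ", from, " to ", to))
  )
  out
}

inv_labeled <- function(m) {
  out <- solve(m)
  dimnames(out) <- rev(dimnames(m))
  out
}

diag3 <- function(space) {
  ch <- space_channels(space)
  m <- diag(3)
  dimnames(m) <- list(ch, ch)
  m
}

#' Build an RGB-to-LMS matrix for arbitrary primaries
#'
#' The matrix columns are the cone sensitivities to each primary: for a
#' monochromatic primary of wavelength `lambda`, the column is the LMS
#' fundamentals read off at `lambda`; for a broadband primary the column is
#' the tristimulus integral of its power spectrum.
#'
#' @param cmfs A `cone_fundamentals` (energy units).
#' @param primaries Either a numeric vector of three monochromatic primary
#'   wavelengths in nm (R, G, B order), or a list of three power-spectrum
#'   tibbles (`wavelength`/`power`).
#' @return A 3x3 matrix mapping RGB tristimulus values to LMS.
#' @export
primaries_matrix <- function(cmfs, primaries) {
  if (attr(cmfs, "units") != "energy") {
    abort("Primary matrices are defined for energy-unit fundamentals")
  }
  cols <- if (is.numeric(primaries)) {
    if (length(primaries) != 3) abort("Need exactly three primaries")
    lapply(primaries, function(lam) {
      i <- match(TRUE, abs(cmfs$wavelength - lam) < 1e-9)
      if (is.na(i)) abort(sprintf("Primary wavelength %g nm is not on the CMF grid", lam))
      c(cmfs$L[i], cmfs$M[i], cmfs$S[i])
    })
  } else {
    lapply(primaries, function(p) unlist(tristimulus(p, cmfs)))
  }
  m <- do.call(cbind, cols)
  dimnames(m) <- list(c("L", "M", "S"), c("R", "G", "B"))
  m
}

#' Tristimulus values of a light
#'
#' Integrates a spectral power distribution against a set of colour
#' matching functions by the rectangle rule on the CMF grid:
#' `sum(P * cmf) * step` per channel.
#'
#' @param power A tibble with columns `wavelength` and `power` (energy
#'   units), covering the CMF grid wavelengths it should contribute to.
#' @param cmfs A `cone_fundamentals` or transformed CMF set (energy units;
#'   pass `power_units = "quantal"` to integrate quantal CMFs against a
#'   quantal power spectrum).
#' @param power_units Units of `power`; must match the CMF units.
#' @return A one-row tibble of tristimulus values, with the channel names
#'   of the CMF space and attribute `space`.
#' @export
tristimulus <- function(power, cmfs, power_units = c("energy", "quantal")) {
  power_units <- match.arg(power_units)
  cmf_units <- attr(cmfs, "units") %||% "energy"
  if (cmf_units != power_units) {
    abort(sprintf("Unit mismatch: %s-unit CMFs with %s-unit power spectrum",
                  cmf_units, power_units))
  }
  step <- attr(cmfs, "step") %||% unique(round(diff(cmfs$wavelength), 9))[1]
  ch <- setdiff(names(cmfs), "wavelength")
  joined <- dplyr::inner_join(as_tibble(cmfs),
                              as_tibble(power)[c("wavelength", "power")],
                              by = "wavelength")
  vals <- purrr::map_dbl(ch, ~ sum(joined[[.x]] * joined$power) * step)
  out <- as_tibble(setNames(as.list(vals), ch))
  attr(out, "space") <- paste(ch, collapse = "")
  out
}

#' Chromaticity coordinates
#'
#' Projects tristimulus values onto the unit-sum plane: each of the first
#' two channels divided by the channel sum (the third coordinate is the
#' complement). Works row-wise on a one-row tristimulus tibble or on a
#' many-row table such as a transformed CMF set; a `wavelength` column, if
#' present, is carried through.
#'
#' @param x A tibble with three channel columns (`L,M,S`, `R,G,B` or
#'   `X,Y,Z`), optionally with a `wavelength` column.
#' @return A tibble of two chromaticity coordinates (named `l,m`, `r,g` or
#'   `x,y` to match the input space).
#' @examples
#' chromaticity(tibble::tibble(L = 1, M = 1, S = 1)) # (1/3, 1/3)
#' @export
chromaticity <- function(x) {
  x <- as_tibble(x)
  ch <- intersect(c("L", "M", "S", "R", "G", "B", "X", "Y", "Z"), names(x))
  if (length(ch) != 3) abort("Need exactly three tristimulus channel columns")
  # restore canonical channel order for the space
  space <- paste(sort(ch), collapse = "")
  ch <- switch(space, LMS = c("L", "M", "S"), BGR = c("R", "G", "B"),
               XYZ = c("X", "Y", "Z"), ch)
  tot <- x[[ch[1]]] + x[[ch[2]]] + x[[ch[3]]]
  if (any(tot == 0)) abort("Chromaticity undefined for zero tristimulus sum")
  out <- tibble(a = x[[ch[1]]] / tot, b = x[[ch[2]]] / tot)
  names(out) <- tolower(ch[1:2])
  if ("wavelength" %in% names(x)) {
    out <- dplyr::bind_cols(tibble(wavelength = x$wavelength), out)
  }
  out
}

#' Transform a set of CMFs to another colour space
#'
#' Applies the exact packaged matrix (or its inverse) pointwise across the
#' wavelength grid. Transformed CMFs are not renormalized: the matrices
#' carry their own scaling conventions.
#'
#' @param cmfs A `cone_fundamentals` or previously transformed CMF tibble.
#' @param to Target space: `"LMS"`, `"RGB"` or `"XYZ"`.
#' @param field `"2deg"` or `"10deg"`; defaults to the observer's field
#'   label when it is one of the standards.
#' @return A tibble `wavelength` + three channel columns, carrying `units`,
#'   `step` and `space` attributes.
#' @export
transform_cmfs <- function(cmfs, to, field = NULL) {
  from_ch <- intersect(c("L", "M", "S", "R", "G", "B", "X", "Y", "Z"),
                       names(cmfs))
  from <- paste(from_ch, collapse = "")
  field <- field %||% guess_field(cmfs)
  m <- cmf_matrix(from, to, field)
  vals <- as.matrix(as_tibble(cmfs)[, colnames(m), drop = FALSE]) %*% t(m)
  out <- dplyr::bind_cols(tibble(wavelength = cmfs$wavelength),
                          as_tibble(as.data.frame(vals)))
  attr(out, "units") <- attr(cmfs, "units")
  attr(out, "step") <- attr(cmfs, "step")
  attr(out, "space") <- toupper(to)
  out
}

guess_field <- function(cmfs) {
  obs <- attr(cmfs, "observer")
  if (!is.null(obs) && obs$field %in% c("2deg", "10deg")) obs$field else "2deg"
}

#' Spectrum locus in a chromaticity diagram
#'
#' Chromaticity coordinates of the monochromatic lights across the CMF
#' grid, in cone (`lm`), Stiles-Burch RGB (`rg`) or XYZ (`xy`) coordinates.
#'
#' @param cmfs A `cone_fundamentals` in energy units.
#' @param space `"lm"`, `"rg"` or `"xy"`.
#' @param field Passed to [transform_cmfs()] for `rg`/`xy`.
#' @return A `cone_locus` tibble: `wavelength` plus two coordinates.
#' @export
spectrum_locus <- function(cmfs, space = c("lm", "rg", "xy"), field = NULL) {
  space <- match.arg(space)
  if (!is.null(attr(cmfs, "units")) && attr(cmfs, "units") != "energy") {
    abort("Spectrum loci are computed from energy-unit CMFs")
  }
  set <- switch(space,
                lm = cmfs,
                rg = transform_cmfs(cmfs, "RGB", field = "10deg"),
                xy = transform_cmfs(cmfs, "XYZ", field = field))
  out <- chromaticity(set)
  structure(out, class = c("cone_locus", class(out)), space = space)
}

#' Plot a spectrum locus
#'
#' @param object A `cone_locus`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.cone_locus <- function(object, ...) {
  nm <- setdiff(names(object), "wavelength")
  ggplot2::ggplot(object, ggplot2::aes(.data[[nm[1]]], .data[[nm[2]]])) +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}
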