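# Pre-receptoral filtering: macular and lens pigment optical densities and
# transmittances, with observer-specific linear scaling of the standard
# density spectra.

#' Macular and lens density scaling for an observer
#'
#' The standard density spectra are scaled linearly per observer. Scalings
#' can be given directly (`k_mac`, `k_lens`; the 2-deg standard is 1 and 1,
#' the 10-deg standard has `k_mac = 0.271`) or, as is common in the
#' literature, as peak densities: macular density at 460 nm
#' (`d_mac460`, standard 0.350) and lens density at 400 nm
#' (`d_lens400`, standard 1.7649).
#'
#' @param k_mac,k_lens Non-negative multiplicative scalings of the standard
#'   macular and lens density spectra.
#' @param d_mac460 Alternative: macular density at 460 nm; sets
#'   `k_mac = d_mac460 / 0.350`.
#' @param d_lens400 Alternative: lens density at 400 nm; sets
#'   `k_lens = d_lens400 / 1.7649`.
#' @return A `filter_scaling` list with elements `k_mac` and `k_lens`.
#' @examples
#' filter_scaling(d_mac460 = 0.095) # a 10-deg-like macular scaling
#' @export
filter_scaling <- function(k_mac = 1, k_lens = 1,
                           d_mac460 = NULL, d_lens400 = NULL) {
  if (!is.null(d_mac460)) {
    if (!missing(k_mac)) abort("Give either k_mac or d_mac460, not both")
    k_mac <- d_mac460 / 0.350
  }
  if (!is.null(d_lens400)) {
    if (!missing(k_lens)) abort("Give either k_lens or d_lens400, not both")
    k_lens <- d_lens400 / 1.7649
  }
  if (k_mac < 0 || k_lens < 0) abort("Filter scalings must be non-negative")
  structure(list(k_mac = k_mac, k_lens = k_lens), class = "filter_scaling")
}

#' Macular pigment optical density
#'
#' Standard macular density spectrum scaled by `k_mac`; zero outside the
#' 375-550 nm support. The standard (k = 1) density is 0.350 at 460 nm.
#'
#' @param lambda_nm Wavelengths in nm (360-850).
#' @param k_mac Non-negative scaling (1 = 2-deg standard, 0.271 = 10-deg).
#' @return Optical density (log10 attenuation) at each wavelength.
#' @export
macular_density <- function(lambda_nm, k_mac = 1) {
  if (k_mac < 0) abort("k_mac must be non-negative")
  k_mac * eval_template(builtin_template("macular"), lambda_nm)
}

#' Lens pigment optical density
#'
#' Standard lens density spectrum scaled by `k_lens`; zero above 660 nm.
#' The standard (k = 1) density is 1.7649 at 400 nm.
#'
#' @param lambda_nm Wavelengths in nm (360-850).
#' @param k_lens Non-negative scaling.
#' @return Optical density (log10 attenuation) at each wavelength.
#' @export
lens_density <- function(lambda_nm, k_lens = 1) {
  if (k_lens < 0) abort("k_lens must be non-negative")
  k_lens * eval_template(builtin_template("lens"), lambda_nm)
}

#' Transmittance of an optical density
#'
#' @param density Non-negative log10 attenuation(s).
#' @return Fraction of light transmitted, `10^(-density)`, in (0, 1].
#' @examples
#' transmittance(0.350) # 0.447
#' @export
transmittance <- function(density) {
  if (any(density < 0)) abort("Optical density must be non-negative")
  10^(-density)
}

#' Total pre-receptoral optical density
#'
#' Sum of the scaled lens and macular densities; densities of stacked
#' filters add (transmittances multiply).
#'
#' @param lambda_nm Wavelengths in nm.
#' @param scaling A [filter_scaling()].
#' @return Total optical density at each wavelength.
#' @export
total_prereceptoral_density <- function(lambda_nm, scaling = filter_scaling()) {
  lens_density(lambda_nm, scaling$k_lens) +
    macular_density(lambda_nm, scaling$k_mac)
}
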