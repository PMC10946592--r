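# Spectral shifts along the log-wavelength axis, opsin genotype shifts, and
# polymorphic / mixture L-cone templates.
#
# Photopigment absorbance spectra are approximately shape invariant on a
# log10-wavelength axis, so a pigment with a different lambda_max is modelled
# by translating the template along that axis: the shifted value at lambda is
# the unshifted value at lambda * 10^(-delta).

#' Convert a peak-wavelength change to the template's angular shift
#'
#' The Fourier angle spans 0..pi over the 360-850 nm log-wavelength range, so
#' a shift of the peak from `lambda_max_1` to `lambda_max_2` corresponds to an
#' angular shift of `pi * log10(lambda_max_1 / lambda_max_2) / log10(850/360)`.
#'
#' @param lambda_max_1,lambda_max_2 Peak wavelengths in nm, within (360, 850).
#' @return Angular shift in radians (signed).
#' @export
delta_theta <- function(lambda_max_1, lambda_max_2) {
  if (any(c(lambda_max_1, lambda_max_2) <= 360) ||
      any(c(lambda_max_1, lambda_max_2) >= 850)) {
    abort("Peak wavelengths must lie within (360, 850) nm")
  }
  pi * log10(lambda_max_1 / lambda_max_2) / log10(850 / 360)
}

#' Convert a shift in nm at a reference peak to log10-wavelength units
#'
#' @param shift_nm Signed peak shift in nm.
#' @param lambda_max_ref Reference peak wavelength in nm.
#' @return Signed shift in log10 nm, `log10((ref + shift) / ref)`.
#' @export
shift_nm_to_log10 <- function(shift_nm, lambda_max_ref) {
  log10((lambda_max_ref + shift_nm) / lambda_max_ref)
}

#' Shift a template along the log-wavelength axis
#'
#' Positive shifts move the peak toward longer wavelengths:
#' `lambda_max(shifted) = lambda_max(unshifted) * 10^delta`. Shifts compose
#' additively. Only log-axis (absorbance) templates can be shifted.
#'
#' @param template A `cone_template` or mixture.
#' @param delta_log10_nm Signed shift in log10 nm.
#' @return A shifted template evaluator of the same class.
#' @examples
#' m_like <- shift_template(builtin_template("L_common"), -0.024187)
#' find_lambda_max(m_like) # 527.3
#' @export
shift_template <- function(template, delta_log10_nm) {
  UseMethod("shift_template")
}

#' @export
shift_template.cone_template <- function(template, delta_log10_nm) {
  if (template$axis != "log10_nm") {
    abort("Only log10-wavelength-axis templates can be spectrally shifted")
  }
  template$shift <- template$shift + delta_log10_nm
  sup <- template_support(template)
  if (sup[1] >= sup[2]) abort("Shift moves the template support outside 360-850 nm")
  template
}

# ---- opsin genotypes --------------------------------------------------------

# Peak shifts (nm) from swapping the L/M-distinguishing residue at each of the
# seven spectrally relevant codons; 233 and 309 do not shift the peak.
# Columns: shift applied on an M-opsin backbone gaining the L residue, and on
# an L backbone gaining the M residue (slightly asymmetric).
codon_shift_table <- function() {
  tibble(
    codon   = c(116L, 180L, 230L, 233L, 277L, 285L, 309L),
    m_aa    = c("Y", "A", "T", "S", "F", "A", "F"),
    l_aa    = c("S", "S", "I", "A", "Y", "T", "Y"),
    m_to_l  = c(0, 3, 3, 0, 7, 14, 0),
    l_to_m  = c(0, -4, -3, 0, -7, -14, 0)
  )
}

#' Peak shift implied by an L/M opsin genotype
#'
#' Sums the tabulated per-codon peak shifts for residue substitutions at the
#' seven spectrally relevant codons (116, 180, 230, 233, 277, 285, 309) of
#' the L and M cone opsins. On an M backbone, codons carrying the L-type
#' residue shift the peak toward longer wavelengths; on an L backbone,
#' M-type residues shift it shorter. Shifts combine additively.
#'
#' Genotypes are given either as a compact string such as `"M[A285T]"`
#' (base opsin, then comma-separated `<from><codon><to>` substitutions in
#' one-letter amino-acid code) or as a base plus an integer vector of
#' substituted codons.
#'
#' @param genotype Genotype string, e.g. `"L[S180A]"` or `"M[A180S,F277Y]"`.
#' @param base Alternatively, `"L"` or `"M"` with `codons` a vector of codon
#'   numbers at which the residue is swapped to the other opsin's type.
#' @param codons Integer vector of substituted codon positions.
#' @return Signed peak shift in nm.
#' @examples
#' genotype_shift_nm("M[A285T]") # +14
#' genotype_shift_nm(base = "L", codons = c(277, 285)) # -21
#' @export
genotype_shift_nm <- function(genotype = NULL, base = NULL, codons = NULL) {
  tab <- codon_shift_table()
  if (!is.null(genotype)) {
    parsed <- parse_genotype(genotype)
    base <- parsed$base
    codons <- parsed$codons
  }
  base <- match.arg(base, c("L", "M"))
  if (length(codons) == 0) return(0)
  codons <- as.integer(codons)
  unknown <- setdiff(codons, tab$codon)
  if (length(unknown)) {
    abort(paste0("Codon(s) with no tabulated spectral effect: ",
                 paste(unknown, collapse = ", ")))
  }
  idx <- match(codons, tab$codon)
  if (base == "M") sum(tab$m_to_l[idx]) else sum(tab$l_to_m[idx])
}

parse_genotype <- function(genotype) {
  m <- regmatches(genotype, regexec("^([LM])\\[([^]]*)\\]$", genotype))[[1]]
  if (length(m) != 3) {
    abort(paste0("Cannot parse genotype '", genotype,
                 "'; expected e.g. \"L[S180A]\" or \"M[A180S,F277Y]\""))
  }
  base <- m[2]
  subs <- trimws(strsplit(m[3], ",")[[1]])
  subs <- subs[nzchar(subs)]
  if (length(subs) == 0) return(list(base = base, codons = integer()))
  tab <- codon_shift_table()
  codons <- vapply(subs, function(s) {
    sm <- regmatches(s, regexec("^([A-Z])([0-9]+)([A-Z])$", s))[[1]]
    if (length(sm) != 4) abort(paste0("Cannot parse substitution '", s, "'"))
    codon <- as.integer(sm[3])
    i <- match(codon, tab$codon)
    if (is.na(i)) abort(paste0("Codon ", codon, " has no tabulated spectral effect"))
    from_exp <- if (base == "L") tab$l_aa[i] else tab$m_aa[i]
    to_exp <- if (base == "L") tab$m_aa[i] else tab$l_aa[i]
    if (sm[2] != from_exp || sm[4] != to_exp) {
      abort(sprintf(
        "Substitution '%s' does not match the %s-opsin residue at codon %d (expected %s%d%s)",
        s, base, codon, from_exp, codon, to_exp))
    }
    codon
  }, integer(1))
  list(base = base, codons = unname(codons))
}

# ---- polymorphic and mixture templates -------------------------------------

#' Polymorphic L-cone absorbance templates
#'
#' The population-mean L-cone template averages two common polymorphic
#' variants that differ at opsin codon 180. This returns the template for a
#' single variant: `ser180` is the dedicated polymorphic fit (peak 553.1 nm);
#' `ala180` is that template shifted by -0.002125 log10 nm (peak 550.4 nm,
#' a 2.7 nm shift toward shorter wavelengths).
#'
#' @param variant `"ser180"` or `"ala180"`.
#' @return A `cone_template`.
#' @export
polymorphic_L <- function(variant = c("ser180", "ala180")) {
  variant <- match.arg(variant)
  ser <- builtin_template("L_ser180_poly")
  if (variant == "ser180") ser else shift_template(ser, -0.002125)
}

#' Mix absorbance templates in linear absorbance
#'
#' Forms the weighted sum of the components' linear absorbances and rescales
#' so the mixture peaks at exactly 1 (peak located at 0.1 nm resolution over
#' the common support).
#'
#' @param templates List of absorbance templates (possibly shifted).
#' @param weights Non-negative weights summing to 1, one per template.
#' @return A `cone_mixture` evaluator usable with [eval_template()],
#'   [find_lambda_max()], [tabulate_template()] and [shift_template()].
#' @examples
#' ser <- builtin_template("L_common")
#' ala <- shift_template(ser, -0.002108)
#' mean_L <- mix_templates(list(ala, ser), c(0.56, 0.44))
#' find_lambda_max(mean_L) # 556.0
#' @export
mix_templates <- function(templates, weights) {
  if (length(templates) != length(weights)) {
    abort("One weight per template is required")
  }
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-8) {
    abort("Weights must be non-negative and sum to 1")
  }
  sup <- purrr::reduce(lapply(templates, template_support),
                       function(x, y) c(max(x[1], y[1]), min(x[2], y[2])))
  if (sup[1] >= sup[2]) abort("Templates have no common support")
  mix <- structure(
    list(components = templates, weights = weights, support = sup,
         peak_value = 1),
    class = "cone_mixture"
  )
  grid <- peak_grid(sup, 0.1)
  mix$peak_value <- max(mixture_linear(mix, grid))
  mix
}

mixture_linear <- function(mix, lambda) {
  vals <- purrr::map2(mix$components, mix$weights, function(t, w) {
    w * eval_template(t, lambda, value = "linear")
  })
  purrr::reduce(vals, `+`) / mix$peak_value
}

#' @export
template_support.cone_mixture <- function(template) template$support

#' @export
eval_template.cone_mixture <- function(template, lambda_nm,
                                       value = c("native", "linear"),
                                       clamp = TRUE) {
  value <- match.arg(value)
  v <- mixture_linear(template, lambda_nm)
  if (value == "linear") v else log10(v)
}

#' @export
shift_template.cone_mixture <- function(template, delta_log10_nm) {
  template$components <- lapply(template$components, shift_template,
                                delta_log10_nm = delta_log10_nm)
  template$support <- purrr::reduce(
    lapply(template$components, template_support),
    function(x, y) c(max(x[1], y[1]), min(x[2], y[2])))
  if (template$support[1] >= template$support[2]) {
    abort("Shift moves the mixture support outside 360-850 nm")
  }
  template
}

#' @export
print.cone_mixture <- function(x, ...) {
  cat("<cone_mixture> of", length(x$components), "templates, weights",
      paste(signif(x$weights, 4), collapse = ":"), "\n")
  invisible(x)
}
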