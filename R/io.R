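# Table I/O, reference comparison and observer configuration files.

#' Write a spectral table to CSV
#'
#' Writes a CMF set, spectrum locus or any wavelength-indexed tibble as a
#' comma-separated table with `#`-prefixed metadata header lines (package
#' version, observer parameters, units) followed by a column header and
#' values printed at fixed precision.
#'
#' @param x A `cone_fundamentals`, `cone_locus` or tibble with a
#'   `wavelength` column.
#' @param path Output file path.
#' @param digits Decimal places for the values (default 8).
#' @return `path`, invisibly.
#' @export
write_cmf_table <- function(x, path, digits = 8) {
  obs <- attr(x, "observer")
  meta <- c(
    paste0("# conefund ", as.character(utils::packageVersion("conefund"))),
    if (!is.null(attr(x, "units"))) paste0("# units: ", attr(x, "units")),
    if (!is.null(attr(x, "space"))) paste0("# space: ", attr(x, "space"))
  )
  if (!is.null(obs)) {
    meta <- c(meta,
      paste0("# field: ", obs$field),
      sprintf("# od: L=%g M=%g S=%g", obs$od["L"], obs$od["M"], obs$od["S"]),
      sprintf("# k_mac: %g", obs$scaling$k_mac),
      sprintf("# k_lens: %g", obs$scaling$k_lens))
  }
  d <- as_tibble(x)
  fmt <- paste0("%.", digits, "f")
  body <- purrr::map(d, function(col) {
    if (is.numeric(col)) sprintf(fmt, col) else as.character(col)
  })
  lines <- c(meta,
             paste(names(d), collapse = ","),
             do.call(paste, c(body, sep = ",")))
  writeLines(lines, path)
  invisible(path)
}

#' Read a spectral table written by [write_cmf_table()]
#'
#' @param path File path.
#' @return A tibble; `#`-metadata lines are parsed into a `meta` attribute.
#' @export
read_cmf_table <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  d <- utils::read.csv(textConnection(lines[!grepl("^#", lines)]))
  out <- as_tibble(d)
  attr(out, "meta") <- sub("^#\\s*", "", meta)
  out
}

#' Read a reference LMS tabulation (cvrl-style CSV)
#'
#' Parses a wavelength,L,M,S comma-separated table such as the published
#' cone-fundamental tabulations: no or optional header, blank cells (e.g.
#' at the long-wavelength end of the S column) treated as missing rather
#' than zero.
#'
#' @param path File path.
#' @return A tibble `wavelength`, `L`, `M`, `S` with the detected grid step
#'   in the `step` attribute; missing values are `NA`.
#' @export
read_reference <- function(path) {
  lines <- readLines(path)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  if (length(keep) == 0) abort("No data rows found")
  first <- strsplit(lines[keep[1]], ",")[[1]]
  has_header <- is.na(suppressWarnings(as.numeric(first[1])))
  if (has_header) keep <- keep[-1]
  rows <- lapply(keep, function(i) {
    f <- strsplit(lines[i], ",")[[1]]
    length(f) <- 4 # pad trailing blanks
    f[is.na(f)] <- ""
    f <- trimws(f)
    v <- suppressWarnings(as.numeric(ifelse(nzchar(f), f, NA)))
    if (is.na(v[1])) {
      abort(sprintf("Malformed row at line %d: '%s'", i, lines[i]))
    }
    if (any(is.na(v[2:4]) & nzchar(f[2:4]))) {
      abort(sprintf("Malformed row at line %d: '%s'", i, lines[i]))
    }
    v
  })
  m <- do.call(rbind, rows)
  if (any(diff(m[, 1]) <= 0)) {
    j <- which(diff(m[, 1]) <= 0)[1]
    abort(sprintf("Non-monotone wavelengths at line %d", keep[j + 1]))
  }
  out <- tibble(wavelength = m[, 1], L = m[, 2], M = m[, 3], S = m[, 4])
  steps <- unique(round(diff(out$wavelength), 9))
  attr(out, "step") <- if (length(steps) == 1) steps else NA_real_
  out
}

#' Mean absolute error between two spectral tabulations
#'
#' Compares channel by channel over the shared wavelengths, reporting the
#' mean absolute difference in linear units and in log10 units. Wavelengths
#' below `lambda_min` (default 400 nm, where the short-wavelength template
#' extensions depart from tabulated standards) and missing values are
#' excluded; log MAEs additionally exclude non-positive values.
#'
#' @param generated,reference Tibbles with `wavelength` plus shared channel
#'   columns.
#' @param lambda_min Exclude wavelengths below this (nm); set to `-Inf` to
#'   compare everything.
#' @return A tibble with one row per channel: `channel`, `mae_linear`,
#'   `mae_log`, `n`; the wavelength range used is stored in the `range`
#'   attribute.
#' @export
compare_mae <- function(generated, reference, lambda_min = 400) {
  ch <- intersect(setdiff(names(generated), "wavelength"),
                  setdiff(names(reference), "wavelength"))
  if (length(ch) == 0) abort("No shared channels to compare")
  j <- dplyr::inner_join(as_tibble(generated), as_tibble(reference),
                         by = "wavelength", suffix = c(".g", ".r"))
  j <- dplyr::filter(j, .data$wavelength >= lambda_min)
  if (nrow(j) == 0) abort("No overlapping wavelengths at or above lambda_min")
  out <- purrr::map_dfr(ch, function(c0) {
    g <- j[[paste0(c0, ".g")]]
    r <- j[[paste0(c0, ".r")]]
    ok <- !is.na(g) & !is.na(r)
    logok <- ok & g > 0 & r > 0
    tibble(channel = c0,
           mae_linear = mean(abs(g[ok] - r[ok])),
           mae_log = if (any(logok)) mean(abs(log10(g[logok]) - log10(r[logok]))) else NA_real_,
           n = sum(ok))
  })
  attr(out, "range") <- range(j$wavelength)
  attr(out, "lambda_min") <- lambda_min
  out
}

# ---- observer configuration files ------------------------------------------

#' Read or write an observer configuration (YAML or JSON)
#'
#' A configuration is a declarative record of [observer()] parameters;
#' unspecified fields default to the standard 2-deg observer. The format is
#' chosen from the file extension (`.yml`/`.yaml` or `.json`).
#'
#' @param obs A `cone_observer`.
#' @param path File path.
#' @return `read_observer_config()` returns a `cone_observer`;
#'   `write_observer_config()` returns `path` invisibly.
#' @export
write_observer_config <- function(obs, path) {
  cfg <- list(
    field = obs$field,
    od = as.list(obs$od),
    k_mac = obs$scaling$k_mac,
    k_lens = obs$scaling$k_lens,
    shift_nm = as.list(obs$shift_nm),
    l_variant = obs$l_variant,
    w_ser = obs$w_ser
  )
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(cfg, path)
  }
  invisible(path)
}

#' @rdname write_observer_config
#' @export
read_observer_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  as_observer(cfg)
}

#' Build an observer from a configuration list
#'
#' @param cfg A named list as produced by [write_observer_config()];
#'   missing entries take the standard 2-deg defaults.
#' @return A `cone_observer`.
#' @export
as_observer <- function(cfg) {
  base <- standard_observer("2deg")
  num3 <- function(x, default) {
    if (is.null(x)) return(default)
    v <- unlist(x)
    default[names(v)] <- v
    default
  }
  observer(
    field = cfg$field %||% "custom",
    od = num3(cfg$od, base$od),
    scaling = filter_scaling(k_mac = cfg$k_mac %||% 1,
                             k_lens = cfg$k_lens %||% 1),
    shift_nm = num3(cfg$shift_nm, c(L = 0, M = 0, S = 0)),
    l_variant = cfg$l_variant %||% "mean",
    w_ser = cfg$w_ser %||% 0.56
  )
}
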