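#' Spectrum objects
#'
#' A sampled intensity-versus-axis curve, experimental or simulated. The
#' axis is strictly increasing, in nanometres (`unit = "nm"`) or wavenumbers
#' (`unit = "wavenumber"`, cm^-1); metadata is a free-form named list
#' (sample id, seeds, normalization state, ...).
#'
#' @param axis Strictly monotonic numeric axis values.
#' @param intensity Numeric intensities, same length as `axis`.
#' @param unit `"nm"` or `"wavenumber"`.
#' @param metadata Named list of metadata.
#' @return Object of class `spectrum`.
#' @export
new_spectrum <- function(axis, intensity, unit = c("nm", "wavenumber"),
                         metadata = list()) {
  unit <- match.arg(unit)
  stopifnot(length(axis) == length(intensity))
  if (!all(is.finite(axis)) || !all(is.finite(intensity))) {
    stop("spectrum contains non-finite values")
  }
  d <- diff(axis)
  if (any(d <= 0)) {
    if (all(d < 0)) {
      axis <- rev(axis); intensity <- rev(intensity)
      metadata$axis_reversed <- TRUE
    } else {
      stop("spectrum axis is not strictly monotonic")
    }
  }
  structure(list(axis = axis, intensity = intensity, unit = unit,
                 metadata = metadata), class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> %d points, %.6g-%.6g %s\n", length(x$axis),
              min(x$axis), max(x$axis),
              if (x$unit == "nm") "nm" else "cm-1"))
  invisible(x)
}

#' @export
as.data.frame.spectrum <- function(x, ...) {
  data.frame(axis = x$axis, intensity = x$intensity)
}

#' @export
plot.spectrum <- function(x, ...) {
  graphics::plot(x$axis, x$intensity, type = "l",
                 xlab = if (x$unit == "nm") "wavelength (nm)" else "wavenumber (cm-1)",
                 ylab = "intensity", ...)
}

#' Read a two-column spectrum from CSV or TSV
#'
#' Accepts an optional header line and `#` comment lines; a descending axis
#' is sorted ascending (and flagged in metadata).
#'
#' @param path File path.
#' @param dialect `"auto"` (by extension), `"csv"`, or `"tsv"`.
#' @param unit Axis unit tag for the result.
#' @return A [new_spectrum()] object.
#' @export
read_spectrum <- function(path, dialect = c("auto", "csv", "tsv"),
                          unit = c("nm", "wavenumber")) {
  dialect <- match.arg(dialect)
  unit <- match.arg(unit)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "tsv" else "csv"
  }
  sep <- if (dialect == "tsv") "\t" else ","
  lines <- readLines(path)
  body <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  # tolerate a single non-numeric header line
  first <- strsplit(body[1], sep, fixed = TRUE)[[1]]
  skip_header <- suppressWarnings(any(is.na(as.numeric(first[1:2]))))
  tab <- utils::read.table(text = body, sep = sep, header = skip_header,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("expected two columns in ", path)
  ax <- suppressWarnings(as.numeric(tab[[1]]))
  it <- suppressWarnings(as.numeric(tab[[2]]))
  bad <- which(is.na(ax) | is.na(it))
  if (length(bad)) {
    stop("non-numeric spectrum row(s) in ", path, " at data line(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  if (anyDuplicated(ax)) stop("duplicate axis values in ", path)
  new_spectrum(ax, it, unit = unit, metadata = list(source = path))
}

#' Write a spectrum as two-column CSV with metadata header
#'
#' @param spec A `spectrum`.
#' @param path Output path. Scalar metadata entries are written as
#'   `# key: value` header lines.
#' @export
write_spectrum <- function(spec, path) {
  hdr <- sprintf("# axis_unit: %s", spec$unit)
  meta <- spec$metadata[vapply(spec$metadata, function(v)
    is.atomic(v) && length(v) == 1, TRUE)]
  if (length(meta)) {
    hdr <- c(hdr, sprintf("# %s: %s", names(meta),
                          vapply(meta, format, "")))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(data.frame(axis = spec$axis, intensity = spec$intensity),
                     con, sep = ",", row.names = FALSE, col.names = TRUE,
                     quote = FALSE)
  invisible(path)
}

# Trapezoidal integral of y over x.
trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

#' Width of a single-band spectrum
#'
#' Full width at half maximum estimated either from the intensity-weighted
#' second moment (`"moments"`, robust to sampling noise; exact for a
#' Gaussian band) or from linear interpolation of the half-maximum
#' crossings (`"halfmax"`).
#'
#' @param spec A `spectrum` containing a single band.
#' @param method `"moments"` or `"halfmax"`.
#' @return FWHM in the spectrum's axis units.
#' @export
spectrum_fwhm <- function(spec, method = c("moments", "halfmax")) {
  method <- match.arg(method)
  x <- spec$axis; y <- spec$intensity
  if (method == "moments") {
    w <- y / sum(y)
    m <- sum(w * x)
    return(2 * sqrt(2 * log(2)) * sqrt(sum(w * (x - m)^2)))
  }
  half <- max(y) / 2
  ix <- which(y >= half)
  cross <- function(i1, i2) stats::approx(y[c(i1, i2)], x[c(i1, i2)],
                                          xout = half)$y
  lo <- if (min(ix) > 1) cross(min(ix) - 1, min(ix)) else x[1]
  hi <- if (max(ix) < length(x)) cross(max(ix) + 1, max(ix)) else x[length(x)]
  hi - lo
}
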