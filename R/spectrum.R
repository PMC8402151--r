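#' Default 3DEP-style frequency grid
#'
#' Twenty log-spaced frequencies spanning 1 kHz to 45 MHz, the band of
#' 20-well DEP reader chips in which each well is energised at one
#' frequency.
#'
#' @param n number of points (default 20).
#' @param f_min,f_max band edges, Hz.
#' @return Strictly increasing numeric vector of frequencies, Hz.
#' @export
default_frequencies <- function(n = 20L, f_min = 1e3, f_max = 4.5e7) {
  if (f_min <= 0 || f_min >= f_max) stop("require 0 < f_min < f_max", call. = FALSE)
  exp(seq(log(f_min), log(f_max), length.out = n))
}

#' DEP light-intensity spectrum
#'
#' One well-row measurement: paired frequencies (Hz) and relative
#' light-intensity changes (arbitrary units), one value per energised
#' well.
#'
#' @param frequencies strictly increasing positive frequencies, Hz.
#' @param intensities intensity values, arbitrary units, same length.
#' @param label free-text label for the measurement.
#' @param well_count number of wells on the chip (default the number of
#'   frequencies).
#' @return An object of class `dep_spectrum`.
#' @export
#' @examples
#' f <- default_frequencies()
#' dep_spectrum(f, sin(seq_along(f)), label = "demo")
dep_spectrum <- function(frequencies, intensities, label = "",
                         well_count = length(frequencies)) {
  frequencies <- as.numeric(frequencies)
  intensities <- as.numeric(intensities)
  if (length(frequencies) != length(intensities)) {
    stop("frequencies and intensities must have the same length", call. = FALSE)
  }
  if (any(!is.finite(frequencies)) || any(frequencies <= 0)) {
    stop("frequencies must be positive and finite", call. = FALSE)
  }
  if (is.unsorted(frequencies, strictly = TRUE)) {
    stop("frequencies must be strictly increasing", call. = FALSE)
  }
  structure(list(frequencies = frequencies, intensities = intensities,
                 label = as.character(label)[1],
                 well_count = as.integer(well_count)),
            class = "dep_spectrum")
}

#' @export
print.dep_spectrum <- function(x, ...) {
  cat(sprintf("DEP spectrum%s: %d points, %.3g Hz - %.3g Hz\n",
              if (nzchar(x$label)) paste0(" '", x$label, "'") else "",
              length(x$frequencies), min(x$frequencies), max(x$frequencies)))
  invisible(x)
}

#' @export
plot.dep_spectrum <- function(x, ..., xlab = "Frequency (Hz)",
                              ylab = "Intensity change (a.u.)") {
  graphics::plot(x$frequencies, x$intensities, log = "x",
                 xlab = xlab, ylab = ylab,
                 main = if (nzchar(x$label)) x$label else "DEP spectrum", ...)
  invisible(x)
}

#' @export
as.data.frame.dep_spectrum <- function(x, ...) {
  data.frame(frequency_hz = x$frequencies, intensity = x$intensities)
}

#' Read DEP spectra from a delimited file
#'
#' Expects a header `frequency_hz,intensity[,intensity_2,...]`; each
#' additional intensity column is treated as a technical repeat and
#' returned as its own spectrum. Comma- and tab-separated files are
#' both accepted (sniffed from the header line).
#'
#' @param path file path.
#' @param label base label; repeats get `_2`, `_3`, ... suffixes.
#' @return A list of [dep_spectrum()] objects (length >= 1).
#' @export
read_dep_spectrum <- function(path, label = basename(path)) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!"frequency_hz" %in% names(df)) {
    stop("spectrum file must have a 'frequency_hz' column", call. = FALSE)
  }
  int_cols <- setdiff(names(df), "frequency_hz")
  if (length(int_cols) == 0L) {
    stop("spectrum file has no intensity columns", call. = FALSE)
  }
  ord <- order(df$frequency_hz)
  lapply(seq_along(int_cols), function(i) {
    lbl <- if (i == 1L) label else paste0(label, "_", i)
    dep_spectrum(df$frequency_hz[ord], df[[int_cols[i]]][ord], label = lbl)
  })
}

#' Write one or more spectra sharing a frequency grid to CSV
#'
#' @param spectra a single [dep_spectrum()] or a list of them on a
#'   common frequency grid (technical repeats).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_dep_spectrum <- function(spectra, path) {
  if (inherits(spectra, "dep_spectrum")) spectra <- list(spectra)
  f <- spectra[[1]]$frequencies
  for (s in spectra) {
    if (!isTRUE(all.equal(s$frequencies, f))) {
      stop("all spectra in one file must share the frequency grid", call. = FALSE)
    }
  }
  df <- data.frame(frequency_hz = f)
  for (i in seq_along(spectra)) {
    nm <- if (i == 1L) "intensity" else paste0("intensity_", i)
    df[[nm]] <- spectra[[i]]$intensities
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
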