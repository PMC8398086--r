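## Titration file I/O, blank handling, and peak extraction.
##
## On-disk format: UTF-8 delimited text (comma default), long format, header
##   wavelength_nm,intensity,quencher_conc_M,temperature_K,pH
## one row per (concentration, wavelength) pair. Buffer-blank rows carry the
## sentinel quencher_conc_M = -1, announced in a leading '#' comment line.

.TITRATION_COLS <- c("wavelength_nm", "intensity", "quencher_conc_M",
                     "temperature_K", "pH")
.BLANK_SENTINEL <- -1

#' Read a titration series from delimited text
#'
#' Expects long-format text with columns `wavelength_nm`, `intensity`,
#' `quencher_conc_M`, `temperature_K`, `pH` (see [writeTitration()] for the
#' writer). Rows are grouped into one spectrum per distinct quencher
#' concentration, sorted ascending; rows with `quencher_conc_M = -1` become
#' the buffer blank. The file must contain the quencher-free scan (F0), a
#' single temperature and a single pH.
#'
#' @param path file to read.
#' @param sep field separator (default `","`).
#' @param schema optional named character vector mapping the canonical
#'   column names to the names used in the file, e.g.
#'   `c(wavelength_nm = "wl")`.
#' @param proteinConc protein concentration in g/L to record (optional).
#' @return a [TitrationSeries-class].
#' @seealso [writeTitration()], [subtractBlank()], [extractPeak()]
#' @export
loadTitration <- function(path, sep = ",", schema = NULL,
                          proteinConc = NA_real_) {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          comment.char = "#", stringsAsFactors = FALSE)
  if (!is.null(schema)) {
    for (canon in names(schema)) {
      i <- match(schema[[canon]], names(df))
      if (!is.na(i)) names(df)[i] <- canon
    }
  }
  miss <- setdiff(.TITRATION_COLS, names(df))
  if (length(miss))
    stop("titration file lacks required column(s): ",
         paste(miss, collapse = ", "))
  if (length(unique(df$temperature_K)) != 1)
    stop("titration file mixes temperatures; one series per (T, pH) expected")
  if (length(unique(df$pH)) != 1)
    stop("titration file mixes pH values; one series per (T, pH) expected")
  if (anyDuplicated(df[, c("quencher_conc_M", "wavelength_nm")]))
    stop("duplicate (quencher_conc_M, wavelength_nm) rows in titration file")

  tK <- df$temperature_K[1]
  pH <- df$pH[1]
  isBlank <- df$quencher_conc_M == .BLANK_SENTINEL
  mkSpec <- function(sub, conc) {
    o <- order(sub$wavelength_nm)
    EmissionSpectrum(sub$wavelength_nm[o], sub$intensity[o],
                     temperature = tK, pH = pH, quencherConc = conc)
  }
  blank <- NULL
  if (any(isBlank)) blank <- mkSpec(df[isBlank, ], 0)
  df <- df[!isBlank, ]
  concs <- sort(unique(df$quencher_conc_M))
  if (!any(concs == 0))
    stop("titration file lacks the zero-concentration scan that supplies F0")
  sp <- lapply(concs, function(cc) mkSpec(df[df$quencher_conc_M == cc, ], cc))
  TitrationSeries(sp, blank = blank, proteinConc = proteinConc)
}

#' Write a titration series to delimited text
#'
#' Long-format writer paired with [loadTitration()]: numerics are written at
#' 12 significant digits, blank rows use the sentinel concentration -1.
#'
#' @param series a [TitrationSeries-class].
#' @param path output file.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
writeTitration <- function(series, path, sep = ",") {
  stopifnot(is(series, "TitrationSeries"))
  if (!length(series@spectra)) stop("empty titration series")
  fmt <- function(x) sprintf("%.12g", x)
  rows <- function(s, conc) {
    paste(fmt(s@wavelength), fmt(s@intensity), fmt(conc),
          fmt(s@temperature), fmt(s@pH), sep = sep)
  }
  out <- c(
    "# long-format titration; blank rows carry quencher_conc_M = -1",
    paste(.TITRATION_COLS, collapse = sep),
    unlist(lapply(series@spectra, function(s) rows(s, s@quencherConc)))
  )
  if (!is.null(series@blank))
    out <- c(out, rows(series@blank, .BLANK_SENTINEL))
  writeLines(out, path)
  invisible(path)
}

#' Subtract the buffer blank from every spectrum
#'
#' Each intensity is reduced by the blank intensity at the same wavelength;
#' the blank is dropped from the result. Without a blank the series is
#' returned unchanged with a warning.
#'
#' @param object a [TitrationSeries-class].
#' @return a blank-free [TitrationSeries-class].
#' @export
setMethod("subtractBlank", "TitrationSeries", function(object, ...) {
  if (is.null(object@blank)) {
    warning("no blank attached; returning series unchanged")
    return(object)
  }
  b <- object@blank@intensity
  sp <- lapply(object@spectra, function(s) {
    s@intensity <- s@intensity - b
    s
  })
  TitrationSeries(sp, blank = NULL, proteinConc = object@proteinConc)
})

## centred moving average; halfWidthPts = 0 is the identity
.smooth_ma <- function(y, halfWidthPts) {
  if (halfWidthPts <= 0) return(y)
  n <- length(y)
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1, i - halfWidthPts)
    hi <- min(n, i + halfWidthPts)
    out[i] <- mean(y[lo:hi])
  }
  out
}

#' Locate the emission maximum of a spectrum
#'
#' The intensity trace is smoothed by a centred moving average of half-width
#' `window` nm, the grid maximum located (lowest wavelength wins exact
#' ties), and the position refined by a 3-point parabolic interpolation.
#' A maximum on the grid edge is returned unrefined with `atBoundary = TRUE`.
#' A flat trace (no peak beyond the tie tolerance) is an error.
#'
#' @param spectrum an [EmissionSpectrum-class] with at least 5 points.
#' @param window smoothing half-width in nm (default 2; 0 disables).
#' @return a [PeakReading-class].
#' @examples
#' wl <- seq(300, 450)
#' s <- EmissionSpectrum(wl, 100 * exp(-(wl - 337)^2 / (2 * 25^2)),
#'                       298, 7.4, 0)
#' extractPeak(s)
#' @export
extractPeak <- function(spectrum, window = 2) {
  stopifnot(is(spectrum, "EmissionSpectrum"))
  wl <- spectrum@wavelength
  y <- spectrum@intensity
  if (length(wl) < 5) stop("need at least 5 points to locate a peak")
  if (window < 0) stop("window must be >= 0")
  step <- stats::median(diff(wl))
  ys <- .smooth_ma(y, round(window / step))
  rng <- max(ys) - min(ys)
  if (rng <= 1e-9 * max(abs(ys), 1))
    stop("degenerate peak: spectrum is flat after smoothing")
  i <- which.max(ys)                       # which.max takes the first tie
  if (i == 1 || i == length(ys))
    return(PeakReading(wl[i], ys[i], atBoundary = TRUE))
  ## 3-point parabola through (i-1, i, i+1)
  y1 <- ys[i - 1]; y2 <- ys[i]; y3 <- ys[i + 1]
  denom <- y1 - 2 * y2 + y3
  if (denom == 0) return(PeakReading(wl[i], y2))
  delta <- 0.5 * (y1 - y3) / denom
  PeakReading(wl[i] + delta * step, y2 - 0.25 * (y1 - y3) * delta)
}

#' Peak intensities across a titration
#'
#' Applies [extractPeak()] to every spectrum and returns the intensities as
#' a vector named by quencher concentration. The first element is F0.
#'
#' @param object a [TitrationSeries-class].
#' @param window smoothing half-width in nm, passed to [extractPeak()].
#' @return named numeric vector of peak intensities.
#' @export
setMethod("peakIntensities", "TitrationSeries", function(object, window = 2) {
  f <- vapply(object@spectra,
              function(s) extractPeak(s, window = window)@intensity,
              numeric(1))
  names(f) <- vapply(object@spectra, function(s)
    format(s@quencherConc, digits = 6), character(1))
  f
})

#' Find UV absorption peaks near expected positions
#'
#' Searches an absorbance spectrum for a local maximum within +/- 10 nm of
#' each expected wavelength (e.g. the 210 nm helix band and the 280 nm
#' aromatic band). When a quencher-free reference is supplied, the
#' hyperchromicity flag records whether every detected peak is more intense
#' than the reference at the same wavelength.
#'
#' @param spectrum an absorbance [EmissionSpectrum-class].
#' @param expected numeric vector of expected peak positions, nm.
#' @param reference optional reference spectrum on the same grid.
#' @param searchWindow half-width of the search window, nm.
#' @return list with elements `peaks` (named list of [PeakReading-class] or
#'   `NULL` for a missing peak), `missing` (numeric vector of expected
#'   positions not found) and `hyperchromic` (`TRUE`/`FALSE`, or `NA`
#'   without a reference).
#' @export
uvAbsorptionPeaks <- function(spectrum, expected, reference = NULL,
                              searchWindow = 10) {
  stopifnot(is(spectrum, "EmissionSpectrum"))
  wl <- spectrum@wavelength
  y <- spectrum@intensity
  peaks <- stats::setNames(vector("list", length(expected)),
                           as.character(expected))
  for (k in seq_along(expected)) {
    sel <- which(wl >= expected[k] - searchWindow &
                 wl <= expected[k] + searchWindow)
    if (length(sel) < 3) next
    ## interior local maxima only
    cand <- sel[sel > 1 & sel < length(wl)]
    cand <- cand[y[cand] >= y[cand - 1] & y[cand] >= y[cand + 1]]
    if (!length(cand)) next
    i <- cand[which.max(y[cand])]
    sub <- EmissionSpectrum(wl[(i - 2):(i + 2)], y[(i - 2):(i + 2)],
                            spectrum@temperature, spectrum@pH,
                            spectrum@quencherConc, kind = spectrum@kind)
    peaks[[k]] <- extractPeak(sub, window = 0)
  }
  found <- !vapply(peaks, is.null, logical(1))
  hyper <- NA
  if (!is.null(reference) && any(found)) {
    refAt <- function(p) stats::approx(reference@wavelength,
                                       reference@intensity,
                                       xout = p@lambdaMax)$y
    hyper <- all(vapply(peaks[found],
                        function(p) p@intensity > refAt(p), logical(1)))
  }
  list(peaks = peaks, missing = expected[!found], hyperchromic = hyper)
}
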