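#' Reflectance spectrum object
#'
#' A reflectance spectrum is the proportion of incident light reflected by a
#' flower (or leaf) surface at each wavelength, here over the bee-visible
#' range 300--700 nm. Wavelengths are stored strictly increasing; duplicate
#' wavelengths are averaged. Negative readings (instrument noise) are clipped
#' to zero; readings above 1 (specular glare) are retained with a warning.
#'
#' @param species_id character label for the species (or "background").
#' @param wavelength numeric vector of wavelengths in nm.
#' @param reflectance numeric vector of reflectance fractions, same length.
#' @return An object of class `refl_spectrum`: a list with elements
#'   `species_id`, `wavelength`, `reflectance`.
#' @examples
#' sp <- refl_spectrum("demo", seq(300, 700, 10), rep(0.5, 41))
#' range(sp$wavelength)
#' @export
refl_spectrum <- function(species_id, wavelength, reflectance) {
  if (!is.character(species_id) || length(species_id) != 1L)
    stop("species_id must be a single character label")
  wavelength <- as.numeric(wavelength)
  reflectance <- as.numeric(reflectance)
  if (length(wavelength) != length(reflectance))
    stop("wavelength and reflectance must have equal length")
  keep <- !(is.na(wavelength))
  wavelength <- wavelength[keep]
  reflectance <- reflectance[keep]
  if (length(wavelength) < 2L)
    stop("a spectrum needs at least 2 wavelength points")
  if (anyNA(reflectance))
    stop("non-numeric or missing reflectance values in spectrum '", species_id, "'")
  o <- order(wavelength)
  wavelength <- wavelength[o]
  reflectance <- reflectance[o]
  if (anyDuplicated(wavelength)) {
    reflectance <- as.numeric(tapply(reflectance, wavelength, mean))
    wavelength <- sort(unique(wavelength))
  }
  if (any(reflectance > 1))
    warning("spectrum '", species_id, "' has reflectance > 1 (glare?); values retained")
  reflectance[reflectance < 0] <- 0
  structure(list(species_id = species_id,
                 wavelength = wavelength,
                 reflectance = reflectance),
            class = "refl_spectrum")
}

#' @export
print.refl_spectrum <- function(x, ...) {
  cat(sprintf("Reflectance spectrum '%s': %d points, %.0f-%.0f nm, reflectance %.3f-%.3f\n",
              x$species_id, length(x$wavelength),
              min(x$wavelength), max(x$wavelength),
              min(x$reflectance), max(x$reflectance)))
  invisible(x)
}

#' The standard 1-nm integration grid, 300 to 700 nm
#' @return Integer-valued numeric vector of 401 wavelengths.
#' @export
default_grid <- function() seq(300, 700, by = 1)

.detect_sep <- function(line) {
  if (lengths(regmatches(line, gregexpr("\t", line))) > 0) "\t" else ","
}

.read_delim_table <- function(path, header) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) stop("empty file: ", path)
  sep <- .detect_sep(first)
  utils::read.table(path, header = header, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE, comment.char = "", strip.white = TRUE)
}

.check_numeric_cols <- function(df, cols, path) {
  for (cn in cols) {
    v <- df[[cn]]
    if (!is.numeric(v)) {
      suppressWarnings(num <- as.numeric(v))
      bad <- which(is.na(num) & !is.na(v) & nzchar(trimws(v)))
      if (length(bad))
        stop("non-numeric value in column '", cn, "' of ", path,
             " at data row ", bad[1L], ": '", v[bad[1L]], "'")
      df[[cn]] <- num
    }
  }
  df
}

#' Read reflectance spectra from disk
#'
#' Supports the three layouts produced by typical spectrometer workflows:
#' \describe{
#'   \item{wide}{first column `wavelength` (nm), one column per species.}
#'   \item{long}{columns `species_id`, `wavelength`, `reflectance`.}
#'   \item{per_species_dir}{a directory of two-column files (wavelength,
#'     reflectance); the species id is the filename stem.}
#' }
#' Delimiter (comma or tab) is auto-detected; per-species files may be
#' headerless. Wavelengths are sorted ascending and duplicates averaged.
#'
#' @param path file (wide/long) or directory (per_species_dir).
#' @param dialect one of "wide", "long", "per_species_dir".
#' @return Named list of [refl_spectrum] objects.
#' @export
read_spectra <- function(path, dialect = c("wide", "long", "per_species_dir")) {
  dialect <- match.arg(dialect)
  if (dialect == "per_species_dir") {
    if (!dir.exists(path)) stop("directory not found: ", path)
    files <- list.files(path, pattern = "\\.(csv|tsv|txt)$", full.names = TRUE)
    if (!length(files)) stop("no spectrum files in directory: ", path)
    out <- lapply(files, function(f) {
      first <- readLines(f, n = 1L)
      if (!length(first)) stop("empty file: ", f)
      sep <- .detect_sep(first)
      has_header <- is.na(suppressWarnings(
        as.numeric(strsplit(first, sep, fixed = TRUE)[[1L]][1L])))
      df <- utils::read.table(f, header = has_header, sep = sep,
                              stringsAsFactors = FALSE)
      if (ncol(df) < 2L) stop("expected two columns in ", f)
      df <- .check_numeric_cols(df, names(df)[1:2], f)
      id <- sub("\\.[^.]*$", "", basename(f))
      refl_spectrum(id, df[[1L]], df[[2L]])
    })
    names(out) <- vapply(out, `[[`, "", "species_id")
    return(out)
  }
  if (!file.exists(path)) stop("file not found: ", path)
  df <- .read_delim_table(path, header = TRUE)
  if (nrow(df) == 0L) stop("no data rows in ", path)
  if (dialect == "wide") {
    if (tolower(names(df)[1L]) != "wavelength")
      stop("wide layout requires first column 'wavelength', got '", names(df)[1L], "'")
    df <- .check_numeric_cols(df, names(df), path)
    wl <- df[[1L]]
    out <- lapply(names(df)[-1L], function(id) refl_spectrum(id, wl, df[[id]]))
    names(out) <- names(df)[-1L]
    return(out)
  }
  # long
  need <- c("species_id", "wavelength", "reflectance")
  if (!all(need %in% names(df)))
    stop("long layout requires columns: ", paste(need, collapse = ", "))
  df <- .check_numeric_cols(df, c("wavelength", "reflectance"), path)
  ids <- unique(df$species_id)
  out <- lapply(ids, function(id) {
    sub <- df[df$species_id == id, ]
    refl_spectrum(as.character(id), sub$wavelength, sub$reflectance)
  })
  names(out) <- as.character(ids)
  out
}

#' Resample a spectrum onto a wavelength grid
#'
#' Linear interpolation onto `grid`, with constant extension permitted over an
#' edge margin of at most 5 nm; a larger coverage gap is an error. Values are
#' floored at zero.
#'
#' @param spectrum a [refl_spectrum].
#' @param grid target wavelengths (nm), strictly increasing.
#' @param edge_margin maximum permitted edge extrapolation in nm (fixed 5).
#' @return A [refl_spectrum] on `grid`.
#' @export
resample_spectrum <- function(spectrum, grid = default_grid(), edge_margin = 5) {
  stopifnot(inherits(spectrum, "refl_spectrum"))
  grid <- as.numeric(grid)
  if (is.unsorted(grid, strictly = TRUE)) stop("grid must be strictly increasing")
  lo_gap <- min(spectrum$wavelength) - min(grid)
  hi_gap <- max(grid) - max(spectrum$wavelength)
  if (lo_gap > edge_margin || hi_gap > edge_margin)
    stop(sprintf("spectrum '%s' does not cover the grid: gap of %.1f nm at the %s edge",
                 spectrum$species_id, max(lo_gap, hi_gap),
                 if (lo_gap >= hi_gap) "short-wavelength" else "long-wavelength"))
  vals <- stats::approx(spectrum$wavelength, spectrum$reflectance,
                        xout = grid, rule = 2)$y
  vals[vals < 0] <- 0
  structure(list(species_id = spectrum$species_id,
                 wavelength = grid, reflectance = vals),
            class = "refl_spectrum")
}

#' Mean background spectrum
#'
#' Pointwise arithmetic mean of a set of (typically leaf) spectra on a common
#' grid; the result is the adaptation background for the bee color model.
#'
#' @param spectra list of [refl_spectrum] on identical grids.
#' @return A [refl_spectrum] with `species_id = "background"`.
#' @export
mean_background <- function(spectra) {
  if (inherits(spectra, "refl_spectrum")) spectra <- list(spectra)
  if (!length(spectra)) stop("need at least one spectrum")
  wl <- spectra[[1L]]$wavelength
  for (sp in spectra)
    if (length(sp$wavelength) != length(wl) || any(sp$wavelength != wl))
      stop("spectra are not on a common grid; resample first")
  m <- rowMeans(vapply(spectra, `[[`, numeric(length(wl)), "reflectance"))
  structure(list(species_id = "background", wavelength = wl, reflectance = m),
            class = "refl_spectrum")
}

#' Visual pigment sensitivity curve (A1 nomogram)
#'
#' Spectral sensitivity of a photoreceptor from its peak wavelength alone,
#' using the Govardovskii A1 visual-pigment template (alpha band plus beta
#' band), peak-normalized to 1. Bee trichromat defaults put the peaks at 350
#' (UV), 440 (blue) and 540 (green) nm.
#'
#' @param lambda_max peak sensitivity wavelength, nm, in \[300, 700\].
#' @param grid evaluation wavelengths (nm).
#' @return A `sensitivity_curve`: list with `lambda_max`, `wavelength`,
#'   `sensitivity`.
#' @export
receptor_template <- function(lambda_max, grid = default_grid()) {
  if (!is.numeric(lambda_max) || length(lambda_max) != 1L ||
      lambda_max < 300 || lambda_max > 700)
    stop("lambda_max must be a single value in [300, 700] nm")
  lam <- as.numeric(grid)
  x <- lambda_max / lam
  # alpha band
  a <- 0.8795 + 0.0459 * exp(-(lambda_max - 300)^2 / 11940)
  S_alpha <- 1 / (exp(69.7 * (a - x)) + exp(28 * (0.922 - x)) +
                  exp(-14.9 * (1.104 - x)) + 0.674)
  # beta band
  lam_beta <- 189 + 0.315 * lambda_max
  b_beta <- -40.5 + 0.195 * lambda_max
  S_beta <- 0.26 * exp(-((lam - lam_beta) / b_beta)^2)
  s <- S_alpha + S_beta
  s <- s / max(s)
  structure(list(lambda_max = lambda_max, wavelength = lam, sensitivity = s),
            class = "sensitivity_curve")
}

#' Bee trichromat receptor set
#'
#' @param peaks named or unnamed numeric of three peak wavelengths (nm);
#'   default `c(uv = 350, blue = 440, green = 540)`.
#' @param grid evaluation wavelengths.
#' @return Named list of three `sensitivity_curve`s (uv, blue, green).
#' @export
bee_receptors <- function(peaks = c(uv = 350, blue = 440, green = 540),
                          grid = default_grid()) {
  if (length(peaks) != 3L) stop("need exactly three receptor peaks")
  if (is.null(names(peaks))) names(peaks) <- c("uv", "blue", "green")
  lapply(as.list(peaks), receptor_template, grid = grid)
}

#' Photon-flux-corrected daylight illuminant
#'
#' The CIE D65 relative spectral power distribution, interpolated to `grid`,
#' converted from energy to relative photon flux (multiplication by
#' wavelength) and normalized to a maximum of 1. Quantum catches in insect
#' photoreceptors count photons, not energy, hence the correction.
#'
#' @param grid wavelengths (nm) within \[300, 700\].
#' @return An `illuminant`: list with `wavelength`, `photon_flux`.
#' @export
d65_photon_flux <- function(grid = default_grid()) {
  grid <- as.numeric(grid)
  if (min(grid) < 300 || max(grid) > 700)
    stop("grid must lie within [300, 700] nm")
  spd <- stats::approx(.d65_wavelength, .d65_power, xout = grid)$y
  flux <- spd * grid
  flux <- flux / max(flux)
  structure(list(wavelength = grid, photon_flux = flux), class = "illuminant")
}

#' Spectral marker points
#'
#' Wavelengths of the steepest transitions in a reflectance spectrum: local
#' maxima of the absolute first derivative after smoothing with a centered
#' moving average. Maxima with slope below `rel_threshold` of the global
#' maximum slope are suppressed. Marker points of flowers classically align
#' with pollinator photoreceptor tuning.
#'
#' @param spectrum a [refl_spectrum] on a uniform grid.
#' @param smooth_window moving-average window in nm (default 11).
#' @param rel_threshold relative slope threshold (default 0.2).
#' @return Sorted numeric vector of wavelengths (possibly empty).
#' @export
detect_marker_points <- function(spectrum, smooth_window = 11, rel_threshold = 0.2) {
  stopifnot(inherits(spectrum, "refl_spectrum"))
  wl <- spectrum$wavelength
  step <- diff(wl)
  if (max(step) - min(step) > 1e-9)
    stop("spectrum must be on a uniform grid; resample first")
  step <- step[1L]
  k <- max(1L, round(smooth_window / step))
  if (k %% 2L == 0L) k <- k + 1L
  sm <- as.numeric(stats::filter(spectrum$reflectance, rep(1 / k, k), sides = 2))
  ok <- !is.na(sm)
  sm <- sm[ok]
  wlm <- wl[ok]
  if (length(sm) < 3L) return(numeric(0))
  d <- abs(diff(sm) / step)
  mids <- (wlm[-1L] + wlm[-length(wlm)]) / 2
  if (max(d) < 1e-12) return(numeric(0))
  # one marker per transition region: contiguous runs above half the slope
  # threshold that reach the full threshold count once, at their steepest
  # point (hysteresis keeps noise at the region edges from splitting a run)
  thr <- rel_threshold * max(d)
  runs <- rle(d >= thr / 2)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- integer(0)
  for (k in which(runs$values)) {
    i <- starts[k]:ends[k]
    if (max(d[i]) >= thr) keep <- c(keep, i[which.max(d[i])])
  }
  sort(mids[keep])
}
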