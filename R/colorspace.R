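#' Receptor excitations under von Kries adaptation
#'
#' Quantum catch of each receptor is the integral (trapezoidal, on the common
#' grid) of reflectance x sensitivity x illuminant photon flux. Catches are
#' normalized by the catch of the adaptation background (von Kries), and the
#' relative catch q is mapped to a bounded excitation E = q / (q + 1), so the
#' background itself sits at E = 0.5 in every receptor.
#'
#' @param flower a [refl_spectrum] on the common grid.
#' @param background adaptation background [refl_spectrum], same grid.
#' @param receptors list of three `sensitivity_curve`s, see [bee_receptors()].
#' @param illuminant an `illuminant`, see [d65_photon_flux()].
#' @return Named numeric `c(uv=, blue=, green=)` of class `excitation_triple`.
#' @export
excitations <- function(flower, background,
                        receptors = bee_receptors(grid = flower$wavelength),
                        illuminant = d65_photon_flux(flower$wavelength)) {
  stopifnot(inherits(flower, "refl_spectrum"), inherits(background, "refl_spectrum"))
  wl <- flower$wavelength
  if (length(background$wavelength) != length(wl) || any(background$wavelength != wl))
    stop("flower and background must share the integration grid")
  E <- vapply(receptors, function(rec) {
    if (length(rec$wavelength) != length(wl) || any(rec$wavelength != wl))
      stop("receptor curve not on the integration grid")
    w <- rec$sensitivity * illuminant$photon_flux
    P <- .trapz(wl, flower$reflectance * w)
    Pb <- .trapz(wl, background$reflectance * w)
    if (Pb <= 0)
      stop("zero background quantum catch in a receptor: degenerate adaptation")
    q <- P / Pb
    q / (q + 1)
  }, numeric(1))
  names(E) <- c("uv", "blue", "green")
  structure(E, class = "excitation_triple")
}

.trapz <- function(x, y) {
  n <- length(x)
  sum((y[-1L] + y[-n]) * diff(x)) / 2
}

.sector_names <- c("BG", "B", "UB", "UV", "UG", "G")

#' Sector of a hue angle
#'
#' The hexagon is tiled into six 60-degree wedges centered on the receptor
#' and blended vertices: BG at 30, B at 90, UB at 150, UV at 210, UG at 270,
#' G at 330 degrees. Wedges are half-open `[vertex - 30, vertex + 30)`, so a
#' boundary angle belongs to the higher wedge.
#'
#' @param theta hue angle(s) in degrees, \[0, 360).
#' @return Character vector of sector labels.
#' @export
hue_sector <- function(theta) {
  theta <- theta %% 360
  .sector_names[floor(theta / 60) %% 6 + 1L]
}

#' Hexagon color locus from excitations
#'
#' Cartesian coordinates in the bee color hexagon:
#' `x = (sqrt(3)/2) (E_g - E_uv)`, `y = E_b - (E_uv + E_g)/2`. Hue is the
#' counterclockwise polar angle theta in \[0, 360); chromatic contrast r is
#' the distance from the achromatic center. The achromatic point (r = 0)
#' reports theta = 0 and an NA sector.
#'
#' @param e an `excitation_triple` (or numeric of three excitations uv, blue,
#'   green).
#' @param species_id optional label carried into the result.
#' @return One-row data.frame with columns `species_id`, `x`, `y`,
#'   `theta_deg`, `r`, `sector`.
#' @export
hexagon_locus <- function(e, species_id = NA_character_) {
  e <- as.numeric(e)
  if (length(e) != 3L) stop("need three excitations (uv, blue, green)")
  x <- sqrt(3) / 2 * (e[3L] - e[1L])
  y <- e[2L] - (e[1L] + e[3L]) / 2
  r <- sqrt(x^2 + y^2)
  if (r < .Machine$double.eps * 8) {
    theta <- 0
    sector <- NA_character_
    r <- 0
  } else {
    theta <- (atan2(y, x) * 180 / pi) %% 360
    sector <- hue_sector(theta)
  }
  data.frame(species_id = species_id, x = x, y = y,
             theta_deg = theta, r = r, sector = sector,
             stringsAsFactors = FALSE)
}

#' Color loci for a set of flower spectra
#'
#' Full mapping pipeline: resample each spectrum to the grid, average
#' replicate spectra sharing a `species_id`, then compute the hexagon locus
#' of each species against the supplied leaf-green background.
#'
#' @param spectra list of [refl_spectrum] (flowers).
#' @param background a [refl_spectrum]; resampled internally.
#' @param grid integration grid (nm), default 1-nm 300--700.
#' @param peaks receptor peak wavelengths, default `c(uv=350, blue=440, green=540)`.
#' @return data.frame of class `color_loci`, one row per species, columns
#'   `species_id`, `x`, `y`, `theta_deg`, `r`, `sector`.
#' @export
hexagon_loci <- function(spectra, background, grid = default_grid(),
                         peaks = c(uv = 350, blue = 440, green = 540)) {
  if (inherits(spectra, "refl_spectrum")) spectra <- list(spectra)
  res <- lapply(spectra, resample_spectrum, grid = grid)
  ids <- vapply(res, `[[`, "", "species_id")
  uids <- unique(ids)
  merged <- lapply(uids, function(id) {
    reps <- res[ids == id]
    if (length(reps) == 1L) return(reps[[1L]])
    m <- mean_background(reps)
    m$species_id <- id
    m
  })
  bg <- resample_spectrum(background, grid = grid)
  receptors <- bee_receptors(peaks, grid = grid)
  illum <- d65_photon_flux(grid)
  rows <- lapply(merged, function(sp)
    hexagon_locus(excitations(sp, bg, receptors, illum), sp$species_id))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("color_loci", "data.frame")
  out
}

#' Euclidean color distance between loci
#'
#' @param a,b one-row locus data.frames (or numeric `c(x, y)`).
#' @return Distance in hexagon units.
#' @export
color_distance <- function(a, b) {
  xy <- function(p) if (is.data.frame(p)) c(p$x[1L], p$y[1L]) else as.numeric(p)[1:2]
  pa <- xy(a); pb <- xy(b)
  sqrt(sum((pa - pb)^2))
}

#' Pairwise color distance matrix
#'
#' @param loci a `color_loci` data.frame.
#' @return Symmetric matrix of Euclidean distances, dimnames = species ids.
#' @export
color_distance_matrix <- function(loci) {
  m <- as.matrix(stats::dist(cbind(loci$x, loci$y)))
  dimnames(m) <- list(loci$species_id, loci$species_id)
  m
}

#' Angular frequency distribution of color loci
#'
#' Counts of chromatic loci (r > 0) in half-open angular bins
#' `[0, bw), [bw, 2 bw), ...`; achromatic loci are excluded from the bins and
#' reported in the `n_achromatic` attribute.
#'
#' @param loci a `color_loci` data.frame.
#' @param bin_width bin width in degrees; must divide 360.
#' @return data.frame with `bin_lo`, `bin_hi`, `count`; attributes
#'   `n_achromatic` and `n_chromatic`.
#' @export
sector_frequency <- function(loci, bin_width = 10) {
  if (360 %% bin_width != 0) stop("bin_width must divide 360")
  chrom <- loci[loci$r > 0, , drop = FALSE]
  breaks <- seq(0, 360, by = bin_width)
  idx <- floor((chrom$theta_deg %% 360) / bin_width) + 1L
  counts <- tabulate(idx, nbins = length(breaks) - 1L)
  out <- data.frame(bin_lo = breaks[-length(breaks)], bin_hi = breaks[-1L],
                    count = counts)
  attr(out, "n_achromatic") <- nrow(loci) - nrow(chrom)
  attr(out, "n_chromatic") <- nrow(chrom)
  out
}

#' Fraction of loci in an angular window
#'
#' Proportion of chromatic loci whose hue lies in the half-open window
#' `[lo, hi)`. The default window 30--90 degrees covers the bee-blue and
#' bee-blue-green sectors where bee innate color preferences concentrate.
#'
#' @param loci a `color_loci` data.frame.
#' @param window numeric `c(lo, hi)` in degrees within \[0, 360).
#' @return Proportion in \[0, 1\] (NaN when no chromatic loci).
#' @export
preference_fraction <- function(loci, window = c(30, 90)) {
  theta <- loci$theta_deg[loci$r > 0] %% 360
  mean(theta >= window[1L] & theta < window[2L])
}
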