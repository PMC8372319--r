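# Broadened photoemission-style spectra from eigenvalue sets: Pseudo-Voigt
# lineshapes (a Lorentzian/Gaussian mixture of shared FWHM, each component
# unit-area normalized) and dataset-level Gaussian envelopes.

#' Spectrum parameters
#'
#' @param eta Lorentzian fraction in [0, 1] (default 0.3: 30 percent
#'   Lorentzian, 70 percent Gaussian).
#' @param fwhm full width at half maximum Gamma in eV (default 0.5; 0.3 is
#'   the common narrow alternative).
#' @param from,to energy grid bounds in eV (NULL: auto from the states,
#'   padded by 5 * fwhm).
#' @param step grid step in eV.
#' @param mode \code{"occupied"} (photoemission: occupied states only),
#'   \code{"all"} (all valid states).
#' @return list of class \code{"spectrum_params"}.
#' @export
spectrum_params <- function(eta = 0.3, fwhm = 0.5, from = NULL, to = NULL,
                            step = 0.01, mode = c("occupied", "all")) {
  stopifnot(eta >= 0, eta <= 1, fwhm > 0, step > 0)
  if (!is.null(from) && !is.null(to)) stopifnot(from < to)
  structure(list(eta = eta, fwhm = fwhm, from = from, to = to, step = step,
                 mode = match.arg(mode)),
            class = "spectrum_params")
}

#' Pseudo-Voigt lineshape
#'
#' eta * L + (1 - eta) * G with both components unit-area normalized and
#' sharing the FWHM Gamma:
#' L(x) = (Gamma/2pi) / ((x - c)^2 + (Gamma/2)^2),
#' G(x) = (2/Gamma) sqrt(ln 2 / pi) exp(-4 ln 2 (x - c)^2 / Gamma^2).
#'
#' @param x energies in eV (vectorized).
#' @param center peak center in eV.
#' @param params a \code{spectrum_params} (eta and fwhm are used).
#' @return intensities (1/eV).
#' @export
pseudo_voigt <- function(x, center, params = spectrum_params()) {
  g <- params$fwhm
  L <- (g / (2 * pi)) / ((x - center)^2 + (g / 2)^2)
  G <- (2 / g) * sqrt(log(2) / pi) * exp(-4 * log(2) * (x - center)^2 / g^2)
  params$eta * L + (1 - params$eta) * G
}

.spectrum_grid <- function(centers, params) {
  lo <- if (is.null(params$from)) min(centers) - 5 * params$fwhm else params$from
  hi <- if (is.null(params$to)) max(centers) + 5 * params$fwhm else params$to
  seq(lo, hi, by = params$step)
}

new_spectrum <- function(energy, intensity, params, level_tag = "") {
  structure(list(energy = energy, intensity = intensity, params = params,
                 level_tag = level_tag),
            class = "ph_spectrum")
}

#' Broadened spectrum of one eigenvalue set
#'
#' Sum of unit-weight Pseudo-Voigt lineshapes centered at the selected
#' states (occupied only in photoemission mode). Over an unbounded grid the
#' integral equals the number of selected states.
#'
#' @param record an \code{eigen_record}, or a plain numeric vector of
#'   energies (then \code{n_occupied} must be given for occupied mode).
#' @param params a \code{spectrum_params}.
#' @param n_occupied occupation count when \code{record} is a bare vector.
#' @return object of class \code{"ph_spectrum"} with \code{energy} (eV) and
#'   \code{intensity} (states/eV).
#' @export
make_spectrum <- function(record, params = spectrum_params(), n_occupied = NULL) {
  if (inherits(record, "eigen_record")) {
    vals <- record$values[record$mask]
    nocc <- record$n_occupied
    tag <- record$level_tag
  } else {
    vals <- as.numeric(record)
    nocc <- if (is.null(n_occupied)) length(vals) else n_occupied
    tag <- ""
  }
  centers <- if (params$mode == "occupied") vals[seq_len(nocc)] else vals
  if (length(centers) == 0L) stop("no states selected for the spectrum")
  grid <- .spectrum_grid(centers, params)
  inten <- rowSums(vapply(centers, function(c0) pseudo_voigt(grid, c0, params),
                          numeric(length(grid))))
  new_spectrum(grid, inten, params, tag)
}

#' Gaussian envelope over many eigenvalue records
#'
#' Places a unit-area Gaussian of the given FWHM on every valid eigenvalue
#' of every record and sums them: the dataset-level view of a level-of-
#' theory shift.
#'
#' @param records list of \code{eigen_record}.
#' @param width Gaussian FWHM in eV.
#' @param from,to,step grid specification in eV (NULL bounds: auto).
#' @param mode \code{"all"} or \code{"occupied"}.
#' @return a \code{"ph_spectrum"}.
#' @export
gaussian_envelope <- function(records, width = 0.5, from = NULL, to = NULL,
                              step = 0.02, mode = c("all", "occupied")) {
  mode <- match.arg(mode)
  if (length(records) == 0L) stop("need at least one record")
  centers <- unlist(lapply(records, function(r) {
    v <- r$values[r$mask]
    if (mode == "occupied") v[seq_len(r$n_occupied)] else v
  }))
  p <- spectrum_params(eta = 0, fwhm = width, from = from, to = to,
                       step = step, mode = "all")
  grid <- .spectrum_grid(centers, p)
  # binned accumulation keeps this linear in the number of states
  inten <- numeric(length(grid))
  for (c0 in centers) inten <- inten + pseudo_voigt(grid, c0, p)
  new_spectrum(grid, inten, p, records[[1]]$level_tag)
}

#' Integrated area of a spectrum (trapezoidal)
#' @param spectrum a \code{ph_spectrum}.
#' @return numeric area (states).
#' @export
spectrum_area <- function(spectrum) {
  x <- spectrum$energy; y <- spectrum$intensity
  sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
}

# indices of strict local maxima of an intensity vector
local_maxima <- function(y) {
  n <- length(y)
  which(y > c(-Inf, y[-n]) & y >= c(y[-1], -Inf))
}

#' Intensity error between two spectra near the reference peaks
#'
#' MAE and RMSE of the intensity difference restricted to grid points
#' within \code{peak_window} of any local maximum of the reference
#' spectrum.
#'
#' @param pred,ref \code{ph_spectrum}s on identical grids.
#' @param peak_window half-width of the peak vicinity in eV (default: the
#'   reference FWHM).
#' @return list with \code{mae} and \code{rmse} (intensity units).
#' @export
spectrum_error <- function(pred, ref, peak_window = NULL) {
  if (length(pred$energy) != length(ref$energy) ||
      max(abs(pred$energy - ref$energy)) > 1e-9)
    stop("spectra must share an identical energy grid")
  if (is.null(peak_window)) peak_window <- ref$params$fwhm
  peaks <- ref$energy[local_maxima(ref$intensity)]
  near <- vapply(ref$energy, function(e) any(abs(e - peaks) <= peak_window),
                 logical(1))
  d <- pred$intensity[near] - ref$intensity[near]
  list(mae = mean(abs(d)), rmse = sqrt(mean(d^2)))
}

#' @export
print.ph_spectrum <- function(x, ...) {
  cat(sprintf("<spectrum%s: %d grid points, %.2f..%.2f eV, area %.2f>\n",
              if (nzchar(x$level_tag)) paste0(" [", x$level_tag, "]") else "",
              length(x$energy), min(x$energy), max(x$energy),
              spectrum_area(x)))
  invisible(x)
}

#' @export
plot.ph_spectrum <- function(x, ...) {
  graphics::plot(x$energy, x$intensity, type = "l",
                 xlab = "energy (eV)", ylab = "intensity (states/eV)", ...)
  invisible(x)
}

#' Write a spectrum to CSV (columns energy_eV, intensity)
#' @param spectrum a \code{ph_spectrum}.
#' @param path output path.
#' @export
write_spectrum <- function(spectrum, path) {
  utils::write.csv(data.frame(energy_eV = spectrum$energy,
                              intensity = spectrum$intensity),
                   path, row.names = FALSE)
  invisible(path)
}
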