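#' Construct a visual system
#'
#' A receiver's visual system for photon-catch calculation: an illuminant
#' irradiance spectrum and one spectral-sensitivity curve per receptor
#' class. Receptor classes are the four single cones (UV, SW, MW, LW),
#' whose catches index colour, and the double cone, whose catch indexes
#' luminance.
#'
#' @param wavelength_nm Strictly increasing wavelength grid (nm).
#' @param illuminant Non-negative irradiance at each wavelength.
#' @param sensitivities Data frame with non-negative columns `uv`, `sw`,
#'   `mw`, `lw`, `double`, one row per wavelength.
#' @return A `visual_system` list.
#' @export
visual_system <- function(wavelength_nm, illuminant, sensitivities) {
  receptors <- c("uv", "sw", "mw", "lw", "double")
  if (any(diff(wavelength_nm) <= 0)) abort("wavelength grid must be strictly increasing")
  if (length(illuminant) != length(wavelength_nm) || any(illuminant < 0)) {
    abort("illuminant must be non-negative and match the wavelength grid")
  }
  sens <- as_tibble(sensitivities)
  if (!all(receptors %in% names(sens))) {
    abort("sensitivities must have columns uv, sw, mw, lw, double")
  }
  if (nrow(sens) != length(wavelength_nm)) {
    abort("sensitivities must have one row per wavelength")
  }
  if (any(as.matrix(sens[receptors]) < 0)) abort("sensitivities must be non-negative")
  structure(list(wavelength_nm = as.numeric(wavelength_nm),
                 illuminant = as.numeric(illuminant),
                 sensitivities = sens[receptors]),
            class = "visual_system")
}

#' Idealised avian-like visual system
#'
#' A synthetic stand-in for a tabulated avian visual model: Gaussian cone
#' sensitivities (UV 370 nm, SW 445 nm, MW 508 nm, LW 565 nm; a broad
#' double cone at 560 nm) under a flat illuminant, on a 300-700 nm grid.
#' Adequate for exercising and testing the photon-catch machinery; not a
#' measured sensitivity set for any real species.
#'
#' @param step_nm Grid step in nm.
#' @return A [visual_system()].
#' @export
ideal_visual_system <- function(step_nm = 1) {
  wl <- seq(300, 700, by = step_nm)
  g <- function(peak, width) exp(-0.5 * ((wl - peak) / width)^2)
  visual_system(
    wavelength_nm = wl,
    illuminant = rep(1, length(wl)),
    sensitivities = tibble(
      uv = g(370, 25), sw = g(445, 30), mw = g(508, 32), lw = g(565, 35),
      double = g(560, 70)
    )
  )
}

#' Photon catch of a receptor viewing a reflectance spectrum
#'
#' The receptor-specific quantal catch: the integral over wavelength of
#' reflectance x illuminant x receptor sensitivity, evaluated by
#' trapezoidal quadrature on a common grid (the overlap of the spectrum's
#' and the visual system's grids, at the finer of the two steps, with
#' linear interpolation). With `normalize = TRUE` the catch is scaled so a
#' perfect white reflector (reflectance 1 everywhere) gives exactly 1.
#'
#' @param spectrum Data frame with columns `wavelength_nm` and
#'   `reflectance` (reflectance in \[0, 1\]).
#' @param vis A [visual_system()].
#' @param receptor One of `"uv"`, `"sw"`, `"mw"`, `"lw"`, `"double"`.
#' @param normalize Scale so that reflectance 1 gives catch 1?
#' @return Non-negative scalar photon catch.
#' @export
photon_catch <- function(spectrum, vis, receptor, normalize = TRUE) {
  stopifnot(inherits(vis, "visual_system"))
  receptor <- match.arg(receptor, names(vis$sensitivities))
  spectrum <- as_tibble(spectrum)
  if (!all(c("wavelength_nm", "reflectance") %in% names(spectrum))) {
    abort("spectrum must have columns wavelength_nm and reflectance")
  }
  wl_s <- spectrum$wavelength_nm
  if (any(diff(wl_s) <= 0)) abort("spectrum wavelengths must be strictly increasing")
  lo <- max(min(wl_s), min(vis$wavelength_nm))
  hi <- min(max(wl_s), max(vis$wavelength_nm))
  if (lo >= hi) abort("spectrum and visual system wavelength ranges do not overlap")
  step <- min(min(diff(wl_s)), min(diff(vis$wavelength_nm)))
  grid <- seq(lo, hi, by = step)
  R <- approx(wl_s, spectrum$reflectance, grid)$y
  I <- approx(vis$wavelength_nm, vis$illuminant, grid)$y
  S <- approx(vis$wavelength_nm, vis$sensitivities[[receptor]], grid)$y
  q <- pracma::trapz(grid, R * I * S)
  if (normalize) {
    denom <- pracma::trapz(grid, I * S)
    if (denom <= 0) abort("illuminant x sensitivity integrates to zero on the common grid")
    q <- q / denom
  }
  q
}

#' All five photon catches of a spectrum
#'
#' @inheritParams photon_catch
#' @return One-row tibble with columns `luminance` (double-cone catch),
#'   `uv`, `sw`, `mw`, `lw`.
#' @export
photon_catches <- function(spectrum, vis = ideal_visual_system(),
                           normalize = TRUE) {
  q <- vapply(c("double", "uv", "sw", "mw", "lw"), function(r) {
    photon_catch(spectrum, vis, r, normalize = normalize)
  }, numeric(1))
  tibble(luminance = q[["double"]], uv = q[["uv"]], sw = q[["sw"]],
         mw = q[["mw"]], lw = q[["lw"]])
}

#' Read a reflectance spectrum from a two-column CSV
#'
#' @param path CSV with columns `wavelength_nm`, `reflectance`.
#' @return Tibble spectrum.
#' @export
read_spectrum_csv <- function(path) {
  x <- as_tibble(read.csv(path))
  if (!all(c("wavelength_nm", "reflectance") %in% names(x))) {
    abort("spectrum CSV must have columns wavelength_nm and reflectance")
  }
  x
}
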