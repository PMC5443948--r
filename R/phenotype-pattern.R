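#' Granularity (Fourier bandpass) spectrum of an egg image
#'
#' The image is mean-padded outside the mask (every non-egg pixel set to
#' the mean gray level of the egg region), Fourier transformed, and split
#' into octave spatial-frequency annuli. The band scales start at
#' half the smaller image dimension and halve per band; the band of scale
#' `s` is the half-open frequency annulus `(1/(2s), 1/s]` (cycles/px), so
#' it contains every spatial period in `[s, 2s)`. The first band extends
#' down to (but excludes) DC and the last up to the Nyquist corner, so
#' the bands tile the whole non-DC frequency plane. The energy of a band
#' is the mean squared value, inside the mask, of the image filtered to
#' that band.
#'
#' @param img An [egg_image()] with mask area of at least 64 px.
#' @param n_bands Number of octave bands; default halves the largest
#'   period down to 2 px.
#' @return Tibble with columns `band`, `scale_px` (the band's scale, the
#'   smallest period it contains), `freq_lo`, `freq_hi` (cycles/px,
#'   half-open `(lo, hi]`), `energy`.
#' @export
granularity_spectrum <- function(img, n_bands = NULL) {
  stopifnot(inherits(img, "egg_image"))
  if (sum(img$mask) < 64) abort("mask area must be at least 64 px")
  n1 <- nrow(img$pixels); n2 <- ncol(img$pixels)
  s_max <- floor(min(n1, n2) / 2)
  max_bands <- floor(log2(s_max / 2)) + 1
  if (is.null(n_bands)) n_bands <- max_bands
  if (n_bands < 2 || max_bands < 2) abort("fewer than 2 feasible octave bands")
  n_bands <- min(n_bands, max_bands)
  scales <- s_max / 2^(0:(n_bands - 1))
  fc <- 1 / scales
  edges <- c(0, fc)
  edges[n_bands + 1] <- Inf         # highest band reaches the Nyquist corner

  mu <- mean(img$pixels[img$mask])
  x <- img$pixels
  x[!img$mask] <- mu
  x <- x - mu                       # DC removal; padding becomes exactly 0
  F <- fft(x)
  # integer frequency indices keep +f / -f exactly symmetric, so every
  # half-open annulus is conjugate-symmetric and the filtered images real
  ky <- seq_len(n1) - 1; ky[ky >= n1 / 2] <- ky[ky >= n1 / 2] - n1
  kx <- seq_len(n2) - 1; kx[kx >= n2 / 2] <- kx[kx >= n2 / 2] - n2
  r <- sqrt(outer((ky / n1)^2, (kx / n2)^2, `+`))

  energy <- vapply(seq_len(n_bands), function(j) {
    sel <- r > edges[j] & r <= edges[j + 1]
    Fj <- F * sel
    yj <- Re(fft(Fj, inverse = TRUE)) / (n1 * n2)
    mean(yj[img$mask]^2)
  }, numeric(1))

  structure(
    tibble(band = seq_len(n_bands), scale_px = scales,
           freq_lo = edges[-(n_bands + 1)], freq_hi = edges[-1],
           energy = energy),
    class = c("granularity_spectrum", "tbl_df", "tbl", "data.frame")
  )
}

otsu_threshold <- function(v) {
  rg <- range(v)
  if (diff(rg) < 1e-12) return(rg[1])
  EBImage::otsu(matrix(v, ncol = 1), range = rg, levels = 256L)
}

#' Five pattern metrics from an egg image
#'
#' Operationalisations of the five classic egg-pattern descriptors on top
#' of the granularity spectrum:
#' \describe{
#'   \item{marking_size}{band centre period (px) with maximal energy —
#'     the predominant marking size; `NA` for a patternless image.}
#'   \item{main_contribution}{maximal band energy as a fraction of total
#'     energy — how much the dominant marking scale contributes.}
#'   \item{contrast}{square root of total bandpass energy — the overall
#'     amplitude of markings against the background.}
#'   \item{coverage}{fraction of egg pixels darker than an Otsu threshold
#'     computed on the egg region.}
#'   \item{dispersion}{coefficient of variation of coverage across five
#'     equal-length longitudinal zones of the egg — high when markings
#'     cluster (e.g. a blunt-pole ring), low when evenly spread.}
#' }
#'
#' @param img An [egg_image()].
#' @param gran Optional precomputed [granularity_spectrum()] of `img`.
#' @return One-row tibble with the five metric columns.
#' @export
pattern_metrics <- function(img, gran = NULL) {
  stopifnot(inherits(img, "egg_image"))
  if (is.null(gran)) gran <- granularity_spectrum(img)
  total <- sum(gran$energy)
  if (total <= 1e-20) {
    size <- NA_real_; contrib <- 0; contrast <- 0
  } else {
    size <- gran$scale_px[which.max(gran$energy)]
    contrib <- max(gran$energy) / total
    contrast <- sqrt(total)
  }

  v <- img$pixels[img$mask]
  if (sd(v) < 1e-10) {
    coverage <- 0; dispersion <- 0
  } else {
    thr <- otsu_threshold(v)
    dark <- img$pixels < thr & img$mask
    coverage <- sum(dark) / sum(img$mask)
    # longitudinal = the egg's long axis
    by_col <- ncol(img$pixels) >= nrow(img$pixels)
    count_along <- function(m) if (by_col) colSums(m) else rowSums(m)
    mask_n <- count_along(img$mask)
    dark_n <- count_along(dark)
    span <- range(which(mask_n > 0))
    cuts <- seq(span[1] - 0.5, span[2] + 0.5, length.out = 6)
    zone <- cut(seq_along(mask_n), cuts, labels = FALSE)
    keep <- !is.na(zone)
    zc <- vapply(1:5, function(z) {
      mz <- sum(mask_n[keep][zone[keep] == z])
      if (mz == 0) return(NA_real_)
      sum(dark_n[keep][zone[keep] == z]) / mz
    }, numeric(1))
    zc <- zc[!is.na(zc)]
    dispersion <- if (mean(zc) > 0) sd(zc) / mean(zc) else 0
  }

  tibble(marking_size = size, main_contribution = contrib,
         contrast = contrast, coverage = coverage, dispersion = dispersion)
}

#' Full 10-trait phenotype from raw measurements
#'
#' Combines the five photon catches of a reflectance spectrum with the
#' five pattern metrics of an egg photograph into the canonical trait
#' vector (see [egg_traits()]).
#'
#' @param spectrum Reflectance spectrum (see [photon_catch()]).
#' @param img An [egg_image()].
#' @param vis A [visual_system()].
#' @param n_bands Passed to [granularity_spectrum()].
#' @return One-row tibble with the ten trait columns in canonical order.
#' @export
egg_phenotype <- function(spectrum, img, vis = ideal_visual_system(),
                          n_bands = NULL) {
  bind_cols(
    photon_catches(spectrum, vis),
    pattern_metrics(img, granularity_spectrum(img, n_bands))
  )[egg_traits()]
}
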