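#' Corrected mean fluorescence (CMF) of a region
#'
#' Mean fluorescence intensity of a region minus the background intensity
#' measured on the same image. A negative result (background brighter than
#' the region) is returned as-is with a warning.
#'
#' @param mean_intensity region mean intensity (arbitrary units, >= 0).
#' @param background_intensity same-image background intensity (>= 0).
#' @return The background-corrected mean intensity.
#' @export
corrected_mean_intensity <- function(mean_intensity, background_intensity) {
  stopifnot(all(mean_intensity >= 0), all(background_intensity >= 0))
  cmf <- mean_intensity - background_intensity
  if (any(cmf < 0)) warning("negative corrected intensity: background exceeds region mean")
  cmf
}

# ratio of two background-corrected regions; the denominator must be positive
cmf_ratio <- function(num_mean, num_bg, den_mean, den_bg, what) {
  num <- corrected_mean_intensity(num_mean, num_bg)
  den <- suppressWarnings(corrected_mean_intensity(den_mean, den_bg))
  if (any(den <= 0)) stop(what, " is undefined: denominator CMF is not positive")
  num / den
}

#' Labeling specificity: AIS over soma corrected intensity
#'
#' @param ais_mean,ais_bg AIS region mean and same-image background.
#' @param soma_mean,soma_bg soma region mean and same-image background.
#' @return CMF(AIS) / CMF(soma).
#' @export
specificity_ratio <- function(ais_mean, ais_bg, soma_mean, soma_bg) {
  cmf_ratio(ais_mean, ais_bg, soma_mean, soma_bg, "specificity ratio")
}

#' Polarity index: AIS over proximal-dendrite corrected intensity
#'
#' Quantifies how strongly a protein is polarized to the axon initial
#' segment relative to dendrites of similar width.
#'
#' @param ais_mean,ais_bg AIS region mean and same-image background.
#' @param dendrite_mean,dendrite_bg dendrite region mean and background.
#' @return CMF(AIS) / CMF(dendrite).
#' @export
polarity_index <- function(ais_mean, ais_bg, dendrite_mean, dendrite_bg) {
  cmf_ratio(ais_mean, ais_bg, dendrite_mean, dendrite_bg, "polarity index")
}

# local maxima of a numeric trace (strictly above the left neighbour,
# at least the right neighbour, so plateau peaks report their left edge);
# profile endpoints are never peaks
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0L))
  i <- 2:(n - 1L)
  i[x[i] > x[i - 1L] & x[i] >= x[i + 1L]]
}

# topographic prominence of each candidate peak: height above the higher
# of the two saddle minima reached before meeting taller terrain
peak_prominence <- function(x, peaks) {
  vapply(peaks, function(p) {
    h <- x[p]
    left <- if (p > 1L) x[seq_len(p - 1L)] else numeric(0L)
    higher <- which(left >= h)
    lmin <- if (length(higher) > 0L) min(left[(max(higher)):(p - 1L)]) else min(c(left, h))
    right <- if (p < length(x)) x[(p + 1L):length(x)] else numeric(0L)
    higher <- which(right >= h)
    rmin <- if (length(higher) > 0L) min(right[seq_len(min(higher))]) else min(c(right, h))
    h - max(lmin, rmin)
  }, numeric(1L))
}

#' Periodicity of a fluorescence line profile
#'
#' Detects local intensity maxima along a 1-D line profile and returns the
#' mean successive peak-to-peak spacing in nanometres — the standard
#' measure of the ~190 nm spectrin-based membrane periodic skeleton.
#' Peaks must exceed a prominence floor (a fraction of the profile's
#' interquartile intensity range, making the measure invariant to
#' intensity scaling) and be separated by a minimum physical distance.
#' An optional 3-point parabolic refinement interpolates subpixel peak
#' positions.
#'
#' @param intensities numeric intensity trace (length >= 3).
#' @param pixel_size physical sampling step in nm per sample (> 0).
#' @param min_prominence_frac minimum peak prominence as a fraction of the
#'   interquartile intensity range (default 0.2).
#' @param min_separation_nm minimum peak separation in nm (default 100,
#'   below any plausible spectrin period).
#' @param refine if `TRUE`, apply 3-point parabolic subpixel refinement.
#' @return List with `mean_spacing_nm`, `spacings_nm` (successive
#'   peak-to-peak distances), `peak_positions_nm` and `n_peaks`.
#' @export
periodicity <- function(intensities, pixel_size,
                        min_prominence_frac = 0.2, min_separation_nm = 100,
                        refine = FALSE) {
  stopifnot(length(intensities) >= 3L, pixel_size > 0)
  x <- as.numeric(intensities)
  peaks <- local_maxima(x)
  if (length(peaks) > 0L) {
    iqr <- stats::IQR(x)
    floor_prom <- min_prominence_frac * iqr
    prom <- peak_prominence(x, peaks)
    peaks <- peaks[prom >= floor_prom]
    prom <- prom[prom >= floor_prom]
  }
  # enforce minimum separation: keep the more prominent peak of any
  # too-close pair (greedy from the most prominent down)
  if (length(peaks) > 1L) {
    min_sep_px <- min_separation_nm / pixel_size
    keep <- logical(length(peaks))
    for (j in order(-prom, peaks)) {
      if (!any(keep & abs(peaks - peaks[j]) < min_sep_px)) keep[j] <- TRUE
    }
    peaks <- sort(peaks[keep])
  }
  if (length(peaks) < 2L) {
    stop("fewer than 2 peaks detected; cannot estimate periodicity")
  }
  pos <- as.numeric(peaks)
  if (refine) {
    pos <- vapply(peaks, function(p) {
      if (p <= 1L || p >= length(x)) return(as.numeric(p))
      denom <- x[p - 1L] - 2 * x[p] + x[p + 1L]
      if (denom == 0) return(as.numeric(p))
      p + 0.5 * (x[p - 1L] - x[p + 1L]) / denom
    }, numeric(1L))
  }
  spacings <- diff(pos) * pixel_size
  list(mean_spacing_nm = mean(spacings), spacings_nm = spacings,
       peak_positions_nm = (pos - 1) * pixel_size, n_peaks = length(peaks))
}

#' Summarize per-neuron imaging metrics as group mean and SEM
#'
#' @param values numeric vector of per-neuron metric values.
#' @return Named vector with `n`, `mean`, `sem`.
#' @export
group_mean_sem <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  c(n = n, mean = mean(values),
    sem = if (n > 1L) stats::sd(values) / sqrt(n) else NA_real_)
}
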