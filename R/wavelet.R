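#' Ricker (Mexican hat) kernel parameterised by peak width
#'
#' The Ricker wavelet \eqn{\psi(t) \propto (1 - t^2/\sigma^2)
#' \exp(-t^2/2\sigma^2)} is the matched filter used throughout: its central
#' positive lobe spans the two zero crossings at \eqn{\pm\sigma}, so the
#' "peak width" W -- the lateral extent of that lobe -- maps to
#' \eqn{\sigma = W/2}. The mapping is held in [ricker_sigma()], the single
#' place the convention lives. Taps are sampled on the bin grid, truncated at
#' \eqn{\pm 4\sigma}, scaled according to \code{scale_norm} and finally
#' mean-subtracted so they sum to zero exactly: the response to any constant
#' track is exactly zero despite truncation.
#'
#' Cross-scale comparability is set by \code{scale_norm}:
#' \describe{
#'   \item{\code{"area"} (default)}{taps scaled by \code{bin_size/sigma}
#'     (unit-area convention). The called-peak response to a flat-topped
#'     feature of half-max width L is then maximised near W = L, which is
#'     what lets a width scan read off the dominant feature scale.}
#'   \item{\code{"energy"}}{L2 convention, \code{sqrt(bin_size/sigma)}.}
#'   \item{\code{"amplitude"}}{unit maximum tap; comparable only within one
#'     width.}
#' }
#'
#' @param peak_width W in bp; must be at least \code{2 * bin_size}, below
#'   which the scale is unresolvable on the grid.
#' @param bin_size bin width in bp.
#' @param scale_norm cross-scale normalisation, see Details.
#' @return a \code{ricker_kernel}: list with \code{peak_width}, \code{sigma},
#'   \code{bin_size}, \code{taps} (odd-length, symmetric, zero-sum).
#' @export
ricker_kernel <- function(peak_width, bin_size,
                          scale_norm = c("area", "energy", "amplitude")) {
  scale_norm <- match.arg(scale_norm)
  if (peak_width < 2 * bin_size)
    stop("peak_width ", peak_width, " is unresolvable at bin size ", bin_size)
  sigma <- ricker_sigma(peak_width)
  half <- floor(4 * sigma / bin_size)
  t <- (-half:half) * bin_size
  taps <- (1 - t^2 / sigma^2) * exp(-t^2 / (2 * sigma^2))
  taps <- taps * switch(scale_norm,
                        area = bin_size / sigma,
                        energy = sqrt(bin_size / sigma),
                        amplitude = 1)
  taps <- taps - mean(taps)
  structure(list(peak_width = peak_width, sigma = sigma,
                 bin_size = bin_size, taps = taps, scale_norm = scale_norm),
            class = "ricker_kernel")
}

#' Peak-width to sigma mapping for the Ricker wavelet
#'
#' W is the distance between the Ricker zero crossings (the width of the
#' central positive lobe), so \eqn{\sigma = W/2}.
#'
#' @param peak_width W in bp.
#' @return sigma in bp.
#' @export
ricker_sigma <- function(peak_width) peak_width / 2

#' @export
print.ricker_kernel <- function(x, ...) {
  cat(sprintf("<ricker_kernel> W = %g bp (sigma %g), %d taps at %g bp, %s\n",
              x$peak_width, x$sigma, length(x$taps), x$bin_size,
              x$scale_norm))
  invisible(x)
}

#' Convolve a signal track with a Ricker kernel
#'
#' Chromosome ends are zero-padded (a known edge bias within ~W of the ends).
#' Masked bins contribute zero to the convolution, but the output is masked
#' wherever the kernel centre sits on a masked bin.
#'
#' @param track a signal [binned_track()] or named list of them.
#' @param kernel a [ricker_kernel()] on the same bin grid.
#' @return convolved track(s); the kernel's \code{peak_width} is carried in
#'   each track's \code{peak_width} element for downstream peak extents.
#' @export
convolve_track <- function(track, kernel) {
  map_tracks(track, function(t) {
    if (t$bin_size != kernel$bin_size)
      stop("kernel bin size does not match track bin size")
    v <- t$values
    masked <- is.na(v)
    v[masked] <- 0
    half <- (length(kernel$taps) - 1L) / 2L
    padded <- c(numeric(half), v, numeric(half))
    conv <- stats::filter(padded, kernel$taps, method = "convolution",
                          sides = 2)
    out <- as.numeric(conv)[(half + 1L):(half + length(v))]
    out[masked] <- NA_real_
    t$values <- out
    t$role <- "signal"
    t$peak_width <- kernel$peak_width
    t
  })
}

#' The root-2 ladder of wavelet peak widths
#'
#' Geometric series multiplying by sqrt(2) per step; the default spans
#' 50 kb to 51.2 Mbp in 21 widths (50 kb times 2^10).
#'
#' @param from,to first and last width in bp.
#' @return numeric vector of widths.
#' @export
ricker_width_ladder <- function(from = 50e3, to = 51.2e6) {
  k <- floor(round(2 * log2(to / from), 9))
  from * sqrt(2)^(0:k)
}

#' Multiscale Ricker transform of one track
#'
#' One convolved track per width, stacked as a matrix for heatmap export.
#' Analysis always uses the raw rows; the optional per-scale rescaling in
#' [export_heatmap()] is display-only.
#'
#' @param track a signal [binned_track()].
#' @param widths ascending wavelet peak widths in bp.
#' @param scale_norm passed to [ricker_kernel()].
#' @return a \code{multiscale_transform}: matrix (widths x bins) with the
#'   width vector as \code{widths} attribute, plus \code{chrom} and
#'   \code{bin_size}.
#' @export
multiscale_transform <- function(track, widths = ricker_width_ladder(),
                                 scale_norm = "area") {
  stopifnot(inherits(track, "binned_track"), !is.unsorted(widths))
  rows <- lapply(widths, function(w)
    convolve_track(track, ricker_kernel(w, track$bin_size, scale_norm))$values)
  m <- do.call(rbind, rows)
  rownames(m) <- format(widths, scientific = FALSE, trim = TRUE)
  structure(m, widths = widths, chrom = track$chrom,
            bin_size = track$bin_size, class = c("multiscale_transform",
                                                 class(m)))
}

#' Default width grid of the closely-spaced scan
#'
#' 100 to 800 kb in 50-kb steps, then 1000, 1500 and 3000 kb.
#' @return numeric vector of widths in bp.
#' @export
scan_width_grid <- function() c(seq(100e3, 800e3, by = 50e3), 1e6, 1.5e6, 3e6)

#' Scan wavelet widths and record called-peak height metrics
#'
#' For each width the track is convolved, positive local maxima are called
#' inside \code{region} (see [call_peaks()]), optionally filtered by a
#' percentile cutoff calibrated on peaks inside \code{late_region}, and the
#' number, sum and mean of the surviving peak heights are recorded. The
#' argmax of the mean-height curve locates the dominant feature scale.
#'
#' @param track a signal [binned_track()] or named list of them.
#' @param region [region_set()] of (early) domains to scan.
#' @param widths wavelet peak widths in bp; defaults to [scan_width_grid()].
#' @param late_region optional [region_set()] whose peaks calibrate the
#'   cutoff at \code{cutoff_percentile}.
#' @param cutoff_percentile percentile (0-100) for the optional cutoff;
#'   \code{NULL} disables it.
#' @param scale_norm passed to [ricker_kernel()].
#' @return a \code{width_scan} data.frame with columns \code{width},
#'   \code{n_peaks}, \code{metric_sum}, \code{metric_mean},
#'   \code{with_cutoff}.
#' @export
width_scan <- function(track, region, widths = scan_width_grid(),
                       late_region = NULL, cutoff_percentile = NULL,
                       scale_norm = "area") {
  if (inherits(track, "binned_track")) track <- list(track)
  if (nrow(region) == 0) stop("empty region set")
  rows <- lapply(widths, function(w) {
    conv <- lapply(track, function(t)
      convolve_track(t, ricker_kernel(w, t$bin_size, scale_norm)))
    peaks <- call_peaks(conv, region)
    if (!is.null(cutoff_percentile) && !is.null(late_region)) {
      late_peaks <- call_peaks(conv, late_region)
      if (nrow(late_peaks) >= 10) {
        cut <- calibrate_cutoff(late_peaks, cutoff_percentile)
        peaks <- peaks[peaks$wavelet_height > cut$threshold_value, ,
                       drop = FALSE]
      }
    }
    data.frame(width = w, n_peaks = nrow(peaks),
               metric_sum = sum(peaks$wavelet_height),
               metric_mean = if (nrow(peaks)) mean(peaks$wavelet_height)
                             else 0,
               with_cutoff = !is.null(cutoff_percentile))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("width_scan", "data.frame")
  out
}

#' Width at which a scan's mean peak height is maximal
#' @param scan a [width_scan()] result.
#' @param metric \code{"mean"} or \code{"sum"}.
#' @return the optimal width in bp.
#' @export
scan_optimum <- function(scan, metric = c("mean", "sum")) {
  metric <- match.arg(metric)
  col <- if (metric == "mean") scan$metric_mean else scan$metric_sum
  scan$width[which.max(col)]
}
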