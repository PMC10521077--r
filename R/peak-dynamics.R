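#' Select isolated Replicon Cluster Domains
#'
#' A domain is isolated when the replication signal in the 500 kb on either
#' side of its wavelet peak is no more than 25\% of the signal under the
#' peak. By default the two flanks are combined before the comparison; with
#' \code{per_side = TRUE} each flank must satisfy the ratio on its own.
#' Sums run over unmasked bins with negative S values included as-is.
#' Peaks whose extent plus flanks cross a chromosome end are excluded, with
#' the reason recorded in the \code{excluded} attribute.
#'
#' @param rcds data.frame from [filter_rcds()] (first timepoint).
#' @param S signal track(s) of the same timepoint.
#' @param flank flank width in bp on each side of the peak extent.
#' @param max_ratio maximum flanking/under signal ratio to accept.
#' @param per_side apply the ratio per flank instead of combined.
#' @return the accepted rows with extra columns \code{under_peak_signal},
#'   \code{flanking_signal}, \code{isolation_ratio}; excluded peaks (with
#'   reasons) in \code{attr(, "excluded")}.
#' @export
select_isolated <- function(rcds, S, flank = 500e3, max_ratio = 0.25,
                            per_side = FALSE) {
  if (inherits(S, "binned_track")) S <- stats::setNames(list(S), S$chrom)
  res <- lapply(seq_len(nrow(rcds)), function(i) {
    tr <- S[[rcds$chrom[i]]]
    es <- rcds$extent_start[i]; ee <- rcds$extent_end[i]
    if (es - flank < 0 || ee + flank > tr$chrom_length)
      return(list(keep = FALSE, reason = "crosses chromosome end"))
    under <- sum_signal_in(tr, es, ee)
    left <- sum_signal_in(tr, es - flank, es)
    right <- sum_signal_in(tr, ee, ee + flank)
    ok <- if (per_side)
      left <= max_ratio * under && right <= max_ratio * under
    else (left + right) <= max_ratio * under
    list(keep = isTRUE(ok), under = under, flankv = left + right,
         reason = if (isTRUE(ok)) NA_character_ else "not isolated")
  })
  keep <- vapply(res, function(r) r$keep, logical(1))
  out <- rcds[keep, , drop = FALSE]
  if (nrow(out)) {
    out$under_peak_signal <- vapply(res[keep], function(r) r$under, 0)
    out$flanking_signal <- vapply(res[keep], function(r) r$flankv, 0)
    out$isolation_ratio <- out$flanking_signal / out$under_peak_signal
  }
  rownames(out) <- NULL
  excl <- data.frame(rcd_id = rcds$rcd_id[!keep],
                     reason = vapply(res[!keep], function(r) r$reason, ""),
                     stringsAsFactors = FALSE)
  attr(out, "excluded") <- excl
  out
}

sum_signal_in <- function(track, from, to) {
  mid <- track_midpoints(track)
  sum(track$values[mid >= from & mid < to], na.rm = TRUE)
}

#' Fine wavelet width grid for isolated-peak fitting
#' @return widths 200 kb to 1200 kb in 25-kb steps.
#' @export
fine_width_grid <- function() seq(200e3, 1200e3, by = 25e3)

#' Optimal wavelet width of one peak across timepoints
#'
#' For each timepoint the peak neighbourhood of the signal track is convolved
#' with every width of the grid and the width maximising the response within
#' \eqn{\pm W/2} of the peak position is recorded. A series whose optimum
#' hits either end of the grid at any timepoint is flagged rejected: such
#' fits have run off the resolvable range.
#'
#' @param peak one row of an RCD data.frame (needs \code{chrom},
#'   \code{position}).
#' @param S_by_tp list over timepoints; each element a signal
#'   [binned_track()] or named list of them (10-kb bins in the reference
#'   analysis).
#' @param grid wavelet widths in bp, default [fine_width_grid()].
#' @param scale_norm passed to [ricker_kernel()].
#' @return list with \code{widths} (bp per timepoint), \code{rejected},
#'   \code{reason}.
#' @export
fit_optimal_wavelet <- function(peak, S_by_tp, grid = fine_width_grid(),
                                scale_norm = "area") {
  widths <- vapply(S_by_tp, function(S) {
    tr <- if (inherits(S, "binned_track")) S else S[[peak$chrom]]
    resp <- vapply(grid, function(W)
      local_peak_response(tr, peak$position, W, scale_norm), 0)
    grid[which.max(resp)]
  }, 0)
  at_edge <- widths <= min(grid) | widths >= max(grid)
  list(widths = widths, rejected = any(at_edge),
       reason = if (any(at_edge))
         sprintf("optimum at grid extreme (timepoint %s)",
                 paste(which(at_edge), collapse = ",")) else NA_character_)
}

## max convolved response over output bins within +/- W/2 of `position`,
## computed on a local slice of the track (zero beyond chromosome ends)
local_peak_response <- function(track, position, W, scale_norm = "area") {
  bin <- track$bin_size
  k <- ricker_kernel(W, bin, scale_norm)
  half <- (length(k$taps) - 1L) / 2L
  cbin <- floor(position / bin) + 1L
  rad <- ceiling((W / 2) / bin)
  lo <- cbin - rad - half
  hi <- cbin + rad + half
  idx <- lo:hi
  v <- numeric(length(idx))
  inside <- idx >= 1L & idx <= length(track$values)
  vals <- track$values[idx[inside]]
  vals[is.na(vals)] <- 0
  v[inside] <- vals
  conv <- as.numeric(stats::filter(v, k$taps, method = "convolution",
                                   sides = 2))
  core <- conv[(half + 1L):(length(conv) - half)]
  max(core, na.rm = TRUE)
}

#' Gaussian fit of one peak by Nelder-Mead least squares
#'
#' Fits \eqn{A \exp(-(x - c)^2 / 2\sigma^2) + B} to the signal in a window
#' (the peak extent padded by \code{pad} on both sides) by Nelder-Mead on a
#' standardised parameterisation. Initial values: centre at the peak
#' position, \eqn{\sigma = W/4}, amplitude the window maximum, baseline 0.
#' On non-convergence the fit restarts once from a perturbed init.
#'
#' @param peak one row of an RCD data.frame.
#' @param S a signal [binned_track()] or named list of them.
#' @param pad window padding beyond the peak extent, bp.
#' @param maxit maximum Nelder-Mead iterations.
#' @param reltol relative convergence tolerance of the simplex.
#' @return a \code{gaussian_fit}: \code{amplitude}, \code{centre},
#'   \code{sigma}, \code{baseline}, \code{fwhm} (= 2 sqrt(2 ln 2) sigma),
#'   \code{converged}, \code{sse}.
#' @export
fit_gaussian <- function(peak, S, pad = 500e3, maxit = 2000,
                         reltol = 1e-10) {
  w <- peak_window(peak, S, pad)
  model <- function(q, x) q[1] * exp(-(x - q[2])^2 / (2 * q[3]^2)) + q[4]
  fit <- nm_fit(w, init = c(a = 1, c = 0, s = 0.25, b = 0), model,
                maxit = maxit, reltol = reltol)
  q <- unname(fit$par)
  sigma <- abs(q[3]) * w$scale_x
  structure(list(amplitude = q[1] * w$scale_y,
                 centre = q[2] * w$scale_x + w$x0,
                 sigma = sigma, baseline = q[4] * w$scale_y,
                 fwhm = 2 * sqrt(2 * log(2)) * sigma,
                 converged = fit$converged,
                 sse = fit$value * w$scale_y^2),
            class = "gaussian_fit")
}

#' Flat-topped Gaussian fit of one peak
#'
#' As [fit_gaussian()] with an additional plateau half-width h:
#' \eqn{A \exp(-\max(|x - c| - h, 0)^2 / 2\sigma^2) + B}. With h = 0 the
#' model reduces to the plain Gaussian; the total width at half maximum is
#' \code{2 h + fwhm}. A diagnostic of peak shape, not on the main growth
#' path.
#'
#' @inheritParams fit_gaussian
#' @param fix_plateau_zero constrain h = 0 (then the result must match
#'   [fit_gaussian()]).
#' @return a \code{flat_gaussian_fit} with the [fit_gaussian()] fields plus
#'   \code{plateau_halfwidth} and \code{total_width_half_max}.
#' @export
fit_flat_topped_gaussian <- function(peak, S, pad = 500e3, maxit = 2000,
                                     reltol = 1e-10,
                                     fix_plateau_zero = FALSE) {
  w <- peak_window(peak, S, pad)
  model <- function(q, x) {
    h <- if (fix_plateau_zero) 0 else abs(q[5])
    d <- pmax(abs(x - q[2]) - h, 0)
    q[1] * exp(-d^2 / (2 * q[3]^2)) + q[4]
  }
  fit <- nm_fit(w, init = c(a = 1, c = 0, s = 0.2, b = 0, h = 0.1), model,
                maxit = maxit, reltol = reltol)
  q <- unname(fit$par)
  sigma <- abs(q[3]) * w$scale_x
  h <- if (fix_plateau_zero) 0 else abs(q[5]) * w$scale_x
  fwhm <- 2 * sqrt(2 * log(2)) * sigma
  structure(list(amplitude = q[1] * w$scale_y,
                 centre = q[2] * w$scale_x + w$x0,
                 sigma = sigma, baseline = q[4] * w$scale_y, fwhm = fwhm,
                 plateau_halfwidth = h,
                 total_width_half_max = 2 * h + fwhm,
                 converged = fit$converged,
                 sse = fit$value * w$scale_y^2),
            class = "flat_gaussian_fit")
}

## extract the fit window and standardisation constants
peak_window <- function(peak, S, pad) {
  if (!inherits(S, "binned_track")) S <- S[[peak$chrom]]
  from <- peak$extent_start - pad
  to <- peak$extent_end + pad
  if (from < 0 || to > S$chrom_length)
    stop("fit window crosses a chromosome end for ", peak$chrom, ":",
         peak$position)
  mid <- track_midpoints(S)
  sel <- mid >= from & mid < to & !is.na(S$values)
  x <- mid[sel]; y <- S$values[sel]
  if (length(x) < 6) stop("too few unmasked bins in the fit window")
  W <- peak$extent_end - peak$extent_start
  scale_y <- max(abs(y))
  if (scale_y == 0) scale_y <- 1
  list(x = x, y = y, x0 = peak$position, scale_x = W,
       scale_y = scale_y)
}

## standardised Nelder-Mead least squares with one perturbed restart
nm_fit <- function(w, init, model, maxit, reltol) {
  xs <- (w$x - w$x0) / w$scale_x
  ys <- w$y / w$scale_y
  a0 <- max(ys)
  init["a"] <- if (a0 > 0) a0 else 1
  obj <- function(q) sum((model(q, xs) - ys)^2)
  run <- function(par) stats::optim(par, obj, method = "Nelder-Mead",
                                    control = list(maxit = maxit,
                                                   reltol = reltol))
  fit <- run(init)
  if (fit$convergence != 0) {
    fit2 <- run(init * stats::runif(length(init), 0.8, 1.2) +
                  c(0, 0.05, 0.05, 0.01, 0.05)[seq_along(init)])
    if (fit2$convergence == 0 || fit2$value < fit$value) fit <- fit2
  }
  list(par = fit$par, value = fit$value, converged = fit$convergence == 0)
}

#' Per-timepoint widths for a cohort of isolated peaks
#'
#' Runs [fit_optimal_wavelet()] or [fit_gaussian()] for every peak and every
#' timepoint and applies the shared rejection rule: a peak is rejected when
#' its fitted width reaches either extreme of \code{[200, 1200]} kb (the
#' wavelet grid ends; for Gaussian fits the FWHM is tested against the same
#' extremes) at any timepoint, or when a Gaussian fit fails to converge.
#'
#' @param rcds data.frame of (isolated) peaks.
#' @param S_by_tp list over timepoints of signal track lists.
#' @param method \code{"wavelet"} or \code{"gaussian"}.
#' @param grid wavelet width grid; its range also bounds Gaussian widths.
#' @param pad Gaussian window padding, bp.
#' @return a \code{width_series} data.frame: one row per peak,
#'   \code{width_t1..width_tT} in bp, \code{rejected}, \code{reason}.
#' @export
peak_width_series <- function(rcds, S_by_tp,
                              method = c("wavelet", "gaussian"),
                              grid = fine_width_grid(), pad = 500e3) {
  method <- match.arg(method)
  nt <- length(S_by_tp)
  rows <- lapply(seq_len(nrow(rcds)), function(i) {
    peak <- rcds[i, , drop = FALSE]
    if (method == "wavelet") {
      f <- fit_optimal_wavelet(peak, S_by_tp, grid)
      widths <- f$widths; rejected <- f$rejected; reason <- f$reason
    } else {
      fits <- lapply(S_by_tp, function(S) fit_gaussian(peak, S, pad = pad))
      widths <- vapply(fits, function(g) g$fwhm, 0)
      bad_conv <- !vapply(fits, function(g) g$converged, logical(1))
      at_edge <- widths <= min(grid) | widths >= max(grid)
      rejected <- any(at_edge) | any(bad_conv)
      reason <- if (any(bad_conv)) "non-convergence"
        else if (any(at_edge)) "width at extreme value" else NA_character_
    }
    out <- as.data.frame(as.list(stats::setNames(widths,
                                                 paste0("width_t",
                                                        seq_len(nt)))))
    out$rcd_id <- peak$rcd_id
    out$rejected <- rejected
    out$reason <- reason
    out
  })
  out <- do.call(rbind, rows)
  class(out) <- c("width_series", "data.frame")
  out
}

#' Width-growth statistics across successive timepoints
#'
#' Per successive-interval width deltas over the accepted peaks, with mean,
#' standard error, 95\% confidence interval and a two-sided one-sample
#' t-test against zero, plus the growth rate in kb/min (mean delta divided
#' by the inter-pulse interval).
#'
#' @param series a [peak_width_series()] result (rejected rows are dropped).
#' @param interval_min minutes between successive pulse starts.
#' @return a \code{growth_stats} list: \code{per_interval} data.frame
#'   (\code{interval, n, mean_delta, se, ci_lo, ci_hi, t, df, p,
#'   rate_kb_min}) and \code{deltas} (matrix of accepted per-peak deltas,
#'   bp).
#' @export
growth_stats <- function(series, interval_min = 30) {
  acc <- series[!series$rejected, , drop = FALSE]
  if (nrow(acc) < 2) stop("need at least 2 accepted peaks")
  wcols <- grep("^width_t", names(acc), value = TRUE)
  wm <- as.matrix(acc[, wcols])
  deltas <- wm[, -1, drop = FALSE] - wm[, -ncol(wm), drop = FALSE]
  per <- lapply(seq_len(ncol(deltas)), function(k) {
    tt <- one_sample_t(deltas[, k])
    data.frame(interval = sprintf("t%d-t%d", k, k + 1), n = tt$n,
               mean_delta = tt$mean, se = tt$se, ci_lo = tt$ci[1],
               ci_hi = tt$ci[2], t = tt$t, df = tt$df, p = tt$p,
               rate_kb_min = tt$mean / 1000 / interval_min,
               stringsAsFactors = FALSE)
  })
  structure(list(per_interval = do.call(rbind, per), deltas = deltas,
                 interval_min = interval_min),
            class = "growth_stats")
}

#' @export
print.growth_stats <- function(x, ...) {
  cat("<growth_stats> per-interval width change (bp) and rate (kb/min):\n")
  print(x$per_interval, row.names = FALSE)
  invisible(x)
}
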