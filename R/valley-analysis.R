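#' Fork-travel trim constant
#'
#' Valleys are trimmed on each side by the distance a fork travels over the
#' full time course: \code{fork_rate} kb/min over \code{minutes} min
#' (default 1.5 kb/min over 120 min = 180 kb).
#'
#' @param fork_rate fork speed in kb/min.
#' @param minutes elapsed minutes.
#' @return trim in bp.
#' @export
fork_travel_trim <- function(fork_rate = 1.5, minutes = 120) {
  fork_rate * 1000 * minutes
}

#' Define inter-peak valleys within early timing domains
#'
#' One valley per adjacent pair of wavelet peaks (called without any height
#' cutoff) lying in the same early timing domain: the gap between the two
#' peak extents, trimmed by \code{trim} on each side to discount fork
#' movement; pairs whose trimmed gap is empty are dropped.
#'
#' @param peaks_t1 data.frame from [call_peaks()] at the first timepoint.
#' @param domains a [timing_domains()] object.
#' @param trim bp removed from each internal edge; default
#'   [fork_travel_trim()].
#' @return data.frame of valleys: \code{chrom}, \code{start}, \code{end},
#'   \code{left_peak_pos}, \code{right_peak_pos}, \code{timing_domain_id},
#'   \code{valley_id}.
#' @export
define_valleys <- function(peaks_t1, domains, trim = fork_travel_trim()) {
  if (!nrow(peaks_t1)) return(empty_valleys())
  peaks_t1$timing_domain_id <- domain_at(domains, peaks_t1$chrom,
                                         peaks_t1$position)
  early_ids <- domains$domain_id[domains$label == "early"]
  p <- peaks_t1[peaks_t1$timing_domain_id %in% early_ids, , drop = FALSE]
  rows <- lapply(split(p, p$timing_domain_id), function(d) {
    if (nrow(d) < 2) return(NULL)
    d <- d[order(d$position), , drop = FALSE]
    i <- seq_len(nrow(d) - 1)
    v <- data.frame(chrom = d$chrom[i],
                    start = d$extent_end[i] + trim,
                    end = d$extent_start[i + 1] - trim,
                    left_peak_pos = d$position[i],
                    right_peak_pos = d$position[i + 1],
                    timing_domain_id = d$timing_domain_id[i],
                    stringsAsFactors = FALSE)
    v[v$start < v$end, , drop = FALSE]
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || !nrow(out)) return(empty_valleys())
  rownames(out) <- NULL
  out$valley_id <- sprintf("V_%s_%d", out$chrom, seq_len(nrow(out)))
  out
}

empty_valleys <- function() {
  data.frame(chrom = character(), start = numeric(), end = numeric(),
             left_peak_pos = numeric(), right_peak_pos = numeric(),
             timing_domain_id = character(), valley_id = character(),
             stringsAsFactors = FALSE)
}

#' Track valleys across later timepoints by flank persistence
#'
#' A valley is tracked when each of its two flanking peaks has a
#' nearest-position match within \code{tolerance} in every later timepoint's
#' peak list; ties between equidistant candidates break toward the higher
#' wavelet peak.
#'
#' @param valleys data.frame from [define_valleys()].
#' @param peaks_later list of peak data.frames for timepoints 2..T.
#' @param tolerance maximum flank position shift in bp.
#' @return the tracked subset of \code{valleys}, with a \code{tracked}
#'   column set TRUE.
#' @export
track_valleys <- function(valleys, peaks_later, tolerance = 100e3) {
  if (!nrow(valleys)) { valleys$tracked <- logical(); return(valleys) }
  ok <- rep(TRUE, nrow(valleys))
  for (pk in peaks_later) {
    for (side in c("left_peak_pos", "right_peak_pos")) {
      ok <- ok & vapply(seq_len(nrow(valleys)), function(i) {
        cand <- pk[pk$chrom == valleys$chrom[i], , drop = FALSE]
        if (!nrow(cand)) return(FALSE)
        d <- abs(cand$position - valleys[[side]][i])
        best <- which(d == min(d))
        if (length(best) > 1)
          best <- best[which.max(cand$wavelet_height[best])]
        d[best] <= tolerance
      }, logical(1))
    }
  }
  out <- valleys[ok, , drop = FALSE]
  out$tracked <- rep(TRUE, nrow(out))
  rownames(out) <- NULL
  out
}

#' Valley signal as a percentage of the flanking peak heights
#'
#' The mean and minimum S over the valley's unmasked bins, each expressed as
#' a percentage of the mean of the two flanking replication peak heights
#' (the max S within each flanking peak extent). Both percentages are
#' invariant to a global rescaling of S.
#'
#' @param valley one row of a [define_valleys()] data.frame.
#' @param S signal track(s) of one timepoint.
#' @param flanking_heights numeric length-2: replication peak heights of the
#'   left and right flanking peak at the same timepoint.
#' @return list \code{(mean_pct, min_pct)}; \code{NULL} (with a warning)
#'   when the mean flanking height is not positive.
#' @export
valley_signal <- function(valley, S, flanking_heights) {
  tr <- if (inherits(S, "binned_track")) S else S[[valley$chrom]]
  fh <- mean(flanking_heights)
  if (!is.finite(fh) || fh <= 0) {
    warning("valley ", valley$valley_id,
            " excluded: non-positive mean flanking height")
    return(NULL)
  }
  mid <- track_midpoints(tr)
  v <- tr$values[mid >= valley$start & mid < valley$end]
  v <- v[!is.na(v)]
  if (!length(v)) return(NULL)
  list(mean_pct = mean(v) / fh * 100, min_pct = min(v) / fh * 100)
}

#' Valley timecourses over all timepoints
#'
#' For every tracked valley, computes [valley_signal()] at each timepoint.
#' Flanking peak heights are taken per timepoint from the replication signal:
#' the max S within each flank's extent around its (timepoint-1) position.
#'
#' @param valleys tracked valleys from [track_valleys()].
#' @param S_by_tp list over timepoints of signal track lists.
#' @param peak_width W used to form flank extents around flank positions.
#' @return data.frame: one row per valley with \code{mean_pct_t*} and
#'   \code{min_pct_t*} columns.
#' @export
valley_timecourses <- function(valleys, S_by_tp, peak_width = 500e3) {
  nt <- length(S_by_tp)
  rows <- lapply(seq_len(nrow(valleys)), function(i) {
    v <- valleys[i, , drop = FALSE]
    vals <- lapply(seq_len(nt), function(k) {
      S <- S_by_tp[[k]]
      tr <- if (inherits(S, "binned_track")) S else S[[v$chrom]]
      fh <- c(max_signal_in(tr, v$left_peak_pos - peak_width / 2,
                            v$left_peak_pos + peak_width / 2),
              max_signal_in(tr, v$right_peak_pos - peak_width / 2,
                            v$right_peak_pos + peak_width / 2))
      valley_signal(v, tr, fh)
    })
    if (any(vapply(vals, is.null, logical(1)))) return(NULL)
    row <- data.frame(valley_id = v$valley_id, stringsAsFactors = FALSE)
    for (k in seq_len(nt)) {
      row[[paste0("mean_pct_t", k)]] <- vals[[k]]$mean_pct
      row[[paste0("min_pct_t", k)]] <- vals[[k]]$min_pct
    }
    row
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(valley_id = character())
  rownames(out) <- NULL
  out
}

#' Valley-filling statistics
#'
#' Per-timepoint distributions of the mean and minimum valley percentages,
#' per-valley filling rates in \%/min (least-squares slope of the
#' percentage against the pulse midpoint time by default, or simple
#' successive differences), a one-sample t-test of the rates against zero
#' with 95\% CI, and the count of valleys whose final minimum exceeds 10\%
#' of the flanking peak height.
#'
#' @param timecourses data.frame from [valley_timecourses()].
#' @param pulse_mid_times pulse midpoint times in minutes (defaults to the
#'   30-min pulse series 10-40, 40-70, 70-100, 100-130, truncated to the
#'   number of timepoints present).
#' @param rate_mode \code{"slope"} (regression) or \code{"diff"}
#'   (successive differences over 30-min intervals).
#' @return a \code{filling_stats} list: \code{per_timepoint},
#'   \code{rates_mean}, \code{rates_min} (per-valley \%/min),
#'   \code{t_mean}, \code{t_min} (one-sample t results),
#'   \code{n_final_min_above_10}, \code{n_valleys}.
#' @export
filling_stats <- function(timecourses,
                          pulse_mid_times = c(25, 55, 85, 115),
                          rate_mode = c("slope", "diff")) {
  rate_mode <- match.arg(rate_mode)
  n <- nrow(timecourses)
  if (n < 2) stop("need at least 2 tracked valleys")
  mcols <- grep("^mean_pct_t", names(timecourses), value = TRUE)
  ncols <- grep("^min_pct_t", names(timecourses), value = TRUE)
  nt <- length(mcols)
  times <- pulse_mid_times[seq_len(nt)]
  mm <- as.matrix(timecourses[, mcols])
  nn <- as.matrix(timecourses[, ncols])
  rate_of <- function(y) {
    if (rate_mode == "slope") {
      sum((times - mean(times)) * (y - mean(y))) /
        sum((times - mean(times))^2)
    } else mean(diff(y) / diff(times))
  }
  rates_mean <- apply(mm, 1, rate_of)
  rates_min <- apply(nn, 1, rate_of)
  per_tp <- data.frame(timepoint = seq_len(nt), time_min = times,
                       mean_pct = colMeans(mm), se_mean =
                         apply(mm, 2, stats::sd) / sqrt(n),
                       min_pct = colMeans(nn), se_min =
                         apply(nn, 2, stats::sd) / sqrt(n))
  structure(list(per_timepoint = per_tp,
                 rates_mean = rates_mean, rates_min = rates_min,
                 t_mean = one_sample_t(rates_mean),
                 t_min = one_sample_t(rates_min),
                 n_final_min_above_10 = sum(nn[, nt] > 10),
                 n_valleys = n),
            class = "filling_stats")
}

#' @export
print.filling_stats <- function(x, ...) {
  cat("<filling_stats>", x$n_valleys, "valleys;",
      x$n_final_min_above_10, "with final min > 10% of flanks\n")
  cat(sprintf("  mean-signal filling rate %.4f %%/min (p = %.3g)\n",
              x$t_mean$mean, x$t_mean$p))
  cat(sprintf("  min-signal  filling rate %.4f %%/min (p = %.3g)\n",
              x$t_min$mean, x$t_min$p))
  invisible(x)
}
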