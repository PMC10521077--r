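#' Call positive local maxima of a convolved track
#'
#' A peak is a bin whose value is positive and strictly greater than both
#' neighbours; a plateau of equal values flanked by lower neighbours yields a
#' single peak at its centre bin (leftmost of the two central bins when the
#' plateau length is even). When \code{region} is given, only peaks whose bin
#' centre lies inside it are kept. Masked bins break the track into segments
#' that are scanned independently.
#'
#' @param convolved convolved track(s) from [convolve_track()] at a single
#'   width.
#' @param region optional [region_set()] restricting peak centres.
#' @return data.frame of wavelet peaks: \code{chrom}, \code{bin},
#'   \code{position} (bin centre, bp), \code{wavelet_height},
#'   \code{width_W}, \code{extent_start}, \code{extent_end} (position
#'   \eqn{\pm} W/2).
#' @export
call_peaks <- function(convolved, region = NULL) {
  if (inherits(convolved, "binned_track")) convolved <- list(convolved)
  rows <- lapply(convolved, function(t) {
    idx <- find_local_maxima(t$values)
    W <- if (!is.null(t$peak_width)) t$peak_width else NA_real_
    pos <- (idx - 0.5) * t$bin_size
    data.frame(chrom = rep(t$chrom, length(idx)), bin = idx, position = pos,
               wavelet_height = t$values[idx],
               width_W = rep(W, length(idx)),
               extent_start = pos - W / 2, extent_end = pos + W / 2,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(region) && nrow(out)) {
    keep <- vapply(seq_len(nrow(out)), function(i) {
      r <- region[region$chrom == out$chrom[i], , drop = FALSE]
      any(out$position[i] >= r$start & out$position[i] < r$end)
    }, logical(1))
    out <- out[keep, , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

## indices of strict positive local maxima, plateaus resolved to their
## centre bin; NA bins act as segment breaks
find_local_maxima <- function(v) {
  n <- length(v)
  if (n == 0) return(integer())
  out <- integer()
  seg_start <- 1L
  na <- is.na(v)
  breaks <- c(which(na), n + 1L)
  for (b in breaks) {
    if (b > seg_start) {
      seg <- v[seg_start:(b - 1L)]
      out <- c(out, seg_start - 1L + plateau_maxima(seg))
    }
    seg_start <- b + 1L
  }
  out
}

plateau_maxima <- function(seg) {
  r <- rle(seg)
  k <- length(r$values)
  if (k == 0) return(integer())
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  left <- c(-Inf, r$values[-k])
  right <- c(r$values[-1], -Inf)
  is_peak <- r$values > 0 & r$values > left & r$values > right
  # centre of the run; leftmost of the two central bins for even lengths
  centre <- starts + (r$lengths - 1L) %/% 2L
  centre[is_peak]
}

#' Calibrate the peak-height cutoff from late-domain peaks
#'
#' The threshold is the nearest-rank percentile (the
#' \code{ceiling(p/100 * n)}-th order statistic) of the late-domain wavelet
#' peak heights, so applying it with a strict \code{>} keeps exactly
#' \code{n - ceiling(p/100 * n)} of the late peaks themselves (for p = 70 and
#' n divisible by 10, exactly 70\% of them are removed).
#'
#' @param late_peaks data.frame of wavelet peaks from late timing domains
#'   (needs \code{>= 10} rows).
#' @param percentile percentile in (0, 100]; 0 gives the minimum height
#'   minus nothing, i.e. no peak is removed.
#' @return a \code{cutoff_calibration}: list with \code{percentile},
#'   \code{threshold_value}, \code{n_late_peaks}.
#' @export
calibrate_cutoff <- function(late_peaks, percentile = 70) {
  n <- nrow(late_peaks)
  if (n < 10)
    stop("only ", n, " late-domain peaks; need >= 10. Consider a fallback ",
         "percentile computed over all peaks instead.")
  h <- sort(late_peaks$wavelet_height)
  thr <- if (percentile <= 0) -Inf else h[ceiling(percentile / 100 * n)]
  structure(list(percentile = percentile, threshold_value = thr,
                 n_late_peaks = n), class = "cutoff_calibration")
}

#' Filter early-domain peaks into Replicon Cluster Domains
#'
#' Keeps peaks with \code{wavelet_height > threshold}, annotates the timing
#' domain containing the peak position, and records the replication peak
#' height: the maximum background-subtracted signal S over the unmasked bins
#' of the peak extent (position \eqn{\pm} W/2).
#'
#' @param early_peaks data.frame from [call_peaks()] on early domains.
#' @param cutoff a [calibrate_cutoff()] result (or \code{NULL} for no
#'   cutoff).
#' @param S signal track(s) on the same genome (any bin size; 50-kb bins in
#'   the reference analysis).
#' @param domains a [timing_domains()] object.
#' @param timepoint identifier stored in the \code{timepoint} column.
#' @return data.frame of RCDs: peak columns plus \code{timing_domain_id},
#'   \code{replication_peak_height}, \code{timepoint}, \code{rcd_id}.
#' @export
filter_rcds <- function(early_peaks, cutoff, S, domains, timepoint = 1L) {
  if (inherits(S, "binned_track")) S <- stats::setNames(list(S), S$chrom)
  thr <- if (is.null(cutoff)) -Inf else cutoff$threshold_value
  out <- early_peaks[early_peaks$wavelet_height > thr, , drop = FALSE]
  if (nrow(out)) {
    out$timing_domain_id <- domain_at(domains, out$chrom, out$position)
    out$replication_peak_height <- vapply(seq_len(nrow(out)), function(i) {
      max_signal_in(S[[out$chrom[i]]], out$extent_start[i],
                    out$extent_end[i])
    }, 0)
    out$timepoint <- timepoint
    out$rcd_id <- sprintf("RCD_t%s_%s_%d", timepoint, out$chrom,
                          seq_len(nrow(out)))
  }
  rownames(out) <- NULL
  out
}

## max S over unmasked bins whose midpoint lies in [from, to)
max_signal_in <- function(track, from, to) {
  if (is.null(track)) return(NA_real_)
  mid <- track_midpoints(track)
  v <- track$values[mid >= from & mid < to]
  v <- v[!is.na(v)]
  if (!length(v)) NA_real_ else max(v)
}

#' Summary statistics of a set of RCDs
#'
#' Adjacent peak-to-peak separations within each timing domain, and the
#' per-domain RCD count against the domain size.
#'
#' @param rcds data.frame from [filter_rcds()].
#' @param domains a [timing_domains()] object.
#' @return list with \code{separations} (bp), \code{mean_separation},
#'   \code{sd_separation}, and \code{per_domain} (data.frame of
#'   \code{domain_id}, \code{domain_size}, \code{n_rcds}).
#' @export
rcd_stats <- function(rcds, domains) {
  seps <- unlist(lapply(split(rcds, rcds$timing_domain_id), function(d) {
    if (nrow(d) < 2) return(numeric())
    diff(sort(d$position))
  }), use.names = FALSE)
  counts <- table(factor(rcds$timing_domain_id,
                         levels = domains$domain_id))
  per_domain <- data.frame(domain_id = domains$domain_id,
                           domain_size = domains$end - domains$start,
                           n_rcds = as.integer(counts),
                           stringsAsFactors = FALSE)
  list(separations = seps,
       mean_separation = if (length(seps)) mean(seps) else NA_real_,
       sd_separation = if (length(seps) > 1) stats::sd(seps) else NA_real_,
       per_domain = per_domain)
}

#' Write an RCD table as BED6+ text
#'
#' Columns: chrom, extent start/end, id, wavelet height, strand ".", then
#' position, replication peak height, domain id and timepoint.
#'
#' @param rcds data.frame from [filter_rcds()].
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_rcd_bed <- function(rcds, path) {
  df <- data.frame(chrom = rcds$chrom,
                   start = format(rcds$extent_start, scientific = FALSE,
                                  trim = TRUE),
                   end = format(rcds$extent_end, scientific = FALSE,
                                trim = TRUE),
                   name = rcds$rcd_id, score = rcds$wavelet_height,
                   strand = ".",
                   position = format(rcds$position, scientific = FALSE,
                                     trim = TRUE),
                   replication_peak_height = rcds$replication_peak_height,
                   domain_id = rcds$timing_domain_id,
                   timepoint = rcds$timepoint)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
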