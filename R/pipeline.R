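#' Run the full RCD pipeline on a pulse time course
#'
#' Orchestrates the stages in order: per-timepoint background normalisation,
#' 500-kb wavelet convolution, late-domain cutoff calibration and RCD
#' calling, isolated-peak width dynamics, valley tracking/filling and the
#' domino ordering statistics. Any stage can be skipped; skipped stages are
#' recorded as such in the returned log. Rerunning with the same inputs and
#' seed reproduces identical tables.
#'
#' @param P_raw,C_raw lists over timepoints of named raw-count track lists
#'   (pull-down and control).
#' @param domains a [timing_domains()] object.
#' @param peak_width wavelet peak width for detection, bp.
#' @param cutoff_percentile late-domain percentile for RCD calling; NULL
#'   disables the cutoff.
#' @param stages character subset of
#'   \code{c("normalize", "rcd", "dynamics", "valleys", "domino")};
#'   normalisation and RCD calling are prerequisites of the rest.
#' @param dynamics_method \code{"gaussian"} or \code{"wavelet"} width
#'   fitting.
#' @param S_dynamics optional list over timepoints of finer-binned signal
#'   tracks for the dynamics stage (defaults to the main S tracks).
#' @param max_gap domino grouping distance, bp.
#' @param interval_min minutes between pulse starts.
#' @return a \code{pipeline_run} list: \code{norm_reports}, \code{S_by_tp},
#'   \code{conv_by_tp}, \code{cutoffs}, \code{rcds_by_tp},
#'   \code{peaks_by_tp}, \code{isolated}, \code{width_series},
#'   \code{growth}, \code{valleys}, \code{valley_timecourses},
#'   \code{filling}, \code{groups_by_tp}, \code{similarity}, \code{log}.
#' @export
run_pipeline <- function(P_raw, C_raw, domains, peak_width = 500e3,
                         cutoff_percentile = 70,
                         stages = c("normalize", "rcd", "dynamics",
                                    "valleys", "domino"),
                         dynamics_method = "gaussian",
                         S_dynamics = NULL, max_gap = 1.6e6,
                         interval_min = 30) {
  stopifnot(length(P_raw) == length(C_raw))
  nt <- length(P_raw)
  run <- list(log = character())
  note <- function(run, msg) { run$log <- c(run$log, msg); run }
  early <- domain_regions(domains, "early")
  late <- domain_regions(domains, "late")

  if (!"normalize" %in% stages) stop("the normalize stage is required")
  norm <- lapply(seq_len(nt), function(k)
    background_normalize(P_raw[[k]], C_raw[[k]]))
  run$S_by_tp <- lapply(norm, `[[`, "S")
  run$norm_reports <- do.call(rbind, lapply(seq_len(nt), function(k)
    normalization_report(norm[[k]]$fit, label = paste0("t", k))))
  run <- note(run, sprintf("normalize: %d timepoints, chosen r = %s",
                           nt, paste(round(run$norm_reports$chosen_r, 4),
                                     collapse = ", ")))

  if (!"rcd" %in% stages) {
    run$log <- c(run$log, "rcd: skipped")
    class(run) <- "pipeline_run"
    return(run)
  }
  run$conv_by_tp <- lapply(run$S_by_tp, function(S)
    lapply(S, function(t)
      convolve_track(t, ricker_kernel(peak_width, t$bin_size))))
  run$peaks_by_tp <- lapply(run$conv_by_tp, call_peaks)
  run$cutoffs <- lapply(seq_len(nt), function(k) {
    if (is.null(cutoff_percentile)) return(NULL)
    late_peaks <- call_peaks(run$conv_by_tp[[k]], late)
    if (nrow(late_peaks) < 10) return(NULL)
    calibrate_cutoff(late_peaks, cutoff_percentile)
  })
  run$rcds_by_tp <- lapply(seq_len(nt), function(k) {
    early_peaks <- call_peaks(run$conv_by_tp[[k]], early)
    filter_rcds(early_peaks, run$cutoffs[[k]], run$S_by_tp[[k]], domains,
                timepoint = k)
  })
  n_early <- vapply(seq_len(nt), function(k)
    nrow(call_peaks(run$conv_by_tp[[k]], early)), 0L)
  run <- note(run, sprintf(
    "rcd: peaks called %s -> above cutoff %s",
    paste(n_early, collapse = "/"),
    paste(vapply(run$rcds_by_tp, nrow, 0L), collapse = "/")))

  if ("dynamics" %in% stages && nt >= 2) {
    Sd <- if (is.null(S_dynamics)) run$S_by_tp else S_dynamics
    run$isolated <- select_isolated(run$rcds_by_tp[[1]],
                                    run$S_by_tp[[1]])
    if (nrow(run$isolated) >= 2) {
      run$width_series <- peak_width_series(run$isolated, Sd,
                                            method = dynamics_method)
      acc <- sum(!run$width_series$rejected)
      if (acc >= 2)
        run$growth <- growth_stats(run$width_series,
                                   interval_min = interval_min)
      run <- note(run, sprintf("dynamics: %d isolated, %d accepted fits",
                               nrow(run$isolated), acc))
    } else run <- note(run, "dynamics: too few isolated peaks")
  } else run <- note(run, "dynamics: skipped")

  if ("valleys" %in% stages && nt >= 2) {
    run$valleys <- track_valleys(
      define_valleys(run$peaks_by_tp[[1]], domains),
      run$peaks_by_tp[-1])
    if (nrow(run$valleys) >= 2) {
      run$valley_timecourses <- valley_timecourses(run$valleys,
                                                   run$S_by_tp,
                                                   peak_width = peak_width)
      if (nrow(run$valley_timecourses) >= 2)
        run$filling <- filling_stats(run$valley_timecourses)
    }
    run <- note(run, sprintf("valleys: %d tracked",
                             if (is.null(run$valleys)) 0L
                             else nrow(run$valleys)))
  } else run <- note(run, "valleys: skipped")

  if ("domino" %in% stages) {
    run$groups_by_tp <- lapply(run$rcds_by_tp, form_groups,
                               max_gap = max_gap)
    run$similarity <- tryCatch(
      lapply(run$groups_by_tp, weighted_similarity_report),
      error = function(e) NULL)
    run <- note(run, sprintf("domino: %s groups per timepoint",
                             paste(vapply(run$groups_by_tp, length, 0L),
                                   collapse = "/")))
  } else run <- note(run, "domino: skipped")

  class(run) <- "pipeline_run"
  run
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("<pipeline_run>\n")
  for (l in x$log) cat(" -", l, "\n")
  invisible(x)
}

#' Write the pipeline's tabular outputs to a directory
#'
#' @param run a [run_pipeline()] result.
#' @param dir output directory (created if absent).
#' @return the directory, invisibly.
#' @export
write_pipeline_tables <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) {
    if (!is.null(df) && nrow(df))
      utils::write.table(df, file.path(dir, name), sep = "\t",
                         quote = FALSE, row.names = FALSE)
  }
  w(run$norm_reports, "normalization_report.tsv")
  for (k in seq_along(run$rcds_by_tp))
    w(run$rcds_by_tp[[k]], sprintf("rcds_t%d.tsv", k))
  w(run$width_series, "width_series.tsv")
  if (!is.null(run$growth)) w(run$growth$per_interval, "growth.tsv")
  w(run$valleys, "valleys.tsv")
  w(run$valley_timecourses, "valley_timecourses.tsv")
  writeLines(run$log, file.path(dir, "pipeline_log.txt"))
  invisible(dir)
}

#' Export a multiscale transform as TSV and (optionally) a heatmap image
#'
#' The TSV always holds the raw convolved values. The image applies the
#' display convention only: each scale row is divided by its maximum and
#' clamped to [0, 1], so zero-or-below is the bottom colour and the
#' per-scale maximum the top.
#'
#' @param ms a [multiscale_transform()] matrix.
#' @param tsv_path output TSV path.
#' @param png_path optional PNG path for the heatmap.
#' @return \code{tsv_path}, invisibly.
#' @export
export_heatmap <- function(ms, tsv_path, png_path = NULL) {
  m <- unclass(ms)
  utils::write.table(m, tsv_path, sep = "\t", quote = FALSE,
                     row.names = TRUE, col.names = FALSE)
  if (!is.null(png_path)) {
    disp <- t(apply(m, 1, function(r) {
      mx <- max(r, na.rm = TRUE)
      if (mx > 0) pmin(pmax(r / mx, 0), 1) else pmax(r * 0, 0)
    }))
    grDevices::png(png_path, width = 900, height = 400)
    graphics::image(t(disp), col = grDevices::hcl.colors(64, "Blue-Red"),
                    zlim = c(0, 1), axes = FALSE,
                    xlab = attr(ms, "chrom"),
                    ylab = "wavelet peak width (sqrt-2 ladder)")
    grDevices::dev.off()
  }
  invisible(tsv_path)
}
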