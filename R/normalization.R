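#' Scale a raw count track to reads per million
#'
#' Values are multiplied by \code{1e6 / total}, where \code{total} is the
#' summed count over unmasked bins -- genome-wide when a list of tracks is
#' given, so the output sums to one million across the genome.
#'
#' @param x a raw-count [binned_track()] or named list of them.
#' @return track(s) with role \code{"rpm"}.
#' @export
normalize_rpm <- function(x) {
  total <- sum(gather_values(x), na.rm = TRUE)
  if (total <= 0) stop("cannot RPM-scale an all-zero track")
  map_tracks(x, function(t) {
    t$values <- t$values * 1e6 / total
    t$role <- "rpm"
    t
  })
}

#' Broken-line breakpoint fit separating background from signal bins
#'
#' For paired pull-down (P) and control (C) RPM tracks, the scatter of
#' \code{y = log(P/C)} against \code{x = log(P+C)} is approximated by a
#' two-segment broken line: a horizontal left segment (no-signal bins, where
#' the P/C ratio is a constant r regardless of coverage) and an ordinary
#' least-squares right segment (signal bins). The breakpoint \code{b} is
#' chosen by exhaustive search over candidate x-quantiles to minimise the
#' total squared error, with no continuity constraint between segments. The
#' background set is \code{G = \{i : log(P_i + C_i) < b\}}; only bins with
#' \code{P > 0} and \code{C > 0} (log-defined) are eligible. Natural
#' logarithms are used; membership of G is invariant to the log base.
#'
#' @param P,C paired rpm tracks (a [binned_track()] or named list each),
#'   same grid.
#' @param n_candidates number of candidate breakpoints, spread over the
#'   empirical quantiles of x between \code{quantile_range}.
#' @param quantile_range x-quantile range searched for the breakpoint.
#' @return a \code{normalization_fit} with elements \code{breakpoint_b},
#'   \code{G} (per-chromosome logical masks), \code{n_background_bins},
#'   \code{n_eligible}, \code{right_slope} and \code{degenerate} (flag set
#'   when the right segment is empty or indistinguishable from horizontal).
#' @export
fit_breakpoint <- function(P, C, n_candidates = 200,
                           quantile_range = c(0.05, 0.95)) {
  if (inherits(P, "binned_track")) P <- list(P)
  if (inherits(C, "binned_track")) C <- list(C)
  stopifnot(length(P) == length(C))
  for (k in seq_along(P)) check_same_grid(P[[k]], C[[k]])
  p <- gather_values(P); c_ <- gather_values(C)
  elig <- !is.na(p) & !is.na(c_) & p > 0 & c_ > 0
  if (sum(elig) < 10)
    stop("fewer than 10 bins with P > 0 and C > 0; cannot fit breakpoint")
  x <- log(p[elig] + c_[elig])
  y <- log(p[elig] / c_[elig])
  cand <- unique(stats::quantile(x, seq(quantile_range[1], quantile_range[2],
                                        length.out = n_candidates),
                                 names = FALSE, type = 7))
  sse <- vapply(cand, function(b) {
    left <- x < b
    nl <- sum(left); nr <- sum(!left)
    if (nl < 2 || nr < 2) return(Inf)
    yl <- y[left]
    s_left <- sum((yl - mean(yl))^2)
    xr <- x[!left]; yr <- y[!left]
    # closed-form OLS residual sum of squares
    sxx <- sum((xr - mean(xr))^2)
    sxy <- sum((xr - mean(xr)) * (yr - mean(yr)))
    syy <- sum((yr - mean(yr))^2)
    s_right <- if (sxx > 0) syy - sxy^2 / sxx else syy
    s_left + s_right
  }, 0)
  if (all(!is.finite(sse))) stop("no admissible breakpoint candidate")
  b <- cand[which.min(sse)]
  in_g <- x < b
  # right-segment slope, for the degeneracy flag
  xr <- x[!in_g]; yr <- y[!in_g]
  slope <- if (length(xr) >= 2 && stats::var(xr) > 0)
    stats::cov(xr, yr) / stats::var(xr) else NA_real_
  degenerate <- !is.finite(slope) || abs(slope) < 1e-3
  # map G back onto per-chromosome masks
  g_all <- logical(length(p))
  g_all[elig] <- in_g
  G <- list()
  off <- 0L
  for (k in seq_along(P)) {
    n <- length(P[[k]]$values)
    G[[k]] <- g_all[(off + 1L):(off + n)]
    off <- off + n
  }
  names(G) <- names(P)
  structure(list(breakpoint_b = b, G = G,
                 n_background_bins = sum(in_g), n_eligible = sum(elig),
                 right_slope = slope, degenerate = degenerate),
            class = "normalization_fit")
}

#' @export
print.normalization_fit <- function(x, ...) {
  cat(sprintf(
    "<normalization_fit> b = %.4f, |G| = %d of %d eligible bins%s\n",
    x$breakpoint_b, x$n_background_bins, x$n_eligible,
    if (isTRUE(x$degenerate)) " (degenerate: no signal segment)" else ""))
  if (!is.null(x$r_hat_cis))
    cat(sprintf("  r_cis = %.4f, r_mode = %.4f, chosen = %s\n",
                x$r_hat_cis, x$r_hat_mode, x$chosen_method))
  invisible(x)
}

#' Estimate the background scaling factor r over the background set G
#'
#' \code{method = "cis"} uses the ratio of sums
#' \eqn{\hat r = \sum_{i \in G} P_i / \sum_{i \in G} C_i}. Because the
#' breakpoint isolation of G is imperfect, G may contain bins with residual
#' signal that bias this ratio upwards; \code{method = "mode"} instead takes
#' the mode of the per-bin \eqn{P_j/C_j} ratio distribution over G, estimated
#' by a Gaussian kernel density (Silverman's rule bandwidth, argmax on a
#' 512-point grid spanning the ratio range). Bins with \code{C = 0} are
#' excluded.
#'
#' @inheritParams fit_breakpoint
#' @param G per-chromosome logical masks as returned by [fit_breakpoint()]
#'   (or a single logical vector for a single track).
#' @param method \code{"cis"} or \code{"mode"}.
#' @return the scalar estimate \eqn{\hat r \ge 0}.
#' @export
estimate_r <- function(P, C, G, method = c("mode", "cis")) {
  method <- match.arg(method)
  if (inherits(P, "binned_track")) P <- list(P)
  if (inherits(C, "binned_track")) C <- list(C)
  if (is.logical(G)) G <- list(G)
  p <- gather_values(P); c_ <- gather_values(C)
  g <- unlist(G, use.names = FALSE)
  stopifnot(length(g) == length(p))
  g <- g & !is.na(p) & !is.na(c_) & c_ > 0
  if (!any(g)) stop("background set G is empty")
  if (method == "cis") return(sum(p[g]) / sum(c_[g]))
  ratios <- p[g] / c_[g]
  if (length(unique(ratios)) == 1L) return(ratios[1])
  d <- stats::density(ratios, bw = "nrd0", n = 512,
                      from = min(ratios), to = max(ratios))
  d$x[which.max(d$y)]
}

#' Subtract scaled control background from the pull-down
#'
#' \eqn{S_i = P_i - r C_i} per bin. Negative values are retained -- display
#' layers may clamp at zero, the analysis does not. Where \code{C = 0} this
#' reduces to \eqn{S_i = P_i}.
#'
#' @inheritParams fit_breakpoint
#' @param r background scaling factor, \code{r >= 0}.
#' @return signal track(s) with role \code{"signal"}.
#' @export
subtract_background <- function(P, C, r) {
  stopifnot(r >= 0)
  single <- inherits(P, "binned_track")
  if (single) { P <- list(P); C <- list(C) }
  stopifnot(length(P) == length(C))
  out <- lapply(seq_along(P), function(k) {
    check_same_grid(P[[k]], C[[k]])
    t <- P[[k]]
    t$values <- P[[k]]$values - r * C[[k]]$values
    t$role <- "signal"
    t
  })
  names(out) <- names(P)
  if (single) out[[1]] else out
}

#' Full normalisation of one pull-down/control pair
#'
#' RPM-scales both tracks, fits the broken-line breakpoint, estimates r by
#' both the ratio-of-sums and the ratio-mode estimator, and subtracts
#' \code{chosen_r * C} from P. The mode estimator is the default because the
#' background set G typically retains some signal-carrying bins, which inflate
#' the ratio of sums but not the ratio mode.
#'
#' @param P_raw,C_raw raw-count track(s) (see [binned_track()]).
#' @param method which estimate to subtract: \code{"mode"} (default) or
#'   \code{"cis"}.
#' @param ... passed to [fit_breakpoint()].
#' @return list with \code{S} (signal track(s)), \code{P}, \code{C} (rpm),
#'   and \code{fit} (a \code{normalization_fit} extended with
#'   \code{r_hat_cis}, \code{r_hat_mode}, \code{chosen_r},
#'   \code{chosen_method}).
#' @export
background_normalize <- function(P_raw, C_raw, method = c("mode", "cis"),
                                 ...) {
  method <- match.arg(method)
  P <- normalize_rpm(P_raw)
  C <- normalize_rpm(C_raw)
  fit <- fit_breakpoint(P, C, ...)
  fit$r_hat_cis <- estimate_r(P, C, fit$G, "cis")
  fit$r_hat_mode <- estimate_r(P, C, fit$G, "mode")
  fit$chosen_method <- method
  fit$chosen_r <- if (method == "mode") fit$r_hat_mode else fit$r_hat_cis
  list(S = subtract_background(P, C, fit$chosen_r), P = P, C = C, fit = fit)
}

#' Tabular normalisation report
#'
#' @param fit an extended \code{normalization_fit} from
#'   [background_normalize()].
#' @param label free-text label column (e.g. the timepoint).
#' @return one-row data.frame (written as TSV by [write_pipeline_tables()]).
#' @export
normalization_report <- function(fit, label = "") {
  data.frame(label = label, breakpoint_b = fit$breakpoint_b,
             n_background_bins = fit$n_background_bins,
             n_eligible = fit$n_eligible,
             r_cis = fit$r_hat_cis, r_mode = fit$r_hat_mode,
             chosen_r = fit$chosen_r, chosen_method = fit$chosen_method,
             degenerate = fit$degenerate, stringsAsFactors = FALSE)
}
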