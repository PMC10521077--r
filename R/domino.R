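#' Group adjacent RCDs along the chromosome
#'
#' Maximal runs of RCDs within one timing domain whose successive
#' peak-to-peak (centre) distance is below \code{max_gap}. Singleton groups
#' are returned but are excluded from all downstream ordering statistics.
#'
#' @param rcds data.frame from [filter_rcds()] (one timepoint), with
#'   \code{position}, \code{timing_domain_id} and
#'   \code{replication_peak_height}.
#' @param max_gap grouping distance in bp (default 1.6 Mbp, twice the mean
#'   within-domain adjacent separation).
#' @param gap_mode \code{"centre"} (peak-to-peak) or \code{"edge"}
#'   (extent edge to extent edge).
#' @return list of \code{rcd_group}s; each is a list with \code{members}
#'   (data.frame ordered along the chromosome), \code{heights}, \code{n},
#'   \code{timing_domain_id}.
#' @export
form_groups <- function(rcds, max_gap = 1.6e6,
                        gap_mode = c("centre", "edge")) {
  gap_mode <- match.arg(gap_mode)
  groups <- list()
  for (d in split(rcds, rcds$timing_domain_id)) {
    d <- d[order(d$position), , drop = FALSE]
    gaps <- if (nrow(d) < 2) numeric() else if (gap_mode == "centre")
      diff(d$position)
    else d$extent_start[-1] - d$extent_end[-nrow(d)]
    run <- cumsum(c(1, gaps >= max_gap))
    for (g in split(d, run)) {
      groups[[length(groups) + 1L]] <- structure(
        list(members = g, heights = g$replication_peak_height,
             n = nrow(g), timing_domain_id = g$timing_domain_id[1]),
        class = "rcd_group")
    }
  }
  groups
}

#' Canonical height-order permutation class of a small group
#'
#' Heights are ranked along the chromosome with 1 for the highest. Because
#' direction along the chromosome is arbitrary, the rank sequence is
#' canonicalised to the lexicographic minimum of itself and its reversal,
#' giving 3 classes for groups of three and 12 for groups of four.
#'
#' @param heights numeric heights ordered along the chromosome (length 3 or
#'   4), or an \code{rcd_group}.
#' @return the class string, e.g. \code{"2-1-3"}.
#' @export
classify_permutation <- function(heights) {
  if (inherits(heights, "rcd_group")) heights <- heights$heights
  n <- length(heights)
  if (!n %in% c(3L, 4L))
    stop("permutation classes are defined for groups of 3 or 4 only")
  if (anyDuplicated(heights))
    warning("tied heights broken by genomic position")
  ranks <- rank(-heights, ties.method = "first")
  canonical_rank_string(ranks)
}

canonical_rank_string <- function(ranks) {
  fwd <- paste(ranks, collapse = "-")
  rev_ <- paste(rev(ranks), collapse = "-")
  if (rev_ < fwd) rev_ else fwd
}

#' All canonical permutation classes for group size n
#' @param n group size (3 or 4).
#' @return sorted character vector of class strings (3 or 12 classes).
#' @export
permutation_classes <- function(n) {
  perms <- all_permutations(n)
  sort(unique(apply(perms, 1, canonical_rank_string)))
}

## matrix of all permutations of 1..n, one per row
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' Permutation-class frequencies per timepoint
#'
#' The percentage of groups of size \code{n} falling in each canonical
#' class, per timepoint, with the mean and SD across timepoints.
#'
#' @param groups_by_tp list over timepoints; each element a list of
#'   \code{rcd_group}s (from [form_groups()]).
#' @param n group size to tabulate (3 or 4).
#' @return data.frame: \code{class}, one \code{pct_t*} column per
#'   timepoint, \code{mean_pct}, \code{sd_pct}. Percentages sum to 100 per
#'   timepoint.
#' @export
permutation_frequencies <- function(groups_by_tp, n) {
  classes <- permutation_classes(n)
  pct <- vapply(groups_by_tp, function(groups) {
    g <- Filter(function(x) x$n == n, groups)
    if (!length(g)) stop("no groups of size ", n, " in a timepoint")
    cls <- vapply(g, classify_permutation, "")
    as.numeric(table(factor(cls, levels = classes))) / length(cls) * 100
  }, numeric(length(classes)))
  pct <- matrix(pct, nrow = length(classes))
  out <- data.frame(class = classes, stringsAsFactors = FALSE)
  for (k in seq_len(ncol(pct))) out[[paste0("pct_t", k)]] <- pct[, k]
  out$mean_pct <- rowMeans(pct)
  out$sd_pct <- apply(pct, 1, stats::sd)
  out
}

#' Null permutation-class frequencies under independent heights
#'
#' Simulates groups of \code{n} i.i.d. Uniform(0,1) heights and tabulates
#' the canonical class percentages -- the reference distribution against
#' which an excess of "domino-like" orderings is judged (uniform: 33.3\%
#' per class for n = 3, 8.3\% for n = 4).
#'
#' @param n group size (3 or 4).
#' @param n_sim number of simulated groups.
#' @return data.frame: \code{class}, \code{pct}.
#' @export
permutation_class_null <- function(n, n_sim = 100000) {
  classes <- permutation_classes(n)
  h <- matrix(stats::runif(n_sim * n), ncol = n)
  ranks <- t(apply(h, 1, function(r) rank(-r, ties.method = "first")))
  fwd <- apply(ranks, 1, paste, collapse = "-")
  bwd <- apply(ranks[, n:1, drop = FALSE], 1, paste, collapse = "-")
  cls <- ifelse(bwd < fwd, bwd, fwd)
  data.frame(class = classes,
             pct = as.numeric(table(factor(cls, levels = classes))) /
               n_sim * 100,
             stringsAsFactors = FALSE)
}

#' Adjacent-height similarity ("domino") metric
#'
#' For an array of n heights ordered along the chromosome, three components
#' are formed from absolute differences: ADFA, the mean over the n-1
#' adjacent pairs of the array as given; ADFSV, the same over the sorted
#' array, which equals (max - min)/(n - 1); and MADFAP, the mean adjacent
#' difference over all orderings of the array, which equals the mean
#' absolute difference over all unordered distinct pairs. The metric is
#' \deqn{1 - (ADFA - ADFSV) / (MADFAP - ADFSV),} equal to 1 when the
#' heights are monotone (distinct values), 0 on average over random
#' orderings, and negative for interleaved ("anti-domino") arrangements.
#' It is invariant to reversal and to affine transforms of the heights, and
#' undefined when MADFAP = ADFSV (constant arrays, and every n = 2 array).
#' For n = 3 the metric is defined but cannot fall below -0.5, so it cannot
#' separate random from anti-ordered arrangements -- the reason 3-groups
#' are excluded from [weighted_similarity_report()].
#'
#' @param heights numeric vector, n >= 2, ordered along the chromosome; or
#'   an \code{rcd_group}.
#' @return an \code{adjacency_metric}: list with \code{value},
#'   \code{adfa}, \code{adfsv}, \code{madfap}, \code{n}, \code{defined}.
#' @export
adjacent_value_similarity <- function(heights) {
  if (inherits(heights, "rcd_group")) heights <- heights$heights
  n <- length(heights)
  if (n < 2) stop("need at least 2 heights")
  adfa <- mean(abs(diff(heights)))
  adfsv <- (max(heights) - min(heights)) / (n - 1)
  madfap <- mean(stats::dist(heights))
  defined <- (madfap - adfsv) > .Machine$double.eps^0.5 * max(madfap, 1)
  value <- if (defined) 1 - (adfa - adfsv) / (madfap - adfsv) else NA_real_
  structure(list(value = value, adfa = adfa, adfsv = adfsv,
                 madfap = madfap, n = n, defined = defined),
            class = "adjacency_metric")
}

#' @export
print.adjacency_metric <- function(x, ...) {
  cat(sprintf(
    "<adjacency_metric> n = %d: ADFA %.4g, ADFSV %.4g, MADFAP %.4g -> %s\n",
    x$n, x$adfa, x$adfsv, x$madfap,
    if (x$defined) sprintf("value %.4f", x$value) else "undefined"))
  invisible(x)
}

#' Replication-weighted similarity report over groups of four or more
#'
#' Each eligible group's metric value is recorded n-1 times in the weighted
#' reporting sample, so larger groups carry proportionally more weight; the
#' once-per-group ("no-rep") sample is reported alongside. Groups of three
#' are omitted: with only three members the metric cannot distinguish
#' random from anti-ordered. Both samples get a one-sample t-test against
#' zero with 95\% CI.
#'
#' @param groups list of \code{rcd_group}s (one timepoint).
#' @param min_n minimum group size (default 4).
#' @return a \code{similarity_report}: \code{values} (per group),
#'   \code{weighted_values}, \code{t_weighted}, \code{t_norep},
#'   \code{n_groups}.
#' @export
weighted_similarity_report <- function(groups, min_n = 4) {
  g <- Filter(function(x) x$n >= min_n, groups)
  vals <- vapply(g, function(x) adjacent_value_similarity(x)$value, 0)
  ns <- vapply(g, function(x) x$n, 0L)
  keep <- !is.na(vals)
  vals <- vals[keep]; ns <- ns[keep]
  if (!length(vals)) stop("no groups with >= ", min_n,
                          " members and a defined metric")
  weighted <- rep(vals, times = ns - 1L)
  structure(list(values = vals, weighted_values = weighted,
                 t_weighted = one_sample_t(weighted),
                 t_norep = one_sample_t(vals),
                 n_groups = length(vals)),
            class = "similarity_report")
}

#' @export
print.similarity_report <- function(x, ...) {
  cat(sprintf(
    "<similarity_report> %d groups; weighted mean %.4f (p = %.3g), no-rep mean %.4f (p = %.3g)\n",
    x$n_groups, x$t_weighted$mean, x$t_weighted$p, x$t_norep$mean,
    x$t_norep$p))
  invisible(x)
}

#' One-sample t-test against zero
#'
#' Standard two-sided one-sample t statistics, returned as plain numbers.
#' With zero sample variance the test is flagged degenerate: p is reported
#' as 1 when the mean is also zero (no evidence of departure, by
#' convention) and NA otherwise.
#'
#' @param values numeric sample (length >= 2).
#' @return list: \code{n, mean, se, ci} (95\%), \code{t, df, p,
#'   degenerate}.
#' @export
one_sample_t <- function(values) {
  n <- length(values)
  if (n < 2) stop("need at least 2 values")
  m <- mean(values)
  s <- stats::sd(values)
  if (s == 0) {
    return(list(n = n, mean = m, se = 0, ci = c(m, m), t = NA_real_,
                df = n - 1, p = if (m == 0) 1 else NA_real_,
                degenerate = TRUE))
  }
  se <- s / sqrt(n)
  tstat <- m / se
  crit <- stats::qt(0.975, n - 1)
  list(n = n, mean = m, se = se, ci = c(m - crit * se, m + crit * se),
       t = tstat, df = n - 1,
       p = 2 * stats::pt(-abs(tstat), n - 1), degenerate = FALSE)
}
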