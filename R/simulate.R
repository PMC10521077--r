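#' Configuration of the synthetic EdU-seq genome
#'
#' Parameterises an explicit kinetic model of clustered replication origins:
#' cells enter S phase across an entry window, each replicon cluster
#' activates stochastically per cell, its fired origins initiate with a
#' small jitter and extend bidirectional forks at a constant rate, and
#' 30-min EdU pulses label the DNA synthesised inside each window. Defaults
#' follow the biology of synchronised early-S U2OS cells: fork rate
#' 1.5 kb/min, S-entry spread over ~45 min, pulses at 10-40, 40-70, 70-100
#' and 100-130 min.
#'
#' @param chrom_lengths named numeric vector of chromosome lengths (bp).
#' @param bin_size bin width in bp.
#' @param domains a [timing_domains()] object for the synthetic genome.
#' @param clusters data.frame with one row per replicon cluster:
#'   \code{chrom}, \code{centre} (bp), \code{width} (bp),
#'   \code{n_origins} (2-10, typically 3-6), \code{t_act_mean},
#'   \code{t_act_sd} (activation-time distribution, min, relative to
#'   S entry), \code{efficiency} (per-cell activation probability in
#'   (0, 1]).
#' @param activation_dist shape of the per-cell activation-time draw around
#'   each cluster's mean: \code{"normal"} (truncated at 0, sd =
#'   \code{t_act_sd}) or \code{"uniform"} (over \code{t_act_mean} plus/minus
#'   \code{sqrt(3) * t_act_sd}, clamped at 0). Uniform activation spread
#'   across the time course keeps cluster interiors replicating throughout,
#'   reproducing the observed flat-topped, steadily widening pulse profiles;
#'   a narrow normal spread instead produces fork-termination splitting.
#' @param coupling \code{list(mode = "off")} or \code{list(mode = "domino",
#'   delay_mean =, delay_sd =, group_gap =)}: with domino coupling on,
#'   clusters within \code{group_gap} of each other form a chain whose mean
#'   activation times increase along a randomly oriented direction by
#'   positive per-step delays.
#' @param fork_rate fork speed in kb/min.
#' @param origin_jitter_sd intra-cluster firing jitter sd in min.
#' @param origin_candidate_factor candidate origin positions per fired
#'   origin (>= 1): each cluster lays out
#'   \code{ceiling(factor * n_origins)} evenly spaced candidates and every
#'   cell fires a random subset of \code{n_origins} of them. A factor of 1
#'   fires all candidates in every cell (deterministic layout).
#' @param entry_window min; cells enter S phase uniformly in this window.
#' @param pulses list of \code{c(start, end)} EdU windows in min, ascending
#'   and non-overlapping.
#' @param n_cells number of simulated cells.
#' @param read_depth expected pull-down reads per labelled kb (per
#'   cell-mean labelled DNA).
#' @param background_rate expected background reads per bin in the
#'   pull-down.
#' @param control_depth expected control reads per bin.
#' @return a validated \code{sim_config} list.
#' @export
sim_config <- function(chrom_lengths, bin_size, domains, clusters,
                       activation_dist = c("normal", "uniform"),
                       coupling = list(mode = "off"),
                       fork_rate = 1.5, origin_jitter_sd = 2,
                       entry_window = c(0, 45),
                       pulses = list(c(10, 40), c(40, 70), c(70, 100),
                                     c(100, 130)),
                       n_cells = 100, read_depth = 2,
                       background_rate = 5, control_depth = 20,
                       origin_candidate_factor = 2) {
  activation_dist <- match.arg(activation_dist)
  stopifnot(origin_candidate_factor >= 1)
  stopifnot(!is.null(names(chrom_lengths)), bin_size > 0,
            all(c("chrom", "centre", "width", "n_origins", "t_act_mean",
                  "t_act_sd", "efficiency") %in% names(clusters)),
            fork_rate > 0, origin_jitter_sd >= 0,
            read_depth >= 0, background_rate >= 0, control_depth >= 0,
            n_cells >= 1)
  stopifnot(all(clusters$chrom %in% names(chrom_lengths)))
  half <- clusters$width / 2
  lens <- chrom_lengths[clusters$chrom]
  if (any(clusters$centre - half < 0 | clusters$centre + half > lens))
    stop("cluster extends beyond its chromosome")
  if (any(clusters$n_origins < 2 | clusters$n_origins > 10))
    stop("n_origins must be in [2, 10]")
  if (any(clusters$efficiency <= 0 | clusters$efficiency > 1))
    stop("efficiency must be in (0, 1]")
  b <- unlist(pulses)
  if (any(diff(b) < 0)) stop("pulses must be ascending and non-overlapping")
  structure(list(chrom_lengths = chrom_lengths, bin_size = bin_size,
                 domains = domains, clusters = clusters,
                 activation_dist = activation_dist,
                 coupling = coupling, fork_rate = fork_rate,
                 origin_jitter_sd = origin_jitter_sd,
                 origin_candidate_factor = origin_candidate_factor,
                 entry_window = entry_window, pulses = pulses,
                 n_cells = n_cells, read_depth = read_depth,
                 background_rate = background_rate,
                 control_depth = control_depth),
            class = "sim_config")
}

## effective per-cluster mean activation times: with domino coupling on,
## chains of nearby clusters get monotone means along a random direction
effective_activation_means <- function(config) {
  cl <- config$clusters
  means <- cl$t_act_mean
  if (!identical(config$coupling$mode, "domino")) return(means)
  cp <- config$coupling
  gap <- if (!is.null(cp$group_gap)) cp$group_gap else 1.6e6
  for (ch in unique(cl$chrom)) {
    i <- which(cl$chrom == ch)
    i <- i[order(cl$centre[i])]
    run <- cumsum(c(1, diff(cl$centre[i]) >= gap))
    for (g in split(i, run)) {
      if (length(g) < 2) next
      delays <- abs(stats::rnorm(length(g) - 1, cp$delay_mean,
                                 cp$delay_sd))
      ramp <- c(0, cumsum(delays))
      if (stats::runif(1) < 0.5) ramp <- rev(ramp)
      means[g] <- cl$t_act_mean[g] + ramp
    }
  }
  means
}

#' Simulate the activation programme of one cell
#'
#' Draws the cell's S-entry time, then for each cluster an activation
#' decision (probability = efficiency), an activation time (entry + a
#' non-negative draw around the cluster's mean), the fired origin subset
#' (chosen uniformly without replacement from candidate positions evenly
#' spaced across the cluster width with jitter) and per-origin initiation
#' times (activation + |jitter|). Replicated intervals at any time t follow
#' by bidirectional fork extension from each origin, forks merging on
#' meeting.
#'
#' @param config a [sim_config()].
#' @param act_means effective per-cluster mean activation times (min);
#'   defaults to the cluster table's means.
#' @return a \code{sim_cell}: list with \code{entry_time},
#'   \code{activated} (logical per cluster), \code{act_time} (min, NA when
#'   silent), \code{origins}, \code{origin_times} (lists per cluster).
#' @export
simulate_cell <- function(config, act_means = NULL) {
  cl <- config$clusters
  k <- nrow(cl)
  if (is.null(act_means)) act_means <- cl$t_act_mean
  entry <- stats::runif(1, config$entry_window[1], config$entry_window[2])
  activated <- stats::runif(k) < cl$efficiency
  act_time <- rep(NA_real_, k)
  na <- sum(activated)
  draw <- if (identical(config$activation_dist, "uniform")) {
    half <- sqrt(3) * cl$t_act_sd[activated]
    stats::runif(na, act_means[activated] - half,
                 act_means[activated] + half)
  } else {
    stats::rnorm(na, act_means[activated], cl$t_act_sd[activated])
  }
  act_time[activated] <- entry + pmax(0, draw)
  origins <- vector("list", k)
  origin_times <- vector("list", k)
  fac <- if (!is.null(config$origin_candidate_factor))
    config$origin_candidate_factor else 2
  for (j in which(activated)) {
    n_cand <- max(as.integer(ceiling(fac * cl$n_origins[j])),
                  cl$n_origins[j])
    spacing <- cl$width[j] / n_cand
    cand <- cl$centre[j] - cl$width[j] / 2 + (seq_len(n_cand) - 0.5) *
      spacing + stats::rnorm(n_cand, 0, spacing / 4)
    fired <- sort(sample(n_cand, cl$n_origins[j]))
    origins[[j]] <- cand[fired]
    origin_times[[j]] <- act_time[j] +
      abs(stats::rnorm(cl$n_origins[j], 0, config$origin_jitter_sd))
  }
  structure(list(entry_time = entry, activated = activated,
                 act_time = act_time, origins = origins,
                 origin_times = origin_times),
            class = "sim_cell")
}

#' Replicated intervals of one cluster of a cell at time t
#'
#' Bidirectional forks extend at the configured rate from each fired origin
#' from its initiation time; the replicated set is the merged union of the
#' per-origin intervals (fork mergers are implicit in the union), clipped
#' to the chromosome.
#'
#' @param cell a [simulate_cell()] result.
#' @param cluster_index which cluster.
#' @param t time in min.
#' @param config the [sim_config()].
#' @return two-column matrix of merged intervals (bp).
#' @export
replicated_intervals <- function(cell, cluster_index, t, config) {
  o <- cell$origins[[cluster_index]]
  ti <- cell$origin_times[[cluster_index]]
  if (is.null(o)) return(matrix(numeric(), ncol = 2))
  v <- config$fork_rate * 1000
  ext <- v * pmax(t - ti, 0)
  len <- config$chrom_lengths[[config$clusters$chrom[cluster_index]]]
  merge_intervals(cbind(pmax(o - ext, 0), pmin(o + ext, len)))
}

#' DNA labelled by one pulse in one cluster of a cell
#'
#' The labelled set is replicated(t2) minus replicated(t1): exactly the DNA
#' synthesised inside the window, so consecutive pulses label disjoint
#' sets.
#'
#' @inheritParams replicated_intervals
#' @param pulse \code{c(t1, t2)} in min.
#' @return two-column matrix of labelled intervals (bp).
#' @export
label_pulse <- function(cell, cluster_index, pulse, config) {
  stopifnot(pulse[1] < pulse[2])
  diff_intervals(replicated_intervals(cell, cluster_index, pulse[2], config),
                 replicated_intervals(cell, cluster_index, pulse[1], config))
}

#' Simulate a full EdU-seq experiment with ground truth
#'
#' Simulates \code{n_cells} activation programmes, accumulates the labelled
#' bp per bin for every pulse, converts the per-cell mean labelled DNA to
#' expected pull-down read intensities (\code{read_depth} reads per
#' labelled kb plus a uniform \code{background_rate} per bin), and samples
#' pull-down and control counts as independent Poisson draws per bin.
#'
#' @param config a [sim_config()].
#' @param seed optional integer seed (all randomness flows from R's RNG).
#' @return list: \code{P}, \code{C} (lists over pulses of named raw-count
#'   track lists), \code{truth} (\code{entry_times}, \code{act_times}
#'   cells-by-clusters matrix, \code{cluster_table} with effective mean
#'   activation times, \code{labelled_fraction} per-pulse expected
#'   labelled-fraction tracks), \code{config}, \code{seed}.
#' @export
simulate_edu_seq <- function(config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cl <- config$clusters
  chroms <- names(config$chrom_lengths)
  bin <- config$bin_size
  nbins <- vapply(config$chrom_lengths, function(l) ceiling(l / bin), 0)
  act_means <- effective_activation_means(config)
  cells <- lapply(seq_len(config$n_cells), function(i)
    simulate_cell(config, act_means))
  times <- sort(unique(unlist(config$pulses)))
  npulse <- length(config$pulses)
  # labelled bp per bin, summed over cells: cov[[pulse]][[chrom]]
  cov <- lapply(seq_len(npulse), function(p)
    lapply(stats::setNames(nm = chroms), function(ch)
      numeric(nbins[[ch]])))
  for (cell in cells) {
    for (j in which(cell$activated)) {
      ch <- cl$chrom[j]
      reps <- lapply(times, function(t)
        replicated_intervals(cell, j, t, config))
      names(reps) <- as.character(times)
      for (p in seq_len(npulse)) {
        t1 <- as.character(config$pulses[[p]][1])
        t2 <- as.character(config$pulses[[p]][2])
        lab <- diff_intervals(reps[[t2]], reps[[t1]])
        if (nrow(lab))
          cov[[p]][[ch]] <- add_interval_coverage(cov[[p]][[ch]], lab, bin)
      }
    }
  }
  P <- vector("list", npulse); C <- vector("list", npulse)
  labelled_fraction <- vector("list", npulse)
  for (p in seq_len(npulse)) {
    P[[p]] <- lapply(stats::setNames(nm = chroms), function(ch) {
      mean_bp <- cov[[p]][[ch]] / config$n_cells
      lambda <- config$read_depth * mean_bp / 1000 + config$background_rate
      binned_track(stats::rpois(length(lambda), lambda), ch, bin,
                   role = "raw_count",
                   chrom_length = config$chrom_lengths[[ch]])
    })
    C[[p]] <- lapply(stats::setNames(nm = chroms), function(ch)
      binned_track(stats::rpois(nbins[[ch]], config$control_depth), ch, bin,
                   role = "raw_count",
                   chrom_length = config$chrom_lengths[[ch]]))
    labelled_fraction[[p]] <- lapply(stats::setNames(nm = chroms),
                                     function(ch) {
      binned_track(pmin(cov[[p]][[ch]] / config$n_cells / bin, 1), ch, bin,
                   role = "signal",
                   chrom_length = config$chrom_lengths[[ch]])
    })
  }
  act_times <- do.call(rbind, lapply(cells, function(x) x$act_time))
  cluster_table <- cl
  cluster_table$effective_t_act_mean <- act_means
  list(P = P, C = C,
       truth = list(entry_times = vapply(cells, function(x) x$entry_time, 0),
                    act_times = act_times,
                    cluster_table = cluster_table,
                    labelled_fraction = labelled_fraction,
                    cells = cells),
       config = config, seed = seed)
}

## regular cluster layout helper used by the presets
cluster_rows <- function(chrom, centres, width, n_origins, t_act_mean,
                         t_act_sd, efficiency) {
  data.frame(chrom = chrom, centre = centres, width = width,
             n_origins = n_origins, t_act_mean = t_act_mean,
             t_act_sd = t_act_sd, efficiency = efficiency,
             stringsAsFactors = FALSE)
}

#' Named benchmark simulation presets
#'
#' Deterministic (seed-controlled via [simulate_edu_seq()]) configurations
#' plus machine-readable expectations, each exercising one pipeline stage:
#' \describe{
#'   \item{basic}{2 x 20 Mbp chromosomes, 50-kb bins, early/late domains,
#'     500-kb clusters every 1.2 Mbp in the early domains with stochastic
#'     activation and 0-45 min staggered S entry. Expectation: the width
#'     scan peaks at the planted 500-kb scale and detection recovers the
#'     planted centres.}
#'   \item{growth}{a synchronous cohort (no entry stagger, efficiency 1) of
#'     isolated 500-kb clusters on 10-kb bins. Expectation: fitted widths
#'     grow by 2 x fork_rate x 30 min = 90 kb per 30-min interval.}
#'   \item{growth_staggered}{as growth but with 0-45 min S entry; the
#'     first-interval growth is suppressed because late-entering cells
#'     contribute narrow peaks.}
#'   \item{valleys}{prominent early clusters every 2.5 Mbp with
#'     late-activating, lower-efficiency clusters in the valley bottoms.
#'     Expectation: valley minimum percentages rise monotonically across
#'     the four pulses.}
#'   \item{domino_null}{~200 groups of four clusters with independent
#'     activation; the weighted adjacent-height similarity has mean ~0.}
#'   \item{domino_coupled}{same layout with domino coupling on (positive
#'     inter-cluster delays along each group); the weighted metric mean is
#'     positive.}
#' }
#'
#' @param preset preset name.
#' @param n_groups number of groups for the domino presets.
#' @param cluster_width planted cluster width for the basic preset, bp.
#' @return list with \code{name}, \code{config} (a [sim_config()]) and
#'   \code{expected} (named list of ground-truth expectations).
#' @export
make_benchmark_suite <- function(preset = c("basic", "growth",
                                            "growth_staggered", "valleys",
                                            "domino_null",
                                            "domino_coupled"),
                                 n_groups = 200, cluster_width = 500e3) {
  preset <- match.arg(preset)
  if (preset == "basic") {
    lens <- c(chrS1 = 20e6, chrS2 = 20e6)
    dom <- timing_domains(data.frame(
      chrom = rep(names(lens), each = 2),
      start = rep(c(2e6, 12e6), 2), end = rep(c(11e6, 19e6), 2),
      label = rep(c("early", "late"), 2)), source = "preset basic")
    centres <- seq(2.8e6, 10.0e6, by = 1.2e6)
    clusters <- do.call(rbind, lapply(names(lens), function(ch)
      cluster_rows(ch, centres, cluster_width, 5, 10, 8, 0.95)))
    config <- sim_config(lens, 50e3, dom, clusters, n_cells = 100,
                         read_depth = 2, background_rate = 5,
                         control_depth = 20)
    expected <- list(planted_width = cluster_width,
                     centres = clusters[, c("chrom", "centre")])
  } else if (preset %in% c("growth", "growth_staggered")) {
    lens <- c(chrS1 = 60e6)
    dom <- timing_domains(data.frame(chrom = "chrS1", start = 1e6,
                                     end = 59e6, label = "early"),
                          source = paste("preset", preset))
    # activation uniform across the 130-min course (mean 65, half-width
    # sqrt(3) * 37.5 = 65): interiors keep replicating in some cells at
    # every pulse, giving the flat-topped, steadily widening profiles seen
    # in real clusters rather than fork-termination splitting. Dense
    # origins (10 per cluster) keep intra-cluster fork travel short
    # relative to the pulse length, so the 2 * v * dt envelope growth
    # applies from the first interval.
    clusters <- cluster_rows("chrS1", seq(3e6, 57e6, by = 3e6), 500e3, 10,
                             65, 37.5, 1)
    entry <- if (preset == "growth") c(0, 0) else c(0, 45)
    config <- sim_config(lens, 10e3, dom, clusters,
                         activation_dist = "uniform",
                         entry_window = entry,
                         n_cells = 300, read_depth = 10,
                         background_rate = 2, control_depth = 20,
                         origin_jitter_sd = 2,
                         origin_candidate_factor = 1)
    expected <- list(growth_per_interval = 2 * config$fork_rate * 1000 * 30)
  } else if (preset == "valleys") {
    lens <- c(chrS1 = 24e6, chrS2 = 24e6)
    dom <- timing_domains(data.frame(chrom = names(lens), start = 1e6,
                                     end = 23e6, label = "early"),
                          source = "preset valleys")
    main_centres <- seq(2e6, 22e6, by = 2e6)
    valley_centres <- main_centres[-length(main_centres)] + 1e6
    # main clusters activate across a broad window (so their profiles stay
    # filled over the course); valley-bottom initiation spans the whole
    # inter-peak gap (origins dispersed across it) and skews late, so the
    # valley minimum rises steadily while staying below the flanking peaks
    clusters <- do.call(rbind, lapply(names(lens), function(ch) rbind(
      cluster_rows(ch, main_centres, 500e3, 5, 65, 37.5, 0.95),
      cluster_rows(ch, valley_centres, 1.0e6, 4, 82.5, 27.4, 0.7))))
    config <- sim_config(lens, 50e3, dom, clusters,
                         activation_dist = "uniform", n_cells = 150,
                         read_depth = 15, background_rate = 10,
                         control_depth = 50)
    expected <- list(valley_centres = valley_centres,
                     min_pct_monotone = TRUE)
  } else {
    per_chrom <- 12L
    n_chrom <- ceiling(n_groups / per_chrom)
    block <- 8e6
    lens <- stats::setNames(rep(per_chrom * block, n_chrom),
                            sprintf("chrS%d", seq_len(n_chrom)))
    built <- 0L
    dom_rows <- list(); cl_rows <- list()
    for (ch in names(lens)) {
      for (b in seq_len(per_chrom)) {
        if (built >= n_groups) break
        g0 <- (b - 1) * block
        dom_rows[[length(dom_rows) + 1L]] <- data.frame(
          chrom = ch, start = g0 + 0.5e6, end = g0 + 5.7e6,
          label = "early")
        dom_rows[[length(dom_rows) + 1L]] <- data.frame(
          chrom = ch, start = g0 + 5.9e6, end = g0 + 7.9e6,
          label = "late")
        cl_rows[[length(cl_rows) + 1L]] <- cluster_rows(
          ch, g0 + 1e6 + (0:3) * 1.2e6, 500e3, 5, 8, 4, 1)
        built <- built + 1L
      }
    }
    dom <- timing_domains(do.call(rbind, dom_rows),
                          source = paste("preset", preset))
    clusters <- do.call(rbind, cl_rows)
    coupling <- if (preset == "domino_coupled")
      list(mode = "domino", delay_mean = 6, delay_sd = 3,
           group_gap = 1.6e6)
    else list(mode = "off")
    config <- sim_config(lens, 50e3, dom, clusters, coupling = coupling,
                         pulses = list(c(10, 40)), n_cells = 60,
                         read_depth = 4, background_rate = 5,
                         control_depth = 20)
    expected <- list(n_groups = built,
                     metric_sign = if (preset == "domino_coupled") 1 else 0)
  }
  list(name = preset, config = config, expected = expected)
}
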