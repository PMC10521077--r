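tiny_config <- function(n_cells = 1, origin_jitter_sd = 0, ...) {
  dom <- timing_domains(data.frame(chrom = "chrT", start = 0, end = 10e6,
                                   label = "early"))
  clusters <- data.frame(chrom = "chrT", centre = 5e6, width = 500e3,
                         n_origins = 5, t_act_mean = 0, t_act_sd = 0,
                         efficiency = 1)
  sim_config(c(chrT = 10e6), 50e3, dom, clusters,
             entry_window = c(0, 0), n_cells = n_cells,
             origin_jitter_sd = origin_jitter_sd, ...)
}

test_that("single-origin fork kinematics are exact", {
  cfg <- tiny_config()
  cfg$clusters$n_origins <- 2   # minimum allowed; use only the first origin
  set.seed(51)
  cell <- simulate_cell(cfg)
  # overwrite with a deterministic single origin firing at t = 0
  cell$origins[[1]] <- 5e6
  cell$origin_times[[1]] <- 0
  rep40 <- replicated_intervals(cell, 1, 40, cfg)
  # fork 1.5 kb/min for 40 min -> origin +/- 60 kb
  expect_equal(rep40, cbind(5e6 - 60e3, 5e6 + 60e3))

  # two origins 100 kb apart, same activation: forks meet at the midpoint
  # at t = 50 / 1.5 min; just after, the union is a single interval
  cell$origins[[1]] <- c(5e6, 5.1e6)
  cell$origin_times[[1]] <- c(0, 0)
  t_meet <- 50 / 1.5
  just_before <- replicated_intervals(cell, 1, t_meet * 0.99, cfg)
  just_after <- replicated_intervals(cell, 1, t_meet * 1.01, cfg)
  expect_equal(nrow(just_before), 2L)
  expect_equal(nrow(just_after), 1L)

  # pulse labelling: origin active from 0, pulse 10-40 labels two bands
  # v*t1 to v*t2 either side of the origin
  cell$origins[[1]] <- 5e6
  cell$origin_times[[1]] <- 0
  lab <- label_pulse(cell, 1, c(10, 40), cfg)
  expect_equal(lab[order(lab[, 1]), ],
               cbind(c(5e6 - 60e3, 5e6 + 15e3), c(5e6 - 15e3, 5e6 + 60e3)))

  # a pulse entirely before activation labels nothing
  cell$origin_times[[1]] <- 50
  expect_equal(nrow(label_pulse(cell, 1, c(10, 40), cfg)), 0L)
})

test_that("consecutive pulses label disjoint sets whose union is the span", {
  cfg <- tiny_config()
  set.seed(52)
  cell <- simulate_cell(cfg)
  pulses <- cfg$pulses
  labs <- lapply(pulses, function(p) label_pulse(cell, 1, p, cfg))
  # pairwise disjoint
  for (i in 1:3) for (j in (i + 1):4) {
    a <- labs[[i]]; b <- labs[[j]]
    for (k in seq_len(nrow(a)))
      expect_true(all(b[, 1] >= a[k, 2] | b[, 2] <= a[k, 1]))
  }
  # union = replicated(t_last) \ replicated(t_first)
  t_first <- pulses[[1]][1]; t_last <- pulses[[4]][2]
  span <- diff_intervals(replicated_intervals(cell, 1, t_last, cfg),
                         replicated_intervals(cell, 1, t_first, cfg))
  got <- merge_intervals(do.call(rbind, labs))
  expect_equal(got, span, tolerance = 1e-9)
})

test_that("efficiency zero silences a cluster in every cell", {
  cfg <- tiny_config(n_cells = 20)
  cfg$clusters$efficiency <- 1e-12   # effectively zero, passes validation
  sim <- simulate_edu_seq(cfg, seed = 53)
  expect_true(all(is.na(sim$truth$act_times)))
  expect_true(all(sim$truth$labelled_fraction[[1]]$chrT$values == 0))
})

test_that("labelled fractions stay in [0, 1] and Poisson sampling is calibrated", {
  bm <- make_benchmark_suite("basic")
  cfg <- bm$config
  cfg$n_cells <- 30
  sim <- simulate_edu_seq(cfg, seed = 54)
  for (p in seq_along(sim$P)) {
    for (ch in names(cfg$chrom_lengths)) {
      lf <- sim$truth$labelled_fraction[[p]][[ch]]$values
      expect_true(all(lf >= 0 & lf <= 1))
    }
  }
  # per-bin Poisson mean over replicates within 3 SE of the expectation
  cfg2 <- tiny_config()
  cfg2$read_depth <- 2; cfg2$background_rate <- 5
  set.seed(55)
  cell_fixed <- simulate_edu_seq(cfg2, seed = 55)
  lambda <- cfg2$read_depth *
    cell_fixed$truth$labelled_fraction[[1]]$chrT$values * 50e3 / 1000 /
    1 * 1 + cfg2$background_rate
  # resample P many times for the same underlying cells is not exposed;
  # instead check the realised counts against lambda in aggregate
  counts <- cell_fixed$P[[1]]$chrT$values
  z <- (sum(counts) - sum(lambda)) / sqrt(sum(lambda))
  expect_lt(abs(z), 4)
})

test_that("pure-background simulation recovers the expected r", {
  dom <- timing_domains(data.frame(chrom = "chrT", start = 0, end = 20e6,
                                   label = "late"))
  clusters <- data.frame(chrom = "chrT", centre = 10e6, width = 500e3,
                         n_origins = 5, t_act_mean = 0, t_act_sd = 0,
                         efficiency = 1e-12)
  cfg <- sim_config(c(chrT = 20e6), 50e3, dom, clusters,
                    n_cells = 5, read_depth = 0, background_rate = 10,
                    control_depth = 40)
  sim <- simulate_edu_seq(cfg, seed = 56)
  P <- normalize_rpm(sim$P[[1]])
  C <- normalize_rpm(sim$C[[1]])
  # after RPM scaling both tracks are uniform in expectation, so r = 1
  # ratio of sums is the exact estimator here; the ratio mode is skewed
  # low at these Poisson counts (the ratio distribution is right-skewed)
  r_cis <- estimate_r(P$chrT, C$chrT, rep(TRUE, 400), "cis")
  expect_lt(abs(r_cis - 1), 0.02)
  r_mode <- estimate_r(P$chrT, C$chrT, rep(TRUE, 400), "mode")
  expect_lt(abs(r_mode - 1), 0.25)
})

test_that("domino coupling orders effective activation means along groups", {
  bm <- make_benchmark_suite("domino_coupled", n_groups = 12)
  sim <- simulate_edu_seq(bm$config, seed = 57)
  ct <- sim$truth$cluster_table
  for (ch in unique(ct$chrom)) {
    d <- ct[ct$chrom == ch, ]
    d <- d[order(d$centre), ]
    run <- cumsum(c(1, diff(d$centre) >= 1.6e6))
    for (g in split(d$effective_t_act_mean, run)) {
      if (length(g) < 2) next
      expect_true(all(diff(g) > 0) || all(diff(g) < 0))
    }
  }
  # without coupling the means are untouched
  bm0 <- make_benchmark_suite("domino_null", n_groups = 12)
  sim0 <- simulate_edu_seq(bm0$config, seed = 57)
  expect_equal(sim0$truth$cluster_table$effective_t_act_mean,
               sim0$truth$cluster_table$t_act_mean)
})

test_that("simulations are reproducible under a fixed seed", {
  bm <- make_benchmark_suite("basic")
  cfg <- bm$config
  cfg$n_cells <- 10
  a <- simulate_edu_seq(cfg, seed = 58)
  b <- simulate_edu_seq(cfg, seed = 58)
  expect_identical(a$P[[1]]$chrS1$values, b$P[[1]]$chrS1$values)
  expect_identical(a$truth$entry_times, b$truth$entry_times)
  c_ <- simulate_edu_seq(cfg, seed = 59)
  expect_false(identical(a$P[[1]]$chrS1$values, c_$P[[1]]$chrS1$values))
})

test_that("an isolated synchronous cluster yields a flat-topped profile", {
  # central plateau flatter than the shoulders: compare variances of the
  # expected labelled fraction inside vs just outside the cluster core
  cfg <- tiny_config(n_cells = 200, origin_jitter_sd = 2)
  cfg$clusters$t_act_sd <- 5
  sim <- simulate_edu_seq(cfg, seed = 60)
  lf <- sim$truth$labelled_fraction[[1]]$chrT$values
  mid <- track_midpoints(sim$truth$labelled_fraction[[1]]$chrT)
  core <- lf[abs(mid - 5e6) < 150e3]
  shoulder <- lf[abs(mid - 5e6) >= 150e3 & abs(mid - 5e6) < 350e3]
  expect_gt(mean(core), mean(shoulder))
  expect_lt(stats::var(core), stats::var(shoulder))
})

test_that("unknown presets and invalid configs are rejected", {
  expect_error(make_benchmark_suite("nope"))
  dom <- timing_domains(data.frame(chrom = "chrT", start = 0, end = 1e6,
                                   label = "early"))
  cl <- data.frame(chrom = "chrT", centre = 0.9e6, width = 500e3,
                   n_origins = 5, t_act_mean = 0, t_act_sd = 0,
                   efficiency = 1)
  expect_error(sim_config(c(chrT = 1e6), 50e3, dom, cl), "beyond")
  cl$centre <- 0.5e6; cl$n_origins <- 15
  expect_error(sim_config(c(chrT = 1e6), 50e3, dom, cl), "n_origins")
  cl$n_origins <- 5; cl$efficiency <- 1.4
  expect_error(sim_config(c(chrT = 1e6), 50e3, dom, cl), "efficiency")
})
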