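# independent brute-force oracle for the adjacency metric, written directly
# from the component definitions
oracle_metric <- function(x) {
  n <- length(x)
  adfa <- mean(abs(diff(x)))
  adfsv <- (max(x) - min(x)) / (n - 1)
  pairs <- combn(n, 2)
  madfap <- mean(abs(x[pairs[1, ]] - x[pairs[2, ]]))
  1 - (adfa - adfsv) / (madfap - adfsv)
}

perms_of <- function(x) {
  n <- length(x)
  if (n == 1) return(matrix(x, 1, 1))
  do.call(rbind, lapply(seq_len(n), function(i)
    cbind(x[i], perms_of(x[-i]))))
}

test_that("grouping splits at gaps of 1.6 Mbp and at domain boundaries", {
  dom <- timing_domains(data.frame(chrom = "chr1", start = c(0, 6.2e6),
                                   end = c(6e6, 20e6),
                                   label = c("early", "early")))
  rcds <- data.frame(chrom = "chr1",
                     position = c(0.5e6, 1.5e6, 3.3e6, 10.5e6),
                     replication_peak_height = c(5, 9, 2, 4),
                     stringsAsFactors = FALSE)
  rcds$timing_domain_id <- domain_at(dom, rcds$chrom, rcds$position)
  g <- form_groups(rcds)
  sizes <- sort(vapply(g, function(x) x$n, 0L))
  expect_equal(sizes, c(1L, 1L, 2L))
  # two nearby RCDs in different domains stay in different groups
  rcds2 <- data.frame(chrom = "chr1", position = c(5.5e6, 6.5e6),
                      replication_peak_height = c(1, 2))
  rcds2$timing_domain_id <- domain_at(dom, rcds2$chrom, rcds2$position)
  expect_length(form_groups(rcds2), 2L)
  # exactly 1.6 Mbp apart does not group (strict less-than)
  rcds3 <- data.frame(chrom = "chr1", position = c(1e6, 2.6e6),
                      replication_peak_height = c(1, 2),
                      timing_domain_id = "d")
  expect_length(form_groups(rcds3), 2L)
})

test_that("permutation classes canonicalise under reversal", {
  expect_equal(classify_permutation(c(5, 9, 2)), "2-1-3")
  expect_equal(classify_permutation(c(2, 9, 5)), "2-1-3")
  expect_equal(classify_permutation(c(1, 2, 3)), "1-2-3")
  expect_equal(classify_permutation(c(3, 2, 1)), "1-2-3")
  expect_length(permutation_classes(3), 3L)
  expect_length(permutation_classes(4), 12L)
  expect_error(classify_permutation(c(1, 2)), "3 or 4")
  expect_warning(classify_permutation(c(2, 2, 1)), "tied")

  # every permutation of 4 distinct heights maps into the 12 classes, and
  # reversal never changes the class
  p <- perms_of(c(4, 7, 1, 9))
  cls <- apply(p, 1, classify_permutation)
  expect_true(all(cls %in% permutation_classes(4)))
  cls_rev <- apply(p[, 4:1], 1, classify_permutation)
  expect_equal(cls, cls_rev)
})

test_that("class frequencies sum to 100 and are uniform under iid heights", {
  set.seed(41)
  groups <- lapply(1:2000, function(i) {
    structure(list(members = NULL, heights = runif(3), n = 3L,
                   timing_domain_id = "d"), class = "rcd_group")
  })
  freq <- permutation_frequencies(list(groups, groups), 3)
  expect_equal(sum(freq$pct_t1), 100)
  expect_equal(sum(freq$pct_t2), 100)
  # 3 * MC standard error around 33.33
  se <- sqrt(100 / 3 * (100 - 100 / 3) / 2000)
  expect_true(all(abs(freq$mean_pct - 100 / 3) < 3 * se))

  # perfectly ordered groups land entirely in class 1-2-3
  ordered <- lapply(1:50, function(i) {
    structure(list(heights = c(3, 2, 1) + i, n = 3L), class = "rcd_group")
  })
  fo <- permutation_frequencies(list(ordered), 3)
  expect_equal(fo$pct_t1[fo$class == "1-2-3"], 100)
})

test_that("adjacency metric components match the hand-derived oracle", {
  m <- adjacent_value_similarity(c(1, 2, 3, 4))
  expect_equal(m$adfa, 1)
  expect_equal(m$adfsv, 1)
  expect_equal(m$value, 1)

  # the maximally interleaved array: each component from its definition
  m2 <- adjacent_value_similarity(c(3, 1, 4, 2))
  expect_equal(m2$adfa, 7 / 3)
  expect_equal(m2$adfsv, 1)
  expect_equal(m2$madfap, 5 / 3)
  expect_equal(m2$value, -1)
  expect_equal(m2$value, oracle_metric(c(3, 1, 4, 2)))

  expect_error(adjacent_value_similarity(5), "at least 2")
  # constant arrays are undefined (MADFAP = ADFSV = 0)
  expect_false(adjacent_value_similarity(c(2, 2, 2, 2))$defined)
  # for n = 2, ADFA = ADFSV = MADFAP: always undefined
  expect_false(adjacent_value_similarity(c(1, 5))$defined)
  # n = 3 is defined but bounded below at -0.5: random and anti-ordered
  # are not separable (why 3-groups are excluded from weighted reports)
  p3 <- perms_of(c(1, 2, 3))
  v3 <- apply(p3, 1, function(z) adjacent_value_similarity(z)$value)
  expect_equal(sort(unique(round(v3, 9))), c(-0.5, 1))
})

test_that("metric mean over all orderings is exactly zero", {
  p <- perms_of(c(1, 2, 3, 4, 5))
  vals <- apply(p, 1, function(x) adjacent_value_similarity(x)$value)
  expect_equal(nrow(p), 120)
  expect_equal(mean(vals), 0, tolerance = 1e-12)
  expect_equal(vals, apply(p, 1, oracle_metric))
})

test_that("metric equals 1 exactly for monotone distinct arrays", {
  set.seed(42)
  for (n in 4:6) {
    x <- sort(sample(1:50, n))
    expect_equal(adjacent_value_similarity(x)$value, 1)
    expect_equal(adjacent_value_similarity(rev(x))$value, 1)
    # and only for monotone arrangements
    p <- perms_of(x)
    vals <- apply(p, 1, function(z) adjacent_value_similarity(z)$value)
    mono <- apply(p, 1, function(z) all(diff(z) > 0) || all(diff(z) < 0))
    expect_true(all(abs(vals[mono] - 1) < 1e-12))
    expect_true(all(vals[!mono] < 1 - 1e-12))
  }
})

test_that("metric is invariant under reversal and affine transforms", {
  set.seed(43)
  for (i in 1:25) {
    x <- runif(sample(4:8, 1))
    v <- adjacent_value_similarity(x)$value
    expect_equal(adjacent_value_similarity(rev(x))$value, v)
    a <- runif(1, 0.1, 5) * sample(c(-1, 1), 1)
    b <- rnorm(1, 0, 10)
    expect_equal(adjacent_value_similarity(a * x + b)$value, v,
                 tolerance = 1e-9)
  }
})

test_that("weighted reporting replicates each group's value n-1 times", {
  g5 <- structure(list(heights = c(1, 3, 2, 5, 4), n = 5L),
                  class = "rcd_group")
  g4 <- structure(list(heights = c(4, 3, 2, 1), n = 4L),
                  class = "rcd_group")
  g3 <- structure(list(heights = c(1, 3, 2), n = 3L), class = "rcd_group")
  v5 <- adjacent_value_similarity(g5)$value
  rep_ <- weighted_similarity_report(list(g5, g4, g3))
  expect_equal(rep_$n_groups, 2L)      # the 3-group is excluded
  expect_equal(sort(unique(rep_$weighted_values)), sort(c(v5, 1)))
  expect_equal(length(rep_$weighted_values), 4L + 3L)
  expect_equal(sum(rep_$weighted_values == v5), 4L)
  expect_error(weighted_similarity_report(list(g3)), "no groups")
})

test_that("one-sample t matches the textbook computation", {
  tt <- one_sample_t(c(2, 4, 6))
  expect_equal(tt$t, 3.4641, tolerance = 1e-4)
  expect_equal(tt$df, 2)
  expect_equal(tt$p, 0.0742, tolerance = 1e-3)
  # agrees with stats::t.test
  ref <- t.test(c(2, 4, 6))
  expect_equal(tt$p, ref$p.value)
  expect_equal(unname(tt$ci), unname(as.numeric(ref$conf.int)))

  expect_true(one_sample_t(c(0, 0, 0, 0))$degenerate)
  expect_equal(one_sample_t(c(0, 0, 0, 0))$p, 1)
  # CI contains the mean and widens under scaling
  x <- c(1, 3, 2, 5)
  t1 <- one_sample_t(x); t2 <- one_sample_t(10 * x)
  expect_true(t1$ci[1] <= t1$mean && t1$mean <= t1$ci[2])
  expect_gt(diff(t2$ci), diff(t1$ci))
})
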