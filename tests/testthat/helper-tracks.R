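# builders shared across test files

make_track <- function(values, chrom = "chr1", bin = 50e3, role = "signal",
                       len = NULL) {
  binned_track(values, chrom, bin, role = role, chrom_length = len)
}

# one flat-topped bump (plateau + gaussian shoulders) with the requested
# full width at half maximum, sampled on the bin grid
flat_bump <- function(n_bins, bin, centre, half_max_width, shoulder_sd,
                      amplitude = 1) {
  mid <- (seq_len(n_bins) - 0.5) * bin
  plateau <- half_max_width - 2 * sqrt(2 * log(2)) * shoulder_sd
  stopifnot(plateau > 0)
  d <- pmax(abs(mid - centre) - plateau / 2, 0)
  amplitude * exp(-d^2 / (2 * shoulder_sd^2))
}

# a small genome of flat-topped clusters for matched-filter tests
bump_genome <- function(half_max_width, spacing = 1.2e6, bin = 50e3,
                        n_bins = 2000, shoulder_sd = 80e3, seed = 1) {
  set.seed(seed)
  x <- numeric(n_bins)
  centres <- seq(5e6, (n_bins * bin) - 5e6, by = spacing)
  for (p in centres)
    x <- x + flat_bump(n_bins, bin, p, half_max_width, shoulder_sd,
                       amplitude = runif(1, 0.5, 1.5))
  list(track = make_track(x, bin = bin), centres = centres)
}

expect_equal_track <- function(a, b) {
  expect_equal(a$values, b$values)
  expect_identical(a$chrom, b$chrom)
  expect_equal(a$bin_size, b$bin_size)
}
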