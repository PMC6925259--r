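test_that("adjust_signal removes covariate structure", {
  set.seed(1)
  gc <- runif(300, 0.3, 0.7)
  # signal an exact step function of GC, constant within each GC decile:
  # the piecewise-constant fit reproduces it and residuals vanish
  br <- quantile(gc, seq(0, 1, 0.1))
  lev <- seq(-0.4, 0.5, 0.1)
  sig <- lev[as.integer(cut(gc, br, include.lowest = TRUE))]
  track <- signal_track(sprintf("p%03d", 1:300), "1", sort(sample.int(1e6, 300)),
                        sig, gc, "II")
  res <- adjust_signal(track, n_gc_bins = 10L)
  expect_lt(max(abs(res)), 1e-10)

  # covariate-independent signal: adjustment is mean-centering
  x <- rnorm(300)
  track2 <- signal_track(sprintf("p%03d", 1:300), "1",
                         sort(sample.int(1e6, 300)), x, rep(0.5, 300), "II")
  expect_warning(res2 <- adjust_signal(track2), "mean-centering")
  expect_equal(res2, x - mean(x))
})

test_that("a planted CN step survives GC adjustment while the GC wave is removed", {
  set.seed(2)
  n <- 400
  gc <- runif(n, 0.3, 0.7)
  wave <- 0.5 * sin(6 * pi * gc)
  step <- c(rep(0, 200), rep(0.5, 200))
  track <- signal_track(sprintf("p%03d", 1:n), "1", sort(sample.int(1e7, n)),
                        wave + step + rnorm(n, 0, 0.05), gc, "II")
  res <- adjust_signal(track, n_gc_bins = 20L)
  expect_lt(abs(diff(c(mean(res[1:200]), mean(res[201:400]))) - 0.5), 0.06)
  # most of the GC wave's variance is removed while the step persists
  expect_lt(sd(res - step), 0.4 * sd(wave))
})

test_that("segment_cbs handles degenerate and noiseless inputs", {
  expect_equal(nrow(segment_cbs(rep(0.1, 50), n_perm = 100, seed = 1)), 1L)
  expect_error(segment_cbs(rnorm(50), n_perm = 50), "at least 100")
  expect_error(segment_cbs(rnorm(3)), "at least 4 probes")

  # noiseless step: exact breakpoint and exact segment means
  x <- c(rep(0, 100), rep(0.5, 100))
  seg <- segment_cbs(x, n_perm = 100, seed = 1)
  expect_equal(nrow(seg), 2L)
  expect_equal(seg$end[1], 100L)
  expect_equal(seg$mean, c(0, 0.5))
})

test_that("the max-arc scan agrees with an exhaustive t-test oracle", {
  set.seed(3)
  for (case in 1:5) {
    n <- sample(12:30, 1)
    x <- rnorm(n, 0, 0.3)
    k <- sample(4:(n - 8), 1)
    x[(k + 1):(k + 4)] <- x[(k + 1):(k + 4)] + 1.5
    got <- pdxfidelity:::.cbs_scan(x, 2L)
    want <- oracle_max_arc(x, 2L)
    expect_equal(c(got$i, got$j), c(want$i, want$j))
    if (is.finite(want$stat)) expect_equal(got$stat, want$stat, tolerance = 1e-8)
  }
})

test_that("small-instance segmentation matches the recursive oracle", {
  set.seed(4)
  cases <- list(
    c(rep(0, 10), rep(2, 10), rep(0, 10)) + rnorm(30, 0, 0.1),
    c(rep(0, 14), rep(1.5, 16)) + rnorm(30, 0, 0.1),
    rnorm(30, 0, 0.1))
  for (x in cases) {
    seg <- segment_cbs(x, n_perm = 500, seed = 5)
    expect_equal(profile_breaks(seg), oracle_segment(x, n_perm = 500))
  }
})

test_that("pure noise rarely splits at alpha 0.01", {
  splits <- vapply(1:20, function(s) {
    set.seed(100 + s)
    nrow(segment_cbs(rnorm(80), alpha = 0.01, n_perm = 1000, seed = s)) - 1L
  }, integer(1))
  expect_lte(mean(splits > 0), 0.05 + 2 * sqrt(0.05 * 0.95 / 20))
})

test_that("planted events are recovered within a 2-probe boundary error", {
  hits <- vapply(1:10, function(s) {
    set.seed(200 + s)
    x <- rnorm(300, 0, 0.1)
    x[101:140] <- x[101:140] + 0.4
    seg <- segment_cbs(x, n_perm = 500, seed = s)
    br <- profile_breaks(seg)
    length(br) >= 2 &&
      min(abs(br - 100)) <= 2 && min(abs(br - 140)) <= 2
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("recenter subtracts the probe-weighted median and is idempotent", {
  mk <- function(means, sizes) {
    ends <- cumsum(sizes)
    p <- data.frame(chrom = "1", start = c(1L, head(ends, -1) + 1L),
                    end = ends, n_probes = sizes, mean = means)
    class(p) <- c("segment_profile", "data.frame")
    p
  }
  one <- recenter(mk(0.3, 100L))
  expect_equal(one$mean, 0)
  # 90% of probes at 0, 10% at +0.5: the gain survives recentering intact
  two <- recenter(mk(c(0, 0.5), c(900L, 100L)))
  expect_equal(two$mean, c(0, 0.5))
  expect_equal(recenter(two)$mean, two$mean)
})

test_that("call_states applies the strict +/-0.2 rule", {
  p <- data.frame(chrom = "1", start = c(1L, 11L, 21L, 31L, 41L),
                  end = c(10L, 20L, 30L, 40L, 50L), n_probes = rep(10L, 5),
                  mean = c(-0.30, 0.25, 0.2, -0.2, 0))
  class(p) <- c("segment_profile", "data.frame")
  st <- call_states(p)
  expect_equal(as.character(st$state),
               c("loss", "gain", "neutral", "neutral", "neutral"))
})

test_that("shared_cn_fraction compares per-probe states antisymmetrically", {
  mk <- function(means, sizes) {
    ends <- cumsum(sizes)
    p <- data.frame(chrom = "1", start = c(1L, head(ends, -1) + 1L),
                    end = ends, n_probes = sizes, mean = means)
    class(p) <- c("segment_profile", "data.frame")
    call_states(p)
  }
  neutral <- mk(0, 100L)
  expect_equal(shared_cn_fraction(neutral, neutral)$shared, 1)
  expect_true(all(shared_cn_fraction(neutral, neutral)$differential == "same"))

  # xenograft with one planted deletion over 10% of probes
  xeno <- mk(c(0, -0.5, 0), c(45L, 10L, 45L))
  sh <- shared_cn_fraction(neutral, xeno)
  expect_equal(sh$shared, 0.9)
  expect_equal(sum(sh$differential == "xeno_loss_relative"), 10L)
  # swapping arguments flips loss and gain
  sw <- shared_cn_fraction(xeno, neutral)
  expect_equal(sum(sw$differential == "xeno_gain_relative"), 10L)
  expect_equal(sum(sw$differential == "xeno_loss_relative"), 0L)
})
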