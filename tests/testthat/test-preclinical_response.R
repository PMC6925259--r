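test_that("volume follows the spherical (pi/6) d^3 formula", {
  expect_equal(volume_from_diameter(1), pi / 6)
  expect_equal(round(volume_from_diameter(1), 4), 0.5236)
  expect_equal(volume_from_diameter(0), 0)
  expect_equal(volume_from_diameter(2), 8 * volume_from_diameter(1))
  expect_error(volume_from_diameter(-1), "non-negative")
})

test_that("rtv is the volume ratio to study initiation", {
  cv <- make_curve(c(0, 7, 14), c(0.25, 0.8, 1.0))
  expect_equal(rtv(cv), 4.0)
  expect_equal(rtv(make_curve(c(0, 7), c(0.3, 0.3))), 1.0)
  expect_equal(rtv(make_curve(c(0, 7), c(0.3, 0))), 0)
  expect_error(rtv(make_curve(c(0, 7), c(0, 0.3))), "positive")
  expect_equal(format_rtv(99), ">10")
  expect_equal(format_rtv(1.19), "1.19")
})

test_that("time to event interpolates the threshold crossing", {
  # V0 = 0.25, RTV-4 threshold 1.0; crossing between days 7 and 14
  cv <- make_curve(c(0, 7, 14), c(0.25, 0.8, 1.2))
  ev <- time_to_event(cv)
  expect_true(ev$event)
  expect_equal(ev$time, 7 + 7 * (1.0 - 0.8) / (1.2 - 0.8)) # 10.5
  # crossing exactly at a measurement day
  ev2 <- time_to_event(make_curve(c(0, 7, 14), c(0.25, 1.0, 1.4)))
  expect_equal(ev2$time, 7)
  # never crossing: censored at the evaluation period
  ev3 <- time_to_event(make_curve(seq(0, 84, 7), rep(0.3, 13)))
  expect_false(ev3$event)
  expect_equal(ev3$time, 84)
  # the 2.5 cm^3 size cap is an event even below RTV 4
  ev4 <- time_to_event(make_curve(c(0, 7), c(2.0, 2.6)))
  expect_true(ev4$event)
  expect_lt(ev4$time, 7)
})

test_that("KM medians and EFS T/C reproduce hand-computable cases", {
  ev_ctrl <- data.frame(time = c(10, 10, 10, 10), event = TRUE)
  ev_trt <- data.frame(time = c(40, 40, 40, 40), event = TRUE)
  expect_equal(km_median(ev_ctrl)$median, 10)
  expect_equal(efs_tc(km_median(ev_trt), km_median(ev_ctrl))$ratio, 4.0)
  # all treated censored: median ">EP", T/C a lower bound EP / control
  ev_cens <- data.frame(time = rep(84, 4), event = FALSE)
  km <- km_median(ev_cens)
  expect_equal(km$label, ">EP")
  tc <- efs_tc(km, km_median(data.frame(time = rep(12, 4), event = TRUE)),
               evaluation_period = 84)
  expect_true(tc$censored)
  expect_equal(tc$ratio, 7.0)
  expect_equal(tc$label, "> 7.0")
})

test_that("the log-rank statistic matches survival::survdiff", {
  set.seed(6)
  for (i in 1:5) {
    time <- round(rexp(12, 0.1), 2) + 1
    event <- runif(12) < 0.8
    group <- rep(c(TRUE, FALSE), each = 6)
    ours <- pdxfidelity:::logrank_stat(time, event, group)
    sd_fit <- survival::survdiff(survival::Surv(time, event) ~ group)
    expect_equal(ours, unname(sd_fit$chisq), tolerance = 1e-8)
  }
})

test_that("exact log-rank enumerates small studies and detects separation", {
  same <- data.frame(time = c(10, 20, 30, 40), event = TRUE)
  lr <- exact_logrank(same, same)
  expect_equal(lr$method, "enumeration")
  expect_equal(lr$p, 1.0)
  far <- data.frame(time = c(60, 70, 75, 80), event = TRUE)
  near <- data.frame(time = c(5, 7, 9, 11), event = TRUE)
  lr2 <- exact_logrank(far, near)
  expect_lt(lr2$p, 0.05)
})

test_that("volume T/C compares arms at the last all-control day", {
  curves <- function(vols, arm) {
    do.call(rbind, lapply(seq_along(vols), function(i) {
      data.frame(mouse_id = paste0(arm, i), day = c(0, 7, 14),
                 volume = c(0.3, 0.3, vols[i]))
    }))
  }
  ctrl <- study_arm(curves(c(1.0, 1.2, 0.8, 1.0), "c"), "control")
  same <- study_arm(curves(c(1.0, 1.2, 0.8, 1.0), "t"), "V")
  vt <- volume_tc(same, ctrl)
  expect_equal(vt$at_day, 14)
  expect_equal(vt$tc, 1.0)
  expect_equal(vt$p, 1.0)
  zero <- study_arm(curves(c(0, 0, 0, 0), "z"), "V")
  expect_equal(volume_tc(zero, ctrl)$tc, 0)
})

test_that("response classes follow their definitions with precedence", {
  # final volume < 0.10: maintained complete response
  expect_equal(as.character(classify_response(
    make_curve(c(0, 21, 42), c(0.4, 0.2, 0.05)))), "MCR")
  # dipped under 0.10 mid-study but regrew: CR, not MCR
  expect_equal(as.character(classify_response(
    make_curve(c(0, 21, 42), c(0.4, 0.08, 0.6)))), "CR")
  # >= 50% regression with measurable tumor: PR
  expect_equal(as.character(classify_response(
    make_curve(c(0, 21, 42), c(0.4, 0.15, 0.3)))), "PR")
  # progression split by the growth-delay value
  grow <- make_curve(c(0, 21, 42), c(0.4, 0.6, 1.2))
  expect_equal(as.character(classify_response(grow, growth_delay = 1.0)), "PD1")
  expect_equal(as.character(classify_response(grow, growth_delay = 2.0)), "PD2")
  expect_error(classify_response(make_curve(0, 0.4)), "at least 2")
})

test_that("median group response takes the lower class on even splits", {
  curves <- rbind(make_curve(c(0, 42), c(0.4, 1.6), "m1"),
                  make_curve(c(0, 42), c(0.4, 1.6), "m2"),
                  make_curve(c(0, 42), c(0.4, 0.05), "m3"),
                  make_curve(c(0, 42), c(0.4, 0.05), "m4"))
  arm <- study_arm(curves, "V")
  resp <- median_group_response(arm, growth_delay = 1.0)
  expect_equal(as.character(resp$calls), c("PD1", "PD1", "MCR", "MCR"))
  expect_equal(as.character(resp$median_call), "PD1")
})

test_that("median call is monotone in treatment effect", {
  kills <- c(0, 0.05, 0.15, 0.3)
  calls <- vapply(kills, function(k) {
    gs <- default_growth_spec()
    gs$X <- gs$control
    gs$X$treatment_kill_rate <- k
    spec <- cohort_spec(growth_spec = gs, seed = 21)
    arm <- simulate_growth_study(spec, "X")
    as.character(median_group_response(arm, growth_delay = 1 + 10 * k)$median_call)
  }, character(1))
  ranks <- match(calls, response_levels)
  expect_true(all(diff(ranks) >= 0))
})

test_that("a full arm report carries Table-style fields", {
  spec <- cohort_spec(seed = 30)
  ctrl <- simulate_growth_study(spec, "control")
  trt <- simulate_growth_study(spec, "VA")
  rep <- arm_response_report(trt, ctrl)
  expect_named(rep, c("model_id", "arm", "km_median", "logrank_p", "efs_tc",
                      "median_final_rtv", "volume_tc", "ranksum_p",
                      "median_response"))
  expect_equal(rep$median_response, "MCR")
  expect_lt(rep$logrank_p, 0.01)
  expect_equal(rep$median_final_rtv, "0.00")
})
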