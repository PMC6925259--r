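#' Objective response class levels, ordered from worst to best
#'
#' PD1 (progression, growth-delay value <= 1.5) < PD2 (progression,
#' growth-delay value > 1.5) < PR (>= 50 percent regression with measurable
#' tumor) < CR (tumor < 0.10 cm^3 at one or more time points) < MCR
#' (tumor < 0.10 cm^3 at end of study).
#' @export
response_levels <- c("PD1", "PD2", "PR", "CR", "MCR")

#' Study arm: growth curves for one model under one treatment
#'
#' @param curves Data frame with columns `mouse_id`, `day`, `volume`
#'   (cm^3); each mouse must start at day 0 with strictly increasing days.
#' @param arm Treatment label (e.g. `"control"`, `"V"`, `"VA"`, `"VAD"`).
#' @param model_id Xenograft model label.
#' @param evaluation_period Study length in days (default 84).
#' @param event_rtv Relative tumor volume defining an event (default 4).
#' @param size_cap Volume in cm^3 at which a mouse leaves study
#'   (default 2.5); reaching it is also an event.
#' @return Object of class `study_arm`.
#' @export
study_arm <- function(curves, arm, model_id = "model",
                      evaluation_period = 84, event_rtv = 4, size_cap = 2.5) {
  stopifnot(is.data.frame(curves),
            all(c("mouse_id", "day", "volume") %in% names(curves)))
  if (nrow(curves) == 0L) stop("empty study arm")
  for (m in unique(curves$mouse_id)) {
    d <- curves$day[curves$mouse_id == m]
    if (d[1L] != 0) stop("each curve must start at day 0")
    if (any(diff(d) <= 0)) stop("days must be strictly increasing")
  }
  if (any(curves$volume < 0)) stop("volumes must be non-negative")
  structure(list(curves = curves, arm = arm, model_id = model_id,
                 evaluation_period = evaluation_period,
                 event_rtv = event_rtv, size_cap = size_cap),
            class = "study_arm")
}

arm_mice <- function(arm) unique(arm$curves$mouse_id)

arm_curve <- function(arm, mouse) {
  cv <- arm$curves[arm$curves$mouse_id == mouse, c("day", "volume")]
  cv[order(cv$day), , drop = FALSE]
}

#' Tumor volume from mean diameter
#'
#' Spherical-tumor volume `(pi/6) d^3` for a mean diameter `d` in cm.
#'
#' @param d Mean diameter in cm (non-negative).
#' @return Volume in cm^3.
#' @examples
#' volume_from_diameter(1) # 0.5236
#' @export
volume_from_diameter <- function(d) {
  if (any(d < 0)) stop("diameter must be non-negative")
  (pi / 6) * d^3
}

# linearly interpolated volume at an arbitrary day within the series
curve_volume_at <- function(curve, day) {
  if (day < min(curve$day) || day > max(curve$day)) {
    stop("day ", day, " outside the measured range")
  }
  stats::approx(curve$day, curve$volume, xout = day)$y
}

#' Relative tumor volume
#'
#' Ratio of the tumor volume at `day` (default: last recorded day, the
#' "final RTV") to the volume at study initiation (day 0).
#'
#' @param curve Data frame with `day`, `volume` for one mouse.
#' @param day Day at which to evaluate; `NULL` for the last recorded day.
#' @return RTV as a ratio.
#' @export
rtv <- function(curve, day = NULL) {
  v0 <- curve$volume[curve$day == 0]
  if (length(v0) != 1L || v0 <= 0) stop("day-0 volume must be positive")
  v <- if (is.null(day)) curve$volume[nrow(curve)] else curve_volume_at(curve, day)
  v / v0
}

#' Table-style formatting of a median RTV
#'
#' Values above 10 are reported as `">10"`.
#' @param x Numeric RTV.
#' @return Character label.
#' @export
format_rtv <- function(x) if (x > 10) ">10" else formatC(x, format = "f", digits = 2)

#' Interpolated time to event for one growth curve
#'
#' An event occurs when the tumor first reaches either `event_rtv` times
#' its day-0 volume or the absolute `size_cap`. The crossing day is
#' linearly interpolated between the bracketing measurement days. Curves
#' that never cross are censored at the evaluation period (or at their last
#' measurement when shorter).
#'
#' @param curve Data frame with `day`, `volume` for one mouse.
#' @param event_rtv RTV defining an event (default 4).
#' @param size_cap Absolute event volume in cm^3 (default 2.5).
#' @param evaluation_period Days (default 84).
#' @return List with `time` (days) and `event` (logical).
#' @export
time_to_event <- function(curve, event_rtv = 4, size_cap = 2.5,
                          evaluation_period = 84) {
  v0 <- curve$volume[curve$day == 0]
  if (length(v0) != 1L || v0 <= 0) stop("day-0 volume must be positive")
  threshold <- min(event_rtv * v0, size_cap)
  hit <- which(curve$volume >= threshold)
  if (length(hit) == 0L) {
    return(list(time = min(max(curve$day), evaluation_period), event = FALSE))
  }
  k <- hit[1L]
  t_ev <- if (k == 1L) {
    curve$day[1L]
  } else {
    d0 <- curve$day[k - 1L]; d1 <- curve$day[k]
    y0 <- curve$volume[k - 1L]; y1 <- curve$volume[k]
    d0 + (d1 - d0) * (threshold - y0) / (y1 - y0)
  }
  if (t_ev > evaluation_period) {
    list(time = evaluation_period, event = FALSE)
  } else {
    list(time = t_ev, event = TRUE)
  }
}

# interpolated event times and statuses for every mouse in an arm
arm_events <- function(arm) {
  mice <- arm_mice(arm)
  res <- lapply(mice, function(m) {
    time_to_event(arm_curve(arm, m), arm$event_rtv, arm$size_cap,
                  arm$evaluation_period)
  })
  data.frame(mouse_id = mice,
             time = vapply(res, `[[`, numeric(1), "time"),
             event = vapply(res, `[[`, logical(1), "event"),
             stringsAsFactors = FALSE)
}

#' Kaplan-Meier median time to event for a study arm
#'
#' The KM median of the interpolated event times; when the survival curve
#' never falls to 0.5 or below within the evaluation period the median is
#' reported as `">EP"` (`Inf` numerically).
#'
#' @param arm A [study_arm], or a data frame with `time` and `event`.
#' @return List with `median` (days, `Inf` when not reached) and `label`.
#' @export
km_median <- function(arm) {
  ev <- if (inherits(arm, "study_arm")) arm_events(arm) else arm
  if (nrow(ev) < 2L) stop("need at least 2 mice per arm")
  fit <- survival::survfit(survival::Surv(ev$time, ev$event) ~ 1)
  med <- unname(summary(fit)$table["median"])
  if (is.na(med)) {
    list(median = Inf, label = ">EP")
  } else {
    list(median = med, label = formatC(med, format = "f", digits = 2))
  }
}

#' Event-free survival T/C ratio (growth-delay value)
#'
#' Ratio of treated to control KM median time to event. When the treated
#' median exceeds the evaluation period the ratio is reported as a lower
#' bound `"> x"` computed with the evaluation period in the numerator.
#'
#' @param treated,control [study_arm] objects (or `km_median()` results).
#' @param evaluation_period Days used for the lower bound (default taken
#'   from the treated arm when available, else 84).
#' @return List with `ratio` (numeric; lower bound when censored),
#'   `label`, and `censored` (logical).
#' @export
efs_tc <- function(treated, control, evaluation_period = NULL) {
  if (inherits(treated, "study_arm")) {
    if (is.null(evaluation_period)) evaluation_period <- treated$evaluation_period
    treated <- km_median(treated)
  }
  if (inherits(control, "study_arm")) control <- km_median(control)
  if (is.null(evaluation_period)) evaluation_period <- 84
  if (!is.finite(control$median)) {
    stop("control arm median time to event not reached; EFS T/C undefined")
  }
  if (!is.finite(treated$median)) {
    r <- evaluation_period / control$median
    list(ratio = r, label = paste0("> ", formatC(r, format = "f", digits = 1)),
         censored = TRUE)
  } else {
    r <- treated$median / control$median
    list(ratio = r, label = formatC(r, format = "f", digits = 1),
         censored = FALSE)
  }
}

# log-rank (Mantel-Haenszel) chi-square statistic; group is logical
# (TRUE = treated)
logrank_stat <- function(time, event, group) {
  o_e <- 0; v <- 0
  for (tt in sort(unique(time[event]))) {
    at_risk <- time >= tt
    n <- sum(at_risk)
    n1 <- sum(at_risk & group)
    d <- sum(event & time == tt)
    d1 <- sum(event & time == tt & group)
    o_e <- o_e + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  if (v <= 0) 0 else o_e^2 / v
}

#' Exact log-rank test
#'
#' Two-sided log-rank test comparing event-free survival between a treated
#' and a control arm. For 16 or fewer total mice the reference distribution
#' is the complete enumeration of group relabelings; for larger studies at
#' least 10,000 random relabelings are used with a fixed seed.
#'
#' @param treated,control [study_arm] objects or data frames with
#'   `time`, `event`.
#' @param n_perm Number of relabelings when enumeration is infeasible.
#' @param seed Seed for the relabeling stream.
#' @return List with `p`, `stat` (chi-square), and `method`
#'   (`"enumeration"` or `"permutation"`).
#' @export
exact_logrank <- function(treated, control, n_perm = 10000L, seed = 1L) {
  et <- if (inherits(treated, "study_arm")) arm_events(treated) else treated
  ec <- if (inherits(control, "study_arm")) arm_events(control) else control
  if (nrow(et) == 0L || nrow(ec) == 0L) stop("empty arm")
  time <- c(et$time, ec$time)
  event <- c(et$event, ec$event)
  n <- length(time)
  n1 <- nrow(et)
  obs <- logrank_stat(time, event, seq_len(n) <= n1)
  eps <- 1e-10
  if (choose(n, n1) <= 13000) {
    labs <- combn(n, n1)
    stats <- apply(labs, 2L, function(ix) {
      logrank_stat(time, event, seq_len(n) %in% ix)
    })
    p <- mean(stats >= obs - eps)
    method <- "enumeration"
  } else {
    set.seed(seed)
    stats <- replicate(n_perm, {
      ix <- sample.int(n, n1)
      logrank_stat(time, event, seq_len(n) %in% ix)
    })
    p <- (1 + sum(stats >= obs - eps)) / (1 + n_perm)
    method <- "permutation"
  }
  list(p = p, stat = obs, method = method)
}

#' Tumor volume T/C ratio with rank-sum test
#'
#' Ratio of mean treated to mean control tumor volume at a comparison day
#' (default: the last day at which every control mouse remains on study),
#' with a two-sided exact Wilcoxon rank-sum p-value.
#'
#' @param treated,control [study_arm] objects.
#' @param at_day Comparison day; `NULL` for the default.
#' @return List with `tc`, `p`, `at_day`, and the per-mouse volumes.
#' @export
volume_tc <- function(treated, control, at_day = NULL) {
  if (is.null(at_day)) {
    at_day <- min(vapply(arm_mice(control), function(m) {
      max(arm_curve(control, m)$day)
    }, numeric(1)))
  }
  vols <- function(arm) vapply(arm_mice(arm), function(m) {
    curve_volume_at(arm_curve(arm, m), at_day)
  }, numeric(1))
  vt <- vols(treated)
  vc <- vols(control)
  if (mean(vc) <= 0) stop("control mean volume is zero at the comparison day")
  p <- suppressWarnings(wilcox.test(vt, vc, exact = TRUE)$p.value)
  list(tc = mean(vt) / mean(vc), p = p, at_day = at_day,
       treated_volumes = vt, control_volumes = vc)
}

#' Objective response call for one mouse
#'
#' Applies the response definitions with precedence MCR > CR > PR > PD:
#' MCR when the final volume is below 0.10 cm^3; CR when the volume falls
#' below 0.10 cm^3 at any time point (but regrows by study end); PR when
#' the volume regresses by at least 50 percent while remaining measurable
#' (>= 0.10 cm^3); otherwise progressive disease, split into PD1
#' (growth-delay value <= 1.5) and PD2 (> 1.5). The growth-delay value is
#' the arm-level EFS T/C ratio.
#'
#' @param curve Data frame with `day`, `volume` for one mouse (>= 2 rows).
#' @param growth_delay Arm-level EFS T/C ratio (numeric; a censored lower
#'   bound is acceptable). `NA` maps progression to PD1.
#' @param measurable Measurability threshold in cm^3 (default 0.10).
#' @return Ordered factor with levels `PD1 < PD2 < PR < CR < MCR`.
#' @export
classify_response <- function(curve, growth_delay = NA_real_,
                              measurable = 0.10) {
  if (nrow(curve) < 2L) stop("need at least 2 measurements")
  v0 <- curve$volume[curve$day == 0]
  if (length(v0) != 1L || v0 <= 0) stop("day-0 volume must be positive")
  final <- curve$volume[nrow(curve)]
  minv <- min(curve$volume)
  call <- if (final < measurable) {
    "MCR"
  } else if (minv < measurable) {
    "CR"
  } else if (minv <= 0.5 * v0) {
    "PR"
  } else if (!is.na(growth_delay) && growth_delay > 1.5) {
    "PD2"
  } else {
    "PD1"
  }
  factor(call, levels = response_levels, ordered = TRUE)
}

#' Median group response for a study arm
#'
#' Per-mouse response calls are ranked PD1 < PD2 < PR < CR < MCR and the
#' arm is assigned the lower median call (ties on an even split resolve to
#' the lower class).
#'
#' @param arm A [study_arm].
#' @param growth_delay Arm-level EFS T/C ratio passed to
#'   [classify_response()].
#' @return List with `median_call` and `calls` (per mouse).
#' @export
median_group_response <- function(arm, growth_delay = NA_real_) {
  calls <- lapply(arm_mice(arm), function(m) {
    classify_response(arm_curve(arm, m), growth_delay)
  })
  calls <- factor(vapply(calls, as.character, character(1)),
                  levels = response_levels, ordered = TRUE)
  sorted <- sort(calls)
  med <- sorted[floor((length(sorted) + 1) / 2)]
  list(median_call = med, calls = setNames(calls, arm_mice(arm)))
}

#' Table-style response report for one treated arm versus control
#'
#' Assembles the standard preclinical testing metrics: KM median time to
#' event, exact log-rank p, EFS T/C, median final RTV, tumor volume T/C
#' with rank-sum p, and the median group response.
#'
#' @param treated,control [study_arm] objects.
#' @param seed Seed for the log-rank permutation fallback.
#' @return One-row data frame.
#' @export
arm_response_report <- function(treated, control, seed = 1L) {
  kmt <- km_median(treated)
  tc <- efs_tc(treated, control, treated$evaluation_period)
  lr <- exact_logrank(treated, control, seed = seed)
  vtc <- volume_tc(treated, control)
  med_rtv <- median(vapply(arm_mice(treated), function(m) {
    rtv(arm_curve(treated, m))
  }, numeric(1)))
  resp <- median_group_response(treated, tc$ratio)
  data.frame(model_id = treated$model_id, arm = treated$arm,
             km_median = kmt$label, logrank_p = lr$p,
             efs_tc = tc$label, median_final_rtv = format_rtv(med_rtv),
             volume_tc = round(vtc$tc, 2), ranksum_p = vtc$p,
             median_response = as.character(resp$median_call),
             stringsAsFactors = FALSE)
}
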