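# Independent oracles used across tests. These deliberately avoid the
# package's internal code paths: statistics come from stats::t.test and
# plain loops.

# exhaustive max circular two-sample t over all arcs, via t.test
oracle_max_arc <- function(x, min_width = 2L) {
  n <- length(x)
  best <- -Inf
  best_ij <- c(NA, NA)
  for (i in 0:(n - min_width)) {
    for (j in (i + min_width):n) {
      k <- j - i
      if (n - k < min_width) next
      inside <- x[(i + 1):j]
      outside <- x[-((i + 1):j)]
      stat <- if (sd(inside) == 0 && sd(outside) == 0) {
        if (abs(mean(inside) - mean(outside)) > 1e-12) Inf else 0
      } else {
        unname(t.test(inside, outside, var.equal = TRUE)$statistic^2)
      }
      if (is.nan(stat)) stat <- 0
      if (stat > best) {
        best <- stat
        best_ij <- c(i, j)
      }
    }
  }
  list(stat = best, i = best_ij[1], j = best_ij[2])
}

# recursive exhaustive segmentation with its own permutation decision;
# intended for instances where the split decision is unambiguous
oracle_segment <- function(x, alpha = 0.01, n_perm = 200L, min_width = 2L) {
  breaks <- integer(0)
  recurse <- function(lo, hi) {
    n <- hi - lo + 1L
    if (n < max(4L, 2L * min_width)) return(invisible(NULL))
    seg <- x[lo:hi]
    obs <- oracle_max_arc(seg, min_width)
    perm <- replicate(n_perm, oracle_max_arc(sample(seg), min_width)$stat)
    p <- mean(perm >= obs$stat - 1e-12)
    if (p >= alpha) return(invisible(NULL))
    b <- sort(setdiff(unique(c(obs$i, obs$j)), c(0L, n)))
    breaks <<- c(breaks, lo - 1L + b)
    bounds <- c(lo, lo + b, hi + 1L)
    for (k in seq_len(length(bounds) - 1L)) {
      recurse(bounds[k], bounds[k + 1L] - 1L)
    }
  }
  recurse(1L, length(x))
  sort(unique(breaks)) # positions b: boundary between probes b and b+1
}

# breakpoints (end positions of all but the last segment) of a profile
profile_breaks <- function(profile) {
  br <- profile$end[-nrow(profile)]
  sort(br)
}

# quick paired beta matrix from two value vectors (one model)
make_pair_bm <- function(primary, xeno, probe_ids = NULL) {
  vals <- cbind(M1_P = primary, M1_X = xeno)
  rownames(vals) <- if (is.null(probe_ids)) {
    sprintf("cg%07d", seq_along(primary))
  } else {
    probe_ids
  }
  beta_matrix(vals, data.frame(sample_id = c("M1_P", "M1_X"),
                               model_id = "M1",
                               tissue = c("primary", "xenograft")))
}

# deterministic growth curve data frame
make_curve <- function(days, volumes, mouse = "m1") {
  data.frame(mouse_id = mouse, day = days, volume = volumes,
             stringsAsFactors = FALSE)
}
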