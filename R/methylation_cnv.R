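#' Adjust methylation-array total signal for GC content and probe type
#'
#' Removes probe-composition effects from the log2 total hybridization
#' signal by a piecewise-constant fit: probes are grouped into GC-content
#' bins (deciles by default) crossed with probe type, and the group mean is
#' subtracted. This is a depth-limited regression-tree adjustment with a
#' fixed, reproducible split structure. Residuals have mean ~0.
#'
#' @param track Data frame with columns `total_signal`, `gc`, and optionally
#'   `probe_type` (see [signal_track]).
#' @param n_gc_bins Number of GC bins (quantile-based), default 10.
#' @return Numeric vector of adjusted signal values (residuals).
#' @export
adjust_signal <- function(track, n_gc_bins = 10L) {
  stopifnot(is.data.frame(track), "total_signal" %in% names(track))
  x <- track$total_signal
  gc <- track$gc
  ptype <- if ("probe_type" %in% names(track)) track$probe_type else "II"
  if (length(unique(gc)) < 2L && length(unique(ptype)) < 2L) {
    warning("constant covariates; adjustment reduces to mean-centering")
    return(x - mean(x))
  }
  br <- unique(quantile(gc, probs = seq(0, 1, length.out = n_gc_bins + 1L)))
  gbin <- if (length(br) > 2L) {
    cut(gc, breaks = br, include.lowest = TRUE)
  } else {
    factor(rep("all", length(gc)))
  }
  grp <- interaction(gbin, ptype, drop = TRUE)
  x - ave(x, grp)
}

#' Signal track constructor
#'
#' Per-probe total-intensity track used for copy-number inference from a
#' methylation array: probe id, chromosome, position, log2 total signal,
#' GC fraction of the probe context, and Infinium probe type (I or II).
#'
#' @param probe_id,chrom,pos,total_signal,gc,probe_type Per-probe vectors.
#' @return Data frame of class `signal_track`, ordered by chromosome and
#'   position.
#' @export
signal_track <- function(probe_id, chrom, pos, total_signal, gc,
                         probe_type = "II") {
  stopifnot(all(gc >= 0 & gc <= 1))
  df <- data.frame(probe_id = as.character(probe_id),
                   chrom = as.character(chrom), pos = as.integer(pos),
                   total_signal = total_signal, gc = gc,
                   probe_type = probe_type, stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$pos), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("signal_track", "data.frame")
  df
}

#' Circular binary segmentation
#'
#' Recursively partitions an adjusted signal vector into constant-mean
#' segments. At each step the arc maximizing the circular two-sample
#' t statistic (arc versus the rest of the segment with its ends joined) is
#' found by exhaustive scan; the split is accepted when its permutation
#' p-value falls below `alpha`. Accepted arcs introduce up to two
#' breakpoints and recursion continues on the children. Deterministic for a
#' fixed `seed`.
#'
#' @param values Numeric vector of adjusted signal values, in genomic order.
#' @param chrom Optional chromosome label per value; segmentation never
#'   crosses a chromosome boundary. Default: a single chromosome.
#' @param alpha Significance level for accepting a split (default 0.01).
#' @param n_perm Number of permutations (default 1000; minimum 100).
#' @param min_width Minimum probes per segment (default 2).
#' @param seed Integer seed controlling the permutation stream.
#' @return Data frame of class `segment_profile` with columns `chrom`,
#'   `start`, `end` (1-based inclusive indices into `values`), `n_probes`,
#'   and `mean`.
#' @export
segment_cbs <- function(values, chrom = NULL, alpha = 0.01, n_perm = 1000L,
                        min_width = 2L, seed = 1L) {
  if (n_perm < 100L) stop("'n_perm' must be at least 100")
  if (is.null(chrom)) chrom <- rep("1", length(values))
  stopifnot(length(chrom) == length(values))
  counter <- new.env()
  counter$k <- 0L
  segs <- list()
  recurse <- function(lo, hi, ch) {
    n <- hi - lo + 1L
    split <- NULL
    if (n >= max(4L, 2L * min_width)) {
      counter$k <- counter$k + 1L
      res <- .cbs_test(values[lo:hi], as.integer(min_width),
                       as.integer(n_perm), alpha,
                       as.integer((seed + 7L * counter$k) %% .Machine$integer.max))
      if (res$p < alpha) split <- res
    }
    if (is.null(split)) {
      segs[[length(segs) + 1L]] <<- data.frame(
        chrom = ch, start = lo, end = hi, n_probes = n,
        mean = mean(values[lo:hi]), stringsAsFactors = FALSE)
      return(invisible(NULL))
    }
    i <- split$i; j <- split$j # 0-based arc [i, j) within values[lo:hi]
    bounds <- unique(c(lo, lo + i, lo + j, hi + 1L))
    for (b in seq_len(length(bounds) - 1L)) {
      recurse(bounds[b], bounds[b + 1L] - 1L, ch)
    }
    invisible(NULL)
  }
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    if (length(idx) < 4L) {
      stop("need at least 4 probes per chromosome (chromosome ", ch, ")")
    }
    recurse(idx[1L], idx[length(idx)], ch)
  }
  out <- do.call(rbind, segs)
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("segment_profile", "data.frame")
  out
}

# lower weighted median: smallest value whose cumulative weight reaches
# half the total
weighted_median <- function(x, w) {
  o <- order(x)
  x <- x[o]; w <- w[o]
  x[which(cumsum(w) >= sum(w) / 2)[1L]]
}

#' Recenter a segment profile
#'
#' Subtracts the probe-weighted median of segment means from every segment
#' mean, so that the bulk (copy-neutral) genome sits at zero. Idempotent.
#'
#' @param profile A `segment_profile` from [segment_cbs()].
#' @return The recentered `segment_profile`.
#' @export
recenter <- function(profile) {
  stopifnot(inherits(profile, "segment_profile"), nrow(profile) >= 1L)
  shift <- weighted_median(profile$mean, profile$n_probes)
  profile$mean <- profile$mean - shift
  attr(profile, "recentered") <- TRUE
  profile
}

#' Call copy-number states from recentered segment means
#'
#' Segments with mean below -0.2 are called `loss` (fewer than 2 copies),
#' above +0.2 `gain` (more than 2 copies), and `neutral` otherwise.
#' Inequalities are strict: a mean of exactly +/-0.2 is neutral.
#'
#' @param profile A recentered `segment_profile`.
#' @param threshold Absolute mean threshold (default 0.2).
#' @return The profile with an added `state` column
#'   (factor: `loss`, `neutral`, `gain`).
#' @export
call_states <- function(profile, threshold = 0.2) {
  stopifnot(inherits(profile, "segment_profile"))
  profile$state <- factor(
    ifelse(profile$mean < -threshold, "loss",
           ifelse(profile$mean > threshold, "gain", "neutral")),
    levels = c("loss", "neutral", "gain"))
  profile
}

# expand per-segment states to the per-probe grid
probe_states <- function(profile) {
  stopifnot(!is.null(profile$state))
  rep(profile$state, profile$end - profile$start + 1L)
}

#' Fraction of the genome with shared copy-number state in a sample pair
#'
#' Compares two state-called segment profiles defined on the same probe
#' grid. Returns the probe-weighted fraction of probes with identical state
#' and a per-probe differential map of the xenograft relative to the
#' primary. Swapping the arguments flips loss and gain in the differential.
#'
#' @param primary,xeno State-called `segment_profile`s (see [call_states()])
#'   over the same probes.
#' @return List with `shared` (fraction), `differential` (factor per probe:
#'   `xeno_loss_relative`, `same`, `xeno_gain_relative`), and `n_probes`.
#' @export
shared_cn_fraction <- function(primary, xeno) {
  sp <- probe_states(primary)
  sx <- probe_states(xeno)
  if (length(sp) != length(sx) || length(sp) == 0L) {
    stop("profiles must cover the same non-empty probe grid")
  }
  rp <- as.integer(sp); rx <- as.integer(sx) # loss=1 < neutral=2 < gain=3
  differential <- factor(
    ifelse(rx < rp, "xeno_loss_relative",
           ifelse(rx > rp, "xeno_gain_relative", "same")),
    levels = c("xeno_loss_relative", "same", "xeno_gain_relative"))
  list(shared = mean(rp == rx), differential = differential,
       n_probes = length(sp))
}
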