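#' Classify variants by primary-versus-xenograft MAF dynamics
#'
#' Each variant with mutant allele frequency (MAF) measured in a primary
#' tumor and its xenograft is assigned to one of five dynamic classes:
#' `shared` (similar MAF on both sides), `enriched` (xenograft/primary MAF
#' ratio above `fold`), `depleted` (ratio below `1/fold`),
#' `primary_private` (detected only in the primary), or `xeno_private`
#' (detected only in the xenograft). A variant is "detected" on a side when
#' its MAF is at least `detect_maf` and is supported by at least
#' `min_reads` reads (when depths are provided). Variants detected on
#' neither side are uninformative and returned as `NA` with a warning.
#' Ratios exactly equal to the fold boundary are `shared`.
#'
#' @param variants Data frame with columns `maf_primary`, `maf_xeno` and
#'   optionally `depth_primary`, `depth_xeno`.
#' @param detect_maf Detection floor on MAF, in (0, 0.5); default 0.02.
#' @param fold Fold-change boundary (> 1); default 2.
#' @param min_reads Minimum supporting reads for detection; default 3.
#' @return Factor with levels `shared`, `enriched`, `depleted`,
#'   `primary_private`, `xeno_private`; `NA` for uninformative variants.
#' @export
classify_dynamics <- function(variants, detect_maf = 0.02, fold = 2,
                              min_reads = 3L) {
  if (detect_maf <= 0 || detect_maf >= 0.5) stop("'detect_maf' must be in (0, 0.5)")
  if (fold <= 1) stop("'fold' must exceed 1")
  mp <- variants$maf_primary
  mx <- variants$maf_xeno
  stopifnot(all(mp >= 0 & mp <= 1), all(mx >= 0 & mx <= 1))
  dp <- if ("depth_primary" %in% names(variants)) variants$depth_primary else Inf
  dx <- if ("depth_xeno" %in% names(variants)) variants$depth_xeno else Inf
  det_p <- mp >= detect_maf & mp * dp >= min_reads
  det_x <- mx >= detect_maf & mx * dx >= min_reads
  cls <- rep(NA_character_, length(mp))
  cls[det_p & !det_x] <- "primary_private"
  cls[!det_p & det_x] <- "xeno_private"
  both <- det_p & det_x
  ratio <- mx / mp
  cls[both & ratio > fold] <- "enriched"
  cls[both & ratio < 1 / fold] <- "depleted"
  cls[both & ratio <= fold & ratio >= 1 / fold] <- "shared"
  if (anyNA(cls)) {
    warning(sum(is.na(cls)), " variant(s) below detection in both samples; ",
            "returned as NA")
  }
  factor(cls, levels = c("shared", "enriched", "depleted",
                         "primary_private", "xeno_private"))
}

#' Cluster variants into clones in paired MAF space
#'
#' Partitions variants by proximity in (primary MAF, xenograft MAF) space
#' with k-medoids (PAM). The number of clones k is chosen over 2..`k_max`
#' by maximum average silhouette width; when the best silhouette falls
#' below `min_silhouette` (one diffuse cloud) a single clone is returned.
#' Clone cellular frequencies are estimated as twice the per-coordinate
#' median MAF of member variants (heterozygous diploid convention), capped
#' at 1.
#'
#' @param variants Data frame with `maf_primary`, `maf_xeno`.
#' @param k_max Maximum number of clones to consider (default 6).
#' @param min_silhouette Silhouette floor below which a single clone is
#'   reported (default 0.5).
#' @return List with `clones` (data frame: `clone_id`, `freq_primary`,
#'   `freq_xeno`, `n_variants`) and `membership` (clone id per variant).
#' @export
cluster_clones <- function(variants, k_max = 6L, min_silhouette = 0.5) {
  if (k_max < 1L) stop("'k_max' must be at least 1")
  x <- cbind(variants$maf_primary, variants$maf_xeno)
  n <- nrow(x)
  if (n < 3L) stop("need at least 3 variants")
  if (nrow(unique(x)) == 1L) {
    membership <- rep(1L, n)
  } else {
    best_k <- 1L
    best_sil <- -Inf
    best_cl <- NULL
    for (k in seq(2L, min(k_max, n - 1L))) {
      if (k > nrow(unique(x)) - 0L) break
      fit <- cluster::pam(x, k = k)
      sil <- fit$silinfo$avg.width
      if (!is.null(sil) && sil > best_sil) {
        best_sil <- sil
        best_k <- k
        best_cl <- fit$clustering
      }
    }
    membership <- if (best_sil >= min_silhouette) best_cl else rep(1L, n)
  }
  clones <- do.call(rbind, lapply(sort(unique(membership)), function(cl) {
    m <- membership == cl
    data.frame(clone_id = cl,
               freq_primary = min(1, 2 * median(x[m, 1L])),
               freq_xeno = min(1, 2 * median(x[m, 2L])),
               n_variants = sum(m))
  }))
  # order clones by descending primary frequency for stable reporting
  ord <- order(-clones$freq_primary, -clones$freq_xeno)
  relabel <- match(clones$clone_id[ord], clones$clone_id)
  clones <- clones[ord, , drop = FALSE]
  clones$clone_id <- seq_len(nrow(clones))
  rownames(clones) <- NULL
  list(clones = clones, membership = match(membership, relabel))
}

#' Non-silent mutation burden per model and side
#'
#' Counts, for each model, the non-silent variants detected (MAF at or
#' above `detect_maf`) in the primary tumor and in the xenograft.
#'
#' @param variants Data frame with `model_id`, `effect_class`
#'   (`"silent"`/`"non-silent"`), `maf_primary`, `maf_xeno`.
#' @param detect_maf Detection floor (default 0.02).
#' @return Data frame with `model_id`, `n_primary`, `n_xeno`.
#' @export
nonsilent_burden <- function(variants, detect_maf = 0.02) {
  ns <- variants[variants$effect_class == "non-silent", , drop = FALSE]
  models <- unique(variants$model_id)
  out <- do.call(rbind, lapply(models, function(m) {
    v <- ns[ns$model_id == m, , drop = FALSE]
    data.frame(model_id = m,
               n_primary = sum(v$maf_primary >= detect_maf),
               n_xeno = sum(v$maf_xeno >= detect_maf),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Cohort medians and IQR of non-silent burden
#'
#' Summarizes per-model non-silent variant counts by side (median and
#' interquartile range) and reports a paired two-tailed t-test comparing
#' per-model primary and xenograft counts.
#'
#' @param burden Data frame from [nonsilent_burden()].
#' @return List with `primary` and `xeno` (each `median`, `q1`, `q3`) and
#'   `paired_t_p`.
#' @export
cohort_burden_medians <- function(burden) {
  summ <- function(x) c(median = median(x),
                        q1 = unname(quantile(x, 0.25)),
                        q3 = unname(quantile(x, 0.75)))
  p <- if (nrow(burden) >= 2L && var(burden$n_primary - burden$n_xeno) > 0) {
    t.test(burden$n_primary, burden$n_xeno, paired = TRUE)$p.value
  } else {
    NA_real_
  }
  list(primary = summ(burden$n_primary), xeno = summ(burden$n_xeno),
       paired_t_p = p)
}
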