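#' Paired methylation beta-value matrix
#'
#' Container for probe x sample methylation fractions (beta values) together
#' with the sample pairing that links each column to a model and tissue.
#' Beta values lie in \[0, 1\]; missing values are `NA` and are dropped
#' pairwise by downstream analyses.
#'
#' @param values Numeric matrix, probes x samples, entries in \[0, 1\] or `NA`.
#'   Row names are probe ids; column names are sample ids.
#' @param pairing Data frame with columns `sample_id`, `model_id`, `tissue`
#'   (`"primary"` or `"xenograft"`), one row per column of `values`.
#' @return An object of class `beta_matrix`.
#' @export
beta_matrix <- function(values, pairing) {
  values <- as.matrix(values)
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("cg%07d", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) stop("'values' must have sample column names")
  rng <- range(values, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 1) stop("beta values must lie in [0, 1]")
  pairing <- as.data.frame(pairing, stringsAsFactors = FALSE)
  req <- c("sample_id", "model_id", "tissue")
  if (!all(req %in% names(pairing))) {
    stop("pairing must have columns sample_id, model_id, tissue")
  }
  if (!setequal(pairing$sample_id, colnames(values))) {
    stop("pairing sample ids must match matrix column names")
  }
  if (!all(pairing$tissue %in% c("primary", "xenograft"))) {
    stop("tissue must be 'primary' or 'xenograft'")
  }
  if (any(duplicated(pairing[, c("model_id", "tissue")]))) {
    stop("each model may have at most one primary and one xenograft sample")
  }
  pairing <- pairing[match(colnames(values), pairing$sample_id), , drop = FALSE]
  rownames(pairing) <- NULL
  structure(list(values = values, pairing = pairing), class = "beta_matrix")
}

#' @export
print.beta_matrix <- function(x, ...) {
  cat(sprintf("beta_matrix: %d probes x %d samples (%d paired models)\n",
              nrow(x$values), ncol(x$values), length(paired_models(x))))
  invisible(x)
}

# model ids having both a primary and a xenograft column
paired_models <- function(bm) {
  tab <- table(bm$pairing$model_id)
  names(tab)[tab == 2L]
}

# sample id for a given model/tissue
sample_for <- function(bm, model, tissue) {
  bm$pairing$sample_id[bm$pairing$model_id == model & bm$pairing$tissue == tissue]
}

#' Tri-state methylation classification
#'
#' Bins a beta value into one of three methylation states: unmethylated
#' (beta < 1/3), hemimethylated (1/3 <= beta < 2/3), or methylated
#' (beta >= 2/3). The half-open bin convention assigns the boundary values
#' 1/3 and 2/3 to the upper bin so that the three bins partition \[0, 1\].
#'
#' @param beta Numeric vector of beta values in \[0, 1\] (`NA` allowed).
#' @return Factor with levels `unmethylated`, `hemimethylated`, `methylated`;
#'   `NA` where `beta` is `NA`.
#' @examples
#' classify_state(c(0.2, 0.5, 0.9, 1/3))
#' @export
classify_state <- function(beta) {
  if (!is.numeric(beta)) stop("'beta' must be numeric")
  bad <- !is.na(beta) & (beta < 0 | beta > 1)
  if (any(bad)) stop("beta values must lie in [0, 1]")
  # bins [0, 1/3), [1/3, 2/3), [2/3, 1]
  cut(beta, breaks = c(0, 1 / 3, 2 / 3, 1),
      labels = c("unmethylated", "hemimethylated", "methylated"),
      right = FALSE, include.lowest = TRUE)
}

#' Methylation retention rate for one sample pair
#'
#' The proportion of shared (non-missing in both samples) probes whose
#' tri-state methylation classification is identical in the two samples.
#' Symmetric in argument order.
#'
#' @param beta_a,beta_b Numeric beta vectors over the same probes.
#' @return List with `rate` (fraction retained), `retained` (logical per
#'   shared probe), and `n_shared` (number of shared probes).
#' @export
retention_rate <- function(beta_a, beta_b) {
  if (length(beta_a) != length(beta_b)) {
    stop("beta vectors must cover the same probes")
  }
  keep <- !is.na(beta_a) & !is.na(beta_b)
  if (!any(keep)) stop("no shared non-missing probes")
  sa <- classify_state(beta_a[keep])
  sb <- classify_state(beta_b[keep])
  retained <- sa == sb
  list(rate = mean(retained), retained = retained, n_shared = sum(keep))
}

#' Per-model retention rates and cohort summary
#'
#' Computes the retention rate for every model with both a primary and a
#' xenograft sample, plus min/median/max across models.
#'
#' @param bm A [beta_matrix].
#' @return List with `table` (data frame: `model_id`, `retention`,
#'   `n_shared`) and `summary` (named vector `min`, `median`, `max`).
#' @export
cohort_retention_summary <- function(bm) {
  stopifnot(inherits(bm, "beta_matrix"))
  models <- paired_models(bm)
  if (length(models) < 1L) stop("no paired models in matrix")
  rows <- lapply(models, function(m) {
    r <- retention_rate(bm$values[, sample_for(bm, m, "primary")],
                        bm$values[, sample_for(bm, m, "xenograft")])
    data.frame(model_id = m, retention = r$rate, n_shared = r$n_shared,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  list(table = tab,
       summary = c(min = min(tab$retention),
                   median = median(tab$retention),
                   max = max(tab$retention)))
}

#' Most variable probes
#'
#' Selects the `k` probes with the largest across-sample variance of beta
#' values (missing values excluded per probe). Ties are broken
#' deterministically by probe id.
#'
#' @param bm A [beta_matrix].
#' @param k Number of probes to select.
#' @return Character vector of probe ids, ordered by decreasing variance.
#' @export
top_variable_probes <- function(bm, k) {
  stopifnot(inherits(bm, "beta_matrix"))
  if (k <= 0) stop("'k' must be positive")
  if (k > nrow(bm$values)) stop("'k' exceeds the number of probes")
  v <- apply(bm$values, 1L, var, na.rm = TRUE)
  ord <- order(-v, rownames(bm$values))
  rownames(bm$values)[ord][seq_len(k)]
}

#' Count primary-xenograft pairs adjacent in the methylation dendrogram
#'
#' Hierarchically clusters all samples on the top-`k` most variable probes
#' (average linkage on 1 - Pearson correlation distance) and counts the
#' models whose primary and xenograft samples are immediate neighbours in
#' the dendrogram leaf order. The count is invariant to reflections of the
#' dendrogram because adjacency is evaluated on the realized leaf order.
#'
#' @param bm A [beta_matrix].
#' @param k Number of most-variable probes to cluster on.
#' @return List with `n_adjacent`, `n_pairs`, `adjacent` (named logical per
#'   model), and `leaf_order` (sample ids in dendrogram order).
#' @export
pair_adjacency_count <- function(bm, k = 20000L) {
  stopifnot(inherits(bm, "beta_matrix"))
  models <- paired_models(bm)
  if (length(models) < 2L) stop("need at least 2 paired models")
  k <- min(k, nrow(bm$values))
  probes <- top_variable_probes(bm, k)
  x <- bm$values[probes, , drop = FALSE]
  cc <- suppressWarnings(cor(x, use = "pairwise.complete.obs"))
  cc[!is.finite(cc)] <- 0
  hc <- hclust(as.dist(1 - cc), method = "average")
  leaves <- colnames(x)[hc$order]
  pos <- match(colnames(x), leaves)
  names(pos) <- colnames(x)
  adjacent <- vapply(models, function(m) {
    abs(pos[sample_for(bm, m, "primary")] -
          pos[sample_for(bm, m, "xenograft")]) == 1L
  }, logical(1))
  list(n_adjacent = sum(adjacent), n_pairs = length(models),
       adjacent = adjacent, leaf_order = leaves)
}
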