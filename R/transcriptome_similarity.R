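#' Gene expression matrix on the log2(FPKM + 0.01) scale
#'
#' @param values Numeric matrix, genes x samples, log2(FPKM + 0.01)
#'   values. Row names are gene ids, column names sample ids.
#' @param pairing Data frame with `sample_id`, `model_id`, `tissue`
#'   (`primary`, `xenograft`, `normal_kidney`, or `fetal_kidney`).
#' @param transformed Set `TRUE` when `values` are already transformed.
#'   Untransformed FPKM input should go through [transform_filter()].
#' @return Object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, pairing, transformed = TRUE) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("'values' must have gene row names and sample column names")
  }
  if (!transformed) stop("raw FPKM input must go through transform_filter()")
  pairing <- as.data.frame(pairing, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "model_id", "tissue") %in% names(pairing))) {
    stop("pairing must have columns sample_id, model_id, tissue")
  }
  ok <- c("primary", "xenograft", "normal_kidney", "fetal_kidney")
  if (!all(pairing$tissue %in% ok)) {
    stop("tissue must be one of: ", paste(ok, collapse = ", "))
  }
  pairing <- pairing[match(colnames(values), pairing$sample_id), , drop = FALSE]
  rownames(pairing) <- NULL
  structure(list(values = values, pairing = pairing),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

em_paired_models <- function(em) {
  p <- em$pairing[em$pairing$tissue %in% c("primary", "xenograft"), ]
  tab <- table(p$model_id)
  names(tab)[tab == 2L]
}

em_sample_for <- function(em, model, tissue) {
  em$pairing$sample_id[em$pairing$model_id == model &
                         em$pairing$tissue == tissue]
}

#' Transform FPKM values and filter unexpressed genes
#'
#' Applies `log2(FPKM + 0.01)` elementwise and removes genes whose maximum
#' transformed value across samples is below 1 (never meaningfully
#' expressed). Negative input is rejected: transformed matrices contain
#' negative values, so this guard also catches accidental
#' double-transformation.
#'
#' @param fpkm Numeric matrix of non-negative FPKM values, genes x samples.
#' @param pairing Pairing data frame (see [expression_matrix]).
#' @return An [expression_matrix] of retained genes.
#' @export
transform_filter <- function(fpkm, pairing) {
  fpkm <- as.matrix(fpkm)
  if (any(fpkm < 0)) {
    stop("negative FPKM values; input may already be log-transformed")
  }
  x <- log2(fpkm + 0.01)
  keep <- apply(x, 1L, max) >= 1
  expression_matrix(x[keep, , drop = FALSE], pairing, transformed = TRUE)
}

#' Spearman correlation matrix with lowest-quartile pair flagging
#'
#' Computes the all-sample Spearman rank correlation matrix over the
#' filtered genes, extracts the per-model primary-xenograft correlation,
#' and flags the pairs falling below the 25th percentile of pair
#' correlations (the lowest-fidelity quartile). The quartile threshold is
#' recomputed from the data at hand. Fewer than 4 pairs disables flagging
#' with a warning.
#'
#' @param em An [expression_matrix].
#' @return List with `cor_matrix`, `pairs` (data frame: `model_id`, `rho`,
#'   `lowest_quartile`), and `threshold`.
#' @export
spearman_pair_analysis <- function(em) {
  stopifnot(inherits(em, "expression_matrix"))
  cc <- cor(em$values, method = "spearman")
  models <- em_paired_models(em)
  rho <- vapply(models, function(m) {
    cc[em_sample_for(em, m, "primary"), em_sample_for(em, m, "xenograft")]
  }, numeric(1))
  if (length(models) >= 4L) {
    thr <- unname(quantile(rho, 0.25))
    flag <- rho < thr
  } else {
    warning("fewer than 4 pairs; lowest-quartile flagging disabled")
    thr <- NA_real_
    flag <- rep(NA, length(rho))
  }
  list(cor_matrix = cc,
       pairs = data.frame(model_id = models, rho = unname(rho),
                          lowest_quartile = unname(flag),
                          stringsAsFactors = FALSE),
       threshold = thr)
}

#' Principal component analysis of expression profiles
#'
#' Gene-centered (unscaled) PCA of the samples, reporting per-component
#' percent variance explained and, when covariates are supplied, the
#' Pearson correlation of each component's sample scores with each
#' covariate (e.g. gene-set scores or percent blastema).
#'
#' @param em An [expression_matrix].
#' @param n_components Number of components to report (truncated to the
#'   matrix rank, with a warning).
#' @param covariates Optional named list/data frame of per-sample numeric
#'   covariates in column order of the matrix.
#' @return List with `scores` (samples x components), `percent_variance`,
#'   and `covariate_correlations` (component x covariate) when supplied.
#' @export
pca_analysis <- function(em, n_components = 5L, covariates = NULL) {
  stopifnot(inherits(em, "expression_matrix"))
  if (ncol(em$values) < 3L) stop("need at least 3 samples")
  pc <- prcomp(t(em$values), center = TRUE, scale. = FALSE)
  pv <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  rank <- sum(pc$sdev > 1e-8)
  if (n_components > rank) {
    warning("requested ", n_components, " components; rank is ", rank)
    n_components <- rank
  }
  scores <- pc$x[, seq_len(n_components), drop = FALSE]
  out <- list(scores = scores,
              percent_variance = pv[seq_len(n_components)])
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    out$covariate_correlations <- cor(scores, covariates)
  }
  out
}

#' Mean z-score of a gene set per sample
#'
#' Each member gene is z-scored across samples (genes with zero variance
#' contribute 0) and the member z-scores are averaged per sample, giving a
#' per-sample gene-set activity score with cohort mean 0.
#'
#' @param em An [expression_matrix].
#' @param genes Character vector of member gene ids.
#' @return Named numeric vector of per-sample scores.
#' @export
gene_set_score <- function(em, genes) {
  stopifnot(inherits(em, "expression_matrix"))
  present <- intersect(genes, rownames(em$values))
  if (length(present) == 0L) stop("no gene-set members present in matrix")
  if (length(present) < length(genes)) {
    message(length(genes) - length(present), " gene-set member(s) absent")
  }
  x <- em$values[present, , drop = FALSE]
  mu <- rowMeans(x)
  s <- apply(x, 1L, sd)
  z <- (x - mu) / ifelse(s > 0, s, Inf) # zero-variance genes score 0
  colMeans(z)
}

#' Per-gene paired differential expression between xenografts and primaries
#'
#' Paired two-tailed t-test per gene on the xenograft-minus-primary
#' differences over paired models, with Benjamini-Hochberg adjustment.
#' Genes whose differences have zero variance get p = 1 and are flagged.
#'
#' @param em An [expression_matrix] with at least 3 paired models.
#' @return Data frame ordered by p-value: `gene`, `mean_diff`, `t`, `p`,
#'   `q`, `degenerate`.
#' @export
paired_de <- function(em) {
  stopifnot(inherits(em, "expression_matrix"))
  models <- em_paired_models(em)
  if (length(models) < 3L) stop("need at least 3 paired models")
  prim <- em$values[, vapply(models, em_sample_for, character(1), em = em,
                             tissue = "primary"), drop = FALSE]
  xeno <- em$values[, vapply(models, em_sample_for, character(1), em = em,
                             tissue = "xenograft"), drop = FALSE]
  d <- xeno - prim
  n <- ncol(d)
  mu <- rowMeans(d)
  s <- apply(d, 1L, sd)
  degenerate <- s <= 0
  tt <- ifelse(degenerate, 0, mu / (s / sqrt(n)))
  p <- ifelse(degenerate, 1, 2 * pt(-abs(tt), df = n - 1))
  q <- p.adjust(p, method = "BH")
  out <- data.frame(gene = rownames(em$values), mean_diff = mu, t = tt,
                    p = p, q = q, degenerate = degenerate,
                    stringsAsFactors = FALSE)
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  out
}
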