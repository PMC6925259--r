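#' Read a per-model cohort annotation table
#'
#' One row per xenograft model with clinical flags, histology concordance,
#' 11p15 status, percent-blastema values, and paired feature flags. Feature
#' presence is encoded as column pairs `<feature>_xeno` / `<feature>_primary`
#' (logical; `NA` when primary tissue was unavailable). The package ships a
#' reconstructed 45-model table (`wtpdx_annotations_synthetic.csv`) whose
#' aggregate statistics match the published cohort.
#'
#' @param path CSV file path; default: the packaged table.
#' @return Data frame of annotations.
#' @export
read_annotations <- function(path = system.file("extdata",
                                                "wtpdx_annotations_synthetic.csv",
                                                package = "pdxfidelity")) {
  read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
}

feature_names <- function(tab) {
  xcols <- grep("_xeno$", names(tab), value = TRUE)
  sub("_xeno$", "", xcols[sub("_xeno$", "_primary", xcols) %in% names(tab)])
}

#' Cohort concordance and prevalence statistics
#'
#' Computes, from an annotation table: histologic concordance counts and
#' percentage; 11p15 status category counts and percentages; per-feature
#' prevalence in xenografts and primaries and pair concordance over
#' evaluable pairs; and the prevalence of combined 1p+16q LOH. Percentages
#' are reported to one decimal.
#'
#' @param tab Annotation data frame (see [read_annotations()]).
#' @return List with `n_models`, `histology`, `status_11p15`, `features`,
#'   and `combined_1p_16q_loh`.
#' @export
concordance_stats <- function(tab) {
  if (nrow(tab) == 0L) stop("empty annotation table")
  n <- nrow(tab)
  pct <- function(k, d = n) round(100 * k / d, 1)
  conc <- sum(tab$histology_concordant)
  cats <- c("UPD", "hemizygous_loss", "LOI", "paternal_gain", "normal")
  cat_n <- vapply(cats, function(s) sum(tab$status_11p15 == s), integer(1))
  feats <- feature_names(tab)
  feat_stats <- do.call(rbind, lapply(feats, function(f) {
    fx <- tab[[paste0(f, "_xeno")]]
    fp <- tab[[paste0(f, "_primary")]]
    evaluable <- !is.na(fp)
    data.frame(feature = f,
               n_xeno = sum(fx), pct_xeno = pct(sum(fx)),
               n_primary = sum(fp[evaluable]),
               n_evaluable = sum(evaluable),
               pair_concordance = round(
                 mean(fx[evaluable] == fp[evaluable]), 3),
               stringsAsFactors = FALSE)
  }))
  comb <- sum(tab$loh_1p_xeno & tab$loh_16q_xeno)
  list(n_models = n,
       histology = list(n_concordant = conc, n_total = n,
                        pct_concordant = pct(conc)),
       status_11p15 = data.frame(status = cats, n = unname(cat_n),
                                 pct = pct(unname(cat_n)),
                                 stringsAsFactors = FALSE),
       features = feat_stats,
       combined_1p_16q_loh = list(n = comb, pct = pct(comb)))
}

#' Classify 11p15 status from copy-number, methylation, and microsatellites
#'
#' Decision cascade over the locus evidence: a copy ratio below the loss
#' threshold gives `hemizygous_loss`; above the gain threshold,
#' `paternal_gain`; copy-neutral with all informative microsatellite
#' markers homozygous gives `UPD` (copy-neutral LOH); copy-neutral with
#' retained heterozygosity and an IC1 (H19) methylation index above the
#' biallelic threshold gives `LOI`; otherwise `normal`. Copy-neutral
#' evidence with no informative marker is `indeterminate`.
#'
#' @param copy_ratio 11p15 copy ratio (1 = diploid).
#' @param ic1,ic2 Methylation indices at imprinting centers 1 and 2, in
#'   \[0, 1\].
#' @param markers Character vector of microsatellite marker states, each
#'   `"het"`, `"hom"`, or `"uninformative"`.
#' @param thresholds List with `loss` (default 0.8), `gain` (1.2), and
#'   `ic1_biallelic` (0.75).
#' @return One of `"UPD"`, `"hemizygous_loss"`, `"LOI"`, `"paternal_gain"`,
#'   `"normal"`, `"indeterminate"`.
#' @export
classify_11p15 <- function(copy_ratio, ic1, ic2, markers,
                           thresholds = list(loss = 0.8, gain = 1.2,
                                             ic1_biallelic = 0.75)) {
  stopifnot(ic1 >= 0, ic1 <= 1, ic2 >= 0, ic2 <= 1,
            all(markers %in% c("het", "hom", "uninformative")))
  if (copy_ratio < thresholds$loss) return("hemizygous_loss")
  if (copy_ratio > thresholds$gain) return("paternal_gain")
  informative <- markers[markers != "uninformative"]
  if (length(informative) == 0L) return("indeterminate")
  if (all(informative == "hom")) return("UPD")
  if (ic1 > thresholds$ic1_biallelic) return("LOI")
  "normal"
}

#' STR profile match report
#'
#' Compares two short-tandem-repeat profiles locus by locus. A locus is
#' identical when the allele sets are equal; it is loss-tolerated when the
#' xenograft's alleles are a strict subset of the primary's (allele loss
#' upon engraftment). The verdict is `"match"` when every shared locus is
#' identical or loss-tolerated, `"mismatch"` otherwise.
#'
#' @param primary,xeno Named lists of per-locus allele vectors.
#' @param min_loci Minimum shared typed loci required (default 8).
#' @return List with `fraction_identical`, `n_loss_tolerated`,
#'   `n_mismatch`, `n_loci`, and `verdict`.
#' @export
str_match <- function(primary, xeno, min_loci = 8L) {
  loci <- intersect(names(primary), names(xeno))
  if (length(loci) < min_loci) {
    stop("need at least ", min_loci, " shared typed loci (got ",
         length(loci), ")")
  }
  identical_l <- vapply(loci, function(l) {
    setequal(primary[[l]], xeno[[l]])
  }, logical(1))
  loss_tol <- vapply(loci, function(l) {
    !setequal(primary[[l]], xeno[[l]]) &&
      all(xeno[[l]] %in% primary[[l]])
  }, logical(1))
  n_mismatch <- sum(!identical_l & !loss_tol)
  list(fraction_identical = mean(identical_l),
       n_loss_tolerated = sum(loss_tol),
       n_mismatch = n_mismatch, n_loci = length(loci),
       verdict = if (n_mismatch == 0L) "match" else "mismatch")
}

#' Paired blastema enrichment between primaries and xenografts
#'
#' Paired two-tailed t-test on percent-blastema values, giving the mean
#' xenograft-minus-primary difference, its 95 percent confidence interval,
#' and the p-value.
#'
#' @param tab Annotation table with `pct_blastema_primary` and
#'   `pct_blastema_xeno` (pairs with either value missing are dropped).
#' @return List with `mean_diff`, `ci` (length 2), `p`, `n_pairs`.
#' @export
blastema_enrichment <- function(tab) {
  keep <- !is.na(tab$pct_blastema_primary) & !is.na(tab$pct_blastema_xeno)
  x <- tab$pct_blastema_xeno[keep]
  y <- tab$pct_blastema_primary[keep]
  if (length(x) < 2L) stop("need at least 2 pairs with blastema values")
  d <- x - y
  if (var(d) == 0) {
    # degenerate: identical differences everywhere
    return(list(mean_diff = mean(d), ci = rep(mean(d), 2L),
                p = if (mean(d) == 0) 1 else 0, n_pairs = length(x)))
  }
  tt <- t.test(x, y, paired = TRUE)
  list(mean_diff = unname(tt$estimate), ci = unname(tt$conf.int),
       p = tt$p.value, n_pairs = length(x))
}

#' Percent blastema across xenograft passages versus the primary tumor
#'
#' For models with serial-passage blastema measurements, compares each
#' passage's percent blastema against the primary-tumor value with a
#' paired two-tailed t-test.
#'
#' @param passages Long data frame with `model_id`, `passage` (integer),
#'   `pct_blastema`.
#' @param primary Data frame with `model_id`, `pct_blastema` of the
#'   primary tumors.
#' @return Data frame per passage: `passage`, `n`, `mean_diff`, `p`.
#' @export
passage_trajectory <- function(passages, primary) {
  out <- do.call(rbind, lapply(sort(unique(passages$passage)), function(pp) {
    sub <- passages[passages$passage == pp, , drop = FALSE]
    merged <- merge(sub, primary, by = "model_id",
                    suffixes = c("_passage", "_primary"))
    if (nrow(merged) < 2L) stop("need at least 2 models with passage data")
    tt <- t.test(merged$pct_blastema_passage, merged$pct_blastema_primary,
                 paired = TRUE)
    data.frame(passage = pp, n = nrow(merged),
               mean_diff = unname(tt$estimate), p = tt$p.value)
  }))
  rownames(out) <- NULL
  out
}
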