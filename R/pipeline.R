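#' Run configuration for an end-to-end cohort analysis
#'
#' @param spec A [cohort_spec] describing the simulated cohort (the run
#'   simulates its inputs; file-based runs call the stage functions
#'   directly).
#' @param stages Character vector of stages to run; any subset of
#'   `"methylation"`, `"cnv"`, `"clones"`, `"response"`, `"transcriptome"`,
#'   `"concordance"`.
#' @param top_k Probe count for methylation clustering.
#' @param detect_maf,fold Clonal-dynamics thresholds.
#' @param cn_alpha,cn_n_perm CBS parameters.
#' @param out_dir Output directory, or `NULL` for no file output.
#' @param seed Overrides `spec$seed` when non-NULL.
#' @return Object of class `run_config`.
#' @export
run_config <- function(spec = cohort_spec(),
                       stages = c("methylation", "cnv", "clones", "response",
                                  "transcriptome", "concordance"),
                       top_k = 20000L, detect_maf = 0.02, fold = 2,
                       cn_alpha = 0.01, cn_n_perm = 1000L,
                       out_dir = NULL, seed = NULL) {
  if (!is.null(seed)) spec$seed <- as.integer(seed)
  known <- c("methylation", "cnv", "clones", "response", "transcriptome",
             "concordance")
  if (!all(stages %in% known)) stop("unknown stage(s): ",
                                    paste(setdiff(stages, known), collapse = ", "))
  structure(list(spec = spec, stages = stages, top_k = top_k,
                 detect_maf = detect_maf, fold = fold, cn_alpha = cn_alpha,
                 cn_n_perm = cn_n_perm, out_dir = out_dir),
            class = "run_config")
}

#' Run the full simulate-then-analyze pipeline
#'
#' Simulates a paired cohort from `config$spec` and pushes it through the
#' enabled analysis stages, collecting a model-level fidelity summary
#' (methylation retention, shared copy-number fraction, pair Spearman
#' correlation, clonal class counts, response calls) plus the packaged
#' cohort concordance statistics. A stage failure is recorded in the run
#' log and the remaining stages proceed. Deterministic for a fixed seed.
#'
#' @param config A [run_config].
#' @return List with per-stage results, `summary` (model-level data
#'   frame), and `log` (character).
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  spec <- config$spec
  res <- list()
  log <- c(sprintf("pdxfidelity run; seed=%d; stages=%s", spec$seed,
                   paste(config$stages, collapse = ",")))
  note <- function(...) log <<- c(log, sprintf(...))
  try_stage <- function(name, expr) {
    if (!(name %in% config$stages)) {
      note("stage %s: disabled", name)
      return(NULL)
    }
    out <- tryCatch(expr, error = function(e) {
      note("stage %s: FAILED (%s)", name, conditionMessage(e))
      NULL
    })
    if (!is.null(out)) note("stage %s: ok", name)
    out
  }

  res$methylation <- try_stage("methylation", {
    bm <- simulate_beta_pair(spec)
    ret <- cohort_retention_summary(bm)
    adj <- pair_adjacency_count(bm, config$top_k)
    list(retention = ret, adjacency = adj)
  })

  res$cnv <- try_stage("cnv", {
    prim <- simulate_cn_signal(spec, events = NULL, seed_offset = 0L)
    xeno <- simulate_cn_signal(spec, events = spec$cn_events, seed_offset = 1L)
    seg <- function(st) {
      call_states(recenter(segment_cbs(adjust_signal(st), chrom = st$chrom,
                                       alpha = config$cn_alpha,
                                       n_perm = config$cn_n_perm,
                                       seed = spec$seed)))
    }
    sp <- seg(prim); sx <- seg(xeno)
    list(primary = sp, xeno = sx, shared = shared_cn_fraction(sp, sx))
  })

  res$clones <- try_stage("clones", {
    v <- simulate_variant_pair_table(spec)
    v$class <- suppressWarnings(
      classify_dynamics(v, config$detect_maf, config$fold))
    per_model <- lapply(split(v, v$model_id), cluster_clones)
    list(variants = v, clones = per_model,
         burden = cohort_burden_medians(nonsilent_burden(v)))
  })

  res$response <- try_stage("response", {
    arms <- names(spec$growth_spec)
    control <- simulate_growth_study(spec, "control")
    reports <- lapply(setdiff(arms, "control"), function(a) {
      arm_response_report(simulate_growth_study(spec, a), control,
                          seed = spec$seed)
    })
    do.call(rbind, reports)
  })

  res$transcriptome <- try_stage("transcriptome", {
    ep <- simulate_expression_pair(spec)
    sp <- spearman_pair_analysis(ep$matrix)
    gs <- gene_set_score(ep$matrix, ep$gene_sets$blastemal)
    pca <- pca_analysis(ep$matrix, n_components = 3L,
                        covariates = list(blastemal = gs))
    list(spearman = sp, gene_set_scores = gs, pca = pca)
  })

  res$concordance <- try_stage("concordance",
                               concordance_stats(read_annotations()))

  models <- sprintf("KT-%02d", seq_len(spec$n_models))
  summary <- data.frame(model_id = models, stringsAsFactors = FALSE)
  if (!is.null(res$methylation)) {
    summary$retention <- res$methylation$retention$table$retention[
      match(models, res$methylation$retention$table$model_id)]
    summary$pair_adjacent <- unname(
      res$methylation$adjacency$adjacent[models])
  }
  if (!is.null(res$transcriptome)) {
    summary$pair_spearman <- res$transcriptome$spearman$pairs$rho[
      match(models, res$transcriptome$spearman$pairs$model_id)]
  }
  if (!is.null(res$clones)) {
    cls <- table(res$clones$variants$model_id, res$clones$variants$class)
    summary$n_shared_variants <- as.integer(cls[models, "shared"])
    summary$n_enriched <- as.integer(cls[models, "enriched"])
    summary$n_primary_private <- as.integer(cls[models, "primary_private"])
  }
  res$summary <- summary
  res$log <- log

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(df, f) write.table(
      df, file.path(config$out_dir, f), sep = "\t", quote = FALSE,
      row.names = FALSE)
    wr(summary, "model_summary.tsv")
    if (!is.null(res$response)) wr(res$response, "response_report.tsv")
    if (!is.null(res$methylation)) {
      wr(res$methylation$retention$table, "retention.tsv")
    }
    writeLines(log, file.path(config$out_dir, "run_log.txt"))
  }
  res
}
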