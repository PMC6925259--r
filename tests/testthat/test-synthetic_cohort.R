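test_that("cohort_spec validates its parameters", {
  expect_error(cohort_spec(retention_rate_target = 1.2), "fraction")
  expect_error(cohort_spec(n_probes = 50), "at least 100")
  expect_error(cohort_spec(clone_table = data.frame(
    freq_primary = 1.3, freq_xeno = 0.5, n_variants = 10L)), "\\[0, 1\\]")
  bad_growth <- default_growth_spec()
  bad_growth$control$measurement_days <- numeric(0)
  expect_error(cohort_spec(growth_spec = bad_growth), "measurement_days")
  bad_growth2 <- default_growth_spec()
  bad_growth2$control$measurement_days <- c(0, 7, 7)
  expect_error(cohort_spec(growth_spec = bad_growth2), "increase strictly")
})

test_that("fixed seed reproduces the cohort bit-identically", {
  spec <- cohort_spec(n_models = 2L, n_probes = 500, seed = 11)
  expect_identical(simulate_beta_pair(spec)$values,
                   simulate_beta_pair(spec)$values)
  expect_identical(simulate_variant_pair_table(spec),
                   simulate_variant_pair_table(spec))
  expect_identical(simulate_growth_study(spec, "V")$curves,
                   simulate_growth_study(spec, "V")$curves)
  expect_identical(simulate_expression_pair(spec)$matrix$values,
                   simulate_expression_pair(spec)$matrix$values)
})

test_that("planted retention 1.0 keeps every probe pair in the same bin", {
  spec <- cohort_spec(n_models = 2L, n_probes = 1000,
                      retention_rate_target = 1.0, seed = 5)
  bm <- simulate_beta_pair(spec)
  ret <- cohort_retention_summary(bm)
  expect_equal(ret$table$retention, c(1, 1))
})

test_that("planted retention 0.85 is recovered within 0.02", {
  spec <- cohort_spec(n_models = 1L, n_probes = 20000L,
                      retention_rate_target = 0.85, seed = 7)
  bm <- simulate_beta_pair(spec)
  ret <- cohort_retention_summary(bm)
  expect_lt(abs(ret$table$retention - 0.85), 0.02)
})

test_that("simulated MAFs follow the planted clone structure", {
  # fully clonal: MAFs cluster at 0.5 on both sides
  spec1 <- cohort_spec(n_models = 1L, clone_table = data.frame(
    freq_primary = 1, freq_xeno = 1, n_variants = 50L), seed = 2)
  v1 <- simulate_variant_pair_table(spec1)
  expect_lt(max(abs(v1$maf_primary - 0.5)), 0.1)
  expect_lt(max(abs(v1$maf_xeno - 0.5)), 0.1)

  # planted 4x frequency expansion shows up as ~4x MAF fold change
  spec2 <- cohort_spec(n_models = 1L, clone_table = data.frame(
    freq_primary = 0.2, freq_xeno = 0.8, n_variants = 200L), seed = 2)
  v2 <- simulate_variant_pair_table(spec2)
  expect_lt(abs(mean(v2$maf_xeno / v2$maf_primary) - 4), 0.5)

  # clone absent from the xenograft: MAFs at/below the detection floor
  spec3 <- cohort_spec(n_models = 1L, clone_table = data.frame(
    freq_primary = 0.4, freq_xeno = 0, n_variants = 50L), seed = 2)
  v3 <- simulate_variant_pair_table(spec3)
  expect_true(all(v3$maf_xeno == 0))
})

test_that("deterministic growth matches closed-form volumes", {
  expect_equal(growth_volume(0.25, 14, 7, 0), 1.0)
  expect_equal(growth_volume(0.25, 0, 7, 0), 0.25)
  # RTV-4 crossing of an untreated exponential curve: log2(4) doublings
  expect_equal(growth_volume(0.3, 2 * 6, 6, 0) / 0.3, 4)
})

test_that("control mice all reach the RTV-4 event before day 84", {
  spec <- cohort_spec(seed = 9)
  ctrl <- simulate_growth_study(spec, "control")
  for (m in unique(ctrl$curves$mouse_id)) {
    cv <- ctrl$curves[ctrl$curves$mouse_id == m, ]
    ev <- time_to_event(cv)
    expect_true(ev$event)
    expect_lt(ev$time, 84)
    # closed-form crossing at log2(4) x doubling_days, up to noise
    expect_lt(abs(ev$time - 12), 5)
  }
})

test_that("a strong kill rate drives volumes below 0.10 by mid-study", {
  gs <- default_growth_spec()
  spec <- cohort_spec(growth_spec = gs, seed = 4)
  trt <- simulate_growth_study(spec, "VAD")
  late <- trt$curves[trt$curves$day >= 42, ]
  expect_true(all(late$volume < 0.10))
  resp <- median_group_response(trt, growth_delay = 4)
  expect_equal(as.character(resp$median_call), "MCR")
})

test_that("noise-free expression pairs are rank-identical; shift separates tissues", {
  spec0 <- cohort_spec(n_models = 3L, n_genes = 300, blastema_shift = 0,
                       expr_noise_sd = 0, seed = 3)
  ep0 <- simulate_expression_pair(spec0)
  sp0 <- suppressWarnings(spearman_pair_analysis(ep0$matrix))
  expect_equal(sp0$pairs$rho, rep(1, 3))

  # with a planted blastemal shift the gene-set score is higher in the
  # xenograft of every pair, and PC1 separates tissues on average
  sep_ok <- score_ok <- logical(20)
  for (s in 1:20) {
    spec <- cohort_spec(n_models = 4L, n_genes = 300, blastema_shift = 1.5,
                        seed = s)
    ep <- simulate_expression_pair(spec)
    sc <- gene_set_score(ep$matrix, ep$gene_sets$blastemal)
    tissue <- ep$matrix$pairing$tissue
    score_ok[s] <- all(sc[tissue == "xenograft"] > sc[tissue == "primary"])
    pc <- pca_analysis(ep$matrix, n_components = 2L)
    pc1 <- pc$scores[, 1L]
    sep_ok[s] <- abs(mean(pc1[tissue == "xenograft"]) -
                       mean(pc1[tissue == "primary"])) >
      2 * sd(pc1[tissue == "primary"]) / sqrt(sum(tissue == "primary"))
  }
  expect_true(all(score_ok))
  expect_gt(mean(sep_ok), 0.8)
})

test_that("simulated STR and 11p15 evidence round-trip their ground truth", {
  spec <- cohort_spec(seed = 6)
  pr <- simulate_str_profiles(spec)
  expect_equal(str_match(pr$primary, pr$xeno)$verdict, "match")
  pr2 <- simulate_str_profiles(spec, n_dropout = 2L)
  m2 <- str_match(pr2$primary, pr2$xeno)
  expect_equal(m2$verdict, "match")
  expect_equal(m2$n_loss_tolerated, 2L)
  for (s in c("UPD", "hemizygous_loss", "LOI", "paternal_gain", "normal")) {
    ev <- simulate_11p15_evidence(s, seed = 8)
    expect_equal(classify_11p15(ev$copy_ratio, ev$ic1, ev$ic2, ev$markers), s)
  }
})
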