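#' Specification for a synthetic paired primary/xenograft cohort
#'
#' Collects the ground-truth parameters of a simulated cohort: how many
#' models, probes, variants and genes to generate; the planted methylation
#' retention rate; the clonal composition shared between each primary tumor
#' and its xenograft; planted copy-number events; per-arm tumor growth
#' parameters; and the blastemal expression shift in xenografts. Every
#' generator draws from a stream derived from `seed`, so a fixed spec
#' reproduces the cohort exactly.
#'
#' @param n_models Number of paired models (default 10).
#' @param n_probes Number of methylation probes (>= 100; default 20000).
#' @param n_variants_per_model Variants per model (default 60).
#' @param n_genes Genes in the expression matrix (>= 200; default 2000).
#' @param retention_rate_target Planted fraction of probes whose tri-state
#'   methylation bin is preserved in the xenograft (default 0.85).
#' @param clone_table Data frame with `freq_primary`, `freq_xeno`,
#'   `n_variants`: the clone structure planted in every model.
#' @param cn_events Data frame with `chrom`, `start_probe`, `end_probe`,
#'   `log_ratio_shift`: copy-number segments planted in the xenograft
#'   signal track.
#' @param growth_spec Named list of arms; each arm is a list with
#'   `baseline_doubling_days`, `treatment_kill_rate` (per day; 0 = control),
#'   `n_mice`, and `measurement_days` (strictly increasing, starting at 0).
#' @param blastema_shift Mean log2-expression shift added to blastemal
#'   gene-set genes in xenografts (default 1.5).
#' @param depth Sequencing depth for simulated MAFs (default 500).
#' @param n_blastemal Size of the designated blastemal gene set
#'   (default 100).
#' @param beta_sd Within-bin jitter of retained xenograft beta values
#'   (default 0.05).
#' @param expr_noise_sd Per-gene expression noise sd (default 0.25).
#' @param cn_noise_sd Probe-level noise sd of the CN signal (default 0.1).
#' @param growth_noise_sd Multiplicative lognormal measurement noise on
#'   tumor volumes (default 0.05).
#' @param seed Integer seed (default 1).
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_models = 10L,
                        n_probes = 20000L,
                        n_variants_per_model = 60L,
                        n_genes = 2000L,
                        retention_rate_target = 0.85,
                        clone_table = data.frame(
                          freq_primary = c(1.0, 0.2, 0.3),
                          freq_xeno = c(1.0, 0.8, 0.0),
                          n_variants = c(30L, 15L, 15L)),
                        cn_events = data.frame(
                          chrom = c("1", "4"),
                          start_probe = c(21L, 31L),
                          end_probe = c(60L, 70L),
                          log_ratio_shift = c(0.5, -0.5),
                          stringsAsFactors = FALSE),
                        growth_spec = default_growth_spec(),
                        blastema_shift = 1.5,
                        depth = 500L,
                        n_blastemal = 100L,
                        beta_sd = 0.05,
                        expr_noise_sd = 0.25,
                        cn_noise_sd = 0.1,
                        growth_noise_sd = 0.05,
                        seed = 1L) {
  if (retention_rate_target < 0 || retention_rate_target > 1) {
    stop("'retention_rate_target' must be a fraction in [0, 1]")
  }
  if (n_probes < 100L) stop("'n_probes' must be at least 100")
  if (n_genes < 200L) stop("'n_genes' must be at least 200")
  if (nrow(clone_table) == 0L) stop("'clone_table' must be non-empty")
  if (any(clone_table$freq_primary > 1 | clone_table$freq_xeno > 1 |
            clone_table$freq_primary < 0 | clone_table$freq_xeno < 0)) {
    stop("clone frequencies must lie in [0, 1]")
  }
  if (n_blastemal < 1L || n_blastemal > n_genes) {
    stop("'n_blastemal' must designate a non-empty gene set")
  }
  for (arm in names(growth_spec)) {
    g <- growth_spec[[arm]]
    if (length(g$measurement_days) == 0L) stop("empty measurement_days")
    if (g$measurement_days[1L] != 0 || any(diff(g$measurement_days) <= 0)) {
      stop("measurement_days must start at 0 and increase strictly")
    }
    if (g$n_mice < 2L) stop("'n_mice' must be at least 2")
    if (g$treatment_kill_rate < 0) stop("'treatment_kill_rate' must be >= 0")
    if (g$baseline_doubling_days <= 0) stop("doubling time must be positive")
  }
  structure(list(n_models = n_models, n_probes = n_probes,
                 n_variants_per_model = n_variants_per_model,
                 n_genes = n_genes,
                 retention_rate_target = retention_rate_target,
                 clone_table = clone_table, cn_events = cn_events,
                 growth_spec = growth_spec, blastema_shift = blastema_shift,
                 depth = depth, n_blastemal = n_blastemal, beta_sd = beta_sd,
                 expr_noise_sd = expr_noise_sd, cn_noise_sd = cn_noise_sd,
                 growth_noise_sd = growth_noise_sd, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Default treatment arms for the growth simulator
#'
#' Weekly measurements over an 84-day study, 8 mice per arm, a 6-day
#' baseline doubling time, and per-day kill rates spanning no effect
#' (control) to strong vincristine-like combination effects.
#' @return Named list of arm specifications.
#' @export
default_growth_spec <- function() {
  arm <- function(kill) list(baseline_doubling_days = 6,
                             treatment_kill_rate = kill, n_mice = 8L,
                             measurement_days = seq(0, 84, by = 7))
  list(control = arm(0), V = arm(0.2), A = arm(0.05), D = arm(0.03),
       VA = arm(0.25), VAD = arm(0.3))
}

# truncated normal draw inside (lo, hi), vectorized and exact
rtruncnorm_vec <- function(mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  u <- runif(length(mean), plo, phi)
  out <- stats::qnorm(u, mean, sd)
  pmin(pmax(out, lo), hi) # numeric safety only
}

bin_bounds <- function(state_idx) {
  lo <- c(0, 1 / 3, 2 / 3)[state_idx]
  hi <- c(1 / 3, 2 / 3, 1)[state_idx]
  list(lo = lo, hi = hi)
}

#' Simulate a paired methylation beta matrix with planted retention
#'
#' Primary-tumor beta values are drawn from a bimodal mixture resembling
#' array data. For a planted fraction `retention_rate_target` of probes the
#' xenograft beta value is re-drawn near the primary value inside the same
#' tri-state bin (truncated normal); remaining probes are re-drawn
#' uniformly inside one of the other two bins, so the planted fraction is
#' exactly the expected retention rate measured downstream.
#'
#' @param spec A [cohort_spec].
#' @return A [beta_matrix] with a primary and a xenograft column per model;
#'   ground-truth retained flags are attached as attribute `"retained"`.
#' @export
simulate_beta_pair <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed + 101L)
  np <- spec$n_probes
  nm <- spec$n_models
  probe_ids <- sprintf("cg%07d", seq_len(np))
  vals <- matrix(NA_real_, np, 2L * nm)
  retained_truth <- matrix(NA, np, nm)
  samples <- character(2L * nm)
  pairing <- NULL
  for (m in seq_len(nm)) {
    # mixture: mostly unmethylated or methylated, some intermediate
    comp <- sample.int(3L, np, replace = TRUE, prob = c(0.45, 0.2, 0.35))
    prim <- ifelse(comp == 1L, stats::rbeta(np, 1.5, 8),
                   ifelse(comp == 2L, stats::rbeta(np, 8, 8),
                          stats::rbeta(np, 8, 1.5)))
    st <- as.integer(classify_state(prim))
    retained <- runif(np) < spec$retention_rate_target
    xeno <- numeric(np)
    bb <- bin_bounds(st)
    xeno[retained] <- rtruncnorm_vec(prim[retained], spec$beta_sd,
                                     bb$lo[retained], bb$hi[retained])
    if (any(!retained)) {
      other <- vapply(st[!retained], function(s) {
        sample(setdiff(1:3, s), 1L)
      }, integer(1))
      ob <- bin_bounds(other)
      xeno[!retained] <- runif(sum(!retained), ob$lo, ob$hi)
    }
    mid <- sprintf("KT-%02d", m)
    vals[, 2L * m - 1L] <- prim
    vals[, 2L * m] <- xeno
    samples[2L * m - 1L] <- paste0(mid, "_P")
    samples[2L * m] <- paste0(mid, "_X")
    retained_truth[, m] <- retained
    pairing <- rbind(pairing, data.frame(
      sample_id = c(paste0(mid, "_P"), paste0(mid, "_X")),
      model_id = mid, tissue = c("primary", "xenograft"),
      stringsAsFactors = FALSE))
  }
  dimnames(vals) <- list(probe_ids, samples)
  bm <- beta_matrix(vals, pairing)
  colnames(retained_truth) <- sprintf("KT-%02d", seq_len(nm))
  attr(bm, "retained") <- retained_truth
  bm
}

#' Simulate a paired variant MAF table with planted clones
#'
#' Variants are assigned to the clones of `spec$clone_table`; the observed
#' MAF on each side is a binomial draw at depth `spec$depth` around half
#' the clone's cellular frequency (heterozygous diploid convention).
#' Clones with zero frequency on one side produce private variants.
#'
#' @param spec A [cohort_spec].
#' @return Data frame with `model_id`, `chrom`, `pos`, `ref`, `alt`,
#'   `gene`, `effect_class`, `maf_primary`, `maf_xeno`, `depth_primary`,
#'   `depth_xeno`, plus the ground-truth `clone_truth` column.
#' @export
simulate_variant_pair_table <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed + 202L)
  ct <- spec$clone_table
  bases <- c("A", "C", "G", "T")
  out <- list()
  for (m in seq_len(spec$n_models)) {
    mid <- sprintf("KT-%02d", m)
    for (k in seq_len(nrow(ct))) {
      nv <- ct$n_variants[k]
      ref <- sample(bases, nv, replace = TRUE)
      alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L),
                    character(1))
      out[[length(out) + 1L]] <- data.frame(
        model_id = mid,
        chrom = as.character(sample.int(22L, nv, replace = TRUE)),
        pos = sample.int(2e8L, nv),
        ref = ref, alt = alt,
        gene = sprintf("GENE%04d", sample.int(5000L, nv)),
        effect_class = sample(c("non-silent", "silent"), nv,
                              replace = TRUE, prob = c(0.7, 0.3)),
        maf_primary = rbinom(nv, spec$depth, ct$freq_primary[k] / 2) / spec$depth,
        maf_xeno = rbinom(nv, spec$depth, ct$freq_xeno[k] / 2) / spec$depth,
        depth_primary = spec$depth, depth_xeno = spec$depth,
        clone_truth = k, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Deterministic mean tumor volume under exponential growth with treatment
#'
#' `V(t) = V0 * 2^(t / doubling_days) * exp(-kill_rate * t)`: exponential
#' baseline growth with a multiplicative per-day treatment kill term.
#'
#' @param v0 Day-0 volume (cm^3).
#' @param day Day(s) at which to evaluate.
#' @param doubling_days Baseline volume doubling time in days.
#' @param kill_rate Treatment kill rate per day (0 = untreated).
#' @return Volume(s) in cm^3.
#' @examples
#' growth_volume(0.25, 14, 7, 0) # two doublings -> 1.0
#' @export
growth_volume <- function(v0, day, doubling_days, kill_rate = 0) {
  v0 * 2^(day / doubling_days) * exp(-kill_rate * day)
}

#' Simulate a growth study arm
#'
#' Each mouse enrolls at a day-0 volume uniform in \[0.2, 0.5\] cm^3
#' (the 200-500 mm^3 enrollment window), then follows [growth_volume()]
#' with multiplicative lognormal measurement noise. Volumes below 0.005
#' cm^3 are recorded as 0 (below measurement resolution). The series stops
#' at the first measurement at or above the 2.5 cm^3 size cap, or at
#' day 84.
#'
#' @param spec A [cohort_spec].
#' @param arm Arm name present in `spec$growth_spec`.
#' @param model_id Model label for the returned arm.
#' @return A [study_arm].
#' @export
simulate_growth_study <- function(spec, arm, model_id = "KT-01") {
  stopifnot(inherits(spec, "cohort_spec"))
  g <- spec$growth_spec[[arm]]
  if (is.null(g)) stop("unknown arm: ", arm)
  set.seed(spec$seed + 303L + sum(utf8ToInt(arm)))
  rows <- list()
  for (i in seq_len(g$n_mice)) {
    v0 <- runif(1, 0.2, 0.5)
    days <- g$measurement_days
    mu <- growth_volume(v0, days, g$baseline_doubling_days,
                        g$treatment_kill_rate)
    noise <- exp(rnorm(length(days), 0, spec$growth_noise_sd))
    noise[1L] <- 1 # day-0 volume is the enrollment measurement
    v <- mu * noise
    v[v < 0.005] <- 0
    over <- which(v >= 2.5)
    if (length(over) > 0L) {
      keep <- seq_len(over[1L])
      days <- days[keep]; v <- v[keep]
    }
    rows[[i]] <- data.frame(mouse_id = sprintf("%s_%s_m%02d", model_id, arm, i),
                            day = days, volume = v, stringsAsFactors = FALSE)
  }
  study_arm(do.call(rbind, rows), arm = arm, model_id = model_id)
}

#' Simulate a paired expression matrix with a blastemal shift
#'
#' Xenograft profiles equal their paired primary profile plus independent
#' noise, with `spec$blastema_shift` added to the designated blastemal gene
#' set, emulating the enrichment of the undifferentiated blastemal
#' compartment upon engraftment. Values are on the log2(FPKM + 0.01) scale.
#'
#' @param spec A [cohort_spec].
#' @return List with `matrix` (an [expression_matrix]) and `gene_sets`
#'   (list with member ids of the `blastemal` set).
#' @export
simulate_expression_pair <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed + 404L)
  ng <- spec$n_genes
  nm <- spec$n_models
  genes <- sprintf("GENE%04d", seq_len(ng))
  blast <- genes[seq_len(spec$n_blastemal)]
  baseline <- rnorm(ng, 3, 2)
  vals <- matrix(NA_real_, ng, 2L * nm)
  samples <- character(2L * nm)
  pairing <- NULL
  for (m in seq_len(nm)) {
    mid <- sprintf("KT-%02d", m)
    prim <- baseline + rnorm(ng, 0, 0.5) + rnorm(ng, 0, spec$expr_noise_sd)
    xeno <- prim + rnorm(ng, 0, spec$expr_noise_sd)
    xeno[seq_len(spec$n_blastemal)] <- xeno[seq_len(spec$n_blastemal)] +
      spec$blastema_shift
    vals[, 2L * m - 1L] <- prim
    vals[, 2L * m] <- xeno
    samples[2L * m - 1L] <- paste0(mid, "_P")
    samples[2L * m] <- paste0(mid, "_X")
    pairing <- rbind(pairing, data.frame(
      sample_id = c(paste0(mid, "_P"), paste0(mid, "_X")),
      model_id = mid, tissue = c("primary", "xenograft"),
      stringsAsFactors = FALSE))
  }
  dimnames(vals) <- list(genes, samples)
  list(matrix = expression_matrix(vals, pairing, transformed = TRUE),
       gene_sets = list(blastemal = blast))
}

#' Simulate a methylation-array total-signal track with planted CN events
#'
#' Generates a per-probe log2 total-signal track over a set of
#' chromosomes, with a smooth GC-content covariate effect, Gaussian probe
#' noise, and the copy-number segments of `events` added on top. Passing
#' `events = NULL` yields a copy-neutral track (e.g. for a primary tumor).
#'
#' @param spec A [cohort_spec].
#' @param events Data frame as `spec$cn_events`, or `NULL` for none.
#' @param n_probes Total probes in the track (default 600, spread over
#'   chromosomes 1-6).
#' @param seed_offset Offset added to `spec$seed` so that paired tracks
#'   share probe positions/GC but have independent noise.
#' @return A [signal_track] with attribute `"truth"` holding the per-probe
#'   planted shift.
#' @export
simulate_cn_signal <- function(spec, events = spec$cn_events,
                               n_probes = 600L, seed_offset = 0L) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed + 505L)
  n_chrom <- 6L
  per <- n_probes %/% n_chrom
  chrom <- rep(as.character(seq_len(n_chrom)), each = per)
  n <- length(chrom)
  pos <- unlist(lapply(seq_len(n_chrom), function(i) sort(sample.int(1e8L, per))))
  gc <- runif(n, 0.3, 0.7)
  gc_effect <- 0.3 * sin(6 * pi * gc)
  ptype <- sample(c("I", "II"), n, replace = TRUE, prob = c(0.15, 0.85))
  set.seed(spec$seed + 505L + seed_offset + 1L)
  truth <- numeric(n)
  if (!is.null(events) && nrow(events) > 0L) {
    for (k in seq_len(nrow(events))) {
      idx <- which(chrom == as.character(events$chrom[k]))
      lo <- events$start_probe[k]; hi <- events$end_probe[k]
      sel <- idx[idx >= idx[1L] + lo - 1L & idx <= idx[1L] + hi - 1L]
      truth[sel] <- truth[sel] + events$log_ratio_shift[k]
    }
  }
  signal <- gc_effect + truth + rnorm(n, 0, spec$cn_noise_sd)
  st <- signal_track(sprintf("cg%07d", seq_len(n)), chrom, pos, signal, gc, ptype)
  attr(st, "truth") <- truth
  st
}

#' Simulate STR authentication profiles for a model pair
#'
#' Draws a 15-locus + Amelogenin short-tandem-repeat profile for a primary
#' tumor and copies it to the xenograft, optionally dropping one allele at
#' `n_dropout` heterozygous loci (allele loss upon engraftment).
#'
#' @param spec A [cohort_spec].
#' @param n_dropout Number of xenograft loci losing one allele (default 0).
#' @return List with `primary` and `xeno` STR profiles (named lists of
#'   allele vectors).
#' @export
simulate_str_profiles <- function(spec, n_dropout = 0L) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed + 606L)
  loci <- c("D3S1358", "TH01", "D21S11", "D18S51", "PentaE", "D5S818",
            "D13S317", "D7S820", "D16S539", "CSF1PO", "PentaD", "vWA",
            "D8S1179", "TPOX", "FGA", "AMEL")
  primary <- lapply(loci, function(l) {
    if (l == "AMEL") return(c("X", "Y"))
    sort(unique(sample(6:18, 2L, replace = TRUE)))
  })
  names(primary) <- loci
  xeno <- primary
  het <- names(primary)[vapply(primary, length, integer(1)) == 2L]
  if (n_dropout > 0L && length(het) > 0L) {
    drop_at <- sample(het, min(n_dropout, length(het)))
    for (l in drop_at) xeno[[l]] <- xeno[[l]][1L]
  }
  list(primary = primary, xeno = xeno)
}

#' Simulate 11p15 evidence consistent with a target status
#'
#' Produces a copy-ratio, IC1/IC2 methylation indices, and five
#' microsatellite marker states that the 11p15 classifier should map back
#' to `status`.
#'
#' @param status One of `"UPD"`, `"hemizygous_loss"`, `"LOI"`,
#'   `"paternal_gain"`, `"normal"`.
#' @param seed Integer seed.
#' @return List with `copy_ratio`, `ic1`, `ic2`, `markers`.
#' @export
simulate_11p15_evidence <- function(status = c("UPD", "hemizygous_loss",
                                               "LOI", "paternal_gain",
                                               "normal"), seed = 1L) {
  status <- match.arg(status)
  set.seed(seed + 707L)
  markers <- c("D11S1363", "D11S922", "D11S4046", "HUMTH01", "D11S988")
  mk <- function(state) setNames(rep(state, 5L), markers)
  switch(status,
    UPD = list(copy_ratio = runif(1, 0.9, 1.1), ic1 = runif(1, 0.8, 1),
               ic2 = runif(1, 0, 0.2), markers = mk("hom")),
    hemizygous_loss = list(copy_ratio = runif(1, 0.45, 0.65),
                           ic1 = runif(1, 0.6, 1), ic2 = runif(1, 0, 0.4),
                           markers = mk("hom")),
    LOI = list(copy_ratio = runif(1, 0.9, 1.1), ic1 = runif(1, 0.8, 1),
               ic2 = runif(1, 0.3, 0.6), markers = mk("het")),
    paternal_gain = list(copy_ratio = runif(1, 1.3, 1.6),
                         ic1 = runif(1, 0.6, 1), ic2 = runif(1, 0.2, 0.5),
                         markers = mk("het")),
    normal = list(copy_ratio = runif(1, 0.9, 1.1), ic1 = runif(1, 0.4, 0.6),
                  ic2 = runif(1, 0.4, 0.6), markers = mk("het")))
}
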