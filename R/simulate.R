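#' Synthetic cohort configuration
#'
#' Parameters of the seeded synthetic two-ancestry cohort generator. The
#' defaults reproduce the statistical structure of a neonatal cord-blood
#' promoter-array study: 112 African-ancestry (AA) and 91 European-ancestry
#' (EA) discovery samples, a 30 + 30 replication panel, 18% of probes with
#' an ancestry effect split 70/30 hypo/hyper in AA, 36% of effects shared
#' with the replication cohort, meQTL flags 2.5-fold enriched among affected
#' probes, and published group means/SDs for maternal age, plasma vitamin D
#' (ng/ml, truncated to the observed 9.4-35.2 range), plasma folate and
#' estimated lymphocyte/granulocyte percentages.
#'
#' Ancestry effects are additive on the M scale (the modelling scale), drawn
#' |N(effect_mean, effect_sd^2)| with sign per the direction split. The
#' planted module carries a latent factor
#' f = c0 + c1 I(AA) + c2 vitD I(EA) + eps with c2 < 0, i.e. a negative
#' vitamin-D slope confined to the European-ancestry group.
#'
#' @param ... overrides of the default fields; unknown names are an error.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(...) {
  cfg <- list(
    n_probes = 5000,
    n_discovery = c(african = 112, european = 91),
    n_replication = c(african = 30, european = 30),
    frac_dm = 0.18,
    frac_dm_low_in_A = 0.70,
    frac_stable = 0.36,
    effect_mean = 0.5,
    effect_sd = 0.2,
    frac_meqtl = 333 / 20595,
    meqtl_fold_in_dm = 2.5,
    module_size = 200,
    module_c0 = 0,
    module_c1 = 0.25,
    module_c2 = -0.035,
    module_factor_sd = 0.3,
    module_loading_range = c(1, 1.5),
    n_comod_blocks = 2,
    comod_block_size = 100,
    comod_block_r = 0.8,
    n_batches = 3,
    batch_location = NULL,     # default: evenly spread in [-0.1, 0.1] M
    batch_probe_sd = 0.15,
    batch_scale = NULL,        # default: evenly spread noise-SD multipliers
    noise_sd = 0.3,
    frac_discriminating = 0.05,
    frac_snp = 0.05,
    frac_sex = 0.02,
    frac_unannotated = 0.01,
    frac_cgi = 15280 / 20595,
    detect_fail_rate = 0.002,
    covariates = list(
      maternal_age_mean = c(25.75, 29.45), maternal_age_sd = c(5.03, 4.50),
      vitamin_d_mean = c(17.74, 20.68), vitamin_d_sd = c(6.03, 6.23),
      vitamin_d_range = c(9.4, 35.2),
      folate_mean = c(28.30, 32.84), folate_sd = c(18.40, 12.16),
      folate_range = c(4.84, 109.14),
      gestational_age_mean = c(38.84, 39.15), gestational_age_sd = c(1.51, 0.91),
      birth_weight_mean = c(3.18, 3.52), birth_weight_sd = c(0.47, 0.42),
      female_frac = c(53 / 112, 50 / 91),
      lymph_pct_mean = c(38.08, 42.73), lymph_pct_sd = c(12.11, 10.23),
      gran_pct_mean = c(48.72, 45.84), gran_pct_sd = c(13.01, 10.51)
    ),
    rng_seed = 1
  )
  ov <- list(...)
  unknown <- setdiff(names(ov), names(cfg))
  if (length(unknown)) stop("unknown config fields: ", paste(unknown, collapse = ", "))
  cfg[names(ov)] <- ov
  if (is.null(cfg$batch_location))
    cfg$batch_location <- if (cfg$n_batches == 1) 0 else
      seq(-0.1, 0.1, length.out = cfg$n_batches)
  if (is.null(cfg$batch_scale))
    cfg$batch_scale <- if (cfg$n_batches == 1) 1 else
      exp(seq(log(1.15), -log(1.15), length.out = cfg$n_batches))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  fr <- c("frac_dm", "frac_dm_low_in_A", "frac_stable", "frac_meqtl",
          "frac_discriminating", "frac_snp", "frac_sex", "frac_unannotated",
          "frac_cgi", "detect_fail_rate")
  for (f in fr)
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop(f, " must lie in [0, 1]")
  for (f in c("n_probes", "n_batches"))
    if (cfg[[f]] < 1) stop(f, " must be positive")
  if (any(cfg$n_discovery < 1) || any(cfg$n_replication < 1))
    stop("cohort sizes must be positive")
  if (length(cfg$batch_location) != cfg$n_batches ||
      length(cfg$batch_scale) != cfg$n_batches)
    stop("batch effect vectors must have one entry per batch")
  if (cfg$meqtl_fold_in_dm < 0) stop("meqtl fold must be non-negative")
  if (cfg$n_comod_blocks < 0 || cfg$comod_block_size < 0 ||
      cfg$comod_block_r < 0 || cfg$comod_block_r >= 1)
    stop("invalid co-methylation block parameters")
  invisible(cfg)
}

# sample() without the scalar-x surprise
resample <- function(x, n) x[sample.int(length(x), n)]

logit2 <- function(b) log2(b / (1 - b))
ilogit2 <- function(m) { e <- 2^m; e / (1 + e) }

# Exact truncated-normal sampling by inverse CDF (vectorized).
rtruncnorm <- function(n, mean, sd, lower, upper) {
  lo <- stats::pnorm(lower, mean, sd)
  hi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(lo + stats::runif(n) * (hi - lo), mean, sd)
}

# Logit-normal cell fraction with approximate target mean/sd on [0,1] scale.
rlogitnorm <- function(n, mean, sd) {
  mu <- stats::qlogis(mean)
  sigma <- sd / (mean * (1 - mean))   # delta method
  stats::plogis(stats::rnorm(n, mu, sigma))
}

#' Simulate cell-type reference beta profiles
#'
#' Generates lymphocyte and granulocyte reference profiles over a bimodal
#' promoter-array baseline (mixture 60% Beta(2,18), 30% Beta(18,2),
#' 10% Beta(5,5)). A designated fraction of probes discriminates the two
#' cell types with |delta beta| >= 0.3; the remaining probes are identical
#' across types. All betas lie strictly inside (0.01, 0.99).
#'
#' @param config a [sim_config].
#' @return a [cell_reference] with the discriminating set recorded; the
#'   shared baseline profile is attached as `attr(, "baseline_beta")`.
#' @export
simulate_reference_profiles <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$rng_seed)
  np <- config$n_probes
  ids <- sprintf("cg%06d", seq_len(np))
  comp <- sample(1:3, np, replace = TRUE, prob = c(0.6, 0.3, 0.1))
  base <- numeric(np)
  base[comp == 1] <- stats::rbeta(sum(comp == 1), 2, 18)
  base[comp == 2] <- stats::rbeta(sum(comp == 2), 18, 2)
  base[comp == 3] <- stats::rbeta(sum(comp == 3), 5, 5)
  base <- pmin(pmax(base, 0.02), 0.98)

  lymph <- gran <- base
  n_disc <- round(config$frac_discriminating * np)
  disc <- sort(sample.int(np, n_disc))
  if (n_disc > 0) {
    # Cell-type-specific methylation marks: high in exactly one of the two
    # types over a low shared baseline, so the residual leukocyte pool is
    # unmethylated at these sites.
    b_lo <- stats::runif(n_disc, 0.03, 0.15)
    gap <- stats::runif(n_disc, 0.3, 0.8 - b_lo)
    b_hi <- b_lo + gap
    lymph_high <- stats::runif(n_disc) < 0.5
    lymph[disc] <- ifelse(lymph_high, b_hi, b_lo)
    gran[disc] <- ifelse(lymph_high, b_lo, b_hi)
    base[disc] <- b_lo
  }
  prof <- cbind(lymphocyte = lymph, granulocyte = gran)
  rownames(prof) <- ids
  ref <- cell_reference(prof, discriminating_set = ids[disc])
  attr(ref, "baseline_beta") <- stats::setNames(base, ids)
  ref
}

#' Simulate discovery and replication cohorts
#'
#' Builds probe-by-sample beta matrices with aligned detection p-values, a
#' probe manifest, a sample sheet and the planted truth. Per sample, beta is
#' the cell-fraction mixture of the reference profiles plus the probe
#' baseline, transported to the M scale where the ancestry effects, planted
#' module factor, batch location/scale effects and Gaussian noise are added,
#' then mapped back to (0,1). The replication cohort is a single cell type
#' with no batches or nutrient covariates and carries only the "stable"
#' subset of ancestry effects. Covariates follow the configured per-group
#' (truncated) normal distributions; vitamin D is lower in the
#' African-ancestry group.
#'
#' @param config a [sim_config].
#' @param reference a [cell_reference] from [simulate_reference_profiles]
#'   with the same number of probes.
#' @return list of class `sim_cohort`: `discovery` and `replication`
#'   ([meth_matrix] objects on the beta scale with detection p-values),
#'   `manifest`, `sheet` (both cohorts; ancestry is a factor with the
#'   European group as reference), `truth` (per-probe and per-sample planted
#'   values) and `reference`.
#' @export
simulate_cohort <- function(config, reference) {
  stopifnot(inherits(config, "sim_config"))
  if (!inherits(reference, "cell_reference") ||
      nrow(reference$profile) != config$n_probes)
    stop("reference and config disagree on the number of probes")
  set.seed(config$rng_seed + 1L)
  np <- config$n_probes
  ids <- rownames(reference$profile)
  base <- attr(reference, "baseline_beta")
  if (is.null(base)) base <- rowMeans(reference$profile)

  ## ---- probe roles ---------------------------------------------------
  disc <- ids %in% reference$discriminating_set
  n_snp <- round(config$frac_snp * np)
  n_sex <- round(config$frac_sex * np)
  n_unann <- round(config$frac_unannotated * np)
  clean_pool <- which(!disc)
  flagged <- resample(clean_pool, n_snp + n_sex + n_unann)
  snp_idx <- flagged[seq_len(n_snp)]
  sex_idx <- flagged[n_snp + seq_len(n_sex)]
  unann_idx <- flagged[n_snp + n_sex + seq_len(n_unann)]
  usable <- setdiff(clean_pool, flagged)

  n_dm <- round(config$frac_dm * np)
  dm_idx <- sort(resample(usable, n_dm))
  n_low <- round(config$frac_dm_low_in_A * n_dm)
  dir_vec <- rep(1, n_dm)
  dir_vec[resample(seq_len(n_dm), n_low)] <- -1
  effects <- dir_vec * abs(stats::rnorm(n_dm, config$effect_mean, config$effect_sd))
  stable_idx <- sort(resample(dm_idx, round(config$frac_stable * n_dm)))
  free <- setdiff(usable, dm_idx)
  mod_idx <- if (config$module_size > 0)
    sort(resample(free, config$module_size)) else integer(0)
  free <- setdiff(free, mod_idx)
  block_idx <- vector("list", config$n_comod_blocks)
  for (b in seq_len(config$n_comod_blocks)) {
    block_idx[[b]] <- sort(resample(free, config$comod_block_size))
    free <- setdiff(free, block_idx[[b]])
  }

  n_meqtl <- round(config$frac_meqtl * np)
  n_meqtl_dm <- min(n_dm, n_meqtl,
                    round(config$meqtl_fold_in_dm * config$frac_meqtl * n_dm))
  meqtl_idx <- c(resample(dm_idx, n_meqtl_dm),
                 resample(setdiff(seq_len(np), dm_idx), n_meqtl - n_meqtl_dm))

  manifest <- data.frame(
    probe_id = ids,
    gene = paste0("GENE", sprintf("%05d", seq_len(np))),
    chromosome = as.character(sample(1:22, np, replace = TRUE)),
    cgi = stats::runif(np) < config$frac_cgi,
    snp_overlap = seq_len(np) %in% snp_idx,
    meqtl = seq_len(np) %in% meqtl_idx,
    stringsAsFactors = FALSE)
  manifest$chromosome[sex_idx] <- sample(c("X", "Y"), n_sex, replace = TRUE)
  manifest$gene[unann_idx] <- NA_character_

  ## ---- discovery samples ---------------------------------------------
  nA <- config$n_discovery[1]; nB <- config$n_discovery[2]
  nd <- nA + nB
  anc <- factor(rep(c("AA", "EA"), c(nA, nB)), levels = c("EA", "AA"))
  gi <- ifelse(anc == "AA", 1L, 2L)   # column per group in covariate params
  cv <- config$covariates
  draw <- function(mean, sd) stats::rnorm(nd, mean[gi], sd[gi])
  draw_trunc <- function(mean, sd, range)
    rtruncnorm(nd, mean[gi], sd[gi], range[1], range[2])

  maternal_age <- draw(cv$maternal_age_mean, cv$maternal_age_sd)
  vitamin_d <- draw_trunc(cv$vitamin_d_mean, cv$vitamin_d_sd, cv$vitamin_d_range)
  folate <- draw_trunc(cv$folate_mean, cv$folate_sd, cv$folate_range)
  gest_age <- draw(cv$gestational_age_mean, cv$gestational_age_sd)
  birth_weight <- draw(cv$birth_weight_mean, cv$birth_weight_sd)
  sex <- ifelse(stats::runif(nd) < cv$female_frac[gi], "F", "M")
  w_l <- rlogitnorm(nd, cv$lymph_pct_mean[gi] / 100, cv$lymph_pct_sd[gi] / 100)
  w_g <- rlogitnorm(nd, cv$gran_pct_mean[gi] / 100, cv$gran_pct_sd[gi] / 100)
  tot <- w_l + w_g
  over <- tot > 0.98
  w_l[over] <- w_l[over] * 0.98 / tot[over]
  w_g[over] <- w_g[over] * 0.98 / tot[over]
  batch <- sample(rep_len(seq_len(config$n_batches), nd))

  # Module factor: ancestry shift plus a vitamin-D slope confined to the
  # European-ancestry group (slope on centered vitamin D; centering is a
  # reparameterization that leaves the planted interaction unchanged).
  factor_eps <- stats::rnorm(nd, 0, config$module_factor_sd)
  vd_center <- cv$vitamin_d_mean[2]
  mod_factor <- config$module_c0 + config$module_c1 * (anc == "AA") +
    config$module_c2 * (vitamin_d - vd_center) * (anc == "EA") + factor_eps
  loadings <- if (length(mod_idx))
    stats::runif(length(mod_idx), config$module_loading_range[1],
                 config$module_loading_range[2]) else numeric(0)
  # Trait-independent co-methylation blocks: shared standard-normal factor
  # per block with loading sized for the target within-block correlation.
  block_lambda <- config$noise_sd *
    sqrt(config$comod_block_r / (1 - config$comod_block_r))
  block_factors <- matrix(stats::rnorm(nd * config$n_comod_blocks), ncol = nd)

  mix <- reference$profile %*% rbind(w_l, w_g) +
    outer(base, 1 - w_l - w_g)
  M <- logit2(pmin(pmax(mix, 1e-6), 1 - 1e-6))
  M[dm_idx, anc == "AA"] <- M[dm_idx, anc == "AA"] + effects
  if (length(mod_idx)) M[mod_idx, ] <- M[mod_idx, ] + outer(loadings, mod_factor)
  for (b in seq_len(config$n_comod_blocks))
    M[block_idx[[b]], ] <- M[block_idx[[b]], ] +
      block_lambda * rep(block_factors[b, ], each = length(block_idx[[b]]))
  gamma <- matrix(stats::rnorm(np * config$n_batches,
                               rep(config$batch_location, each = np),
                               config$batch_probe_sd),
                  nrow = np)
  M <- M + gamma[, batch]
  M <- M + matrix(stats::rnorm(np * nd), nrow = np) *
    rep(config$noise_sd * config$batch_scale[batch], each = np)
  beta_disc <- ilogit2(M)
  disc_ids <- sprintf("D%03d", seq_len(nd))
  dimnames(beta_disc) <- list(ids, disc_ids)

  ## ---- replication samples -------------------------------------------
  nrA <- config$n_replication[1]; nrB <- config$n_replication[2]
  nr <- nrA + nrB
  anc_r <- factor(rep(c("AA", "EA"), c(nrA, nrB)), levels = c("EA", "AA"))
  Mr <- matrix(logit2(pmin(pmax(base, 1e-6), 1 - 1e-6)), nrow = np, ncol = nr)
  stable_pos <- match(stable_idx, dm_idx)
  Mr[stable_idx, anc_r == "AA"] <- Mr[stable_idx, anc_r == "AA"] +
    effects[stable_pos]
  Mr <- Mr + matrix(stats::rnorm(np * nr, 0, config$noise_sd), nrow = np)
  beta_rep <- ilogit2(Mr)
  rep_ids <- sprintf("R%03d", seq_len(nr))
  dimnames(beta_rep) <- list(ids, rep_ids)

  detp <- function(nc) {
    p <- matrix(stats::runif(np * nc, 0, 1e-4), nrow = np)
    fail <- matrix(stats::runif(np * nc) < config$detect_fail_rate, nrow = np)
    p[fail] <- stats::runif(sum(fail), 0.001, 0.1)
    p
  }
  dp_disc <- detp(nd); dimnames(dp_disc) <- dimnames(beta_disc)
  dp_rep <- detp(nr); dimnames(dp_rep) <- dimnames(beta_rep)

  sheet <- data.frame(
    sample_id = c(disc_ids, rep_ids),
    cohort = rep(c("discovery", "replication"), c(nd, nr)),
    ancestry = factor(c(as.character(anc), as.character(anc_r)),
                      levels = c("EA", "AA")),
    sex = c(sex, rep(NA_character_, nr)),
    batch = c(batch, rep(NA_integer_, nr)),
    maternal_age = c(maternal_age, rep(NA_real_, nr)),
    vitamin_d = c(vitamin_d, rep(NA_real_, nr)),
    folate = c(folate, rep(NA_real_, nr)),
    gestational_age = c(gest_age, rep(NA_real_, nr)),
    birth_weight = c(birth_weight, rep(NA_real_, nr)),
    stringsAsFactors = FALSE)

  truth_probes <- data.frame(
    probe_id = ids,
    effect = 0, direction = 0, stable = FALSE,
    meqtl = manifest$meqtl,
    module_member = seq_len(np) %in% mod_idx,
    loading = 0,
    comod_block = 0L,
    stringsAsFactors = FALSE)
  truth_probes$effect[dm_idx] <- effects
  truth_probes$direction[dm_idx] <- dir_vec
  truth_probes$stable[stable_idx] <- TRUE
  if (length(mod_idx)) truth_probes$loading[mod_idx] <- loadings
  for (b in seq_len(config$n_comod_blocks))
    truth_probes$comod_block[block_idx[[b]]] <- b

  truth_samples <- data.frame(
    sample_id = c(disc_ids, rep_ids),
    cohort = rep(c("discovery", "replication"), c(nd, nr)),
    lymph_true = c(w_l, rep(NA_real_, nr)),
    gran_true = c(w_g, rep(NA_real_, nr)),
    batch = c(batch, rep(NA_integer_, nr)),
    module_factor = c(mod_factor, rep(NA_real_, nr)),
    stringsAsFactors = FALSE)

  structure(list(
    discovery = meth_matrix(beta_disc, dp_disc, scale = "beta"),
    replication = meth_matrix(beta_rep, dp_rep, scale = "beta"),
    manifest = manifest,
    sheet = sheet,
    truth = structure(list(probes = truth_probes, samples = truth_samples,
                           config = config), class = "sim_truth"),
    reference = reference), class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("sim_cohort: %d probes; discovery %d samples, replication %d samples\n",
              nrow(x$discovery$values), ncol(x$discovery$values),
              ncol(x$replication$values)))
  cat(sprintf("  planted: %d ancestry-affected probes (%d stable), module of %d, %d meQTL flags\n",
              sum(x$truth$probes$effect != 0), sum(x$truth$probes$stable),
              sum(x$truth$probes$module_member), sum(x$truth$probes$meqtl)))
  invisible(x)
}

#' Write a synthetic cohort to TSV/JSON fixture files
#'
#' Emits the pipeline's on-disk formats: beta and detection p-value matrix
#' TSVs for both cohorts, manifest and sample-sheet TSVs, the reference
#' profile TSV, truth tables, and the configuration as JSON. The files
#' round-trip losslessly through the package readers.
#'
#' @param sim a `sim_cohort` from [simulate_cohort].
#' @param directory output directory (created if needed).
#' @return named character vector of file paths.
#' @export
write_fixture_set <- function(sim, directory) {
  if (!inherits(sim, "sim_cohort")) stop("expected a 'sim_cohort'")
  if (ncol(sim$discovery$values) == 0 || nrow(sim$sheet) == 0)
    stop("empty sample set")
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  fp <- function(f) file.path(directory, f)
  paths <- c(
    discovery_beta = fp("discovery_beta.tsv"),
    discovery_detection = fp("discovery_detection.tsv"),
    replication_beta = fp("replication_beta.tsv"),
    replication_detection = fp("replication_detection.tsv"),
    manifest = fp("manifest.tsv"),
    sheet = fp("samples.tsv"),
    reference = fp("reference.tsv"),
    truth_probes = fp("truth_probes.tsv"),
    truth_samples = fp("truth_samples.tsv"),
    config = fp("config.json"))
  write_matrix(sim$discovery$values, paths["discovery_beta"])
  write_matrix(sim$discovery$detection_p, paths["discovery_detection"])
  write_matrix(sim$replication$values, paths["replication_beta"])
  write_matrix(sim$replication$detection_p, paths["replication_detection"])
  write_manifest(sim$manifest, paths["manifest"])
  write_sheet(sim$sheet, paths["sheet"])
  write_reference(sim$reference, paths["reference"])
  write_table_tsv(sim$truth$probes, paths["truth_probes"])
  write_table_tsv(sim$truth$samples, paths["truth_samples"])
  cfg <- unclass(sim$truth$config)
  jsonlite::write_json(cfg, paths["config"], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  paths
}
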