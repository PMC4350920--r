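test_that("detection-p masking is inclusive at the threshold and monotone", {
  v <- matrix(runif(12, 0.1, 0.9), 3, 4)
  dp <- matrix(0, 3, 4)
  dp[1, 1] <- 0.001        # exactly at threshold: must be masked
  dp[2, 2] <- 0.0009999    # just below: kept
  mm <- make_mm(v, dp)
  out <- mask_low_confidence(mm)
  expect_true(is.na(out$values[1, 1]))
  expect_false(is.na(out$values[2, 2]))
  expect_equal(sum(is.na(out$values)), 1)

  # all detection p = 0: nothing new masked
  expect_equal(sum(is.na(mask_low_confidence(make_mm(v, matrix(0, 3, 4)))$values)), 0)
  # threshold 0 masks everything
  expect_true(all(is.na(mask_low_confidence(mm, p_threshold = 0)$values)))
  # monotone in threshold
  m_strict <- mask_low_confidence(mm, 1e-4)
  expect_true(all(is.na(m_strict$values[is.na(out$values)])))
  expect_error(mask_low_confidence(make_mm(v)), "detection")
})

test_that("beta/M transforms match closed forms and invert each other", {
  v <- matrix(c(0.5, 0.8, 0.2, 0.4), 2, 2)
  mm <- beta_to_m(make_mm(v))
  expect_equal(mm$values[1, 1], 0)
  expect_equal(mm$values[2, 1], 2)     # log2(0.8/0.2)
  expect_equal(mm$values[1, 2], -2)
  expect_equal(mm$scale, "m")

  # antisymmetry M(beta) = -M(1 - beta)
  b <- matrix(runif(40, 0.01, 0.99), 8, 5)
  expect_equal(beta_to_m(make_mm(b))$values,
               -beta_to_m(make_mm(1 - b))$values, tolerance = 1e-12)

  # round trip through clipping, mask preserved
  b[2, 3] <- NA
  dimnames(b) <- list(sprintf("cg%06d", 1:8), sprintf("S%03d", 1:5))
  back <- m_to_beta(beta_to_m(make_mm(b)))
  expect_equal(back$values, b, tolerance = 1e-12)
  expect_true(is.na(back$values[2, 3]))

  expect_error(beta_to_m(beta_to_m(make_mm(b))), "already")
  expect_error(m_to_beta(make_mm(b)), "not on the M scale")
})

test_that("probe filters drop by category in order and account for every probe", {
  v <- matrix(runif(10 * 4, 0.1, 0.9), 10, 4,
              dimnames = list(sprintf("cg%06d", 1:10), sprintf("S%03d", 1:4)))
  mm <- make_mm(v)
  man <- data.frame(probe_id = rownames(v),
                    gene = paste0("G", 1:10),
                    chromosome = rep("3", 10),
                    snp_overlap = FALSE, meqtl = FALSE)
  man$snp_overlap[c(1, 5)] <- TRUE
  man$chromosome[7] <- "X"
  man$gene[9] <- NA
  out <- filter_probes(mm, man)
  expect_equal(out$report$n_dropped_snp, 2)
  expect_equal(out$report$n_dropped_sex, 1)
  expect_equal(out$report$n_dropped_unannotated, 1)
  expect_equal(out$report$n_output_probes, 6)
  expect_setdiff <- setdiff(rownames(out$matrix$values),
                            rownames(v)[c(1, 5, 7, 9)])
  expect_equal(nrow(out$matrix$values), 6)

  # a probe both SNP-flagged and on chrX counts once, as SNP (first rule)
  man2 <- man; man2$snp_overlap[7] <- TRUE
  out2 <- filter_probes(mm, man2)
  expect_equal(out2$report$n_dropped_snp, 3)
  expect_equal(out2$report$n_dropped_sex, 0)

  # no flags: identity
  man3 <- man; man3$snp_overlap <- FALSE; man3$chromosome <- "3"; man3$gene <- "G"
  expect_equal(filter_probes(mm, man3)$matrix$values, v, ignore_attr = FALSE)

  expect_error(filter_probes(mm, man[-1, ]), "absent from manifest")
})

test_that("masking and probe filtering commute", {
  sim <- simulate_small(3)
  a <- filter_probes(mask_low_confidence(sim$discovery), sim$manifest)$matrix
  b <- mask_low_confidence(filter_probes(sim$discovery, sim$manifest)$matrix)
  expect_identical(a$values, b$values)
})

test_that("filter bookkeeping matches planted manifest counts on the synthetic cohort", {
  sim <- simulate_small(5)
  out <- filter_probes(mask_low_confidence(sim$discovery), sim$manifest)
  np <- nrow(sim$discovery$values)
  expect_equal(out$report$n_dropped_snp, sum(sim$manifest$snp_overlap))
  expect_equal(out$report$n_dropped_sex,
               sum(sim$manifest$chromosome %in% c("X", "Y")))
  expect_equal(out$report$n_dropped_unannotated, sum(is.na(sim$manifest$gene)))
  expect_equal(out$report$n_output_probes,
               np - out$report$n_dropped_snp - out$report$n_dropped_sex -
                 out$report$n_dropped_unannotated)
})

test_that("batch correction removes planted location/scale shifts and protects ancestry", {
  cfg <- sim_config(n_probes = 800, n_batches = 2,
                    batch_location = c(0, 0.5), batch_scale = c(1, 1.5),
                    frac_dm_low_in_A = 0, effect_sd = 0.1,
                    module_size = 0, n_comod_blocks = 0, rng_seed = 11)
  sim <- simulate_cohort(cfg, simulate_reference_profiles(cfg))
  sh <- discovery_sheet(sim)
  m <- beta_to_m(sim$discovery)
  batch_rej <- function(mm) {
    ps <- apply(mm$values, 1, function(y)
      anova(lm(y ~ sh$ancestry + factor(sh$batch)))[["Pr(>F)"]][2])
    mean(ps < 0.05)
  }
  expect_gt(batch_rej(m), 0.9)
  corr <- combat_adjust(m, sh$batch, sh[, "ancestry", drop = FALSE])
  expect_lte(batch_rej(corr), 0.08)

  pre <- fit_site_models(m, sh, covariates = "maternal_age")
  post <- fit_site_models(corr, sh, covariates = "maternal_age")
  tp <- sim$truth$probes
  dm <- tp$effect[match(pre$probe_id, tp$probe_id)] != 0
  expect_lt(abs(mean(post$estimate[dm]) / mean(pre$estimate[dm]) - 1), 0.10)

  # near-idempotent: re-running only re-removes estimation noise
  corr2 <- combat_adjust(corr, sh$batch, sh[, "ancestry", drop = FALSE])
  expect_lt(sqrt(mean((corr2$values - corr$values)^2, na.rm = TRUE)), 0.01)
})

test_that("batch correction edge cases: single batch, masks, confounding", {
  sim <- simulate_small(7, n_batches = 1)
  sh <- discovery_sheet(sim)
  m <- beta_to_m(mask_low_confidence(sim$discovery))
  expect_message(out <- combat_adjust(m, sh$batch), "single batch")
  expect_identical(out$values, m$values)

  sim2 <- simulate_small(8)
  sh2 <- discovery_sheet(sim2)
  m2 <- beta_to_m(mask_low_confidence(sim2$discovery))
  corr <- combat_adjust(m2, sh2$batch, sh2[, "ancestry", drop = FALSE])
  expect_identical(is.na(corr$values), is.na(m2$values))  # mask preserved

  # batch perfectly confounded with the protected covariate
  fake_batch <- as.integer(sh2$ancestry)
  expect_error(combat_adjust(m2, fake_batch, sh2[, "ancestry", drop = FALSE]),
               "confounded")
})
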