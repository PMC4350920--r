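test_that("soft-threshold adjacency matches closed forms", {
  set.seed(51)
  x <- rnorm(30)
  v <- rbind(p1 = x, p2 = 2 * x + 3, p3 = -x)      # perfectly correlated set
  colnames(v) <- paste0("s", 1:30)
  a <- pairwise_adjacency(v, 6)
  expect_equal(a["p1", "p2"], 1, tolerance = 1e-12)
  expect_equal(a["p1", "p3"], 1, tolerance = 1e-12)  # unsigned network
  expect_equal(diag(a), setNames(rep(0, 3), rownames(a)))

  # power 1 equals |correlation|
  set.seed(52)
  w <- matrix(rnorm(8 * 40), 8, 40,
              dimnames = list(paste0("p", 1:8), paste0("s", 1:40)))
  a1 <- pairwise_adjacency(w, 1)
  expect_equal(unname(a1), unname(abs(cor(t(w))) - diag(8)), tolerance = 1e-12)

  # exactly orthogonal probes have zero adjacency
  u <- rbind(p1 = c(1, -1, 1, -1, 1, -1), p2 = c(1, 1, -1, -1, 1, 1) - 2 / 3)
  u["p2", ] <- residuals(lm(u["p2", ] ~ u["p1", ]))
  colnames(u) <- paste0("s", 1:6)
  expect_equal(pairwise_adjacency(u, 3)["p1", "p2"], 0, tolerance = 1e-12)

  expect_warning(pairwise_adjacency(rbind(w, pX = rep(1, 40)), 2), "constant")
  expect_error(pairwise_adjacency(w, 0.5), "power")
  expect_error(pairwise_adjacency(w[, 1:2], 2), "3 samples")
})

test_that("TOM equals triple-loop brute force and its closed-form limits", {
  set.seed(53)
  for (i in 1:20) {
    a <- random_adjacency(sample(4:8, 1))
    expect_equal(topological_overlap(a), tom_brute(a), tolerance = 1e-12)
  }
  # empty graph
  z <- matrix(0, 5, 5, dimnames = list(paste0("p", 1:5), paste0("p", 1:5)))
  tz <- topological_overlap(z)
  expect_true(all(tz[upper.tri(tz)] == 0) && all(diag(tz) == 1))
  # complete graph: TOM exactly 1 off-diagonal
  cg <- 1 - diag(6)
  dimnames(cg) <- list(paste0("p", 1:6), paste0("p", 1:6))
  expect_equal(unname(topological_overlap(cg)), matrix(1, 6, 6), tolerance = 1e-12)

  bad <- random_adjacency(4); bad[1, 2] <- bad[1, 2] + 0.1
  expect_error(topological_overlap(bad), "symmetric")
})

test_that("TOM stays in [0,1] for random adjacencies", {
  set.seed(54)
  for (i in 1:20) {
    tom <- topological_overlap(random_adjacency(sample(5:15, 1)))
    expect_true(all(tom >= -1e-12 & tom <= 1 + 1e-12))
  }
})

test_that("scale-free fit index is high for exact power-law degrees", {
  k <- rep(1:20, times = round(2000 * (1:20)^-2))
  expect_gte(methweave:::scale_free_fit(k), 0.95)
  expect_error(methweave:::scale_free_fit(rep(3, 50)), "degenerate")
})

test_that("soft-threshold scan reports monotone mean connectivity", {
  set.seed(55)
  f <- rnorm(50)
  x <- outer(rnorm(60, 1, 0.3), f) + matrix(rnorm(3000, 0, 0.8), 60, 50)
  dimnames(x) <- list(paste0("p", 1:60), paste0("s", 1:50))
  st <- pick_soft_threshold(x, candidate_powers = 1:10)
  expect_true(all(diff(st$fit_table$mean_k) <= 1e-10))
  expect_true(st$soft_power %in% 1:10)
  expect_equal(nrow(st$fit_table), 10)
})

test_that("module detection recovers planted blocks and labels by size", {
  set.seed(56)
  n <- 60
  f1 <- rnorm(n); f2 <- rnorm(n)
  lam <- sqrt(0.8 / 0.2)
  blocks <- rbind(
    outer(rep(lam, 120), f1) + matrix(rnorm(120 * n), 120, n),
    outer(rep(lam, 80), f2) + matrix(rnorm(80 * n), 80, n),
    matrix(rnorm(60 * n), 60, n))
  dimnames(blocks) <- list(sprintf("p%03d", 1:260), paste0("s", 1:n))
  adj <- pairwise_adjacency(blocks, 6)
  mods <- detect_modules(1 - topological_overlap(adj))
  truth <- rep(c("A", "B", "noise"), c(120, 80, 60))
  expect_equal(length(setdiff(unique(mods$assignment), "Meth0")), 2)
  # Meth1 is the larger block
  expect_gte(sum(mods$assignment == "Meth1"), sum(mods$assignment == "Meth2"))
  expect_gte(mean(mods$assignment[truth == "A"] == "Meth1"), 0.95)
  expect_gte(mean(mods$assignment[truth == "B"] == "Meth2"), 0.95)
  expect_gte(mean(mods$assignment[truth == "noise"] == "Meth0"), 0.9)
  if (requireNamespace("mclust", quietly = TRUE))
    expect_gte(mclust::adjustedRandIndex(mods$assignment, truth), 0.9)
})

test_that("i.i.d. noise yields no modules; boundary settings yield singletons", {
  set.seed(57)
  noise <- matrix(rnorm(150 * 40), 150, 40,
                  dimnames = list(sprintf("p%03d", 1:150), paste0("s", 1:40)))
  adj <- pairwise_adjacency(noise, 6)
  mods <- detect_modules(1 - topological_overlap(adj))
  expect_true(all(mods$assignment == "Meth0"))

  small <- adj[1:8, 1:8]
  m2 <- detect_modules(1 - topological_overlap(small),
                       min_module_size = 1, cut_height = 0)
  expect_equal(length(unique(m2$assignment)), 8)  # every probe its own module
})

test_that("module eigengenes are unit-norm, oriented, and recover planted factors", {
  set.seed(58)
  n <- 80
  f <- rnorm(n)
  x <- rbind(outer(runif(40, 0.8, 1.2), f) + matrix(rnorm(40 * n, 0, 0.3), 40, n),
             matrix(rnorm(20 * n), 20, n))
  dimnames(x) <- list(sprintf("p%03d", 1:60), paste0("s", 1:n))
  assign <- setNames(rep(c("Meth1", "Meth0"), c(40, 20)), rownames(x))
  me <- module_eigengenes(x, assign)
  expect_equal(colnames(me$eigengenes), "Meth1")   # Meth0 excluded
  expect_equal(sum(me$eigengenes[, 1]^2), 1, tolerance = 1e-9)
  expect_gt(abs(cor(me$eigengenes[, 1], f)), 0.95)
  expect_gte(cor(me$eigengenes[, 1], rowMeans(scale(t(x[1:40, ])))), 0)

  # global sign flip: the orientation rule tracks the flipped mean profile,
  # so the eigengene flips deterministically (no arbitrary SVD sign)
  me_flip <- module_eigengenes(-x, assign)
  expect_equal(me$eigengenes, -me_flip$eigengenes, tolerance = 1e-9)
  expect_gte(cor(me_flip$eigengenes[, 1], rowMeans(scale(t(-x[1:40, ])))), 0)

  # identical probes: variance explained is 1
  xx <- x[rep(1, 5), ]; rownames(xx) <- paste0("q", 1:5)
  me1 <- module_eigengenes(xx, setNames(rep("Meth1", 5), rownames(xx)))
  expect_equal(unname(me1$var_explained), 1, tolerance = 1e-12)

  flat <- matrix(1, 3, 10, dimnames = list(paste0("p", 1:3), paste0("s", 1:10)))
  expect_error(module_eigengenes(flat, setNames(rep("Meth1", 3), rownames(flat))),
               "zero-variance")
})

test_that("intramodular connectivity matches the complete-graph closed form", {
  cg <- 1 - diag(7)
  dimnames(cg) <- list(paste0("p", 1:7), paste0("p", 1:7))
  assign <- setNames(c(rep("Meth1", 5), rep("Meth0", 2)), rownames(cg))
  k <- intramodular_connectivity(cg, assign)
  expect_equal(unname(k$k_within[1:5]), rep(4, 5))   # module size 5: k = s - 1
  expect_equal(unname(k$k_within[6:7]), rep(1, 2))   # Meth0 peers only
  expect_equal(names(k$hubs), "Meth1")               # Meth0 never a hub list
  expect_equal(k$hubs$Meth1, paste0("p", 1:5))       # ties broken by probe id
})

test_that("hub ranking surfaces the strongest-loading planted probe", {
  set.seed(59)
  n <- 100
  f <- rnorm(n)
  lam <- c(2, runif(29, 0.4, 0.8))
  x <- outer(lam, f) + matrix(rnorm(30 * n, 0, 0.4), 30, n)
  dimnames(x) <- list(sprintf("p%03d", 1:30), paste0("s", 1:n))
  adj <- pairwise_adjacency(x, 6)
  assign <- setNames(rep("Meth1", 30), rownames(x))
  hubs <- intramodular_connectivity(adj, assign, n_hubs = 3)$hubs$Meth1
  expect_true("p001" %in% hubs)
})

test_that("bivariate module-trait tests use the Bonferroni family size", {
  set.seed(60)
  n <- 90
  me <- matrix(rnorm(n * 9), n, 9,
               dimnames = list(paste0("s", 1:n), paste0("Meth", 1:9)))
  sheet <- data.frame(sample_id = paste0("s", 1:n),
                      ancestry = factor(rep(c("EA", "AA"), length.out = n),
                                        levels = c("EA", "AA")),
                      vitamin_d = rnorm(n, 20, 6),
                      me1_copy = me[, 1])
  out <- module_trait_bivariate(me, sheet, c("ancestry", "vitamin_d"))
  expect_equal(unique(out$bonferroni_cutoff), 0.05 / 9)
  expect_equal(round(unique(out$bonferroni_cutoff), 3), 0.006)
  expect_equal(nrow(out), 18)

  # an eigengene regressed on itself is a perfect fit
  dup <- suppressWarnings(module_trait_bivariate(me, sheet, "me1_copy"))
  expect_equal(dup$coefficient[dup$module == "Meth1"], 1, tolerance = 1e-9)
  expect_lt(dup$p[dup$module == "Meth1"], 1e-12)

  sheet$flat <- 1
  expect_error(module_trait_bivariate(me, sheet, "flat"), "constant trait")
})

test_that("interaction model reports all terms and refuses a single group", {
  set.seed(61)
  n <- 120
  sheet <- data.frame(sample_id = paste0("s", 1:n),
                      ancestry = factor(rep(c("EA", "AA"), each = n / 2),
                                        levels = c("EA", "AA")),
                      vitamin_d = rnorm(n, 20, 6))
  vdc <- sheet$vitamin_d - mean(sheet$vitamin_d)
  me <- 0.3 * (sheet$ancestry == "AA") - 0.04 * vdc * (sheet$ancestry == "EA") +
    rnorm(n, 0, 0.2)
  names(me) <- sheet$sample_id
  fit <- module_trait_interaction(me, sheet)
  expect_equal(nrow(fit$terms), 3)
  expect_gt(fit$terms$Coeff[3], 0)      # slope confined to EA: positive interaction
  expect_lt(fit$terms$p_value[3], 0.01)
  expect_equal(fit$df[1], 3)
  expect_true(fit$r_squared >= 0 && fit$r_squared <= 1)
  # oracle cross-check against a direct lm fit
  direct <- summary(lm(me ~ ancestry * I(vitamin_d - mean(vitamin_d)),
                       data = sheet))
  expect_equal(fit$terms$Coeff, unname(direct$coefficients[2:4, 1]),
               tolerance = 1e-9)
  expect_equal(fit$r_squared, direct$r.squared, tolerance = 1e-12)

  only_ea <- sheet[sheet$ancestry == "EA", ]
  expect_error(module_trait_interaction(me[only_ea$sample_id], only_ea),
               "one ancestry group")
})

test_that("interaction p-values are uniform when no interaction is planted", {
  ps <- vapply(1:40, function(seed) {
    cfg <- sim_config(n_probes = 60, frac_dm = 0, module_size = 40,
                      module_c1 = 0, module_c2 = 0, n_comod_blocks = 0,
                      frac_discriminating = 0, frac_snp = 0, frac_sex = 0,
                      frac_unannotated = 0, rng_seed = seed)
    sim <- simulate_cohort(cfg, simulate_reference_profiles(cfg))
    sh <- discovery_sheet(sim)
    m <- beta_to_m(sim$discovery)
    tp <- sim$truth$probes
    assign <- setNames(ifelse(tp$module_member, "Meth1", "Meth0"), tp$probe_id)
    me <- module_eigengenes(m$values, assign)
    module_trait_interaction(
      setNames(me$eigengenes[, 1], rownames(me$eigengenes)), sh)$terms$p_value[3]
  }, numeric(1))
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})
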