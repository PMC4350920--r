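#' Soft-threshold adjacency matrix
#'
#' Unsigned weighted-network adjacency: a_ij = |cor(x_i, x_j)|^power with
#' Pearson correlation across samples (complete pairwise observations).
#' The diagonal is set to 0 by convention so that row sums are
#' connectivities. Constant probes, and probes with more than
#' `max_missing_frac` missing entries, are dropped with a warning.
#'
#' @param m a [meth_matrix] on the M scale, or a plain probe-by-sample
#'   numeric matrix.
#' @param soft_power positive soft-thresholding power.
#' @param max_missing_frac drop probes with a higher missing fraction
#'   (default 0.2).
#' @return symmetric adjacency matrix with zero diagonal, entries in \[0,1\].
#' @export
pairwise_adjacency <- function(m, soft_power, max_missing_frac = 0.2) {
  x <- network_input(m)
  if (!is.numeric(soft_power) || soft_power < 1) stop("soft power must be >= 1")
  if (ncol(x) < 3) stop("need at least 3 samples")
  miss <- rowMeans(is.na(x))
  v <- apply(x, 1, stats::var, na.rm = TRUE)
  bad <- miss > max_missing_frac | !is.finite(v) | v == 0
  if (any(bad)) {
    warning(sprintf("dropping %d constant or high-missingness probes", sum(bad)))
    x <- x[!bad, , drop = FALSE]
  }
  a <- abs(stats::cor(t(x), use = "pairwise.complete.obs"))^soft_power
  a[!is.finite(a)] <- 0
  diag(a) <- 0
  a
}

network_input <- function(m) {
  if (inherits(m, "meth_matrix")) {
    if (m$scale != "m") stop("network construction expects M-scale input")
    m$values
  } else if (is.matrix(m) && is.numeric(m)) m
  else stop("expected a meth_matrix or numeric matrix")
}

#' Scale-free soft-threshold selection
#'
#' For each candidate power, computes connectivities k_i = sum_j a_ij, bins
#' them into `n_bins` equal-width bins, and regresses log10(bin frequency)
#' on log10(bin mean k) over non-empty bins. The signed fit index is
#' R^2 x sign(-slope); a scale-free topology gives a high positive value.
#' The chosen power is the smallest whose signed fit reaches `r2_target`,
#' falling back to the argmax when none does.
#'
#' @param m input as in [pairwise_adjacency].
#' @param candidate_powers integer vector of powers to scan (default 1:20).
#' @param r2_target signed fit threshold (default 0.85).
#' @param n_bins number of connectivity bins (default 10).
#' @return list: `soft_power` and `fit_table` (power, signed fit, mean k,
#'   max k).
#' @export
pick_soft_threshold <- function(m, candidate_powers = 1:20, r2_target = 0.85,
                                n_bins = 10) {
  x <- network_input(m)
  cmat <- abs(stats::cor(t(x), use = "pairwise.complete.obs"))
  cmat[!is.finite(cmat)] <- 0
  diag(cmat) <- 0
  tab <- data.frame(power = candidate_powers, fit = NA_real_,
                    mean_k = NA_real_, max_k = NA_real_)
  for (i in seq_along(candidate_powers)) {
    k <- rowSums(cmat^candidate_powers[i])
    tab$mean_k[i] <- mean(k)
    tab$max_k[i] <- max(k)
    tab$fit[i] <- scale_free_fit(k, n_bins)
  }
  ok <- which(!is.na(tab$fit) & tab$fit >= r2_target)
  pw <- if (length(ok)) tab$power[ok[1]] else tab$power[which.max(tab$fit)]
  list(soft_power = pw, fit_table = tab)
}

# Signed scale-free fit index from a connectivity vector.
scale_free_fit <- function(k, n_bins = 10) {
  if (max(k) - min(k) <= .Machine$double.eps * max(1, max(k)))
    stop("degenerate connectivity: all k identical")
  br <- seq(min(k), max(k), length.out = n_bins + 1)
  bin <- cut(k, breaks = br, include.lowest = TRUE)
  freq <- tapply(k, bin, length)
  mk <- tapply(k, bin, mean)
  keep <- !is.na(freq) & freq > 0 & mk > 0
  if (sum(keep) < 3) return(NA_real_)
  fit <- stats::lm(log10(as.numeric(freq[keep])) ~ log10(as.numeric(mk[keep])))
  r2 <- summary(fit)$r.squared
  r2 * sign(-stats::coef(fit)[2])
}

#' Topological overlap matrix
#'
#' TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij) for
#' i != j, TOM_ii = 1. Shared-neighbour similarity of a weighted network;
#' the dissimilarity 1 - TOM feeds hierarchical module detection.
#'
#' @param adjacency symmetric matrix with zero diagonal, entries in \[0,1\].
#' @return the TOM matrix (unit diagonal).
#' @export
topological_overlap <- function(adjacency) {
  a <- adjacency
  if (!isSymmetric(unname(a), tol = 1e-10)) stop("adjacency must be symmetric")
  if (any(diag(a) != 0)) stop("adjacency diagonal must be zero")
  if (any(a < 0 | a > 1)) stop("adjacency entries must lie in [0, 1]")
  k <- rowSums(a)
  num <- a %*% a + a
  den <- outer(k, k, pmin) + 1 - a
  tom <- num / den
  diag(tom) <- 1
  dimnames(tom) <- dimnames(a)
  tom
}

#' Hierarchical module detection
#'
#' Average-linkage hierarchical clustering of the dissimilarity (1 - TOM)
#' with a static cut: the tree is cut at `cut_height`, clusters smaller than
#' `min_module_size` are relegated to the unassigned bin `Meth0`, and the
#' surviving clusters are labelled `Meth1`, `Meth2`, ... by decreasing size
#' (ties broken by the lexicographically smallest contained probe id).
#' Detection is fully deterministic.
#'
#' @param dissimilarity symmetric dissimilarity matrix in \[0,1\]
#'   (typically `1 - topological_overlap(a)`).
#' @param min_module_size smallest retained cluster (default 30).
#' @param cut_height static tree-cut height (default 0.99).
#' @return list: `assignment` (named character vector probe -> module
#'   label), `dendrogram` (the `hclust` tree), `sizes` (named module sizes,
#'   decreasing).
#' @export
detect_modules <- function(dissimilarity, min_module_size = 30,
                           cut_height = 0.99) {
  d <- dissimilarity
  if (any(d < -1e-8 | d > 1 + 1e-8)) stop("dissimilarity must lie in [0, 1]")
  ids <- rownames(d)
  if (is.null(ids)) ids <- paste0("p", seq_len(nrow(d)))
  h <- stats::hclust(stats::as.dist(d), method = "average")
  cl <- stats::cutree(h, h = cut_height)
  names(cl) <- ids
  sizes <- table(cl)
  big <- names(sizes)[sizes >= min_module_size]
  assignment <- rep("Meth0", length(cl))
  names(assignment) <- ids
  if (length(big)) {
    min_id <- vapply(big, function(b) min(ids[cl == b]), character(1))
    ord <- big[order(-as.numeric(sizes[big]), min_id)]
    for (i in seq_along(ord))
      assignment[cl == as.integer(ord[i])] <- paste0("Meth", i)
  }
  tab <- table(assignment)
  mods <- setdiff(names(tab), "Meth0")
  mods <- mods[order(as.integer(sub("^Meth", "", mods)))]
  list(assignment = assignment, dendrogram = h,
       sizes = tab[c(mods, intersect("Meth0", names(tab)))])
}

#' Module eigengenes
#'
#' Per module, probes are standardized across samples and the module
#' eigengene is the first right singular vector of the sample-by-probe
#' block (unit norm). Its sign is oriented so that its correlation with the
#' module's mean standardized profile is non-negative, which makes results
#' invariant to global sign flips of the input. `Meth0` is excluded.
#'
#' @param m a [meth_matrix] on the M scale or a probe-by-sample matrix.
#' @param assignment named character vector probe -> module label (see
#'   [detect_modules]).
#' @return list: `eigengenes` (sample x module matrix, columns unit norm)
#'   and `var_explained` (per-module proportion of variance captured).
#' @export
module_eigengenes <- function(m, assignment) {
  x <- network_input(m)
  mods <- setdiff(sort(unique(assignment)), "Meth0")
  mods <- mods[order(as.integer(sub("^Meth", "", mods)))]
  if (!length(mods)) stop("no modules to summarize")
  me <- matrix(NA_real_, nrow = ncol(x), ncol = length(mods),
               dimnames = list(colnames(x), mods))
  ve <- stats::setNames(numeric(length(mods)), mods)
  for (j in seq_along(mods)) {
    probes <- names(assignment)[assignment == mods[j]]
    if (length(probes) < 2) stop("module with fewer than 2 probes: ", mods[j])
    block <- x[probes, , drop = FALSE]
    sds <- apply(block, 1, stats::sd, na.rm = TRUE)
    if (all(sds == 0 | !is.finite(sds)))
      stop("module contains only zero-variance probes: ", mods[j])
    block <- block[sds > 0, , drop = FALSE]
    z <- t(scale(t(block)))                       # standardize probes
    if (anyNA(z)) {
      mu <- rowMeans(z, na.rm = TRUE)
      for (i in seq_len(nrow(z))) z[i, is.na(z[i, ])] <- mu[i]
    }
    sv <- svd(t(z), nu = 1, nv = 0)
    e <- sv$u[, 1]
    if (stats::cor(e, colMeans(z)) < 0) e <- -e
    me[, j] <- e
    ve[j] <- sv$d[1]^2 / sum(sv$d^2)
  }
  list(eigengenes = me, var_explained = ve)
}

#' Intramodular connectivity and hub probes
#'
#' kWithin_i is the sum of adjacency from probe i to the other members of
#' its own module. Hubs are the top `n_hubs` probes per module by kWithin
#' (ties broken by probe id); `Meth0` probes get a kWithin against their
#' Meth0 peers but are excluded from hub lists.
#'
#' @param adjacency adjacency matrix (rownames = probe ids).
#' @param assignment named character vector probe -> module label.
#' @param n_hubs hubs reported per module (default 10).
#' @return list: `k_within` (named numeric vector) and `hubs` (named list of
#'   probe id vectors per module).
#' @export
intramodular_connectivity <- function(adjacency, assignment, n_hubs = 10) {
  ids <- rownames(adjacency)
  if (!all(ids %in% names(assignment))) stop("assignment does not cover adjacency")
  mod <- assignment[ids]
  kw <- stats::setNames(numeric(length(ids)), ids)
  for (mo in unique(mod)) {
    members <- ids[mod == mo]
    sub <- adjacency[members, members, drop = FALSE]
    kw[members] <- rowSums(sub)
  }
  hubs <- lapply(setdiff(sort(unique(mod)), "Meth0"), function(mo) {
    members <- ids[mod == mo]
    members[order(-kw[members], members)][seq_len(min(n_hubs, length(members)))]
  })
  names(hubs) <- setdiff(sort(unique(mod)), "Meth0")
  list(k_within = kw, hubs = hubs)
}

#' Bivariate module-trait associations
#'
#' Simple regression of each module eigengene on each trait (categorical
#' traits coded as indicators), with unadjusted p-values and a Bonferroni
#' flag at 0.05 divided by the number of modules tested.
#'
#' @param MEs sample x module eigengene matrix.
#' @param sheet sample sheet aligned to the rows of `MEs` (matched by
#'   `sample_id`).
#' @param traits character vector of sheet columns.
#' @param n_modules_for_bonferroni family size for the Bonferroni cutoff
#'   (default: number of modules in `MEs`).
#' @return data frame: module, trait, coefficient, p, `bonferroni_cutoff`,
#'   `significant`.
#' @export
module_trait_bivariate <- function(MEs, sheet, traits,
                                   n_modules_for_bonferroni = ncol(MEs)) {
  sheet <- align_sheet(sheet, rownames(MEs))
  cutoff <- 0.05 / n_modules_for_bonferroni
  rows <- list()
  for (tr in traits) {
    x <- sheet[[tr]]
    if (is.character(x)) x <- factor(x)
    ok <- !is.na(x)
    if ((is.factor(x) && nlevels(droplevels(x[ok])) < 2) ||
        (!is.factor(x) && stats::var(as.numeric(x[ok])) == 0))
      stop("constant trait: ", tr)
    for (mo in colnames(MEs)) {
      fit <- stats::lm(MEs[ok, mo] ~ x[ok])
      sm <- summary(fit)$coefficients
      rows[[length(rows) + 1]] <- data.frame(
        module = mo, trait = tr,
        coefficient = sm[2, 1], p = sm[2, 4])
    }
  }
  out <- do.call(rbind, rows)
  out$bonferroni_cutoff <- cutoff
  out$significant <- out$p <= cutoff
  rownames(out) <- NULL
  out
}

#' Ancestry-by-nutrient interaction model for a module eigengene
#'
#' Multiple regression of a module eigengene on the ancestry indicator,
#' the (optionally centered) nutrient, and their product. Reports
#' coefficient, SE, t and p per term together with the model R-squared,
#' F statistic, degrees of freedom and overall p. Samples missing the
#' nutrient are dropped; both ancestry groups must remain.
#'
#' @param me numeric module eigengene vector, aligned to `sheet` rows by
#'   names (or position when unnamed).
#' @param sheet sample sheet data frame.
#' @param group ancestry column (two-level, default `"ancestry"`).
#' @param nutrient nutrient column (default `"vitamin_d"`).
#' @param center center the nutrient before forming the product
#'   (default `TRUE`).
#' @return list of class `module_trait_interaction`: `terms` (data frame
#'   with Coeff, SE, t-Ratio, p-value rows for the group, nutrient and
#'   interaction terms), `r_squared`, `f_statistic`, `df`, `p_overall`,
#'   `n_used`.
#' @export
module_trait_interaction <- function(me, sheet, group = "ancestry",
                                     nutrient = "vitamin_d", center = TRUE) {
  if (!is.null(names(me))) sheet <- align_sheet(sheet, names(me))
  g <- factor(sheet[[group]])
  v <- sheet[[nutrient]]
  ok <- !is.na(me) & !is.na(g) & !is.na(v)
  if (sum(ok) < 30) stop("fewer than 30 samples after missing-nutrient drop")
  g <- droplevels(g[ok]); v <- v[ok]; y <- me[ok]
  if (nlevels(g) < 2)
    stop("only one ancestry group present: interaction not estimable")
  if (center) v <- v - mean(v)
  fit <- stats::lm(y ~ g * v)
  sm <- summary(fit)
  co <- sm$coefficients
  terms <- data.frame(
    term = c(group, nutrient, paste0(group, " x ", nutrient)),
    Coeff = co[2:4, 1], SE = co[2:4, 2], t_Ratio = co[2:4, 3],
    p_value = co[2:4, 4], row.names = NULL)
  structure(list(terms = terms,
                 r_squared = sm$r.squared,
                 f_statistic = unname(sm$fstatistic[1]),
                 df = unname(sm$fstatistic[2:3]),
                 p_overall = stats::pf(sm$fstatistic[1], sm$fstatistic[2],
                                       sm$fstatistic[3], lower.tail = FALSE),
                 n_used = sum(ok)),
            class = "module_trait_interaction")
}

#' @export
print.module_trait_interaction <- function(x, ...) {
  cat("module-trait interaction model:\n")
  print(format(x$terms, digits = 3), row.names = FALSE)
  cat(sprintf("R^2 = %.3f, F(%d, %d) = %.2f, p = %.3g, n = %d\n",
              x$r_squared, x$df[1], x$df[2], x$f_statistic,
              x$p_overall, x$n_used))
  invisible(x)
}
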