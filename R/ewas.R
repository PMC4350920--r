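#' Per-CpG covariate-adjusted linear models
#'
#' Fits an ordinary least-squares model per probe, M-value ~ focal predictor
#' + covariates, and tests the focal coefficient with a two-sided t test.
#' A two-level factor focal predictor is coded as an indicator of its second
#' level (the first level is the reference, recorded in the result
#' attributes). Analysis is complete-case per probe: masked entries are
#' dropped, never imputed. Probes with fewer than `rank + 3` complete cases
#' or a singular design are skipped and reported via
#' `attr(result, "skipped")`; zero-variance probes get coefficient 0 and
#' p = 1, flagged in `attr(result, "zero_variance")`.
#'
#' @param m a [meth_matrix] on the M scale.
#' @param sheet sample sheet data frame, rows aligned to the samples of `m`
#'   (matched by `sample_id`).
#' @param focal name of the focal predictor column (default `"ancestry"`).
#' @param covariates character vector of adjustment covariate columns.
#' @return data frame of class `site_results`: `probe_id`, `estimate`
#'   (M units per focal unit), `se`, `t`, `p`, `q` (Benjamini-Hochberg over
#'   all tested probes), `direction` (sign of the estimate), `n_used`.
#' @export
fit_site_models <- function(m, sheet,
                            focal = "ancestry",
                            covariates = c("maternal_age", "lymph_frac", "gran_frac")) {
  stopifnot_meth_matrix(m)
  if (m$scale != "m") stop("site models expect M-scale input; run beta_to_m first")
  sheet <- align_sheet(sheet, sample_ids(m))
  fit_probe_lms(m$values, sheet, focal, covariates)
}

#' Maternal-nutrient association models
#'
#' Per-probe regression of M-values on a maternal nutrient (vitamin D or
#' folate). Unadjusted fits are simple regressions; adjusted fits add
#' ancestry, maternal age and the estimated cell fractions as covariates.
#' Samples missing the nutrient are dropped.
#'
#' @param m a [meth_matrix] on the M scale.
#' @param sheet sample sheet data frame.
#' @param nutrient `"vitamin_d"` or `"folate"`.
#' @param adjusted add the covariate set (default `TRUE`).
#' @return A `site_results` data frame (see [fit_site_models]).
#' @export
fit_nutrient_models <- function(m, sheet, nutrient = c("vitamin_d", "folate"),
                                adjusted = TRUE) {
  stopifnot_meth_matrix(m)
  if (m$scale != "m") stop("nutrient models expect M-scale input")
  nutrient <- match.arg(nutrient)
  sheet <- align_sheet(sheet, sample_ids(m))
  keep <- !is.na(sheet[[nutrient]])
  if (sum(keep) < 30)
    stop("nutrient non-missing for fewer than 30 samples")
  vals <- m$values[, keep, drop = FALSE]
  sub <- sheet[keep, , drop = FALSE]
  covs <- if (adjusted) c("ancestry", "maternal_age", "lymph_frac", "gran_frac")
          else character(0)
  fit_probe_lms(vals, sub, nutrient, covs)
}

align_sheet <- function(sheet, ids) {
  if (!"sample_id" %in% names(sheet)) stop("sheet needs a 'sample_id' column")
  idx <- match(ids, sheet$sample_id)
  if (anyNA(idx)) stop("sheet does not cover all samples")
  sheet[idx, , drop = FALSE]
}

# Shared per-probe OLS engine. Groups probes by missingness pattern so the
# normal-equations factorisation is reused across probes.
fit_probe_lms <- function(Y, sheet, focal, covariates) {
  for (v in c(focal, covariates))
    if (!v %in% names(sheet)) stop("column not in sheet: ", v)
  fvals <- sheet[[focal]]
  if (is.character(fvals)) fvals <- factor(fvals)
  if (is.factor(fvals)) {
    if (nlevels(droplevels(fvals)) < 2) stop("focal predictor is constant")
  } else if (stats::var(fvals, na.rm = TRUE) == 0) {
    stop("focal predictor has zero variance")
  }
  df <- data.frame(.focal = fvals, sheet[covariates], check.names = FALSE)
  ok_row <- stats::complete.cases(df)
  X_all <- stats::model.matrix(~ ., data = df[ok_row, , drop = FALSE])
  focal_col <- if (is.factor(fvals)) paste0(".focal", levels(fvals)[2]) else ".focal"
  fc <- match(focal_col, colnames(X_all))
  ref_level <- if (is.factor(fvals)) levels(fvals)[1] else NA_character_

  kap <- kappa(X_all, exact = FALSE)
  if (kap > 1e6)
    warning(sprintf("design matrix condition number %.3g exceeds 1e6", kap))

  Y <- Y[, ok_row, drop = FALSE]
  p_rank <- ncol(X_all)
  n_probes <- nrow(Y)
  est <- se <- tval <- pval <- rep(NA_real_, n_probes)
  n_used <- integer(n_probes)
  zero_var <- logical(n_probes)
  skipped <- logical(n_probes)

  miss <- is.na(Y)
  pattern <- if (any(miss)) apply(miss, 1, function(z) paste(which(z), collapse = ","))
             else rep("", n_probes)
  for (key in unique(pattern)) {
    rows <- which(pattern == key)
    use <- if (key == "") rep(TRUE, ncol(Y)) else {
      u <- rep(TRUE, ncol(Y)); u[as.integer(strsplit(key, ",")[[1]])] <- FALSE; u
    }
    X <- X_all[use, , drop = FALSE]
    n <- nrow(X)
    n_used[rows] <- n
    if (n < p_rank + 3 || qr(X)$rank < p_rank) {
      skipped[rows] <- TRUE
      next
    }
    XtX <- crossprod(X)
    Vinv <- solve(XtX)
    Yg <- Y[rows, use, drop = FALSE]
    coefs <- (Yg %*% X) %*% Vinv          # n_probes_g x p
    fitted <- tcrossprod(coefs, X)
    rss <- rowSums((Yg - fitted)^2)
    dfree <- n - p_rank
    sigma2 <- rss / dfree
    rowvar <- apply(Yg, 1, stats::var)
    zv <- rowvar <= .Machine$double.eps
    e <- coefs[, fc]
    s <- sqrt(sigma2 * Vinv[fc, fc])
    tv <- e / s
    pv <- 2 * stats::pt(-abs(tv), dfree)
    e[zv] <- 0; s[zv] <- NA_real_; tv[zv] <- 0; pv[zv] <- 1
    est[rows] <- e; se[rows] <- s; tval[rows] <- tv; pval[rows] <- pv
    zero_var[rows] <- zv
  }

  keep <- !skipped
  res <- data.frame(probe_id = rownames(Y)[keep],
                    estimate = est[keep], se = se[keep], t = tval[keep],
                    p = pval[keep], q = bh_adjust(pval[keep]),
                    direction = sign(est[keep]), n_used = n_used[keep],
                    row.names = NULL)
  class(res) <- c("site_results", "data.frame")
  attr(res, "focal") <- focal
  attr(res, "reference_level") <- ref_level
  attr(res, "skipped") <- rownames(Y)[skipped]
  attr(res, "zero_variance") <- rownames(Y)[zero_var & keep]
  res
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment:
#' q(i) = min over j with p(j) >= p(i) of m * p(j) / rank(j), capped at 1,
#' mapped back to the input order.
#'
#' @param p_values numeric vector of p-values in \[0,1\].
#' @return numeric vector of q-values in input order.
#' @export
bh_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Global methylation summary
#'
#' Per-sample mean of unmasked M-values, group means/SDs, and the
#' group-difference p-value from a one-way linear model. Additional sample
#' covariates can be screened as predictors of the per-sample mean.
#'
#' @param m a [meth_matrix] on the M scale.
#' @param sheet sample sheet data frame.
#' @param group grouping column (default `"ancestry"`).
#' @param predictors optional character vector of further sheet columns to
#'   regress the per-sample mean on (one at a time).
#' @return list of class `global_meth_summary`: `sample_means`, per-group
#'   `group_stats` (mean, sd, n), `p_group`, and `predictor_p`.
#' @export
summarize_global_methylation <- function(m, sheet, group = "ancestry",
                                         predictors = NULL) {
  stopifnot_meth_matrix(m)
  if (m$scale != "m") stop("expected M-scale input")
  sheet <- align_sheet(sheet, sample_ids(m))
  g <- factor(sheet[[group]])
  if (nlevels(droplevels(g)) < 2) stop("need at least 2 groups")
  if (any(table(droplevels(g)) == 0)) stop("empty group")
  sm <- colMeans(m$values, na.rm = TRUE)
  stats_tab <- do.call(rbind, lapply(levels(g), function(lv) {
    x <- sm[g == lv]
    data.frame(group = lv, mean = mean(x), sd = stats::sd(x), n = length(x))
  }))
  p_group <- if (stats::var(sm) == 0) 1 else
    stats::anova(stats::lm(sm ~ g))[["Pr(>F)"]][1]
  predictor_p <- NULL
  if (!is.null(predictors)) {
    predictor_p <- vapply(predictors, function(v) {
      x <- sheet[[v]]
      ok <- !is.na(x)
      if (is.character(x)) x <- factor(x)
      fit <- stats::lm(sm[ok] ~ x[ok])
      stats::anova(fit)[["Pr(>F)"]][1]
    }, numeric(1))
  }
  structure(list(sample_means = sm, group_stats = stats_tab,
                 p_group = p_group, predictor_p = predictor_p),
            class = "global_meth_summary")
}

#' @export
print.global_meth_summary <- function(x, ...) {
  cat("global methylation (per-sample mean M):\n")
  print(x$group_stats, row.names = FALSE)
  cat(sprintf("group difference p = %.4g\n", x$p_group))
  invisible(x)
}
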