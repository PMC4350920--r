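#' Empirical-Bayes batch correction
#'
#' Removes batch location and scale effects with the parametric
#' empirical-Bayes model (ComBat): per-probe standardization given the
#' protected covariates, normal/inverse-gamma shrinkage of per-batch
#' location/scale estimates, and back-transformation. Protected biological
#' covariates (e.g. ancestry) are included in the model so their fit is
#' retained in the adjusted data.
#'
#' Masked (`NA`) entries are excluded from estimation by imputing the probe
#' mean for the adjustment arithmetic and re-masking afterwards. Probes with
#' zero variance are returned unchanged. With a single batch the input is
#' returned as is.
#'
#' The M scale is recommended (the location/scale model is better specified
#' there); beta-scale input is accepted, in which case adjusted values are
#' clipped back to \[0,1\].
#'
#' @param m a [meth_matrix].
#' @param batch per-sample batch labels (coerced to factor), length equal to
#'   the number of samples; each batch needs at least 2 samples.
#' @param covariates optional data frame of per-sample covariates to protect
#'   (model matrix built as `~ .`).
#' @return The adjusted `meth_matrix`.
#' @export
combat_adjust <- function(m, batch, covariates = NULL) {
  stopifnot_meth_matrix(m)
  batch <- factor(batch)
  if (length(batch) != ncol(m$values))
    stop("'batch' must have one label per sample")
  if (nlevels(batch) < 2) {
    message("single batch: nothing to correct")
    return(m)
  }
  if (any(table(batch) < 2))
    stop("each batch needs at least 2 samples")

  mod <- NULL
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    mod <- stats::model.matrix(~ ., data = covariates)
    full <- cbind(mod, stats::model.matrix(~ batch))
    if (qr(full)$rank < ncol(mod) + nlevels(batch) - 1)
      stop("batch is confounded with a protected covariate (singular design)")
  }

  x <- m$values
  mask <- is.na(x)
  pm <- rowMeans(x, na.rm = TRUE)
  pm[!is.finite(pm)] <- 0
  for (i in which(rowSums(mask) > 0)) x[i, mask[i, ]] <- pm[i]

  v <- apply(x, 1, stats::var)
  fixed <- v <= .Machine$double.eps
  adj <- x
  if (any(!fixed)) {
    adj[!fixed, ] <- suppressMessages(
      sva::ComBat(dat = x[!fixed, , drop = FALSE], batch = batch, mod = mod,
                  par.prior = TRUE, prior.plots = FALSE))
  }
  adj[mask] <- NA_real_
  if (m$scale == "beta") adj <- pmin(pmax(adj, 0), 1)
  m$values <- adj
  m
}
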