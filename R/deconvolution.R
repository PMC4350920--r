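#' Cell-type reference profiles
#'
#' Reference beta profiles for leukocyte populations, used for
#' reference-based deconvolution of whole-blood methylation.
#'
#' @param profile numeric matrix of beta values, probes in rows, one column
#'   per cell type; row and column names required.
#' @param discriminating_set optional character vector of probe ids used for
#'   projection (must be a subset of the rownames). May be filled in later by
#'   [select_discriminating_probes].
#' @return An object of class `cell_reference`.
#' @export
cell_reference <- function(profile, discriminating_set = NULL) {
  if (!is.matrix(profile) || !is.numeric(profile))
    stop("'profile' must be a numeric matrix (probes x cell types)")
  if (ncol(profile) < 2) stop("at least 2 cell types are required")
  if (is.null(rownames(profile)) || is.null(colnames(profile)))
    stop("'profile' needs probe rownames and cell-type colnames")
  if (any(profile < 0 | profile > 1, na.rm = TRUE))
    stop("reference profiles must be on the beta scale in [0, 1]")
  if (!is.null(discriminating_set)) {
    bad <- setdiff(discriminating_set, rownames(profile))
    if (length(bad)) stop("discriminating probes not in profile: ",
                          paste(utils::head(bad, 5), collapse = ", "))
  }
  structure(list(profile = profile,
                 cell_types = colnames(profile),
                 discriminating_set = discriminating_set),
            class = "cell_reference")
}

#' @export
print.cell_reference <- function(x, ...) {
  cat(sprintf("cell_reference: %d probes x %d cell types (%s); %d discriminating probes\n",
              nrow(x$profile), length(x$cell_types),
              paste(x$cell_types, collapse = ", "),
              length(x$discriminating_set)))
  invisible(x)
}

#' Select cell-type discriminating probes
#'
#' For each cell type, probes are ranked by how strongly they separate that
#' type from the mean of the others: by moderated two-sample |t| when
#' per-replicate reference profiles are available, otherwise by |delta beta|.
#' The top `top_n_per_type` probes are taken per type, split evenly between
#' the hyper- and hypomethylated directions, and the union is returned.
#'
#' @param ref a [cell_reference].
#' @param replicate_profiles optional named list, one probe-by-replicate beta
#'   matrix per cell type (>= 2 replicates each).
#' @param top_n_per_type probes selected per cell type (default 100).
#' @return The `cell_reference` with `discriminating_set` filled in.
#' @export
select_discriminating_probes <- function(ref, replicate_profiles = NULL,
                                         top_n_per_type = 100) {
  if (!inherits(ref, "cell_reference")) stop("expected a 'cell_reference'")
  prof <- ref$profile
  n_half <- ceiling(top_n_per_type / 2)
  sel <- character(0)
  for (ct in ref$cell_types) {
    if (!is.null(replicate_profiles)) {
      if (is.null(replicate_profiles[[ct]]) || ncol(replicate_profiles[[ct]]) < 2)
        stop("need >= 2 replicate profiles per cell type")
      this <- replicate_profiles[[ct]]
      other <- do.call(cbind, replicate_profiles[setdiff(ref$cell_types, ct)])
      stat <- row_t_stat(this[rownames(prof), , drop = FALSE],
                         other[rownames(prof), , drop = FALSE])
    } else {
      stat <- prof[, ct] - rowMeans(prof[, setdiff(colnames(prof), ct), drop = FALSE])
    }
    nonzero <- sum(abs(stat) > 0, na.rm = TRUE)
    if (nonzero == 0)
      stop("cell types are indistinguishable: no discriminating probes")
    if (nonzero < top_n_per_type)
      stop(sprintf("only %d candidate probes separate '%s'; %d requested",
                   nonzero, ct, top_n_per_type))
    up <- order(stat, decreasing = TRUE)[seq_len(n_half)]
    dn <- order(stat, decreasing = FALSE)[seq_len(n_half)]
    sel <- union(sel, rownames(prof)[c(up, dn)])
  }
  ref$discriminating_set <- sel
  ref
}

# Welch two-sample t statistic per row.
row_t_stat <- function(a, b) {
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- apply(a, 1, stats::var); vb <- apply(b, 1, stats::var)
  (ma - mb) / sqrt(va / ncol(a) + vb / ncol(b) + 1e-12)
}

#' Estimate cell-type fractions by constrained projection
#'
#' Per sample, solves min ||R w - y||^2 over the discriminating probe set,
#' subject to w >= 0 and sum(w) <= 1 (Houseman-style reference-based
#' deconvolution). The fractions need not sum to 1 because only a subset of
#' leukocyte types is modelled. The quadratic program is solved exactly by
#' enumerating active sets of the (small) constraint system.
#'
#' @param m a [meth_matrix] on the beta scale.
#' @param ref a [cell_reference] with a non-empty `discriminating_set`
#'   present in `m`.
#' @return data frame with `sample_id`, one fraction column per cell type,
#'   and `residual_norm`. Samples for which every discriminating probe is
#'   masked get `NA` fractions.
#' @export
estimate_fractions <- function(m, ref) {
  stopifnot_meth_matrix(m)
  if (m$scale != "beta") stop("deconvolution operates on the beta scale")
  if (!inherits(ref, "cell_reference")) stop("expected a 'cell_reference'")
  disc <- intersect(ref$discriminating_set, probe_ids(m))
  if (!length(disc)) stop("no discriminating probes present in the matrix")
  R <- ref$profile[disc, , drop = FALSE]
  Y <- m$values[disc, , drop = FALSE]
  k <- ncol(R)
  out <- matrix(NA_real_, nrow = ncol(Y), ncol = k,
                dimnames = list(colnames(Y), colnames(R)))
  rn <- rep(NA_real_, ncol(Y))
  for (s in seq_len(ncol(Y))) {
    y <- Y[, s]
    ok <- !is.na(y)
    if (!any(ok)) next
    fit <- solve_simplex_ls(R[ok, , drop = FALSE], y[ok])
    out[s, ] <- fit$w
    rn[s] <- fit$resid
  }
  df <- data.frame(sample_id = colnames(Y), out, residual_norm = rn,
                   row.names = NULL, check.names = FALSE)
  df
}

# Exact small QP: min ||A w - y||^2 s.t. w >= 0, sum(w) <= 1.
# Enumerates all subsets of active constraints {w_i = 0} x {sum = 1}, solves
# each equality-constrained least squares via KKT, keeps the feasible
# solution with the lowest objective. Exhaustive, hence globally optimal.
solve_simplex_ls <- function(A, y, tol = 1e-9) {
  k <- ncol(A)
  AtA <- crossprod(A); Aty <- crossprod(A, y)
  best <- NULL; best_obj <- Inf
  for (zero_mask in 0:(2^k - 1)) {
    zero <- as.logical(bitwAnd(zero_mask, 2^(seq_len(k) - 1)))
    free <- which(!zero)
    for (sum_active in c(FALSE, TRUE)) {
      w <- numeric(k)
      if (length(free) == 0) {
        if (sum_active) next
      } else {
        H <- AtA[free, free, drop = FALSE]
        g <- Aty[free, ]
        if (sum_active) {
          # KKT system with equality sum(w_free) = 1
          kk <- length(free)
          M <- rbind(cbind(H, rep(1, kk)), c(rep(1, kk), 0))
          sol <- tryCatch(solve(M, c(g, 1)), error = function(e) NULL)
          if (is.null(sol)) next
          w[free] <- sol[seq_len(kk)]
        } else {
          sol <- tryCatch(solve(H, g), error = function(e) NULL)
          if (is.null(sol)) next
          w[free] <- sol
        }
      }
      if (any(w < -tol) || sum(w) > 1 + tol) next
      w <- pmax(w, 0)
      r <- A %*% w - y
      obj <- sum(r^2)
      if (obj < best_obj - 1e-15) {
        best_obj <- obj
        best <- w
      }
    }
  }
  list(w = as.numeric(best), resid = sqrt(best_obj))
}
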