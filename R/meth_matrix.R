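#' Probe-by-sample methylation matrix
#'
#' Container for array methylation values on either the beta scale
#' (methylated fraction in \[0,1\]) or the M scale (logit2 of beta), with an
#' optional aligned detection p-value matrix. Masked (low-confidence or
#' filtered) entries are stored as `NA`; the missingness mask is therefore
#' `is.na(values)`.
#'
#' @param values numeric matrix, probes in rows, samples in columns. Row and
#'   column names are required and must be unique.
#' @param detection_p optional numeric matrix in \[0,1\], same shape and
#'   dimnames as `values`.
#' @param scale `"beta"` or `"m"`.
#' @return An object of class `meth_matrix`: a list with elements `values`,
#'   `detection_p` and `scale`.
#' @export
meth_matrix <- function(values, detection_p = NULL, scale = c("beta", "m")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have probe rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate probe ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  if (scale == "beta") {
    rng <- range(values, na.rm = TRUE)
    if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 1))
      stop("beta-scale values must lie in [0, 1]")
  }
  if (!is.null(detection_p)) {
    if (!identical(dim(detection_p), dim(values)))
      stop("'detection_p' must have the same shape as 'values'")
    if (!identical(dimnames(detection_p), dimnames(values)))
      dimnames(detection_p) <- dimnames(values)
    if (any(detection_p < 0 | detection_p > 1, na.rm = TRUE))
      stop("detection p-values must lie in [0, 1]")
  }
  structure(list(values = values, detection_p = detection_p, scale = scale),
            class = "meth_matrix")
}

#' @export
print.meth_matrix <- function(x, ...) {
  cat(sprintf("meth_matrix: %d probes x %d samples [%s scale], %d masked entries\n",
              nrow(x$values), ncol(x$values), x$scale, sum(is.na(x$values))))
  invisible(x)
}

#' @export
dim.meth_matrix <- function(x) dim(x$values)

probe_ids <- function(m) rownames(m$values)
sample_ids <- function(m) colnames(m$values)

stopifnot_meth_matrix <- function(m) {
  if (!inherits(m, "meth_matrix")) stop("expected a 'meth_matrix' object")
  invisible(m)
}

#' Mask low-confidence measurements
#'
#' Entries whose detection p-value is greater than or equal to the threshold
#' are set to `NA`. The comparison is inclusive: an entry with detection
#' p-value exactly equal to the threshold is treated as missing.
#'
#' @param m a [meth_matrix] on the beta scale with a detection p-value matrix.
#' @param p_threshold detection p-value threshold (default 0.001).
#' @return The masked `meth_matrix`.
#' @export
mask_low_confidence <- function(m, p_threshold = 0.001) {
  stopifnot_meth_matrix(m)
  if (is.null(m$detection_p))
    stop("no detection p-value matrix present")
  if (!is.numeric(p_threshold) || length(p_threshold) != 1 ||
      p_threshold < 0 || p_threshold > 1)
    stop("'p_threshold' must be a single probability")
  fail <- m$detection_p >= p_threshold
  m$values[fail] <- NA_real_
  m
}

#' Beta to M-value transform
#'
#' M = log2(beta' / (1 - beta')) with beta' clipped to
#' \[epsilon, 1 - epsilon\] so the transform is total. `NA` entries (the
#' missingness mask) are preserved.
#'
#' @param m a [meth_matrix] on the beta scale.
#' @param epsilon clipping bound (default 1e-6).
#' @return A `meth_matrix` on the M scale.
#' @export
beta_to_m <- function(m, epsilon = 1e-6) {
  stopifnot_meth_matrix(m)
  if (m$scale != "beta") stop("input is already on the M scale")
  b <- pmin(pmax(m$values, epsilon), 1 - epsilon)
  m$values <- log2(b / (1 - b))
  m$scale <- "m"
  m
}

#' M-value to beta inverse transform
#'
#' Inverse of [beta_to_m]: beta = 2^M / (1 + 2^M).
#'
#' @param m a [meth_matrix] on the M scale.
#' @return A `meth_matrix` on the beta scale.
#' @export
m_to_beta <- function(m) {
  stopifnot_meth_matrix(m)
  if (m$scale != "m") stop("input is not on the M scale")
  e <- 2^m$values
  m$values <- e / (1 + e)
  m$scale <- "beta"
  m
}
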