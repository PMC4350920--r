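#' Per-probe replication tests
#'
#' Two-sided unpaired rank-sum (Wilcoxon) test per probe between the two
#' ancestry groups of a replication cohort, with direction defined as the
#' sign of the group-mean M difference (African-ancestry minus
#' European-ancestry group, i.e. second factor level minus reference level).
#'
#' @param m a [meth_matrix] on the M scale.
#' @param sheet sample sheet covering the samples of `m`.
#' @param group grouping column (default `"ancestry"`), a two-level factor.
#' @return data frame: `probe_id`, `p_replication`, `direction_replication`.
#' @export
replication_tests <- function(m, sheet, group = "ancestry") {
  stopifnot_meth_matrix(m)
  if (m$scale != "m") stop("expected M-scale input")
  sheet <- align_sheet(sheet, sample_ids(m))
  g <- factor(sheet[[group]])
  if (nlevels(droplevels(g)) != 2) stop("replication test needs exactly 2 groups")
  lv <- levels(droplevels(g))
  a <- m$values[, g == lv[2], drop = FALSE]   # focal (African-ancestry) group
  b <- m$values[, g == lv[1], drop = FALSE]
  p <- numeric(nrow(a)); d <- numeric(nrow(a))
  for (i in seq_len(nrow(a))) {
    xa <- a[i, !is.na(a[i, ])]; xb <- b[i, !is.na(b[i, ])]
    if (length(xa) < 2 || length(xb) < 2) { p[i] <- NA; d[i] <- NA; next }
    p[i] <- stats::wilcox.test(xa, xb, exact = FALSE)$p.value
    d[i] <- sign(mean(xa) - mean(xb))
  }
  data.frame(probe_id = probe_ids(m), p_replication = p,
             direction_replication = d, row.names = NULL)
}

#' Two-criterion cross-cohort replication filter
#'
#' A probe counts as ancestry-specific when (1) its discovery q-value is at
#' or below `fdr_threshold`, (2) its replication p-value is at or below
#' `nominal_threshold` (both thresholds inclusive), and (3) the direction of
#' effect agrees in both cohorts. Discovery-significant probes absent from
#' the replication table are classified not-replicated and counted in
#' `attr(result, "n_missing_from_replication")`.
#'
#' @param discovery a `site_results` data frame (see [fit_site_models]).
#' @param replication data frame with columns `probe_id`, `p_replication`,
#'   `direction_replication` (see [replication_tests]).
#' @param fdr_threshold discovery FDR threshold (default 0.05).
#' @param nominal_threshold replication nominal p threshold (default 0.05).
#' @return data frame of class `replication_records`: per discovery probe,
#'   `probe_id`, `q_discovery`, `direction_discovery`, `p_replication`,
#'   `direction_replication`, `replicated`, and `class` (one of
#'   `"low_in_african"`, `"high_in_african"`, `"not_replicated"`).
#' @export
replication_filter <- function(discovery, replication,
                               fdr_threshold = 0.05, nominal_threshold = 0.05) {
  need <- c("probe_id", "p_replication", "direction_replication")
  if (!all(need %in% names(replication)))
    stop("replication table needs columns: ", paste(need, collapse = ", "))
  if (!length(intersect(discovery$probe_id, replication$probe_id)))
    stop("no probes shared between discovery and replication")
  if (anyNA(discovery$direction))
    stop("missing direction in discovery results")
  idx <- match(discovery$probe_id, replication$probe_id)
  p_rep <- replication$p_replication[idx]
  d_rep <- replication$direction_replication[idx]
  sig <- discovery$q <= fdr_threshold
  rep_ok <- !is.na(p_rep) & !is.na(d_rep) &
    p_rep <= nominal_threshold & d_rep == discovery$direction
  replicated <- sig & rep_ok
  cls <- rep("not_replicated", nrow(discovery))
  cls[replicated & discovery$direction < 0] <- "low_in_african"
  cls[replicated & discovery$direction > 0] <- "high_in_african"
  out <- data.frame(probe_id = discovery$probe_id,
                    q_discovery = discovery$q,
                    direction_discovery = discovery$direction,
                    p_replication = p_rep,
                    direction_replication = d_rep,
                    replicated = replicated,
                    class = cls, row.names = NULL)
  class(out) <- c("replication_records", "data.frame")
  attr(out, "n_missing_from_replication") <- sum(sig & is.na(idx))
  attr(out, "fdr_threshold") <- fdr_threshold
  attr(out, "nominal_threshold") <- nominal_threshold
  out
}

#' Direction classification of replicated probes
#'
#' @param records a `replication_records` data frame.
#' @return list: `n_low`, `n_high`, `n_replicated`, and `fractions`
#'   (low/high proportions among replicated probes; they sum to 1).
#' @export
classify_directions <- function(records) {
  if (!nrow(records)) stop("no records")
  n_low <- sum(records$class == "low_in_african")
  n_high <- sum(records$class == "high_in_african")
  n_rep <- n_low + n_high
  fr <- if (n_rep > 0) c(low = n_low / n_rep, high = n_high / n_rep)
        else c(low = NA_real_, high = NA_real_)
  list(n_low = n_low, n_high = n_high, n_replicated = n_rep, fractions = fr)
}

#' Hypergeometric set-enrichment test
#'
#' Upper-tail hypergeometric probability of observing at least `k` annotated
#' probes among `n` selected, given `K` annotated in a background of `N`:
#' P(X >= k) = sum_{j=k}^{min(n,K)} C(K,j) C(N-K,n-j) / C(N,n), evaluated in
#' log space so tails down to ~1e-300 (and their log10 beyond that) are
#' reported accurately. Fold enrichment is k N / (n K). The same operation,
#' fed an arbitrary user-supplied annotation set, serves as a generic gene
#' set enrichment utility.
#'
#' @param N background count.
#' @param K annotated count in the background.
#' @param n selected count.
#' @param k annotated count among the selected.
#' @return list of class `enrichment_result`: the four counts, `expected`
#'   overlap, `fold`, `p` and `log10_p`.
#' @export
hypergeometric_enrichment <- function(N, K, n, k) {
  for (v in list(N, K, n, k))
    if (length(v) != 1 || v < 0 || v != round(v)) stop("counts must be single non-negative integers")
  if (K > N || n > N) stop("K and n must not exceed N")
  if (k > min(n, K)) stop("k must not exceed min(n, K)")
  lp <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE)
  expected <- n * K / N
  fold <- if (expected > 0) k / expected else NA_real_
  structure(list(N = N, K = K, n = n, k = k, expected = expected,
                 fold = fold, p = exp(lp), log10_p = lp / log(10)),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("hypergeometric enrichment: %d / %d selected vs %d / %d background\n",
              x$k, x$n, x$K, x$N))
  cat(sprintf("  expected overlap %.2f, fold %.3f, P(X >= k) = %.4g (log10 = %.2f)\n",
              x$expected, x$fold, x$p, x$log10_p))
  invisible(x)
}
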