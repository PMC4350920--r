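# Shared fixture builders. Everything is generated in code; no stored data.

# Tiny probe-by-sample matrix with explicit dimnames.
make_mm <- function(values, detection_p = NULL, scale = "beta") {
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("cg%06d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("S%03d", seq_len(ncol(values)))
  if (!is.null(detection_p)) dimnames(detection_p) <- dimnames(values)
  meth_matrix(values, detection_p, scale = scale)
}

# Small synthetic cohort for fast unit tests.
small_config <- function(seed = 1, ...) {
  sim_config(n_probes = 400, n_discovery = c(african = 40, european = 35),
             n_replication = c(african = 15, european = 15),
             module_size = 0, n_comod_blocks = 0, rng_seed = seed, ...)
}

simulate_small <- function(seed = 1, ...) {
  cfg <- small_config(seed, ...)
  simulate_cohort(cfg, simulate_reference_profiles(cfg))
}

discovery_sheet <- function(sim) sim$sheet[sim$sheet$cohort == "discovery", ]

# Independent brute-force oracles -------------------------------------------

# BH step-up by the definitional min-over-suffix rule.
bh_brute <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    r <- which(ord == i)          # rank of p[i]
    q[i] <- min(1, min(m / (r:m) * p[ord[r:m]]))
  }
  q
}

# Hypergeometric upper tail by direct pmf summation.
hyper_tail_brute <- function(N, K, n, k) {
  if (k > min(n, K)) return(0)
  sum(stats::dhyper(k:min(n, K), K, N - K, n))
}

# TOM by the definitional triple loop.
tom_brute <- function(a) {
  n <- nrow(a)
  k <- rowSums(a)
  out <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    num <- a[i, j]
    for (u in seq_len(n))
      if (u != i && u != j) num <- num + a[i, u] * a[u, j]
    out[i, j] <- num / (min(k[i], k[j]) + 1 - a[i, j])
  }
  dimnames(out) <- dimnames(a)
  out
}

# Random symmetric adjacency with zero diagonal, entries in [0,1].
random_adjacency <- function(n) {
  a <- matrix(stats::runif(n * n), n, n)
  a <- (a + t(a)) / 2
  diag(a) <- 0
  dimnames(a) <- list(paste0("p", seq_len(n)), paste0("p", seq_len(n)))
  a
}
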