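#' Probe-level quality filters
#'
#' Removes, in order: probes flagged as overlapping a common SNP, probes on
#' the sex chromosomes, probes without a gene annotation, and (optionally)
#' probes whose median detection p-value across samples exceeds a threshold.
#' Each probe is counted in exactly one category, the first that applies.
#'
#' The median-detection rule is off by default: entry-level masking at
#' detection p >= 0.001 (see [mask_low_confidence]) is the operative QC, and
#' a probe-level median rule is only meaningful with a deliberately chosen
#' threshold.
#'
#' @param m a [meth_matrix].
#' @param manifest data frame with columns `probe_id`, `gene`, `chromosome`,
#'   `snp_overlap` (logical); must cover every probe of `m`.
#' @param drop_snp,drop_sex,drop_unannotated logical switches (all `TRUE` by
#'   default).
#' @param median_detection_threshold optional probability; probes with median
#'   detection p-value >= this threshold are dropped. `NULL` (default)
#'   disables the rule.
#' @return list with elements `matrix` (the filtered `meth_matrix`) and
#'   `report` (class `filter_report`: input/output and per-rule drop counts).
#' @export
filter_probes <- function(m, manifest, drop_snp = TRUE, drop_sex = TRUE,
                          drop_unannotated = TRUE,
                          median_detection_threshold = NULL) {
  stopifnot_meth_matrix(m)
  ids <- probe_ids(m)
  missing_ids <- setdiff(ids, manifest$probe_id)
  if (length(missing_ids))
    stop("probe ids absent from manifest: ",
         paste(utils::head(missing_ids, 5), collapse = ", "))
  man <- manifest[match(ids, manifest$probe_id), , drop = FALSE]

  drop_cat <- rep(NA_character_, length(ids))
  if (drop_snp)
    drop_cat[is.na(drop_cat) & man$snp_overlap] <- "snp"
  if (drop_sex)
    drop_cat[is.na(drop_cat) & toupper(man$chromosome) %in% c("X", "Y")] <- "sex"
  if (drop_unannotated)
    drop_cat[is.na(drop_cat) & (is.na(man$gene) | man$gene == "")] <- "unannotated"
  if (!is.null(median_detection_threshold)) {
    if (is.null(m$detection_p))
      stop("median detection rule requires a detection p-value matrix")
    med <- apply(m$detection_p, 1, stats::median, na.rm = TRUE)
    drop_cat[is.na(drop_cat) & med >= median_detection_threshold] <- "detection"
  }

  keep <- is.na(drop_cat)
  out <- m
  out$values <- m$values[keep, , drop = FALSE]
  if (!is.null(m$detection_p))
    out$detection_p <- m$detection_p[keep, , drop = FALSE]

  report <- structure(list(
    n_input_probes      = length(ids),
    n_masked_entries    = sum(is.na(m$values)),
    n_dropped_snp       = sum(drop_cat == "snp", na.rm = TRUE),
    n_dropped_sex       = sum(drop_cat == "sex", na.rm = TRUE),
    n_dropped_unannotated = sum(drop_cat == "unannotated", na.rm = TRUE),
    n_dropped_detection = sum(drop_cat == "detection", na.rm = TRUE),
    n_output_probes     = sum(keep)
  ), class = "filter_report")
  stopifnot(report$n_output_probes ==
    report$n_input_probes - report$n_dropped_snp - report$n_dropped_sex -
    report$n_dropped_unannotated - report$n_dropped_detection)
  list(matrix = out, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf(
    "probe filter: %d in -> %d out (snp %d, sex %d, unannotated %d, detection %d); %d masked entries\n",
    x$n_input_probes, x$n_output_probes, x$n_dropped_snp, x$n_dropped_sex,
    x$n_dropped_unannotated, x$n_dropped_detection, x$n_masked_entries))
  invisible(x)
}
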