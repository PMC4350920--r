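#' @title On-disk formats
#' @description
#' All tables are UTF-8 tab-separated values without quoting; missing
#' entries are encoded `NA`. Matrix TSVs have `probe_id` as the first
#' column and one column per sample. Probe and sample ids are restricted to
#' `[A-Za-z0-9_.-]`. Files with CRLF line endings parse identically.
#' @name methweave-formats
NULL

ID_RE <- "^[A-Za-z0-9_.-]+$"

write_table_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

read_table_tsv <- function(path) {
  nf <- utils::count.fields(path, sep = "\t", quote = "", comment.char = "")
  if (length(unique(nf)) != 1)
    stop("ragged rows in ", path)
  utils::read.delim(path, sep = "\t", quote = "", comment.char = "",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

check_ids <- function(ids, what) {
  if (anyNA(ids) || !all(grepl(ID_RE, ids)))
    stop(what, " ids must match [A-Za-z0-9_.-]+")
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate ", what, " id: ", paste(utils::head(dup, 5), collapse = ", "))
  invisible(ids)
}

#' Write / read a probe-by-sample matrix TSV
#'
#' @param values numeric matrix with probe rownames and sample colnames.
#' @param path file path.
#' @return `write_matrix` returns the path invisibly; `read_matrix` returns
#'   the numeric matrix.
#' @export
write_matrix <- function(values, path) {
  check_ids(rownames(values), "probe")
  check_ids(colnames(values), "sample")
  df <- data.frame(probe_id = rownames(values), values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_table_tsv(df, path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  df <- read_table_tsv(path)
  if (names(df)[1] != "probe_id") stop("first column must be 'probe_id'")
  check_ids(df$probe_id, "probe")
  check_ids(names(df)[-1], "sample")
  vals <- df[, -1, drop = FALSE]
  bad <- !vapply(vals, is.numeric, logical(1))
  if (any(bad))
    stop("non-numeric cells in column(s): ",
         paste(names(vals)[bad], collapse = ", "))
  m <- as.matrix(vals)
  rownames(m) <- df$probe_id
  m
}

#' Write / read the sample sheet TSV
#'
#' On reading, an `ancestry` column is converted to a factor with
#' `ancestry_reference` as the reference (first) level, so that regression
#' coefficients are consistently African-minus-European when the reference
#' is the European group.
#'
#' @param sheet sample sheet data frame (needs `sample_id`).
#' @param path file path.
#' @param ancestry_reference reference ancestry level (default `"EA"`).
#' @return `write_sheet` returns the path invisibly; `read_sheet` the data
#'   frame.
#' @export
write_sheet <- function(sheet, path) {
  if (!"sample_id" %in% names(sheet)) stop("sheet needs a 'sample_id' column")
  check_ids(sheet$sample_id, "sample")
  write_table_tsv(sheet, path)
}

#' @rdname write_sheet
#' @export
read_sheet <- function(path, ancestry_reference = "EA") {
  df <- read_table_tsv(path)
  if (!"sample_id" %in% names(df)) stop("sheet needs a 'sample_id' column")
  check_ids(df$sample_id, "sample")
  if ("ancestry" %in% names(df)) {
    lv <- unique(df$ancestry[!is.na(df$ancestry)])
    lv <- c(intersect(ancestry_reference, lv), setdiff(sort(lv), ancestry_reference))
    df$ancestry <- factor(df$ancestry, levels = lv)
  }
  df
}

#' Write / read the probe manifest TSV
#'
#' Columns: `probe_id`, `gene`, `chromosome` (string, `"1"`..`"22"`, `"X"`,
#' `"Y"`), `cgi`, `snp_overlap`, `meqtl`.
#'
#' @param manifest manifest data frame.
#' @param path file path.
#' @return `write_manifest` returns the path invisibly; `read_manifest` the
#'   data frame.
#' @export
write_manifest <- function(manifest, path) {
  check_ids(manifest$probe_id, "probe")
  write_table_tsv(manifest, path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  df <- read_table_tsv(path)
  need <- c("probe_id", "gene", "chromosome", "snp_overlap", "meqtl")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("manifest missing columns: ", paste(miss, collapse = ", "))
  check_ids(df$probe_id, "probe")
  df$chromosome <- as.character(df$chromosome)
  df$gene <- as.character(df$gene)
  df
}

#' Write / read cell-type reference profiles
#'
#' Probes-by-cell-types beta TSV with a trailing logical `discriminating`
#' column marking the projection probe set.
#'
#' @param ref a [cell_reference].
#' @param path file path.
#' @return `write_reference` returns the path invisibly; `read_reference`
#'   a `cell_reference`.
#' @export
write_reference <- function(ref, path) {
  if (!inherits(ref, "cell_reference")) stop("expected a 'cell_reference'")
  df <- data.frame(probe_id = rownames(ref$profile), ref$profile,
                   discriminating = rownames(ref$profile) %in% ref$discriminating_set,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_table_tsv(df, path)
}

#' @rdname write_reference
#' @export
read_reference <- function(path) {
  df <- read_table_tsv(path)
  if (names(df)[1] != "probe_id" || !"discriminating" %in% names(df))
    stop("reference TSV needs 'probe_id' first and a 'discriminating' column")
  check_ids(df$probe_id, "probe")
  types <- setdiff(names(df), c("probe_id", "discriminating"))
  prof <- as.matrix(df[types])
  rownames(prof) <- df$probe_id
  cell_reference(prof, discriminating_set = df$probe_id[df$discriminating])
}
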