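# Delimited-text input/output for Ct tables. Two layouts are supported:
# long  : columns sample_id, gene, ct [, well, treatment, age, tissue,
#         subject_id, biological_replicate]
# wide  : sample_id [, metadata columns], one column per gene
# Separator auto-detected from the extension (.csv -> comma, else tab).

.meta_columns <- c("treatment", "age", "tissue", "subject_id",
                   "biological_replicate")
.missing_markers <- c("", "nd", "n.d.", "na", "n/a", "nan", "undetermined",
                      "undet", "-")

# Parse a character Ct column: conventional not-detected markers become NA,
# anything else non-numeric is an error naming the offending rows.
parse_ct_column <- function(x, what = "ct") {
  if (is.numeric(x)) return(as.numeric(x))
  x_chr <- trimws(as.character(x))
  miss <- is.na(x_chr) | tolower(x_chr) %in% .missing_markers
  out <- suppressWarnings(as.numeric(x_chr))
  bad <- which(!miss & is.na(out))
  if (length(bad)) {
    show <- bad[seq_len(min(3L, length(bad)))]
    stop(sprintf("non-numeric %s value(s) %s at data row(s) %s",
                 what, paste(sQuote(x_chr[show]), collapse = ", "),
                 paste(show, collapse = ", ")))
  }
  out[miss] <- NA_real_
  out
}

infer_sep <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

# Build a ct_matrix from unique long records, preserving order of first
# appearance for both genes and samples; absent combinations become NA.
long_to_matrix <- function(long, efficiency = 2, ct_range = c(5, 40)) {
  gene_ids <- unique(long$gene)
  sample_ids <- unique(long$sample_id)
  m <- matrix(NA_real_, length(gene_ids), length(sample_ids),
              dimnames = list(gene_ids, sample_ids))
  m[cbind(match(long$gene, gene_ids), match(long$sample_id, sample_ids))] <-
    long$ct
  ct_matrix(m, efficiency = efficiency, ct_range = ct_range)
}

extract_meta <- function(tab) {
  present <- intersect(.meta_columns, names(tab))
  if (!length(present)) return(NULL)
  meta <- unique(tab[c("sample_id", present)])
  if (anyDuplicated(meta$sample_id))
    stop("inconsistent metadata: sample(s) ",
         paste(unique(meta$sample_id[duplicated(meta$sample_id)]), collapse = ", "),
         " carry conflicting factor values")
  if ("biological_replicate" %in% names(meta))
    meta$biological_replicate <- as.integer(meta$biological_replicate)
  rownames(meta) <- NULL
  meta
}

#' Read a Ct table from delimited text
#'
#' Reads long- or wide-layout cycle-threshold tables exported from qPCR
#' instrument software. Blank cells and conventional not-detected markers
#' (`ND`, `NA`, `NaN`, `Undetermined`, `-`) become missing values; any other
#' non-numeric Ct is an error naming the row. When a long table carries a
#' `well` column with several wells per (sample, gene), technical replicates
#' are collapsed via [collapse_technical_replicates()].
#'
#' @param path Path to a `.csv` (comma) or `.tsv`/other (tab) file with a
#'   header row.
#' @param layout `"long"` (columns `sample_id`, `gene`, `ct`, optional
#'   `well` and metadata columns) or `"wide"` (`sample_id`, optional
#'   metadata columns, one column per gene).
#' @param sep Field separator; default inferred from the file extension.
#' @param collapse_policy,range_threshold Passed to
#'   [collapse_technical_replicates()] when wells are present.
#' @param efficiency,ct_range Passed to [ct_matrix()].
#' @return A list with `ct` (a [ct_matrix()]) and `meta` (a `data.frame`, or
#'   `NULL` when the file has no metadata columns).
#' @export
read_ct_table <- function(path, layout = c("long", "wide"), sep = NULL,
                          collapse_policy = c("mean", "outlier_drop"),
                          range_threshold = 0.5,
                          efficiency = 2, ct_range = c(5, 40)) {
  layout <- match.arg(layout)
  collapse_policy <- match.arg(collapse_policy)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) sep <- infer_sep(path)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character", quote = "\"",
                           comment.char = "", blank.lines.skip = TRUE)
  if (nrow(raw) == 0L) stop("empty table: ", path)

  if (layout == "long") {
    need <- c("sample_id", "gene", "ct")
    miss <- setdiff(need, names(raw))
    if (length(miss))
      stop("long layout requires column(s): ", paste(miss, collapse = ", "))
    long <- data.frame(sample_id = raw$sample_id, gene = raw$gene,
                       ct = parse_ct_column(raw$ct), stringsAsFactors = FALSE)
    has_well <- "well" %in% names(raw)
    if (has_well) long$well <- raw$well
    key <- paste(long$sample_id, long$gene, sep = "\r")
    if (!has_well && anyDuplicated(key)) {
      dup <- unique(key[duplicated(key)])
      stop("duplicate (sample, gene) rows without a `well` column: ",
           paste(gsub("\r", "/", dup[seq_len(min(3L, length(dup)))]),
                 collapse = ", "))
    }
    n_missing <- sum(is.na(long$ct))
    if (n_missing > 0L)
      message(sprintf("%d missing Ct value(s) in %s", n_missing, path))
    ct <- if (has_well && anyDuplicated(key)) {
      collapse_technical_replicates(long, policy = collapse_policy,
                                    range_threshold = range_threshold,
                                    efficiency = efficiency,
                                    ct_range = ct_range)
    } else {
      long_to_matrix(long, efficiency = efficiency, ct_range = ct_range)
    }
    meta <- extract_meta(raw)
  } else {
    if (!"sample_id" %in% names(raw))
      stop("wide layout requires a `sample_id` column")
    if (anyDuplicated(raw$sample_id))
      stop("duplicated sample_id rows in wide layout: ",
           paste(unique(raw$sample_id[duplicated(raw$sample_id)]), collapse = ", "))
    gene_cols <- setdiff(names(raw), c("sample_id", "well", .meta_columns))
    if (!length(gene_cols)) stop("wide layout has no gene columns")
    m <- vapply(gene_cols, function(g) parse_ct_column(raw[[g]], what = g),
                numeric(nrow(raw)))
    m <- matrix(m, nrow = nrow(raw),
                dimnames = list(raw$sample_id, gene_cols))
    n_missing <- sum(is.na(m))
    if (n_missing > 0L)
      message(sprintf("%d missing Ct value(s) in %s", n_missing, path))
    ct <- ct_matrix(t(m), efficiency = efficiency, ct_range = ct_range)
    meta <- extract_meta(raw)
  }
  list(ct = ct, meta = meta)
}

# Full-precision numeric formatting so write -> read round-trips exactly.
fmt_num <- function(v) ifelse(is.na(v), "", sprintf("%.17g", v))

#' Write a Ct table as delimited text
#'
#' Inverse of [read_ct_table()]: present values round-trip bit-identically
#' (written with 17 significant digits) and missing entries are preserved as
#' empty cells.
#'
#' @param x A [ct_matrix()].
#' @param path Output path; `.csv` writes comma-separated, anything else tab.
#' @param meta Optional sample metadata merged into the output.
#' @param layout `"wide"` (default) or `"long"`.
#' @return `path`, invisibly.
#' @export
write_ct_table <- function(x, path, meta = NULL, layout = c("wide", "long")) {
  layout <- match.arg(layout)
  x <- as_ct(x)
  if (!is.null(meta)) check_meta(x, meta)
  sep <- infer_sep(path)
  if (layout == "wide") {
    tab <- data.frame(sample_id = colnames(x$ct), stringsAsFactors = FALSE)
    if (!is.null(meta)) {
      ord <- meta[match(tab$sample_id, meta$sample_id), , drop = FALSE]
      for (cn in setdiff(names(ord), "sample_id")) tab[[cn]] <- ord[[cn]]
    }
    for (g in rownames(x$ct)) tab[[g]] <- fmt_num(x$ct[g, ])
  } else {
    tab <- data.frame(
      sample_id = rep(colnames(x$ct), each = nrow(x$ct)),
      gene = rep(rownames(x$ct), times = ncol(x$ct)),
      ct = fmt_num(as.vector(x$ct)),
      stringsAsFactors = FALSE)
    if (!is.null(meta)) {
      ord <- meta[match(tab$sample_id, meta$sample_id), , drop = FALSE]
      for (cn in setdiff(names(ord), "sample_id")) tab[[cn]] <- ord[[cn]]
    }
  }
  utils::write.table(tab, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

collapse_wells <- function(v, policy, threshold) {
  v <- v[!is.na(v)]
  if (!length(v)) return(NA_real_)
  if (policy == "outlier_drop" && length(v) >= 2L &&
      (max(v) - min(v)) > threshold) {
    d <- abs(v - stats::median(v))
    worst <- which(d == max(d))
    # value-based tie rule (drop the highest Ct) keeps the result
    # independent of well order
    if (length(worst) > 1L) worst <- worst[which.max(v[worst])]
    v <- v[-worst]
  }
  mean(v)
}

#' Collapse technical replicate wells to one Ct per (sample, gene)
#'
#' qPCR reactions are typically run in technical triplicate. Policy `"mean"`
#' takes the arithmetic mean of the wells. Policy `"outlier_drop"` first
#' checks the well range: if `max - min` exceeds `range_threshold` cycles,
#' the well farthest from the median is dropped (ties broken by dropping the
#' higher Ct) before averaging the remainder. All-missing wells collapse to
#' a missing entry.
#'
#' @param ct_long Long-form `data.frame` with columns `sample_id`, `gene`,
#'   `ct` (and optionally `well`; the well index itself is not used).
#' @param policy `"mean"` (default) or `"outlier_drop"`.
#' @param range_threshold Non-negative well-range threshold in cycles for
#'   the outlier rule.
#' @param efficiency,ct_range Passed to [ct_matrix()].
#' @return A [ct_matrix()] with one collapsed Ct per (gene, sample).
#' @examples
#' long <- data.frame(sample_id = "s1", gene = "g1", well = 1:3,
#'                    ct = c(20.0, 20.1, 21.5))
#' as.matrix(collapse_technical_replicates(long, "outlier_drop"))  # 20.05
#' @export
collapse_technical_replicates <- function(ct_long,
                                          policy = c("mean", "outlier_drop"),
                                          range_threshold = 0.5,
                                          efficiency = 2, ct_range = c(5, 40)) {
  policy <- match.arg(policy)
  if (!is.numeric(range_threshold) || length(range_threshold) != 1L ||
      is.na(range_threshold) || range_threshold < 0)
    stop("`range_threshold` must be a single non-negative number of cycles")
  need <- c("sample_id", "gene", "ct")
  miss <- setdiff(need, names(ct_long))
  if (length(miss))
    stop("`ct_long` requires column(s): ", paste(miss, collapse = ", "))
  if (nrow(ct_long) == 0L) stop("`ct_long` is empty")
  ct <- parse_ct_column(ct_long$ct)
  key <- paste(ct_long$sample_id, ct_long$gene, sep = "\r")
  grp <- factor(key, levels = unique(key))
  collapsed <- vapply(split(ct, grp), collapse_wells, numeric(1),
                      policy = policy, threshold = range_threshold)
  first <- !duplicated(key)
  long1 <- data.frame(sample_id = ct_long$sample_id[first],
                      gene = ct_long$gene[first],
                      ct = unname(collapsed), stringsAsFactors = FALSE)
  long_to_matrix(long1, efficiency = efficiency, ct_range = ct_range)
}
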