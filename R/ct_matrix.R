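#' Ct matrix container
#'
#' Bundles a genes x samples matrix of qRT-PCR cycle-threshold (Ct) values
#' with per-gene amplification efficiencies. Ct is the cycle at which a
#' reaction crosses the fluorescence detection threshold and is inversely,
#' logarithmically related to starting template amount. The efficiency is
#' the per-cycle amplification factor: 2 means perfect doubling.
#'
#' Missing wells are `NA`. Ct values outside `ct_range` raise a warning, not
#' an error, because plausible ranges differ between platforms.
#'
#' @param ct Numeric matrix with genes in rows (rownames = gene symbols) and
#'   samples in columns (colnames = sample ids). `NA`/`NaN` mark missing
#'   reactions.
#' @param efficiency A single amplification factor recycled to every gene,
#'   or a vector named by gene. Must exceed 1; values above 2.5 are
#'   implausible for PCR and trigger a warning. Percent efficiencies from a
#'   dilution series convert via [efficiency_factor()].
#' @param ct_range Length-2 numeric, the plausible Ct window in cycles.
#' @return An object of class `ct_matrix`: a list with elements `ct`
#'   (numeric matrix), `efficiency` (named numeric) and `ct_range`.
#' @seealso [read_ct_table()], [complete_ct()], [subset_samples()],
#'   [validate_ct()]
#' @examples
#' m <- matrix(c(20, 22, 21, 23), nrow = 2,
#'             dimnames = list(c("actb", "h3a"), c("s1", "s2")))
#' x <- ct_matrix(m)
#' genes(x)
#' @export
ct_matrix <- function(ct, efficiency = 2, ct_range = c(5, 40)) {
  if (is.data.frame(ct)) ct <- as.matrix(ct)
  if (!is.matrix(ct))
    stop("`ct` must be a matrix with genes in rows and samples in columns")
  storage.mode(ct) <- "double"
  if (nrow(ct) < 1L || ncol(ct) < 1L) stop("empty Ct matrix")
  if (is.null(rownames(ct)) || any(is.na(rownames(ct))) || any(!nzchar(rownames(ct))))
    stop("`ct` must carry gene symbols as rownames")
  if (is.null(colnames(ct)) || any(is.na(colnames(ct))) || any(!nzchar(colnames(ct))))
    stop("`ct` must carry sample ids as colnames")
  if (anyDuplicated(rownames(ct)))
    stop("duplicated gene symbols: ",
         paste(unique(rownames(ct)[duplicated(rownames(ct))]), collapse = ", "))
  if (anyDuplicated(colnames(ct)))
    stop("duplicated sample ids: ",
         paste(unique(colnames(ct)[duplicated(colnames(ct))]), collapse = ", "))
  ct[is.nan(ct)] <- NA_real_
  if (any(is.infinite(ct), na.rm = TRUE)) stop("Ct values must be finite or NA")
  if (!is.numeric(ct_range) || length(ct_range) != 2L || ct_range[1] >= ct_range[2])
    stop("`ct_range` must be two increasing numbers (cycles)")
  n_out <- sum(ct < ct_range[1] | ct > ct_range[2], na.rm = TRUE)
  if (n_out > 0L)
    warning(sprintf("%d Ct value(s) outside the plausible range [%g, %g] cycles",
                    n_out, ct_range[1], ct_range[2]))

  eff <- efficiency
  if (is.null(names(eff))) {
    if (length(eff) == 1L) {
      eff <- rep(as.numeric(eff), nrow(ct))
    } else if (length(eff) != nrow(ct)) {
      stop("`efficiency` must be length 1 or one value per gene")
    }
    names(eff) <- rownames(ct)
  } else {
    miss <- setdiff(rownames(ct), names(eff))
    if (length(miss))
      stop("no efficiency supplied for gene(s): ", paste(miss, collapse = ", "))
    eff <- as.numeric(eff[rownames(ct)])
    names(eff) <- rownames(ct)
  }
  if (any(!is.finite(eff)) || any(eff <= 1))
    stop("amplification efficiencies must be finite and > 1")
  if (any(eff > 2.5))
    warning("amplification efficiency above 2.5 is implausible for PCR")

  structure(list(ct = ct, efficiency = eff, ct_range = as.numeric(ct_range)),
            class = "ct_matrix")
}

# Coerce plain matrices on method entry so every estimator accepts either.
as_ct <- function(x) {
  if (inherits(x, "ct_matrix")) return(x)
  if (is.matrix(x) || is.data.frame(x)) return(ct_matrix(x))
  stop("expected a `ct_matrix` or a genes x samples matrix")
}

#' @export
print.ct_matrix <- function(x, ...) {
  cat(sprintf("ct_matrix: %d gene(s) x %d sample(s), %d missing value(s)\n",
              nrow(x$ct), ncol(x$ct), sum(is.na(x$ct))))
  cat("genes: ", paste(rownames(x$ct), collapse = ", "), "\n", sep = "")
  if (length(unique(x$efficiency)) == 1L) {
    cat(sprintf("efficiency: %g (all genes)\n", x$efficiency[1]))
  } else {
    cat("efficiency: per-gene, range ",
        paste(signif(range(x$efficiency), 4), collapse = "-"), "\n", sep = "")
  }
  invisible(x)
}

#' @export
dim.ct_matrix <- function(x) dim(x$ct)

#' @export
as.matrix.ct_matrix <- function(x, ...) x$ct

#' Gene and sample identifiers of a Ct matrix
#' @param x A [ct_matrix()].
#' @return Character vector of gene symbols or sample ids.
#' @export
genes <- function(x) rownames(as_ct(x)$ct)

#' @rdname genes
#' @export
samples <- function(x) colnames(as_ct(x)$ct)

#' Drop samples with any missing Ct (complete-case policy)
#'
#' Every stability estimator here needs a full gene x sample block, so
#' samples with at least one missing Ct among the analysed genes are removed
#' before analysis. The number of dropped samples is reported.
#'
#' @param x A [ct_matrix()] or genes x samples matrix.
#' @param quiet Suppress the message about dropped samples.
#' @return A `ct_matrix` restricted to complete samples, with the dropped
#'   sample ids in attribute `"dropped_samples"`.
#' @export
complete_ct <- function(x, quiet = FALSE) {
  x <- as_ct(x)
  keep <- colSums(is.na(x$ct)) == 0L
  dropped <- colnames(x$ct)[!keep]
  if (length(dropped) && !quiet)
    message(sprintf("complete-case policy: dropping %d sample(s) with missing Ct: %s",
                    length(dropped), paste(dropped, collapse = ", ")))
  if (!any(keep))
    stop("no complete samples remain after complete-case filtering")
  x$ct <- x$ct[, keep, drop = FALSE]
  attr(x, "dropped_samples") <- dropped
  x
}

# Check that a metadata table pairs exactly with the Ct matrix samples.
check_meta <- function(x, meta) {
  if (!is.data.frame(meta) || !"sample_id" %in% names(meta))
    stop("`meta` must be a data.frame with a `sample_id` column")
  if (anyDuplicated(meta$sample_id))
    stop("duplicated sample_id in metadata: ",
         paste(unique(meta$sample_id[duplicated(meta$sample_id)]), collapse = ", "))
  only_ct <- setdiff(colnames(x$ct), meta$sample_id)
  only_meta <- setdiff(meta$sample_id, colnames(x$ct))
  if (length(only_ct) || length(only_meta))
    stop("Ct matrix and metadata sample sets differ; only in Ct matrix: {",
         paste(only_ct, collapse = ", "), "}; only in metadata: {",
         paste(only_meta, collapse = ", "), "}")
  invisible(TRUE)
}

#' Subset samples by design-factor levels
#'
#' Selects the samples whose metadata match every named condition, e.g.
#' `treatment = "control"` or `tissue = c("gills", "kidney")`. Genes are
#' unchanged. Used by the stratified analysis driver to form per-treatment,
#' per-age and per-tissue strata.
#'
#' @param x A [ct_matrix()].
#' @param meta Sample metadata `data.frame` with a `sample_id` column and one
#'   column per design factor.
#' @param ... Named conditions, `factor = level(s)`.
#' @return A list with the filtered `ct` ([ct_matrix()]) and `meta`.
#' @examples
#' sim <- generate_ct_data(silverside_design_config(seed = 1))
#' ctl <- subset_samples(sim$ct, sim$meta, treatment = "control")
#' ncol(as.matrix(ctl$ct))  # 36 samples: 9 fish x 4 tissues
#' @export
subset_samples <- function(x, meta, ...) {
  x <- as_ct(x)
  check_meta(x, meta)
  cond <- list(...)
  if (!length(cond) || is.null(names(cond)) || any(!nzchar(names(cond))))
    stop("supply at least one named condition, e.g. treatment = \"control\"")
  unknown <- setdiff(names(cond), names(meta))
  if (length(unknown))
    stop("unknown design factor(s): ", paste(unknown, collapse = ", "))
  keep <- rep(TRUE, nrow(meta))
  for (f in names(cond)) {
    lv <- as.character(cond[[f]])
    have <- unique(as.character(meta[[f]]))
    absent <- setdiff(lv, have)
    if (length(absent))
      stop(sprintf("level(s) %s absent from factor '%s' (levels: %s)",
                   paste(absent, collapse = ", "), f, paste(have, collapse = ", ")))
    keep <- keep & as.character(meta[[f]]) %in% lv
  }
  pred <- paste(sprintf("%s=%s", names(cond),
                        vapply(cond, function(v) paste(v, collapse = "/"), "")),
                collapse = " & ")
  if (!any(keep)) stop("empty selection for predicate: ", pred)
  ids <- meta$sample_id[keep]
  x$ct <- x$ct[, match(ids, colnames(x$ct)), drop = FALSE]
  list(ct = x, meta = meta[keep, , drop = FALSE])
}

#' Validate a Ct matrix against its metadata
#'
#' Reports missing-data load per gene and per sample, flags the genes and
#' samples that exceed `max_missing_fraction` (downstream analyses exclude
#' them under the complete-case policy), and lists out-of-range Ct values.
#'
#' @param x A [ct_matrix()].
#' @param meta Optional sample metadata; if given, sample sets must match
#'   exactly (mismatch is an error listing the symmetric difference).
#' @param max_missing_fraction Missing-fraction threshold above which a gene
#'   or sample is listed for exclusion.
#' @return An object of class `ct_validation` (see fields in the example).
#' @examples
#' m <- matrix(c(20, NA, 21, 23), nrow = 2,
#'             dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' rep <- validate_ct(ct_matrix(m), max_missing_fraction = 0.2)
#' rep$exclude_genes
#' @export
validate_ct <- function(x, meta = NULL, max_missing_fraction = 0.2) {
  x <- as_ct(x)
  if (!is.null(meta)) check_meta(x, meta)
  if (!is.numeric(max_missing_fraction) || max_missing_fraction < 0 ||
      max_missing_fraction > 1)
    stop("`max_missing_fraction` must be in [0, 1]")
  miss_gene <- rowMeans(is.na(x$ct))
  miss_sample <- colMeans(is.na(x$ct))
  rng <- x$ct_range
  oor_idx <- which(x$ct < rng[1] | x$ct > rng[2], arr.ind = TRUE)
  out_of_range <- data.frame(
    gene = rownames(x$ct)[oor_idx[, 1]],
    sample = colnames(x$ct)[oor_idx[, 2]],
    ct = x$ct[oor_idx],
    stringsAsFactors = FALSE)
  res <- list(
    n_genes = nrow(x$ct),
    n_samples = ncol(x$ct),
    n_missing = sum(is.na(x$ct)),
    max_missing_fraction = max_missing_fraction,
    missing_fraction_by_gene = miss_gene,
    missing_fraction_by_sample = miss_sample,
    exclude_genes = names(miss_gene)[miss_gene > max_missing_fraction],
    exclude_samples = names(miss_sample)[miss_sample > max_missing_fraction],
    incomplete_samples = colnames(x$ct)[colSums(is.na(x$ct)) > 0L],
    out_of_range = out_of_range)
  class(res) <- "ct_validation"
  res
}

#' @export
print.ct_validation <- function(x, ...) {
  cat(sprintf("Ct validation: %d gene(s) x %d sample(s), %d missing value(s)\n",
              x$n_genes, x$n_samples, x$n_missing))
  cat(sprintf("genes over %.0f%% missing: %s\n", 100 * x$max_missing_fraction,
              if (length(x$exclude_genes)) paste(x$exclude_genes, collapse = ", ") else "none"))
  cat(sprintf("samples over %.0f%% missing: %s\n", 100 * x$max_missing_fraction,
              if (length(x$exclude_samples)) paste(x$exclude_samples, collapse = ", ") else "none"))
  cat(sprintf("samples dropped by complete-case analyses: %d\n",
              length(x$incomplete_samples)))
  cat(sprintf("out-of-range Ct values: %d\n", nrow(x$out_of_range)))
  invisible(x)
}

#' Write a validation report as a machine-readable JSON file
#'
#' @param report A `ct_validation` object from [validate_ct()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_validation <- function(report, path) {
  stopifnot(inherits(report, "ct_validation"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
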