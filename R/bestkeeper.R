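#' BestKeeper descriptive statistics, index and correlations
#'
#' Computes per-gene descriptive statistics of raw Ct values (geometric and
#' arithmetic mean, extremes, dispersion, coefficient of variation), the
#' BestKeeper index (per-sample geometric mean of Ct across the candidate
#' genes) and each gene's Pearson correlation with the index. Two rankings
#' are available: ascending dispersion (`"sd"`; lower SD = more stable; the
#' conservative choice usually fed into a consensus) or descending `|r|`
#' (`"correlation"`; genes that track the common index best).
#'
#' The dispersion dialect is the sample SD by default; the original
#' BestKeeper tool's mean absolute deviation around the arithmetic mean is
#' available via `dispersion = "mad"`. Both are always reported in the
#' descriptor table. Unlike the delta-Ct/geNorm/NormFinder statistics,
#' BestKeeper works on raw Ct, so it is deliberately sensitive to global
#' per-sample shifts.
#'
#' A constant gene (or constant index) has an undefined correlation; its
#' `|r|` is set to 0 with a warning so rankings remain total.
#'
#' @param x A [ct_matrix()] or genes x samples matrix; >= 2 genes and >= 3
#'   complete samples (the correlation p-value needs n >= 3).
#' @param ranking_mode `"sd"` (dispersion, lower-is-stable) or
#'   `"correlation"` (`|r|`, higher-is-stable).
#' @param dispersion Dispersion dialect: `"sd"` (sample SD, n-1) or `"mad"`
#'   (mean absolute deviation around the mean).
#' @param index_genes Optional subset of genes used to build the index;
#'   default all analysed genes.
#' @return An object of class `bestkeeper_result`: list with `descriptors`
#'   (per-gene table incl. `r` and two-sided `p_value` from the t transform
#'   with n-2 df), `index` (per-sample), `stability` (a
#'   [stability_table()]), and the modes used.
#' @examples
#' m <- rbind(A = c(20, 22, 21), B = c(21, 23, 22))
#' colnames(m) <- paste0("s", 1:3)
#' bk <- bestkeeper(m)
#' bk$index
#' @export
bestkeeper <- function(x, ranking_mode = c("sd", "correlation"),
                       dispersion = c("sd", "mad"), index_genes = NULL) {
  ranking_mode <- match.arg(ranking_mode)
  dispersion <- match.arg(dispersion)
  x <- complete_ct(as_ct(x), quiet = TRUE)
  m <- x$ct
  if (nrow(m) < 2L) stop("at least 2 genes are required")
  if (ncol(m) < 3L)
    stop("at least 3 complete samples are required for index correlations")
  if (any(m <= 0)) stop("Ct values must be positive for geometric means")

  ar <- rowMeans(m)
  geo <- exp(rowMeans(log(m)))
  sd_ct <- apply(m, 1L, stats::sd)
  mad_ct <- rowMeans(abs(m - ar))
  disp <- if (dispersion == "sd") sd_ct else mad_ct

  if (is.null(index_genes)) index_genes <- rownames(m)
  unknown <- setdiff(index_genes, rownames(m))
  if (length(unknown))
    stop("index gene(s) not in the matrix: ", paste(unknown, collapse = ", "))
  index <- exp(colMeans(log(m[index_genes, , drop = FALSE])))

  corr <- t(vapply(rownames(m), function(g) {
    v <- m[g, ]
    if (stats::sd(v) == 0 || stats::sd(index) == 0) {
      warning(sprintf("constant Ct for gene '%s' (or constant index): correlation undefined, |r| set to 0",
                      g))
      return(c(r = 0, p = 1))
    }
    ht <- stats::cor.test(v, index, method = "pearson",
                          alternative = "two.sided")
    c(r = unname(ht$estimate), p = ht$p.value)
  }, numeric(2)))

  descriptors <- data.frame(
    gene = rownames(m), n = ncol(m),
    geo_mean_ct = unname(geo), ar_mean_ct = unname(ar),
    min_ct = unname(apply(m, 1L, min)), max_ct = unname(apply(m, 1L, max)),
    sd_ct = unname(sd_ct), mad_ct = unname(mad_ct),
    cv_pct = unname(100 * disp / ar),
    r = unname(corr[, "r"]), p_value = unname(corr[, "p"]),
    stringsAsFactors = FALSE)

  stab <- if (ranking_mode == "sd") {
    stability_table("bestkeeper_sd", stats::setNames(disp, rownames(m)),
                    "lower_is_stable")
  } else {
    stability_table("bestkeeper_corr",
                    stats::setNames(abs(corr[, "r"]), rownames(m)),
                    "higher_is_stable")
  }
  structure(list(descriptors = descriptors, index = index, stability = stab,
                 ranking_mode = ranking_mode, dispersion = dispersion,
                 index_genes = index_genes),
            class = "bestkeeper_result")
}

#' @export
print.bestkeeper_result <- function(x, ...) {
  cat(sprintf("BestKeeper: %d genes, %d samples; ranking by %s (dispersion dialect: %s)\n",
              nrow(x$descriptors), length(x$index), x$ranking_mode,
              x$dispersion))
  print.data.frame(x$descriptors, row.names = FALSE, digits = 4)
  invisible(x)
}
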