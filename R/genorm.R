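# geNorm: expression ratios of ideal reference genes are constant across
# samples, so a gene's average pairwise log-ratio SD (the M-value) measures
# its instability. Stepwise exclusion of the highest-M gene yields a ranking
# whose final pair cannot be separated; the pairwise variation V(n/n+1)
# between normalisation factors built from the top n vs n+1 genes indicates
# how many reference genes suffice.

#' Transform Ct values to relative quantities
#'
#' Per gene, `q = E ^ (minCt - Ct)` where `E` is the gene's amplification
#' efficiency and `minCt` its minimum Ct over samples, so the most abundant
#' sample gets q = 1 and all quantities lie in (0, 1]. Samples with missing
#' Ct are dropped first (complete-case policy).
#'
#' @param x A [ct_matrix()] or genes x samples matrix (efficiency then
#'   defaults to 2, perfect doubling).
#' @return Numeric genes x samples matrix of relative quantities.
#' @examples
#' m <- rbind(g1 = c(20, 22))
#' colnames(m) <- c("s1", "s2")
#' genorm_quantities(m)  # 1, 0.25
#' @export
genorm_quantities <- function(x) {
  x <- complete_ct(as_ct(x), quiet = TRUE)
  m <- x$ct
  # efficiency vector recycles down rows (column-major), matching genes
  x$efficiency ^ (apply(m, 1, min) - m)
}

# Accept either a quantity matrix or Ct input for the geNorm entry points.
as_quantities <- function(q) {
  if (inherits(q, "ct_matrix")) return(genorm_quantities(q))
  if (is.data.frame(q)) q <- as.matrix(q)
  if (!is.matrix(q) || !is.numeric(q))
    stop("expected a relative-quantity matrix or a `ct_matrix`")
  if (is.null(rownames(q))) stop("quantity matrix needs gene rownames")
  if (anyNA(q)) stop("quantity matrix must be complete (no NA)")
  if (any(q <= 0)) stop("relative quantities must be strictly positive")
  q
}

pairwise_log_ratio_sd <- function(q) {
  L <- log2(q)
  S <- stats::cov(t(L))
  v <- outer(diag(S), diag(S), "+") - 2 * S
  v[v < 0] <- 0
  sqrt(v)
}

#' geNorm expression-stability measure M
#'
#' `V_jk` is the sample standard deviation across samples of
#' `log2(q_j / q_k)`; gene j's M-value averages `V_jk` over all partner
#' genes k. Lower M = more stable. The classical definition uses the
#' arithmetic mean of the pairwise SDs; `mean_type = "geometric"` is offered
#' as a dialect switch.
#'
#' @param q Relative-quantity matrix from [genorm_quantities()] (or a
#'   [ct_matrix()], transformed automatically), >= 2 genes, >= 2 samples.
#' @param mean_type How pairwise SDs are averaged into M.
#' @return A [stability_table()] with method `"genorm"`.
#' @export
genorm_m <- function(q, mean_type = c("arithmetic", "geometric")) {
  mean_type <- match.arg(mean_type)
  q <- as_quantities(q)
  if (nrow(q) < 2L) stop("at least 2 genes are required")
  if (ncol(q) < 2L) stop("at least 2 samples are required")
  sd_pair <- pairwise_log_ratio_sd(q)
  G <- nrow(q)
  vals <- if (mean_type == "arithmetic") {
    rowSums(sd_pair) / (G - 1L)
  } else {
    vapply(seq_len(G), function(j) {
      r <- sd_pair[j, -j]
      if (any(r == 0)) 0 else exp(mean(log(r)))
    }, numeric(1))
  }
  stability_table("genorm", stats::setNames(as.numeric(vals), rownames(q)),
                  "lower_is_stable")
}

#' geNorm stepwise exclusion ranking
#'
#' Iteratively recomputes M on the remaining gene set and removes the gene
#' with the highest M until two genes remain. The final pair cannot be
#' separated by geNorm and shares ranks 1-2 (tie-averaged to 1.5 each);
#' genes excluded later rank better. Each gene is annotated with the M-value
#' it had at exclusion (the final pair carries its common two-gene M). Exact
#' ties in the highest M are broken by excluding the lexicographically last
#' gene; every tie-break is recorded in the `"log"` attribute.
#'
#' @inheritParams genorm_m
#' @return An object of class `genorm_ranking` (also a `data.frame`) with
#'   columns `gene`, `m_value`, `rank`, `step`, `tied`.
#' @export
genorm_stepwise <- function(q, mean_type = c("arithmetic", "geometric")) {
  mean_type <- match.arg(mean_type)
  q <- as_quantities(q)
  G <- nrow(q)
  if (G < 3L) stop("stepwise exclusion needs at least 3 genes")
  remaining <- rownames(q)
  rows <- list()
  log_lines <- character()
  step <- 0L
  while (length(remaining) > 2L) {
    step <- step + 1L
    mt <- genorm_m(q[remaining, , drop = FALSE], mean_type)
    worst <- max(mt$value)
    cand <- mt$gene[mt$value == worst]
    tied <- length(cand) > 1L
    drop_gene <- sort(cand)[length(cand)]
    if (tied)
      log_lines <- c(log_lines,
                     sprintf("step %d: highest M tied (%.6g) among %s; excluded lexicographically last gene '%s'",
                             step, worst, paste(cand, collapse = ", "), drop_gene))
    rows[[step]] <- data.frame(gene = drop_gene, m_value = worst,
                               rank = G - step + 1L, step = step,
                               tied = tied, stringsAsFactors = FALSE)
    remaining <- setdiff(remaining, drop_gene)
  }
  final_m <- genorm_m(q[remaining, , drop = FALSE], mean_type)
  rows[[step + 1L]] <- data.frame(gene = final_m$gene,
                                  m_value = final_m$value,
                                  rank = 1.5, step = step + 1L, tied = TRUE,
                                  stringsAsFactors = FALSE)
  out <- do.call(rbind, rev(rows))
  rownames(out) <- NULL
  attr(out, "mean_type") <- mean_type
  attr(out, "log") <- log_lines
  attr(out, "all_tied") <- isTRUE(all(abs(out$m_value - out$m_value[1]) <
                                        .Machine$double.eps^0.5))
  class(out) <- c("genorm_ranking", "data.frame")
  out
}

#' @export
print.genorm_ranking <- function(x, ...) {
  cat(sprintf("geNorm stepwise ranking (%s partner mean); final pair tied at rank 1.5\n",
              attr(x, "mean_type")))
  print.data.frame(x[order(x$rank, x$gene), ], row.names = FALSE, digits = 4)
  if (isTRUE(attr(x, "all_tied")))
    cat("note: all M-values equal; ordering is the deterministic tie-break only\n")
  invisible(x)
}

#' geNorm pairwise variation V(n/n+1)
#'
#' `NF_n` is the per-sample geometric mean of relative quantities over the
#' top n genes of the ranking; `V(n/n+1)` is the sample SD across samples of
#' `log2(NF_n / NF_{n+1})` for n = 2..G-1. Small V values indicate that
#' adding the (n+1)-th gene changes the normalisation factor little.
#'
#' @inheritParams genorm_m
#' @param ranking A [genorm_stepwise()] result, or a character vector of
#'   genes ordered best to worst; `NULL` recomputes the stepwise ranking.
#' @return Named numeric vector `V2/3`, `V3/4`, ...
#' @export
genorm_pairwise_variation <- function(q, ranking = NULL) {
  q <- as_quantities(q)
  G <- nrow(q)
  if (G < 3L) stop("pairwise variation needs at least 3 genes")
  if (ncol(q) < 2L) stop("at least 2 samples are required")
  if (is.null(ranking)) ranking <- genorm_stepwise(q)
  ord <- if (inherits(ranking, "genorm_ranking")) {
    ranking$gene[order(ranking$rank, ranking$gene)]
  } else {
    as.character(ranking)
  }
  if (!setequal(ord, rownames(q)) || length(ord) != G)
    stop("`ranking` must cover exactly the genes of `q`")
  L <- log2(q[ord, , drop = FALSE])
  # running per-sample mean of log2 q over the top n genes = log2 NF_n
  cm <- apply(L, 2L, cumsum) / seq_len(G)
  v <- vapply(2:(G - 1L), function(n) stats::sd(cm[n, ] - cm[n + 1L, ]),
              numeric(1))
  stats::setNames(v, sprintf("V%d/%d", 2:(G - 1L), 3:G))
}
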