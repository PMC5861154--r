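#' Comparative delta-Ct stability
#'
#' For every unordered gene pair (j, k) the per-sample difference
#' `dCt = Ct_j - Ct_k` is formed and its sample standard deviation (n-1
#' denominator) across samples computed. A gene's stability value is the
#' arithmetic mean of these pairwise SDs over all pairs containing it; a low
#' mean SD means the gene varies little relative to every other candidate.
#' Because dCt differences cancel per-sample constants, the statistic is
#' invariant to global mRNA-content (loading) shifts.
#'
#' Samples with any missing Ct are dropped first (complete-case policy).
#'
#' @param x A [ct_matrix()] or genes x samples matrix with >= 2 genes and
#'   >= 2 complete samples.
#' @return A [stability_table()] with method `"dct"`, direction
#'   lower-is-stable.
#' @examples
#' m <- rbind(A = c(20, 20, 20), B = c(22, 22, 22), C = c(24, 25, 26))
#' colnames(m) <- paste0("s", 1:3)
#' dct_stability(m)  # A = 0.5, B = 0.5, C = 1.0
#' @export
dct_stability <- function(x) {
  x <- complete_ct(as_ct(x), quiet = TRUE)
  m <- x$ct
  if (nrow(m) < 2L) stop("at least 2 genes are required")
  if (ncol(m) < 2L) stop("at least 2 complete samples are required")
  # Var(Ct_j - Ct_k) = S_jj + S_kk - 2 S_jk from the gene covariance matrix
  S <- stats::cov(t(m))
  v <- outer(diag(S), diag(S), "+") - 2 * S
  v[v < 0] <- 0  # guard against tiny negative rounding
  sd_pair <- sqrt(v)
  vals <- rowSums(sd_pair) / (nrow(m) - 1L)  # diagonal is zero
  stability_table("dct", stats::setNames(vals, rownames(m)),
                  "lower_is_stable")
}
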