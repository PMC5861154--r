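#' Rank genes by a stability statistic
#'
#' Ascending ranks for "lower is more stable" statistics (delta-Ct SD,
#' geNorm M, NormFinder rho, BestKeeper dispersion), descending for
#' "higher is more stable" (BestKeeper |r|). Exact ties receive the average
#' of the ranks they span, so ranks always sum to n(n+1)/2.
#'
#' @param values Named numeric vector of per-gene stability values; all must
#'   be finite.
#' @param direction `"lower_is_stable"` or `"higher_is_stable"`.
#' @return Named numeric vector of ranks.
#' @examples
#' rank_genes(c(h3a = 2.57, ef1a = 2.82, actb = 2.82, atp1a = 4.98))
#' @export
rank_genes <- function(values, direction = c("lower_is_stable",
                                             "higher_is_stable")) {
  direction <- match.arg(direction)
  if (!is.numeric(values) || is.null(names(values)) ||
      any(!nzchar(names(values))))
    stop("`values` must be a numeric vector named by gene")
  if (!length(values)) stop("no stability values to rank")
  bad <- names(values)[!is.finite(values)]
  if (length(bad))
    stop("non-finite stability value for gene(s): ", paste(bad, collapse = ", "))
  r <- if (direction == "lower_is_stable") rank(values, ties.method = "average")
       else rank(-values, ties.method = "average")
  stats::setNames(as.numeric(r), names(values))
}

#' Construct a per-method stability table
#'
#' A small data.frame (`gene`, `value`, `rank`) carrying the method name and
#' ranking direction as attributes; the common currency the consensus
#' aggregation consumes.
#'
#' @param method Method label, e.g. `"dct"`, `"genorm"`, `"normfinder"`,
#'   `"bestkeeper_sd"`, `"bestkeeper_corr"`.
#' @param values Named numeric vector of per-gene stability values.
#' @param direction Ranking direction, see [rank_genes()].
#' @return An object of class `stability_table` (also a `data.frame`).
#' @export
stability_table <- function(method, values,
                            direction = c("lower_is_stable",
                                          "higher_is_stable")) {
  direction <- match.arg(direction)
  r <- rank_genes(values, direction)
  out <- data.frame(gene = names(values), value = unname(as.numeric(values)),
                    rank = unname(r), stringsAsFactors = FALSE)
  attr(out, "method") <- method
  attr(out, "direction") <- direction
  class(out) <- c("stability_table", "data.frame")
  out
}

#' @export
print.stability_table <- function(x, ...) {
  cat(sprintf("stability table: method %s (%s)\n",
              attr(x, "method"), attr(x, "direction")))
  print.data.frame(x[order(x$rank), ], row.names = FALSE, digits = 4)
  invisible(x)
}

# Pull a named rank vector out of the objects a consensus can be fed with.
extract_ranks <- function(obj, label = "method") {
  r <- if (inherits(obj, "stability_table") || inherits(obj, "genorm_ranking")) {
    stats::setNames(obj$rank, obj$gene)
  } else if (is.numeric(obj) && !is.null(names(obj))) {
    obj
  } else {
    stop(sprintf("'%s' is not a stability table, geNorm ranking or named rank vector",
                 label))
  }
  if (any(!is.finite(r)) || any(r <= 0))
    stop(sprintf("'%s' contains non-finite or non-positive ranks", label))
  r
}

#' Aggregate per-method ranks into a consensus ranking
#'
#' Computes, per gene, the geometric mean of its ranks across stability
#' methods and orders genes by ascending geometric mean: the gene with the
#' lowest geometric mean rank is the consensus most-stable candidate. All
#' methods must cover the identical gene set.
#'
#' @param rank_lists Named list with one element per method: a
#'   [stability_table()], a [genorm_stepwise()] ranking, or a named rank
#'   vector.
#' @return An object of class `consensus_table` (also a `data.frame`) with
#'   one `rank_<method>` column per method, the geometric mean (`geomean`,
#'   full precision; printed to 2 decimals) and `final_rank` (ties
#'   averaged).
#' @examples
#' aggregate_consensus(list(a = c(g1 = 1, g2 = 2), b = c(g1 = 2, g2 = 1)))
#' @export
aggregate_consensus <- function(rank_lists) {
  if (!is.list(rank_lists) || length(rank_lists) < 2L)
    stop("at least 2 methods are required for a consensus")
  if (is.null(names(rank_lists)) || any(!nzchar(names(rank_lists))))
    stop("`rank_lists` must be a named list (one name per method)")
  ranks <- mapply(extract_ranks, rank_lists, names(rank_lists),
                  SIMPLIFY = FALSE)
  gene_set <- names(ranks[[1]])
  for (m in names(ranks)) {
    missing <- setdiff(gene_set, names(ranks[[m]]))
    extra <- setdiff(names(ranks[[m]]), gene_set)
    if (length(missing) || length(extra))
      stop(sprintf("method '%s' does not cover the same gene set (missing: %s; extra: %s)",
                   m,
                   if (length(missing)) paste(missing, collapse = ", ") else "none",
                   if (length(extra)) paste(extra, collapse = ", ") else "none"))
  }
  R <- vapply(ranks, function(r) r[gene_set], numeric(length(gene_set)))
  R <- matrix(R, nrow = length(gene_set),
              dimnames = list(gene_set, names(ranks)))
  geomean <- exp(rowMeans(log(R)))
  final <- rank(geomean, ties.method = "average")
  out <- data.frame(gene = gene_set, R, geomean = unname(geomean),
                    final_rank = unname(final), stringsAsFactors = FALSE,
                    check.names = FALSE, row.names = NULL)
  names(out)[seq_along(ranks) + 1L] <- paste0("rank_", names(ranks))
  out <- out[order(out$geomean, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("consensus_table", "data.frame")
  out
}

#' @export
print.consensus_table <- function(x, ...) {
  cat("consensus ranking (geometric mean of per-method ranks; lower = more stable)\n")
  shown <- x
  shown$geomean <- round(shown$geomean, 2)
  print.data.frame(shown, row.names = FALSE)
  invisible(x)
}
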