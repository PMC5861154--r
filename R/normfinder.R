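# Model-based stability (NormFinder-type). Ct values are sample-centred to
# remove global mRNA-content differences; per gene the centred values are
# decomposed into an intragroup residual variance and an intergroup
# deviation of group means. The stability value combines a shrunken
# intergroup deviation with the intragroup standard error, so a gene is
# penalised both for noisy replicates and for systematic treatment shifts.
#
# All constants of the committed decomposition live in normfinder_decomp()
# and the two exported functions below so the formula is auditable in one
# place:
#   z_is        = Ct_is - mean_i(Ct_is)                 (sample centring)
#   s2_ig       = residual variance of z in group g     (n_g - 1)
#   sigma2_ig   = max(0, (s2_ig - mean_i(s2_ig)/I) / (1 - 2/I))
#                 method-of-moments correction for the centring, I = genes
#   d_ig        = zbar_ig - mean_g(zbar_ig)             (unweighted)
#   gamma2_g    = max(0, var_i(d_ig) - mean_i(sigma2_ig / n_g))
#   dtilde_ig   = d_ig * gamma2_g / (gamma2_g + sigma2_ig / n_g)
#   rho_i       = mean_g( |dtilde_ig| + sigma_ig / sqrt(n_g) )
#   single group: rho_i = sigma_ig

normfinder_decomp <- function(m, groups) {
  I <- nrow(m)
  z <- sweep(m, 2L, colMeans(m))
  gl <- levels(groups)
  n_g <- vapply(gl, function(g) sum(groups == g), numeric(1))
  zbar <- vapply(gl, function(g) rowMeans(z[, groups == g, drop = FALSE]),
                 numeric(I))
  s2 <- vapply(gl, function(g) apply(z[, groups == g, drop = FALSE], 1L,
                                     stats::var),
               numeric(I))
  zbar <- matrix(zbar, nrow = I, dimnames = list(rownames(m), gl))
  s2 <- matrix(s2, nrow = I, dimnames = list(rownames(m), gl))
  sbar2 <- colMeans(s2)
  sigma2 <- sweep(s2, 2L, sbar2 / I) / (1 - 2 / I)
  sigma2[sigma2 < 0] <- 0
  list(z = z, zbar = zbar, s2 = s2, sbar2 = sbar2, sigma2 = sigma2,
       n_g = n_g, I = I, group_levels = gl)
}

check_normfinder_input <- function(m, groups) {
  if (nrow(m) < 3L)
    stop("the variance decomposition needs at least 3 genes")
  if (is.null(groups)) groups <- rep("all", ncol(m))
  if (length(groups) != ncol(m))
    stop("`groups` must give one label per sample")
  groups <- factor(as.character(groups))
  tab <- table(groups)
  small <- names(tab)[tab < 3L]
  if (length(small))
    stop("group(s) with fewer than 3 complete samples: ",
         paste(small, collapse = ", "))
  groups
}

# Stability from the decomposition pieces shared by the single-gene and
# pseudo-gene (pair) paths.
nf_rho <- function(d_row, sigma2_row, n_g, gamma2) {
  se2 <- sigma2_row / n_g
  den <- gamma2 + se2
  dt <- ifelse(den == 0, 0, d_row * gamma2 / den)
  mean(abs(dt) + sqrt(se2))
}

#' Model-based (NormFinder-type) stability value
#'
#' Combines each gene's estimated intragroup variance with its (shrunken)
#' intergroup deviation into a single stability value rho; lower = more
#' stable. With a single group (or `groups = NULL`) rho reduces to the
#' corrected intragroup standard deviation. The decomposition operates on
#' sample-centred Ct values, so global per-sample shifts cancel.
#'
#' @param x A [ct_matrix()] or genes x samples matrix with >= 3 genes (the
#'   centring correction needs at least 3).
#' @param groups Optional per-sample group labels (e.g. treatment); every
#'   group needs >= 3 complete samples.
#' @return A [stability_table()] with method `"normfinder"`; the attribute
#'   `"groups"` records the grouping used.
#' @export
normfinder_stability <- function(x, groups = NULL) {
  x <- complete_ct(as_ct(x), quiet = TRUE)
  m <- x$ct
  groups <- check_normfinder_input(m, groups)
  d <- normfinder_decomp(m, groups)
  if (nlevels(groups) == 1L) {
    rho <- sqrt(d$sigma2[, 1L])
  } else {
    dm <- d$zbar - rowMeans(d$zbar)
    se2 <- sweep(d$sigma2, 2L, d$n_g, "/")
    gamma2 <- pmax(0, apply(dm, 2L, stats::var) - colMeans(se2))
    rho <- vapply(seq_len(nrow(m)), function(i)
      nf_rho(dm[i, ], d$sigma2[i, ], d$n_g, gamma2), numeric(1))
    names(rho) <- rownames(m)
  }
  out <- stability_table("normfinder",
                         stats::setNames(as.numeric(rho), rownames(m)),
                         "lower_is_stable")
  attr(out, "groups") <- groups
  out
}

#' Best two-gene combination under the model-based stability value
#'
#' For every gene pair a pseudo-gene is formed whose sample-centred values
#' are the mean of the two genes' centred values; its group deviations and
#' intragroup variance are re-estimated empirically (with the centring
#' correction and shrinkage constants of the full gene set) and its
#' stability value computed. Averaging two genes with opposing treatment
#' responses cancels intergroup deviation, so a pair can beat both members.
#'
#' @inheritParams normfinder_stability
#' @return An object of class `normfinder_pair`: list with `best_pair`,
#'   `stability` (the pair's combined value), `pairs` (all pairs, ascending)
#'   and `singles` (the single-gene [stability_table()]).
#' @export
normfinder_best_pair <- function(x, groups = NULL) {
  x <- complete_ct(as_ct(x), quiet = TRUE)
  m <- x$ct
  groups <- check_normfinder_input(m, groups)
  d <- normfinder_decomp(m, groups)
  single <- nlevels(groups) == 1L
  gamma2 <- NULL
  if (!single) {
    dm <- d$zbar - rowMeans(d$zbar)
    se2 <- sweep(d$sigma2, 2L, d$n_g, "/")
    gamma2 <- pmax(0, apply(dm, 2L, stats::var) - colMeans(se2))
  }
  pair_idx <- utils::combn(rownames(m), 2L)
  rho_pair <- apply(pair_idx, 2L, function(p) {
    zp <- (d$z[p[1], ] + d$z[p[2], ]) / 2
    zbar_p <- vapply(d$group_levels, function(g) mean(zp[groups == g]),
                     numeric(1))
    s2_p <- vapply(d$group_levels, function(g) stats::var(zp[groups == g]),
                   numeric(1))
    sigma2_p <- pmax(0, (s2_p - d$sbar2 / d$I) / (1 - 2 / d$I))
    if (single) {
      sqrt(sigma2_p[[1]])
    } else {
      dp <- zbar_p - mean(zbar_p)
      nf_rho(dp, sigma2_p, d$n_g, gamma2)
    }
  })
  pairs <- data.frame(gene1 = pair_idx[1, ], gene2 = pair_idx[2, ],
                      stability = as.numeric(rho_pair),
                      stringsAsFactors = FALSE)
  pairs <- pairs[order(pairs$stability, pairs$gene1, pairs$gene2), ]
  rownames(pairs) <- NULL
  structure(list(best_pair = c(pairs$gene1[1], pairs$gene2[1]),
                 stability = pairs$stability[1],
                 pairs = pairs,
                 singles = normfinder_stability(x, groups)),
            class = "normfinder_pair")
}

#' @export
print.normfinder_pair <- function(x, ...) {
  cat(sprintf("best two-gene combination: %s + %s (combined stability %.4g)\n",
              x$best_pair[1], x$best_pair[2], x$stability))
  invisible(x)
}
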