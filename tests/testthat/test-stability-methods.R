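# The four stability estimators: worked examples, degenerate cases, and
# agreement with independent brute-force oracles.

test_that("delta-Ct stability matches the hand-computed example", {
  m <- rbind(A = c(20, 20, 20), B = c(22, 22, 22), C = c(24, 25, 26))
  colnames(m) <- paste0("s", 1:3)
  st <- dct_stability(m)
  vals <- stats::setNames(st$value, st$gene)
  expect_equal(vals, c(A = 0.5, B = 0.5, C = 1.0))

  ident <- rbind(A = c(20, 21, 23), B = c(20, 21, 23))
  colnames(ident) <- paste0("s", 1:3)
  expect_equal(dct_stability(ident)$value, c(0, 0))

  expect_error(dct_stability(m[, 1, drop = FALSE]), "2 complete samples")
  expect_error(dct_stability(m[1, , drop = FALSE]), "2 genes")
})

test_that("delta-Ct agrees with the double-loop oracle on random matrices", {
  for (seed in 1:10) {
    m <- rand_ct(8, 20, seed = seed)
    st <- dct_stability(m)
    expect_equal(stats::setNames(st$value, st$gene), naive_dct(m),
                 tolerance = 1e-10)
  }
})

test_that("relative quantities scale each gene to a maximum of 1", {
  m <- rbind(g1 = c(20, 22), g2 = c(25, 25))
  colnames(m) <- c("s1", "s2")
  q <- genorm_quantities(ct_matrix(m))
  expect_equal(q["g1", ], c(s1 = 1, s2 = 0.25))
  expect_equal(q["g2", ], c(s1 = 1, s2 = 1))
  expect_true(all(q > 0 & q <= 1))
  expect_equal(unname(apply(q, 1, max)), c(1, 1))

  # efficiency-consistent transforms: E = 4 over half the Ct gap = E = 2
  m2 <- rbind(gA = c(20, 21), gB = c(20, 20.5))
  colnames(m2) <- c("s1", "s2")
  qa <- genorm_quantities(ct_matrix(m2[1, , drop = FALSE], efficiency = 2))
  qb <- suppressWarnings(
    genorm_quantities(ct_matrix(m2[2, , drop = FALSE], efficiency = 4)))
  expect_equal(unname(qa[1, ]), unname(qb[1, ]), tolerance = 1e-12)
})

test_that("geNorm M matches the hand-computed example and the oracle", {
  m <- rbind(A = c(20, 21), B = c(25, 26), C = c(30, 30))
  colnames(m) <- c("s1", "s2")
  st <- genorm_m(genorm_quantities(ct_matrix(m)))
  vals <- stats::setNames(st$value, st$gene)
  # V_AB = 0, V_AC = V_BC = sd(log2 ratio) = sd(c(0, -1)) = 0.7071
  expect_equal(vals[c("A", "B")], c(A = 1, B = 1) * stats::sd(c(0, -1)) / 2,
               tolerance = 1e-12)
  expect_equal(unname(vals["C"]), stats::sd(c(0, -1)), tolerance = 1e-12)

  for (seed in 11:20) {
    q <- genorm_quantities(ct_matrix(rand_ct(8, 20, seed = seed)))
    st <- genorm_m(q)
    expect_equal(stats::setNames(st$value, st$gene), naive_genorm_m(q),
                 tolerance = 1e-10)
  }
  expect_error(genorm_m(matrix(-1, 2, 2,
                               dimnames = list(c("a", "b"), c("x", "y")))),
               "positive")
})

test_that("perfectly covarying genes get M = 0", {
  m <- rbind(A = c(18, 20, 25), B = c(21, 23, 28))  # constant ratio
  colnames(m) <- paste0("s", 1:3)
  st <- genorm_m(genorm_quantities(ct_matrix(m)))
  expect_equal(st$value, c(0, 0), tolerance = 1e-12)
})

test_that("with two genes, M equals the delta-Ct pairwise SD (E = 2)", {
  for (seed in 1:10) {
    m <- rand_ct(2, 15, seed = seed)
    st <- genorm_m(genorm_quantities(ct_matrix(m)))
    expect_equal(st$value, rep(stats::sd(m[1, ] - m[2, ]), 2),
                 tolerance = 1e-12)
  }
})

test_that("stepwise exclusion removes the worst gene and ties the final pair", {
  m <- rbind(A = c(20, 21), B = c(25, 26), C = c(30, 30))
  colnames(m) <- c("s1", "s2")
  gr <- genorm_stepwise(genorm_quantities(ct_matrix(m)))
  expect_identical(gr$gene[gr$rank == 3], "C")
  expect_equal(sort(gr$rank), c(1.5, 1.5, 3))
  expect_equal(gr$m_value[gr$gene == "C"], stats::sd(c(0, -1)),
               tolerance = 1e-12)
  # the final pair carries its common two-gene M
  expect_equal(gr$m_value[gr$rank == 1.5], c(0, 0), tolerance = 1e-12)
})

test_that("stepwise order matches brute-force recomputation of M", {
  for (seed in 1:5) {
    q <- genorm_quantities(ct_matrix(rand_ct(6, 15, seed = seed)))
    gr <- genorm_stepwise(q)
    remaining <- rownames(q)
    for (s in seq_len(4)) {
      mv <- naive_genorm_m(q[remaining, , drop = FALSE])
      worst <- names(which.max(mv))
      row <- gr[gr$step == s, ]
      expect_identical(row$gene, worst)
      expect_equal(row$m_value, unname(max(mv)), tolerance = 1e-10)
      remaining <- setdiff(remaining, worst)
    }
  }
})

test_that("stepwise tie-break is deterministic and logged", {
  m <- rbind(a = c(20, 20, 20), b = c(21, 21, 21), c = c(22, 22, 22))
  colnames(m) <- paste0("s", 1:3)
  gr <- genorm_stepwise(genorm_quantities(ct_matrix(m)))
  # all M are zero; the lexicographically last gene is excluded first
  expect_identical(gr$gene[gr$step == 1], "c")
  expect_true(isTRUE(attr(gr, "all_tied")))
  expect_true(length(attr(gr, "log")) >= 1)
})

test_that("pairwise variation matches the naive normalisation-factor oracle", {
  for (seed in 21:25) {
    q <- genorm_quantities(ct_matrix(rand_ct(5, 20, seed = seed)))
    gr <- genorm_stepwise(q)
    ord <- gr$gene[order(gr$rank, gr$gene)]
    expect_equal(genorm_pairwise_variation(q, gr), naive_pairwise_v(q, ord),
                 tolerance = 1e-10)
  }
})

test_that("pairwise variation is zero for identical top genes", {
  m <- rbind(a = c(20, 21, 22), b = c(20, 21, 22), c = c(20, 21, 22),
             d = c(25, 24, 26))
  colnames(m) <- paste0("s", 1:3)
  q <- genorm_quantities(ct_matrix(m))
  v <- genorm_pairwise_variation(q, c("a", "b", "c", "d"))
  expect_equal(unname(v["V2/3"]), 0, tolerance = 1e-12)
  # appending a constant-offset gene: V3/4 is the SD of a deterministic
  # log-ratio, computable by hand from the top-3 geometric mean
  nf3 <- exp(colMeans(log(q[c("a", "b", "c"), ])))
  nf4 <- exp(colMeans(log(q)))
  expect_equal(unname(v["V3/4"]), stats::sd(log2(nf3 / nf4)),
               tolerance = 1e-12)
})

test_that("NormFinder handles the degenerate single-group cases", {
  m <- matrix(rep(c(20, 21, 23, 22), each = 4), 4, byrow = FALSE,
              dimnames = list(paste0("g", 1:4), paste0("s", 1:4)))
  expect_equal(normfinder_stability(m)$value, rep(0, 4))

  m2 <- rand_ct(4, 8, seed = 3, noise_sd = 0.5)
  m2[1, ] <- m2[2, ] + 1  # after centring, genes 1 and 2 share residuals
  st <- normfinder_stability(m2)
  expect_equal(st$value[1], st$value[2], tolerance = 1e-12)

  expect_error(normfinder_stability(m2[1:2, ]), "3 genes")
  expect_error(normfinder_stability(m2, groups = rep(c("a", "b"), c(6, 2))),
               "fewer than 3")
  expect_error(normfinder_stability(m2, groups = "a"), "one label per sample")
})

test_that("a zero-residual gene floors at stability 0", {
  m <- rand_ct(4, 10, seed = 5, noise_sd = 0.8)
  # gene 1 = mean of the others, so its sample-centred values are constant
  # (zero residual variance) and the correction floors its estimate at 0
  m[1, ] <- colMeans(m[2:4, ])
  st <- normfinder_stability(m)
  expect_equal(unname(st$value[st$gene == "g1"]), 0, tolerance = 1e-12)
})

test_that("NormFinder agrees with its literal transcription oracle", {
  for (seed in 1:8) {
    m <- rand_ct(6, 24, seed = seed, noise_sd = 0.5)
    grp <- rep(c("a", "b"), each = 12)
    expect_equal(stats::setNames(normfinder_stability(m, grp)$value,
                                 paste0("g", 1:6)),
                 naive_normfinder(m, grp), tolerance = 1e-12)
    expect_equal(stats::setNames(normfinder_stability(m)$value,
                                 paste0("g", 1:6)),
                 naive_normfinder(m, rep("x", 24)), tolerance = 1e-12)
  }
})

test_that("NormFinder flags a clear group shift as least stable", {
  hits <- vapply(1:50, function(s) {
    cfg <- shifted_group_config(seed = s, sigma_tech = 0.15, delta = 1.0)
    sim <- generate_ct_data(cfg)
    nf <- normfinder_stability(sim$ct, groups = sim$meta$treatment)
    nf$gene[which.max(nf$value)] == "g6"
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("identical-row pair stability equals the single-gene value", {
  m <- rand_ct(5, 20, seed = 9, noise_sd = 0.5)
  m[2, ] <- m[1, ] + 3  # identical after centring up to a row constant
  grp <- rep(c("a", "b"), each = 10)
  bp <- normfinder_best_pair(m, grp)
  i <- which(bp$pairs$gene1 == "g1" & bp$pairs$gene2 == "g2")
  s1 <- bp$singles$value[bp$singles$gene == "g1"]
  expect_equal(bp$pairs$stability[i], s1, tolerance = 1e-12)
  expect_equal(bp$singles$value[bp$singles$gene == "g2"], s1,
               tolerance = 1e-12)
  # self-pairing is structurally impossible
  expect_false(any(bp$pairs$gene1 == bp$pairs$gene2))
})

test_that("opposite group shifts cancel in a pair", {
  ok <- vapply(1:20, function(s) {
    set.seed(s)
    m <- matrix(stats::rnorm(6 * 20, 0, 0.3), 6, 20) + 20
    dimnames(m) <- list(paste0("g", 1:6), paste0("s", 1:20))
    grp <- rep(c("a", "b"), each = 10)
    m["g5", grp == "b"] <- m["g5", grp == "b"] + 1
    m["g6", grp == "b"] <- m["g6", grp == "b"] - 1
    bp <- normfinder_best_pair(m, grp)
    i <- which(bp$pairs$gene1 == "g5" & bp$pairs$gene2 == "g6")
    bp$pairs$stability[i] <
      min(bp$singles$value[bp$singles$gene %in% c("g5", "g6")])
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("the best pair usually beats its members on study-design data", {
  frac <- mean(vapply(1:50, function(s) {
    sim <- generate_ct_data(silverside_design_config(seed = s))
    bp <- normfinder_best_pair(sim$ct, groups = sim$meta$treatment)
    sv <- stats::setNames(bp$singles$value, bp$singles$gene)
    bp$stability <= min(sv[bp$best_pair])
  }, logical(1)))
  expect_gte(frac, 0.80)
})

test_that("BestKeeper descriptors, index and correlations are coherent", {
  m <- rbind(A = c(20, 22, 21.5), B = c(21, 23, 22.4))
  colnames(m) <- paste0("s", 1:3)
  bk <- bestkeeper(m)
  expect_equal(unname(bk$index),
               sqrt(m["A", ] * m["B", ]), ignore_attr = TRUE)
  d <- bk$descriptors
  expect_true(all(d$min_ct <= d$geo_mean_ct & d$geo_mean_ct <= d$ar_mean_ct &
                    d$ar_mean_ct <= d$max_ct))
  expect_true(all(abs(d$r) <= 1))
  expect_true(all(d$p_value > 0 & d$p_value <= 1))
  # co-monotone genes correlate almost perfectly with their index (the
  # geometric mean is not affine in Ct, so r is near but not exactly 1)
  expect_equal(d$r, c(1, 1), tolerance = 1e-3)
  m2 <- rbind(A = c(20, 22), B = c(21, 23))
  colnames(m2) <- c("s1", "s2")
  # with two samples the index itself is still the per-sample geomean
  expect_error(bestkeeper(m2), "3 complete samples")

  expect_error(bestkeeper(m[, 1:2]), "3 complete samples")
  expect_error(bestkeeper(m[1, , drop = FALSE]), "2 genes")
})

test_that("BestKeeper ranks by dispersion or by |r| as requested", {
  set.seed(77)
  m <- rbind(a = 20 + stats::rnorm(12, 0, 0.5),
             b = 22 + stats::rnorm(12, 0, 1.0),
             c = 24 + stats::rnorm(12, 0, 0.2))
  colnames(m) <- paste0("s", 1:12)
  bk_sd <- bestkeeper(m, ranking_mode = "sd")
  expect_identical(attr(bk_sd$stability, "direction"), "lower_is_stable")
  expect_equal(stats::setNames(bk_sd$stability$rank, bk_sd$stability$gene),
               c(a = 2, b = 3, c = 1))
  bk_r <- bestkeeper(m, ranking_mode = "correlation")
  expect_identical(attr(bk_r$stability, "direction"), "higher_is_stable")
  expect_equal(stats::setNames(bk_r$stability$value, bk_r$stability$gene),
               stats::setNames(abs(bk_r$descriptors$r), bk_r$descriptors$gene))
  # mad dialect reports the mean absolute deviation around the mean
  bk_mad <- bestkeeper(m, dispersion = "mad")
  expect_equal(stats::setNames(bk_mad$stability$value, bk_mad$stability$gene),
               stats::setNames(rowMeans(abs(m - rowMeans(m))), rownames(m)))
})

test_that("a constant gene is ranked first in sd mode, |r| = 0 with warning", {
  m <- rbind(const = rep(20, 6), wob = 22 + c(-1, 1, -1, 1, -1, 1))
  colnames(m) <- paste0("s", 1:6)
  expect_warning(bk <- bestkeeper(m), "constant")
  expect_equal(bk$descriptors$sd_ct[1], 0)
  expect_equal(bk$descriptors$cv_pct[1], 0)
  expect_equal(bk$stability$rank[bk$stability$gene == "const"], 1)
  expect_equal(bk$descriptors$r[1], 0)
})
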