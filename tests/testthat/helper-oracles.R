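# Shared fixtures and independent brute-force oracles. The oracles use
# plain double loops over gene pairs / ranked subsets, deliberately
# different from the covariance-based implementations they check.

rand_ct <- function(n_genes = 8, n_samples = 20, seed = 1, noise_sd = 1,
                    mu_range = c(15, 30)) {
  set.seed(seed)
  mu <- stats::runif(n_genes, mu_range[1], mu_range[2])
  m <- matrix(stats::rnorm(n_genes * n_samples, 0, noise_sd), n_genes) + mu
  dimnames(m) <- list(paste0("g", seq_len(n_genes)),
                      paste0("s", seq_len(n_samples)))
  m
}

naive_dct <- function(m) {
  G <- nrow(m)
  out <- stats::setNames(numeric(G), rownames(m))
  for (j in seq_len(G)) {
    acc <- numeric(0)
    for (k in seq_len(G)) {
      if (k != j) acc <- c(acc, stats::sd(m[j, ] - m[k, ]))
    }
    out[j] <- mean(acc)
  }
  out
}

naive_genorm_m <- function(q) {
  L <- log2(q)
  G <- nrow(q)
  out <- stats::setNames(numeric(G), rownames(q))
  for (j in seq_len(G)) {
    acc <- numeric(0)
    for (k in seq_len(G)) {
      if (k != j) acc <- c(acc, stats::sd(L[j, ] - L[k, ]))
    }
    out[j] <- mean(acc)
  }
  out
}

naive_pairwise_v <- function(q, ordered_genes) {
  G <- length(ordered_genes)
  out <- numeric(0)
  for (n in 2:(G - 1)) {
    nf_n <- apply(q[ordered_genes[1:n], , drop = FALSE], 2,
                  function(col) prod(col)^(1 / n))
    nf_n1 <- apply(q[ordered_genes[1:(n + 1)], , drop = FALSE], 2,
                   function(col) prod(col)^(1 / (n + 1)))
    out <- c(out, stats::sd(log2(nf_n / nf_n1)))
  }
  stats::setNames(out, sprintf("V%d/%d", 2:(G - 1), 3:G))
}

# Literal transcription of the committed variance decomposition, written
# independently of the package's matrix algebra.
naive_normfinder <- function(m, groups) {
  I <- nrow(m)
  groups <- factor(groups)
  gl <- levels(groups)
  z <- m
  for (s in seq_len(ncol(m))) z[, s] <- m[, s] - mean(m[, s])
  zbar <- matrix(0, I, length(gl))
  s2 <- matrix(0, I, length(gl))
  n_g <- numeric(length(gl))
  for (gi in seq_along(gl)) {
    cols <- which(groups == gl[gi])
    n_g[gi] <- length(cols)
    for (i in seq_len(I)) {
      zbar[i, gi] <- mean(z[i, cols])
      s2[i, gi] <- stats::var(z[i, cols])
    }
  }
  sigma2 <- matrix(0, I, length(gl))
  for (gi in seq_along(gl)) {
    sbar2 <- mean(s2[, gi])
    for (i in seq_len(I)) {
      sigma2[i, gi] <- max(0, (s2[i, gi] - sbar2 / I) / (1 - 2 / I))
    }
  }
  if (length(gl) == 1L) return(stats::setNames(sqrt(sigma2[, 1]), rownames(m)))
  d <- zbar - rowMeans(zbar)
  rho <- numeric(I)
  gamma2 <- numeric(length(gl))
  for (gi in seq_along(gl)) {
    gamma2[gi] <- max(0, stats::var(d[, gi]) - mean(sigma2[, gi] / n_g[gi]))
  }
  for (i in seq_len(I)) {
    acc <- numeric(length(gl))
    for (gi in seq_along(gl)) {
      se2 <- sigma2[i, gi] / n_g[gi]
      dt <- if (gamma2[gi] + se2 == 0) 0 else
        d[i, gi] * gamma2[gi] / (gamma2[gi] + se2)
      acc[gi] <- abs(dt) + sqrt(se2)
    }
    rho[i] <- mean(acc)
  }
  stats::setNames(rho, rownames(m))
}

# Two-group dataset with a single group-shifted gene against pure technical
# noise, used by the NormFinder detection checks.
shifted_group_config <- function(seed, n_genes = 6, n_per_group = 10,
                                 sigma_tech = 1, tech_reps = 3,
                                 delta = 1.0) {
  cfg <- simple_design_config(n_genes, n_per_group, seed = seed,
                              sigma_range = c(0, 0), sigma_sample = 0.8,
                              sigma_tech = sigma_tech,
                              tech_reps = tech_reps)
  cfg$treatments <- c("grpA", "grpB")
  cfg$shifts <- matrix(0, n_genes, 2,
                       dimnames = list(cfg$genes$gene, c("grpA", "grpB")))
  cfg$shifts[n_genes, "grpB"] <- delta
  cfg
}
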