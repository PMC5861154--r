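# Synthetic Ct generator. The generative model works on the Ct (log2
# expression) scale, where additive Gaussian effects correspond to
# log-normal expression -- the assumption implicit in all four stability
# estimators:
#   Ct_{g,s,w} = mu_g + delta_{g,treatment(s)} + a_s + b_{g,s} + e_{g,s,w}
# with a_s ~ N(0, sigma_sample^2)   global mRNA-content effect per
#                                   biological sample (animal x tissue,
#                                   each tissue is its own RT reaction)
#      b_{g,s} ~ N(0, sigma_g^2)    per-gene biological variation
#      e_{g,s,w} ~ N(0, sigma_tech^2)  technical well noise
# The injected ground-truth instability score of a gene is
# sqrt(sigma_g^2 + var_t(delta_{g,t})) (sample variance over treatment
# levels), so both noisy genes and treatment-responsive genes are "bad".

validate_sim_config <- function(cfg) {
  g <- cfg$genes
  if (!is.data.frame(g) || !all(c("gene", "mu", "sigma_g") %in% names(g)))
    stop("`genes` must be a data.frame with columns gene, mu, sigma_g")
  if (anyDuplicated(g$gene)) stop("duplicated gene names in config")
  if (any(!is.finite(g$mu)) || any(g$mu <= 5) || any(g$mu >= 40))
    stop("gene baselines mu must lie in (5, 40) cycles")
  if (any(!is.finite(g$sigma_g)) || any(g$sigma_g < 0))
    stop("per-gene SDs must be >= 0")
  for (p in c("sigma_sample", "sigma_tech")) {
    if (!is.numeric(cfg[[p]]) || length(cfg[[p]]) != 1L ||
        !is.finite(cfg[[p]]) || cfg[[p]] < 0)
      stop(sprintf("`%s` must be a single non-negative number", p))
  }
  for (p in c("animals", "tech_reps")) {
    if (!is.numeric(cfg[[p]]) || cfg[[p]] < 1L)
      stop(sprintf("`%s` must be >= 1", p))
  }
  if (!length(cfg$treatments) || !length(cfg$ages) || !length(cfg$tissues))
    stop("design factors must each have at least one level")
  if (!identical(rownames(cfg$shifts), g$gene) ||
      !identical(colnames(cfg$shifts), cfg$treatments))
    stop("`shifts` must be a genes x treatments matrix matching the config")
  if (any(!is.finite(cfg$shifts))) stop("treatment shifts must be finite")
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1L || !is.finite(cfg$seed))
    stop("`seed` must be a single integer")
  invisible(cfg)
}

new_sim_config <- function(seed, treatments, ages, tissues, animals,
                           tech_reps, sigma_sample, sigma_tech, genes,
                           shifts) {
  cfg <- structure(list(seed = as.integer(seed),
                        treatments = as.character(treatments),
                        ages = as.character(ages),
                        tissues = as.character(tissues),
                        animals = as.integer(animals),
                        tech_reps = as.integer(tech_reps),
                        sigma_sample = sigma_sample,
                        sigma_tech = sigma_tech,
                        genes = genes, shifts = shifts),
                   class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

#' Generator configuration emulating the silverside exposure study design
#'
#' Eight candidate reference genes measured over 3 treatments (control, a
#' glyphosate-based herbicide, seawater) x 3 ages x 3 fish x 4 tissues
#' (108 biological samples) in technical triplicate. The sodium/potassium
#' ATPase gene `atp1a` plays the treatment-responsive control: it carries
#' +1.5 / +2.0 cycle shifts under the herbicide and seawater exposures.
#' `gapdh` and `tuba` carry inflated biological variance, the histone
#' `h3a` the lowest, so the injected ground-truth stability ordering has
#' `h3a` most stable and `atp1a` least stable.
#'
#' @param seed Integer seed; the config plus seed fully determines the
#'   generated dataset.
#' @param sigma_sample SD (cycles) of the global per-sample mRNA-content
#'   effect (drawn per animal x tissue, since each tissue is an independent
#'   RT reaction).
#' @param sigma_tech SD (cycles) of technical well noise.
#' @param treatments,ages,tissues,animals,tech_reps Design levels and
#'   counts; `animals` is animals per treatment x age cell.
#' @param genes Optional replacement gene table (`gene`, `mu`, `sigma_g`).
#' @param shifts Optional genes x treatments matrix of Ct shifts (cycles).
#' @return A `sim_config` for [generate_ct_data()].
#' @export
silverside_design_config <- function(seed = 1L,
                                     sigma_sample = 0.8,
                                     sigma_tech = 0.15,
                                     treatments = c("control", "roundup",
                                                    "seawater"),
                                     ages = c("adult", "juvenile", "immature"),
                                     tissues = c("brain", "gills",
                                                 "hepatopancreas", "kidney"),
                                     animals = 3L, tech_reps = 3L,
                                     genes = NULL, shifts = NULL) {
  if (is.null(genes)) {
    genes <- data.frame(
      gene = c("18s", "actb", "ef1a", "eif3g", "gapdh", "h3a", "atp1a",
               "tuba"),
      mu = c(12, 18, 17, 22, 20, 19, 23, 21),
      sigma_g = c(0.5, 0.35, 0.3, 0.4, 0.8, 0.2, 0.4, 0.8),
      stringsAsFactors = FALSE)
  }
  if (is.null(shifts)) {
    shifts <- matrix(0, nrow(genes), length(treatments),
                     dimnames = list(genes$gene, treatments))
    if ("atp1a" %in% genes$gene) {
      if ("roundup" %in% treatments) shifts["atp1a", "roundup"] <- 1.5
      if ("seawater" %in% treatments) shifts["atp1a", "seawater"] <- 2.0
    }
  }
  new_sim_config(seed, treatments, ages, tissues, animals, tech_reps,
                 sigma_sample, sigma_tech, genes, shifts)
}

#' Minimal single-factor generator configuration
#'
#' A small flat design (one treatment-like factor, one tissue) used for
#' quick simulations and the command-line `simulate --genes N --samples N`
#' path. Per-gene SDs are spread over `sigma_range` so the truth ordering
#' is non-trivial.
#'
#' @param n_genes,n_samples Matrix dimensions after technical collapsing.
#' @param seed Integer seed.
#' @param sigma_range Range of per-gene biological SDs (cycles).
#' @param tech_reps Technical replicates per reaction.
#' @inheritParams silverside_design_config
#' @return A `sim_config`.
#' @export
simple_design_config <- function(n_genes, n_samples, seed = 1L,
                                 sigma_range = c(0.2, 0.8),
                                 sigma_sample = 0.8, sigma_tech = 0.15,
                                 tech_reps = 3L) {
  if (n_genes < 1L || n_samples < 1L) stop("`n_genes` and `n_samples` must be >= 1")
  genes <- data.frame(
    gene = paste0("g", seq_len(n_genes)),
    mu = 16 + (seq_len(n_genes) - 1L) %% 10,
    sigma_g = seq(sigma_range[1], sigma_range[2], length.out = n_genes),
    stringsAsFactors = FALSE)
  shifts <- matrix(0, n_genes, 1L, dimnames = list(genes$gene, "all"))
  new_sim_config(seed, "all", "all", "all", n_samples, tech_reps,
                 sigma_sample, sigma_tech, genes, shifts)
}

#' Generate a synthetic Ct dataset with known ground truth
#'
#' Draws a dataset from the generative model described in the package
#' vignette: per-gene baselines plus treatment shifts, global per-sample
#' effects, per-gene biological noise and technical well noise, all
#' Gaussian on the Ct scale. The same config and seed always produce a
#' bit-identical dataset.
#'
#' @param config A `sim_config`, e.g. [silverside_design_config()].
#' @return An object of class `ct_sim`: list with
#'   \describe{
#'     \item{ct}{collapsed [ct_matrix()] (technical wells averaged)}
#'     \item{meta}{sample metadata (`sample_id`, `subject_id`, `treatment`,
#'       `age`, `tissue`, `biological_replicate`)}
#'     \item{long}{well-level long-form records}
#'     \item{truth}{per-gene injected instability score
#'       `sqrt(sigma_g^2 + var_t(delta))` and the implied true ordering}
#'     \item{config}{the config used}
#'   }
#' @export
generate_ct_data <- function(config) {
  if (!inherits(config, "sim_config"))
    stop("`config` must be a `sim_config` (see silverside_design_config())")
  validate_sim_config(config)
  set.seed(config$seed)
  g <- config$genes
  G <- nrow(g)

  meta <- expand.grid(tissue = config$tissues,
                      animal = seq_len(config$animals),
                      age = config$ages,
                      treatment = config$treatments,
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  meta$subject_id <- sprintf("%s_%s_f%d", meta$treatment, meta$age,
                             meta$animal)
  meta$sample_id <- sprintf("%s_%s", meta$subject_id, meta$tissue)
  meta$biological_replicate <- as.integer(meta$animal)
  meta <- meta[, c("sample_id", "subject_id", "treatment", "age", "tissue",
                   "biological_replicate")]
  S <- nrow(meta)
  W <- config$tech_reps

  a <- stats::rnorm(S, 0, config$sigma_sample)
  b <- matrix(stats::rnorm(G * S), G, S) * g$sigma_g
  delta <- config$shifts[, meta$treatment, drop = FALSE]
  base <- g$mu + delta + matrix(a, G, S, byrow = TRUE) + b
  e <- array(stats::rnorm(G * S * W, 0, config$sigma_tech), dim = c(G, S, W))
  wells <- array(base, dim = c(G, S, W)) + e

  idx <- expand.grid(well = seq_len(W), gene = seq_len(G),
                     sample = seq_len(S), KEEP.OUT.ATTRS = FALSE)
  long <- data.frame(sample_id = meta$sample_id[idx$sample],
                     gene = g$gene[idx$gene],
                     well = idx$well,
                     ct = wells[cbind(idx$gene, idx$sample, idx$well)],
                     treatment = meta$treatment[idx$sample],
                     age = meta$age[idx$sample],
                     tissue = meta$tissue[idx$sample],
                     subject_id = meta$subject_id[idx$sample],
                     stringsAsFactors = FALSE)

  collapsed <- base + apply(e, c(1L, 2L), mean)
  dimnames(collapsed) <- list(g$gene, meta$sample_id)
  ct <- ct_matrix(collapsed, efficiency = 2)

  shift_var <- apply(config$shifts, 1L, stats::var)
  if (ncol(config$shifts) < 2L) shift_var <- rep(0, G)
  score <- sqrt(g$sigma_g^2 + shift_var)
  truth <- data.frame(gene = g$gene, sigma_g = g$sigma_g,
                      shift_var = unname(shift_var),
                      score = unname(score),
                      true_rank = rank(score, ties.method = "average"),
                      stringsAsFactors = FALSE)

  structure(list(ct = ct, meta = meta, long = long, truth = truth,
                 config = config),
            class = "ct_sim")
}

#' @export
print.ct_sim <- function(x, ...) {
  cat(sprintf("synthetic Ct dataset: %d genes x %d samples (%d wells), seed %d\n",
              nrow(x$ct$ct), ncol(x$ct$ct), nrow(x$long), x$config$seed))
  ord <- x$truth$gene[order(x$truth$score)]
  cat("true stability ordering (best to worst): ",
      paste(ord, collapse = " > "), "\n", sep = "")
  invisible(x)
}

# Pooled cross-treatment consensus used by recovery_eval: the injected truth
# scores include treatment shifts, so recovery is judged on the consensus
# that pools all treatments (NormFinder grouped by treatment).
pooled_consensus <- function(ct, meta, group_factor = "treatment") {
  ctc <- complete_ct(ct, quiet = TRUE)
  groups <- NULL
  if (!is.null(group_factor) && group_factor %in% names(meta)) {
    gvec <- as.character(meta[[group_factor]][match(colnames(ctc$ct),
                                                    meta$sample_id)])
    if (length(unique(gvec)) >= 2L) groups <- gvec
  }
  q <- genorm_quantities(ctc)
  gn <- if (nrow(ctc$ct) >= 3L) genorm_stepwise(q) else genorm_m(q)
  aggregate_consensus(list(dct = dct_stability(ctc),
                           genorm = gn,
                           normfinder = normfinder_stability(ctc, groups),
                           bestkeeper = bestkeeper(ctc)$stability))
}

#' Evaluate recovery of the injected stability ordering
#'
#' Runs the generator and the pooled cross-treatment consensus once per
#' seed and summarises how often the consensus recovers the injected truth:
#' the fraction of seeds in which (a) the truth-least-stable gene is ranked
#' consensus-last, (b) the truth-most-stable gene lands in the consensus
#' top 2, and (c) the Spearman correlation between truth scores and
#' consensus geometric-mean ranks. When truth or consensus is fully tied
#' (e.g. a zero-noise config) the per-seed metrics are `NA` with a warning.
#'
#' @param n_seeds Number of independent simulated datasets.
#' @param config A `sim_config`; seeds `config$seed + 0:(n_seeds-1)` are
#'   used unless `seeds` is given.
#' @param seeds Optional explicit integer seed vector (length `n_seeds`).
#' @param group_factor Metadata factor passed to NormFinder as grouping.
#' @return An object of class `recovery_summary`: list with `per_seed`
#'   data.frame and the summary fractions `frac_worst_last`,
#'   `frac_best_top2`, `mean_spearman`.
#' @export
recovery_eval <- function(n_seeds, config = silverside_design_config(),
                          seeds = NULL, group_factor = "treatment") {
  if (!is.numeric(n_seeds) || length(n_seeds) != 1L || n_seeds < 1)
    stop("`n_seeds` must be a single integer >= 1")
  n_seeds <- as.integer(n_seeds)
  if (is.null(seeds)) seeds <- config$seed + seq_len(n_seeds) - 1L
  if (length(seeds) != n_seeds) stop("`seeds` must have length `n_seeds`")

  per <- lapply(seeds, function(s) {
    cfg <- config
    cfg$seed <- as.integer(s)
    sim <- generate_ct_data(cfg)
    cons <- suppressWarnings(pooled_consensus(sim$ct, sim$meta, group_factor))
    gm <- stats::setNames(cons$geomean, cons$gene)[sim$truth$gene]
    truth <- sim$truth
    if (diff(range(truth$score)) == 0 || diff(range(gm)) == 0) {
      return(data.frame(seed = s, worst_last = NA, best_top2 = NA,
                        spearman = NA_real_))
    }
    worst <- truth$gene[truth$score == max(truth$score)]
    best <- truth$gene[truth$score == min(truth$score)]
    data.frame(
      seed = s,
      worst_last = length(worst) == 1L && all(gm[worst] >= gm),
      best_top2 = length(best) == 1L && sum(gm < gm[best]) < 2L,
      spearman = stats::cor(truth$score, gm, method = "spearman"))
  })
  per <- do.call(rbind, per)
  if (all(is.na(per$worst_last)))
    warning("recovery fractions undefined: stabilities fully tied in every seed")
  structure(list(per_seed = per,
                 n_seeds = n_seeds,
                 frac_worst_last = mean(per$worst_last, na.rm = TRUE),
                 frac_best_top2 = mean(per$best_top2, na.rm = TRUE),
                 mean_spearman = mean(per$spearman, na.rm = TRUE)),
            class = "recovery_summary")
}

#' @export
print.recovery_summary <- function(x, ...) {
  cat(sprintf("recovery over %d seeds:\n", x$n_seeds))
  cat(sprintf("  least-stable gene ranked last: %.1f%%\n",
              100 * x$frac_worst_last))
  cat(sprintf("  most-stable gene in top 2:     %.1f%%\n",
              100 * x$frac_best_top2))
  cat(sprintf("  mean Spearman(truth, consensus): %.3f\n", x$mean_spearman))
  invisible(x)
}
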