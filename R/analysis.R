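# Stratified analysis driver: runs the four stability estimators and the
# geometric-mean consensus per stratum of a multi-factor design
# (stratifying factor x each remaining-factor level) plus a pooled
# all-data consensus.

# First candidate factor that has >= 2 levels and >= 3 samples per level in
# this stratum; NULL -> single-group NormFinder.
pick_group_factor <- function(meta, candidates) {
  for (f in candidates) {
    if (!f %in% names(meta)) next
    lv <- table(as.character(meta[[f]]))
    if (length(lv) >= 2L && all(lv >= 3L)) return(f)
  }
  NULL
}

analyze_stratum <- function(ctm, meta_sub, group_candidates, genorm_mean,
                            bestkeeper_dispersion, consensus_bestkeeper,
                            min_samples, note, label) {
  ctc <- complete_ct(ctm, quiet = TRUE)
  n_dropped <- length(attr(ctc, "dropped_samples"))
  if (n_dropped > 0L)
    note("stratum '%s': dropped %d incomplete sample(s) (complete-case policy)",
         label, n_dropped)
  if (ncol(ctc$ct) < max(min_samples, 3L))
    stop(sprintf("fewer than %d complete samples", max(min_samples, 3L)))
  meta_c <- meta_sub[match(colnames(ctc$ct), meta_sub$sample_id), ,
                     drop = FALSE]
  gf <- pick_group_factor(meta_c, group_candidates)
  groups <- if (is.null(gf)) NULL else as.character(meta_c[[gf]])
  note("stratum '%s': NormFinder groups = %s", label,
       if (is.null(gf)) "single group" else gf)

  dct <- dct_stability(ctc)
  q <- genorm_quantities(ctc)
  gn <- if (nrow(ctc$ct) >= 3L) genorm_stepwise(q, mean_type = genorm_mean)
        else genorm_m(q, mean_type = genorm_mean)
  for (line in attr(gn, "log")) note("stratum '%s': geNorm %s", label, line)
  pv <- if (nrow(ctc$ct) >= 3L) genorm_pairwise_variation(q, gn) else NULL
  nf <- normfinder_stability(ctc, groups)
  bk <- bestkeeper(ctc, ranking_mode = consensus_bestkeeper,
                   dispersion = bestkeeper_dispersion)
  consensus <- aggregate_consensus(list(dct = dct, genorm = gn,
                                        normfinder = nf,
                                        bestkeeper = bk$stability))
  list(label = label, n_samples = ncol(ctc$ct), n_dropped = n_dropped,
       group_factor = if (is.null(gf)) "none" else gf,
       consensus = consensus, pairwise_variation = pv,
       stability = list(dct = dct, genorm = gn, normfinder = nf,
                        bestkeeper = bk))
}

#' Run the full stratified stability analysis
#'
#' Reproduces the standard reference-gene validation workflow on a
#' multi-factor design: for each level of `stratify_by` (typically the
#' treatment) the four stability estimators and the geometric-mean
#' consensus are run on the treatment-level data and on each level of every
#' `within` factor (e.g. each age pooled over tissues, and each tissue
#' pooled over ages); a pooled all-data consensus is computed as well.
#' Within each stratum the NormFinder grouping uses the first residual
#' design factor with at least two levels (>= 3 samples each); with no such
#' factor the single-group model is used. Strata with fewer than
#' `min_samples` complete samples are skipped with a warning.
#'
#' @param x A [ct_matrix()].
#' @param meta Sample metadata with `sample_id` plus the design factors.
#' @param stratify_by Primary stratifying factor (default `"treatment"`);
#'   `NULL` analyses the pooled data only.
#' @param within Secondary factors analysed level-by-level inside each
#'   primary stratum.
#' @param genorm_mean Partner-mean dialect for geNorm M, see [genorm_m()].
#' @param bestkeeper_dispersion Dispersion dialect, see [bestkeeper()].
#' @param consensus_bestkeeper Which BestKeeper ranking feeds the consensus:
#'   `"sd"` (default, the conservative dispersion ranking) or
#'   `"correlation"`.
#' @param min_samples Minimum complete samples per stratum.
#' @param verbose Emit progress/log messages.
#' @return An object of class `stability_report`: list with `pooled` (the
#'   all-data stratum result), `strata` (named list of per-stratum
#'   results), `options`, and the run `log` (every optioned decision in
#'   force). Each stratum result holds the `consensus_table`, the four
#'   per-method tables and the geNorm pairwise variation.
#' @seealso [write_report()]
#' @export
run_full_analysis <- function(x, meta,
                              stratify_by = "treatment",
                              within = c("age", "tissue"),
                              genorm_mean = c("arithmetic", "geometric"),
                              bestkeeper_dispersion = c("sd", "mad"),
                              consensus_bestkeeper = c("sd", "correlation"),
                              min_samples = 3L, verbose = TRUE) {
  genorm_mean <- match.arg(genorm_mean)
  bestkeeper_dispersion <- match.arg(bestkeeper_dispersion)
  consensus_bestkeeper <- match.arg(consensus_bestkeeper)
  x <- as_ct(x)
  check_meta(x, meta)
  if (!is.null(stratify_by) && !stratify_by %in% names(meta))
    stop(sprintf("stratifying factor '%s' not found in metadata", stratify_by))
  within <- intersect(within, names(meta))

  run_log <- character()
  note <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    if (verbose) message(msg)
    run_log <<- c(run_log, msg)
    invisible(NULL)
  }
  note("tie policy: average ranks everywhere; geNorm final pair enters consensus as ranks 1.5/1.5")
  note("geNorm M partner mean: %s", genorm_mean)
  note("BestKeeper dispersion dialect: %s; consensus fed by the %s ranking",
       bestkeeper_dispersion, consensus_bestkeeper)
  note("missing data: complete-case per stratum")

  strata_def <- list(pooled = list(filter = list(),
                                   groups = c(stratify_by, within)))
  if (!is.null(stratify_by)) {
    for (lv in unique(as.character(meta[[stratify_by]]))) {
      base <- stats::setNames(list(lv), stratify_by)
      strata_def[[sprintf("%s=%s", stratify_by, lv)]] <-
        list(filter = base, groups = within)
      for (f in within) {
        for (v in unique(as.character(meta[[f]]))) {
          strata_def[[sprintf("%s=%s|%s=%s", stratify_by, lv, f, v)]] <-
            list(filter = c(base, stats::setNames(list(v), f)),
                 groups = setdiff(within, f))
        }
      }
    }
  }

  results <- list()
  for (nm in names(strata_def)) {
    def <- strata_def[[nm]]
    res <- tryCatch({
      sub <- if (length(def$filter)) {
        do.call(subset_samples, c(list(x = x, meta = meta), def$filter))
      } else {
        list(ct = x, meta = meta)
      }
      analyze_stratum(sub$ct, sub$meta, def$groups, genorm_mean,
                      bestkeeper_dispersion, consensus_bestkeeper,
                      min_samples, note, nm)
    }, error = function(e) {
      warning(sprintf("stratum '%s' skipped: %s", nm, conditionMessage(e)),
              call. = FALSE)
      NULL
    })
    if (!is.null(res)) {
      res$filter <- def$filter
      results[[nm]] <- res
    }
  }
  if (is.null(results$pooled)) stop("pooled analysis failed; nothing to report")
  structure(list(pooled = results$pooled,
                 strata = results[setdiff(names(results), "pooled")],
                 options = list(stratify_by = stratify_by, within = within,
                                genorm_mean = genorm_mean,
                                bestkeeper_dispersion = bestkeeper_dispersion,
                                consensus_bestkeeper = consensus_bestkeeper,
                                min_samples = min_samples),
                 log = run_log),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("stability report: pooled + %d strata\n", length(x$strata)))
  cat("pooled consensus (most to least stable): ",
      paste(x$pooled$consensus$gene, collapse = " > "), "\n", sep = "")
  invisible(x)
}

sanitize_filename <- function(x) gsub("[^A-Za-z0-9_.=-]", "_", x)

#' Write a stability report to delimited-text and JSON files
#'
#' One tab-separated consensus table per stratum (columns `gene`,
#' `rank_dct`, `rank_genorm`, `rank_normfinder`, `rank_bestkeeper`,
#' `geomean`, `final_rank`), per-method stability value tables, a
#' machine-readable `summary.json` for the whole run (full precision) and
#' the run log. Output is a pure function of the report, so identical
#' analyses rewrite byte-identical files.
#'
#' @param report A `stability_report` from [run_full_analysis()].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "stability_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  all_strata <- c(list(pooled = report$pooled), report$strata)
  for (nm in names(all_strata)) {
    st <- all_strata[[nm]]
    base <- sanitize_filename(nm)
    cons <- st$consensus
    cons$geomean <- round(cons$geomean, 2)  # printed precision; JSON keeps full
    utils::write.table(cons, file.path(dir, paste0("consensus_", base, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    meth <- do.call(rbind, lapply(names(st$stability), function(m) {
      tb <- st$stability[[m]]
      if (inherits(tb, "bestkeeper_result")) tb <- tb$stability
      val <- if (inherits(tb, "genorm_ranking")) tb$m_value else tb$value
      data.frame(method = m, gene = tb$gene, value = val,
                 rank = tb$rank, stringsAsFactors = FALSE)
    }))
    utils::write.table(meth, file.path(dir, paste0("stability_", base, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  summary <- list(
    options = report$options,
    log = report$log,
    strata = lapply(all_strata, function(st) list(
      label = st$label,
      n_samples = st$n_samples,
      n_dropped = st$n_dropped,
      normfinder_group_factor = st$group_factor,
      pairwise_variation = as.list(st$pairwise_variation),
      consensus = st$consensus)))
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  writeLines(report$log, file.path(dir, "run_log.txt"))
  invisible(dir)
}
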