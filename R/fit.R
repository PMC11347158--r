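#' Fit the synthesis model: filters, ratios and context analyses
#'
#' The central estimator of the package. Given conversion profiles for a
#' three-condition labeling study, it constructs the Initial dataset
#' (expression above `cpm_min` in every sample, curated ids only), tests
#' each unit for labeling above the no-4SU background, applies the
#' drug-floor filter to obtain the Final dataset, computes the
#' background-subtracted synthesis ratio per Final unit, and runs the
#' genomic-context analyses (group comparisons on location class, host-gene
#' class and the three Microprocessor cis-motifs; Spearman correlation with
#' TSS distance) on the context-deduplicated set. A sample-level PCA of the
#' conversion-rate matrix is attached as QC.
#'
#' @param profiles profiles data frame from [quantify_study()] or
#'   [simulate_profiles()].
#' @param annotation per-miRNA annotation data frame.
#' @param curated curated high-confidence id list.
#' @param params a [filter_params()].
#' @param test group-comparison test, `"welch"` or `"wilcoxon"`.
#' @return An object of class `mirna_synthesis` with elements `membership`,
#'   `results` (ratio table), `context_set`, `comparisons` (named list of
#'   [group_compare()] results), `tss` (correlation `htest` or NULL),
#'   `rate_matrix` (unit x sample), `pca` (sample-level [stats::prcomp]),
#'   `params`, `n` (stage sizes).
#' @seealso [run_pipeline()] for the full raw-reads-to-fit driver.
#' @export
mirna_synthesis <- function(profiles, annotation, curated,
                            params = filter_params(),
                            test = c("welch", "wilcoxon")) {
  test <- match.arg(test)
  membership <- dataset_membership(profiles, curated, annotation, params)
  final <- membership$unit[membership$in_final]
  results <- if (length(final))
    synthesis_ratio(profiles, final, annotation)
  else
    cbind(data.frame(unit = character(), mean_rate_control = numeric(),
                     mean_rate_dmso = numeric(), mean_rate_plab = numeric(),
                     bg_sub_dmso = numeric(), bg_sub_plab = numeric(),
                     ratio = numeric(), mean_cpm = numeric()),
          annotation[0, setdiff(names(annotation), "mirna_id"),
                     drop = FALSE])

  ctx <- membership$unit[membership$in_context_set]
  ctx_results <- results[results$unit %in% ctx, , drop = FALSE]
  groupings <- c("location_class", "gene_class",
                 "motif_CNNC", "motif_basal_UG", "motif_apical_UGU")
  groupings <- intersect(groupings, names(ctx_results))
  comparisons <- stats::setNames(lapply(groupings, function(g)
    tryCatch(withCallingHandlers(
      group_compare(ctx_results, g, test = test),
      warning = function(w) invokeRestart("muffleWarning")),
      error = function(e) NULL)), groupings)

  tss <- if (nrow(ctx_results) >= 3L &&
             "tss_distance_nt" %in% names(ctx_results))
    tryCatch(tss_correlation(ctx_results), error = function(e) NULL)
  else NULL

  rate_matrix <- local({
    units <- sort(unique(profiles$unit))
    samples <- unique(profiles$sample)
    m <- matrix(0, length(units), length(samples),
                dimnames = list(units, samples))
    m[cbind(match(profiles$unit, units),
            match(profiles$sample, samples))] <- profiles$conversion_rate
    m
  })
  pca <- if (ncol(rate_matrix) >= 2L && nrow(rate_matrix) >= 2L)
    prcomp(t(rate_matrix), center = TRUE, scale. = FALSE)
  else NULL

  structure(list(membership = membership, results = results,
                 context_set = ctx, comparisons = comparisons, tss = tss,
                 rate_matrix = rate_matrix, pca = pca, params = params,
                 test = test,
                 n = c(all = nrow(membership),
                       initial = sum(membership$in_initial),
                       labeled = sum(membership$labeled %in% TRUE),
                       final = sum(membership$in_final),
                       context = length(ctx))),
            class = "mirna_synthesis")
}

#' @export
print.mirna_synthesis <- function(x, ...) {
  cat("miRNA synthesis fit (background-subtracted conversion ratios)\n")
  cat(sprintf("  units: %d total -> %d initial -> %d labeled -> %d final (%d context-eligible)\n",
              x$n["all"], x$n["initial"], x$n["labeled"], x$n["final"],
              x$n["context"]))
  if (nrow(x$results))
    cat(sprintf("  median synthesis ratio: %.3f\n",
                median(x$results$ratio)))
  invisible(x)
}

#' @export
summary.mirna_synthesis <- function(object, ...) {
  print(object)
  if (nrow(object$results)) {
    cat("  ratio quantiles:\n")
    print(round(quantile(object$results$ratio,
                         c(0.1, 0.25, 0.5, 0.75, 0.9)), 3))
  }
  for (cc in object$comparisons) if (!is.null(cc)) print(cc)
  if (!is.null(object$tss))
    cat(sprintf("  TSS-distance correlation (%s): rho = %.3f, p = %.3g\n",
                object$tss$method, unname(object$tss$estimate),
                object$tss$p.value))
  invisible(object)
}

#' @export
coef.mirna_synthesis <- function(object, ...) {
  stats::setNames(object$results$ratio, object$results$unit)
}

#' Plot a fitted synthesis analysis
#'
#' `"ratio_box"` draws the per-group ratio box plots (median with 10th/90th
#' percentile boxes), `"rates"` the per-condition conversion-rate
#' distributions, `"pca"` the sample scores of the QC PCA.
#'
#' @param x a [mirna_synthesis()] object.
#' @param type which panel to draw.
#' @param by grouping column for `"ratio_box"`.
#' @param ... passed to the underlying plotting functions.
#' @export
plot.mirna_synthesis <- function(x, type = c("ratio_box", "rates", "pca"),
                                 by = "location_class", ...) {
  type <- match.arg(type)
  if (type == "ratio_box") {
    res <- x$results[x$results$unit %in% x$context_set, , drop = FALSE]
    if (!nrow(res)) stop("no context-eligible units to plot")
    graphics::boxplot(ratio ~ get(by), data = res,
                      xlab = by, ylab = "synthesis ratio", ...)
    graphics::abline(h = 1, lty = 2, col = "grey50")
  } else if (type == "rates") {
    m <- x$rate_matrix
    graphics::boxplot(m, las = 2, ylab = "T>C conversion rate",
                      log = if (all(m > 0)) "y" else "", ...)
  } else {
    if (is.null(x$pca)) stop("no PCA available")
    sc <- x$pca$x
    graphics::plot(sc[, 1], sc[, 2], xlab = "PC1", ylab = "PC2", ...)
    graphics::text(sc[, 1], sc[, 2], rownames(sc), pos = 3, cex = 0.7)
  }
  invisible(x)
}

#' Run the full pipeline on a simulated study
#'
#' Chains simulation, trimming, conversion-aware quantification with SNP
#' masking, dataset filtering and the synthesis fit under one seed.
#'
#' @param config a [sim_config()].
#' @param trim a [trim_params()]; the adapter defaults to the config's.
#' @param align an [align_params()].
#' @param filter a [filter_params()].
#' @param flank template flank passed to [build_index()].
#' @return A list with `bundle` (reference + truth), `profiles`, and `fit`
#'   (the [mirna_synthesis()] object).
#' @export
run_pipeline <- function(config, trim = NULL, align = align_params(),
                         filter = filter_params(), flank = 3L) {
  study <- simulate_study(config)
  if (is.null(trim)) trim <- trim_params(adapter_seq = config$adapter_seq)
  index <- build_index(study$bundle$mature, study$bundle$loci,
                       study$bundle$genome, flank = flank)
  profiles <- quantify_study(study$libraries, study$samples, index,
                             trim = trim, align = align)
  fit <- mirna_synthesis(profiles, study$bundle$annotation,
                         study$bundle$curated, filter)
  list(bundle = study$bundle, index = index, profiles = profiles,
       fit = fit)
}
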