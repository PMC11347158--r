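#' Background-subtracted synthesis ratios
#'
#' For each Final-dataset unit, computes replicate-mean conversion rates
#' per condition, subtracts the no-4SU background mean from the vehicle and
#' drug means, and forms the synthesis ratio
#' `(drug - background) / (vehicle - background)`: 1 means synthesis is
#' unchanged by the drug, 0 means fully suppressed. Ratios are not clamped;
#' values above 1 (apparent increase) are reported as-is. Each replicate's
#' rate is weighted equally (mean of rates, not pooled counts).
#'
#' @param profiles profiles data frame.
#' @param final_set Final-dataset unit ids; upstream filters guarantee
#'   `bg_sub_dmso > 0` and `bg_sub_plab >= 0` for them, so ratios are
#'   finite and non-negative.
#' @param annotation optional annotation data frame; context columns are
#'   joined on the unit's first member id.
#' @return Data frame: unit, mean_rate_control, mean_rate_dmso,
#'   mean_rate_plab, bg_sub_dmso, bg_sub_plab, ratio, mean_cpm, plus
#'   annotation columns when supplied.
#' @export
synthesis_ratio <- function(profiles, final_set, annotation = NULL) {
  sub <- profiles[profiles$unit %in% final_set, , drop = FALSE]
  mean_by <- function(cond, col = "conversion_rate") {
    x <- sub[sub$condition == cond, , drop = FALSE]
    out <- tapply(x[[col]], x$unit, mean)
    out[match(final_set, names(out))]
  }
  mc <- mean_by("control_no4su")
  md <- mean_by("dmso_4su")
  mp <- mean_by("plab_4su")
  bg_d <- md - mc
  bg_p <- mp - mc
  if (any(is.na(bg_d)) || any(bg_d <= 0))
    stop("bg_sub_dmso <= 0 for supplied unit(s): ",
         paste(final_set[is.na(bg_d) | bg_d <= 0], collapse = ", "),
         "; filter contract violated", call. = FALSE)

  cpm_t <- tapply(sub$cpm, sub$unit, mean)
  cpm_all <- cpm_t[match(final_set, names(cpm_t))]
  out <- data.frame(unit = final_set,
                    mean_rate_control = as.numeric(mc),
                    mean_rate_dmso = as.numeric(md),
                    mean_rate_plab = as.numeric(mp),
                    bg_sub_dmso = as.numeric(bg_d),
                    bg_sub_plab = as.numeric(bg_p),
                    ratio = as.numeric(bg_p / bg_d),
                    mean_cpm = as.numeric(cpm_all),
                    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(annotation)) {
    first_member <- vapply(strsplit(final_set, "[|]"), `[`, character(1), 1)
    idx <- match(first_member, annotation$mirna_id)
    for (col in setdiff(names(annotation), "mirna_id"))
      out[[col]] <- annotation[[col]][idx]
  }
  out
}

#' Compare synthesis ratios between two groups
#'
#' Two-sided Welch two-sample t-test (default) or Mann-Whitney between the
#' ratios of two groups, with per-group median and 10th/90th percentiles —
#' the summaries used in the box plots.
#'
#' @param results a [synthesis_ratio()] table restricted to the
#'   context-eligible set.
#' @param by grouping column name (e.g. `location_class`, `gene_class`, or
#'   a motif flag).
#' @param levels the two group levels to compare; defaults to sensible
#'   pairs for the standard groupings, otherwise the two most frequent
#'   levels.
#' @param test `"welch"` or `"wilcoxon"`.
#' @return A list of class `group_comparison`: `by`, `groups` (data frame
#'   n/median/q10/q90 per level), `statistic`, `p_value`, `test`; or `NULL`
#'   (with a warning) when a group has fewer than 2 observations.
#' @export
group_compare <- function(results, by, levels = NULL,
                          test = c("welch", "wilcoxon")) {
  test <- match.arg(test)
  if (!by %in% names(results))
    stop("grouping column '", by, "' not in results", call. = FALSE)
  if (is.null(levels)) {
    levels <- switch(by,
                     location_class = c("intronic", "exonic"),
                     gene_class = c("lncRNA", "protein_coding"),
                     names(sort(table(results[[by]]), decreasing = TRUE))[1:2])
  }
  g1 <- results$ratio[results[[by]] %in% levels[1]]
  g2 <- results$ratio[results[[by]] %in% levels[2]]
  if (length(g1) < 2L || length(g2) < 2L) {
    warning("group with n < 2 for '", by, "'; comparison skipped")
    return(NULL)
  }
  ht <- if (test == "welch") t.test(g1, g2)
        else suppressWarnings(wilcox.test(g1, g2))
  summ <- function(x) c(n = length(x), median = median(x),
                        q10 = unname(quantile(x, 0.1)),
                        q90 = unname(quantile(x, 0.9)))
  groups <- as.data.frame(rbind(summ(g1), summ(g2)))
  groups <- cbind(level = as.character(levels), groups,
                  stringsAsFactors = FALSE)
  structure(list(by = by, groups = groups,
                 statistic = unname(ht$statistic),
                 p_value = ht$p.value, test = test),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("synthesis-ratio comparison by %s (%s test)\n", x$by, x$test))
  print(x$groups, row.names = FALSE, digits = 3)
  cat(sprintf("  statistic = %.3f, p = %.4g\n", x$statistic, x$p_value))
  invisible(x)
}

#' Correlation of synthesis ratio with TSS distance
#'
#' Spearman rank correlation (Pearson by flag) between the synthesis ratio
#' and the distance of the mature miRNA from its transcription start site.
#'
#' @param results a [synthesis_ratio()] table carrying `tss_distance_nt`.
#' @param method `"spearman"` or `"pearson"`.
#' @return An `htest` from [stats::cor.test()].
#' @export
tss_correlation <- function(results, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  ok <- complete.cases(results$ratio, results$tss_distance_nt)
  if (sum(ok) < 3L)
    stop("need at least 3 units with TSS distance", call. = FALSE)
  x <- results$ratio[ok]
  y <- results$tss_distance_nt[ok]
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    # fully tied input: no rank association by convention
    return(structure(list(estimate = c(rho = 0), p.value = 1,
                          method = paste(method, "(degenerate: ties)"),
                          data.name = "ratio vs tss_distance_nt"),
                     class = "htest"))
  }
  suppressWarnings(cor.test(x, y, method = method))
}

#' Write report tables for a fitted analysis
#'
#' Emits plain TSV tables: the ratio table, the group-comparison summary,
#' the unit x sample conversion-rate matrix, the top-N most expressed units
#' ordered by genomic-location class then descending expression, and the
#' sample PCA scores (QC).
#'
#' @param fit a [mirna_synthesis()] object.
#' @param outdir output directory.
#' @param top_n number of top expressed units for the ranked table.
#' @return Invisibly, the named vector of file paths.
#' @export
write_report <- function(fit, outdir, top_n = 25L) {
  stopifnot(inherits(fit, "mirna_synthesis"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(ratios = file.path(outdir, "ratios.tsv"),
             comparisons = file.path(outdir, "comparisons.tsv"),
             matrix = file.path(outdir, "rate_matrix.tsv"),
             top = file.path(outdir, "top_expressed.tsv"),
             membership = file.path(outdir, "membership.tsv"),
             pca = file.path(outdir, "pca_samples.tsv"))
  wt <- function(x, p) write.table(x, p, sep = "\t", quote = FALSE,
                                   row.names = FALSE)
  wt(fit$results, paths["ratios"])
  comp <- do.call(rbind, lapply(fit$comparisons, function(cc) {
    if (is.null(cc)) return(NULL)
    data.frame(grouping = cc$by, level = cc$groups$level, n = cc$groups$n,
               median = cc$groups$median, q10 = cc$groups$q10,
               q90 = cc$groups$q90, statistic = cc$statistic,
               p_value = cc$p_value, test = cc$test,
               stringsAsFactors = FALSE)
  }))
  if (is.null(comp))
    comp <- data.frame(grouping = character(), level = character(),
                       n = integer(), median = numeric(), q10 = numeric(),
                       q90 = numeric(), statistic = numeric(),
                       p_value = numeric(), test = character())
  wt(comp, paths["comparisons"])

  rm_df <- data.frame(unit = rownames(fit$rate_matrix),
                      fit$rate_matrix, check.names = FALSE)
  wt(rm_df, paths["matrix"])

  res <- fit$results
  if (nrow(res) && "location_class" %in% names(res)) {
    top <- utils::head(res[order(-res$mean_cpm), , drop = FALSE], top_n)
    top <- top[order(top$location_class, -top$mean_cpm), , drop = FALSE]
  } else {
    top <- utils::head(res[order(-res$mean_cpm), , drop = FALSE], top_n)
  }
  wt(top, paths["top"])
  wt(fit$membership, paths["membership"])
  pca <- fit$pca
  if (!is.null(pca)) {
    wt(data.frame(sample = rownames(pca$x), pca$x[, , drop = FALSE],
                  check.names = FALSE), paths["pca"])
  } else {
    wt(data.frame(sample = character()), paths["pca"])
  }
  invisible(paths)
}
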