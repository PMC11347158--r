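#' Dataset filter parameters
#'
#' @param cpm_min expression threshold; a unit must exceed this CPM in
#'   every sample of every condition.
#' @param alpha adjusted-significance threshold for the above-background
#'   labeling test.
#' @param adjust_method multiple-testing adjustment (Benjamini-Hochberg).
#' @return An object of class `filter_params`.
#' @export
filter_params <- function(cpm_min = 100, alpha = 0.05,
                          adjust_method = "BH") {
  if (cpm_min < 0) stop("cpm_min must be >= 0", call. = FALSE)
  if (alpha <= 0 || alpha >= 1)
    stop("alpha must be in (0, 1)", call. = FALSE)
  structure(list(cpm_min = cpm_min, alpha = alpha,
                 adjust_method = adjust_method),
            class = "filter_params")
}

unit_members_of <- function(profiles) {
  m <- attr(profiles, "unit_members")
  if (is.null(m)) {
    u <- unique(profiles$unit)
    m <- stats::setNames(strsplit(u, "[|]"), u)
  }
  m
}

#' Initial dataset: expressed and curated units
#'
#' A unit enters the Initial dataset iff its CPM exceeds `cpm_min` in every
#' sample (the "in all datasets" reading: per replicate, not per condition
#' mean) and at least one of its member miRNAs is on the curated
#' high-confidence list.
#'
#' @param profiles profiles data frame ([quantify_study()] or
#'   [simulate_profiles()]).
#' @param curated character vector of curated miRNA ids.
#' @param params a [filter_params()].
#' @return Character vector of retained unit ids.
#' @export
initial_filter <- function(profiles, curated, params = filter_params()) {
  samples <- attr(profiles, "samples")
  if (!is.null(samples)) {
    missing <- setdiff(samples$sample, unique(profiles$sample))
    if (length(missing))
      stop("profiles missing sample(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
  }
  members <- unit_members_of(profiles)
  ok_cpm <- tapply(profiles$cpm > params$cpm_min, profiles$unit, all)
  units <- names(ok_cpm)[ok_cpm]
  is_curated <- vapply(members[units], function(m)
    any(m %in% curated), logical(1))
  sort(units[is_curated])
}

#' Above-background labeling test
#'
#' For each unit, pools T>C and reference-T counts over the 4SU + vehicle
#' replicates and over the no-4SU control replicates, and tests one-sided
#' whether the vehicle conversion rate exceeds the control rate with the
#' exact conditional (hypergeometric) test on the pooled 2x2 table of
#' conversions vs non-conversions by condition. P-values are BH-adjusted
#' across tested units; a unit is labeled when its pooled vehicle rate is
#' above control and `p_adj < alpha`. Units with zero pooled coverage in
#' either condition are untestable and excluded.
#'
#' @param profiles profiles data frame.
#' @param units units to test (typically the [initial_filter()] result).
#' @param params a [filter_params()].
#' @return Data frame: unit, tc/coverage pooled per condition, p_value,
#'   p_adj, labeled (NA when untestable). The `alpha_direction` attribute
#'   records that significance is taken as `p_adj < alpha`.
#' @export
labeling_test <- function(profiles, units, params = filter_params()) {
  if (length(units) == 0L) {
    out <- data.frame(unit = character(), tc_dmso = integer(),
                      t_coverage_dmso = integer(), tc_control = integer(),
                      t_coverage_control = integer(), p_value = numeric(),
                      p_adj = numeric(), labeled = logical())
    attr(out, "alpha_direction") <-
      sprintf("labeled requires p_adj < %g (one-sided, vehicle > background)",
              params$alpha)
    return(out)
  }
  sub <- profiles[profiles$unit %in% units, , drop = FALSE]
  pool <- function(cond, col) {
    x <- sub[sub$condition == cond, , drop = FALSE]
    out <- tapply(x[[col]], x$unit, sum)
    out[match(units, names(out))]
  }
  tc_d <- pool("dmso_4su", "tc_count")
  cov_d <- pool("dmso_4su", "t_coverage")
  tc_c <- pool("control_no4su", "tc_count")
  cov_c <- pool("control_no4su", "t_coverage")

  testable <- !is.na(cov_d) & !is.na(cov_c) & cov_d > 0 & cov_c > 0
  # one-sided exact conditional test: hypergeometric upper tail of the
  # vehicle conversion count given the table margins
  p <- rep(NA_real_, length(units))
  p[testable] <- phyper(tc_d[testable] - 1,
                        tc_d[testable] + tc_c[testable],
                        (cov_d - tc_d)[testable] + (cov_c - tc_c)[testable],
                        cov_d[testable],
                        lower.tail = FALSE)
  p_adj <- rep(NA_real_, length(units))
  p_adj[testable] <- p.adjust(p[testable], method = params$adjust_method)
  dir_up <- tc_d / pmax(cov_d, 1) > tc_c / pmax(cov_c, 1)
  labeled <- ifelse(testable, dir_up & p_adj < params$alpha, NA)

  out <- data.frame(unit = units,
                    tc_dmso = as.integer(tc_d),
                    t_coverage_dmso = as.integer(cov_d),
                    tc_control = as.integer(tc_c),
                    t_coverage_control = as.integer(cov_c),
                    p_value = p, p_adj = p_adj, labeled = labeled,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "alpha_direction") <-
    sprintf("labeled requires p_adj < %g (one-sided, vehicle > background)",
            params$alpha)
  out
}

#' Drug-floor filter: Final dataset
#'
#' A labeled unit is retained in the Final dataset iff its mean conversion
#' rate over drug (PlaB) replicates is at least the mean over no-4SU
#' control replicates; a unit exactly at the boundary is kept (only units
#' strictly below background are excluded).
#'
#' @param profiles profiles data frame.
#' @param labeled character vector of labeled unit ids.
#' @return Character vector of Final-dataset unit ids.
#' @export
plab_floor_filter <- function(profiles, labeled) {
  sub <- profiles[profiles$unit %in% labeled, , drop = FALSE]
  mean_rate <- function(cond) {
    x <- sub[sub$condition == cond, , drop = FALSE]
    out <- tapply(x$conversion_rate, x$unit, mean)
    out[match(labeled, names(out))]
  }
  ok <- mean_rate("plab_4su") >= mean_rate("control_no4su")
  sort(labeled[!is.na(ok) & ok])
}

#' Context deduplication for grouped analyses
#'
#' Units whose member miRNAs map to genomic locations with differing
#' context (or whose own annotation is `mixed`) are excluded from
#' context-grouped analyses, though they stay in the ratio table.
#'
#' @param units unit ids (typically the Final dataset).
#' @param annotation annotation data frame (`mirna_id`, `location_class`,
#'   `gene_class`, ...).
#' @param members named list mapping unit to member miRNA ids; by default
#'   units named `id1|id2` are split on `|`.
#' @return Character vector of units eligible for context grouping.
#' @export
context_dedup <- function(units, annotation, members = NULL) {
  if (is.null(members))
    members <- stats::setNames(strsplit(units, "[|]"), units)
  keep <- logical(length(units))
  for (i in seq_along(units)) {
    ann <- annotation[annotation$mirna_id %in% members[[units[i]]], ,
                      drop = FALSE]
    if (nrow(ann) == 0L) {
      warning("unit '", units[i],
              "' has no annotation; excluded from context grouping")
      next
    }
    same <- length(unique(ann$location_class)) == 1L &&
      length(unique(ann$gene_class)) == 1L
    keep[i] <- same && !any(ann$location_class == "mixed")
  }
  sort(units[keep])
}

#' Full dataset-membership table
#'
#' Runs [initial_filter()], [labeling_test()], [plab_floor_filter()] and
#' [context_dedup()] and assembles one row per unit with inclusion flags
#' and the reason a unit dropped out.
#'
#' @param profiles profiles data frame.
#' @param curated curated id list.
#' @param annotation annotation data frame.
#' @param params a [filter_params()].
#' @return Data frame: unit, in_initial, p_value, p_adj, labeled, in_final,
#'   in_context_set, exclusion_reason.
#' @export
dataset_membership <- function(profiles, curated, annotation,
                               params = filter_params()) {
  units <- sort(unique(profiles$unit))
  initial <- initial_filter(profiles, curated, params)
  lt <- labeling_test(profiles, initial, params)
  labeled <- lt$unit[!is.na(lt$labeled) & lt$labeled]
  final <- plab_floor_filter(profiles, labeled)
  ctx <- context_dedup(final, annotation,
                       members = unit_members_of(profiles)[final])

  m <- data.frame(unit = units,
                  in_initial = units %in% initial,
                  p_value = lt$p_value[match(units, lt$unit)],
                  p_adj = lt$p_adj[match(units, lt$unit)],
                  labeled = lt$labeled[match(units, lt$unit)],
                  in_final = units %in% final,
                  in_context_set = units %in% ctx,
                  stringsAsFactors = FALSE)
  m$exclusion_reason <- ifelse(
    !m$in_initial, "initial_filter",
    ifelse(is.na(m$labeled), "untestable",
           ifelse(!m$labeled, "not_labeled",
                  ifelse(!m$in_final, "plab_below_control", "none"))))
  attr(m, "labeling_note") <- attr(lt, "alpha_direction")
  m
}
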