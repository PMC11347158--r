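#' Simulation configuration for labeled small-RNA libraries
#'
#' Describes a three-condition metabolic-labeling study: a no-4SU background
#' control, 4SU + vehicle (DMSO), and 4SU + drug (PlaB, an SF3B1 splicing
#' inhibitor). Each miRNA has a per-condition fraction of "new" molecules;
#' every reference T of a new molecule is emitted as C with probability
#' `p_inc` (the product of 4SU incorporation and chemical conversion
#' efficiency), which places conversion rates in the sub-percent regime for
#' realistic labeling fractions.
#'
#' @param n_mirnas number of mature miRNAs to simulate.
#' @param seq_length_range integer range of mature lengths (nt).
#' @param u_content_range range of per-miRNA U (i.e. reference T) content.
#' @param expression_law heavy-tailed abundance law; a list with `dist =
#'   "lognormal"`, `meanlog`, `sdlog`. Weights are normalized to sum to 1.
#' @param reads_per_sample reads emitted per library.
#' @param conditions data frame with columns `condition` (one of
#'   `control_no4su`, `dmso_4su`, `plab_4su`) and `n_replicates`.
#' @param p_inc probability that a U in a new molecule yields a detected
#'   T>C conversion.
#' @param new_fraction_law per-miRNA law of the fraction of new molecules
#'   under vehicle; list with `dist = "beta"`, `shape1`, `shape2`.
#' @param suppression_law per-miRNA law of the multiplicative reduction of
#'   the new fraction under drug; list with `dist = "uniform"`, `min`, `max`.
#' @param n_unsuppressed number of miRNAs forced to suppression 1
#'   (drug-insensitive, as observed for e.g. miR-21).
#' @param seq_error per-base substitution error probability; errors pick one
#'   of the three alternative bases uniformly, so the error contribution to
#'   the T>C rate is `seq_error / 3`.
#' @param snp_spec `NULL` to auto-place `n_snps` T>C SNPs, or a data frame
#'   with columns `mirna_id`, `position` (1-based in the mature sequence),
#'   `alt`, `freq` (allele frequency, 0.5 heterozygous or 1 homozygous).
#' @param n_snps number of SNPs to auto-place when `snp_spec` is `NULL`.
#' @param adapter_seq 3' adapter ligated after the insert.
#' @param n_random_flank randomized bases on each side of the insert
#'   (NEXTflex-style libraries use 4).
#' @param read_length fixed sequencing read length (nt); short inserts
#'   guarantee adapter read-through on every read.
#' @param n_dup_same_context miRNAs given a second genomic locus with the
#'   same genomic context.
#' @param n_dup_mixed_context miRNAs given a second locus with a different
#'   context (annotated `mixed`).
#' @param n_uncurated miRNAs withheld from the curated high-confidence list.
#' @param genome_flank plain genomic sequence placed on each side of every
#'   locus in the synthetic genome.
#' @param seed integer seed; a fixed seed makes all outputs byte-identical.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_mirnas = 50,
                       seq_length_range = c(20L, 23L),
                       u_content_range = c(0.2, 0.35),
                       expression_law = list(dist = "lognormal",
                                             meanlog = 0, sdlog = 1.5),
                       reads_per_sample = 50000L,
                       conditions = data.frame(
                         condition = CONDITIONS,
                         n_replicates = 4L),
                       p_inc = 0.02,
                       new_fraction_law = list(dist = "beta",
                                               shape1 = 2, shape2 = 8),
                       suppression_law = list(dist = "uniform",
                                              min = 0.2, max = 1),
                       n_unsuppressed = 2L,
                       seq_error = 0.001,
                       snp_spec = NULL,
                       n_snps = 2L,
                       adapter_seq = "TGGAATTCTCGGGTGCCAAGG",
                       n_random_flank = 4L,
                       read_length = 75L,
                       n_dup_same_context = 2L,
                       n_dup_mixed_context = 2L,
                       n_uncurated = 3L,
                       genome_flank = 30L,
                       seed = 1L) {
  cfg <- list(n_mirnas = as.integer(n_mirnas),
              seq_length_range = as.integer(seq_length_range),
              u_content_range = u_content_range,
              expression_law = expression_law,
              reads_per_sample = as.integer(reads_per_sample),
              conditions = conditions,
              p_inc = p_inc,
              new_fraction_law = new_fraction_law,
              suppression_law = suppression_law,
              n_unsuppressed = as.integer(n_unsuppressed),
              seq_error = seq_error,
              snp_spec = snp_spec,
              n_snps = as.integer(n_snps),
              adapter_seq = toupper(adapter_seq),
              n_random_flank = as.integer(n_random_flank),
              read_length = as.integer(read_length),
              n_dup_same_context = as.integer(n_dup_same_context),
              n_dup_mixed_context = as.integer(n_dup_mixed_context),
              n_uncurated = as.integer(n_uncurated),
              genome_flank = as.integer(genome_flank),
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  bad <- function(field, why)
    stop("invalid sim_config field '", field, "': ", why, call. = FALSE)
  if (is.na(cfg$n_mirnas) || cfg$n_mirnas < 0)
    bad("n_mirnas", "must be a non-negative integer")
  if (length(cfg$seq_length_range) != 2 ||
      any(cfg$seq_length_range < 1) || diff(cfg$seq_length_range) < 0)
    bad("seq_length_range", "must be an increasing positive pair")
  if (any(cfg$u_content_range < 0) || any(cfg$u_content_range > 1))
    bad("u_content_range", "fractions must lie in [0, 1]")
  if (cfg$reads_per_sample <= 0)
    bad("reads_per_sample", "must be > 0")
  if (!all(c("condition", "n_replicates") %in% names(cfg$conditions)))
    bad("conditions", "needs columns 'condition' and 'n_replicates'")
  if (!all(cfg$conditions$condition %in% CONDITIONS))
    bad("conditions", paste("labels must be among:",
                            paste(CONDITIONS, collapse = ", ")))
  for (p in c("p_inc", "seq_error"))
    if (cfg[[p]] < 0 || cfg[[p]] > 1) bad(p, "probability must be in [0, 1]")
  if (cfg$suppression_law$dist == "uniform" &&
      (cfg$suppression_law$min < 0 || cfg$suppression_law$max > 1))
    bad("suppression_law", "suppression factors must lie in [0, 1]")
  if (!is.null(cfg$snp_spec)) {
    need <- c("mirna_id", "position", "alt", "freq")
    if (!all(need %in% names(cfg$snp_spec)))
      bad("snp_spec", paste("needs columns", paste(need, collapse = ", ")))
    if (!all(cfg$snp_spec$freq >= 0 & cfg$snp_spec$freq <= 1))
      bad("snp_spec", "allele frequencies must lie in [0, 1]")
  }
  if (!grepl("^[ACGT]+$", cfg$adapter_seq))
    bad("adapter_seq", "must be a non-empty ACGT string")
  if (cfg$n_random_flank < 0) bad("n_random_flank", "must be >= 0")
  if (cfg$read_length < 1) bad("read_length", "must be >= 1")
  if (is.na(cfg$seed)) bad("seed", "must be an integer")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_mirnas, "miRNAs,",
      x$reads_per_sample, "reads/sample\n")
  cat("  conditions:",
      paste(sprintf("%s x%d", x$conditions$condition,
                    x$conditions$n_replicates), collapse = ", "), "\n")
  cat(sprintf("  p_inc=%.3g seq_error=%.3g seed=%d\n",
              x$p_inc, x$seq_error, x$seed))
  invisible(x)
}

draw_law <- function(law, n) {
  switch(law$dist,
         lognormal = rlnorm(n, law$meanlog, law$sdlog),
         beta = rbeta(n, law$shape1, law$shape2),
         uniform = runif(n, law$min, law$max),
         constant = rep(law$value, n),
         stop("unknown distribution '", law$dist, "'", call. = FALSE))
}

# stable per-sample seed derived from the study seed
sample_seed <- function(seed, condition, replicate) {
  ci <- match(condition, CONDITIONS)
  as.integer((as.double(seed) + 131071 * ci + 8191 * replicate) %%
               .Machine$integer.max)
}
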