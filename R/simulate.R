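#' Generate a synthetic miRNA reference bundle with ground truth
#'
#' Builds, from a [sim_config()], the full reference a labeling study needs:
#' mature sequences, a synthetic genome carrying every genomic locus (some
#' miRNAs get a second locus, with the same or a different genomic context),
#' a BED table of loci, a per-miRNA annotation table (genomic-location
#' class, host-gene class, Microprocessor cis-motif flags, TSS distance), a
#' curated high-confidence list with a configurable subset withheld, and the
#' simulation truth (expression weights, per-condition new-molecule
#' fractions, suppression factors, SNP alleles).
#'
#' @param config a [sim_config()].
#' @return A list of class `ref_bundle` with elements `mature`
#'   ([Biostrings::DNAStringSet]), `genome` (DNAStringSet), `loci`
#'   ([GenomicRanges::GRanges], BED-style 0-based on export), `annotation`
#'   (data frame), `curated` (character), `truth` (data frame), `snp_spec`
#'   (data frame or NULL) and `config`.
#' @export
generate_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_mirnas

  if (n == 0L) {
    empty <- empty_bundle(config)
    return(empty)
  }

  ids <- sprintf("sim-mir-%03d", seq_len(n))
  lens <- sample(seq(config$seq_length_range[1], config$seq_length_range[2]),
                 n, replace = TRUE)
  ucont <- runif(n, config$u_content_range[1], config$u_content_range[2])
  seqs <- vapply(seq_len(n), function(i) {
    p <- c((1 - ucont[i]) / 3, (1 - ucont[i]) / 3, (1 - ucont[i]) / 3,
           ucont[i])
    paste(sample(BASES, lens[i], replace = TRUE, prob = p), collapse = "")
  }, character(1))

  w <- draw_law(config$expression_law, n)
  w <- w / sum(w)

  location <- sample(c("intronic", "exonic", "other"), n, replace = TRUE,
                     prob = c(0.5, 0.35, 0.15))
  gene <- sample(c("protein_coding", "lncRNA", "other"), n, replace = TRUE,
                 prob = c(0.5, 0.4, 0.1))
  motif_cnnc <- rbinom(n, 1, 0.5)
  motif_ug <- rbinom(n, 1, 0.3)
  motif_ugu <- rbinom(n, 1, 0.4)
  tss <- round(rlnorm(n, meanlog = 9, sdlog = 1.2))

  # second loci: same-context duplicates keep their class, mixed-context
  # duplicates are re-annotated "mixed" and drop out of context groupings
  n_dup <- min(n, config$n_dup_same_context + config$n_dup_mixed_context)
  dup_ids <- sample(ids, n_dup)
  mixed_ids <- utils::head(dup_ids, min(config$n_dup_mixed_context, n_dup))
  location[ids %in% mixed_ids] <- "mixed"

  curated <- sort(setdiff(ids, sample(ids, min(config$n_uncurated, n))))

  snp_spec <- config$snp_spec
  if (is.null(snp_spec) && config$n_snps > 0L) {
    has_t <- which(vapply(seqs, function(s)
      grepl("T", s, fixed = TRUE), logical(1)))
    pick <- sample(has_t, min(config$n_snps, length(has_t)))
    snp_spec <- do.call(rbind, lapply(pick, function(i) {
      tpos <- gregexpr("T", seqs[i], fixed = TRUE)[[1]]
      data.frame(mirna_id = ids[i],
                 position = sample(as.integer(tpos), 1),
                 alt = "C",
                 freq = sample(c(0.5, 1), 1, prob = c(0.7, 0.3)))
    }))
    rownames(snp_spec) <- NULL
  }

  f_dmso <- draw_law(config$new_fraction_law, n)
  supp <- draw_law(config$suppression_law, n)
  if (config$n_unsuppressed > 0L)
    supp[sample(n, min(config$n_unsuppressed, n))] <- 1
  truth <- data.frame(mirna_id = ids,
                      expression_weight = w,
                      new_fraction_control = 0,
                      new_fraction_dmso = f_dmso,
                      new_fraction_plab = f_dmso * supp,
                      p_inc = config$p_inc,
                      suppression = supp,
                      true_ratio = supp,
                      stringsAsFactors = FALSE)

  annotation <- data.frame(mirna_id = ids,
                           location_class = location,
                           gene_class = gene,
                           motif_CNNC = motif_cnnc,
                           motif_basal_UG = motif_ug,
                           motif_apical_UGU = motif_ugu,
                           tss_distance_nt = tss,
                           stringsAsFactors = FALSE)

  # lay every locus on one synthetic chromosome, each with plain flanks;
  # minus-strand loci carry the reverse complement in the genome
  locus_ids <- c(ids, dup_ids)
  locus_seqs <- seqs[match(locus_ids, ids)]
  strands <- sample(c("+", "-"), length(locus_ids), replace = TRUE)
  fl <- config$genome_flank
  segs <- character(length(locus_ids))
  starts <- integer(length(locus_ids))
  pos <- 0L
  for (k in seq_along(locus_ids)) {
    flank5 <- paste(sample(BASES, fl, replace = TRUE), collapse = "")
    flank3 <- paste(sample(BASES, fl, replace = TRUE), collapse = "")
    seg <- paste0(flank5, locus_seqs[k], flank3)
    if (strands[k] == "-") seg <- revcomp(seg)
    segs[k] <- seg
    starts[k] <- pos + fl        # 0-based start of the mature sequence
    pos <- pos + nchar(seg)
  }
  genome <- Biostrings::DNAStringSet(
    stats::setNames(paste(segs, collapse = ""), "chrS1"))
  loci <- GenomicRanges::GRanges(
    seqnames = "chrS1",
    ranges = IRanges::IRanges(start = starts + 1L,
                              width = nchar(locus_seqs)),
    strand = strands,
    name = locus_ids,
    score = 0L)

  mature <- Biostrings::DNAStringSet(stats::setNames(seqs, ids))
  structure(list(mature = mature, genome = genome, loci = loci,
                 annotation = annotation, curated = curated,
                 truth = truth, snp_spec = snp_spec, config = config),
            class = "ref_bundle")
}

empty_bundle <- function(config) {
  structure(list(mature = Biostrings::DNAStringSet(),
                 genome = Biostrings::DNAStringSet(),
                 loci = GenomicRanges::GRanges(),
                 annotation = data.frame(mirna_id = character(),
                                         location_class = character(),
                                         gene_class = character(),
                                         motif_CNNC = integer(),
                                         motif_basal_UG = integer(),
                                         motif_apical_UGU = integer(),
                                         tss_distance_nt = integer()),
                 curated = character(),
                 truth = data.frame(mirna_id = character()),
                 snp_spec = NULL, config = config),
            class = "ref_bundle")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Write a reference bundle to disk
#'
#' Emits `mature.fa`, `genome.fa`, `loci.bed` (BED6, 0-based half-open),
#' `annotation.tsv`, `curated.txt` (one id per line) and `truth.tsv`.
#'
#' @param bundle a [generate_reference()] result.
#' @param dir output directory (created if needed).
#' @return Invisibly, the named vector of file paths.
#' @export
write_reference <- function(bundle, dir) {
  stopifnot(inherits(bundle, "ref_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(mature = file.path(dir, "mature.fa"),
             genome = file.path(dir, "genome.fa"),
             loci = file.path(dir, "loci.bed"),
             annotation = file.path(dir, "annotation.tsv"),
             curated = file.path(dir, "curated.txt"),
             truth = file.path(dir, "truth.tsv"))
  Biostrings::writeXStringSet(bundle$mature, paths["mature"])
  Biostrings::writeXStringSet(bundle$genome, paths["genome"])
  rtracklayer::export(bundle$loci, paths["loci"], format = "BED")
  write.table(bundle$annotation, paths["annotation"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  writeLines(bundle$curated, paths["curated"])
  write.table(bundle$truth, paths["truth"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Simulate one labeled small-RNA library
#'
#' Emits `reads_per_sample` reads for one condition/replicate. Each molecule
#' is drawn by expression weight; SNP alleles are applied first, then the
#' molecule is "new" with the condition's per-miRNA new fraction (0 for the
#' no-4SU control), each reference T of a new molecule converts to C with
#' probability `p_inc`, and per-base sequencing errors are applied last.
#' Reads are `n_random_flank` random nt + insert + `n_random_flank` random
#' nt + 3' adapter, padded to the fixed read length; qualities are constant.
#'
#' @param bundle a [generate_reference()] result.
#' @param condition one of the configured condition labels.
#' @param replicate replicate number (drives the per-sample seed).
#' @param path optional FASTQ output path (gzipped when it ends in `.gz`).
#' @return Invisibly when `path` is given, otherwise a list with `ids`,
#'   `reads`, `mirna_id` (true origin per read) and `is_new`.
#' @export
simulate_library <- function(bundle, condition, replicate = 1L,
                             path = NULL) {
  stopifnot(inherits(bundle, "ref_bundle"))
  config <- bundle$config
  if (!condition %in% config$conditions$condition)
    stop("unknown condition label '", condition, "'", call. = FALSE)
  set.seed(sample_seed(config$seed, condition, replicate))

  truth <- bundle$truth
  n_reads <- config$reads_per_sample
  fcol <- switch(condition,
                 control_no4su = "new_fraction_control",
                 dmso_4su = "new_fraction_dmso",
                 plab_4su = "new_fraction_plab")
  counts <- as.vector(rmultinom(1, n_reads, truth$expression_weight))

  inserts <- character(n_reads)
  origin <- character(n_reads)
  is_new <- logical(n_reads)
  ptr <- 0L
  for (i in seq_len(config$n_mirnas)) {
    cnt <- counts[i]
    if (cnt == 0L) next
    s <- as.character(bundle$mature[[i]])
    len <- nchar(s)
    m <- matrix(strsplit(s, "")[[1]], nrow = len, ncol = cnt)
    snps <- bundle$snp_spec
    if (!is.null(snps)) {
      for (r in which(snps$mirna_id == truth$mirna_id[i])) {
        sel <- runif(cnt) < snps$freq[r]
        m[snps$position[r], sel] <- snps$alt[r]
      }
    }
    new <- runif(cnt) < truth[[fcol]][i]
    if (any(new) && config$p_inc > 0) {
      conv <- m == "T" &
        matrix(new, nrow = len, ncol = cnt, byrow = TRUE) &
        matrix(runif(len * cnt) < config$p_inc, nrow = len)
      m[conv] <- "C"
    }
    if (config$seq_error > 0) {
      err <- matrix(runif(len * cnt) < config$seq_error, nrow = len)
      if (any(err)) {
        cur <- m[err]
        alt_tab <- rbind(A = c("C", "G", "T"), C = c("A", "G", "T"),
                         G = c("A", "C", "T"), T = c("A", "C", "G"))
        m[err] <- alt_tab[cbind(match(cur, BASES),
                                sample.int(3, length(cur), replace = TRUE))]
      }
    }
    idx <- ptr + seq_len(cnt)
    inserts[idx] <- do.call(paste0, lapply(seq_len(len), function(r) m[r, ]))
    origin[idx] <- truth$mirna_id[i]
    is_new[idx] <- new
    ptr <- ptr + cnt
  }

  nf <- config$n_random_flank
  rand_flank <- function()
    do.call(paste0, lapply(seq_len(nf), function(r)
      sample(BASES, n_reads, replace = TRUE)))
  f5 <- if (nf > 0) rand_flank() else ""
  f3 <- if (nf > 0) rand_flank() else ""
  full <- paste0(f5, inserts, f3, config$adapter_seq,
                 strrep("A", config$read_length))
  reads <- substr(full, 1L, config$read_length)
  ids <- sprintf("sim_%s_rep%d_%06d|%s", condition, replicate,
                 seq_len(n_reads), origin)

  if (!is.null(path)) {
    qual <- strrep("I", config$read_length)
    con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
    on.exit(close(con))
    writeLines(as.vector(rbind(paste0("@", ids), reads, "+", qual)), con)
    return(invisible(path))
  }
  list(ids = ids, reads = reads, mirna_id = origin, is_new = is_new)
}

#' Simulate a complete labeling study
#'
#' Generates the reference bundle and one library per configured
#' condition/replicate.
#'
#' @param config a [sim_config()].
#' @param dir optional directory; when given, reference files and per-sample
#'   FASTQs are written there and paths are returned instead of reads.
#' @param gzip write gzipped FASTQ when `dir` is used.
#' @return A list with `bundle`, `samples` (data frame: sample, condition,
#'   replicate, and `path` when written) and, without `dir`, `libraries`
#'   (named list of [simulate_library()] results).
#' @export
simulate_study <- function(config, dir = NULL, gzip = FALSE) {
  bundle <- generate_reference(config)
  cond <- config$conditions
  samples <- do.call(rbind, lapply(seq_len(nrow(cond)), function(i)
    data.frame(condition = cond$condition[i],
               replicate = seq_len(cond$n_replicates[i]))))
  samples$sample <- sprintf("%s_rep%d", samples$condition, samples$replicate)
  samples <- samples[, c("sample", "condition", "replicate")]

  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_reference(bundle, file.path(dir, "reference"))
    ext <- if (gzip) ".fastq.gz" else ".fastq"
    samples$path <- file.path(dir, paste0(samples$sample, ext))
    for (i in seq_len(nrow(samples)))
      simulate_library(bundle, samples$condition[i], samples$replicate[i],
                       path = samples$path[i])
    return(list(bundle = bundle, samples = samples))
  }
  libraries <- lapply(seq_len(nrow(samples)), function(i)
    simulate_library(bundle, samples$condition[i], samples$replicate[i]))
  names(libraries) <- samples$sample
  list(bundle = bundle, samples = samples, libraries = libraries)
}

#' Expected per-miRNA T>C conversion rate under the labeling model
#'
#' Analytic oracle for the simulator: at a reference-T position the read
#' shows C with probability
#' `f * p_inc * (1 - e) + (1 - f * p_inc) * e / 3`,
#' where `f` is the condition's new-molecule fraction and `e` the per-base
#' sequencing error rate (errors pick one of three alternatives uniformly;
#' an error on a converted base moves it off C, hence the `(1 - e)` factor).
#'
#' @param truth the `truth` data frame of a [generate_reference()] bundle.
#' @param condition condition label.
#' @param seq_error per-base sequencing error probability.
#' @return Named numeric vector of expected conversion rates.
#' @export
expected_conversion_rate <- function(truth, condition, seq_error = 0) {
  fcol <- switch(condition,
                 control_no4su = "new_fraction_control",
                 dmso_4su = "new_fraction_dmso",
                 plab_4su = "new_fraction_plab",
                 stop("unknown condition label '", condition, "'",
                      call. = FALSE))
  f <- truth[[fcol]]
  p <- truth$p_inc
  e <- seq_error
  stats::setNames(f * p * (1 - e) + (1 - f * p) * e / 3, truth$mirna_id)
}

#' Sample conversion profiles directly from the labeling model
#'
#' Fast profile-level counterpart of read-level simulation: per sample, read
#' counts are multinomial in the expression weights, reference-T coverage is
#' read count times the miRNA's T content, and conversion counts are
#' binomial at the analytic expected rate. SNPs and the trimming/alignment
#' stages are bypassed (they are identity in expectation); useful for
#' calibration studies needing many replicate studies.
#'
#' @param bundle a [generate_reference()] result.
#' @param seed seed for this draw (defaults to the bundle seed).
#' @return A profiles data frame as produced by [count_conversions()], with
#'   a `samples` attribute.
#' @export
simulate_profiles <- function(bundle, seed = bundle$config$seed) {
  stopifnot(inherits(bundle, "ref_bundle"))
  config <- bundle$config
  set.seed(as.integer(seed %% .Machine$integer.max))
  truth <- bundle$truth
  n_t <- vapply(as.character(bundle$mature), function(s)
    sum(strsplit(s, "")[[1]] == "T"), integer(1))

  cond <- config$conditions
  samples <- do.call(rbind, lapply(seq_len(nrow(cond)), function(i)
    data.frame(condition = cond$condition[i],
               replicate = seq_len(cond$n_replicates[i]))))
  samples$sample <- sprintf("%s_rep%d", samples$condition, samples$replicate)

  rows <- lapply(seq_len(nrow(samples)), function(i) {
    rate <- expected_conversion_rate(truth, samples$condition[i],
                                     config$seq_error)
    rc <- as.vector(rmultinom(1, config$reads_per_sample,
                              truth$expression_weight))
    tcov <- rc * n_t
    tc <- rbinom(length(tcov), tcov, rate)
    data.frame(unit = truth$mirna_id,
               sample = samples$sample[i],
               condition = samples$condition[i],
               replicate = samples$replicate[i],
               read_count = rc,
               cpm = rc / sum(rc) * 1e6,
               t_coverage = tcov,
               tc_count = tc,
               conversion_rate = ifelse(tcov > 0, tc / tcov, 0),
               stringsAsFactors = FALSE)
  })
  profiles <- do.call(rbind, rows)
  attr(profiles, "samples") <- samples[, c("sample", "condition",
                                           "replicate")]
  attr(profiles, "unit_members") <-
    stats::setNames(as.list(truth$mirna_id), truth$mirna_id)
  profiles
}
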