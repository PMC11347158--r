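# Independent brute-force oracles and fixture builders. These deliberately
# re-derive the scoring and counting rules with plain loops, sharing no code
# with the package internals.

# Per-read, per-template, per-offset, per-base enumeration of the
# conversion-aware assignment rule.
oracle_align_one <- function(insert, templates, nm_max, integrity_min,
                             conv_in_integrity = TRUE) {
  ib <- strsplit(insert, "")[[1]]
  il <- length(ib)
  best <- list(score = -1, unit = NA_integer_, offset = NA_integer_,
               conv = NA_integer_, mm = NA_integer_, tie = FALSE)
  for (u in seq_along(templates)) {
    tb <- strsplit(templates[u], "")[[1]]
    tl <- length(tb)
    if (il > tl) next
    ubest <- -1; uoff <- NA; uconv <- NA; umm <- NA
    for (o in 0:(tl - il)) {
      m <- 0L; cv <- 0L
      for (b in seq_len(il)) {
        t <- tb[o + b]; r <- ib[b]
        if (r == t) m <- m + 1L
        else if (t == "T" && r == "C") { m <- m + 1L; cv <- cv + 1L }
      }
      if (m > ubest) { ubest <- m; uoff <- o; uconv <- cv; umm <- il - m }
    }
    if (ubest > best$score) {
      best <- list(score = ubest, unit = u, offset = uoff, conv = uconv,
                   mm = umm, tie = FALSE)
    } else if (ubest == best$score) best$tie <- TRUE
  }
  if (is.na(best$unit) || best$tie) return(NULL)
  integ <- if (conv_in_integrity) (best$score - best$conv) / il
           else best$score / il
  if (best$mm > nm_max || integ < integrity_min) return(NULL)
  best
}

# Oracle totals for a whole instance: per-template read_count, t_coverage,
# tc_count over all reference-T positions (no mask).
oracle_quantify <- function(inserts, templates, nm_max, integrity_min,
                            conv_in_integrity = TRUE) {
  nu <- length(templates)
  rc <- integer(nu); tcov <- integer(nu); tc <- integer(nu)
  assign <- rep(NA_integer_, length(inserts))
  for (i in seq_along(inserts)) {
    hit <- oracle_align_one(inserts[i], templates, nm_max, integrity_min,
                            conv_in_integrity)
    if (is.null(hit)) next
    u <- hit$unit
    assign[i] <- u
    rc[u] <- rc[u] + 1L
    tb <- strsplit(templates[u], "")[[1]]
    ib <- strsplit(inserts[i], "")[[1]]
    for (b in seq_along(ib)) {
      p <- hit$offset + b
      if (tb[p] == "T") {
        tcov[u] <- tcov[u] + 1L
        if (ib[b] == "C") tc[u] <- tc[u] + 1L
      }
    }
  }
  list(assign = assign, read_count = rc, t_coverage = tcov, tc_count = tc)
}

rand_dna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
}

# Minimal feature index over plain templates (no genome, no flank).
index_from_seqs <- function(seqs, ids = sprintf("t%02d", seq_along(seqs))) {
  mature <- Biostrings::DNAStringSet(stats::setNames(seqs, ids))
  if (length(seqs) == 0L)
    return(build_index(mature, GenomicRanges::GRanges(), genome = NULL,
                       flank = 0L))
  loci <- GenomicRanges::GRanges(
    seqnames = "chr1",
    ranges = IRanges::IRanges(start = seq_along(seqs) * 100L,
                              width = nchar(seqs)),
    strand = "+", name = ids, score = 0L)
  build_index(mature, loci, genome = NULL, flank = 0L)
}

# Hand-built profiles table: one row per unit x sample.
make_profiles <- function(units, samples, read_count, cpm, t_coverage,
                          tc_count) {
  grid <- expand.grid(unit = units, sample = samples$sample,
                      stringsAsFactors = FALSE)
  grid <- grid[order(match(grid$sample, samples$sample),
                     match(grid$unit, units)), ]
  p <- data.frame(grid,
                  condition = samples$condition[match(grid$sample,
                                                      samples$sample)],
                  replicate = samples$replicate[match(grid$sample,
                                                      samples$sample)],
                  read_count = read_count, cpm = cpm,
                  t_coverage = t_coverage, tc_count = tc_count,
                  stringsAsFactors = FALSE)
  p$conversion_rate <- ifelse(p$t_coverage > 0,
                              p$tc_count / p$t_coverage, 0)
  rownames(p) <- NULL
  attr(p, "samples") <- samples
  attr(p, "unit_members") <- stats::setNames(as.list(units), units)
  p
}

study_samples <- function(n_rep = 2L) {
  data.frame(
    sample = c(sprintf("control_no4su_rep%d", seq_len(n_rep)),
               sprintf("dmso_4su_rep%d", seq_len(n_rep)),
               sprintf("plab_4su_rep%d", seq_len(n_rep))),
    condition = rep(c("control_no4su", "dmso_4su", "plab_4su"),
                    each = n_rep),
    replicate = rep(seq_len(n_rep), 3L),
    stringsAsFactors = FALSE)
}
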