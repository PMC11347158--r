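#' Alignment parameters for conversion-aware read assignment
#'
#' @param nm_max maximum non-conversion mismatches per read.
#' @param integrity_min minimum mapping integrity (matching fraction of the
#'   insert). With `conv_in_integrity = TRUE` (default) T>C conversions are
#'   counted as mismatches here — for a ~22 nt read a single non-conversion
#'   mismatch already fails 0.95, so this filter dominates the `nm_max`
#'   filter on short reads.
#' @param conv_in_integrity whether conversions count against integrity.
#' @param allow_shift maximum 5'/3' offset (nt) of the insert relative to
#'   the mature sequence within the extended template; `NULL` allows any
#'   placement inside the template.
#' @return An object of class `align_params`.
#' @export
align_params <- function(nm_max = 3L, integrity_min = 0.95,
                         conv_in_integrity = TRUE, allow_shift = NULL) {
  if (integrity_min < 0 || integrity_min > 1)
    stop("integrity_min must be in [0, 1]", call. = FALSE)
  structure(list(nm_max = as.integer(nm_max),
                 integrity_min = integrity_min,
                 conv_in_integrity = isTRUE(conv_in_integrity),
                 allow_shift = allow_shift),
            class = "align_params")
}

#' Build a feature index of mature miRNA counting units
#'
#' Collapses identical mature sequences into a single counting unit (so
#' miRNAs mapping to more than one genomic location, or distinct names with
#' the same sequence, are retained but counted once) and extracts an
#' extended template per unit — the mature sequence plus a small genomic
#' flank from one of its loci — so templated end variants still align.
#'
#' @param mature mature-sequence FASTA path or [Biostrings::DNAStringSet].
#' @param loci BED6 path or [GenomicRanges::GRanges] with a `name` column
#'   matching the FASTA ids.
#' @param genome optional genome FASTA path or DNAStringSet; without it
#'   templates carry no flank.
#' @param flank flanking nt to include on each side of the mature sequence.
#' @return An object of class `feature_index`: `units` data frame (`unit`,
#'   `members`, `sequence`, `template`, `mature_offset` — 0-based start of
#'   the mature sequence within the template).
#' @export
build_index <- function(mature, loci, genome = NULL, flank = 3L) {
  if (is.character(mature))
    mature <- Biostrings::readDNAStringSet(mature)
  if (is.character(loci))
    loci <- rtracklayer::import(loci, format = "BED")
  if (is.character(genome))
    genome <- Biostrings::readDNAStringSet(genome)
  flank <- as.integer(flank)

  ids <- names(mature)
  locus_names <- if (length(loci)) loci$name else character()
  orphan_fa <- setdiff(ids, locus_names)
  orphan_bed <- setdiff(locus_names, ids)
  if (length(orphan_fa) || length(orphan_bed))
    stop("FASTA/BED id mismatch; orphans: ",
         paste(c(orphan_fa, orphan_bed), collapse = ", "), call. = FALSE)

  if (length(mature) == 0L) {
    return(structure(list(units = data.frame(unit = character(),
                                             members = character(),
                                             sequence = character(),
                                             template = character(),
                                             mature_offset = integer()),
                          flank = flank),
                     class = "feature_index"))
  }

  seqs <- as.character(mature)
  groups <- split(ids, seqs)
  units <- data.frame(
    unit = vapply(groups, function(g) paste(sort(g), collapse = "|"),
                  character(1)),
    members = vapply(groups, function(g) paste(sort(g), collapse = ","),
                     character(1)),
    sequence = names(groups),
    stringsAsFactors = FALSE)
  rownames(units) <- NULL
  units <- units[order(units$unit), , drop = FALSE]

  tmpl <- character(nrow(units))
  moff <- integer(nrow(units))
  for (k in seq_len(nrow(units))) {
    member1 <- sort(strsplit(units$members[k], ",")[[1]])[1]
    if (is.null(genome) || flank == 0L) {
      tmpl[k] <- units$sequence[k]
      moff[k] <- 0L
      next
    }
    hit <- which(loci$name == member1)[1]
    chr <- as.character(GenomicRanges::seqnames(loci))[hit]
    st <- GenomicRanges::start(loci)[hit]
    en <- GenomicRanges::end(loci)[hit]
    strand <- as.character(GenomicRanges::strand(loci))[hit]
    chrlen <- Biostrings::width(genome)[match(chr, names(genome))]
    left <- if (strand == "-") min(flank, chrlen - en) else min(flank, st - 1L)
    right <- if (strand == "-") min(flank, st - 1L) else min(flank, chrlen - en)
    lo <- st - (if (strand == "-") right else left)
    hi <- en + (if (strand == "-") left else right)
    seg <- as.character(Biostrings::subseq(genome[[chr]], lo, hi))
    if (strand == "-") seg <- revcomp(seg)
    tmpl[k] <- seg
    moff[k] <- left
  }
  units$template <- tmpl
  units$mature_offset <- moff
  structure(list(units = units, flank = flank), class = "feature_index")
}

cpp_offset_bounds <- function(index, params) {
  u <- index$units
  tlen <- nchar(u$template)
  if (is.null(params$allow_shift))
    return(list(o_min = rep(0L, nrow(u)), end_max = tlen))
  s <- as.integer(params$allow_shift)
  list(o_min = pmax(0L, u$mature_offset - s),
       end_max = pmin(tlen, u$mature_offset + nchar(u$sequence) + s))
}

#' Assign inserts to counting units with conversion-aware scoring
#'
#' Every insert is compared ungapped against every unit template at every
#' allowed offset. The score is the number of matching bases, where a
#' template T read as C counts as a match but is recorded as a conversion.
#' The highest-scoring unit wins; a score tie between different units
#' leaves the read unassigned. An assigned read is kept only if its
#' non-conversion mismatches are at most `nm_max` and its mapping integrity
#' passes `integrity_min`.
#'
#' @param inserts character vector of trimmed insert sequences.
#' @param index a [build_index()] result.
#' @param params an [align_params()].
#' @return Data frame per insert: `unit` (NA when unassigned or filtered),
#'   `offset` (0-based within the template), `n_conv`, `n_mm`.
#' @export
align_read <- function(inserts, index, params = align_params()) {
  stopifnot(inherits(index, "feature_index"))
  b <- cpp_offset_bounds(index, params)
  res <- .align_count_cpp(inserts, index$units$template,
                          rep(1L, length(inserts)),
                          params$nm_max, params$integrity_min,
                          params$conv_in_integrity, b$o_min, b$end_max)
  sel <- res$unit > 0L
  unit <- rep(NA_character_, length(inserts))
  unit[sel] <- index$units$unit[res$unit[sel]]
  out <- data.frame(unit = unit, offset = res$offset, n_conv = res$n_conv,
                    n_mm = res$n_mm, stringsAsFactors = FALSE)
  out$offset[!sel] <- NA_integer_
  out$n_conv[!sel] <- NA_integer_
  out$n_mm[!sel] <- NA_integer_
  out
}

#' Quantify one trimmed library against a feature index
#'
#' Deduplicates inserts, assigns them with [align_read()] scoring, and
#' accumulates per-unit read counts plus per-template-position coverage and
#' C counts (the position-level data that SNP masking and conversion
#' counting consume).
#'
#' @param trimmed a [trim_reads()] result or character vector of inserts.
#' @param index a [build_index()] result.
#' @param params an [align_params()].
#' @return An object of class `quant_sample`: `read_count` (named per
#'   unit), `cov` and `ccnt` (per-unit integer vectors over template
#'   positions), `n_assigned`, `n_input`.
#' @export
quantify_sample <- function(trimmed, index, params = align_params()) {
  stopifnot(inherits(index, "feature_index"))
  inserts <- if (inherits(trimmed, "trimmed_library")) trimmed$insert_seq
             else as.character(trimmed)
  uq <- unique(inserts)
  wt <- tabulate(match(inserts, uq), nbins = length(uq))
  b <- cpp_offset_bounds(index, params)
  res <- .align_count_cpp(uq, index$units$template, as.integer(wt),
                          params$nm_max, params$integrity_min,
                          params$conv_in_integrity, b$o_min, b$end_max)
  nu <- nrow(index$units)
  rc <- integer(nu)
  assigned <- res$unit > 0L
  if (any(assigned)) {
    agg <- tapply(wt[assigned], res$unit[assigned], sum)
    rc[as.integer(names(agg))] <- as.integer(agg)
  }
  structure(list(read_count = stats::setNames(rc, index$units$unit),
                 cov = stats::setNames(res$cov, index$units$unit),
                 ccnt = stats::setNames(res$ccnt, index$units$unit),
                 n_assigned = sum(rc), n_input = length(inserts)),
            class = "quant_sample")
}

#' Call a SNP mask from no-4SU control samples
#'
#' Pools position-level counts over the supplied control samples and masks
#' every reference-T template position whose C fraction reaches
#' `min_alt_fraction` at coverage of at least `min_coverage`. The 0.4
#' default catches heterozygous T/C loci (allele frequency 0.5) without
#' masking genuine labeling, which stays far below it. Only no-4SU samples
#' should be supplied so that labeling signal can never be masked.
#'
#' @param quants list of [quantify_sample()] results (control samples).
#' @param index the shared [build_index()].
#' @param min_alt_fraction minimum C fraction to mask.
#' @param min_coverage minimum pooled coverage to consider a position.
#' @return An object of class `snp_mask`: data frame `unit`, `position`
#'   (1-based template position), `coverage`, `c_fraction`.
#' @export
call_snp_mask <- function(quants, index, min_alt_fraction = 0.4,
                          min_coverage = 10L) {
  stopifnot(length(quants) >= 1L, inherits(index, "feature_index"))
  units <- index$units
  rows <- list()
  for (k in seq_len(nrow(units))) {
    tmpl <- strsplit(units$template[k], "")[[1]]
    cov <- Reduce(`+`, lapply(quants, function(q) q$cov[[k]]))
    cc <- Reduce(`+`, lapply(quants, function(q) q$ccnt[[k]]))
    tpos <- which(tmpl == "T")
    hit <- tpos[cov[tpos] >= min_coverage &
                  cc[tpos] / pmax(cov[tpos], 1L) >= min_alt_fraction]
    if (length(hit))
      rows[[length(rows) + 1L]] <-
        data.frame(unit = units$unit[k], position = hit,
                   coverage = cov[hit],
                   c_fraction = cc[hit] / cov[hit],
                   stringsAsFactors = FALSE)
  }
  mask <- if (length(rows)) do.call(rbind, rows)
          else data.frame(unit = character(), position = integer(),
                          coverage = integer(), c_fraction = numeric())
  structure(mask, class = c("snp_mask", "data.frame"),
            min_alt_fraction = min_alt_fraction,
            min_coverage = as.integer(min_coverage))
}

#' Conversion profile of one sample
#'
#' Computes, per counting unit: assigned read count, CPM (reads per million
#' assigned), reference-T coverage and T>C count over unmasked template-T
#' positions, and the conversion rate `tc_count / t_coverage` (0 when
#' coverage is 0). Masked positions are excluded from both numerator and
#' denominator.
#'
#' @param quant a [quantify_sample()] result.
#' @param index the shared [build_index()].
#' @param mask optional [call_snp_mask()] result.
#' @param sample,condition,replicate sample metadata copied into the rows.
#' @return Data frame: unit, sample, condition, replicate, read_count,
#'   cpm, t_coverage, tc_count, conversion_rate.
#' @export
count_conversions <- function(quant, index, mask = NULL,
                              sample = NA_character_,
                              condition = NA_character_,
                              replicate = NA_integer_) {
  stopifnot(inherits(quant, "quant_sample"), inherits(index, "feature_index"))
  units <- index$units
  total <- quant$n_assigned
  tcov <- integer(nrow(units))
  tc <- integer(nrow(units))
  for (k in seq_len(nrow(units))) {
    tmpl <- strsplit(units$template[k], "")[[1]]
    tpos <- which(tmpl == "T")
    if (!is.null(mask) && nrow(mask)) {
      drop <- mask$position[mask$unit == units$unit[k]]
      tpos <- setdiff(tpos, drop)
    }
    tcov[k] <- sum(quant$cov[[k]][tpos])
    tc[k] <- sum(quant$ccnt[[k]][tpos])
  }
  data.frame(unit = units$unit,
             sample = sample, condition = condition, replicate = replicate,
             read_count = as.integer(quant$read_count),
             cpm = if (total > 0) quant$read_count / total * 1e6 else 0,
             t_coverage = tcov,
             tc_count = tc,
             conversion_rate = ifelse(tcov > 0, tc / tcov, 0),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Quantify a whole study: trim, assign, mask SNPs, profile
#'
#' Convenience driver over [trim_reads()], [quantify_sample()],
#' [call_snp_mask()] (on the no-4SU control samples) and
#' [count_conversions()] for every sample.
#'
#' @param libraries named list of libraries (reads or [trim_reads()]
#'   results or FASTQ paths), in the order of `samples`.
#' @param samples data frame with `sample`, `condition`, `replicate`.
#' @param index a [build_index()] result.
#' @param trim a [trim_params()]; set `NULL` if `libraries` are already
#'   trimmed.
#' @param align an [align_params()].
#' @param snp_min_alt_fraction,snp_min_coverage passed to [call_snp_mask()].
#' @return A profiles data frame (one row per unit x sample) with
#'   attributes `samples`, `unit_members` and `snp_mask`.
#' @export
quantify_study <- function(libraries, samples, index,
                           trim = trim_params(), align = align_params(),
                           snp_min_alt_fraction = 0.4,
                           snp_min_coverage = 10L) {
  stopifnot(nrow(samples) == length(libraries))
  quants <- vector("list", nrow(samples))
  for (i in seq_len(nrow(samples))) {
    lib <- libraries[[i]]
    trimmed <- if (inherits(lib, "trimmed_library") || is.null(trim)) lib
               else trim_reads(lib, trim)
    quants[[i]] <- quantify_sample(trimmed, index, align)
  }
  ctrl <- which(samples$condition == "control_no4su")
  mask <- if (length(ctrl))
    call_snp_mask(quants[ctrl], index, snp_min_alt_fraction,
                  snp_min_coverage)
  else NULL
  profiles <- do.call(rbind, lapply(seq_len(nrow(samples)), function(i)
    count_conversions(quants[[i]], index, mask,
                      sample = samples$sample[i],
                      condition = samples$condition[i],
                      replicate = samples$replicate[i])))
  attr(profiles, "samples") <- samples[, c("sample", "condition",
                                           "replicate")]
  attr(profiles, "unit_members") <-
    stats::setNames(strsplit(index$units$members, ","), index$units$unit)
  attr(profiles, "snp_mask") <- mask
  profiles
}
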