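#' Trimming parameters for randomized-adapter small-RNA libraries
#'
#' Encodes the read clean-up used for NEXTflex-style libraries: 3' adapter
#' removal, an extra 4 nt clipped from the 3' end (the randomized bases),
#' a maximum-length filter of 30 nt applied after the 3' clip, then 4 nt
#' clipped from the 5' end, and a minimum insert length applied last.
#'
#' @param adapter_seq 3' adapter sequence.
#' @param min_overlap minimum adapter prefix length that must match.
#' @param adapter_mismatch_rate maximum mismatch fraction in the matched
#'   adapter prefix.
#' @param clip3,clip5 randomized bases clipped from the 3' / 5' ends.
#' @param max_length maximum length after adapter removal and the 3' clip.
#' @param min_length minimum insert length after all clipping; the
#'   shortest annotated mature miRNAs motivate the default of 16.
#' @param keep_no_adapter keep reads in which no adapter is found
#'   (default discards them: a genuine short insert must read through into
#'   adapter).
#' @return An object of class `trim_params`.
#' @export
trim_params <- function(adapter_seq = "TGGAATTCTCGGGTGCCAAGG",
                        min_overlap = 3L,
                        adapter_mismatch_rate = 0.1,
                        clip3 = 4L, clip5 = 4L,
                        max_length = 30L, min_length = 16L,
                        keep_no_adapter = FALSE) {
  p <- list(adapter_seq = toupper(adapter_seq),
            min_overlap = as.integer(min_overlap),
            adapter_mismatch_rate = adapter_mismatch_rate,
            clip3 = as.integer(clip3), clip5 = as.integer(clip5),
            max_length = as.integer(max_length),
            min_length = as.integer(min_length),
            keep_no_adapter = isTRUE(keep_no_adapter))
  if (p$clip3 < 0 || p$clip5 < 0)
    stop("clip3 and clip5 must be >= 0", call. = FALSE)
  if (p$adapter_mismatch_rate < 0 || p$adapter_mismatch_rate > 1)
    stop("adapter_mismatch_rate must be in [0, 1]", call. = FALSE)
  if (p$max_length <= p$clip5 + p$min_length)
    warning("max_length <= clip5 + min_length leaves a narrow keep window")
  structure(p, class = "trim_params")
}

DISCARD_REASONS <- c("none", "no_adapter_policy", "too_long", "too_short")

#' Remove the 3' adapter from reads
#'
#' Finds, per read, the longest read suffix matching a prefix of the
#' adapter (at least `min_overlap` bases, at most
#' `floor(adapter_mismatch_rate * overlap)` mismatches) and removes it.
#' Reads without a detectable adapter pass through unchanged and are
#' flagged.
#'
#' @param reads character vector of read sequences.
#' @param params a [trim_params()].
#' @return A data frame with `seq` (adapter-trimmed) and `adapter_found`.
#' @export
remove_adapter <- function(reads, params = trim_params()) {
  stopifnot(inherits(params, "trim_params"))
  cut <- .find_adapter_cpp(toupper(reads), params$adapter_seq,
                           params$min_overlap,
                           params$adapter_mismatch_rate)
  found <- cut >= 0L
  out <- ifelse(found, substr(reads, 1L, pmax(cut, 0L)), reads)
  data.frame(seq = out, adapter_found = found, stringsAsFactors = FALSE)
}

#' Clip randomized bases and apply length filters
#'
#' Applies, in order: clip `clip3` bases from the 3' end; discard if the
#' remainder exceeds `max_length`; clip `clip5` bases from the 5' end;
#' discard if the remainder is shorter than `min_length`. This matches the
#' stated tool order (the 3' clip happens during adapter removal, the 5'
#' clip at mapping).
#'
#' @param seqs character vector of adapter-trimmed sequences.
#' @param params a [trim_params()].
#' @param adapter_found logical vector; reads without adapter are discarded
#'   unless `params$keep_no_adapter`.
#' @return A data frame with `insert_seq` (NA for discarded reads) and
#'   `discard_reason` (factor: none, no_adapter_policy, too_long,
#'   too_short).
#' @export
clip_and_filter <- function(seqs, params = trim_params(),
                            adapter_found = TRUE) {
  stopifnot(inherits(params, "trim_params"))
  n <- length(seqs)
  adapter_found <- rep_len(adapter_found, n)
  reason <- rep("none", n)
  len <- nchar(seqs)

  s3 <- substr(seqs, 1L, pmax(len - params$clip3, 0L))
  len3 <- nchar(s3)
  too_long <- len3 > params$max_length
  ins <- substr(s3, params$clip5 + 1L, len3)
  too_short <- nchar(ins) < params$min_length

  reason[too_short] <- "too_short"
  reason[too_long] <- "too_long"     # length check precedes the 5' clip
  if (!params$keep_no_adapter) reason[!adapter_found] <- "no_adapter_policy"
  keep <- reason == "none"
  data.frame(insert_seq = ifelse(keep, ins, NA_character_),
             discard_reason = factor(reason, levels = DISCARD_REASONS),
             stringsAsFactors = FALSE)
}

#' Trim a library from raw reads to insert sequences
#'
#' Runs [remove_adapter()] then [clip_and_filter()] on a FASTQ file or an
#' in-memory library and tallies discard reasons.
#'
#' @param input FASTQ path (gzip supported), a [simulate_library()] result,
#'   or a character vector of reads.
#' @param params a [trim_params()].
#' @param output optional FASTQ path for kept inserts.
#' @param report optional TSV path for the per-reason count table.
#' @return A list of class `trimmed_library`: `ids`, `insert_seq` (kept
#'   inserts only), `discard_reason` (per input read) and `report`
#'   (data frame of counts by reason, including `kept`).
#' @export
trim_reads <- function(input, params = trim_params(), output = NULL,
                       report = NULL) {
  if (is.character(input) && length(input) == 1L && file.exists(input)) {
    fq <- Biostrings::readDNAStringSet(input, format = "fastq")
    reads <- as.character(fq)
    ids <- sub("\\s.*$", "", names(fq))
  } else if (is.list(input)) {
    reads <- input$reads
    ids <- input$ids
  } else {
    reads <- as.character(input)
    ids <- sprintf("read_%d", seq_along(reads))
  }

  ad <- remove_adapter(reads, params)
  cf <- clip_and_filter(ad$seq, params, adapter_found = ad$adapter_found)
  keep <- cf$discard_reason == "none"

  tab <- table(cf$discard_reason)
  rep_df <- data.frame(reason = c("kept", DISCARD_REASONS[-1]),
                       count = c(sum(keep),
                                 as.integer(tab[DISCARD_REASONS[-1]])),
                       stringsAsFactors = FALSE)
  rep_df$count[is.na(rep_df$count)] <- 0L

  if (!is.null(output)) {
    con <- if (grepl("\\.gz$", output)) gzfile(output, "wb")
           else file(output, "wb")
    writeLines(as.vector(rbind(paste0("@", ids[keep]), cf$insert_seq[keep],
                               "+", strrep("I", nchar(cf$insert_seq[keep])))),
               con)
    close(con)
  }
  if (!is.null(report))
    write.table(rep_df, report, sep = "\t", quote = FALSE,
                row.names = FALSE)

  structure(list(ids = ids[keep], insert_seq = cf$insert_seq[keep],
                 discard_reason = cf$discard_reason, report = rep_df),
            class = "trimmed_library")
}
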