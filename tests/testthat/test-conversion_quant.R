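test_that("identical mature sequences collapse to one counting unit", {
  seqs <- c(a = "ACGTACGTACGTACGTACGTAC",
            b = "ACGTACGTACGTACGTACGTAC",
            c = "GGGGCCCCAAAATTTTGGGGCC")
  idx <- index_from_seqs(unname(seqs), names(seqs))
  expect_equal(nrow(idx$units), 2)
  expect_true("a|b" %in% idx$units$unit)
  expect_equal(idx$units$members[idx$units$unit == "a|b"], "a,b")

  empty <- index_from_seqs(character(0), character(0))
  expect_equal(nrow(empty$units), 0)

  uq <- rand_dna(50, 22)
  expect_equal(nrow(index_from_seqs(uq)$units), 50)
})

test_that("index templates carry genomic flanks, strand-aware", {
  cfg <- sim_config(n_mirnas = 12, seed = 41)
  b <- generate_reference(cfg)
  idx <- build_index(b$mature, b$loci, b$genome, flank = 3L)
  for (k in seq_len(nrow(idx$units))) {
    u <- idx$units[k, ]
    expect_equal(substr(u$template, u$mature_offset + 1,
                        u$mature_offset + nchar(u$sequence)),
                 u$sequence)
    expect_equal(nchar(u$template), nchar(u$sequence) + 6)
  }
  # both strands occur in the generated loci
  expect_setequal(unique(as.character(GenomicRanges::strand(b$loci))),
                  c("+", "-"))
})

test_that("FASTA/BED id mismatches are reported with the orphan names", {
  mature <- Biostrings::DNAStringSet(c(x = "ACGTACGTACGTACGTACGT"))
  loci <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 20),
                                 strand = "+", name = "y", score = 0L)
  expect_error(build_index(mature, loci), "x")
  expect_error(build_index(mature, loci), "y")
})

test_that("conversion-aware scoring follows the hand-traced rules", {
  tmpl <- "ACGTACGTACGTACGTACGTAC"   # 22 nt
  idx <- index_from_seqs(tmpl, "m1")
  p <- align_params(nm_max = 3, integrity_min = 0.95)

  r <- align_read(tmpl, idx, p)
  expect_equal(r$unit, "m1")
  expect_equal(r$n_conv, 0)
  expect_equal(r$n_mm, 0)

  one_conv <- sub("T", "C", tmpl)    # first T read as C
  r1 <- align_read(one_conv, idx, p)
  expect_equal(r1$unit, "m1")        # integrity 21/22 ~ 0.9545 passes
  expect_equal(r1$n_conv, 1)
  expect_equal(r1$n_mm, 0)

  two_mm <- tmpl
  substr(two_mm, 1, 1) <- "T"
  substr(two_mm, 5, 5) <- "T"
  r2 <- align_read(two_mm, idx, p)   # 20/22 ~ 0.909 fails integrity
  expect_true(is.na(r2$unit))

  # the same read passes when the integrity filter is relaxed
  r3 <- align_read(two_mm, idx, align_params(nm_max = 3,
                                             integrity_min = 0.9))
  expect_equal(r3$unit, "m1")
  expect_equal(r3$n_mm, 2)
})

test_that("score ties across distinct units leave reads unassigned", {
  t1 <- "AAAACCCCGGGGTTTTAAAACC"
  t2 <- sub("^A", "C", t1)           # differs at one base
  idx <- index_from_seqs(c(t1, t2))
  # a read one mismatch from both templates scores equally against them
  read <- sub("^A", "G", t1)
  r <- align_read(read, idx, align_params(integrity_min = 0.9))
  expect_true(is.na(r$unit))
  # an exact read is uniquely assigned
  expect_equal(align_read(t1, idx, align_params())$unit, "t01")
})

test_that("assignment and counting match the brute-force oracle", {
  set.seed(101)
  for (rep in 1:6) {
    templates <- unique(rand_dna(sample(3:6, 1), sample(18:24, 1)))
    idx <- index_from_seqs(templates)
    nm <- sample(1:3, 1)
    integ <- sample(c(0.7, 0.85, 0.95), 1)
    reads <- vapply(1:40, function(i) {
      s <- sample(templates, 1)
      b <- strsplit(s, "")[[1]]
      for (j in seq_along(b)) {
        if (runif(1) < 0.05) b[j] <- sample(c("A", "C", "G", "T"), 1)
        if (b[j] == "T" && runif(1) < 0.1) b[j] <- "C"
      }
      paste(b, collapse = "")
    }, character(1))
    p <- align_params(nm_max = nm, integrity_min = integ)
    got <- quantify_sample(reads, idx, p)
    exp <- oracle_quantify(reads, idx$units$template, nm, integ)
    expect_equal(unname(got$read_count), exp$read_count)
    prof <- count_conversions(got, idx)
    expect_equal(prof$t_coverage, exp$t_coverage)
    expect_equal(prof$tc_count, exp$tc_count)
  }
})

test_that("SNP masking follows the allele-fraction and coverage rules", {
  # template with one T; engineer read stacks with chosen C fractions
  tmpl <- "AAGTAAGGAAGGAAGGAAGG"    # single T at position 4
  idx <- index_from_seqs(tmpl, "m1")
  p <- align_params(integrity_min = 0.9)
  as_c <- sub("T", "C", tmpl)

  q_het <- quantify_sample(c(rep(tmpl, 10), rep(as_c, 10)), idx, p)
  m_het <- call_snp_mask(list(q_het), idx)
  expect_equal(nrow(m_het), 1)       # 10/20 = 0.5 >= 0.4 masked
  expect_equal(m_het$position, 4)

  q_low <- quantify_sample(c(rep(tmpl, 17), rep(as_c, 3)), idx, p)
  expect_equal(nrow(call_snp_mask(list(q_low), idx)), 0)  # 0.15 < 0.4

  q_thin <- quantify_sample(c(rep(tmpl, 2), rep(as_c, 3)), idx, p)
  expect_equal(nrow(call_snp_mask(list(q_thin), idx)), 0) # coverage 5 < 10

  # masked positions leave numerator and denominator together
  prof_m <- count_conversions(q_het, idx, m_het)
  prof_u <- count_conversions(q_het, idx)
  expect_equal(prof_m$t_coverage, 0)  # only one T position and it is masked
  expect_equal(prof_m$tc_count, 0)
  expect_equal(prof_u$t_coverage, 20)
  expect_equal(prof_u$tc_count, 10)
})

test_that("conversion rates and CPM follow the counting arithmetic", {
  # 10 T positions; 2 reads, one conversion in one read -> 1/20
  tmpl <- paste(rep("AT", 10), collapse = "")
  idx <- index_from_seqs(tmpl, "m1")
  p <- align_params(integrity_min = 0.9)
  one_conv <- sub("T", "C", tmpl)
  q <- quantify_sample(c(tmpl, one_conv), idx, p)
  prof <- count_conversions(q, idx)
  expect_equal(prof$t_coverage, 20)
  expect_equal(prof$tc_count, 1)
  expect_equal(prof$conversion_rate, 0.05)

  # masking the converted position drops it from both sides: 0/18
  mask <- data.frame(unit = "m1", position = 2, coverage = 2,
                     c_fraction = 0.5)
  prof2 <- count_conversions(q, idx, mask)
  expect_equal(prof2$t_coverage, 18)
  expect_equal(prof2$conversion_rate, 0)

  # CPM: 10 reads of 100000 assigned -> 100
  t2 <- "GGGGCCCCAAAAGGGGCCCCAA"
  idx2 <- index_from_seqs(c(tmpl, t2))
  q2 <- quantify_sample(c(rep(tmpl, 10), rep(t2, 99990)), idx2, p)
  prof3 <- count_conversions(q2, idx2)
  expect_equal(prof3$cpm[prof3$unit == "t01"], 100)
  expect_equal(sum(prof3$cpm), 1e6)
})

test_that("adding masked positions never increases conversion totals", {
  set.seed(7)
  templates <- rand_dna(4, 22)
  idx <- index_from_seqs(templates)
  reads <- sample(templates, 200, replace = TRUE)
  reads <- vapply(reads, function(s) {
    b <- strsplit(s, "")[[1]]
    b[b == "T" & runif(length(b)) < 0.2] <- "C"
    paste(b, collapse = "")
  }, character(1), USE.NAMES = FALSE)
  q <- quantify_sample(reads, idx, align_params(integrity_min = 0.8))
  base <- count_conversions(q, idx)
  masks <- data.frame(unit = rep(idx$units$unit, each = 2),
                      position = rep(c(3L, 9L), nrow(idx$units)),
                      coverage = 0L, c_fraction = 0)
  masked <- count_conversions(q, idx, masks)
  expect_true(all(masked$t_coverage <= base$t_coverage))
  expect_true(all(masked$tc_count <= base$tc_count))
})

test_that("quantified simulations recover the labeling rate", {
  # seq_error 0, no SNPs: per-unit rate within 3 binomial SE of f * p_inc
  # under the integrity variant that does not penalize conversions (the
  # penalizing variant drops reads carrying >= 2 conversions, which biases
  # the rate low; checked below)
  cfg <- sim_config(n_mirnas = 8, reads_per_sample = 20000, seq_error = 0,
                    n_snps = 0, seed = 19)
  b <- generate_reference(cfg)
  idx <- build_index(b$mature, b$loci, b$genome)
  lib <- trim_reads(simulate_library(b, "dmso_4su", 1),
                    trim_params(adapter_seq = cfg$adapter_seq))
  q <- quantify_sample(lib, idx, align_params(conv_in_integrity = FALSE))
  prof <- count_conversions(q, idx)
  truth_rate <- b$truth$new_fraction_dmso * b$truth$p_inc
  names(truth_rate) <- b$truth$mirna_id
  for (k in seq_len(nrow(prof))) {
    if (prof$t_coverage[k] < 5000) next
    tr <- truth_rate[[prof$unit[k]]]
    se <- sqrt(tr * (1 - tr) / prof$t_coverage[k])
    expect_lt(abs(prof$conversion_rate[k] - tr), 3 * se)
  }

  # the conversion-penalizing default never exceeds the permissive variant
  q_strict <- quantify_sample(lib, idx, align_params())
  prof_strict <- count_conversions(q_strict, idx)
  expect_true(all(prof_strict$read_count <= prof$read_count))
  expect_true(all(prof_strict$tc_count <= prof$tc_count))
})
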