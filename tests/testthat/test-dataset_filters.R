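# Hand-computed fixture: 4 units x (2+2+2 samples).
#  mirA: expressed everywhere, curated, strongly labeled, PlaB above control
#  mirB: cpm 99 in one control replicate -> fails the in-all-samples rule
#  mirC: expressed, NOT curated
#  mirD: expressed, curated, labeled, but PlaB mean rate below control
fixture_profiles <- function() {
  samples <- study_samples(2L)
  units <- c("mirA", "mirB", "mirC", "mirD")
  cpm <- c(500, 99, 300, 200,      # control rep1
           500, 150, 300, 200,     # control rep2
           500, 150, 300, 200,     # dmso rep1
           500, 150, 300, 200,     # dmso rep2
           500, 150, 300, 200,     # plab rep1
           500, 150, 300, 200)     # plab rep2
  tcov <- rep(10000L, 24)
  tc <- c(5,  5,  5, 10,           # control: background ~5e-4
          5,  5,  5, 10,
          50, 50, 50, 50,          # dmso: labeled
          50, 50, 50, 50,
          30, 30, 30,  5,          # plab: mirD drops below control
          30, 30, 30,  9)
  make_profiles(units, samples, read_count = as.integer(cpm * 10),
                cpm = cpm, t_coverage = tcov, tc_count = tc)
}

fixture_annotation <- function() {
  data.frame(mirna_id = c("mirA", "mirB", "mirC", "mirD"),
             location_class = c("intronic", "exonic", "intronic", "exonic"),
             gene_class = c("lncRNA", "protein_coding", "lncRNA",
                            "protein_coding"),
             motif_CNNC = c(1, 0, 1, 0),
             motif_basal_UG = c(0, 1, 0, 1),
             motif_apical_UGU = c(1, 1, 0, 0),
             tss_distance_nt = c(1000, 5000, 20000, 800),
             stringsAsFactors = FALSE)
}

test_that("initial filter applies the per-sample CPM and curation rules", {
  prof <- fixture_profiles()
  curated <- c("mirA", "mirB", "mirD")
  got <- initial_filter(prof, curated)
  expect_setequal(got, c("mirA", "mirD"))  # mirB: cpm 99 once; mirC: uncurated

  # boundary: cpm must strictly exceed the threshold
  prof2 <- fixture_profiles()
  prof2$cpm[prof2$unit == "mirB"] <- 100
  expect_false("mirB" %in% initial_filter(prof2, curated))

  # a missing sample is reported by name
  prof3 <- fixture_profiles()
  prof3 <- prof3[prof3$sample != "plab_4su_rep2", ]
  expect_error(initial_filter(prof3, curated), "plab_4su_rep2")
})

test_that("labeling test matches the exact hypergeometric computation", {
  samples <- study_samples(1L)
  prof <- make_profiles("m1", samples,
                        read_count = 1000L, cpm = 1000,
                        t_coverage = 10000L,
                        tc_count = c(5L, 50L, 20L))
  lt <- labeling_test(prof, "m1")
  # independent oracle: one-sided Fisher on the pooled 2x2 table
  oracle <- fisher.test(matrix(c(50, 9950, 5, 9995), 2),
                        alternative = "greater")$p.value
  expect_equal(lt$p_value, oracle, tolerance = 1e-12)
  expect_lt(lt$p_value, 1e-6)
  expect_true(lt$labeled)

  # identical pooled counts: no signal
  prof_eq <- make_profiles("m1", samples, 1000L, 1000, 10000L,
                           tc_count = c(50L, 50L, 50L))
  lt_eq <- labeling_test(prof_eq, "m1")
  expect_gte(lt_eq$p_value, 0.5)
  expect_false(lt_eq$labeled)

  # vehicle below background is never labeled
  prof_dn <- make_profiles("m1", samples, 1000L, 1000, 10000L,
                           tc_count = c(50L, 5L, 20L))
  expect_false(labeling_test(prof_dn, "m1")$labeled)

  # zero coverage in a condition is untestable
  prof_z <- make_profiles("m1", samples, 1000L, 1000,
                          t_coverage = c(0L, 10000L, 10000L),
                          tc_count = c(0L, 50L, 20L))
  expect_true(is.na(labeling_test(prof_z, "m1")$labeled))
})

test_that("BH adjustment is monotone and never below the raw p", {
  samples <- study_samples(1L)
  units <- sprintf("m%d", 1:6)
  tc <- c(rep(5L, 6),                       # control
          c(60L, 50L, 40L, 20L, 10L, 6L),   # dmso, graded signal
          rep(5L, 6))                       # plab
  prof <- make_profiles(units, samples, 1000L, 1000, 10000L, tc)
  lt <- labeling_test(prof, units)
  expect_true(all(lt$p_adj >= lt$p_value - 1e-15))
  ord <- order(lt$p_value)
  expect_true(all(diff(lt$p_adj[ord]) >= -1e-15))
})

test_that("drug-floor filter keeps the boundary and drops below-control", {
  prof <- fixture_profiles()
  # mean rates: mirA plab 30/10000 > control 5/10000 -> kept
  # mirD plab (5+9)/2 = 7 < control 10 -> dropped
  got <- plab_floor_filter(prof, c("mirA", "mirD"))
  expect_equal(got, "mirA")

  # exact equality is retained
  prof_eq <- fixture_profiles()
  prof_eq$tc_count[prof_eq$unit == "mirD" &
                     prof_eq$condition == "plab_4su"] <- 10L
  prof_eq$conversion_rate <- ifelse(prof_eq$t_coverage > 0,
                                    prof_eq$tc_count / prof_eq$t_coverage, 0)
  expect_setequal(plab_floor_filter(prof_eq, c("mirA", "mirD")),
                  c("mirA", "mirD"))
})

test_that("context deduplication excludes mixed and discordant units", {
  ann <- data.frame(mirna_id = c("a", "b", "c", "d"),
                    location_class = c("intronic", "intronic", "exonic",
                                       "mixed"),
                    gene_class = c("lncRNA", "lncRNA", "lncRNA", "lncRNA"),
                    stringsAsFactors = FALSE)
  # collapsed unit with two same-context members is retained
  expect_equal(context_dedup("a|b", ann), "a|b")
  # members with differing context are excluded
  expect_length(context_dedup("a|c", ann), 0)
  # a single mixed-location miRNA is excluded
  expect_length(context_dedup("d", ann), 0)
  # single-locus unit retained
  expect_equal(context_dedup("c", ann), "c")
  expect_warning(ctx <- context_dedup("zz", ann), "annotation")
  expect_length(ctx, 0)
})

test_that("membership table is internally consistent and nested", {
  prof <- fixture_profiles()
  m <- dataset_membership(prof, curated = c("mirA", "mirB", "mirD"),
                          annotation = fixture_annotation())
  expect_equal(m$unit, sort(unique(prof$unit)))
  expect_true(all(m$in_final <= m$in_initial))
  expect_true(all(m$in_context_set <= m$in_final))
  expect_equal(m$exclusion_reason[m$unit == "mirB"], "initial_filter")
  expect_equal(m$exclusion_reason[m$unit == "mirC"], "initial_filter")
  expect_equal(m$exclusion_reason[m$unit == "mirD"], "plab_below_control")
  expect_equal(m$exclusion_reason[m$unit == "mirA"], "none")
  expect_match(attr(m, "labeling_note"), "p_adj <")
})

test_that("filters nest monotonically on simulated studies", {
  cfg <- sim_config(n_mirnas = 30, reads_per_sample = 50000, seed = 77)
  b <- generate_reference(cfg)
  prof <- simulate_profiles(b, seed = 2)
  m <- dataset_membership(prof, b$curated, b$annotation)
  expect_true(all(m$in_final <= m$in_initial))
  expect_true(all(m$in_context_set <= m$in_final))
  labeled_n <- sum(m$labeled %in% TRUE)
  expect_lte(sum(m$in_final), labeled_n)
  expect_lte(labeled_n, sum(m$in_initial))
})
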