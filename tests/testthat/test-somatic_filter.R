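test_that("caller merging does set union/intersection with provenance", {
  a <- make_calls("S1", pos = c(1L, 2L), depth = c(100L, 300L),
                  alt_reads = c(10L, 30L), callers = "mutect")
  b <- make_calls("S1", pos = c(2L, 3L), depth = c(250L, 120L),
                  alt_reads = c(25L, 12L), callers = "varscan2")
  u <- merge_callers(a, b, "union")
  expect_setequal(u$pos, c(1L, 2L, 3L))
  expect_equal(u$callers[u$pos == 2L], "mutect,varscan2")
  expect_equal(u$callers[u$pos == 1L], "mutect")
  # depth taken from the deeper caller at shared loci
  expect_equal(u$depth[u$pos == 2L], 300L)
  expect_equal(u$alt_reads[u$pos == 2L], 30L)

  i <- merge_callers(a, b, "intersection")
  expect_equal(i$pos, 2L)

  b2 <- b
  b2$sample_id <- "S2"
  expect_error(merge_callers(a, b2), "different samples")
})

test_that("filter boundaries: 200x inclusive, 1% strictly exceeded", {
  blood <- make_calls("BL", pos = 999L)[0, ]  # clean blood, zero rows
  cfg <- filter_config()
  t1 <- make_calls("T1", pos = 1L, depth = 200L, alt_reads = 3L,
                   af = 0.011)
  expect_equal(nrow(apply_somatic_filters(t1, blood, cfg)$passing), 1L)

  t2 <- make_calls("T1", pos = 2L, depth = 2500L, alt_reads = 25L,
                   af = 0.010)
  r2 <- apply_somatic_filters(t2, blood, cfg)
  expect_equal(nrow(r2$passing), 0L)
  expect_equal(r2$rejected$reason, "af")

  t3 <- make_calls("T1", pos = 3L, depth = 199L, alt_reads = 100L)
  r3 <- apply_somatic_filters(t3, blood, cfg)
  expect_equal(r3$rejected$reason, "depth")
})

test_that("germline exclusion and reason precedence", {
  tumor <- make_calls("T1", pos = c(10L, 20L, 30L),
                      depth = c(150L, 2500L, 2500L),
                      alt_reads = c(75L, 1200L, 1000L))
  blood <- make_calls("BL", pos = c(10L, 20L),
                      depth = c(100L, 100L), alt_reads = c(48L, 47L))
  res <- apply_somatic_filters(tumor, blood)
  # pos 10 is both germline and under-covered: germline wins (precedence)
  expect_equal(res$rejected$reason[res$rejected$pos == 10L], "germline")
  expect_equal(res$rejected$reason[res$rejected$pos == 20L], "germline")
  expect_equal(res$passing$pos, 30L)
  expect_error(apply_somatic_filters(tumor, NULL), "blood")
})

test_that("low blood coverage flags the locus but keeps it", {
  tumor <- make_calls("T1", pos = 10L, depth = 2500L, alt_reads = 1200L)
  blood <- make_calls("BL", pos = 10L, depth = 40L, alt_reads = 20L)
  expect_warning(res <- apply_somatic_filters(tumor, blood),
                 "blood coverage")
  expect_equal(nrow(res$passing), 1L)
  expect_true(res$passing$blood_low_coverage)
})

test_that("extra per-call predicates hook in after the built-in reasons", {
  tumor <- make_calls("T1", pos = c(1L, 2L), depth = 2500L,
                      alt_reads = c(250L, 500L))
  blood <- make_calls("BL", pos = 99L)[0, ]
  cfg <- filter_config(extra_predicates = list(
    max_af_half = function(calls) calls$af <= 0.15))
  res <- apply_somatic_filters(tumor, blood, cfg)
  expect_equal(res$passing$pos, 1L)
  expect_equal(res$rejected$reason, "max_af_half")
  expect_equal(unname(filter_summary(res$rejected)["max_af_half"]), 1L)
})

test_that("filter_summary counts every rejection exactly once", {
  tumor <- make_calls("T1", pos = 1:6,
                      depth = c(100L, 120L, 2500L, 2500L, 2500L, 2500L),
                      alt_reads = c(50L, 60L, 20L, 10L, 800L, 900L))
  blood <- make_calls("BL", pos = c(5L, 6L), depth = 200L, alt_reads = 100L)
  res <- apply_somatic_filters(tumor, blood)
  s <- filter_summary(res$rejected)
  expect_equal(unname(s[c("germline", "depth", "af")]), c(2L, 2L, 2L))
  expect_equal(sum(s), nrow(res$rejected))
  expect_equal(sum(filter_summary(res$rejected[0, ])), 0L)
})

test_that("tightening thresholds never enlarges the passing set", {
  set.seed(11)
  blood <- make_calls("BL", pos = 1000L)[0, ]
  for (rep in 1:60) {
    calls <- random_calls(sample(5:25, 1L), "T1")
    loose <- apply_somatic_filters(calls, blood,
                                   filter_config(min_depth = 100L,
                                                 min_af = 0.01))
    tight <- apply_somatic_filters(calls, blood,
                                   filter_config(min_depth = 200L,
                                                 min_af = 0.05))
    lk <- locus_key(loose$passing)
    tk <- locus_key(tight$passing)
    expect_true(all(tk %in% lk))
    # partition: passing + rejected = input, disjoint
    expect_equal(nrow(loose$passing) + nrow(loose$rejected), nrow(calls))
    expect_length(intersect(lk, locus_key(loose$rejected)), 0L)
  }
})

test_that("caller merge order does not change the union passing set", {
  set.seed(12)
  blood <- make_calls("BL", pos = 1000L)[0, ]
  for (rep in 1:20) {
    a <- random_calls(sample(3:10, 1L), "T1")
    b <- random_calls(sample(3:10, 1L), "T1")
    ab <- apply_somatic_filters(merge_callers(a, b, "union"), blood)
    ba <- apply_somatic_filters(merge_callers(b, a, "union"), blood)
    expect_setequal(locus_key(ab$passing), locus_key(ba$passing))
  }
})
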