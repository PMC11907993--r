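test_that("composite scan finds the ID-like control hit with full annotation", {
  hits <- scan_composites("AAGGCGCCAACTTGTCTGAA", "pGC_SBE", "SBE", 5)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$up_start, 2L)
  expect_equal(hits$up_end, 8L)
  expect_equal(hits$down_start, 13L)
  expect_equal(hits$down_end, 18L)
  expect_identical(hits$spacer_seq, "AACTT")
  expect_setequal(strsplit(hits$modes, ",")[[1]],
                  c("face_to_back", "back_to_back"))
  expect_identical(hits$label, "BMP_responsive")
})

test_that("composite scan edge cases: empty input, bad spacer, ordered pairs", {
  expect_equal(nrow(scan_composites("", "pGC_SBE", "SBE", 5)), 0L)
  expect_error(scan_composites("ACGT", "pGC_SBE", "SBE", -1), ">= 0")
  # B upstream of A is found unordered but not ordered
  seq <- "TTGTCTGAACTTGGCGCCTT"
  expect_equal(nrow(scan_composites(seq, "pGC_SBE", "SBE", 5)), 1L)
  expect_equal(nrow(scan_composites(seq, "pGC_SBE", "SBE", 5,
                                    ordered = TRUE)), 0L)
  expect_equal(nrow(scan_composites(seq, "SBE", "pGC_SBE", 5,
                                    ordered = TRUE)), 1L)
})

test_that("scanner agrees with the brute-force double-loop oracle", {
  set.seed(101)
  els <- canonical_elements()
  classes <- composite_classes()
  for (i in 1:30) {
    s <- rand_dna(500)
    for (k in seq_len(nrow(classes))) {
      ea <- els[[classes$element_a[k]]]
      eb <- els[[classes$element_b[k]]]
      hits <- scan_composites(s, ea, eb, c(3L, 5L, 7L))
      expect_identical(hit_keys(hits),
                       brute_scan_keys(s, ea, eb, c(3L, 5L, 7L)),
                       info = sprintf("seq %d class %s", i,
                                      classes$class_id[k]))
    }
  }
})

test_that("screening a planted set recovers exactly the truth table", {
  ps <- make_planted_set(n = 60, count = 3)
  sc <- screen_regions(ps$regions, ps$sequences)
  idl <- sc$region_table[sc$region_table$class_id == "pGC_SBE+SBE/5", ]
  expect_setequal(idl$region_id[idl$positive], ps$truth$region_id)
  cs <- sc$class_summary
  expect_equal(cs$n_positive[cs$class_id == "pGC_SBE+SBE/5"], 3L)
  expect_equal(cs$n_total[1], 60L)
  expect_equal(cs$fraction_positive[cs$class_id == "pGC_SBE+SBE/5"], 0.05)
})

test_that("screening an empty region set yields zero counts and NA fractions", {
  regions <- data.frame(chrom = character(0), start = integer(0),
                        end = integer(0), region_id = character(0))
  sc <- screen_regions(regions, c(chr1 = "ACGTACGT"))
  expect_true(all(sc$class_summary$n_positive == 0L))
  expect_true(all(is.na(sc$class_summary$fraction_positive)))
})

test_that("region positivity is invariant under reverse complement", {
  ps <- make_planted_set(n = 40, count = 4, minus_strand = 0.5)
  fwd <- screen_regions(ps$regions, ps$sequences)
  rev <- screen_regions(ps$regions,
                        reverse_complement_peakset(ps)$sequences)
  f <- fwd$region_table[order(fwd$region_table$region_id,
                              fwd$region_table$class_id), ]
  r <- rev$region_table[order(rev$region_table$region_id,
                              rev$region_table$class_id), ]
  expect_identical(f$positive, r$positive)
  expect_identical(f$n_hits, r$n_hits)
  # back-to-back achievability is preserved per region and class
  btb_set <- function(sc) {
    h <- sc$hits[grepl("back_to_back", sc$hits$modes), ]
    sort(unique(paste(h$region_id, h$class_id)))
  }
  expect_identical(btb_set(fwd), btb_set(rev))
})

test_that("planting only ever grows a region's positive class set", {
  ps <- generate_background(20, 300, 0.41, seed = 3)
  before <- screen_regions(ps$regions, ps$sequences)$region_table
  planted <- plant_composites(ps, "pGC_SBE", "pGC_SBE", count = 20, seed = 5)
  after <- screen_regions(planted$regions, planted$sequences)$region_table
  key <- function(rt) paste(rt$region_id, rt$class_id)
  pos_before <- key(before)[before$positive]
  pos_after <- key(after)[after$positive]
  expect_true(all(pos_before %in% pos_after))
  expect_true(all(paste(planted$truth$region_id, planted$truth$class_id)
                  %in% pos_after))
})

test_that("regions outside the genome are excluded with an error record", {
  seqs <- c(chr1 = rand_dna(200))
  regions <- data.frame(chrom = c("chr1", "chr1", "chr2"),
                        start = c(0L, 150L, 0L), end = c(100L, 400L, 50L),
                        region_id = c("ok", "past_end", "no_chrom"))
  sc <- screen_regions(regions, seqs)
  expect_setequal(sc$excluded$region_id, c("past_end", "no_chrom"))
  expect_equal(sc$class_summary$n_total[1], 1L)
})

test_that("multi-dataset aggregation sums totals and rejects duplicates", {
  ps1 <- make_planted_set(n = 20, count = 2, seed = 1, plant_seed = 2)
  ps2 <- generate_background(15, 300, 0.41, seed = 9)
  s1 <- screen_regions(ps1$regions, ps1$sequences)
  s2 <- screen_regions(ps2$regions, ps2$sequences)
  long <- summarize_screen(list(a = s1, b = s2))
  a_tot <- long[long$dataset == "a" & long$class_id == "all_classes", ]
  expect_equal(a_tot$n_total, 20L)
  expect_gte(a_tot$n_positive, 2L)
  b_tot <- long[long$dataset == "b" & long$class_id == "all_classes", ]
  expect_equal(b_tot$n_positive, 0L)
  one <- summarize_screen(list(a = s1))
  expect_equal(one[one$class_id != "all_classes", "n_positive"],
               s1$class_summary$n_positive)
  expect_error(summarize_screen(list(a = s1, a = s2)), "duplicate dataset")
  expect_error(summarize_screen(list(s1)), "named")
})

test_that("fractions across planting rates stay within binomial bounds", {
  rates <- c(0, 0.005, 0.02)
  n <- 200
  summaries <- list()
  for (i in seq_along(rates)) {
    ps <- generate_background(n, 120, 0.41, seed = 20 + i)
    ps <- plant_composites(ps, count = round(rates[i] * n), seed = 30 + i)
    summaries[[sprintf("d%d", i)]] <- screen_regions(ps$regions, ps$sequences)
  }
  long <- summarize_screen(summaries)
  idl <- long[long$class_id == "pGC_SBE+SBE/5", ]
  for (i in seq_along(rates)) {
    ci <- stats::binom.test(round(rates[i] * n), n)$conf.int
    expect_gte(idl$fraction_positive[i], ci[1])
    expect_lte(idl$fraction_positive[i], ci[2])
  }
})
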