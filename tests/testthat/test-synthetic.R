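test_that("generators are pure functions of parameters and seed", {
  a <- generate_background(20, 120, 0.41, seed = 7)
  b <- generate_background(20, 120, 0.41, seed = 7)
  expect_identical(a$sequences, b$sequences)
  c <- generate_background(20, 120, 0.41, seed = 8)
  expect_false(identical(a$sequences, c$sequences))
  pa <- plant_composites(a, count = 5, seed = 3)
  pb <- plant_composites(b, count = 5, seed = 3)
  expect_identical(pa$sequences, pb$sequences)
  expect_identical(pa$truth, pb$truth)
  expect_identical(sample_linkers(50, seed = 5), sample_linkers(50, seed = 5))
  expect_identical(simulate_binding_curve(1, 500, 1.8, c(10, 100, 1000),
                                          noise_sd = 0.05, seed = 2),
                   simulate_binding_curve(1, 500, 1.8, c(10, 100, 1000),
                                          noise_sd = 0.05, seed = 2))
})

test_that("rejection-sampled background contains no composite of any class", {
  ps <- generate_background(50, 300, 0.41, seed = 13)
  sc <- screen_regions(ps$regions, ps$sequences)
  expect_true(all(sc$class_summary$n_positive == 0L))
  expect_equal(nrow(ps$truth), 0L)
})

test_that("background base composition matches the target GC content", {
  ps <- generate_background(200, 500, 0.41, seed = 21)
  all_seq <- paste(ps$sequences, collapse = "")
  gc <- mean(strsplit(all_seq, "")[[1]] %in% c("G", "C"))
  expect_lt(abs(gc - 0.41), 0.01)
})

test_that("generator input validation", {
  expect_error(generate_background(5, 30, 0.41, seed = 1), ">= 50")
  expect_error(generate_background(5, 100, 1.2, seed = 1), "gc")
  expect_error(sample_linkers(10, positions = 7), "positions")
  expect_error(sample_linkers(10, g_prob = 0.2), "g_prob")
  expect_error(plant_composites(generate_background(5, 100, 0.4, seed = 1),
                                seed = 1), "rate or count")
})

test_that("planting writes the composite verbatim at the recorded offset", {
  ps <- plant_composites(generate_background(30, 200, 0.41, seed = 2),
                         count = 10, seed = 4)
  for (i in seq_len(nrow(ps$truth))) {
    tr <- ps$truth[i, ]
    seq <- ps$sequences[[tr$region_id]]
    expected <- paste0("GGCGCC", tr$spacer_seq, "GTCTG")
    written <- substr(seq, tr$start + 1L, tr$start + nchar(expected))
    expect_identical(written,
                     if (tr$strand == "minus") reverse_complement(expected)
                     else expected)
  }
  # rate 0 plants nothing
  p0 <- plant_composites(generate_background(10, 100, 0.41, seed = 5),
                         rate = 0, seed = 1)
  expect_equal(nrow(p0$truth), 0L)
})

test_that("minus-strand plants screen identically to plus-strand plants", {
  base <- generate_background(30, 200, 0.41, seed = 6)
  plus <- plant_composites(base, count = 6, minus_strand = FALSE, seed = 9)
  minus <- plant_composites(base, count = 6, minus_strand = TRUE, seed = 9)
  expect_identical(plus$truth$region_id, minus$truth$region_id)
  cls <- composite_classes()
  s_plus <- screen_regions(plus$regions, plus$sequences, cls)
  s_minus <- screen_regions(minus$regions, minus$sequences, cls)
  idl <- function(s) {
    rt <- s$region_table
    sort(rt$region_id[rt$class_id == "pGC_SBE+SBE/5" & rt$positive])
  }
  expect_identical(idl(s_plus), idl(s_minus))
})

test_that("regions too short for the composite are skipped with a note", {
  ps <- generate_background(3, 100, 0.41, seed = 8)
  ps$sequences[[1]] <- substr(ps$sequences[[1]], 1, 10)  # force a short region
  expect_warning(
    planted <- plant_composites(ps, count = 3, seed = 2),
    "too short")
  expect_lt(nrow(planted$truth), 3L)
})

test_that("boosted linker sampling honors its probability parameters", {
  l <- sample_linkers(300, positions = c(2, 3), g_prob = 1.0, seed = 12)
  expect_true(all(substr(l, 2, 2) == "G"))
  expect_true(all(substr(l, 3, 3) == "G"))
  expect_identical(sample_linkers(0, seed = 1), character(0))
  g1 <- mean(substr(sample_linkers(2000, g_prob = 0.6, seed = 3), 1, 1) == "G")
  expect_lt(abs(g1 - 0.25), 0.05)
})

test_that("simulated binding curves sit on the model when noiseless", {
  x <- c(50, 238, 500, 1000)
  cv <- simulate_binding_curve(1, 238, 1, x, noise_sd = 0)
  expect_equal(cv$fraction_bound, hill_model(x, 1, 238, 1))
  expect_equal(cv$fraction_bound[2], 0.5)
  noisy <- simulate_binding_curve(0.95, 300, 1.5, x, noise_sd = 5, seed = 1)
  expect_true(all(noisy$fraction_bound >= 0 & noisy$fraction_bound <= 1))
  two <- simulate_binding_curve(1, 300, 1, x, noise_sd = 0.01,
                                replicates = 2, seed = 4)
  expect_equal(nrow(two), 8L)
  expect_equal(unique(two$replicate), c(1L, 2L))
})

test_that("the default regime keeps composite positives rare (below 1%)", {
  ps <- plant_composites(generate_background(300, 300, 0.41, seed = 30),
                         count = 2, seed = 31)
  sc <- screen_regions(ps$regions, ps$sequences)
  expect_true(all(sc$class_summary$fraction_positive < 0.01))
  expect_gt(max(sc$class_summary$fraction_positive), 0)
})

test_that("peak sets export to FASTA/BED/truth/params files", {
  ps <- plant_composites(generate_background(10, 100, 0.41, seed = 1),
                         count = 2, seed = 2)
  prefix <- file.path(withr::local_tempdir(), "ps")
  paths <- write_peakset(ps, prefix)
  expect_true(all(file.exists(paths)))
  back <- read_fasta(paths["fasta"])
  expect_identical(back, ps$sequences)
  bed <- read_bed(paths["bed"])
  expect_equal(nrow(bed), 10L)
  truth <- utils::read.delim(paths["truth"])
  expect_equal(nrow(truth), 2L)
})
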