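test_that("the ID-like control insert assembles exactly as specified", {
  cas <- reporter_cassette(c("pGC_SBE", "SBE"))
  x <- build_insert(cas, spacers = "CTRL", construct_id = "IDL")
  expect_match(x$sequence, "GGCGCCAACTTGTCTG", fixed = TRUE)
  expect_match(x$sequence, mlp_sequence(), fixed = TRUE)
  expect_true(startsWith(x$sequence, "GGTACC"))        # KpnI context
  expect_match(x$sequence, "CTCGAG", fixed = TRUE)     # XhoI
  expect_match(x$sequence, "AGATCT", fixed = TRUE)     # BglII
  expect_equal(x$spacer_to_mlp, 10L)
})

test_that("every construct keeps a 10-bp motif-to-MLP distance and one MLP copy", {
  lib <- enumerate_library(seed = 4)
  for (x in lib$constructs[sample(length(lib$constructs), 20)]) {
    mlp_at <- regexpr(mlp_sequence(), x$sequence, fixed = TRUE)[1]
    cassette_end <- nchar(x$sequence) - nchar(mlp_sequence()) - 10L
    expect_equal(mlp_at - 1L - cassette_end, 10L, info = x$construct_id)
    n_mlp <- lengths(regmatches(x$sequence,
                                gregexpr(mlp_sequence(), x$sequence,
                                         fixed = TRUE)))
    expect_equal(n_mlp, 1L)
  }
})

test_that("insert assembly is deterministic and validates its inputs", {
  cas <- reporter_cassette(c("pGC_SBE", "pGC_SBE"))
  a <- build_insert(cas, "AATTA", "c1")
  b <- build_insert(cas, "AATTA", "c1")
  expect_identical(a$sequence, b$sequence)
  expect_error(build_insert(cas, character(0), "c2"), "spacer")
  expect_error(build_insert(cas, "AAGTA", "c3"), "GC-poor")  # G in spacer
  expect_error(build_insert(cas, "IDX", "c4"), "unknown linker")
  expect_error(build_insert(cas, "ACCTA", "c5"), "GC-poor")  # two C
  big <- reporter_cassette(rep("pGC_SBE", 6))
  expect_error(build_insert(big, rep("AATTA", 5), "c6",
                            synthesis_limit = 100L), "synthesis limit")
})

test_that("antisense motifs are written as their reverse complement", {
  cas <- reporter_cassette(c("SBE", "pGC_SBE"),
                           orientations = c("antisense", "sense"))
  x <- build_insert(cas, "AACTT", "fa")
  expect_match(x$sequence, "CAGACAACTTGGCGCC", fixed = TRUE)
})

test_that("the default library is large, distinct and correctly sized per series", {
  lib <- enumerate_library(seed = 1)
  m <- lib$manifest
  expect_gte(nrow(m), 65L)
  expect_equal(anyDuplicated(m$construct_id), 0L)
  expect_equal(anyDuplicated(m$sequence), 0L)
  expect_equal(sum(m$series == "copy_number"), 6L)
  expect_equal(sum(m$series == "spacing"), 49L)
  # one permutation construct per position x substitution
  expect_equal(sum(m$series == "permutation"), 18L)
  # same seed reproduces the library byte-for-byte
  lib2 <- enumerate_library(seed = 1)
  expect_identical(m$sequence, lib2$manifest$sequence)
  empty <- enumerate_library(config = list(), seed = 1)
  expect_equal(length(empty$constructs), 0L)
})

test_that("predicted labels follow the spacing, orientation and copy-number rules", {
  lib <- enumerate_library(seed = 2)
  labels <- merge(label_library(lib), lib$manifest, by = c("construct_id",
                                                           "series"))
  sp <- labels[labels$series == "spacing", ]
  expect_identical(sp$bmp_label == "BMP_responsive",
                   sp$param_a == 5L | sp$param_b == 5L)
  cn <- labels[labels$series == "copy_number", ]
  expect_identical(cn$bmp_label == "BMP_responsive", cn$param_a >= 2L)
  ori <- labels[labels$series == "orientation", ]
  expect_true(all(ori$bmp_label == "nonresponsive"))
  expect_identical(ori$tgfb, startsWith(ori$variant, "pSBE"))
  het <- labels[labels$series == "hetero_orientation", ]
  expect_identical(
    het$bmp_label[match(c("sense", "sbe_antisense", "full_antisense"),
                        het$variant)],
    c("BMP_responsive", "nonresponsive", "BMP_responsive_weak"))
  idl <- labels[labels$series == "id_linker", ]
  expect_true(all(idl$bmp_label == "BMP_responsive"))
  perm <- labels[labels$series == "permutation", ]
  expect_true(all(perm$bmp_label != "BMP_responsive"))
})

test_that("adding copies of a responsive composite never loses the label", {
  lib <- enumerate_library(seed = 3)
  labels <- label_library(lib)
  cn <- merge(labels, lib$manifest[, c("construct_id", "param_a")],
              by = "construct_id")
  cn <- cn[cn$series == "copy_number" & cn$param_a >= 2, ]
  expect_true(all(cn$bmp_label == "BMP_responsive"))
})

test_that("predicted labels agree fully with the expected assay outcomes", {
  report <- check_library(enumerate_library(seed = 1))
  expect_equal(attr(report, "agreement"), 1.0)
})

test_that("library inserts round-trip through FASTA byte-identically", {
  lib <- enumerate_library(config = list(id_linkers = c("ID1", "CTRL"),
                                         copy_numbers = 1:3), seed = 6)
  fa <- withr::local_tempfile(fileext = ".fa")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  manifest <- write_library(lib, fa, tsv)
  back <- read_fasta(fa)
  expect_identical(unname(back[manifest$construct_id]), manifest$sequence)
})
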