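toy_model <- function() {
  # three-gene toy annotation on one 10-kb chromosome; gene B's intron
  # overlaps gene A's exon so precedence is exercised
  feats <- data.frame(
    chrom = "chr1",
    start = c(2000, 2600, 2400, 4000, 6000),
    end = c(2500, 3000, 2800, 4500, 6500),
    class = c("exon", "intron", "intron", "utr", "exon"))
  tss <- data.frame(chrom = "chr1", pos = 1200, strand = "+")
  annotation_model(feats, tss, c(chr1 = 10000))
}

test_that("regions are classified by midpoint with precedence tie-breaks", {
  m <- toy_model()
  regions <- data.frame(
    chrom = "chr1",
    start = c(900, 2000, 2650, 2440, 4100, 8000),
    end = c(1100, 2200, 2750, 2460, 4300, 8200),
    region_id = c("prom", "exonic", "intronic", "exon_vs_intron", "utr5",
                  "desert"))
  cls <- classify_regions(regions, m)
  expect_identical(cls$class,
                   c("promoter", "exon", "intron", "exon", "utr",
                     "intergenic"))
  # midpoint 200 bp upstream of the TSS falls in the [-1000, +100] window
  expect_identical(cls$class[cls$region_id == "prom"], "promoter")
})

test_that("unknown chromosomes yield an error record, not a crash", {
  m <- toy_model()
  cls <- classify_regions(data.frame(chrom = "chrX", start = 0, end = 100),
                          m)
  expect_true(is.na(cls$class))
  expect_match(cls$error, "unknown chromosome")
})

test_that("genomic shares respect precedence flattening and sum to one", {
  m <- toy_model()
  sh <- m$class_genomic_share
  expect_equal(sum(sh), 1)
  expect_equal(unname(sh["promoter"]), 1100 / 10000)
  # gene A's exon [2000,2500) wins over gene B's intron [2400,2800):
  # intron keeps [2500,2800) + [2600,3000) merged -> [2500,3000)
  expect_equal(unname(sh["exon"]), (500 + 500) / 10000)
  expect_equal(unname(sh["intron"]), 500 / 10000)
})

test_that("proportional positives give unit enrichment everywhere", {
  feats <- data.frame(chrom = "chr1", start = 0, end = 500, class = "exon")
  m <- annotation_model(feats, NULL, c(chr1 = 1000))
  expect_equal(unname(m$class_genomic_share[c("exon", "intergenic")]),
               c(0.5, 0.5))
  regions <- data.frame(chrom = "chr1",
                        start = c(100, 200, 300, 600, 700, 800),
                        end = c(120, 220, 320, 620, 720, 820))
  dist <- normalized_distribution(classify_regions(regions, m), m)
  expect_equal(dist$enrichment, c(1, 1))
  expect_equal(sum(dist$raw_pct), 100, tolerance = 1e-9)
})

test_that("the 8-vs-2 half-genome toy gives enrichments 1.6 and 0.4", {
  feats <- data.frame(chrom = "chr1", start = 0, end = 500, class = "exon")
  m <- annotation_model(feats, NULL, c(chr1 = 1000))
  mids_exon <- seq(50, 400, length.out = 8)
  mids_int <- c(600, 900)
  regions <- data.frame(chrom = "chr1",
                        start = c(mids_exon, mids_int) - 10,
                        end = c(mids_exon, mids_int) + 10)
  dist <- normalized_distribution(classify_regions(regions, m), m)
  expect_equal(dist$enrichment[dist$class == "exon"], 1.6)
  expect_equal(dist$enrichment[dist$class == "intergenic"], 0.4)
  expect_equal(sum(dist$normalized_pct), 100)
})

test_that("enrichment is invariant to doubling every count", {
  feats <- data.frame(chrom = "chr1", start = 0, end = 300, class = "exon")
  m <- annotation_model(feats, NULL, c(chr1 = 1000))
  regions <- data.frame(chrom = "chr1", start = c(50, 150, 400, 500),
                        end = c(70, 170, 420, 520))
  d1 <- normalized_distribution(classify_regions(regions, m), m)
  d2 <- normalized_distribution(
    classify_regions(rbind(regions, regions), m), m)
  expect_equal(d1$enrichment, d2$enrichment)
  expect_equal(d1$raw_pct, d2$raw_pct)
})

test_that("a single positive region concentrates 100% raw share", {
  m <- toy_model()
  d <- normalized_distribution(
    classify_regions(data.frame(chrom = "chr1", start = 2100, end = 2200), m),
    m)
  expect_equal(nrow(d), 1L)
  expect_equal(d$raw_pct, 100)
  expect_identical(d$class, "exon")
})

test_that("three-fold intergenic over-representation is recovered at n=500", {
  m <- annotation_model(
    data.frame(chrom = "chr1", start = 0, end = 8000, class = "exon"),
    NULL, c(chr1 = 10000))
  expect_equal(unname(m$class_genomic_share["intergenic"]), 0.2)
  set.seed(17)
  n <- 500
  in_intergenic <- stats::runif(n) < 3 * 0.2
  mids <- ifelse(in_intergenic, sample(8010:9990, n, replace = TRUE),
                 sample(10:7990, n, replace = TRUE))
  regions <- data.frame(chrom = "chr1", start = mids - 5, end = mids + 5)
  d <- normalized_distribution(classify_regions(regions, m), m)
  enr <- d$enrichment[d$class == "intergenic"]
  expect_lt(abs(enr - 3) / 3, 0.2)
})

test_that("any-overlap classification differs from midpoint when asked", {
  m <- toy_model()
  region <- data.frame(chrom = "chr1", start = 2450, end = 3400)
  expect_identical(classify_regions(region, m)$class, "intron")  # midpoint
  expect_identical(classify_regions(region, m, by = "any")$class, "exon")
})
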