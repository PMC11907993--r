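# Seed-reproducible synthetic data: peak sets with planted composites,
# enriched linker samples, and noisy binding curves.

#' Generate a composite-free background peak set
#'
#' Draws ChIP-seq-peak-like regions of i.i.d. bases at a target GC content
#' and rejection-samples each region until it contains no occurrence of any
#' composite class in `classes` — so any composite later found in the set
#' was planted, and planting truth tables are exact. Each region is emitted
#' as its own synthetic chromosome.
#'
#' @param n_regions Number of regions.
#' @param region_length Region length(s) in bp (recycled; >= 50).
#' @param gc GC content in (0, 1); `P(G) = P(C) = gc / 2`.
#' @param seed Integer seed; identical parameters and seed reproduce the
#'   set byte-for-byte.
#' @param classes Composite classes the background must avoid (default: all
#'   canonical pairs at 5-bp spacing).
#' @param max_attempts Rejection-sampling cap per region.
#' @return An object of class `synthetic_peakset`: list with `sequences`
#'   (named character), `regions` (BED-like data.frame), `truth` (empty
#'   planting table) and `params`.
#' @export
generate_background <- function(n_regions, region_length = 300L, gc = 0.41,
                                seed = 1L, classes = composite_classes(),
                                max_attempts = 10000L) {
  stopifnot(n_regions >= 0, gc > 0, gc < 1, all(region_length >= 50L))
  lens <- rep_len(as.integer(region_length), max(n_regions, 0L))
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  registry <- canonical_elements()
  needed <- unique(c(classes$element_a, classes$element_b))
  elements <- lapply(needed, .as_element, registry = registry)
  names(elements) <- needed
  seqs <- .with_seed(seed, {
    vapply(seq_len(n_regions), function(i) {
      for (attempt in seq_len(max_attempts)) {
        s <- paste(sample(names(probs), lens[i], replace = TRUE, prob = probs),
                   collapse = "")
        if (!.has_any_composite(s, elements, classes)) return(s)
      }
      stop(sprintf("rejection sampling failed for region %d after %d attempts",
                   i, max_attempts), call. = FALSE)
    }, character(1))
  })
  ids <- sprintf("region_%04d", seq_len(n_regions))
  names(seqs) <- ids
  structure(list(
    sequences = seqs,
    regions = data.frame(chrom = ids, start = 0L, end = lens,
                         region_id = ids, stringsAsFactors = FALSE),
    truth = .empty_truth(),
    params = list(n_regions = n_regions, region_length = region_length,
                  gc = gc, seed = seed)),
    class = "synthetic_peakset")
}

.empty_truth <- function() {
  data.frame(region_id = character(0), class_id = character(0),
             element_a = character(0), element_b = character(0),
             start = integer(0), strand = character(0),
             spacer_seq = character(0), stringsAsFactors = FALSE)
}

.has_any_composite <- function(seq, elements, classes) {
  occ <- lapply(elements, function(el) element_occurrences(seq, el))
  for (k in seq_len(nrow(classes))) {
    a <- occ[[classes$element_a[k]]]
    b <- occ[[classes$element_b[k]]]
    s <- classes$spacer_len[k]
    if (nrow(a) && nrow(b) &&
        (any(outer(a$end + s, b$start, "==")) ||
         any(outer(b$end + s, a$start, "==")))) {
      return(TRUE)
    }
  }
  FALSE
}

#' @export
print.synthetic_peakset <- function(x, ...) {
  cat(sprintf("<synthetic_peakset> %d regions, %d planted composite(s)\n",
              nrow(x$regions), nrow(x$truth)))
  invisible(x)
}

#' Plant composite motifs into a synthetic peak set
#'
#' Overwrites the sequence of randomly selected regions with one composite
#' each (`element_a` + spacer + `element_b`, optionally written as the
#' reverse complement to emulate minus-strand loci) at a uniform-random
#' valid offset, and records the ground truth. One plant per selected
#' region, so positive-region counts equal planted counts.
#'
#' @param peakset A [generate_background()] result.
#' @param element_a,element_b Elements of the planted class (default the
#'   ID-like pGC-SBE/SBE heterocomposite).
#' @param rate Fraction of regions to plant (`round(rate * n)` regions), or
#'   give `count` directly.
#' @param count Number of regions to plant (overrides `rate`).
#' @param spacer_len Spacer length (default 5).
#' @param linker_sampler Function `(len) -> string` drawing the spacer
#'   (default: uniform ACGT under the generator's RNG stream).
#' @param minus_strand Logical (recycled) or fraction in \[0, 1\]: plant the
#'   reverse complement of the composite.
#' @param seed Integer seed.
#' @return The updated `synthetic_peakset` with sequences overwritten and
#'   `truth` extended. Regions too short for the composite are skipped with
#'   a warning.
#' @export
plant_composites <- function(peakset, element_a = "pGC_SBE",
                             element_b = "SBE", rate = NULL, count = NULL,
                             spacer_len = 5L, linker_sampler = NULL,
                             minus_strand = FALSE, seed = 1L) {
  stopifnot(inherits(peakset, "synthetic_peakset"))
  ea <- .as_element(element_a)
  eb <- .as_element(element_b)
  n <- nrow(peakset$regions)
  if (is.null(count)) {
    if (is.null(rate)) stop("give rate or count", call. = FALSE)
    stopifnot(rate >= 0, rate <= 1)
    count <- round(rate * n)
  }
  stopifnot(count <= n)
  if (count == 0L) return(peakset)
  if (is.null(linker_sampler)) {
    linker_sampler <- function(len) {
      paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
    }
  }
  class_id <- .class_id(ea$id, eb$id, spacer_len)
  comp_len <- ea$length + spacer_len + eb$length
  truth_rows <- list()
  .with_seed(seed, {
    chosen <- sample.int(n, count)
    strand_flags <- if (is.numeric(minus_strand) && length(minus_strand) == 1L
                        && minus_strand > 0 && minus_strand < 1) {
      stats::runif(count) < minus_strand
    } else rep_len(as.logical(minus_strand), count)
    for (k in seq_along(chosen)) {
      i <- chosen[k]
      rid <- peakset$regions$region_id[i]
      len <- nchar(peakset$sequences[[rid]])
      if (len < comp_len) {
        warning(sprintf("region %s too short for composite, skipped", rid))
        next
      }
      offset <- sample.int(len - comp_len + 1L, 1L) - 1L
      spacer <- if (spacer_len > 0) linker_sampler(spacer_len) else ""
      composite <- paste0(ea$variants[1], spacer, eb$variants[1])
      written <- if (strand_flags[k]) reverse_complement(composite) else
        composite
      s <- peakset$sequences[[rid]]
      substr(s, offset + 1L, offset + comp_len) <- written
      peakset$sequences[[rid]] <- s
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        region_id = rid, class_id = class_id, element_a = ea$id,
        element_b = eb$id, start = offset,
        strand = if (strand_flags[k]) "minus" else "plus",
        spacer_seq = spacer, stringsAsFactors = FALSE)
    }
  })
  if (length(truth_rows)) {
    peakset$truth <- rbind(peakset$truth, do.call(rbind, truth_rows))
  }
  peakset$params$planted <- c(peakset$params$planted, list(list(
    class_id = class_id, count = count, seed = seed)))
  peakset
}

#' Sample synthetic 5-bp linkers with positional G enrichment
#'
#' i.i.d. uniform bases except at the boosted positions, where
#' `P(G) = g_prob` (the remaining probability split evenly) — emulating
#' guanine enrichment at spacer positions +2/+3.
#'
#' @param n Number of linkers.
#' @param positions Boosted positions (subset of `1:len`).
#' @param g_prob Guanine probability at boosted positions, in (0.25, 1].
#' @param len Linker length (default 5).
#' @param seed Integer seed.
#' @return Character vector of `n` linkers.
#' @export
sample_linkers <- function(n, positions = c(2L, 3L), g_prob = 0.6,
                           len = 5L, seed = 1L) {
  stopifnot(n >= 0, all(positions %in% seq_len(len)),
            g_prob > 0.25, g_prob <= 1)
  if (n == 0L) return(character(0))
  .with_seed(seed, {
    cols <- lapply(seq_len(len), function(p) {
      probs <- if (p %in% positions) {
        c(A = (1 - g_prob) / 3, C = (1 - g_prob) / 3, G = g_prob,
          T = (1 - g_prob) / 3)
      } else rep(0.25, 4)
      sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = probs)
    })
    do.call(paste0, cols)
  })
}

#' Simulate a noisy Hill binding curve
#'
#' Responses are [hill_model()] values plus Gaussian noise, clipped to
#' `[0, 1]` (fraction bound is a bounded quantity).
#'
#' @param bmax,kd,h Hill parameters.
#' @param concentrations Concentration series.
#' @param noise_sd Gaussian noise standard deviation (>= 0).
#' @param replicates Number of replicate series (points stacked).
#' @param seed Integer seed.
#' @return data.frame `concentration`, `fraction_bound`, `replicate`.
#' @export
simulate_binding_curve <- function(bmax, kd, h, concentrations,
                                   noise_sd = 0, replicates = 1L,
                                   seed = 1L) {
  stopifnot(noise_sd >= 0, replicates >= 1L)
  mu <- hill_model(concentrations, bmax, kd, h)
  .with_seed(seed, {
    do.call(rbind, lapply(seq_len(replicates), function(r) {
      y <- mu + stats::rnorm(length(mu), sd = noise_sd)
      data.frame(concentration = concentrations,
                 fraction_bound = pmin(1, pmax(0, y)),
                 replicate = r)
    }))
  })
}

#' Write a synthetic peak set to FASTA + BED + truth TSV + params JSON
#'
#' @param peakset A `synthetic_peakset`.
#' @param prefix Output path prefix; writes `<prefix>.fa`, `<prefix>.bed`,
#'   `<prefix>.truth.tsv`, `<prefix>.params.json`.
#' @return Invisibly, the named vector of written paths.
#' @export
write_peakset <- function(peakset, prefix) {
  stopifnot(inherits(peakset, "synthetic_peakset"))
  paths <- c(fasta = paste0(prefix, ".fa"), bed = paste0(prefix, ".bed"),
             truth = paste0(prefix, ".truth.tsv"),
             params = paste0(prefix, ".params.json"))
  write_fasta(peakset$sequences, paths["fasta"])
  bed <- peakset$regions[, c("chrom", "start", "end", "region_id")]
  utils::write.table(bed, paths["bed"], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  .write_tsv(peakset$truth, paths["truth"])
  jsonlite::write_json(peakset$params, paths["params"], auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(paths)
}
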