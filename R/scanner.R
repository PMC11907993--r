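# Composite-motif scanning and peak-region screening.

.mode_string <- function(modes) paste(modes, collapse = ",")

# Canonical composite class id: GC-rich elements listed first so ids are
# pair-order independent ("pGC_SBE+SBE/5" whichever way the pair is given).
.CLASS_ORDER <- c("pGC_SBE", "npGC_SBE", "FIVE_GC", "SBE", "pSBE")

.class_id <- function(a, b, spacer_len) {
  rank <- function(x) {
    r <- match(x, .CLASS_ORDER)
    ifelse(is.na(r), length(.CLASS_ORDER) + 1L, r)
  }
  swap <- rank(b) < rank(a) | (rank(b) == rank(a) & b < a)
  first <- ifelse(swap, b, a)
  second <- ifelse(swap, a, b)
  sprintf("%s+%s/%d", first, second, spacer_len)
}

.empty_hits <- function() {
  data.frame(up_element = character(0), up_start = integer(0),
             up_end = integer(0), up_strands = character(0),
             down_element = character(0), down_start = integer(0),
             down_end = integer(0), down_strands = character(0),
             spacer_len = integer(0), spacer_seq = character(0),
             modes = character(0), label = character(0),
             stringsAsFactors = FALSE)
}

# Pair two occurrence tables at fixed gaps; sequence is needed for spacers.
.pair_occurrences <- function(sequence, occ_up, occ_down, spacer_len) {
  out <- list()
  k <- 0L
  for (s in spacer_len) {
    if (nrow(occ_up) == 0L || nrow(occ_down) == 0L) next
    for (i in seq_len(nrow(occ_up))) {
      want_start <- occ_up$end[i] + s
      j <- which(occ_down$start == want_start)
      for (jj in j) {
        modes <- classify_binding_modes(occ_up$strands[i],
                                        occ_down$strands[jj])
        spacer <- if (s == 0L) "" else
          substr(sequence, occ_up$end[i] + 1L, occ_up$end[i] + s)
        k <- k + 1L
        out[[k]] <- data.frame(
          up_element = occ_up$element_id[i],
          up_start = occ_up$start[i], up_end = occ_up$end[i],
          up_strands = occ_up$strands[i],
          down_element = occ_down$element_id[jj],
          down_start = occ_down$start[jj], down_end = occ_down$end[jj],
          down_strands = occ_down$strands[jj],
          spacer_len = s, spacer_seq = spacer,
          modes = .mode_string(modes),
          label = predict_responsiveness(occ_up$element_id[i],
                                         occ_up$strands[i],
                                         occ_down$element_id[jj],
                                         occ_down$strands[jj], s),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (k == 0L) return(.empty_hits())
  do.call(rbind, out)
}

#' Scan a sequence for composite motifs
#'
#' Finds all ordered pairs of element instances separated by exactly
#' `spacer_len` intervening bases on the reference strand, together with the
#' spacer sequence, the achievable binding modes and the predicted
#' responsiveness label. By default pairs are unordered for heterocomposites
#' (both `A-N5-B` and `B-N5-A` arrangements are reported), matching how the
#' antisense heterocomposite `CAGAC-N5-GGCGCC` is detected.
#'
#' @param sequence A single DNA string.
#' @param element_a,element_b [binding_element()] objects or canonical ids.
#' @param spacer_len Non-negative integer spacer length(s); a vector scans
#'   several spacings in one pass.
#' @param ordered If `TRUE`, only `element_a` upstream of `element_b` is
#'   reported.
#' @return A data.frame of hits (one row per composite) with 0-based
#'   half-open coordinates, columns `up_element`, `up_start`, `up_end`,
#'   `up_strands`, `down_element`, `down_start`, `down_end`, `down_strands`,
#'   `spacer_len`, `spacer_seq`, `modes`, `label`, sorted by `up_start`.
#' @examples
#' scan_composites("AAGGCGCCAACTTGTCTGAA", "pGC_SBE", "SBE", 5)
#' @export
scan_composites <- function(sequence, element_a, element_b, spacer_len = 5L,
                            ordered = FALSE) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (any(spacer_len < 0)) stop("spacer_len must be >= 0", call. = FALSE)
  spacer_len <- as.integer(spacer_len)
  element_a <- .as_element(element_a)
  element_b <- .as_element(element_b)
  sequence <- toupper(sequence)
  occ_a <- element_occurrences(sequence, element_a)
  occ_b <- element_occurrences(sequence, element_b)
  hits <- .pair_occurrences(sequence, occ_a, occ_b, spacer_len)
  if (!ordered && element_a$id != element_b$id) {
    hits <- rbind(hits, .pair_occurrences(sequence, occ_b, occ_a, spacer_len))
  }
  key <- with(hits, paste(up_start, down_start, up_element, down_element,
                          spacer_len))
  hits <- hits[!duplicated(key), , drop = FALSE]
  hits <- hits[order(hits$up_start, hits$down_start, hits$spacer_len), ,
               drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Default composite class table
#'
#' All unordered element pairs (homo- and heterocomposites) from a registry,
#' at a fixed spacer length. Class ids read `A+B/spacer`.
#'
#' @param elements Named list of [binding_element()] objects.
#' @param spacer_len Spacer length in bp (default 5).
#' @return data.frame with columns `class_id`, `element_a`, `element_b`,
#'   `spacer_len`.
#' @export
composite_classes <- function(elements = canonical_elements(),
                              spacer_len = 5L) {
  ids <- names(elements)
  pairs <- expand.grid(a = seq_along(ids), b = seq_along(ids))
  pairs <- pairs[pairs$a <= pairs$b, , drop = FALSE]
  data.frame(
    class_id = .class_id(ids[pairs$a], ids[pairs$b], spacer_len),
    element_a = ids[pairs$a],
    element_b = ids[pairs$b],
    spacer_len = as.integer(spacer_len),
    stringsAsFactors = FALSE)
}

# Resolve region sequences from either a per-region set (names match
# region_id) or a genome set (names match chrom; substring extracted).
.region_sequence <- function(region, sequences) {
  if (!is.null(names(sequences)) && region$region_id %in% names(sequences)) {
    seq <- sequences[[region$region_id]]
    if (region$end - region$start == nchar(seq) && region$start == 0L) {
      return(seq)
    }
  }
  if (!region$chrom %in% names(sequences)) {
    stop(sprintf("chromosome '%s' not in sequence set", region$chrom),
         call. = FALSE)
  }
  chrom_seq <- sequences[[region$chrom]]
  if (region$start < 0L || region$end > nchar(chrom_seq)) {
    stop(sprintf("region %s [%d,%d) outside chromosome '%s' (length %d)",
                 region$region_id, region$start, region$end, region$chrom,
                 nchar(chrom_seq)), call. = FALSE)
  }
  substr(chrom_seq, region$start + 1L, region$end)
}

#' Screen peak regions for composite-motif positivity
#'
#' For every region and composite class, scans the region sequence for
#' composite hits; a region is positive for a class iff it carries at least
#' one hit of that class. This mirrors occurrence counting of composite
#' motif libraries over ChIP-seq peak BED files: per-class counts of
#' positive regions and fractions of the total are returned.
#'
#' @param regions data.frame with columns `chrom`, `start`, `end` and
#'   optionally `region_id` (see [read_bed()]); may be `NULL`, in which case
#'   every sequence in `sequences` is one region.
#' @param sequences Named character vector (or `DNAStringSet`) keyed either
#'   by region id (per-region sequences) or by chromosome (genome).
#' @param classes Composite class table, see [composite_classes()].
#' @param mask_lowercase If `TRUE`, soft-masked (lowercase) bases are
#'   replaced by `N` before scanning instead of being uppercased.
#' @return An object of class `screen_summary`: list with `class_summary`
#'   (class_id, n_positive, n_total, fraction_positive), `region_table`
#'   (long region x class positivity), `hits` (all hits with `region_id`
#'   and genome-absolute coordinates) and `excluded` (per-region error
#'   records for unresolvable regions).
#' @export
screen_regions <- function(regions, sequences,
                           classes = composite_classes(),
                           mask_lowercase = FALSE) {
  if (methods::is(sequences, "DNAStringSet")) {
    sequences <- as.character(sequences)
  }
  stopifnot(is.character(sequences), !is.null(names(sequences)))
  if (is.null(regions)) {
    regions <- data.frame(chrom = names(sequences), start = 0L,
                          end = nchar(sequences),
                          region_id = names(sequences),
                          stringsAsFactors = FALSE)
  }
  if (is.null(regions$region_id)) {
    regions$region_id <- sprintf("%s:%d-%d", regions$chrom, regions$start,
                                 regions$end)
  }
  stopifnot(nrow(classes) >= 1L)
  registry <- canonical_elements()
  needed <- unique(c(classes$element_a, classes$element_b))
  elements <- lapply(needed, .as_element, registry = registry)
  names(elements) <- needed

  region_rows <- list()
  hit_rows <- list()
  excluded <- list()
  for (i in seq_len(nrow(regions))) {
    region <- regions[i, , drop = FALSE]
    seq <- tryCatch(.region_sequence(region, sequences), error = identity)
    if (inherits(seq, "error")) {
      excluded[[length(excluded) + 1L]] <- data.frame(
        region_id = region$region_id, reason = conditionMessage(seq),
        stringsAsFactors = FALSE)
      next
    }
    if (mask_lowercase) {
      seq <- gsub("[acgtn]", "N", seq)
    }
    seq <- toupper(seq)
    occ <- lapply(elements, function(el) element_occurrences(seq, el))
    for (k in seq_len(nrow(classes))) {
      cls <- classes[k, ]
      hits <- .pair_occurrences(seq, occ[[cls$element_a]],
                                occ[[cls$element_b]], cls$spacer_len)
      if (cls$element_a != cls$element_b) {
        hits <- rbind(hits, .pair_occurrences(seq, occ[[cls$element_b]],
                                              occ[[cls$element_a]],
                                              cls$spacer_len))
      }
      region_rows[[length(region_rows) + 1L]] <- data.frame(
        region_id = region$region_id, class_id = cls$class_id,
        n_hits = nrow(hits), positive = nrow(hits) > 0L,
        stringsAsFactors = FALSE)
      if (nrow(hits) > 0L) {
        hits <- cbind(region_id = region$region_id, class_id = cls$class_id,
                      hits, stringsAsFactors = FALSE)
        hits$up_start_abs <- hits$up_start + region$start
        hits$down_end_abs <- hits$down_end + region$start
        hit_rows[[length(hit_rows) + 1L]] <- hits
      }
    }
  }
  region_table <- if (length(region_rows)) do.call(rbind, region_rows) else
    data.frame(region_id = character(0), class_id = character(0),
               n_hits = integer(0), positive = logical(0))
  n_total <- nrow(regions) - length(excluded)
  class_summary <- do.call(rbind, lapply(seq_len(nrow(classes)), function(k) {
    sub <- region_table[region_table$class_id == classes$class_id[k], ]
    n_pos <- sum(sub$positive)
    data.frame(class_id = classes$class_id[k],
               element_a = classes$element_a[k],
               element_b = classes$element_b[k],
               spacer_len = classes$spacer_len[k],
               n_positive = n_pos, n_total = n_total,
               fraction_positive = if (n_total > 0) n_pos / n_total else NA_real_,
               stringsAsFactors = FALSE)
  }))
  structure(list(
    class_summary = class_summary,
    region_table = region_table,
    hits = if (length(hit_rows)) do.call(rbind, hit_rows) else
      cbind(data.frame(region_id = character(0), class_id = character(0)),
            .empty_hits(),
            data.frame(up_start_abs = integer(0), down_end_abs = integer(0))),
    excluded = if (length(excluded)) do.call(rbind, excluded) else
      data.frame(region_id = character(0), reason = character(0))),
    class = "screen_summary")
}

#' @export
print.screen_summary <- function(x, ...) {
  cat(sprintf("<screen_summary> %d regions x %d classes, %d hits",
              max(x$class_summary$n_total, 0), nrow(x$class_summary),
              nrow(x$hits)))
  if (nrow(x$excluded) > 0) cat(sprintf(", %d excluded", nrow(x$excluded)))
  cat("\n")
  pos <- x$class_summary[x$class_summary$n_positive > 0, ]
  if (nrow(pos)) print(pos[, c("class_id", "n_positive", "n_total",
                               "fraction_positive")], row.names = FALSE)
  invisible(x)
}

#' Aggregate screens across datasets into a long table
#'
#' @param summaries Named list of `screen_summary` objects (names are
#'   dataset ids; duplicates are rejected).
#' @return data.frame with columns `dataset`, `class_id`, `n_positive`,
#'   `n_total`, `fraction_positive`; one `all_classes` totals row per
#'   dataset counting regions positive for at least one class.
#' @export
summarize_screen <- function(summaries) {
  stopifnot(is.list(summaries), length(summaries) >= 1L)
  ids <- names(summaries)
  if (is.null(ids) || any(!nzchar(ids))) {
    stop("summaries must be a named list (dataset ids)", call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate dataset id '%s'", ids[duplicated(ids)][1]),
         call. = FALSE)
  }
  rows <- lapply(ids, function(id) {
    s <- summaries[[id]]
    stopifnot(inherits(s, "screen_summary"))
    cs <- s$class_summary
    rt <- s$region_table
    any_pos <- if (nrow(rt)) sum(tapply(rt$positive, rt$region_id, any)) else 0L
    n_total <- if (nrow(cs)) cs$n_total[1] else 0L
    rbind(
      data.frame(dataset = id, class_id = cs$class_id,
                 n_positive = cs$n_positive, n_total = cs$n_total,
                 fraction_positive = cs$fraction_positive,
                 stringsAsFactors = FALSE),
      data.frame(dataset = id, class_id = "all_classes",
                 n_positive = as.integer(any_pos), n_total = n_total,
                 fraction_positive = if (n_total > 0) any_pos / n_total
                 else NA_real_,
                 stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
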