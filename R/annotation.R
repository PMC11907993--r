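# Functional genomic-region assignment and abundance-normalized enrichment.

.DEFAULT_PRECEDENCE <- c("promoter", "utr", "exon", "intron", "intergenic")

# Minimal half-open interval arithmetic on two-column matrices (start, end).
.merge_intervals <- function(m) {
  if (nrow(m) == 0L) return(m)
  m <- m[order(m[, 1], m[, 2]), , drop = FALSE]
  out <- m[1, , drop = FALSE]
  for (i in seq_len(nrow(m))[-1]) {
    last <- nrow(out)
    if (m[i, 1] <= out[last, 2]) {
      out[last, 2] <- max(out[last, 2], m[i, 2])
    } else {
      out <- rbind(out, m[i, , drop = FALSE])
    }
  }
  out
}

.subtract_intervals <- function(m, sub) {
  # m minus sub; both merged half-open interval matrices
  if (nrow(m) == 0L || nrow(sub) == 0L) return(m)
  pieces <- list()
  for (i in seq_len(nrow(m))) {
    s <- m[i, 1]; e <- m[i, 2]
    cur <- s
    for (j in seq_len(nrow(sub))) {
      if (sub[j, 2] <= cur || sub[j, 1] >= e) next
      if (sub[j, 1] > cur) {
        pieces[[length(pieces) + 1L]] <- c(cur, sub[j, 1])
      }
      cur <- max(cur, sub[j, 2])
    }
    if (cur < e) pieces[[length(pieces) + 1L]] <- c(cur, e)
  }
  if (length(pieces) == 0L) return(m[0, , drop = FALSE])
  do.call(rbind, pieces)
}

.interval_width <- function(m) if (nrow(m) == 0L) 0 else sum(m[, 2] - m[, 1])

#' Build an annotation model from class intervals and TSS positions
#'
#' Assembles the per-class interval sets used to classify peak regions into
#' functional genomic classes, and computes each class's share of the
#' genome. Promoter intervals are derived from TSS positions with a
#' configurable window (default -1000..+100 bp, strand-aware). Genomic
#' shares are computed with precedence flattening (promoter > utr > exon >
#' intron), the remainder being intergenic, so shares sum to 1.
#'
#' @param features data.frame with columns `chrom`, `start`, `end`, `class`
#'   (0-based half-open; classes among `utr`, `exon`, `intron`; may be
#'   empty).
#' @param tss data.frame with columns `chrom`, `pos` and optionally `strand`
#'   (`+`/`-`), or `NULL` for no promoters.
#' @param chrom_sizes Named numeric vector of chromosome lengths.
#' @param promoter_window Length-2 vector: offsets of the promoter interval
#'   relative to the TSS on its own strand (default `c(-1000, 100)`).
#' @param precedence Class precedence, highest first.
#' @return An object of class `annotation_model` with per-class interval
#'   lists and `class_genomic_share`.
#' @export
annotation_model <- function(features, tss = NULL, chrom_sizes,
                             promoter_window = c(-1000, 100),
                             precedence = .DEFAULT_PRECEDENCE) {
  stopifnot(is.numeric(chrom_sizes), !is.null(names(chrom_sizes)))
  if (is.null(features)) {
    features <- data.frame(chrom = character(0), start = numeric(0),
                           end = numeric(0), class = character(0))
  }
  stopifnot(all(c("chrom", "start", "end", "class") %in% names(features)))
  if (nrow(features) && any(features$end <= features$start)) {
    stop("feature intervals must satisfy end > start", call. = FALSE)
  }
  feats <- features
  if (!is.null(tss) && nrow(tss) > 0) {
    strand <- if ("strand" %in% names(tss)) tss$strand else "+"
    strand <- rep_len(strand, nrow(tss))
    pstart <- ifelse(strand == "+", tss$pos + promoter_window[1],
                     tss$pos - promoter_window[2])
    pend <- ifelse(strand == "+", tss$pos + promoter_window[2],
                   tss$pos - promoter_window[1])
    prom <- data.frame(chrom = tss$chrom, start = pmax(0, pstart),
                       end = pend, class = "promoter",
                       stringsAsFactors = FALSE)
    prom <- prom[prom$end > prom$start, , drop = FALSE]
    feats <- rbind(feats[, c("chrom", "start", "end", "class")], prom)
  }
  unknown <- setdiff(unique(feats$class), precedence)
  if (length(unknown) > 0) {
    stop(sprintf("feature class '%s' not in precedence order", unknown[1]),
         call. = FALSE)
  }
  if (nrow(feats) && !all(feats$chrom %in% names(chrom_sizes))) {
    stop("feature chromosome missing from chrom_sizes", call. = FALSE)
  }
  # clip to chromosome bounds
  if (nrow(feats)) {
    feats$end <- pmin(feats$end, chrom_sizes[feats$chrom])
    feats <- feats[feats$end > feats$start, , drop = FALSE]
  }
  genome_size <- sum(chrom_sizes)
  classes <- setdiff(precedence, "intergenic")
  shares <- stats::setNames(numeric(length(classes)), classes)
  covered <- lapply(names(chrom_sizes), function(ch) {
    matrix(numeric(0), ncol = 2)
  })
  names(covered) <- names(chrom_sizes)
  for (cls in classes) {
    sub <- feats[feats$class == cls, , drop = FALSE]
    w <- 0
    for (ch in unique(sub$chrom)) {
      m <- .merge_intervals(as.matrix(sub[sub$chrom == ch, c("start", "end")]))
      m <- .subtract_intervals(m, covered[[ch]])
      w <- w + .interval_width(m)
      covered[[ch]] <- .merge_intervals(rbind(covered[[ch]], m))
    }
    shares[cls] <- w / genome_size
  }
  shares <- c(shares, intergenic = 1 - sum(shares))
  structure(list(features = feats,
                 chrom_sizes = chrom_sizes,
                 precedence = precedence,
                 promoter_window = promoter_window,
                 class_genomic_share = shares),
            class = "annotation_model")
}

#' @export
print.annotation_model <- function(x, ...) {
  cat(sprintf("<annotation_model> %d features on %d chromosomes\n",
              nrow(x$features), length(x$chrom_sizes)))
  print(round(x$class_genomic_share, 4))
  invisible(x)
}

#' Classify regions into functional genomic classes
#'
#' Assigns each region the class of the feature interval containing its
#' midpoint (the convention used by peak-annotation tools), ties broken by
#' the model's precedence order (promoter > utr > exon > intron); midpoints
#' covered by no feature are intergenic. With `by = "any"`, any overlap of
#' the full region counts instead of the midpoint.
#'
#' @param regions data.frame with columns `chrom`, `start`, `end` and
#'   optionally `region_id`.
#' @param model An [annotation_model()].
#' @param by `"midpoint"` (default) or `"any"`.
#' @return data.frame `region_id`, `chrom`, `midpoint`, `class`; regions on
#'   chromosomes absent from the model are returned with class `NA` and an
#'   `error` message column entry.
#' @export
classify_regions <- function(regions, model, by = c("midpoint", "any")) {
  by <- match.arg(by)
  stopifnot(inherits(model, "annotation_model"))
  if (is.null(regions$region_id)) {
    regions$region_id <- sprintf("%s:%d-%d", regions$chrom, regions$start,
                                 regions$end)
  }
  feats <- model$features
  out <- lapply(seq_len(nrow(regions)), function(i) {
    r <- regions[i, ]
    mid <- floor((r$start + r$end) / 2)
    if (!r$chrom %in% names(model$chrom_sizes)) {
      return(data.frame(region_id = r$region_id, chrom = r$chrom,
                        midpoint = mid, class = NA_character_,
                        error = sprintf("unknown chromosome '%s'", r$chrom),
                        stringsAsFactors = FALSE))
    }
    sub <- feats[feats$chrom == r$chrom, , drop = FALSE]
    hit <- if (by == "midpoint") {
      sub$start <= mid & mid < sub$end
    } else {
      sub$start < r$end & r$start < sub$end
    }
    cls <- if (any(hit)) {
      hits <- unique(sub$class[hit])
      model$precedence[min(match(hits, model$precedence))]
    } else "intergenic"
    data.frame(region_id = r$region_id, chrom = r$chrom, midpoint = mid,
               class = cls, error = NA_character_, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Class distribution of positive regions, normalized by genomic abundance
#'
#' Computes the raw percentage of composite-positive regions per functional
#' class and divides it by the class's share of the genome, so a class
#' hosting positives exactly in proportion to its genomic abundance scores
#' an enrichment of 1. Enrichments are also rescaled to sum to 100%
#' (`normalized_pct`) for plotting.
#'
#' @param region_classes Output of [classify_regions()] on the positive
#'   regions (rows with `NA` class are dropped with a warning).
#' @param model The [annotation_model()] that classified them.
#' @return data.frame `class`, `n`, `raw_pct`, `genomic_share`,
#'   `enrichment`, `normalized_pct` for classes with at least one positive.
#' @export
normalized_distribution <- function(region_classes, model) {
  stopifnot(inherits(model, "annotation_model"))
  rc <- region_classes[!is.na(region_classes$class), , drop = FALSE]
  if (nrow(rc) < nrow(region_classes)) {
    warning(sprintf("%d region(s) dropped (unclassifiable)",
                    nrow(region_classes) - nrow(rc)))
  }
  if (nrow(rc) == 0L) stop("no classified positive regions", call. = FALSE)
  counts <- table(rc$class)
  classes <- names(counts)
  shares <- model$class_genomic_share[classes]
  if (any(is.na(shares) | shares <= 0)) {
    stop("positive regions in a class with zero genomic share", call. = FALSE)
  }
  raw_pct <- 100 * as.numeric(counts) / sum(counts)
  enrichment <- (raw_pct / 100) / shares
  data.frame(class = classes,
             n = as.integer(counts),
             raw_pct = raw_pct,
             genomic_share = as.numeric(shares),
             enrichment = as.numeric(enrichment),
             normalized_pct = 100 * as.numeric(enrichment) / sum(enrichment),
             stringsAsFactors = FALSE, row.names = NULL)
}
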