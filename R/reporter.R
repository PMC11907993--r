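# Synthetic luciferase reporter insert library.

#' Minimal adenoviral major late promoter (MLP) sequence
#'
#' The minimal promoter placed downstream of every motif cassette.
#' @return The MLP as a DNA string.
#' @export
mlp_sequence <- function() {
  "GGGCTATAAAAGGGGGTGGGGGCGCGTTCGTCCTCACTCTCTTCC"
}

# Restriction-site context: KpnI upstream of the cassette; the 10-bp
# motif-to-MLP gap is the overlapping XhoI/BglII junction CTCGAG+ATCT.
.KPNI <- "GGTACC"
.MLP_JUNCTION <- "CTCGAGATCT"

#' Named linker sequences used in the heterocomposite reporters
#'
#' The native 5-bp linkers of the ID1/ID2/ID3 loci plus the synthetic
#' GC-poor control linker.
#' @return Named character vector (`ID1`, `ID2`, `ID3`, `CTRL`).
#' @export
named_linkers <- function() {
  c(ID1 = "TGGCT", ID2 = "AGAGA", ID3 = "AGGCT", CTRL = "AACTT")
}

#' Generate a GC-poor spacer sequence
#'
#' Spacer rule for unnamed linkers: bases drawn from A/T, with a single C
#' placed at a random position for spacers of 4 bp or more (so no spacer
#' ever contains a G or more than one C, and cannot create a SMAD element).
#' Draws from the current RNG stream; seed at the call site for
#' reproducibility.
#'
#' @param len Spacer length (>= 0).
#' @return A DNA string of length `len`.
#' @export
gc_poor_spacer <- function(len) {
  stopifnot(len >= 0)
  if (len == 0L) return("")
  bases <- sample(c("A", "T"), len, replace = TRUE)
  if (len >= 4L) bases[sample.int(len, 1L)] <- "C"
  paste(bases, collapse = "")
}

.is_gc_poor <- function(spacer) {
  !grepl("G", spacer) && lengths(regmatches(spacer, gregexpr("C", spacer))) <= 1L
}

#' Assemble a motif cassette
#'
#' @param elements Character vector of element ids (canonical, or arbitrary
#'   ids when `sequences` is supplied).
#' @param orientations `"sense"` or `"antisense"` per motif (recycled).
#' @param sequences Optional explicit sense sequences per motif (needed for
#'   non-canonical elements such as single-nucleotide permutation variants).
#' @return data.frame `element_id`, `sequence`, `orientation`.
#' @export
reporter_cassette <- function(elements, orientations = "sense",
                              sequences = NULL) {
  stopifnot(length(elements) >= 1L)
  orientations <- rep_len(orientations, length(elements))
  stopifnot(all(orientations %in% c("sense", "antisense")))
  if (is.null(sequences)) {
    registry <- canonical_elements()
    sequences <- vapply(elements, function(id) {
      .as_element(id, registry)$sequence[1]
    }, character(1))
  }
  data.frame(element_id = elements, sequence = toupper(sequences),
             orientation = orientations, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Build a reporter insert from a cassette specification
#'
#' Deterministic assembly: KpnI site, the motif cassette (motifs written
#' sense or antisense, separated by the given spacers), the 10-bp
#' overlapping XhoI/BglII junction, and the MLP. The distance from the
#' MLP-proximal motif's end to the MLP start is therefore exactly 10 bp.
#' Spacers must be named linkers or GC-poor (no G, at most one C).
#'
#' @param cassette A [reporter_cassette()] data.frame.
#' @param spacers Character vector of inter-motif spacer sequences (length
#'   `nrow(cassette) - 1`); entries may be names from [named_linkers()].
#' @param construct_id Construct identifier.
#' @param series Series tag (which design series the construct belongs to).
#' @param params Optional list of series parameters kept as provenance.
#' @param synthesis_limit Maximum insert length in bp (default 300).
#' @return An object of class `reporter_construct` with the full insert
#'   `sequence`.
#' @examples
#' cas <- reporter_cassette(c("pGC_SBE", "SBE"))
#' build_insert(cas, spacers = "AACTT", construct_id = "IDL")
#' @export
build_insert <- function(cassette, spacers = character(0), construct_id,
                         series = "custom", params = list(),
                         synthesis_limit = 300L) {
  stopifnot(is.data.frame(cassette), nrow(cassette) >= 1L)
  n <- nrow(cassette)
  if (length(spacers) != n - 1L) {
    stop(sprintf("need %d spacer(s) for %d motifs", n - 1L, n), call. = FALSE)
  }
  nl <- named_linkers()
  spacers <- vapply(spacers, function(s) {
    if (s %in% names(nl)) return(nl[[s]])
    s <- toupper(s)
    if (s %in% nl) return(s)
    if (!grepl("^[ACGT]*$", s)) {
      stop(sprintf("unknown linker name or non-DNA spacer '%s'", s),
           call. = FALSE)
    }
    if (!.is_gc_poor(s)) {
      stop(sprintf("spacer '%s' is neither a named linker nor GC-poor", s),
           call. = FALSE)
    }
    s
  }, character(1), USE.NAMES = FALSE)
  motif_seqs <- ifelse(cassette$orientation == "antisense",
                       reverse_complement(cassette$sequence),
                       cassette$sequence)
  cassette_seq <- motif_seqs[1]
  if (n > 1L) {
    for (i in 2:n) {
      cassette_seq <- paste0(cassette_seq, spacers[i - 1L], motif_seqs[i])
    }
  }
  insert <- paste0(.KPNI, cassette_seq, .MLP_JUNCTION, mlp_sequence())
  if (nchar(insert) > synthesis_limit) {
    stop(sprintf("insert of %d bp exceeds synthesis limit %d",
                 nchar(insert), synthesis_limit), call. = FALSE)
  }
  n_mlp <- lengths(regmatches(insert, gregexpr(mlp_sequence(), insert,
                                               fixed = TRUE)))
  if (n_mlp != 1L) {
    stop("MLP sequence must appear exactly once in the insert", call. = FALSE)
  }
  gap <- regexpr(mlp_sequence(), insert, fixed = TRUE)[1] - 1L -
    (nchar(.KPNI) + nchar(cassette_seq))
  stopifnot(gap == 10L)
  structure(list(construct_id = construct_id, series = series,
                 params = params, cassette = cassette, spacers = spacers,
                 spacer_to_mlp = 10L, sequence = insert),
            class = "reporter_construct")
}

#' @export
print.reporter_construct <- function(x, ...) {
  cat(sprintf("<reporter_construct> %s [%s]: %d motif(s), %d bp\n",
              x$construct_id, x$series, nrow(x$cassette), nchar(x$sequence)))
  invisible(x)
}

#' Default reporter library design space
#'
#' The series of the construct library: a 3-motif pGC-SBE spacing grid
#' (linker a x linker b), homotypic orientation sets for npGC-SBE, SBE and
#' pSBE, a pGC-SBE copy-number series (1-6 motifs, 5-bp spacers), the
#' ID-linker heterocomposite variants, the heterocomposite orientation
#' variants, and the single-nucleotide pGC-SBE permutation series.
#'
#' @return A config list consumed by [enumerate_library()]. Set any entry
#'   to `NULL`/empty to drop a series.
#' @export
library_config <- function() {
  list(
    spacing_a = c(2L, 3L, 4L, 5L, 6L, 10L, 20L),
    spacing_b = c(2L, 3L, 4L, 5L, 6L, 10L, 20L),
    orientation_elements = c("npGC_SBE", "SBE", "pSBE"),
    copy_numbers = 1:6,
    id_linkers = c("ID1", "ID2", "ID3", "CTRL"),
    hetero_orientations = c("sense", "sbe_antisense", "full_antisense"),
    permutation_positions = 1:6,
    permutation_bases = c("A", "C", "G", "T")
  )
}

#' Enumerate the reporter construct library
#'
#' Builds every construct of the configured design series with
#' seed-reproducible GC-poor spacers. Construct ids are unique by
#' construction (duplicates are an error).
#'
#' @param config Design space, see [library_config()]; an empty list yields
#'   an empty library.
#' @param seed Integer seed for the GC-poor spacer draws.
#' @return An object of class `reporter_library`: list of
#'   `reporter_construct`s plus a `manifest` data.frame (`construct_id`,
#'   `series`, `n_motifs`, `param_a`, `param_b`, `linker`, `variant`,
#'   `insert_length`, `sequence`).
#' @export
enumerate_library <- function(config = library_config(), seed = 1L) {
  constructs <- list()
  add <- function(x) constructs[[length(constructs) + 1L]] <<- x
  .with_seed(seed, {
    pgc <- "pGC_SBE"
    # 3-motif pGC spacing grid
    for (a in config$spacing_a) {
      for (b in config$spacing_b) {
        cas <- reporter_cassette(rep(pgc, 3))
        add(build_insert(cas, spacers = c(gc_poor_spacer(a),
                                          gc_poor_spacer(b)),
                         construct_id = sprintf("spacing_a%02d_b%02d", a, b),
                         series = "spacing", params = list(a = a, b = b)))
      }
    }
    # homotypic orientation series (palindromic pSBE has one orientation)
    for (el in config$orientation_elements) {
      pal <- is_palindromic(.as_element(el))
      combos <- if (pal) list(c("sense", "sense")) else
        list(c("sense", "sense"), c("sense", "antisense"),
             c("antisense", "sense"), c("antisense", "antisense"))
      for (ori in combos) {
        tag <- paste0(substr(ori[1], 1, 1), substr(ori[2], 1, 1))
        cas <- reporter_cassette(rep(el, 2), orientations = ori)
        add(build_insert(cas, spacers = gc_poor_spacer(5L),
                         construct_id = sprintf("orientation_%s_%s", el, tag),
                         series = "orientation",
                         params = list(element = el, orientation = tag)))
      }
    }
    # pGC copy-number series, 5-bp spacers
    for (n in config$copy_numbers) {
      cas <- reporter_cassette(rep(pgc, n))
      spc <- if (n > 1) vapply(seq_len(n - 1), function(i) gc_poor_spacer(5L),
                               character(1)) else character(0)
      add(build_insert(cas, spacers = spc,
                       construct_id = sprintf("copy_number_%d", n),
                       series = "copy_number", params = list(n = n)))
    }
    # ID-linker heterocomposite series
    for (lk in config$id_linkers) {
      cas <- reporter_cassette(c(pgc, "SBE"))
      add(build_insert(cas, spacers = lk,
                       construct_id = sprintf("id_linker_%s", lk),
                       series = "id_linker", params = list(linker = lk)))
    }
    # heterocomposite orientation series
    for (variant in config$hetero_orientations) {
      cas <- switch(variant,
        sense = reporter_cassette(c(pgc, "SBE")),
        sbe_antisense = reporter_cassette(c(pgc, "SBE"),
                                          orientations = c("sense",
                                                           "antisense")),
        full_antisense = reporter_cassette(c("SBE", pgc),
                                           orientations = c("antisense",
                                                            "sense")),
        stop(sprintf("unknown heterocomposite orientation '%s'", variant),
             call. = FALSE))
      add(build_insert(cas, spacers = gc_poor_spacer(5L),
                       construct_id = sprintf("hetero_%s", variant),
                       series = "hetero_orientation",
                       params = list(variant = variant)))
    }
    # single-nucleotide pGC permutation series
    ref <- .as_element(pgc)$sequence[1]
    for (pos in config$permutation_positions) {
      for (base in setdiff(config$permutation_bases,
                           substr(ref, pos, pos))) {
        mut <- ref
        substr(mut, pos, pos) <- base
        mid <- sprintf("pGC_mut_%d%s", pos, base)
        cas <- reporter_cassette(c(mid, "SBE"),
                                 sequences = c(mut, "GTCTG"))
        add(build_insert(cas, spacers = gc_poor_spacer(5L),
                         construct_id = sprintf("permutation_%d%s", pos, base),
                         series = "permutation",
                         params = list(position = pos, base = base)))
      }
    }
  })
  ids <- vapply(constructs, `[[`, character(1), "construct_id")
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate construct_id '%s'", ids[duplicated(ids)][1]),
         call. = FALSE)
  }
  manifest <- do.call(rbind, lapply(constructs, function(x) {
    p <- x$params
    data.frame(construct_id = x$construct_id, series = x$series,
               n_motifs = nrow(x$cassette),
               param_a = if (!is.null(p$a)) p$a else
                 if (!is.null(p$n)) p$n else
                 if (!is.null(p$position)) p$position else NA_integer_,
               param_b = if (!is.null(p$b)) p$b else NA_integer_,
               linker = if (!is.null(p$linker)) p$linker else NA_character_,
               variant = if (!is.null(p$variant)) p$variant else
                 if (!is.null(p$orientation)) p$orientation else
                 if (!is.null(p$base)) p$base else
                 if (!is.null(p$element)) p$element else NA_character_,
               insert_length = nchar(x$sequence),
               sequence = x$sequence, stringsAsFactors = FALSE)
  }))
  if (!is.null(manifest)) {
    # variant column for the orientation series needs both element and code
    ori <- manifest$series == "orientation"
    if (any(ori)) {
      els <- vapply(constructs[ori], function(x) x$params$element, character(1))
      codes <- vapply(constructs[ori], function(x) x$params$orientation,
                      character(1))
      manifest$variant[ori] <- paste(els, codes, sep = ":")
    }
  } else {
    manifest <- data.frame(construct_id = character(0), series = character(0),
                           n_motifs = integer(0), param_a = integer(0),
                           param_b = integer(0), linker = character(0),
                           variant = character(0), insert_length = integer(0),
                           sequence = character(0))
  }
  names(constructs) <- ids
  structure(list(constructs = constructs, manifest = manifest, seed = seed),
            class = "reporter_library")
}

#' @export
print.reporter_library <- function(x, ...) {
  cat(sprintf("<reporter_library> %d constructs\n", length(x$constructs)))
  print(table(x$manifest$series))
  invisible(x)
}

# Strand availability of a cassette motif as a composite-grammar strand set.
.cassette_strands <- function(sequence, orientation) {
  pal <- is_palindromic(sequence)
  if (pal) "both" else if (orientation == "sense") "plus" else "minus"
}

.best_bmp <- function(labels) {
  if ("BMP_responsive" %in% labels) "BMP_responsive"
  else if ("BMP_responsive_weak" %in% labels) "BMP_responsive_weak"
  else "nonresponsive"
}

#' Predicted responsiveness labels for a construct library
#'
#' Applies the composite-grammar responsiveness predicate to every pair of
#' adjacent motifs in each construct; a construct is BMP-responsive iff at
#' least one adjacent pair is (the strongest pair label wins), and
#' TGF-beta-responsive iff an adjacent pSBE pair at 5-bp spacing exists.
#'
#' @param library A [enumerate_library()] result (or a list of
#'   `reporter_construct`s).
#' @return data.frame `construct_id`, `series`, `bmp_label`, `tgfb`.
#' @export
label_library <- function(library) {
  constructs <- if (inherits(library, "reporter_library")) {
    library$constructs
  } else library
  rows <- lapply(constructs, function(x) {
    cas <- x$cassette
    pair_labels <- character(0)
    if (nrow(cas) > 1L) {
      for (i in seq_len(nrow(cas) - 1L)) {
        up <- cas[i, ]; down <- cas[i + 1L, ]
        pair_labels <- c(pair_labels, predict_responsiveness(
          up$element_id, .cassette_strands(up$sequence, up$orientation),
          down$element_id, .cassette_strands(down$sequence, down$orientation),
          nchar(x$spacers[i])))
      }
    }
    data.frame(construct_id = x$construct_id, series = x$series,
               bmp_label = .best_bmp(pair_labels),
               tgfb = "TGFB_responsive" %in% pair_labels,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Qualitative reporter-assay outcomes expected per construct
#'
#' The rule table distilled from the dual-luciferase series: 3-motif
#' spacing constructs respond to BMP iff one linker is 5 bp; homotypic
#' npGC-SBE/SBE orientations never respond and the 5-bp pSBE pair responds
#' to TGF-beta only; copy-number constructs respond from two motifs up;
#' all four ID-linker heterocomposites respond; of the heterocomposite
#' orientations, sense responds, the SBE-antisense arrangement does not,
#' and the fully antisense arrangement responds weakly; every
#' single-nucleotide pGC-SBE permutation loses full responsiveness
#' (`non_strong`). This table is derived from the assay outcomes, not from
#' the grammar predictor, so comparing the two is a genuine cross-check.
#'
#' @param library A [enumerate_library()] result.
#' @return data.frame `construct_id`, `expected_bmp` (one of `responsive`,
#'   `weak`, `none`, `non_strong`), `expected_tgfb` (logical).
#' @export
expected_library_outcomes <- function(library) {
  m <- library$manifest
  expected_bmp <- character(nrow(m))
  expected_tgfb <- logical(nrow(m))
  for (i in seq_len(nrow(m))) {
    expected_bmp[i] <- switch(m$series[i],
      spacing = if (m$param_a[i] == 5L || m$param_b[i] == 5L) "responsive"
                else "none",
      orientation = "none",
      copy_number = if (m$param_a[i] >= 2L) "responsive" else "none",
      id_linker = "responsive",
      hetero_orientation = switch(m$variant[i],
                                  sense = "responsive",
                                  sbe_antisense = "none",
                                  full_antisense = "weak"),
      permutation = "non_strong",
      "none")
    expected_tgfb[i] <- m$series[i] == "orientation" &&
      startsWith(m$variant[i], "pSBE")
  }
  data.frame(construct_id = m$construct_id, expected_bmp = expected_bmp,
             expected_tgfb = expected_tgfb, stringsAsFactors = FALSE)
}

#' Consistency report: predicted labels vs expected assay outcomes
#'
#' @param library A [enumerate_library()] result.
#' @return data.frame per construct with predicted and expected outcomes
#'   and an `agree` flag; the overall agreement fraction is attached as
#'   attribute `"agreement"`.
#' @export
check_library <- function(library) {
  pred <- label_library(library)
  exp <- expected_library_outcomes(library)
  stopifnot(identical(pred$construct_id, exp$construct_id))
  pred_bmp <- c(BMP_responsive = "responsive", BMP_responsive_weak = "weak",
                TGFB_responsive = "none",
                nonresponsive = "none")[pred$bmp_label]
  agree <- vapply(seq_len(nrow(pred)), function(i) {
    bmp_ok <- if (exp$expected_bmp[i] == "non_strong") {
      pred_bmp[i] %in% c("weak", "none")
    } else identical(unname(pred_bmp[i]), exp$expected_bmp[i])
    bmp_ok && pred$tgfb[i] == exp$expected_tgfb[i]
  }, logical(1))
  out <- data.frame(construct_id = pred$construct_id, series = pred$series,
                    predicted_bmp = unname(pred_bmp),
                    predicted_tgfb = pred$tgfb,
                    expected_bmp = exp$expected_bmp,
                    expected_tgfb = exp$expected_tgfb,
                    agree = agree, stringsAsFactors = FALSE)
  attr(out, "agreement") <- mean(agree)
  out
}

#' Write library inserts as multi-FASTA plus a TSV manifest
#'
#' @param library A [enumerate_library()] result.
#' @param fasta_path,manifest_path Output paths.
#' @return Invisibly, the manifest data.frame (with labels).
#' @export
write_library <- function(library, fasta_path, manifest_path) {
  labels <- label_library(library)
  m <- merge(library$manifest, labels[, c("construct_id", "bmp_label",
                                          "tgfb")], by = "construct_id",
             sort = FALSE)
  seqs <- stats::setNames(m$sequence, m$construct_id)
  write_fasta(seqs, fasta_path)
  utils::write.table(m, manifest_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(m)
}
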