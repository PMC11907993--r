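# SMAD binding elements and IUPAC sequence utilities.

.IUPAC <- Biostrings::IUPAC_CODE_MAP

.STRAND_LEVELS <- c("plus", "minus", "both")

.check_iupac <- function(seq, what = "sequence") {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  bad <- which(!(chars %in% names(.IUPAC)))
  if (length(bad) > 0) {
    stop(sprintf("non-IUPAC character '%s' in %s at position %d",
                 chars[bad[1]], what, bad[1]), call. = FALSE)
  }
  invisible(TRUE)
}

#' Reverse complement of a DNA sequence
#'
#' Watson-Crick reverse complement over the full IUPAC alphabet (degenerate
#' codes map to their complements, e.g. R <-> Y). Needed throughout for
#' antisense-strand matching: the 5-mer SBE `GTCTG` read on the antisense
#' strand appears as `CAGAC` on the reference strand.
#'
#' @param seq Character vector of DNA sequences (IUPAC codes, case
#'   insensitive). Empty strings are returned unchanged.
#' @return Character vector of reverse complements, same length as `seq`.
#' @examples
#' reverse_complement("GTCTG")   # "CAGAC"
#' reverse_complement("GGCGCC")  # palindromic, maps to itself
#' @export
reverse_complement <- function(seq) {
  stopifnot(is.character(seq))
  vapply(seq, function(s) {
    s <- toupper(s)
    if (nchar(s) == 0L) return("")
    .check_iupac(s)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, character(1), USE.NAMES = FALSE)
}

#' Expand a degenerate IUPAC sequence into all concrete ACGT variants
#'
#' @param seq Single DNA string over IUPAC codes.
#' @param max_variants Safety cap on the expansion size.
#' @return Character vector of concrete sequences (ACGT only).
#' @export
expand_degenerate <- function(seq, max_variants = 4096L) {
  seq <- toupper(seq)
  if (nchar(seq) == 0L) return("")
  .check_iupac(seq)
  sets <- lapply(strsplit(seq, "", fixed = TRUE)[[1]],
                 function(ch) strsplit(.IUPAC[[ch]], "", fixed = TRUE)[[1]])
  n <- prod(vapply(sets, length, integer(1)))
  if (n > max_variants) {
    stop(sprintf("degenerate expansion of '%s' has %d variants (cap %d)",
                 seq, n, max_variants), call. = FALSE)
  }
  grid <- do.call(expand.grid, c(rev(sets), stringsAsFactors = FALSE))
  apply(grid[, rev(seq_along(sets)), drop = FALSE], 1L, paste0, collapse = "")
}

#' Construct a SMAD binding element
#'
#' A binding element is a short recognition sequence written 5'->3' on the
#' strand that carries the +1 guanine contacted by the MH1 beta-hairpin
#' arginine. `sequence` may hold several degenerate variants (the 5GC family
#' is `GGCGC` or `GGCCG`, which no single IUPAC string captures without
#' overmatching).
#'
#' @param id Short element name (e.g. `"pGC_SBE"`).
#' @param sequence Character vector of one or more IUPAC sequence variants,
#'   each at least 4 bp.
#' @param plus_one_offset 0-based index of the +1 guanine within the written
#'   sequence (0 for all canonical elements).
#' @return An object of class `binding_element` with pre-expanded concrete
#'   `variants` and `rc_variants`, and a `palindromic` flag.
#' @seealso [canonical_elements()], [is_palindromic()]
#' @export
binding_element <- function(id, sequence, plus_one_offset = 0L) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id),
            is.character(sequence), length(sequence) >= 1L)
  sequence <- toupper(sequence)
  for (s in sequence) {
    if (nchar(s) < 4L) {
      stop(sprintf("element '%s': sequence '%s' shorter than 4 bp", id, s),
           call. = FALSE)
    }
    .check_iupac(s, what = sprintf("element '%s'", id))
  }
  lens <- unique(nchar(sequence))
  if (length(lens) != 1L) {
    stop(sprintf("element '%s': variants differ in length", id), call. = FALSE)
  }
  variants <- unique(unlist(lapply(sequence, expand_degenerate)))
  rc_variants <- unique(reverse_complement(variants))
  el <- structure(
    list(id = id,
         sequence = sequence,
         length = lens,
         plus_one_offset = as.integer(plus_one_offset),
         variants = variants,
         rc_variants = rc_variants,
         palindromic = setequal(variants, rc_variants)),
    class = "binding_element")
  el
}

#' @export
print.binding_element <- function(x, ...) {
  cat(sprintf("<binding_element> %s: %s (%d bp%s)\n",
              x$id, paste(x$sequence, collapse = "|"), x$length,
              if (x$palindromic) ", palindromic" else ""))
  invisible(x)
}

#' Is an element (or sequence) palindromic?
#'
#' True when the reverse complement equals the sequence itself; for
#' degenerate sequences, when the expanded variant sets coincide. The
#' palindromic GC-rich SBE `GGCGCC` and the palindromic SBE `GTCTAGAC` are
#' the same on both strands; `GTCTG` and `GGCTCC` are not.
#'
#' @param x A `binding_element` or a DNA string.
#' @return Logical scalar.
#' @export
is_palindromic <- function(x) {
  if (inherits(x, "binding_element")) return(x$palindromic)
  stopifnot(is.character(x), length(x) == 1L)
  v <- expand_degenerate(x)
  setequal(v, reverse_complement(v))
}

#' Canonical SMAD binding element table
#'
#' The five elements recognized by SMAD MH1 domains: the classical SBE
#' (`GTCTG`), the palindromic GC-rich SBE (`GGCGCC`), the non-palindromic
#' GC-rich SBE (`GGCTCC`), the palindromic SBE (`GTCTAGAC`), and the 5GC
#' family (`GGCGC` / `GGCCG`).
#'
#' @return Named list of [binding_element()] objects.
#' @export
canonical_elements <- function() {
  if (is.null(.registry_cache$canonical)) {
    .registry_cache$canonical <- list(
      SBE      = binding_element("SBE",      "GTCTG"),
      pGC_SBE  = binding_element("pGC_SBE",  "GGCGCC"),
      npGC_SBE = binding_element("npGC_SBE", "GGCTCC"),
      pSBE     = binding_element("pSBE",     "GTCTAGAC"),
      FIVE_GC  = binding_element("FIVE_GC",  c("GGCGC", "GGCCG"))
    )
  }
  .registry_cache$canonical
}

.registry_cache <- new.env(parent = emptyenv())

#' Read user-defined binding elements from a TSV file
#'
#' Expected columns: `id`, `sequence` (IUPAC; multiple variants separated by
#' `|`), optional `plus_one_offset`.
#'
#' @param path Path to a tab-separated file with a header row.
#' @return Named list of [binding_element()] objects.
#' @export
read_elements <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("id", "sequence") %in% names(tab))) {
    stop("element table must have columns 'id' and 'sequence'", call. = FALSE)
  }
  if (anyDuplicated(tab$id)) {
    stop(sprintf("duplicate element id '%s'", tab$id[duplicated(tab$id)][1]),
         call. = FALSE)
  }
  offs <- if ("plus_one_offset" %in% names(tab)) tab$plus_one_offset else 0L
  offs <- rep_len(offs, nrow(tab))
  els <- lapply(seq_len(nrow(tab)), function(i) {
    binding_element(tab$id[i],
                    strsplit(tab$sequence[i], "|", fixed = TRUE)[[1]],
                    offs[i])
  })
  names(els) <- tab$id
  els
}

# Resolve an element argument: a binding_element, or a canonical id.
.as_element <- function(x, registry = canonical_elements()) {
  if (inherits(x, "binding_element")) return(x)
  if (is.character(x) && length(x) == 1L && x %in% names(registry)) {
    return(registry[[x]])
  }
  stop(sprintf("unknown element '%s'", as.character(x)[1]), call. = FALSE)
}
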