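# Strand-aware exact occurrence detection for binding elements.

# All matches of a set of same-length concrete ACGT variants in a sequence.
# Zero-width lookahead makes the scan overlap-aware. Returns 0-based starts.
.match_starts <- function(sequence, variants) {
  variants <- variants[nchar(variants) > 0L & nchar(variants) <= nchar(sequence)]
  if (length(variants) == 0L) return(integer(0))
  pattern <- paste0("(?=(?:", paste(variants, collapse = "|"), "))")
  m <- gregexpr(pattern, sequence, perl = TRUE)[[1]]
  if (m[1] == -1L) return(integer(0))
  as.integer(m) - 1L
}

#' Find all occurrences of a binding element in a sequence
#'
#' Exact, strand-aware matching: an instance is reported wherever the
#' element sequence (any concrete variant) matches the plus strand, or its
#' reverse complement does (a minus-strand site). Palindromic sites match on
#' both strands and are reported once with `strands = "both"`. Overlapping
#' instances are all reported. Bases other than A/C/G/T in the subject never
#' match.
#'
#' @param sequence A single DNA string (uppercased internally).
#' @param element A [binding_element()] or canonical element id.
#' @return A data.frame with columns `element_id`, `start`, `end` (0-based
#'   half-open on the plus strand) and `strands` (`"plus"`, `"minus"` or
#'   `"both"`), sorted by `start`.
#' @examples
#' element_occurrences("CAGAC", "SBE")     # minus-strand SBE
#' element_occurrences("GGCGCC", "pGC_SBE") # palindromic, strands "both"
#' @export
element_occurrences <- function(sequence, element) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  element <- .as_element(element)
  sequence <- toupper(sequence)
  empty <- data.frame(element_id = character(0), start = integer(0),
                      end = integer(0), strands = character(0),
                      stringsAsFactors = FALSE)
  if (nchar(sequence) < element$length) return(empty)
  plus_starts <- .match_starts(sequence, element$variants)
  minus_starts <- .match_starts(sequence, element$rc_variants)
  starts <- sort(unique(c(plus_starts, minus_starts)))
  if (length(starts) == 0L) return(empty)
  strands <- ifelse(starts %in% plus_starts & starts %in% minus_starts,
                    "both",
                    ifelse(starts %in% plus_starts, "plus", "minus"))
  data.frame(element_id = element$id,
             start = starts,
             end = starts + element$length,
             strands = strands,
             stringsAsFactors = FALSE)
}

.expand_strands <- function(strands) {
  if (length(strands) == 0L || any(!strands %in% .STRAND_LEVELS)) {
    stop("strand set must be a nonempty subset of plus/minus/both",
         call. = FALSE)
  }
  s <- unique(unlist(lapply(strands, function(x) {
    if (x == "both") c("plus", "minus") else x
  })))
  s
}

#' Classify achievable binding modes of two element instances
#'
#' Two MH1 domains read their elements 5'->3' from the +1 guanine. For each
#' strand assignment (u, d) of the upstream and downstream instance the pair
#' binds: upstream on minus with downstream on plus puts both +1 guanines
#' adjacent to the spacer on opposing strands (back-to-back); the converse
#' points both domains at each other (face-to-face); same-strand
#' assignments give face-to-back. The result is the union over all strand
#' assignments the two instances allow.
#'
#' @param upstream_strands,downstream_strands Strand availability of the
#'   two instances: subsets of `"plus"`, `"minus"`, `"both"`.
#' @return Character vector, subset of `c("face_to_face", "face_to_back",
#'   "back_to_back")`.
#' @examples
#' classify_binding_modes("both", "plus")   # face_to_back + back_to_back
#' classify_binding_modes("both", "minus")  # no back_to_back
#' @export
classify_binding_modes <- function(upstream_strands, downstream_strands) {
  up <- .expand_strands(upstream_strands)
  down <- .expand_strands(downstream_strands)
  modes <- character(0)
  for (u in up) {
    for (d in down) {
      modes <- c(modes,
                 if (u == "minus" && d == "plus") "back_to_back"
                 else if (u == "plus" && d == "minus") "face_to_face"
                 else "face_to_back")
    }
  }
  intersect(c("face_to_face", "face_to_back", "back_to_back"), unique(modes))
}

.RESPONSIVE_LABELS <- c("BMP_responsive", "BMP_responsive_weak",
                        "TGFB_responsive", "nonresponsive")

#' Predict BMP/TGF-beta responsiveness of a composite motif
#'
#' Encodes the minimal-requirement rule established by the reporter series:
#' a composite drives BMP signaling only when its two elements are spaced by
#' exactly 5 bp, can be bound back-to-back, and the pair is drawn from
#' {pGC-SBE, SBE} with at least one pGC-SBE. The fully antisense arrangement
#' (SBE upstream on the minus strand, i.e. `CAGAC-N5-GGCGCC`) retains BMP
#' sensitivity only weakly and is graded `BMP_responsive_weak`. Two 5-bp
#' spaced pSBE motifs respond to TGF-beta instead. Everything else —
#' including all npGC-SBE- and 5GC-containing pairs and any non-5-bp
#' spacing — is `nonresponsive`.
#'
#' @param up_id,down_id Element ids of the upstream and downstream instance.
#'   Ids outside the responsive whitelist (e.g. mutated variants) simply
#'   yield `nonresponsive`.
#' @param up_strands,down_strands Strand availability sets.
#' @param spacer_len Spacer length in bp (non-negative integer).
#' @return One of `"BMP_responsive"`, `"BMP_responsive_weak"`,
#'   `"TGFB_responsive"`, `"nonresponsive"`.
#' @examples
#' predict_responsiveness("pGC_SBE", "both", "SBE", "plus", 5)  # BMP_responsive
#' predict_responsiveness("SBE", "minus", "pGC_SBE", "both", 5) # weak
#' predict_responsiveness("pGC_SBE", "both", "pGC_SBE", "both", 6) # nonresponsive
#' @export
predict_responsiveness <- function(up_id, up_strands, down_id, down_strands,
                                   spacer_len) {
  if (!is.character(up_id) || !nzchar(up_id) ||
      !is.character(down_id) || !nzchar(down_id)) {
    stop("element ids must be nonempty strings", call. = FALSE)
  }
  if (spacer_len < 0) stop("spacer_len must be >= 0", call. = FALSE)
  modes <- classify_binding_modes(up_strands, down_strands)
  ids <- c(up_id, down_id)
  if (spacer_len == 5 && all(ids == "pSBE")) return("TGFB_responsive")
  bmp_ok <- spacer_len == 5 &&
    "back_to_back" %in% modes &&
    all(ids %in% c("pGC_SBE", "SBE")) &&
    any(ids == "pGC_SBE")
  if (!bmp_ok) return("nonresponsive")
  # back-to-back requires the upstream element on the minus strand; when
  # that element is the (non-palindromic) SBE the whole locus is the full
  # antisense arrangement, which responds only weakly.
  if (up_id == "SBE") "BMP_responsive_weak" else "BMP_responsive"
}
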