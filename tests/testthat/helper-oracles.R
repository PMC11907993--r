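# Independent brute-force oracles and small fixture builders.

rand_dna <- function(len, bases = c("A", "C", "G", "T")) {
  paste(sample(bases, len, replace = TRUE), collapse = "")
}

# Brute-force occurrence matcher: checks the substring at every offset
# against the element's concrete variants (plus) and their reverse
# complements (minus). Independent of the package's regex-based scan path.
brute_occurrences <- function(seq, element) {
  L <- element$length
  n <- nchar(seq)
  empty <- data.frame(element_id = character(0), start = integer(0),
                      end = integer(0), strands = character(0),
                      stringsAsFactors = FALSE)
  if (n < L) return(empty)
  offs <- seq_len(n - L + 1L)
  subs <- substring(seq, offs, offs + L - 1L)
  plus <- subs %in% element$variants
  minus <- subs %in% element$rc_variants
  keep <- which(plus | minus)
  if (length(keep) == 0L) return(empty)
  data.frame(element_id = element$id,
             start = keep - 1L,
             end = keep - 1L + L,
             strands = ifelse(plus[keep] & minus[keep], "both",
                              ifelse(plus[keep], "plus", "minus")),
             stringsAsFactors = FALSE)
}

# Brute-force composite matcher: double loop over all occurrence position
# pairs, keeping pairs at the exact gap. Returns a key per hit.
brute_scan_keys <- function(seq, element_a, element_b, spacer_lens,
                            ordered = FALSE) {
  occ_a <- brute_occurrences(seq, element_a)
  occ_b <- brute_occurrences(seq, element_b)
  keys <- character(0)
  pair_up <- function(up, down) {
    for (i in seq_len(nrow(up))) {
      for (j in seq_len(nrow(down))) {
        gap <- down$start[j] - up$end[i]
        if (gap %in% spacer_lens) {
          keys <<- c(keys, paste(up$element_id[i], up$start[i],
                                 down$element_id[j], down$start[j], gap))
        }
      }
    }
  }
  pair_up(occ_a, occ_b)
  if (!ordered && element_a$id != element_b$id) pair_up(occ_b, occ_a)
  sort(unique(keys))
}

hit_keys <- function(hits) {
  sort(unique(paste(hits$up_element, hits$up_start, hits$down_element,
                    hits$down_start, hits$spacer_len)))
}

# A tiny planted peak set shared by several tests.
make_planted_set <- function(n = 60, count = 3, seed = 7, plant_seed = 11,
                             ...) {
  ps <- generate_background(n, 300, 0.41, seed = seed)
  plant_composites(ps, rate = NULL, count = count, seed = plant_seed, ...)
}

reverse_complement_peakset <- function(ps) {
  ps$sequences <- vapply(ps$sequences, smadscan::reverse_complement,
                         character(1))
  ps
}
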