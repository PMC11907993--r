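# Standard-format readers/writers and the umbrella pipeline.

#' Read a FASTA file into a named sequence set
#'
#' Sequences are uppercase-normalized and keyed by the first
#' whitespace-delimited token of each header. Empty files, duplicate ids
#' and non-IUPAC characters are explicit errors.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path),
                               call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop(sprintf("empty FASTA file: %s", path),
                              call. = FALSE)
  ids <- vapply(strsplit(names(set), "\\s+"), `[[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate FASTA id '%s' in %s", ids[duplicated(ids)][1],
                 path), call. = FALSE)
  }
  seqs <- toupper(as.character(set))
  for (i in seq_along(seqs)) {
    .check_iupac(seqs[i], what = sprintf("record '%s'", ids[i]))
  }
  stats::setNames(seqs, ids)
}

#' Write a named sequence set as FASTA
#'
#' @param seqs Named character vector of DNA sequences.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  set <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a BED3+ interval file
#'
#' 0-based half-open intervals; the optional fourth column is used as
#' `region_id`, otherwise ids are `chrom:start-end`. Output is sorted by
#' chromosome and start so downstream results are input-order independent.
#'
#' @param path Path to a tab-separated BED file (no header).
#' @return data.frame `chrom`, `start`, `end`, `region_id`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path),
                               call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                 !startsWith(lines, "track")]
  if (length(lines) == 0L) stop(sprintf("empty BED file: %s", path),
                                call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  out <- lapply(seq_along(fields), function(i) {
    f <- fields[[i]]
    if (length(f) < 3L) {
      stop(sprintf("%s line %d: fewer than 3 BED fields", path, i),
           call. = FALSE)
    }
    start <- suppressWarnings(as.integer(f[2]))
    end <- suppressWarnings(as.integer(f[3]))
    if (is.na(start) || is.na(end)) {
      stop(sprintf("%s line %d: non-integer coordinates", path, i),
           call. = FALSE)
    }
    if (end <= start) {
      stop(sprintf("%s line %d: end <= start", path, i), call. = FALSE)
    }
    data.frame(chrom = f[1], start = start, end = end,
               region_id = if (length(f) >= 4L && nzchar(f[4])) f[4] else
                 sprintf("%s:%d-%d", f[1], start, end),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$chrom, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.file_checksums <- function(paths) {
  paths <- unlist(paths[!vapply(paths, is.null, logical(1))])
  if (length(paths) == 0L) return(list())
  paths <- paths[file.exists(paths)]
  if (length(paths) == 0L) return(list())
  as.list(tools::md5sum(paths))
}

#' Run the screening pipeline: scan, count, profile, annotate
#'
#' Executes the composite screen over a peak set, builds the linker profile
#' of all 5-bp-spacer hits, optionally computes the functional-region
#' distribution of positive regions, writes all intermediates as TSV, and
#' emits a JSON run manifest (parameters, input checksums, seed, package
#' version, timestamp). Reruns with identical inputs and seed reproduce
#' identical outputs.
#'
#' @param config List (or path to a JSON file) with entries: `fasta`
#'   (genome or per-region FASTA path) or `sequences` (named vector), `bed`
#'   (optional regions path) or `regions` (data.frame), optional `classes`
#'   (data.frame, default [composite_classes()]), `spacer_len` (default 5),
#'   `out_prefix` (required), `seed` (default 1), and optionally
#'   `annotation = list(features, tss, chrom_sizes)` for the
#'   distribution stage.
#' @return Invisibly, a list with the `screen_summary`, `linker_profile`
#'   (or `NULL` if no hits), `distribution` (or `NULL`) and the written
#'   file paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config), !is.null(config$out_prefix))
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  spacer_len <- if (is.null(config$spacer_len)) 5L else
    as.integer(config$spacer_len)
  classes <- if (is.null(config$classes)) {
    composite_classes(spacer_len = spacer_len)
  } else config$classes

  sequences <- if (!is.null(config$sequences)) config$sequences else {
    if (is.null(config$fasta)) {
      stop("pipeline stage 'input': no fasta/sequences given", call. = FALSE)
    }
    tryCatch(read_fasta(config$fasta), error = function(e) {
      stop(sprintf("pipeline stage 'input': %s", conditionMessage(e)),
           call. = FALSE)
    })
  }
  regions <- if (!is.null(config$regions)) config$regions else {
    if (is.null(config$bed)) NULL else read_bed(config$bed)
  }

  screen <- screen_regions(regions, sequences, classes = classes)
  prefix <- config$out_prefix
  paths <- c(hits = paste0(prefix, ".hits.tsv"),
             summary = paste0(prefix, ".summary.tsv"),
             manifest = paste0(prefix, ".manifest.json"))
  .write_tsv(screen$hits, paths[["hits"]])
  .write_tsv(screen$class_summary, paths[["summary"]])

  profile <- NULL
  if (nrow(screen$hits) > 0L) {
    linkers <- extract_linkers(screen$hits)
    profile <- linker_profile(linkers)
    paths <- c(paths, profile = paste0(prefix, ".linker_profile.tsv"))
    write_profile(profile, paths[["profile"]])
  }

  distribution <- NULL
  if (!is.null(config$annotation)) {
    ann <- config$annotation
    model <- annotation_model(ann$features, ann$tss, ann$chrom_sizes)
    rt <- screen$region_table
    pos_ids <- unique(rt$region_id[rt$positive])
    if (length(pos_ids) > 0L && !is.null(regions)) {
      pos_regions <- regions[regions$region_id %in% pos_ids, , drop = FALSE]
      distribution <- normalized_distribution(
        classify_regions(pos_regions, model), model)
      paths <- c(paths, distribution = paste0(prefix, ".distribution.tsv"))
      .write_tsv(distribution, paths[["distribution"]])
    }
  }

  manifest <- list(
    command = "run_pipeline",
    version = as.character(utils::packageVersion("smadscan")),
    parameters = list(spacer_len = spacer_len,
                      n_classes = nrow(classes),
                      out_prefix = prefix),
    inputs = .file_checksums(list(config$fasta, config$bed)),
    seed = seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, paths[["manifest"]], auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(list(screen = screen, profile = profile,
                 distribution = distribution, paths = paths))
}
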