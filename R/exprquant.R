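#' Construct a probe set for exact k-mer quantification
#'
#' @param ids probe identifiers.
#' @param sequences probe sequences (alphabet ACGT; each exactly
#'   `probe_length` bases).
#' @param probe_length required probe length (default 32, the word size that
#'   forces a complete match in the haplotype-probe search design).
#' @return data frame of class `probe_set` with columns `id`, `sequence`.
#' @export
probe_set <- function(ids, sequences, probe_length = 32L) {
  sequences <- toupper(sequences)
  stopifnot(length(ids) == length(sequences), !anyDuplicated(ids))
  if (any(grepl("[^ACGT]", sequences)))
    stop("probe sequences must use the A/C/G/T alphabet only")
  if (any(nchar(sequences) != probe_length))
    stop("every probe must be exactly ", probe_length, " bases")
  structure(data.frame(id = ids, sequence = sequences,
                       stringsAsFactors = FALSE),
            class = c("probe_set", "data.frame"),
            probe_length = as.integer(probe_length))
}

.as_dna_set <- function(reads) {
  if (inherits(reads, "DNAStringSet")) reads
  else Biostrings::DNAStringSet(toupper(as.character(reads)))
}

#' Count reads containing a probe verbatim
#'
#' A read scores a hit when it contains the probe as an exact substring (or
#' its reverse complement, when both strands are searched); each read is
#' counted at most once. One mismatching base removes a read from the count
#' - the "complete fit" matching rule.
#'
#' @param reads character vector or [Biostrings::DNAStringSet] of reads.
#' @param probe probe sequence (length at most the read length).
#' @param both_strands also match the reverse complement (default `TRUE`).
#' @return integer hit count.
#' @export
count_exact_hits <- function(reads, probe, both_strands = TRUE) {
  if (!nzchar(probe)) stop("empty probe")
  reads <- .as_dna_set(reads)
  probe <- toupper(probe)
  hit <- Biostrings::vcountPattern(probe, reads, fixed = TRUE) > 0L
  if (both_strands)
    hit <- hit | Biostrings::vcountPattern(revcomp(probe), reads,
                                           fixed = TRUE) > 0L
  sum(hit)
}

#' FPKM transform of an exact-probe hit count
#'
#' `fpkm = 1e9 * hits / (probe_length * library_size)` - fragments per
#' kilobase of feature per million reads, with the probe itself as the
#' feature (the only length available under probe-based counting; absolute
#' values therefore differ from transcript-length FPKM by a constant
#' factor). A probe is called detected only at `min_reads` or more hits
#' (default 3); undetected probes report an FPKM of zero.
#'
#' @param hits read count (`>= 0`).
#' @param probe_length feature length in bases (`> 0`).
#' @param library_size total reads in the library (`> 0`).
#' @param min_reads minimal hit count for detection (default 3).
#' @param probe_id optional identifier carried into the result.
#' @return object of class `expression_result`: `probe_id`, `hits`, `fpkm`,
#'   `detected`.
#' @export
fpkm <- function(hits, probe_length = 32L, library_size, min_reads = 3L,
                 probe_id = NA_character_) {
  stopifnot(is_count(hits), probe_length > 0)
  if (!is_count(library_size) || library_size == 0)
    stop("library_size must be a positive count")
  detected <- hits >= min_reads
  value <- if (detected) 1e9 * hits / (probe_length * library_size) else 0
  structure(list(probe_id = probe_id, hits = as.integer(hits),
                 fpkm = value, detected = detected),
            class = "expression_result")
}

#' @export
print.expression_result <- function(x, ...) {
  cat(sprintf("<expression_result %s> hits = %d, FPKM = %.3f%s\n",
              x$probe_id, x$hits, x$fpkm,
              if (x$detected) "" else " (below detection threshold)"))
  invisible(x)
}

#' Quantify a probe set across labelled read libraries
#'
#' Counts exact probe hits in every library, applies the FPKM transform and
#' the detection threshold, and returns a long-format table suitable for
#' group comparisons with [anova_oneway()].
#'
#' @param libraries named list of read sets (character vectors or
#'   [Biostrings::DNAStringSet]s); names are the library labels and must be
#'   unique.
#' @param probes a [probe_set()] (or data frame with `id`, `sequence`).
#' @param metadata optional data frame with a `library` column plus
#'   annotation columns (e.g. `stage`, `sex`), merged into the result.
#' @param min_reads detection threshold (default 3).
#' @param both_strands search both strands (default `TRUE`).
#' @return data frame with columns `library`, `probe`, `hits`, `fpkm`,
#'   `detected`, plus any metadata columns.
#' @export
expression_profile <- function(libraries, probes, metadata = NULL,
                               min_reads = 3L, both_strands = TRUE) {
  stopifnot(is.list(libraries), length(libraries) >= 1L)
  labels <- names(libraries)
  if (is.null(labels) || any(!nzchar(labels)) || anyDuplicated(labels))
    stop("libraries must carry unique non-empty labels")
  probes <- as.data.frame(probes)
  stopifnot(all(c("id", "sequence") %in% names(probes)))
  rows <- list()
  for (lib in labels) {
    reads <- .as_dna_set(libraries[[lib]])
    lib_size <- length(reads)
    for (j in seq_len(nrow(probes))) {
      hits <- if (lib_size == 0) 0L
              else count_exact_hits(reads, probes$sequence[j], both_strands)
      r <- if (lib_size == 0)
        list(hits = 0L, fpkm = 0, detected = FALSE)
      else fpkm(hits, nchar(probes$sequence[j]), lib_size, min_reads)
      rows[[length(rows) + 1L]] <- data.frame(
        library = lib, probe = probes$id[j], hits = r$hits, fpkm = r$fpkm,
        detected = r$detected, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(metadata)) {
    stopifnot("library" %in% names(metadata))
    out <- merge(out, metadata, by = "library", sort = FALSE)
  }
  out[order(match(out$library, labels)), , drop = FALSE]
}
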