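# Plain-text interchange formats: FASTA for haplotypes and reads, TSV for
# traces and cohorts, JSON for gene models and estimates.

#' Write haplotypes to FASTA with key=value metadata in the description
#' @param haplotypes list of [haplotype()]s.
#' @param path output FASTA path.
#' @export
write_haplotypes_fasta <- function(haplotypes, path) {
  stopifnot(all(vapply(haplotypes, inherits, logical(1), "haplotype")))
  seqs <- Biostrings::DNAStringSet(
    vapply(haplotypes, `[[`, "", "sequence"))
  names(seqs) <- vapply(haplotypes, function(h) {
    sprintf("%s chromosome=%s role=%s", h$id, h$chromosome, h$role)
  }, "")
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read haplotypes from FASTA written by [write_haplotypes_fasta()]
#' @param path FASTA path.
#' @return list of [haplotype()]s.
#' @export
read_haplotypes_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  lapply(seq_along(seqs), function(i) {
    fields <- strsplit(names(seqs)[i], "\\s+")[[1]]
    kv <- fields[grepl("=", fields)]
    meta <- setNames(sub(".*=", "", kv), sub("=.*", "", kv))
    haplotype(id = fields[1], sequence = as.character(seqs[[i]]),
              chromosome = meta[["chromosome"]] %||% "Z",
              role = meta[["role"]] %||% "other")
  })
}

#' Write a chromatogram as TSV (`pos A C G T`)
#' @param trace a [chromatogram()].
#' @param path output TSV path.
#' @export
write_trace_tsv <- function(trace, path) {
  stopifnot(inherits(trace, "chromatogram"))
  df <- data.frame(pos = seq(trace$anchor,
                             length.out = nrow(trace$heights)),
                   trace$heights, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a chromatogram from TSV written by [write_trace_tsv()]
#' @param path TSV path.
#' @return a [chromatogram()].
#' @export
read_trace_tsv <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  stopifnot(all(c("pos", DNA_ALPHABET) %in% names(df)))
  chromatogram(as.matrix(df[, DNA_ALPHABET]), anchor = df$pos[1])
}

#' Write a cohort table as TSV
#' @param cohort data frame from [gen_cohort()].
#' @param path output TSV path.
#' @export
write_cohort_tsv <- function(cohort, path) {
  write.table(cohort, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a cohort table from TSV
#' @param path TSV path.
#' @return data frame with `id`, `sex`, marker columns and (if present)
#'   `truth_sd`.
#' @export
read_cohort_tsv <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Write a gene model as JSON
#' @param model a [gene_model()].
#' @param path output JSON path.
#' @export
write_gene_model_json <- function(model, path) {
  stopifnot(inherits(model, "gene_model"))
  jsonlite::write_json(
    list(name = model$name, exons = model$exon_lengths,
         introns = model$intron_lengths, sequence = model$sequence,
         cds = model$cds),
    path, auto_unbox = TRUE, null = "null", digits = NA)
  invisible(path)
}

#' Read a gene model from JSON
#' @param path JSON path with fields `name`, `exons`, `introns` and
#'   optionally `sequence` and `cds`.
#' @return a [gene_model()].
#' @export
read_gene_model_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  gene_model(name = x$name, exon_lengths = x$exons,
             intron_lengths = x$introns %||% integer(0),
             sequence = x$sequence, cds = x$cds)
}

#' Write a mixture estimate as JSON
#' @param estimate a [mixture_estimate()].
#' @param path output JSON path.
#' @export
write_estimate_json <- function(estimate, path) {
  stopifnot(inherits(estimate, "mixture_estimate"))
  jsonlite::write_json(
    list(proportions = as.list(estimate$proportions),
         r2 = estimate$r_squared, method = estimate$method),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
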