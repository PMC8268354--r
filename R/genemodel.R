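#' Construct an exon/intron gene model
#'
#' Represents a gene as alternating exons and introns from the transcription
#' start, optionally with the genomic sequence and the CDS interval on the
#' spliced transcript (1-based inclusive). The three-exon banf2w organization
#' (exons 119/127/231 bp, introns 1002/668 bp; genomic 2147 bp, transcript
#' 477 bp) is the motivating case.
#'
#' @param name gene name.
#' @param exon_lengths positive integer vector.
#' @param intron_lengths positive integer vector, one fewer than exons (may
#'   be empty for single-exon genes).
#' @param sequence optional genomic DNA from the transcription start; its
#'   length must equal the genomic length.
#' @param cds optional `c(start, end)` CDS coordinates on the transcript.
#' @return object of class `gene_model`.
#' @export
gene_model <- function(name, exon_lengths, intron_lengths = integer(0),
                       sequence = NULL, cds = NULL) {
  stopifnot(length(exon_lengths) >= 1L, all(exon_lengths > 0),
            all(intron_lengths > 0),
            length(intron_lengths) == length(exon_lengths) - 1L)
  if (!is.null(sequence)) {
    sequence <- toupper(sequence)
    if (nchar(sequence) != sum(exon_lengths) + sum(intron_lengths))
      stop("sequence length does not equal the genomic length")
  }
  if (!is.null(cds)) {
    stopifnot(length(cds) == 2L, cds[1] >= 1L, cds[2] >= cds[1],
              cds[2] <= sum(exon_lengths))
  }
  structure(list(name = name, exon_lengths = as.integer(exon_lengths),
                 intron_lengths = as.integer(intron_lengths),
                 sequence = sequence, cds = cds),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model %s> %d exon(s) (%s), genomic %d bp, transcript %d bp\n",
              x$name, length(x$exon_lengths),
              paste(x$exon_lengths, collapse = "/"),
              genomic_length(x), transcript_length(x)))
  invisible(x)
}

#' Genomic length of a gene model (exons plus introns)
#' @param model a [gene_model()].
#' @return length in bases.
#' @export
genomic_length <- function(model) {
  stopifnot(inherits(model, "gene_model"))
  sum(model$exon_lengths) + sum(model$intron_lengths)
}

#' Transcript length of a gene model (sum of exons)
#' @param model a [gene_model()].
#' @return length in bases.
#' @export
transcript_length <- function(model) {
  stopifnot(inherits(model, "gene_model"))
  sum(model$exon_lengths)
}

# genomic [start, end] of intron i, counting from the transcription start
.intron_interval <- function(model, i) {
  start <- sum(model$exon_lengths[seq_len(i)]) +
    sum(model$intron_lengths[seq_len(i - 1L)]) + 1L
  c(start, start + model$intron_lengths[i] - 1L)
}

#' Validate canonical GT..AG splice sites of every intron
#'
#' Checks, case-insensitively, that each intron of the model begins with the
#' canonical donor dinucleotide GT and ends with the acceptor AG.
#'
#' @param model a [gene_model()] carrying its genomic sequence.
#' @return list with `pass` (logical) and `introns`, a data frame of per-
#'   intron donor/acceptor dinucleotides and validity flags.
#' @export
validate_splice_sites <- function(model) {
  stopifnot(inherits(model, "gene_model"))
  if (is.null(model$sequence))
    stop("gene model carries no sequence; splice sites cannot be checked")
  n <- length(model$intron_lengths)
  if (n == 0L)
    return(list(pass = TRUE,
                introns = data.frame(intron = integer(0),
                                     donor = character(0),
                                     acceptor = character(0),
                                     ok = logical(0))))
  rows <- lapply(seq_len(n), function(i) {
    iv <- .intron_interval(model, i)
    donor <- substr(model$sequence, iv[1], iv[1] + 1L)
    acceptor <- substr(model$sequence, iv[2] - 1L, iv[2])
    data.frame(intron = i, donor = donor, acceptor = acceptor,
               ok = toupper(donor) == "GT" && toupper(acceptor) == "AG",
               stringsAsFactors = FALSE)
  })
  introns <- do.call(rbind, rows)
  list(pass = all(introns$ok), introns = introns)
}

#' Extract the spliced transcript sequence from a gene model
#' @param model a [gene_model()] carrying its genomic sequence.
#' @return transcript DNA string (exons concatenated).
#' @export
spliced_transcript <- function(model) {
  stopifnot(inherits(model, "gene_model"))
  if (is.null(model$sequence)) stop("gene model carries no sequence")
  pieces <- character(length(model$exon_lengths))
  pos <- 1L
  for (i in seq_along(model$exon_lengths)) {
    pieces[i] <- substr(model$sequence, pos,
                        pos + model$exon_lengths[i] - 1L)
    pos <- pos + model$exon_lengths[i] +
      if (i <= length(model$intron_lengths)) model$intron_lengths[i] else 0L
  }
  paste(pieces, collapse = "")
}

#' Translate a CDS on a transcript with the standard genetic code
#'
#' The CDS must start with ATG, have length divisible by three, and end in a
#' stop codon; the returned peptide excludes the terminal stop, so a 273-base
#' CDS encodes 90 residues and a 270-base CDS 89 (the banf2 versus banf2w
#' coding difference). An internal stop is an error naming the codon index.
#'
#' @param transcript transcript DNA string.
#' @param cds `c(start, end)` 1-based inclusive CDS interval.
#' @return amino-acid string of length `nchar(cds)/3 - 1`.
#' @export
translate_cds <- function(transcript, cds) {
  transcript <- toupper(transcript)
  stopifnot(length(cds) == 2L, cds[1] >= 1L, cds[2] <= nchar(transcript))
  cds_seq <- substr(transcript, cds[1], cds[2])
  n <- nchar(cds_seq)
  if (n %% 3L != 0L)
    stop("CDS length ", n, " is not a multiple of three")
  codons <- substring(cds_seq, seq(1L, n, 3L), seq(3L, n, 3L))
  if (codons[1] != "ATG") stop("CDS does not begin with ATG")
  aa <- Biostrings::GENETIC_CODE[codons]
  if (any(is.na(aa))) stop("CDS contains an untranslatable codon")
  if (aa[length(aa)] != "*") stop("CDS does not end in a stop codon")
  internal_stop <- which(aa[-length(aa)] == "*")
  if (length(internal_stop))
    stop("internal stop codon at codon index ", internal_stop[1])
  paste(aa[-length(aa)], collapse = "")
}

#' Find polyadenylation-signal motif occurrences
#'
#' Returns every (possibly overlapping) start position of the motif,
#' 1-based. The canonical signal AATAAA typically occurs twice in the
#' trailing sequence of the banf2w third exon.
#'
#' @param sequence DNA string.
#' @param motif motif to search (default `"AATAAA"`).
#' @return integer vector of start positions (possibly empty).
#' @export
find_polya_signals <- function(sequence, motif = "AATAAA") {
  stopifnot(nzchar(motif))
  sequence <- toupper(sequence)
  hits <- gregexpr(paste0("(?=", motif, ")"), sequence, perl = TRUE)[[1]]
  if (hits[1] == -1L) integer(0) else as.integer(hits)
}

#' Construct an aligned sequence pair
#'
#' @param seq_a,seq_b gapped strings of equal length (gap character `-`).
#' @param window optional `c(start, end)` 1-based inclusive interval on
#'   alignment columns (default: the whole alignment).
#' @return object of class `aligned_pair`.
#' @export
aligned_pair <- function(seq_a, seq_b, window = NULL) {
  seq_a <- toupper(seq_a); seq_b <- toupper(seq_b)
  if (nchar(seq_a) != nchar(seq_b))
    stop("aligned sequences must have equal (gapped) lengths")
  if (is.null(window)) window <- c(1L, nchar(seq_a))
  stopifnot(length(window) == 2L, window[1] >= 1L,
            window[2] >= window[1])
  if (window[2] > nchar(seq_a))
    stop("window extends outside the alignment")
  structure(list(seq_a = seq_a, seq_b = seq_b,
                 window = as.integer(window)),
            class = "aligned_pair")
}

#' Global pairwise alignment utility
#'
#' Needleman-Wunsch global alignment (match +1, mismatch -1, linear gap -2)
#' producing an [aligned_pair()]; provided as plumbing so divergence can be
#' computed from raw sequences when no external alignment is supplied.
#'
#' @param a,b ungapped DNA strings.
#' @param window optional window on alignment columns.
#' @return an [aligned_pair()].
#' @export
align_pair <- function(a, b, window = NULL) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(toupper(a)), Biostrings::DNAString(toupper(b)),
    type = "global", substitutionMatrix = mat,
    gapOpening = 0, gapExtension = 2)
  aligned_pair(as.character(Biostrings::alignedPattern(aln)),
               as.character(Biostrings::alignedSubject(aln)), window)
}

#' Windowed divergence between two aligned sequences
#'
#' Counts events within the window: substitution columns (both sequences
#' have bases and they differ) plus maximal contiguous gap runs, each run
#' counted as a single event regardless of length (an indel is one event).
#' Columns where both sequences are gapped (alignment padding) are neither
#' events nor run members. Divergence is events divided by the window width
#' in columns.
#'
#' @param pair an [aligned_pair()].
#' @return divergence fraction in `[0, 1]`, with attributes
#'   `substitutions`, `gap_runs`, `events` and `width`.
#' @export
window_divergence <- function(pair) {
  stopifnot(inherits(pair, "aligned_pair"))
  w <- pair$window
  a <- strsplit(substr(pair$seq_a, w[1], w[2]), "")[[1]]
  b <- strsplit(substr(pair$seq_b, w[1], w[2]), "")[[1]]
  width <- w[2] - w[1] + 1L
  gap_a <- a == "-"; gap_b <- b == "-"
  subs <- sum(!gap_a & !gap_b & a != b)
  count_runs <- function(gap_self, gap_other) {
    run <- gap_self & !gap_other
    sum(run & !c(FALSE, run[-length(run)]))
  }
  gap_runs <- count_runs(gap_a, gap_b) + count_runs(gap_b, gap_a)
  events <- subs + gap_runs
  structure(events / width, substitutions = subs, gap_runs = gap_runs,
            events = events, width = width)
}
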