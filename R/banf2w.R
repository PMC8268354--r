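# The published exon/intron organization of the O. aureus banf2w gene and a
# synthetic sequence builder shaped to it. Only the organization (lengths,
# splice-site convention, 3' trailer of exon 3) is real annotation data; the
# remaining bases of the builder's output are random and the result is a
# synthetic stand-in, not the deposited sequence.

#' Exon/intron organization of the banf2w gene
#'
#' The W-linked female-specific banf2 copy has a three-exon structure with a
#' non-coding first exon: exons of 119, 127 and 231 bp separated by introns
#' of 1002 and 668 bp (genomic span 2147 bp, transcript 477 bp). The coding
#' sequence starts at the ATG two bases into exon 2 and, in banf2w, runs 270
#' bases (89 residues plus stop; the standard banf2 copies encode 90). The
#' trailing 93 bases of exon 3, downstream of the last sense codon, carry
#' two putative AATAAA polyadenylation signals.
#'
#' @return list with `name`, `exon_lengths`, `intron_lengths`, `cds`
#'   (transcript coordinates), `cds_length`, `exon3_trailer` (3' end of
#'   exon 3 beginning with the final CTG codon and the TGA stop).
#' @export
banf2w_organization <- function() {
  list(name = "banf2w",
       exon_lengths = c(119L, 127L, 231L),
       intron_lengths = c(1002L, 668L),
       cds = c(121L, 390L),
       cds_length = 270L,
       exon3_trailer = paste0(
         "CTGTGAGGCCCCGCCCCCTTTACCTGAGAGGCACCTCTCAGCTGATTATGTGCTGAGCATG",
         "AATAAAACATAAATAAAGTTTGTGTGCCGGAG"))
}

# random in-frame sense codons (no stop), n bases (n divisible by 3)
.random_coding <- function(n) {
  stopifnot(n %% 3L == 0L)
  stops <- c("TAA", "TAG", "TGA")
  codons <- apply(expand.grid(DNA_ALPHABET, DNA_ALPHABET, DNA_ALPHABET),
                  1L, paste, collapse = "")
  sense <- setdiff(codons, stops)
  paste(sample(sense, n / 3L, replace = TRUE), collapse = "")
}

#' Build a synthetic gene sequence shaped like the banf2w organization
#'
#' Constructs a [gene_model()] with the banf2w exon/intron lengths, canonical
#' GT..AG intron ends, an open reading frame from the ATG in exon 2 to the
#' TGA stop in exon 3, and the real exon-3 trailer; all other bases are
#' random under the seed. Intended for structure-validation tests and
#' examples where the deposited genomic sequence is not required.
#'
#' @param seed integer seed.
#' @return a [gene_model()] carrying its (synthetic) sequence and CDS.
#' @export
synthetic_banf2w_gene <- function(seed = 1L) {
  org <- banf2w_organization()
  with_local_seed(derive_seed(seed, "banf2w_gene"), {
    trailer <- org$exon3_trailer
    exon1 <- random_dna(org$exon_lengths[1])
    # exon2: 1 leading base + ATG + 123 coding bases = 127
    exon2 <- paste0("G", "ATG", .random_coding(123L))
    exon3 <- paste0(.random_coding(org$exon_lengths[3] - nchar(trailer)),
                    trailer)
    introns <- vapply(org$intron_lengths, function(L) {
      paste0("GT", random_dna(L - 4L), "AG")
    }, "")
    genomic <- paste0(exon1, introns[1], exon2, introns[2], exon3)
    gene_model(org$name, org$exon_lengths, org$intron_lengths,
               sequence = genomic, cds = org$cds)
  })
}
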