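#' Simulation configuration for the WZ/ZZ study design
#'
#' Bundles every knob of the synthetic-data generator. Defaults reproduce the
#' study conditions of the banf2w mapping design: a case-control cohort of 48
#' phenotypic females and 48 males sampled by sex, a sex-reversal rate of 1/96
#' (about one discordant individual expected in the cohort), chromatogram
#' peak-height noise with a 5% coefficient of variation, and perfectly linked
#' markers unless a per-marker recombination fraction says otherwise.
#'
#' @param seed integer RNG seed; a fixed seed yields byte-identical outputs.
#' @param n_females,n_males cohort sizes by latent sex-determination genotype
#'   (females are WZ, males ZZ at simulation truth).
#' @param recomb_fraction default per-marker recombination fraction to the
#'   sex-determination locus, in `[0, 1]`.
#' @param sex_reversal_rate probability that an individual's phenotypic sex
#'   disagrees with its WZ/ZZ genotype.
#' @param noise_cv coefficient of variation of chromatogram peak heights
#'   (dimensionless, `>= 0`).
#' @param gain mean peak height per unit gene copy (arbitrary signal units).
#' @param read_length simulated read length in bases.
#' @param library_size number of reads per simulated library.
#' @return object of class `sim_config` (a validated list).
#' @export
sim_config <- function(seed = 1L, n_females = 48L, n_males = 48L,
                       recomb_fraction = 0, sex_reversal_rate = 1 / 96,
                       noise_cv = 0.05, gain = 100, read_length = 100L,
                       library_size = 10000L) {
  stopifnot(is_count(seed), is_count(n_females), is_count(n_males),
            is_probability(recomb_fraction), is_probability(sex_reversal_rate),
            is.numeric(noise_cv), noise_cv >= 0,
            is.numeric(gain), gain > 0,
            is_count(read_length), is_count(library_size))
  structure(list(seed = as.integer(seed), n_females = as.integer(n_females),
                 n_males = as.integer(n_males),
                 recomb_fraction = recomb_fraction,
                 sex_reversal_rate = sex_reversal_rate, noise_cv = noise_cv,
                 gain = gain, read_length = as.integer(read_length),
                 library_size = as.integer(library_size)),
            class = "sim_config")
}

#' Construct a haplotype (a named gene-copy sequence)
#'
#' @param id haplotype name.
#' @param sequence DNA string (A/C/G/T/N).
#' @param chromosome chromosome of residence, `"W"` or `"Z"`.
#' @param role one of `"banf2a"`, `"banf2b"`, `"banf2c"`, `"banf2w"`,
#'   `"other"`. The W-specific role `banf2w` must reside on W.
#' @param annotations optional list of edit annotations (substitution
#'   positions, deletion interval) in template coordinates.
#' @return object of class `haplotype`.
#' @export
haplotype <- function(id, sequence, chromosome = c("Z", "W"),
                      role = c("other", "banf2a", "banf2b", "banf2c", "banf2w"),
                      annotations = list()) {
  chromosome <- match.arg(chromosome)
  role <- match.arg(role)
  sequence <- toupper(sequence)
  if (!nzchar(sequence) || grepl("[^ACGTN]", sequence))
    stop("haplotype sequence must be a non-empty A/C/G/T/N string")
  if (role == "banf2w" && chromosome != "W")
    stop("role 'banf2w' implies chromosome 'W'")
  structure(list(id = id, sequence = sequence, chromosome = chromosome,
                 role = role, annotations = annotations),
            class = "haplotype")
}

#' @export
print.haplotype <- function(x, ...) {
  cat(sprintf("<haplotype %s> %s-linked, role %s, %d bp\n",
              x$id, x$chromosome, x$role, nchar(x$sequence)))
  invisible(x)
}

#' Generate a set of gene-copy haplotypes with a W-specific variant
#'
#' Draws one random template sequence and returns `n_z_copies` Z-linked copies
#' of it plus, optionally, one W-linked variant (`banf2w`) carrying exactly
#' `n_substitutions` substitutions and one internal deletion of `indel_length`
#' bases. Edit positions are recorded in the W haplotype's annotations (in
#' template coordinates). This mirrors the multi-copy banf2 locus in which the
#' female-specific copy differs from its Z-linked paralogs by a small coding
#' deletion and a handful of substitutions.
#'
#' @param base_length template length in bases (`>= 60`).
#' @param n_z_copies number of identical Z-linked copies (roles banf2a,
#'   banf2b, then `other`).
#' @param include_w_variant whether to add the W-linked variant copy.
#' @param indel_length length of the W variant's deletion (`>= 0`; 0 skips
#'   the deletion).
#' @param n_substitutions number of substitutions on the W variant.
#' @param seed integer seed.
#' @return list of [haplotype()] objects.
#' @export
gen_haplotype_set <- function(base_length, n_z_copies = 3L,
                              include_w_variant = TRUE, indel_length = 3L,
                              n_substitutions = 2L, seed = 1L) {
  stopifnot(is_count(base_length), is_count(n_z_copies), n_z_copies >= 1,
            is_count(indel_length), is_count(n_substitutions), is_count(seed))
  if (base_length < 60)
    stop("base_length must be at least 60 bases")
  margin <- 10L
  if (include_w_variant &&
      base_length - 2L * margin < indel_length + n_substitutions + 2L)
    stop("base_length too small to place the requested edits")
  with_local_seed(derive_seed(seed, "haplotypes"), {
    template <- random_dna(base_length)
    z_roles <- c("banf2a", "banf2b", rep("other", max(0, n_z_copies - 2L)))
    haps <- lapply(seq_len(n_z_copies), function(i) {
      haplotype(id = paste0("z", i, "_", z_roles[i]), sequence = template,
                chromosome = "Z", role = z_roles[i])
    })
    if (include_w_variant) {
      interior <- seq(margin + 1L, base_length - margin)
      del_start <- if (indel_length > 0)
        sample(interior[interior + indel_length - 1L <= max(interior)], 1L)
      else NA_integer_
      del_cols <- if (indel_length > 0)
        seq(del_start, del_start + indel_length - 1L) else integer(0)
      candidates <- setdiff(interior, del_cols)
      sub_pos <- if (n_substitutions > 0)
        sort(sample(candidates, n_substitutions)) else integer(0)
      chars <- strsplit(template, "")[[1]]
      for (p in sub_pos)
        chars[p] <- sample(setdiff(DNA_ALPHABET, chars[p]), 1L)
      if (indel_length > 0) chars <- chars[-del_cols]
      haps <- c(haps, list(haplotype(
        id = "w_banf2w", sequence = paste(chars, collapse = ""),
        chromosome = "W", role = "banf2w",
        annotations = list(substitutions = sub_pos,
                           deletion = if (indel_length > 0)
                             c(start = del_start, length = indel_length)
                           else NULL))))
    }
    haps
  })
}

#' Synthesize a composite Sanger chromatogram from a haplotype mixture
#'
#' Peak heights follow the linear mixture model: at each window position the
#' height on each base channel is `gain` times the summed copy numbers of the
#' haplotypes carrying that base there, each contribution perturbed by
#' multiplicative Gaussian noise with coefficient of variation `noise_cv`
#' (truncated at zero). Haplotypes are anchored at the window start in their
#' own coordinates, so an internal deletion shifts all downstream bases of
#' that haplotype and turns post-deletion positions into mixed peaks — the
#' mechanism that makes trace decomposition informative.
#'
#' @param haplotypes list of [haplotype()] objects.
#' @param copy_numbers integer copy number per haplotype (aligned 1:1; all
#'   `>= 0`, at least one positive).
#' @param window `c(start, end)` 1-based inclusive interval, interpreted in
#'   each haplotype's own coordinates.
#' @param noise_cv coefficient of variation of peak heights; 0 gives a
#'   deterministic trace.
#' @param gain mean height per unit copy.
#' @param seed integer seed (ignored when `noise_cv = 0`).
#' @return a [chromatogram()] with one row per window position.
#' @export
gen_trace <- function(haplotypes, copy_numbers, window, noise_cv = 0.05,
                      gain = 100, seed = 1L) {
  stopifnot(length(haplotypes) == length(copy_numbers),
            all(vapply(haplotypes, inherits, logical(1), "haplotype")),
            all(copy_numbers >= 0), is.numeric(noise_cv), noise_cv >= 0)
  if (!any(copy_numbers > 0)) stop("all copy numbers are zero")
  if (length(window) != 2L || window[2] < window[1])
    stop("empty or invalid window")
  lens <- vapply(haplotypes, function(h) nchar(h$sequence), integer(1))
  if (any(window[2] > lens))
    stop("window extends past the (shifted) end of haplotype(s): ",
         paste(vapply(haplotypes[window[2] > lens], `[[`, "", "id"),
               collapse = ", "))
  pos <- seq(window[1], window[2])
  L <- length(pos)
  bases <- vapply(haplotypes, function(h) {
    strsplit(substr(h$sequence, window[1], window[2]), "")[[1]]
  }, character(L))
  bases <- matrix(bases, nrow = L)
  heights <- matrix(0, nrow = L, ncol = 4L,
                    dimnames = list(NULL, DNA_ALPHABET))
  make_noise <- function(n) {
    if (noise_cv == 0) rep(1, n) else pmax(0, 1 + rnorm(n, 0, noise_cv))
  }
  with_local_seed(derive_seed(seed, "trace"), {
    for (h in seq_along(haplotypes)) {
      if (copy_numbers[h] == 0) next
      contrib <- gain * copy_numbers[h] * make_noise(L)
      for (i in seq_len(L)) {
        b <- bases[i, h]
        if (b %in% DNA_ALPHABET)
          heights[i, b] <- heights[i, b] + contrib[i]
      }
    }
    chromatogram(heights, anchor = window[1])
  })
}

#' Simulate a case-control cohort under the WZ/ZZ model
#'
#' Generates `n_females` WZ-truth and `n_males` ZZ-truth individuals (sampled
#' by sex, case-control style). Phenotypic sex is flipped with probability
#' `sex_reversal_rate`. Each marker genotype is inherited from the maternal W
#' or Z chromosome with the marker's recombination fraction to the
#' sex-determination locus (the paternal allele is always Z-linked), giving
#' genotypes `"W/Z"` or `"Z/Z"`. Truth columns are retained so parameter
#' recovery can be tested.
#'
#' @param config a [sim_config()].
#' @param markers data frame with columns `name` and optionally
#'   `recomb_fraction` (default taken from `config`) and `position_kbp`.
#' @return data frame with columns `id`, `sex` (`"F"`/`"M"`, phenotype), one
#'   genotype column per marker, and `truth_sd` (`"WZ"`/`"ZZ"`).
#' @export
gen_cohort <- function(config, markers) {
  stopifnot(inherits(config, "sim_config"), is.data.frame(markers),
            "name" %in% names(markers))
  n <- config$n_females + config$n_males
  if (n == 0) stop("cohort size is zero")
  rf <- markers$recomb_fraction %||% rep(config$recomb_fraction, nrow(markers))
  stopifnot(all(rf >= 0 & rf <= 1))
  with_local_seed(derive_seed(config$seed, "cohort"), {
    truth <- c(rep("WZ", config$n_females), rep("ZZ", config$n_males))
    flip <- runif(n) < config$sex_reversal_rate
    sex <- ifelse(xor(truth == "WZ", flip), "F", "M")
    out <- data.frame(id = sprintf("ind%03d", seq_len(n)), sex = sex,
                      stringsAsFactors = FALSE)
    for (m in seq_len(nrow(markers))) {
      recombined <- runif(n) < rf[m]
      maternal_w <- xor(truth == "WZ", recombined)
      out[[markers$name[m]]] <- ifelse(maternal_w, "W/Z", "Z/Z")
    }
    out$truth_sd <- truth
    out
  })
}

#' Simulate a read library with planted exact probe occurrences
#'
#' Builds `library_size` reads of `read_length` bases. For each transcript,
#' exactly `n_fwd` reads carry the transcript's designated probe verbatim and
#' `n_rev` carry its reverse complement; all remaining reads are random
#' background, rejection-sampled so they contain no probe in either
#' orientation. Planted counts are therefore exact ground truth for
#' [count_exact_hits()].
#'
#' @param transcripts data frame with columns `id`, `sequence`, `n_fwd` and
#'   optionally `n_rev` (default 0) and `probe` (default: the first
#'   `probe_length` bases of `sequence`).
#' @param read_length read length in bases (`>= probe_length`).
#' @param library_size total number of reads.
#' @param seed integer seed.
#' @param probe_length probe length in bases (default 32).
#' @return named [Biostrings::DNAStringSet] of reads, in randomized order.
#' @export
gen_reads <- function(transcripts, read_length, library_size, seed = 1L,
                      probe_length = 32L) {
  stopifnot(is.data.frame(transcripts),
            all(c("id", "sequence") %in% names(transcripts)),
            is_count(read_length), is_count(library_size))
  if (read_length < probe_length)
    stop("read_length must be at least the probe length (", probe_length, ")")
  n_fwd <- transcripts$n_fwd %||% rep(0L, nrow(transcripts))
  n_rev <- transcripts$n_rev %||% rep(0L, nrow(transcripts))
  probes <- transcripts$probe %||%
    toupper(substr(transcripts$sequence, 1L, probe_length))
  if (any(nchar(probes) != probe_length))
    stop("every probe must be exactly ", probe_length, " bases")
  n_planted <- sum(n_fwd) + sum(n_rev)
  if (n_planted > library_size)
    stop("planted read counts exceed library_size")
  forbidden <- unique(c(probes, revcomp(probes)))
  clean <- function(read, allow = character(0)) {
    hits <- vapply(setdiff(forbidden, allow), grepl, logical(1), x = read,
                   fixed = TRUE)
    !any(hits)
  }
  with_local_seed(derive_seed(seed, "reads"), {
    reads <- character(library_size)
    k <- 0L
    for (t in seq_len(nrow(transcripts))) {
      for (orient in c(rep("F", n_fwd[t]), rep("R", n_rev[t]))) {
        probe <- if (orient == "F") probes[t] else revcomp(probes[t])
        repeat {
          offset <- sample.int(read_length - probe_length + 1L, 1L)
          read <- paste0(
            if (offset > 1L) random_dna(offset - 1L) else "", probe,
            random_dna(read_length - probe_length - offset + 1L))
          if (clean(read, allow = probe)) break
        }
        k <- k + 1L
        reads[k] <- read
      }
    }
    for (i in seq_len(library_size - n_planted)) {
      tries <- 0L
      repeat {
        read <- random_dna(read_length)
        if (clean(read)) break
        tries <- tries + 1L
        if (tries > 1000L)
          stop("cannot sample probe-free background at this read_length")
      }
      k <- k + 1L
      reads[k] <- read
    }
    reads <- reads[sample.int(library_size)]
    out <- Biostrings::DNAStringSet(reads)
    names(out) <- sprintf("read%06d", seq_len(library_size))
    out
  })
}
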