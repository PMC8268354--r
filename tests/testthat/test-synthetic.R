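test_that("gen_haplotype_set places exactly the requested edits", {
  haps <- gen_haplotype_set(300, 3, TRUE, indel_length = 3,
                            n_substitutions = 2, seed = 7)
  expect_length(haps, 4L)
  z <- haps[[1]]; w <- haps[[4]]
  expect_true(all(vapply(haps[1:3], function(h)
    identical(h$sequence, z$sequence), logical(1))))
  expect_equal(w$chromosome, "W")
  expect_equal(w$role, "banf2w")
  expect_equal(nchar(w$sequence), 297L)
  # pairwise comparison oracle: reconstruct W from the template using the
  # recorded annotations and compare to the generated string
  ann <- w$annotations
  expect_length(ann$substitutions, 2L)
  chars <- strsplit(z$sequence, "")[[1]]
  wchars <- strsplit(w$sequence, "")[[1]]
  del <- seq(ann$deletion["start"], length.out = ann$deletion["length"])
  template_idx <- seq_along(chars)[-del]
  mismatches <- which(chars[-del] != wchars)
  expect_length(mismatches, 2L)  # exactly the substituted positions differ
  expect_setequal(template_idx[mismatches], ann$substitutions)
})

test_that("haplotype generation is deterministic in the seed and validates", {
  a <- gen_haplotype_set(300, 4, TRUE, 3, 3, seed = 11)
  b <- gen_haplotype_set(300, 4, TRUE, 3, 3, seed = 11)
  expect_identical(a, b)
  expect_length(a, 5L)  # five-copy configuration
  c1 <- gen_haplotype_set(300, 1, FALSE, 0, 0, seed = 1)
  expect_length(c1, 1L)
  expect_equal(nchar(c1[[1]]$sequence), 300L)
  expect_false(grepl("[^ACGT]", c1[[1]]$sequence))
  expect_error(gen_haplotype_set(50, 1, FALSE, 0, 0, seed = 1), "60")
  expect_error(gen_haplotype_set(60, 1, TRUE, 30, 30, seed = 1),
               "too small")
  expect_error(haplotype("x", "ACGT", "Z", "banf2w"), "chromosome")
})

test_that("noiseless traces obey the linear mixture model exactly", {
  pair <- make_snp_pair(len = 24, site = 10)
  # copies (2,1): minor channel carries exactly 1/3 at the SNP
  tr <- gen_trace(pair, c(2, 1), c(1, 24), noise_cv = 0, gain = 50)
  h <- tr$heights[10, ]
  expect_equal(sort(h[h > 0] / sum(h)), c(1 / 3, 2 / 3),
               ignore_attr = TRUE)
  # signal conservation: every column sum equals gain * total copies
  expect_equal(unname(rowSums(tr$heights)), rep(50 * 3, 24))
  # four equal copies, one W: W channel carries exactly 25% where it differs
  haps <- gen_haplotype_set(300, 3, TRUE, 0, 2, seed = 3)
  sub <- haps[[4]]$annotations$substitutions[1]
  tr4 <- gen_trace(haps, c(1, 1, 1, 1), c(1, 300), noise_cv = 0, gain = 10)
  hh <- tr4$heights[sub, ]
  expect_equal(min(hh[hh > 0]) / sum(hh), 0.25)
  # determinism with noise off and with noise on under a fixed seed
  expect_identical(tr4, gen_trace(haps, c(1, 1, 1, 1), c(1, 300),
                                  noise_cv = 0, gain = 10))
  n1 <- gen_trace(haps, c(1, 1, 1, 1), c(1, 300), 0.05, 10, seed = 9)
  n2 <- gen_trace(haps, c(1, 1, 1, 1), c(1, 300), 0.05, 10, seed = 9)
  expect_identical(n1, n2)
  expect_error(gen_trace(pair, c(0, 0), c(1, 24)), "zero")
  expect_error(gen_trace(pair, c(1, 1), c(5, 4)), "window")
  expect_error(gen_trace(pair, c(1, 1), c(1, 25)), "past")
})

test_that("cohort simulation respects truth, reversal and recombination", {
  markers <- data.frame(name = "m1", recomb_fraction = 0)
  cfg <- sim_config(seed = 5, n_females = 48, n_males = 48,
                    sex_reversal_rate = 0)
  coh <- gen_cohort(cfg, markers)
  expect_equal(nrow(coh), 96L)
  # perfect linkage, no reversal: genotype-by-sex table is [[48,0],[0,48]]
  tab <- table(coh$m1, coh$sex)
  expect_equal(unname(tab["W/Z", "F"]), 48L)
  expect_equal(unname(tab["Z/Z", "M"]), 48L)
  expect_true(all(coh$truth_sd[coh$sex == "F"] == "WZ"))
  expect_identical(coh, gen_cohort(cfg, markers))
  # recombination fraction recovers within binomial error at n = 2000
  big <- gen_cohort(sim_config(seed = 11, n_females = 1000, n_males = 1000,
                               sex_reversal_rate = 0),
                    data.frame(name = "m1", recomb_fraction = 0.25))
  disc <- mean((big$truth_sd == "WZ") != (big$m1 == "W/Z"))
  se <- sqrt(0.25 * 0.75 / 2000)
  expect_lt(abs(disc - 0.25), 4 * se)
})

test_that("read libraries carry exactly the planted probe occurrences", {
  # non-palindromic repeat so forward and reverse plants stay distinct
  tr <- data.frame(id = "t1", sequence = paste(rep("AACGT", 8), collapse = ""),
                   n_fwd = 5L)
  lib <- gen_reads(tr, read_length = 60, library_size = 500, seed = 2)
  expect_length(lib, 500L)
  probe <- substr(tr$sequence, 1, 32)
  hits <- sum(Biostrings::vcountPattern(probe, lib) > 0)
  expect_equal(hits, 5L)
  # plant zero: scanning finds nothing
  lib0 <- gen_reads(data.frame(id = "t1", sequence = tr$sequence,
                               n_fwd = 0L), 60, 200, seed = 3)
  expect_equal(sum(Biostrings::vcountPattern(probe, lib0) > 0), 0L)
  # orientation-aware planting: forward-only scan sees only forward plants
  tr2 <- data.frame(id = "t1", sequence = tr$sequence,
                    n_fwd = 3L, n_rev = 2L)
  lib2 <- gen_reads(tr2, 60, 300, seed = 4)
  fwd <- sum(Biostrings::vcountPattern(probe, lib2) > 0)
  rev <- sum(Biostrings::vcountPattern(revcomp(probe), lib2) > 0)
  expect_equal(fwd, 3L)
  expect_equal(fwd + rev, 5L)
  expect_identical(as.character(lib2), as.character(gen_reads(tr2, 60, 300,
                                                              seed = 4)))
  expect_error(gen_reads(tr, read_length = 20, library_size = 10),
               "read_length")
  expect_error(gen_reads(tr, 60, 3), "exceed")
})
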