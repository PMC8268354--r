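test_that("signature matrices encode SNPs, indels and identifiability", {
  pair <- make_snp_pair(len = 50, site = 25)
  sig <- build_signatures(pair, 1, 50)
  expect_true(attr(sig, "identifiable"))
  # one differing site: columns differ in exactly 2 rows (two channels)
  expect_equal(sum(sig[, 1] != sig[, 2]), 2L)
  # identical haplotypes: identical columns, flag cleared
  twins <- list(pair[[1]], haplotype("h1b", pair[[1]]$sequence, "Z"))
  sig2 <- build_signatures(twins, 1, 50)
  expect_false(attr(sig2, "identifiable"))
  expect_equal(length(attr(sig2, "groups")), 1L)
  # a 3-base deletion shifts everything downstream of it
  haps <- gen_haplotype_set(300, 1, TRUE, 3, 0, seed = 5)
  del <- haps[[2]]$annotations$deletion
  sig3 <- build_signatures(haps, 1, 297)
  per_pos <- colSums(matrix(sig3[, 1] != sig3[, 2], nrow = 4)) > 0
  expect_true(all(!per_pos[seq_len(del["start"] - 1)]))
  expect_gt(mean(per_pos[del["start"]:297]), 0.5)
  expect_error(build_signatures(haps, 1, 298), "past")
})

test_that("noiseless decomposition recovers weights to machine precision", {
  pair <- make_snp_pair(len = 50, site = 25)
  for (w in list(c(3, 1), c(2, 1), c(1, 4), c(5, 2))) {
    tr <- gen_trace(pair, w, c(1, 50), noise_cv = 0, gain = 80)
    est <- decompose_trace(tr, build_signatures(pair, 1, 50))
    expect_equal(unname(est$proportions), w / sum(w), tolerance = 1e-12)
    expect_equal(est$r_squared, 1)
    # scale invariance: scaling all heights leaves proportions unchanged
    tr2 <- chromatogram(tr$heights * 7.3, anchor = tr$anchor)
    est2 <- decompose_trace(tr2, build_signatures(pair, 1, 50))
    expect_equal(est2$proportions, est$proportions, tolerance = 1e-12)
  }
})

test_that("decomposition rejects degenerate inputs", {
  pair <- make_snp_pair(len = 50, site = 25)
  twins <- list(pair[[1]], haplotype("h1b", pair[[1]]$sequence, "Z"))
  tr <- gen_trace(twins, c(1, 1), c(1, 50), noise_cv = 0)
  expect_error(decompose_trace(tr, build_signatures(twins, 1, 50)),
               "collapse_signatures")
  merged <- collapse_signatures(build_signatures(twins, 1, 50))
  est <- decompose_trace(tr, merged)
  expect_equal(unname(est$proportions), 1)
  expect_error(chromatogram(matrix(0, 10, 4)), "positive")
  short <- gen_trace(pair, c(1, 1), c(1, 40), noise_cv = 0)
  expect_error(decompose_trace(short, build_signatures(pair, 1, 50)),
               "match")
})

test_that("NNLS matches the exhaustive simplex grid-search oracle", {
  pair <- make_snp_pair(len = 10, site = 5)
  for (w in list(c(3, 1), c(1, 1), c(1, 5))) {
    tr <- gen_trace(pair, w, c(1, 10), noise_cv = 0.05, gain = 100,
                    seed = sum(w) * 17)
    S <- build_signatures(pair, 1, 10)
    est <- decompose_trace(tr, S)
    oracle <- grid_oracle(unclass(S), as.numeric(t(tr$heights)), res = 1e-3)
    expect_equal(unname(est$proportions), oracle, tolerance = 2e-3)
  }
  # three haplotypes differing at two sites
  trio <- c(make_snp_pair(len = 10, site = 3), make_snp_pair(10, 8)[2])
  trio[[3]] <- haplotype("h3", trio[[3]]$sequence, "Z", "banf2b")
  S3 <- build_signatures(trio, 1, 10)
  expect_true(attr(S3, "identifiable"))
  tr3 <- gen_trace(trio, c(2, 1, 1), c(1, 10), noise_cv = 0.05, gain = 100,
                   seed = 99)
  est3 <- decompose_trace(tr3, S3)
  oracle3 <- grid_oracle(unclass(S3), as.numeric(t(tr3$heights)), res = 1e-3)
  expect_equal(unname(est3$proportions), oracle3, tolerance = 2e-3)
})

test_that("minor-proportion estimates are unbiased under 5% peak noise", {
  haps <- gen_haplotype_set(300, 3, TRUE, 3, 2, seed = 7)
  wl <- 297L
  sig <- collapse_signatures(build_signatures(haps, 1, wl))
  ests <- vapply(1:200, function(r) {
    tr <- gen_trace(haps, c(1, 1, 1, 1), c(1, wl), noise_cv = 0.05,
                    gain = 100, seed = 1000 + r)
    w_fraction_of(decompose_trace(tr, sig))
  }, numeric(1))
  se <- sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests) - 0.25), 3 * se + 1e-4)
  expect_true(all(abs(ests - 0.25) < 0.05))
})

test_that("forward and reverse orientations combine by mean and min", {
  p_f <- mixture_estimate(c(a = 0.76, b = 0.24), r_squared = 0.99)
  p_r <- mixture_estimate(c(b = 0.26, a = 0.74), r_squared = 0.95)
  comb <- combine_orientations(p_f, p_r)
  expect_equal(unname(comb$proportions["b"]), 0.25)
  expect_equal(comb$r_squared, 0.95)
  expect_equal(combine_orientations(p_f, p_f)$proportions, p_f$proportions)
  # the ~33% reading: F minor 0.30, R minor 0.36 average to 0.33
  f <- mixture_estimate(c(z = 0.70, w = 0.30))
  r <- mixture_estimate(c(z = 0.64, w = 0.36))
  expect_equal(unname(combine_orientations(f, r)$proportions["w"]), 0.33)
  expect_error(combine_orientations(
    p_f, mixture_estimate(c(a = 0.5, c = 0.5))), "ismatch")
})

test_that("peak ratios read copy proportions off a single informative site", {
  h <- matrix(0, 3, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  h[2, "T"] <- 200; h[2, "C"] <- 100; h[1, "A"] <- 10; h[3, "G"] <- 10
  tr <- chromatogram(h, anchor = 11)
  pr <- peak_ratio(tr, 12, c("T", "C"))
  expect_equal(unname(pr$proportions), c(2 / 3, 1 / 3))
  h[2, "C"] <- 200
  expect_equal(unname(peak_ratio(chromatogram(h, 11), 12,
                                 c("T", "C"))$proportions), c(0.5, 0.5))
  # a noiseless 3-copy T,T,C male mixture shows C at exactly 1/3
  base <- paste(rep("ACGT", 6), collapse = "")
  t_hap <- haplotype("a", base, "Z", "banf2a")
  chars <- strsplit(base, "")[[1]]; chars[12] <- "C"  # template has T here
  c_hap <- haplotype("b", paste(chars, collapse = ""), "Z", "banf2b")
  tr3 <- gen_trace(list(t_hap, c_hap), c(2, 1), c(1, 24), noise_cv = 0)
  pr3 <- peak_ratio(tr3, 12, c("T", "C"))
  expect_equal(unname(pr3$proportions["C"]), 1 / 3)
  expect_error(peak_ratio(tr, 99, c("T", "C")), "outside")
  expect_error(peak_ratio(tr, 11, c("C", "G")), "zero")
})
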