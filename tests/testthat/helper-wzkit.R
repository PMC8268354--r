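# Shared fixtures and independent oracles, all built in code.

gcd_pair <- function(a, b) if (b == 0L) a else gcd_pair(b, a %% b)

# hand-built two-haplotype pair differing at one site
make_snp_pair <- function(len = 20L, site = 10L) {
  base <- paste(rep(c("A", "C", "G", "T"), length.out = len), collapse = "")
  chars <- strsplit(base, "")[[1]]
  alt <- chars
  alt[site] <- setdiff(c("A", "C", "G", "T"), chars[site])[1]
  list(haplotype("h1", base, "Z", "banf2a"),
       haplotype("h2", paste(alt, collapse = ""), "W", "banf2w"))
}

# independent brute-force Freeman-Halton p-value for small r x 2 tables
brute_force_rxc <- function(tab) {
  tab <- as.matrix(tab)
  N <- sum(tab)
  c1 <- sum(tab[, 1])
  rt <- rowSums(tab)
  all <- expand.grid(lapply(rt, function(m) 0:m))
  all <- all[rowSums(all) == c1, , drop = FALSE]
  p <- apply(all, 1L, function(a) prod(choose(rt, a)) / choose(N, c1))
  pobs <- prod(choose(rt, tab[, 1])) / choose(N, c1)
  sum(p[p <= pobs * (1 + 1e-7)])
}

# exhaustive simplex grid-search oracle for NNLS mixture proportions
# (2 or 3 columns); optimal scale per proportion vector is closed-form
grid_oracle <- function(S, y, res = 1e-3) {
  k <- ncol(S)
  eval_props <- function(P) {
    M <- S %*% t(P)
    num <- colSums(M * y)
    den <- colSums(M * M)
    s <- pmax(num / den, 0)
    ssr <- sum(y^2) - 2 * s * num + s^2 * den
    P[which.min(ssr), ]
  }
  if (k == 2L) {
    p1 <- seq(0, 1, by = res)
    best <- eval_props(cbind(p1, 1 - p1))
  } else if (k == 3L) {
    coarse <- expand.grid(p1 = seq(0, 1, by = 0.01),
                          p2 = seq(0, 1, by = 0.01))
    coarse <- coarse[coarse$p1 + coarse$p2 <= 1, ]
    b <- eval_props(cbind(coarse$p1, coarse$p2,
                          1 - coarse$p1 - coarse$p2))
    fine <- expand.grid(
      p1 = seq(max(0, b[1] - 0.02), min(1, b[1] + 0.02), by = res),
      p2 = seq(max(0, b[2] - 0.02), min(1, b[2] + 0.02), by = res))
    fine <- fine[fine$p1 + fine$p2 <= 1, ]
    best <- eval_props(cbind(fine$p1, fine$p2, 1 - fine$p1 - fine$p2))
  } else stop("oracle supports 2 or 3 columns")
  unname(best)
}

# genotype-by-sex cohort reconstructed from published per-marker counts:
# each marker column is filled to match the printed female/male genotype
# counts (markers are assigned independently; only marginals matter here)
make_marker_table3_cohort <- function() {
  sexes <- c(rep("F", 48L), rep("M", 48L))
  fill <- function(f_counts, m_counts) {
    c(rep(names(f_counts), f_counts), rep(names(m_counts), m_counts))
  }
  data.frame(
    id = sprintf("ind%02d", 1:96), sex = sexes,
    UNH168 = fill(c(`N/N` = 5, `N/W` = 22, `N/Z` = 8, `Z/W` = 13, `Z/Z` = 0),
                  c(`N/N` = 12, `N/W` = 2, `N/Z` = 29, `Z/W` = 0, `Z/Z` = 5)),
    Paics_long = fill(c(`F/F` = 27, `F/S` = 21, `S/S` = 0),
                      c(`F/F` = 14, `F/S` = 29, `S/S` = 5)),
    Banf2_del = fill(c(`F/S` = 48, `S/S` = 0), c(`F/S` = 1, `S/S` = 47)),
    Banf2_w = fill(c(`W/Z` = 48, `Z/Z` = 0), c(`W/Z` = 1, `Z/Z` = 47)),
    Paics_short = fill(c(P = 48, A = 0), c(P = 1, A = 47)),
    M1_like = fill(c(`F/F` = 4, `F/S` = 25, `S/S` = 19),
                   c(`F/F` = 5, `F/S` = 10, `S/S` = 33)),
    stringsAsFactors = FALSE)
}

table3_markers <- function() {
  data.frame(
    name = c("UNH168", "Paics_long", "Banf2_del", "Banf2_w",
             "Paics_short", "M1_like"),
    position_kbp = c(64515, 73159, 73177, 73178, 73217, 73394),
    stringsAsFactors = FALSE)
}

# forward+reverse decomposition of a copy mixture, returning the combined
# W-specific proportion estimate
decompose_both_ways <- function(haps, copies, noise_cv, seed, gain = 100) {
  wl <- min(vapply(haps, function(h) nchar(h$sequence), integer(1)))
  haps_r <- lapply(haps, function(h)
    haplotype(h$id, revcomp(h$sequence), h$chromosome, h$role))
  sig_f <- collapse_signatures(build_signatures(haps, 1L, wl))
  sig_r <- collapse_signatures(build_signatures(haps_r, 1L, wl))
  tr_f <- gen_trace(haps, copies, c(1L, wl), noise_cv = noise_cv,
                    gain = gain, seed = seed)
  tr_r <- gen_trace(haps_r, copies, c(1L, wl), noise_cv = noise_cv,
                    gain = gain, seed = seed + 100000L)
  combine_orientations(decompose_trace(tr_f, sig_f),
                       decompose_trace(tr_r, sig_r))
}

w_fraction_of <- function(estimate) {
  unname(estimate$proportions[grep("banf2w", names(estimate$proportions))])
}
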