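#' Two-sided Fisher exact test for a 2x2 genotype-by-sex table
#'
#' Direct hypergeometric enumeration with both margins fixed: the two-sided
#' p-value is the sum of point probabilities of all tables no more probable
#' than the observed one (point-probability method, with a relative tie
#' tolerance of 1e-7). This is the method behind the marker-sex association
#' p-values of the WZ/ZZ mapping design, where a 48:1 / 0:47 split yields
#' p of order 1e-26.
#'
#' @param table 2x2 matrix of non-negative integer counts (rows genotypes,
#'   columns sexes).
#' @return two-sided p-value.
#' @export
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  stopifnot(nrow(table) == 2L, ncol(table) == 2L, all(table >= 0),
            all(table == floor(table)))
  N <- sum(table)
  r1 <- sum(table[1, ]); c1 <- sum(table[, 1])
  if (r1 == 0 || r1 == N || c1 == 0 || c1 == N) {
    warning("empty margin: no association is testable; p = 1")
    return(1)
  }
  support <- max(0L, r1 + c1 - N):min(r1, c1)
  probs <- dhyper(support, c1, N - c1, r1)
  p_obs <- dhyper(table[1, 1], c1, N - c1, r1)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# all first-column count vectors (a_1..a_r) with a_i <= row_i, sum = c1
.enumerate_col1 <- function(row_totals, c1) {
  r <- length(row_totals)
  out <- list()
  recurse <- function(i, remaining, acc) {
    if (i > r) {
      if (remaining == 0L) out[[length(out) + 1L]] <<- acc
      return(invisible())
    }
    rest_max <- if (i < r) sum(row_totals[(i + 1L):r]) else 0L
    lo <- max(0L, remaining - rest_max)
    hi <- min(row_totals[i], remaining)
    if (lo > hi) return(invisible())
    for (a in lo:hi) recurse(i + 1L, remaining - a, c(acc, a))
  }
  recurse(1L, c1, integer(0))
  out
}

#' Freeman-Halton exact test for an r x 2 contingency table
#'
#' Exact generalization of Fisher's test to r x 2 tables: all tables with
#' both margins fixed are enumerated, each with probability
#' `prod(choose(row_total_i, a_i)) / choose(N, c1)`, and the p-value is the
#' sum of probabilities of tables no more probable than the observed one
#' (relative tie tolerance 1e-7). Feasible for up to 8 genotype rows, the
#' scale of the multi-genotype markers in the association tables.
#'
#' @param table r x 2 matrix of non-negative integer counts, `r <= 8`.
#' @return two-sided exact p-value.
#' @export
fisher_exact_rxc <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(table >= 0), all(table == floor(table)))
  if (ncol(table) != 2L)
    stop("only two-column (genotype x sex) tables are supported")
  if (nrow(table) > 8L)
    stop("tables with more than 8 rows are beyond the enumeration bound")
  keep <- rowSums(table) > 0
  table <- table[keep, , drop = FALSE]
  if (nrow(table) < 2L) {
    warning("fewer than two non-empty genotype rows; p = 1")
    return(1)
  }
  N <- sum(table)
  c1 <- sum(table[, 1])
  if (c1 == 0 || c1 == N) {
    warning("empty sex margin: no association is testable; p = 1")
    return(1)
  }
  row_totals <- rowSums(table)
  configs <- .enumerate_col1(as.integer(row_totals), as.integer(c1))
  logp <- vapply(configs, function(a) {
    sum(lchoose(row_totals, a)) - lchoose(N, c1)
  }, numeric(1))
  logp_obs <- sum(lchoose(row_totals, table[, 1])) - lchoose(N, c1)
  min(1, sum(exp(logp[logp <= logp_obs + log1p(1e-7)])))
}

#' Allele frequencies at a biallelic W/Z locus
#' @param p_z frequency of the Z allele in `[0, 1]`.
#' @return object of class `allele_freqs` with `p_z` and `q_w = 1 - p_z`.
#' @export
allele_freqs <- function(p_z = 0.5) {
  stopifnot(is_probability(p_z))
  structure(list(p_z = p_z, q_w = 1 - p_z), class = "allele_freqs")
}

#' Hardy-Weinberg expected genotype counts
#'
#' Expected (ZZ, WZ, WW) counts under random mating: `n * (p^2, 2pq, q^2)`.
#'
#' @param freqs an [allele_freqs()] (or a bare `p_z` value).
#' @param n sample size.
#' @return named numeric vector `c(ZZ, WZ, WW)`.
#' @export
hwe_expected <- function(freqs, n) {
  if (is.numeric(freqs)) freqs <- allele_freqs(freqs)
  stopifnot(inherits(freqs, "allele_freqs"), is_count(n))
  p <- freqs$p_z; q <- freqs$q_w
  setNames(n * c(p^2, 2 * p * q, q^2), c("ZZ", "WZ", "WW"))
}

#' Expected genotype counts under constrained inheritance models
#'
#' Three inheritance models for the distribution of W among females:
#' `autosomal` is plain Hardy-Weinberg; `lethal_ww` eliminates the WW class
#' and renormalizes (`p^2/(1-q^2), 2pq/(1-q^2), 0`); `female_w` makes the
#' heterozygote the only female class (`0, n, 0`).
#'
#' @param model_name `"autosomal"`, `"lethal_ww"` or `"female_w"`.
#' @param freqs an [allele_freqs()] (or a bare `p_z`).
#' @param n sample size.
#' @return named numeric vector `c(ZZ, WZ, WW)` summing to `n`.
#' @export
model_expected <- function(model_name = c("autosomal", "lethal_ww",
                                          "female_w"), freqs, n) {
  model_name <- match.arg(model_name)
  if (is.numeric(freqs)) freqs <- allele_freqs(freqs)
  stopifnot(inherits(freqs, "allele_freqs"), is_count(n))
  p <- freqs$p_z; q <- freqs$q_w
  out <- switch(model_name,
    autosomal = hwe_expected(freqs, n),
    lethal_ww = {
      if (q == 1) stop("lethal_ww model undefined at q_w = 1")
      setNames(n * c(p^2, 2 * p * q, 0) / (1 - q^2), c("ZZ", "WZ", "WW"))
    },
    female_w = setNames(c(0, n, 0), c("ZZ", "WZ", "WW")))
  out
}

#' Pearson chi-squared goodness of fit of observed against expected counts
#'
#' `chi2 = sum((O - E)^2 / E)` over cells with positive expectation; a cell
#' with observed counts but zero expectation rejects the model outright
#' (p = 0). Degrees of freedom are the number of supported cells minus one;
#' a saturated model (df 0, chi2 0) has p = 1.
#'
#' @param observed,expected equal-length non-negative count vectors.
#' @param model_name optional label carried into the result.
#' @return object of class `gof_result`: `chi2`, `df`, `p`, `expected`,
#'   `model_name`.
#' @export
gof_pearson <- function(observed, expected, model_name = NULL) {
  stopifnot(length(observed) == length(expected), all(observed >= 0),
            all(expected >= 0))
  supported <- expected > 0
  if (any(observed[!supported] > 0)) {
    res <- list(chi2 = Inf, df = sum(supported) - 1L, p = 0,
                expected = expected, model_name = model_name)
    return(structure(res, class = "gof_result"))
  }
  chi2 <- sum((observed[supported] - expected[supported])^2 /
                expected[supported])
  df <- sum(supported) - 1L
  p <- if (df == 0L) as.numeric(chi2 == 0)
       else pchisq(chi2, df, lower.tail = FALSE)
  structure(list(chi2 = chi2, df = df, p = p, expected = expected,
                 model_name = model_name), class = "gof_result")
}

#' @export
print.gof_result <- function(x, ...) {
  cat(sprintf("<gof_result%s> chi2 = %.4g, df = %d, p = %.3g\n",
              if (is.null(x$model_name)) "" else paste0(" ", x$model_name),
              x$chi2, x$df, x$p))
  invisible(x)
}

#' Chi-squared test for deviation from Hardy-Weinberg equilibrium
#'
#' Allele frequencies are estimated from the genotype counts
#' (`q_w = (WZ + 2 WW) / 2N`), expectations are Hardy-Weinberg, and the
#' statistic is compared to chi-squared on one degree of freedom (three
#' classes, one estimated parameter). The absence of WW homozygotes among
#' W carriers drives the deviation that flags a sex-linked locus.
#'
#' @param genotype_counts named or positional counts `c(ZZ, WZ, WW)`.
#' @return a `gof_result`; monomorphic input gives p = 1.
#' @export
hwe_deviation_test <- function(genotype_counts) {
  stopifnot(length(genotype_counts) == 3L, all(genotype_counts >= 0),
            sum(genotype_counts) > 0)
  o <- as.numeric(genotype_counts)
  n <- sum(o)
  q <- (o[2] + 2 * o[3]) / (2 * n)
  if (q == 0 || q == 1) {
    return(structure(list(chi2 = 0, df = 1L, p = 1,
                          expected = hwe_expected(allele_freqs(1 - q), n),
                          model_name = "hwe"), class = "gof_result"))
  }
  expected <- hwe_expected(allele_freqs(1 - q), n)
  chi2 <- sum((o - expected)^2 / expected)
  structure(list(chi2 = chi2, df = 1L,
                 p = pchisq(chi2, 1L, lower.tail = FALSE),
                 expected = expected, model_name = "hwe"),
            class = "gof_result")
}

#' Marker-by-marker exact association scan with critical-interval report
#'
#' For each marker column of the cohort, builds the genotype-by-sex
#' contingency table (dominant markers are first collapsed to
#' presence/absence of the dominant allele), applies the exact test matching
#' the table's dimension, and ranks markers by p-value. The critical interval
#' is delimited by the nearest flanking markers, on either side of the block
#' of maximally associated markers, that do not reach the block's minimal
#' p-value; its span is reported in the positions' units.
#'
#' @param cohort data frame with a `sex` column (`"F"`/`"M"`) and one
#'   genotype column per marker.
#' @param markers data frame with columns `name` and optionally
#'   `position_kbp` and `dominant` (logical; dominant markers code carriers
#'   by presence of the `"W"`-bearing or listed `dominant_allele`).
#' @param alpha significance threshold used only for labelling (default
#'   0.05); raw p-values are reported without multiplicity adjustment.
#' @return list with `results` (data frame: marker, position_kbp, test, p),
#'   `tables` (named list of contingency tables) and `critical_interval`
#'   (list: lower, upper, span_kbp; `NULL` when positions are absent).
#' @export
association_scan <- function(cohort, markers, alpha = 0.05) {
  stopifnot(is.data.frame(cohort), "sex" %in% names(cohort),
            is.data.frame(markers), "name" %in% names(markers))
  if (!all(markers$name %in% names(cohort)))
    stop("cohort lacks genotype columns for some markers")
  sex <- factor(cohort$sex, levels = c("F", "M"))
  if (any(is.na(sex))) stop("sex column must contain only 'F' and 'M'")
  single_sex <- length(unique(cohort$sex)) < 2L
  if (single_sex)
    warning("single-sex cohort: association is untestable; all p = 1")
  dominant <- markers$dominant %||% rep(FALSE, nrow(markers))
  tables <- list()
  res <- data.frame(marker = markers$name,
                    position_kbp = markers$position_kbp %||%
                      rep(NA_real_, nrow(markers)),
                    test = NA_character_, p = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(markers))) {
    g <- as.character(cohort[[markers$name[i]]])
    if (dominant[i]) {
      allele <- markers$dominant_allele[i] %||% "W"
      g <- ifelse(grepl(allele, g, fixed = TRUE), "P", "A")
    }
    tab <- table(genotype = g, sex = sex)
    tab <- unclass(tab)[order(rownames(unclass(tab))), , drop = FALSE]
    tables[[markers$name[i]]] <- tab
    if (single_sex) {
      res$test[i] <- "none"; res$p[i] <- 1
      next
    }
    if (nrow(tab) < 2L) {
      res$test[i] <- "none"; res$p[i] <- 1
      next
    }
    if (nrow(tab) == 2L) {
      res$test[i] <- "fisher_2x2"
      res$p[i] <- fisher_exact_2x2(tab)
    } else {
      res$test[i] <- "freeman_halton"
      res$p[i] <- fisher_exact_rxc(tab)
    }
  }
  res$significant <- res$p <= alpha
  interval <- NULL
  if (!all(is.na(res$position_kbp))) {
    pos_res <- res[!is.na(res$position_kbp), ]
    p_min <- min(pos_res$p)
    in_block <- pos_res$p <= p_min * (1 + 1e-7)
    block_lo <- min(pos_res$position_kbp[in_block])
    block_hi <- max(pos_res$position_kbp[in_block])
    below <- pos_res$position_kbp[!in_block & pos_res$position_kbp < block_lo]
    above <- pos_res$position_kbp[!in_block & pos_res$position_kbp > block_hi]
    lower <- if (length(below)) max(below) else block_lo
    upper <- if (length(above)) min(above) else block_hi
    interval <- list(lower = lower, upper = upper, span_kbp = upper - lower)
  }
  list(results = res[order(res$p), ], tables = tables,
       critical_interval = interval)
}

#' One-way analysis of variance across groups
#'
#' Classical fixed-effects decomposition (equal-variance F test), the test
#' used for comparing expression values between developmental stages and
#' haplotype classes.
#'
#' @param groups list of numeric vectors (>= 2 groups; at least one group
#'   with >= 2 values).
#' @return list with `F`, `p`, and `df` (numerator, denominator).
#' @export
anova_oneway <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L,
            all(lengths(groups) >= 1L), any(lengths(groups) >= 2L))
  values <- unlist(groups)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (all(values == values[1]))
    stop("all values identical: F is undefined (0/0)")
  fit <- oneway.test(values ~ g, var.equal = TRUE)
  list(F = unname(fit$statistic), p = unname(fit$p.value),
       df = unname(fit$parameter))
}
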