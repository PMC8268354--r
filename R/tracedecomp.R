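#' Construct a chromatogram (per-position four-channel peak heights)
#'
#' @param heights numeric matrix, one row per trace position, columns the
#'   A/C/G/T channels; all entries non-negative, at least one positive row.
#' @param anchor 1-based coordinate of the first row.
#' @param annotations optional named list of informative sites.
#' @return object of class `chromatogram`.
#' @export
chromatogram <- function(heights, anchor = 1L, annotations = list()) {
  heights <- as.matrix(heights)
  if (ncol(heights) != 4L)
    stop("heights must have four channel columns (A, C, G, T)")
  colnames(heights) <- DNA_ALPHABET
  if (any(heights < 0)) stop("peak heights must be non-negative")
  if (!any(rowSums(heights) > 0)) stop("trace has no positive row")
  structure(list(heights = heights, anchor = as.integer(anchor),
                 annotations = annotations),
            class = "chromatogram")
}

#' @export
print.chromatogram <- function(x, ...) {
  cat(sprintf("<chromatogram> %d positions, anchor %d, mean height %.1f\n",
              nrow(x$heights), x$anchor, mean(x$heights)))
  invisible(x)
}

#' Build the binary signature (design) matrix for trace decomposition
#'
#' Each candidate haplotype contributes one column; rows are (position,
#' channel) pairs over the anchored window, ordered position-major with
#' channels A, C, G, T. Haplotypes are anchored at `anchor` in their own
#' coordinates, so an internal deletion shifts a haplotype's downstream bases
#' relative to the others — exactly the signal the decomposition exploits.
#' Haplotypes identical over the window yield identical columns and are
#' reported as an unidentifiable group; merge them with
#' [collapse_signatures()] before fitting.
#'
#' @param haplotypes list of [haplotype()] objects.
#' @param anchor 1-based start coordinate of the window.
#' @param window_length window length in bases.
#' @return binary matrix of class `signature_matrix` with attributes
#'   `anchor`, `window_length`, `groups` (list of identical-column groups)
#'   and `identifiable` (no duplicated columns).
#' @export
build_signatures <- function(haplotypes, anchor, window_length) {
  stopifnot(length(haplotypes) >= 1,
            all(vapply(haplotypes, inherits, logical(1), "haplotype")),
            is_count(anchor), anchor >= 1, is_count(window_length),
            window_length >= 1)
  lens <- vapply(haplotypes, function(h) nchar(h$sequence), integer(1))
  too_short <- anchor + window_length - 1L > lens
  if (any(too_short))
    stop("window extends past the shifted end of haplotype(s): ",
         paste(vapply(haplotypes[too_short], `[[`, "", "id"), collapse = ", "))
  ids <- vapply(haplotypes, `[[`, "", "id")
  S <- vapply(haplotypes, function(h) {
    bases <- strsplit(substr(h$sequence, anchor,
                             anchor + window_length - 1L), "")[[1]]
    as.numeric(t(outer(bases, DNA_ALPHABET, `==`)))
  }, numeric(4L * window_length))
  S <- matrix(S, nrow = 4L * window_length, dimnames = list(
    paste0("p", rep(seq(anchor, anchor + window_length - 1L), each = 4L),
           "_", rep(DNA_ALPHABET, window_length)),
    ids))
  keys <- apply(S, 2L, paste, collapse = "")
  groups <- split(ids, factor(keys, levels = unique(keys)))
  names(groups) <- vapply(groups, paste, "", collapse = "+")
  structure(S, class = c("signature_matrix", "matrix"),
            anchor = as.integer(anchor),
            window_length = as.integer(window_length),
            groups = unname(groups)[lengths(groups) >= 1],
            identifiable = !anyDuplicated(keys))
}

#' Merge identical signature columns into identifiable groups
#'
#' Haplotypes indistinguishable over the decomposition window (for example
#' the identical Z-linked banf2a/banf2b copies outside their diagnostic SNP)
#' are collapsed into a single column named by joining their ids with `+`.
#' The fitted weight of a merged column is the summed weight of its members.
#'
#' @param signatures a [build_signatures()] result.
#' @return `signature_matrix` with unique columns.
#' @export
collapse_signatures <- function(signatures) {
  stopifnot(inherits(signatures, "signature_matrix"))
  groups <- attr(signatures, "groups")
  cols <- vapply(groups, function(g) g[[1]], "")
  S <- signatures[, cols, drop = FALSE]
  colnames(S) <- vapply(groups, paste, "", collapse = "+")
  structure(S, class = c("signature_matrix", "matrix"),
            anchor = attr(signatures, "anchor"),
            window_length = attr(signatures, "window_length"),
            groups = groups, identifiable = TRUE)
}

#' Construct a mixture estimate
#' @param proportions named non-negative fractions summing to 1.
#' @param weights raw non-negative fit coefficients.
#' @param r_squared fit quality in `[0, 1]`.
#' @param method `"nnls"` or `"peak_ratio"`.
#' @return object of class `mixture_estimate`.
#' @export
mixture_estimate <- function(proportions, weights = proportions,
                             r_squared = 1, method = c("nnls", "peak_ratio")) {
  method <- match.arg(method)
  stopifnot(all(proportions >= 0), abs(sum(proportions) - 1) < 1e-9,
            r_squared >= 0, r_squared <= 1, all(weights >= 0))
  structure(list(proportions = proportions, weights = weights,
                 r_squared = r_squared, method = method),
            class = "mixture_estimate")
}

#' @export
print.mixture_estimate <- function(x, ...) {
  cat(sprintf("<mixture_estimate> method %s, R^2 = %.4f\n", x$method,
              x$r_squared))
  print(round(x$proportions, 4))
  invisible(x)
}

#' Decompose a composite chromatogram into haplotype mixture proportions
#'
#' Non-negative least-squares fit of the trace heights, flattened over
#' (position, channel) rows, on the binary signature columns; the estimated
#' proportions are the NNLS weights normalized to sum to one. This is a
#' linear trace-decomposition estimator in the style of the TIDE family of
#' chromatogram mixture tools. For a noiseless trace generated from weights
#' `w` and identifiable signatures it recovers `w / sum(w)` to machine
#' precision with `R^2 = 1`.
#'
#' @param trace a [chromatogram()] whose window matches `signatures`.
#' @param signatures a [build_signatures()] (or [collapse_signatures()])
#'   matrix; identical columns must be merged first.
#' @return a [mixture_estimate()]; `r_squared` is `1 - SSR/SST` (SST about
#'   the mean height), clamped to `[0, 1]`.
#' @export
decompose_trace <- function(trace, signatures) {
  stopifnot(inherits(trace, "chromatogram"),
            inherits(signatures, "signature_matrix"))
  y <- as.numeric(t(trace$heights))
  if (length(y) != nrow(signatures))
    stop("trace rows do not match signature rows")
  if (trace$anchor != attr(signatures, "anchor"))
    stop("trace anchor does not match signature anchor")
  if (all(y == 0)) stop("all-zero trace")
  if (!attr(signatures, "identifiable") ||
      anyDuplicated(apply(signatures, 2L, paste, collapse = "")))
    stop("signatures contain identical columns; merge them with ",
         "collapse_signatures() before decomposing")
  fit <- pracma::lsqnonneg(unclass(signatures), y)
  w <- pmax(fit$x, 0)
  if (sum(w) == 0) stop("degenerate fit: all weights zero")
  names(w) <- colnames(signatures)
  ssr <- sum((y - as.numeric(signatures %*% w))^2)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst == 0) as.numeric(ssr == 0) else 1 - ssr / sst
  mixture_estimate(proportions = w / sum(w), weights = w,
                   r_squared = min(max(r2, 0), 1), method = "nnls")
}

#' Combine forward- and reverse-orientation mixture estimates
#'
#' Proportions are averaged (unweighted mean per haplotype) and the combined
#' fit quality is the more conservative (minimum) of the two.
#'
#' @param estimate_f,estimate_r [mixture_estimate()]s over the same
#'   haplotype set.
#' @return combined [mixture_estimate()].
#' @export
combine_orientations <- function(estimate_f, estimate_r) {
  stopifnot(inherits(estimate_f, "mixture_estimate"),
            inherits(estimate_r, "mixture_estimate"))
  if (estimate_f$method != estimate_r$method)
    stop("cannot combine estimates with different methods")
  nf <- names(estimate_f$proportions)
  if (!setequal(nf, names(estimate_r$proportions)))
    stop("mismatched haplotype sets between orientations")
  pr <- (estimate_f$proportions[nf] + estimate_r$proportions[nf]) / 2
  mixture_estimate(proportions = pr / sum(pr),
                   weights = (estimate_f$weights[nf] +
                                estimate_r$weights[nf]) / 2,
                   r_squared = min(estimate_f$r_squared,
                                   estimate_r$r_squared),
                   method = estimate_f$method)
}

#' Per-allele peak-height proportions at an informative site
#'
#' The single-site estimator used alongside full decomposition: at a
#' diagnostic SNP the channel peak-height ratio reveals the copy proportions
#' directly (e.g. the C/T ratio distinguishing a duplicated Z-linked copy).
#'
#' @param trace a [chromatogram()].
#' @param site 1-based coordinate (in trace coordinates, honoring `anchor`).
#' @param alleles channels to compare, e.g. `c("C", "T")`.
#' @return named proportions over the listed channels, method `peak_ratio`.
#' @export
peak_ratio <- function(trace, site, alleles) {
  stopifnot(inherits(trace, "chromatogram"), length(alleles) >= 2,
            all(alleles %in% DNA_ALPHABET))
  row <- site - trace$anchor + 1L
  if (row < 1L || row > nrow(trace$heights))
    stop("site outside the trace window")
  h <- trace$heights[row, alleles]
  if (sum(h) == 0) stop("zero total height at the requested site")
  mixture_estimate(proportions = h / sum(h), weights = h,
                   r_squared = 1, method = "peak_ratio")
}
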