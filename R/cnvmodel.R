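#' Construct an integer copy ratio
#'
#' @param major count of non-W-specific copies (`>= 1`).
#' @param minor count of W-specific copies (`>= 1`).
#' @param max_total maximum total copy number allowed (default 5, the upper
#'   bound of banf2 copy number observed in diploid cichlids).
#' @return object of class `copy_ratio` with fields `major`, `minor`,
#'   `total` and `predicted_minor_fraction`.
#' @export
copy_ratio <- function(major, minor, max_total = 5L) {
  stopifnot(is_count(major), major >= 1, is_count(minor), minor >= 1,
            major + minor <= max_total)
  structure(list(major = as.integer(major), minor = as.integer(minor),
                 total = as.integer(major + minor),
                 predicted_minor_fraction = minor / (major + minor)),
            class = "copy_ratio")
}

#' @export
print.copy_ratio <- function(x, ...) {
  cat(sprintf("<copy_ratio> %d:%d (total %d, minor fraction %.3f)\n",
              x$major, x$minor, x$total, x$predicted_minor_fraction))
  invisible(x)
}

#' Infer the integer copy ratio behind an estimated minor-signal fraction
#'
#' Finds the pair (major, minor) with `major + minor <= max_total` whose
#' implied minor fraction `minor / (major + minor)` is closest to the
#' estimate; ties are broken toward the smaller total, then the smaller
#' minor count. A 25% W-specific signal thus reads as a 3:1 model, 33% as
#' 2:1 and 20% as 4:1 — the three copy-model readings of the banf2 locus.
#'
#' @param minor_fraction estimated W-specific signal fraction, in (0, 1).
#' @param max_total maximum total copy number (`>= 2`).
#' @return a [copy_ratio()].
#' @export
infer_copy_ratio <- function(minor_fraction, max_total = 5L) {
  stopifnot(is.numeric(minor_fraction), length(minor_fraction) == 1L,
            minor_fraction > 0, minor_fraction < 1,
            is_count(max_total), max_total >= 2)
  grid <- expand.grid(major = seq_len(max_total - 1L),
                      minor = seq_len(max_total - 1L))
  grid <- grid[grid$major + grid$minor <= max_total, ]
  grid$total <- grid$major + grid$minor
  grid$err <- abs(grid$minor / grid$total - minor_fraction)
  grid <- grid[order(grid$err, grid$total, grid$minor), ]
  copy_ratio(grid$major[1], grid$minor[1], max_total)
}

#' Construct a per-chromosome gene-configuration model
#'
#' @param sex_genotype `"WZ"`, `"ZZ"` or `"WW"`.
#' @param w_copies list of character vectors, the gene-copy roles on each W
#'   chromosome (empty list for ZZ).
#' @param z_copies list of character vectors, the roles on each Z chromosome.
#' @return object of class `chromosome_model`.
#' @export
chromosome_model <- function(sex_genotype = c("WZ", "ZZ", "WW"),
                             w_copies = list(), z_copies = list()) {
  sex_genotype <- match.arg(sex_genotype)
  n_w <- switch(sex_genotype, WZ = 1L, ZZ = 0L, WW = 2L)
  n_z <- switch(sex_genotype, WZ = 1L, ZZ = 2L, WW = 0L)
  stopifnot(length(w_copies) == n_w, length(z_copies) == n_z)
  roles_w <- unlist(w_copies)
  roles_z <- unlist(z_copies)
  if ("banf2w" %in% roles_z)
    stop("banf2w is W-specific and cannot reside on a Z chromosome")
  if (sex_genotype == "ZZ" && length(roles_w) > 0)
    stop("ZZ models carry no W chromosome")
  structure(list(sex_genotype = sex_genotype, w_copies = w_copies,
                 z_copies = z_copies,
                 total_copies = length(roles_w) + length(roles_z),
                 w_specific_copies = length(roles_w)),
            class = "chromosome_model")
}

#' @export
print.chromosome_model <- function(x, ...) {
  fmt <- function(copies, chrom) {
    if (!length(copies)) return(character(0))
    sprintf("%s{%s}", chrom,
            vapply(copies, paste, "", collapse = ","))
  }
  cat(sprintf("<chromosome_model %s, %d copies> %s\n", x$sex_genotype,
              x$total_copies,
              paste(c(fmt(x$w_copies, "W"), fmt(x$z_copies, "Z")),
                    collapse = " + ")))
  invisible(x)
}

#' Enumerate gene-configuration models consistent with the copy counts
#'
#' The W chromosome carries the W-specific roles (banf2w and, when two
#' W-specific copies are present, banf2c); each Z chromosome carries one copy
#' (banf2a) or, when a Z duplication is allowed, two (banf2a plus banf2b).
#' Returns every assignment matching the requested totals, ordered
#' canonically (fewest Z duplications first).
#'
#' @param sex_genotype `"WZ"`, `"ZZ"` or `"WW"`.
#' @param total_copies total gene copies in the diploid genome.
#' @param w_specific_copies W-resident copies per W chromosome (0 for ZZ).
#' @param z_duplication_allowed may a Z chromosome carry the banf2b
#'   duplication?
#' @return list of [chromosome_model()]s (possibly empty when counts cannot
#'   be satisfied).
#' @export
enumerate_models <- function(sex_genotype = c("WZ", "ZZ", "WW"), total_copies,
                             w_specific_copies,
                             z_duplication_allowed = FALSE) {
  sex_genotype <- match.arg(sex_genotype)
  stopifnot(is_count(total_copies), is_count(w_specific_copies))
  if (sex_genotype == "ZZ" && w_specific_copies != 0)
    stop("ZZ genotypes carry no W-specific copies")
  if (w_specific_copies > total_copies)
    stop("w_specific_copies exceeds total_copies")
  n_w <- switch(sex_genotype, WZ = 1L, ZZ = 0L, WW = 2L)
  n_z <- switch(sex_genotype, WZ = 1L, ZZ = 2L, WW = 0L)
  per_w <- if (n_w > 0) w_specific_copies / n_w else 0
  if (per_w != floor(per_w))
    stop("w_specific_copies must divide evenly across W chromosomes")
  w_roles <- switch(as.character(min(per_w, 2)),
                    "0" = character(0), "1" = "banf2w",
                    "2" = c("banf2w", "banf2c"))
  if (per_w > 2) w_roles <- c(w_roles, rep("other", per_w - 2))
  z_options <- list(`1` = "banf2a")
  if (z_duplication_allowed) z_options$`2` <- c("banf2a", "banf2b")
  z_configs <- if (n_z == 0) list(list()) else {
    combos <- expand.grid(rep(list(seq_along(z_options)), n_z))
    # unordered chromosome pairs: keep non-decreasing index combinations
    combos <- combos[apply(combos, 1L, function(r) all(diff(r) >= 0)), ,
                     drop = FALSE]
    lapply(seq_len(nrow(combos)), function(i) {
      lapply(as.integer(combos[i, ]), function(j) z_options[[j]])
    })
  }
  models <- list()
  for (zc in z_configs) {
    total <- n_w * length(w_roles) + length(unlist(zc))
    if (total != total_copies) next
    models[[length(models) + 1L]] <- chromosome_model(
      sex_genotype = sex_genotype,
      w_copies = rep(list(w_roles), n_w), z_copies = zc)
  }
  models[order(vapply(models, function(m) length(unlist(m$z_copies)),
                      numeric(1)))]
}

#' Classify an individual into a copy ratio and chromosome model
#'
#' Pipeline glue for per-individual genotyping: combine the available mixture
#' estimates, read off the W-specific signal fraction, infer the integer copy
#' ratio, enumerate the chromosome models consistent with the phenotypic sex
#' and pick those matching the total copy number. The concordance flag is
#' `FALSE` when the W-specific signal contradicts the phenotypic sex (a
#' phenotypic male with W signal above `threshold`, or a female without).
#'
#' For W-negative (ZZ) individuals the Z copy number is resolved from the
#' informative-site allele proportions (`site_ratios`, e.g. the C/T
#' peak-height split): the C-like allele marks the banf2b duplication.
#'
#' @param estimates a [mixture_estimate()] or list of them (e.g. forward and
#'   reverse orientations, combined by [combine_orientations()]).
#' @param sex phenotypic sex, `"F"` or `"M"`.
#' @param w_id name of the W-specific haplotype in the proportions (default:
#'   the entry matching `"banf2w"`).
#' @param site_ratios optional named allele proportions at the informative
#'   SNP (used to size ZZ models), e.g. `c(T = 2/3, C = 1/3)`.
#' @param threshold W-specific fraction above which a W chromosome is called
#'   (default 0.10, halfway between noise and the smallest true fraction).
#' @param max_total maximum total copy number.
#' @return list with `ratio` (a [copy_ratio()] or `NULL`), `models` (list of
#'   [chromosome_model()]s, possibly empty if unresolvable), `w_fraction`,
#'   and `concordant` (logical).
#' @export
classify_individual <- function(estimates, sex = c("F", "M"), w_id = NULL,
                                site_ratios = NULL, threshold = 0.10,
                                max_total = 5L) {
  sex <- match.arg(sex)
  if (inherits(estimates, "mixture_estimate")) estimates <- list(estimates)
  stopifnot(length(estimates) >= 1,
            all(vapply(estimates, inherits, logical(1), "mixture_estimate")))
  est <- Reduce(combine_orientations, estimates)
  if (is.null(w_id)) {
    w_id <- grep("banf2w", names(est$proportions), value = TRUE)
    if (length(w_id) > 1L) stop("ambiguous W-specific haplotype id")
  }
  w_frac <- if (length(w_id) == 1L && w_id %in% names(est$proportions))
    unname(est$proportions[[w_id]]) else 0
  has_w <- w_frac >= threshold
  concordant <- has_w == (sex == "F")
  if (has_w) {
    ratio <- infer_copy_ratio(w_frac, max_total)
    models <- list()
    for (wsc in 2:1) for (dup in c(FALSE, TRUE)) {
      if (wsc > ratio$total - 1L) next
      models <- c(models, enumerate_models("WZ", ratio$total, wsc, dup))
    }
    models <- unique(models)
  } else {
    minor_z <- if (!is.null(site_ratios) && "C" %in% names(site_ratios))
      unname(site_ratios[["C"]]) else 0
    if (minor_z >= threshold) {
      zr <- infer_copy_ratio(minor_z, max_total = 4L)
      total <- zr$total
    } else total <- 2L
    ratio <- NULL
    models <- enumerate_models("ZZ", total, 0L,
                               z_duplication_allowed = total > 2L)
  }
  list(ratio = ratio, models = models, w_fraction = w_frac,
       concordant = concordant)
}
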