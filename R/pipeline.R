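#' Assemble (or load) a pipeline configuration
#'
#' A pipeline configuration bundles the simulation knobs, per-stage toggles
#' and module parameters for [run_pipeline()]. Configurations can be written
#' by hand as YAML or JSON; unspecified fields fall back to the defaults of
#' [sim_config()].
#'
#' @param path optional YAML or JSON file to load.
#' @param ... fields overriding the loaded/default values: any [sim_config()]
#'   field, `stages` (character subset of `simulate`, `decompose`,
#'   `infer_cnv`, `associate`, `inherit_test`, `quantify`), `markers` (data
#'   frame), `max_total`, `w_threshold`, `min_reads`, `r2_threshold`.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(path = NULL, ...) {
  base <- list(stages = c("simulate", "decompose", "infer_cnv", "associate",
                          "inherit_test", "quantify"),
               max_total = 5L, w_threshold = 0.10, min_reads = 3L,
               r2_threshold = 0.9,
               markers = data.frame(
                 name = c("flank_lo", "sd_marker", "flank_hi"),
                 position_kbp = c(73159, 73178, 73394),
                 recomb_fraction = c(0.05, 0, 0.05)))
  if (!is.null(path)) {
    loaded <- if (grepl("\\.json$", path, ignore.case = TRUE))
      jsonlite::read_json(path, simplifyVector = TRUE)
    else yaml::read_yaml(path)
    if (!is.null(loaded$markers)) loaded$markers <- as.data.frame(loaded$markers)
    base[names(loaded)] <- loaded
  }
  dots <- list(...)
  base[names(dots)] <- dots
  sim_fields <- intersect(names(base), names(formals(sim_config)))
  cfg <- do.call(sim_config, base[sim_fields])
  structure(c(unclass(cfg),
              base[setdiff(names(base), names(formals(sim_config)))]),
            class = "pipeline_config")
}

.provenance_header <- function(config) {
  # a readable fingerprint: seed plus a digest of the flattened config
  flat <- paste(names(unclass(config)),
                vapply(unclass(config), function(x)
                  paste(format(unlist(x)), collapse = ","), ""),
                sep = "=", collapse = ";")
  sprintf("# wzkit %s | seed=%d | config_sum=%08x",
          as.character(utils::packageVersion("wzkit")), config$seed,
          sum(utf8ToInt(flat) * seq_along(utf8ToInt(flat))) %% 0xffffffff)
}

#' Run the full inference chain on synthetic (or supplied) data
#'
#' Executes the enabled stages in pipeline order: simulate the haplotype
#' set, composite chromatograms, cohort and read libraries; decompose the
#' female trace by NNLS (forward and reverse orientations combined);
#' infer the integer copy model; scan marker-sex association with exact
#' tests and report the critical interval; test the inheritance models
#' against the observed female genotype distribution; and quantify the
#' W-specific and standard probes across the read libraries. Writes a JSON
#' report plus TSV tables (with provenance headers) when `outdir` is given.
#'
#' @param config a [pipeline_config()].
#' @param outdir optional output directory (created if missing).
#' @return report list (invisibly when writing to `outdir`).
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  stages <- config$stages
  report <- list(seed = config$seed, stages = stages)
  sim <- NULL
  if ("simulate" %in% stages) {
    haps <- gen_haplotype_set(base_length = 300L, n_z_copies = 3L,
                              include_w_variant = TRUE, indel_length = 3L,
                              n_substitutions = 2L, seed = config$seed)
    window <- c(1L, min(vapply(haps, function(h) nchar(h$sequence),
                               integer(1))))
    trace_f <- gen_trace(haps, rep(1L, length(haps)), window,
                         noise_cv = config$noise_cv, gain = config$gain,
                         seed = config$seed)
    haps_r <- lapply(haps, function(h) {
      haplotype(h$id, revcomp(h$sequence), h$chromosome, h$role)
    })
    trace_r <- gen_trace(haps_r, rep(1L, length(haps)), window,
                         noise_cv = config$noise_cv, gain = config$gain,
                         seed = config$seed + 1L)
    cohort <- gen_cohort(sim_config(
      seed = config$seed, n_females = config$n_females,
      n_males = config$n_males, recomb_fraction = config$recomb_fraction,
      sex_reversal_rate = config$sex_reversal_rate), config$markers)
    w_probe <- substr(haps[[length(haps)]]$sequence, 41L, 72L)
    z_probe <- substr(haps[[1]]$sequence, 101L, 132L)
    libs <- list(
      female_gonad = gen_reads(data.frame(
        id = c("banf2w", "banf2"), sequence = c(w_probe, z_probe),
        n_fwd = c(12L, 6L)), config$read_length, config$library_size,
        seed = config$seed),
      male_gonad = gen_reads(data.frame(
        id = "banf2", sequence = z_probe, n_fwd = 18L),
        config$read_length, config$library_size, seed = config$seed + 1L))
    sim <- list(haplotypes = haps, haplotypes_rev = haps_r,
                trace_f = trace_f, trace_r = trace_r, window = window,
                cohort = cohort, libraries = libs,
                probes = probe_set(c("banf2w", "banf2"),
                                   c(w_probe, z_probe)))
    report$simulate <- list(n_haplotypes = length(haps),
                            cohort_n = nrow(cohort))
  }
  if ("decompose" %in% stages) {
    if (is.null(sim)) stop("decompose stage requires the simulate stage")
    sig_f <- collapse_signatures(build_signatures(
      sim$haplotypes, sim$window[1], diff(sim$window) + 1L))
    sig_r <- collapse_signatures(build_signatures(
      sim$haplotypes_rev, sim$window[1], diff(sim$window) + 1L))
    est <- combine_orientations(decompose_trace(sim$trace_f, sig_f),
                                decompose_trace(sim$trace_r, sig_r))
    report$decompose <- list(proportions = as.list(est$proportions),
                             r2 = est$r_squared,
                             usable = est$r_squared >= config$r2_threshold)
    sim$estimate <- est
  }
  if ("infer_cnv" %in% stages) {
    if (is.null(sim$estimate)) stop("infer_cnv requires the decompose stage")
    cls <- classify_individual(sim$estimate, sex = "F",
                               threshold = config$w_threshold,
                               max_total = config$max_total)
    report$infer_cnv <- list(
      major = cls$ratio$major, minor = cls$ratio$minor,
      w_fraction = cls$w_fraction, concordant = cls$concordant,
      n_models = length(cls$models))
  }
  if ("associate" %in% stages) {
    if (is.null(sim)) stop("associate stage requires the simulate stage")
    scan <- association_scan(sim$cohort, config$markers)
    report$associate <- list(
      results = scan$results, critical_interval = scan$critical_interval)
    sim$scan <- scan
  }
  if ("inherit_test" %in% stages) {
    if (is.null(sim)) stop("inherit_test requires the simulate stage")
    top <- config$markers$name[1]
    if (!is.null(sim$scan))
      top <- sim$scan$results$marker[1]
    females <- sim$cohort[sim$cohort$sex == "F", ]
    counts <- c(ZZ = sum(females[[top]] == "Z/Z"),
                WZ = sum(females[[top]] == "W/Z"), WW = 0L)
    n <- sum(counts)
    models <- c("autosomal", "lethal_ww", "female_w")
    gof <- lapply(models, function(m) {
      gof_pearson(counts, model_expected(m, allele_freqs(0.5), n), m)
    })
    report$inherit_test <- data.frame(
      model = models,
      chi2 = vapply(gof, `[[`, numeric(1), "chi2"),
      p = vapply(gof, `[[`, numeric(1), "p"))
    report$hwe <- unclass(hwe_deviation_test(counts))[c("chi2", "df", "p")]
  }
  if ("quantify" %in% stages) {
    if (is.null(sim)) stop("quantify requires the simulate stage")
    prof <- expression_profile(sim$libraries, sim$probes,
                               min_reads = config$min_reads)
    report$quantify <- prof
  }
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    header <- .provenance_header(config)
    jsonlite::write_json(report, file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    writeLines(c(header, make_report(report)),
               file.path(outdir, "report.txt"))
    return(invisible(report))
  }
  report
}

.fmt2 <- function(x) ifelse(is.na(x), "NA", formatC(signif(x, 2)))

#' Format stage outputs as human-readable report tables
#'
#' Deterministic section order (pipeline order), numbers rounded to two
#' significant figures in the text rendering; full precision is preserved in
#' the JSON report written by [run_pipeline()].
#'
#' @param report report list from [run_pipeline()].
#' @return character vector of report lines.
#' @export
make_report <- function(report) {
  if (length(report) == 0) stop("no stage outputs to report")
  lines <- character(0)
  add <- function(...) lines <<- c(lines, ...)
  if (!is.null(report$decompose)) {
    add("== Trace decomposition ==",
        paste0(names(report$decompose$proportions), ": ",
               .fmt2(unlist(report$decompose$proportions)), collapse = "  "),
        sprintf("R^2 = %s", .fmt2(report$decompose$r2)), "")
  }
  if (!is.null(report$infer_cnv)) {
    add("== Copy model ==",
        sprintf("ratio %d:%d (W fraction %s, concordant: %s)",
                report$infer_cnv$major, report$infer_cnv$minor,
                .fmt2(report$infer_cnv$w_fraction),
                report$infer_cnv$concordant), "")
  }
  if (!is.null(report$associate)) {
    res <- report$associate$results
    add("== Marker-sex association ==",
        sprintf("%-12s %-12s %s", "marker", "position_kbp", "p"),
        sprintf("%-12s %-12s %s", res$marker,
                .fmt2(res$position_kbp), .fmt2(res$p)))
    ci <- report$associate$critical_interval
    if (!is.null(ci))
      add(sprintf("critical interval: %s-%s Kbp (span %s Kbp)",
                  .fmt2(ci$lower), .fmt2(ci$upper), .fmt2(ci$span_kbp)))
    add("")
  }
  if (!is.null(report$inherit_test)) {
    it <- report$inherit_test
    add("== Inheritance models ==",
        sprintf("%-12s %-10s %s", "model", "chi2", "p"),
        sprintf("%-12s %-10s %s", it$model, .fmt2(it$chi2), .fmt2(it$p)), "")
  }
  if (!is.null(report$quantify)) {
    q <- report$quantify
    add("== Expression (FPKM) ==",
        sprintf("%-14s %-10s %-6s %-10s %s",
                "library", "probe", "hits", "fpkm", "detected"),
        sprintf("%-14s %-10s %-6d %-10s %s", q$library, q$probe, q$hits,
                .fmt2(q$fpkm), q$detected), "")
  }
  if (!length(lines)) lines <- "== empty report =="
  lines
}
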