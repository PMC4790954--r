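#' Pipeline configuration
#'
#' Collects every stage default of the end-to-end analysis in one flat
#' list so a whole run is determined by configuration plus seed.  Values
#' mirror the module defaults: read depth 6, 75% completeness, MAF 0.1,
#' segregation alpha 0.01, grouping LOD 10, distortion p 1e-5,
#' nearest-neighbour stress 2.5 cM, three ordering rounds, 1000
#' permutations at alpha 0.05, 1.8-LOD support intervals, cofactor spacing
#' 1.51 cM, 30 cM QTL separation and 50 cM cofactor proximity.
#'
#' @param ... Overrides of the defaults listed above (see
#'   `formals(pipeline_config)`).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    min_depth = 6L, site_completeness = 0.75, sample_completeness = 0.75,
    maf = 0.10, alpha_seg = 0.01,
    lod_min = 10, distortion_p = 1e-5, nn_stress = 2.5, order_rounds = 3,
    step_cM = 1.0, error_prob = 1e-4,
    n_perm = 1000, alpha = 0.05, drop = 1.8,
    spacing_cM = 1.51, min_sep_cM = 30, cof_prox_cM = 50,
    genome_mb = NULL, seed = 1L
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown options: ", paste(unknown, collapse = ", "),
                            call. = FALSE)
  cfg[names(dots)] <- dots
  structure(cfg, class = "pipeline_config")
}

#' Run the whole pipeline on a genotype table and phenotypes
#'
#' Executes marker calling, curation, map construction, map statistics and
#' single-trait scans in order, mirroring the standard workflow for a GBS
#' F2 family: site/sample filters, intercross-marker identification,
#' distortion and duplicate curation, LOD grouping, maximum-likelihood
#' ordering with Kosambi distances, stress pruning, then permutation-
#' thresholded EM interval mapping per trait.  Stage counts are collected
#' so the report shows how many markers survive each step.
#'
#' @param table A `genotype_table` with a flagged progenitor.
#' @param pheno Optional phenotype tibble (`sample` column plus traits);
#'   traits flagged binary (attribute or 0/1 values) use the binary model.
#' @param cfg A [pipeline_config()].
#' @return A list of class `pipeline_result`: `stage_counts`, `map`,
#'   `stats`, `scans` (named list of `qtl_scan`), `thresholds`, `peaks`.
#' @export
run_pipeline <- function(table, pheno = NULL, cfg = pipeline_config()) {
  fcfg <- filter_config(cfg$min_depth, cfg$site_completeness,
                        cfg$sample_completeness, cfg$maf,
                        alpha_seg = cfg$alpha_seg)
  filtered <- filter_sites(table, fcfg)
  ic <- call_intercross_markers(filtered, fcfg)
  map <- build_map(ic, lod_min = cfg$lod_min, distortion_p = cfg$distortion_p,
                   max_stress_cM = cfg$nn_stress, n_rounds = cfg$order_rounds)
  stats <- map_statistics(map, genome_mb = cfg$genome_mb)
  stage_counts <- tibble::tibble(
    stage = c("input_sites", "after_site_filters", "intercross_markers",
              "after_curation", "mapped_markers"),
    n = c(nrow(table$calls), nrow(filtered$calls), nrow(ic$calls),
          nrow(ic$calls) - length(attr(map, "curation")$distorted) -
            nrow(attr(map, "curation")$duplicates),
          nrow(map))
  )
  scans <- list(); thresholds <- list(); peaks <- list()
  if (!is.null(pheno)) {
    probs <- genotype_probabilities(map, ic, cfg$step_cM, cfg$error_prob)
    binary <- attr(pheno, "binary")
    for (tr in setdiff(names(pheno), "sample")) {
      is_bin <- if (!is.null(binary) && tr %in% names(binary)) binary[[tr]] else {
        v <- pheno[[tr]]; all(is.na(v) | v %in% c(0, 1))
      }
      model <- if (isTRUE(is_bin)) "binary" else "normal"
      sc <- scan_single(probs, pheno, tr, model)
      thr <- permutation_threshold(probs, pheno, tr, model,
                                   n_perm = cfg$n_perm, alpha = cfg$alpha,
                                   seed = cfg$seed + match(tr, names(pheno)))
      scans[[tr]] <- sc
      thresholds[[tr]] <- as.numeric(thr)
      peaks[[tr]] <- qtl_peaks(sc, thr, cfg$drop)
    }
  }
  structure(list(stage_counts = stage_counts, map = map, stats = stats,
                 scans = scans, thresholds = thresholds, peaks = peaks,
                 config = cfg),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  print(x$stage_counts)
  print(x$stats)
  for (tr in names(x$peaks)) {
    cat(sprintf("trait '%s': threshold %.2f, %d peak(s)\n", tr,
                x$thresholds[[tr]], nrow(x$peaks[[tr]])))
  }
  invisible(x)
}

#' Serialise a pipeline report to JSON
#'
#' @param result A `pipeline_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(result, path) {
  rep <- list(
    schema = "hetlink-report-1",
    stage_counts = result$stage_counts,
    map_stats = glance(result$stats),
    thresholds = result$thresholds,
    peaks = result$peaks
  )
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
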