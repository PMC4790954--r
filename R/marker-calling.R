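#' Marker-filtering configuration
#'
#' Bundles the site/sample filtering thresholds used for GBS intercross
#' marker calling: a minimum per-call read depth, 75% completeness by site
#' across progeny and by progeny across sites, a minor-allele-frequency
#' floor, a minimum presence fraction, and the significance level of the
#' 1:2:1 segregation test.
#'
#' @param min_depth Calls with known depth below this are masked missing
#'   (default 6).
#' @param min_site_completeness Minimum fraction of progeny called per site
#'   (default 0.75).
#' @param min_sample_completeness Minimum fraction of sites called per
#'   progeny (default 0.75).
#' @param maf_min Minimum minor allele frequency among called progeny alleles
#'   (default 0.10).
#' @param min_presence Minimum fraction of progeny with a call (default 0.40).
#' @param alpha_seg Significance level of the chi-squared 1:2:1 test
#'   (default 0.01).
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(min_depth = 6L, min_site_completeness = 0.75,
                          min_sample_completeness = 0.75, maf_min = 0.10,
                          min_presence = 0.40, alpha_seg = 0.01) {
  fr <- c(min_site_completeness, min_sample_completeness, maf_min,
          min_presence, alpha_seg)
  stopifnot(all(fr >= 0 & fr <= 1), min_depth >= 0)
  structure(list(min_depth = as.integer(min_depth),
                 min_site_completeness = min_site_completeness,
                 min_sample_completeness = min_sample_completeness,
                 maf_min = maf_min, min_presence = min_presence,
                 alpha_seg = alpha_seg),
            class = "filter_config")
}

#' Chi-squared goodness-of-fit test for 1:2:1 segregation
#'
#' Tests observed AA/AB/BB counts against the Mendelian 1:2:1 expectation for
#' a co-dominant intercross marker in an F2 family, using the asymptotic
#' chi-squared distribution with 2 degrees of freedom (for which the p-value
#' has the closed form `exp(-chi2 / 2)`).
#'
#' @param n_AA,n_AB,n_BB Non-negative genotype counts (vectorised).
#' @param alpha Significance level; markers "pass" (look Mendelian) when
#'   `p > alpha`.
#' @return A tibble with columns `n_AA`, `n_AB`, `n_BB`, `chi2`, `df`,
#'   `pvalue`, `passed`.
#' @export
segregation_test <- function(n_AA, n_AB, n_BB, alpha = 0.01) {
  n <- n_AA + n_AB + n_BB
  if (any(n < 1)) stop("all-zero genotype counts", call. = FALSE)
  e_AA <- n / 4; e_AB <- n / 2; e_BB <- n / 4
  chi2 <- (n_AA - e_AA)^2 / e_AA + (n_AB - e_AB)^2 / e_AB +
    (n_BB - e_BB)^2 / e_BB
  p <- stats::pchisq(chi2, df = 2, lower.tail = FALSE)
  tibble::tibble(n_AA = n_AA, n_AB = n_AB, n_BB = n_BB,
                 chi2 = chi2, df = 2L, pvalue = p, passed = p > alpha)
}

#' Apply depth and completeness filters to a genotype table
#'
#' Filtering proceeds in a fixed order: (1) calls with a known read depth
#' (depth > 0) below `min_depth` are masked missing; (2) sites failing
#' site-completeness, MAF, or presence among progeny are dropped; (3) progeny
#' below sample-completeness (computed on the surviving sites) are dropped.
#' The progenitor is exempt from sample-completeness removal.  Depth masking
#' precedes the completeness computation, so depth-failed calls count as
#' missing — the stricter reading of running the filters jointly.
#'
#' @param table A `genotype_table`.
#' @param cfg A [filter_config()].
#' @return The filtered `genotype_table` with attribute `report`: a tibble of
#'   stage-by-stage survivor counts.
#' @export
filter_sites <- function(table, cfg = filter_config()) {
  stopifnot(inherits(table, "genotype_table"))
  if (nrow(table$calls) == 0) stop("empty genotype table", call. = FALSE)
  calls <- table$calls
  depths <- table$depths
  masked <- depths > 0L & depths < cfg$min_depth
  calls[masked] <- NA_character_
  progeny <- setdiff(colnames(calls), table$progenitor)
  pc <- calls[, progeny, drop = FALSE]
  n_prog <- length(progeny)

  called <- rowSums(!is.na(pc))
  completeness <- called / n_prog
  n_b <- rowSums(pc == "BB", na.rm = TRUE) * 2 + rowSums(pc == "AB", na.rm = TRUE)
  maf <- pmin(n_b, 2 * called - n_b) / pmax(2 * called, 1)
  presence <- completeness

  keep_complete <- completeness >= cfg$min_site_completeness
  keep_maf <- maf >= cfg$maf_min
  keep_presence <- presence >= cfg$min_presence
  keep_site <- keep_complete & keep_maf & keep_presence

  report <- tibble::tibble(
    stage = c("input_sites", "after_site_completeness", "after_maf",
              "after_presence", "sites_retained"),
    n = c(nrow(calls), sum(keep_complete), sum(keep_complete & keep_maf),
          sum(keep_site), sum(keep_site))
  )
  if (!any(keep_site)) {
    stop("all sites removed by filters; consider relaxing min_depth/",
         "completeness/MAF thresholds", call. = FALSE)
  }
  calls <- calls[keep_site, , drop = FALSE]
  depths <- depths[keep_site, , drop = FALSE]

  pc <- calls[, progeny, drop = FALSE]
  samp_comp <- colSums(!is.na(pc)) / nrow(pc)
  keep_samp <- progeny[samp_comp >= cfg$min_sample_completeness]
  keep_cols <- c(if (!is.na(table$progenitor)) table$progenitor, keep_samp)
  keep_cols <- intersect(colnames(calls), keep_cols)
  report <- dplyr::bind_rows(report, tibble::tibble(
    stage = c("input_progeny", "progeny_retained"),
    n = c(n_prog, length(keep_samp))
  ))
  mk <- table$markers[match(rownames(calls), table$markers$id), , drop = FALSE]
  out <- genotype_table(calls[, keep_cols, drop = FALSE],
                        depths[, keep_cols, drop = FALSE], mk,
                        if (!is.na(table$progenitor)) table$progenitor)
  attr(out, "report") <- report
  out
}

#' Identify co-dominant intercross (hk x hk) markers
#'
#' Retains the markers that (a) are heterozygous in the flagged F1
#' progenitor and (b) segregate 1:2:1 among the F2 progeny by the
#' chi-squared goodness-of-fit test at `cfg$alpha_seg`.  Sites where the
#' progenitor call is missing are rejected (counted separately), not
#' imputed: progenitor heterozygosity is the defining criterion for an
#' intercross marker.  The returned table contains progeny only.
#'
#' @param table A `genotype_table` with a flagged progenitor.
#' @param cfg A [filter_config()]; only `alpha_seg` is used here.
#' @return A progeny-only `genotype_table` of intercross markers, with
#'   attributes `segregation` (the per-marker [segregation_test()] tibble
#'   over progenitor-heterozygous sites) and `report` (stage counts,
#'   including sites rejected for a missing progenitor call).
#' @export
call_intercross_markers <- function(table, cfg = filter_config()) {
  stopifnot(inherits(table, "genotype_table"))
  if (is.na(table$progenitor)) {
    stop("no progenitor flagged in table", call. = FALSE)
  }
  prog_call <- table$calls[, table$progenitor]
  prog_missing <- is.na(prog_call)
  prog_het <- !prog_missing & prog_call == "AB"
  cnt <- gt_counts(table)
  het_idx <- which(prog_het)
  seg <- segregation_test(cnt$n_AA[het_idx], cnt$n_AB[het_idx],
                          cnt$n_BB[het_idx], alpha = cfg$alpha_seg)
  seg <- dplyr::bind_cols(tibble::tibble(marker = cnt$marker[het_idx]), seg)
  keep <- het_idx[seg$passed]
  report <- tibble::tibble(
    stage = c("input_sites", "progenitor_missing", "progenitor_heterozygous",
              "intercross_markers"),
    n = c(nrow(table$calls), sum(prog_missing), sum(prog_het), length(keep))
  )
  out <- gt_progeny(gt_subset(table, markers = keep))
  attr(out, "segregation") <- seg
  attr(out, "report") <- report
  attr(out, "marker_type") <- "hkxhk"
  out
}
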