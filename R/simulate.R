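#' Build a simulated true map
#'
#' Regularly spaced markers on a set of linkage groups, with physical
#' coordinates collinear with genetic positions (1 cM laid out at a constant
#' bp/cM rate per chromosome).
#'
#' @param n_groups Number of linkage groups (default 19, a grape-like
#'   karyotype).
#' @param n_markers Markers per group.
#' @param length_cM Genetic length of each group (recycled).
#' @param mb_per_cM Physical-to-genetic rate used to lay out bp coordinates.
#' @return A `genetic_map` tibble (columns `group`, `marker`, `cM`, `chrom`,
#'   `bp`).
#' @export
sim_map <- function(n_groups = 19, n_markers = 10, length_cM = 80,
                    mb_per_cM = 0.2) {
  length_cM <- rep_len(length_cM, n_groups)
  out <- purrr::map_dfr(seq_len(n_groups), function(g) {
    cm <- seq(0, length_cM[g], length.out = n_markers)
    tibble::tibble(
      group = g,
      marker = sprintf("S%02d_%d", g, round(cm * mb_per_cM * 1e6) + 1L),
      cM = cm,
      chrom = sprintf("chr%02d", g),
      bp = as.integer(round(cm * mb_per_cM * 1e6)) + 1L
    )
  })
  class(out) <- c("genetic_map", class(out))
  out
}

#' Simulation configuration for an F2/GBS family
#'
#' Describes the study design the simulator emulates: a single heterozygous
#' F1 individual selfed to produce an F2 family genotyped by GBS at
#' co-dominant biallelic markers segregating 1:2:1, with read-depth-driven
#' heterozygote undercalling and missingness, and one or more quantitative
#' or binary trait architectures.
#'
#' @param n_progeny F2 family size (default 424).
#' @param map True genetic map (a `genetic_map`; default [sim_map()]).
#' @param map_fun Map function for interval transition probabilities
#'   (`"kosambi"` or `"haldane"`).
#' @param qtl A list of QTL/trait specifications; each element a list with
#'   `trait` (name), `group`, `cM`, and either `binary = TRUE` (fully
#'   dominant binary locus) or `a`, `d`, `sigma` (additive and dominance
#'   effects and residual SD), optional `mu` (trait mean), optional
#'   `parent`/`beta` for a causal chain (trait = beta * parent trait + QTL
#'   terms + noise).  Several elements may share a `trait` name (multi-QTL
#'   traits).
#' @param depth_mean,depth_size Negative-binomial read-depth model
#'   (mean 12, size 8 by default: about 10% of calls fall below depth 6 and
#'   heterozygote undercalling is active at roughly 0.4% of retained calls).
#' @param min_depth Calls with sampled depth below this are emitted missing
#'   by the noise model (default 1: only zero-depth calls are missing;
#'   depth-based masking is normally left to [filter_sites()]).
#' @param extra_missing Additional independent per-call missingness rate.
#' @param seed Mandatory seed for every stochastic run.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_progeny = 424, map = sim_map(),
                       map_fun = c("kosambi", "haldane"),
                       qtl = list(),
                       depth_mean = 12, depth_size = 8,
                       min_depth = 1, extra_missing = 0.02,
                       seed = NULL) {
  map_fun <- match.arg(map_fun)
  if (is.null(seed)) stop("a seed is required for every simulation", call. = FALSE)
  stopifnot(n_progeny >= 1, depth_mean > 0,
            extra_missing >= 0, extra_missing <= 1)
  bad <- vapply(split(map$cM, map$group), function(x) any(diff(x) < 0), logical(1))
  if (any(bad)) stop("map positions must be non-decreasing within groups", call. = FALSE)
  structure(list(n_progeny = as.integer(n_progeny), map = map,
                 map_fun = map_fun, qtl = qtl,
                 depth_mean = depth_mean, depth_size = depth_size,
                 min_depth = min_depth, extra_missing = extra_missing,
                 seed = as.integer(seed)),
            class = "sim_config")
}

map_fun_inv <- function(d, fun) {
  if (fun == "kosambi") kosambi_inv(d) else 0.5 * (1 - exp(-d / 50))
}

#' Simulate latent F2 genotypes
#'
#' Generates the complete (error-free) genotypes of an F2 family: per
#' progeny and linkage group a Markov chain over marker intervals with F2
#' transition matrices derived from the inverse map function of the
#' inter-marker distances.  Marginal genotype frequencies are (1/4, 1/2,
#' 1/4) and the progenitor is heterozygous at every marker.
#'
#' @param cfg A [sim_config()].
#' @return A list: `table` (latent `genotype_table` including the
#'   heterozygous progenitor `"F1"`, no missing calls) and `truth` (a
#'   `sim_truth` list recording the generating map, QTL specifications and
#'   latent genotype matrix).
#' @export
simulate_f2 <- function(cfg) {
  set.seed(cfg$seed)
  map <- cfg$map
  n <- cfg$n_progeny
  m <- nrow(map)
  geno <- matrix(NA_integer_, m, n)  # 1=AA 2=AB 3=BB
  for (g in unique(map$group)) {
    idx <- which(map$group == g)
    cm <- map$cM[idx]
    first <- idx[1]
    geno[first, ] <- sample.int(3, n, replace = TRUE, prob = c(0.25, 0.5, 0.25))
    for (k in seq_along(idx)[-1]) {
      r <- map_fun_inv(cm[k] - cm[k - 1], cfg$map_fun)
      trans <- f2_transition(r)
      prev <- geno[idx[k - 1], ]
      u <- stats::runif(n)
      cum <- t(apply(trans, 1, cumsum))
      geno[idx[k], ] <- 1L + (u > cum[prev, 1]) + (u > cum[prev, 2])
    }
  }
  samples <- c("F1", sprintf("F2_%03d", seq_len(n)))
  calls <- cbind(AB = rep("AB", m), matrix(CALL_CODES[geno], m, n))
  colnames(calls) <- samples
  rownames(calls) <- map$marker
  markers <- tibble::tibble(id = map$marker, chrom = map$chrom,
                            pos = map$bp, ref = "A", alt = "B")
  tbl <- genotype_table(calls, NULL, markers, "F1")
  truth <- structure(list(map = map, qtl = cfg$qtl, genotypes = geno,
                          samples = samples[-1], config = cfg),
                     class = "sim_truth")
  list(table = tbl, truth = truth)
}

#' Apply GBS observation noise to latent genotypes
#'
#' Emulates depth-limited GBS genotyping: a read depth is drawn per call
#' from a negative-binomial model; a true heterozygote whose sampled reads
#' all carry the same allele (probability `2^(1 - D)`) is undercalled as
#' that allele's homozygote; calls with depth below `min_depth` are emitted
#' missing; additional missingness is applied independently.  Homozygotes
#' are never miscalled.
#'
#' @param latent A latent `genotype_table` from [simulate_f2()].
#' @param cfg The [sim_config()] used to generate it.
#' @param seed Optional seed (defaults to `cfg$seed + 1`).
#' @return The observed `genotype_table` with per-call depths, and
#'   attributes `undercalled` and `masked` (logical matrices).
#' @export
apply_gbs_noise <- function(latent, cfg, seed = NULL) {
  set.seed(seed %||% (cfg$seed + 1L))
  calls <- latent$calls
  m <- nrow(calls); n <- ncol(calls)
  depth <- if (is.infinite(cfg$depth_size)) {
    ## degenerate depth model: every call at exactly depth_mean reads
    matrix(as.integer(round(cfg$depth_mean)), m, n)
  } else {
    matrix(stats::rnbinom(m * n, size = cfg$depth_size,
                          mu = cfg$depth_mean), m, n)
  }
  het <- calls == "AB"
  p_under <- 2^(1 - depth)
  under <- het & depth >= 1 & stats::runif(m * n) < p_under
  ## the observed allele's homozygote: each sampled allele equally likely
  calls[under] <- ifelse(stats::runif(sum(under)) < 0.5, "AA", "BB")
  masked <- depth < max(cfg$min_depth, 1) |
    stats::runif(m * n) < cfg$extra_missing
  calls[masked] <- NA_character_
  dimnames(depth) <- dimnames(calls)
  out <- genotype_table(calls, depth, latent$markers, latent$progenitor)
  attr(out, "undercalled") <- under & !masked
  attr(out, "masked") <- masked
  out
}

#' Simulate trait values from latent genotypes
#'
#' Quantitative traits follow `y = mu + sum_q (a_q x_add + d_q x_dom) + e`
#' with `x_add` in `{-1, 0, +1}` for `{AA, AB, BB}`, `x_dom = 1` for
#' heterozygotes and Gaussian residuals; a positive additive effect raises
#' the trait through the B (grandparent-2) allele.  A binary-dominant trait
#' is 1 for carriers of the B allele.  A trait with `parent`/`beta` forms a
#' causal chain: `beta` times the parent trait is added before the residual,
#' yielding data in which the parent trait d-separates the QTL from the
#' child trait.
#'
#' @param latent A latent `genotype_table` from [simulate_f2()].
#' @param cfg The [sim_config()]; its `qtl` field defines the architectures.
#' @param seed Optional seed (defaults to `cfg$seed + 2`).
#' @return A phenotype tibble (`sample` column plus one column per trait)
#'   with attribute `binary`.
#' @export
simulate_traits <- function(latent, cfg, seed = NULL) {
  set.seed(seed %||% (cfg$seed + 2L))
  prog <- gt_progeny(latent)
  n <- ncol(prog$calls)
  out <- tibble::tibble(sample = colnames(prog$calls))
  specs <- cfg$qtl
  traits <- unique(vapply(specs, `[[`, "", "trait"))
  is_bin <- stats::setNames(logical(length(traits)), traits)
  for (tr in traits) {
    sub <- specs[vapply(specs, function(s) s$trait == tr, logical(1))]
    y <- rep(sub[[1]]$mu %||% 0, n)
    binary <- isTRUE(sub[[1]]$binary)
    sigma <- sub[[1]]$sigma %||% 1
    for (s in sub) {
      in_grp <- which(cfg$map$group == s$group)
      if (!length(in_grp)) stop("QTL group not on the map: trait ", tr, call. = FALSE)
      idx <- in_grp[which.min(abs(cfg$map$cM[in_grp] - s$cM))]
      if (abs(cfg$map$cM[idx] - s$cM) > 1e-9) {
        ## QTL must sit on a marker; snap to the nearest one
        idx <- idx[1]
      }
      gcall <- prog$calls[cfg$map$marker[idx[1]], ]
      x_add <- c(AA = -1, AB = 0, BB = 1)[gcall]
      x_dom <- as.numeric(gcall == "AB")
      if (binary) {
        y <- pmax(y, as.numeric(gcall %in% c("AB", "BB")))
      } else {
        y <- y + (s$a %||% 0) * x_add + (s$d %||% 0) * x_dom
      }
    }
    if (!binary) {
      p <- sub[[1]]$parent
      if (!is.null(p)) y <- y + (sub[[1]]$beta %||% 1) * out[[p]]
      y <- y + stats::rnorm(n, 0, sigma)
    }
    out[[tr]] <- y
    is_bin[tr] <- binary
  }
  attr(out, "binary") <- is_bin
  out
}

#' Write a simulated family as a VCF file
#'
#' Emits the observed genotype table as a minimal VCF 4.1 text file with GT
#' and DP fields, suitable for round-tripping through [read_vcf()].
#'
#' @param table A `genotype_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(table, path) {
  gt_code <- c(AA = "0/0", AB = "0/1", BB = "1/1")
  header <- c(
    "##fileformat=VCFv4.1",
    "##source=hetlink-simulator",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(table$calls)), collapse = "\t")
  )
  mk <- table$markers
  body <- vapply(seq_len(nrow(table$calls)), function(i) {
    g <- gt_code[table$calls[i, ]]
    g[is.na(g)] <- "./."
    paste(c(mk$chrom[i] %|NA|% "1", mk$pos[i] %|NA|% i, mk$id[i],
            mk$ref[i] %|NA|% "A", mk$alt[i] %|NA|% "T", ".", "PASS", ".",
            "GT:DP", paste0(g, ":", table$depths[i, ])), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path, useBytes = TRUE)
  invisible(path)
}

`%|NA|%` <- function(a, b) if (is.na(a)) b else a
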