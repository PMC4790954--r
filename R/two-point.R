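#' Kosambi map function and its inverse
#'
#' Converts a recombination fraction to a Kosambi map distance,
#' `d = 25 * ln((1 + 2r) / (1 - 2r))` centiMorgans, and back,
#' `r = tanh(d / 50) / 2`.  The Kosambi function allows partial crossover
#' interference and is the convention used throughout this package.
#'
#' @param r Recombination fraction(s) in `[0, 0.5)`.
#' @param d Map distance(s) in cM, `>= 0`.
#' @return `kosambi()`: distance in cM; `kosambi_inv()`: recombination
#'   fraction.
#' @export
kosambi <- function(r) {
  if (any(r < 0 | r >= 0.5)) {
    stop("recombination fraction must be in [0, 0.5); r = 0.5 maps to an ",
         "infinite distance", call. = FALSE)
  }
  25 * log((1 + 2 * r) / (1 - 2 * r))
}

#' @rdname kosambi
#' @export
kosambi_inv <- function(d) {
  if (any(d < 0)) stop("map distance must be non-negative", call. = FALSE)
  0.5 * tanh(d / 50)
}

## F2 joint genotype class probabilities for a coupling-phase pair at
## recombination fraction r: two independent meioses, gamete haplotypes
## {(1-r)/2, r/2, r/2, (1-r)/2}.  Classes are ordered
## (AA,AA) (AA,AB) (AA,BB) (AB,AA) (AB,AB) (AB,BB) (BB,AA) (BB,AB) (BB,BB).
f2_pair_probs <- function(r) {
  p <- 1 - r
  cbind(p^2 / 4, p * r / 2, r^2 / 4,
        p * r / 2, (p^2 + r^2) / 2, p * r / 2,
        r^2 / 4, p * r / 2, p^2 / 4)
}

## Expected recombinant gametes (out of 2) per class; the double-heterozygote
## class is a mixture of 0- and 2-recombinant gamete pairs.
f2_pair_recs <- function(r) {
  p <- 1 - r
  dh <- 2 * r^2 / (p^2 + r^2)
  cbind(0, 1, 2, 1, dh, 1, 2, 1, 0)
}

tp_loglik <- function(counts, r) {
  pr <- f2_pair_probs(r)
  lp <- ifelse(counts > 0, counts * log(pr), 0)
  rowSums(lp)
}

## Vectorised EM over many pairs.  `counts` is an n_pairs x 9 matrix of joint
## genotype counts in the class order above.  The EM is run unconstrained on
## [0, 1]; a maximum above 0.5 corresponds to the repulsion phase, for which
## r_hat = 1 - r*.  Two starts (0.25, 0.75) guard against the likelihood's
## two phase branches.
tp_em <- function(counts, tol = 1e-10, max_iter = 500) {
  n2 <- 2 * rowSums(counts)
  run <- function(r0) {
    r <- rep(r0, nrow(counts))
    for (it in seq_len(max_iter)) {
      rec <- f2_pair_recs(r)
      r_new <- rowSums(counts * rec) / n2
      r_new <- pmin(pmax(r_new, 1e-12), 1 - 1e-12)
      if (max(abs(r_new - r)) < tol) { r <- r_new; break }
      r <- r_new
    }
    r
  }
  r1 <- run(0.25)
  r2 <- run(0.75)
  ll1 <- tp_loglik(counts, r1)
  ll2 <- tp_loglik(counts, r2)
  use2 <- ll2 > ll1 + 1e-12
  r <- ifelse(use2, r2, r1)
  ll <- pmax(ll1, ll2)
  phase <- ifelse(r > 0.5, "repulsion", "coupling")
  r_hat <- ifelse(r > 0.5, 1 - r, r)
  lod <- (ll - tp_loglik(counts, rep(0.5, nrow(counts)))) / log(10)
  tibble::tibble(r_hat = pmin(r_hat, 0.5), lod = pmax(lod, 0), phase = phase)
}

pair_counts <- function(calls_a, calls_b) {
  out <- numeric(9)
  k <- 1
  for (ga in CALL_CODES) for (gb in CALL_CODES) {
    out[k] <- sum(calls_a == ga & calls_b == gb, na.rm = TRUE)
    k <- k + 1
  }
  ## class order is (g1, g2) with g2 fastest; reorder to the f2_pair_probs
  ## convention (g1 = AA row first, g2 varying): identical here.
  out
}

#' Two-point recombination fraction between two markers
#'
#' Maximum-likelihood estimate of the recombination fraction between two
#' co-dominant F2 markers under the 9-class joint genotype likelihood
#' (the double-heterozygote class is a recombinant/non-recombinant mixture),
#' maximised by EM over both phase assignments.  Individuals missing at
#' either marker contribute only marginal information, which cancels from
#' the likelihood ratio, so the estimate uses jointly-called individuals.
#'
#' @param geno_a,geno_b Call vectors (`"AA"`/`"AB"`/`"BB"`/`NA`) over the
#'   same individuals.
#' @return A one-row tibble: `r_hat` (in `[0, 0.5]`), `lod`
#'   (`log10 L(r_hat) / L(0.5)`), `phase` (`"coupling"` or `"repulsion"`),
#'   `n` (jointly-called individuals), `reliable` (`FALSE` when `n < 10`).
#' @export
estimate_two_point <- function(geno_a, geno_b) {
  stopifnot(length(geno_a) == length(geno_b))
  cnt <- matrix(pair_counts(geno_a, geno_b), 1, 9)
  n <- sum(cnt)
  res <- tp_em(cnt)
  res$n <- as.integer(n)
  res$reliable <- n >= 10
  res
}

#' All pairwise two-point estimates for a genotype table
#'
#' Computes recombination fraction, linkage LOD and phase for every marker
#' pair, using indicator-matrix cross-products to tally the 9 joint classes
#' and a vectorised EM across pairs.
#'
#' @param table A progeny `genotype_table` of intercross markers.
#' @return A list of class `two_point_set`: `pairs` (tibble of the upper
#'   triangle), and matrices `r`, `lod`, `phase_repulsion` (logical),
#'   `n` with marker ids as dimnames.
#' @export
two_point_all <- function(table) {
  calls <- gt_progeny(table)$calls
  m <- nrow(calls)
  ids <- rownames(calls)
  ind <- lapply(CALL_CODES, function(g) (!is.na(calls) & calls == g) * 1)
  names(ind) <- CALL_CODES
  cross <- list()
  for (ga in CALL_CODES) for (gb in CALL_CODES) {
    cross[[paste0(ga, gb)]] <- tcrossprod(ind[[ga]], ind[[gb]])
  }
  iu <- which(upper.tri(matrix(0, m, m)), arr.ind = TRUE)
  counts <- sapply(cross, function(mat) mat[iu])
  if (m == 2) counts <- matrix(counts, nrow = 1)
  res <- tp_em(counts)
  n_joint <- rowSums(counts)
  pairs <- tibble::tibble(
    marker_a = ids[iu[, 1]], marker_b = ids[iu[, 2]],
    r_hat = res$r_hat, lod = res$lod, phase = res$phase,
    n = as.integer(n_joint), reliable = n_joint >= 10
  )
  mk_mat <- function(v, diag_val) {
    out <- matrix(diag_val, m, m, dimnames = list(ids, ids))
    out[iu] <- v
    out[iu[, c(2, 1), drop = FALSE]] <- v
    out
  }
  structure(list(
    pairs = pairs,
    r = mk_mat(res$r_hat, 0),
    lod = mk_mat(res$lod, 0),
    phase_repulsion = mk_mat(res$phase == "repulsion", FALSE) > 0,
    n = mk_mat(n_joint, 0)
  ), class = "two_point_set")
}
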