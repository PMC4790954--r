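#' Place cofactors along a genetic map
#'
#' Lays a grid at `spacing_cM` within each linkage group, snaps every grid
#' point to the nearest mapped marker, and collapses duplicates.
#'
#' @param map A `genetic_map`.
#' @param spacing_cM Grid spacing (default 1.51).
#' @return A tibble `group`, `marker`, `cM` of cofactor markers.
#' @export
place_cofactors <- function(map, spacing_cM = 1.51) {
  stopifnot(nrow(map) > 0, spacing_cM > 0)
  purrr::map_dfr(unique(map$group), function(g) {
    sub <- map[map$group == g, ]
    pts <- seq(0, max(sub$cM), by = spacing_cM)
    snap <- vapply(pts, function(p) which.min(abs(sub$cM - p)), integer(1))
    snap <- unique(snap)
    tibble::tibble(group = g, marker = sub$marker[snap], cM = sub$cM[snap])
  })
}

#' Effective number of independent tests (Li-Ji) and joint-scan threshold
#'
#' Computes, per linkage group, the eigenvalues of the correlation matrix of
#' the marker additive scores and the effective number of tests
#' `M_eff = sum_i ( I(lambda_i >= 1) + (lambda_i - floor(lambda_i)) )`;
#' sums `M_eff` over groups; converts the genome-wide level `alpha` to a
#' per-test level `alpha* = 1 - (1 - alpha)^(1 / M_eff)` and a threshold
#' `-log10(alpha*)` on the joint-scan profile.
#'
#' @param x A `geno_prob` object, or a numeric individuals x markers
#'   additive-score matrix (then treated as one group).
#' @param alpha Genome-wide significance level (default 0.05).
#' @return A list of class `li_ji`: `m_eff`, `alpha_star`, `threshold`,
#'   `per_group` (tibble `group`, `n_markers`, `m_eff`).
#' @export
li_ji_threshold <- function(x, alpha = 0.05) {
  meff_of <- function(scores) {
    sds <- apply(scores, 2, stats::sd)
    scores <- scores[, sds > 1e-12, drop = FALSE]
    m <- ncol(scores)
    if (m == 0) return(0)
    if (m == 1) return(1)
    lambda <- eigen(stats::cor(scores), symmetric = TRUE,
                    only.values = TRUE)$values
    ## guard the floor() discontinuity against eigenvalue round-off
    lambda <- pmax(round(lambda, 8), 0)
    sum((lambda >= 1) + (lambda - floor(lambda)))
  }
  if (inherits(x, "geno_prob")) {
    per_group <- purrr::map_dfr(unique(x$grid$group), function(g) {
      idx <- which(x$grid$group == g & !is.na(x$grid$marker))
      gp <- genetic_predictors(x, idx)
      tibble::tibble(group = g, n_markers = length(idx),
                     m_eff = meff_of(gp$add))
    })
  } else {
    per_group <- tibble::tibble(group = 1L, n_markers = ncol(x),
                                m_eff = meff_of(as.matrix(x)))
  }
  m_eff <- sum(per_group$m_eff)
  alpha_star <- 1 - (1 - alpha)^(1 / m_eff)
  structure(list(m_eff = m_eff, alpha_star = alpha_star,
                 threshold = -log10(alpha_star), per_group = per_group),
            class = "li_ji")
}

## Bivariate fixed-effects fit with unstructured 2x2 residual covariance by
## iterative GLS (REML-style residual covariance re-estimation).  With
## complete cases and an identical design for both traits the GLS update
## coincides with per-trait OLS, so the iteration converges immediately;
## the loop and cap are retained for the general contract.
fit_bivariate <- function(X, Y, max_iter = 1000, tol = 1e-8) {
  n <- nrow(Y)
  qrX <- qr(X)
  rank <- qrX$rank
  used <- qrX$pivot[seq_len(rank)]
  Xr <- X[, used, drop = FALSE]
  B_old <- NULL
  for (it in seq_len(max_iter)) {
    fit <- stats::lm.fit(Xr, Y)
    B <- fit$coefficients
    E <- fit$residuals
    Sigma <- crossprod(E) / max(n - rank, 1)   # REML divisor
    if (!is.null(B_old) && max(abs(B - B_old)) < tol) break
    B_old <- B
  }
  XtXi <- chol2inv(chol(crossprod(Xr)))
  list(coef = B, Sigma = Sigma, XtXi = XtXi, used = used, rank = rank,
       resid = E, n = n)
}

## Wald test that the coefficients at rows `rows` (of the reduced design)
## are zero for both traits, under cov(vec(B)) = Sigma %x% XtXi.
wald_joint <- function(fit, rows) {
  theta <- c(fit$coef[rows, 1], fit$coef[rows, 2])
  V <- fit$Sigma %x% fit$XtXi[rows, rows, drop = FALSE]
  ok <- !is.na(theta)
  theta <- theta[ok]; V <- V[ok, ok, drop = FALSE]
  if (!length(theta)) return(list(stat = 0, df = 0L, p = 1))
  stat <- tryCatch(drop(t(theta) %*% solve(V, theta)), error = function(e) NA_real_)
  df <- length(theta)
  list(stat = stat, df = df,
       p = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Joint two-trait QTL scan with cofactors
#'
#' At each grid position fits the bivariate mixed model
#' `y_ij = mu + T_j + sum_f (x_if^add c_jf^add + x_if^dom c_jf^dom)
#' + x_i^add alpha_j^add + x_i^dom alpha_j^dom + TE_ij`,
#' where `j` indexes the two traits, `F` is the cofactor set (cofactors
#' within `cof_prox_cM` of the tested position are excluded), the genetic
#' predictors are posterior-expected additive and dominance codes, and the
#' trait residuals `TE_ij` have an unstructured 2x2 covariance estimated by
#' iterative REML-style updates (iteration cap 1000).  The profile reported
#' is `-log10 p` of the joint Wald test that all four tested-position
#' effects are zero.
#'
#' @param probs A `geno_prob`.
#' @param pheno Phenotype tibble; complete cases on both traits are used.
#' @param traits Character vector of exactly two trait names.
#' @param cofactors Cofactor tibble from [place_cofactors()] (or `NULL` for
#'   a cofactor-free scan).
#' @param cof_prox_cM Minimum cofactor proximity to the tested position
#'   (default 50 cM).
#' @return A tibble of class `joint_scan`: `group`, `cM`, `marker`, `bp`,
#'   `neglog10p`, `a1`, `d1`, `a2`, `d2`, `converged`; attributes `traits`,
#'   `n`.
#' @export
joint_scan <- function(probs, pheno, traits, cofactors = NULL,
                       cof_prox_cM = 50) {
  stopifnot(length(traits) == 2)
  idx <- match(probs$samples, pheno$sample)
  Y <- cbind(pheno[[traits[1]]][idx], pheno[[traits[2]]][idx])
  keep <- stats::complete.cases(Y)
  Y <- Y[keep, , drop = FALSE]
  n <- nrow(Y)
  grid <- probs$grid
  cof_idx <- if (!is.null(cofactors) && nrow(cofactors)) {
    match(cofactors$marker, grid$marker)
  } else integer()
  gp_cof <- if (length(cof_idx)) genetic_predictors(probs, cof_idx)
  res <- purrr::map_dfr(seq_len(nrow(grid)), function(k) {
    if (length(cof_idx)) {
      near <- grid$group[cof_idx] == grid$group[k] &
        abs(grid$cM[cof_idx] - grid$cM[k]) < cof_prox_cM
      use <- !near
      Xc <- cbind(gp_cof$add[keep, use, drop = FALSE],
                  gp_cof$dom[keep, use, drop = FALSE])
    } else Xc <- NULL
    gq <- genetic_predictors(probs, k)
    X <- cbind(`(Intercept)` = 1, Xc, q_add = gq$add[keep, 1],
               q_dom = gq$dom[keep, 1])
    p <- ncol(X)
    fit <- tryCatch(fit_bivariate(X, Y), error = function(e) NULL)
    if (is.null(fit)) {
      return(tibble::tibble(neglog10p = NA_real_, a1 = NA_real_,
                            d1 = NA_real_, a2 = NA_real_, d2 = NA_real_,
                            converged = FALSE))
    }
    rows <- match(c(p - 1, p), fit$used)
    w <- wald_joint(fit, rows[!is.na(rows)])
    co <- function(r, j) {
      if (is.na(rows[r])) NA_real_ else unname(fit$coef[rows[r], j])
    }
    tibble::tibble(
      neglog10p = -log10(max(w$p, 1e-300)),
      a1 = co(1, 1), d1 = co(2, 1), a2 = co(1, 2), d2 = co(2, 2),
      converged = is.finite(w$stat)
    )
  })
  out <- dplyr::bind_cols(grid[, c("group", "cM", "marker", "bp")], res)
  class(out) <- c("joint_scan", class(out))
  attr(out, "traits") <- traits
  attr(out, "n") <- n
  out
}

#' Backward selection of joint QTL and final effect estimation
#'
#' Candidate peaks of the joint profile above the threshold are greedily
#' selected in order of decreasing significance subject to a minimum
#' pairwise separation (within a group) of `min_sep_cM`.  The simplified
#' model `y_ij = mu + T_j + sum_l (x_il^add alpha_jl^add + x_il^dom
#' alpha_jl^dom) + GT_ij` is then fitted over the selected loci jointly;
#' loci whose 4-df joint test falls below the threshold are removed
#' iteratively (weakest first).  Per-trait effects and explained-variance
#' fractions are reported.
#'
#' @param scan A `joint_scan`.
#' @param probs The `geno_prob` used for the scan.
#' @param pheno,traits As in [joint_scan()].
#' @param threshold Profile threshold (e.g. `li_ji_threshold(...)$threshold`).
#' @param min_sep_cM Minimum separation of selected QTL (default 30).
#' @return A tibble of class `joint_qtl`: one row per retained locus with
#'   `group`, `cM`, `marker`, `neglog10p`, per-trait `a1`, `d1`, `a2`, `d2`,
#'   and `r2_1`, `r2_2` (drop-one explained-variance fractions per trait).
#' @export
backselect_qtl <- function(scan, probs, pheno, traits, threshold,
                           min_sep_cM = 30) {
  ok <- !is.na(scan$neglog10p) & scan$converged
  cand <- scan[ok & scan$neglog10p > threshold, ]
  empty <- tibble::tibble(group = integer(), cM = numeric(),
                          marker = character(), neglog10p = numeric(),
                          a1 = numeric(), d1 = numeric(), a2 = numeric(),
                          d2 = numeric(), r2_1 = numeric(), r2_2 = numeric())
  class(empty) <- c("joint_qtl", class(empty))
  if (nrow(cand) == 0) return(empty)
  cand <- cand[order(-cand$neglog10p, cand$group, cand$cM), ]
  sel <- cand[0, ]
  for (i in seq_len(nrow(cand))) {
    row <- cand[i, ]
    clash <- sel$group == row$group & abs(sel$cM - row$cM) < min_sep_cM
    if (!any(clash)) sel <- dplyr::bind_rows(sel, row)
  }
  idx <- match(probs$samples, pheno$sample)
  Y <- cbind(pheno[[traits[1]]][idx], pheno[[traits[2]]][idx])
  keep <- stats::complete.cases(Y)
  Y <- Y[keep, , drop = FALSE]
  grid <- probs$grid

  fit_loci <- function(sel) {
    gi <- vapply(seq_len(nrow(sel)), function(i) {
      which(grid$group == sel$group[i] & abs(grid$cM - sel$cM[i]) < 1e-9)[1]
    }, integer(1))
    gp <- genetic_predictors(probs, gi)
    X <- matrix(1, nrow(Y), 1)
    for (i in seq_along(gi)) X <- cbind(X, gp$add[keep, i], gp$dom[keep, i])
    fit <- fit_bivariate(X, Y)
    tests <- lapply(seq_along(gi), function(i) {
      rows <- match(c(2 * i, 2 * i + 1), fit$used)
      wald_joint(fit, rows[!is.na(rows)])
    })
    list(fit = fit, tests = tests, gi = gi)
  }

  repeat {
    if (nrow(sel) == 0) return(empty)
    fl <- fit_loci(sel)
    nl10 <- vapply(fl$tests, function(t) -log10(max(t$p, 1e-300)), numeric(1))
    if (all(nl10 > threshold)) break
    sel <- sel[-which.min(nl10), ]
  }
  fit <- fl$fit
  tss <- colSums(scale(Y, scale = FALSE)^2)
  r2 <- vapply(seq_len(nrow(sel)), function(i) {
    sub <- sel[-i, , drop = FALSE]
    rss_red <- if (nrow(sub)) colSums(fit_loci(sub)$fit$resid^2)
               else tss
    (rss_red - colSums(fit$resid^2)) / tss
  }, numeric(2))
  r2 <- matrix(r2, nrow = 2)
  eff <- function(i, r, j) {
    rows <- match(2 * i + r - 1, fit$used)
    if (is.na(rows)) NA_real_ else fit$coef[rows, j]
  }
  out <- tibble::tibble(
    group = sel$group, cM = sel$cM, marker = sel$marker,
    neglog10p = vapply(fl$tests, function(t) -log10(max(t$p, 1e-300)), numeric(1)),
    a1 = vapply(seq_len(nrow(sel)), eff, numeric(1), r = 1, j = 1),
    d1 = vapply(seq_len(nrow(sel)), eff, numeric(1), r = 2, j = 1),
    a2 = vapply(seq_len(nrow(sel)), eff, numeric(1), r = 1, j = 2),
    d2 = vapply(seq_len(nrow(sel)), eff, numeric(1), r = 2, j = 2),
    r2_1 = pmax(r2[1, ], 0), r2_2 = pmax(r2[2, ], 0)
  )
  class(out) <- c("joint_qtl", class(out))
  attr(out, "traits") <- traits
  attr(out, "Sigma") <- fit$Sigma
  out
}
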