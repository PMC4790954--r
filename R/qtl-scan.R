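align_trait <- function(probs, pheno, trait) {
  stopifnot(trait %in% names(pheno))
  y <- pheno[[trait]][match(probs$samples, pheno$sample)]
  ok <- !is.na(y)
  list(y = y[ok], keep = which(ok))
}

gauss_loglik <- function(resid, n) {
  s2 <- sum(resid^2) / n
  -n / 2 * (log(2 * pi * s2) + 1)
}

## Vectorised-across-positions EM for the 3-genotype-class mixture.
## P: n x npos x 3 posterior probabilities; y: response.  Returns per-
## position log-likelihood and class means (penetrances for binary).
em_mixture <- function(P, y, model, tol = 1e-8, max_iter = 1000) {
  n <- length(y); npos <- dim(P)[2]
  Pg <- lapply(1:3, function(g) matrix(P[, , g], n, npos))
  rep_row <- function(v) matrix(v, n, npos, byrow = TRUE)
  if (model == "normal") {
    mu <- vapply(Pg, function(p) colSums(p * y) / pmax(colSums(p), 1e-12),
                 numeric(npos))
    mu <- t(matrix(mu, npos, 3))          # 3 x npos
    sigma <- rep(stats::sd(y) + 1e-12, npos)
  } else {
    mu <- vapply(Pg, function(p) colSums(p * y) / pmax(colSums(p), 1e-12),
                 numeric(npos))
    mu <- t(matrix(pmin(pmax(mu, 1e-9), 1 - 1e-9), npos, 3))
  }
  ll_old <- rep(-Inf, npos)
  for (it in seq_len(max_iter)) {
    W <- vector("list", 3)
    S <- matrix(0, n, npos)
    for (g in 1:3) {
      dens <- if (model == "normal") {
        stats::dnorm(y, rep_row(mu[g, ]), rep_row(sigma))
      } else {
        rep_row(mu[g, ])^y * rep_row(1 - mu[g, ])^(1 - y)
      }
      W[[g]] <- Pg[[g]] * dens
      S <- S + W[[g]]
    }
    ll <- colSums(log(pmax(S, 1e-300)))
    if (max(abs(ll - ll_old)) < tol * (1 + max(abs(ll)))) { ll_old <- ll; break }
    ll_old <- ll
    sw <- lapply(W, function(w) w / S)
    if (model == "normal") {
      ssq <- rep(0, npos)
      for (g in 1:3) {
        cw <- colSums(sw[[g]])
        mu[g, ] <- colSums(sw[[g]] * y) / pmax(cw, 1e-12)
        ssq <- ssq + colSums(sw[[g]] * (y - rep_row(mu[g, ]))^2)
      }
      sigma <- sqrt(pmax(ssq / n, 1e-12))
    } else {
      for (g in 1:3) {
        cw <- colSums(sw[[g]])
        mu[g, ] <- pmin(pmax(colSums(sw[[g]] * y) / pmax(cw, 1e-12),
                             1e-9), 1 - 1e-9)
      }
    }
  }
  list(loglik = ll_old, mu = mu)
}

## EM at one position with fixed covariates (composite interval mapping).
## M-step is a weighted least-squares (normal) or weighted logistic
## (binary) fit on class-expanded data.
em_covar <- function(p3, y, X, model, tol = 1e-8, max_iter = 200) {
  n <- length(y)
  Xe <- rbind(cbind(cls1 = 1, cls2 = 0, cls3 = 0, X),
              cbind(cls1 = 0, cls2 = 1, cls3 = 0, X),
              cbind(cls1 = 0, cls2 = 0, cls3 = 1, X))
  ye <- rep(y, 3)
  w <- c(p3[, 1], p3[, 2], p3[, 3])
  ll_old <- -Inf
  fitted <- NULL
  for (it in seq_len(max_iter)) {
    keep <- w > 1e-12
    if (model == "normal") {
      fit <- stats::lm.wfit(Xe[keep, , drop = FALSE], ye[keep], w[keep])
      mu_e <- drop(Xe %*% ifelse(is.na(fit$coefficients), 0, fit$coefficients))
      sigma <- sqrt(sum(w[keep] * fit$residuals^2) / n)
      dens <- stats::dnorm(ye, mu_e, sigma)
    } else {
      fit <- suppressWarnings(stats::glm.fit(
        Xe[keep, , drop = FALSE], ye[keep], weights = w[keep],
        family = stats::binomial()))
      eta <- drop(Xe %*% ifelse(is.na(fit$coefficients), 0, fit$coefficients))
      pe <- stats::plogis(eta)
      dens <- pe^ye * (1 - pe)^(1 - ye)
    }
    dm <- matrix(dens, n, 3)
    S <- rowSums(p3 * dm)
    ll <- sum(log(pmax(S, 1e-300)))
    wm <- p3 * dm / S
    w <- c(wm[, 1], wm[, 2], wm[, 3])
    if (abs(ll - ll_old) < tol * (1 + abs(ll))) { ll_old <- ll; break }
    ll_old <- ll
    fitted <- fit
  }
  cls <- if (model == "normal") {
    fit$coefficients[1:3]
  } else stats::plogis(fit$coefficients[1:3])
  list(loglik = ll_old, mu = matrix(cls, 3, 1))
}

#' Single-trait QTL genome scan
#'
#' EM interval mapping over the genotype-probability grid.  At each
#' position the three-genotype-class model is fitted by EM against the
#' null: a Gaussian mixture weighted by the posterior genotype
#' probabilities for a normal trait, per-class Bernoulli penetrances for a
#' binary (0/1) trait.  `LOD = log10(L1 / L0)`.  When `cofactors` are
#' given, both models condition on the cofactor markers' additive and
#' dominance predictors, excluding cofactors within `window_cM` of the
#' tested position (composite interval mapping).  Additive and dominance
#' effects come from the class means: `a = (mu_BB - mu_AA) / 2`,
#' `d = mu_AB - (mu_AA + mu_BB) / 2` — a positive `a` means the B
#' (grandparent-2) allele raises the trait.  `R^2 = 1 - 10^(-2 LOD / n)`.
#'
#' @param probs A `geno_prob` grid.
#' @param pheno A phenotype tibble (`sample` column plus traits).
#' @param trait Trait column name.
#' @param model `"normal"` or `"binary"`.
#' @param cofactors Optional character vector of cofactor marker ids (see
#'   [select_cofactors()]).
#' @param window_cM Exclusion window around the tested position for
#'   cofactors (default 10).
#' @return A tibble of class `qtl_scan`: `group`, `cM`, `marker`, `bp`,
#'   `lod`, `a`, `d`, with attributes `n`, `model`, `trait`.
#' @export
scan_single <- function(probs, pheno, trait, model = c("normal", "binary"),
                        cofactors = NULL, window_cM = 10) {
  model <- match.arg(model)
  al <- align_trait(probs, pheno, trait)
  y <- al$y
  if (model == "binary") {
    if (!all(y %in% c(0, 1))) stop("binary model requires a 0/1 trait", call. = FALSE)
    if (length(unique(y)) < 2) stop("binary trait has a single class", call. = FALSE)
  }
  P <- probs$probs[al$keep, , , drop = FALSE]
  n <- length(y)
  grid <- probs$grid
  npos <- nrow(grid)

  if (is.null(cofactors)) {
    fit <- em_mixture(P, y, model)
    ll0 <- if (model == "normal") {
      gauss_loglik(y - mean(y), n)
    } else {
      p0 <- mean(y); sum(y) * log(p0) + sum(1 - y) * log(1 - p0)
    }
    lod <- pmax((fit$loglik - ll0) / log(10), 0)
    a <- (fit$mu[3, ] - fit$mu[1, ]) / 2
    d <- fit$mu[2, ] - (fit$mu[1, ] + fit$mu[3, ]) / 2
  } else {
    cof_idx <- match(cofactors, grid$marker)
    if (anyNA(cof_idx)) stop("cofactor markers not on the grid", call. = FALSE)
    gp <- genetic_predictors(probs, cof_idx)
    Xall <- cbind(gp$add[al$keep, , drop = FALSE],
                  gp$dom[al$keep, , drop = FALSE])
    lod <- a <- d <- numeric(npos)
    for (k in seq_len(npos)) {
      same_grp <- grid$group[cof_idx] == grid$group[k]
      excl <- same_grp & abs(grid$cM[cof_idx] - grid$cM[k]) < window_cM
      use <- c(!excl, !excl)
      X <- Xall[, use, drop = FALSE]
      qrX <- qr(cbind(1, X))
      keep_cols <- setdiff(qrX$pivot[seq_len(qrX$rank)], 1L) - 1L
      X <- X[, keep_cols, drop = FALSE]
      if (model == "normal") {
        f0 <- stats::lm.fit(cbind(1, X), y)
        ll0 <- gauss_loglik(f0$residuals, n)
      } else {
        f0 <- suppressWarnings(stats::glm.fit(cbind(1, X), y,
                                              family = stats::binomial()))
        p0 <- f0$fitted.values
        ll0 <- sum(y * log(p0) + (1 - y) * log(1 - p0))
      }
      f1 <- em_covar(matrix(P[, k, ], n, 3), y, X, model)
      lod[k] <- max((f1$loglik - ll0) / log(10), 0)
      a[k] <- (f1$mu[3, 1] - f1$mu[1, 1]) / 2
      d[k] <- f1$mu[2, 1] - (f1$mu[1, 1] + f1$mu[3, 1]) / 2
    }
    ll0 <- NA_real_
  }
  out <- tibble::tibble(group = grid$group, cM = grid$cM,
                        marker = grid$marker, bp = grid$bp,
                        lod = lod, a = a, d = d)
  class(out) <- c("qtl_scan", class(out))
  attr(out, "n") <- n
  attr(out, "model") <- model
  attr(out, "trait") <- trait
  out
}

#' Forward selection of cofactor markers for composite interval mapping
#'
#' Greedy forward selection of marker cofactors by residual sum of squares
#' of the linear model of the trait on the selected markers' additive and
#' dominance predictors, capped at `max_cofactors`.
#'
#' @inheritParams scan_single
#' @param max_cofactors Maximum number of cofactors (default 3).
#' @return Character vector of selected marker ids (possibly empty).
#' @export
select_cofactors <- function(probs, pheno, trait, max_cofactors = 3) {
  al <- align_trait(probs, pheno, trait)
  y <- al$y
  grid <- probs$grid
  cand <- which(!is.na(grid$marker))
  gp <- genetic_predictors(probs, cand)
  add <- gp$add[al$keep, , drop = FALSE]
  dom <- gp$dom[al$keep, , drop = FALSE]
  chosen <- integer()
  X <- matrix(1, length(y), 1)
  for (step in seq_len(max_cofactors)) {
    rss <- vapply(seq_along(cand), function(j) {
      if (j %in% chosen) return(Inf)
      sum(stats::lm.fit(cbind(X, add[, j], dom[, j]), y)$residuals^2)
    }, numeric(1))
    best <- which.min(rss)
    rss0 <- sum(stats::lm.fit(X, y)$residuals^2)
    n <- length(y)
    ## require the added marker to be worthwhile by BIC
    if (n * log(rss[best] / n) + 2 * log(n) >= n * log(rss0 / n)) break
    chosen <- c(chosen, best)
    X <- cbind(X, add[, best], dom[, best])
  }
  grid$marker[cand[chosen]]
}

#' Genome-wide LOD threshold by trait permutation
#'
#' Permutes the trait values across individuals, records the genome-wide
#' maximum LOD of each permuted scan, and returns the empirical
#' `(1 - alpha)` quantile.
#'
#' @inheritParams scan_single
#' @param n_perm Number of permutations (default 1000; at least 100).
#' @param alpha Genome-wide significance level (default 0.05).
#' @param seed Seed for reproducibility.
#' @return The LOD threshold (numeric scalar) with attribute `null_max`
#'   (the permutation maxima).
#' @export
permutation_threshold <- function(probs, pheno, trait,
                                  model = c("normal", "binary"),
                                  n_perm = 1000, alpha = 0.05, seed = 1) {
  model <- match.arg(model)
  if (n_perm < 100) stop("n_perm must be at least 100", call. = FALSE)
  al <- align_trait(probs, pheno, trait)
  y <- al$y
  P <- probs$probs[al$keep, , , drop = FALSE]
  n <- length(y)
  ll0 <- if (model == "normal") {
    gauss_loglik(y - mean(y), n)
  } else {
    p0 <- mean(y); sum(y) * log(p0) + sum(1 - y) * log(1 - p0)
  }
  set.seed(seed)
  null_max <- vapply(seq_len(n_perm), function(b) {
    yp <- sample(y)
    fit <- em_mixture(P, yp, model, tol = 1e-6, max_iter = 200)
    max((fit$loglik - ll0) / log(10))
  }, numeric(1))
  thr <- unname(stats::quantile(null_max, 1 - alpha))
  attr(thr, "null_max") <- null_max
  thr
}

#' LOD support interval around a scan peak
#'
#' The widest contiguous run of grid positions around the peak whose LOD
#' stays within `drop` of the peak LOD, restricted to the peak's linkage
#' group.  Physical bounds are the positions of the nearest genotyped
#' markers at or outside the interval ends.  An interval reaching the group
#' boundary is flagged truncated.
#'
#' @param scan A `qtl_scan`.
#' @param drop LOD drop defining the interval (1.5 or 1.8 conventionally).
#' @param peak Optional list/row with `group` and `cM`; default the
#'   genome-wide maximum (ties broken toward the smaller cM).
#' @return A one-row tibble: `group`, `peak_cM`, `lod`, `lo_cM`, `hi_cM`,
#'   `lo_bp`, `hi_bp`, `truncated`.
#' @export
support_interval <- function(scan, drop = 1.8, peak = NULL) {
  if (is.null(peak)) {
    i <- which(scan$lod == max(scan$lod))
    i <- i[order(scan$cM[i])][1]
    peak <- list(group = scan$group[i], cM = scan$cM[i])
  }
  sub <- scan[scan$group == peak$group, ]
  sub <- sub[order(sub$cM), ]
  pk <- which.min(abs(sub$cM - peak$cM))
  cut <- sub$lod[pk] - drop
  above <- sub$lod >= cut
  lo <- pk; while (lo > 1 && above[lo - 1]) lo <- lo - 1
  hi <- pk; while (hi < nrow(sub) && above[hi + 1]) hi <- hi + 1
  mk <- which(!is.na(sub$marker))
  lo_mk <- mk[mk <= lo]
  hi_mk <- mk[mk >= hi]
  lo_bp <- if (length(lo_mk)) sub$bp[max(lo_mk)] else sub$bp[mk[1]]
  hi_bp <- if (length(hi_mk)) sub$bp[min(hi_mk)] else sub$bp[mk[length(mk)]]
  tibble::tibble(group = peak$group, peak_cM = sub$cM[pk], lod = sub$lod[pk],
                 lo_cM = sub$cM[lo], hi_cM = sub$cM[hi],
                 lo_bp = lo_bp, hi_bp = hi_bp,
                 truncated = lo == 1 || hi == nrow(sub))
}

#' Call QTL peaks from a genome scan
#'
#' One peak per linkage group whose maximum LOD exceeds the threshold, with
#' effects, explained variance and LOD support interval.
#'
#' @param scan A `qtl_scan`.
#' @param threshold Genome-wide LOD threshold (e.g. from
#'   [permutation_threshold()]).
#' @param drop Support-interval LOD drop (default 1.8).
#' @return A tibble, one row per significant peak: `group`, `peak_cM`,
#'   `marker` (nearest genotyped marker), `bp`, `lod`, `a`, `d`, `r2`,
#'   `lo_cM`, `hi_cM`, `lo_bp`, `hi_bp`, `truncated`.
#' @export
qtl_peaks <- function(scan, threshold, drop = 1.8) {
  n <- attr(scan, "n")
  purrr::map_dfr(unique(scan$group), function(g) {
    sub <- scan[scan$group == g, ]
    if (max(sub$lod) <= threshold) return(NULL)
    i <- which(sub$lod == max(sub$lod))
    i <- i[order(sub$cM[i])][1]
    si <- support_interval(scan, drop, list(group = g, cM = sub$cM[i]))
    mk <- which(!is.na(sub$marker))
    nearest <- mk[which.min(abs(sub$cM[mk] - sub$cM[i]))]
    tibble::tibble(group = g, peak_cM = sub$cM[i],
                   marker = sub$marker[nearest], bp = sub$bp[nearest],
                   lod = sub$lod[i], a = sub$a[i], d = sub$d[i],
                   r2 = 1 - 10^(-2 * sub$lod[i] / n),
                   lo_cM = si$lo_cM, hi_cM = si$hi_cM,
                   lo_bp = si$lo_bp, hi_bp = si$hi_bp,
                   truncated = si$truncated)
  })
}
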