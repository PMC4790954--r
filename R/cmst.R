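#' Causal model selection test for two traits sharing a QTL
#'
#' Compares four Gaussian models for the dependence structure between two
#' traits and a shared QTL `Q`:
#' \describe{
#'   \item{causal}{`T1 ~ Q` then `T2 ~ T1` (Q affects T2 only through T1).}
#'   \item{reactive}{`T2 ~ Q` then `T1 ~ T2`.}
#'   \item{independent}{`T1 ~ Q` and `T2 ~ Q`.}
#'   \item{full}{`T1 ~ Q` and `T2 ~ Q + T1` (nine free parameters).}
#' }
#' Each QTL term is a three-genotype-class mean (3 parameters, entered
#' through the posterior genotype probabilities at the locus) and each model
#' component has one residual variance.  Models are fitted by maximum
#' likelihood; log-likelihood, parameter counts, AIC
#' (`-2 logLik + 2 k`) and BIC (`-2 logLik + k log n`) are reported with the
#' selected model under each criterion.
#'
#' @param pheno Phenotype tibble with a `sample` column.
#' @param trait1,trait2 Trait column names (trait1 plays T1).
#' @param qtl_probs Either a `geno_prob` with `at = c(group, cM)` giving the
#'   locus, or directly an individuals x 3 matrix of genotype probabilities
#'   aligned to `pheno$sample` order.
#' @param at Optional `c(group, cM)` locus when `qtl_probs` is a
#'   `geno_prob`.
#' @return A tibble of class `cmst_result` (`model`, `logLik`, `n_params`,
#'   `AIC`, `BIC`) with attributes `best_aic`, `best_bic`, `n`.
#' @export
cmst <- function(pheno, trait1, trait2, qtl_probs, at = NULL) {
  if (inherits(qtl_probs, "geno_prob")) {
    stopifnot(!is.null(at), length(at) == 2)
    k <- which(qtl_probs$grid$group == at[1] &
                 abs(qtl_probs$grid$cM - at[2]) < 1e-6)
    if (!length(k)) stop("locus not on the probability grid", call. = FALSE)
    Q <- matrix(qtl_probs$probs[, k[1], ], ncol = 3)
    idx <- match(qtl_probs$samples, pheno$sample)
  } else {
    Q <- as.matrix(qtl_probs)
    stopifnot(ncol(Q) == 3)
    idx <- seq_len(nrow(Q))
  }
  t1 <- pheno[[trait1]][idx]
  t2 <- pheno[[trait2]][idx]
  keep <- stats::complete.cases(t1, t2) & stats::complete.cases(Q)
  t1 <- t1[keep]; t2 <- t2[keep]; Q <- Q[keep, , drop = FALSE]
  n <- length(t1)
  if (stats::sd(t1) < 1e-12 || stats::sd(t2) < 1e-12) {
    stop("degenerate (zero-variance) trait", call. = FALSE)
  }
  ll_lm <- function(y, X) {
    fit <- stats::lm.fit(X, y)
    npar <- fit$rank + 1L  # coefficients + residual variance
    list(ll = gauss_loglik(fit$residuals, n), k = npar)
  }
  one <- matrix(1, n, 1)
  m_q1 <- ll_lm(t1, Q)
  m_q2 <- ll_lm(t2, Q)
  m_21 <- ll_lm(t2, cbind(one, t1))
  m_12 <- ll_lm(t1, cbind(one, t2))
  m_f2 <- ll_lm(t2, cbind(Q, t1))
  models <- tibble::tibble(
    model = c("causal", "reactive", "independent", "full"),
    logLik = c(m_q1$ll + m_21$ll, m_q2$ll + m_12$ll,
               m_q1$ll + m_q2$ll, m_q1$ll + m_f2$ll),
    n_params = c(m_q1$k + m_21$k, m_q2$k + m_12$k,
                 m_q1$k + m_q2$k, m_q1$k + m_f2$k)
  )
  models$AIC <- -2 * models$logLik + 2 * models$n_params
  models$BIC <- -2 * models$logLik + models$n_params * log(n)
  class(models) <- c("cmst_result", class(models))
  attr(models, "best_aic") <- models$model[which.min(models$AIC)]
  attr(models, "best_bic") <- models$model[which.min(models$BIC)]
  attr(models, "n") <- n
  models
}

#' @export
print.cmst_result <- function(x, ...) {
  cat(sprintf("<cmst_result> n = %d\n", attr(x, "n")))
  print(tibble::as_tibble(x))
  cat("best by AIC:", attr(x, "best_aic"),
      "| best by BIC:", attr(x, "best_bic"), "\n")
  invisible(x)
}
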