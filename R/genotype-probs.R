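#' Posterior genotype probabilities on a cM grid
#'
#' Runs the forward-backward algorithm for the F2 hidden Markov model along
#' each linkage group: latent genotypes form a Markov chain with transition
#' matrices from the inverse-Kosambi of inter-position distances; observed
#' marker calls emit through a symmetric genotyping-error model (a true
#' genotype is observed correctly with probability `1 - error_prob`, as
#' either wrong code with `error_prob / 2`); missing calls emit uniformly.
#' The grid contains every marker position plus pseudomarkers every
#' `step_cM`.
#'
#' @param map A `genetic_map`.
#' @param table A progeny `genotype_table` containing the mapped markers.
#' @param step_cM Grid step between pseudomarkers (default 1 cM).
#' @param error_prob Genotyping-error rate (default 1e-4).
#' @return An object of class `geno_prob`: `grid` (tibble `group`, `cM`,
#'   `marker` — `NA` for pseudomarkers — `chrom`, `bp`), `probs` (array
#'   individuals x grid positions x 3 genotype classes), `samples`,
#'   `error_prob`.
#' @export
genotype_probabilities <- function(map, table, step_cM = 1.0,
                                   error_prob = 1e-4) {
  prog <- gt_progeny(table)
  missing_mk <- setdiff(map$marker, rownames(prog$calls))
  if (length(missing_mk)) {
    stop("mapped markers absent from genotype table: ",
         paste(utils::head(missing_mk, 5), collapse = ", "), call. = FALSE)
  }
  n <- ncol(prog$calls)
  samples <- colnames(prog$calls)
  grids <- list(); probs <- list()
  for (g in unique(map$group)) {
    sub <- map[map$group == g, ]
    pseudo <- setdiff(seq(0, max(sub$cM), by = step_cM), sub$cM)
    cm <- sort(unique(c(sub$cM, pseudo)))
    mk <- sub$marker[match(cm, sub$cM)]
    npos <- length(cm)
    num <- matrix(NA_integer_, npos, n)
    obs <- !is.na(mk)
    num[obs, ] <- match(prog$calls[mk[obs], , drop = FALSE], CALL_CODES)
    emit <- function(o) {
      e <- matrix(1, n, 3)
      ok <- !is.na(o)
      if (any(ok)) {
        e[ok, ] <- error_prob / 2
        if (error_prob == 0) e[ok, ] <- 0
        e[cbind(which(ok), o[ok])] <- 1 - error_prob
      }
      e
    }
    trans <- lapply(seq_len(max(npos - 1, 0)), function(k) {
      f2_transition(kosambi_inv(cm[k + 1] - cm[k]))
    })
    ## forward
    alpha <- array(0, c(n, npos, 3))
    phi <- matrix(rep(c(0.25, 0.5, 0.25), each = n), n, 3) * emit(num[1, ])
    phi <- phi / rowSums(phi)
    alpha[, 1, ] <- phi
    if (npos > 1) for (k in 2:npos) {
      phi <- (phi %*% trans[[k - 1]]) * emit(num[k, ])
      phi <- phi / rowSums(phi)
      alpha[, k, ] <- phi
    }
    ## backward
    beta <- matrix(1, n, 3)
    post <- array(0, c(n, npos, 3))
    post[, npos, ] <- alpha[, npos, ]
    if (npos > 1) for (k in (npos - 1):1) {
      beta <- (beta * emit(num[k + 1, ])) %*% t(trans[[k]])
      beta <- beta / rowSums(beta)
      p <- alpha[, k, ] * beta
      post[, k, ] <- p / rowSums(p)
    }
    grids[[as.character(g)]] <- tibble::tibble(
      group = g, cM = cm, marker = mk,
      chrom = sub$chrom[match(mk, sub$marker)],
      bp = sub$bp[match(mk, sub$marker)]
    )
    probs[[as.character(g)]] <- post
  }
  grid <- dplyr::bind_rows(grids)
  all_probs <- array(0, c(n, nrow(grid), 3),
                     dimnames = list(samples, NULL, CALL_CODES))
  at <- 0
  for (g in names(probs)) {
    np <- dim(probs[[g]])[2]
    all_probs[, at + seq_len(np), ] <- probs[[g]]
    at <- at + np
  }
  structure(list(grid = grid, probs = all_probs, samples = samples,
                 error_prob = error_prob, map = map),
            class = "geno_prob")
}

#' @export
print.geno_prob <- function(x, ...) {
  cat(sprintf("<geno_prob> %d individuals x %d grid positions (%d groups, error_prob %g)\n",
              dim(x$probs)[1], dim(x$probs)[2], length(unique(x$grid$group)),
              x$error_prob))
  invisible(x)
}

## Posterior-expected genetic predictors at given grid indices:
## additive x_add = P(BB) - P(AA) in [-1, 1]; dominance x_dom = P(AB).
genetic_predictors <- function(probs, idx) {
  x_add <- probs$probs[, idx, 3, drop = FALSE] - probs$probs[, idx, 1, drop = FALSE]
  x_dom <- probs$probs[, idx, 2, drop = FALSE]
  list(add = matrix(x_add, dim(probs$probs)[1]),
       dom = matrix(x_dom, dim(probs$probs)[1]))
}
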