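#' Curate intercross markers before mapping
#'
#' Removes markers with highly significant segregation distortion
#' (1:2:1 chi-squared p below `distortion_p`) and collapses loci that
#' duplicate genetic information — markers whose call vectors are identical,
#' treating missing as a wildcard match — to a single representative (the
#' marker with fewest missing calls), with the membership recorded.
#'
#' @param table A progeny `genotype_table` of intercross markers.
#' @param distortion_p Distortion removal threshold (default `1e-5`).
#' @return The curated `genotype_table`, with attributes `distorted`
#'   (removed marker ids) and `duplicates` (tibble `representative`,
#'   `member`).
#' @export
curate_for_mapping <- function(table, distortion_p = 1e-5) {
  cnt <- gt_counts(table)
  seg <- segregation_test(cnt$n_AA, cnt$n_AB, cnt$n_BB)
  distorted <- cnt$marker[seg$pvalue <= distortion_p]
  keep <- setdiff(rownames(table$calls), distorted)
  out <- gt_subset(table, markers = keep)

  calls <- gt_progeny(out)$calls
  m <- nrow(calls)
  n_miss <- rowSums(is.na(calls))
  ord <- order(n_miss)  # prefer the most complete marker as representative
  rep_of <- rep(NA_integer_, m)
  ## wildcard-duplicate detection: no observed disagreement between vectors
  num <- matrix(match(calls, CALL_CODES), m)  # 1/2/3, NA missing
  for (a_pos in seq_along(ord)) {
    i <- ord[a_pos]
    if (!is.na(rep_of[i])) next
    rep_of[i] <- i
    if (a_pos == length(ord)) break
    cand <- ord[(a_pos + 1):length(ord)]
    cand <- cand[is.na(rep_of[cand])]
    if (!length(cand)) next
    vi <- num[i, ]
    for (j in cand) {
      vj <- num[j, ]
      both <- !is.na(vi) & !is.na(vj)
      if (!any(vi[both] != vj[both])) rep_of[j] <- i
    }
  }
  ids <- rownames(calls)
  dup <- tibble::tibble(representative = ids[rep_of], member = ids)
  dup <- dup[dup$representative != dup$member, , drop = FALSE]
  out <- gt_subset(out, markers = ids[rep_of == seq_len(m)])
  attr(out, "distorted") <- distorted
  attr(out, "duplicates") <- dup
  out
}

#' Group markers into linkage groups
#'
#' Single-linkage clustering of markers using the pairwise linkage LOD:
#' connected components of the graph whose edges are pairs with
#' `lod >= lod_min`.  Singleton components are reported as unplaced.
#'
#' @param tp A `two_point_set` from [two_point_all()], or a symmetric LOD
#'   matrix with marker dimnames.
#' @param lod_min Grouping threshold (default 10, linkage-independence LOD).
#' @return A tibble `marker`, `group` (integer, ordered by decreasing group
#'   size; unplaced singletons have `group = NA`).
#' @export
group_markers <- function(tp, lod_min = 10) {
  lod <- if (inherits(tp, "two_point_set")) tp$lod else tp
  m <- nrow(lod)
  ids <- rownames(lod)
  adj <- lod >= lod_min
  diag(adj) <- FALSE
  ## union-find connected components
  parent <- seq_len(m)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  edge <- which(adj & upper.tri(adj), arr.ind = TRUE)
  for (k in seq_len(nrow(edge))) {
    a <- find(edge[k, 1]); b <- find(edge[k, 2])
    if (a != b) parent[b] <- a
  }
  comp <- vapply(seq_len(m), find, integer(1))
  sizes <- table(comp)
  keep <- names(sizes)[sizes > 1]
  ord <- keep[order(-sizes[keep], as.integer(keep))]
  grp <- match(as.character(comp), ord)
  tibble::tibble(marker = ids, group = grp)
}

## Resolve a consistent A/B labelling within a group: flip markers so every
## high-LOD pair is in coupling, propagating along a maximum-LOD spanning
## tree.  Grandparents are ungenotyped, so the labelling is an arbitrary but
## consistent convention.
resolve_phase <- function(tp, members) {
  m <- length(members)
  flip <- stats::setNames(rep(FALSE, m), members)
  if (m < 2) return(flip)
  lod <- tp$lod[members, members, drop = FALSE]
  repl <- tp$phase_repulsion[members, members, drop = FALSE]
  visited <- rep(FALSE, m)
  visited[1] <- TRUE
  for (step in seq_len(m - 1)) {
    sub <- lod[visited, !visited, drop = FALSE]
    best <- which(sub == max(sub), arr.ind = TRUE)[1, ]
    from <- which(visited)[best[1]]
    to <- which(!visited)[best[2]]
    flip[to] <- xor(flip[from], repl[from, to])
    visited[to] <- TRUE
  }
  flip
}

flip_calls <- function(calls, flip) {
  for (id in names(flip)[flip]) {
    v <- calls[id, ]
    calls[id, ] <- ifelse(v == "AA", "BB", ifelse(v == "BB", "AA", v))
  }
  calls
}

## F2 one-locus transition matrix between two loci at recombination
## fraction r (rows: genotype at locus 1; cols: locus 2).
f2_transition <- function(r) {
  p <- 1 - r
  matrix(c(p^2, 2 * p * r, r^2,
           p * r, p^2 + r^2, p * r,
           r^2, 2 * p * r, p^2),
         3, 3, byrow = TRUE)
}

## Forward log-likelihood of an ordered marker block under the F2 Markov
## chain.  `num` is an m x n matrix of numeric genotypes (1/2/3, NA missing)
## in map order; `r_vec` the m-1 interval recombination fractions.
hmm_order_loglik <- function(num, r_vec, error_prob = 1e-4) {
  m <- nrow(num); n <- ncol(num)
  emit <- function(obs) {
    e <- matrix(1, n, 3)
    ok <- !is.na(obs)
    if (any(ok)) {
      e[ok, ] <- error_prob / 2
      e[cbind(which(ok), obs[ok])] <- 1 - error_prob
    }
    e
  }
  phi <- matrix(rep(c(0.25, 0.5, 0.25), each = n), n, 3) * emit(num[1, ])
  ll <- log(rowSums(phi))
  phi <- phi / rowSums(phi)
  if (m > 1) {
    for (k in 2:m) {
      phi <- (phi %*% f2_transition(r_vec[k - 1])) * emit(num[k, ])
      s <- rowSums(phi)
      ll <- ll + log(s)
      phi <- phi / s
    }
  }
  sum(ll)
}

order_objective <- function(ord, num, r_mat, error_prob = 1e-4) {
  r_adj <- r_mat[cbind(ord[-length(ord)], ord[-1])]
  r_adj <- pmin(pmax(r_adj, 1e-6), 0.499)
  hmm_order_loglik(num[ord, , drop = FALSE], r_adj, error_prob)
}

greedy_seriation <- function(r_mat, lod_mat) {
  m <- nrow(r_mat)
  if (m <= 2) return(seq_len(m))
  start <- which(lod_mat == max(lod_mat), arr.ind = TRUE)[1, ]
  ord <- as.integer(start)
  left <- setdiff(seq_len(m), ord)
  while (length(left)) {
    d_head <- r_mat[ord[1], left]
    d_tail <- r_mat[ord[length(ord)], left]
    if (min(d_head) <= min(d_tail)) {
      pick <- left[which.min(d_head)]
      ord <- c(pick, ord)
    } else {
      pick <- left[which.min(d_tail)]
      ord <- c(ord, pick)
    }
    left <- setdiff(left, pick)
  }
  ord
}

#' Order the markers of one linkage group
#'
#' Builds an ordered map for a single linkage group: an initial order from
#' greedy seriation on two-point recombination fractions, refined by
#' `n_rounds` of deterministic local search (2-opt segment reversals plus
#' single-marker insertions) maximising the multipoint likelihood of the
#' observed genotypes under a Markov chain along the order.  Adjacent
#' distances are Kosambi-transformed interval estimates, each refined
#' against the multipoint likelihood.  The output order is canonical:
#' smaller physical coordinate first when physical data exist, otherwise
#' the lexicographically smaller terminal marker first.
#'
#' @param table A progeny `genotype_table` containing the group's markers.
#' @param members Marker ids of the group.
#' @param tp A `two_point_set` covering the members.
#' @param n_rounds Local-search improvement passes (default 3).
#' @param error_prob Genotyping-error rate for the multipoint emission model.
#' @return A tibble `marker`, `cM` (starting at 0), `flipped` (the phase
#'   convention applied per marker), with attribute `loglik`.
#' @export
order_group <- function(table, members, tp = NULL, n_rounds = 3,
                        error_prob = 1e-4) {
  calls_all <- gt_progeny(table)$calls
  members <- intersect(members, rownames(calls_all))
  m <- length(members)
  if (m == 0) stop("no group members found in table", call. = FALSE)
  if (m == 1) {
    return(structure(tibble::tibble(marker = members, cM = 0, flipped = FALSE),
                     loglik = NA_real_))
  }
  sub <- gt_subset(table, markers = members)
  if (is.null(tp)) tp <- two_point_all(sub)
  flip <- resolve_phase(tp, members)
  calls <- flip_calls(calls_all[members, , drop = FALSE], flip)
  num <- matrix(match(calls, CALL_CODES), m, dimnames = dimnames(calls))
  r_mat <- tp$r[members, members, drop = FALSE]
  lod_mat <- tp$lod[members, members, drop = FALSE]

  ord <- greedy_seriation(r_mat, lod_mat)
  best_ll <- order_objective(ord, num, r_mat, error_prob)
  for (round in seq_len(n_rounds)) {
    improved <- FALSE
    ## 2-opt segment reversals
    for (i in seq_len(m - 1)) for (j in (i + 1):m) {
      cand <- ord
      cand[i:j] <- rev(cand[i:j])
      ll <- order_objective(cand, num, r_mat, error_prob)
      if (ll > best_ll + 1e-9) { ord <- cand; best_ll <- ll; improved <- TRUE }
    }
    ## single-marker insertions
    for (i in seq_len(m)) for (j in seq_len(m)) {
      if (i == j) next
      cand <- append(ord[-i], ord[i], after = j - 1)
      ll <- order_objective(cand, num, r_mat, error_prob)
      if (ll > best_ll + 1e-9) { ord <- cand; best_ll <- ll; improved <- TRUE }
    }
    if (!improved) break
  }

  ## multipoint refinement of interval recombination fractions
  r_adj <- pmin(pmax(r_mat[cbind(ord[-m], ord[-1])], 1e-6), 0.499)
  onum <- num[ord, , drop = FALSE]
  for (k in seq_len(m - 1)) {
    f <- function(rk) {
      rr <- r_adj; rr[k] <- rk
      hmm_order_loglik(onum, rr, error_prob)
    }
    opt <- stats::optimize(f, c(1e-6, 0.499), maximum = TRUE, tol = 1e-5)
    r_adj[k] <- opt$maximum
  }
  best_ll <- hmm_order_loglik(onum, r_adj, error_prob)

  ## canonical orientation
  ids <- members[ord]
  mk <- table$markers[match(ids, table$markers$id), ]
  rev_it <- if (!all(is.na(mk$pos))) {
    w <- which(!is.na(mk$pos))
    mk$pos[w[1]] > mk$pos[w[length(w)]]
  } else ids[1] > ids[m]
  if (rev_it) { ids <- rev(ids); r_adj <- rev(r_adj) }
  structure(
    tibble::tibble(marker = ids, cM = c(0, cumsum(kosambi(r_adj))),
                   flipped = unname(flip[ids])),
    loglik = best_ll
  )
}

#' Prune markers by nearest-neighbour stress
#'
#' Per-marker stress is the mean absolute difference between the marker's
#' map distance to each of its (up to two) nearest neighbours on the map and
#' the corresponding two-point Kosambi distance; genotyping errors inflate a
#' marker's apparent recombination with both neighbours, so high stress
#' flags unreliable markers.  Markers exceeding `max_stress_cM` are removed
#' iteratively, worst first, with positions re-fitted after each removal
#' from the two-point estimates of the new adjacencies.
#'
#' @param ordered A tibble from [order_group()] (columns `marker`, `cM`).
#' @param tp A `two_point_set` covering the markers.
#' @param max_stress_cM Removal threshold in cM (default 2.5); `Inf`
#'   disables pruning.
#' @return The pruned map tibble, with attribute `pruned` — a tibble of
#'   removed markers and their stress.
#' @export
nn_stress_prune <- function(ordered, tp, max_stress_cM = 2.5) {
  pruned <- tibble::tibble(marker = character(), stress_cM = numeric())
  repeat {
    m <- nrow(ordered)
    if (m < 3) break
    stress <- nn_stress(ordered, tp)
    worst <- which.max(stress)
    if (stress[worst] <= max_stress_cM) break
    pruned <- dplyr::bind_rows(pruned, tibble::tibble(
      marker = ordered$marker[worst], stress_cM = stress[worst]))
    ordered <- refit_positions(ordered[-worst, ], tp)
  }
  attr(ordered, "pruned") <- pruned
  ordered
}

nn_stress <- function(ordered, tp) {
  m <- nrow(ordered)
  ids <- ordered$marker
  vapply(seq_len(m), function(i) {
    nb <- c(if (i > 1) i - 1, if (i < m) i + 1)
    devs <- vapply(nb, function(j) {
      map_d <- abs(ordered$cM[i] - ordered$cM[j])
      r <- min(tp$r[ids[i], ids[j]], 0.4999)
      abs(map_d - kosambi(r))
    }, numeric(1))
    mean(devs)
  }, numeric(1))
}

refit_positions <- function(ordered, tp) {
  ids <- ordered$marker
  m <- length(ids)
  if (m < 2) { ordered$cM <- 0; return(ordered) }
  r_adj <- pmin(pmax(tp$r[cbind(ids[-m], ids[-1])], 0), 0.499)
  ordered$cM <- c(0, cumsum(kosambi(r_adj)))
  ordered
}

#' Assemble a genetic map from ordered groups
#'
#' @param group_maps A list of ordered-group tibbles (from [order_group()]
#'   or [nn_stress_prune()]).
#' @param markers Optional marker metadata tibble (`id`, `chrom`, `pos`) for
#'   physical coordinates.
#' @return A tibble of class `genetic_map`: `group`, `marker`, `cM`,
#'   `chrom`, `bp`.
#' @export
genetic_map <- function(group_maps, markers = NULL) {
  out <- purrr::imap_dfr(group_maps, function(gm, g) {
    tibble::tibble(group = as.integer(g), marker = gm$marker, cM = gm$cM)
  })
  if (!is.null(markers)) {
    idx <- match(out$marker, markers$id)
    out$chrom <- markers$chrom[idx]
    out$bp <- markers$pos[idx]
  } else {
    out$chrom <- NA_character_
    out$bp <- NA_integer_
  }
  class(out) <- c("genetic_map", class(out))
  out
}

#' Summary statistics of a genetic map
#'
#' Computes the descriptive statistics conventionally reported for a linkage
#' map: marker and group counts, total length, mean inter-marker distance
#' (reported to 2 decimals), physical-to-genetic ratio in Mb/cM (3 decimals)
#' when a genome size is supplied, the largest adjacent-marker gap, genome
#' coverage (mean over groups of the physical span of mapped markers over
#' the chromosome length) when chromosome lengths are supplied, and
#' per-group Spearman rank correlation between genetic and physical position
#' (collinearity check).
#'
#' @param map A `genetic_map`.
#' @param genome_mb Optional genome size in Mb.
#' @param chrom_lengths Optional named vector of chromosome lengths in bp
#'   (names matching `map$chrom`).
#' @return A list of class `map_stats` (also tidyable via `glance()`).
#' @export
map_statistics <- function(map, genome_mb = NULL, chrom_lengths = NULL) {
  stopifnot(nrow(map) > 0)
  by_grp <- split(map, map$group)
  lens <- vapply(by_grp, function(g) max(g$cM), numeric(1))
  gaps <- unlist(lapply(by_grp, function(g) diff(sort(g$cM))))
  total_cM <- sum(lens)
  n_markers <- nrow(map)
  rho <- vapply(by_grp, function(g) {
    ok <- !is.na(g$bp)
    if (sum(ok) < 3) return(NA_real_)
    abs(stats::cor(g$cM[ok], g$bp[ok], method = "spearman"))
  }, numeric(1))
  coverage <- NULL
  if (!is.null(chrom_lengths)) {
    cov_g <- vapply(by_grp, function(g) {
      ok <- !is.na(g$bp)
      if (!any(ok)) return(NA_real_)
      chr <- g$chrom[ok][1]
      if (!chr %in% names(chrom_lengths)) return(NA_real_)
      diff(range(g$bp[ok])) / chrom_lengths[[chr]]
    }, numeric(1))
    coverage <- mean(cov_g, na.rm = TRUE)
  }
  structure(list(
    n_markers = n_markers,
    n_groups = length(by_grp),
    total_cM = round(total_cM, 1),
    density_cM_per_marker = round(total_cM / n_markers, 2),
    mb_per_cM = if (!is.null(genome_mb)) round(genome_mb / total_cM, 3) else NA_real_,
    max_gap_cM = if (length(gaps)) round(max(gaps), 1) else 0,
    coverage_fraction = coverage %||% NA_real_,
    collinearity_rho = rho
  ), class = "map_stats")
}

#' @export
print.map_stats <- function(x, ...) {
  cat("<map_stats>\n")
  cat(sprintf("  markers: %d in %d groups\n", x$n_markers, x$n_groups))
  cat(sprintf("  total length: %.1f cM (density %.2f cM/marker, max gap %.1f cM)\n",
              x$total_cM, x$density_cM_per_marker, x$max_gap_cM))
  if (!is.na(x$mb_per_cM)) cat(sprintf("  physical ratio: %.3f Mb/cM\n", x$mb_per_cM))
  if (!is.na(x$coverage_fraction)) {
    cat(sprintf("  genome coverage: %.1f%%\n", 100 * x$coverage_fraction))
  }
  invisible(x)
}

#' Build a full genetic map from an intercross genotype table
#'
#' Convenience wrapper chaining [curate_for_mapping()], [two_point_all()],
#' [group_markers()], [order_group()] and [nn_stress_prune()] over all
#' linkage groups.
#'
#' @param table A progeny `genotype_table` of intercross markers.
#' @param lod_min Grouping LOD threshold (default 10).
#' @param distortion_p Distortion filter p-value (default 1e-5).
#' @param max_stress_cM Nearest-neighbour stress threshold (default 2.5).
#' @param n_rounds Ordering optimisation rounds (default 3).
#' @return A `genetic_map` tibble, with attributes `curation` (removed /
#'   collapsed markers), `unplaced` (singleton markers) and `pruned`.
#' @export
build_map <- function(table, lod_min = 10, distortion_p = 1e-5,
                      max_stress_cM = 2.5, n_rounds = 3) {
  cur <- curate_for_mapping(table, distortion_p)
  tp <- two_point_all(cur)
  grp <- group_markers(tp, lod_min)
  groups <- sort(unique(grp$group[!is.na(grp$group)]))
  pruned_all <- list()
  gmaps <- lapply(groups, function(g) {
    members <- grp$marker[!is.na(grp$group) & grp$group == g]
    om <- order_group(cur, members, tp, n_rounds)
    om <- nn_stress_prune(om, tp, max_stress_cM)
    pruned_all[[as.character(g)]] <<- attr(om, "pruned")
    om
  })
  map <- genetic_map(gmaps, cur$markers)
  attr(map, "curation") <- list(distorted = attr(cur, "distorted"),
                                duplicates = attr(cur, "duplicates"))
  attr(map, "unplaced") <- grp$marker[is.na(grp$group)]
  attr(map, "pruned") <- dplyr::bind_rows(pruned_all)
  map
}
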