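test_that("curation removes distorted markers and collapses duplicates", {
  fam <- shared_family()
  clean <- gt_progeny(fam$sim$table)

  # byte-identical duplicate row collapses to one representative
  calls <- clean$calls[1:5, ]
  calls <- rbind(calls, dup = calls[1, ])
  tab <- genotype_table(calls)
  cur <- curate_for_mapping(tab)
  dup <- attr(cur, "duplicates")
  expect_equal(nrow(dup), 1)
  expect_equal(dup$member, "dup")
  expect_equal(dup$representative, rownames(calls)[1])
  expect_equal(nrow(cur$calls), 5)

  # removal iff 1:2:1 p <= 1e-5, p from the closed-form oracle
  n_cls <- c(150, 120, 30)
  p_orc <- exp(-sum((n_cls - sum(n_cls) * c(.25, .5, .25))^2 /
                      (sum(n_cls) * c(.25, .5, .25))) / 2)
  distorted <- rep(c("AA", "AB", "BB"), n_cls)
  tab2 <- genotype_table(rbind(clean$calls[1:3, ], bad = distorted))
  cur2 <- curate_for_mapping(tab2)
  expect_equal("bad" %in% attr(cur2, "distorted"), p_orc <= 1e-5)

  # clean simulated panel: nothing removed
  cur3 <- curate_for_mapping(clean)
  expect_equal(length(attr(cur3, "distorted")), 0)
  expect_equal(nrow(attr(cur3, "duplicates")), 0)
})

test_that("wildcard duplicates (missing as match) collapse", {
  a <- c("AA", "AB", "BB", "AB", "AA", "BB")
  b <- a; b[c(2, 5)] <- NA
  tab <- genotype_table(rbind(full = a, holes = b,
                              other = c("BB", "AB", "AA", "AB", "BB", "AA")))
  cur <- curate_for_mapping(tab)
  expect_equal(sort(rownames(cur$calls)), c("full", "other"))
  expect_equal(attr(cur, "duplicates")$member, "holes")
})

test_that("single-linkage grouping is transitive and splits unlinked cliques", {
  ids <- paste0("m", 1:5)
  lod <- matrix(0, 5, 5, dimnames = list(ids, ids))
  lod["m1", "m2"] <- lod["m2", "m1"] <- 15
  lod["m2", "m3"] <- lod["m3", "m2"] <- 12   # chain: m1-m2-m3, m1-m3 weak
  lod["m4", "m5"] <- lod["m5", "m4"] <- 20
  grp <- group_markers(lod, 10)
  g <- setNames(grp$group, grp$marker)
  expect_equal(length(unique(g[c("m1", "m2", "m3")])), 1)
  expect_equal(length(unique(g[c("m4", "m5")])), 1)
  expect_false(g[["m1"]] == g[["m4"]])
})

test_that("simulated multi-group panel recovers the true group structure", {
  fam <- shared_family()
  tp <- two_point_all(fam$ic)
  grp <- group_markers(tp, 10)
  placed <- grp[!is.na(grp$group), ]
  expect_equal(length(unique(placed$group)), 3)
  truth_chr <- fam$sim$truth$map$chrom[match(placed$marker,
                                             fam$sim$truth$map$marker)]
  expect_true(all(tapply(truth_chr, placed$group,
                         function(x) length(unique(x))) == 1))
})

test_that("3-marker ordering matches the exhaustive multipoint oracle", {
  # oracle: enumerate the 3 distinct orders; for each, maximise over interval
  # recombination fractions the exact likelihood computed by summing over all
  # 27 latent genotype paths
  trans3 <- function(r) {
    p <- 1 - r
    matrix(c(p^2, 2 * p * r, r^2,
             p * r, p^2 + r^2, p * r,
             r^2, 2 * p * r, p^2), 3, 3, byrow = TRUE)
  }
  oracle_ll <- function(obs) {  # obs: 3 x n of 1/2/3
    function(r) {
      T1 <- trans3(r[1]); T2 <- trans3(r[2])
      pri <- c(.25, .5, .25)
      tot <- 0
      for (i in seq_len(ncol(obs))) {
        s <- 0
        for (g1 in 1:3) for (g2 in 1:3) for (g3 in 1:3) {
          s <- s + pri[g1] * T1[g1, g2] * T2[g2, g3] *
            (obs[1, i] == g1) * (obs[2, i] == g2) * (obs[3, i] == g3)
        }
        tot <- tot + log(s)
      }
      tot
    }
  }
  set.seed(11)
  for (rep in 1:5) {
    cfg <- sim_config(n_progeny = 60,
                      map = sim_map(n_groups = 1, n_markers = 3,
                                    length_cM = 30),
                      seed = 500 + rep)
    sim <- simulate_f2(cfg)
    calls <- gt_progeny(sim$table)$calls
    obs <- matrix(match(calls, c("AA", "AB", "BB")), 3)
    ids <- rownames(calls)
    orders <- list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L))
    scores <- vapply(orders, function(o) {
      f <- oracle_ll(obs[o, ])
      stats::optim(c(0.1, 0.1), function(r) -f(pmin(pmax(r, 1e-4), 0.49)),
                   method = "L-BFGS-B", lower = 1e-4, upper = 0.49)$value * -1
    }, numeric(1))
    best <- orders[[which.max(scores)]]
    om <- order_group(gt_subset(sim$table, markers = ids), ids,
                      error_prob = 0)
    got <- match(om$marker, ids)
    expect_true(identical(got, best) || identical(got, rev(best)))
  }
})

test_that("ordering is invariant to input marker order and error-free recovery", {
  cfg <- sim_config(n_progeny = 424,
                    map = sim_map(n_groups = 1, n_markers = 12,
                                  length_cM = 55),
                    seed = 77)
  sim <- simulate_f2(cfg)
  ids <- rownames(sim$table$calls)
  om1 <- order_group(sim$table, ids)
  om2 <- order_group(sim$table, rev(ids))
  expect_identical(om1$marker, om2$marker)
  expect_equal(om1$cM, om2$cM, tolerance = 1e-3)
  # true order recovered (canonical orientation has bp increasing)
  truth <- sim$truth$map$marker
  expect_identical(om1$marker, truth)
})

test_that("marker-order recovery holds across seeded replicates", {
  ok <- 0
  for (rep in 1:12) {
    cfg <- sim_config(n_progeny = 424,
                      map = sim_map(n_groups = 1, n_markers = 15,
                                    length_cM = 70),
                      seed = 9000 + rep)
    sim <- simulate_f2(cfg)
    om <- order_group(sim$table, rownames(sim$table$calls))
    ok <- ok + identical(om$marker, sim$truth$map$marker)
  }
  expect_gte(ok, 11)
})

test_that("group length is recovered within 10% on dense noise-free data", {
  cfg <- sim_config(n_progeny = 424,
                    map = sim_map(n_groups = 1, n_markers = 20,
                                  length_cM = 80),
                    seed = 13)
  sim <- simulate_f2(cfg)
  om <- order_group(sim$table, rownames(sim$table$calls))
  expect_lt(abs(max(om$cM) - 80) / 80, 0.10)
})

test_that("nearest-neighbour stress flags an error-ridden marker", {
  cfg <- sim_config(n_progeny = 300,
                    map = sim_map(n_groups = 1, n_markers = 10,
                                  length_cM = 45),
                    seed = 21)
  sim <- simulate_f2(cfg)
  tab <- gt_progeny(sim$table)
  # noise-free: nothing removed
  tp0 <- two_point_all(tab)
  om0 <- order_group(tab, rownames(tab$calls), tp0)
  pr0 <- nn_stress_prune(om0, tp0)
  expect_equal(nrow(attr(pr0, "pruned")), 0)

  # inject 20% genotyping errors into one interior marker
  set.seed(5)
  calls <- tab$calls
  bad <- rownames(calls)[5]
  hit <- sample(ncol(calls), round(0.2 * ncol(calls)))
  calls[bad, hit] <- sample(c("AA", "AB", "BB"), length(hit), TRUE)
  tab2 <- genotype_table(calls, markers = tab$markers)
  tp <- two_point_all(tab2)
  om <- order_group(tab2, rownames(calls), tp)
  stress <- hetlink:::nn_stress(om, tp)
  expect_equal(om$marker[which.max(stress)], bad)

  # threshold Inf is the identity
  pr_inf <- nn_stress_prune(om, tp, Inf)
  expect_identical(pr_inf$marker, om$marker)
})

test_that("map statistics compute density, Mb/cM, gaps and collinearity", {
  # two synthetic maps with the published dimensions of a dense GBS map and
  # a sparse SSR map
  mk_map <- function(n, total) {
    m <- tibble::tibble(group = 1L, marker = paste0("m", 1:n),
                        cM = seq(0, total, length.out = n),
                        chrom = "chr01", bp = seq_len(n) * 1000L)
    class(m) <- c("genetic_map", class(m))
    m
  }
  dense <- map_statistics(mk_map(1449, 2423.9), genome_mb = 458.8)
  expect_equal(dense$density_cM_per_marker, 1.67)
  expect_equal(dense$mb_per_cM, 0.189)
  sparse <- map_statistics(mk_map(120, 1784), genome_mb = 458.8)
  expect_equal(sparse$density_cM_per_marker, 14.87)
  expect_equal(sparse$mb_per_cM, 0.257)

  expect_equal(unname(dense$collinearity_rho), 1)

  m <- mk_map(10, 90)
  st <- map_statistics(m, chrom_lengths = c(chr01 = 18000))
  expect_equal(st$coverage_fraction, (10000 - 1000) / 18000)
  expect_equal(st$max_gap_cM, 10)
})

test_that("total map length is invariant under group order reversal", {
  fam <- shared_family()
  st1 <- map_statistics(fam$map)
  rev_map <- fam$map[order(-fam$map$group, fam$map$cM), ]
  rev_map$group <- max(fam$map$group) + 1L - rev_map$group
  class(rev_map) <- class(fam$map)
  st2 <- map_statistics(rev_map)
  expect_equal(st1$total_cM, st2$total_cM)
  expect_equal(st1$n_markers, st2$n_markers)
})
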