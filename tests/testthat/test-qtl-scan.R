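test_that("fully dominant binary trait gives a = d = 0.5 at its marker", {
  cfg <- sim_config(n_progeny = 120,
                    map = sim_map(n_groups = 1, n_markers = 5, length_cM = 40),
                    qtl = list(list(trait = "color", group = 1, cM = 20,
                                    binary = TRUE)),
                    seed = 31)
  sim <- simulate_f2(cfg)
  ph <- simulate_traits(sim$table, cfg)
  probs <- genotype_probabilities(sim$truth$map, gt_progeny(sim$table),
                                  step_cM = 5, error_prob = 0)
  sc <- scan_single(probs, ph, "color", "binary")
  at <- which(probs$grid$cM == 20 & !is.na(probs$grid$marker))
  expect_equal(sc$a[at], 0.5, tolerance = 1e-6)
  expect_equal(sc$d[at], 0.5, tolerance = 1e-6)
  expect_equal(which.max(sc$lod), at)
  # binary class means are exactly (0, 1, 1) over (AA, AB, BB)
  g <- gt_progeny(sim$table)$calls[probs$grid$marker[at], ]
  expect_true(all(ph$color[g == "AA"] == 0))
  expect_true(all(ph$color[g != "AA"] == 1))
})

test_that("EM scans agree with direct likelihood maximisation at markers", {
  fam <- shared_family()
  probs <- fam$probs
  mk <- which(!is.na(probs$grid$marker))[c(2, 9, 17)]
  y <- fam$pheno$acid[match(probs$samples, fam$pheno$sample)]

  for (k in mk) {
    P <- matrix(probs$probs[, k, ], ncol = 3)
    # oracle: direct numerical maximisation of the observed-data likelihood
    nll <- function(par) {
      mu <- par[1:3]; s <- exp(par[4])
      -sum(log(P[, 1] * dnorm(y, mu[1], s) + P[, 2] * dnorm(y, mu[2], s) +
                 P[, 3] * dnorm(y, mu[3], s)))
    }
    opt <- optim(c(mean(y) - .5, mean(y), mean(y) + .5, log(sd(y))), nll,
                 method = "BFGS", control = list(reltol = 1e-14))
    ll0 <- sum(dnorm(y, mean(y), sqrt(mean((y - mean(y))^2)), log = TRUE))
    lod_oracle <- (-opt$value - ll0) / log(10)
    sc <- scan_single(probs, fam$pheno, "acid", "normal")
    expect_equal(sc$lod[k], lod_oracle, tolerance = 1e-4)
  }
})

test_that("binary EM agrees with direct penetrance-likelihood maximisation", {
  fam <- shared_family()
  probs <- fam$probs
  y <- fam$pheno$color[match(probs$samples, fam$pheno$sample)]
  k <- which(!is.na(probs$grid$marker))[5]
  P <- matrix(probs$probs[, k, ], ncol = 3)
  nll <- function(q) {
    pi <- plogis(q)
    -sum(log(P[, 1] * dbinom(y, 1, pi[1]) + P[, 2] * dbinom(y, 1, pi[2]) +
               P[, 3] * dbinom(y, 1, pi[3])))
  }
  opt <- optim(rep(0, 3), nll, method = "BFGS", control = list(reltol = 1e-14))
  p0 <- mean(y)
  ll0 <- sum(y) * log(p0) + sum(1 - y) * log(1 - p0)
  lod_oracle <- (-opt$value - ll0) / log(10)
  sc <- scan_single(probs, fam$pheno, "color", "binary")
  expect_equal(sc$lod[k], lod_oracle, tolerance = 1e-4)
})

test_that("LOD is invariant to affine trait rescaling; phase flip negates a", {
  fam <- shared_family()
  sc1 <- scan_single(fam$probs, fam$pheno, "acid", "normal")
  ph2 <- fam$pheno
  ph2$acid <- 3.7 * ph2$acid - 11
  sc2 <- scan_single(fam$probs, ph2, "acid", "normal")
  expect_equal(sc1$lod, sc2$lod, tolerance = 1e-6)

  # flip the A/B convention of every marker in one group
  probs_f <- fam$probs
  idx <- which(probs_f$grid$group == 1)
  probs_f$probs[, idx, ] <- probs_f$probs[, idx, 3:1]
  sc3 <- scan_single(probs_f, fam$pheno, "acid", "normal")
  expect_equal(sc3$lod[idx], sc1$lod[idx], tolerance = 1e-6)
  expect_equal(sc3$a[idx], -sc1$a[idx], tolerance = 1e-6)
  expect_equal(sc3$d[idx], sc1$d[idx], tolerance = 1e-6)
})

test_that("R-squared satisfies its LOD identity and peaks carry intervals", {
  fam <- shared_family()
  sc <- scan_single(fam$probs, fam$pheno, "acid", "normal")
  pk <- qtl_peaks(sc, threshold = 3, drop = 1.8)
  n <- attr(sc, "n")
  expect_true(nrow(pk) >= 1)
  expect_equal(pk$r2, 1 - 10^(-2 * pk$lod / n), tolerance = 1e-9)
  expect_true(all(pk$lo_cM <= pk$peak_cM & pk$peak_cM <= pk$hi_cM))
  expect_true(all(pk$r2 >= 0 & pk$r2 <= 1))
})

test_that("support intervals handle spikes, plateaus and boundaries", {
  spike <- tibble::tibble(group = 1L, cM = 0:10, marker = paste0("m", 0:10),
                          bp = (0:10) * 1000L,
                          lod = c(rep(0, 5), 8, rep(0, 5)), a = 0, d = 0)
  class(spike) <- c("qtl_scan", class(spike))
  si <- support_interval(spike, drop = 1.5)
  expect_equal(si$lo_cM, 5)
  expect_equal(si$hi_cM, 5)
  expect_false(si$truncated)

  flat <- spike
  flat$lod <- rep(4, 11)
  sf <- support_interval(flat, drop = 1.5)
  expect_equal(c(sf$lo_cM, sf$hi_cM), c(0, 10))
  expect_true(sf$truncated)
})

test_that("support interval covers the true QTL in most replicates", {
  hits <- 0
  for (rep in 1:20) {
    cfg <- sim_config(n_progeny = 424,
                      map = sim_map(n_groups = 1, n_markers = 10,
                                    length_cM = 60),
                      qtl = list(list(trait = "y", group = 1, cM = 26.67,
                                      a = 1, d = 0, sigma = 1)),
                      seed = 3000 + rep)
    sim <- simulate_f2(cfg)
    ph <- simulate_traits(sim$table, cfg)
    probs <- genotype_probabilities(sim$truth$map, gt_progeny(sim$table),
                                    step_cM = 2)
    sc <- scan_single(probs, ph, "y", "normal")
    si <- support_interval(sc, drop = 1.8)
    true_cm <- sim$truth$map$cM[5]
    hits <- hits + (si$lo_cM <= true_cm && true_cm <= si$hi_cM)
  }
  expect_gte(hits, 17)  # nominal >= 90% coverage
})

test_that("permutation thresholds are reproducible and quantile-consistent", {
  fam <- shared_family()
  sub <- fam$probs
  t1 <- permutation_threshold(sub, fam$pheno, "acid", "normal",
                              n_perm = 100, seed = 4)
  t2 <- permutation_threshold(sub, fam$pheno, "acid", "normal",
                              n_perm = 100, seed = 4)
  expect_identical(as.numeric(t1), as.numeric(t2))
  t_all <- permutation_threshold(sub, fam$pheno, "acid", "normal",
                                 n_perm = 100, alpha = 1, seed = 4)
  expect_equal(as.numeric(t_all), min(attr(t_all, "null_max")))
  expect_error(permutation_threshold(sub, fam$pheno, "acid", n_perm = 50),
               "100")
})

test_that("composite interval mapping absorbs a background QTL", {
  cfg <- sim_config(n_progeny = 300,
                    map = sim_map(n_groups = 2, n_markers = 8, length_cM = 50),
                    qtl = list(
                      list(trait = "y", group = 1, cM = 21.43, a = 1, d = 0,
                           sigma = 1),
                      list(trait = "y", group = 2, cM = 28.57, a = 0.8, d = 0)
                    ),
                    seed = 55)
  sim <- simulate_f2(cfg)
  ph <- simulate_traits(sim$table, cfg)
  probs <- genotype_probabilities(sim$truth$map, gt_progeny(sim$table),
                                  step_cM = 5)
  cof <- select_cofactors(probs, ph, "y", max_cofactors = 3)
  expect_gte(length(cof), 1)
  sc_im <- scan_single(probs, ph, "y", "normal")
  sc_cim <- scan_single(probs, ph, "y", "normal", cofactors = cof)
  # conditioning on the other group's QTL sharpens the scan near the target
  g1 <- probs$grid$group == 1
  expect_equal(probs$grid$cM[g1][which.max(sc_cim$lod[g1])],
               probs$grid$cM[g1][which.max(sc_im$lod[g1])],
               tolerance = 10)
  expect_true(max(sc_cim$lod[g1]) > 3)
})

test_that("binary scans refuse degenerate traits", {
  fam <- shared_family()
  ph <- fam$pheno
  ph$flat <- 1
  expect_error(scan_single(fam$probs, ph, "flat", "binary"), "single class")
  ph$cont <- rnorm(nrow(ph))
  expect_error(scan_single(fam$probs, ph, "cont", "binary"), "0/1")
})
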