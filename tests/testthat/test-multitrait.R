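test_that("cofactor placement snaps the spacing grid to markers", {
  mk_map <- function(cm) {
    m <- tibble::tibble(group = 1L, marker = paste0("m", seq_along(cm)),
                        cM = cm, chrom = "c", bp = seq_along(cm))
    class(m) <- c("genetic_map", class(m))
    m
  }
  # dense map: every grid point snaps to a distinct marker
  dense <- mk_map(seq(0, 10, by = 0.5))
  cof <- place_cofactors(dense, 1.51)
  expect_equal(nrow(cof), floor(10 / 1.51) + 1)
  expect_true(all(cof$marker %in% dense$marker))

  # spacing larger than the group: one cofactor per group
  two_groups <- dplyr::bind_rows(mk_map(c(0, 5)),
                                 dplyr::mutate(mk_map(c(0, 4)), group = 2L,
                                               marker = c("n1", "n2")))
  class(two_groups) <- c("genetic_map", class(two_groups))
  cof2 <- place_cofactors(two_groups, 100)
  expect_equal(nrow(cof2), 2)

  # duplicates collapse
  sparse <- mk_map(c(0, 9))
  cof3 <- place_cofactors(sparse, 1.51)
  expect_equal(nrow(cof3), 2)
})

test_that("Li-Ji effective test count matches eigenvalue closed forms", {
  # orthogonal scores: M_eff = m
  set.seed(8)
  X <- qr.Q(qr(matrix(rnorm(100 * 6), 100, 6)))
  lj <- li_ji_threshold(X, alpha = 0.05)
  expect_equal(lj$m_eff, 6, tolerance = 1e-9)
  expect_equal(lj$alpha_star, 1 - 0.95^(1 / 6), tolerance = 1e-12)
  expect_equal(lj$threshold, -log10(lj$alpha_star), tolerance = 1e-12)

  # perfectly correlated scores: M_eff = 1
  base <- rnorm(60)
  X2 <- cbind(base, 2 * base + 1, -base, 0.5 * base)
  expect_equal(li_ji_threshold(X2)$m_eff, 1, tolerance = 1e-9)

  # hand-computed M_eff from the eigen-decomposition oracle
  set.seed(9)
  X3 <- matrix(rnorm(80 * 5), 80, 5)
  X3[, 2] <- X3[, 1] + rnorm(80, sd = 0.4)
  lam <- eigen(cor(X3), only.values = TRUE)$values
  meff_hand <- sum((lam >= 1) + (lam - floor(lam)))
  expect_equal(li_ji_threshold(X3)$m_eff, meff_hand, tolerance = 1e-12)

  # bounded by the marker count; monotone in correlation for two markers
  fam <- shared_family()
  lj_map <- li_ji_threshold(fam$probs)
  expect_lte(lj_map$m_eff, sum(!is.na(fam$probs$grid$marker)))
  rho_meff <- vapply(c(0, 0.5, 0.9), function(rho) {
    z <- MASS::mvrnorm(500, c(0, 0), matrix(c(1, rho, rho, 1), 2),
                       empirical = TRUE)
    li_ji_threshold(z)$m_eff
  }, numeric(1))
  expect_true(all(diff(rho_meff) <= 1e-8))
  z1 <- cbind(base, base)
  expect_equal(li_ji_threshold(z1)$m_eff, 1, tolerance = 1e-9)
})

test_that("joint scan effects at a marker equal per-trait least squares", {
  fam <- shared_family()
  ph <- fam$pheno
  js <- joint_scan(fam$probs, ph, c("acid", "color"), cofactors = NULL)
  k <- which(!is.na(fam$probs$grid$marker))[12]
  gp <- hetlink:::genetic_predictors(fam$probs, k)
  idx <- match(fam$probs$samples, ph$sample)
  keep <- complete.cases(ph$acid[idx], ph$color[idx])
  f1 <- lm(ph$acid[idx][keep] ~ gp$add[keep, 1] + gp$dom[keep, 1])
  f2 <- lm(ph$color[idx][keep] ~ gp$add[keep, 1] + gp$dom[keep, 1])
  expect_equal(unname(js$a1[k]), unname(coef(f1)[2]), tolerance = 1e-8)
  expect_equal(unname(js$d1[k]), unname(coef(f1)[3]), tolerance = 1e-8)
  expect_equal(unname(js$a2[k]), unname(coef(f2)[2]), tolerance = 1e-8)
})

test_that("duplicated traits give identical additive effect estimates", {
  fam <- shared_family()
  ph <- fam$pheno
  ph$acid2 <- ph$acid + 5
  js <- joint_scan(fam$probs, ph, c("acid", "acid2"))
  ok <- !is.na(js$a1)
  expect_equal(js$a1[ok], js$a2[ok], tolerance = 1e-6)
  expect_equal(js$d1[ok], js$d2[ok], tolerance = 1e-6)
})

test_that("a shared QTL with opposite-sign effects is recovered", {
  cfg <- sim_config(n_progeny = 424,
                    map = sim_map(n_groups = 2, n_markers = 8, length_cM = 50),
                    qtl = list(
                      list(trait = "MA", group = 1, cM = 21.43, a = 0.60,
                           d = 0, sigma = 1),
                      list(trait = "SS", group = 1, cM = 21.43, a = -0.62,
                           d = 0, sigma = 1)
                    ),
                    seed = 66)
  sim <- simulate_f2(cfg)
  ph <- simulate_traits(sim$table, cfg)
  probs <- genotype_probabilities(sim$truth$map, gt_progeny(sim$table),
                                  step_cM = 5)
  js <- joint_scan(probs, ph, c("MA", "SS"))
  lj <- li_ji_threshold(probs)
  sel <- backselect_qtl(js, probs, ph, c("MA", "SS"), lj$threshold)
  expect_equal(nrow(sel), 1)
  expect_equal(sel$group, 1)
  expect_gt(sel$a1, 0.3)          # sign pattern matches truth
  expect_lt(sel$a2, -0.3)
  expect_equal(sel$a1, 0.60, tolerance = 0.25)
  expect_equal(sel$a2, -0.62, tolerance = 0.25)
})

test_that("joint-scan null profiles stay below the Li-Ji threshold", {
  cfg0 <- sim_config(n_progeny = 200,
                     map = sim_map(n_groups = 2, n_markers = 8,
                                   length_cM = 50),
                     seed = 100)
  sim <- simulate_f2(cfg0)
  probs <- genotype_probabilities(sim$truth$map, gt_progeny(sim$table),
                                  step_cM = 10)
  lj <- li_ji_threshold(probs)
  set.seed(17)
  below <- 0; B <- 40
  for (b in 1:B) {
    ph <- tibble::tibble(sample = sim$truth$samples,
                         t1 = rnorm(200), t2 = rnorm(200))
    js <- joint_scan(probs, ph, c("t1", "t2"))
    below <- below + (max(js$neglog10p, na.rm = TRUE) < lj$threshold)
  }
  # nominal 95% of null genomes below threshold; allow 3 binomial SE
  expect_gte(below / B, 0.95 - 3 * sqrt(0.05 * 0.95 / B))
})

test_that("backward selection enforces separation and drops weak loci", {
  cfg <- sim_config(n_progeny = 424,
                    map = sim_map(n_groups = 1, n_markers = 15,
                                  length_cM = 70),
                    qtl = list(
                      list(trait = "y1", group = 1, cM = 5, a = 0.8, d = 0,
                           sigma = 1),
                      list(trait = "y1", group = 1, cM = 65, a = 0.8, d = 0),
                      list(trait = "y2", group = 1, cM = 5, a = 0.6, d = 0,
                           sigma = 1)
                    ),
                    seed = 44)
  sim <- simulate_f2(cfg)
  ph <- simulate_traits(sim$table, cfg)
  probs <- genotype_probabilities(sim$truth$map, gt_progeny(sim$table),
                                  step_cM = 5)
  js <- joint_scan(probs, ph, c("y1", "y2"))
  lj <- li_ji_threshold(probs)
  sel <- backselect_qtl(js, probs, ph, c("y1", "y2"), lj$threshold,
                        min_sep_cM = 30)
  # two QTL 60 cM apart are both retained
  expect_equal(nrow(sel), 2)
  expect_gte(abs(diff(sel$cM)), 30)
  expect_true(all(sel$r2_1 >= 0 & sel$r2_1 <= 1))

  # peaks closer than the separation collapse to the stronger one
  sel_wide <- backselect_qtl(js, probs, ph, c("y1", "y2"), lj$threshold,
                             min_sep_cM = 100)
  expect_equal(nrow(sel_wide), 1)

  # empty profile gives an empty QTL list, not an error
  none <- backselect_qtl(js, probs, ph, c("y1", "y2"), threshold = 1e6)
  expect_equal(nrow(none), 0)
})
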