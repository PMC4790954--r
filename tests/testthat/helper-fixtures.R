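# Fixtures built in code: tiny VCF/hapmap files and cached simulated
# families shared across test files.

write_tiny_vcf <- function(path) {
  lines <- c(
    "##fileformat=VCFv4.1",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tF1\tP1\tP2",
    "chr1\t100\tm1\tA\tT\t.\tPASS\t.\tGT:DP\t0/1:12\t0/0:8\t1/1:9",
    "chr1\t200\tm2\tG\tC\t.\tPASS\t.\tGT:DP\t0|1:7\t1/0:6\t./.:0",
    "chr1\t300\tm3\tA\tC,G\t.\tPASS\t.\tGT:DP\t0/1:5\t0/2:5\t1/2:5",
    "chr1\t400\tm4\tT\tG\t.\tPASS\t.\tGT:DP\t0/1:20\t0/1:4\t1/1:15"
  )
  writeLines(lines, path)
  path
}

write_tiny_hapmap <- function(path) {
  # same biallelic content as the tiny VCF (m1, m2, m4), IUPAC diploid codes
  hdr <- paste(c("rs#", "alleles", "chrom", "pos", "strand", "assembly#",
                 "center", "protLSID", "assayLSID", "panelLSID", "QCcode",
                 "F1", "P1", "P2"), collapse = "\t")
  rows <- c(
    paste(c("m1", "A/T", "chr1", "100", "+", rep("NA", 6), "W", "A", "T"),
          collapse = "\t"),
    paste(c("m2", "G/C", "chr1", "200", "+", rep("NA", 6), "S", "S", "N"),
          collapse = "\t"),
    paste(c("m4", "T/G", "chr1", "400", "+", rep("NA", 6), "K", "K", "G"),
          collapse = "\t")
  )
  writeLines(c(hdr, rows), path)
  path
}

# Direct 9-class joint likelihood for a coupling-phase F2 marker pair,
# written independently of the package EM: the brute-force oracle.
oracle_pair_loglik <- function(counts, r) {
  p <- 1 - r
  probs <- c(p^2 / 4, p * r / 2, r^2 / 4,
             p * r / 2, (p^2 + r^2) / 2, p * r / 2,
             r^2 / 4, p * r / 2, p^2 / 4)
  sum(ifelse(counts > 0, counts * log(probs), 0))
}

oracle_pair_counts <- function(a, b) {
  codes <- c("AA", "AB", "BB")
  out <- numeric(9); k <- 1
  for (ga in codes) for (gb in codes) {
    out[k] <- sum(a == ga & b == gb, na.rm = TRUE); k <- k + 1
  }
  out
}

# Grid + golden-section maximisation of the oracle likelihood over both
# phases (repulsion = coupling at 1 - r).
oracle_two_point <- function(a, b) {
  counts <- oracle_pair_counts(a, b)
  grid <- seq(0, 1, by = 0.001)
  ll <- vapply(grid, function(r) oracle_pair_loglik(counts, r), numeric(1))
  i <- which.max(ll)
  lo <- grid[max(i - 2, 1)]; hi <- grid[min(i + 2, length(grid))]
  opt <- stats::optimize(function(r) oracle_pair_loglik(counts, r),
                         c(lo, hi), maximum = TRUE, tol = 1e-9)
  # the maximum may sit on the r = 0 or r = 1 boundary
  if (ll[i] > opt$objective) opt <- list(maximum = grid[i], objective = ll[i])
  r_star <- opt$maximum
  lod <- (opt$objective - oracle_pair_loglik(counts, 0.5)) / log(10)
  list(r_hat = if (r_star > 0.5) 1 - r_star else r_star,
       phase = if (r_star > 0.5) "repulsion" else "coupling",
       lod = max(lod, 0))
}

# A cached small noisy family used by several test files.
shared_family <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(
        n_progeny = 300,
        map = sim_map(n_groups = 3, n_markers = 10, length_cM = 60),
        qtl = list(
          list(trait = "color", group = 1, cM = 30, binary = TRUE),
          list(trait = "acid", group = 2, cM = 30, a = 1, d = 0.3, sigma = 1)
        ),
        seed = 42
      )
      sim <- simulate_f2(cfg)
      obs <- apply_gbs_noise(sim$table, cfg)
      ph <- simulate_traits(sim$table, cfg)
      ic <- call_intercross_markers(filter_sites(obs))
      map <- build_map(ic)
      probs <- genotype_probabilities(map, ic, step_cM = 2)
      cache <<- list(cfg = cfg, sim = sim, obs = obs, pheno = ph,
                     ic = ic, map = map, probs = probs)
    }
    cache
  }
})
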