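test_that("Weir-Cockerham components match hand-derived cases", {
  # complete fixation in opposite directions -> theta = 1
  p <- toy_panel(matrix(c(rep(0L, 10), rep(2L, 10)), ncol = 1),
                 subpop = rep(c("P1", "P2"), each = 10))
  comp <- wc_fst_components(p)
  expect_equal(comp$theta, 1)

  # pop1 (AA=4, Aa=2, aa=4): p=0.5, h=0.2; pop2 (AA=9, aa=1): p=0.9, h=0
  p <- toy_panel(matrix(c(rep(0L, 4), 1L, 1L, rep(2L, 4),
                          rep(2L, 9), 0L), ncol = 1),
                 subpop = rep(c("P1", "P2"), each = 10))
  comp <- wc_fst_components(p)
  expect_equal(comp$a, 0.063889, tolerance = 1e-5)
  expect_equal(comp$b, 0.136111, tolerance = 1e-5)
  expect_equal(comp$c_w, 0.05)
  expect_equal(comp$theta, 0.255556, tolerance = 1e-5)

  # identical populations, p = 0.5 at HWE with h = 0.5 (n = 10 each):
  # theta is slightly negative, -1/18; checked on the scalar oracle, and
  # the implementation on the nearest realizable genotype configuration
  expect_equal(wc_oracle(c(10, 10), c(0.5, 0.5), c(0.5, 0.5))$theta,
               -0.0556, tolerance = 1e-3)
  g <- c(0L, 0L, 1L, 1L, 1L, 1L, 1L, 2L, 2L, 0L)  # p = 0.45, h = 0.5
  p <- toy_panel(matrix(c(g, g), ncol = 1), subpop = rep(c("P1", "P2"),
                                                         each = 10))
  comp <- wc_fst_components(p)
  expect_equal(comp$theta,
               wc_oracle(c(10, 10), c(0.45, 0.45), c(0.5, 0.5))$theta,
               tolerance = 1e-12)
  expect_lt(comp$theta, 0)

  # pooled-monomorphic SNP undefined
  p <- toy_panel(matrix(0L, 20, 1), subpop = rep(c("P1", "P2"), each = 10))
  expect_false(wc_fst_components(p)$defined)
})

test_that("vectorized theta agrees with the scalar textbook oracle", {
  set.seed(25)
  checked <- 0L
  while (checked < 1000L) {
    n1 <- sample(2:30, 1); n2 <- sample(2:30, 1)
    g1 <- sample(0:2, n1, replace = TRUE, prob = runif(3))
    g2 <- sample(0:2, n2, replace = TRUE, prob = runif(3))
    pbar <- (sum(g1) + sum(g2)) / (2 * (n1 + n2))
    if (pbar == 0 || pbar == 1) next
    p <- toy_panel(matrix(c(g1, g2), ncol = 1),
                   subpop = rep(c("P1", "P2"), c(n1, n2)))
    comp <- wc_fst_components(p)
    orc <- wc_oracle(c(n1, n2), c(mean(g1) / 2, mean(g2) / 2),
                     c(mean(g1 == 1), mean(g2 == 1)))
    expect_equal(comp$theta, orc$theta, tolerance = 1e-10)
    expect_equal(comp$a, orc$a, tolerance = 1e-10)
    checked <- checked + 1L
  }
})

test_that("theta is invariant to which allele is labelled alternate", {
  p <- drop_monomorphic(tiny_sim(seed = 26))
  comp <- wc_fst_components(p)
  q <- p
  q$dosage[, 5] <- 2L - q$dosage[, 5]
  q$haplotypes[, 5] <- 1L - q$haplotypes[, 5]
  comp2 <- wc_fst_components(q)
  expect_equal(comp2$theta[5], comp$theta[5], tolerance = 1e-12)
})

test_that("global F_ST summarizes defined SNPs with the sd convention", {
  p <- toy_panel(matrix(c(rep(0L, 10), rep(2L, 10)), ncol = 1),
                 subpop = rep(c("P1", "P2"), each = 10))
  g <- global_fst(p)
  expect_equal(g$fst_mean, 1)
  expect_equal(g$fst_sd, 0)  # single defined SNP: sd reported as 0
})

test_that("window theta is the ratio of averages over defined SNPs", {
  p <- drop_monomorphic(tiny_sim(seed = 27))
  comp <- wc_fst_components(p)
  w <- fst_window_track(p, window_snps = 15L)
  k <- 10L
  snps <- w$first_snp_index[k] + 0:14
  def <- comp$defined[snps]
  expect_equal(w$theta[k],
               sum(comp$a[snps][def]) /
                 sum((comp$a + comp$b + comp$c_w)[snps][def]),
               tolerance = 1e-12)
  expect_equal(w$het[k],
               mean((2 * comp$pbar * (1 - comp$pbar))[snps][def]),
               tolerance = 1e-12)
  # windows per chromosome = SNPs - 14 when every window has a defined SNP
  expect_equal(nrow(w), sum(table(p$map$chrom) - 14L))
})

test_that("outlier calling flags constructed peaks and respects chromosomes", {
  set.seed(28)
  n <- 2000L
  base <- tibble::tibble(
    chrom = rep(c("1", "2"), each = n / 2),
    start_bp = rep(seq_len(n / 2) * 1e5, 2),
    end_bp = rep(seq_len(n / 2) * 1e5 + 14e5, 2),
    first_snp_index = c(seq_len(n / 2), seq_len(n / 2)),
    n_snps = 15L,
    theta = rnorm(n, 0.05, 0.01),
    het = runif(n, 0.2, 0.5))
  # all windows equal theta: nothing flagged
  flat <- dplyr::mutate(base, theta = 0.05)
  res <- suppressMessages(fst_outlier_regions(flat))
  expect_equal(nrow(res$regions), 0L)

  # three consecutive windows far above their bin
  peak <- base
  peak$theta[300:302] <- 0.5
  res <- suppressMessages(fst_outlier_regions(peak))
  expect_equal(nrow(res$regions), 1L)
  expect_equal(res$regions$n_units, 3L)
  expect_equal(res$regions$start_bp, peak$start_bp[300])
  expect_equal(res$regions$end_bp, peak$end_bp[302])

  # two flagged windows on different chromosomes never form a region
  split2 <- base
  split2$theta[c(n / 2, n / 2 + 1)] <- 0.5
  res <- suppressMessages(fst_outlier_regions(split2))
  expect_equal(nrow(res$regions), 0L)
})

test_that("per-bin thresholds come from the bin's own percentile", {
  set.seed(29)
  n <- 1000L
  w <- tibble::tibble(
    chrom = "1", start_bp = seq_len(n) * 1e5,
    end_bp = seq_len(n) * 1e5 + 14e5, first_snp_index = seq_len(n),
    n_snps = 15L, theta = rnorm(n, 0.05, 0.01), het = runif(n))
  res <- suppressMessages(
    fst_outlier_regions(w, n_bins = 4L, percentile = 90,
                        min_bin_size = 10L, smooth = FALSE))
  ww <- res$windows
  for (b in unique(ww$het_bin)) {
    sel <- ww$het_bin == b
    expect_equal(unique(ww$threshold[sel]),
                 unname(quantile(ww$theta[sel], 0.9, type = 7)))
  }
})
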