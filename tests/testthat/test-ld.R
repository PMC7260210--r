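test_that("pair_r matches hand-computed haplotype counts", {
  # counts AB=4, Ab=1, aB=1, ab=4 over 10 haplotypes:
  # D = 0.4 - 0.5*0.5 = 0.15, r = 0.15/0.25 = 0.6, r2 = 0.36
  hap <- cbind(c(rep(1L, 5), rep(0L, 5)),
               c(rep(1L, 4), 0L, 1L, rep(0L, 4)))
  r <- pair_r(hap_panel(hap), 1, 2)
  expect_equal(r$r_signed, 0.6)
  expect_equal(r$r2, 0.36)

  # perfectly coupled columns
  hap2 <- cbind(c(1L, 1L, 0L, 0L), c(1L, 1L, 0L, 0L))
  r <- pair_r(hap_panel(hap2), 1, 2)
  expect_equal(r$r_signed, 1)

  # balanced independent columns
  hap3 <- cbind(c(1L, 1L, 0L, 0L), c(1L, 0L, 1L, 0L))
  expect_equal(pair_r(hap_panel(hap3), 1, 2)$r_signed, 0)

  # monomorphic column -> undefined, not zero
  hap4 <- cbind(c(1L, 1L, 1L, 1L), c(1L, 0L, 1L, 0L))
  expect_true(is.na(pair_r(hap_panel(hap4), 1, 2)$r_signed))

  # cross-chromosome pairs are refused
  p2 <- hap_panel(hap2, chrom = c("1", "2"), pos_bp = c(1e5, 1e5))
  expect_error(pair_r(p2, 1, 2), "different chromosomes")
})

test_that("signed r from counts equals the Pearson correlation oracle", {
  set.seed(13)
  for (rep in 1:20) {
    hap <- matrix(rbinom(40, 1, runif(1, 0.2, 0.8)), 20, 2)
    p <- hap_panel(hap)
    r <- pair_r(p, 1, 2)$r_signed
    # oracle: D over sqrt of allele-frequency products, from raw counts
    p1 <- mean(hap[, 1]); p2 <- mean(hap[, 2])
    if (p1 %in% c(0, 1) || p2 %in% c(0, 1)) {
      expect_true(is.na(r))
    } else {
      d <- mean(hap[, 1] == 1 & hap[, 2] == 1) - p1 * p2
      expect_equal(r, d / sqrt(p1 * (1 - p1) * p2 * (1 - p2)),
                   tolerance = 1e-12)
    }
  }
})

test_that("r2 is invariant to allele swaps; signed r flips sign", {
  p <- drop_monomorphic(tiny_sim(seed = 14))
  i <- 3L; j <- 5L
  base <- pair_r(p, i, j, pop = "popA")
  q <- p
  q$haplotypes[, i] <- 1L - q$haplotypes[, i]
  q$dosage[, i] <- 2L - q$dosage[, i]
  swapped <- pair_r(q, i, j, pop = "popA")
  expect_equal(swapped$r_signed, -base$r_signed)
  expect_equal(swapped$r2, base$r2)
})

test_that("ld_decay bins pairs half-open and reports empty bins", {
  # two SNPs 55 kb apart with r2 = 0.36 -> only bin [50, 60) is filled
  hap <- cbind(c(rep(1L, 5), rep(0L, 5)),
               c(rep(1L, 4), 0L, 1L, rep(0L, 4)))
  p <- hap_panel(hap, pos_bp = c(100e3, 155e3))
  d <- ld_decay(p, by_subpop = FALSE)
  filled <- d[!is.na(d$mean_r2), ]
  expect_equal(nrow(filled), 1L)
  expect_equal(filled$bin_lo, 50e3)
  expect_equal(filled$mean_r2, 0.36)
  expect_equal(sum(d$n_pairs), 1L)
  # a panel with no pairs under the largest bin edge: all bins empty
  p2 <- hap_panel(hap, pos_bp = c(1e6, 3e6))
  d2 <- ld_decay(p2, by_subpop = FALSE)
  expect_true(all(is.na(d2$mean_r2)))
})

test_that("adjacent summaries count n-1 pairs and shrink under MAF filters", {
  p <- drop_monomorphic(tiny_sim(seed = 15))
  out <- adjacent_r2_summary(p, maf_thresholds = c(0, 0.05, 0.2))
  adj <- out[out$class == "adjacent", ]
  one <- adj[adj$subpop == "popA", ]
  # adjacency = consecutive retained SNPs per chromosome, counting pairs
  # with r defined within the subpopulation
  fA <- colMeans(p$dosage[p$subpop == "popA", ]) / 2
  poly <- fA > 0 & fA < 1
  ch <- p$map$chrom
  n_def <- sum(poly[-length(poly)] & poly[-1] & ch[-length(ch)] == ch[-1])
  expect_equal(one$n_pairs[1], n_def)
  # raising the MAF threshold never increases the pair count
  expect_true(all(diff(one$n_pairs) <= 0))

  # identical columns 40 kb apart put the first distance class at r2 = 1
  hap <- matrix(rep(c(1L, 0L), each = 6), 12, 2)
  p2 <- hap_panel(hap, pos_bp = c(10e3, 50e3))
  out2 <- adjacent_r2_summary(p2, maf_thresholds = 0)
  expect_equal(out2$mean_r2[out2$class == "(0,100]kb"], c(1, 1))
})

test_that("phase persistence is 1 for identical populations and flips with sign", {
  p <- tiny_sim(seed = 16)
  # build a two-population panel whose popB haplotypes copy popA's
  na <- sum(p$subpop == "popA")
  ha <- p$haplotypes[1:(2 * na), ]
  twin <- hap_panel(rbind(ha, ha),
                    pos_bp = p$map$pos_bp, chrom = p$map$chrom,
                    subpop = rep(c("A", "B"), each = na))
  ph <- phase_persistence(twin, max_bin_bp = 2e6)
  expect_true(all(abs(ph$phase_corr[!is.na(ph$phase_corr)] - 1) < 1e-12))

  # bin-level Pearson on a hand example
  rm_ <- c(0.9, 0.1, 0.5); rn_ <- c(0.7, 0.3, 0.2)
  expect_equal(round(cor(rm_, rn_), 3), 0.756)
})

test_that("required_marker_density floors genome length over spacing", {
  expect_equal(required_marker_density(2875, 100), 28750L)
  expect_equal(required_marker_density(1000, 100), 10000L)
  expect_equal(required_marker_density(2875, 50), 57500L)
})
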