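test_that("raw varLD matches the closed-form 2x2 case and basic identities", {
  # identical matrices
  m <- matrix(c(1, 0.5, 0.5, 1), 2)
  expect_equal(raw_varld(m, m), 0)
  # 2x2 closed form: eigenvalues 1 +- rho vs identity -> |0.36| + |-0.36|
  a <- matrix(c(1, 0.36, 0.36, 1), 2)
  expect_equal(raw_varld(a, diag(2)), 0.72)
  # symmetry of the score
  expect_equal(raw_varld(a, diag(2)), raw_varld(diag(2), a))
  # asymmetric input refused
  bad <- matrix(c(1, 0.2, 0.3, 1), 2)
  expect_error(raw_varld(bad, diag(2)), "symmetric")
  expect_error(raw_varld(diag(2), diag(3)), "dimension")
})

test_that("the score is invariant under a common SNP permutation", {
  set.seed(19)
  for (rep in 1:5) {
    x <- matrix(rnorm(225), 15)
    a <- cov2cor(crossprod(x))
    y <- matrix(rnorm(225), 15)
    b <- cov2cor(crossprod(y))
    perm <- sample(15)
    expect_equal(raw_varld(a[perm, perm], b[perm, perm]), raw_varld(a, b),
                 tolerance = 1e-9)
  }
})

test_that("window matrices are symmetric r2 with unit diagonal", {
  p <- drop_monomorphic(tiny_sim(seed = 20))
  snps <- which(p$map$chrom == "1")[1:15]
  m <- window_ld_matrix(p, snps, "popA")
  expect_true(isSymmetric(m))
  expect_equal(diag(m), rep(1, 15), ignore_attr = TRUE)
  expect_true(all(m >= 0 & m <= 1))
  # off-diagonal equals squared pair_r
  expect_equal(m[1, 2], pair_r(p, snps[1], snps[2], pop = "popA")$r2)
  # monomorphic-within-population SNP: zero off-diagonal, unit diagonal
  q <- p
  idxA <- which(q$subpop == "popA")
  q$haplotypes[c(2 * idxA - 1, 2 * idxA), snps[3]] <- 0L
  q$dosage[idxA, snps[3]] <- 0L
  m2 <- window_ld_matrix(q, snps, "popA")
  expect_true(all(m2[3, -3] == 0))
  expect_equal(m2[3, 3], 1)
  # cross-chromosome windows refused
  expect_error(window_ld_matrix(p, c(1, n_snps(p)), "popA"), "one chromosome")
})

test_that("scan scores conserve the eigenvalue trace and match brute force", {
  p <- drop_monomorphic(tiny_sim(seed = 22))
  vl <- varld_scan(p)
  expect_equal(nrow(vl$track),
               sum(table(p$map$chrom) - 15 + 1))
  # trace conservation: eigenvalues of each window matrix sum to 15
  set.seed(1)
  labs <- unique(p$subpop)
  for (k in sample(nrow(vl$track), 5)) {
    w <- vl$track[k, ]
    snps <- w$first_snp_index + 0:14
    ma <- window_ld_matrix(p, snps, labs[1])
    mb <- window_ld_matrix(p, snps, labs[2])
    expect_equal(sum(eigen(ma, only.values = TRUE)$values), 15,
                 tolerance = 1e-9)
    expect_equal(sum(eigen(mb, only.values = TRUE)$values), 15,
                 tolerance = 1e-9)
    # brute-force recomputation of the reported raw score
    expect_equal(raw_varld(ma, mb), w$raw_score, tolerance = 1e-9)
  }
})

test_that("identical populations give zero scores and no regions", {
  p <- tiny_sim(seed = 23)
  na <- sum(p$subpop == "popA")
  ha <- p$haplotypes[1:(2 * na), ]
  twin <- hap_panel(rbind(ha, ha),
                    pos_bp = p$map$pos_bp, chrom = p$map$chrom,
                    subpop = rep(c("A", "B"), each = na))
  vl <- varld_scan(twin)
  expect_true(all(vl$track$raw_score == 0))
  expect_equal(nrow(vl$regions), 0L)
})

test_that("a homogenized LD region in one population is called", {
  p <- drop_monomorphic(tiny_sim(seed = 24))
  idxB <- which(p$subpop == "popB")
  reg <- which(p$map$chrom == "2" & p$map$pos_bp >= 5e6 &
                 p$map$pos_bp <= 9e6)
  hr <- sort(c(2 * idxB - 1, 2 * idxB))
  src <- p$haplotypes[hr[1], reg]
  p$haplotypes[hr, reg] <- matrix(rep(src, each = length(hr)), length(hr))
  p$dosage[idxB, reg] <- matrix(rep(2L * src, each = length(idxB)),
                                length(idxB))
  # at this track length the 99.9th percentile admits only the single top
  # window; the 99th exercises the region-calling mechanics
  vl <- varld_scan(p, percentile = 99)
  expect_gte(nrow(vl$regions), 1L)
  expect_true(any(vl$regions$chrom == "2" &
                    vl$regions$start_bp <= 9e6 &
                    vl$regions$end_bp >= 5e6))
})

test_that("short chromosomes are skipped with a warning", {
  set.seed(30)
  hap <- matrix(rbinom(10 * 23, 1, 0.5), 10, 23)
  p <- hap_panel(hap, chrom = rep(c("1", "2"), c(20, 3)),
                 pos_bp = c(seq_len(20) * 1e5, seq_len(3) * 1e5),
                 subpop = rep(c("A", "B"), length.out = 5))
  # chromosome 2 (3 SNPs) is skipped; chromosome 1 still scans
  expect_warning(vl <- varld_scan(p, window_snps = 15), "skipped")
  expect_true(all(vl$track$chrom == "1"))
  # every chromosome too short: nothing to scan
  p2 <- subset_panel(p, snps = p$map$chrom == "2")
  expect_error(suppressWarnings(varld_scan(p2, window_snps = 15)),
               "no chromosome")
})
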