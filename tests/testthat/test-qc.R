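test_that("call-rate filter removes samples before SNPs at the 0.90 cutoff", {
  # complete panel: nothing removed
  p <- toy_panel(matrix(1L, 4, 10))
  q <- filter_call_rate(p)
  expect_equal(n_samples(q), 4L)
  expect_equal(n_snps(q), 10L)
  expect_equal(sum(qc_report(q)$n_removed), 0L)

  # sample missing 2 of 10 genotypes (call rate 0.8 < 0.9) is removed
  d <- matrix(1L, 4, 10)
  d[2, 1:2] <- NA
  q <- filter_call_rate(toy_panel(d))
  expect_equal(n_samples(q), 3L)

  # SNP missing in 3 of 20 remaining samples (0.85 < 0.9) is removed,
  # judged after sample filtering
  d <- matrix(1L, 20, 10)
  d[1:3, 5] <- NA
  q <- filter_call_rate(toy_panel(d))
  expect_equal(n_samples(q), 20L)  # sample call rate 0.9 kept (>=)
  expect_equal(n_snps(q), 9L)
  rep <- qc_report(q)
  expect_equal(rep$n_removed[rep$unit == "snp"], 1L)

  # removing every sample aborts with a report
  d <- matrix(NA_integer_, 3, 10)
  expect_error(filter_call_rate(toy_panel(d)), "every sample")
})

test_that("1-df chi-square HWE test matches the direct formula", {
  # exact HWE: (25, 50, 25) -> chi-square 0, p = 1
  res <- hwe_chisq(25, 50, 25)
  expect_equal(res$chisq, 0)
  expect_equal(res$p, 1)

  # all 100 heterozygous: chi-square = 25 + 50 + 25 = 100
  res <- hwe_chisq(0, 100, 0)
  expect_equal(res$chisq, 100)
  expect_equal(res$p, pchisq(100, 1, lower.tail = FALSE))
  expect_lt(res$p, 1e-5)

  # (60, 30, 10): expected (56.25, 37.5, 6.25) at p-hat 0.75
  res <- hwe_chisq(60, 30, 10)
  expect_equal(res$chisq, 0.25 + 1.5 + 2.25)
  expect_equal(res$p, pchisq(4, 1, lower.tail = FALSE), tolerance = 1e-12)
  expect_gt(res$p, 1e-5)

  # monomorphic counts are not testable
  expect_true(is.na(hwe_chisq(50, 0, 0)$p))
})

test_that("hwe_filter drops a SNP failing in either subpopulation", {
  # SNP1 in HWE everywhere; SNP2 all-heterozygous in P2 only
  d <- cbind(c(rep(0L, 5), rep(1L, 10), rep(2L, 5),
               rep(0L, 5), rep(1L, 10), rep(2L, 5)),
             c(rep(c(0L, 1L, 2L, 1L), 5),
               rep(1L, 20)))
  p <- toy_panel(d, subpop = rep(c("P1", "P2"), each = 20))
  q <- hwe_filter(p, p_max = 1e-4)
  expect_equal(n_snps(q), 1L)
  expect_equal(q$map$snp_id, "s1")
  # pooled scope dilutes the deviation below this threshold
  q2 <- hwe_filter(p, p_max = 1e-8, scope = "pooled")
  expect_equal(n_snps(q2), 2L)
})

test_that("QC filters are idempotent and their counts reconcile", {
  p <- tiny_sim(seed = 3)
  d <- p$dosage
  set.seed(1)
  d[sample(length(d), 300)] <- NA
  p <- toy_panel(d, pos_bp = p$map$pos_bp, chrom = p$map$chrom,
                 subpop = p$subpop)
  q1 <- hwe_filter(filter_call_rate(p))
  q2 <- hwe_filter(filter_call_rate(q1))
  expect_identical(unname(q1$dosage), unname(q2$dosage))
  expect_equal(sum(qc_report(q2)$n_removed[4:6]), 0)
  rep <- qc_report(q1)
  expect_true(all(rep$n_in - rep$n_removed == rep$n_out))
  # snp filters chain: call-rate snp out feeds hwe in
  expect_equal(rep$n_out[rep$step == "call_rate" & rep$unit == "snp"],
               rep$n_in[rep$step == "hwe"])
})

test_that("keep_shared_polymorphic intersects maps and drops monomorphics", {
  mk <- function(dosage, pos, ids, subpop, ref = "A", alt = "B") {
    map <- data.frame(chrom = "1", pos_bp = pos, snp_id = ids,
                      allele_ref = ref, allele_alt = alt)
    genotype_panel(map, dosage, sprintf("%s_%d", subpop, seq_len(nrow(dosage))),
                   rep(subpop, nrow(dosage)))
  }
  a <- mk(matrix(c(0L, 1L, 1L, 2L, 0L, 0L), 2, 3), c(100, 200, 300),
          c("x1", "x2", "x3"), "P1")
  b <- mk(matrix(c(1L, 1L, 0L, 1L), 2, 2), c(100, 200), c("y1", "y2"), "P2")
  m <- keep_shared_polymorphic(a, b)
  # x3 present only in A -> dropped; all shared SNPs polymorphic pooled
  expect_equal(m$map$pos_bp, c(100, 200))
  expect_equal(n_samples(m), 4L)
  expect_equal(sort(unique(m$subpop)), c("P1", "P2"))

  # jointly monomorphic SNP removed
  a2 <- mk(matrix(c(0L, 0L, 1L, 2L), 2, 2), c(100, 200), c("x1", "x2"), "P1")
  b2 <- mk(matrix(c(0L, 0L, 0L, 1L), 2, 2), c(100, 200), c("y1", "y2"), "P2")
  m2 <- keep_shared_polymorphic(a2, b2)
  expect_equal(m2$map$pos_bp, 200)

  # swapped ref/alt recoded to panel A's orientation
  b3 <- mk(matrix(c(2L, 2L, 1L, 1L), 2, 2), c(100, 200), c("y1", "y2"),
           "P2", ref = "B", alt = "A")
  m3 <- keep_shared_polymorphic(a2, b3)
  expect_equal(unname(m3$dosage[3:4, ]), c(1L, 1L))

  # disjoint maps abort
  c2 <- mk(matrix(c(0L, 1L), 2, 1), 900, "z", "P2")
  expect_error(keep_shared_polymorphic(a, c2), "no shared")
})

test_that("summarize_panel computes folded MAF and observed heterozygosity", {
  # every genotype heterozygous: HET 1 +- 0
  p <- toy_panel(matrix(1L, 3, 4))
  s <- summarize_panel(p)
  expect_equal(s$het_mean[s$subpop == "General"], 1)
  expect_equal(s$het_sd[s$subpop == "General"], 0)

  # alt frequency 0.7 folds to MAF 0.3 (and 0.6 to 0.4)
  p <- toy_panel(matrix(c(2L, 2L, 1L, 1L, 1L, 1L, 1L, 0L, 2L, 2L), 5, 2))
  s <- summarize_panel(p)
  expect_equal(s$maf_mean[s$subpop == "General"], mean(c(0.3, 0.4)))

  # hand-counted 2 x 2 panel
  p <- toy_panel(matrix(c(1L, 1L, 0L, 2L), 2, 2), subpop = c("P1", "P2"))
  s <- summarize_panel(p)
  expect_equal(s$het_mean[s$subpop == "General"], 0.5)
  expect_equal(s$maf_mean[s$subpop == "General"], 0.5)
})
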