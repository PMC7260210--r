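# a single-sample panel from a dosage vector at fixed spacing
roh_fixture <- function(d, spacing = 50e3, pos = NULL) {
  toy_panel(matrix(as.integer(d), 1), subpop = "P1",
            pos_bp = if (is.null(pos)) seq_along(d) * spacing else pos)
}

test_that("both detectors call one segment over a clean homozygous run", {
  p <- roh_fixture(rep(0L, 60))  # 60 SNPs, 50 kb spacing, span 2.95 Mb
  for (f in list(detect_roh_sliding, detect_roh_consecutive)) {
    segs <- f(p)
    expect_equal(nrow(segs), 1L)
    expect_equal(segs$n_snps, 60L)
    expect_equal(segs$start_bp, 50e3)
    expect_equal(segs$end_bp, 3000e3)
    expect_equal(segs$length_bp, 2950001)
  }
})

test_that("a fully heterozygous sample yields no segments", {
  p <- roh_fixture(rep(1L, 60))
  expect_equal(nrow(detect_roh_sliding(p)), 0L)
  expect_equal(nrow(suppressMessages(detect_roh_consecutive(p))), 0L)
})

test_that("runs split at gaps above 1 Mb and short pieces are dropped", {
  # 60 homozygous SNPs with a 1.2 Mb gap after SNP 40: left piece 1.95 Mb
  # survives, right piece (19 SNPs over 0.9 Mb) fails the length screen
  pos <- c(seq_len(40) * 50e3, 40 * 50e3 + 1.2e6 + seq_len(20) * 50e3)
  p <- roh_fixture(rep(0L, 60), pos = pos)
  for (f in list(detect_roh_sliding, detect_roh_consecutive)) {
    segs <- f(p)
    expect_equal(nrow(segs), 1L)
    expect_equal(segs$n_snps, 40L)
    expect_equal(segs$end_bp, 2000e3)
  }
})

test_that("the consecutive detector splits runs holding two heterozygotes", {
  # hets at SNPs 30 and 60 of 100: sub-runs keep at most one het each
  d <- rep(0L, 100)
  d[c(30, 60)] <- 1L
  segs <- detect_roh_consecutive(roh_fixture(d))
  expect_gte(nrow(segs), 2L)
  for (k in seq_len(nrow(segs))) {
    on <- which(seq_along(d) * 50e3 >= segs$start_bp[k] &
                  seq_along(d) * 50e3 <= segs$end_bp[k])
    expect_lte(sum(d[on] == 1L), 1L)
  }
})

test_that("segments respect the density screen", {
  # 20 homozygous SNPs spread over 4 Mb: mean spacing 200 kb > 120 kb
  p <- roh_fixture(rep(0L, 20), spacing = 200e3)
  expect_equal(nrow(suppressMessages(detect_roh_sliding(p))), 0L)
  expect_equal(nrow(suppressMessages(detect_roh_consecutive(p))), 0L)
})

test_that("F_ROH is covered-length over map-covered genome", {
  p <- tiny_sim(seed = 17)
  map_len <- sum(tapply(p$map$pos_bp, p$map$chrom, function(x) max(x) - min(x)))
  segs <- tibble::tibble(sample = p$samples[1], subpop = p$subpop[1],
                         chrom = "1", start_bp = 1e6, end_bp = 1e6 + map_len / 10,
                         n_snps = 10L, length_bp = map_len / 10 + 1)
  f <- f_roh(segs, p)
  expect_equal(f$f_roh[1], (map_len / 10 + 1) / map_len)
  # samples without segments get zero
  expect_true(all(f$f_roh[-1] == 0))
  # no segments at all
  f0 <- f_roh(segs[0, ], p)
  expect_true(all(f0$f_roh == 0))
})

test_that("length summaries count thresholds as strict exceedances", {
  segs <- tibble::tibble(sample = paste0("s", 1:4), subpop = "P1",
                         chrom = "1", start_bp = 1,
                         end_bp = c(2, 5, 9, 20) * 1e6,
                         n_snps = 10L,
                         length_bp = c(2, 5, 9, 20) * 1e6)
  s <- roh_length_summary(segs)
  expect_equal(s$pct_gt_4Mb, 75)
  expect_equal(s$pct_gt_8Mb, 50)
  expect_equal(s$pct_gt_16Mb, 25)
  expect_equal(s$n_segments, 4L)
  # all segments exactly 1 Mb: nothing exceeds
  segs1 <- dplyr::mutate(segs, length_bp = 1e6)
  expect_true(all(roh_length_summary(segs1)$pct_gt_4Mb == 0))
  # empty input
  expect_equal(nrow(roh_length_summary(segs[0, ])), 0L)
})

test_that("autozygosity scores are coverage proportions with inclusive ends", {
  p <- toy_panel(matrix(0L, 10, 5), subpop = rep("P1", 10))
  segs <- tibble::tibble(sample = p$samples[1:3], subpop = "P1",
                         chrom = "1", start_bp = 1e5, end_bp = 3e5,
                         n_snps = 3L, length_bp = 2e5 + 1)
  tr <- autozygosity_track(segs, p)
  # SNPs at 1e5..3e5 covered for 3 of 10 samples; segment end inclusive
  expect_equal(tr$score, c(0.3, 0.3, 0.3, 0, 0))
  # full coverage
  segs_all <- tibble::tibble(sample = p$samples, subpop = "P1",
                             chrom = "1", start_bp = 1e5, end_bp = 5e5,
                             n_snps = 5L, length_bp = 4e5 + 1)
  expect_true(all(autozygosity_track(segs_all, p)$score == 1))
})

test_that("island calling needs two adjacent extreme SNPs", {
  mk_track <- function(score) {
    tibble::tibble(subpop = "P1", chrom = "1",
                   pos_bp = seq_along(score) * 1e5,
                   snp_id = paste0("s", seq_along(score)), score = score)
  }
  # two adjacent extremes among 3,000 SNPs (well under 0.1% of the track,
  # so the interpolated 99.9th percentile stays at the background score)
  sc <- rep(0.1, 3000)
  sc[1500:1501] <- 0.9
  isl <- roh_islands(mk_track(sc))
  expect_equal(nrow(isl), 1L)
  expect_equal(isl$start_bp, 1500e5)
  expect_equal(isl$end_bp, 1501e5)
  expect_equal(isl$n_units, 2L)
  expect_equal(isl$source, "ROH_P1")
  # a single isolated extreme SNP is not an island
  sc2 <- rep(0.1, 3000)
  sc2[1500] <- 0.9
  expect_equal(nrow(roh_islands(mk_track(sc2))), 0L)
  # constant track: strict exceedance yields nothing
  expect_equal(nrow(roh_islands(mk_track(rep(0.5, 3000)))), 0L)
})

test_that("island calling is invariant to sample order", {
  p <- tiny_sim(seed = 18, inbred_fraction = c(0.4, 0))
  segs <- detect_roh_sliding(p)
  isl1 <- roh_islands(autozygosity_track(segs, p))
  perm <- sample(n_samples(p))
  p2 <- subset_panel(p, samples = perm)
  isl2 <- roh_islands(autozygosity_track(detect_roh_sliding(p2), p2))
  expect_equal(dplyr::arrange(isl1, source, chrom, start_bp),
               dplyr::arrange(isl2, source, chrom, start_bp))
})

test_that("segment length converts to generations since the ancestor", {
  expect_equal(generations_to_ancestor(8), 6L)
  expect_equal(generations_to_ancestor(16), 3L)
  expect_equal(generations_to_ancestor(50), 1L)
  expect_equal(generations_to_ancestor(c(8, 16)), c(6L, 3L))
})
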