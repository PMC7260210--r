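# fixture builders shared across test files; everything is generated in code

# panel from a dosage matrix; SNPs spaced 100 kb on one chromosome unless
# positions/chromosomes are given
toy_panel <- function(dosage, pos_bp = NULL, chrom = NULL, subpop = NULL,
                      haplotypes = NULL, coat_color = NULL) {
  dosage <- as.matrix(dosage)
  m <- ncol(dosage)
  if (is.null(pos_bp)) pos_bp <- seq_len(m) * 1e5
  if (is.null(chrom)) chrom <- rep("1", m)
  map <- data.frame(chrom = chrom, pos_bp = pos_bp,
                    snp_id = paste0("s", seq_len(m)),
                    allele_ref = "A", allele_alt = "B")
  n <- nrow(dosage)
  if (is.null(subpop)) subpop <- rep(c("P1", "P2"), length.out = n)
  genotype_panel(map, dosage, samples = sprintf("ind%03d", seq_len(n)),
                 subpop = subpop, coat_color = coat_color,
                 haplotypes = haplotypes)
}

# panel built from a haplotype matrix (rows 2k-1, 2k belong to sample k)
hap_panel <- function(hap, pos_bp = NULL, chrom = NULL, subpop = NULL) {
  hap <- as.matrix(hap)
  d <- hap[seq(1, nrow(hap), 2), , drop = FALSE] +
    hap[seq(2, nrow(hap), 2), , drop = FALSE]
  toy_panel(d, pos_bp = pos_bp, chrom = chrom, subpop = subpop,
            haplotypes = hap)
}

# small fast simulation shared by module tests (cached per options)
tiny_sim <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(seed = seed, n_chrom = 2L, snps_per_chrom = 150L,
         chrom_length_bp = 15e6, n_samples_per_pop = 50L,
         effective_size = c(40L, 40L), split_generations = 5L,
         ancestral_generations = 5L),
    list(...))
  simulate_two_pops(do.call(sim_config, args))
}

# textbook scalar Weir & Cockerham (1984) oracle written in the general
# r-population form, independent of the vectorized implementation
wc_oracle <- function(n, p, h) {
  r <- length(n)
  nbar <- mean(n)
  nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n * p) / (r * nbar)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / (r * nbar)
  a <- nbar / nc * (s2 - 1 / (nbar - 1) *
                      (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                              (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  list(a = a, b = b, c = cc, theta = a / (a + b + cc))
}

# brute-force VanRaden method-1 GRM by explicit double loop
grm_bruteforce <- function(dosage, p0 = 0.5) {
  n <- nrow(dosage)
  m <- ncol(dosage)
  g <- matrix(0, n, n)
  denom <- 2 * m * p0 * (1 - p0)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      g[i, j] <- sum((dosage[i, ] - 2 * p0) * (dosage[j, ] - 2 * p0)) / denom
    }
  }
  g
}

# does any region in `regions` on `chrom` cover position `pos`?
region_covers <- function(regions, chrom, pos) {
  any(regions$chrom == chrom & regions$start_bp <= pos &
        regions$end_bp >= pos)
}
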