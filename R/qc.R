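#' Marker and sample quality control
#'
#' The QC filters reproduce the standard pre-analysis pipeline for two
#' genotyping panels that must end up on a single shared set of markers:
#' call-rate filtering (samples before SNPs), a per-subpopulation
#' Hardy-Weinberg equilibrium screen, and the intersection to shared
#' polymorphic SNPs. Each filter returns the filtered panel with a running
#' log attached; [qc_report()] retrieves it as a tibble.
#'
#' @name qc
NULL

qc_log_add <- function(panel, step, unit, n_in, n_removed, params = "") {
  log <- attr(panel, "qc_log")
  row <- tibble::tibble(step = step, unit = unit, n_in = n_in,
                        n_removed = n_removed, n_out = n_in - n_removed,
                        params = params)
  attr(panel, "qc_log") <- if (is.null(log)) row else dplyr::bind_rows(log, row)
  panel
}

#' Retrieve the QC log of a panel
#'
#' @param panel A `genotype_panel` that has passed through one or more QC
#'   filters.
#' @return A tibble with one row per filter step: `step`, `unit` (sample or
#'   snp), `n_in`, `n_removed`, `n_out`, `params`. Removal counts reconcile
#'   exactly: each step's `n_out` is the next step's `n_in` for that unit.
#' @export
qc_report <- function(panel) {
  log <- attr(panel, "qc_log")
  if (is.null(log)) {
    tibble::tibble(step = character(), unit = character(),
                   n_in = integer(), n_removed = integer(),
                   n_out = integer(), params = character())
  } else {
    log
  }
}

#' Filter samples and SNPs by genotype call rate
#'
#' Samples are filtered before SNPs: per-SNP call rates are recomputed on the
#' retained samples, so a sample with pervasive missingness cannot drag down
#' otherwise good markers.
#'
#' @param panel A `genotype_panel`.
#' @param sample_min,snp_min Minimum call rate (fraction of non-missing
#'   genotypes) for samples and SNPs, in `(0, 1]`. Default 0.90 for both.
#' @return The filtered `genotype_panel` (QC log attached).
#' @export
filter_call_rate <- function(panel, sample_min = 0.90, snp_min = 0.90) {
  stopifnot(sample_min > 0, sample_min <= 1, snp_min > 0, snp_min <= 1)
  log0 <- attr(panel, "qc_log")
  obs <- !is.na(panel$dosage)
  cr_sample <- rowMeans(obs)
  keep_s <- cr_sample >= sample_min
  if (!any(keep_s)) {
    stop("call-rate filter removed every sample (min over samples = ",
         signif(max(cr_sample), 3), ")", call. = FALSE)
  }
  n_in_s <- n_samples(panel)
  panel2 <- if (all(keep_s)) panel else subset_panel(panel, samples = keep_s)
  cr_snp <- colMeans(!is.na(panel2$dosage))
  keep_m <- cr_snp >= snp_min
  n_in_m <- n_snps(panel2)
  out <- if (all(keep_m)) panel2 else subset_panel(panel2, snps = keep_m)
  attr(out, "qc_log") <- log0
  out <- qc_log_add(out, "call_rate", "sample", n_in_s, sum(!keep_s),
                    paste0("sample_min=", sample_min))
  qc_log_add(out, "call_rate", "snp", n_in_m, sum(!keep_m),
             paste0("snp_min=", snp_min))
}

#' One-degree-of-freedom chi-square Hardy-Weinberg test
#'
#' Goodness-of-fit of observed genotype counts to the expected
#' Hardy-Weinberg proportions at the sample allele frequency. Monomorphic
#' counts are not testable and return `NA`.
#'
#' @param n_ref_hom,n_het,n_alt_hom Genotype counts.
#' @return A list with `chisq` and `p`.
#' @export
hwe_chisq <- function(n_ref_hom, n_het, n_alt_hom) {
  n <- n_ref_hom + n_het + n_alt_hom
  if (n == 0) return(list(chisq = NA_real_, p = NA_real_))
  p <- (2 * n_alt_hom + n_het) / (2 * n)
  if (p <= 0 || p >= 1) return(list(chisq = NA_real_, p = NA_real_))
  e <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
  x2 <- sum((c(n_ref_hom, n_het, n_alt_hom) - e)^2 / e)
  list(chisq = x2, p = stats::pchisq(x2, df = 1, lower.tail = FALSE))
}

#' Remove SNPs deviating from Hardy-Weinberg equilibrium
#'
#' A SNP is removed when the 1-df chi-square HWE p-value falls below `p_max`
#' in any tested group. With `scope = "subpop"` (default) the test runs
#' separately inside each subpopulation, mirroring per-dataset filtering
#' before the panels are merged; `scope = "pooled"` tests all samples
#' jointly. SNPs monomorphic within a group are skipped by the test there
#' (the shared-polymorphic filter owns them).
#'
#' @param panel A `genotype_panel`.
#' @param p_max Removal threshold on the HWE p-value (default `1e-5`).
#' @param scope `"subpop"` or `"pooled"`.
#' @return The filtered `genotype_panel` (QC log attached).
#' @export
hwe_filter <- function(panel, p_max = 1e-5, scope = c("subpop", "pooled")) {
  scope <- match.arg(scope)
  groups <- if (scope == "subpop") unique(panel$subpop) else "pooled"
  fail <- rep(FALSE, n_snps(panel))
  for (g in groups) {
    d <- if (identical(g, "pooled")) panel$dosage else
      panel$dosage[panel$subpop == g, , drop = FALSE]
    n0 <- colSums(d == 0L, na.rm = TRUE)
    n1 <- colSums(d == 1L, na.rm = TRUE)
    n2 <- colSums(d == 2L, na.rm = TRUE)
    p <- vapply(seq_along(n0),
                function(j) hwe_chisq(n0[j], n1[j], n2[j])$p, numeric(1))
    fail <- fail | (!is.na(p) & p < p_max)
  }
  out <- if (any(fail)) subset_panel(panel, snps = !fail) else panel
  attr(out, "qc_log") <- attr(panel, "qc_log")
  qc_log_add(out, "hwe", "snp", n_snps(panel), sum(fail),
             paste0("p_max=", p_max, ", scope=", scope))
}

#' Merge two panels on their shared polymorphic SNPs
#'
#' Retains the (chromosome, position) intersection of the two maps, dropping
#' SNPs whose allele pairs disagree (strand flips are not resolved) with a
#' warning, recoding panel B dosages/haplotypes to panel A's ref/alt
#' orientation where the alleles match in swapped order, and removing SNPs
#' monomorphic in the pooled sample. Sample sets must be disjoint.
#'
#' @param panel_a,panel_b `genotype_panel`s on the same reference
#'   coordinates.
#' @return A merged `genotype_panel` carrying both panels' samples and
#'   subpopulation labels (QC log attached).
#' @export
keep_shared_polymorphic <- function(panel_a, panel_b) {
  if (any(panel_b$samples %in% panel_a$samples)) {
    stop("sample ids overlap between the two panels", call. = FALSE)
  }
  key_a <- paste(panel_a$map$chrom, panel_a$map$pos_bp)
  key_b <- paste(panel_b$map$chrom, panel_b$map$pos_bp)
  ia <- which(key_a %in% key_b)
  if (!length(ia)) stop("no shared (chrom, pos) between panels", call. = FALSE)
  ib <- match(key_a[ia], key_b)
  ma <- panel_a$map[ia, ]; mb <- panel_b$map[ib, ]
  same <- ma$allele_ref == mb$allele_ref & ma$allele_alt == mb$allele_alt
  swap <- ma$allele_ref == mb$allele_alt & ma$allele_alt == mb$allele_ref
  if (any(!(same | swap))) {
    warning(sum(!(same | swap)), " shared position(s) dropped for ",
            "incompatible alleles", call. = FALSE)
  }
  keep <- same | swap
  ia <- ia[keep]; ib <- ib[keep]; swap <- swap[keep]
  n_in_union <- length(unique(c(key_a, key_b)))
  a <- subset_panel(panel_a, snps = ia)
  b <- subset_panel(panel_b, snps = ib)
  if (any(swap)) {
    b$dosage[, swap] <- 2L - b$dosage[, swap]
    if (has_haplotypes(b)) b$haplotypes[, swap] <- 1L - b$haplotypes[, swap]
  }
  dosage <- rbind(a$dosage, b$dosage)
  hap <- if (has_haplotypes(a) && has_haplotypes(b)) {
    rbind(a$haplotypes, b$haplotypes)
  } else {
    NULL
  }
  coat <- if (!is.null(a$coat_color) && !is.null(b$coat_color)) {
    c(a$coat_color, b$coat_color)
  } else {
    NULL
  }
  merged <- genotype_panel(a$map, dosage, c(a$samples, b$samples),
                           c(a$subpop, b$subpop), coat, hap)
  freq <- colMeans(merged$dosage, na.rm = TRUE) / 2
  poly <- !is.na(freq) & freq > 0 & freq < 1
  n_before <- n_snps(merged)
  out <- if (all(poly)) merged else subset_panel(merged, snps = poly)
  out <- qc_log_add(out, "shared", "snp", n_in_union,
                    n_in_union - n_before, "intersection + allele match")
  qc_log_add(out, "monomorphic", "snp", n_before, sum(!poly), "pooled MAF > 0")
}

#' Drop SNPs monomorphic in the pooled sample
#'
#' The single-panel form of the shared-polymorphic rule: SNPs whose pooled
#' alternate-allele frequency is exactly 0 or 1 (or entirely missing) carry
#' no information for any diversity or differentiation statistic and are
#' removed.
#'
#' @param panel A `genotype_panel`.
#' @return The filtered `genotype_panel` (QC log attached).
#' @export
drop_monomorphic <- function(panel) {
  f <- colMeans(panel$dosage, na.rm = TRUE) / 2
  poly <- !is.na(f) & f > 0 & f < 1
  out <- if (all(poly)) panel else subset_panel(panel, snps = poly)
  attr(out, "qc_log") <- attr(panel, "qc_log")
  qc_log_add(out, "monomorphic", "snp", n_snps(panel), sum(!poly),
             "pooled MAF > 0")
}

#' Per-subpopulation MAF and heterozygosity summary
#'
#' Mean and standard deviation of the per-SNP minor allele frequency (within
#' group, folded to `[0, 0.5]`) and of the per-sample observed
#' heterozygosity (fraction of heterozygous non-missing genotypes), for each
#' subpopulation and for the pooled panel.
#'
#' @param panel A `genotype_panel`.
#' @return A tibble with columns `subpop` (including `"General"`),
#'   `n_samples`, `n_snps`, `maf_mean`, `maf_sd`, `het_mean`, `het_sd`.
#' @export
summarize_panel <- function(panel) {
  one <- function(p, label) {
    freq <- colMeans(p$dosage, na.rm = TRUE) / 2
    maf <- pmin(freq, 1 - freq)
    het <- rowMeans(p$dosage == 1L, na.rm = TRUE)
    tibble::tibble(subpop = label, n_samples = n_samples(p),
                   n_snps = n_snps(p),
                   maf_mean = mean(maf, na.rm = TRUE),
                   maf_sd = stats::sd(maf[!is.na(maf)]),
                   het_mean = mean(het, na.rm = TRUE),
                   het_sd = if (length(het) > 1) stats::sd(het) else 0)
  }
  dplyr::bind_rows(
    one(panel, "General"),
    purrr::map_dfr(split_by_subpop(panel), ~ one(.x, .x$subpop[1]))
  )
}
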