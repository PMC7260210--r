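#' Construct a genotype panel
#'
#' The central data container: a samples-by-SNPs alternate-allele dosage
#' matrix tied to a marker map and per-sample metadata, optionally carrying
#' phased haplotypes. All downstream analyses (QC, GRM, ROH, LD, varLD,
#' F_ST, signature calling) take a `genotype_panel` as their first argument.
#'
#' @param map A data frame with one row per SNP and columns `chrom`
#'   (chromosome label, coerced to character), `pos_bp` (1-based base-pair
#'   position), `snp_id`, `allele_ref` and `allele_alt` (single-character
#'   alleles). Positions must be strictly increasing within each chromosome
#'   and every SNP biallelic.
#' @param dosage Integer matrix (samples x SNPs) counting copies of the
#'   alternate allele: values in `{0, 1, 2}` with `NA` for missing.
#' @param samples Character vector of sample identifiers (unique).
#' @param subpop Character vector of subpopulation labels, one per sample.
#'   Two-population analyses require exactly two distinct labels.
#' @param coat_color Optional character vector of per-sample coat colors (or
#'   any secondary grouping), one per sample.
#' @param haplotypes Optional phased haplotype matrix `(2 * samples) x SNPs`
#'   with values in `{0, 1}`; rows `2k - 1` and `2k` belong to sample `k`.
#'   Haplotype sums must equal `dosage` at every non-missing genotype;
#'   haplotypes carry no missing values.
#'
#' @return An object of class `genotype_panel`.
#' @export
genotype_panel <- function(map, dosage, samples, subpop,
                           coat_color = NULL, haplotypes = NULL) {
  map <- validate_marker_map(map)
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  samples <- as.character(samples)
  subpop <- as.character(subpop)

  if (anyDuplicated(samples)) stop("duplicate sample ids", call. = FALSE)
  if (nrow(dosage) != length(samples)) {
    stop("dosage has ", nrow(dosage), " rows but ", length(samples),
         " samples were given", call. = FALSE)
  }
  if (ncol(dosage) != nrow(map)) {
    stop("dosage has ", ncol(dosage), " columns but the map has ",
         nrow(map), " SNPs", call. = FALSE)
  }
  if (length(subpop) != length(samples)) {
    stop("subpop must have one label per sample", call. = FALSE)
  }
  bad <- dosage[!is.na(dosage)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L)) {
    stop("dosage values must be 0, 1, 2 or NA", call. = FALSE)
  }
  if (!is.null(coat_color)) {
    coat_color <- as.character(coat_color)
    if (length(coat_color) != length(samples)) {
      stop("coat_color must have one value per sample", call. = FALSE)
    }
  }
  if (!is.null(haplotypes)) {
    haplotypes <- as.matrix(haplotypes)
    storage.mode(haplotypes) <- "integer"
    if (nrow(haplotypes) != 2L * length(samples) ||
        ncol(haplotypes) != nrow(map)) {
      stop("haplotypes must be a (2 * samples) x SNPs matrix", call. = FALSE)
    }
    if (anyNA(haplotypes) || !all(haplotypes %in% c(0L, 1L))) {
      stop("haplotypes must be strictly binary with no missing values",
           call. = FALSE)
    }
    hsum <- haplotypes[seq(1L, nrow(haplotypes), by = 2L), , drop = FALSE] +
      haplotypes[seq(2L, nrow(haplotypes), by = 2L), , drop = FALSE]
    obs <- !is.na(dosage)
    if (any(hsum[obs] != dosage[obs])) {
      stop("haplotype sums disagree with dosages at non-missing genotypes",
           call. = FALSE)
    }
  }
  rownames(dosage) <- samples
  colnames(dosage) <- map$snp_id
  structure(
    list(map = map, dosage = dosage, samples = samples, subpop = subpop,
         coat_color = coat_color, haplotypes = haplotypes),
    class = "genotype_panel"
  )
}

#' Validate a marker map
#'
#' @param map Data frame with columns `chrom`, `pos_bp`, `snp_id`,
#'   `allele_ref`, `allele_alt`.
#' @return The map as a tibble with canonical column types.
#' @keywords internal
validate_marker_map <- function(map) {
  need <- c("chrom", "pos_bp", "snp_id", "allele_ref", "allele_alt")
  miss <- setdiff(need, names(map))
  if (length(miss)) {
    stop("marker map is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  map <- tibble::as_tibble(map)[need]
  map$chrom <- as.character(map$chrom)
  map$pos_bp <- as.numeric(map$pos_bp)
  map$snp_id <- as.character(map$snp_id)
  if (anyNA(map$pos_bp) || any(map$pos_bp < 1)) {
    stop("pos_bp must be positive 1-based positions", call. = FALSE)
  }
  dec <- unlist(tapply(map$pos_bp, factor(map$chrom, unique(map$chrom)),
                       function(p) diff(p) <= 0), use.names = FALSE)
  if (any(dec)) {
    stop("positions must be strictly increasing within each chromosome",
         call. = FALSE)
  }
  same <- !is.na(map$allele_ref) & !is.na(map$allele_alt) &
    map$allele_ref == map$allele_alt
  if (any(nchar(map$allele_ref) != 1L) || any(nchar(map$allele_alt) != 1L) ||
      any(same)) {
    stop("alleles must be distinct single characters (biallelic SNPs)",
         call. = FALSE)
  }
  map
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat("<genotype_panel> ", length(x$samples), " samples x ", nrow(x$map),
      " SNPs on ", length(unique(x$map$chrom)), " chromosome(s)\n", sep = "")
  tab <- table(x$subpop)
  cat("  subpopulations: ",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n", sep = "")
  cat("  phased haplotypes: ", if (has_haplotypes(x)) "yes" else "no",
      "\n", sep = "")
  invisible(x)
}

#' Number of samples / SNPs in a panel
#' @param panel A `genotype_panel`.
#' @return Integer count.
#' @export
n_samples <- function(panel) length(panel$samples)

#' @rdname n_samples
#' @export
n_snps <- function(panel) nrow(panel$map)

#' Does a panel carry phased haplotypes?
#' @param panel A `genotype_panel`.
#' @return Logical scalar.
#' @export
has_haplotypes <- function(panel) !is.null(panel$haplotypes)

#' Subset a panel by samples and/or SNPs
#'
#' Keeps the dosage matrix, map, metadata and haplotypes in step.
#'
#' @param panel A `genotype_panel`.
#' @param samples Sample index (integer/logical) or character ids; `NULL`
#'   keeps all.
#' @param snps SNP index (integer/logical vector over map rows); `NULL`
#'   keeps all.
#' @return A `genotype_panel`.
#' @export
subset_panel <- function(panel, samples = NULL, snps = NULL) {
  si <- seq_along(panel$samples)
  if (!is.null(samples)) {
    si <- if (is.character(samples)) match(samples, panel$samples) else si[samples]
    if (anyNA(si)) stop("unknown sample id in subset", call. = FALSE)
  }
  mi <- seq_len(nrow(panel$map))
  if (!is.null(snps)) mi <- mi[snps]
  hap <- NULL
  if (has_haplotypes(panel)) {
    hr <- as.vector(rbind(2L * si - 1L, 2L * si))
    hap <- panel$haplotypes[hr, mi, drop = FALSE]
  }
  out <- genotype_panel(
    map = panel$map[mi, , drop = FALSE],
    dosage = panel$dosage[si, mi, drop = FALSE],
    samples = panel$samples[si],
    subpop = panel$subpop[si],
    coat_color = if (is.null(panel$coat_color)) NULL else panel$coat_color[si],
    haplotypes = hap
  )
  # carry bookkeeping attributes (QC log, simulation truth) through subsets
  for (at in c("qc_log", "sim_truth")) {
    if (!is.null(attr(panel, at))) attr(out, at) <- attr(panel, at)
  }
  out
}

#' Split a panel by subpopulation
#'
#' @param panel A `genotype_panel`.
#' @return Named list of `genotype_panel`s, one per subpopulation label (in
#'   order of first appearance).
#' @export
split_by_subpop <- function(panel) {
  labs <- unique(panel$subpop)
  stats::setNames(
    lapply(labs, function(l) subset_panel(panel, samples = panel$subpop == l)),
    labs
  )
}

#' Haplotype rows belonging to a set of samples
#' @param idx Integer sample indices.
#' @return Integer row indices into the haplotype matrix.
#' @keywords internal
hap_rows <- function(idx) as.vector(rbind(2L * idx - 1L, 2L * idx))

#' Per-SNP alternate-allele frequency
#'
#' @param panel A `genotype_panel`.
#' @param by `"pooled"` (default) or `"subpop"`.
#' @return A tibble with `snp_id`, `chrom`, `pos_bp`, optionally `subpop`,
#'   and `alt_freq` (NA where no genotype is observed).
#' @export
alt_frequency <- function(panel, by = c("pooled", "subpop")) {
  by <- match.arg(by)
  base <- panel$map[c("snp_id", "chrom", "pos_bp")]
  if (by == "pooled") {
    dplyr::mutate(base,
                  alt_freq = unname(colMeans(panel$dosage, na.rm = TRUE)) / 2)
  } else {
    purrr::map_dfr(split_by_subpop(panel), function(p) {
      dplyr::mutate(base,
                    subpop = p$subpop[1],
                    alt_freq = unname(colMeans(p$dosage, na.rm = TRUE)) / 2)
    })
  }
}

# two-subpopulation precondition used by the comparative analyses
assert_two_pops <- function(panel) {
  labs <- unique(panel$subpop)
  if (length(labs) != 2L) {
    stop("this analysis requires exactly two subpopulation labels, found ",
         length(labs), call. = FALSE)
  }
  labs
}
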