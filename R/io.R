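#' Read a genotype panel from PLINK or VCF files
#'
#' Supported formats: PLINK text (`prefix.ped` + `prefix.map`), PLINK binary
#' (`prefix.bed` + `prefix.bim` + `prefix.fam`, SNP-major), and VCF. A VCF
#' whose GT fields are all phased (`|` separator) yields a panel carrying
#' haplotypes; any unphased record withholds haplotypes with a warning.
#' PLINK input never yields haplotypes.
#'
#' Subpopulation labels are taken from the PLINK family (FID) column, or in
#' VCF from `##SAMPLE=<ID=...,Subpop=...>` header lines as written by
#' [write_panel()]; the `subpop` argument overrides both.
#'
#' @param path File prefix (PLINK) or file path (VCF).
#' @param format One of `"plink_text"`, `"plink_bed"`, `"vcf"`.
#' @param subpop Optional per-sample subpopulation labels: a single label, a
#'   vector in sample order, or a named vector keyed by sample id.
#' @return A `genotype_panel` (with haplotypes when the VCF is fully phased).
#' @export
read_panel <- function(path, format = c("plink_text", "plink_bed", "vcf"),
                       subpop = NULL) {
  format <- match.arg(format)
  panel <- switch(format,
    plink_text = read_plink_text(path),
    plink_bed = read_plink_bed(path),
    vcf = read_vcf_panel(path)
  )
  if (!is.null(subpop)) {
    if (!is.null(names(subpop))) {
      subpop <- unname(subpop[panel$samples])
    } else if (length(subpop) == 1L) {
      subpop <- rep(subpop, length(panel$samples))
    }
    panel$subpop <- as.character(subpop)
    panel <- genotype_panel(panel$map, panel$dosage, panel$samples,
                            panel$subpop, panel$coat_color, panel$haplotypes)
  }
  panel
}

#' Write a genotype panel to PLINK or VCF files
#'
#' The inverse of [read_panel()]. PLINK output drops haplotype phase; VCF
#' output writes phased GT (`|`) when the panel carries haplotypes and
#' unphased GT otherwise, plus `##SAMPLE` header lines holding subpopulation
#' and coat-color labels so that a read/write cycle preserves them.
#'
#' @param panel A `genotype_panel`.
#' @param path File prefix (PLINK) or file path (VCF).
#' @param format One of `"plink_text"`, `"plink_bed"`, `"vcf"`.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path, format = c("plink_text", "plink_bed", "vcf")) {
  format <- match.arg(format)
  switch(format,
    plink_text = write_plink_text(panel, path),
    plink_bed = write_plink_bed(panel, path),
    vcf = write_vcf_panel(panel, path)
  )
  invisible(path)
}

# ---- PLINK text ------------------------------------------------------------

read_plink_text <- function(prefix) {
  map_file <- paste0(prefix, ".map")
  ped_file <- paste0(prefix, ".ped")
  for (f in c(map_file, ped_file)) {
    if (!file.exists(f)) stop("file not found: ", f, call. = FALSE)
  }
  mp <- utils::read.table(map_file, header = FALSE,
                          colClasses = c("character", "character",
                                         "numeric", "numeric"))
  ped <- utils::read.table(ped_file, header = FALSE,
                           colClasses = "character")
  m <- nrow(mp)
  if (ncol(ped) != 6L + 2L * m) {
    stop("ped/map mismatch: expected ", 6L + 2L * m, " ped columns, found ",
         ncol(ped), call. = FALSE)
  }
  n <- nrow(ped)
  a1 <- as.matrix(ped[, 6L + 2L * seq_len(m) - 1L, drop = FALSE])
  a2 <- as.matrix(ped[, 6L + 2L * seq_len(m), drop = FALSE])
  allele_ref <- allele_alt <- character(m)
  dosage <- matrix(NA_integer_, n, m)
  for (j in seq_len(m)) {
    obs <- c(a1[, j], a2[, j])
    lev <- sort(unique(obs[obs != "0"]))
    if (length(lev) > 2L) {
      stop("SNP ", mp[j, 2L], " has more than two alleles", call. = FALSE)
    }
    if (length(lev) == 0L) lev <- c("A", "B")
    if (length(lev) == 1L) {
      lev <- sort(c(lev, setdiff(c("A", "B", "C", "G", "T", "N"), lev)[1L]))
    }
    allele_ref[j] <- lev[1L]
    allele_alt[j] <- lev[2L]
    d <- (a1[, j] == lev[2L]) + (a2[, j] == lev[2L])
    d[a1[, j] == "0" | a2[, j] == "0"] <- NA_integer_
    dosage[, j] <- as.integer(d)
  }
  map <- tibble::tibble(chrom = mp[[1L]], pos_bp = mp[[4L]],
                        snp_id = mp[[2L]], allele_ref = allele_ref,
                        allele_alt = allele_alt)
  genotype_panel(map, dosage, samples = ped[[2L]], subpop = ped[[1L]])
}

write_plink_text <- function(panel, prefix) {
  map <- panel$map
  utils::write.table(
    data.frame(map$chrom, map$snp_id, 0, map$pos_bp),
    paste0(prefix, ".map"),
    quote = FALSE, row.names = FALSE, col.names = FALSE, sep = "\t"
  )
  n <- n_samples(panel); m <- n_snps(panel)
  al <- matrix("0", n, 2L * m)
  for (j in seq_len(m)) {
    d <- panel$dosage[, j]
    first <- ifelse(is.na(d), "0", ifelse(d >= 1L, map$allele_alt[j],
                                          map$allele_ref[j]))
    second <- ifelse(is.na(d), "0", ifelse(d == 2L, map$allele_alt[j],
                                           map$allele_ref[j]))
    al[, 2L * j - 1L] <- first
    al[, 2L * j] <- second
  }
  ped <- cbind(panel$subpop, panel$samples, "0", "0", "0", "-9", al)
  utils::write.table(ped, paste0(prefix, ".ped"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE, sep = " ")
  invisible(prefix)
}

# ---- PLINK binary (SNP-major .bed) -----------------------------------------

read_plink_bed <- function(prefix) {
  bed_file <- paste0(prefix, ".bed")
  bim_file <- paste0(prefix, ".bim")
  fam_file <- paste0(prefix, ".fam")
  for (f in c(bed_file, bim_file, fam_file)) {
    if (!file.exists(f)) stop("file not found: ", f, call. = FALSE)
  }
  bim <- utils::read.table(bim_file, header = FALSE,
                           colClasses = c("character", "character", "numeric",
                                          "numeric", "character", "character"))
  fam <- utils::read.table(fam_file, header = FALSE, colClasses = "character")
  n <- nrow(fam); m <- nrow(bim)
  raw <- readBin(bed_file, "raw", n = 3L + m * ceiling(n / 4))
  if (length(raw) < 3L || raw[1L] != as.raw(0x6c) || raw[2L] != as.raw(0x1b)) {
    stop("not a PLINK .bed file: ", bed_file, call. = FALSE)
  }
  if (raw[3L] != as.raw(0x01)) {
    stop("only SNP-major .bed files are supported", call. = FALSE)
  }
  bps <- ceiling(n / 4)
  body <- as.integer(raw[-(1:3)])
  # 2-bit codes per sample: 0 = hom A1, 1 = missing, 2 = het, 3 = hom A2
  codes <- matrix(0L, 4L * bps, m)
  block <- matrix(body, bps, m)
  for (k in 0:3) {
    codes[seq_len(bps) * 4L - 3L + k, ] <- block %% 4L
    block <- block %/% 4L
  }
  codes <- codes[seq_len(n), , drop = FALSE]
  dosage <- matrix(c(2L, NA_integer_, 1L, 0L)[codes + 1L], n, m)
  map <- tibble::tibble(chrom = bim[[1L]], pos_bp = bim[[4L]],
                        snp_id = bim[[2L]], allele_ref = bim[[6L]],
                        allele_alt = bim[[5L]])
  genotype_panel(map, dosage, samples = fam[[2L]], subpop = fam[[1L]])
}

write_plink_bed <- function(panel, prefix) {
  map <- panel$map
  utils::write.table(
    data.frame(map$chrom, map$snp_id, 0, map$pos_bp,
               map$allele_alt, map$allele_ref),
    paste0(prefix, ".bim"),
    quote = FALSE, row.names = FALSE, col.names = FALSE, sep = "\t"
  )
  utils::write.table(
    data.frame(panel$subpop, panel$samples, 0, 0, 0, -9),
    paste0(prefix, ".fam"),
    quote = FALSE, row.names = FALSE, col.names = FALSE, sep = "\t"
  )
  n <- n_samples(panel); m <- n_snps(panel)
  bps <- ceiling(n / 4)
  # dosage (alt copies) -> 2-bit code: 2 -> 0 (hom A1), NA -> 1, 1 -> 2, 0 -> 3
  code <- matrix(1L, 4L * bps, m)
  d <- panel$dosage
  cd <- matrix(NA_integer_, n, m)
  cd[!is.na(d) & d == 2L] <- 0L
  cd[is.na(d)] <- 1L
  cd[!is.na(d) & d == 1L] <- 2L
  cd[!is.na(d) & d == 0L] <- 3L
  code[seq_len(n), ] <- cd
  if (4L * bps > n) code[(n + 1L):(4L * bps), ] <- 0L  # padding beyond n
  dim(code) <- c(4L, bps * m)
  bytes <- colSums(code * c(1L, 4L, 16L, 64L))
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(bytes), con)
  invisible(prefix)
}

# ---- VCF -------------------------------------------------------------------

read_vcf_panel <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L,
                                       dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  bad <- grepl(",", alt) | nchar(fix[, "REF"]) != 1L | nchar(alt) != 1L
  if (any(bad)) {
    stop("non-biallelic or non-SNP record(s): ",
         paste(fix[bad, "ID"], collapse = ", "), call. = FALSE)
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1L)
  gt <- t(gt)  # samples x SNPs
  samples <- rownames(gt)
  phased <- grepl("|", gt, fixed = TRUE)
  missing <- is.na(gt) | grepl("\\.", gt)
  a1 <- as.integer(substr(gt, 1L, 1L))
  a2 <- as.integer(substr(gt, 3L, 3L))
  dosage <- a1 + a2
  dosage[missing] <- NA_integer_
  dim(dosage) <- dim(gt)
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0(fix[, "CHROM"], "_",
                                         fix[, "POS"])[is.na(ids) | ids == "."]
  map <- tibble::tibble(chrom = fix[, "CHROM"],
                        pos_bp = as.numeric(fix[, "POS"]),
                        snp_id = ids,
                        allele_ref = fix[, "REF"], allele_alt = alt)
  hap <- NULL
  if (!any(missing) && all(phased)) {
    hap <- matrix(0L, 2L * nrow(dosage), ncol(dosage))
    hap[seq(1L, nrow(hap), 2L), ] <- a1
    hap[seq(2L, nrow(hap), 2L), ] <- a2
  } else if (any(phased) && !all(phased | missing)) {
    warning("mixed phased/unphased GT records: haplotypes withheld",
            call. = FALSE)
  }
  meta <- vcf@meta
  sub_lab <- parse_sample_meta(meta, samples, "Subpop")
  coat <- parse_sample_meta(meta, samples, "CoatColor")
  if (all(is.na(sub_lab))) sub_lab <- rep("unknown", length(samples))
  genotype_panel(map, dosage, samples = samples, subpop = sub_lab,
                 coat_color = if (all(is.na(coat))) NULL else coat,
                 haplotypes = hap)
}

parse_sample_meta <- function(meta, samples, key) {
  lines <- grep("^##SAMPLE=<", meta, value = TRUE)
  out <- rep(NA_character_, length(samples))
  for (ln in lines) {
    body <- sub("^##SAMPLE=<", "", sub(">$", "", ln))
    kv <- strsplit(body, ",", fixed = TRUE)[[1L]]
    kv <- strsplit(kv, "=", fixed = TRUE)
    vals <- stats::setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
    i <- match(vals[["ID"]], samples)
    if (!is.na(i) && key %in% names(vals)) out[i] <- vals[[key]]
  }
  out
}

write_vcf_panel <- function(panel, path) {
  map <- panel$map
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=subpopscan",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    vapply(seq_along(panel$samples), function(i) {
      extra <- if (is.null(panel$coat_color)) "" else
        paste0(",CoatColor=", panel$coat_color[i])
      paste0("##SAMPLE=<ID=", panel$samples[i],
             ",Subpop=", panel$subpop[i], extra, ">")
    }, character(1L)),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", panel$samples), collapse = "\t")
  ), con)
  n <- n_samples(panel); m <- n_snps(panel)
  if (has_haplotypes(panel)) {
    h1 <- panel$haplotypes[seq(1L, 2L * n, 2L), , drop = FALSE]
    h2 <- panel$haplotypes[seq(2L, 2L * n, 2L), , drop = FALSE]
    gt <- matrix(paste0(h1, "|", h2), n, m)
  } else {
    gt <- matrix("./.", n, m)
    gt[!is.na(panel$dosage) & panel$dosage == 0L] <- "0/0"
    gt[!is.na(panel$dosage) & panel$dosage == 1L] <- "0/1"
    gt[!is.na(panel$dosage) & panel$dosage == 2L] <- "1/1"
  }
  lines <- vapply(seq_len(m), function(j) {
    paste(c(map$chrom[j], format(map$pos_bp[j], scientific = FALSE),
            map$snp_id[j], map$allele_ref[j], map$allele_alt[j],
            ".", "PASS", ".", "GT", gt[, j]), collapse = "\t")
  }, character(1L))
  writeLines(lines, con)
  invisible(path)
}

# ---- candidate regions -----------------------------------------------------

#' Write candidate regions as BED (plus a 1-based companion TSV)
#'
#' Regions are held internally in 1-based inclusive coordinates; the BED file
#' converts to 0-based half-open at this single point. A companion TSV with
#' the original 1-based inclusive coordinates is written next to it.
#'
#' @param regions A tibble with columns `chrom`, `start_bp`, `end_bp`,
#'   `source`, `n_units` (as produced by [roh_islands()],
#'   [fst_outlier_regions()], [varld_scan()]).
#' @param path Output BED path; the companion TSV replaces the extension
#'   with `.tsv`.
#' @return `path`, invisibly.
#' @export
write_regions <- function(regions, path) {
  cols <- c("chrom", "start_bp", "end_bp", "source", "n_units")
  regions <- tibble::as_tibble(regions)
  for (cl in setdiff(cols, names(regions))) regions[[cl]] <- NA
  regions <- regions[cols]
  if (nrow(regions)) {
    stopifnot(all(regions$start_bp <= regions$end_bp))
    num <- suppressWarnings(as.numeric(regions$chrom))
    regions <- regions[order(is.na(num), num, regions$chrom,
                             regions$start_bp), ]
  }
  bed <- data.frame(chrom = regions$chrom,
                    start = regions$start_bp - 1,
                    end = regions$end_bp,
                    name = regions$source,
                    score = regions$n_units)
  con <- file(path, "w")
  writeLines("#chrom\tstart\tend\tname\tscore", con)
  close(con)
  if (nrow(bed)) {
    utils::write.table(format(bed, scientific = FALSE, trim = TRUE),
                       path, append = TRUE, quote = FALSE, sep = "\t",
                       row.names = FALSE, col.names = FALSE)
  }
  tsv <- sub("\\.bed$", ".tsv", path)
  if (identical(tsv, path)) tsv <- paste0(path, ".tsv")
  utils::write.table(regions, tsv, quote = FALSE, sep = "\t",
                     row.names = FALSE)
  invisible(path)
}
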