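#' Run the full two-subpopulation scan
#'
#' Orchestrates QC, relatedness (GRM / inbreeding / PCA), both ROH
#' detectors with island calling, LD decay and phase persistence, the varLD
#' scan, the F_ST outlier scan, and consensus signature calling over one
#' panel, writing every track and region table plus a JSON manifest (all
#' parameters, the seed, file hashes) into an output directory. Reruns with
#' the same inputs and seed are bit-identical for every deterministic
#' stage.
#'
#' @param panel A two-subpopulation `genotype_panel` with haplotypes, or a
#'   path understood by [read_panel()] (then `format` applies).
#' @param out_dir Output directory (created if needed).
#' @param format Input format when `panel` is a path.
#' @param params Named list overriding defaults; recognized entries:
#'   `sample_call_rate`, `snp_call_rate`, `hwe_p_max`, `roh` (a
#'   [roh_params()] list), `island_percentile`, `window_snps`,
#'   `fst_bins`, `fst_percentile`, `varld_percentile`, `min_consecutive`,
#'   `min_adjacent`.
#' @param subset Optional named character vector filtering samples on
#'   metadata before analysis, e.g. `c(coat_color = "black")`.
#' @param seed Integer seed recorded in the manifest and set before the run
#'   (the scan itself is deterministic; the seed covers any stochastic
#'   extension).
#' @return Invisibly, a list with all stage results (`qc`, `summary`,
#'   `grm`, `f` [F_GRM and F_ROH per sample], `pca`, `roh`, `islands`,
#'   `ld_decay`, `adjacent_r2`, `phase`, `varld`, `fst`, `signatures`,
#'   `report`, `manifest`).
#' @export
run_pipeline <- function(panel, out_dir, format = "vcf", params = list(),
                         subset = NULL, seed = 1L) {
  t0 <- Sys.time()
  stage <- function(what) {
    message(sprintf("[%6.1fs] %s", as.numeric(difftime(Sys.time(), t0,
                                                       units = "secs")),
                    what))
  }
  if (is.character(panel)) {
    if (!file.exists(panel) && !file.exists(paste0(panel, ".ped")) &&
        !file.exists(paste0(panel, ".bed"))) {
      stop("input not found: ", panel, call. = FALSE)
    }
    panel <- read_panel(panel, format = format)
  }
  stopifnot(inherits(panel, "genotype_panel"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)

  p <- utils::modifyList(list(
    sample_call_rate = 0.90, snp_call_rate = 0.90, hwe_p_max = 1e-5,
    roh = roh_params(), island_percentile = 99.9, window_snps = 15L,
    fst_bins = 20L, fst_percentile = 99.9, varld_percentile = 99.9,
    min_consecutive = 2L, min_adjacent = 2L), params)

  if (!is.null(subset)) {
    keep <- rep(TRUE, n_samples(panel))
    for (field in names(subset)) {
      v <- panel[[field]]
      if (is.null(v)) stop("no metadata field '", field, "'", call. = FALSE)
      keep <- keep & v == subset[[field]]
    }
    panel <- subset_panel(panel, samples = keep)
  }
  assert_two_pops(panel)

  stage("qc")
  panel <- filter_call_rate(panel, p$sample_call_rate, p$snp_call_rate)
  panel <- hwe_filter(panel, p$hwe_p_max)
  panel <- drop_monomorphic(panel)
  qc <- qc_report(panel)
  smry <- summarize_panel(panel)

  stage("relatedness")
  grm <- compute_grm(panel)
  fg <- f_grm(grm)
  pca <- pca_grm(grm, n_components = 10L)

  stage("roh")
  roh_s <- detect_roh_sliding(panel, p$roh)
  roh_c <- detect_roh_consecutive(panel, p$roh)
  fr <- f_roh(roh_s, panel)
  f_tbl <- dplyr::left_join(fg, fr, by = c("sample", "subpop"))
  track <- autozygosity_track(roh_s, panel)
  islands <- roh_islands(track, p$island_percentile, p$min_adjacent)

  stage("ld")
  decay <- ld_decay(panel)
  adj <- adjacent_r2_summary(panel)
  phase <- if (has_haplotypes(panel)) phase_persistence(panel) else NULL

  stage("varld")
  vl <- varld_scan(panel, p$window_snps, p$varld_percentile,
                   p$min_consecutive)
  stage("fst")
  fw <- fst_window_track(panel, p$window_snps)
  fo <- fst_outlier_regions(fw, p$fst_bins, p$fst_percentile,
                            p$min_consecutive)
  gf <- global_fst(panel)

  stage("signatures")
  sig <- consensus_signatures(islands, fo$regions, vl$regions)
  rep_tbl <- signature_report(sig, track, fo$windows, vl$track)

  wt <- function(x, name) {
    f <- file.path(out_dir, name)
    utils::write.table(x, f, sep = "\t", quote = FALSE, row.names = FALSE)
    f
  }
  files <- c(
    wt(qc, "qc_report.tsv"), wt(smry, "panel_summary.tsv"),
    wt(f_tbl, "inbreeding.tsv"), wt(tidy(pca), "pca_coordinates.tsv"),
    wt(glance(pca), "pca_variance.tsv"),
    wt(roh_s, "roh_sliding.tsv"), wt(roh_c, "roh_consecutive.tsv"),
    wt(roh_length_summary(roh_s), "roh_summary.tsv"),
    wt(track, "autozygosity_track.tsv"),
    wt(decay, "ld_decay.tsv"), wt(adj, "adjacent_r2.tsv"),
    wt(vl$track, "varld_track.tsv"), wt(fo$windows, "fst_windows.tsv"),
    wt(gf, "global_fst.tsv"), wt(rep_tbl, "signatures.tsv"))
  if (!is.null(phase)) files <- c(files, wt(phase, "phase_persistence.tsv"))
  write_regions(islands, file.path(out_dir, "roh_islands.bed"))
  write_regions(fo$regions, file.path(out_dir, "fst_regions.bed"))
  write_regions(vl$regions, file.path(out_dir, "varld_regions.bed"))
  if (nrow(sig)) {
    write_regions(dplyr::mutate(sig, source = sources, n_units = n_sources),
                  file.path(out_dir, "signatures.bed"))
  } else {
    write_regions(tibble::tibble(chrom = character(), start_bp = numeric(),
                                 end_bp = numeric(), source = character(),
                                 n_units = integer()),
                  file.path(out_dir, "signatures.bed"))
  }
  files <- c(files,
             file.path(out_dir, c("roh_islands.bed", "roh_islands.tsv",
                                  "fst_regions.bed", "fst_regions.tsv",
                                  "varld_regions.bed", "varld_regions.tsv",
                                  "signatures.bed", "signatures.tsv")))
  files <- unique(files[file.exists(files)])

  stage("write outputs")
  manifest <- list(
    package_version = as.character(utils::packageVersion("subpopscan")),
    seed = seed,
    n_samples = n_samples(panel), n_snps = n_snps(panel),
    subpopulations = as.list(table(panel$subpop)),
    parameters = lapply(p, function(x) if (is.object(x)) unclass(x) else x),
    files = as.list(stats::setNames(unname(tools::md5sum(files)),
                                    basename(files))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(panel = panel, qc = qc, summary = smry, grm = grm,
                 f = f_tbl, pca = pca,
                 roh = list(sliding = roh_s, consecutive = roh_c),
                 islands = islands, autozygosity = track,
                 ld_decay = decay, adjacent_r2 = adj, phase = phase,
                 varld = vl, fst = list(windows = fo$windows,
                                        regions = fo$regions, global = gf),
                 signatures = sig, report = rep_tbl, manifest = manifest))
}

#' Read a flat key-value run configuration file
#'
#' Lines of the form `key = value` (`#` comments and blank lines ignored).
#' Values are parsed as numbers when possible, with `true`/`false` mapped
#' to logicals.
#'
#' @param path Configuration file path.
#' @return A named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    if (length(kv) < 2L) stop("bad config line: ", ln, call. = FALSE)
    key <- trimws(kv[1L])
    val <- trimws(paste(kv[-1L], collapse = "="))
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else
      if (tolower(val) %in% c("true", "false")) tolower(val) == "true" else val
  }
  out
}
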