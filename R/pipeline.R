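#' Demo pipeline configuration
#'
#' A complete, self-contained run configuration on seeded synthetic data:
#' the demo alignment locus (three planted motif sites at conservation
#' counts 4, 6, 7), one simulated ChIP extract pair over the candidate
#' amplicons, and a simulated expression matrix with a planted regulated
#' subset.
#'
#' @param seed Integer master seed for every stage.
#' @param out_dir Output directory for \code{\link{run_pipeline}}.
#' @return A run-configuration list.
#' @export
demo_run_config <- function(seed = 1L, out_dir = file.path(tempdir(), "run")) {
  list(
    seed = as.integer(seed),
    out_dir = out_dir,
    motif = "TAATCY",
    min_species = 6L,
    amplicon_target_len = 110L,
    control = list(region_len = 110L, exclusion = 1000L, n = 2L),
    alignment = list(simulate = TRUE),
    chip = list(simulate = TRUE, true_occupancy = 0.02, antibody = "Pitx2"),
    expression = list(simulate = TRUE, n_genes = 200L,
                      cutoffs = c(1.2, 1.4, 2.0)))
}

.write_tsv <- function(d, file, stamp) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(paste0("# ", stamp), con)
  utils::write.table(d, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

.log_line <- function(log, ...) c(log, paste0(...))

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order: alignment acquisition (file or
#' simulation), motif scanning and conservation annotation, candidate and
#' control selection, amplicon design, ChIP occupancy quantification, and
#' expression contrast with fold scanning. Writes the result tables, a
#' stage log and a provenance manifest into the output directory. Rerunning
#' with an identical configuration reproduces byte-identical tables: every
#' source of randomness is seeded from \code{config$seed} and every table
#' is stamped with the configuration hash and seed.
#'
#' @param config A configuration list (see \code{\link{demo_run_config}})
#'   or the path to a YAML file containing one. Recognised fields:
#'   \code{seed}, \code{out_dir}, \code{motif}, \code{min_species},
#'   \code{amplicon_target_len}, \code{control} (\code{region_len},
#'   \code{exclusion}, \code{n}); \code{alignment} (either
#'   \code{simulate = TRUE} with optional \code{\link{aln_sim_config}}
#'   fields, or \code{file} + \code{ref_species}, FASTA or MAF by
#'   extension); \code{chip} (either \code{simulate = TRUE} with optional
#'   \code{\link{chip_sim_config}} fields, or \code{plates}, a vector of
#'   plate CSV paths; plus \code{antibody}); \code{expression} (either
#'   \code{simulate = TRUE} with optional \code{\link{expr_sim_config}}
#'   fields, or \code{matrix} + \code{genotypes}; plus \code{cutoffs} and
#'   optional \code{exclude_set} to drop one replicate set by id).
#' @return Invisibly, a list with the output directory, the result tables
#'   and the file paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$seed)) stop("config$seed is required")
  if (is.null(config$out_dir)) stop("config$out_dir is required")
  seed <- as.integer(config$seed)
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_path <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(config, cfg_path)
  # the hash covers everything that affects the results; the output
  # location does not, so identical analyses hash identically
  hash_path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(config[setdiff(names(config), "out_dir")], hash_path)
  cfg_md5 <- unname(tools::md5sum(hash_path))
  unlink(hash_path)
  stamp <- sprintf("config_md5=%s seed=%d", cfg_md5, seed)
  log <- character(0)
  fail <- function(stage, msg) stop("stage '", stage, "' failed: ", msg,
                                    call. = FALSE)

  ## stage: alignment
  log <- .log_line(log, "[alignment] start")
  aln <- config$alignment
  if (isTRUE(aln$simulate)) {
    acfg_args <- aln[setdiff(names(aln), c("simulate"))]
    acfg <- do.call(aln_sim_config, c(acfg_args, list(seed = seed)))
    sim <- simulate_alignment(acfg)
    block <- sim$block
    .write_tsv(sim$truth, file.path(out_dir, "alignment_truth.tsv"), stamp)
    log <- .log_line(log, "[alignment] simulated demo locus, ",
                     nchar(ref_sequence(block)), " bp, ",
                     length(block$rows), " species")
  } else {
    if (is.null(aln$file)) fail("alignment", "need simulate=TRUE or a file")
    if (!file.exists(aln$file)) fail("alignment", paste0("missing file ",
                                                         aln$file))
    block <- if (grepl("\\.maf$", aln$file, ignore.case = TRUE))
      concat_blocks(read_maf(aln$file, aln$ref_species))
    else read_aligned_fasta(aln$file, ref_species = aln$ref_species)
    log <- .log_line(log, "[alignment] read ", aln$file)
  }

  ## stage: motif scan / conservation / selection
  motif <- if (is.null(config$motif)) "TAATCY" else config$motif
  min_species <- if (is.null(config$min_species)) 6L else config$min_species
  sites <- scan_reference_motifs(block, motif = motif)
  sites <- annotate_conservation(block, sites)
  export_sites_bed(sites, file.path(out_dir, "sites.bed"))
  cand <- select_candidate_sites(sites, min_species = min_species)
  log <- .log_line(log, "[motifs] ", nrow(sites), " sites scanned, ",
                   nrow(cand), " candidates at min_species=", min_species)
  seq_len_ref <- nchar(ref_sequence(block))
  target_len <- if (is.null(config$amplicon_target_len)) 110L
                else config$amplicon_target_len
  amplicons <- if (nrow(cand) > 0L)
    design_amplicon_window(cand, seq_len_ref, target_len)
  else data.frame(chrom = character(), start = integer(), end = integer(),
                  site_id = character(), length = integer())
  .write_tsv(amplicons, file.path(out_dir, "amplicons.tsv"), stamp)
  ctl <- config$control
  controls <- select_control_regions(
    seq_len_ref, sites,
    region_len = if (is.null(ctl$region_len)) 110L else ctl$region_len,
    exclusion = if (is.null(ctl$exclusion)) 1000L else ctl$exclusion,
    n = if (is.null(ctl$n)) 2L else ctl$n)
  .write_tsv(controls, file.path(out_dir, "controls.tsv"), stamp)
  log <- .log_line(log, "[motifs] ", nrow(amplicons), " amplicons, ",
                   nrow(controls), " control regions")

  ## stage: ChIP occupancy
  chip <- config$chip
  antibody <- if (is.null(chip$antibody)) "Pitx2" else chip$antibody
  if (isTRUE(chip$simulate)) {
    ccfg_args <- chip[setdiff(names(chip), c("simulate", "antibody"))]
    ccfg <- do.call(chip_sim_config, c(ccfg_args, list(seed = seed + 1L)))
    amp_ids <- if (nrow(amplicons) > 0L) amplicons$site_id else "amp1"
    plate <- simulate_chip_pair(ccfg, amplicons = amp_ids,
                                antibody = antibody)
    write_plate_csv(plate, file.path(out_dir, "plate.csv"))
    log <- .log_line(log, "[chip] simulated extract pair over ",
                     length(amp_ids), " amplicons (k_true = ",
                     signif(attr(plate, "k_true"), 4), ")")
  } else {
    if (is.null(chip$plates)) fail("chip", "need simulate=TRUE or plates")
    plate <- do.call(rbind, lapply(chip$plates, read_plate_csv))
    log <- .log_line(log, "[chip] read ", length(chip$plates), " plate(s)")
  }
  occ <- analyze_occupancy(plate, antibody = antibody)
  if (is.null(occ)) occ <- data.frame()
  .write_tsv(occ, file.path(out_dir, "occupancy.tsv"), stamp)
  for (i in seq_len(nrow(occ)))
    if (!is.na(occ$k[i]) && fold_deviation(occ$k[i]) > 2)
      log <- .log_line(log, "[chip] warning: pair ", occ$pair_id[i],
                       " has k outside [0.5, 2]")
  log <- .log_line(log, "[chip] ", nrow(occ), " occupancy rows (codes: ",
                   paste(unique(occ$code), collapse = " "), ")")

  ## stage: expression
  expr <- config$expression
  cutoffs <- if (is.null(expr$cutoffs)) c(1.2, 1.4, 2.0) else expr$cutoffs
  if (isTRUE(expr$simulate)) {
    ecfg_args <- expr[setdiff(names(expr),
                              c("simulate", "cutoffs", "exclude_set"))]
    ecfg <- do.call(expr_sim_config, c(ecfg_args, list(seed = seed + 2L)))
    esim <- simulate_expression(ecfg)
    mat <- esim$matrix
    genotypes <- esim$genotypes
    replicate_set <- esim$replicate_set
    .write_tsv(esim$truth, file.path(out_dir, "expression_truth.tsv"),
               stamp)
    log <- .log_line(log, "[expression] simulated ", nrow(mat),
                     " genes x ", ncol(mat), " arrays")
  } else {
    if (is.null(expr$matrix)) fail("expression",
                                   "need simulate=TRUE or a matrix file")
    mat <- read_expression_matrix(expr$matrix)
    genotypes <- unlist(expr$genotypes)
    replicate_set <- if (is.null(expr$replicate_set)) rep(NA, ncol(mat))
                     else unlist(expr$replicate_set)
    log <- .log_line(log, "[expression] read ", expr$matrix)
  }
  if (!is.null(expr$exclude_set)) {
    drop <- replicate_set %in% expr$exclude_set
    mat <- mat[, !drop, drop = FALSE]
    genotypes <- genotypes[!drop]
    log <- .log_line(log, "[expression] excluded replicate set(s) ",
                     paste(expr$exclude_set, collapse = ","),
                     " (", sum(drop), " arrays)")
  }
  folds <- fold_table(mat, genotypes)
  .write_tsv(folds, file.path(out_dir, "fold_records.tsv"), stamp)
  fscan <- fold_scan_fdr(mat, genotypes, cutoffs)
  .write_tsv(fscan, file.path(out_dir, "fold_scan.tsv"), stamp)
  log <- .log_line(log, "[expression] fold scan at cutoffs ",
                   paste(cutoffs, collapse = ","))

  ## provenance manifest + log
  writeLines(log, file.path(out_dir, "run.log"))
  files <- sort(setdiff(list.files(out_dir), "manifest.tsv"))
  manifest <- data.frame(
    file = files,
    md5 = unname(tools::md5sum(file.path(out_dir, files))),
    config_md5 = cfg_md5, seed = seed, stringsAsFactors = FALSE)
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(out_dir = out_dir, sites = sites, candidates = cand,
                 amplicons = amplicons, controls = controls,
                 occupancy = occ, fold_records = folds, fold_scan = fscan,
                 log = log, manifest = manifest))
}

.read_run_tsv <- function(path) {
  if (!file.exists(path)) return(NULL)
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Render a human-readable run report
#'
#' Summarises a completed run directory as markdown: per-amplicon
#' occupancy with significance codes and normalization coefficients, the
#' fold-scan table, and the code legend. Missing tables produce a partial
#' report with warnings rather than an error.
#'
#' @param run_dir Directory written by \code{\link{run_pipeline}}.
#' @param file Optional path to also write the report to.
#' @return Character vector of report lines, invisibly if \code{file} is
#'   given.
#' @export
render_report <- function(run_dir, file = NULL) {
  out <- c("# Run report", "")
  man <- .read_run_tsv(file.path(run_dir, "manifest.tsv"))
  if (!is.null(man))
    out <- c(out, sprintf("Config hash: %s; seed: %s", man$config_md5[1],
                          man$seed[1]), "")
  occ <- .read_run_tsv(file.path(run_dir, "occupancy.tsv"))
  out <- c(out, "## Occupancy", "")
  if (is.null(occ)) {
    warning("occupancy table missing; partial report")
    out <- c(out, "WARNING: occupancy table missing.", "")
  } else if (nrow(occ) == 0L) {
    out <- c(out, "No amplicons measured.", "")
  } else {
    for (pair in unique(occ$pair_id))
      out <- c(out, sprintf("Extract pair %s: normalization coefficient k = %.3g",
                            pair, occ$k[occ$pair_id == pair][1]))
    out <- c(out, "")
    out <- c(out, "| amplicon | pair | % occupancy | +/- | p | code |",
             "|---|---|---|---|---|---|")
    for (i in seq_len(nrow(occ)))
      out <- c(out, sprintf("| %s | %s | %s | %s | %s | %s |",
                            occ$amplicon_id[i], occ$pair_id[i],
                            .fmt(occ$percent_occupancy[i]),
                            .fmt(occ$percent_sd[i]), .fmt(occ$p_value[i]),
                            occ$code[i]))
    out <- c(out, "",
             paste("Codes: **** (>99.99%), *** (>99%), ** (>95%),",
                   "* (>90%), ± (>70%), ne (no evidence),",
                   "nd (not detected)."), "")
  }
  fs <- .read_run_tsv(file.path(run_dir, "fold_scan.tsv"))
  out <- c(out, "## Fold scan", "")
  if (is.null(fs)) {
    warning("fold-scan table missing; partial report")
    out <- c(out, "WARNING: fold-scan table missing.", "")
  } else {
    out <- c(out, "| cutoff | observed | null | FDR |", "|---|---|---|---|")
    for (i in seq_len(nrow(fs)))
      out <- c(out, sprintf("| %.3g | %d | %.3g | %s |", fs$cutoff[i],
                            fs$n_observed[i], fs$n_null[i],
                            .fmt(fs$fdr[i])))
    out <- c(out, "")
  }
  if (!is.null(file)) {
    writeLines(out, file)
    return(invisible(out))
  }
  out
}

.fmt <- function(x) ifelse(is.na(x), "nd", sprintf("%.3g", x))
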