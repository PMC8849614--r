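# Configuration, typed CSV I/O and the full synthetic-data pipeline driver:
# simulate -> measure -> phenostats -> scan -> peaks, with a hashed manifest.

#' Build and validate a pipeline configuration
#'
#' Accepts a YAML file path or a list; unspecified fields take documented
#' defaults. The global `seed` fans out to per-stage seeds as
#' `seed * 100 + stage counter` (stages numbered in execution order), so
#' stages are reproducible in isolation.
#'
#' @param x YAML file path or named list of overrides.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(x = list()) {
  if (is.character(x)) x <- yaml::read_yaml(x)
  stopifnot(is.list(x))
  cfg <- list(
    out_dir = tempfile("rosetteqtl_run_"),
    seed = 1,
    # synthetic rosettes (measure stage demonstration)
    n_rosettes = 3, image_size_px = 1024,
    # MAGIC simulation
    n_founders = 19, n_chromosomes = 5, n_markers_per_chrom = 100,
    chrom_length_cM = 100, n_lines = 200, breakpoints_per_chrom = 1,
    genotyping_error = 0.01,
    # planted QTL and phenotypes
    causal_marker = NULL, qtl_variance_fraction = 0.2,
    v_line = 1, v_e = 1, n_replicates = 3,
    das = 35:44,
    # scan
    scan_traits = "PRA", scan_das = 35, alpha = 0.05, n_perm = 100,
    hmm_error = 0.01, mosaic_density = 1,
    # annotation
    gff3 = NULL)
  unknown <- setdiff(names(x), names(cfg))
  if (length(unknown) > 0)
    stop(sprintf("unknown config field: %s", paste(unknown, collapse = ", ")))
  cfg[names(x)] <- x
  if (cfg$n_perm < 1) stop("n_perm must be >= 1")
  if (cfg$alpha <= 0 || cfg$alpha >= 1) stop("alpha must be in (0, 1)")
  if (cfg$n_lines < 30) stop("n_lines must be >= 30 for the scan stage")
  if (!all(cfg$scan_das %in% cfg$das)) stop("scan_das must be within das")
  if (!is.null(cfg$gff3) && !file.exists(cfg$gff3))
    stop(sprintf("gff3 file not found: %s", cfg$gff3))
  if (abs(cfg$seed) >= 2^31) stop("seed must be below 2^31 in magnitude")
  structure(cfg, class = "pipeline_config")
}

#' Read a long-format phenotype table
#'
#' @param path CSV with columns `line`, `replicate`, `das` and one numeric
#'   column per descriptor.
#' @return Validated data.frame.
#' @export
read_phenotype_table <- function(path) {
  t <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("line", "replicate", "das")
  miss <- setdiff(need, colnames(t))
  if (length(miss) > 0)
    stop(sprintf("missing column(s): %s", paste(miss, collapse = ", ")))
  descs <- setdiff(colnames(t), need)
  if (length(descs) == 0) stop("no descriptor columns")
  for (d in c("replicate", "das", descs)) {
    v <- t[[d]]
    if (is.character(v)) {
      conv <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(conv) & !is.na(v) & v != "NA" & v != "")
      if (length(bad) > 0)
        stop(sprintf("non-numeric value in column '%s' at row %d", d, bad[1]))
      t[[d]] <- conv
    }
  }
  t
}

#' Write a phenotype table (round-trips with [read_phenotype_table()])
#' @param t table to write.
#' @param path output CSV path.
#' @export
write_phenotype_table <- function(t, path) {
  utils::write.csv(t, path, row.names = FALSE)
  invisible(path)
}

.write_stage <- function(obj, path) {
  utils::write.csv(obj, path, row.names = FALSE)
  path
}

#' Run the full synthetic pipeline
#'
#' Executes, in order: rosette simulation + morphometry, MAGIC simulation,
#' phenotype simulation with one planted QTL, phenostats (averaging,
#' correlations, heritability, morphospace), the founder-probability scan
#' with a permutation threshold, and peak calling/filtering/tabulation
#' (nearest-gene annotation when a GFF3 is configured). Every output file's
#' MD5 is recorded in `manifest.csv`; identical configs reproduce identical
#' hashes. A stage failure halts with the stage name.
#'
#' @param config a `pipeline_config` (or anything accepted by
#'   [pipeline_config()]).
#' @return Invisibly, a list with `manifest` (data.frame `file`, `md5`),
#'   `out_dir`, `qtls`, `causal_marker`, and the per-stage objects.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  stage_seed <- function(i) config$seed * 100 + i
  stage <- function(name, expr) {
    tryCatch(force(expr), error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  log_line <- function(...) message(sprintf(...))

  # -- stage 1: rosettes + morphometry ------------------------------------
  rosettes <- stage("simulate-rosettes", {
    rows <- NULL
    for (i in seq_len(config$n_rosettes)) {
      # keep the physical frame fixed as the pixel size varies
      sp <- rosette_spec(n_leaves = 5 + (i - 1) %% 5,
                         image_size_px = config$image_size_px,
                         mm_per_px = 0.05 * 1024 / config$image_size_px,
                         seed = stage_seed(1) + i)
      g <- generate_rosette_mask(sp)
      meas <- measure_rosette(g$mask)
      oracle <- analytic_descriptors(g$shape)
      rows <- rbind(rows,
                    data.frame(rosette = i, source = c("raster", "oracle"),
                               rbind(meas, oracle), stringsAsFactors = FALSE))
    }
    rows
  })
  files <- c(files, .write_stage(rosettes,
                                 file.path(config$out_dir, "rosette_descriptors.csv")))
  log_line("stage simulate-rosettes: %d rosettes", config$n_rosettes)

  # -- stage 2: MAGIC simulation ------------------------------------------
  sim <- stage("simulate-magic", {
    panel <- simulate_founders(config$n_founders, config$n_chromosomes,
                               config$n_markers_per_chrom,
                               config$chrom_length_cM, seed = stage_seed(2))
    pop <- simulate_magic_population(panel, config$n_lines,
                                     config$breakpoints_per_chrom,
                                     config$genotyping_error,
                                     seed = stage_seed(3))
    list(panel = panel, pop = pop)
  })
  founders_df <- cbind(sim$panel$map,
                       as.data.frame(t(sim$panel$alleles)))
  files <- c(files,
             .write_stage(founders_df, file.path(config$out_dir, "founders.csv")),
             .write_stage(data.frame(line = rownames(sim$pop$calls),
                                     as.data.frame(sim$pop$calls)),
                          file.path(config$out_dir, "rils.csv")),
             .write_stage(sim$pop$truth, file.path(config$out_dir, "truth.csv")))
  log_line("stage simulate-magic: %d lines x %d markers",
           nrow(sim$pop$calls), ncol(sim$pop$calls))

  # -- stage 3: phenotypes with one planted QTL ---------------------------
  causal <- config$causal_marker
  if (is.null(causal))
    causal <- sim$panel$map$marker[ceiling(nrow(sim$panel$map) / 2)]
  pheno <- stage("simulate-phenotypes", {
    set.seed(stage_seed(4))
    effects <- stats::rnorm(config$n_founders)
    plans <- stats::setNames(lapply(descriptor_names(), function(nm)
      qtl_plan(causal, effects, config$v_line, config$v_e,
               config$n_replicates,
               target_variance_fraction = config$qtl_variance_fraction)),
      descriptor_names())
    simulate_phenotypes(sim$pop, plans, das = config$das,
                        seed = stage_seed(5))
  })
  files <- c(files, .write_stage(pheno, file.path(config$out_dir, "phenotypes.csv")))
  log_line("stage simulate-phenotypes: %d rows, causal marker %s",
           nrow(pheno), causal)

  # -- stage 4: phenostats -------------------------------------------------
  ps <- stage("phenostats", {
    avg <- average_replicates(pheno)
    herit <- heritability_all(pheno[pheno$das %in% config$scan_das, ,
                                    drop = FALSE])
    model <- build_morphospace(avg)
    list(avg = avg, herit = herit, model = model)
  })
  files <- c(files,
             .write_stage(ps$avg, file.path(config$out_dir, "averaged.csv")),
             .write_stage(ps$herit, file.path(config$out_dir, "heritability.csv")),
             .write_stage(data.frame(descriptor = rownames(ps$model$loadings),
                                     ps$model$loadings),
                          file.path(config$out_dir, "pca_loadings.csv")),
             .write_stage(ps$model$scores, file.path(config$out_dir, "pca_scores.csv")))
  for (d in config$scan_das) {
    cm <- correlations_by_das(ps$avg, d)
    files <- c(files, .write_stage(data.frame(descriptor = rownames(cm), cm),
                                   file.path(config$out_dir,
                                             sprintf("correlations_%d.csv", d))))
  }
  log_line("stage phenostats: %d averaged rows", nrow(ps$avg))

  # -- stage 5: scan -------------------------------------------------------
  scan <- stage("scan", {
    probs <- infer_founder_probabilities(sim$pop, config$hmm_error,
                                         config$mosaic_density)
    scans <- list(); thr <- NULL
    for (d in config$scan_das) for (tr in config$scan_traits) {
      sub <- ps$avg[ps$avg$das == d, , drop = FALSE]
      y <- stats::setNames(sub[[tr]], sub$line)
      s <- scan_trait(probs, y, trait = tr, das = d)
      th <- permutation_threshold(probs, y, config$alpha, config$n_perm,
                                  seed = stage_seed(6))
      scans[[sprintf("%s_%d", tr, d)]] <- list(scan = s, threshold = th)
      thr <- rbind(thr, data.frame(trait = tr, das = d, alpha = config$alpha,
                                   n_perm = config$n_perm,
                                   threshold = th$threshold,
                                   seed = th$seed, stringsAsFactors = FALSE))
    }
    list(probs = probs, scans = scans, thresholds = thr)
  })
  for (nm in names(scan$scans)) {
    s <- scan$scans[[nm]]$scan
    files <- c(files, .write_stage(cbind(s$table, s$effects),
                                   file.path(config$out_dir,
                                             sprintf("scan_%s.csv", nm))))
  }
  files <- c(files, .write_stage(scan$thresholds,
                                 file.path(config$out_dir, "thresholds.csv")))
  log_line("stage scan: %d trait x das combinations", length(scan$scans))

  # -- stage 6: peaks ------------------------------------------------------
  qtls <- stage("peaks", {
    recs <- NULL
    for (nm in names(scan$scans)) {
      sc <- scan$scans[[nm]]
      recs <- rbind(recs, call_qtl_peaks(sc$scan, sc$threshold))
    }
    if (is.null(recs)) recs <- call_qtl_peaks(scan$scans[[1]]$scan, Inf)
    kept <- filter_redundant_qtls(recs)
    if (!is.null(config$gff3) && nrow(kept) > 0) {
      genes <- read_genes_gff3(config$gff3)
      kept <- annotate_qtls(kept, sim$panel$map, genes)
    }
    list(raw = recs, kept = kept, tables = tabulate_qtls(kept))
  })
  files <- c(files,
             .write_stage(qtls$kept, file.path(config$out_dir, "qtls.csv")),
             .write_stage(qtls$tables$by_day, file.path(config$out_dir, "tables_day.csv")),
             .write_stage(qtls$tables$by_trait, file.path(config$out_dir, "tables_variable.csv")),
             .write_stage(qtls$tables$by_chrom, file.path(config$out_dir, "tables_chrom.csv")))
  log_line("stage peaks: %d raw, %d kept", nrow(qtls$raw), nrow(qtls$kept))

  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  manifest <- manifest[order(manifest$file), , drop = FALSE]
  rownames(manifest) <- NULL
  utils::write.csv(manifest, file.path(config$out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(list(manifest = manifest, out_dir = config$out_dir,
                 qtls = qtls$kept, causal_marker = causal,
                 rosettes = rosettes, sim = sim, phenotypes = pheno,
                 phenostats = ps, scan = scan))
}
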