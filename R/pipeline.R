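#' Run the full mapping pipeline
#'
#' Orchestrates: genotype calling and filtering, the chromosome I ploidy
#' screen, a per-condition nonparametric genome scan with a permutation
#' threshold, a split-population secondary scan at each peak, and the
#' phenotype statistics (floor-aware normalization for censored conditions,
#' broad-sense heritability, locus variance decomposition, disome group
#' tests, and the rich-medium vs additive correlation). Writes every result
#' table, a run log with seeds and dropped-record reconciliation, and a
#' machine-readable JSON summary; a stage failure aborts with the stage
#' named, retaining partial outputs.
#'
#' @param config named list or path to a YAML file. Recognized keys:
#'   * `mode`: `"synthetic"` (default) or `"files"`.
#'   * synthetic mode: `n_progeny`, `seed`, `n_markers`, `mean_depth`,
#'     `disome_fraction` override the simulator defaults.
#'   * files mode: `geno_pheno` (combined table path), optional `counts`
#'     (allele-count TSV) and `read_counts` (per-chromosome read-count TSV).
#'   * shared: `conditions` (default: all in the phenotype table),
#'     `day` (default 4), `n_perm` (default 1000), `alpha` (0.01),
#'     `split_n_perm` (1000), `n_tests` (12), `min_markers` (synthetic
#'     default scales 750/5848 to the simulated panel), `similarity`
#'     (0.90), `drug_area_cut` (5), `floor_cut` (5),
#'     `normalize_conditions` (default `c("rapamycin", "caffeine")`),
#'     `out_dir` (required).
#' @return report list (per-condition scans, stats, ploidy, counts),
#'   invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_config(config)
  cfg <- config
  get <- function(key, default) if (is.null(cfg[[key]])) default else cfg[[key]]
  out_dir <- cfg$out_dir
  if (is.null(out_dir)) stop("config must set out_dir")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  logit <- function(...) {
    log_lines <<- c(log_lines, sprintf(...))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(log_lines, file.path(out_dir, "run_log.txt"))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  mode <- get("mode", "synthetic")
  seed <- as.integer(get("seed", 1L))
  logit("crossqtl %s pipeline; seed %d",
        as.character(utils::packageVersion("crossqtl")), seed)

  truth <- NULL
  read_counts <- NULL
  if (mode == "synthetic") {
    params <- sim_params(
      n_progeny = get("n_progeny", 412L),
      chromosomes = default_chromosomes(get("n_markers", 537)),
      mean_depth = get("mean_depth", 20),
      disome_fraction = get("disome_fraction", 0.5),
      seed = seed
    )
    sim <- stage("simulate", simulate_cross(params))
    truth <- sim$truth
    counts <- sim$counts
    pheno <- sim$pheno
    read_counts <- simulate_chromosome_reads(truth, params)
    write_sim_truth(truth, file.path(out_dir, "truth.tsv"))
    G <- stage("genotype_calling", call_progeny_genotypes(counts))
    default_min_markers <- round(750 / 5848 * ncol(counts$reads_p1))
  } else {
    tab <- stage("read_inputs",
                 read_genotype_phenotype_table(cfg$geno_pheno,
                                               day = get("day", 4)))
    G <- tab$geno
    pheno <- tab$pheno
    if (!is.null(cfg$counts)) {
      counts <- stage("read_inputs", read_allele_counts(cfg$counts))
      G <- stage("genotype_calling", call_progeny_genotypes(counts))
    }
    if (!is.null(cfg$read_counts)) {
      rc <- read_tsv(cfg$read_counts)
      read_counts <- as.matrix(rc[, -1])
      rownames(read_counts) <- rc[[1]]
    }
    default_min_markers <- 750
  }
  n_input_strains <- nrow(G$calls)
  n_input_markers <- ncol(G$calls)

  # the coverage filter needs pre-filter read counts, which only exist when
  # genotypes were called from allele counts in this run
  checks <- "duplicate"
  if (mode == "synthetic" || !is.null(cfg$counts)) {
    checks <- c("coverage", checks)
  }
  if (!is.null(pheno) && "YPD+Kan" %in% pheno$condition) {
    checks <- c(checks, "drug")
  }
  if (!is.null(pheno) && any(pheno$condition == get("ypd_condition", "YPD") &
                               pheno$day == 4)) {
    checks <- c(checks, "growth")
  }
  G <- stage("strain_filter",
             filter_strains(G, pheno,
                            similarity_threshold = get("similarity", 0.90),
                            min_markers = get("min_markers",
                                              default_min_markers),
                            drug_area_cut = get("drug_area_cut", 5),
                            checks = checks))
  G <- stage("marker_filter", filter_markers(G))
  dropped <- G$strains[!G$strains$retained, c("strain", "reason")]
  write_tsv(dropped, file.path(out_dir, "dropped_strains.tsv"))
  write_tsv(G$dropped_markers, file.path(out_dir, "dropped_markers.tsv"))
  logit("strains: %d in = %d retained + %d dropped", n_input_strains,
        nrow(G$calls), nrow(dropped))
  logit("markers: %d in = %d retained + %d dropped", n_input_markers,
        ncol(G$calls), nrow(G$dropped_markers))
  for (code in unique(dropped$reason)) {
    logit("  dropped strains [%s]: %d", code, sum(dropped$reason == code))
  }

  ploidy <- NULL
  if (!is.null(read_counts)) {
    ploidy <- stage("ploidy_screen",
                    relative_copy_number(read_counts[rownames(G$calls), ,
                                                     drop = FALSE]))
    write_ploidy_table(ploidy, file.path(out_dir, "ploidy.tsv"))
    logit("ploidy: %d chrI disomes / %d strains",
          sum(ploidy$chr1_class == "disome"), nrow(G$calls))
  }

  day <- get("day", 4)
  conds <- get("conditions", setdiff(unique(pheno$condition[pheno$day == day]),
                                     c("YPD+Kan", "YPD+Nat")))
  n_perm <- get("n_perm", 1000)
  alpha <- get("alpha", 0.01)
  norm_conds <- get("normalize_conditions", c("rapamycin", "caffeine"))
  floor_cut <- get("floor_cut", 5)

  scans <- list(); splits <- list(); stats <- list()
  for (cn in conds) {
    means <- stage("genome_scan", strain_means(pheno, cn, day))
    sc <- stage("genome_scan",
                genome_scan(G, means, n_perm = n_perm, alpha = alpha,
                            seed = seed))
    scans[[cn]] <- sc
    write_scan_result(sc, file.path(out_dir, paste0("scan_", cn, ".tsv")))
    peak <- attr(sc, "peak")
    logit("scan %s: peak %s LOD %.2f threshold %.2f", cn, peak,
          max(sc$lod), attr(sc, "threshold"))

    sp <- stage("split_scan",
                split_scan(G, means, peak,
                           n_perm = get("split_n_perm", 1000),
                           alpha = alpha, n_tests = get("n_tests", 12),
                           seed = seed))
    splits[[cn]] <- sp
    for (a in names(sp)) {
      write_scan_result(sp[[a]],
                        file.path(out_dir,
                                  paste0("split_scan_", cn, "_", a, ".tsv")))
    }

    st <- stage("pheno_stats",
                condition_stats(G, pheno, cn, day, peak,
                                normalize = cn %in% norm_conds,
                                floor_cut = floor_cut, ploidy = ploidy))
    st$peak_lod <- max(sc$lod)
    st$threshold <- as.numeric(attr(sc, "threshold"))
    stats[[cn]] <- st
  }

  cor_yc <- NULL
  if (all(c("YPD", "copper") %in% conds)) {
    cor_yc <- condition_correlation(strain_means(pheno, "YPD", day),
                                    strain_means(pheno, "copper", day))
    logit("YPD-copper Pearson r: %.3f", cor_yc)
  }

  summary <- list(
    seed = seed,
    n_strains = nrow(G$calls),
    n_markers = ncol(G$calls),
    conditions = lapply(stats, function(s) s[setdiff(names(s),
                                                     "normalized_means")]),
    ypd_copper_r = cor_yc
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  stats_df <- do.call(rbind, lapply(names(stats), function(cn) {
    s <- stats[[cn]]
    data.frame(condition = cn, peak = s$peak, peak_lod = s$peak_lod,
               threshold = s$threshold, mean_diff = s$mean_diff,
               H2 = null2na(s$H2), sigma2_s = null2na(s$sigma2_s),
               prop_genetic = null2na(s$prop_genetic),
               disome_p = null2na(s$disome_p),
               disome_diff = null2na(s$disome_diff),
               stringsAsFactors = FALSE)
  }))
  write_tsv(stats_df, file.path(out_dir, "stats.tsv"))
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(list(geno = G, scans = scans, splits = splits, stats = stats,
                 ploidy = ploidy, ypd_copper_r = cor_yc,
                 truth = truth, log = log_lines))
}

null2na <- function(x) if (is.null(x)) NA_real_ else x

# per-condition statistics at the scan peak: subpopulation mean difference
# (on quantile-normalized means for censored conditions), heritability from
# replicates, locus variance decomposition, and euploid-vs-disome tests
condition_stats <- function(G, pheno, condition, day, peak, normalize = FALSE,
                            floor_cut = 5, ploidy = NULL) {
  means <- strain_means(pheno, condition, day)
  means <- means[names(means) %in% rownames(G$calls)]
  allele <- setNames(G$calls[, peak], rownames(G$calls))[names(means)]
  used_means <- means
  if (normalize) {
    for (a in c("P1", "P2")) {
      idx <- which(!is.na(allele) & allele == a)
      if (length(idx)) {
        used_means[idx] <- quantile_normalize_floored(means[idx],
                                                      floor_cut = floor_cut)
      }
    }
  }
  m1 <- mean(used_means[!is.na(allele) & allele == "P1"])
  m2 <- mean(used_means[!is.na(allele) & allele == "P2"])

  out <- list(peak = peak, mean_diff = abs(m2 - m1),
              mean_P1 = m1, mean_P2 = m2,
              normalized = normalize, normalized_means = used_means)

  reps <- pheno[pheno$condition == condition & pheno$day == day &
                  pheno$strain %in% rownames(G$calls), ]
  n_reps <- max(table(reps$strain))
  if (n_reps >= 2) {
    vc <- heritability(reps, strain_means = if (normalize) used_means
                       else NULL)
    lv <- tryCatch(
      suppressWarnings(locus_variance(used_means, allele, vc)),
      error = function(e) NULL)
    out$H2 <- vc$H2
    out$sigma2_s <- vc$sigma2_s
    out$sigma2_e <- vc$sigma2_e
    if (!is.null(lv)) {
      out$prop_genetic <- lv$proportion_genetic
      out$explained <- lv$explained
      out$residual_genetic <- lv$residual_genetic
    }
  }

  if (!is.null(ploidy)) {
    cls <- ploidy$chr1_class[names(means)]
    eu <- means[!is.na(cls) & cls == "euploid"]
    di <- means[!is.na(cls) & cls == "disome"]
    if (length(eu) > 0 && length(di) > 0) {
      gt <- group_difference_tests(eu, di)
      out$disome_p <- gt$p
      out$disome_diff <- gt$mean_diff
    }
  }
  out
}
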