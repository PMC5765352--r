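# All tables are TSV with '#'-prefixed metadata header lines and 1-based
# genome coordinates; marker columns are named <chrom>_<pos>.

write_tsv <- function(df, path, meta = character(0)) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (m in meta) writeLines(paste0("# ", m), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  read.delim(path, comment.char = "#", check.names = FALSE,
             stringsAsFactors = FALSE, ...)
}

#' Write / read a combined genotype + phenotype table
#'
#' One row per strain: `strain`, `is_parent`, per-condition mean-area
#' columns named `area.<condition>.d<day>`, then marker call columns named
#' `<chrom>_<pos>` holding `P1`/`P2`/`NA`. This mirrors the layout of a
#' mapping-study supplementary genotype/phenotype table (progeny rows plus
#' two parent rows).
#'
#' @param G a `geno_matrix` (retained strains are written).
#' @param pheno long phenotype data.frame; collapsed to per-strain means.
#' @param path output path.
#' @param parents optional named character vector, e.g.
#'   `c(P1 = "sake", P2 = "tecc")`: appends one pure-genotype row per
#'   parent.
#' @return `path`, invisibly.
#' @export
write_genotype_phenotype_table <- function(G, pheno, path, parents = NULL) {
  stopifnot(inherits(G, "geno_matrix"))
  strains <- rownames(G$calls)
  combos <- unique(pheno[, c("condition", "day")])
  combos <- combos[order(combos$condition, combos$day), ]
  # areas are written at fixed 4-decimal precision (sub-micrometre^2, far
  # below measurement error) so that write -> read -> write is stable
  ph <- lapply(seq_len(nrow(combos)), function(i) {
    m <- strain_means(pheno, combos$condition[i], combos$day[i])
    round(as.numeric(m[strains]), 4)
  })
  names(ph) <- paste0("area.", combos$condition, ".d", combos$day)
  df <- data.frame(strain = strains, is_parent = FALSE,
                   as.data.frame(ph, check.names = FALSE),
                   stringsAsFactors = FALSE, check.names = FALSE)
  calls <- as.data.frame(G$calls, stringsAsFactors = FALSE,
                         check.names = FALSE)
  df <- cbind(df, calls)
  if (!is.null(parents)) {
    for (al in names(parents)) {
      prow <- df[1, , drop = FALSE]
      prow$strain <- parents[[al]]
      prow$is_parent <- TRUE
      prow[, names(ph)] <- if (parents[[al]] %in% pheno$strain) {
        lapply(seq_len(nrow(combos)), function(i) {
          m <- strain_means(pheno, combos$condition[i], combos$day[i])
          round(as.numeric(m[parents[[al]]]), 4)
        })
      } else NA_real_
      prow[, colnames(G$calls)] <- al
      df <- rbind(df, prow)
    }
  }
  write_tsv(df, path,
            meta = c("crossqtl genotype+phenotype table",
                     sprintf("strains: %d  markers: %d", nrow(df),
                             ncol(G$calls))))
}

#' @rdname write_genotype_phenotype_table
#' @param day day index assigned to the phenotype rows on reading (the
#'   per-column day suffix is used; this is only a fallback).
#' @return `read_genotype_phenotype_table`: list with `geno` (progeny-only
#'   `geno_matrix`), `pheno` (long table, one replicate per strain), and
#'   `parents` (data.frame of parent rows, possibly empty).
#' @export
read_genotype_phenotype_table <- function(path, day = 4) {
  df <- read_tsv(path)
  if (!"strain" %in% names(df)) stop("missing 'strain' column")
  dup <- df$strain[duplicated(df$strain)]
  if (length(dup)) stop("duplicated strain IDs: ",
                        paste(unique(dup), collapse = ", "))
  if (!"is_parent" %in% names(df)) df$is_parent <- FALSE
  marker_cols <- grep("^[^ ]+_[0-9]+$", names(df), value = TRUE)
  marker_cols <- setdiff(marker_cols, c("strain", "is_parent"))
  pheno_cols <- grep("^area\\.", names(df), value = TRUE)
  if (length(marker_cols) == 0L) stop("no marker columns (<chrom>_<pos>)")

  prog <- df[!df$is_parent, , drop = FALSE]
  calls <- as.matrix(prog[, marker_cols, drop = FALSE])
  calls[!(calls %in% c("P1", "P2"))] <- NA_character_
  n_bad <- sum(!(as.matrix(prog[, marker_cols]) %in% c("P1", "P2", NA, "NA",
                                                       "")))
  if (n_bad > 0) message(n_bad, " malformed genotype cells set to missing")
  rownames(calls) <- prog$strain
  chrom <- sub("_[0-9]+$", "", marker_cols)
  pos <- as.integer(sub("^.*_", "", marker_cols))
  markers <- data.frame(marker = marker_cols, chrom = chrom, pos = pos,
                        stringsAsFactors = FALSE)
  G <- geno_matrix(calls, markers)

  pheno <- NULL
  if (length(pheno_cols)) {
    parsed <- regmatches(pheno_cols,
                         regexec("^area\\.(.+)\\.d([0-9]+)$", pheno_cols))
    pheno <- do.call(rbind, lapply(seq_along(pheno_cols), function(i) {
      cond <- if (length(parsed[[i]]) == 3) parsed[[i]][2] else
        sub("^area\\.", "", pheno_cols[i])
      dy <- if (length(parsed[[i]]) == 3) as.integer(parsed[[i]][3]) else day
      data.frame(strain = prog$strain, condition = cond, day = dy,
                 replicate = 1L,
                 area = suppressWarnings(as.numeric(prog[[pheno_cols[i]]])),
                 stringsAsFactors = FALSE)
    }))
    pheno <- pheno[!is.na(pheno$area), , drop = FALSE]
  }
  list(geno = G, pheno = pheno,
       parents = df[df$is_parent, , drop = FALSE])
}

#' Write / read a long replicate phenotype table
#'
#' Columns `strain`, `condition`, `day`, `replicate`, `area`.
#' @param pheno long phenotype data.frame.
#' @param path file path.
#' @export
write_phenotype_table <- function(pheno, path) {
  write_tsv(pheno, path, meta = "crossqtl replicate phenotype table (mm^2)")
}

#' @rdname write_phenotype_table
#' @export
read_phenotype_table <- function(path) {
  df <- read_tsv(path)
  need <- c("strain", "condition", "day", "replicate", "area")
  if (!all(need %in% names(df))) {
    stop("phenotype table must have columns: ", paste(need, collapse = ", "))
  }
  df
}

#' Write / read a strain x marker allele-count table (long TSV)
#'
#' Columns `strain`, `marker`, `chrom`, `pos`, `reads_p1`, `reads_p2`.
#' @param counts an `allele_counts` object.
#' @param path file path.
#' @export
write_allele_counts <- function(counts, path) {
  stopifnot(inherits(counts, "allele_counts"))
  mk <- counts$markers
  df <- data.frame(
    strain = rep(rownames(counts$reads_p1), times = ncol(counts$reads_p1)),
    marker = rep(mk$marker, each = nrow(counts$reads_p1)),
    reads_p1 = as.vector(counts$reads_p1),
    reads_p2 = as.vector(counts$reads_p2),
    stringsAsFactors = FALSE
  )
  write_tsv(df, path, meta = "crossqtl allele-count table")
}

#' @rdname write_allele_counts
#' @export
read_allele_counts <- function(path) {
  df <- read_tsv(path)
  need <- c("strain", "marker", "reads_p1", "reads_p2")
  if (!all(need %in% names(df))) {
    stop("allele-count table must have columns: ",
         paste(need, collapse = ", "))
  }
  strains <- unique(df$strain)
  mk_ids <- unique(df$marker)
  r1 <- matrix(NA_integer_, length(strains), length(mk_ids),
               dimnames = list(strains, mk_ids))
  r2 <- r1
  r1[cbind(match(df$strain, strains), match(df$marker, mk_ids))] <- df$reads_p1
  r2[cbind(match(df$strain, strains), match(df$marker, mk_ids))] <- df$reads_p2
  markers <- data.frame(marker = mk_ids,
                        chrom = sub("_[0-9]+$", "", mk_ids),
                        pos = as.integer(sub("^.*_", "", mk_ids)),
                        stringsAsFactors = FALSE)
  structure(list(reads_p1 = r1, reads_p2 = r2, markers = markers),
            class = "allele_counts")
}

#' Write / read a parental SNP table
#' @param snps data.frame from [build_parental_snp_table()].
#' @param path file path.
#' @export
write_snp_table <- function(snps, path) {
  write_tsv(snps, path, meta = "crossqtl parental SNP table (1-based)")
}

#' @rdname write_snp_table
#' @export
read_snp_table <- function(path) {
  df <- read_tsv(path)
  need <- c("chrom", "pos", "base_p1", "base_p2")
  if (!all(need %in% names(df))) {
    stop("SNP table must have columns: ", paste(need, collapse = ", "))
  }
  df
}

#' Write a genome-scan result table
#'
#' Columns `marker`, `chrom`, `pos`, `lod`, `n_used`, `above_threshold`;
#' the threshold and alpha are recorded in the metadata header.
#' @param scan a `scan_result`.
#' @param path file path.
#' @export
write_scan_result <- function(scan, path) {
  thr <- attr(scan, "threshold")
  df <- as.data.frame(scan)
  df$above_threshold <- if (is.na(thr)) NA else df$lod >= thr
  write_tsv(df, path,
            meta = c("crossqtl genome scan",
                     sprintf("peak: %s", attr(scan, "peak")),
                     sprintf("threshold: %s alpha: %s n_perm: %s",
                             format(thr), format(attr(scan, "alpha")),
                             format(attr(scan, "n_perm")))))
}

#' Write a ploidy report table
#'
#' One row per strain, one relative copy-number column per chromosome,
#' plus the chromosome I class.
#' @param report a `ploidy_report`.
#' @param path file path.
#' @export
write_ploidy_table <- function(report, path) {
  stopifnot(inherits(report, "ploidy_report"))
  df <- data.frame(strain = rownames(report$copy_number),
                   round(report$copy_number, 4),
                   chr1_class = as.character(report$chr1_class),
                   stringsAsFactors = FALSE, check.names = FALSE)
  write_tsv(df, path, meta = "crossqtl relative chromosome copy number")
}

#' Write the simulation ground truth
#'
#' One row per strain: disome flag, expected phenotype means per condition
#' (`em.<condition>`), then true genotypes at every marker.
#' @param truth a `sim_truth`.
#' @param path file path.
#' @export
write_sim_truth <- function(truth, path) {
  stopifnot(inherits(truth, "sim_truth"))
  em <- as.data.frame(truth$expected_means, check.names = FALSE)
  names(em) <- paste0("em.", names(em))
  df <- data.frame(strain = rownames(truth$genotypes),
                   disome_chrI = unname(truth$disome_flags),
                   em,
                   as.data.frame(truth$genotypes, check.names = FALSE),
                   stringsAsFactors = FALSE, check.names = FALSE)
  write_tsv(df, path, meta = "crossqtl simulation ground truth")
}

#' Read a pipeline configuration file
#'
#' A single declarative YAML (`key: value`) file; see [run_pipeline()] for
#' the recognized keys.
#' @param path file path.
#' @return named list.
#' @export
read_config <- function(path) {
  yaml::read_yaml(path)
}
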