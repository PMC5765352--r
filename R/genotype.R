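#' Construct a genotype matrix object
#'
#' Container for strain x marker genotype calls with marker and strain
#' metadata, the central data structure of the mapping pipeline.
#'
#' @param calls character matrix (strains x markers) with values `"P1"`,
#'   `"P2"` or `NA`; dimnames required.
#' @param markers data.frame with columns `marker`, `chrom`, `pos` matching
#'   the columns of `calls`.
#' @param has_reads optional logical matrix, same shape as `calls`: whether
#'   the strain had any sequencing reads at the marker (used by the marker
#'   coverage filter). Defaults to `!is.na(calls)`.
#' @param n_covered optional integer vector: markers with reads per strain,
#'   counted before any marker filtering (used by the strain coverage
#'   filter). Defaults to `rowSums(has_reads)`.
#' @return object of class `geno_matrix` with elements `calls`, `markers`,
#'   `strains` (metadata with `retained`/`reason`), `has_reads`,
#'   `dropped_markers`.
#' @export
geno_matrix <- function(calls, markers, has_reads = NULL, n_covered = NULL) {
  stopifnot(is.matrix(calls), !is.null(rownames(calls)),
            !is.null(colnames(calls)))
  bad <- setdiff(unique(as.vector(calls)), c("P1", "P2", NA))
  if (length(bad)) stop("invalid genotype codes: ", paste(bad, collapse = ", "))
  if (!identical(colnames(calls), markers$marker)) {
    stop("marker metadata does not match call matrix columns")
  }
  if (is.null(has_reads)) has_reads <- !is.na(calls)
  if (is.null(n_covered)) n_covered <- rowSums(has_reads)
  strains <- data.frame(strain = rownames(calls),
                        n_covered = as.integer(n_covered),
                        retained = TRUE, reason = NA_character_,
                        stringsAsFactors = FALSE)
  structure(list(calls = calls, markers = markers, strains = strains,
                 has_reads = has_reads,
                 dropped_markers = data.frame(marker = character(0),
                                              reason = character(0),
                                              stringsAsFactors = FALSE)),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("Genotype matrix: %d strains x %d markers (%d strains dropped, %d markers dropped)\n",
              nrow(x$calls), ncol(x$calls), sum(!x$strains$retained),
              nrow(x$dropped_markers)))
  invisible(x)
}

# confident base per row of an {A,C,G,T} count matrix: the top base must be
# at least `min_ratio` times the runner-up (any positive count beats zero)
confident_base <- function(m, min_ratio) {
  m <- as.matrix(m)
  top_i <- max.col(m, ties.method = "first")
  top <- m[cbind(seq_len(nrow(m)), top_i)]
  rest <- m
  rest[cbind(seq_len(nrow(m)), top_i)] <- -1L
  second <- rest[cbind(seq_len(nrow(m)), max.col(rest, ties.method = "first"))]
  second <- pmax(second, 0L)
  ok <- top > 0 & top >= min_ratio * second
  ifelse(ok, colnames(m)[top_i], NA_character_)
}

#' Build the parental SNP table from per-position base counts
#'
#' A position enters the marker universe iff both parents have a confident
#' base (most common base at least `min_ratio` times more frequent than the
#' second most frequent; a runner-up count of zero is always confident when
#' any reads are present) and the two confident bases differ. Indels are
#' assumed excluded upstream.
#'
#' @param counts_p1,counts_p2 data.frames with columns `chrom`, `pos`, `A`,
#'   `C`, `G`, `T`: per-position nucleotide counts for each parent.
#' @param min_ratio confidence ratio (default 5).
#' @return data.frame with columns `chrom`, `pos`, `base_p1`, `base_p2`.
#' @export
build_parental_snp_table <- function(counts_p1, counts_p2, min_ratio = 5) {
  for (nmi in list(counts_p1, counts_p2)) {
    need <- c("chrom", "pos", "A", "C", "G", "T")
    if (!all(need %in% names(nmi))) {
      stop("parent count table must have columns: ",
           paste(need, collapse = ", "))
    }
    if (any(is.na(nmi$pos)) || any(nmi$pos < 1)) {
      stop("malformed position record at row ",
           which(is.na(nmi$pos) | nmi$pos < 1)[1])
    }
    key <- paste(nmi$chrom, nmi$pos)
    if (anyDuplicated(key)) {
      stop("duplicated position: ", key[duplicated(key)][1])
    }
    cm <- as.matrix(nmi[, c("A", "C", "G", "T")])
    if (any(is.na(cm)) || any(cm < 0)) {
      stop("malformed base counts (negative or missing)")
    }
  }
  k1 <- paste(counts_p1$chrom, counts_p1$pos)
  k2 <- paste(counts_p2$chrom, counts_p2$pos)
  common <- intersect(k1, k2)
  i1 <- match(common, k1); i2 <- match(common, k2)
  b1 <- confident_base(counts_p1[i1, c("A", "C", "G", "T")], min_ratio)
  b2 <- confident_base(counts_p2[i2, c("A", "C", "G", "T")], min_ratio)
  keep <- !is.na(b1) & !is.na(b2) & b1 != b2
  out <- data.frame(chrom = counts_p1$chrom[i1][keep],
                    pos = counts_p1$pos[i1][keep],
                    base_p1 = b1[keep], base_p2 = b2[keep],
                    stringsAsFactors = FALSE)
  out[order(out$chrom, out$pos), , drop = FALSE]
}

#' Call progeny genotypes from parental-base read counts
#'
#' At each marker a strain is assigned the genotype of whichever parent's
#' base is most frequent in its reads, provided that count is at least
#' `min_ratio` times the count of the other parental base; otherwise the
#' call is missing.
#'
#' @param counts an `allele_counts` object (matrices `reads_p1`,
#'   `reads_p2`, marker map).
#' @param snps optional parental SNP table from
#'   [build_parental_snp_table()]; when given, every marker in `counts`
#'   must be present in it (by `chrom_pos`).
#' @param min_ratio confidence ratio (default 5).
#' @return a [geno_matrix()] with per-strain pre-filter coverage counts.
#' @export
call_progeny_genotypes <- function(counts, snps = NULL, min_ratio = 5) {
  stopifnot(inherits(counts, "allele_counts"))
  r1 <- counts$reads_p1; r2 <- counts$reads_p2
  if (!is.null(snps)) {
    snp_key <- paste0(snps$chrom, "_", snps$pos)
    missing <- setdiff(counts$markers$marker, snp_key)
    if (length(missing)) {
      stop("markers absent from the parental SNP table: ",
           paste(utils::head(missing, 5), collapse = ", "))
    }
  }
  calls <- matrix(NA_character_, nrow(r1), ncol(r1), dimnames = dimnames(r1))
  calls[r1 > 0 & r1 >= min_ratio * r2] <- "P1"
  calls[r2 > 0 & r2 >= min_ratio * r1] <- "P2"
  geno_matrix(calls, counts$markers, has_reads = (r1 + r2) > 0)
}

#' Drop unreliable markers
#'
#' A marker is retained iff it has sequencing reads in at least
#' `min_strain_frac` of the strains and its P1:P2 call ratio lies within
#' `[1/max_ratio, max_ratio]` (inclusive). Markers with zero calls for
#' either parent fail the ratio test.
#'
#' @param G a `geno_matrix`.
#' @param min_strain_frac minimum fraction of strains with reads (default 0.05).
#' @param max_ratio maximum allele-call skew (default 2).
#' @return the filtered `geno_matrix`; dropped markers and reasons are
#'   appended to `$dropped_markers`.
#' @export
filter_markers <- function(G, min_strain_frac = 0.05, max_ratio = 2) {
  stopifnot(inherits(G, "geno_matrix"))
  frac <- colMeans(G$has_reads)
  n1 <- colSums(G$calls == "P1", na.rm = TRUE)
  n2 <- colSums(G$calls == "P2", na.rm = TRUE)
  ratio_ok <- n1 > 0 & n2 > 0 & (n1 / n2) >= 1 / max_ratio &
    (n1 / n2) <= max_ratio
  cov_ok <- frac >= min_strain_frac
  keep <- cov_ok & ratio_ok
  if (any(!keep)) {
    reason <- ifelse(!cov_ok, "low_coverage", "skewed_ratio")
    G$dropped_markers <- rbind(G$dropped_markers,
                               data.frame(marker = colnames(G$calls)[!keep],
                                          reason = reason[!keep],
                                          stringsAsFactors = FALSE))
    G$calls <- G$calls[, keep, drop = FALSE]
    G$has_reads <- G$has_reads[, keep, drop = FALSE]
    G$markers <- G$markers[keep, , drop = FALSE]
  }
  G
}

#' Drop unreliable or redundant strains
#'
#' Applies, in order and with reason codes: (a) `low_coverage` - reads at
#' fewer than `min_markers` marker positions, counted before marker
#' filtering; (b) `drug_double_resistant` - day-`drug_day` area above
#' `drug_area_cut` on both drug-marker plates; (c) `no_growth` - zero area
#' on the rich-medium condition at day `ypd_day`; (d) `near_duplicate` -
#' genotype identity above `similarity_threshold` (over markers called in
#' both strains) with an already-retained strain, scanning strains in
#' lexicographic order and keeping the first of each pair.
#'
#' @param G a `geno_matrix`.
#' @param pheno long phenotype data.frame (`strain`, `condition`, `day`,
#'   `area`); required for the drug and growth checks.
#' @param similarity_threshold genotype identity above which the later
#'   strain is dropped (default 0.90).
#' @param min_markers minimum covered marker positions (default 750, the
#'   scale of a full RAD-seq candidate-position panel).
#' @param drug_area_cut area (mm^2) above which growth on a drug plate
#'   counts as resistant (default 5).
#' @param checks which filters to run (default all four).
#' @param drug_conditions,drug_day the two drug-marker conditions and their
#'   assay day.
#' @param ypd_condition,ypd_day the rich-medium condition and its no-growth
#'   assay day.
#' @return the filtered `geno_matrix`; `$strains` keeps every input strain
#'   with its `retained` flag and drop `reason`.
#' @export
filter_strains <- function(G, pheno = NULL, similarity_threshold = 0.90,
                           min_markers = 750,
                           drug_area_cut = 5,
                           checks = c("coverage", "drug", "growth",
                                      "duplicate"),
                           drug_conditions = c("YPD+Kan", "YPD+Nat"),
                           drug_day = 2, ypd_condition = "YPD", ypd_day = 4) {
  stopifnot(inherits(G, "geno_matrix"))
  checks <- match.arg(checks, several.ok = TRUE)
  st <- G$strains
  active <- st$retained
  drop <- function(idx, code) {
    newly <- active & seq_along(active) %in% idx
    st$retained[newly] <<- FALSE
    st$reason[newly] <<- code
    active[newly] <<- FALSE
  }

  if ("coverage" %in% checks) {
    drop(which(st$n_covered < min_markers), "low_coverage")
  }
  if ("drug" %in% checks) {
    a1 <- cond_mean(pheno, drug_conditions[1], drug_day, st$strain)
    a2 <- cond_mean(pheno, drug_conditions[2], drug_day, st$strain)
    drop(which(!is.na(a1) & !is.na(a2) &
                 a1 > drug_area_cut & a2 > drug_area_cut),
         "drug_double_resistant")
  }
  if ("growth" %in% checks) {
    ay <- cond_mean(pheno, ypd_condition, ypd_day, st$strain)
    drop(which(!is.na(ay) & ay <= 0), "no_growth")
  }
  if ("duplicate" %in% checks) {
    ord <- order(st$strain)
    num <- matrix(match(G$calls, c("P1", "P2")), nrow = nrow(G$calls),
                  dimnames = dimnames(G$calls))
    kept_idx <- integer(0)
    for (i in ord) {
      if (!active[i]) next
      row_i <- match(st$strain[i], rownames(num))
      if (is.na(row_i)) next
      if (length(kept_idx)) {
        x <- num[row_i, ]
        K <- num[kept_idx, , drop = FALSE]
        both <- !is.na(x)[col(K)] & !is.na(K)
        same <- both & K == rep(x, each = nrow(K))
        shared <- rowSums(both)
        ident <- ifelse(shared > 0, rowSums(same) / shared, 0)
        if (any(ident > similarity_threshold)) {
          drop(i, "near_duplicate")
          next
        }
      }
      kept_idx <- c(kept_idx, row_i)
    }
  }

  keep <- rownames(G$calls) %in% st$strain[st$retained]
  G$strains <- st
  G$calls <- G$calls[keep, , drop = FALSE]
  G$has_reads <- G$has_reads[keep, , drop = FALSE]
  G
}

# per-strain mean area for one condition at one day; errors if absent
cond_mean <- function(pheno, condition, day, strains) {
  if (is.null(pheno)) {
    stop("phenotype table required for condition '", condition, "'")
  }
  sub <- pheno[pheno$condition == condition & pheno$day == day, , drop = FALSE]
  if (nrow(sub) == 0L) {
    stop("phenotype table has no data for condition '", condition,
         "' at day ", day)
  }
  m <- tapply(sub$area, sub$strain, mean)
  as.numeric(m[strains])
}

#' Per-strain mean phenotype for one condition
#'
#' @param pheno long phenotype data.frame.
#' @param condition condition name.
#' @param day assay day (default 4).
#' @return named numeric vector of mean areas (mm^2) per strain.
#' @export
strain_means <- function(pheno, condition, day = 4) {
  sub <- pheno[pheno$condition == condition & pheno$day == day, , drop = FALSE]
  if (nrow(sub) == 0L) {
    stop("no phenotype data for condition '", condition, "' at day ", day)
  }
  m <- tapply(sub$area, sub$strain, mean)
  setNames(as.numeric(m), names(m))
}
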