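#' Kruskal-Wallis LOD score at a single marker
#'
#' Rank-based association between a phenotype and a two-class genotype:
#' the Kruskal-Wallis statistic H (midranks for ties, tie-corrected
#' denominator) mapped to the LOD scale as `H / (2 ln 10)`, the standard
#' nonparametric single-QTL scan statistic. Strains with missing genotype
#' or phenotype are excluded; if either genotype class is then empty the
#' score is reported as 0 with attribute `degenerate = TRUE`.
#'
#' @param phenotype numeric vector of per-strain values (mm^2).
#' @param genotype parallel vector of `"P1"`/`"P2"`/`NA` calls.
#' @return LOD score (numeric scalar, >= 0); attribute `n_used` gives the
#'   number of strains entering the statistic.
#' @export
kw_lod <- function(phenotype, genotype) {
  stopifnot(length(phenotype) == length(genotype))
  ok <- !is.na(phenotype) & is.finite(phenotype) & genotype %in% c("P1", "P2")
  y <- phenotype[ok]
  g <- genotype[ok]
  n <- length(y)
  n1 <- sum(g == "P1")
  n2 <- n - n1
  if (n1 == 0L || n2 == 0L) {
    return(structure(0, degenerate = TRUE, n_used = n))
  }
  r <- rank(y)
  R1 <- sum(r[g == "P1"])
  R2 <- n * (n + 1) / 2 - R1
  H <- 12 / (n * (n + 1)) *
    (n1 * (R1 / n1 - (n + 1) / 2)^2 + n2 * (R2 / n2 - (n + 1) / 2)^2)
  t <- table(y)
  C <- 1 - sum(t^3 - t) / (n^3 - n)
  lod <- if (C <= 0) 0 else H / C / (2 * log(10))
  structure(lod, degenerate = FALSE, n_used = n)
}

# align a named phenotype vector with the rows of a geno_matrix
align_phenotype <- function(G, phenotype) {
  if (!is.null(names(phenotype))) {
    phenotype <- phenotype[match(rownames(G$calls), names(phenotype))]
  } else if (length(phenotype) != nrow(G$calls)) {
    stop("phenotype length does not match the number of strains")
  }
  as.numeric(phenotype)
}

#' Nonparametric single-locus genome scan
#'
#' Computes [kw_lod()] at every marker. The peak is the maximum-LOD marker,
#' ties broken by lowest chromosome (marker-map order) then position. When
#' `n_perm > 0` a genome-wide permutation threshold at level `alpha` is
#' attached (see [permutation_threshold()]).
#'
#' @param G a `geno_matrix` (filtered).
#' @param phenotype named numeric vector of per-strain values; names are
#'   matched to strains, otherwise positional.
#' @param n_perm number of permutations for the threshold (0 = none).
#' @param alpha genome-wide significance level (default 0.01).
#' @param seed optional integer seed for the permutations.
#' @return `scan_result`: data.frame (`marker`, `chrom`, `pos`, `lod`,
#'   `n_used`, `degenerate`) with attributes `peak`, `threshold`, `alpha`,
#'   `n_perm`, `seed`.
#' @export
genome_scan <- function(G, phenotype, n_perm = 0, alpha = 0.01, seed = NULL) {
  stopifnot(inherits(G, "geno_matrix"))
  if (ncol(G$calls) == 0L) stop("no markers to scan")
  y <- align_phenotype(G, phenotype)
  lods <- numeric(ncol(G$calls))
  nu <- integer(ncol(G$calls))
  dg <- logical(ncol(G$calls))
  for (j in seq_len(ncol(G$calls))) {
    l <- kw_lod(y, G$calls[, j])
    lods[j] <- l
    nu[j] <- attr(l, "n_used")
    dg[j] <- attr(l, "degenerate")
  }
  res <- data.frame(marker = G$markers$marker, chrom = G$markers$chrom,
                    pos = G$markers$pos, lod = lods, n_used = nu,
                    degenerate = dg, stringsAsFactors = FALSE)
  chrom_idx <- match(res$chrom, unique(G$markers$chrom))
  ord <- order(-res$lod, chrom_idx, res$pos)
  peak <- res$marker[ord[1]]
  thr <- NA_real_
  if (n_perm > 0) {
    thr <- permutation_threshold(G, y, n_perm = n_perm, alpha = alpha,
                                 seed = seed)
  }
  structure(res, class = c("scan_result", "data.frame"),
            peak = peak, threshold = as.numeric(thr), alpha = alpha,
            n_perm = n_perm, seed = seed)
}

#' @export
print.scan_result <- function(x, ...) {
  pk <- x[x$marker == attr(x, "peak"), ]
  cat(sprintf("Genome scan: %d markers; peak %s (LOD %.2f)\n",
              nrow(x), pk$marker, pk$lod))
  if (!is.na(attr(x, "threshold"))) {
    cat(sprintf("  permutation threshold (alpha=%g, n=%d): %.2f\n",
                attr(x, "alpha"), attr(x, "n_perm"), attr(x, "threshold")))
  }
  invisible(x)
}

#' Genome-wide permutation LOD threshold
#'
#' Shuffles the phenotype vector across strains, keeping genotype rows
#' intact (so the marker correlation structure is preserved), records the
#' genome-wide maximum LOD of each permutation, and returns the
#' `ceiling((1-alpha) * n_perm)`-th order statistic.
#'
#' @inheritParams genome_scan
#' @param n_perm number of permutations (>= 100).
#' @return numeric threshold; attribute `max_lods` holds the permutation
#'   null distribution of the genome-wide maximum.
#' @export
permutation_threshold <- function(G, phenotype, n_perm = 1000, alpha = 0.01,
                                  seed = NULL) {
  stopifnot(inherits(G, "geno_matrix"))
  if (n_perm < 100) stop("n_perm must be >= 100")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  y <- align_phenotype(G, phenotype)
  keep <- !is.na(y) & is.finite(y)
  y <- y[keep]
  gcode <- matrix(match(G$calls[keep, , drop = FALSE], c("P1", "P2")),
                  nrow = sum(keep))
  gcode[is.na(gcode)] <- 0L
  storage.mode(gcode) <- "integer"
  # dense integer rank keys: tied values share a key
  dr <- match(y, sort(unique(y)))
  if (!is.null(seed)) set.seed(seed)
  maxl <- kw_perm_max_cpp(dr, gcode, as.integer(n_perm))
  thr <- sort(maxl)[ceiling((1 - alpha) * n_perm)]
  structure(thr, max_lods = maxl, alpha = alpha, n_perm = n_perm)
}

#' Split-population secondary genome scans
#'
#' To expose minor-effect loci masked by a major-effect QTL, the mapping
#' population is split by the allele carried at `split_marker` (strains
#' with a missing call there are ignored) and each subset is scanned
#' independently, with its own permutation threshold at the
#' Bonferroni-adjusted level `alpha / n_tests`.
#'
#' @inheritParams genome_scan
#' @param split_marker marker id to condition on (typically the peak of the
#'   primary scan).
#' @param n_perm permutations per subset (default 1000).
#' @param n_tests Bonferroni correction count (default 12, e.g. 6
#'   conditions x 2 subsets).
#' @return list of two `scan_result`s named `P1` and `P2`.
#' @export
split_scan <- function(G, phenotype, split_marker, n_perm = 1000,
                       alpha = 0.01, n_tests = 12, seed = NULL) {
  stopifnot(inherits(G, "geno_matrix"))
  if (!split_marker %in% colnames(G$calls)) {
    stop("split marker not found: ", split_marker)
  }
  y <- align_phenotype(G, phenotype)
  allele <- G$calls[, split_marker]
  out <- list()
  for (a in c("P1", "P2")) {
    idx <- which(!is.na(allele) & allele == a)
    if (length(idx) == 0L) stop("no strains carry the ", a, " allele at ",
                                split_marker)
    if (length(idx) < 10L) {
      warning("subset ", a, " has fewer than 10 strains (",
              length(idx), ")")
    }
    Gs <- G
    Gs$calls <- G$calls[idx, , drop = FALSE]
    Gs$has_reads <- G$has_reads[idx, , drop = FALSE]
    Gs$strains <- G$strains[G$strains$strain %in% rownames(Gs$calls), ,
                            drop = FALSE]
    out[[a]] <- genome_scan(Gs, y[idx], n_perm = n_perm,
                            alpha = alpha / n_tests, seed = seed)
  }
  structure(out, class = "split_scan_result", split_marker = split_marker,
            n_tests = n_tests)
}

#' @export
print.split_scan_result <- function(x, ...) {
  cat(sprintf("Split scans at %s (Bonferroni n=%d)\n",
              attr(x, "split_marker"), attr(x, "n_tests")))
  for (a in names(x)) {
    cat(sprintf(" subset %s: ", a)); print(x[[a]])
  }
  invisible(x)
}

#' LOD profile plot
#'
#' @param x a `scan_result`.
#' @param ... passed to [plot()].
#' @export
plot.scan_result <- function(x, ...) {
  chroms <- unique(x$chrom)
  offs <- c(0, cumsum(tapply(x$pos, factor(x$chrom, levels = chroms),
                             max)))[seq_along(chroms)]
  gx <- x$pos + offs[match(x$chrom, chroms)]
  plot(gx, x$lod, type = "p", pch = 16, cex = 0.5,
       xlab = "genome coordinate (bp, chromosomes concatenated)",
       ylab = "LOD", ...)
  if (!is.na(attr(x, "threshold"))) {
    graphics::abline(h = attr(x, "threshold"), col = "red")
  }
  invisible(x)
}
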