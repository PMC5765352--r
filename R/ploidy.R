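#' Relative chromosome copy number and chromosome I disomy classification
#'
#' Estimates per-strain relative chromosome copy numbers from the
#' proportion of aligned reads per chromosome. For every chromosome except
#' chromosome I the proportion is normalized by its median across strains
#' (most strains assumed euploid). Chromosome I, which can segregate as a
#' disome in roughly half the progeny, is instead normalized by the
#' cross-strain mean proportion divided by 1.5 (the population mean under
#' 1:1 disome segregation is 1.5x the haploid value). Each strain is then
#' rescaled so its median copy number is exactly 1, and chromosome I is
#' classified: disome for values in \[1.5, 2.5\], euploid for \[0.5, 1.5),
#' unresolved outside \[0.5, 2.5\] (assumed sequencing artifacts).
#'
#' @param read_counts strain x chromosome matrix of aligned-read counts
#'   (rownames = strains, colnames = chromosomes).
#' @param chr1 name of the column holding chromosome I (default `"chrI"`).
#' @return object of class `ploidy_report`: `copy_number` matrix and
#'   per-strain `chr1_class` factor (`euploid`/`disome`/`unresolved`).
#' @export
relative_copy_number <- function(read_counts, chr1 = "chrI") {
  m <- as.matrix(read_counts)
  if (nrow(m) < 2L) stop("need read counts for at least 2 strains")
  if (is.null(rownames(m))) rownames(m) <- paste0("S", seq_len(nrow(m)))
  if (!chr1 %in% colnames(m)) stop("chromosome column '", chr1, "' not found")
  if (any(m < 0)) stop("negative read counts")
  tot <- rowSums(m)
  if (any(tot == 0)) {
    stop("strain with zero total reads: ",
         paste(rownames(m)[tot == 0], collapse = ", "))
  }
  p <- m / tot
  r <- p
  other <- setdiff(colnames(m), chr1)
  for (cn in other) r[, cn] <- p[, cn] / median(p[, cn])
  r[, chr1] <- p[, chr1] / (mean(p[, chr1]) / 1.5)
  med <- apply(r, 1, median)
  r <- r / med
  v <- r[, chr1]
  cls <- ifelse(v >= 1.5 & v <= 2.5, "disome",
                ifelse(v >= 0.5 & v < 1.5, "euploid", "unresolved"))
  structure(list(copy_number = r,
                 chr1_class = setNames(factor(cls, levels = c("euploid",
                                                              "disome",
                                                              "unresolved")),
                                       rownames(m)),
                 chr1 = chr1),
            class = "ploidy_report")
}

#' @export
print.ploidy_report <- function(x, ...) {
  tab <- table(x$chr1_class)
  cat(sprintf("Ploidy report: %d strains x %d chromosomes\n",
              nrow(x$copy_number), ncol(x$copy_number)))
  cat(sprintf("  %s classes: %s\n", x$chr1,
              paste(names(tab), tab, sep = "=", collapse = ", ")))
  invisible(x)
}
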