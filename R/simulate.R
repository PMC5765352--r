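#' Simulate progeny genotypes for a haploid two-parent cross
#'
#' Each progeny chromosome is a haploid mosaic of P1/P2 blocks generated
#' under the Haldane (no-interference, Poisson crossover) model: markers are
#' placed evenly along each chromosome's genetic map and the genotype
#' process switches parent between adjacent markers with probability
#' `r(d) = (1 - exp(-2d/100))/2` for map distance `d` cM. Chromosome I disomy
#' is an independent Bernoulli draw per progeny.
#'
#' @param params a [sim_params()] object.
#' @return object of class `sim_truth`: complete strain x marker genotype
#'   matrix (`"P1"`/`"P2"`), marker map, disome flags, snapped QTL effects,
#'   and per-strain expected phenotype means per condition.
#' @export
simulate_genotypes <- function(params) {
  validate_sim_params(params)
  set.seed(stage_seed(params$seed, 1L))
  ch <- params$chromosomes
  n <- params$n_progeny
  strains <- sprintf("S%04d", seq_len(n))

  marker_list <- lapply(seq_len(nrow(ch)), function(i) {
    m <- ch$n_markers[i]
    frac <- if (m == 1L) 0.5 else (seq_len(m) - 1) / (m - 1)
    pos_bp <- pmax(1L, as.integer(round(frac * (ch$len_bp[i] - 1))) + 1L)
    # enforce distinct physical positions on very short chromosomes
    while (anyDuplicated(pos_bp)) {
      pos_bp[duplicated(pos_bp)] <- pos_bp[duplicated(pos_bp)] + 1L
    }
    data.frame(marker = paste0(ch$name[i], "_", pos_bp),
               chrom = ch$name[i], pos = pos_bp,
               pos_cM = frac * ch$len_cM[i], stringsAsFactors = FALSE)
  })
  markers <- do.call(rbind, marker_list)
  rownames(markers) <- NULL

  # alternate alleles at each marker (used when emitting pileup-style counts)
  bases <- c("A", "C", "G", "T")
  b1 <- sample(bases, nrow(markers), replace = TRUE)
  b2 <- vapply(b1, function(b) sample(setdiff(bases, b), 1L), character(1))
  markers$base_p1 <- b1
  markers$base_p2 <- unname(b2)

  geno <- matrix(NA_integer_, nrow = n, ncol = nrow(markers),
                 dimnames = list(strains, markers$marker))
  col0 <- 0L
  for (i in seq_len(nrow(ch))) {
    m <- ch$n_markers[i]
    pos_cM <- marker_list[[i]]$pos_cM
    start <- rbinom(n, 1L, 0.5)
    if (m > 1L) {
      d <- diff(pos_cM)
      r <- 0.5 * (1 - exp(-2 * d / 100))
      sw <- matrix(rbinom(n * (m - 1L), 1L, rep(r, each = n)), nrow = n)
      cums <- sw
      if (m > 2L) for (j in 2:(m - 1L)) cums[, j] <- cums[, j - 1L] + cums[, j]
      g <- (start + cbind(0L, cums)) %% 2L
    } else {
      g <- matrix(start, ncol = 1L)
    }
    geno[, col0 + seq_len(m)] <- g + 1L
    col0 <- col0 + m
  }
  calls <- matrix(c("P1", "P2")[geno], nrow = n,
                  dimnames = dimnames(geno))

  disome <- setNames(runif(n) < params$disome_fraction, strains)

  qe <- snap_qtl_effects(params$qtl_effects, markers)
  em <- expected_means(calls, disome, qe, params)

  structure(list(genotypes = calls, markers = markers, strains = strains,
                 disome_flags = disome, qtl_effects = qe,
                 expected_means = em, chromosomes = ch, params = params),
            class = "sim_truth")
}

# snap each configured effect to the nearest marker on its chromosome
snap_qtl_effects <- function(qe, markers) {
  if (is.null(qe) || nrow(qe) == 0L) {
    return(cbind(qe, marker = character(0)))
  }
  qe$marker <- vapply(seq_len(nrow(qe)), function(i) {
    mk <- markers[markers$chrom == qe$chrom[i], ]
    if (nrow(mk) == 0L) stop("QTL effect on unknown chromosome: ", qe$chrom[i])
    mk$marker[which.min(abs(mk$pos - qe$pos[i]))]
  }, character(1))
  qe
}

expected_means <- function(calls, disome, qe, params) {
  cond <- params$conditions
  em <- matrix(rep(cond$baseline, each = nrow(calls)),
               nrow = nrow(calls),
               dimnames = list(rownames(calls), cond$condition))
  for (i in seq_len(nrow(qe))) {
    carrier <- calls[, qe$marker[i]] == qe$allele[i]
    em[carrier, qe$condition[i]] <- em[carrier, qe$condition[i]] + qe$effect[i]
  }
  de <- params$disome_effects
  for (cn in names(de)) {
    if (cn %in% colnames(em)) em[disome, cn] <- em[disome, cn] + de[[cn]]
  }
  em
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("Simulated cross: %d progeny x %d markers on %d chromosomes\n",
              nrow(x$genotypes), ncol(x$genotypes), nrow(x$chromosomes)))
  cat(sprintf("  chrI disomes: %d; conditions: %s\n",
              sum(x$disome_flags),
              paste(colnames(x$expected_means), collapse = ", ")))
  invisible(x)
}

#' Simulate marker allele counts for each progeny strain
#'
#' Per strain x marker, total depth is negative-binomial with mean
#' `mean_depth` (variance `mu + dispersion*mu^2`; Poisson when the
#' dispersion is 0). Reads report the parental base of the chromosome they
#' come from, flipped with probability `error_rate`. Chromosome I markers in
#' disomic strains have doubled expected depth; when the extra copy is
#' heterozygous (`disome_het`), reads split evenly between the two copies.
#'
#' @param truth a `sim_truth` from [simulate_genotypes()].
#' @param params the same [sim_params()] object.
#' @return object of class `allele_counts`: matrices `reads_p1`, `reads_p2`
#'   (strain x marker) and the marker map.
#' @export
simulate_allele_counts <- function(truth, params) {
  stopifnot(inherits(truth, "sim_truth"))
  set.seed(stage_seed(params$seed, 2L))
  calls <- truth$genotypes
  n <- nrow(calls); m <- ncol(calls)
  chrI <- truth$markers$chrom == "chrI"
  mult <- matrix(1, n, m)
  mult[truth$disome_flags, chrI] <- 2

  mu <- params$mean_depth * mult
  depth <- if (params$depth_dispersion > 0) {
    matrix(rnbinom(n * m, size = 1 / params$depth_dispersion, mu = mu),
           n, m)
  } else {
    matrix(rpois(n * m, lambda = mu), n, m)
  }

  e <- params$error_rate
  # reads supporting the resident copy's base
  own <- matrix(rbinom(n * m, depth, 1 - e), n, m)
  r1 <- ifelse(calls == "P1", own, depth - own)
  r2 <- depth - r1

  if (params$disome_het && any(truth$disome_flags)) {
    # heterozygous disome cells on chrI: resident recombinant copy is P2
    # there, extra copy is P1; each read picks a copy uniformly
    het <- matrix(FALSE, n, m)
    het[truth$disome_flags, chrI] <- calls[truth$disome_flags, chrI] == "P2"
    idx <- which(het)
    if (length(idx)) {
      d <- depth[idx]
      from_p1 <- rbinom(length(idx), d, 0.5)
      r1[idx] <- rbinom(length(idx), from_p1, 1 - e) +
        rbinom(length(idx), d - from_p1, e)
      r2[idx] <- d - r1[idx]
    }
  }
  dimnames(r1) <- dimnames(r2) <- dimnames(calls)
  structure(list(reads_p1 = r1, reads_p2 = r2, markers = truth$markers),
            class = "allele_counts")
}

#' Simulate per-position base counts for the two parent strains
#'
#' Emits pileup-style nucleotide count tables at the simulated marker
#' positions (plus sequencing error on the off bases), the input expected by
#' [build_parental_snp_table()].
#'
#' @inheritParams simulate_allele_counts
#' @param depth mean sequencing depth per position for the parents.
#' @return list of two data.frames (`p1`, `p2`) with columns
#'   `chrom`, `pos`, `A`, `C`, `G`, `T`.
#' @export
simulate_parent_counts <- function(truth, params, depth = 30) {
  stopifnot(inherits(truth, "sim_truth"))
  set.seed(stage_seed(params$seed, 4L))
  mk <- truth$markers
  e <- params$error_rate
  one_parent <- function(base) {
    d <- rpois(nrow(mk), depth)
    err <- rbinom(nrow(mk), d, e)
    out <- matrix(0L, nrow(mk), 4, dimnames = list(NULL, c("A", "C", "G", "T")))
    out[cbind(seq_len(nrow(mk)), match(base, colnames(out)))] <- d - err
    # errors land on a random other base
    if (any(err > 0)) {
      alt <- (match(base, colnames(out)) + sample(1:3, nrow(mk),
                                                  replace = TRUE) - 1L) %% 4L + 1L
      out[cbind(seq_len(nrow(mk)), alt)] <-
        out[cbind(seq_len(nrow(mk)), alt)] + err
    }
    cbind(mk[, c("chrom", "pos")], as.data.frame(out))
  }
  list(p1 = one_parent(mk$base_p1), p2 = one_parent(mk$base_p2))
}

#' Simulate replicate colony-area phenotypes
#'
#' Each replicate is `max(N(floor, floor_sd^2), mu + N(0, noise_sd^2))`
#' where `mu` is the strain's expected mean for the condition (baseline plus
#' allele-matched QTL and disome effects): censoring by a noisy growth floor
#' rather than truncation.
#'
#' @inheritParams simulate_allele_counts
#' @return long data.frame with columns `strain`, `condition`, `day`,
#'   `replicate`, `area` (mm^2).
#' @export
simulate_phenotypes <- function(truth, params) {
  stopifnot(inherits(truth, "sim_truth"))
  set.seed(stage_seed(params$seed, 3L))
  em <- truth$expected_means
  cond <- params$conditions
  nrep <- params$n_replicates
  n <- nrow(em)
  out <- vector("list", nrow(cond))
  for (i in seq_len(nrow(cond))) {
    mu <- rep(em[, cond$condition[i]], times = nrep)
    val <- mu + rnorm(n * nrep, 0, cond$noise_sd[i])
    fl <- rnorm(n * nrep, params$floor, params$floor_sd)
    out[[i]] <- data.frame(
      strain = rep(rownames(em), times = nrep),
      condition = cond$condition[i],
      day = cond$day[i],
      replicate = rep(seq_len(nrep), each = n),
      area = pmax(fl, val),
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Simulate a complete cross: genotypes, allele counts, and phenotypes
#'
#' @param params a [sim_params()] object.
#' @return list with elements `truth` (`sim_truth`), `counts`
#'   (`allele_counts`), `pheno` (long phenotype data.frame).
#' @export
simulate_cross <- function(params = sim_params()) {
  truth <- simulate_genotypes(params)
  counts <- simulate_allele_counts(truth, params)
  pheno <- simulate_phenotypes(truth, params)
  list(truth = truth, counts = counts, pheno = pheno)
}

#' Total aligned-read counts per strain and chromosome
#'
#' Sums marker read depth within chromosomes, the input for
#' [relative_copy_number()].
#'
#' @param counts an `allele_counts` object.
#' @return strain x chromosome matrix of read counts.
#' @export
chromosome_read_counts <- function(counts) {
  stopifnot(inherits(counts, "allele_counts"))
  depth <- counts$reads_p1 + counts$reads_p2
  chrom <- counts$markers$chrom
  out <- vapply(unique(chrom), function(cn) {
    rowSums(depth[, chrom == cn, drop = FALSE])
  }, numeric(nrow(depth)))
  out
}

#' Simulate whole-genome aligned-read totals per strain and chromosome
#'
#' Chromosome copy-number screens use all aligned reads, not just reads at
#' marker positions, so their per-chromosome totals are far less noisy than
#' summed marker depths. Reads per strain x chromosome are negative-binomial
#' with mean proportional to physical chromosome length times copy number
#' (2 for chromosome I in disomic strains); the mild overdispersion models
#' library-size and mappability variation.
#'
#' @inheritParams simulate_allele_counts
#' @param mean_reads mean total aligned reads per strain.
#' @param dispersion chromosome-level negative-binomial overdispersion
#'   (variance `mu + dispersion * mu^2`; 0 = Poisson).
#' @return strain x chromosome matrix of read counts.
#' @export
simulate_chromosome_reads <- function(truth, params, mean_reads = 2e5,
                                      dispersion = 5e-4) {
  stopifnot(inherits(truth, "sim_truth"))
  set.seed(stage_seed(params$seed, 5L))
  ch <- truth$chromosomes
  frac <- ch$len_bp / sum(ch$len_bp)
  n <- length(truth$strains)
  copy <- matrix(1, n, nrow(ch), dimnames = list(truth$strains, ch$name))
  copy[truth$disome_flags, ch$name == "chrI"] <- 2
  mu <- mean_reads * matrix(frac, n, nrow(ch), byrow = TRUE) * copy
  counts <- if (dispersion > 0) {
    rnbinom(n * nrow(ch), size = 1 / dispersion, mu = mu)
  } else {
    rpois(n * nrow(ch), lambda = mu)
  }
  matrix(counts, n, nrow(ch), dimnames = dimnames(copy))
}

#' Find the marker nearest a genomic coordinate
#'
#' @param markers marker map data.frame with `marker`, `chrom`, `pos`
#'   columns (e.g. `truth$markers` or `G$markers`).
#' @param chrom chromosome name.
#' @param pos 1-based physical position.
#' @return marker id (character).
#' @export
nearest_marker <- function(markers, chrom, pos) {
  mk <- markers[markers$chrom == chrom, ]
  if (nrow(mk) == 0L) stop("no markers on chromosome ", chrom)
  mk$marker[which.min(abs(mk$pos - pos))]
}
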