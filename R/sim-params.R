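#' Default chromosome configuration for a yeast cross simulation
#'
#' Sixteen nuclear chromosomes with physical lengths close to the
#' S. cerevisiae reference assembly and genetic lengths from a conventional
#' genome-wide average recombination rate, giving a map of roughly 4,400 cM.
#' Marker counts are allocated proportionally to physical length so that the
#' default panel is about `n_markers` markers genome-wide.
#'
#' @param n_markers target total marker count across the genome.
#' @param cM_per_kb average genetic-to-physical map ratio (cM per kb).
#' @return data.frame with columns `name`, `len_bp`, `len_cM`, `n_markers`.
#' @export
default_chromosomes <- function(n_markers = 537, cM_per_kb = 0.365) {
  kb <- c(230, 813, 317, 1532, 577, 270, 1091, 563, 440, 746,
          667, 1078, 924, 784, 1091, 948)
  roman <- c("I", "II", "III", "IV", "V", "VI", "VII", "VIII", "IX", "X",
             "XI", "XII", "XIII", "XIV", "XV", "XVI")
  nm <- pmax(3L, as.integer(round(n_markers * kb / sum(kb))))
  data.frame(
    name = paste0("chr", roman),
    len_bp = as.integer(kb * 1000),
    len_cM = round(kb * cM_per_kb, 1),
    n_markers = nm,
    stringsAsFactors = FALSE
  )
}

# Per-condition generative setup emulating the cross phenotypes: a
# major-effect locus per condition (plus condition-specific secondary loci),
# a shared panel of 12 minor "polygenic" loci whose summed variance sets the
# residual genetic variance, and replicate noise sized so that broad-sense
# heritability and the proportion of genetic variance explained by the major
# locus land at realistic values for this cross (H2 0.95-0.99, proportions
# 0.23-0.51). Effects are in mm^2 and apply to carriers of `allele`.
default_condition_setup <- function() {
  conditions <- data.frame(
    condition = c("YPD", "copper", "rapamycin", "caffeine",
                  "sodium", "ethanol", "SD"),
    baseline = c(25, 24, 25, 22, 20, 10, 20),
    noise_sd = c(4.30, 3.62, 2.63, 1.80, 2.50, 1.50, 2.00),
    bg_var   = c(67.8, 78.5, 75.0, 41.6, 20.0, 6.0, 2.0),
    day = 4L,
    stringsAsFactors = FALSE
  )

  major <- data.frame(
    chrom = c("chrXV", "chrXV", "chrXV", "chrX", "chrXV",
              "chrIV", "chrXV", "chrIX", "chrXV", "chrXV"),
    pos = c(643999L, 643999L, 643999L, 565000L, 643999L,
            527628L, 643999L, 409532L, 643999L, 643999L),
    condition = c("YPD", "copper", "rapamycin", "rapamycin", "caffeine",
                  "sodium", "sodium", "ethanol", "ethanol", "SD"),
    allele = c("P1", "P1", "P1", "P1", "P1",
               "P2", "P1", "P1", "P1", "P1"),
    effect = c(-9, -10.5, -18.7, -6, -12.4,
               -14, -3, -3.5, -2, -17),
    stringsAsFactors = FALSE
  )

  # shared minor-locus panel, one mid-chromosome locus on 12 chromosomes
  # that carry no major locus; alternating signs, magnitude per condition
  # solving sum(effect^2)/4 = bg_var
  bg_chrom <- c("chrII", "chrIII", "chrV", "chrVI", "chrVII", "chrVIII",
                "chrX", "chrXI", "chrXII", "chrXIII", "chrXIV", "chrXVI")
  bg_pos <- c(400000L, 160000L, 290000L, 135000L, 545000L, 280000L,
              300000L, 330000L, 540000L, 460000L, 390000L, 470000L)
  sgn <- rep(c(1, -1), 6)
  bg <- do.call(rbind, lapply(seq_len(nrow(conditions)), function(i) {
    mag <- 2 * sqrt(conditions$bg_var[i] / 12)
    data.frame(chrom = bg_chrom, pos = bg_pos,
               condition = conditions$condition[i],
               allele = "P1", effect = sgn * mag,
               stringsAsFactors = FALSE)
  }))

  list(conditions = conditions[, c("condition", "baseline", "noise_sd", "day")],
       qtl_effects = rbind(major, bg),
       disome_effects = c(caffeine = -2.54, ethanol = -1.05))
}

#' Simulation parameters for a synthetic haploid cross
#'
#' Bundles everything the simulator needs: the cross size, the genetic map,
#' planted QTL effects, phenotype noise and floor structure, sequencing
#' depth model, and chromosome I disomy. Defaults emulate the mapping
#' population of a sake x tecc style cross: 412 progeny, 16 chromosomes with
#' ~537 markers, seven growth conditions with a shared major-effect locus on
#' chrXV plus condition-specific loci, a chromosome I disome segregating at
#' 1:1, and colony areas censored by a hard growth floor.
#'
#' @param n_progeny number of haploid progeny strains.
#' @param chromosomes data.frame as from [default_chromosomes()].
#' @param qtl_effects data.frame with columns `chrom`, `pos`, `condition`,
#'   `allele` ("P1"/"P2") and `effect` (mm^2, added to carriers of `allele`);
#'   each row is snapped to the nearest simulated marker on its chromosome.
#' @param conditions data.frame with columns `condition`, `baseline` (mm^2),
#'   `noise_sd` (mm^2), `day`.
#' @param disome_effects named numeric, mm^2 added to chromosome I disomic
#'   strains per condition.
#' @param floor,floor_sd growth floor mean and noise (mm^2); observed areas
#'   are `max(N(floor, floor_sd^2), expected + N(0, noise_sd^2))`.
#' @param mean_depth mean sequencing reads per marker.
#' @param depth_dispersion negative-binomial overdispersion; depth variance
#'   is `mu + dispersion * mu^2` (0 = Poisson).
#' @param error_rate probability a read reports the wrong parental base.
#' @param disome_fraction probability a progeny carries an extra chromosome I.
#' @param disome_het if `TRUE` the extra chromosome I copy is a
#'   non-recombinant P1 chromosome (heterozygous wherever the resident copy
#'   is P2); if `FALSE` it duplicates the strain's own chromosome I.
#' @param n_replicates phenotype replicates per strain x condition.
#' @param seed integer master seed; stage substreams are derived from it.
#' @return object of class `sim_params`.
#' @export
sim_params <- function(n_progeny = 412L,
                       chromosomes = default_chromosomes(),
                       qtl_effects = NULL,
                       conditions = NULL,
                       disome_effects = NULL,
                       floor = 2,
                       floor_sd = 0.75,
                       mean_depth = 20,
                       depth_dispersion = 0.5,
                       error_rate = 0.002,
                       disome_fraction = 0.5,
                       disome_het = TRUE,
                       n_replicates = 4L,
                       seed = 1L) {
  setup <- default_condition_setup()
  if (is.null(qtl_effects)) {
    # default planted loci only make sense on chromosomes that exist in
    # this (possibly reduced) genome configuration
    qtl_effects <- setup$qtl_effects
    qtl_effects <- qtl_effects[qtl_effects$chrom %in% chromosomes$name, ,
                               drop = FALSE]
  }
  if (is.null(conditions)) conditions <- setup$conditions
  if (is.null(disome_effects)) disome_effects <- setup$disome_effects

  p <- list(n_progeny = as.integer(n_progeny), chromosomes = chromosomes,
            qtl_effects = qtl_effects, conditions = conditions,
            disome_effects = disome_effects, floor = floor,
            floor_sd = floor_sd, mean_depth = mean_depth,
            depth_dispersion = depth_dispersion, error_rate = error_rate,
            disome_fraction = disome_fraction, disome_het = disome_het,
            n_replicates = as.integer(n_replicates), seed = as.integer(seed))
  class(p) <- "sim_params"
  validate_sim_params(p)
  p
}

validate_sim_params <- function(p) {
  stopifnot(inherits(p, "sim_params"))
  if (p$n_progeny < 1L) stop("n_progeny must be >= 1")
  ch <- p$chromosomes
  need <- c("name", "len_bp", "len_cM", "n_markers")
  if (!all(need %in% names(ch))) {
    stop("chromosomes must have columns: ", paste(need, collapse = ", "))
  }
  if (any(ch$n_markers < 1L)) {
    stop("chromosome with zero markers: ",
         paste(ch$name[ch$n_markers < 1L], collapse = ", "))
  }
  if (any(ch$len_cM < 0)) stop("negative genetic length")
  if (anyDuplicated(ch$name)) stop("duplicated chromosome names")
  if (p$error_rate < 0 || p$error_rate >= 0.5) {
    stop("error_rate must be in [0, 0.5)")
  }
  if (p$floor < 0) stop("floor must be >= 0")
  if (any(p$conditions$noise_sd <= 0)) stop("noise_sd must be > 0")
  if (p$disome_fraction < 0 || p$disome_fraction > 1) {
    stop("disome_fraction must be in [0, 1]")
  }
  if (p$n_replicates < 1L) stop("n_replicates must be >= 1")
  if (p$mean_depth < 0) stop("mean_depth must be >= 0")
  if (p$depth_dispersion < 0) stop("depth_dispersion must be >= 0")
  invisible(p)
}

# Deterministic per-stage substream seeds derived from the master seed, so
# that e.g. regenerating phenotypes does not disturb the genotype stream.
stage_seed <- function(seed, stage) {
  as.integer((as.double(seed) * 48271 + stage * 7919) %% 2147483629)
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Synthetic cross parameters\n")
  cat(sprintf("  progeny: %d, chromosomes: %d, markers: %d\n",
              x$n_progeny, nrow(x$chromosomes), sum(x$chromosomes$n_markers)))
  cat(sprintf("  conditions: %s\n",
              paste(x$conditions$condition, collapse = ", ")))
  cat(sprintf("  planted QTL rows: %d; disome fraction %.2f; seed %d\n",
              nrow(x$qtl_effects), x$disome_fraction, x$seed))
  invisible(x)
}
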