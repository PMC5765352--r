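# Independent oracles used across the suite. These deliberately take the
# dumbest correct route (scalar loops, closed forms, exhaustive
# enumeration) and share no code with the package internals.

# tie-corrected Wilcoxon rank-sum chi-square on the LOD scale; for two
# groups this equals the Kruskal-Wallis statistic
oracle_ranksum_lod <- function(y, g) {
  ok <- !is.na(y) & g %in% c("P1", "P2")
  y <- y[ok]; g <- g[ok]
  n1 <- sum(g == "P1"); n2 <- sum(g == "P2"); N <- n1 + n2
  if (n1 == 0 || n2 == 0 || N < 2) return(0)
  r <- rank(y)
  R1 <- sum(r[g == "P1"])
  v <- n1 * n2 / (N * (N - 1)) * (sum(r^2) - N * (N + 1)^2 / 4)
  if (v <= 0) return(0)
  (R1 - n1 * (N + 1) / 2)^2 / v / (2 * log(10))
}

# scalar re-statement of the parental 5x confidence rule
oracle_confident_base <- function(counts, min_ratio = 5) {
  counts <- sort(unlist(counts), decreasing = TRUE)
  if (counts[1] == 0) return(NA_character_)
  if (counts[1] >= min_ratio * counts[2]) names(counts)[1] else NA_character_
}

# scalar re-statement of the progeny 5x call rule
oracle_call <- function(r1, r2, min_ratio = 5) {
  if (r1 > 0 && r1 >= min_ratio * r2) return("P1")
  if (r2 > 0 && r2 >= min_ratio * r1) return("P2")
  NA_character_
}

# exact two-sided Mann-Whitney p by enumeration of all group assignments
oracle_mw_exact_p <- function(x, y) {
  pool <- c(x, y)
  n1 <- length(x)
  u_of <- function(idx) {
    xs <- pool[idx]; ys <- pool[-idx]
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  }
  u_obs <- u_of(seq_len(n1))
  all_u <- combn(length(pool), n1, u_of)
  mu <- length(x) * length(y) / 2
  mean(abs(all_u - mu) >= abs(u_obs - mu) - 1e-9)
}

# small complete-genotype cross used by several scan tests
make_null_dataset <- function(n_strains, n_markers, seed,
                              n_chrom = 8, len_cM = 80) {
  ch <- data.frame(name = paste0("chr", as.roman(1:n_chrom)),
                   len_bp = 500000L, len_cM = len_cM,
                   n_markers = ceiling(n_markers / n_chrom),
                   stringsAsFactors = FALSE)
  ch$name[1] <- "chrI"
  p <- sim_params(n_progeny = n_strains, chromosomes = ch,
                  qtl_effects = data.frame(chrom = character(0),
                                           pos = integer(0),
                                           condition = character(0),
                                           allele = character(0),
                                           effect = numeric(0)),
                  disome_fraction = 0, seed = seed)
  truth <- simulate_genotypes(p)
  G <- geno_matrix(truth$genotypes, truth$markers[, c("marker", "chrom",
                                                      "pos")])
  set.seed(seed + 5000)
  list(G = G, y = setNames(rnorm(n_strains), rownames(truth$genotypes)),
       params = p, truth = truth)
}
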