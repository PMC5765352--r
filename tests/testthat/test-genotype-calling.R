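counts_df <- function(chrom, pos, A = 0, C = 0, G = 0, T = 0) {
  data.frame(chrom = chrom, pos = pos, A = A, C = C, G = G, T = T,
             stringsAsFactors = FALSE)
}

test_that("parental SNP table applies the 5x confidence rule on both parents", {
  p1 <- rbind(counts_df("chrI", 100, A = 10),
              counts_df("chrI", 200, A = 10, C = 3),
              counts_df("chrI", 300, A = 15, C = 3),
              counts_df("chrI", 400, G = 8))
  p2 <- rbind(counts_df("chrI", 100, C = 10),
              counts_df("chrI", 200, C = 10),
              counts_df("chrI", 300, C = 12),
              counts_df("chrI", 400, G = 20))
  snps <- build_parental_snp_table(p1, p2)
  # pos 100: clean difference; pos 200: P1 ambiguous (10 < 5*3);
  # pos 300: boundary 15 = 5*3 is confident; pos 400: same base
  expect_identical(snps$pos, c(100, 300))
  expect_identical(snps$base_p1, c("A", "A"))
  expect_identical(snps$base_p2, c("C", "C"))
})

test_that("SNP table construction matches a scalar rule-by-rule oracle", {
  set.seed(902)
  for (rep in 1:30) {
    n <- sample(3:20, 1)
    mk_counts <- function() {
      m <- matrix(rpois(4 * n, lambda = sample(c(0.5, 3, 10), 1)), n, 4)
      data.frame(chrom = "chrII", pos = seq_len(n) * 10,
                 A = m[, 1], C = m[, 2], G = m[, 3], T = m[, 4])
    }
    c1 <- mk_counts(); c2 <- mk_counts()
    got <- build_parental_snp_table(c1, c2)
    exp_rows <- Filter(Negate(is.null), lapply(seq_len(n), function(i) {
      b1 <- oracle_confident_base(c1[i, c("A", "C", "G", "T")])
      b2 <- oracle_confident_base(c2[i, c("A", "C", "G", "T")])
      if (!is.na(b1) && !is.na(b2) && b1 != b2) {
        data.frame(chrom = "chrII", pos = c1$pos[i], base_p1 = b1,
                   base_p2 = b2, stringsAsFactors = FALSE)
      }
    }))
    want <- if (length(exp_rows)) do.call(rbind, exp_rows) else
      data.frame(chrom = character(0), pos = numeric(0),
                 base_p1 = character(0), base_p2 = character(0))
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want)
  }
})

test_that("malformed parent tables are rejected with the position named", {
  good <- counts_df("chrI", 100, A = 10)
  bad <- counts_df("chrI", NA, A = 10)
  expect_error(build_parental_snp_table(bad, good), "position")
  dup <- rbind(counts_df("chrI", 5, A = 9), counts_df("chrI", 5, C = 9))
  expect_error(build_parental_snp_table(dup, good), "chrI 5")
})

make_counts <- function(r1, r2, chrom = "chrI", pos = NULL) {
  n <- nrow(r1)
  if (is.null(pos)) pos <- seq_len(ncol(r1)) * 100
  mk <- data.frame(marker = paste0(chrom, "_", pos), chrom = chrom,
                   pos = pos, stringsAsFactors = FALSE)
  dimnames(r1) <- dimnames(r2) <- list(sprintf("S%02d", seq_len(n)),
                                       mk$marker)
  structure(list(reads_p1 = r1, reads_p2 = r2, markers = mk),
            class = "allele_counts")
}

test_that("progeny calls follow the 5x rule, exhaustively vs enumeration", {
  # boundary examples
  cts <- make_counts(matrix(c(10, 4, 0, 5, 1), 5, 1),
                     matrix(c(1, 1, 0, 1, 0), 5, 1))
  G <- call_progeny_genotypes(cts)
  expect_identical(unname(G$calls[, 1]), c("P1", NA, NA, "P1", "P1"))

  # every count pair with total <= 12
  pairs <- expand.grid(r1 = 0:12, r2 = 0:12)
  pairs <- pairs[pairs$r1 + pairs$r2 <= 12, ]
  cts <- make_counts(matrix(pairs$r1, ncol = 1), matrix(pairs$r2, ncol = 1))
  G <- call_progeny_genotypes(cts)
  want <- mapply(oracle_call, pairs$r1, pairs$r2)
  expect_identical(unname(G$calls[, 1]), unname(want))
})

test_that("calling is symmetric under swapping the parent labels", {
  set.seed(913)
  r1 <- matrix(rpois(300, 4), 20, 15)
  r2 <- matrix(rpois(300, 4), 20, 15)
  Ga <- call_progeny_genotypes(make_counts(r1, r2))
  Gb <- call_progeny_genotypes(make_counts(r2, r1))
  swapped <- c(P1 = "P2", P2 = "P1")[Ga$calls]
  dim(swapped) <- dim(Ga$calls); dimnames(swapped) <- dimnames(Ga$calls)
  expect_identical(Gb$calls, swapped)
})

test_that("markers absent from the SNP table are rejected", {
  cts <- make_counts(matrix(5, 2, 2), matrix(0, 2, 2))
  snps <- data.frame(chrom = "chrI", pos = 100, base_p1 = "A",
                     base_p2 = "C")
  expect_error(call_progeny_genotypes(cts, snps), "chrI_200")
  snps2 <- rbind(snps, data.frame(chrom = "chrI", pos = 200,
                                  base_p1 = "G", base_p2 = "T"))
  expect_silent(call_progeny_genotypes(cts, snps2))
})

test_that("marker filter drops low-coverage and skewed markers, inclusively at 2:1", {
  set.seed(924)
  n <- 100
  calls <- matrix("P1", n, 4,
                  dimnames = list(sprintf("S%03d", 1:n),
                                  paste0("chrI_", 1:4 * 100)))
  calls[1:50, 1] <- "P2"                      # balanced: keep
  calls[, 2] <- c(rep("P1", 30), rep("P2", 15), rep(NA, 55))  # ratio 2.0: keep
  calls[, 3] <- c(rep("P1", 31), rep("P2", 15), rep(NA, 54))  # ratio > 2: drop
  calls[, 4] <- "P1"                          # no P2 calls: drop
  has_reads <- !is.na(calls)
  has_reads[5:100, 4] <- FALSE                # reads in 4% of strains
  mk <- data.frame(marker = colnames(calls), chrom = "chrI",
                   pos = 1:4 * 100, stringsAsFactors = FALSE)
  G <- filter_markers(geno_matrix(calls, mk, has_reads = has_reads))
  expect_identical(colnames(G$calls), c("chrI_100", "chrI_200"))
  expect_setequal(G$dropped_markers$marker, c("chrI_300", "chrI_400"))
  expect_identical(
    G$dropped_markers$reason[G$dropped_markers$marker == "chrI_400"],
    "low_coverage")
})

test_that("marker filter equals an independent two-rule oracle and is idempotent", {
  set.seed(935)
  for (rep in 1:20) {
    n <- 40; m <- 25
    r1 <- matrix(rpois(n * m, sample(c(0.2, 1, 6), 1)), n, m)
    r2 <- matrix(rpois(n * m, sample(c(0.2, 1, 6), 1)), n, m)
    G0 <- call_progeny_genotypes(make_counts(r1, r2))
    G1 <- filter_markers(G0)
    keep_oracle <- vapply(seq_len(m), function(j) {
      frac <- mean(r1[, j] + r2[, j] > 0)
      n1 <- sum(G0$calls[, j] == "P1", na.rm = TRUE)
      n2 <- sum(G0$calls[, j] == "P2", na.rm = TRUE)
      frac >= 0.05 && n1 > 0 && n2 > 0 && n1 <= 2 * n2 && n2 <= 2 * n1
    }, logical(1))
    expect_identical(as.character(colnames(G1$calls)),
                     colnames(G0$calls)[keep_oracle])
    G2 <- filter_markers(G1)
    expect_identical(G2$calls, G1$calls)
    expect_identical(G2$dropped_markers, G1$dropped_markers)
  }
})

planted_strain_fixture <- function() {
  set.seed(946)
  n_mark <- 800
  strains <- c("A01", "A02", "B01", "B02", "C01", "D01", "D02", "E01")
  calls <- matrix(sample(c("P1", "P2"), length(strains) * n_mark,
                         replace = TRUE),
                  nrow = length(strains),
                  dimnames = list(strains, paste0("chrI_", seq_len(n_mark))))
  calls["B02", ] <- calls["B01", ]           # exact duplicate of B01
  has_reads <- matrix(TRUE, length(strains), n_mark,
                      dimnames = dimnames(calls))
  has_reads["A02", 750:n_mark] <- FALSE      # 749 covered markers
  mk <- data.frame(marker = colnames(calls), chrom = "chrI",
                   pos = seq_len(n_mark), stringsAsFactors = FALSE)
  G <- geno_matrix(calls, mk, has_reads = has_reads)
  pheno <- rbind(
    data.frame(strain = strains, condition = "YPD+Kan", day = 2,
               replicate = 1, area = c(1, 1, 1, 1, 8, 1, 1, 9)),
    data.frame(strain = strains, condition = "YPD+Nat", day = 2,
               replicate = 1, area = c(9, 9, 1, 1, 7, 1, 1, 6)),
    data.frame(strain = strains, condition = "YPD", day = 4,
               replicate = 1, area = c(20, 20, 20, 20, 20, 0, 20, 20)))
  list(G = G, pheno = pheno)
}

test_that("strain filter recovers a planted drop set with its reason codes", {
  fx <- planted_strain_fixture()
  G <- filter_strains(fx$G, fx$pheno, min_markers = 750)
  st <- G$strains
  got <- setNames(st$reason, st$strain)
  expect_identical(got[["A02"]], "low_coverage")       # 749 < 750
  expect_identical(got[["B02"]], "near_duplicate")     # identical to B01
  expect_identical(got[["C01"]], "drug_double_resistant")
  expect_identical(got[["E01"]], "drug_double_resistant")
  expect_identical(got[["D01"]], "no_growth")
  expect_setequal(st$strain[st$retained], c("A01", "B01", "D02"))
  expect_identical(rownames(G$calls), c("A01", "B01", "D02"))

  # idempotence
  G2 <- filter_strains(G, fx$pheno, min_markers = 750)
  expect_identical(G2$calls, G$calls)
  expect_identical(G2$strains, G$strains)
})

test_that("strain filter names a missing phenotype condition", {
  fx <- planted_strain_fixture()
  ph <- fx$pheno[fx$pheno$condition != "YPD+Nat", ]
  expect_error(filter_strains(fx$G, ph, min_markers = 750), "YPD\\+Nat")
})

test_that("noiseless simulated counts reproduce the truth at every covered marker", {
  p <- sim_params(n_progeny = 60, error_rate = 0, mean_depth = 12,
                  depth_dispersion = 0, disome_fraction = 0, seed = 57)
  truth <- simulate_genotypes(p)
  G <- call_progeny_genotypes(simulate_allele_counts(truth, p))
  covered <- !is.na(G$calls)
  expect_identical(G$calls[covered], truth$genotypes[covered])
})
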