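test_that("quantile normalization preserves rank order and imputes the floor", {
  set.seed(120)
  v <- pmax(rnorm(150, 18, 5), rnorm(150, 2, 0.5))
  names(v) <- sprintf("S%03d", 1:150)
  out <- quantile_normalize_floored(v, floor_cut = 5)
  expect_identical(names(out), names(v))
  expect_identical(rank(out, ties.method = "average"),
                   rank(v, ties.method = "average"))
  # tied inputs map to tied outputs
  v2 <- c(v, v[3]); names(v2) <- c(names(v), "dup")
  out2 <- quantile_normalize_floored(v2)
  expect_equal(unname(out2["dup"]), unname(out2[3]))
  # an uncensored normal sample is approximately reproduced
  set.seed(121)
  w <- rnorm(300, 20, 4)
  ow <- quantile_normalize_floored(w, floor_cut = 5)
  expect_gt(cor(w, ow), 0.99)
  expect_lt(max(abs(sort(w) - sort(ow))), 2)
})

test_that("normalization recovers the latent normal parameters under censoring", {
  mus <- sigmas <- numeric(40)
  for (s in seq_len(40)) {
    set.seed(200 + s)
    v <- pmax(rnorm(200, 20, 4), rnorm(200, 2, 0.5))
    out <- quantile_normalize_floored(v, floor_cut = 5)
    mus[s] <- attr(out, "mu"); sigmas[s] <- attr(out, "sigma")
  }
  expect_lt(abs(mean(mus) - 20), 1)
  expect_lt(abs(mean(sigmas) - 4), 0.5)
})

test_that("degenerate normalization inputs are rejected", {
  expect_error(quantile_normalize_floored(c(rep(1, 30), rep(8, 5))),
               "at least 10")
  expect_error(quantile_normalize_floored(rep(20, 30)), "sigma")
})

rep_table <- function(means, noise_sd, n_rep, seed) {
  set.seed(seed)
  data.frame(strain = rep(names(means), each = n_rep),
             area = rep(means, each = n_rep) +
               rnorm(length(means) * n_rep, 0, noise_sd))
}

test_that("heritability is 1 when replicates agree exactly", {
  means <- setNames(seq(10, 30, length.out = 20), paste0("S", 1:20))
  d <- data.frame(strain = rep(names(means), each = 3),
                  area = rep(means, each = 3))
  vc <- heritability(d, method = "moments")
  expect_equal(vc$sigma2_w, 0)
  expect_equal(vc$H2, 1)
  expect_equal(vc$n_bar, 3)
})

test_that("heritability matches its closed-form expectation and both fitters agree", {
  h2 <- numeric(6)
  for (s in seq_len(6)) {
    set.seed(400 + s)
    means <- setNames(rnorm(200, 20, 3), sprintf("S%03d", 1:200))
    d <- rep_table(means, noise_sd = 1, n_rep = 4, seed = 500 + s)
    vr <- heritability(d, method = "reml")
    vm <- heritability(d, method = "moments")
    # balanced design: REML residual variance equals the pooled MSE
    expect_equal(vr$sigma2_w, vm$sigma2_w, tolerance = 1e-6)
    expect_equal(vr$H2, vm$H2, tolerance = 1e-6)
    h2[s] <- vr$H2
  }
  # sigma2_s ~ 9 + 1/4, sigma2_e = 1/4: H2 ~ 1 - 0.25/9.25
  expect_lt(abs(mean(h2) - (1 - 0.25 / 9.25)), 0.02)
})

test_that("heritability is invariant under affine rescaling", {
  means <- setNames(rnorm(100, 30, 4), sprintf("S%03d", 1:100))
  d <- rep_table(means, noise_sd = 1.5, n_rep = 3, seed = 9)
  v1 <- heritability(d)
  d2 <- d; d2$area <- 2 * d$area + 7
  v2 <- heritability(d2, min_area = 2 * 5 + 7)
  expect_equal(v2$H2, v1$H2, tolerance = 1e-6)
  expect_equal(v2$sigma2_w, 4 * v1$sigma2_w, tolerance = 1e-6)
})

test_that("heritability filters floor measurements and rejects degenerate input", {
  means <- setNames(rnorm(50, 20, 3), sprintf("S%03d", 1:50))
  d <- rep_table(means, noise_sd = 1, n_rep = 3, seed = 10)
  # floor junk below the cutoff must not change the within fit
  junk <- data.frame(strain = d$strain[1:30], area = runif(30, 0, 4.9))
  expect_equal(heritability(rbind(d, junk))$sigma2_w,
               heritability(d)$sigma2_w, tolerance = 1e-6)
  const <- data.frame(strain = rep(c("a", "b"), each = 2), area = rep(9, 4))
  expect_error(heritability(const), "zero variance")
  expect_error(heritability(d[1:2, ]), "fewer than 2 strains")
})

test_that("locus variance obeys the conservation identity and tracks the truth", {
  set.seed(77)
  al <- setNames(sample(c("P1", "P2"), 300, replace = TRUE),
                 sprintf("S%03d", 1:300))
  means <- setNames(ifelse(al == "P1", 10, 20) + rnorm(300, 0, 0.8),
                    names(al))
  d <- rep_table(means, noise_sd = 0.5, n_rep = 3, seed = 78)
  vc <- heritability(d)
  lv <- locus_variance(means, al, vc)
  expect_equal(lv$explained + lv$sigma2_ns, vc$sigma2_s, tolerance = 1e-9)
  # allele nearly determines the mean: most genetic variance explained
  expect_gt(lv$proportion_genetic, 0.95)
  expect_lt(lv$proportion_genetic, 1.05)

  # null locus: explained ~ 0, negative values reported with a warning
  al0 <- setNames(sample(al), names(al))
  expect_lt(abs(suppressWarnings(locus_variance(means, al0,
                                                vc))$explained) /
              vc$sigma2_s, 0.05)
  neg <- list(sigma2_s = 1, sigma2_e = 0.01, H2 = 0.9)
  class(neg) <- "variance_components"
  expect_warning(locus_variance(setNames(c(1, 2, 3, 4), letters[1:4]),
                                setNames(c("P1", "P2", "P1", "P2"),
                                         letters[1:4]), neg),
                 "negative explained")
  expect_error(locus_variance(means, setNames(rep("P1", 300), names(al)),
                              vc), "empty")
})

test_that("interaction ANOVA detects planted interactions and stays calibrated", {
  # near-deterministic balanced 2x2 with one deviant cell
  set.seed(90)
  allele <- rep(c("P1", "P2"), each = 40)
  additive <- rep(rep(c("no", "yes"), each = 20), 2)
  mu <- ifelse(allele == "P2" & additive == "yes", 20, 10)
  out <- interaction_anova(mu + rnorm(80, 0, 0.01), allele, additive)
  expect_gt(out$F, 1e4)
  expect_lt(out$p, 1e-10)

  # null: additive and allele effects only; p should be uniform
  set.seed(91)
  rejections <- 0
  for (s in 1:120) {
    a <- rep(c("P1", "P2"), each = 60)
    m <- rep(rep(c("no", "yes"), each = 30), 2)
    y <- 10 + 3 * (a == "P2") + 2 * (m == "yes") + rnorm(120, 0, 2)
    if (interaction_anova(y, a, m)$p < 0.05) rejections <- rejections + 1
  }
  expect_lte(rejections, qbinom(0.999, 120, 0.05))

  # power: allele effect doubles with the additive
  set.seed(92)
  detected <- 0
  for (s in 1:20) {
    a <- rep(c("P1", "P2"), each = 412)
    m <- rep(rep(c("no", "yes"), each = 206), 2)
    y <- 10 + 4 * (a == "P2") + 4 * (a == "P2") * (m == "yes") +
      rnorm(824, 0, 4)
    if (interaction_anova(y, a, m)$p < 0.01) detected <- detected + 1
  }
  expect_gte(detected, 18)

  expect_error(interaction_anova(1:3, c("P1", "P1", "P2"),
                                 c("no", "no", "no")), "empty design cell")
})

test_that("Mann-Whitney comparisons match exact enumeration and report mean shifts", {
  out <- group_difference_tests(c(1, 2, 3), c(4, 5, 6))
  expect_equal(out$U, 0)
  expect_equal(out$p, 0.1)
  expect_equal(out$p, oracle_mw_exact_p(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(out$mean_diff, -3)

  x <- c(2, 4, 9, 11, 3)
  y <- c(5, 8, 1, 12)
  expect_equal(group_difference_tests(x, y)$p, oracle_mw_exact_p(x, y))

  same <- c(3, 5, 8, 10, 14)
  out2 <- group_difference_tests(same, same)
  expect_equal(out2$mean_diff, 0)
  expect_gt(out2$p, 0.95)

  # large tied samples: tie-corrected normal approximation stays sane
  set.seed(13)
  xa <- sample(rep(1:5, 8)); xb <- sample(rep(1:5, 8))
  p <- group_difference_tests(xa, xb)$p
  expect_true(p > 0 && p <= 1)
  expect_error(group_difference_tests(numeric(0), 1:3), "non-empty")
})

test_that("condition correlations behave at the extremes and reject degeneracy", {
  a <- setNames(c(1, 5, 3, 8), letters[1:4])
  expect_equal(condition_correlation(a, a), 1)
  expect_equal(condition_correlation(a, -a), -1)
  b <- setNames(c(2, 1, 7, 9, 4), c("a", "b", "c", "d", "zz"))
  expect_equal(condition_correlation(a, b), cor(a, b[letters[1:4]]))
  expect_error(condition_correlation(a, setNames(rep(1, 4), letters[1:4])),
               "zero variance")
  expect_error(condition_correlation(a[1:2], a[1:2] * 2), "fewer than 3")
})
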