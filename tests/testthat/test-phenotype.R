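test_that("the indel crosstab books every accession exactly once", {
  calls <- data.frame(
    accession = sprintf("A%02d", 1:10),
    rc_score = c("1", "1", "1", "0", "1", "0", "0", "ambiguous", "1", "1"),
    stringsAsFactors = FALSE)
  colours <- stats::setNames(
    c(rep("red", 5), rep("white", 3), "purple", "brown"),
    sprintf("A%02d", 1:10))
  ct <- rc_crosstab(calls, colours)
  expect_equal(sum(ct$table), 10)
  expect_equal(ct$ambiguous, "A08")
  # percentages are within-score and exclude the ambiguous call
  expect_equal(unname(colSums(ct$pct_within_score)), c(100, 100))
  # discordant: pigmented with the deletion (score 0) or white without it;
  # only A04 (red, score 0) qualifies here
  expect_setequal(ct$discordant$accession, "A04")
  expect_length(ct$unmatched, 0)

  # unmatched ids are reported, not dropped silently
  ct2 <- rc_crosstab(calls[1:8, ], colours)
  expect_setequal(ct2$unmatched, c("A09", "A10"))
})

test_that("a perfectly concordant screen has empty discordance", {
  classes <- stats::setNames(c(rep("red", 30), rep("white", 10)),
                             sprintf("B%02d", 1:40))
  calls <- simulate_indel_calls(classes, concordance = 1, rng_seed = 2)
  ct <- rc_crosstab(calls, classes)
  expect_equal(nrow(ct$discordant), 0)
  expect_equal(unname(ct$table["white", "0"]), 10L)
  expect_equal(unname(ct$pct_within_score["white", "0"]), 100)
})

test_that("descriptive statistics match hand values", {
  tt <- data.frame(accession = c("a", "b", "c"),
                   colour_class = "red",
                   x = c(1, 2, 3), k = c(5, 5, 5),
                   stringsAsFactors = FALSE)
  d <- describe_traits(tt)
  x <- d[d$trait == "x", ]
  expect_equal(x$median, 2)
  expect_equal(x$mean, 2)
  expect_equal(x$sd, 1)
  expect_equal(x$cv, 0.5)
  expect_equal(x$range, 2)
  k <- d[d$trait == "k", ]
  expect_equal(k$cv, 0)
  expect_true(is.na(k$normal))
  expect_error(describe_traits(tt[1:2, ]), "3 accessions")
})

test_that("trait correlations recover trivial and generating structure", {
  tt <- data.frame(accession = letters[1:6], colour_class = "red",
                   u = 1:6, v = 2 * (1:6) + 3, w = -(1:6),
                   stringsAsFactors = FALSE)
  ct <- trait_correlations(tt)
  expect_equal(ct$r["u", "v"], 1)
  expect_equal(ct$r["u", "w"], -1)
  expect_equal(unname(diag(ct$r)), rep(1, 3))
  expect_true(isSymmetric(ct$r))

  # a known generating correlation is recovered at large n
  set.seed(7)
  n <- 4000
  z <- stats::rnorm(n)
  tt2 <- data.frame(accession = paste0("s", 1:n), colour_class = "red",
                    a = z, b = 0.8 * z + sqrt(1 - 0.64) * stats::rnorm(n),
                    stringsAsFactors = FALSE)
  ct2 <- trait_correlations(tt2)
  expect_lt(abs(ct2$r["a", "b"] - 0.8), 0.03)
  expect_lt(ct2$p["a", "b"], 1e-10)

  # degenerate traits are flagged, not silently zeroed
  tt$flat <- 1
  ct3 <- trait_correlations(tt)
  expect_true("flat" %in% attr(ct3, "degenerate"))
  expect_true(is.na(ct3$r["u", "flat"]))
})

test_that("two perfectly collinear traits load a single component", {
  tt <- data.frame(accession = letters[1:8], colour_class = "red",
                   p = 1:8, q = 3 * (1:8) - 1, stringsAsFactors = FALSE)
  pc <- trait_pca(tt)
  expect_equal(pc$pct_variance[1], 100)
  tt$flat <- 2
  expect_warning(pc2 <- trait_pca(tt), "constant")
  expect_equal(ncol(pc2$loadings), 2)
})

test_that("trait PCA on the simulated panel concentrates variance in few axes", {
  classes <- stats::setNames(
    sample(c("red", "purple", "white"), 200, replace = TRUE),
    sprintf("C%03d", 1:200))
  set.seed(3)
  tt <- simulate_traits(classes, rng_seed = 3)
  pc <- trait_pca(tt)
  expect_gt(sum(pc$pct_variance[1:3]), 60)
  expect_equal(nrow(pc$scores), 200)
  expect_equal(pc$scores$colour_class, unname(tt$colour_class))
})

test_that("the ANOVA degrees of freedom follow the class design", {
  classes <- stats::setNames(
    rep(c("red", "purple", "mixed", "white", "variable purple"),
        c(60, 50, 40, 30, 17)), sprintf("D%03d", 1:197))
  tt <- simulate_traits(classes, rng_seed = 5)
  a <- colour_anova(tt, "length")
  expect_equal(a$df, c(4, 192))
  expect_true(is.finite(a$F))
})

test_that("the F statistic is invariant to affine rescaling of the trait", {
  classes <- stats::setNames(rep(c("red", "white"), each = 25),
                             paste0("e", 1:50))
  tt <- simulate_traits(classes, rng_seed = 11)
  a1 <- colour_anova(tt, "width", transform = "none")
  tt$width <- 10 * tt$width + 100
  a2 <- colour_anova(tt, "width", transform = "none")
  expect_equal(a1$F, a2$F)
  expect_equal(a1$p, a2$p)
})

test_that("ANOVA matches the closed-form three-group computation", {
  y <- c(1, 2, 3, 4, 5, 6, 7, 8, 9)
  cl <- rep(c("red", "purple", "white"), each = 3)
  tt <- data.frame(accession = paste0("f", 1:9), colour_class = cl,
                   y = y, stringsAsFactors = FALSE)
  gm <- tapply(y, cl, mean)
  ssb <- sum(3 * (gm - mean(y))^2)
  ssw <- sum((y - gm[cl])^2)
  f_hand <- (ssb / 2) / (ssw / 6)
  a <- colour_anova(tt, "y", transform = "none")
  expect_equal(a$F, f_hand)
  expect_equal(a$df, c(2, 6))
  # Tukey table covers all 3 pairwise comparisons
  expect_equal(nrow(a$tukey), 3)
})

test_that("heteroscedastic traits are transformed, and post-hoc is withheld when that fails", {
  set.seed(21)
  n <- 40
  cl <- rep(c("red", "white"), each = n)
  # multiplicative noise: heteroscedastic raw, homoscedastic after log
  y <- exp(stats::rnorm(2 * n, mean = rep(c(2, 4), each = n), sd = 0.3))
  tt <- data.frame(accession = paste0("g", 1:(2 * n)), colour_class = cl,
                   y = y, stringsAsFactors = FALSE)
  a <- colour_anova(tt, "y")
  expect_equal(a$transform_applied, "log")
  expect_false(a$precluded)
  expect_false(is.null(a$tukey))

  # variance heterogeneity that log cannot fix: post-hoc withheld
  set.seed(22)
  y2 <- c(stats::rnorm(n, 50, 0.1), stats::rnorm(n, 50, 25))
  y2 <- pmax(y2, 0.1)
  tt2 <- data.frame(accession = paste0("h", 1:(2 * n)), colour_class = cl,
                    y = y2, stringsAsFactors = FALSE)
  a2 <- colour_anova(tt2, "y")
  expect_true(a2$precluded)
  expect_null(a2$tukey)
})

test_that("singleton classes are dropped with a warning and inputs validated", {
  classes <- stats::setNames(c(rep("red", 10), rep("white", 10), "mixed"),
                             paste0("i", 1:21))
  tt <- simulate_traits(classes, rng_seed = 31)
  expect_warning(a <- colour_anova(tt, "area", transform = "none"),
                 "single member")
  expect_equal(a$dropped_classes, "mixed")
  expect_equal(a$df, c(1, 18))
  expect_error(colour_anova(tt, "no_such_trait"), "unknown trait")
})

test_that("the gate holds its nominal type-I error on null data", {
  # positive-valued null: both classes share one distribution, so the
  # rejection rate at alpha = 0.05 must sit near 0.05
  set.seed(41)
  cl <- rep(c("red", "white"), each = 20)
  p <- vapply(1:400, function(i) {
    y <- stats::rnorm(40, mean = 10, sd = 1)
    tt <- data.frame(accession = paste0("j", 1:40), colour_class = cl,
                     y = y, stringsAsFactors = FALSE)
    colour_anova(tt, "y")$p
  }, numeric(1))
  rate <- mean(p < 0.05)
  expect_gt(rate, 0.02)
  expect_lt(rate, 0.09)
})
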