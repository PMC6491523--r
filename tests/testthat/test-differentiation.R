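# independent check of the Weir-Cockerham components: nested ANOVA on allele
# copies fitted with stats::aov, components recovered from the expected mean
# squares. Used to validate wc_fst on data with missing calls.
.aov_theta <- function(gm, group_labels, pair) {
  keep <- group_labels %in% pair
  d <- gm$dosage[keep, , drop = FALSE]
  gl <- group_labels[keep]
  num <- 0; den <- 0
  for (loc in seq_len(ncol(d))) {
    x <- d[, loc]
    use <- !is.na(x)
    n_g <- table(gl[use])
    if (length(n_g) < 2 || any(n_g < 2)) next
    x <- x[use]; g <- factor(gl[use])
    # copy 1 carries the alt allele when dosage >= 1; copy 2 when dosage == 2
    y <- c(as.numeric(x >= 1L), as.numeric(x == 2L))
    id <- factor(rep(seq_along(x), 2))
    gg <- factor(rep(as.character(g), 2))
    fit <- stats::aov(y ~ gg + Error(id))
    msp <- summary(fit)[[1]][[1]]["gg", "Mean Sq"]
    msi <- summary(fit)[[1]][[1]]["Residuals", "Mean Sq"]
    msw <- summary(fit)[[2]][[1]]["Residuals", "Mean Sq"]
    n_i <- as.numeric(n_g)
    nbar <- mean(n_i)
    nc <- (sum(2 * n_i) - sum((2 * n_i)^2) / sum(2 * n_i)) / (length(n_i) - 1)
    a <- (msp - msi) / nc
    b <- (msi - msw) / 2
    cc <- msw
    if (!is.finite(a + b + cc) || (a + b + cc) == 0) next
    num <- num + a
    den <- den + a + b + cc
  }
  num / den
}

test_that("theta matches closed-form extremes", {
  # two groups fixed for opposite alleles: theta = 1
  d <- rbind(a1 = c(0L, 0L), a2 = c(0L, 0L),
             b1 = c(2L, 2L), b2 = c(2L, 2L))
  gm <- toy_panel(d, groups = c("A", "A", "B", "B"))
  f <- wc_fst(gm, group_labels(gm, "subspecies"), c("A", "B"))
  expect_equal(f$theta, 1)

  # a group compared to a copy of itself: theta approximately 0 (can be
  # slightly negative, which the estimator must not clamp away)
  sim <- two_group_panel(n_per_group = 80, n_markers = 600, F = 0,
                         selfing = 0, missing = 0, seed = 61)
  gl <- group_labels(sim$panel, "subspecies")
  f0 <- wc_fst(sim$panel, gl, c("A", "B"))
  expect_lt(abs(f0$theta), 0.03)
})

test_that("wc_fst agrees with an independent aov-based oracle", {
  sim <- two_group_panel(n_per_group = 15, n_markers = 40, F = 0.3,
                         selfing = 2, missing = 0.08, seed = 71)
  gl <- group_labels(sim$panel, "subspecies")
  mine <- wc_fst(sim$panel, gl, c("A", "B"))$theta
  oracle <- .aov_theta(sim$panel, gl, c("A", "B"))
  expect_equal(mine, oracle, tolerance = 1e-10)
})

test_that("theta is invariant to group label names and accession order", {
  sim <- two_group_panel(n_per_group = 25, n_markers = 200, F = 0.2,
                         seed = 83)
  gm <- sim$panel
  gl <- group_labels(gm, "subspecies")
  t1 <- wc_fst(gm, gl, c("A", "B"))$theta
  # swap the pair order
  expect_equal(wc_fst(gm, gl, c("B", "A"))$theta, t1)
  # rename groups
  gl2 <- ifelse(gl == "A", "zzz", "aaa")
  expect_equal(wc_fst(gm, gl2, c("aaa", "zzz"))$theta, t1)
  # permute accessions
  set.seed(4)
  perm <- sample(nrow(gm$dosage))
  expect_equal(wc_fst(gm_subset(gm, accessions = perm), gl[perm],
                      c("A", "B"))$theta, t1)
})

test_that("the pairwise matrix is symmetric and consistent with wc_fst", {
  cfg <- panel_config(n_markers = 300, groups = data.frame(
    group = c("A", "B", "C"), n = c(20, 25, 30), F = c(0.1, 0.3, 0.5)),
    selfing_generations = 3, n_duplicates = 0, missing_rate = 0.03,
    rng_seed = 90)
  sim <- simulate_panel(cfg)
  gl <- sim$truth$group
  fm <- fst_matrix(sim$panel, gl)
  expect_true(isSymmetric(fm$theta))
  expect_equal(fm$theta["A", "B"],
               wc_fst(sim$panel, gl, c("A", "B"))$theta)
  expect_equal(fm$mean_fst, mean(fm$theta[upper.tri(fm$theta)]))
  # more diverged pairs are more differentiated
  expect_gt(fm$theta["A", "C"], fm$theta["A", "B"])
})

test_that("AMOVA degrees of freedom follow the nested design", {
  expect_equal(unname(amova_df(307, 3)), c(2L, 304L, 307L, 613L))
  expect_equal(unname(amova_df(417, 5)), c(4L, 412L, 417L, 833L))
  df <- amova_df(100, 4)
  expect_equal(sum(df[1:3]), df[["total"]])
})

test_that("percentage arithmetic reproduces published-style tables", {
  # the printed components are rounded to one decimal, so the middle share
  # can differ from the printed percentage by up to ~0.06 points
  expect_lt(max(abs(amova_percentages(c(161.7, 161.1, 20.3)) -
                      c(47.1, 46.9, 5.9))), 0.06)
  expect_equal(round(amova_percentages(c(28.1, 226.7, 20.3)), 1),
               c(10.2, 82.4, 7.4))
  expect_equal(round(amova_percentages(c(43.30, 230.10, 17.75)), 2),
               c(14.87, 79.03, 6.10))
  expect_equal(sum(amova_percentages(c(3, -1, 9))), 100)
})

test_that("the AMOVA table is internally consistent", {
  sim <- two_group_panel(n_per_group = 40, n_markers = 300, F = 0.4,
                         selfing = 4, missing = 0.04, seed = 101)
  tab <- amova(sim$panel, group_labels(sim$panel, "subspecies"))
  expect_s3_class(tab, "amova_table")
  expect_equal(tab$df, c(1L, 78L, 80L, 159L))
  expect_equal(tab$MS[1:3], tab$SS[1:3] / tab$df[1:3])
  expect_equal(tab$SS[4], sum(tab$SS[1:3]))
  expect_equal(sum(tab$pct[1:3]), 100)
  expect_equal(tab$variance[4], sum(tab$variance[1:3]))
  # strongly diverged selfing groups: most variation between groups and
  # among accessions, little within
  expect_lt(tab$pct[3], 15)
  expect_gt(tab$pct[1], 20)
})

test_that("AMOVA between-group share vanishes for a panmictic panel", {
  cfg <- panel_config(n_markers = 400, groups = data.frame(
    group = "A", n = 120, F = 0), selfing_generations = 0,
    n_duplicates = 0, missing_rate = 0, rng_seed = 111)
  gm <- simulate_panel(cfg)$panel
  fake <- rep(c("x", "y"), length.out = 120)
  tab <- amova(gm, fake, n_perm = 99, rng_seed = 2)
  expect_lt(abs(tab$pct[1]), 2)
  expect_gt(attr(tab, "p_between"), 0.05)
})

test_that("AMOVA detects real structure via the permutation test", {
  sim <- two_group_panel(n_per_group = 30, n_markers = 200, F = 0.4,
                         selfing = 3, seed = 121)
  tab <- amova(sim$panel, group_labels(sim$panel, "subspecies"),
               n_perm = 99, rng_seed = 3)
  expect_equal(attr(tab, "p_between"), 0.01)
})

test_that("AMOVA agrees with two-group theta in direction and scale", {
  sim <- two_group_panel(n_per_group = 50, n_markers = 500, F = 0.3,
                         selfing = 0, missing = 0, seed = 131)
  gl <- group_labels(sim$panel, "subspecies")
  theta <- wc_fst(sim$panel, gl, c("A", "B"))$theta
  tab <- amova(sim$panel, gl)
  phi <- tab$variance[1] / tab$variance[4]
  expect_equal(phi, theta, tolerance = 0.02)
})

test_that("singleton groups are merged with a warning or rejected when strict", {
  sim <- two_group_panel(n_per_group = 20, n_markers = 100, seed = 141)
  gl <- group_labels(sim$panel, "subspecies")
  gl[1] <- "stray"
  expect_warning(tab <- amova(sim$panel, gl), "unassigned")
  expect_equal(tab$df[1], 2L)  # A, B, unassigned
  expect_error(amova(sim$panel, gl, strict = TRUE), "size 1")
})
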