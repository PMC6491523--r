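#' Weir-Cockerham multilocus FST (theta) for one group pair
#'
#' Computes the per-locus variance components a (among populations), b
#' (among individuals within populations) and c (within individuals) of the
#' Weir & Cockerham (1984) estimator for two populations, and returns the
#' multilocus ratio-of-sums estimate `theta = sum(a) / sum(a + b + c)`.
#' Loci where either group has fewer than 2 genotyped members, or where the
#' denominator is undefined (monomorphic overall), are skipped and counted.
#' Values are not clamped: small negative estimates are legitimate for
#' undifferentiated groups.
#'
#' @param gm a [genotype_matrix]
#' @param group_labels group id per accession.
#' @param pair character vector of two group ids.
#' @return a list with `theta`, `n_loci_used`, `n_loci_skipped` and the
#'   per-locus component matrix `components` (columns `a`, `b`, `c`).
#' @export
wc_fst <- function(gm, group_labels, pair) {
  stopifnot(length(pair) == 2)
  i1 <- group_labels == pair[1]
  i2 <- group_labels == pair[2]
  if (sum(i1) < 2 || sum(i2) < 2)
    stop("both groups need at least 2 accessions")
  d1 <- gm$dosage[i1, , drop = FALSE]
  d2 <- gm$dosage[i2, , drop = FALSE]

  n1 <- colSums(!is.na(d1)); n2 <- colSums(!is.na(d2))
  p1 <- colMeans(d1, na.rm = TRUE) / 2
  p2 <- colMeans(d2, na.rm = TRUE) / 2
  h1 <- colMeans(d1 == 1L, na.rm = TRUE)
  h2 <- colMeans(d2 == 1L, na.rm = TRUE)

  r <- 2
  nbar <- (n1 + n2) / 2
  nc <- 2 * nbar - (n1^2 + n2^2) / (2 * nbar)
  pbar <- (n1 * p1 + n2 * p2) / (2 * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (2 * nbar)

  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2

  usable <- n1 >= 2 & n2 >= 2 & is.finite(a) & is.finite(b) & is.finite(cc) &
    (a + b + cc) != 0
  if (sum(usable) < 2)
    stop("fewer than 2 usable loci for the pair ",
         pair[1], " / ", pair[2])
  theta <- sum(a[usable]) / sum(a[usable] + b[usable] + cc[usable])
  list(theta = theta,
       n_loci_used = sum(usable),
       n_loci_skipped = sum(!usable),
       components = cbind(a = a, b = b, c = cc))
}

#' Pairwise FST matrix over all groups
#'
#' Runs [wc_fst()] for every pair of groups with at least 2 members and
#' reports the symmetric theta matrix plus the mean off-diagonal value (the
#' average differentiation over all groups). Groups with fewer than 2
#' members are skipped with a warning.
#'
#' @inheritParams wc_fst
#' @return an object of class `fst_matrix`: list with `theta` (symmetric
#'   matrix, `NA` diagonal), `n_loci` (per-pair usable locus counts) and
#'   `mean_fst`.
#' @export
fst_matrix <- function(gm, group_labels) {
  tab <- table(group_labels)
  small <- names(tab)[tab < 2]
  if (length(small) > 0)
    warning("skipping group(s) with < 2 members: ",
            paste(small, collapse = ", "))
  groups <- names(tab)[tab >= 2]
  k <- length(groups)
  if (k < 2) stop("need at least 2 groups with >= 2 members")
  theta <- matrix(NA_real_, k, k, dimnames = list(groups, groups))
  nl <- matrix(NA_integer_, k, k, dimnames = list(groups, groups))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      f <- wc_fst(gm, group_labels, c(groups[i], groups[j]))
      theta[i, j] <- theta[j, i] <- f$theta
      nl[i, j] <- nl[j, i] <- f$n_loci_used
    }
  }
  structure(list(theta = theta, n_loci = nl,
                 mean_fst = mean(theta[upper.tri(theta)])),
            class = "fst_matrix")
}

#' @export
print.fst_matrix <- function(x, ...) {
  cat("Pairwise Weir-Cockerham FST over", nrow(x$theta), "groups; mean =",
      round(x$mean_fst, 4), "\n")
  print(round(x$theta, 4))
  invisible(x)
}

#' AMOVA degrees of freedom
#'
#' For `N` diploid accessions in `G` groups with a within-accession stratum:
#' between groups `G - 1`, among accessions within groups `N - G`, within
#' accessions `N` (one independent contrast between the two allele copies of
#' each accession), total `2N - 1`.
#'
#' @param N number of accessions.
#' @param G number of groups.
#' @return named integer vector `c(between, among_within, within, total)`.
#' @export
amova_df <- function(N, G) {
  c(between = as.integer(G - 1),
    among_within = as.integer(N - G),
    within = as.integer(N),
    total = as.integer(2 * N - 1))
}

#' Percentage of variation from AMOVA variance components
#'
#' The reporting arithmetic of an AMOVA table: each variance component as a
#' percentage of the component total. Negative components are retained.
#'
#' @param components numeric vector of variance components (between groups,
#'   among accessions within groups, within accessions).
#' @return numeric vector of percentages summing to 100.
#' @export
amova_percentages <- function(components) {
  100 * components / sum(components)
}

#' Hierarchical analysis of molecular variance (three strata)
#'
#' Distance-based AMOVA on allele-copy data for unphased diploid SNP
#' genotypes. Each accession contributes two allele copies per locus
#' (dosage 0 -> 0,0; 1 -> 0,1; 2 -> 1,1), and squared Euclidean allele-copy
#' differences summed over loci are exactly the sums of squares of a nested
#' ANOVA with strata: between groups / among accessions within groups /
#' within accessions. Sums of squares are accumulated per locus over
#' non-missing calls; degrees of freedom follow [amova_df()] on the full
#' design. Variance components come from the expected mean squares
#' (within-accession copies occur in pairs, so the among-accession
#' coefficient is 2; the between-group coefficient uses the standard
#' unequal-group-size correction). Negative components are retained and
#' flagged, not truncated.
#'
#' @param gm a [genotype_matrix]
#' @param group_labels group id per accession; groups of size 1 are merged
#'   into `"unassigned"` with a warning (or rejected when `strict = TRUE`).
#' @param strict reject singleton groups instead of merging.
#' @param n_perm permutations for a between-group p-value (0 = off).
#' @param rng_seed seed for the permutation test.
#' @return an object of class `amova_table`: a data.frame with one row per
#'   stratum (`source`, `df`, `SS`, `MS`, `variance`, `pct`) plus a `Total`
#'   row, with attributes `negative_components` and (if requested) `p_between`.
#' @export
amova <- function(gm, group_labels, strict = FALSE, n_perm = 0,
                  rng_seed = 1L) {
  group_labels <- as.character(group_labels)
  tab <- table(group_labels)
  if (any(tab < 2)) {
    if (strict) stop("group(s) of size 1: ",
                     paste(names(tab)[tab < 2], collapse = ", "))
    warning("merging singleton group(s) into 'unassigned': ",
            paste(names(tab)[tab < 2], collapse = ", "))
    group_labels[group_labels %in% names(tab)[tab < 2]] <- "unassigned"
  }
  if (length(unique(group_labels)) < 2)
    stop("need at least 2 groups of >= 2 accessions")

  ss <- .amova_ss(gm$dosage, group_labels)
  N <- nrow(gm$dosage)
  G <- length(unique(group_labels))
  df <- amova_df(N, G)
  MS <- ss / df[1:3]

  n_g <- as.numeric(table(group_labels))
  # EMS coefficient for the between-group component on allele copies
  n0 <- (2 * N - sum((2 * n_g)^2) / (2 * N)) / (G - 1)
  sig_c <- MS[3]
  sig_b <- (MS[2] - MS[3]) / 2
  sig_a <- (MS[1] - MS[2]) / n0
  comp <- c(sig_a, sig_b, sig_c)
  pct <- amova_percentages(comp)

  out <- data.frame(
    source = c("Between groups", "Between accessions within groups",
               "Within accessions", "Total"),
    df = as.integer(df),
    SS = c(ss, sum(ss)),
    MS = c(MS, sum(ss) / df[4]),
    variance = c(comp, sum(comp)),
    pct = c(pct, 100),
    stringsAsFactors = FALSE)
  attr(out, "negative_components") <- any(comp < 0)

  if (n_perm > 0) {
    set.seed(rng_seed)
    obs <- sig_a
    ge <- 1L
    for (b in seq_len(n_perm)) {
      gl <- sample(group_labels)
      ssb <- .amova_ss(gm$dosage, gl)
      msb <- ssb / df[1:3]
      if ((msb[1] - msb[2]) / n0 >= obs) ge <- ge + 1L
    }
    attr(out, "p_between") <- ge / (n_perm + 1)
  }
  class(out) <- c("amova_table", "data.frame")
  out
}

# nested sums of squares on allele copies, accumulated over loci with
# missing calls dropped per locus
.amova_ss <- function(dosage, group_labels) {
  groups <- unique(group_labels)
  ss_w <- 0; ss_a <- 0; ss_b <- 0
  m <- dosage / 2            # individual allele-copy means
  ok <- !is.na(dosage)
  # within accessions: each het contributes 2 * (1/2)^2 = 1/2
  ss_w <- sum(dosage == 1L, na.rm = TRUE) * 0.5

  # per-locus group means and grand means over non-missing calls
  for (loc in seq_len(ncol(dosage))) {
    mi <- m[, loc]
    use <- ok[, loc]
    if (!any(use)) next
    gl <- group_labels[use]
    mi <- mi[use]
    gmean <- tapply(mi, gl, mean)
    ngl <- tapply(mi, gl, length)
    grand <- sum(gmean * ngl) / sum(ngl)
    ss_a <- ss_a + sum(2 * (mi - gmean[gl])^2)
    ss_b <- ss_b + sum(2 * ngl * (gmean - grand)^2)
  }
  c(between = ss_b, among_within = ss_a, within = ss_w)
}

#' @export
print.amova_table <- function(x, ...) {
  cat("AMOVA\n")
  y <- as.data.frame(x)
  y$SS <- round(y$SS, 1); y$MS <- round(y$MS, 2)
  y$variance <- round(y$variance, 3); y$pct <- round(y$pct, 2)
  print(y, row.names = FALSE)
  if (isTRUE(attr(x, "negative_components")))
    cat("note: negative variance component(s) retained\n")
  if (!is.null(attr(x, "p_between")))
    cat("permutation p (between groups):", attr(x, "p_between"), "\n")
  invisible(x)
}
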