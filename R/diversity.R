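#' Per-locus, per-group diversity statistics
#'
#' For each group and locus with at least `min_n` genotyped members, returns
#' the alternate-allele frequency `p`, the genotyped sample count `n`, the
#' observed heterozygosity `Ho` (heterozygote fraction), the raw expected
#' heterozygosity `He_raw = 2p(1-p)` and Nei's unbiased estimate
#' `He_unbiased = 2p(1-p) * 2n/(2n-1)`. Loci with fewer genotyped members
#' are skipped for that group.
#'
#' @param gm a [genotype_matrix]
#' @param group_labels character vector of group ids per accession (see
#'   [group_labels()]); a single group is assumed when `NULL`.
#' @param min_n minimum genotyped samples per (group, locus) (default 2).
#' @return data.frame with columns `group`, `marker`, `n`, `p`, `Ho`,
#'   `He_raw`, `He_unbiased`.
#' @export
locus_stats <- function(gm, group_labels = NULL, min_n = 2) {
  if (is.null(group_labels)) group_labels <- rep("all", nrow(gm$dosage))
  stopifnot(length(group_labels) == nrow(gm$dosage))
  out <- lapply(unique(group_labels), function(g) {
    d <- gm$dosage[group_labels == g, , drop = FALSE]
    n <- colSums(!is.na(d))
    p <- colMeans(d, na.rm = TRUE) / 2
    ho <- colMeans(d == 1L, na.rm = TRUE)
    he <- 2 * p * (1 - p)
    heu <- he * (2 * n) / (2 * n - 1)
    keep <- n >= min_n
    data.frame(group = g, marker = colnames(gm$dosage)[keep],
               n = n[keep], p = p[keep], Ho = ho[keep],
               He_raw = he[keep], He_unbiased = heu[keep],
               row.names = NULL, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Rarefied allelic richness
#'
#' Per group, the expected number of distinct alleles per locus in a random
#' draw of `2 * rarefaction_g` allele copies (hypergeometric rarefaction),
#' averaged over loci. Rarefaction makes allele counts comparable across
#' unequal group sizes. With biallelic SNPs the per-locus value lies in
#' `[1, 2]`.
#'
#' @param gm a [genotype_matrix]
#' @param group_labels group id per accession; single group when `NULL`.
#' @param rarefaction_g standardised sample size in individuals; default the
#'   smallest group's minimum genotyped count across loci.
#' @return data.frame with columns `group`, `Ar_mean`, `Ar_sd`, `g`.
#' @export
allelic_richness <- function(gm, group_labels = NULL, rarefaction_g = NULL) {
  if (is.null(group_labels)) group_labels <- rep("all", nrow(gm$dosage))
  groups <- unique(group_labels)
  counts <- lapply(groups, function(g) {
    d <- gm$dosage[group_labels == g, , drop = FALSE]
    n_copies <- 2L * colSums(!is.na(d))
    alt <- colSums(d, na.rm = TRUE)
    cbind(n = n_copies, alt = alt)
  })
  if (is.null(rarefaction_g)) {
    min_copies <- min(vapply(counts, function(x) min(x[, "n"]), numeric(1)))
    rarefaction_g <- floor(min_copies / 2)
  }
  if (rarefaction_g < 1) stop("rarefaction size must be >= 1")
  gcopies <- 2L * rarefaction_g

  ar_locus <- function(n, alt) {
    # expected allele count in a draw of gcopies from n observed copies
    if (n < gcopies) return(NA_real_)
    ref <- n - alt
    pa <- function(k) {
      # P(allele with k copies absent from the draw) = C(n-k, g)/C(n, g)
      if (k == 0) return(NA_real_)  # allele not observed at all
      exp(lchoose(n - k, gcopies) - lchoose(n, gcopies))
    }
    present <- c(ref, alt)
    sum(vapply(present[present > 0], function(k) 1 - pa(k), numeric(1)))
  }

  out <- lapply(seq_along(groups), function(i) {
    cc <- counts[[i]]
    ar <- vapply(seq_len(nrow(cc)),
                 function(j) ar_locus(cc[j, "n"], cc[j, "alt"]),
                 numeric(1))
    data.frame(group = groups[i],
               Ar_mean = mean(ar, na.rm = TRUE),
               Ar_sd = stats::sd(ar, na.rm = TRUE),
               g = rarefaction_g,
               row.names = NULL, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Multilocus inbreeding coefficient with bootstrap confidence interval
#'
#' FIS is the ratio-of-averages statistic
#' `1 - mean_loci(Ho) / mean_loci(He_unbiased)` per group, with a percentile
#' confidence interval obtained by resampling loci with replacement. Under t
#' generations of selfing from Hardy-Weinberg the expectation is
#' `1 - (1/2)^t`.
#'
#' @param gm a [genotype_matrix]
#' @param group_labels group id per accession; single group when `NULL`.
#' @param n_boot bootstrap replicates (default 1000).
#' @param ci confidence level (default 0.95).
#' @param rng_seed integer seed for the bootstrap.
#' @return data.frame with columns `group`, `FIS`, `FIS_low`, `FIS_high`,
#'   `n_loci`. Groups whose mean He is zero get `NA` (undefined).
#' @export
fis <- function(gm, group_labels = NULL, n_boot = 1000, ci = 0.95,
                rng_seed = 1L) {
  ls <- locus_stats(gm, group_labels)
  set.seed(rng_seed)
  alpha <- (1 - ci) / 2
  out <- lapply(split(ls, ls$group), function(x) {
    use <- x[is.finite(x$He_unbiased), , drop = FALSE]
    if (nrow(use) < 2 || mean(use$He_unbiased) == 0)
      return(data.frame(group = x$group[1], FIS = NA_real_,
                        FIS_low = NA_real_, FIS_high = NA_real_,
                        n_loci = nrow(use), stringsAsFactors = FALSE))
    f <- 1 - mean(use$Ho) / mean(use$He_unbiased)
    bs <- vapply(seq_len(n_boot), function(b) {
      i <- sample.int(nrow(use), replace = TRUE)
      he <- mean(use$He_unbiased[i])
      if (he == 0) return(NA_real_)
      1 - mean(use$Ho[i]) / he
    }, numeric(1))
    qs <- stats::quantile(bs, c(alpha, 1 - alpha), na.rm = TRUE,
                          names = FALSE)
    data.frame(group = x$group[1], FIS = f, FIS_low = qs[1],
               FIS_high = qs[2], n_loci = nrow(use),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Per-accession heterozygosity
#'
#' Heterozygous calls divided by non-missing calls, per accession.
#' Accessions with no non-missing calls are `NA` and listed in the
#' `"undefined"` attribute.
#'
#' @param gm a [genotype_matrix]
#' @return named numeric vector.
#' @export
per_accession_het <- function(gm) {
  het <- rowSums(gm$dosage == 1L, na.rm = TRUE)
  n <- rowSums(!is.na(gm$dosage))
  out <- het / n
  out[n == 0] <- NA_real_
  attr(out, "undefined") <- rownames(gm$dosage)[n == 0]
  out
}

#' Group-wise diversity summary table
#'
#' One row per group: total alleles observed across loci (`A`, capped at 2
#' per biallelic locus), `A` as a percentage of the maximum `2 * n_loci`,
#' rarefied allelic richness (mean and SD over loci), observed and unbiased
#' expected heterozygosity (mean and SD over loci), and multilocus FIS with
#' its bootstrap confidence interval.
#'
#' @inheritParams fis
#' @param rarefaction_g passed to [allelic_richness()].
#' @return data.frame with columns `group`, `n`, `A`, `pct_alleles`,
#'   `Ar_mean`, `Ar_sd`, `Ho_mean`, `Ho_sd`, `He_mean`, `He_sd`, `FIS`,
#'   `FIS_low`, `FIS_high`.
#' @export
diversity_summary <- function(gm, group_labels = NULL, n_boot = 1000,
                              ci = 0.95, rarefaction_g = NULL,
                              rng_seed = 1L) {
  if (is.null(group_labels)) group_labels <- rep("all", nrow(gm$dosage))
  ls <- locus_stats(gm, group_labels)
  ar <- allelic_richness(gm, group_labels, rarefaction_g)
  fi <- fis(gm, group_labels, n_boot = n_boot, ci = ci, rng_seed = rng_seed)
  n_loci <- ncol(gm$dosage)
  base <- lapply(split(ls, ls$group), function(x) {
    # observed allele count per locus: 2 if polymorphic in the group, else 1
    a <- sum(ifelse(x$p > 0 & x$p < 1, 2L, 1L))
    data.frame(group = x$group[1],
               n = sum(group_labels == x$group[1]),
               A = a,
               pct_alleles = 100 * a / (2 * n_loci),
               Ho_mean = mean(x$Ho), Ho_sd = stats::sd(x$Ho),
               He_mean = mean(x$He_unbiased),
               He_sd = stats::sd(x$He_unbiased),
               stringsAsFactors = FALSE)
  })
  base <- do.call(rbind, base)
  out <- merge(merge(base, ar[, c("group", "Ar_mean", "Ar_sd")],
                     by = "group"),
               fi[, c("group", "FIS", "FIS_low", "FIS_high")], by = "group")
  rownames(out) <- NULL
  out[, c("group", "n", "A", "pct_alleles", "Ar_mean", "Ar_sd",
          "Ho_mean", "Ho_sd", "He_mean", "He_sd",
          "FIS", "FIS_low", "FIS_high")]
}
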