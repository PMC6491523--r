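#' Pairwise identity-by-state distance
#'
#' For each accession pair, the mean over co-called markers of
#' `|d_i - d_j| / 2` on the dosage scale — i.e. one minus the average
#' fraction of shared alleles. Identical genotypes have distance 0 and
#' opposite homozygotes at every locus have distance 1. Pairs with zero
#' co-called markers are `NA` (undefined, never silently 0).
#'
#' @param gm a [genotype_matrix] with at least 2 accessions.
#' @return symmetric numeric matrix with zero diagonal.
#' @export
ibs_distance <- function(gm) {
  if (nrow(gm$dosage) < 2) stop("need at least 2 accessions")
  d <- gm$dosage
  M <- !is.na(d)
  d0 <- d
  d0[!M] <- 0L
  storage.mode(d0) <- "double"
  storage.mode(M) <- "double"
  # sum over co-called loci of |d_i - d_j| via the identity
  # |a-b| = a + b - 2*min(a,b); with 0/1/2 dosages, decompose by indicators
  A0 <- (d0 == 0) * M
  A1 <- (d0 == 1) * M
  A2 <- (d0 == 2) * M
  # |d_i - d_j| summed: pairs (0,1),(1,2) contribute 1; (0,2) contributes 2
  S <- A0 %*% t(A1) + A1 %*% t(A0) +
    A1 %*% t(A2) + A2 %*% t(A1) +
    2 * (A0 %*% t(A2) + A2 %*% t(A0))
  n_shared <- M %*% t(M)
  out <- S / (2 * n_shared)
  out[n_shared == 0] <- NA_real_
  diag(out) <- 0
  dimnames(out) <- list(rownames(d), rownames(d))
  out
}

#' Method-of-moments probability of identity (PI-HAT)
#'
#' Estimates, for every accession pair, the probabilities of sharing 0, 1 or
#' 2 alleles identical by descent from the observed identity-by-state counts
#' and the panel allele frequencies (the classical method-of-moments IBD
#' estimator used for cryptic-relatedness screening). The reported statistic
#' is `PI = P(IBD=2) + 0.5 * P(IBD=1)`, clamped to `[0, 1]`: 1 for exact
#' duplicates, about 0.5 for full sibs, about 0 for unrelated pairs drawn
#' from the frequency pool.
#'
#' @param gm a [genotype_matrix]; allele frequencies are taken from the full
#'   panel (a monomorphic-only panel is rejected as uninformative).
#' @return symmetric numeric matrix in `[0, 1]` with unit diagonal.
#' @export
estimate_pi <- function(gm) {
  if (nrow(gm$dosage) < 2) stop("need at least 2 accessions")
  d <- gm$dosage
  p <- alt_allele_freq(gm)
  q <- 1 - p
  poly <- !is.na(p) & p > 0 & p < 1
  if (!any(poly))
    stop("panel is monomorphic at every locus; allele frequencies are uninformative")

  M <- !is.na(d)
  d0 <- d; d0[!M] <- -1L
  A0 <- (d0 == 0) * 1; A1 <- (d0 == 1) * 1; A2 <- (d0 == 2) * 1
  Mn <- M * 1

  # observed IBS counts over co-called loci
  N0 <- A0 %*% t(A2) + A2 %*% t(A0)
  N2 <- A0 %*% t(A0) + A1 %*% t(A1) + A2 %*% t(A2)
  n_shared <- Mn %*% t(Mn)
  N1 <- n_shared - N0 - N2

  # per-locus expected IBS-state probabilities under IBD = 0 / 1
  e0_ibd0 <- 2 * p^2 * q^2
  e1_ibd0 <- 4 * p^3 * q + 4 * p * q^3
  e2_ibd0 <- p^4 + q^4 + 4 * p^2 * q^2
  e1_ibd1 <- 2 * p * q              # = 2 p^2 q + 2 p q^2 with p + q = 1
  e2_ibd1 <- p^2 + q^2

  wexp <- function(e) (Mn %*% diag(e, length(e))) %*% t(Mn)
  E00 <- wexp(e0_ibd0)
  E10 <- wexp(e1_ibd0)
  E20 <- wexp(e2_ibd0)
  E11 <- wexp(e1_ibd1)
  E21 <- wexp(e2_ibd1)

  P0 <- N0 / E00
  P0[!is.finite(P0)] <- 0
  P0 <- pmin(pmax(P0, 0), 1)
  P1 <- (N1 - P0 * E10) / E11
  P1[!is.finite(P1)] <- 0
  P1 <- pmin(pmax(P1, 0), 1)
  P2 <- (N2 - P0 * E20 - P1 * E21) / n_shared
  P2[!is.finite(P2)] <- 0
  P2 <- pmin(pmax(P2, 0), 1)

  pi_hat <- pmin(pmax(P2 + 0.5 * P1, 0), 1)
  pi_hat[n_shared == 0] <- NA_real_
  diag(pi_hat) <- 1
  pi_hat <- (pi_hat + t(pi_hat)) / 2  # symmetrise exactly
  dimnames(pi_hat) <- list(rownames(d), rownames(d))
  pi_hat
}

#' Full relatedness computation
#'
#' Bundles [ibs_distance()], [estimate_pi()], the shared-call count matrix
#' and per-accession call rates into one object, which is the input to
#' [find_duplicates()].
#'
#' @param gm a [genotype_matrix]
#' @return an object of class `relatedness_result` with elements
#'   `ibs_distance`, `pi_hat`, `n_shared_calls`, `call_rate`.
#' @export
relatedness <- function(gm) {
  M <- (!is.na(gm$dosage)) * 1
  n_shared <- M %*% t(M)
  dimnames(n_shared) <- list(rownames(gm$dosage), rownames(gm$dosage))
  structure(list(ibs_distance = ibs_distance(gm),
                 pi_hat = estimate_pi(gm),
                 n_shared_calls = n_shared,
                 call_rate = sample_call_rate(gm)),
            class = "relatedness_result")
}

#' @export
print.relatedness_result <- function(x, ...) {
  cat("relatedness_result over", nrow(x$pi_hat), "accessions\n")
  up <- x$pi_hat[upper.tri(x$pi_hat)]
  cat("  pairs with PI >= 0.99:", sum(up >= 0.99, na.rm = TRUE), "\n")
  invisible(x)
}

#' Duplicate detection and core-collection selection
#'
#' Clusters accessions by single-linkage transitive closure over pairs whose
#' estimated PI reaches `pi_threshold`, then selects one representative per
#' cluster: the member with the highest genotype call rate, ties broken by
#' the lexicographically smallest accession id. The representatives form the
#' core collection. Selection is deterministic and invariant to the input
#' accession order.
#'
#' @param rel a `relatedness_result` from [relatedness()].
#' @param pi_threshold duplicate threshold in `(0, 1]` (default 0.99; use
#'   `1.0` to require a literal estimated-PI of one).
#' @return an object of class `core_selection`: list with
#'   `duplicate_clusters` (list of id sets, singletons included),
#'   `representatives` and `core_ids`.
#' @export
find_duplicates <- function(rel, pi_threshold = 0.99) {
  stopifnot(inherits(rel, "relatedness_result"))
  if (pi_threshold <= 0 || pi_threshold > 1)
    stop("pi_threshold must lie in (0, 1]")
  pi <- rel$pi_hat
  ids <- rownames(pi)
  n <- length(ids)
  # union-find over duplicate edges
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  edges <- which(pi >= pi_threshold & upper.tri(pi), arr.ind = TRUE)
  if (nrow(edges) > 0) {
    for (k in seq_len(nrow(edges))) {
      ri <- find(edges[k, 1]); rj <- find(edges[k, 2])
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  clusters <- split(ids, root)
  # canonical order: by smallest member id, for permutation invariance
  clusters <- clusters[order(vapply(clusters, function(s) min(s),
                                    character(1)))]
  clusters <- unname(lapply(clusters, sort))
  reps <- vapply(clusters, function(s) {
    cr <- rel$call_rate[s]
    best <- s[cr == max(cr)]
    sort(best)[1]
  }, character(1))
  structure(list(duplicate_clusters = clusters,
                 representatives = reps,
                 core_ids = sort(reps),
                 pi_threshold = pi_threshold),
            class = "core_selection")
}

#' @export
print.core_selection <- function(x, ...) {
  sizes <- lengths(x$duplicate_clusters)
  cat("core_selection:", length(x$core_ids), "core accessions from",
      sum(sizes), "input accessions (",
      sum(sizes > 1), "duplicate clusters )\n")
  invisible(x)
}

#' Write a core selection as JSON
#' @param core a `core_selection`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_core_selection <- function(core, path) {
  jsonlite::write_json(list(core_ids = core$core_ids,
                            representatives = core$representatives,
                            duplicate_clusters = core$duplicate_clusters,
                            pi_threshold = core$pi_threshold),
                       path, auto_unbox = TRUE)
  invisible(path)
}
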