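#' Additive (VanRaden) relationship matrix
#'
#' Centres dosages by twice the panel allele frequency, imputes missing calls
#' to the locus mean (i.e. zero after centring) and normalises by
#' `2 * sum(p * (1 - p))`:
#' `A = Z Z' / (2 sum p(1-p))`. Duplicate accessions have identical rows and
#' the mean diagonal is approximately `1 + FIS` for inbred panels.
#'
#' @param gm a post-QC [genotype_matrix]; monomorphic-only panels are
#'   rejected.
#' @return an object of class `relationship_matrix`: list with `A`, `p`
#'   (allele frequencies), `norm` (the normalisation constant).
#' @export
relationship_matrix <- function(gm) {
  p <- alt_allele_freq(gm)
  poly <- is.finite(p) & p > 0 & p < 1
  if (!any(poly)) stop("panel is monomorphic at every locus")
  d <- gm$dosage[, poly, drop = FALSE]
  p <- p[poly]
  Z <- sweep(d, 2, 2 * p)
  Z[is.na(Z)] <- 0
  norm <- 2 * sum(p * (1 - p))
  A <- tcrossprod(Z) / norm
  dimnames(A) <- list(rownames(gm$dosage), rownames(gm$dosage))
  structure(list(A = A, p = p, norm = norm,
                 markers = colnames(gm$dosage)[poly]),
            class = "relationship_matrix")
}

#' PCA of a genotype panel via its relationship matrix
#'
#' Eigendecomposition of the additive relationship matrix. Scores are
#' `eigenvectors * sqrt(eigenvalues)`; the percentage of variance per
#' component uses eigenvalue shares with negative eigenvalues floored at
#' zero (they can arise from missing-call imputation) and flagged. When
#' called on a [genotype_matrix] the result also carries marker-space
#' loadings, allele frequencies and the normalisation constant, enabling
#' [pca_project()].
#'
#' @param x a [genotype_matrix] or a `relationship_matrix`.
#' @param n_pcs number of components to keep (truncated to the available
#'   rank with a warning).
#' @return an object of class `grm_pca`: list with `eigenvalues`,
#'   `pct_variance`, `scores` and — when computed from genotypes —
#'   `loadings`, `p`, `norm`, `markers`.
#' @export
grm_pca <- function(x, n_pcs = 10) {
  rel <- NULL
  gm <- NULL
  if (inherits(x, "genotype_matrix")) {
    gm <- x
    rel <- relationship_matrix(gm)
  } else if (inherits(x, "relationship_matrix")) {
    rel <- x
  } else stop("x must be a genotype_matrix or relationship_matrix")

  eg <- eigen(rel$A, symmetric = TRUE)
  pos <- pmax(eg$values, 0)
  rank <- sum(pos > 1e-10 * max(pos))
  if (n_pcs > rank) {
    warning("n_pcs (", n_pcs, ") exceeds the available rank (", rank,
            "); truncating")
    n_pcs <- rank
  }
  idx <- seq_len(n_pcs)
  scores <- eg$vectors[, idx, drop = FALSE] %*%
    diag(sqrt(pos[idx]), n_pcs)
  rownames(scores) <- rownames(rel$A)
  colnames(scores) <- paste0("PC", idx)
  out <- list(eigenvalues = eg$values,
              pct_variance = 100 * pos / sum(pos),
              scores = scores,
              negative_eigenvalues = any(eg$values < -1e-10 * max(pos)))
  if (!is.null(gm)) {
    # marker-space basis for projection: V = Zs' U D^{-1}, Zs = Z / sqrt(norm)
    d <- gm$dosage[, rel$markers, drop = FALSE]
    Z <- sweep(d, 2, 2 * rel$p)
    Z[is.na(Z)] <- 0
    Zs <- Z / sqrt(rel$norm)
    V <- crossprod(Zs, eg$vectors[, idx, drop = FALSE]) %*%
      diag(1 / sqrt(pos[idx]), n_pcs)
    rownames(V) <- rel$markers
    colnames(V) <- paste0("PC", idx)
    out$loadings <- V
    out$p <- rel$p
    out$norm <- rel$norm
    out$markers <- rel$markers
  }
  structure(out, class = "grm_pca")
}

#' Project new samples onto a reference PCA basis
#'
#' New samples are centred with the reference panel's allele frequencies and
#' multiplied onto the reference marker loadings, so a reference-panel
#' projection of the reference itself reproduces the original scores.
#' Missing calls are imputed to the reference locus mean. Only the marker
#' intersection is used (a warning is raised below 50 shared markers; zero
#' shared markers is an error).
#'
#' @param reference a `grm_pca` computed from a [genotype_matrix].
#' @param new_gm a [genotype_matrix] of samples to project.
#' @return numeric matrix of scores (samples x components).
#' @export
pca_project <- function(reference, new_gm) {
  if (is.null(reference$loadings))
    stop("reference PCA lacks marker loadings; compute it from a genotype_matrix")
  shared <- intersect(reference$markers, colnames(new_gm$dosage))
  if (length(shared) == 0) stop("no shared markers between panels")
  if (length(shared) < 50)
    warning("only ", length(shared), " shared markers; projection may be unstable")
  p <- reference$p[match(shared, reference$markers)]
  d <- new_gm$dosage[, shared, drop = FALSE]
  Z <- sweep(d, 2, 2 * p)
  Z[is.na(Z)] <- 0
  scores <- (Z / sqrt(reference$norm)) %*%
    reference$loadings[shared, , drop = FALSE]
  rownames(scores) <- rownames(new_gm$dosage)
  scores
}

#' PCA on the pairwise genetic distance matrix
#'
#' The second ordination path: classical metric scaling (principal
#' coordinates) of the identity-by-state distance matrix. Exposed alongside
#' [grm_pca()] because both orderings are informative on array panels;
#' neither is privileged.
#'
#' @param gm a [genotype_matrix]
#' @param n_pcs number of coordinates.
#' @return list with `scores` and `pct_variance`.
#' @export
distance_pca <- function(gm, n_pcs = 2) {
  d <- ibs_distance(gm)
  if (anyNA(d)) stop("distance matrix has undefined entries")
  fit <- stats::cmdscale(stats::as.dist(d), k = n_pcs, eig = TRUE)
  pos <- pmax(fit$eig, 0)
  list(scores = fit$points, pct_variance = 100 * pos / sum(pos))
}

#' Neighbour-joining tree with locus-bootstrap supports
#'
#' Builds an unrooted neighbour-joining tree from the identity-by-state
#' distance matrix (or any complete, non-negative distance matrix). When a
#' genotype panel and `n_boot > 0` are supplied, loci are resampled with
#' replacement, the tree is rebuilt per replicate and bipartition recovery
#' percentages (0-100) are attached as internal node labels.
#'
#' @param x a [genotype_matrix] (distances computed via [ibs_distance()])
#'   or a complete distance matrix / `dist`.
#' @param n_boot bootstrap replicates (default 100; 0 disables supports —
#'   always the case when `x` is a bare distance matrix).
#' @param rng_seed integer seed for the bootstrap.
#' @return an `ape::phylo` tree; internal node labels hold bootstrap
#'   supports when computed.
#' @export
nj_tree <- function(x, n_boot = 100, rng_seed = 1L) {
  from_gm <- inherits(x, "genotype_matrix")
  d <- if (from_gm) ibs_distance(x) else as.matrix(x)
  if (nrow(d) < 3) stop("need at least 3 taxa")
  if (anyNA(d)) stop("distance matrix has undefined entries")
  if (any(d < 0)) stop("distance matrix has negative entries")
  tree <- ape::nj(stats::as.dist(d))
  if (from_gm && n_boot > 0) {
    set.seed(rng_seed)
    L <- ncol(x$dosage)
    btrees <- vector("list", n_boot)
    for (b in seq_len(n_boot)) {
      idx <- sample.int(L, replace = TRUE)
      gb <- x
      gb$dosage <- x$dosage[, idx, drop = FALSE]
      colnames(gb$dosage) <- sprintf("b%05d", seq_len(L))
      db <- ibs_distance(gb)
      db[is.na(db)] <- mean(db, na.rm = TRUE)
      btrees[[b]] <- ape::nj(stats::as.dist(db))
    }
    class(btrees) <- "multiPhylo"
    counts <- ape::prop.clades(tree, btrees, rooted = FALSE)
    counts[is.na(counts)] <- 0
    tree$node.label <- round(100 * counts / n_boot, 1)
  }
  tree
}

#' Write a tree in Newick format
#' @param tree an `ape::phylo`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
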