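#' Fingerprinting fitness: uniquely identified accessions
#'
#' Accessions are profiled over a marker subset keeping only homozygous
#' calls; heterozygous and missing calls are wildcards that match anything.
#' Two accessions are distinguished iff they are opposite homozygotes at at
#' least one subset marker, and an accession counts toward the fitness iff
#' it is distinguished from every other accession.
#'
#' @param gm a [genotype_matrix]
#' @param marker_subset character marker ids or integer column indices; must
#'   be non-empty and within the panel.
#' @return integer count of uniquely identified accessions (`<= n_accessions`).
#' @export
fingerprint_fitness <- function(gm, marker_subset) {
  if (length(marker_subset) == 0) stop("marker subset must be non-empty")
  if (is.character(marker_subset))
    marker_subset <- match(marker_subset, colnames(gm$dosage))
  if (anyNA(marker_subset) || any(marker_subset < 1) ||
      any(marker_subset > ncol(gm$dosage)))
    stop("marker subset outside the panel")
  d <- gm$dosage[, marker_subset, drop = FALSE]
  .fitness_dosage(d)
}

# fitness on a raw dosage sub-matrix
.fitness_dosage <- function(d) {
  h0 <- (!is.na(d) & d == 0L) * 1
  h2 <- (!is.na(d) & d == 2L) * 1
  P <- tcrossprod(h0, h2)         # P[i, j] = markers where i hom-ref, j hom-alt
  dis <- (P + t(P)) > 0
  sum(rowSums(dis) == nrow(d) - 1L)
}

# precompute, per marker, which accession pairs it distinguishes
# (pairs indexed in upper-triangle order); only used when small enough
.pair_coverage <- function(d) {
  n <- nrow(d)
  pr <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  M <- matrix(FALSE, ncol(d), nrow(pr))
  for (m in seq_len(ncol(d))) {
    x <- d[, m]
    M[m, ] <- (!is.na(x[pr[, 1]]) & !is.na(x[pr[, 2]])) &
      ((x[pr[, 1]] == 0L & x[pr[, 2]] == 2L) |
         (x[pr[, 1]] == 2L & x[pr[, 2]] == 0L))
  }
  list(M = M, pairs = pr, n = n)
}

.fitness_from_coverage <- function(cov, subset) {
  v <- cov$M[subset[1], ]
  for (s in subset[-1]) v <- v | cov$M[s, ]
  if (all(v)) return(cov$n)
  bad <- cov$pairs[!v, , drop = FALSE]
  cov$n - length(unique(c(bad[, 1], bad[, 2])))
}

# choose the cheaper fitness evaluator for repeated calls
.fitness_factory <- function(d) {
  n <- nrow(d)
  if (as.double(n) * (n - 1) / 2 * ncol(d) <= 2e7) {
    cov <- .pair_coverage(d)
    function(subset) .fitness_from_coverage(cov, subset)
  } else {
    function(subset) .fitness_dosage(d[, subset, drop = FALSE])
  }
}

#' Genetic-algorithm configuration for fingerprint selection
#'
#' Defaults follow the published tuning for array-based rice fingerprinting:
#' partially matched crossover at rate 0.35, survival (elitist truncation)
#' rate 0.30, population size 50,000 and no mutation. For test-scale panels
#' much smaller populations suffice.
#'
#' @param k subset size (number of markers to select).
#' @param population_size GA population (default 50000).
#' @param crossover_rate probability an offspring is produced by partially
#'   matched crossover rather than copied from a parent (default 0.35).
#' @param survival_rate fraction of the population kept by elitist
#'   truncation each generation (default 0.30).
#' @param mutation_rate per-gene probability of replacement with a random
#'   unused marker (default 0).
#' @param max_generations hard generation cap (default 100).
#' @param plateau_generations stop after this many generations without
#'   best-fitness improvement (default 20).
#' @param min_ibs_distance threshold for the post-hoc identity-by-state
#'   check on unresolved pairs (default 0.05).
#' @param rng_seed integer seed.
#' @return an object of class `ga_config`.
#' @export
ga_config <- function(k, population_size = 50000L, crossover_rate = 0.35,
                      survival_rate = 0.30, mutation_rate = 0,
                      max_generations = 100L, plateau_generations = 20L,
                      min_ibs_distance = 0.05, rng_seed = 1L) {
  if (k < 1) stop("k must be >= 1")
  if (population_size < 2) stop("population_size must be >= 2")
  rates <- c(crossover_rate, survival_rate, mutation_rate)
  if (any(rates < 0) || any(rates > 1)) stop("rates must lie in [0, 1]")
  structure(list(k = as.integer(k),
                 population_size = as.integer(population_size),
                 crossover_rate = crossover_rate,
                 survival_rate = survival_rate,
                 mutation_rate = mutation_rate,
                 max_generations = as.integer(max_generations),
                 plateau_generations = as.integer(plateau_generations),
                 min_ibs_distance = min_ibs_distance,
                 rng_seed = as.integer(rng_seed)),
            class = "ga_config")
}

# partially matched crossover adapted to distinct-index vectors: copy parent
# 1, splice a random segment of parent 2, then repair duplicates using the
# PMX mapping (segment values of one parent map to the other's), falling
# back to random unused markers when the mapping loops
.pmx <- function(p1, p2, n_markers) {
  k <- length(p1)
  if (k == 1) return(if (stats::runif(1) < 0.5) p1 else p2)
  cuts <- sort(sample.int(k, 2))
  child <- p1
  seg <- cuts[1]:cuts[2]
  child[seg] <- p2[seg]
  outside <- setdiff(seq_len(k), seg)
  for (i in outside) {
    v <- child[i]
    guard <- 0L
    while (v %in% child[seg] && guard < k) {
      v <- p1[match(v, p2[seg]) + cuts[1] - 1L]
      guard <- guard + 1L
    }
    child[i] <- v
  }
  # repair any residual duplicates with random unused markers
  dup <- duplicated(child)
  if (any(dup)) {
    pool <- setdiff(seq_len(n_markers), child[!dup])
    child[dup] <- sample(pool, sum(dup))
  }
  child
}

#' Genetic-algorithm selection of a minimal fingerprinting SNP set
#'
#' Evolves fixed-length vectors of `k` distinct marker indices to maximise
#' [fingerprint_fitness()]. Each generation the top `survival_rate` fraction
#' is kept (elitist truncation) and the rest of the population is refilled
#' by partially matched crossover between random survivors (applied at
#' `crossover_rate`, otherwise a parent is copied), with optional per-gene
#' mutation. The run stops when every accession is uniquely identified, at
#' `max_generations`, or after `plateau_generations` without improvement.
#' Pairs that no homozygous profile can distinguish are reported together
#' with their identity-by-state distance and whether it clears
#' `min_ibs_distance` (the post-hoc identity rule for heterozygous
#' accessions).
#'
#' @param gm a [genotype_matrix] (normally a duplicate-free core; exact
#'   duplicates put a hard ceiling on the attainable fitness).
#' @param config a [ga_config()].
#' @return an object of class `fingerprint_panel`: list with `markers`
#'   (selected ids), `fitness`, `generations_run`, `trace` (best fitness per
#'   generation) and `unresolved_pairs` (data.frame, possibly empty).
#' @export
ga_select <- function(gm, config) {
  stopifnot(inherits(config, "ga_config"))
  n_m <- ncol(gm$dosage)
  n_acc <- nrow(gm$dosage)
  k <- config$k
  if (k > n_m) stop("k exceeds the number of markers")
  n_surv <- max(1L, floor(config$survival_rate * config$population_size))
  if (config$population_size < n_surv) stop("population smaller than survivors")

  set.seed(config$rng_seed)
  fit_fun <- .fitness_factory(gm$dosage)

  pop <- t(replicate(config$population_size, sample.int(n_m, k)))
  if (k == 1) pop <- matrix(pop, ncol = 1)
  fitness <- apply(pop, 1, fit_fun)

  trace <- integer(0)
  best_fit <- -1L
  stagnant <- 0L
  gens <- 0L
  for (gen in seq_len(config$max_generations)) {
    gens <- gen
    ord <- order(fitness, decreasing = TRUE)
    pop <- pop[ord, , drop = FALSE]
    fitness <- fitness[ord]
    gen_best <- fitness[1]
    trace <- c(trace, gen_best)
    if (gen_best > best_fit) {
      best_fit <- gen_best
      stagnant <- 0L
    } else stagnant <- stagnant + 1L
    if (gen_best >= n_acc) break
    if (stagnant >= config$plateau_generations) break
    if (gen == config$max_generations) break

    surv <- pop[seq_len(n_surv), , drop = FALSE]
    n_off <- config$population_size - n_surv
    off <- matrix(0L, n_off, k)
    for (i in seq_len(n_off)) {
      pa <- sample.int(n_surv, 2, replace = n_surv < 2)
      child <- if (stats::runif(1) < config$crossover_rate)
        .pmx(surv[pa[1], ], surv[pa[2], ], n_m)
      else surv[pa[1], ]
      if (config$mutation_rate > 0) {
        mut <- which(stats::runif(k) < config$mutation_rate)
        if (length(mut) > 0) {
          pool <- setdiff(seq_len(n_m), child)
          child[mut] <- sample(pool, length(mut))
        }
      }
      off[i, ] <- child
    }
    off_fit <- apply(off, 1, fit_fun)
    pop <- rbind(surv, off)
    fitness <- c(fitness[seq_len(n_surv)], off_fit)
  }

  best <- pop[which.max(fitness), ]
  .fingerprint_panel(gm, sort(best), max(fitness), gens, trace,
                     config$min_ibs_distance)
}

.fingerprint_panel <- function(gm, subset, fitness, gens, trace,
                               min_ibs_distance) {
  cnt <- pairwise_polymorphic_counts(gm, subset)
  un <- which(cnt == 0 & upper.tri(cnt), arr.ind = TRUE)
  unresolved <- data.frame(accession1 = character(0),
                           accession2 = character(0),
                           ibs_distance = numeric(0),
                           distinct_by_ibs = logical(0))
  if (nrow(un) > 0) {
    ibs <- ibs_distance(gm)
    unresolved <- data.frame(
      accession1 = rownames(cnt)[un[, 1]],
      accession2 = rownames(cnt)[un[, 2]],
      ibs_distance = ibs[un],
      distinct_by_ibs = ibs[un] >= min_ibs_distance,
      stringsAsFactors = FALSE)
  }
  structure(list(markers = colnames(gm$dosage)[subset],
                 fitness = as.integer(fitness),
                 generations_run = gens,
                 trace = trace,
                 unresolved_pairs = unresolved),
            class = "fingerprint_panel")
}

#' @export
print.fingerprint_panel <- function(x, ...) {
  cat("fingerprint_panel:", length(x$markers), "markers; fitness",
      x$fitness, "after", x$generations_run, "generation(s)\n")
  invisible(x)
}

#' Exhaustive-search fingerprint selection (oracle)
#'
#' Maximises [fingerprint_fitness()] over all `choose(n_markers, k)` subsets
#' (bounded at one million; larger instances are rejected in favour of
#' [greedy_select()] or [ga_select()]). Ties are broken by lexicographic
#' subset order, so the result is deterministic.
#'
#' @param gm a [genotype_matrix]
#' @param k subset size.
#' @param min_ibs_distance post-hoc identity threshold (as in [ga_select()]).
#' @return a `fingerprint_panel`.
#' @export
brute_force_select <- function(gm, k, min_ibs_distance = 0.05) {
  n_m <- ncol(gm$dosage)
  if (k > n_m) stop("k exceeds the number of markers")
  if (choose(n_m, k) > 1e6)
    stop("choose(n_markers, k) exceeds 1e6; use greedy_select or ga_select")
  fit_fun <- .fitness_factory(gm$dosage)
  combs <- utils::combn(n_m, k)
  best_fit <- -1L
  best <- NULL
  for (i in seq_len(ncol(combs))) {
    f <- fit_fun(combs[, i])
    if (f > best_fit) {
      best_fit <- f
      best <- combs[, i]
      if (best_fit == nrow(gm$dosage)) break
    }
  }
  .fingerprint_panel(gm, best, best_fit, 0L, integer(0), min_ibs_distance)
}

#' Greedy forward fingerprint selection
#'
#' Adds at each step the marker that most increases the number of newly
#' distinguished accession pairs (ties broken by smallest marker index)
#' until `k` markers are chosen. Fast feasibility oracle and lower bound for
#' the GA.
#'
#' @inheritParams brute_force_select
#' @return a `fingerprint_panel`.
#' @export
greedy_select <- function(gm, k, min_ibs_distance = 0.05) {
  n_m <- ncol(gm$dosage)
  if (k > n_m) stop("k exceeds the number of markers")
  cov <- .pair_coverage(gm$dosage)
  chosen <- integer(0)
  covered <- rep(FALSE, nrow(cov$pairs))
  for (step in seq_len(k)) {
    gains <- vapply(seq_len(n_m), function(m) {
      if (m %in% chosen) return(-1L)
      sum(cov$M[m, ] & !covered)
    }, integer(1))
    pick <- which.max(gains)   # which.max takes the smallest index on ties
    chosen <- c(chosen, pick)
    covered <- covered | cov$M[pick, ]
  }
  chosen <- sort(chosen)
  fit <- .fitness_from_coverage(cov, chosen)
  .fingerprint_panel(gm, chosen, fit, 0L, integer(0), min_ibs_distance)
}

#' Pairwise polymorphic-marker counts over a subset
#'
#' For every accession pair, the number of subset markers at which both
#' accessions are homozygous and differ — the diagnostic used to visualise
#' the informativeness of a fingerprint panel. Zero-count pairs should be
#' cross-checked against the identity-by-state rule (see
#' `unresolved_pairs` in [ga_select()]).
#'
#' @param gm a [genotype_matrix]
#' @param marker_subset character ids or integer indices.
#' @return symmetric integer matrix (diagonal 0).
#' @export
pairwise_polymorphic_counts <- function(gm, marker_subset) {
  if (is.character(marker_subset))
    marker_subset <- match(marker_subset, colnames(gm$dosage))
  if (anyNA(marker_subset)) stop("unknown marker id in subset")
  d <- gm$dosage[, marker_subset, drop = FALSE]
  h0 <- (!is.na(d) & d == 0L) * 1
  h2 <- (!is.na(d) & d == 2L) * 1
  P <- tcrossprod(h0, h2)
  out <- P + t(P)
  storage.mode(out) <- "integer"
  dimnames(out) <- list(rownames(gm$dosage), rownames(gm$dosage))
  out
}
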