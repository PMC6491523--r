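#' Configuration for a synthetic SNP panel
#'
#' Describes a structured, partially inbred diploid SNP panel in the style of
#' genebank rice collections genotyped on a fixed array: a set of diverged
#' subpopulations (e.g. indica-like and japonica-like clusters), strong
#' selfing, exact-duplicate accessions, and i.i.d. missing calls.
#'
#' Subpopulation allele frequencies follow the Balding-Nichols model: for a
#' locus with ancestral frequency p0 and group divergence F, the group
#' frequency is Beta(p0(1-F)/F, (1-p0)(1-F)/F), so that the expected
#' Weir-Cockerham FST between two groups of equal divergence is F. Genotypes
#' are drawn under Hardy-Weinberg within groups and then pushed toward
#' homozygosity by `selfing_generations` rounds of selfing (each round halves
#' the heterozygote fraction, so the expected inbreeding coefficient is
#' 1 - (1/2)^t after t rounds).
#'
#' @param n_markers number of biallelic markers.
#' @param n_chromosomes chromosomes over which markers are spread evenly.
#' @param groups data.frame with columns `group` (id), `n` (accessions) and
#'   `F` (divergence in `[0, 1)`); `F = 0` means the group uses the ancestral
#'   frequencies directly.
#' @param selfing_generations non-negative integer count of selfing rounds.
#' @param n_duplicates number of exact-copy accessions appended to the panel;
#'   sources are drawn with replacement, so duplicate clusters of size > 2
#'   can arise. Copies are made before missingness is injected.
#' @param missing_rate i.i.d. missing-call probability in `[0, 1)`.
#' @param ancestral_maf_range length-2 numeric in `(0, 0.5]`, the uniform
#'   range for ancestral allele frequencies.
#' @param n_low_call_samples number of accessions given an elevated missing
#'   rate (`low_call_missing_rate`), to exercise the sample call-rate filter.
#' @param low_call_missing_rate missing rate applied to those samples.
#' @param rng_seed integer seed; the whole simulation is reproducible from it.
#'
#' @return an object of class `panel_config`.
#' @export
panel_config <- function(n_markers = 1536L,
                         n_chromosomes = 12L,
                         groups = data.frame(
                           group = c("indica", "japonica"),
                           n = c(132L, 175L),
                           F = c(0.5, 0.5)),
                         selfing_generations = 4L,
                         n_duplicates = 282L,
                         missing_rate = 0.05,
                         ancestral_maf_range = c(0.1, 0.5),
                         n_low_call_samples = 0L,
                         low_call_missing_rate = 0.10,
                         rng_seed = 1L) {
  groups <- as.data.frame(groups)
  stopifnot(all(c("group", "n", "F") %in% names(groups)))
  if (sum(groups$n) < 2) stop("need at least 2 accessions in total")
  if (any(groups$F < 0) || any(groups$F >= 1))
    stop("group divergence F must lie in [0, 1)")
  if (n_duplicates < 0) stop("n_duplicates must be >= 0")
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must lie in [0, 1)")
  if (length(ancestral_maf_range) != 2 ||
      ancestral_maf_range[1] <= 0 || ancestral_maf_range[2] > 0.5 ||
      ancestral_maf_range[1] > ancestral_maf_range[2])
    stop("ancestral_maf_range must be (low, high) within (0, 0.5]")
  if (selfing_generations < 0) stop("selfing_generations must be >= 0")
  structure(list(n_markers = as.integer(n_markers),
                 n_chromosomes = as.integer(n_chromosomes),
                 groups = groups,
                 selfing_generations = as.integer(selfing_generations),
                 n_duplicates = as.integer(n_duplicates),
                 missing_rate = missing_rate,
                 ancestral_maf_range = ancestral_maf_range,
                 n_low_call_samples = as.integer(n_low_call_samples),
                 low_call_missing_rate = low_call_missing_rate,
                 rng_seed = as.integer(rng_seed)),
            class = "panel_config")
}

# one round of selfing on a dosage matrix: each heterozygote becomes a
# homozygote with probability 1/2 (offspring of a self are 1/4 AA, 1/2 Aa,
# 1/4 aa; conditional on leaving the het class, the two homozygotes are
# equally likely)
.self_once <- function(d) {
  het <- which(d == 1L)
  if (length(het) == 0) return(d)
  fix <- het[stats::runif(length(het)) < 0.5]
  if (length(fix) > 0)
    d[fix] <- 2L * (stats::runif(length(fix)) < 0.5)
  d
}

#' Simulate a structured, inbred SNP panel with duplicates and missingness
#'
#' @param config a [panel_config]
#' @return a list with elements
#'   \describe{
#'     \item{panel}{a [genotype_matrix] of all accessions (base + duplicate
#'       copies) with passport columns `region`, `merged_region`,
#'       `subspecies` (the generating group), `colour_class`, `country`.}
#'     \item{truth}{a list recording the generative state: `group` per
#'       accession, `duplicate_pairs` (source, copy), `duplicate_clusters`,
#'       `core_ids` (one id per distinct genotype), per-group divergence `F`,
#'       `ancestral_freq` and per-group realized `group_freq`,
#'       `low_call_samples`, and the `colour_class` per accession.}
#'   }
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "panel_config"))
  set.seed(config$rng_seed)
  L <- config$n_markers
  G <- nrow(config$groups)

  p0 <- stats::runif(L, config$ancestral_maf_range[1],
                     config$ancestral_maf_range[2])
  pg <- matrix(NA_real_, L, G, dimnames = list(NULL, config$groups$group))
  for (g in seq_len(G)) {
    F <- config$groups$F[g]
    if (F == 0) {
      pg[, g] <- p0
    } else {
      pg[, g] <- stats::rbeta(L, p0 * (1 - F) / F, (1 - p0) * (1 - F) / F)
    }
  }

  n_base <- sum(config$groups$n)
  group_of <- rep(config$groups$group, config$groups$n)
  dos <- matrix(NA_integer_, n_base, L)
  row0 <- 0L
  for (g in seq_len(G)) {
    n_g <- config$groups$n[g]
    # HWE draw: dosage ~ Binomial(2, p) per locus
    block <- matrix(stats::rbinom(n_g * L, 2L, rep(pg[, g], each = n_g)),
                    n_g, L)
    dos[row0 + seq_len(n_g), ] <- block
    row0 <- row0 + n_g
  }
  for (t in seq_len(config$selfing_generations)) dos <- .self_once(dos)

  base_ids <- sprintf("ACC%04d", seq_len(n_base))
  rownames(dos) <- base_ids

  # duplicates: exact copies (pre-missingness) of sources drawn with
  # replacement, so clusters of size > 2 occur, as in real genebank panels
  dup_pairs <- NULL
  dup_ids <- character(0)
  if (config$n_duplicates > 0) {
    src <- sample(base_ids, config$n_duplicates, replace = TRUE)
    dup_ids <- sprintf("DUP%04d", seq_len(config$n_duplicates))
    dos <- rbind(dos, dos[src, , drop = FALSE])
    rownames(dos) <- c(base_ids, dup_ids)
    dup_pairs <- data.frame(source = src, copy = dup_ids,
                            stringsAsFactors = FALSE)
  }
  n_all <- nrow(dos)
  all_ids <- rownames(dos)
  group_all <- c(group_of, if (config$n_duplicates > 0)
    group_of[match(dup_pairs$source, base_ids)])

  # clusters: each base accession plus all its copies
  clusters <- split(all_ids, c(base_ids, if (config$n_duplicates > 0)
    dup_pairs$source))
  clusters <- unname(clusters)

  # missingness, i.i.d. with an optional per-sample elevation
  miss_rate <- rep(config$missing_rate, n_all)
  low_call <- character(0)
  if (config$n_low_call_samples > 0) {
    low_idx <- sample(n_all, config$n_low_call_samples)
    miss_rate[low_idx] <- config$low_call_missing_rate
    low_call <- all_ids[low_idx]
  }
  if (any(miss_rate > 0)) {
    miss <- matrix(stats::runif(n_all * L), n_all, L) < miss_rate
    dos[miss] <- NA_integer_
  }

  regions <- c("NCR", "CAR", "Ilocos", "Cagayan Valley", "Central Luzon",
               "Calabarzon", "MIMAROPA", "Bicol", "Visayas",
               "Mindanao1", "Mindanao2", "Mindanao3")
  region <- sample(regions, n_all, replace = TRUE)
  colour_levels <- c("red", "variable purple", "purple", "white", "mixed")
  colour_prob <- c(0.8147, 0.0761, 0.0489, 0.0143, 0.0460)
  colour <- sample(colour_levels, n_all, replace = TRUE,
                   prob = colour_prob / sum(colour_prob))
  # copies share the source accession's passport
  if (config$n_duplicates > 0) {
    i_copy <- match(dup_pairs$copy, all_ids)
    i_src <- match(dup_pairs$source, all_ids)
    region[i_copy] <- region[i_src]
    colour[i_copy] <- colour[i_src]
  }

  chrom <- rep(seq_len(config$n_chromosomes), length.out = L)
  chrom <- sort(chrom)
  pos <- unlist(lapply(split(seq_len(L), chrom),
                       function(ix) seq(100000L, by = 250000L,
                                        length.out = length(ix))))
  map <- data.frame(marker = sprintf("S%02d_%09d", chrom, pos),
                    chrom = chrom, pos = pos, ref = "A", alt = "G",
                    stringsAsFactors = FALSE)
  colnames(dos) <- map$marker

  passport <- data.frame(accession = all_ids,
                         region = region,
                         merged_region = region,
                         subspecies = group_all,
                         colour_class = colour,
                         country = "Philippines",
                         stringsAsFactors = FALSE)

  panel <- genotype_matrix(dos, marker_map = map, passport = passport)
  truth <- list(group = stats::setNames(group_all, all_ids),
                duplicate_pairs = dup_pairs,
                duplicate_clusters = clusters,
                core_ids = base_ids,
                divergence_F = stats::setNames(config$groups$F,
                                               config$groups$group),
                ancestral_freq = p0,
                group_freq = pg,
                low_call_samples = low_call,
                colour_class = stats::setNames(colour, all_ids),
                config = config)
  list(panel = panel, truth = truth)
}

#' Simulate full-sib pairs within a panmictic population
#'
#' Parents are drawn under Hardy-Weinberg from uniform allele frequencies;
#' each full-sib pair receives independent meioses from the same two parents.
#' Useful for checking method-of-moments kinship estimators against their
#' expectations (mean PI-HAT of 0.5 for full sibs).
#'
#' @param n_pairs number of sib pairs (panel holds `2 * n_pairs` accessions).
#' @param n_loci number of biallelic loci.
#' @param maf_range uniform range of allele frequencies.
#' @param rng_seed integer seed.
#' @return list with `panel` (a [genotype_matrix]) and `pairs` (two-column
#'   matrix of accession ids forming each sib pair).
#' @export
simulate_full_sibs <- function(n_pairs, n_loci = 1000L,
                               maf_range = c(0.1, 0.5), rng_seed = 1L) {
  set.seed(rng_seed)
  p <- stats::runif(n_loci, maf_range[1], maf_range[2])
  gamete <- function(parent) {
    # transmit one allele per locus: for dosage 0/2 deterministic, het -> coin
    out <- parent / 2
    het <- which(parent == 1L)
    out[het] <- stats::rbinom(length(het), 1L, 0.5)
    out
  }
  dos <- matrix(NA_integer_, 2L * n_pairs, n_loci)
  for (k in seq_len(n_pairs)) {
    mum <- stats::rbinom(n_loci, 2L, p)
    dad <- stats::rbinom(n_loci, 2L, p)
    dos[2L * k - 1L, ] <- as.integer(gamete(mum) + gamete(dad))
    dos[2L * k, ] <- as.integer(gamete(mum) + gamete(dad))
  }
  ids <- sprintf("SIB%04d", seq_len(2L * n_pairs))
  rownames(dos) <- ids
  panel <- genotype_matrix(dos)
  pairs <- cbind(ids[seq(1, 2 * n_pairs, by = 2)],
                 ids[seq(2, 2 * n_pairs, by = 2)])
  list(panel = panel, pairs = pairs)
}

#' Default seed-trait class means and covariance
#'
#' Per-class mean values for the ten seed traits measured by multi-spectral
#' imaging of dehulled grain: geometric traits (area in mm^2, length and
#' width in mm, roundness) and colour-appearance traits (CIE L*, a*, b*, hue
#' angle in degrees, saturation, intensity). The defaults encode the ordering
#' seen in pigmented rice: red accessions have the highest lightness, a* and
#' intensity, purple the lowest, and variable purple the lowest saturation
#' and b*. Geometric means are identical across classes (seed colour and
#' seed geometry are unrelated).
#'
#' The default covariance is shared across classes and built from a factor
#' model (guaranteeing positive semi-definiteness) whose generating
#' correlations include r(intensity, L*) = 0.99, r(a*, b*) ~ 0.88 and
#' r(roundness, width) ~ -0.62.
#'
#' @return `default_trait_means()`: a 5 x 10 matrix (classes x traits);
#'   `default_trait_cov()`: a 10 x 10 covariance matrix.
#' @export
default_trait_means <- function() {
  traits <- c("area", "length", "width", "roundness",
              "L", "a", "b", "hue", "saturation", "intensity")
  m <- rbind(
    red               = c(13.0, 6.5, 2.6, 0.50, 38, 12.0, 15.0, 51, 19.0, 95),
    purple            = c(13.0, 6.5, 2.6, 0.50, 25, 4.0, 5.0, 52, 7.0, 55),
    `variable purple` = c(13.0, 6.5, 2.6, 0.50, 30, 6.0, 4.5, 54, 6.5, 65),
    white             = c(13.0, 6.5, 2.6, 0.50, 55, 3.0, 14.0, 70, 14.0, 120),
    mixed             = c(13.0, 6.5, 2.6, 0.50, 45, 9.0, 13.0, 55, 16.0, 100))
  colnames(m) <- traits
  m
}

#' @rdname default_trait_means
#' @export
default_trait_cov <- function() {
  traits <- c("area", "length", "width", "roundness",
              "L", "a", "b", "hue", "saturation", "intensity")
  # factor loadings: f1 colour/lightness, f2 yellowness, f3 size, f4 shape
  load <- rbind(
    area       = c(0.00, 0.00, 0.90, 0.00),
    length     = c(0.00, 0.00, 0.75, 0.00),
    width      = c(0.00, 0.00, 0.75, -0.55),
    roundness  = c(0.00, 0.00, -0.20, 0.85),
    L          = c(0.995, 0.00, 0.00, 0.00),
    a          = c(0.75, 0.55, 0.00, 0.00),
    b          = c(0.90, 0.38, 0.00, 0.00),
    hue        = c(-0.40, -0.50, 0.00, 0.00),
    saturation = c(0.93, 0.00, 0.00, 0.00),
    intensity  = c(0.995, 0.00, 0.00, 0.00))
  corr <- load %*% t(load)
  diag(corr) <- 1
  sds <- c(area = 1.5, length = 0.5, width = 0.2, roundness = 0.05,
           L = 4, a = 2, b = 2.5, hue = 4, saturation = 3, intensity = 12)
  cov <- diag(sds) %*% corr %*% diag(sds)
  dimnames(cov) <- list(traits, traits)
  cov
}

#' Simulate per-accession seed-trait tables
#'
#' Draws multivariate-normal trait vectors per accession, with means set by
#' the accession's pericarp colour class and a shared within-class
#' covariance. The simulated values stand in for per-accession means of 20
#' imaged seeds.
#'
#' @param truth the `truth` element of [simulate_panel()] output (uses its
#'   `colour_class`), or any named character vector of colour classes.
#' @param class_means classes x traits matrix; default [default_trait_means()].
#' @param class_cov traits x traits positive semi-definite covariance;
#'   default [default_trait_cov()].
#' @param rng_seed integer seed.
#' @return a data.frame (`accession`, `colour_class`, one column per trait).
#' @export
simulate_traits <- function(truth, class_means = NULL, class_cov = NULL,
                            rng_seed = 1L) {
  classes <- if (is.list(truth)) truth$colour_class else truth
  if (is.null(classes) || length(classes) == 0)
    stop("no colour classes available in 'truth'")
  if (is.null(names(classes)))
    names(classes) <- sprintf("ACC%04d", seq_along(classes))
  if (is.null(class_means)) class_means <- default_trait_means()
  if (is.null(class_cov)) class_cov <- default_trait_cov()
  class_means <- as.matrix(class_means)
  class_cov <- as.matrix(class_cov)
  if (!isSymmetric(unname(class_cov)))
    stop("class_cov must be symmetric")
  ev <- eigen(class_cov, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev)))
    stop("class_cov is not positive semi-definite")
  unknown <- setdiff(unique(classes), rownames(class_means))
  if (length(unknown) > 0)
    stop("no trait means for colour class(es): ",
         paste(unknown, collapse = ", "))

  set.seed(rng_seed)
  n <- length(classes)
  vals <- MASS::mvrnorm(n, mu = rep(0, ncol(class_cov)), Sigma = class_cov)
  vals <- vals + class_means[classes, , drop = FALSE]
  colnames(vals) <- colnames(class_means)
  # keep domains sane: geometric traits positive, hue wrapped to [0, 360)
  for (tr in intersect(c("area", "length", "width", "roundness"),
                       colnames(vals)))
    vals[, tr] <- pmax(vals[, tr], 1e-3)
  if ("hue" %in% colnames(vals)) vals[, "hue"] <- vals[, "hue"] %% 360
  out <- data.frame(accession = names(classes),
                    colour_class = unname(classes),
                    vals, row.names = NULL, check.names = FALSE,
                    stringsAsFactors = FALSE)
  out
}

#' Simulate binary indel calls at a pigmentation locus
#'
#' Emulates a presence/absence PCR screen of a loss-of-pigmentation deletion:
#' the deletion is scored 0 when present and 1 when absent. White accessions
#' carry the deletion with probability `concordance`; pigmented accessions
#' carry it with probability `1 - concordance`.
#'
#' @param truth as in [simulate_traits()] (colour classes are taken from it).
#' @param concordance probability in `[0, 1]` that an accession's call agrees
#'   with the expectation from its pericarp colour.
#' @param rng_seed integer seed.
#' @return a data.frame (`accession`, `rc_score` in `{0, 1}`) with attribute
#'   `"discordant"` listing accessions whose call contradicts their colour.
#' @export
simulate_indel_calls <- function(truth, concordance = 1, rng_seed = 1L) {
  classes <- if (is.list(truth)) truth$colour_class else truth
  if (is.null(classes) || length(classes) == 0)
    stop("no colour classes available in 'truth'")
  if (concordance < 0 || concordance > 1)
    stop("concordance must lie in [0, 1]")
  set.seed(rng_seed)
  white <- classes == "white"
  p_del <- ifelse(white, concordance, 1 - concordance)
  score <- ifelse(stats::runif(length(classes)) < p_del, 0L, 1L)
  discordant <- names(classes)[(white & score == 1L) |
                                 (!white & score == 0L)]
  out <- data.frame(accession = names(classes), rc_score = score,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "discordant") <- discordant
  out
}

#' Inject a block of correlated marker copies (for LD-pruning tests)
#'
#' Appends or overwrites markers with noisy copies of a source marker so
#' that a high-LD block exists by construction. Each copy equals the source
#' dosage with independent per-call flips at rate `flip_rate`.
#'
#' @param gm a [genotype_matrix]
#' @param source_marker marker id to copy.
#' @param target_markers ids of markers (downstream of the source) whose
#'   columns are replaced by noisy copies.
#' @param flip_rate per-call probability of replacing the copied dosage with
#'   a random one.
#' @param rng_seed integer seed.
#' @return the modified [genotype_matrix].
#' @export
inject_ld_block <- function(gm, source_marker, target_markers,
                            flip_rate = 0, rng_seed = 1L) {
  set.seed(rng_seed)
  src <- gm$dosage[, source_marker]
  for (m in target_markers) {
    col <- src
    if (flip_rate > 0) {
      fl <- which(stats::runif(length(col)) < flip_rate)
      col[fl] <- sample(0:2, length(fl), replace = TRUE)
    }
    gm$dosage[, m] <- col
  }
  gm
}
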