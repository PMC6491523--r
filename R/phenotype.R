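#' Cross-tabulate pigmentation-locus indel calls against pericarp colour
#'
#' The deletion screen is scored 0 (deletion present) / 1 (deletion absent);
#' calls flagged `"ambiguous"` (multi-band PCR profiles) are excluded from
#' the percentage columns and counted separately. Discordant accessions are
#' pigmented carriers of the deletion and white non-carriers.
#'
#' @param calls data.frame with columns `accession` and `rc_score`
#'   (0, 1 or `"ambiguous"`).
#' @param colours data.frame with columns `accession` and `colour_class`,
#'   or a named character vector of colour classes.
#' @return list with `table` (colour x score counts, all colour classes kept
#'   as zero rows), `pct_within_score` (column percentages excluding
#'   ambiguous calls), `discordant` (data.frame), `ambiguous` (ids) and
#'   `unmatched` (ids present in only one input).
#' @export
rc_crosstab <- function(calls, colours) {
  if (is.vector(colours) || is.factor(colours))
    colours <- data.frame(accession = names(colours),
                          colour_class = as.character(colours),
                          stringsAsFactors = FALSE)
  unmatched <- c(setdiff(calls$accession, colours$accession),
                 setdiff(colours$accession, calls$accession))
  ids <- intersect(calls$accession, colours$accession)
  sc <- as.character(calls$rc_score[match(ids, calls$accession)])
  cl <- colours$colour_class[match(ids, colours$accession)]

  amb <- ids[sc == "ambiguous"]
  ok <- sc != "ambiguous"
  tab <- table(colour = factor(cl, levels = unique(colours$colour_class)),
               rc_score = factor(sc, levels = c("0", "1", "ambiguous")))
  clean <- tab[, c("0", "1"), drop = FALSE]
  pct <- sweep(clean, 2, colSums(clean), "/") * 100
  pct[, colSums(clean) == 0] <- NA_real_

  pig <- ok & cl != "white" & sc == "0"
  wht <- ok & cl == "white" & sc == "1"
  discordant <- data.frame(
    accession = ids[pig | wht],
    colour_class = cl[pig | wht],
    rc_score = as.integer(sc[pig | wht]),
    stringsAsFactors = FALSE)
  list(table = tab, pct_within_score = pct, discordant = discordant,
       ambiguous = amb, unmatched = unmatched)
}

#' Descriptive statistics per seed trait
#'
#' Minimum, maximum, range, median, mean, variance, standard deviation and
#' coefficient of variation (SD / mean) per numeric trait column, with a
#' Shapiro-Wilk normality flag at `alpha`. Constant traits get CV 0 and the
#' normality test is skipped (flagged `NA`).
#'
#' @param tt trait table: data.frame with `accession`, `colour_class` and
#'   numeric trait columns (at least 3 accessions).
#' @param alpha significance level for the normality flag (default 0.05).
#' @return data.frame, one row per trait.
#' @export
describe_traits <- function(tt, alpha = 0.05) {
  traits <- names(tt)[vapply(tt, is.numeric, logical(1))]
  if (nrow(tt) < 3) stop("need at least 3 accessions")
  rows <- lapply(traits, function(tr) {
    x <- tt[[tr]][!is.na(tt[[tr]])]
    s <- stats::sd(x)
    constant <- s == 0
    sw <- if (constant) NA_real_ else stats::shapiro.test(x)$p.value
    data.frame(trait = tr,
               n = length(x),
               min = min(x), max = max(x), range = max(x) - min(x),
               median = stats::median(x), mean = mean(x),
               variance = stats::var(x), sd = s,
               cv = if (constant) 0 else s / mean(x),
               shapiro_p = sw,
               normal = if (constant) NA else sw >= alpha,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pairwise Pearson correlations between traits
#'
#' Pearson r on pairwise-complete observations with two-sided p-values from
#' the t distribution. Zero-variance traits yield `NA` and are listed in the
#' `"degenerate"` attribute.
#'
#' @param tt trait table as in [describe_traits()].
#' @return list with matrices `r`, `p` and `n`.
#' @export
trait_correlations <- function(tt) {
  traits <- names(tt)[vapply(tt, is.numeric, logical(1))]
  X <- as.matrix(tt[, traits, drop = FALSE])
  k <- ncol(X)
  r <- matrix(NA_real_, k, k, dimnames = list(traits, traits))
  p <- r
  nm <- matrix(NA_integer_, k, k, dimnames = list(traits, traits))
  degenerate <- character(0)
  for (i in seq_len(k)) {
    for (j in i:k) {
      ok <- !is.na(X[, i]) & !is.na(X[, j])
      n <- sum(ok)
      nm[i, j] <- nm[j, i] <- n
      if (n < 3) next
      if (stats::sd(X[ok, i]) == 0 || stats::sd(X[ok, j]) == 0) {
        degenerate <- union(degenerate,
                            traits[c(i, j)[c(stats::sd(X[ok, i]) == 0,
                                             stats::sd(X[ok, j]) == 0)]])
        next
      }
      rr <- stats::cor(X[ok, i], X[ok, j])
      r[i, j] <- r[j, i] <- rr
      if (i == j) { p[i, j] <- NA_real_; next }
      tstat <- rr * sqrt((n - 2) / max(1 - rr^2, .Machine$double.eps))
      p[i, j] <- p[j, i] <- 2 * stats::pt(-abs(tstat), n - 2)
    }
  }
  out <- list(r = r, p = p, n = nm)
  attr(out, "degenerate") <- degenerate
  out
}

#' PCA of standardised seed traits
#'
#' Traits are standardised to unit variance before the eigendecomposition;
#' constant traits are dropped with a warning. Scores carry the colour class
#' for plotting.
#'
#' @param tt trait table as in [describe_traits()].
#' @return list with `eigenvalues`, `pct_variance`, `scores` (data.frame
#'   including `colour_class`), `loadings`.
#' @export
trait_pca <- function(tt) {
  traits <- names(tt)[vapply(tt, is.numeric, logical(1))]
  if (length(traits) < 2) stop("need at least 2 traits")
  if (nrow(tt) < 3) stop("need at least 3 accessions")
  X <- as.matrix(tt[, traits, drop = FALSE])
  keep <- apply(X, 2, function(x) stats::sd(x, na.rm = TRUE) > 0)
  if (!all(keep)) {
    warning("dropping constant trait(s): ",
            paste(traits[!keep], collapse = ", "))
    X <- X[, keep, drop = FALSE]
  }
  fit <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  ev <- fit$sdev^2
  scores <- data.frame(accession = tt$accession,
                       colour_class = tt$colour_class,
                       fit$x, stringsAsFactors = FALSE)
  list(eigenvalues = ev,
       pct_variance = 100 * ev / sum(ev),
       scores = scores,
       loadings = fit$rotation)
}

#' One-way ANOVA of a trait across colour classes, with assumption gating
#'
#' Fits a one-way ANOVA of `trait ~ colour_class` (df = classes - 1,
#' N - classes). Residual normality (Shapiro-Wilk) and variance homogeneity
#' (Bartlett) are tested at `alpha`; when Bartlett fails, the configured
#' transform (natural log by default) is applied and both tests repeated. A
#' trait that is still heterogeneous after transformation is marked
#' `precluded` and gets no post-hoc comparisons. Otherwise Tukey HSD
#' intervals are computed on the analysis (possibly transformed) scale.
#' Classes with a single member are dropped with a warning.
#'
#' @param tt trait table as in [describe_traits()].
#' @param trait trait column name.
#' @param transform `"log"` (natural log; requires positive values),
#'   `"none"`, or a function.
#' @param alpha gating significance level (default 0.05).
#' @return list with `trait`, `F`, `df` (length 2), `p`, `tukey` (data.frame
#'   or `NULL`), `shapiro_p`, `bartlett_p`, `transform_applied`, `precluded`,
#'   `dropped_classes`.
#' @export
colour_anova <- function(tt, trait, transform = "log", alpha = 0.05) {
  if (!trait %in% names(tt)) stop("unknown trait: ", trait)
  dat <- data.frame(y = tt[[trait]],
                    class = as.character(tt$colour_class),
                    stringsAsFactors = FALSE)
  dat <- dat[!is.na(dat$y), , drop = FALSE]
  tab <- table(dat$class)
  dropped <- names(tab)[tab < 2]
  if (length(dropped) > 0) {
    warning("dropping class(es) with a single member: ",
            paste(dropped, collapse = ", "))
    dat <- dat[!dat$class %in% dropped, , drop = FALSE]
  }
  if (length(unique(dat$class)) < 2)
    stop("need at least 2 classes with >= 2 members")
  dat$class <- factor(dat$class)

  run <- function(y) {
    fit <- stats::aov(y ~ class, data = data.frame(y = y,
                                                   class = dat$class))
    sm <- summary(fit)[[1]]
    list(fit = fit,
         F = sm$`F value`[1],
         df = c(sm$Df[1], sm$Df[2]),
         p = sm$`Pr(>F)`[1],
         shapiro_p = stats::shapiro.test(stats::residuals(fit))$p.value,
         bartlett_p = stats::bartlett.test(y, dat$class)$p.value)
  }

  res <- run(dat$y)
  applied <- "none"
  if (res$bartlett_p < alpha && !identical(transform, "none")) {
    f <- if (is.function(transform)) transform
    else if (transform == "log") {
      if (any(dat$y <= 0)) stop("log transform requires positive values")
      log
    } else stop("unknown transform: ", transform)
    res <- run(f(dat$y))
    applied <- if (is.function(transform)) "custom" else transform
  }
  precluded <- res$bartlett_p < alpha

  tukey <- NULL
  if (!precluded) {
    th <- stats::TukeyHSD(res$fit)$class
    tukey <- data.frame(comparison = rownames(th), th,
                        row.names = NULL, stringsAsFactors = FALSE)
  }
  list(trait = trait, F = res$F, df = res$df, p = res$p, tukey = tukey,
       shapiro_p = res$shapiro_p, bartlett_p = res$bartlett_p,
       transform_applied = applied, precluded = precluded,
       dropped_classes = dropped)
}
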