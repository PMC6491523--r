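#' Construct a genotype matrix object
#'
#' The central container of the package: a diploid, biallelic SNP dosage
#' matrix (accessions in rows, markers in columns) together with a marker map
#' and accession passport data. Dosages are coded 0 (reference homozygote),
#' 1 (heterozygote), 2 (alternate homozygote); missing calls are `NA`.
#'
#' @param dosage integer matrix, accessions x markers, values in
#'   `c(0L, 1L, 2L, NA)`. Row names are taken as accession ids and column
#'   names as marker ids when `accession_ids`/`marker_ids` are not given.
#' @param marker_map data.frame with one row per marker and columns
#'   `marker`, `chrom`, `pos` (1-based), `ref`, `alt`. Must be sorted by
#'   `(chrom, pos)`.
#' @param passport data.frame with one row per accession and at least a
#'   column `accession`; typical extra columns are `region`,
#'   `merged_region`, `colour_class` and `country`.
#' @param accession_ids,marker_ids optional character vectors overriding the
#'   dimnames of `dosage`.
#'
#' @return An object of class `genotype_matrix`: a list with elements
#'   `dosage`, `marker_map`, `passport`.
#' @export
genotype_matrix <- function(dosage, marker_map = NULL, passport = NULL,
                            accession_ids = NULL, marker_ids = NULL) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  if (!is.null(accession_ids)) rownames(dosage) <- accession_ids
  if (!is.null(marker_ids)) colnames(dosage) <- marker_ids
  if (is.null(rownames(dosage)))
    rownames(dosage) <- sprintf("ACC%04d", seq_len(nrow(dosage)))
  if (is.null(colnames(dosage)))
    colnames(dosage) <- sprintf("M%05d", seq_len(ncol(dosage)))

  bad <- stats::na.omit(unique(as.vector(dosage)))
  if (length(setdiff(bad, c(0L, 1L, 2L))) > 0)
    stop("dosage values must be 0, 1, 2 or NA")
  if (anyDuplicated(rownames(dosage)))
    stop("accession ids must be unique")
  if (anyDuplicated(colnames(dosage)))
    stop("marker ids must be unique")

  if (is.null(marker_map)) {
    marker_map <- data.frame(
      marker = colnames(dosage),
      chrom = 1L,
      pos = seq_len(ncol(dosage)),
      ref = "A", alt = "G",
      stringsAsFactors = FALSE
    )
  }
  marker_map <- as.data.frame(marker_map)
  req <- c("marker", "chrom", "pos")
  if (!all(req %in% names(marker_map)))
    stop("marker_map needs columns: ", paste(req, collapse = ", "))
  if (!all(marker_map$marker == colnames(dosage)))
    stop("marker_map$marker must match dosage column names, in order")
  if (any(marker_map$pos < 1)) stop("marker positions must be >= 1")
  o <- order(marker_map$chrom, marker_map$pos)
  if (!all(o == seq_len(nrow(marker_map))))
    stop("marker_map must be sorted by (chrom, pos)")

  if (is.null(passport)) {
    passport <- data.frame(accession = rownames(dosage),
                           stringsAsFactors = FALSE)
  }
  passport <- as.data.frame(passport)
  if (!"accession" %in% names(passport))
    stop("passport needs an 'accession' column")
  if (!all(passport$accession == rownames(dosage)))
    stop("passport$accession must match dosage row names, in order")

  structure(list(dosage = dosage, marker_map = marker_map,
                 passport = passport),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$dosage), "accessions x",
      ncol(x$dosage), "markers\n")
  cat("  chromosomes:", length(unique(x$marker_map$chrom)),
      " missing calls:",
      sprintf("%.2f%%", 100 * mean(is.na(x$dosage))), "\n")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Number of accessions / markers
#' @param gm a [genotype_matrix]
#' @return integer count.
#' @export
n_accessions <- function(gm) nrow(gm$dosage)

#' @rdname n_accessions
#' @export
n_markers <- function(gm) ncol(gm$dosage)

#' Subset a genotype matrix
#'
#' @param gm a [genotype_matrix]
#' @param accessions,markers character ids or logical/integer indices; `NULL`
#'   keeps everything.
#' @return a [genotype_matrix]
#' @export
gm_subset <- function(gm, accessions = NULL, markers = NULL) {
  acc <- if (is.null(accessions)) seq_len(nrow(gm$dosage)) else accessions
  mk <- if (is.null(markers)) seq_len(ncol(gm$dosage)) else markers
  if (is.character(acc)) acc <- match(acc, rownames(gm$dosage))
  if (is.character(mk)) mk <- match(mk, colnames(gm$dosage))
  if (anyNA(acc) || anyNA(mk)) stop("unknown accession or marker id")
  if (is.logical(acc)) acc <- which(acc)
  if (is.logical(mk)) mk <- which(mk)
  genotype_matrix(gm$dosage[acc, mk, drop = FALSE],
                  marker_map = gm$marker_map[mk, , drop = FALSE],
                  passport = gm$passport[acc, , drop = FALSE])
}

#' Per-marker and per-accession call rates, allele frequencies
#'
#' `marker_call_rate` and `sample_call_rate` return the fraction of
#' non-missing calls per marker column / accession row. `alt_allele_freq`
#' returns the alternate-allele frequency per marker computed from allele
#' counts on non-missing calls; `minor_allele_freq` folds it at 0.5.
#'
#' @param gm a [genotype_matrix]
#' @return named numeric vector.
#' @export
marker_call_rate <- function(gm) colMeans(!is.na(gm$dosage))

#' @rdname marker_call_rate
#' @export
sample_call_rate <- function(gm) rowMeans(!is.na(gm$dosage))

#' @rdname marker_call_rate
#' @export
alt_allele_freq <- function(gm) colMeans(gm$dosage, na.rm = TRUE) / 2

#' @rdname marker_call_rate
#' @export
minor_allele_freq <- function(gm) {
  p <- alt_allele_freq(gm)
  pmin(p, 1 - p)
}

#' Accession group labels from the passport
#'
#' Convenience accessor: returns the passport column named by `group_by` as a
#' character vector aligned with the dosage rows.
#'
#' @param gm a [genotype_matrix]
#' @param group_by passport column name (e.g. `"region"` or `"subspecies"`).
#' @return character vector of length `n_accessions(gm)`.
#' @export
group_labels <- function(gm, group_by) {
  if (!group_by %in% names(gm$passport))
    stop("no passport column called '", group_by, "'")
  as.character(gm$passport[[group_by]])
}
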