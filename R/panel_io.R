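#' Read a HapMap genotype file
#'
#' Parses the tab-separated HapMap text format (header `rs# alleles chrom pos
#' strand assembly# center protLSID assayLSID panelLSID QCcode` followed by
#' one column per sample; diploid genotype strings such as `AA`, `AG`, `NN`).
#' Genotypes are converted to alternate-allele dosages using the marker's
#' `alleles` column (`ref/alt`); `NN` and `--` map to missing. When the
#' alleles column does not name two valid nucleotides the alleles are
#' inferred from the observed calls, taking the major allele as reference.
#' Markers at which a third allele is observed are dropped with a warning.
#'
#' @param path file path.
#' @return a [genotype_matrix] (passport holds accession ids only).
#' @export
read_hapmap <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (length(lines) < 1) stop("empty HapMap file: ", path)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (length(header) < 12 || header[1] != "rs#")
    stop("malformed HapMap header (expected 'rs#' plus 11 metadata columns)")
  sample_ids <- header[-(1:11)]
  n_s <- length(sample_ids)
  body <- lines[-1]
  body <- body[nzchar(body)]

  n_m <- length(body)
  ids <- character(n_m); chrom <- character(n_m); pos <- integer(n_m)
  ref <- character(n_m); alt <- character(n_m)
  dos <- matrix(NA_integer_, n_s, n_m)
  drop <- logical(n_m)

  valid <- c("A", "C", "G", "T")
  for (i in seq_len(n_m)) {
    f <- strsplit(body[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != 11 + n_s)
      stop("malformed HapMap row at line ", i + 1, ": expected ",
           11 + n_s, " fields, got ", length(f))
    ids[i] <- f[1]; chrom[i] <- f[3]; pos[i] <- as.integer(f[4])
    calls <- toupper(f[-(1:11)])
    calls[calls %in% c("NN", "--", "N")] <- NA
    obs <- sort(unique(unlist(strsplit(stats::na.omit(calls), ""))))
    obs <- intersect(obs, valid)

    al <- toupper(strsplit(f[2], "/", fixed = TRUE)[[1]])
    if (length(al) == 2 && all(al %in% valid) && al[1] != al[2]) {
      r <- al[1]; a <- al[2]
    } else {
      # infer from observed calls: major allele = reference
      if (length(obs) == 0) { r <- "A"; a <- "G" }
      else if (length(obs) == 1) { r <- obs[1]; a <- setdiff(valid, r)[1] }
      else {
        cnt <- table(factor(unlist(strsplit(stats::na.omit(calls), "")),
                            levels = obs))
        ord <- names(sort(cnt, decreasing = TRUE))
        r <- ord[1]; a <- ord[2]
      }
    }
    extra <- setdiff(obs, c(r, a))
    if (length(extra) > 0) {
      warning("dropping marker ", ids[i],
              ": more than two alleles observed")
      drop[i] <- TRUE
      next
    }
    ref[i] <- r; alt[i] <- a
    m1 <- substr(calls, 1, 1); m2 <- substr(calls, 2, 2)
    d <- (m1 == a) + (m2 == a)
    d[is.na(calls)] <- NA_integer_
    dos[, i] <- as.integer(d)
  }

  keep <- !drop
  dos <- dos[, keep, drop = FALSE]
  chrom_int <- suppressWarnings(as.integer(chrom))
  if (!anyNA(chrom_int)) chrom <- chrom_int  # numeric labels sort naturally
  map <- data.frame(marker = ids[keep],
                    chrom = chrom[keep],
                    pos = pos[keep],
                    ref = ref[keep], alt = alt[keep],
                    stringsAsFactors = FALSE)
  o <- order(map$chrom, map$pos)
  map <- map[o, , drop = FALSE]
  dos <- dos[, o, drop = FALSE]
  rownames(map) <- NULL
  rownames(dos) <- sample_ids
  colnames(dos) <- map$marker
  genotype_matrix(dos, marker_map = map)
}

#' Write a genotype matrix as HapMap text
#'
#' @param gm a [genotype_matrix]
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_hapmap <- function(gm, path) {
  map <- gm$marker_map
  header <- c("rs#", "alleles", "chrom", "pos", "strand", "assembly#",
              "center", "protLSID", "assayLSID", "panelLSID", "QCcode",
              rownames(gm$dosage))
  geno_str <- function(j) {
    d <- gm$dosage[, j]
    r <- map$ref[j]; a <- map$alt[j]
    out <- c(paste0(r, r), paste0(r, a), paste0(a, a))[d + 1L]
    out[is.na(d)] <- "NN"
    out
  }
  rows <- vapply(seq_len(ncol(gm$dosage)), function(j) {
    paste(c(map$marker[j], paste0(map$ref[j], "/", map$alt[j]),
            map$chrom[j], map$pos[j], "+", "NA", "NA", "NA", "NA", "NA",
            "NA", geno_str(j)), collapse = "\t")
  }, character(1))
  writeLines(c(paste(header, collapse = "\t"), rows), path)
  invisible(path)
}

#' Read / write the dosage CSV dialect
#'
#' A genotype panel is stored as three diffable CSV files sharing a prefix:
#' `<prefix>_dosage.csv` (one row per accession, first column `accession`,
#' one integer dosage column per marker, `NA` for missing),
#' `<prefix>_markers.csv` (the marker map) and `<prefix>_passport.csv`.
#'
#' @param gm a [genotype_matrix]
#' @param prefix path prefix for the three files.
#' @return `write_dosage_csv`: the prefix, invisibly. `read_dosage_csv`: a
#'   [genotype_matrix].
#' @export
write_dosage_csv <- function(gm, prefix) {
  d <- data.frame(accession = rownames(gm$dosage), gm$dosage,
                  check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(d, paste0(prefix, "_dosage.csv"), row.names = FALSE)
  utils::write.csv(gm$marker_map, paste0(prefix, "_markers.csv"),
                   row.names = FALSE)
  utils::write.csv(gm$passport, paste0(prefix, "_passport.csv"),
                   row.names = FALSE)
  invisible(prefix)
}

#' @rdname write_dosage_csv
#' @export
read_dosage_csv <- function(prefix) {
  d <- utils::read.csv(paste0(prefix, "_dosage.csv"), check.names = FALSE,
                       stringsAsFactors = FALSE)
  map <- utils::read.csv(paste0(prefix, "_markers.csv"),
                         stringsAsFactors = FALSE)
  pp_path <- paste0(prefix, "_passport.csv")
  pp <- if (file.exists(pp_path))
    utils::read.csv(pp_path, stringsAsFactors = FALSE) else NULL
  dos <- as.matrix(d[, -1, drop = FALSE])
  rownames(dos) <- d$accession
  genotype_matrix(dos, marker_map = map, passport = pp)
}

#' Read a VCF into a genotype matrix (GT field, biallelic records)
#'
#' Thin wrapper around `vcfR`: keeps biallelic SNP records, converts the GT
#' field to alternate-allele dosage and treats half or fully missing calls as
#' missing.
#'
#' @param path VCF file path (may be bgzipped).
#' @return a [genotype_matrix]
#' @export
read_vcf_panel <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the 'vcfR' package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  bi <- !grepl(",", fix$ALT) & nchar(fix$REF) == 1 & nchar(fix$ALT) == 1
  if (!any(bi)) stop("no biallelic SNP records in ", path)
  gt <- vcfR::extract.gt(v, element = "GT")[bi, , drop = FALSE]
  fix <- fix[bi, , drop = FALSE]
  gt <- gsub("|", "/", gt, fixed = TRUE)
  dos <- matrix(NA_integer_, ncol(gt), nrow(gt))
  conv <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L)
  for (i in seq_len(nrow(gt)))
    dos[, i] <- unname(conv[gt[i, ]])
  ids <- fix$ID
  ids[is.na(ids) | ids == "."] <- paste0(fix$CHROM, "_", fix$POS)[
    is.na(ids) | ids == "."]
  chrom <- fix$CHROM
  chrom_int <- suppressWarnings(as.integer(chrom))
  if (!anyNA(chrom_int)) chrom <- chrom_int
  map <- data.frame(marker = ids, chrom = chrom,
                    pos = as.integer(fix$POS),
                    ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE)
  o <- order(map$chrom, map$pos)
  rownames(dos) <- colnames(gt)
  colnames(dos) <- map$marker
  genotype_matrix(dos[, o, drop = FALSE], marker_map = map[o, , drop = FALSE])
}

.qc_report <- function(step, removed, threshold, axis) {
  structure(list(step = step, removed = removed, threshold = threshold,
                 axis = axis, n_removed = length(removed)),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC step '", x$step, "': removed ", x$n_removed, " ", x$axis,
      "(s)\n", sep = "")
  invisible(x)
}

#' Write a QC report (or list of reports) as JSON
#' @param report a `qc_report` or list of them.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path) {
  if (inherits(report, "qc_report")) report <- list(report)
  jsonlite::write_json(lapply(report, unclass), path, auto_unbox = TRUE)
  invisible(path)
}

#' Marker quality-control filters
#'
#' `filter_markers` removes markers whose call rate (fraction of non-missing
#' calls over samples) falls below `min_call_rate`, then markers whose minor
#' allele frequency (from allele counts on non-missing calls) falls below
#' `min_maf` — in that order, which is recorded in the report.
#' `filter_samples` removes accessions by row call rate.
#'
#' @param gm a [genotype_matrix]
#' @param min_call_rate minimum retained call rate (default 0.95).
#' @param min_maf minimum retained minor allele frequency (default 0.05).
#' @return list with elements `panel` (filtered [genotype_matrix]) and
#'   `report` (list of `qc_report`s, one per applied filter).
#' @export
filter_markers <- function(gm, min_call_rate = 0.95, min_maf = 0.05) {
  if (ncol(gm$dosage) == 0) stop("empty panel")
  cr <- marker_call_rate(gm)
  rm_cr <- colnames(gm$dosage)[cr < min_call_rate]
  gm1 <- if (length(rm_cr) > 0)
    gm_subset(gm, markers = setdiff(colnames(gm$dosage), rm_cr)) else gm
  if (ncol(gm1$dosage) == 0)
    stop("all markers removed by the call-rate filter")
  maf <- minor_allele_freq(gm1)
  maf[is.nan(maf)] <- 0  # all-missing column: treat as uninformative
  rm_maf <- colnames(gm1$dosage)[maf < min_maf]
  gm2 <- if (length(rm_maf) > 0)
    gm_subset(gm1, markers = setdiff(colnames(gm1$dosage), rm_maf)) else gm1
  if (ncol(gm2$dosage) == 0)
    stop("all markers removed by the MAF filter")
  list(panel = gm2,
       report = list(.qc_report("marker_call_rate", rm_cr, min_call_rate,
                                "marker"),
                     .qc_report("maf", rm_maf, min_maf, "marker")))
}

#' @rdname filter_markers
#' @export
filter_samples <- function(gm, min_call_rate = 0.95) {
  if (nrow(gm$dosage) == 0) stop("empty panel")
  cr <- sample_call_rate(gm)
  rm_s <- rownames(gm$dosage)[cr < min_call_rate]
  out <- if (length(rm_s) > 0)
    gm_subset(gm, accessions = setdiff(rownames(gm$dosage), rm_s)) else gm
  if (nrow(out$dosage) == 0)
    stop("all samples removed by the call-rate filter")
  list(panel = out,
       report = list(.qc_report("sample_call_rate", rm_s, min_call_rate,
                                "sample")))
}

#' Composite LD r-squared between genotype dosage vectors
#'
#' Linkage disequilibrium for unphased, partially inbred diploids is measured
#' on genotype dosages directly: the squared Pearson correlation of the two
#' dosage vectors over pairwise-complete samples. This is the standard
#' composite (Burrows-type) genotypic r-squared and needs no phasing or
#' within-group Hardy-Weinberg assumption.
#'
#' @param x,y integer dosage vectors.
#' @return squared correlation, or `NA` when either vector is constant on the
#'   pairwise-complete subset.
#' @export
composite_r2 <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2) return(NA_real_)
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) return(NA_real_)
  stats::cor(x[ok], y[ok])^2
}

#' Windowed LD pruning
#'
#' Slides a window of `window` markers along the map in steps of `increment`
#' markers. Within each window, every retained pair is tested with
#' [composite_r2()]; when the value exceeds `r2_threshold` the downstream
#' marker (higher map position) is removed. Passes repeat until no window
#' contains an offending pair, so the result is stable under re-application.
#'
#' @param gm a [genotype_matrix] (markers must be map-sorted, which the
#'   container guarantees).
#' @param window window size in markers (default 2921).
#' @param increment window step in markers (default 5).
#' @param r2_threshold removal threshold (default 0.8, strict `>`).
#' @return list with `panel` and `report` as in [filter_markers()].
#' @export
ld_prune <- function(gm, window = 2921, increment = 5, r2_threshold = 0.8) {
  if (window < 2) stop("window must be >= 2 markers")
  if (increment < 1) stop("increment must be >= 1")
  M <- ncol(gm$dosage)
  keep <- rep(TRUE, M)
  d <- gm$dosage
  repeat {
    changed <- FALSE
    starts <- unique(c(seq(1L, max(1L, M - as.integer(window) + 1L),
                           by = as.integer(increment)),
                       max(1L, M - as.integer(window) + 1L)))
    for (s in starts) {
      w <- s:min(M, s + window - 1L)
      w <- w[keep[w]]
      if (length(w) < 2) next
      r2 <- suppressWarnings(stats::cor(d[, w, drop = FALSE],
                                        use = "pairwise.complete.obs")^2)
      for (ii in seq_len(length(w) - 1L)) {
        if (!keep[w[ii]]) next
        for (jj in (ii + 1L):length(w)) {
          if (!keep[w[jj]]) next
          v <- r2[ii, jj]
          if (!is.na(v) && v > r2_threshold) {
            keep[w[jj]] <- FALSE
            changed <- TRUE
          }
        }
      }
    }
    if (!changed) break
  }
  removed <- colnames(gm$dosage)[!keep]
  panel <- if (length(removed) > 0) gm_subset(gm, markers = keep) else gm
  list(panel = panel,
       report = list(.qc_report("ld_prune", removed, r2_threshold,
                                "marker")))
}
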