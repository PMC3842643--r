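#' Encode polymorphic-locus genotypes additively
#'
#' For regression each call at a parentally polymorphic locus is coded as
#' the count of parent-2 alleles: 0 (homozygous parent 1), 1 (heterozygous)
#' or 2 (homozygous parent 2). Missing calls, and calls carrying an allele
#' that belongs to neither parent (undefined under the biparental coding),
#' are set to `NA`; the number of non-parental calls dropped is reported in
#' a message.
#'
#' @param x A [genotype_matrix()].
#' @param classification A [classify_loci()] result from the same matrix.
#' @return Numeric matrix (polymorphic markers x individuals) of codes in
#'   `{0, 1, 2}` with `NA` for missing or non-parental calls.
#' @export
encode_genotypes <- function(x, classification) {
  poly <- classification$status == "polymorphic"
  if (!any(poly)) stop("no polymorphic loci to encode", call. = FALSE)
  mk <- classification$marker[poly]
  calls <- unclass(x)[mk, , drop = FALSE]
  a1 <- classification$allele_p1[poly]
  a2 <- classification$allele_p2[poly]
  c1 <- .allele1(calls); c2 <- .allele2(calls)
  parental <- (c1 == a1 | c1 == a2) & (c2 == a1 | c2 == a2)
  codes <- as.numeric((c2 == a2) + (c1 == a2))
  nonpar <- !is.na(parental) & !parental
  codes[nonpar] <- NA_real_
  n_nonpar <- sum(nonpar)
  if (n_nonpar > 0)
    message(n_nonpar, " call(s) with non-parental alleles excluded from ",
            "genotype coding")
  dim(codes) <- dim(calls)
  dimnames(codes) <- dimnames(calls)
  codes
}

#' Single-marker regression scan
#'
#' Per polymorphic marker, ordinary least squares of the trait on the
#' additive genotype code: variance explained `R^2 = SSR/SST`, the F
#' statistic on `(1, n-2)` degrees of freedom, and its p-value. With one
#' regressor this is identical to the squared Pearson correlation and, for
#' two genotype classes, to single-factor ANOVA. Markers with fewer than 3
#' usable lines or fewer than 2 distinct genotype classes are reported as
#' not testable (`NA` statistics).
#'
#' @param codes Numeric code matrix from [encode_genotypes()].
#' @param phenotypes Phenotype data.frame (`individual`, `value`).
#' @param retained Optional individual ids to restrict the scan to (e.g.
#'   the `retained` set of [flag_variants()]); default all phenotyped lines.
#' @param map Optional marker map merged into the output.
#' @return A data.frame of class `qtl_scan` with columns `marker`
#'   (plus `chrom`, `pos` if a map is given), `n_used`, `r2`, `fstat`, `p`.
#' @export
single_factor_scan <- function(codes, phenotypes, retained = NULL,
                               map = NULL) {
  lines <- intersect(colnames(codes), phenotypes$individual)
  if (!is.null(retained)) lines <- intersect(lines, retained)
  dropped <- sum(!(colnames(codes) %in% phenotypes$individual))
  if (dropped > 0)
    message(dropped, " line(s) without phenotype records dropped from scan")
  if (length(lines) < 3)
    stop("fewer than 3 lines with genotype codes and phenotypes",
         call. = FALSE)
  y <- phenotypes$value[match(lines, phenotypes$individual)]
  if (stats::var(y) == 0)
    warning("zero phenotypic variance: no marker is testable",
            call. = FALSE)
  cm <- codes[, lines, drop = FALSE]

  one <- function(x) {
    ok <- !is.na(x)
    n <- sum(ok)
    if (n < 3 || length(unique(x[ok])) < 2 || stats::var(y[ok]) == 0)
      return(c(n, NA_real_, NA_real_, NA_real_))
    r2 <- stats::cor(x[ok], y[ok])^2
    fstat <- (n - 2) * r2 / (1 - r2)
    c(n, r2, fstat, stats::pf(fstat, 1, n - 2, lower.tail = FALSE))
  }
  res <- t(apply(cm, 1, one))
  out <- data.frame(marker = rownames(cm), n_used = as.integer(res[, 1]),
                    r2 = res[, 2], fstat = res[, 3], p = res[, 4],
                    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(map)) {
    i <- match(out$marker, map$marker)
    out <- data.frame(out[, "marker", drop = FALSE],
                      chrom = map$chrom[i], pos = map$pos[i],
                      out[, c("n_used", "r2", "fstat", "p")],
                      stringsAsFactors = FALSE)
  }
  structure(out, class = c("qtl_scan", "data.frame"))
}

#' @export
print.qtl_scan <- function(x, ...) {
  cat("qtl_scan: ", nrow(x), " markers (",
      sum(is.na(x$r2)), " not testable)\n", sep = "")
  top <- x[order(-replace(x$r2, is.na(x$r2), -1)), ]
  print.data.frame(utils::head(top, 5))
  invisible(x)
}

#' QTL scan across variant-exclusion thresholds
#'
#' Re-runs the single-marker scan after excluding flagged lines at each
#' similarity threshold, plus a baseline at threshold 0 (no exclusion), and
#' reports the maximum variance explained and the marker attaining it. The
#' number of excluded lines is non-decreasing in the threshold.
#'
#' @param codes Numeric code matrix from [encode_genotypes()].
#' @param phenotypes Phenotype data.frame (`individual`, `value`).
#' @param report A [similarity_report()] for the same lines.
#' @param thresholds Ascending similarity thresholds; 0 (baseline) is added
#'   if absent.
#' @param rule Flag rule, see [flag_variants()].
#' @param map Optional marker map for marker annotation.
#' @return A data.frame with columns `threshold`, `n_excluded`, `n_used`,
#'   `max_r2`, `marker`.
#' @export
compare_across_thresholds <- function(codes, phenotypes, report,
                                      thresholds = c(0.90, 0.95, 0.99),
                                      rule = c("strict", "inclusive"),
                                      map = NULL) {
  rule <- match.arg(rule)
  thresholds <- sort(unique(c(0, thresholds)))
  if (is.unsorted(thresholds)) stop("thresholds must be ascending")
  rows <- lapply(thresholds, function(t) {
    if (t == 0) {
      retained <- report$individual
    } else {
      retained <- flag_variants(report, t, rule)$retained
    }
    scan <- single_factor_scan(codes, phenotypes, retained = retained,
                               map = map)
    best <- which.max(replace(scan$r2, is.na(scan$r2), -Inf))
    data.frame(threshold = t,
               n_excluded = nrow(report) - length(retained),
               n_used = scan$n_used[best], max_r2 = scan$r2[best],
               marker = scan$marker[best], stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
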