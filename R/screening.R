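#' Flag putative variants below a similarity threshold
#'
#' Offspring whose similarity falls below the threshold are flagged as
#' putative variants (outcross, seed mixture, sample or genotyping error).
#' The default rule is strict (`S < t`): an offspring sitting exactly at the
#' threshold is retained. The inclusive alternative (`S <= t`) is exposed
#' because published usage mixes the two conventions; the choice should be
#' deliberate, not silent. Offspring with undefined S (no scored loci) are
#' always flagged and listed separately: parentage cannot be certified
#' without data.
#'
#' @param report A [similarity_report()].
#' @param threshold Similarity threshold in `(0, 1]`.
#' @param rule `"strict"` flags `S < threshold`; `"inclusive"` flags
#'   `S <= threshold`.
#' @return A list of class `variant_flags`: `threshold`, `rule`, `flagged`
#'   (ids below threshold, including those with undefined S), `retained`,
#'   and `undefined` (the subset of `flagged` with no scored loci).
#' @examples
#' \dontrun{flag_variants(report, 0.90)}
#' @export
flag_variants <- function(report, threshold, rule = c("strict", "inclusive")) {
  rule <- match.arg(rule)
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      is.na(threshold) || threshold <= 0 || threshold > 1)
    stop("threshold must be a single number in (0, 1]", call. = FALSE)
  s <- report$S
  low <- if (rule == "strict") s < threshold else s <= threshold
  undef <- is.na(s)
  flag <- undef | (low %in% TRUE)
  structure(list(threshold = threshold, rule = rule,
                 flagged = report$individual[flag],
                 retained = report$individual[!flag],
                 undefined = report$individual[undef]),
            class = "variant_flags")
}

#' @export
print.variant_flags <- function(x, ...) {
  cat("variant_flags at threshold ", x$threshold, " (", x$rule, "): ",
      length(x$flagged), " flagged, ", length(x$retained), " retained",
      if (length(x$undefined)) paste0(" (", length(x$undefined),
                                      " with undefined S)"), "\n", sep = "")
  invisible(x)
}

#' Partition a genotype matrix by locus classification
#'
#' Splits the marker rows into the monomorphic, polymorphic and excluded
#' sets. Marker sets are disjoint, their union is the full panel, and the
#' individuals are unchanged in each part; an empty part is a valid 0-row
#' matrix that still round-trips through the table writer.
#'
#' @param x A [genotype_matrix()].
#' @param classification [classify_loci()] result from the same matrix.
#' @return A list with `genotype_matrix` elements `monomorphic`,
#'   `polymorphic`, `excluded`.
#' @export
partition_dataset <- function(x, classification) {
  if (!identical(classification$marker, markers(x)))
    stop("classification does not match the matrix markers", call. = FALSE)
  lapply(c(monomorphic = "monomorphic", polymorphic = "polymorphic",
           excluded = "excluded"),
         function(st) x[classification$status == st, , drop = FALSE])
}

#' Tabulate locus classifications per chromosome
#'
#' @param classification A [classify_loci()] result.
#' @param map A marker map data.frame (`marker`, `chrom`, `pos`) covering
#'   every classified marker.
#' @return A data.frame with one row per chromosome and columns `chrom`,
#'   `monomorphic`, `polymorphic`, `excluded`; column sums equal the global
#'   classification counts.
#' @export
summarize_by_chromosome <- function(classification, map) {
  absent <- setdiff(classification$marker, map$marker)
  if (length(absent))
    stop("marker(s) absent from map: ",
         paste(utils::head(absent, 10), collapse = ", "),
         if (length(absent) > 10) ", ...", call. = FALSE)
  chrom <- map$chrom[match(classification$marker, map$marker)]
  tab <- table(chrom = chrom,
               status = factor(classification$status,
                               levels = c("monomorphic", "polymorphic",
                                          "excluded")))
  out <- as.data.frame.matrix(tab)
  data.frame(chrom = rownames(out), out, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Histogram of similarity values
#'
#' Bins are left-closed, right-open, with the last bin closed on the right,
#' so counts over any covering set of edges sum to the number of offspring
#' with a defined S.
#'
#' @param report A [similarity_report()].
#' @param bin_edges Strictly increasing numeric edges covering `[0, 1]`.
#' @return A data.frame with columns `lower`, `upper`, `count`.
#' @examples
#' \dontrun{similarity_histogram(report, seq(0, 1, by = 0.05))}
#' @export
similarity_histogram <- function(report, bin_edges = seq(0, 1, by = 0.05)) {
  e <- as.numeric(bin_edges)
  if (length(e) < 2 || any(diff(e) <= 0))
    stop("bin edges must be strictly increasing", call. = FALSE)
  if (e[1] > 0 || e[length(e)] < 1)
    stop("bin edges must cover [0, 1]", call. = FALSE)
  s <- report$S[!is.na(report$S)]
  idx <- findInterval(s, e, rightmost.closed = TRUE)
  k <- length(e) - 1L
  data.frame(lower = e[-length(e)], upper = e[-1],
             count = tabulate(idx, nbins = k))
}
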