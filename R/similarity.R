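#' @title Scoring progeny against parents at monomorphic loci
#' @name trio_core
#' @description
#' At a locus where both parents are homozygous for the same allele, a
#' progeny call is scored by the number of its alleles that match that
#' shared parental allele: 2 (both parental), 1 (one parental, one foreign)
#' or 0 (no parental allele, including a heterozygote of two foreign
#' alleles). Over all scored monomorphic loci the similarity of an offspring
#' to its parents is
#' \deqn{S = (2a + b) / (2a + 2b + 2c)}
#' where a, b, c count loci scored 2, 1 and 0 — equivalently the fraction of
#' the offspring's alleles at scored monomorphic loci that are parental. A
#' missing progeny call contributes to none of a, b, c; it is tallied
#' separately (m) and shrinks the denominator, so assay failure is never
#' conflated with non-parentage.
NULL

#' Score progeny calls against the shared parental allele
#'
#' @param parent_allele Single-character shared parental allele(s); recycled
#'   against `calls`.
#' @param calls Canonical progeny calls (vector or matrix).
#' @return Integer scores in `{0, 1, 2}`, `NA` for missing calls. Matrix
#'   input yields a matrix of the same shape.
#' @examples
#' score_calls("A", c("AA", "AT", "TT", NA))
#' @export
score_calls <- function(parent_allele, calls) {
  sc <- ((.allele1(calls) == parent_allele) +
         (.allele2(calls) == parent_allele))
  sc <- as.integer(sc)
  if (is.matrix(calls)) {
    dim(sc) <- dim(calls)
    dimnames(sc) <- dimnames(calls)
  } else {
    names(sc) <- names(calls)
  }
  sc
}

#' Tally 0/1/2 scores for one offspring over the monomorphic loci
#'
#' @param x A [genotype_matrix()].
#' @param classification A [classify_loci()] result from the same matrix.
#' @param offspring Individual id present in `x`.
#' @return Named integer vector `c(a, b, c, m)`: counts of loci scored 2, 1
#'   and 0, and of missing progeny calls. `a + b + c + m` equals the number
#'   of monomorphic loci.
#' @export
count_scores <- function(x, classification, offspring) {
  if (!offspring %in% individuals(x))
    stop("offspring id not found in genotype matrix: ", offspring,
         call. = FALSE)
  mono <- classification$status == "monomorphic"
  shared <- classification$allele_shared[mono]
  calls <- unclass(x)[classification$marker[mono], offspring]
  sc <- score_calls(shared, calls)
  c(a = sum(sc == 2L, na.rm = TRUE), b = sum(sc == 1L, na.rm = TRUE),
    c = sum(sc == 0L, na.rm = TRUE), m = sum(is.na(sc)))
}

#' Parent-offspring similarity from score counts
#'
#' \eqn{S = (2a+b) / (2(a+b+c))}: the fraction of parental alleles carried
#' by the offspring across scored monomorphic loci. Undefined (returned as
#' `NA`, with a warning) when no locus was scored (`a+b+c = 0`).
#'
#' @param a,b,c Counts of loci scored 2, 1 and 0. `a` may also be the full
#'   named vector from [count_scores()], in which case `b` and `c` are taken
#'   from it.
#' @return Similarity in `[0, 1]`, or `NA`.
#' @examples
#' similarity(938, 0, 0)   # perfect offspring
#' similarity(1, 1, 1)     # 0.5
#' @export
similarity <- function(a, b = NULL, c = NULL) {
  if (is.null(b) && is.null(c) && !is.null(names(a))) {
    b <- a[["b"]]; c <- a[["c"]]; a <- a[["a"]]
  }
  stopifnot(all(a >= 0), all(b >= 0), all(c >= 0))
  denom <- a + b + c
  s <- ifelse(denom > 0, (2 * a + b) / (2 * denom), NA_real_)
  if (anyNA(s))
    warning("similarity undefined for ", sum(is.na(s)),
            " offspring with no scored monomorphic loci", call. = FALSE)
  s
}

#' Per-offspring similarity report
#'
#' Classifies loci (unless a classification is supplied), tallies 0/1/2
#' scores for every offspring over the monomorphic loci, and computes the
#' similarity statistic S for each.
#'
#' @param x A [genotype_matrix()].
#' @param parent1,parent2 Parent individual ids.
#' @param offspring Individual ids to score; default all individuals except
#'   the parents.
#' @param classification Optional precomputed [classify_loci()] result.
#' @return A data.frame of class `similarity_report` with columns
#'   `individual`, `a`, `b`, `c`, `m`, `S`. Attributes: `parents`,
#'   `classification`, `n_monomorphic`.
#' @export
similarity_report <- function(x, parent1, parent2, offspring = NULL,
                              classification = NULL) {
  if (is.null(classification))
    classification <- classify_loci(x, parent1, parent2)
  if (is.null(offspring))
    offspring <- setdiff(individuals(x), c(parent1, parent2))
  absent <- setdiff(offspring, individuals(x))
  if (length(absent))
    stop("offspring id(s) not found in genotype matrix: ",
         paste(absent, collapse = ", "), call. = FALSE)
  mono <- classification$status == "monomorphic"
  shared <- classification$allele_shared[mono]
  calls <- unclass(x)[classification$marker[mono], offspring, drop = FALSE]
  sc <- score_calls(shared, calls)
  a <- colSums(sc == 2L, na.rm = TRUE)
  b <- colSums(sc == 1L, na.rm = TRUE)
  cc <- colSums(sc == 0L, na.rm = TRUE)
  m <- colSums(is.na(sc))
  s <- suppressWarnings(similarity(a, b, cc))
  if (anyNA(s))
    warning("similarity undefined for ", sum(is.na(s)),
            " offspring with no scored monomorphic loci", call. = FALSE)
  structure(
    data.frame(individual = offspring, a = unname(a), b = unname(b),
               c = unname(cc), m = unname(m), S = unname(s),
               stringsAsFactors = FALSE),
    parents = attr(classification, "parents"),
    classification = classification,
    n_monomorphic = sum(mono),
    class = c("similarity_report", "data.frame"))
}

#' @export
print.similarity_report <- function(x, ...) {
  par <- attr(x, "parents")
  cat("similarity_report: ", nrow(x), " offspring vs parents ",
      par[1], " x ", par[2], " over ", attr(x, "n_monomorphic"),
      " monomorphic loci\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("... (", nrow(x) - 10, " more)\n", sep = "")
  invisible(x)
}

#' Write a similarity report with flag columns
#'
#' Tab-separated output: one row per offspring with the score counts, S,
#' and one logical flag column per threshold. Column semantics are
#' documented in `#`-prefixed header comment lines.
#'
#' @param report A [similarity_report()].
#' @param path Output path.
#' @param thresholds Similarity thresholds for the flag columns.
#' @param rule Flag rule, see [flag_variants()].
#' @return `path`, invisibly.
#' @export
write_similarity_report <- function(report, path,
                                    thresholds = c(0.90, 0.95, 0.99),
                                    rule = c("strict", "inclusive")) {
  rule <- match.arg(rule)
  df <- as.data.frame(report)
  for (t in thresholds) {
    fl <- flag_variants(report, t, rule)
    df[[sprintf("flag_%g", t)]] <- df$individual %in% fl$flagged
  }
  par <- attr(report, "parents")
  hdr <- c(
    paste0("# parent-offspring similarity report; parents ", par[1], " x ",
           par[2], "; ", attr(report, "n_monomorphic"), " monomorphic loci"),
    "# a,b,c: monomorphic loci scored 2/1/0; m: missing progeny calls",
    "# S = (2a+b)/(2(a+b+c)); NA when no locus scored",
    paste0("# flag_<t>: TRUE if flagged as variant at threshold t (rule: ",
           rule, ")"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
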