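#' Classify loci by parental polymorphism status
#'
#' Given the calls of the two inbred parents, every marker receives exactly
#' one status: *monomorphic* (both parents homozygous, non-missing, for the
#' same allele), *polymorphic* (both parents homozygous, non-missing, for
#' different alleles), or *excluded*. A locus is excluded when either parent
#' is missing (`parent_missing`) or heterozygous (`parent_heterozygous`):
#' the 0/1/2 scoring and the similarity formula are defined only for
#' identical homozygous parents, and a heterozygous call in an inbred parent
#' is an anomaly worth surfacing rather than silently scoring.
#'
#' @param x A [genotype_matrix()].
#' @param parent1,parent2 Individual ids of the two parents; must be present
#'   in `x`.
#' @return A data.frame of class `locus_classification` with columns
#'   `marker`, `status` (`"monomorphic"`, `"polymorphic"`, `"excluded"`),
#'   `reason` (`NA`, `"parent_missing"` or `"parent_heterozygous"`),
#'   `allele_shared` (the common parental allele at monomorphic loci),
#'   `allele_p1`, `allele_p2` (parental alleles at polymorphic loci).
#'   Attributes `parents` and `counts` record the parent ids and the status
#'   tally.
#' @examples
#' calls <- rbind(m1 = c("AA", "AA", "AA"), m2 = c("AA", "GG", "AG"))
#' colnames(calls) <- c("P1", "P2", "L1")
#' classify_loci(genotype_matrix(calls), "P1", "P2")
#' @export
classify_loci <- function(x, parent1, parent2) {
  for (p in c(parent1, parent2))
    if (!p %in% individuals(x))
      stop("parent id not found in genotype matrix: ", p, call. = FALSE)
  p1 <- unclass(x)[, parent1]
  p2 <- unclass(x)[, parent2]
  p1a <- .allele1(p1); p1b <- .allele2(p1)
  p2a <- .allele1(p2); p2b <- .allele2(p2)

  miss <- is.na(p1) | is.na(p2)
  het <- !miss & (p1a != p1b | p2a != p2b)
  mono <- !miss & !het & p1a == p2a
  poly <- !miss & !het & p1a != p2a

  status <- character(nrow(x))
  status[mono] <- "monomorphic"
  status[poly] <- "polymorphic"
  status[miss | het] <- "excluded"
  reason <- rep(NA_character_, nrow(x))
  reason[miss] <- "parent_missing"
  reason[het & !miss] <- "parent_heterozygous"

  cl <- data.frame(marker = markers(x), status = status, reason = reason,
                   allele_shared = ifelse(mono, p1a, NA_character_),
                   allele_p1 = ifelse(poly, p1a, NA_character_),
                   allele_p2 = ifelse(poly, p2a, NA_character_),
                   stringsAsFactors = FALSE)
  structure(cl,
            parents = c(parent1 = parent1, parent2 = parent2),
            counts = c(monomorphic = sum(mono), polymorphic = sum(poly),
                       excluded = sum(miss | het)),
            class = c("locus_classification", "data.frame"))
}

#' @export
print.locus_classification <- function(x, ...) {
  cnt <- attr(x, "counts")
  par <- attr(x, "parents")
  cat("locus_classification for parents ", par[1], " x ", par[2], ":\n",
      "  monomorphic ", cnt["monomorphic"],
      ", polymorphic ", cnt["polymorphic"],
      ", excluded ", cnt["excluded"], "\n", sep = "")
  invisible(x)
}
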