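#' @title Genotype matrices and call normalization
#' @name genotype_matrix
#' @description
#' A `genotype_matrix` holds diploid allele calls for a fixed SNP panel as a
#' character matrix with markers in rows and individuals in columns. Each
#' cell is a canonical two-letter call with alleles sorted alphabetically
#' (`"AG"`, never `"GA"`), or `NA` for a missing call. Allele order is never
#' meaningful; sorting at construction makes calls order-insensitive and
#' makes normalization idempotent.
NULL

#' Default missing-data tokens accepted on input
#'
#' @format Character vector of tokens treated as a missing call when reading
#'   genotype tables.
#' @export
MISSING_TOKENS_DEFAULT <- c("--", "NA", "", ".", "./.")

# IUPAC nucleotide ambiguity codes for the six biallelic heterozygotes.
.IUPAC_HET <- c(R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC")

# Normalize a character vector of raw call tokens to canonical two-letter
# sorted calls. Returns a list with `calls` (NA where missing or bad) and
# `bad` (logical: token neither parseable nor a declared missing token).
.normalize_tokens <- function(x, missing_tokens = MISSING_TOKENS_DEFAULT) {
  x <- trimws(as.character(x))
  out <- rep(NA_character_, length(x))
  bad <- rep(FALSE, length(x))
  miss <- is.na(x) | x %in% missing_tokens
  n <- nchar(x)
  n[is.na(x)] <- 0L

  one <- !miss & n == 1L
  if (any(one)) {
    up <- toupper(x[one])
    het <- up %in% names(.IUPAC_HET)
    hom <- grepl("^[A-Z0-9]$", up) & !het
    res <- rep(NA_character_, sum(one))
    res[het] <- unname(.IUPAC_HET[up[het]])
    res[hom] <- paste0(up[hom], up[hom])
    out[one] <- res
    bad[one] <- !(het | hom)
  }

  two <- !miss & n == 2L
  if (any(two)) {
    a1 <- toupper(substr(x[two], 1L, 1L))
    a2 <- toupper(substr(x[two], 2L, 2L))
    ok <- grepl("^[A-Z0-9]$", a1) & grepl("^[A-Z0-9]$", a2)
    out[two][ok] <- paste0(pmin(a1, a2), pmax(a1, a2))[ok]
    bad[two] <- !ok
  }

  sla <- !miss & n == 3L & substr(x, 2L, 2L) %in% c("/", "|")
  if (any(sla)) {
    a1 <- toupper(substr(x[sla], 1L, 1L))
    a2 <- toupper(substr(x[sla], 3L, 3L))
    ok <- grepl("^[A-Z0-9]$", a1) & grepl("^[A-Z0-9]$", a2)
    out[sla][ok] <- paste0(pmin(a1, a2), pmax(a1, a2))[ok]
    bad[sla] <- !ok
  }

  bad[!miss & !one & !two & !sla] <- TRUE
  list(calls = out, bad = bad)
}

#' Normalize genotype call tokens to canonical form
#'
#' Accepts two-letter calls (`"AG"`), slash- or pipe-separated calls
#' (`"A/G"`), single letters for homozygotes (`"A"`), and IUPAC ambiguity
#' codes for heterozygotes (`"R"` = A/G, `"W"` = A/T, ...). Alleles are
#' sorted so that `(A,T)` and `(T,A)` yield the same canonical call.
#'
#' @param x Character vector of raw call tokens.
#' @param missing_tokens Tokens mapped to a missing call (`NA`).
#' @return Character vector of canonical two-letter calls, `NA` for missing.
#' @examples
#' normalize_calls(c("AA", "A/T", "W", "TA", "--"))
#' @export
normalize_calls <- function(x, missing_tokens = MISSING_TOKENS_DEFAULT) {
  res <- .normalize_tokens(x, missing_tokens)
  if (any(res$bad)) {
    i <- which(res$bad)[1]
    stop("unparseable genotype call token '", x[i], "' at position ", i,
         call. = FALSE)
  }
  res$calls
}

#' Construct a genotype matrix
#'
#' @param calls Character matrix of canonical calls (markers x individuals),
#'   or raw tokens which will be normalized.
#' @param marker_ids,individual_ids Row/column identifiers; default taken
#'   from `dimnames(calls)`. Must be unique and non-missing.
#' @param missing_tokens Passed to [normalize_calls()].
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(calls, marker_ids = rownames(calls),
                            individual_ids = colnames(calls),
                            missing_tokens = MISSING_TOKENS_DEFAULT) {
  if (!is.matrix(calls)) stop("`calls` must be a matrix", call. = FALSE)
  if (is.null(marker_ids) || is.null(individual_ids))
    stop("marker and individual ids are required", call. = FALSE)
  marker_ids <- as.character(marker_ids)
  individual_ids <- as.character(individual_ids)
  if (anyDuplicated(marker_ids))
    stop("duplicate marker id: ",
         paste(unique(marker_ids[duplicated(marker_ids)]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(individual_ids))
    stop("duplicate individual id: ",
         paste(unique(individual_ids[duplicated(individual_ids)]),
               collapse = ", "), call. = FALSE)
  if (length(marker_ids) != nrow(calls) ||
      length(individual_ids) != ncol(calls))
    stop("id lengths do not match matrix dimensions", call. = FALSE)
  norm <- matrix(normalize_calls(calls, missing_tokens),
                 nrow = nrow(calls),
                 dimnames = list(marker_ids, individual_ids))
  structure(norm, class = c("genotype_matrix", "matrix"))
}

#' @export
`[.genotype_matrix` <- function(x, i, j, ..., drop = FALSE) {
  y <- unclass(x)[i, j, drop = FALSE]
  structure(y, class = class(x))
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix: ", nrow(x), " markers x ", ncol(x),
      " individuals (", sum(is.na(x)), " missing calls)\n", sep = "")
  k <- min(5L, nrow(x)); m <- min(6L, ncol(x))
  print(unclass(x)[seq_len(k), seq_len(m), drop = FALSE], quote = FALSE)
  if (nrow(x) > k || ncol(x) > m) cat("...\n")
  invisible(x)
}

#' Marker identifiers of a genotype matrix
#' @param x A `genotype_matrix`.
#' @return Character vector.
#' @export
markers <- function(x) rownames(x)

#' Individual identifiers of a genotype matrix
#' @param x A `genotype_matrix`.
#' @return Character vector.
#' @export
individuals <- function(x) colnames(x)

# Split canonical calls into their two allele characters.
.allele1 <- function(calls) substr(calls, 1L, 1L)
.allele2 <- function(calls) substr(calls, 2L, 2L)
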