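#' @title Reading and writing genotype tables, marker maps and phenotypes
#' @name genotype_io
#' @description
#' The canonical on-disk dialect is a tab-separated table with markers in
#' rows: first column the marker id, header row of individual ids, calls as
#' two-letter strings, missing calls written `"--"`. The transposed layout
#' (individuals in rows) is accepted via the `orientation` argument and
#' internalized, so downstream code always sees markers x individuals.
NULL

.read_delim_matrix <- function(path, sep = "\t") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L)
    stop("genotype table needs a header row and at least one data row: ",
         path, call. = FALSE)
  cells <- strsplit(lines, sep, fixed = TRUE)
  widths <- lengths(cells)
  if (any(widths != widths[1]))
    stop("ragged row ", which(widths != widths[1])[1], " in ", path,
         " (expected ", widths[1], " fields, found ",
         widths[widths != widths[1]][1], ")", call. = FALSE)
  header <- cells[[1]]
  body <- do.call(rbind, cells[-1])
  list(row_ids = body[, 1], col_ids = header[-1],
       cells = body[, -1, drop = FALSE])
}

#' Read a genotype table
#'
#' @param path Path to a delimited text table with a header row and ids in
#'   the first column. Lines starting with `#` are ignored.
#' @param orientation `"markers"` if markers are in rows (canonical),
#'   `"individuals"` if individuals are in rows; the result is always
#'   markers x individuals.
#' @param missing_tokens Tokens read as missing calls.
#' @param sep Field separator.
#' @return A [genotype_matrix()].
#' @export
read_genotype_table <- function(path,
                                orientation = c("markers", "individuals"),
                                missing_tokens = MISSING_TOKENS_DEFAULT,
                                sep = "\t") {
  orientation <- match.arg(orientation)
  tab <- .read_delim_matrix(path, sep)
  norm <- .normalize_tokens(tab$cells, missing_tokens)
  if (any(norm$bad)) {
    i <- which(norm$bad)[1]
    rc <- arrayInd(i, dim(tab$cells))
    stop("unparseable call token '", tab$cells[i], "' at data row ",
         rc[1], ", column ", rc[2], " of ", path, call. = FALSE)
  }
  calls <- matrix(norm$calls, nrow = nrow(tab$cells),
                  dimnames = list(tab$row_ids, tab$col_ids))
  if (orientation == "individuals") calls <- t(calls)
  genotype_matrix(calls, missing_tokens = missing_tokens)
}

#' Write a genotype table
#'
#' Inverse of [read_genotype_table()]: `read_genotype_table()` applied to
#' the written file recovers the matrix exactly.
#'
#' @param x A `genotype_matrix`.
#' @param path Output path.
#' @param orientation Row layout, as in [read_genotype_table()].
#' @param missing_token Token written for missing calls.
#' @param sep Field separator.
#' @param id_column Name of the leading id column in the header.
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(x, path, orientation = c("markers",
                                 "individuals"), missing_token = "--",
                                 sep = "\t", id_column = "id") {
  orientation <- match.arg(orientation)
  m <- unclass(x)
  if (orientation == "individuals") m <- t(m)
  m[is.na(m)] <- missing_token
  header <- paste(c(id_column, colnames(m)), collapse = sep)
  rows <- paste(rownames(m), apply(m, 1, paste, collapse = sep), sep = sep)
  ok <- tryCatch({
    writeLines(c(header, rows), path); TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write genotype table to ", path, call. = FALSE)
  invisible(path)
}

#' Read a marker map
#'
#' A tab-separated table with columns marker, chromosome, position (1-based,
#' base pairs or centimorgans; the unit is the user's convention and is not
#' interpreted).
#'
#' @param path Path to the map file.
#' @param sep Field separator.
#' @return A data.frame with columns `marker`, `chrom`, `pos`.
#' @export
read_marker_map <- function(path, sep = "\t") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = c("character", "character", "numeric"),
                          comment.char = "#", stringsAsFactors = FALSE)
  if (ncol(df) != 3L)
    stop("marker map must have 3 columns (marker, chrom, pos): ", path,
         call. = FALSE)
  names(df) <- c("marker", "chrom", "pos")
  if (anyDuplicated(df$marker))
    stop("duplicate marker id in map: ",
         paste(unique(df$marker[duplicated(df$marker)]), collapse = ", "),
         call. = FALSE)
  if (any(df$pos < 0)) stop("negative map position", call. = FALSE)
  df
}

#' Write a marker map
#' @param map A marker map data.frame (`marker`, `chrom`, `pos`).
#' @param path Output path.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_marker_map <- function(map, path, sep = "\t") {
  utils::write.table(map, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a phenotype table
#'
#' Two tab-separated columns: individual id and a finite numeric trait
#' value. Phenotypes must be complete; a missing or non-numeric value is a
#' hard error (pre-filter incomplete records before use).
#'
#' @param path Path to the phenotype file.
#' @param sep Field separator.
#' @return A data.frame with columns `individual`, `value`.
#' @export
read_phenotypes <- function(path, sep = "\t") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", comment.char = "#",
                          stringsAsFactors = FALSE)
  if (ncol(df) != 2L)
    stop("phenotype table must have 2 columns (individual, value): ", path,
         call. = FALSE)
  names(df) <- c("individual", "value")
  val <- suppressWarnings(as.numeric(df$value))
  bad <- is.na(val) | !is.finite(val)
  if (any(bad))
    stop("non-numeric or missing phenotype for individual(s): ",
         paste(df$individual[bad], collapse = ", "), call. = FALSE)
  if (anyDuplicated(df$individual))
    stop("duplicate individual id in phenotypes: ",
         paste(unique(df$individual[duplicated(df$individual)]),
               collapse = ", "), call. = FALSE)
  data.frame(individual = df$individual, value = val,
             stringsAsFactors = FALSE)
}

#' Import genotypes from a VCF file
#'
#' Reads biallelic SNP records with a GT field and resolves genotype indices
#' to REF/ALT nucleotides. Multiallelic records are skipped with a warning
#' reporting the count; half-missing genotypes (e.g. `"./1"`) are coerced to
#' missing. CHROM/POS populate the returned marker map (1-based, as in the
#' VCF standard).
#'
#' @param path Path to a VCF 4.x file (plain or bgzipped).
#' @return A list with elements `genotypes` (a [genotype_matrix()]) and
#'   `map` (marker map data.frame).
#' @export
import_vcf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (nrow(v@gt) == 0 || !("FORMAT" %in% colnames(v@gt)))
    stop("VCF has no genotype (FORMAT) data: ", path, call. = FALSE)
  has_gt <- grepl("(^|:)GT(:|$)", v@gt[, "FORMAT"])
  if (!all(has_gt))
    stop("GT missing from FORMAT at record ", which(!has_gt)[1], call. = FALSE)
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi)) {
    warning(sum(multi), " multiallelic record(s) skipped", call. = FALSE)
  }
  keep <- !multi
  if (!any(keep)) stop("no biallelic records in ", path, call. = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")[keep, , drop = FALSE]
  ref <- fix[keep, "REF"]; alt <- fix[keep, "ALT"]
  ids <- fix[keep, "ID"]
  noid <- is.na(ids) | ids == "."
  ids[noid] <- paste0(fix[keep, "CHROM"], "_", fix[keep, "POS"])[noid]

  a1 <- sub("[/|].*$", "", gt)
  a2 <- sub("^.*[/|]", "", gt)
  lk <- function(idx, i) ifelse(idx == "0", ref[i],
                         ifelse(idx == "1", alt[i], NA_character_))
  i <- row(gt)
  c1 <- lk(a1, i); c2 <- lk(a2, i)
  calls <- ifelse(is.na(gt) | is.na(c1) | is.na(c2), NA_character_,
                  paste0(pmin(c1, c2), pmax(c1, c2)))
  dim(calls) <- dim(gt)
  dimnames(calls) <- list(ids, colnames(gt))
  list(genotypes = genotype_matrix(calls),
       map = data.frame(marker = ids, chrom = fix[keep, "CHROM"],
                        pos = as.numeric(fix[keep, "POS"]),
                        stringsAsFactors = FALSE))
}
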