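#' @title Workflow orchestration
#' @name workflow
#' @description
#' The `run_*` functions compose the module functions into the four
#' workflow steps — parentage check, dataset partitioning, population
#' simulation and the QTL threshold comparison — writing tab-separated
#' results under an output directory. They back the `snptrio` command-line
#' script (`inst/cli/snptrio.R`) and are deterministic functions of their
#' inputs and seed: reruns produce byte-identical files. Progress and
#' warnings go to the message stream; results go to files only.
NULL

.out_path <- function(out_dir, name) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  file.path(out_dir, name)
}

.write_json_summary <- function(summary, path) {
  pairs <- vapply(names(summary), function(k) {
    v <- summary[[k]]
    val <- if (is.character(v))
      paste0('"', v, '"')
    else paste0(format(v, scientific = FALSE, trim = TRUE), collapse = ", ")
    if (length(v) > 1) val <- paste0("[", val, "]")
    paste0('  "', k, '": ', val)
  }, character(1))
  writeLines(c("{", paste0(pairs, collapse = ",\n"), "}"), path)
  invisible(path)
}

#' Run the parent-offspring check
#'
#' Reads a genotype table, classifies loci against the named parents,
#' computes the similarity report, and writes the report (with flag columns
#' at each threshold), per-threshold flagged-line lists, and optionally a
#' per-chromosome classification summary.
#'
#' @param genotype_file Path to a genotype table.
#' @param parents Character vector of the two parent ids.
#' @param thresholds Similarity thresholds for flagging.
#' @param out_dir Output directory (created if needed).
#' @param orientation,missing_tokens Passed to [read_genotype_table()].
#' @param rule Flag rule, see [flag_variants()].
#' @param map_file Optional marker map path; enables the chromosome summary.
#' @param json_summary Write `run_summary.json` with run metadata.
#' @return Invisibly, a list with the report, classification and flag sets.
#' @export
run_check <- function(genotype_file, parents,
                      thresholds = c(0.90, 0.95, 0.99), out_dir = ".",
                      orientation = "markers",
                      missing_tokens = MISSING_TOKENS_DEFAULT,
                      rule = c("strict", "inclusive"), map_file = NULL,
                      json_summary = FALSE) {
  rule <- match.arg(rule)
  stopifnot(length(parents) == 2)
  x <- read_genotype_table(genotype_file, orientation = orientation,
                           missing_tokens = missing_tokens)
  cl <- classify_loci(x, parents[1], parents[2])
  rep <- similarity_report(x, parents[1], parents[2], classification = cl)
  write_similarity_report(rep, .out_path(out_dir, "similarity_report.tsv"),
                          thresholds = thresholds, rule = rule)
  flags <- lapply(thresholds, function(t) flag_variants(rep, t, rule))
  names(flags) <- sprintf("%g", thresholds)
  for (t in names(flags))
    writeLines(flags[[t]]$flagged,
               .out_path(out_dir, sprintf("flagged_%s.txt", t)))
  if (!is.null(map_file)) {
    map <- read_marker_map(map_file)
    utils::write.table(summarize_by_chromosome(cl, map),
                       .out_path(out_dir, "chromosome_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  cnt <- attr(cl, "counts")
  message("classified ", nrow(cl), " markers: ", cnt["monomorphic"],
          " monomorphic, ", cnt["polymorphic"], " polymorphic, ",
          cnt["excluded"], " excluded")
  for (t in names(flags))
    message("threshold ", t, ": ", length(flags[[t]]$flagged),
            " flagged line(s)")
  if (json_summary)
    .write_json_summary(
      list(n_markers = nrow(cl), n_offspring = nrow(rep),
           n_monomorphic = unname(cnt["monomorphic"]),
           n_polymorphic = unname(cnt["polymorphic"]),
           n_excluded = unname(cnt["excluded"]),
           thresholds = thresholds,
           n_flagged = vapply(flags, function(f) length(f$flagged),
                              numeric(1)),
           rule = rule),
      .out_path(out_dir, "run_summary.json"))
  invisible(list(report = rep, classification = cl, flags = flags))
}

#' Partition a genotype table by parental polymorphism status
#'
#' Writes `monomorphic.tsv`, `polymorphic.tsv` and `excluded.tsv` in the
#' canonical genotype-table dialect.
#'
#' @inheritParams run_check
#' @return Invisibly, the list of partitioned matrices.
#' @export
run_partition <- function(genotype_file, parents, out_dir = ".",
                          orientation = "markers",
                          missing_tokens = MISSING_TOKENS_DEFAULT) {
  stopifnot(length(parents) == 2)
  x <- read_genotype_table(genotype_file, orientation = orientation,
                           missing_tokens = missing_tokens)
  cl <- classify_loci(x, parents[1], parents[2])
  parts <- partition_dataset(x, cl)
  for (nm in names(parts))
    write_genotype_table(parts[[nm]],
                         .out_path(out_dir, paste0(nm, ".tsv")))
  message("partitioned ", nrow(x), " markers into ",
          paste(vapply(parts, nrow, integer(1)), collapse = "/"),
          " (monomorphic/polymorphic/excluded)")
  invisible(parts)
}

#' Simulate a RIL population to files
#'
#' @param config A [sim_config()], or a path to a YAML configuration file.
#' @param out_dir Output directory; writes `genotypes.tsv`, `map.tsv` and
#'   `truth.tsv`.
#' @param seed Optional override of the configuration seed.
#' @return Invisibly, the `ril_sim` object.
#' @export
run_simulate <- function(config, out_dir = ".", seed = NULL) {
  if (is.character(config)) config <- read_sim_config(config)
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) config$seed <- as.integer(seed)
  sim <- simulate_ril_population(config)
  write_genotype_table(sim$genotypes, .out_path(out_dir, "genotypes.tsv"))
  write_marker_map(sim$map, .out_path(out_dir, "map.tsv"))
  write_truth_labels(sim, .out_path(out_dir, "truth.tsv"))
  message("simulated ", config$n_lines, " lines x ", config$n_markers,
          " markers (seed ", config$seed, ")")
  invisible(sim)
}

#' Run the QTL threshold comparison
#'
#' Scans every polymorphic marker for trait association, then repeats the
#' scan after excluding flagged lines at each similarity threshold, and
#' writes the per-marker scan (`qtl_scan.tsv`) and the threshold comparison
#' (`threshold_comparison.tsv`).
#'
#' @inheritParams run_check
#' @param phenotype_file Path to a phenotype table.
#' @return Invisibly, a list with the scan and the comparison table.
#' @export
run_qtl <- function(genotype_file, phenotype_file, parents,
                    thresholds = c(0.90, 0.95, 0.99), out_dir = ".",
                    orientation = "markers",
                    missing_tokens = MISSING_TOKENS_DEFAULT,
                    rule = c("strict", "inclusive"), map_file = NULL) {
  rule <- match.arg(rule)
  stopifnot(length(parents) == 2)
  x <- read_genotype_table(genotype_file, orientation = orientation,
                           missing_tokens = missing_tokens)
  phen <- read_phenotypes(phenotype_file)
  map <- if (!is.null(map_file)) read_marker_map(map_file) else NULL
  cl <- classify_loci(x, parents[1], parents[2])
  rep <- similarity_report(x, parents[1], parents[2], classification = cl)
  codes <- encode_genotypes(x, cl)
  scan <- single_factor_scan(codes, phen, map = map)
  cmp <- compare_across_thresholds(codes, phen, rep,
                                   thresholds = thresholds, rule = rule,
                                   map = map)
  utils::write.table(as.data.frame(scan),
                     .out_path(out_dir, "qtl_scan.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cmp, .out_path(out_dir, "threshold_comparison.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  message("scan over ", nrow(scan), " polymorphic markers; max R2 ",
          sprintf("%.3f", max(scan$r2, na.rm = TRUE)))
  invisible(list(scan = scan, comparison = cmp))
}
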