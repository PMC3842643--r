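#' @title Simulation of bi-parental RIL populations
#' @name ril_simulator
#' @description
#' Generates synthetic recombinant inbred line (RIL) populations from a
#' cross of two fully inbred (homozygous) parents advanced by single-seed
#' descent, with ground-truth contamination labels, so the parent-offspring
#' test is verifiable end to end without external data. Meiosis places
#' crossovers as a Poisson process along each chromosome (no interference);
#' after g generations of selfing a line retains residual heterozygosity
#' (1/2)^g per initially heterozygous locus in expectation. Contaminant
#' lines are built from a synthetic unrelated genome that agrees with the
#' shared parental allele at each monomorphic locus independently with
#' probability p, which gives closed-form expected similarities:
#' E\[S\] = (1+p)/2 for an outcross (one parental gamete, one contaminant
#' gamete) and E\[S\] = p for a seed mixture (entirely contaminant).
NULL

.CHROM_LEN <- 1e8  # bp span of each simulated chromosome

#' Simulation configuration
#'
#' Defaults emulate a soybean fixed-panel study design: 1,536 SNPs on 20
#' chromosomes, ~37% polymorphic between the parents, 150 F5-derived lines
#' (four generations of selfing from the F1).
#'
#' @param n_markers Number of markers on the panel.
#' @param n_chromosomes Number of chromosomes; markers are spread uniformly.
#' @param polymorphic_fraction Fraction of markers at which the parents
#'   carry different alleles; exactly
#'   `round(polymorphic_fraction * n_markers)` loci are made polymorphic.
#' @param n_lines Number of derived lines.
#' @param generations_of_selfing Meiosis generations after the F1 (4 gives
#'   F5 plants).
#' @param recombination Expected crossovers per chromosome per meiosis
#'   (Poisson mean).
#' @param error_rate Per-allele miscall probability applied to progeny
#'   calls (parents exempt).
#' @param contamination List of contamination events, each a list with
#'   `type` (`"outcross"` or `"seed_mixture"`), `count`, and `sharing` (the
#'   contaminant's allele-sharing probability p at monomorphic loci).
#' @param seed Master RNG seed; every simulation output is a deterministic
#'   function of the configuration.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_markers = 1536, n_chromosomes = 20,
                       polymorphic_fraction = 0.37, n_lines = 150,
                       generations_of_selfing = 4, recombination = 1.0,
                       error_rate = 0, contamination = list(), seed = 1) {
  stopifnot(n_markers >= 1, n_chromosomes >= 1,
            n_markers >= n_chromosomes,
            polymorphic_fraction >= 0, polymorphic_fraction <= 1,
            n_lines >= 1, generations_of_selfing >= 1,
            recombination >= 0, error_rate >= 0, error_rate <= 1)
  for (ct in contamination) {
    if (!is.list(ct) || !all(c("type", "count", "sharing") %in% names(ct)))
      stop("each contamination entry needs type, count, sharing",
           call. = FALSE)
    if (!ct$type %in% c("outcross", "seed_mixture"))
      stop("unknown contamination type: ", ct$type, call. = FALSE)
    stopifnot(ct$count >= 0, ct$sharing >= 0, ct$sharing <= 1)
  }
  total <- sum(vapply(contamination, function(ct) ct$count, numeric(1)))
  if (total > n_lines)
    stop("contaminated lines (", total, ") exceed n_lines (", n_lines, ")",
         call. = FALSE)
  structure(list(n_markers = as.integer(n_markers),
                 n_chromosomes = as.integer(n_chromosomes),
                 polymorphic_fraction = polymorphic_fraction,
                 n_lines = as.integer(n_lines),
                 generations_of_selfing = as.integer(generations_of_selfing),
                 recombination = recombination, error_rate = error_rate,
                 contamination = contamination, seed = as.integer(seed)),
            class = "sim_config")
}

#' Read a simulation configuration from a YAML file
#'
#' Keys mirror the arguments of [sim_config()]; `contamination` is a YAML
#' sequence of mappings with keys `type`, `count`, `sharing`.
#'
#' @param path Path to the YAML file.
#' @return A `sim_config`.
#' @export
read_sim_config <- function(path) {
  vals <- yaml::read_yaml(path)
  unknown <- setdiff(names(vals), names(formals(sim_config)))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(sim_config, vals)
}

# Parents, marker map and panel (assay allele) definition. Does not seed
# the RNG; callers own the stream.
.sim_parents <- function(config) {
  n <- config$n_markers; nc <- config$n_chromosomes
  per <- rep(n %/% nc, nc)
  if (n %% nc) per[seq_len(n %% nc)] <- per[seq_len(n %% nc)] + 1L
  chrom <- rep(seq_len(nc), per)
  pos <- unlist(lapply(per, function(k) sort(sample.int(.CHROM_LEN, k))))
  marker <- sprintf("M%0*d", nchar(n), seq_len(n))
  map <- data.frame(marker = marker, chrom = as.character(chrom), pos = pos,
                    stringsAsFactors = FALSE)
  nuc <- c("A", "C", "G", "T")
  a1 <- sample(nuc, n, replace = TRUE)
  a2 <- vapply(a1, function(x) sample(setdiff(nuc, x), 1), character(1))
  n_poly <- round(config$polymorphic_fraction * n)
  poly <- rep(FALSE, n)
  if (n_poly > 0) poly[sample.int(n, n_poly)] <- TRUE
  assay <- data.frame(marker = marker, allele1 = a1, allele2 = unname(a2),
                      polymorphic = poly, stringsAsFactors = FALSE)
  p1 <- paste0(a1, a1)
  p2 <- ifelse(poly, paste0(assay$allele2, assay$allele2), p1)
  calls <- cbind(P1 = p1, P2 = p2)
  rownames(calls) <- marker
  list(genotypes = genotype_matrix(calls), map = map, assay = assay)
}

#' Simulate the two inbred parents and the marker panel
#'
#' Both parents are homozygous at every locus; exactly
#' `round(polymorphic_fraction * n_markers)` loci carry different parental
#' alleles. Markers are spread uniformly over the chromosomes with sorted
#' positions, and each locus is assigned the two assay alleles of a
#' biallelic SNP.
#'
#' @param config A [sim_config()].
#' @return A list with `genotypes` (2-column [genotype_matrix()], ids
#'   `"P1"`, `"P2"`), `map` (marker map), and `assay` (per-marker assay
#'   alleles and polymorphism indicator).
#' @export
simulate_parents <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  .sim_parents(config)
}

# One meiotic gamete from a pair of haplotypes (vectors of 0/1 parental
# origin), with Poisson crossovers per chromosome and uniform breakpoints.
.meiosis <- function(haps, chr_idx, chr_pos, recomb) {
  gam <- integer(nrow(haps))
  for (ci in seq_along(chr_idx)) {
    idx <- chr_idx[[ci]]
    k <- stats::rpois(1, recomb)
    start <- sample.int(2L, 1L) - 1L
    if (k == 0L) {
      strand <- rep(start, length(idx))
    } else {
      bp <- sort(stats::runif(k, 0, .CHROM_LEN))
      strand <- (start + findInterval(chr_pos[[ci]], bp)) %% 2L
    }
    gam[idx] <- haps[cbind(idx, strand + 1L)]
  }
  gam
}

#' Simulate an F-generation RIL population with ground-truth labels
#'
#' Each true line descends from the F1 (heterozygous at every polymorphic
#' locus) through `generations_of_selfing` rounds of selfing, carrying one
#' seed forward per generation (single-seed descent). Contaminated lines
#' replace randomly chosen lines: an outcross carries one parental gamete
#' and one gamete from a synthetic unrelated genome; a seed mixture is
#' entirely that unrelated genome. Per-allele genotyping error is applied
#' to progeny (never parents) at rate `error_rate`. Output is bit-identical
#' across runs for a fixed configuration.
#'
#' @param config A [sim_config()].
#' @return A list of class `ril_sim`: `genotypes` (parents `P1`, `P2` plus
#'   `n_lines` lines), `map`, `assay`, `truth` (data.frame `individual`,
#'   `status`, `sharing`), `config`.
#' @export
simulate_ril_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  par <- .sim_parents(config)
  n <- config$n_markers
  chr_idx <- split(seq_len(n), par$map$chrom)[unique(par$map$chrom)]
  chr_pos <- lapply(chr_idx, function(i) par$map$pos[i])

  # allele carried by a haplotype of parental origin 0 (P1) or 1 (P2)
  al_p1 <- par$assay$allele1
  al_p2 <- ifelse(par$assay$polymorphic, par$assay$allele2, al_p1)

  status <- rep("true_offspring", config$n_lines)
  sharing <- rep(NA_real_, config$n_lines)
  total <- sum(vapply(config$contamination, function(ct) ct$count,
                      numeric(1)))
  if (total > 0) {
    picks <- sample.int(config$n_lines, total)
    at <- 1L
    for (ct in config$contamination) {
      if (ct$count == 0) next
      sel <- picks[at:(at + ct$count - 1L)]
      status[sel] <- ct$type
      sharing[sel] <- ct$sharing
      at <- at + ct$count
    }
  }

  contam_genome <- function(p) {
    u <- stats::runif(n)
    ifelse(par$assay$polymorphic,
           ifelse(u < 0.5, al_p1, par$assay$allele2),
           ifelse(u < p, al_p1, par$assay$allele2))
  }

  line_call <- function(i) {
    if (status[i] == "true_offspring") {
      haps <- cbind(rep(0L, n), rep(1L, n))  # F1
      for (g in seq_len(config$generations_of_selfing))
        haps <- cbind(.meiosis(haps, chr_idx, chr_pos, config$recombination),
                      .meiosis(haps, chr_idx, chr_pos, config$recombination))
      x1 <- ifelse(haps[, 1] == 0L, al_p1, al_p2)
      x2 <- ifelse(haps[, 2] == 0L, al_p1, al_p2)
    } else if (status[i] == "outcross") {
      x1 <- al_p1                      # gamete from the parental lineage
      x2 <- contam_genome(sharing[i])  # gamete from the unrelated genome
    } else {                           # seed mixture: unrelated throughout
      x1 <- contam_genome(sharing[i])
      x2 <- x1
    }
    paste0(pmin(x1, x2), pmax(x1, x2))
  }

  calls <- vapply(seq_len(config$n_lines), line_call, character(n))
  ids <- sprintf("L%0*d", nchar(config$n_lines), seq_len(config$n_lines))
  colnames(calls) <- ids
  all_calls <- cbind(unclass(par$genotypes), calls)
  gm <- genotype_matrix(all_calls)
  if (config$error_rate > 0)
    gm <- apply_genotyping_error(gm, config$error_rate, par$assay,
                                 seed = NULL, exempt = c("P1", "P2"))
  structure(list(genotypes = gm, map = par$map, assay = par$assay,
                 truth = data.frame(individual = ids, status = status,
                                    sharing = sharing,
                                    stringsAsFactors = FALSE),
                 config = config),
            class = "ril_sim")
}

#' @export
print.ril_sim <- function(x, ...) {
  cat("ril_sim: ", x$config$n_markers, " markers x ", x$config$n_lines,
      " lines (+2 parents), ", sum(x$assay$polymorphic),
      " polymorphic loci, ",
      sum(x$truth$status != "true_offspring"), " contaminated line(s)\n",
      sep = "")
  invisible(x)
}

#' Apply per-allele genotyping error
#'
#' Each allele call of a non-exempt individual is independently replaced by
#' the locus's other assay allele with probability `error_rate`, the
#' symmetric miscall model of a biallelic fixed panel. At a monomorphic
#' locus each miscalled allele loses exactly one parental allele, so the
#' expected population similarity is `1 - error_rate`.
#'
#' @param x A [genotype_matrix()] whose markers match `assay`.
#' @param error_rate Per-allele miscall probability in `[0, 1]`.
#' @param assay Per-marker assay alleles (`marker`, `allele1`, `allele2`),
#'   as produced by [simulate_parents()].
#' @param seed Optional seed; `NULL` continues the current RNG stream.
#' @param exempt Individual ids left untouched (the parents define the
#'   panel and are exempt by default).
#' @return A new `genotype_matrix`.
#' @export
apply_genotyping_error <- function(x, error_rate, assay, seed = NULL,
                                   exempt = c("P1", "P2")) {
  stopifnot(error_rate >= 0, error_rate <= 1)
  if (!is.null(seed)) set.seed(seed)
  if (error_rate == 0) return(x)
  idx <- match(markers(x), assay$marker)
  if (anyNA(idx))
    stop("assay alleles missing for some markers", call. = FALSE)
  cols <- setdiff(individuals(x), exempt)
  m <- unclass(x)
  sub <- m[, cols, drop = FALSE]
  a1 <- matrix(assay$allele1[idx], nrow(sub), ncol(sub))
  a2 <- matrix(assay$allele2[idx], nrow(sub), ncol(sub))
  flip_allele <- function(al) {
    other <- ifelse(al == a1, a2, a1)
    hit <- matrix(stats::runif(length(al)) < error_rate, nrow(al))
    ifelse(hit, other, al)
  }
  x1 <- flip_allele(.allele1(sub))
  x2 <- flip_allele(.allele2(sub))
  out <- paste0(pmin(x1, x2), pmax(x1, x2))
  out[is.na(x1) | is.na(x2)] <- NA_character_
  m[, cols] <- out
  genotype_matrix(m)
}

#' Simulate a quantitative phenotype with one planted QTL
#'
#' Trait values follow an additive single-QTL model:
#' `y = beta * g + shift * [contaminated] + e`, where `g` counts the
#' parent-2 alleles at the QTL marker (0, 1 or 2) and `e` is Gaussian noise.
#' Contaminated lines receive a constant phenotype shift, emulating the
#' off-type phenotypes that variants contribute to a field trial.
#'
#' @param sim A [simulate_ril_population()] result.
#' @param qtl_marker Marker id of the planted QTL; must be polymorphic.
#' @param beta Additive effect per parent-2 allele.
#' @param noise_sd Standard deviation of the Gaussian noise.
#' @param contaminant_shift Constant added to lines whose truth status is
#'   not `true_offspring`.
#' @param seed Optional seed; `NULL` continues the current RNG stream.
#' @return A phenotype data.frame (`individual`, `value`) covering every
#'   line (parents excluded).
#' @export
simulate_phenotype <- function(sim, qtl_marker, beta, noise_sd,
                               contaminant_shift = 0, seed = NULL) {
  stopifnot(inherits(sim, "ril_sim"), noise_sd >= 0)
  if (!is.null(seed)) set.seed(seed)
  row <- match(qtl_marker, sim$assay$marker)
  if (is.na(row)) stop("unknown marker: ", qtl_marker, call. = FALSE)
  if (!sim$assay$polymorphic[row])
    stop("QTL marker must be polymorphic between the parents: ", qtl_marker,
         call. = FALSE)
  lines <- sim$truth$individual
  calls <- unclass(sim$genotypes)[qtl_marker, lines]
  g <- score_calls(sim$assay$allele2[row], calls)
  g[is.na(g)] <- 0L
  y <- beta * g + contaminant_shift *
    (sim$truth$status != "true_offspring") +
    stats::rnorm(length(lines), 0, noise_sd)
  data.frame(individual = lines, value = y, stringsAsFactors = FALSE)
}

#' Noise level yielding a target QTL variance explained
#'
#' From the variance decomposition `R^2 = beta^2 var(g) / (beta^2 var(g) +
#' sigma^2)`, returns the `sigma` giving the requested R^2 for a given
#' effect size and genotype-code sample.
#'
#' @param beta Additive effect per allele.
#' @param codes Numeric genotype codes at the QTL marker.
#' @param target_r2 Desired fraction of phenotypic variance in `(0, 1)`.
#' @return Noise standard deviation.
#' @export
noise_sd_for_r2 <- function(beta, codes, target_r2) {
  stopifnot(target_r2 > 0, target_r2 < 1)
  vg <- stats::var(codes, na.rm = TRUE)
  sqrt(beta^2 * vg * (1 / target_r2 - 1))
}

#' Write simulation truth labels
#' @param sim A `ril_sim`.
#' @param path Output path (tab-separated sidecar).
#' @return `path`, invisibly.
#' @export
write_truth_labels <- function(sim, path) {
  utils::write.table(sim$truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
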