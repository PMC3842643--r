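# Shared fixtures and independent oracles for the test suite.

# Naive per-locus scoring loop: an independent reimplementation of the
# monomorphic-locus tallies used as an oracle for count_scores().
naive_counts <- function(x, parent1, parent2, offspring) {
  m <- unclass(x)
  a <- b <- cc <- mm <- 0L
  for (mk in rownames(m)) {
    g1 <- m[mk, parent1]; g2 <- m[mk, parent2]
    if (is.na(g1) || is.na(g2)) next
    al1 <- strsplit(g1, "")[[1]]; al2 <- strsplit(g2, "")[[1]]
    if (al1[1] != al1[2] || al2[1] != al2[2]) next  # a parent heterozygous
    if (al1[1] != al2[1]) next                      # polymorphic
    go <- m[mk, offspring]
    if (is.na(go)) { mm <- mm + 1L; next }
    sc <- sum(strsplit(go, "")[[1]] == al1[1])
    if (sc == 2) a <- a + 1L else if (sc == 1) b <- b + 1L else cc <- cc + 1L
  }
  c(a = a, b = b, c = cc, m = mm)
}

# Random genotype matrix with missing calls, for round-trip and oracle tests.
random_genotype_matrix <- function(n_markers, n_ind, p_missing = 0.05) {
  nuc <- c("A", "C", "G", "T")
  a1 <- sample(nuc, n_markers * n_ind, replace = TRUE)
  a2 <- sample(nuc, n_markers * n_ind, replace = TRUE)
  calls <- paste0(pmin(a1, a2), pmax(a1, a2))
  calls[stats::runif(length(calls)) < p_missing] <- NA
  dim(calls) <- c(n_markers, n_ind)
  dimnames(calls) <- list(sprintf("m%03d", seq_len(n_markers)),
                          sprintf("i%03d", seq_len(n_ind)))
  genotype_matrix(calls)
}

# Five-marker trio fixture with hand-computed similarities:
#   O1: scores 2,2,1,0 over the four monomorphic loci -> S = 5/8 = 0.625
#   O2: scores 2,2,2,2 -> S = 1
toy_trio <- function() {
  calls <- rbind(
    m1 = c(P1 = "AA", P2 = "AA", O1 = "AA", O2 = "AA"),
    m2 = c(P1 = "CC", P2 = "CC", O1 = "CC", O2 = "CC"),
    m3 = c(P1 = "AA", P2 = "AA", O1 = "AT", O2 = "AA"),
    m4 = c(P1 = "TT", P2 = "TT", O1 = "GG", O2 = "TT"),
    m5 = c(P1 = "AA", P2 = "GG", O1 = "AG", O2 = "GG"))
  genotype_matrix(calls)
}

# Small simulation configurations used across tests; sized for speed while
# keeping binomial standard errors tight.
small_cfg <- function(n_markers = 400, n_chromosomes = 10, n_lines = 40,
                      ...) {
  sim_config(n_markers = n_markers, n_chromosomes = n_chromosomes,
             n_lines = n_lines, ...)
}

# Write a minimal VCF 4.2 file; records is a data.frame with columns
# chrom, pos, id, ref, alt, and one column per sample holding GT strings.
write_test_vcf <- function(path, records, samples) {
  hdr <- c("##fileformat=VCFv4.2",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  rows <- apply(records, 1, function(r) {
    paste(c(r[["chrom"]], r[["pos"]], r[["id"]], r[["ref"]], r[["alt"]],
            ".", "PASS", ".", "GT", r[samples]), collapse = "\t")
  })
  writeLines(c(hdr, rows), path)
  path
}
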