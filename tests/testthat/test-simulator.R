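test_that("simulated parents honor the panel configuration", {
  cfg <- sim_config(seed = 3)
  par <- simulate_parents(cfg)
  expect_equal(nrow(par$genotypes), 1536)
  expect_equal(individuals(par$genotypes), c("P1", "P2"))
  # exactly round(fraction x markers) polymorphic loci
  cl <- classify_loci(par$genotypes, "P1", "P2")
  expect_equal(unname(attr(cl, "counts")["polymorphic"]),
               round(0.37 * 1536))
  expect_equal(unname(attr(cl, "counts")["excluded"]), 0L)
  # both parents homozygous everywhere
  m <- unclass(par$genotypes)
  expect_true(all(substr(m, 1, 1) == substr(m, 2, 2)))
  # 20 chromosomes, sorted positions within each
  expect_equal(sort(unique(as.integer(par$map$chrom))), 1:20)
  for (ch in split(par$map$pos, par$map$chrom))
    expect_false(is.unsorted(ch))
  # polymorphic_fraction = 0 makes the parents identical
  par0 <- simulate_parents(sim_config(n_markers = 100, n_chromosomes = 5,
                                      polymorphic_fraction = 0, seed = 3))
  m0 <- unclass(par0$genotypes)
  expect_equal(m0[, "P1"], m0[, "P2"])
})

test_that("configuration validation rejects impossible settings", {
  expect_error(sim_config(polymorphic_fraction = 1.5))
  expect_error(sim_config(error_rate = -0.1))
  expect_error(sim_config(n_lines = 5, contamination = list(
    list(type = "outcross", count = 9, sharing = 0.5))), "exceed")
  expect_error(sim_config(contamination = list(
    list(type = "clone", count = 1, sharing = 0.5))), "unknown contamination")
  expect_error(sim_config(contamination = list(list(type = "outcross"))),
               "needs type, count, sharing")
})

test_that("a clean population has similarity 1 at every line", {
  cfg <- small_cfg(seed = 12)
  sim <- simulate_ril_population(cfg)
  rep <- similarity_report(sim$genotypes, "P1", "P2")
  expect_equal(nrow(rep), 40)
  expect_true(all(rep$S == 1.0))
  expect_true(all(sim$truth$status == "true_offspring"))
  expect_length(flag_variants(rep, 0.99)$flagged, 0)
})

test_that("residual heterozygosity after four selfing generations is near (1/2)^4", {
  cfg <- sim_config(n_markers = 600, n_chromosomes = 10, n_lines = 100,
                    seed = 19)
  sim <- simulate_ril_population(cfg)
  cl <- classify_loci(sim$genotypes, "P1", "P2")
  poly <- cl$marker[cl$status == "polymorphic"]
  calls <- unclass(sim$genotypes)[poly, sim$truth$individual]
  het_rate <- mean(substr(calls, 1, 1) != substr(calls, 2, 2))
  p <- 0.5^4
  se <- sqrt(p * (1 - p) / length(calls))
  expect_lt(abs(het_rate - p), 3 * se + 0.005)  # loci within a line covary
})

test_that("parental allele frequencies at polymorphic loci stay near one half", {
  cfg <- sim_config(n_markers = 600, n_chromosomes = 10, n_lines = 100,
                    seed = 23)
  sim <- simulate_ril_population(cfg)
  cl <- classify_loci(sim$genotypes, "P1", "P2")
  poly <- which(cl$status == "polymorphic")
  calls <- unclass(sim$genotypes)[cl$marker[poly], sim$truth$individual]
  a2 <- cl$allele_p2[poly]
  freq2 <- mean(score_calls(a2, calls), na.rm = TRUE) / 2
  expect_lt(abs(freq2 - 0.5), 0.02)
})

test_that("genotyping error follows the symmetric assay-allele model", {
  cfg <- small_cfg(seed = 31)
  sim <- simulate_ril_population(cfg)
  # error_rate 0 is the identity
  same <- apply_genotyping_error(sim$genotypes, 0, sim$assay, seed = 1)
  expect_identical(unclass(same), unclass(sim$genotypes))
  # error_rate 1 flips every allele: every progeny scores 0 at monomorphic
  # loci, while the parents are exempt and unchanged
  flipped <- apply_genotyping_error(sim$genotypes, 1, sim$assay, seed = 1)
  cl <- classify_loci(flipped, "P1", "P2")
  expect_equal(unclass(flipped)[, c("P1", "P2")],
               unclass(sim$genotypes)[, c("P1", "P2")])
  rep <- similarity_report(flipped, "P1", "P2", classification = cl)
  expect_true(all(rep$S == 0))
  # intermediate rate: mean similarity tracks 1 - error_rate
  cfg2 <- small_cfg(seed = 32, error_rate = 0.05)
  rep2 <- similarity_report(simulate_ril_population(cfg2)$genotypes,
                            "P1", "P2")
  n_alleles <- 2 * sum(rep2$a + rep2$b + rep2$c)
  se <- sqrt(0.05 * 0.95 / n_alleles)
  expect_lt(abs(mean(rep2$S) - 0.95), 3 * se)
})

test_that("simulation output is bit-identical under a fixed seed", {
  cfg <- small_cfg(seed = 77, error_rate = 0.01, contamination = list(
    list(type = "seed_mixture", count = 2, sharing = 0.5)))
  s1 <- simulate_ril_population(cfg)
  s2 <- simulate_ril_population(cfg)
  expect_identical(unclass(s1$genotypes), unclass(s2$genotypes))
  expect_identical(s1$map, s2$map)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_ril_population(small_cfg(seed = 78, error_rate = 0.01,
    contamination = list(list(type = "seed_mixture", count = 2,
                              sharing = 0.5))))
  expect_false(identical(unclass(s1$genotypes), unclass(s3$genotypes)))
})

test_that("contaminated lines match their requested labels and expected similarity", {
  cfg <- sim_config(n_markers = 800, n_chromosomes = 10, n_lines = 60,
                    seed = 41, contamination = list(
                      list(type = "outcross", count = 5, sharing = 0.6),
                      list(type = "seed_mixture", count = 4, sharing = 0.6)))
  sim <- simulate_ril_population(cfg)
  expect_equal(sum(sim$truth$status == "outcross"), 5)
  expect_equal(sum(sim$truth$status == "seed_mixture"), 4)
  rep <- similarity_report(sim$genotypes, "P1", "P2")
  s <- rep$S[match(sim$truth$individual, rep$individual)]
  n_mono <- attr(rep, "n_monomorphic")
  # outcross: one parental gamete plus a p-sharing gamete -> E[S] = (1+p)/2
  out <- s[sim$truth$status == "outcross"]
  se_out <- sqrt(0.6 * 0.4 / n_mono) / 2
  expect_lt(abs(mean(out) - 0.8), 3 * se_out / sqrt(5) + 0.01)
  # seed mixture: both alleles from the p-sharing genome -> E[S] = p
  mix <- s[sim$truth$status == "seed_mixture"]
  se_mix <- sqrt(0.6 * 0.4 / n_mono)
  expect_lt(abs(mean(mix) - 0.6), 3 * se_mix / sqrt(4) + 0.01)
  expect_true(all(s[sim$truth$status == "true_offspring"] == 1))
})

test_that("phenotype simulation plants a recoverable QTL", {
  cfg <- small_cfg(seed = 51)
  sim <- simulate_ril_population(cfg)
  cl <- classify_loci(sim$genotypes, "P1", "P2")
  qm <- cl$marker[cl$status == "polymorphic"][10]
  # no noise, no shift: the trait is a deterministic function of the code
  ph <- simulate_phenotype(sim, qm, beta = 1, noise_sd = 0, seed = 52)
  codes <- suppressMessages(encode_genotypes(sim$genotypes, cl))
  scan <- single_factor_scan(codes, ph)
  expect_equal(scan$r2[scan$marker == qm], 1.0)
  expect_error(simulate_phenotype(sim, cl$marker[cl$status == "monomorphic"][1],
                                  1, 1), "polymorphic")
  # determinism under a fixed seed
  p1 <- simulate_phenotype(sim, qm, 1, 0.5, seed = 53)
  p2 <- simulate_phenotype(sim, qm, 1, 0.5, seed = 53)
  expect_identical(p1, p2)
  # noise_sd_for_r2 hits the target variance fraction in expectation
  g <- codes[qm, sim$truth$individual]
  sdn <- noise_sd_for_r2(1, g, 0.33)
  r2s <- replicate(40, {
    ph <- simulate_phenotype(sim, qm, 1, sdn)
    y <- ph$value[match(names(g), ph$individual)]
    stats::cor(g, y)^2
  })
  expect_lt(abs(mean(r2s) - 0.33), 3 * stats::sd(r2s) / sqrt(40) + 0.02)
})

test_that("YAML configuration round-trips into sim_config", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("n_markers: 200", "n_chromosomes: 5", "n_lines: 12",
               "polymorphic_fraction: 0.4", "seed: 9", "contamination:",
               "  - type: outcross", "    count: 2", "    sharing: 0.55"),
             path)
  cfg <- read_sim_config(path)
  expect_s3_class(cfg, "sim_config")
  expect_equal(cfg$n_markers, 200L)
  expect_equal(cfg$contamination[[1]]$sharing, 0.55)
  writeLines("bogus_key: 1", path)
  expect_error(read_sim_config(path), "unknown configuration key")
})
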