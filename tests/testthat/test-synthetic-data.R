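test_that("array generator is deterministic and dimensionally consistent", {
  cfg <- array_scenario(n_samples = 24, n_probesets = 30, seed = 5)
  a <- generate_array_experiment(cfg)
  b <- generate_array_experiment(cfg)
  expect_identical(a$signal, b$signal)
  expect_identical(a$truth$genotypes, b$truth$genotypes)
  expect_true(validate_truth_bundle(a))
  f1 <- tempfile(); f2 <- tempfile()
  write_signal_table(a$signal, f1)
  write_signal_table(b$signal, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("an all-monomorphic mix yields one genotype per probeset", {
  cfg <- array_scenario(n_samples = 20, n_probesets = 15,
                        category_mix = c(diploidized = 0, homoeologous = 0,
                                         monomorphic = 1, null_allele = 0,
                                         low_quality = 0),
                        missing_rate = 0, seed = 2)
  sim <- generate_array_experiment(cfg)
  expect_true(all(apply(sim$truth$genotypes, 2L,
                        function(col) length(unique(col)) == 1L)))
})

test_that("null-allele carrier fraction matches otv_frequency", {
  cfg <- array_scenario(n_samples = 1000, n_probesets = 30,
                        category_mix = c(diploidized = 0, homoeologous = 0,
                                         monomorphic = 0, null_allele = 1,
                                         low_quality = 0),
                        otv_frequency = 0.3, seed = 3)
  sim <- generate_array_experiment(cfg)
  frac <- mean(sim$truth$genotypes == "OO")
  n <- length(sim$truth$genotypes)
  expect_lt(abs(frac - 0.3), 3 * sqrt(0.3 * 0.7 / n))
})

test_that("generator truth reproduces the forward transform exactly", {
  sim <- generate_array_experiment(array_scenario(n_samples = 20,
                                                  n_probesets = 10,
                                                  missing_rate = 0, seed = 7))
  cs <- to_contrast_size(sim$signal$signal_a, sim$signal$signal_b)
  ok <- !sim$truth$points$missing
  expect_lt(max(abs(cs$contrast[ok] - sim$truth$points$true_contrast[ok])),
            1e-10)
  expect_lt(max(abs(cs$size[ok] - sim$truth$points$true_size[ok])), 1e-10)
})

test_that("scenario validation rejects bad configurations", {
  expect_error(array_scenario(n_samples = 0), "positive")
  expect_error(array_scenario(category_mix = c(diploidized = 0.5,
                                               homoeologous = 0.1,
                                               monomorphic = 0.1,
                                               null_allele = 0.1,
                                               low_quality = 0.1)), "sum to 1")
  expect_error(array_scenario(missing_rate = 1.2), "0, 1")
  expect_error(panel_scenario(fst = 0), "fst")
  expect_error(ril_scenario(generation = 1), "generation")
  expect_error(ril_scenario(distortion_loci = data.frame(
    chromosome = 1, position = 500, bias = 0.7)), "within")
})

test_that("group allele-frequency divergence vanishes as fst tends to 0", {
  lo <- generate_population_panel(panel_scenario(n_groups = 4, n_loci = 200,
                                                 fst = 1e-4, seed = 4))
  spread_lo <- mean(apply(lo$truth$group_freq, 2L, var))
  hi <- generate_population_panel(panel_scenario(n_groups = 4, n_loci = 200,
                                                 fst = 0.3, seed = 4))
  spread_hi <- mean(apply(hi$truth$group_freq, 2L, var))
  expect_lt(spread_lo, 1e-3)
  expect_gt(spread_hi, 50 * spread_lo)
})

test_that("panel missingness matches the configured rate", {
  pan <- generate_population_panel(panel_scenario(n_groups = 2,
                                                  samples_per_group = 50,
                                                  n_loci = 400,
                                                  missing_rate = 0.01,
                                                  seed = 6))
  n <- length(pan$genotypes)
  expect_lt(abs(mean(pan$genotypes == "NN") - 0.01),
            3 * sqrt(0.01 * 0.99 / n))
})

test_that("a structured 2-group panel separates into two NJ clades", {
  pan <- generate_population_panel(panel_scenario(n_groups = 2,
                                                  samples_per_group = 12,
                                                  n_loci = 500, fst = 0.3,
                                                  seed = 8))
  tr <- nj_tree(simple_matching_distance(pan$genotypes))
  g1 <- pan$truth$groups$sample_id[pan$truth$groups$group == "G1"]
  expect_true(ape::is.monophyletic(tr$tree, g1))
})

test_that("RIL residual heterozygosity matches (1/2)^(generation-1)", {
  ril <- generate_ril_f6(ril_scenario(n_individuals = 430,
                                      n_chromosomes = 5,
                                      markers_per_chromosome = 200,
                                      missing_rate = 0, seed = 9))
  g <- ril$genotypes[-(1:2), ]
  per_ind <- rowMeans(g == "AB")
  se <- sd(per_ind) / sqrt(length(per_ind))  # individuals are independent
  expect_lt(abs(mean(per_ind) - 1 / 32), 3 * se)
  expect_identical(unique(as.vector(ril$genotypes[1:2, ])), c("AA", "BB"))
})

test_that("markers at zero distance have identical genotype columns", {
  ril <- generate_ril_f6(ril_scenario(n_individuals = 60, n_chromosomes = 1,
                                      markers_per_chromosome = 120,
                                      chromosome_length_cM = 30,
                                      missing_rate = 0, seed = 10))
  map <- ril$truth$map
  dup <- which(diff(map$position_cM) == 0)
  expect_gt(length(dup), 0)
  for (k in dup) {
    expect_identical(ril$genotypes[, k], ril$genotypes[, k + 1])
  }
})

test_that("adjacent-marker recombination follows the inverse Kosambi map", {
  expect_equal(inverse_mapping_function(10, "kosambi"), tanh(0.2) / 2)
  expect_equal(inverse_mapping_function(10, "haldane"),
               (1 - exp(-0.2)) / 2)
  ril <- generate_ril_f6(ril_scenario(n_individuals = 2000,
                                      n_chromosomes = 1,
                                      markers_per_chromosome = 2,
                                      chromosome_length_cM = 20,
                                      missing_rate = 0, seed = 11))
  gap <- diff(ril$truth$map$position_cM)
  g <- ril$genotypes[-(1:2), ]
  hom <- g[, 1] %in% c("AA", "BB") & g[, 2] %in% c("AA", "BB")
  r_obs <- mean(g[hom, 1] != g[hom, 2])
  r_exp <- inverse_mapping_function(gap, "kosambi")
  expect_lt(abs(r_obs - r_exp), 3 * sqrt(r_exp * (1 - r_exp) / sum(hom)))
})

test_that("distortion loci bias allele transmission as configured", {
  dl <- data.frame(chromosome = 1, position = 50, bias = 0.8)
  ril <- generate_ril_f6(ril_scenario(n_individuals = 1000,
                                      n_chromosomes = 1,
                                      markers_per_chromosome = 20,
                                      chromosome_length_cM = 100,
                                      distortion_loci = dl,
                                      missing_rate = 0, seed = 12))
  map <- ril$truth$map
  k <- which.min(abs(map$position_cM - 50))
  col <- ril$genotypes[-(1:2), k]
  p_a <- mean(col == "AA") / mean(col %in% c("AA", "BB"))
  expect_lt(abs(p_a - 0.8), 3 * sqrt(0.8 * 0.2 / 1000))
})

test_that("variant generator realizes classes, Ts fraction and depth law", {
  vr <- generate_variant_records(4000, n_lines = 10,
                                 class_mix = c(0, 0, 0, 1), seed = 13)
  gt <- as.matrix(vr$records[, vr$line_names])
  expect_true(all(gt == "AB"))
  vr2 <- generate_variant_records(10000, tstv_target = 2, seed = 14)
  tt <- ts_tv(vr2$records)
  frac <- tt$ts / (tt$ts + tt$tv)
  expect_lt(abs(frac - 2 / 3), 3 * sqrt(2 / 3 * 1 / 3 / 10000))
  vr3 <- generate_variant_records(200, depth_distribution = 4, seed = 15)
  expect_equal(nrow(filter_variants(vr3$records)$kept), 0L)
  expect_error(generate_variant_records(10, n_lines = 1), "at least 2")
  expect_error(generate_variant_records(10, class_mix = c(1, 0, 0)),
               "classes 1-4")
})

test_that("VCF writing and reading round-trips records", {
  skip_if_not_installed("vcfR")
  vr <- generate_variant_records(150, seed = 16)
  f <- tempfile(fileext = ".vcf")
  write_variant_vcf(vr$records, f)
  back <- read_variant_vcf(f)
  expect_equal(back$pos, vr$records$pos)
  expect_equal(back$depth, vr$records$depth)
  expect_equal(back$rms_mq, vr$records$rms_mq)
  for (l in vr$line_names) expect_identical(back[[l]], vr$records[[l]])
})
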