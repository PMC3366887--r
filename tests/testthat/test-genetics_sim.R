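test_that("ld_stats reproduces the textbook cases", {
  ind <- ld_stats(0.15, 0.3, 0.5)   # independence: p_ab = p_a p_b
  expect_equal(ind$D, 0)
  expect_equal(ind$d_prime, 0)
  expect_equal(ind$r_squared, 0)

  perfect <- ld_stats(0.5, 0.5, 0.5)
  expect_equal(perfect$d_prime, 1)
  expect_equal(perfect$r_squared, 1)

  mid <- ld_stats(0.25, 0.3, 0.5)
  expect_equal(mid$D, 0.10, tolerance = 1e-12)
  expect_equal(mid$r_squared, 0.10^2 / (0.21 * 0.25), tolerance = 1e-12)

  expect_error(ld_stats(0.6, 0.3, 0.5), "inconsistent")
  expect_error(ld_stats(-0.1, 0.3, 0.5), "\\[0, 1\\]")
})

test_that("ld_stats matches a brute-force 2x2 haplotype-count oracle", {
  set.seed(23)
  for (i in 1:60) {
    counts <- rmultinom(1, sample(20:200, 1), prob = runif(4, 0.05, 1))[, 1]
    if (any(counts + c(counts[2], counts[1], counts[4], counts[3]) == 0)) next
    n <- sum(counts)
    p_ab <- counts[1] / n
    p_a <- (counts[1] + counts[2]) / n
    p_b <- (counts[1] + counts[3]) / n
    if (p_a %in% c(0, 1) || p_b %in% c(0, 1)) next
    got <- ld_stats(p_ab, p_a, p_b)
    ref <- oracle_ld_from_counts(counts[1], counts[2], counts[3], counts[4])
    expect_equal(got$D, ref$D, tolerance = 1e-12)
    expect_equal(got$d_prime, ref$d_prime, tolerance = 1e-12)
    expect_equal(got$r_squared, ref$r_squared, tolerance = 1e-12)
  }
})

test_that("the default haplotype model emulates the published LD scenario", {
  m <- hap_model()
  expect_equal(sum(m$freq), 1, tolerance = 1e-12)
  ld_mt <- model_ld(m, c("marker", "transcript"))
  expect_equal(ld_mt$d_prime, 1, tolerance = 1e-6)
  expect_equal(ld_mt$r_squared, 0.71, tolerance = 0.005)
  # marker placed on the causal variant itself
  expect_equal(model_ld(m, c("marker", "causal"))$r_squared, 1,
               tolerance = 1e-9)
  expect_error(hap_model(p_causal = 0), "p_causal")
})

test_that("sampled cohorts reproduce the model's allele and LD structure", {
  cfg <- sim_config(n_patients = 5000L)
  co <- sample_cohort(cfg, seed = 101)
  haps <- rbind(
    data.frame(m = co$truth$hap1_marker, t = co$truth$hap1_transcript),
    data.frame(m = co$truth$hap2_marker, t = co$truth$hap2_transcript))
  n <- nrow(haps)   # 10,000 haplotypes
  p_t <- mean(haps$t == "num")
  se <- sqrt(0.32 * 0.68 / n)
  expect_lt(abs(p_t - 0.32), 3 * se)

  p_m <- mean(haps$m == "G")
  expect_lt(abs(p_m - 0.2504), 3 * sqrt(0.2504 * 0.7496 / n))

  got <- ld_stats(mean(haps$m == "G" & haps$t == "num"), p_m, p_t)
  want <- model_ld(cfg$model, c("marker", "transcript"))
  expect_lt(abs(got$r_squared - want$r_squared), 0.05)
  expect_gt(got$d_prime, 0.97)
})

test_that("complete LD yields no recombinant haplotypes", {
  # D' = 1 with p_marker < p_transcript: every G haplotype carries "num"
  co <- sample_cohort(sim_config(n_patients = 2000L), seed = 11)
  haps_m <- c(co$truth$hap1_marker, co$truth$hap2_marker)
  haps_t <- c(co$truth$hap1_transcript, co$truth$hap2_transcript)
  expect_equal(sum(haps_m == "G" & haps_t == "den"), 0L)
})

test_that("cohort sampling is reproducible for a fixed seed", {
  cfg <- sim_config(n_patients = 50L)
  a <- sample_cohort(cfg, seed = 99)
  b <- sample_cohort(cfg, seed = 99)
  expect_identical(a, b)
  c2 <- sample_cohort(cfg, seed = 100)
  expect_false(identical(a$truth, c2$truth))
})

test_that("noise-free measurements hit the exact expected ratios", {
  hap_up <- c(transcript = "num", causal = "up")
  hap_dn <- c(transcript = "den", causal = "down")

  cfg0 <- sim_config(fold_change = 1, ct_noise_sd = 0)
  mm <- simulate_measurements(hap_up, hap_dn, cfg0, seed = 1)
  expect_equal(normalize_allelic_ratio(mm$cdna, mm$gdna)$value, 1,
               tolerance = 1e-12)

  cfg2 <- sim_config(fold_change = 2, ct_noise_sd = 0)
  mm2 <- simulate_measurements(hap_up, hap_dn, cfg2, seed = 1)
  expect_equal(normalize_allelic_ratio(mm2$cdna, mm2$gdna)$value, 2,
               tolerance = 1e-12)

  # orientation: effect on the denominator allele inverts the ratio
  mm_inv <- simulate_measurements(c(transcript = "num", causal = "down"),
                                  c(transcript = "den", causal = "up"),
                                  cfg2, seed = 1)
  expect_equal(normalize_allelic_ratio(mm_inv$cdna, mm_inv$gdna)$value, 0.5,
               tolerance = 1e-12)

  # peak platform, noise-free
  cfgp <- sim_config(fold_change = 2, peak_cv = 0,
                     platform = "extension_peak")
  mmp <- simulate_measurements(hap_up, hap_dn, cfgp, seed = 1)
  expect_equal(normalize_allelic_ratio(mmp$cdna, mmp$gdna)$value, 2,
               tolerance = 1e-12)

  # homozygotes are skipped with a notice
  expect_message(
    out <- simulate_measurements(hap_up, hap_up, cfg2, seed = 1),
    "homozygous")
  expect_null(out)
})

test_that("measurement simulation is deterministic given its seed", {
  hap_up <- c(transcript = "num", causal = "up")
  hap_dn <- c(transcript = "den", causal = "down")
  cfg <- sim_config(fold_change = 1.5)
  a <- simulate_measurements(hap_up, hap_dn, cfg, seed = 5)
  b <- simulate_measurements(hap_up, hap_dn, cfg, seed = 5)
  expect_identical(a, b)
})

test_that("the noisy null keeps the normalised ratio centred on 1", {
  cfg <- sim_config(fold_change = 1, ct_noise_sd = 0.2)
  hap_up <- c(transcript = "num", causal = "up")
  hap_dn <- c(transcript = "den", causal = "down")
  vals <- vapply(1:800, function(i) {
    mm <- simulate_measurements(hap_up, hap_dn, cfg, seed = 4000 + i)
    normalize_allelic_ratio(mm$cdna, mm$gdna)$value
  }, numeric(1))
  expect_lt(abs(median(vals) - 1), 0.02)
})

test_that("the mean normalised ratio recovers the true fold change", {
  hap_up <- c(transcript = "num", causal = "up")
  hap_dn <- c(transcript = "den", causal = "down")
  for (f in c(1, 1.5, 2, 5.47)) {
    cfg <- sim_config(fold_change = f, ct_noise_sd = 0.2)
    vals <- vapply(1:1000, function(i) {
      mm <- simulate_measurements(hap_up, hap_dn, cfg,
                                  seed = cell_seed(round(100 * f), i))
      normalize_allelic_ratio(mm$cdna, mm$gdna)$value
    }, numeric(1))
    expect_lt(abs(mean(vals) / f - 1), 0.02)
  }
})

test_that("simulated cohort tables feed the whole pipeline", {
  cfg <- sim_config(fold_change = 3, ct_noise_sd = 0.25, n_patients = 40L)
  sim <- simulate_cohort_tables(cfg, seed = 202)
  # only transcript-SNP heterozygotes are measurable
  het <- is_het(sim$samples$rs5992854_gen)
  expect_equal(sort(sim$ratios$patient_id),
               sort(sim$samples$patient_id[het]))
  # tables round-trip through the text format and re-quantify identically
  path <- tempfile(fileext = ".tsv")
  write_replicate_table(sim$replicates, path)
  res <- quantify_allelic_table(read_replicate_table(path))
  merged <- merge(res, sim$ratios, by.x = "sample_id", by.y = "patient_id")
  expect_equal(merged$value, merged$ratio, tolerance = 1e-9)
})

test_that("marker-attenuated association is weaker than at the causal SNP", {
  # same cohorts, stratified once by a marker with r^2 < 1 to the causal
  # variant and once by the causal genotype itself
  # the transcript SNP is an imperfect readout (p_t < p_c, D' = 1) so the
  # causal genotype still varies among measurable heterozygotes
  model <- hap_model(p_causal = 0.4, p_marker = 0.4, p_transcript = 0.2,
                     d_prime_mc = 0.6, d_prime_tc = 1)
  cfg <- sim_config(model = model, fold_change = 3, ct_noise_sd = 0.25,
                    n_patients = 40L)
  p_marker <- numeric(0); p_causal <- numeric(0)
  for (i in 1:30) {
    sim <- simulate_cohort_tables(cfg, seed = cell_seed(777, i))
    if (nrow(sim$ratios) < 6) next
    samples <- sim$samples
    samples$causal_gen <- geno_key(paste0(
      ifelse(sim$truth$hap1_causal == "up", "G", "A"),
      ifelse(sim$truth$hap2_causal == "up", "G", "A")))
    sm <- tryCatch(suppressWarnings(
      stratify_by_marker(sim$ratios, samples, marker = "rs2277831")),
      error = function(e) NULL)
    sc <- tryCatch(suppressWarnings(
      stratify_by_marker(sim$ratios, samples, marker = "causal")),
      error = function(e) NULL)
    if (is.null(sm) || is.null(sc)) next
    p_marker <- c(p_marker, sm$p_value)
    p_causal <- c(p_causal, sc$p_value)
  }
  expect_gt(length(p_marker), 10)
  expect_gte(mean(p_causal < 0.05), mean(p_marker < 0.05))
})

test_that("a strong in-phase effect is detected by marker stratification", {
  cfg <- sim_config(fold_change = 3, ct_noise_sd = 0.25, n_patients = 30L)
  hits <- 0L; n_runs <- 20L
  for (i in seq_len(n_runs)) {
    sim <- simulate_cohort_tables(cfg, seed = cell_seed(31415, i))
    strat <- tryCatch(suppressWarnings(
      stratify_by_marker(sim$ratios, sim$samples)),
      error = function(e) NULL)
    if (!is.null(strat) && any(strat$p_value < 0.05)) hits <- hits + 1L
  }
  expect_gt(hits / n_runs, 0.5)
})

test_that("the power study reports calibrated null rates and high power", {
  grid <- data.frame(fold_change = c(1, 5.47), ct_noise_sd = c(0.25, 0.3))
  pw <- run_power_study(grid, n_sims = 300L, master_seed = 42L)
  # null: exact MW rejects at most alpha (conservative test)
  null_row <- pw[pw$fold_change == 1, ]
  se <- sqrt(0.05 * 0.95 / 300)
  expect_lte(null_row$mw_rate, 0.05 + 3 * se)
  # extreme effect: threshold call nearly always fires
  f_row <- pw[pw$fold_change == 5.47, ]
  expect_gt(f_row$aei_rate, 0.95)
  expect_true(all(pw$aei_lo <= pw$aei_rate & pw$aei_rate <= pw$aei_hi))
  expect_error(run_power_study(grid, n_sims = 0L), "n_sims")
})

test_that("power-study cells are independently reproducible", {
  grid <- data.frame(fold_change = 2, ct_noise_sd = 0.25)
  a <- run_power_study(grid, n_sims = 50L, master_seed = 9L)
  b <- run_power_study(grid, n_sims = 50L, master_seed = 9L)
  expect_identical(a, b)
})
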