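#' Pairwise linkage-disequilibrium statistics from haplotype frequencies
#'
#' Standard two-locus LD measures for biallelic SNPs. With `p_ab` the
#' frequency of the haplotype carrying the reference allele at both loci and
#' `p_a`, `p_b` the reference-allele frequencies:
#' `D = p_ab - p_a * p_b`;
#' `D' = D / Dmax` where `Dmax = min(p_a (1 - p_b), (1 - p_a) p_b)` for
#' `D > 0` and `min(p_a p_b, (1 - p_a)(1 - p_b))` for `D < 0`;
#' `r^2 = D^2 / (p_a (1 - p_a) p_b (1 - p_b))`.
#'
#' @param p_ab Frequency of the doubly-reference haplotype.
#' @param p_a,p_b Reference-allele frequencies at the two loci.
#' @return List with `D`, `d_prime`, `r_squared`.
#' @examples
#' ld_stats(0.25, 0.3, 0.5)  # D = 0.10, r^2 ~= 0.190
#' @export
ld_stats <- function(p_ab, p_a, p_b) {
  if (any(c(p_ab, p_a, p_b) < 0) || any(c(p_ab, p_a, p_b) > 1)) {
    stop("frequencies must lie in [0, 1]", call. = FALSE)
  }
  tol <- 1e-12
  if (p_ab > min(p_a, p_b) + tol || p_ab < max(0, p_a + p_b - 1) - tol) {
    stop("`p_ab` is inconsistent with the allele frequencies", call. = FALSE)
  }
  D <- p_ab - p_a * p_b
  d_max <- if (D >= 0) {
    min(p_a * (1 - p_b), (1 - p_a) * p_b)
  } else {
    min(p_a * p_b, (1 - p_a) * (1 - p_b))
  }
  het <- p_a * (1 - p_a) * p_b * (1 - p_b)
  list(D = D,
       d_prime = if (d_max == 0) 0 else D / d_max,
       r_squared = if (het == 0) 0 else D^2 / het)
}

#' Three-locus haplotype model for a tagged cis-regulatory variant
#'
#' Builds haplotype frequencies over three biallelic loci: a causal
#' regulatory variant (alleles `up`/`down`, where `up` multiplies the
#' haplotype's expression by the configured fold change), a marker SNP (the
#' GWAS-associated variant one stratifies by), and a transcript SNP (the
#' exonic read-out used to distinguish the two alleles' mRNA). The marker
#' and the transcript SNP are each coupled to the causal variant with a
#' requested `D'` (positive coupling: marker reference allele and transcript
#' numerator allele ride with `up`), and are conditionally independent given
#' the causal allele — a deliberately simple structure that still produces
#' arbitrary pairwise `D'`/`r^2` to the causal site.
#'
#' The defaults emulate the published rs5992854 scenario: transcript-allele
#' frequency 0.32, complete coupling (`D' = 1`) to the causal variant, and a
#' marker frequency of 0.2504 placed on the causal variant itself, which
#' yields marker-transcript `r^2 ~= 0.71`.
#'
#' @param p_causal Frequency of the expression-raising (`up`) allele.
#' @param p_marker Frequency of the marker's reference (G) allele.
#' @param p_transcript Frequency of the transcript SNP's numerator allele.
#' @param d_prime_mc `D'` between marker and causal variant (1 = marker is a
#'   perfect tag; with equal frequencies the marker is the causal variant).
#' @param d_prime_tc `D'` between transcript SNP and causal variant.
#' @param marker_id,transcript_id SNP identifiers used in emitted tables.
#' @return Object of class `hap_model`: a data.frame of the eight haplotypes
#'   (`marker`, `causal`, `transcript`, `freq`) plus metadata attributes.
#' @examples
#' m <- hap_model()
#' sum(m$freq)  # 1
#' @export
hap_model <- function(p_causal = 0.2504, p_marker = 0.2504,
                      p_transcript = 0.32,
                      d_prime_mc = 1, d_prime_tc = 1,
                      marker_id = "rs2277831", transcript_id = "rs5992854") {
  stopifnot(p_causal > 0, p_causal < 1, p_marker > 0, p_marker < 1,
            p_transcript > 0, p_transcript < 1,
            abs(d_prime_mc) <= 1, abs(d_prime_tc) <= 1)
  cond <- function(p_x, d_prime) {
    d_max <- if (d_prime >= 0) {
      min(p_x * (1 - p_causal), (1 - p_x) * p_causal)
    } else {
      min(p_x * p_causal, (1 - p_x) * (1 - p_causal))
    }
    D <- d_prime * d_max
    p_x_up <- p_x * p_causal + D        # freq of (ref allele, up)
    c(up = p_x_up / p_causal,
      down = (p_x - p_x_up) / (1 - p_causal))
  }
  pm <- cond(p_marker, d_prime_mc)      # P(marker = G | causal)
  pt <- cond(p_transcript, d_prime_tc)  # P(transcript = num | causal)
  if (any(c(pm, pt) < -1e-12) || any(c(pm, pt) > 1 + 1e-12)) {
    stop("requested D' values are inconsistent with the allele frequencies",
         call. = FALSE)
  }
  pm <- pmin(pmax(pm, 0), 1); pt <- pmin(pmax(pt, 0), 1)

  grid <- expand.grid(marker = c("G", "A"), causal = c("up", "down"),
                      transcript = c("num", "den"),
                      stringsAsFactors = FALSE)
  p_c <- ifelse(grid$causal == "up", p_causal, 1 - p_causal)
  p_m <- ifelse(grid$marker == "G", pm[grid$causal], 1 - pm[grid$causal])
  p_t <- ifelse(grid$transcript == "num", pt[grid$causal],
                1 - pt[grid$causal])
  grid$freq <- p_c * p_m * p_t
  stopifnot(abs(sum(grid$freq) - 1) < 1e-9)
  structure(grid, class = c("hap_model", "data.frame"),
            marker_id = marker_id, transcript_id = transcript_id,
            p_causal = p_causal, p_marker = p_marker,
            p_transcript = p_transcript)
}

#' Pairwise LD between two loci of a haplotype model
#'
#' Marginalises a [hap_model()] to two loci and computes [ld_stats()] for
#' the (reference, reference) haplotype, where the reference alleles are
#' `G` (marker), `up` (causal) and `num` (transcript).
#'
#' @param model A `hap_model`.
#' @param loci Character vector of two of `"marker"`, `"causal"`,
#'   `"transcript"`.
#' @return As [ld_stats()].
#' @export
model_ld <- function(model, loci = c("marker", "causal")) {
  stopifnot(inherits(model, "hap_model"), length(loci) == 2L,
            all(loci %in% c("marker", "causal", "transcript")))
  ref <- c(marker = "G", causal = "up", transcript = "num")
  a <- model[[loci[1]]] == ref[loci[1]]
  b <- model[[loci[2]]] == ref[loci[2]]
  ld_stats(sum(model$freq[a & b]), sum(model$freq[a]), sum(model$freq[b]))
}

#' Simulation configuration for a synthetic cis-eQTL cohort
#'
#' Bundles the haplotype model, effect size and measurement-noise settings
#' that drive the generator. Defaults follow the emulated study design:
#' four replicates per template, additive Gaussian Ct noise of 0.25 cycles,
#' multiplicative lognormal peak noise with a 15% coefficient of variation,
#' and a baseline Ct of 30 cycles at unit copy number (which cancels in all
#' ratios but keeps emitted tables realistic).
#'
#' @param model A [hap_model()].
#' @param fold_change Expression of an `up` haplotype relative to a `down`
#'   haplotype (F >= 1 by convention; F = 1 is the null).
#' @param ct_noise_sd SD of per-replicate Ct noise, cycles.
#' @param peak_cv Lognormal sdlog of per-replicate peak noise (fractional).
#' @param n_patients Cohort size.
#' @param n_replicates Replicates per template (default 4).
#' @param platform `"taqman"` or `"extension_peak"`.
#' @param c0 Baseline Ct at unit copy number, cycles.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(model = hap_model(), fold_change = 1,
                       ct_noise_sd = 0.25, peak_cv = 0.15,
                       n_patients = 30L, n_replicates = 4L,
                       platform = c("taqman", "extension_peak"), c0 = 30) {
  platform <- match.arg(platform)
  stopifnot(inherits(model, "hap_model"), fold_change > 0,
            ct_noise_sd >= 0, peak_cv >= 0, n_patients >= 1,
            n_replicates >= 1)
  structure(
    list(model = model, fold_change = fold_change,
         ct_noise_sd = ct_noise_sd, peak_cv = peak_cv,
         n_patients = as.integer(n_patients),
         n_replicates = as.integer(n_replicates),
         platform = platform, c0 = c0),
    class = "sim_config"
  )
}

#' Sample a cohort of phased diploid patients
#'
#' Draws two haplotypes per patient independently from the model's
#' haplotype frequencies (random mating / Hardy-Weinberg equilibrium) and
#' derives unphased genotypes at the marker and transcript SNPs. Phase and
#' the causal-variant alleles are returned in a separate hidden-truth table
#' that the analysis pipeline never sees.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; a fixed seed reproduces the cohort exactly.
#' @return List with `patients` (data.frame: `patient_id`,
#'   `<marker_id>_gen`, `<transcript_id>_gen` — unordered genotype strings)
#'   and `truth` (data.frame with per-haplotype marker/causal/transcript
#'   alleles).
#' @examples
#' co <- sample_cohort(sim_config(n_patients = 5), seed = 1)
#' co$patients
#' @export
sample_cohort <- function(config, seed) {
  stopifnot(inherits(config, "sim_config"))
  model <- config$model
  if (any(model$freq < 0) || sum(model$freq > 0) < 2L) {
    stop("degenerate haplotype frequency vector", call. = FALSE)
  }
  n <- config$n_patients
  idx <- local_seed(seed, matrix(
    sample.int(nrow(model), size = 2L * n, replace = TRUE,
               prob = model$freq),
    ncol = 2L))
  truth <- data.frame(
    patient_id = sprintf("P%03d", seq_len(n)),
    hap1_marker = model$marker[idx[, 1]],
    hap1_causal = model$causal[idx[, 1]],
    hap1_transcript = model$transcript[idx[, 1]],
    hap2_marker = model$marker[idx[, 2]],
    hap2_causal = model$causal[idx[, 2]],
    hap2_transcript = model$transcript[idx[, 2]],
    stringsAsFactors = FALSE
  )
  geno <- function(a, b) geno_key(paste0(a, b))
  patients <- data.frame(patient_id = truth$patient_id,
                         stringsAsFactors = FALSE)
  patients[[paste0(attr(model, "marker_id"), "_gen")]] <-
    geno(truth$hap1_marker, truth$hap2_marker)
  patients[[paste0(attr(model, "transcript_id"), "_gen")]] <-
    geno(ifelse(truth$hap1_transcript == "num", "T", "C"),
         ifelse(truth$hap2_transcript == "num", "T", "C"))
  list(patients = patients, truth = truth)
}

#' Simulate replicate-level allelic measurements for one heterozygote
#'
#' Given the phased haplotypes of a patient heterozygous at the transcript
#' SNP, emits a genomic-DNA and a cDNA replicate set. Each haplotype
#' expresses at level 1 (`down`) or `fold_change` (`up`); cDNA allele copy
#' numbers are proportional to the expression of the haplotype carrying the
#' allele, gDNA copies are 1:1. TaqMan replicates get
#' `Ct = c0 - log2(copies) + N(0, ct_noise_sd)` independently per replicate
#' and probe; extension peaks get `copies * LogNormal(0, peak_cv)`. With
#' zero noise the normalised allelic ratio is exactly the expression ratio
#' of the two haplotypes.
#'
#' @param hap1,hap2 Named character vectors or one-row data.frame fields
#'   with elements `transcript` (`"num"`/`"den"`) and `causal`
#'   (`"up"`/`"down"`).
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @param sample_id Sample identifier for the emitted replicate sets.
#' @return List with `gdna` and `cdna` [replicate_set()] objects, or `NULL`
#'   (with a message) when the patient is homozygous at the transcript SNP.
#' @export
simulate_measurements <- function(hap1, hap2, config, seed,
                                  sample_id = "sim") {
  stopifnot(inherits(config, "sim_config"))
  if (hap1[["transcript"]] == hap2[["transcript"]]) {
    message("skipping ", sample_id, ": homozygous at the transcript SNP")
    return(NULL)
  }
  level <- function(h) if (h[["causal"]] == "up") config$fold_change else 1
  # copies of the numerator allele come from whichever haplotype carries it
  if (hap1[["transcript"]] == "num") {
    copies_cdna <- c(level(hap1), level(hap2))
  } else {
    copies_cdna <- c(level(hap2), level(hap1))
  }
  copies_gdna <- c(1, 1)
  snp <- attr(config$model, "transcript_id")
  k <- config$n_replicates

  local_seed(seed, {
    emit <- function(copies, template) {
      if (config$platform == "taqman") {
        s1 <- config$c0 - log2(copies[1]) + stats::rnorm(k, 0, config$ct_noise_sd)
        s2 <- config$c0 - log2(copies[2]) + stats::rnorm(k, 0, config$ct_noise_sd)
      } else {
        s1 <- copies[1] * stats::rlnorm(k, 0, config$peak_cv)
        s2 <- copies[2] * stats::rlnorm(k, 0, config$peak_cv)
      }
      replicate_set(sample_id, snp, template, config$platform, s1, s2)
    }
    list(gdna = emit(copies_gdna, "gDNA"), cdna = emit(copies_cdna, "cDNA"))
  })
}

#' Simulate a full cohort's input tables
#'
#' Samples a cohort, simulates replicate-level measurements for every
#' patient heterozygous at the transcript SNP, and returns the tables in
#' exactly the formats the analysis functions consume, so the whole pipeline
#' can be exercised end to end on synthetic data.
#'
#' @inheritParams sample_cohort
#' @return List with `samples` (genotype table, one row per patient),
#'   `replicates` (a list of [replicate_set()]s, writable with
#'   [write_replicate_table()]), `truth` (hidden phase/causal table) and
#'   `ratios` (long data.frame `patient_id`, `tissue`, `snp_id`, `genotype`,
#'   `ratio` of normalised allelic ratios, ready for [summarize_gene()] /
#'   [stratify_by_marker()]).
#' @examples
#' sim <- simulate_cohort_tables(sim_config(n_patients = 10), seed = 7)
#' head(sim$ratios)
#' @export
simulate_cohort_tables <- function(config, seed) {
  co <- sample_cohort(config, seed = seed)
  snp <- attr(config$model, "transcript_id")
  gcol <- paste0(snp, "_gen")
  sets <- list(); rows <- list()
  for (i in seq_len(nrow(co$truth))) {
    tr <- co$truth[i, ]
    if (tr$hap1_transcript == tr$hap2_transcript) next
    mm <- simulate_measurements(
      c(transcript = tr$hap1_transcript, causal = tr$hap1_causal),
      c(transcript = tr$hap2_transcript, causal = tr$hap2_causal),
      config, seed = (seed + 1000003 * i) %% 2147483629L,
      sample_id = tr$patient_id
    )
    nar <- normalize_allelic_ratio(mm$cdna, mm$gdna)
    sets[[length(sets) + 1L]] <- mm$gdna
    sets[[length(sets) + 1L]] <- mm$cdna
    rows[[length(rows) + 1L]] <- data.frame(
      patient_id = tr$patient_id, tissue = "synthetic", snp_id = snp,
      genotype = co$patients[[gcol]][i], ratio = nar$value,
      stringsAsFactors = FALSE)
  }
  ratios <- if (length(rows)) do.call(rbind, rows) else
    data.frame(patient_id = character(), tissue = character(),
               snp_id = character(), genotype = character(),
               ratio = numeric())
  list(samples = co$patients, replicates = sets, truth = co$truth,
       ratios = ratios)
}

# Deterministic per-cell seed derivation from a master seed (documented
# scheme: linear hash modulo a prime below 2^31).
cell_seed <- function(master_seed, i) {
  as.integer((as.numeric(master_seed) + 7919 * as.numeric(i)) %% 2147483629)
}

#' Type-I error and power of the design across a parameter grid
#'
#' For each grid cell, simulates fully informative heterozygotes (one `up`
#' and one `down` haplotype, so the true allelic ratio is the fold change F)
#' and reports the fraction of measurements called imbalanced at the
#' threshold and the fraction with exact Mann-Whitney p below `alpha`; at
#' F = 1 these are the type-I error rates of the two rules. Optionally also
#' simulates whole cohorts and reports the power of the marker-stratified
#' Kruskal-Wallis test. Binomial 95% confidence bounds (Clopper-Pearson)
#' accompany every rate. Cell seeds derive deterministically from
#' `master_seed` so each cell is independently reproducible.
#'
#' @param grid data.frame with columns `fold_change` and `ct_noise_sd`
#'   (and optionally `peak_cv`); one row per cell.
#' @param config Base [sim_config()] supplying everything the grid does not
#'   vary.
#' @param n_sims Simulated measurements per cell.
#' @param kw_cohorts Whole-cohort simulations per cell for the
#'   Kruskal-Wallis power column (0 disables).
#' @param alpha Nominal test level.
#' @param threshold AEI fold-difference threshold.
#' @param master_seed Master seed for the deterministic per-cell scheme.
#' @return data.frame: grid columns plus `aei_rate`, `aei_lo`, `aei_hi`,
#'   `mw_rate`, `mw_lo`, `mw_hi`, and (if `kw_cohorts > 0`) `kw_rate`,
#'   `kw_lo`, `kw_hi`.
#' @export
run_power_study <- function(grid, config = sim_config(), n_sims = 200L,
                            kw_cohorts = 0L, alpha = 0.05, threshold = 0.20,
                            master_seed = 1L) {
  stopifnot(is.data.frame(grid), nrow(grid) >= 1L,
            all(c("fold_change", "ct_noise_sd") %in% names(grid)))
  if (n_sims < 1L) stop("`n_sims` must be >= 1", call. = FALSE)
  ci <- function(x, n, prefix) {
    b <- stats::binom.test(x, n)$conf.int
    stats::setNames(data.frame(x / n, b[1], b[2]),
                    paste0(prefix, c("_rate", "_lo", "_hi")))
  }
  out <- lapply(seq_len(nrow(grid)), function(i) {
    cfg <- config
    cfg$fold_change <- grid$fold_change[i]
    cfg$ct_noise_sd <- grid$ct_noise_sd[i]
    if ("peak_cv" %in% names(grid)) cfg$peak_cv <- grid$peak_cv[i]
    s0 <- cell_seed(master_seed, i)
    hap_up <- c(transcript = "num", causal = "up")
    hap_dn <- c(transcript = "den", causal = "down")
    n_aei <- 0L; n_mw <- 0L
    for (j in seq_len(n_sims)) {
      mm <- simulate_measurements(hap_up, hap_dn, cfg,
                                  seed = cell_seed(s0, j))
      nar <- normalize_allelic_ratio(mm$cdna, mm$gdna)
      n_aei <- n_aei + call_aei(nar$value, threshold = threshold)
      n_mw <- n_mw +
        (mann_whitney_exact(nar$cdna_ratios, nar$gdna_ratios) < alpha)
    }
    row <- cbind(grid[i, , drop = FALSE],
                 ci(n_aei, n_sims, "aei"), ci(n_mw, n_sims, "mw"))
    if (kw_cohorts > 0L) {
      marker_id <- attr(cfg$model, "marker_id")
      n_kw <- 0L
      for (j in seq_len(kw_cohorts)) {
        sim <- simulate_cohort_tables(cfg, seed = cell_seed(s0 + 1L, j))
        strat <- tryCatch(
          suppressWarnings(stratify_by_marker(sim$ratios, sim$samples,
                                              marker = marker_id)),
          error = function(e) NULL)
        n_kw <- n_kw + (!is.null(strat) && any(strat$p_value < alpha))
      }
      row <- cbind(row, ci(n_kw, kw_cohorts, "kw"))
    }
    row
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
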