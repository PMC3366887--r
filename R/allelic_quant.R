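#' Per-replicate allelic ratio from a dual-probe qPCR Ct pair
#'
#' Converts a pair of threshold-cycle values from the two allele-specific
#' probes (FAM for the first-listed allele, VIC for the second) into an
#' allelic ratio under the perfect-doubling model:
#' `2^(-ct_1) / 2^(-ct_2) = efficiency^(ct_2 - ct_1)`. With the default
#' efficiency of 2 one cycle of separation corresponds to a two-fold allelic
#' difference.
#'
#' @param ct_1 Ct of the probe for the numerator allele (cycles).
#' @param ct_2 Ct of the probe for the denominator allele (cycles).
#' @param efficiency Per-cycle amplification factor, fixed at 2 by default;
#'   configurable per assay but never inferred from data.
#' @return Dimensionless allelic ratio(s) > 0. Vectorised over replicates.
#' @examples
#' taqman_ratio(24, 25)  # one cycle earlier on FAM -> ratio 2
#' taqman_ratio(26, 24)  # 0.25
#' @export
taqman_ratio <- function(ct_1, ct_2, efficiency = 2) {
  if (!all(is.finite(ct_1)) || !all(is.finite(ct_2))) {
    stop("Ct values must be finite", call. = FALSE)
  }
  if (length(ct_1) != length(ct_2)) {
    stop("`ct_1` and `ct_2` must have equal length", call. = FALSE)
  }
  if (!is.finite(efficiency) || efficiency <= 1) {
    stop("`efficiency` must be > 1", call. = FALSE)
  }
  efficiency^(ct_2 - ct_1)
}

#' Per-replicate allelic ratio from primer-extension peak intensities
#'
#' Each single-base extension product produces a mass-spectrometry peak whose
#' intensity is proportional to the amount of the corresponding allele, so
#' the allelic ratio is the direct intensity quotient.
#'
#' @param peak_1 Peak intensity for the numerator allele (a.u.), > 0.
#' @param peak_2 Peak intensity for the denominator allele (a.u.), > 0.
#' @return Dimensionless allelic ratio(s). Vectorised over replicates.
#' @examples
#' peak_ratio(1500, 500)  # 3
#' @export
peak_ratio <- function(peak_1, peak_2) {
  if (!all(is.finite(peak_1)) || !all(is.finite(peak_2))) {
    stop("peak intensities must be finite", call. = FALSE)
  }
  if (length(peak_1) != length(peak_2)) {
    stop("`peak_1` and `peak_2` must have equal length", call. = FALSE)
  }
  if (any(peak_1 <= 0) || any(peak_2 <= 0)) {
    stop("zero or negative peak intensity (assay dropout)", call. = FALSE)
  }
  peak_1 / peak_2
}

#' Per-replicate allelic ratios of a replicate set
#'
#' Applies the platform's ratio transform ([taqman_ratio()] or
#' [peak_ratio()]) to every replicate of a [replicate_set()].
#'
#' @param x A `replicate_set`.
#' @param efficiency Amplification efficiency for the taqman platform.
#' @return Numeric vector of per-replicate allelic ratios.
#' @export
allelic_ratios <- function(x, efficiency = 2) {
  stopifnot(inherits(x, "replicate_set"))
  if (x$platform == "taqman") {
    taqman_ratio(x$signal_1, x$signal_2, efficiency = efficiency)
  } else {
    peak_ratio(x$signal_1, x$signal_2)
  }
}

#' Normalise a cDNA allelic ratio against its genomic-DNA reference
#'
#' The genomic DNA of a heterozygote carries the two alleles in an exact 1:1
#' ratio, so the average allelic ratio measured on gDNA captures the assay's
#' allele-specific signal bias. The normalised allelic ratio divides the
#' average cDNA ratio by the average gDNA ratio:
#'
#' \deqn{\mathrm{NAR} = \frac{\overline{r}_{\mathrm{cDNA}}}{\overline{r}_{\mathrm{gDNA}}}}
#'
#' A value of 1 means both alleles are transcribed equally; departures
#' indicate allelic expression imbalance. The default averaging rule is the
#' arithmetic mean of the raw per-replicate ratios; a geometric (log-domain)
#' mean is available because averaging of ratios is asymmetric around 1.
#'
#' @param cdna,gdna `replicate_set` objects sharing `snp_id` and `platform`;
#'   `cdna` must have `template == "cDNA"` and `gdna` `"gDNA"`.
#' @param average `"arithmetic"` (default) or `"geometric"`.
#' @param efficiency Amplification efficiency passed to [taqman_ratio()].
#' @return An object of class `normalized_allelic_ratio`: a list with
#'   `sample_id`, `snp_id`, `platform`, `value`, `cdna_ratios`,
#'   `gdna_ratios`, `average`.
#' @examples
#' g <- replicate_set("s1", "rs11538", "gDNA", "extension_peak",
#'                    signal_1 = c(100, 100, 100, 100),
#'                    signal_2 = c(100, 100, 100, 100))
#' c <- replicate_set("s1", "rs11538", "cDNA", "extension_peak",
#'                    signal_1 = c(200, 200, 200, 200),
#'                    signal_2 = c(100, 100, 100, 100))
#' normalize_allelic_ratio(c, g)$value  # 2
#' @export
normalize_allelic_ratio <- function(cdna, gdna,
                                    average = c("arithmetic", "geometric"),
                                    efficiency = 2) {
  average <- match.arg(average)
  stopifnot(inherits(cdna, "replicate_set"), inherits(gdna, "replicate_set"))
  if (cdna$template != "cDNA" || gdna$template != "gDNA") {
    stop("arguments must be (cDNA, gDNA) replicate sets, in that order",
         call. = FALSE)
  }
  if (cdna$snp_id != gdna$snp_id || cdna$platform != gdna$platform) {
    stop("cDNA and gDNA replicate sets must share snp_id and platform",
         call. = FALSE)
  }
  rc <- allelic_ratios(cdna, efficiency = efficiency)
  rg <- allelic_ratios(gdna, efficiency = efficiency)
  avg <- switch(average,
                arithmetic = function(v) mean(v),
                geometric = function(v) exp(mean(log(v))))
  structure(
    list(sample_id = cdna$sample_id, snp_id = cdna$snp_id,
         platform = cdna$platform, value = avg(rc) / avg(rg),
         cdna_ratios = rc, gdna_ratios = rg, average = average),
    class = "normalized_allelic_ratio"
  )
}

#' @export
print.normalized_allelic_ratio <- function(x, ...) {
  cat(sprintf("<normalized_allelic_ratio> %s %s: %.3f (%d cDNA / %d gDNA replicates)\n",
              x$sample_id, x$snp_id, x$value,
              length(x$cdna_ratios), length(x$gdna_ratios)))
  invisible(x)
}

#' Quantify normalised allelic ratios for a whole replicate table
#'
#' Pairs each cDNA replicate set with the gDNA replicate set of the same
#' (sample, SNP) and computes the normalised allelic ratio plus the exact
#' Mann-Whitney comparison of the per-replicate cDNA vs gDNA ratio
#' distributions.
#'
#' @param sets List of `replicate_set` objects, e.g. from
#'   [read_replicate_table()].
#' @param threshold Fold-difference fraction for the imbalance call
#'   (default 0.20).
#' @inheritParams normalize_allelic_ratio
#' @inheritParams call_aei
#' @return A data.frame with one row per (sample, SNP): `sample_id`,
#'   `snp_id`, `platform`, `value`, `imbalanced`, `p_value`,
#'   `n_cdna`, `n_gdna`. Samples lacking either template are skipped with a
#'   warning.
#' @export
quantify_allelic_table <- function(sets, threshold = 0.20,
                                   average = c("arithmetic", "geometric"),
                                   scale = c("ratio", "log"),
                                   efficiency = 2) {
  average <- match.arg(average)
  scale <- match.arg(scale)
  key <- vapply(sets, function(s) paste(s$sample_id, s$snp_id, sep = "|"),
                character(1))
  rows <- lapply(split(sets, key), function(pair) {
    tmpl <- vapply(pair, `[[`, character(1), "template")
    if (!all(c("cDNA", "gDNA") %in% tmpl)) {
      warning("skipping ", pair[[1]]$sample_id, "/", pair[[1]]$snp_id,
              ": need both cDNA and gDNA replicate sets", call. = FALSE)
      return(NULL)
    }
    nar <- normalize_allelic_ratio(pair[[which(tmpl == "cDNA")[1]]],
                                   pair[[which(tmpl == "gDNA")[1]]],
                                   average = average, efficiency = efficiency)
    data.frame(sample_id = nar$sample_id, snp_id = nar$snp_id,
               platform = nar$platform, value = nar$value,
               imbalanced = call_aei(nar$value, threshold = threshold,
                                     scale = scale),
               p_value = mann_whitney_exact(nar$cdna_ratios, nar$gdna_ratios),
               n_cdna = length(nar$cdna_ratios),
               n_gdna = length(nar$gdna_ratios),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(sample_id = character(), snp_id = character(),
                      platform = character(), value = numeric(),
                      imbalanced = logical(), p_value = numeric(),
                      n_cdna = integer(), n_gdna = integer())
  }
  rownames(out) <- NULL
  out
}
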