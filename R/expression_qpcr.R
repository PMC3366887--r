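#' Delta-Ct relative expression
#'
#' Computes the delta-Ct of a test gene against a set of housekeeping
#' (control) genes: `delta Ct = Ct(test) - mean(Ct(controls))`. Lower
#' delta-Ct means higher expression (one cycle is roughly a two-fold change
#' under perfect amplification efficiency). No `2^-dCt` transform is
#' applied; downstream analyses operate on the cycle scale.
#'
#' @param ct_test Ct of the test gene (cycles). May be a vector; the control
#'   mean is subtracted elementwise.
#' @param ct_controls Non-empty numeric vector of control-gene Ct values
#'   (cycles).
#' @return delta-Ct in cycles.
#' @examples
#' delta_ct(25, c(18, 19, 20))  # 6
#' @export
delta_ct <- function(ct_test, ct_controls) {
  if (length(ct_controls) == 0L) {
    stop("`ct_controls` must be non-empty", call. = FALSE)
  }
  if (!all(is.finite(ct_test)) || !all(is.finite(ct_controls))) {
    stop("all Ct values must be finite", call. = FALSE)
  }
  ct_test - mean(ct_controls)
}

#' Regress relative expression on marker genotype
#'
#' Ordinary least-squares regression of per-patient delta-Ct on the additive
#' dosage of the marker SNP's G allele (0 = AA, 1 = GA, 2 = GG), with a
#' two-sided t-test on the slope. This is the total-expression arm of a
#' cis-eQTL analysis: a nonzero slope means expression tracks genotype.
#' Additive dosage coding is the standard eQTL convention.
#'
#' @param records A data.frame with columns `delta_ct` (cycles) and
#'   `dosage` (0, 1 or 2 copies of the G allele). A `genotype` column of
#'   strings (`"AA"`, `"GA"`/`"AG"`, `"GG"`) is accepted instead of
#'   `dosage`.
#' @return A list of class `regression_result`: `slope` (delta-Ct per allele
#'   copy), `intercept`, `p_value` (two-sided, for slope != 0; 1 when the
#'   residual variance is exactly zero and the slope is zero), `n`, and
#'   `group_means` (mean delta-Ct per dosage, for the genotype-stratified
#'   plot).
#' @examples
#' set.seed(1)
#' rec <- data.frame(dosage = rep(0:2, each = 10),
#'                   delta_ct = 6 - 0.5 * rep(0:2, each = 10) + rnorm(30, 0, 0.3))
#' expression_vs_genotype(rec)$slope
#' @export
expression_vs_genotype <- function(records) {
  stopifnot(is.data.frame(records), "delta_ct" %in% names(records))
  if (!"dosage" %in% names(records)) {
    if (!"genotype" %in% names(records)) {
      stop("`records` needs a `dosage` or `genotype` column", call. = FALSE)
    }
    key <- geno_key(records$genotype)
    records$dosage <- vapply(strsplit(key, ""), function(a) sum(a == "G"),
                             numeric(1))
  }
  if (!all(records$dosage %in% 0:2)) {
    stop("`dosage` must be 0, 1 or 2 copies of the G allele", call. = FALSE)
  }
  if (nrow(records) < 3L || length(unique(records$dosage)) < 2L) {
    stop("degenerate design: need >= 3 records and >= 2 distinct genotypes",
         call. = FALSE)
  }
  fit <- stats::lm(delta_ct ~ dosage, data = records)
  # a perfect fit is handled explicitly below; silence summary.lm's notice
  sm <- withCallingHandlers(
    summary(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  coefs <- sm$coefficients
  p <- coefs["dosage", "Pr(>|t|)"]
  # (numerically) zero residual variance: a flat fit carries no evidence
  # against the null, a perfect nonzero slope is maximal evidence
  scale0 <- stats::sd(records$delta_ct) + 1
  if (is.nan(p) || sm$sigma < 1e-10 * scale0) {
    p <- if (abs(coefs["dosage", "Estimate"]) < 1e-10 * scale0) 1
         else .Machine$double.xmin
  }
  structure(
    list(slope = unname(coefs["dosage", "Estimate"]),
         intercept = unname(coefs["(Intercept)", "Estimate"]),
         p_value = p,
         n = nrow(records),
         group_means = tapply(records$delta_ct, records$dosage, mean)),
    class = "regression_result"
  )
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("<regression_result> n = %d, slope = %.4f dCt/allele, p = %.4g\n",
              x$n, x$slope, x$p_value))
  invisible(x)
}
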