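#' Call allelic expression imbalance from a normalised allelic ratio
#'
#' A measurement shows allelic expression imbalance (AEI) when the fold
#' difference in expression between the two alleles reaches the threshold
#' fraction. On the raw ratio scale the rule is asymmetric and both bounds
#' are inclusive: with the default 20% threshold, a normalised ratio of 1.20
#' or above, or 0.80 or below, is imbalanced (0.81 and 1.19 are not). The
#' `"log"` scale applies the symmetric rule `|log2 r| >= log2(1 + threshold)`
#' instead, whose lower cutoff is 1/1.2 ~= 0.833.
#'
#' @param value Normalised allelic ratio(s), > 0. A
#'   `normalized_allelic_ratio` object is also accepted.
#' @param threshold Fold-difference fraction in (0, 1); default 0.20.
#' @param scale `"ratio"` (asymmetric bounds `1 - threshold`,
#'   `1 + threshold`; default) or `"log"` (symmetric in log2).
#' @return Logical vector: `TRUE` where imbalanced.
#' @examples
#' call_aei(c(2.82, 0.80, 0.83, 1.19, 1.20))
#' @export
call_aei <- function(value, threshold = 0.20, scale = c("ratio", "log")) {
  scale <- match.arg(scale)
  if (inherits(value, "normalized_allelic_ratio")) value <- value$value
  if (!is.numeric(value) || any(value <= 0, na.rm = TRUE)) {
    stop("`value` must be positive ratios", call. = FALSE)
  }
  if (!is.finite(threshold) || threshold <= 0 || threshold >= 1) {
    stop("`threshold` must lie in (0, 1)", call. = FALSE)
  }
  if (scale == "ratio") {
    value >= 1 + threshold | value <= 1 - threshold
  } else {
    abs(log2(value)) >= log2(1 + threshold)
  }
}

# One-sided/two-sided exact Mann-Whitney machinery. U is computed from
# midrank sums so ties are handled identically in the observed statistic and
# in the enumerated null.
mw_u_from_ranks <- function(ranks_x, n, m) {
  sum(ranks_x) - n * (n + 1) / 2
}

#' Exact two-sided Mann-Whitney test
#'
#' Compares two samples with the Mann-Whitney U statistic. For small inputs
#' (`length(x) + length(y) <= exact_limit`) the null distribution of U is
#' enumerated exactly over all `choose(n+m, n)` assignments of the observed
#' pooled values (midranks, so ties are exact too); the two-sided p doubles
#' the smaller one-sided tail and is capped at 1. Larger inputs use the
#' normal approximation with tie correction and continuity correction.
#'
#' With four replicates per group — the usual qPCR design — the smallest
#' achievable two-sided exact p is 2/70 ~= 0.029: a 4-vs-4 comparison can
#' never yield p-values like 0.004 however clean the separation.
#'
#' @param x,y Non-empty numeric vectors (e.g. per-replicate cDNA and gDNA
#'   allelic ratios).
#' @param exact_limit Largest pooled size for which full enumeration is used
#'   (default 20; `choose(20, 10)` = 184756 assignments).
#' @return Two-sided p-value in (0, 1].
#' @examples
#' mann_whitney_exact(1:4, 5:8)       # complete separation: 2/70
#' mann_whitney_exact(c(1, 3), c(2, 4))  # maximally central: 1
#' @export
mann_whitney_exact <- function(x, y, exact_limit = 20L) {
  if (length(x) == 0L || length(y) == 0L) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("all values must be finite", call. = FALSE)
  }
  n <- length(x); m <- length(y); N <- n + m
  pooled <- c(x, y)
  r <- rank(pooled)                      # midranks
  u_obs <- mw_u_from_ranks(r[seq_len(n)], n, m)

  if (N <= exact_limit) {
    combs <- utils::combn(N, n)
    u_all <- colSums(matrix(r[combs], nrow = n)) - n * (n + 1) / 2
    eps <- 1e-9
    p_lo <- mean(u_all <= u_obs + eps)
    p_hi <- mean(u_all >= u_obs - eps)
    min(1, 2 * min(p_lo, p_hi))
  } else {
    mu <- n * m / 2
    tie_tab <- table(pooled)
    sigma2 <- n * m / 12 *
      ((N + 1) - sum(tie_tab^3 - tie_tab) / (N * (N - 1)))
    if (sigma2 <= 0) return(1)          # everything tied
    z <- (u_obs - mu - sign(u_obs - mu) * 0.5) / sqrt(sigma2)
    min(1, 2 * stats::pnorm(-abs(z)))
  }
}

#' Kruskal-Wallis test with tie correction and permutation option
#'
#' Rank-based k-sample test of identical distributions. The default route
#' computes the tie-corrected H statistic and a chi-square p-value on k - 1
#' degrees of freedom (via [stats::kruskal.test()]); when every pooled value
#' is identical H is 0 and p is 1. `p_method = "permutation"` instead
#' permutes group labels: full enumeration of all distinct assignments when
#' the pooled size is at most `exact_limit`, otherwise Monte-Carlo with
#' `n_perm` draws (reproducible for a fixed `seed`).
#'
#' @param groups List of >= 2 non-empty numeric vectors.
#' @param p_method `"chisq"` (default) or `"permutation"`.
#' @param exact_limit Pooled-size cap for full enumeration (default 10).
#' @param n_perm Monte-Carlo permutations when enumeration is infeasible.
#' @param seed Integer seed for the Monte-Carlo branch.
#' @return List with `h` (tie-corrected H), `p_value`, `df`, `method`.
#' @examples
#' kruskal_wallis(list(1:3, 4:6, 7:9))$h  # 7.2
#' @export
kruskal_wallis <- function(groups, p_method = c("chisq", "permutation"),
                           exact_limit = 10L, n_perm = 10000L, seed = 1L) {
  p_method <- match.arg(p_method)
  groups <- groups[lengths(groups) > 0L]
  if (length(groups) < 2L) {
    stop("need at least two non-empty groups", call. = FALSE)
  }
  sizes <- lengths(groups)
  pooled <- unlist(groups, use.names = FALSE)
  N <- length(pooled)
  if (N < 3L) stop("need a total of at least 3 observations", call. = FALSE)
  k <- length(groups)

  if (length(unique(pooled)) == 1L) {
    return(list(h = 0, p_value = 1, df = k - 1L, method = "degenerate"))
  }

  r <- rank(pooled)
  g <- rep(seq_len(k), sizes)
  tie_tab <- table(pooled)
  tie_corr <- 1 - sum(tie_tab^3 - tie_tab) / (N^3 - N)
  h_of <- function(rr) {
    (12 / (N * (N + 1)) * sum(tapply(rr, g, sum)^2 / sizes) - 3 * (N + 1)) /
      tie_corr
  }
  h <- h_of(r)

  if (p_method == "chisq") {
    kt <- stats::kruskal.test(pooled, factor(g))
    list(h = unname(kt$statistic), p_value = kt$p.value, df = k - 1L,
         method = "chisq")
  } else {
    eps <- 1e-9
    if (N <= exact_limit) {
      perms <- all_group_assignments(N, sizes)
      h_all <- apply(perms, 2L, function(ord) h_of(r[ord]))
      list(h = h, p_value = mean(h_all >= h - eps), df = k - 1L,
           method = "permutation_exact")
    } else {
      h_mc <- local_seed(seed, replicate(n_perm, h_of(sample(r))))
      list(h = h, p_value = (1 + sum(h_mc >= h - eps)) / (n_perm + 1),
           df = k - 1L, method = "permutation_mc")
    }
  }
}

# Evaluate `expr` under `seed` without disturbing the caller's RNG stream.
local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

# Enumerate all distinct assignments of N pooled observations to groups of
# the given sizes. Returns an N x n_assignments matrix of index orderings
# (first sizes[1] rows are group 1, etc.).
all_group_assignments <- function(N, sizes) {
  recurse <- function(avail, sizes) {
    if (length(sizes) == 1L) return(matrix(avail, ncol = 1L))
    picks <- utils::combn(avail, sizes[1])
    cols <- lapply(seq_len(ncol(picks)), function(j) {
      rest <- recurse(setdiff(avail, picks[, j]), sizes[-1])
      rbind(matrix(picks[, j], nrow = sizes[1], ncol = ncol(rest)), rest)
    })
    do.call(cbind, cols)
  }
  recurse(seq_len(N), sizes)
}

#' Summarise allelic expression imbalance for one gene
#'
#' Patient-level aggregation of AEI across a gene's transcript SNPs:
#' heterozygous patients are counted uniquely by `patient_id` across all
#' their tissue rows, and a patient is AEI-positive if any measurement at
#' any of the gene's transcript SNPs in any tissue is called imbalanced.
#' The maximal ratio over the gene's retained measurements is reported with
#' the SNP and patient attaining it.
#'
#' @param ratios Long data.frame of measurements with columns `patient_id`,
#'   `snp_id`, `ratio` (e.g. `load_table2()$ratios`).
#' @param samples Per-sample data.frame with `patient_id` and one
#'   `<snp_id>_gen` genotype column per panel SNP
#'   (e.g. `load_table2()$samples`).
#' @param gene Gene symbol present in the panel.
#' @param threshold,scale Passed to [call_aei()].
#' @param panel SNP panel data.frame (default [snp_panel()]).
#' @return A list of class `gene_aei_summary`: `gene`,
#'   `n_heterozygous_patients`, `n_aei_patients`, `aei_patient_ids`,
#'   `het_patient_ids`, `max_ratio`, `max_ratio_snp`, `max_ratio_patient`
#'   (maxima are `NA` when the gene has no measurements).
#' @examples
#' t2 <- load_table2()
#' summarize_gene(t2$ratios, t2$samples, "BCL2L13")
#' @export
summarize_gene <- function(ratios, samples, gene, threshold = 0.20,
                           scale = c("ratio", "log"), panel = snp_panel()) {
  scale <- match.arg(scale)
  gene_snps <- panel$snp_id[panel$gene == gene & panel$snp_id != "rs2277831"]
  if (length(gene_snps) == 0L) stop("unknown gene: ", gene, call. = FALSE)

  het_ids <- character(0)
  for (s in gene_snps) {
    col <- paste0(s, "_gen")
    if (!col %in% names(samples)) next
    het_ids <- union(het_ids,
                     samples$patient_id[which(is_het(samples[[col]]))])
  }

  rg <- ratios[ratios$snp_id %in% gene_snps, , drop = FALSE]
  aei_ids <- if (nrow(rg)) {
    sort(unique(rg$patient_id[call_aei(rg$ratio, threshold = threshold,
                                       scale = scale)]))
  } else character(0)

  if (nrow(rg)) {
    i_max <- which.max(rg$ratio)
    max_ratio <- rg$ratio[i_max]
    max_snp <- rg$snp_id[i_max]
    max_patient <- rg$patient_id[i_max]
  } else {
    max_ratio <- NA_real_; max_snp <- NA_character_
    max_patient <- NA_character_
  }

  structure(
    list(gene = gene,
         n_heterozygous_patients = length(het_ids),
         n_aei_patients = length(aei_ids),
         aei_patient_ids = aei_ids,
         het_patient_ids = sort(het_ids),
         max_ratio = max_ratio, max_ratio_snp = max_snp,
         max_ratio_patient = max_patient),
    class = "gene_aei_summary"
  )
}

#' @export
print.gene_aei_summary <- function(x, ...) {
  cat(sprintf("<gene_aei_summary> %s: %d/%d patients AEI-positive/heterozygous, max ratio %.2f (%s, patient %s)\n",
              x$gene, x$n_aei_patients, x$n_heterozygous_patients,
              x$max_ratio, x$max_ratio_snp, x$max_ratio_patient))
  invisible(x)
}

#' Flag AEI on a measurement table
#'
#' Adds an `imbalanced` column to a long ratio table, applying [call_aei()]
#' row-wise.
#'
#' @inheritParams summarize_gene
#' @return `ratios` with an extra logical `imbalanced` column.
#' @export
aei_call_table <- function(ratios, threshold = 0.20,
                           scale = c("ratio", "log")) {
  scale <- match.arg(scale)
  stopifnot(is.data.frame(ratios))
  ratios$imbalanced <- if (nrow(ratios)) {
    call_aei(ratios$ratio, threshold = threshold, scale = scale)
  } else logical(0)
  ratios
}

#' Associate allelic ratios with a marker genotype
#'
#' For each transcript SNP, reduces the measurements to one value per
#' patient — the mean of `log2(normalised ratio)` across that patient's
#' tissues/measurements at the SNP — groups the per-patient values by the
#' genotype at the marker SNP, and applies the Kruskal-Wallis test per SNP.
#' If a cis-regulatory variant were tagged by the marker, marker
#' heterozygotes would show systematically larger allelic departures than
#' homozygotes. No multiple-testing adjustment is applied. Signed log2
#' ratios in the assay's declared allele orientation are used.
#'
#' @param ratios Long measurement data.frame (`patient_id`, `snp_id`,
#'   `ratio`).
#' @param samples Per-sample data.frame carrying `patient_id` and
#'   `<marker>_gen`; patients with a missing marker genotype are excluded
#'   with a warning.
#' @param marker Marker SNP id (default `"rs2277831"`).
#' @param p_method Passed to [kruskal_wallis()].
#' @return A data.frame with one row per transcript SNP: `snp_id`, group
#'   sizes `n_AA`, `n_GA`, `n_GG`, `h`, `p_value`. The per-patient grouped
#'   values are attached as the `"groups"` attribute (a named list of lists).
#' @examples
#' t2 <- load_table2()
#' stratify_by_marker(t2$ratios, t2$samples)
#' @export
stratify_by_marker <- function(ratios, samples, marker = "rs2277831",
                               p_method = c("chisq", "permutation")) {
  p_method <- match.arg(p_method)
  mcol <- paste0(marker, "_gen")
  if (!mcol %in% names(samples)) {
    stop("samples table lacks marker genotype column ", mcol, call. = FALSE)
  }
  geno_by_patient <- tapply(samples[[mcol]], samples$patient_id,
                            function(g) {
                              u <- unique(geno_key(g[!is.na(g)]))
                              if (length(u) == 1L) u else NA_character_
                            })
  # render group labels in the printed convention (AA / GA / GG)
  relabel <- c(AA = "AA", AG = "GA", GG = "GG")

  out <- list(); grp_attr <- list()
  for (s in unique(ratios$snp_id)) {
    rs <- ratios[ratios$snp_id == s, , drop = FALSE]
    per_patient <- tapply(log2(rs$ratio), rs$patient_id, mean)
    geno <- geno_by_patient[names(per_patient)]
    drop <- is.na(geno)
    if (any(drop)) {
      warning("excluding ", sum(drop), " patient(s) without ", marker,
              " genotype at ", s, call. = FALSE)
      per_patient <- per_patient[!drop]; geno <- geno[!drop]
    }
    label <- relabel[geno]
    groups <- split(as.numeric(per_patient), factor(label, levels = c("AA", "GA", "GG")))
    nonempty <- groups[lengths(groups) > 0L]
    kw <- kruskal_wallis(nonempty, p_method = p_method)
    out[[s]] <- data.frame(snp_id = s,
                           n_AA = length(groups$AA), n_GA = length(groups$GA),
                           n_GG = length(groups$GG),
                           h = kw$h, p_value = kw$p_value,
                           stringsAsFactors = FALSE)
    grp_attr[[s]] <- groups
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "groups") <- grp_attr
  res
}
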