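#' Construct a set of replicate allelic measurements
#'
#' A replicate set holds the raw per-replicate signal pairs for one
#' (sample, SNP, template) combination on one platform: paired Ct values for
#' a dual-probe (FAM/VIC) TaqMan assay, or paired peak intensities for a
#' single-base primer-extension assay. `signal_1` always belongs to the
#' first-listed (numerator) allele of the assay.
#'
#' @param sample_id Sample identifier.
#' @param snp_id Assay SNP identifier.
#' @param template `"gDNA"` or `"cDNA"`.
#' @param platform `"taqman"` (signals are Ct cycles) or `"extension_peak"`
#'   (signals are peak intensities in arbitrary units).
#' @param signal_1,signal_2 Numeric vectors of equal length (>= 1), one
#'   entry per replicate. Ct values must lie in \[0, 45\]; peak intensities
#'   must be strictly positive.
#' @return An object of class `replicate_set`.
#' @examples
#' replicate_set("s1", "rs5992854", "cDNA", "taqman",
#'               signal_1 = c(24.1, 24.0, 24.2, 23.9),
#'               signal_2 = c(25.0, 25.1, 24.9, 25.2))
#' @export
replicate_set <- function(sample_id, snp_id,
                          template = c("gDNA", "cDNA"),
                          platform = c("taqman", "extension_peak"),
                          signal_1, signal_2) {
  template <- match.arg(template)
  platform <- match.arg(platform)
  signal_1 <- as.numeric(signal_1)
  signal_2 <- as.numeric(signal_2)
  if (length(signal_1) < 1L || length(signal_1) != length(signal_2)) {
    stop("need >= 1 replicate and equal-length signal vectors", call. = FALSE)
  }
  if (!all(is.finite(signal_1)) || !all(is.finite(signal_2))) {
    stop("all signals must be finite", call. = FALSE)
  }
  if (platform == "taqman" &&
      (any(signal_1 < 0 | signal_1 > 45) || any(signal_2 < 0 | signal_2 > 45))) {
    stop("Ct values must lie in [0, 45]", call. = FALSE)
  }
  if (platform == "extension_peak" &&
      (any(signal_1 <= 0) || any(signal_2 <= 0))) {
    stop("peak intensities must be strictly positive", call. = FALSE)
  }
  structure(
    list(sample_id = as.character(sample_id), snp_id = as.character(snp_id),
         template = template, platform = platform,
         signal_1 = signal_1, signal_2 = signal_2),
    class = "replicate_set"
  )
}

#' @export
print.replicate_set <- function(x, ...) {
  cat(sprintf("<replicate_set> %s %s %s (%s), %d replicates\n",
              x$sample_id, x$snp_id, x$template, x$platform,
              length(x$signal_1)))
  invisible(x)
}

REPLICATE_COLS <- c("sample_id", "snp_id", "template", "platform",
                    "replicate", "signal_1", "signal_2")

detect_delim <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0L) return("\t")
  if (grepl("\t", first)) "\t" else ","
}

#' Read a replicate-level allelic measurement table
#'
#' Reads a delimited text file (comma or tab, auto-detected) with columns
#' `sample_id`, `snp_id`, `template`, `platform`, `replicate`, `signal_1`,
#' `signal_2` and groups rows into [replicate_set()] objects by
#' (sample, SNP, template). Rows are ordered by their replicate index within
#' each group.
#'
#' @param path Path to the file.
#' @return A list of `replicate_set` objects, named
#'   `"<sample_id>|<snp_id>|<template>"`. A header-only file yields an empty
#'   list.
#' @seealso [write_replicate_table()]
#' @export
read_replicate_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  delim <- detect_delim(path)
  df <- utils::read.delim(path, sep = delim, stringsAsFactors = FALSE,
                          colClasses = "character", check.names = FALSE)
  missing_cols <- setdiff(REPLICATE_COLS, names(df))
  if (length(missing_cols) > 0L) {
    stop("replicate table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(df) == 0L) return(list())

  # +1 for the header: report line numbers as they appear in the file
  lineno <- seq_len(nrow(df)) + 1L
  bad <- function(v) is.na(suppressWarnings(as.numeric(v)))
  bad_rows <- bad(df$signal_1) | bad(df$signal_2) | bad(df$replicate)
  if (any(bad_rows)) {
    stop("non-numeric signal/replicate value(s) at line(s): ",
         paste(lineno[bad_rows], collapse = ", "), call. = FALSE)
  }
  df$signal_1 <- as.numeric(df$signal_1)
  df$signal_2 <- as.numeric(df$signal_2)
  df$replicate <- as.integer(as.numeric(df$replicate))

  key <- paste(df$sample_id, df$snp_id, df$template, sep = "|")
  out <- lapply(split(df, key), function(g) {
    g <- g[order(g$replicate), , drop = FALSE]
    if (!identical(g$replicate, seq_len(nrow(g)))) {
      stop("replicate indices not contiguous for ",
           g$sample_id[1], "/", g$snp_id[1], "/", g$template[1],
           call. = FALSE)
    }
    if (length(unique(g$platform)) != 1L) {
      stop("mixed platforms within one replicate set for ",
           g$sample_id[1], "/", g$snp_id[1], call. = FALSE)
    }
    replicate_set(g$sample_id[1], g$snp_id[1], g$template[1], g$platform[1],
                  g$signal_1, g$signal_2)
  })
  out[order(names(out))]
}

#' Write replicate sets back to a delimited table
#'
#' Inverse of [read_replicate_table()]: serialises a list of
#' [replicate_set()] objects to a TSV with the canonical column order.
#'
#' @param sets List of `replicate_set` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_replicate_table <- function(sets, path) {
  rows <- lapply(sets, function(s) {
    data.frame(sample_id = s$sample_id, snp_id = s$snp_id,
               template = s$template, platform = s$platform,
               replicate = seq_along(s$signal_1),
               signal_1 = s$signal_1, signal_2 = s$signal_2,
               stringsAsFactors = FALSE)
  })
  df <- if (length(rows)) do.call(rbind, rows) else
    stats::setNames(as.data.frame(matrix(nrow = 0, ncol = 7)), REPLICATE_COLS)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

TISSUE_CODES <- c("Cart (K)" = "cartilage_knee", "Cart (H)" = "cartilage_hip",
                  "Fat pad" = "fat_pad", "Syn" = "synovium",
                  "Can bn" = "cancellous_bone", "OP" = "osteophyte")

# md5 of the packaged fixture, frozen when the transcription was finalised
TABLE2_MD5 <- "7f8f10db6b885c5794dc7174efeec815"

#' Load the packaged 33-patient allelic expression table
#'
#' Loads the transcription of the published allelic-expression table for 33
#' joint-tissue patients (35 tissue rows: patients 52 and 60 each contributed
#' two tissues) shipped with the package. Each row carries sex, age, tissue,
#' the genotype at the marker SNP rs2277831 and, for each of the eight
#' transcript SNPs, the genotype plus — where the patient is heterozygous —
#' the normalised allelic expression ratio printed to two decimals. Em-dash
#' cells (homozygotes) are encoded as missing, never as zero. Patient 42 is
#' the one non-osteoarthritis (neck-of-femur fracture) donor.
#'
#' @param check_integrity Verify the fixture's md5 checksum and structural
#'   invariants before returning (default `TRUE`).
#' @return A list with components:
#'   \describe{
#'     \item{samples}{data.frame, one row per tissue sample (35 rows):
#'       `patient_id`, `sex`, `age`, `tissue` (canonical code), `disease`
#'       (`"OA"`/`"NOF"`), and one genotype column per SNP
#'       (`<snp>_gen`, `NA` never occurs here — every genotype was typed).}
#'     \item{ratios}{long data.frame of heterozygous measurements:
#'       `patient_id`, `tissue`, `snp_id`, `gene`, `genotype`, `ratio`.}
#'   }
#' @examples
#' t2 <- load_table2()
#' nrow(t2$samples)                        # 35 tissue rows
#' length(unique(t2$samples$patient_id))   # 33 patients
#' @export
load_table2 <- function(check_integrity = TRUE) {
  path <- system.file("extdata", "table2_allelic_expression.tsv",
                      package = "aeiquant", mustWork = TRUE)
  if (check_integrity) {
    md5 <- unname(tools::md5sum(path))
    if (!identical(md5, TABLE2_MD5)) {
      stop("fixture integrity error: checksum mismatch for ", basename(path),
           call. = FALSE)
    }
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  df$age <- as.integer(df$age)
  panel <- snp_panel()
  transcript <- panel$snp_id[panel$snp_id != "rs2277831"]

  samples <- df[, c("patient_id", "sex", "age", "tissue")]
  samples$tissue <- unname(TISSUE_CODES[samples$tissue])
  samples$disease <- ifelse(samples$patient_id == "42", "NOF", "OA")
  for (s in c(transcript, "rs2277831")) {
    samples[[paste0(s, "_gen")]] <- df[[paste0(s, "_gen")]]
  }

  ratios <- do.call(rbind, lapply(transcript, function(s) {
    aer <- df[[paste0(s, "_aer")]]
    keep <- aer != "-"
    data.frame(patient_id = df$patient_id[keep],
               tissue = samples$tissue[keep],
               snp_id = s,
               gene = panel$gene[panel$snp_id == s],
               genotype = df[[paste0(s, "_gen")]][keep],
               ratio = as.numeric(aer[keep]),
               stringsAsFactors = FALSE)
  }))
  rownames(ratios) <- NULL

  if (check_integrity) {
    stopifnot(nrow(samples) == 35L,
              length(unique(samples$patient_id)) == 33L,
              all(is_het(ratios$genotype)),
              all(!is.na(samples$rs2277831_gen)))
    hom_with_ratio <- vapply(transcript, function(s) {
      any(!is_het(df[[paste0(s, "_gen")]]) & df[[paste0(s, "_aer")]] != "-")
    }, logical(1))
    if (any(hom_with_ratio)) {
      stop("fixture integrity error: ratio present for a homozygote",
           call. = FALSE)
    }
  }
  list(samples = samples, ratios = ratios)
}

#' Write an analysis report as TSV plus a JSON summary
#'
#' Serialises a result table deterministically: columns in their existing
#' order, ratios rendered to 2 decimal places (matching how normalised
#' allelic ratios are conventionally printed) and p-values to 4, plus a JSON
#' sidecar with row counts and, when present, the number of imbalanced calls.
#'
#' @param results A data.frame (e.g. from [aei_call_table()] or
#'   [stratify_by_marker()]).
#' @param path Output TSV path; the JSON summary is written to
#'   `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path) {
  stopifnot(is.data.frame(results))
  out <- results
  for (nm in names(out)) {
    if (nm %in% c("ratio", "value", "max_ratio", "log2_ratio")) {
      out[[nm]] <- sprintf("%.2f", out[[nm]])
    } else if (grepl("^p(_value)?$|p_value", nm)) {
      out[[nm]] <- sprintf("%.4f", out[[nm]])
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  summary <- list(n_rows = nrow(results))
  if ("imbalanced" %in% names(results)) {
    summary$n_imbalanced <- sum(results$imbalanced, na.rm = TRUE)
  }
  jsonlite::write_json(summary, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
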