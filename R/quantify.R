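#' Peak intensity in an assignment window
#'
#' Reads the intensity of a characteristic band as the maximum intensity
#' within `position +/- window_halfwidth` on a preprocessed spectrum.
#'
#' @param s A preprocessed [raman_spectrum()].
#' @param assignment One row of [peak_catalog()] (or any list with
#'   `position`, `window_halfwidth`, `analyte`).
#' @return The peak intensity (numeric scalar). Non-positive values are
#'   returned as-is; callers flag them for exclusion from ratio formation.
#' @export
peak_intensity <- function(s, assignment) {
  lo <- assignment$position - assignment$window_halfwidth
  hi <- assignment$position + assignment$window_halfwidth
  inw <- s$shifts >= lo & s$shifts <= hi
  if (!any(inw)) {
    stop("assignment error: window [", lo, ", ", hi, "] for ",
         assignment$analyte, " does not intersect the axis of ", s$spectrum_id)
  }
  max(s$intensities[inw])
}

#' Internal-standard log ratio
#'
#' The relative quantification value of an analyte band against the internal
#' standard: `log10(I_target / I_standard)`. Scaling both intensities by any
#' positive constant leaves the ratio unchanged, which is what makes the
#' quantity comparable across acquisitions.
#'
#' @param I_target Analyte peak intensity (> 0).
#' @param I_standard Internal-standard peak intensity (> 0).
#' @param base Logarithm base (default 10, so one unit is a decade).
#' @return The dimensionless quantitative ratio value.
#' @export
#' @examples
#' quant_ratio(10, 10)   # 0
#' quant_ratio(100, 10)  # 1
quant_ratio <- function(I_target, I_standard, base = 10) {
  if (!is.finite(I_target) || !is.finite(I_standard) ||
      I_target <= 0 || I_standard <= 0) {
    stop("undefined ratio: intensities must be positive and finite ",
         "(got I_target = ", I_target, ", I_standard = ", I_standard, ")")
  }
  log(I_target / I_standard, base = base)
}

#' Quantification table for a batch
#'
#' One internal-standard log ratio per (spectrum, analyte) pair for the seven
#' amino acids of the catalog. Spectra in which the analyte or internal
#' standard window yields a non-positive intensity are omitted from the table
#' and listed in the `flagged` attribute.
#'
#' @param batch List of preprocessed spectra.
#' @param catalog Peak assignment catalog ([peak_catalog()] by default).
#' @param base Logarithm base passed to [quant_ratio()].
#' @return Data frame with columns `spectrum_id`, `sample_id`, `analyte`,
#'   `I_target`, `I_standard`, `ratio`; attribute `flagged` records omitted
#'   (spectrum, analyte) pairs.
#' @export
quant_table <- function(batch, catalog = peak_catalog(), base = 10) {
  std <- catalog[catalog$is_standard, , drop = FALSE]
  if (nrow(std) != 1) stop("catalog must contain exactly one internal standard")
  targets <- catalog[!catalog$is_standard, , drop = FALSE]
  rows <- vector("list", length(batch))
  flagged <- list()
  for (i in seq_along(batch)) {
    s <- batch[[i]]
    I_std <- peak_intensity(s, std)
    I_tgt <- vapply(seq_len(nrow(targets)), function(j)
      peak_intensity(s, targets[j, ]), numeric(1))
    ok <- I_tgt > 0 & I_std > 0
    if (any(!ok)) {
      flagged[[length(flagged) + 1L]] <- data.frame(
        spectrum_id = s$spectrum_id, analyte = targets$analyte[!ok],
        stringsAsFactors = FALSE)
    }
    if (any(ok)) {
      rows[[i]] <- data.frame(
        spectrum_id = s$spectrum_id, sample_id = s$sample_id,
        analyte = targets$analyte[ok],
        I_target = I_tgt[ok], I_standard = I_std,
        ratio = log(I_tgt[ok] / I_std, base = base),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(spectrum_id = character(0), sample_id = character(0),
                      analyte = character(0), I_target = numeric(0),
                      I_standard = numeric(0), ratio = numeric(0))
  }
  rownames(out) <- NULL
  attr(out, "flagged") <- if (length(flagged)) do.call(rbind, flagged) else NULL
  out
}

#' Group comparison of quantification ratios
#'
#' Per analyte, a two-sided Mann-Whitney U test (normal approximation) of
#' the log ratios between the pregnancy and non-pregnancy groups, tiered as
#' `**` (p < 0.01, extremely significant), `*` (p < 0.05, significant) or
#' `ns`. The effect direction is the sign of the non-pregnancy minus
#' pregnancy median. A Welch t-test and per-sample aggregation (mean ratio
#' over a sample's replicates) are available behind flags, as is
#' Benjamini-Hochberg adjustment (off by default, matching the seven
#' unadjusted per-analyte tests of the analysis this reproduces).
#'
#' @param table Output of [quant_table()].
#' @param manifest Cohort manifest carrying `sample_id` and `label` (used
#'   when the table's spectra lack labels); may be `NULL` if `table` has a
#'   `label` column.
#' @param alpha_levels Two significance thresholds, `c(0.05, 0.01)`.
#' @param test `"wilcox"` (default) or `"welch"`.
#' @param per_sample Aggregate replicate spectra to one mean ratio per sample
#'   before testing (default `FALSE`: per-spectrum observations).
#' @param p_adjust Multiplicity adjustment across analytes, as in
#'   [stats::p.adjust()] (default `"none"`).
#' @return Data frame, one row per analyte: group medians, the rank-sum
#'   statistic, `p_value`, `direction` (+1 if elevated in non-pregnancy) and
#'   `tier`.
#' @export
compare_groups <- function(table, manifest = NULL,
                           alpha_levels = c(0.05, 0.01),
                           test = c("wilcox", "welch"),
                           per_sample = FALSE, p_adjust = "none") {
  test <- match.arg(test)
  stopifnot(length(alpha_levels) == 2, alpha_levels[1] > alpha_levels[2])
  if (is.null(table$label)) {
    if (is.null(manifest)) stop("a manifest is needed to label the ratios")
    lab <- unique(manifest[, c("sample_id", "label")])
    table$label <- lab$label[match(table$sample_id, lab$sample_id)]
  }
  table <- table[!is.na(table$label), , drop = FALSE]
  if (!all(outcome_levels() %in% table$label)) {
    stop("both outcome groups must be present for a comparison")
  }
  if (per_sample) {
    agg <- stats::aggregate(ratio ~ sample_id + analyte + label, table, mean)
    table <- agg
  }
  analytes <- unique(table$analyte)
  res <- lapply(analytes, function(a) {
    d <- table[table$analyte == a, ]
    xp <- d$ratio[d$label == "pregnancy"]
    xn <- d$ratio[d$label == "non_pregnancy"]
    if (length(xp) < 3 || length(xn) < 3) {
      stop("insufficient data: analyte ", a, " has ", length(xp),
           " pregnancy and ", length(xn), " non-pregnancy observations ",
           "(>= 3 each required)")
    }
    if (test == "wilcox") {
      ht <- stats::wilcox.test(xn, xp, exact = FALSE, correct = FALSE)
    } else {
      ht <- stats::t.test(xn, xp)
    }
    data.frame(analyte = a,
               median_pregnancy = stats::median(xp),
               median_non_pregnancy = stats::median(xn),
               statistic = unname(ht$statistic),
               p_value = ht$p.value,
               direction = sign(stats::median(xn) - stats::median(xp)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_value <- stats::p.adjust(out$p_value, method = p_adjust)
  out$tier <- ifelse(out$p_value < alpha_levels[2], "**",
                     ifelse(out$p_value < alpha_levels[1], "*", "ns"))
  rownames(out) <- NULL
  out
}
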