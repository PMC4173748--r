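#' Wilson score confidence interval for a binomial proportion
#'
#' Used for variant-allele-fraction uncertainty because it behaves well at
#' the small alternate-read counts typical of mosaic variants (the Wald
#' interval collapses to zero width at alt = 0).
#'
#' @param alt number of variant-supporting reads (0 <= alt <= total).
#' @param total total reads at the site (> 0).
#' @param conf confidence level (default 0.95).
#' @return numeric vector `c(lower, upper)` of fractions in \[0, 1\].
#' @export
wilson_ci <- function(alt, total, conf = 0.95) {
  if (total <= 0) stop("total must be positive")
  if (alt < 0 || alt > total) stop("alt must lie in [0, total]")
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- alt / total
  denom <- 1 + z^2 / total
  centre <- (p + z^2 / (2 * total)) / denom
  half <- (z / denom) * sqrt(p * (1 - p) / total + z^2 / (4 * total^2))
  c(lower = max(0, centre - half), upper = min(1, centre + half))
}

#' Quantify a variant allele fraction from read counts
#'
#' The variant allele fraction (VAF) is `alt / total`; it is reported both as
#' a fraction and as a whole-number percentage truncated toward zero (31 of
#' 206 reads is 15%), with a Wilson score confidence interval. A constitutive
#' heterozygous variant is expected near 50%; a markedly lower VAF indicates
#' mosaicism.
#'
#' @param alt variant-supporting read count.
#' @param total total read count (> 0).
#' @param conf confidence level for the interval (default 0.95).
#' @param sample_id,tissue,age optional sample metadata carried through to
#'   reports (tissue e.g. `"blood"`, `"saliva"`, `"buccal"`; age in years).
#' @return list of class `allele_quant`: `alt`, `total`, `vaf`, `percent`,
#'   `ci` (lower/upper fractions), `conf`, plus any metadata.
#' @examples
#' quantify_vaf(31, 206)$percent   # 15
#' @export
quantify_vaf <- function(alt, total, conf = 0.95, sample_id = NA_character_,
                         tissue = NA_character_, age = NA_real_) {
  if (total <= 0) stop("total read count must be positive")
  if (alt < 0 || alt > total) stop("alt must lie in [0, total]")
  structure(list(alt = alt, total = total, vaf = alt / total,
                 percent = percent_truncated(alt, total, 0L),
                 ci = wilson_ci(alt, total, conf), conf = conf,
                 sample_id = sample_id, tissue = tissue, age = age),
            class = "allele_quant")
}

#' Quantification from an instrument-reported percentage
#'
#' Pyrosequencing allele-quantification output arrives as a percentage
#' rather than as read counts; this helper converts it to an equivalent
#' count pair at a stated effective sample size so it can flow through the
#' same machinery.
#'
#' @param percent variant allele percentage in \[0, 100\].
#' @param n_equivalent effective number of observations the percentage
#'   represents (default 100).
#' @param ... passed to [quantify_vaf()].
#' @return an `allele_quant`.
#' @export
quantify_from_percent <- function(percent, n_equivalent = 100L, ...) {
  if (percent < 0 || percent > 100) stop("percent must lie in [0, 100]")
  quantify_vaf(round(percent / 100 * n_equivalent), n_equivalent, ...)
}

#' @export
print.allele_quant <- function(x, ...) {
  cat(sprintf("VAF %d/%d = %.3f (%d%%), %g%% CI [%.3f, %.3f]\n",
              x$alt, x$total, x$vaf, x$percent, 100 * x$conf,
              x$ci[["lower"]], x$ci[["upper"]]))
  invisible(x)
}

#' Compare two mosaic levels
#'
#' Fold ratio of the two variant allele fractions plus a flag for whether
#' their confidence intervals intersect (non-overlap is evidence that the
#' mosaic level genuinely differs between the samples, e.g. across tissues
#' or sampling times).
#'
#' @param a,b `allele_quant` objects (numerator and denominator of the
#'   ratio).
#' @return list with `ratio` (`NA` when `b` has VAF 0), `ci_overlap`
#'   (logical), and the two inputs.
#' @export
compare_levels <- function(a, b) {
  stopifnot(inherits(a, "allele_quant"), inherits(b, "allele_quant"))
  ratio <- if (b$vaf > 0) a$vaf / b$vaf else NA_real_
  overlap <- a$ci[["lower"]] <= b$ci[["upper"]] &&
    b$ci[["lower"]] <= a$ci[["upper"]]
  list(ratio = ratio, ci_overlap = overlap, a = a, b = b)
}

#' Classify a quantification against the heterozygous expectation
#'
#' A constitutive heterozygous variant has true VAF 0.5. The call is
#' `consistent-with-mosaic` when the whole confidence interval lies below
#' `0.5 - margin`, `consistent-with-heterozygous` when the interval covers
#' the entire band `[0.5 - margin, 0.5 + margin]`, and `indeterminate`
#' otherwise.
#'
#' @param q an `allele_quant`.
#' @param margin half-width of the heterozygous band (default 0.05).
#' @return one of `"consistent-with-mosaic"`,
#'   `"consistent-with-heterozygous"`, `"indeterminate"`.
#' @export
flag_mosaic <- function(q, margin = 0.05) {
  stopifnot(inherits(q, "allele_quant"))
  lo <- 0.5 - margin
  hi <- 0.5 + margin
  if (q$ci[["upper"]] < lo) return("consistent-with-mosaic")
  if (q$ci[["lower"]] <= lo && q$ci[["upper"]] >= hi)
    return("consistent-with-heterozygous")
  "indeterminate"
}

#' Read a table of read counts for mosaic quantification
#'
#' CSV with columns `sample_id, tissue, age, alt, total` (age may be empty).
#'
#' @param path CSV file path.
#' @return data frame with those columns.
#' @export
read_mosaic_counts <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  need <- c("sample_id", "tissue", "alt", "total")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("counts file lacks column(s): ", paste(missing_cols, collapse = ", "))
  if (!"age" %in% names(df)) df$age <- NA_real_
  if (any(df$total <= 0)) stop("total read counts must be positive")
  if (any(df$alt < 0 | df$alt > df$total)) stop("alt must lie in [0, total]")
  df
}

#' Quantify every sample in a counts table
#'
#' @param counts data frame as returned by [read_mosaic_counts()].
#' @param conf confidence level.
#' @param margin heterozygous band half-width for [flag_mosaic()].
#' @return data frame with one row per sample: VAF, truncated percent,
#'   Wilson bounds and the mosaic call.
#' @export
quantify_table <- function(counts, conf = 0.95, margin = 0.05) {
  rows <- lapply(seq_len(nrow(counts)), function(i) {
    q <- quantify_vaf(counts$alt[i], counts$total[i], conf,
                      sample_id = counts$sample_id[i],
                      tissue = counts$tissue[i], age = counts$age[i])
    data.frame(sample_id = counts$sample_id[i], tissue = counts$tissue[i],
               age = counts$age[i], alt = q$alt, total = q$total,
               vaf = q$vaf, percent = q$percent,
               ci_lower = q$ci[["lower"]], ci_upper = q$ci[["upper"]],
               call = flag_mosaic(q, margin), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
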