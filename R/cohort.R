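#' @keywords internal
"_PACKAGE"

## Closed set of genotype groups used throughout the package. "negative"
## marks cases in which no causative mutation was identified.
GENE_GROUPS <- c("NIPBL", "SMC1A", "SMC3", "HDAC8", "RAD21", "ANKRD11",
                 "CNV", "negative")

SEX_LEVELS <- c("male", "female", "unknown")

#' Assemble a phenotype cohort table
#'
#' Builds and validates the per-patient table used by every downstream stage.
#' One row per individual; growth measurements are z-scores (SD units against
#' an age/sex growth reference, negative = growth failure), `severity_score`
#' is the published composite clinical severity score (consumed as given, not
#' computed here), and `gestalt_1` .. `gestalt_3` hold per-rater facial
#' gestalt scores on the 1-10 scale (10 = highly typical of CdLS). Missing
#' values are kept as `NA` and never imputed.
#'
#' @param patient_id character vector of unique identifiers.
#' @param sex one of `"male"`, `"female"`, `"unknown"` per patient.
#' @param birth_weight_sd,weight_sd,height_sd,ofc_sd growth z-scores (birth
#'   weight, weight and height at last assessment, occipital frontal
#'   circumference); `NA` allowed.
#' @param severity_score non-negative clinical severity score or `NA`.
#' @param gene_group genotype group; one of
#'   `r paste0('\x60', GENE_GROUPS, '\x60', collapse = ", ")`.
#' @param mosaic logical: is the causative mutation mosaic?
#' @param gestalt matrix or data frame of per-rater gestalt scores (columns =
#'   raters, entries in \[1, 10\] or `NA`), or `NULL` for no ratings.
#' @return a `data.frame` of class `cdls_cohort`.
#' @seealso [read_cohort()], [summarize_yield()]
#' @export
cdls_cohort <- function(patient_id, sex = "unknown", birth_weight_sd = NA_real_,
                        weight_sd = NA_real_, height_sd = NA_real_,
                        ofc_sd = NA_real_, severity_score = NA_real_,
                        gene_group = "negative", mosaic = FALSE,
                        gestalt = NULL) {
  n <- length(patient_id)
  df <- data.frame(
    patient_id = as.character(patient_id),
    sex = rep_len(as.character(sex), n),
    birth_weight_sd = rep_len(as.numeric(birth_weight_sd), n),
    weight_sd = rep_len(as.numeric(weight_sd), n),
    height_sd = rep_len(as.numeric(height_sd), n),
    ofc_sd = rep_len(as.numeric(ofc_sd), n),
    severity_score = rep_len(as.numeric(severity_score), n),
    gene_group = rep_len(as.character(gene_group), n),
    mosaic = rep_len(as.logical(mosaic), n),
    stringsAsFactors = FALSE
  )
  if (!is.null(gestalt)) {
    gestalt <- as.matrix(gestalt)
    stopifnot(nrow(gestalt) == n)
    for (j in seq_len(ncol(gestalt)))
      df[[paste0("gestalt_", j)]] <- as.numeric(gestalt[, j])
  }
  validate_cohort(df)
}

gestalt_columns <- function(df) grep("^gestalt_[0-9]+$", names(df), value = TRUE)

validate_cohort <- function(df) {
  required <- c("patient_id", "sex", "birth_weight_sd", "weight_sd",
                "height_sd", "ofc_sd", "severity_score", "gene_group",
                "mosaic")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("cohort table lacks column(s): ", paste(missing_cols, collapse = ", "))
  bad_sex <- !is.na(df$sex) & !(df$sex %in% SEX_LEVELS)
  if (any(bad_sex))
    stop("invalid sex value(s) at row(s) ", paste(which(bad_sex), collapse = ", "))
  bad_gene <- is.na(df$gene_group) | !(df$gene_group %in% GENE_GROUPS)
  if (any(bad_gene))
    stop("gene_group outside {", paste(GENE_GROUPS, collapse = ", "),
         "} at row(s) ", paste(which(bad_gene), collapse = ", "))
  for (col in c("birth_weight_sd", "weight_sd", "height_sd", "ofc_sd")) {
    bad <- !is.na(df[[col]]) & !is.finite(df[[col]])
    if (any(bad))
      stop("non-finite ", col, " at row(s) ", paste(which(bad), collapse = ", "))
  }
  bad_sev <- !is.na(df$severity_score) &
    (!is.finite(df$severity_score) | df$severity_score < 0)
  if (any(bad_sev))
    stop("severity_score must be non-negative; offending row(s) ",
         paste(which(bad_sev), collapse = ", "))
  for (col in gestalt_columns(df)) {
    bad <- !is.na(df[[col]]) & (df[[col]] < 1 | df[[col]] > 10)
    if (any(bad))
      stop("gestalt rating outside [1, 10] in column ", col, " at row(s) ",
           paste(which(bad), collapse = ", "))
  }
  class(df) <- unique(c("cdls_cohort", class(df)))
  df
}

#' Read a cohort table from delimited text
#'
#' Reads a comma- or tab-separated file (delimiter autodetected from the
#' header line) with one row per patient and the columns documented in
#' [cdls_cohort()]. Empty cells and `"NA"` encode missing values, which are
#' preserved as `NA`. The table is validated; a gestalt rating outside
#' \[1, 10\] or an unknown genotype group is an error naming the offending
#' rows.
#'
#' @param path path to the delimited text file.
#' @return a validated `cdls_cohort` data frame.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (lengths(regmatches(header, gregexpr("\t", header))) >
             lengths(regmatches(header, gregexpr(",", header)))) "\t" else ","
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep,
                      na.strings = c("", "NA"), stringsAsFactors = FALSE,
                      fill = FALSE, check.names = TRUE, comment.char = ""),
    error = function(e) stop("malformed cohort file '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if ("mosaic" %in% names(df)) df$mosaic <- as.logical(df$mosaic)
  numeric_cols <- intersect(c("birth_weight_sd", "weight_sd", "height_sd",
                              "ofc_sd", "severity_score",
                              gestalt_columns(df)), names(df))
  for (col in numeric_cols) df[[col]] <- as.numeric(df[[col]])
  validate_cohort(df)
}

#' Write a cohort table to tab-separated text
#'
#' Numeric fields are serialised with 17 significant digits so that
#' `read_cohort(write_cohort(x))` reproduces every present value bit-exactly.
#'
#' @param cohort a `cdls_cohort` data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  out <- as.data.frame(cohort)
  for (col in names(out))
    if (is.numeric(out[[col]]) && !is.integer(out[[col]]))
      out[[col]] <- ifelse(is.na(out[[col]]), NA,
                           formatC(out[[col]], digits = 17, format = "g"))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Truncated percentage
#'
#' Reports `100 * numerator / denominator` truncated toward zero at a fixed
#' number of decimal places. This is the reporting convention used throughout
#' the package for mutation yields, branch purities and variant-allele
#' percentages (44/56 is reported as 78, not 79; 6/163 as 3.6, not 3.7).
#' Computed in exact integer arithmetic, so no floating-point rounding can
#' push a value across the truncation boundary.
#'
#' @param numerator non-negative count (vectorised).
#' @param denominator positive count.
#' @param decimals number of decimal places retained (default 1).
#' @return truncated percentage(s).
#' @examples
#' percent_truncated(46, 163)       # 28.2
#' percent_truncated(44, 56, 0)     # 78
#' @export
percent_truncated <- function(numerator, denominator, decimals = 1L) {
  if (any(denominator <= 0)) stop("denominator must be positive")
  if (any(numerator < 0)) stop("numerator must be non-negative")
  f <- 10^decimals
  ## %/% on integer-valued doubles is exact floor division here: numerators
  ## and denominators are counts well below 2^53.
  (100 * numerator * f) %/% denominator / f
}

#' Severity category from the clinical severity score
#'
#' Scores below 15 are mild, 15 to 22 (both inclusive) moderate, and above
#' 22 severe.
#'
#' @param score non-negative severity score (vectorised; `NA` passes through).
#' @return factor with levels `mild`, `moderate`, `severe`.
#' @export
categorize_severity <- function(score) {
  if (any(!is.na(score) & score < 0)) stop("severity score must be non-negative")
  labs <- ifelse(score < 15, "mild", ifelse(score <= 22, "moderate", "severe"))
  factor(labs, levels = c("mild", "moderate", "severe"))
}

#' Mutation-yield summary for a cohort
#'
#' Counts mutation-positive cases per genotype group and reports each as a
#' percentage of the full cohort under the truncation convention of
#' [percent_truncated()]. The total is the sum of positives over all
#' non-negative groups.
#'
#' @param cohort a `cdls_cohort` data frame (or any data frame with a
#'   `gene_group` column).
#' @param decimals decimal places for the reported percentages (default 1).
#' @return list of class `yield_summary` with components `n` (cohort size),
#'   `counts` (named integer vector over positive groups), `percent` (named
#'   truncated percentages), `total` (total mutation count) and
#'   `total_percent`.
#' @export
summarize_yield <- function(cohort, decimals = 1L) {
  if (nrow(cohort) == 0) stop("empty cohort")
  groups <- setdiff(GENE_GROUPS, "negative")
  counts <- vapply(groups, function(g) sum(cohort$gene_group == g), integer(1))
  n <- nrow(cohort)
  structure(list(
    n = n,
    counts = counts,
    percent = percent_truncated(counts, n, decimals),
    total = sum(counts),
    total_percent = percent_truncated(sum(counts), n, decimals)
  ), class = "yield_summary")
}

#' @export
print.yield_summary <- function(x, ...) {
  cat("Mutation yield in cohort of", x$n, "individuals\n")
  for (g in names(x$counts))
    if (x$counts[[g]] > 0)
      cat(sprintf("  %-8s %3d (%s%%)\n", g, x$counts[[g]],
                  format(x$percent[[g]])))
  cat(sprintf("  total    %3d (%s%%)\n", x$total, format(x$total_percent)))
  invisible(x)
}

#' @export
print.cdls_cohort <- function(x, ...) {
  cat("CdLS cohort:", nrow(x), "individuals,",
      length(gestalt_columns(x)), "gestalt rater column(s)\n")
  NextMethod()
}
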