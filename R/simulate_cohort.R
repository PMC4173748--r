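## Default per-group phenotype distributions for the synthetic cohort.
## Group sizes follow the screened cohort composition (46 NIPBL, 5 SMC1A,
## 5 SMC3, 6 HDAC8, 1 RAD21, 3 ANKRD11, 2 CNV, 95 negative = 163). Means
## encode the qualitative genotype-phenotype structure: NIPBL cases show
## progressive growth failure (moderate prenatal deficit, marked postnatal
## deficit), high severity and the most typical facial gestalt; SMC1A shows
## postnatal weight normalisation; HDAC8 milder growth failure with marked
## microcephaly; ANKRD11 a normal head circumference; mutation-negative
## cases are intermediate and heterogeneous. SDs of ~1 z-unit are typical
## of clinical growth data. Mosaic rates reflect the observed 3/46 NIPBL,
## 1/5 SMC1A and 1/5 SMC3 mosaic fractions.
default_cohort_groups <- function() {
  g <- function(n, bw, wt, ht, ofc, sev, ges, mosaic = 0)
    list(n = n, birth_weight = bw, weight = wt, height = ht, ofc = ofc,
         severity = sev, gestalt = ges, mosaic_rate = mosaic)
  list(
    NIPBL    = g(46, c(-2.3, 1.0), c(-3.4, 1.2), c(-3.0, 1.2), c(-3.0, 1.0),
                 c(24, 5), c(8.0, 1.2), 3 / 46),
    SMC1A    = g(5, c(-1.3, 0.9), c(-0.9, 1.0), c(-1.6, 1.0), c(-2.6, 1.0),
                 c(18, 4), c(6.0, 1.5), 1 / 5),
    SMC3     = g(5, c(-1.6, 0.9), c(-1.8, 1.0), c(-1.9, 1.0), c(-3.2, 1.0),
                 c(18, 4), c(6.0, 1.5), 1 / 5),
    HDAC8    = g(6, c(-1.0, 0.9), c(-1.6, 1.0), c(-1.8, 1.0), c(-2.9, 1.0),
                 c(17, 4), c(6.0, 1.5)),
    RAD21    = g(1, c(-1.2, 0.9), c(-1.5, 1.0), c(-1.5, 1.0), c(-2.0, 1.0),
                 c(15, 4), c(5.5, 1.5)),
    ANKRD11  = g(3, c(-1.0, 0.9), c(-1.2, 1.0), c(-1.4, 1.0), c(-0.3, 0.8),
                 c(14, 4), c(6.0, 1.5)),
    CNV      = g(2, c(-1.4, 1.0), c(-1.8, 1.2), c(-1.8, 1.2), c(-2.2, 1.2),
                 c(16, 5), c(5.5, 1.8)),
    negative = g(95, c(-1.5, 1.2), c(-2.0, 1.5), c(-2.0, 1.5), c(-2.3, 1.3),
                 c(16, 5), c(5.0, 1.8))
  )
}

#' Configuration for the synthetic cohort generator
#'
#' @param groups named list of per-group settings; each entry holds `n` and
#'   `c(mean, sd)` pairs for `birth_weight`, `weight`, `height`, `ofc`
#'   (z-scores), `severity` (clinical score) and `gestalt` (latent facial
#'   typicality on the 1-10 scale), plus a `mosaic_rate`. Defaults emulate
#'   an atypically-enriched CdLS referral cohort of 163; see
#'   `cdlsmosaic:::default_cohort_groups`.
#' @param n_raters number of independent gestalt raters (default 3).
#' @param rater_sd SD of the Gaussian rater noise added to the latent
#'   gestalt score before rounding to the integer 1-10 scale (default 1).
#' @param missingness named per-field probabilities that a value is missing
#'   (fields: the growth z-scores, `severity_score`, `gestalt` per rating).
#' @param seed random seed; every run with the same config is identical.
#' @return list of class `cohort_sim_config`.
#' @export
cohort_sim_config <- function(groups = default_cohort_groups(),
                              n_raters = 3L, rater_sd = 1,
                              missingness = c(birth_weight_sd = 0.20,
                                              weight_sd = 0.05,
                                              height_sd = 0.10,
                                              ofc_sd = 0.10,
                                              severity_score = 0.10,
                                              gestalt = 0.15),
                              seed = 1L) {
  stopifnot(all(vapply(groups, function(g) g$n >= 0, logical(1))))
  if (rater_sd < 0) stop("rater_sd must be non-negative")
  if (any(missingness < 0 | missingness > 1))
    stop("missingness probabilities must lie in [0, 1]")
  structure(list(groups = groups, n_raters = as.integer(n_raters),
                 rater_sd = rater_sd, missingness = missingness,
                 seed = as.integer(seed)),
            class = "cohort_sim_config")
}

#' Generate a synthetic phenotype cohort
#'
#' Draws per-group growth z-scores, severity scores and a latent gestalt
#' score from the configured Gaussians; each rater's score is the latent
#' score plus independent Gaussian noise, rounded to the integer scale and
#' clipped to \[1, 10\]. Missingness is applied independently per field at
#' the configured rates. Growth and severity values are rounded to one
#' decimal, matching the precision of clinical records; severity is clipped
#' at zero.
#'
#' @param config a [cohort_sim_config()].
#' @return a `cdls_cohort` data frame.
#' @export
generate_cohort <- function(config = cohort_sim_config()) {
  stopifnot(inherits(config, "cohort_sim_config"))
  set.seed(config$seed)
  rows <- list()
  id <- 0L
  miss <- function(x, p) ifelse(stats::runif(length(x)) < p, NA_real_, x)
  for (gname in names(config$groups)) {
    g <- config$groups[[gname]]
    if (g$n == 0) next
    draw <- function(par, n = g$n) round(stats::rnorm(n, par[1], par[2]), 1)
    latent <- stats::rnorm(g$n, g$gestalt[1], g$gestalt[2])
    ratings <- sapply(seq_len(config$n_raters), function(r)
      pmin(10, pmax(1, round(latent + stats::rnorm(g$n, 0, config$rater_sd)))))
    ratings <- matrix(ratings, nrow = g$n)
    for (r in seq_len(config$n_raters))
      ratings[, r] <- miss(ratings[, r], config$missingness[["gestalt"]])
    m <- config$missingness
    rows[[gname]] <- data.frame(
      patient_id = sprintf("P%04d", id + seq_len(g$n)),
      sex = sample(c("male", "female"), g$n, replace = TRUE),
      birth_weight_sd = miss(draw(g$birth_weight), m[["birth_weight_sd"]]),
      weight_sd = miss(draw(g$weight), m[["weight_sd"]]),
      height_sd = miss(draw(g$height), m[["height_sd"]]),
      ofc_sd = miss(draw(g$ofc), m[["ofc_sd"]]),
      severity_score = miss(pmax(0, draw(g$severity)), m[["severity_score"]]),
      gene_group = gname,
      mosaic = stats::runif(g$n) < (g$mosaic_rate %||% 0),
      stringsAsFactors = FALSE
    )
    for (r in seq_len(config$n_raters))
      rows[[gname]][[paste0("gestalt_", r)]] <- ratings[, r]
    id <- id + g$n
  }
  validate_cohort(do.call(rbind, c(rows, list(make.row.names = FALSE))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
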