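## Printed inputs for the worked examples: the published screened-cohort
## composition (gene-positive counts among 163 screened individuals), the
## growth-tree branch memberships, the NIPBL-like filter result on the
## mutation-negative group, and the exome read counts of the mosaic
## nonsense mutation.
REPORTED <- list(
  cohort_n = 163L,
  gene_counts = c(NIPBL = 46L, SMC1A = 5L, SMC3 = 5L, HDAC8 = 6L,
                  RAD21 = 1L),
  nipbl_branch = c(target = 44L, total = 56L),
  strict_branch = c(target = 32L, total = 34L),
  negative_filter = c(flagged = 19L, total = 103L),
  exome_reads = c(alt = 31L, total = 206L),
  saliva_percents = c(53, 10)
)

## Minimal cohort carrying a stated genotype composition; used to recompute
## yield percentages from the printed counts.
cohort_from_counts <- function(gene_counts, cohort_n) {
  n_neg <- cohort_n - sum(gene_counts)
  stopifnot(n_neg >= 0)
  genes <- c(rep(names(gene_counts), gene_counts), rep("negative", n_neg))
  cdls_cohort(patient_id = sprintf("R%03d", seq_along(genes)),
              gene_group = genes)
}

## Mutation-negative cohort in which exactly `flagged` of `total` records
## satisfy the NIPBL-like growth rule.
negative_cohort_with_flagged <- function(flagged, total) {
  cdls_cohort(patient_id = sprintf("N%03d", seq_len(total)),
              weight_sd = c(rep(-3.0, flagged), rep(-1.0, total - flagged)),
              birth_weight_sd = rep(-2.0, total),
              gene_group = "negative")
}

#' Recompute the published worked examples
#'
#' Re-derives each printed cohort-level number from its stated inputs using
#' the package's own machinery: mutation yields via [summarize_yield()] on a
#' cohort with the published genotype composition, branch purities via
#' [branch_purity()], the NIPBL-like fraction via
#' [apply_nipbl_like_filter()] on a mutation-negative cohort constructed to
#' contain the stated number of rule-satisfying records, and the mosaic
#' variant allele fraction via [quantify_vaf()] on the exome read counts.
#'
#' @return data frame with columns `name`, `value`, `expected`, `pass`.
#' @export
worked_examples <- function() {
  yd <- summarize_yield(cohort_from_counts(REPORTED$gene_counts,
                                           REPORTED$cohort_n))
  filt <- apply_nipbl_like_filter(
    negative_cohort_with_flagged(REPORTED$negative_filter[["flagged"]],
                                 REPORTED$negative_filter[["total"]]))
  vaf <- quantify_vaf(REPORTED$exome_reads[["alt"]],
                      REPORTED$exome_reads[["total"]])
  sal <- REPORTED$saliva_percents
  ratio <- compare_levels(quantify_from_percent(sal[1]),
                          quantify_from_percent(sal[2]))$ratio
  tab <- data.frame(
    name = c("NIPBL yield (%)", "HDAC8 yield (%)", "total mutations",
             "NIPBL branch purity (%)", "strict branch purity (%)",
             "exome mosaic VAF (%)", "NIPBL-like fraction (%)",
             "saliva mosaic fold ratio"),
    value = c(yd$percent[["NIPBL"]], yd$percent[["HDAC8"]], yd$total,
              branch_purity(REPORTED$nipbl_branch[["target"]],
                            REPORTED$nipbl_branch[["total"]]),
              branch_purity(REPORTED$strict_branch[["target"]],
                            REPORTED$strict_branch[["total"]]),
              vaf$percent, filt$percent, ratio),
    expected = c(28.2, 3.6, 63, 78, 94, 15, 18, 5.3),
    stringsAsFactors = FALSE
  )
  tab$pass <- abs(tab$value - tab$expected) < 1e-9
  tab
}

#' Configuration for an end-to-end pipeline run
#'
#' Stage parameters default to the values the analysis is defined with:
#' tree `minsplit` 3 and `maxdepth` 3, NIPBL-like thresholds -2.4 / -4.4 SD,
#' gestalt concordance threshold 0.60, severity cutoffs 15 / 22. One global
#' seed is expanded into fixed per-stage substreams, so disabling one stage
#' leaves the others' draws unchanged.
#'
#' @param cohort path to a cohort file, a `cdls_cohort`, or `NULL` to
#'   synthesise one from `cohort_config`.
#' @param cohort_config a [cohort_sim_config()] used when `cohort` is
#'   `NULL` (its seed is overridden by the pipeline substream).
#' @param stages named logical vector enabling stages `gestalt`, `yield`,
#'   `tree`, `filter`, `faces`, `mosaic`.
#' @param tree_features feature columns for the tree fit.
#' @param tree_cfg a [tree_config()].
#' @param filter a [nipbl_like_filter()].
#' @param gestalt_threshold concordance gate (default 0.60).
#' @param face_config a [face_sim_config()] for the synthetic face stage.
#' @param faces_per_group named sizes for the face stage.
#' @param mosaic_counts path to a counts CSV, a data frame, or `NULL` for
#'   the bundled demonstration counts.
#' @param margin heterozygous band half-width for mosaic calls.
#' @param outdir output directory (created if needed).
#' @param seed global seed.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = NULL,
                            cohort_config = cohort_sim_config(),
                            stages = c(gestalt = TRUE, yield = TRUE,
                                       tree = TRUE, filter = TRUE,
                                       faces = TRUE, mosaic = TRUE),
                            tree_features = c("weight_sd", "birth_weight_sd",
                                              "ofc_sd", "severity_score",
                                              "gestalt"),
                            tree_cfg = tree_config(),
                            filter = nipbl_like_filter(),
                            gestalt_threshold = 0.60,
                            face_config = face_sim_config(),
                            faces_per_group = c(NIPBL = 6, negative = 6),
                            mosaic_counts = NULL,
                            margin = 0.05,
                            outdir = tempfile("cdls_report_"),
                            seed = 1L) {
  defaults <- c(gestalt = TRUE, yield = TRUE, tree = TRUE, filter = TRUE,
                faces = TRUE, mosaic = TRUE)
  defaults[names(stages)] <- stages
  structure(list(cohort = cohort, cohort_config = cohort_config,
                 stages = defaults, tree_features = tree_features,
                 tree_cfg = tree_cfg, filter = filter,
                 gestalt_threshold = gestalt_threshold,
                 face_config = face_config,
                 faces_per_group = faces_per_group,
                 mosaic_counts = mosaic_counts, margin = margin,
                 outdir = outdir, seed = as.integer(seed)),
            class = "pipeline_config")
}

demo_mosaic_counts <- function() {
  data.frame(
    sample_id = c("exome_blood", "saliva_14.3y", "saliva_18.3y"),
    tissue = c("blood", "saliva", "saliva"),
    age = c(NA, 14.3, 18.3),
    alt = c(31L, 53L, 10L),
    total = c(206L, 100L, 100L),
    stringsAsFactors = FALSE
  )
}

#' Run the analysis pipeline end-to-end
#'
#' Loads or synthesises the cohort, then runs the enabled stages in
#' dependency order: gestalt aggregation and inter-rater concordance,
#' mutation-yield summary, classification-tree fit over the phenotype
#' features, the NIPBL-like filter on the mutation-negative subgroup,
#' synthetic average-face construction per group, and mosaic variant
#' quantification. Writes `report.json` (plus an average-face PNG per group
#' and the fitted tree as JSON) under `config$outdir`. A failing stage is
#' recorded in the report's `errors` and does not stop later stages.
#' Identical config and seed give byte-identical reports.
#'
#' @param config a [pipeline_config()].
#' @return the report list, invisibly, with attribute `"ok"` (FALSE when a
#'   stage failed).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  ## fixed per-stage substreams derived from the global seed
  substream <- function(k) (config$seed * 131L + k) %% 2147483647L
  report <- list(package_version = as.character(utils::packageVersion("cdlsmosaic")),
                 seed = config$seed,
                 stages = names(which(config$stages)))
  errors <- list()
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      errors[[name]] <<- conditionMessage(e)
      NULL
    })
  }

  cohort <- if (is.null(config$cohort)) {
    cc <- config$cohort_config
    cc$seed <- substream(1L)
    generate_cohort(cc)
  } else if (is.character(config$cohort)) {
    read_cohort(config$cohort)
  } else {
    validate_cohort(config$cohort)
  }
  report$cohort <- list(n = nrow(cohort),
                        groups = as.list(table(cohort$gene_group)))

  if (config$stages[["gestalt"]]) {
    report$gestalt <- run_stage("gestalt", {
      panel <- gestalt_panel(cohort)
      conc <- rater_concordance(panel, config$gestalt_threshold)
      scores <- suppressWarnings(aggregate_ratings(panel))
      cohort$gestalt <- scores
      list(concordance = conc$pairs, threshold = conc$threshold,
           pass = conc$pass,
           mean_score_by_group = lapply(
             split(scores, cohort$gene_group), function(v)
               if (all(is.na(v))) NA else round(mean(v, na.rm = TRUE), 3)))
    })
  }

  if (config$stages[["yield"]])
    report$yield <- run_stage("yield", unclass(summarize_yield(cohort)))

  if (config$stages[["tree"]]) {
    report$tree <- run_stage("tree", {
      feats <- intersect(config$tree_features, names(cohort))
      positive <- cohort[cohort$gene_group != "negative", , drop = FALSE]
      fit <- fit_tree(positive, feats, "gene_group", config$tree_cfg)
      tree_to_json(fit, file.path(config$outdir, "tree.json"))
      jsonlite::fromJSON(tree_to_json(fit), simplifyVector = FALSE)
    })
  }

  if (config$stages[["filter"]]) {
    report$nipbl_like <- run_stage("filter", {
      neg <- cohort[cohort$gene_group == "negative", , drop = FALSE]
      res <- apply_nipbl_like_filter(neg, config$filter)
      list(weight_threshold = config$filter$weight_threshold,
           birth_weight_threshold = config$filter$birth_weight_threshold,
           n_negative = res$n, n_flagged = res$n_flagged,
           percent = res$percent,
           flagged_ids = neg$patient_id[res$flagged])
    })
  }

  if (config$stages[["faces"]]) {
    report$faces <- run_stage("faces", {
      fc <- config$face_config
      fc$seed <- substream(2L)
      faces <- generate_faces(fc, config$faces_per_group)
      out <- list()
      for (grp in names(config$faces_per_group)) {
        sub <- Filter(function(f) f$group == grp, faces)
        avg <- build_average_face(sub, group = grp)
        write_average_face(avg, file.path(config$outdir,
                                          paste0("average_face_", grp, ".png")))
        out[[grp]] <- list(n = avg$n, gpa_iterations = avg$gpa$iterations,
                           gpa_converged = avg$gpa$converged,
                           mean_shape = round(avg$shape, 6))
      }
      out
    })
  }

  if (config$stages[["mosaic"]]) {
    report$mosaic <- run_stage("mosaic", {
      counts <- if (is.null(config$mosaic_counts)) demo_mosaic_counts()
      else if (is.character(config$mosaic_counts))
        read_mosaic_counts(config$mosaic_counts)
      else config$mosaic_counts
      tab <- quantify_table(counts, margin = config$margin)
      comparisons <- NULL
      if (nrow(tab) >= 2) {
        saliva <- which(tab$tissue == "saliva")
        if (length(saliva) >= 2) {
          q <- lapply(saliva[1:2], function(i)
            quantify_vaf(tab$alt[i], tab$total[i]))
          cl <- compare_levels(q[[1]], q[[2]])
          comparisons <- list(samples = tab$sample_id[saliva[1:2]],
                              ratio = cl$ratio, ci_overlap = cl$ci_overlap)
        }
      }
      list(table = tab, comparison = comparisons)
    })
  }

  report$worked_examples <- run_stage("worked_examples", worked_examples())
  if (length(errors)) report$errors <- errors
  jsonlite::write_json(report, file.path(config$outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null", force = TRUE)
  invisible(structure(report, ok = !length(errors)))
}
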