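# End-to-end study replica: simulate an imaging cohort, delineate every
# lesion with each configured method, screen contours, extract features,
# build per-method prognostic models, stratify into risk tertiles and
# summarise cross-method concordance.

#' Configuration of an end-to-end study run
#'
#' @param n_patients Cohort size.
#' @param phantom_template [phantom_spec()] jittered per patient.
#' @param true_betas Named log-hazard coefficients of the data-generating
#'   process (see [cohort_spec()]).
#' @param methods Segmentation methods to evaluate (subset of
#'   [PETAS_METHODS]).
#' @param qc_threshold Minimum fraction of acceptable contours a method
#'   needs to be retained (default 0.90).
#' @param covariates Candidate covariates for the prognostic models.
#' @param p_remove Backward-elimination removal threshold.
#' @param dcfg,tcfg Discretisation and texture configs.
#' @param baseline_hazard_scale,censoring_rate_target Survival process
#'   parameters (see [cohort_spec()]).
#' @param box_margin Bounding-box dilation around the truth mask (voxels).
#' @param out_dir Optional output directory for report files.
#' @param seed Master seed; all stage seeds derive from it via
#'   [stage_seed()].
#' @return Object of class `run_config`.
#' @export
run_config <- function(n_patients = 60L,
                       phantom_template = phantom_spec(),
                       true_betas = c(age = 0.02, treatment = -1.0,
                                      stage = 0.14, skewness = 0.7,
                                      kurtosis = 0.3, glnu = 0.02),
                       methods = PETAS_METHODS,
                       qc_threshold = 0.90,
                       covariates = c("age", "treatment", "stage",
                                      "skewness", "kurtosis", "glnu"),
                       p_remove = 0.05,
                       dcfg = discretisation_config(),
                       tcfg = texture_config(),
                       baseline_hazard_scale = log(2) / 17,
                       censoring_rate_target = 0.31,
                       box_margin = 8L,
                       out_dir = NULL,
                       seed = 1L) {
  stopifnot(all(methods %in% PETAS_METHODS),
            qc_threshold >= 0, qc_threshold <= 1)
  structure(as.list(environment()), class = "run_config")
}

#' Run the end-to-end segmentation-dependence study
#'
#' Pipeline: generate an imaging cohort; delineate every lesion with each
#' configured method inside a truth-derived bounding box; screen contours
#' with [flag_failed_contour()]; exclude methods whose acceptable fraction
#' falls below the QC threshold and patients without an acceptable contour
#' under every retained method; extract the ten features per (patient,
#' method); build per-method Cox models by backward elimination; compute
#' prognostic scores and risk tertiles; summarise pairwise change counts,
#' per-tier concordance and per-tier cross-model log-rank tests. Fully
#' reproducible from the master seed.
#'
#' @param cfg A [run_config()].
#' @return Object of class `study_report` (see fields in the source); when
#'   `cfg$out_dir` is set, also writes cohort/features/model/strat/
#'   concordance files there.
#' @export
run_study <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  cspec <- cohort_spec(n_patients = cfg$n_patients,
                       true_betas = cfg$true_betas,
                       baseline_hazard_scale = cfg$baseline_hazard_scale,
                       censoring_rate_target = cfg$censoring_rate_target,
                       seed = stage_seed(cfg$seed, 1L))
  cohort <- generate_cohort(cspec, phantom_template = cfg$phantom_template,
                            dcfg = cfg$dcfg, tcfg = cfg$tcfg)
  n <- nrow(cohort$clinical)
  message(sprintf("[cohort] seed %d: generated %d patients (%d events)",
                  cspec$seed, n, sum(cohort$clinical$event)))

  # segment every lesion with every method, screen each contour
  methods <- cfg$methods
  acceptable <- matrix(FALSE, n, length(methods),
                       dimnames = list(cohort$clinical$patient_id, methods))
  seg <- vector("list", n)
  for (p in seq_len(n)) {
    ph <- cohort$phantoms[[p]]
    box <- truth_bounding_box(ph$truth$mask, cfg$box_margin)
    seg[[p]] <- list(box = box, masks = list())
    for (m in methods) {
      res <- segment_mtv(ph$volume, box, m)
      ok <- !flag_failed_contour(res, box, ph$truth)
      acceptable[p, m] <- ok
      seg[[p]]$masks[[m]] <- res
    }
  }
  qc <- colMeans(acceptable)
  retained <- methods[qc >= cfg$qc_threshold]
  message(sprintf("[qc] acceptable fractions: %s",
                  paste(sprintf("%s %.2f", methods, qc), collapse = ", ")))
  if (length(retained) == 0L)
    stop("every segmentation method failed the QC screen")
  message(sprintf("[qc] retained methods: %s",
                  paste(retained, collapse = ", ")))

  # common cohort: patients acceptable under all retained methods
  keep <- rowSums(acceptable[, retained, drop = FALSE]) == length(retained)
  clinical <- cohort$clinical[keep, , drop = FALSE]
  message(sprintf("[cohort] analysed %d = generated %d - excluded %d",
                  sum(keep), n, n - sum(keep)))

  # per-method feature extraction on the delineated masks
  feature_rows <- list()
  for (m in retained) {
    for (p in which(keep)) {
      ph <- cohort$phantoms[[p]]
      fv <- extract_features(ph$volume, seg[[p]]$masks[[m]]$mask,
                             cfg$dcfg, cfg$tcfg, method_name = m)
      feature_rows[[length(feature_rows) + 1L]] <-
        cbind(data.frame(patient_id = cohort$clinical$patient_id[p],
                         method = m, stringsAsFactors = FALSE),
              as.data.frame(unclass(fv)))
    }
  }
  features <- do.call(rbind, feature_rows)

  # drop patients with any non-finite texture covariate under any method
  tex <- intersect(cfg$covariates, c("skewness", "kurtosis", "glnu"))
  bad <- if (length(tex)) {
    unique(features$patient_id[
      rowSums(!is.finite(as.matrix(features[, tex, drop = FALSE]))) > 0])
  } else character(0)
  if (length(bad)) {
    message(sprintf("[features] dropping %d patient(s) with undefined features",
                    length(bad)))
    clinical <- clinical[!clinical$patient_id %in% bad, , drop = FALSE]
    features <- features[!features$patient_id %in% bad, , drop = FALSE]
  }
  if (nrow(clinical) < 10L)
    stop("fewer than 10 analysable patients; increase the cohort size")

  # per-method prognostic model, scores and tertile stratification
  models <- list(); equations <- list(); strats <- list(); km_groups <- list()
  for (m in retained) {
    fm <- features[features$method == m, , drop = FALSE]
    fm <- fm[match(clinical$patient_id, fm$patient_id), , drop = FALSE]
    dat <- data.frame(os_months = clinical$os_months,
                      event = clinical$event,
                      age = clinical$age_years,
                      treatment = clinical$treatment_code,
                      stage = clinical$stage_code,
                      skewness = fm$skewness, kurtosis = fm$kurtosis,
                      glnu = fm$glnu)
    model <- backward_conditional(dat, cfg$covariates, cfg$p_remove)
    eq <- prognostic_equation(model)
    scores <- prognostic_score(eq, clinical, fm)
    strat <- stratify_tertiles(scores, clinical$patient_id)
    models[[m]] <- model
    equations[[m]] <- eq
    strats[[m]] <- strat
    km_groups[[m]] <- lapply(split(seq_len(nrow(clinical)),
                                   strat$assignments$risk_group),
                             function(ix) {
                               if (length(ix) == 0L || sum(clinical$event[ix]) < 1L)
                                 return(NULL)
                               kaplan_meier(clinical$os_months[ix],
                                            clinical$event[ix])
                             })
  }

  concordance <- if (length(retained) >= 2L) change_counts(strats) else NULL
  conc_tiers <- if (length(retained) >= 2L) concordant_counts(strats) else NULL
  tier_lr <- if (length(retained) >= 2L)
    tryCatch(cross_model_tier_logrank(strats, clinical),
             error = function(e) NULL) else NULL

  report <- structure(list(
    cohort = cohort, qc = qc, retained = retained,
    n_generated = n, n_excluded = n - nrow(clinical),
    n_analysed = nrow(clinical),
    clinical = clinical, features = features,
    models = models, equations = equations, stratifications = strats,
    concordance = concordance, concordant_counts = conc_tiers,
    tier_logrank = tier_lr, km_risk_groups = km_groups,
    km_overall = kaplan_meier(clinical$os_months, clinical$event),
    config = cfg), class = "study_report")
  if (!is.null(cfg$out_dir)) write_report(report, cfg$out_dir)
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("Study report: %d/%d patients analysed, methods %s\n",
              x$n_analysed, x$n_generated,
              paste(x$retained, collapse = ", ")))
  cat(sprintf("Overall median OS %.1f months\n", x$km_overall$median))
  if (!is.null(x$concordance)) print(x$concordance)
  invisible(x)
}

#' Write a study report to disk
#'
#' Emits cohort.csv, features.csv, model_<METHOD>.csv,
#' equation_<METHOD>.json, strat_<METHOD>.csv, change_counts.csv,
#' concordant_counts.csv and tier_logrank.csv. Deterministic: the same
#' config and seed give byte-identical files.
#'
#' @param report A `study_report`.
#' @param dir Output directory (created if needed).
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$clinical, file.path(dir, "cohort.csv"),
                   row.names = FALSE)
  utils::write.csv(report$features, file.path(dir, "features.csv"),
                   row.names = FALSE)
  for (m in report$retained) {
    utils::write.csv(report$models[[m]]$covariates,
                     file.path(dir, paste0("model_", m, ".csv")),
                     row.names = FALSE)
    jsonlite::write_json(report$equations[[m]]$terms,
                         file.path(dir, paste0("equation_", m, ".json")),
                         dataframe = "rows", digits = NA)
    utils::write.csv(report$stratifications[[m]]$assignments,
                     file.path(dir, paste0("strat_", m, ".csv")),
                     row.names = FALSE)
  }
  if (!is.null(report$concordance)) {
    utils::write.csv(report$concordance$n_changed,
                     file.path(dir, "change_counts.csv"))
    utils::write.csv(data.frame(tier = names(report$concordant_counts),
                                n = as.integer(report$concordant_counts)),
                     file.path(dir, "concordant_counts.csv"),
                     row.names = FALSE)
  }
  if (!is.null(report$tier_logrank))
    utils::write.csv(report$tier_logrank,
                     file.path(dir, "tier_logrank.csv"), row.names = FALSE)
  invisible(dir)
}
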