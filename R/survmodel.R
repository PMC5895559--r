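# Per-segmentation-method prognostic modelling: Cox proportional hazards
# (via survival::coxph, Breslow ties) behind a fixed model-summary surface,
# backward elimination on likelihood-ratio removal tests, prognostic
# scores, risk-tertile stratification, Kaplan-Meier and log-rank.

cox_row <- function(name, estimate, se, p_value = NA_real_) {
  data.frame(name = name, estimate = estimate, se = se,
             p_value = p_value,
             hazard_ratio = exp(estimate),
             ci95_low = exp(estimate - 1.96 * se),
             ci95_high = exp(estimate + 1.96 * se),
             stringsAsFactors = FALSE)
}

#' Fit a Cox proportional-hazards model
#'
#' Maximises the Cox partial likelihood (Breslow tie handling by default)
#' for the requested covariates and summarises each retained covariate with
#' its log-hazard estimate, Wald p-value, hazard ratio `exp(estimate)` and
#' 95% CI `exp(estimate +/- 1.96 SE)`.
#'
#' @param data Data frame with columns `os_months`, `event` and the
#'   covariates.
#' @param covariates Character vector of covariate column names.
#' @param ties Tie handling, `"breslow"` (default) or `"efron"`.
#' @return Object of class `cox_model`: `covariates` data frame (name,
#'   estimate, se, p_value, hazard_ratio, ci95_low, ci95_high), `loglik`,
#'   `n`, `n_events`.
#' @export
fit_cox <- function(data, covariates, ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  if (sum(data$event) < 2L) stop("need at least 2 events")
  missing_cov <- setdiff(covariates, names(data))
  if (length(missing_cov))
    stop("covariates not in data: ", paste(missing_cov, collapse = ", "))
  if (length(covariates) == 0L) {
    fit0 <- survival::coxph(survival::Surv(os_months, event) ~ 1,
                            data = data, ties = ties)
    return(structure(list(covariates = cox_row(character(0), numeric(0),
                                               numeric(0), numeric(0)),
                          loglik = fit0$loglik[1], n = nrow(data),
                          n_events = sum(data$event), ties = ties),
                     class = "cox_model"))
  }
  fml <- stats::as.formula(paste("survival::Surv(os_months, event) ~",
                                 paste(covariates, collapse = " + ")))
  fit <- survival::coxph(fml, data = data, ties = ties,
                         control = survival::coxph.control(eps = 1e-9,
                                                           iter.max = 100))
  beta <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  if (any(!is.finite(beta)) || any(!is.finite(se)))
    stop("Cox fit did not produce finite estimates (non-convergence)")
  if (any(abs(beta) > 20))
    stop("monotone partial likelihood (separation) for: ",
         paste(names(beta)[abs(beta) > 20], collapse = ", "))
  z <- beta / se
  structure(list(
    covariates = cox_row(covariates, unname(beta), unname(se),
                         2 * stats::pnorm(-abs(unname(z)))),
    loglik = fit$loglik[2], n = fit$n, n_events = fit$nevent,
    ties = ties), class = "cox_model")
}

#' @export
print.cox_model <- function(x, digits = 3, ...) {
  cat(sprintf("Cox model (%s ties): %d subjects, %d events, logLik %.3f\n",
              x$ties, x$n, x$n_events, x$loglik))
  if (nrow(x$covariates) == 0L) {
    cat("  (no covariates retained)\n")
    return(invisible(x))
  }
  df <- x$covariates
  cat(sprintf("  %-12s %9s %9s %8s %8s\n", "", "estimate", "p", "HR",
              "95% CI"))
  for (i in seq_len(nrow(df)))
    cat(sprintf("  %-12s %9.3f %9.3g %8.3f %s\n", df$name[i],
                df$estimate[i], df$p_value[i], df$hazard_ratio[i],
                sprintf("%.3f-%.3f", df$ci95_low[i], df$ci95_high[i])))
  invisible(x)
}

null_loglik <- function(data, ties) {
  survival::coxph(survival::Surv(os_months, event) ~ 1, data = data,
                  ties = ties)$loglik[1]
}

#' Backward elimination for Cox models
#'
#' Approximates stepwise "backward conditional" selection: at each step the
#' covariate with the largest removal p-value (likelihood-ratio test of the
#' current model with vs without it) is removed while that p-value exceeds
#' `p_remove`, refitting after each removal. Ties break on covariate order.
#'
#' @inheritParams fit_cox
#' @param full_covariates Covariates of the starting (full) model.
#' @param p_remove Removal threshold (default 0.05).
#' @return The final `cox_model`; its `removed` attribute lists the dropped
#'   covariates in removal order. All covariates removed yields an empty
#'   model with a warning.
#' @export
backward_conditional <- function(data, full_covariates, p_remove = 0.05,
                                 ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  covs <- full_covariates
  removed <- character(0)
  repeat {
    if (length(covs) == 0L) {
      warning("all covariates removed; returning the empty model")
      out <- fit_cox(data, character(0), ties)
      attr(out, "removed") <- removed
      return(out)
    }
    full <- fit_cox(data, covs, ties)
    pvals <- vapply(covs, function(cv) {
      ll_red <- if (length(covs) > 1L)
        fit_cox(data, setdiff(covs, cv), ties)$loglik
      else null_loglik(data, ties)
      stats::pchisq(2 * (full$loglik - ll_red), df = 1,
                    lower.tail = FALSE)
    }, numeric(1))
    worst <- which.max(pvals)
    if (pvals[worst] > p_remove) {
      removed <- c(removed, covs[worst])
      covs <- covs[-worst]
    } else {
      attr(full, "removed") <- removed
      return(full)
    }
  }
}

#' Prognostic equation of a model
#'
#' Ordered (covariate, coefficient) pairs; the prognostic score of a
#' patient is the sum of coefficient times covariate value.
#'
#' @param x A `cox_model`, or a named numeric vector of coefficients.
#' @return Object of class `prognostic_equation`.
#' @export
prognostic_equation <- function(x) {
  if (inherits(x, "cox_model")) {
    terms <- data.frame(name = x$covariates$name,
                        coefficient = x$covariates$estimate,
                        stringsAsFactors = FALSE)
  } else {
    if (is.null(names(x))) stop("coefficients must be named")
    terms <- data.frame(name = names(x), coefficient = as.numeric(x),
                        stringsAsFactors = FALSE)
  }
  structure(list(terms = terms), class = "prognostic_equation")
}

#' @export
print.prognostic_equation <- function(x, ...) {
  if (nrow(x$terms) == 0L) { cat("score = 0\n"); return(invisible(x)) }
  cat("score =",
      paste(sprintf("(%s x %.3f)", x$terms$name, x$terms$coefficient),
            collapse = " + "), "\n")
  invisible(x)
}

# Resolve one covariate name against a clinical record and feature vector.
resolve_covariate <- function(name, record, features) {
  clin <- c(age = "age_years", treatment = "treatment_code",
            stage = "stage_code")
  if (name %in% names(clin)) return(record[[clin[[name]]]])
  if (!is.null(features) && !is.null(features[[name]]))
    return(features[[name]])
  stop("cannot resolve covariate '", name, "' from the clinical record ",
       "or feature vector")
}

#' Prognostic score for one patient
#'
#' Summation of the products of the equation's covariates (age in years,
#' treatment coded 1 = curative / 2 = palliative, stage coded 1-8 for
#' IA..IV, texture features) and their coefficients.
#'
#' @param eq A [prognostic_equation()].
#' @param record One-row data frame / list with the clinical fields.
#' @param features Optional feature vector / list for texture covariates.
#' @return The score (numeric scalar, or vector when `record` has several
#'   rows).
#' @export
prognostic_score <- function(eq, record, features = NULL) {
  if (nrow(eq$terms) == 0L)
    return(rep(0, max(1L, NROW(record$age_years))))
  vals <- lapply(eq$terms$name, resolve_covariate, record = record,
                 features = features)
  as.vector(Reduce(`+`, Map(`*`, eq$terms$coefficient, vals)))
}

#' Stratify patients into risk tertiles by prognostic score
#'
#' Patients are ranked by score (higher score = higher risk) and split at
#' ranks ceiling(n/3) and ceiling(2n/3) into low / intermediate / high
#' groups. Scores tied with a boundary score are assigned to the
#' lower-risk group (group sizes may then deviate and are reported).
#'
#' @param scores Numeric prognostic scores.
#' @param patient_ids Optional identifiers (defaults to index).
#' @return Object of class `risk_stratification`: `assignments` data frame
#'   (patient_id, score, risk_group), `sizes`, `ranges` (per-group score
#'   ranges) and the boundary scores.
#' @export
stratify_tertiles <- function(scores, patient_ids = NULL) {
  n <- length(scores)
  if (n < 3L) stop("need at least 3 patients")
  if (is.null(patient_ids)) patient_ids <- as.character(seq_len(n))
  lev <- c("low", "intermediate", "high")
  if (diff(range(scores)) == 0) {
    warning("all prognostic scores identical; degenerate single group")
    group <- factor(rep("low", n), levels = lev)
    b1 <- b2 <- scores[1]
  } else {
    s <- sort(scores)
    b1 <- s[ceiling(n / 3)]
    b2 <- s[ceiling(2 * n / 3)]
    group <- factor(ifelse(scores <= b1, "low",
                    ifelse(scores <= b2, "intermediate", "high")),
                    levels = lev)
  }
  ranges <- t(vapply(lev, function(g) {
    if (!any(group == g)) return(c(NA_real_, NA_real_))
    range(scores[group == g])
  }, numeric(2)))
  colnames(ranges) <- c("min", "max")
  structure(list(
    assignments = data.frame(patient_id = patient_ids, score = scores,
                             risk_group = group, stringsAsFactors = FALSE),
    sizes = table(group), ranges = ranges, boundaries = c(b1, b2)),
    class = "risk_stratification")
}

#' @export
print.risk_stratification <- function(x, ...) {
  cat("Risk stratification (tertiles of prognostic score):\n")
  for (g in rownames(x$ranges))
    cat(sprintf("  %-13s n = %3d  (%.2f to %.2f)\n", g, x$sizes[[g]],
                x$ranges[g, "min"], x$ranges[g, "max"]))
  invisible(x)
}

#' Kaplan-Meier estimate
#'
#' Product-limit estimator with log(-log) confidence intervals; the median
#' is the first time at which survival drops to 0.5 or below (NA with an
#' open-ended CI when survival never reaches 0.5).
#'
#' @param times Follow-up times (months).
#' @param events Logical/0-1 event indicators (>= 1 event required).
#' @param conf_level Confidence level (default 0.95).
#' @return Object of class `km_estimate`: `time`, `surv`, `lower`,
#'   `upper`, `median`, `median_ci`, and the underlying survfit object.
#' @export
kaplan_meier <- function(times, events, conf_level = 0.95) {
  if (sum(events) < 1L) stop("need at least 1 event")
  df <- data.frame(t = times, e = as.integer(events))
  fit <- survival::survfit(survival::Surv(t, e) ~ 1, data = df,
                           conf.type = "log-log", conf.int = conf_level)
  tab <- summary(fit)$table
  med <- if (any(fit$surv <= 0.5)) min(fit$time[fit$surv <= 0.5]) else NA_real_
  structure(list(time = fit$time, surv = fit$surv, lower = fit$lower,
                 upper = fit$upper,
                 median = med,
                 median_ci = unname(c(tab["0.95LCL"], tab["0.95UCL"])),
                 n = length(times), n_events = sum(events), fit = fit),
            class = "km_estimate")
}

#' Survival probability at given times from a KM estimate
#'
#' @param km A [kaplan_meier()] result.
#' @param times Times at which to evaluate the curve.
#' @export
km_survival_at <- function(km, times) {
  summary(km$fit, times = times, extend = TRUE)$surv
}

#' @export
print.km_estimate <- function(x, ...) {
  cat(sprintf(
    "Kaplan-Meier: %d subjects, %d events, median %.1f (95%% CI %.1f-%.1f)\n",
    x$n, x$n_events, x$median, x$median_ci[1], x$median_ci[2]))
  invisible(x)
}

#' K-sample log-rank test
#'
#' @param groups Named list; each element a list/data frame with `times`
#'   and `events`.
#' @return List with `chi2`, `df` (groups - 1) and `p` (chi-square upper
#'   tail).
#' @export
logrank_test <- function(groups) {
  if (length(groups) < 2L) stop("need at least 2 groups")
  sizes <- vapply(groups, function(g) length(g$times), integer(1))
  if (any(sizes == 0L))
    stop("group(s) with no subjects: ",
         paste(names(groups)[sizes == 0L], collapse = ", "))
  df <- do.call(rbind, lapply(seq_along(groups), function(i)
    data.frame(t = groups[[i]]$times, e = as.integer(groups[[i]]$events),
               g = i)))
  if (sum(df$e) < 1L) stop("need at least 1 event in total")
  sd <- survival::survdiff(survival::Surv(t, e) ~ g, data = df)
  k <- length(groups)
  list(chi2 = unname(sd$chisq), df = k - 1L,
       p = stats::pchisq(sd$chisq, k - 1L, lower.tail = FALSE))
}
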