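# Cross-method agreement of risk stratification: pairwise change counts,
# per-tier concordant counts, and per-tier cross-model log-rank tests.

check_same_patients <- function(strats) {
  ids <- lapply(strats, function(s) sort(s$assignments$patient_id))
  ref <- ids[[1]]
  for (i in seq_along(ids)[-1]) {
    if (!identical(ids[[i]], ref)) {
      extra <- setdiff(ids[[i]], ref)
      miss <- setdiff(ref, ids[[i]])
      stop("stratifications cover different patients; symmetric ",
           "difference: ", paste(c(extra, miss), collapse = ", "))
    }
  }
  invisible(TRUE)
}

# Risk-group labels aligned to the patient order of the first
# stratification.
aligned_groups <- function(strats) {
  ref_ids <- strats[[1]]$assignments$patient_id
  vapply(strats, function(s) {
    a <- s$assignments
    as.character(a$risk_group[match(ref_ids, a$patient_id)])
  }, character(length(ref_ids)))
}

#' Pairwise risk-group change counts between segmentation methods
#'
#' For every unordered pair of methods, counts the patients whose risk
#' group differs between the two stratifications, with the percentage of
#' the common cohort (1 decimal place).
#'
#' @param strats Named list of [stratify_tertiles()] results covering the
#'   identical patient set.
#' @return Object of class `concordance_matrix` with symmetric
#'   `n_changed` and `pct_changed` matrices (zero diagonal) and `n`.
#' @export
change_counts <- function(strats) {
  stopifnot(length(strats) >= 2L, !is.null(names(strats)))
  check_same_patients(strats)
  G <- aligned_groups(strats)
  n <- nrow(G)
  k <- ncol(G)
  nc <- matrix(0L, k, k, dimnames = list(names(strats), names(strats)))
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    d <- sum(G[, i] != G[, j])
    nc[i, j] <- d; nc[j, i] <- d
  }
  structure(list(n_changed = nc, pct_changed = round(100 * nc / n, 1),
                 n = n), class = "concordance_matrix")
}

#' @export
print.concordance_matrix <- function(x, ...) {
  cat(sprintf("Patients changing risk group (n = %d), count (%%):\n", x$n))
  m <- x$n_changed
  for (i in seq_len(nrow(m))[-1]) {
    cat(sprintf("  %-6s", rownames(m)[i]))
    for (j in seq_len(i - 1L))
      cat(sprintf(" %4d (%4.1f)", m[i, j], x$pct_changed[i, j]))
    cat("\n")
  }
  cat(paste0("         ", paste(sprintf("%-11s", colnames(m)[-ncol(m)]),
                                collapse = " ")), "\n")
  invisible(x)
}

#' Per-tier concordant patient counts across all methods
#'
#' For each risk tier, the number of patients assigned that tier by every
#' method.
#'
#' @inheritParams change_counts
#' @return Named integer vector (low, intermediate, high).
#' @export
concordant_counts <- function(strats) {
  check_same_patients(strats)
  G <- aligned_groups(strats)
  vapply(c(low = "low", intermediate = "intermediate", high = "high"),
         function(tier) sum(rowSums(G == tier) == ncol(G)),
         integer(1))
}

#' Per-tier log-rank comparison of risk groups across models
#'
#' For each tier, compares overall survival between the per-method
#' memberships of that tier with a K-sample log-rank test. The groups are
#' not disjoint (the same patient can sit in the tier under several
#' models); the statistic is descriptive. Methods whose tier is empty are
#' dropped with a warning.
#'
#' @inheritParams change_counts
#' @param survival_data Data frame with `patient_id`, `os_months`,
#'   `event`.
#' @return Data frame with one row per tier: tier, chi2, df, p.
#' @export
cross_model_tier_logrank <- function(strats, survival_data) {
  stopifnot(length(strats) >= 2L)
  check_same_patients(strats)
  out <- lapply(c("low", "intermediate", "high"), function(tier) {
    groups <- list()
    for (m in names(strats)) {
      a <- strats[[m]]$assignments
      ids <- a$patient_id[a$risk_group == tier]
      if (length(ids) == 0L) {
        warning("method ", m, " has an empty ", tier,
                "-risk tier; dropped from the comparison")
        next
      }
      rows <- match(ids, survival_data$patient_id)
      groups[[m]] <- list(times = survival_data$os_months[rows],
                          events = survival_data$event[rows])
    }
    lr <- logrank_test(groups)
    data.frame(tier = tier, chi2 = lr$chi2, df = lr$df, p = lr$p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
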