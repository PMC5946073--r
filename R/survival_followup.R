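#' Classify case-group subjects as carriers of a genotype combination
#'
#' Evaluates the combination on the long-lived (case) cohort; subjects
#' with a missing genotype at any combination locus are excluded and
#' their count recorded in the `"n_excluded"` attribute.
#'
#' @param study A [genotype_study()] with survival fields on cases.
#' @param combination A [genotype_combination()].
#' @return Named logical vector (carrier status) over the included case
#'   subjects.
#' @export
classify_carriers <- function(study, combination) {
  cases <- subset_subjects(study, study$phenotype == "case")
  carrier <- matches_combination(cases, combination)
  keep <- !is.na(carrier)
  out <- carrier[keep]
  names(out) <- cases$subject_ids[keep]
  if (!any(out) || all(out))
    stop("no carrier/noncarrier contrast for combination '",
         combination$label, "'", call. = FALSE)
  attr(out, "n_excluded") <- sum(!keep)
  out
}

#' Kaplan-Meier product-limit survival curve
#'
#' @param times Follow-up in months (>= 0).
#' @param events 1 = death observed, 0 = censored.
#' @return Data.frame of class `km_curve` with `time`, `n_risk`,
#'   `n_event` and `survival` (the step function; starts at 1).
#' @export
kaplan_meier <- function(times, events) {
  if (any(times < 0)) stop("negative survival time", call. = FALSE)
  if (!length(times)) stop("no subjects", call. = FALSE)
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  out <- data.frame(time = c(0, fit$time),
                    n_risk = c(length(times), fit$n.risk),
                    n_event = c(0, fit$n.event),
                    survival = c(1, fit$surv))
  class(out) <- c("km_curve", "data.frame")
  out
}

#' Two-group Mantel-Cox log-rank test
#'
#' @param times_a,events_a Group A follow-up and event indicators.
#' @param times_b,events_b Group B.
#' @return List with `chi2` (1 df) and `p`.
#' @export
logrank_test <- function(times_a, events_a, times_b, events_b) {
  if (!length(times_a) || !length(times_b))
    stop("both groups must be non-empty", call. = FALSE)
  if (sum(events_a) + sum(events_b) == 0)
    stop("no events observed", call. = FALSE)
  grp <- factor(c(rep("a", length(times_a)), rep("b", length(times_b))))
  sd <- survival::survdiff(
    survival::Surv(c(times_a, times_b), c(events_a, events_b)) ~ grp)
  list(chi2 = sd$chisq, p = stats::pchisq(sd$chisq, df = 1,
                                          lower.tail = FALSE))
}

#' Cox proportional-hazards ratio for a binary carrier covariate
#'
#' Partial-likelihood fit with Breslow tie handling (months-resolution
#' follow-up makes ties frequent); Efron is available via `ties`. Wald
#' 95% interval on the log-hazard scale.
#'
#' @param times,events Follow-up and event indicators.
#' @param carrier Logical covariate.
#' @param ties `"breslow"` (default) or `"efron"`.
#' @return List with `hr`, `ci`, `log_hr`, `se` and `p` (Wald).
#' @export
cox_hr <- function(times, events, carrier, ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  carrier <- as.logical(carrier)
  if (length(unique(carrier)) < 2L)
    stop("carrier covariate is constant", call. = FALSE)
  fit <- tryCatch(
    survival::coxph(survival::Surv(times, events) ~ carrier,
                    ties = ties,
                    control = survival::coxph.control(eps = 1e-8,
                                                      iter.max = 50)),
    warning = function(w) stop("Cox fit did not converge cleanly: ",
                               conditionMessage(w), call. = FALSE))
  beta <- unname(stats::coef(fit))
  se <- sqrt(unname(fit$var[1, 1]))
  if (!is.finite(beta) || !is.finite(se) || se > 50)
    stop("monotone partial likelihood (complete separation?)",
         call. = FALSE)
  list(hr = exp(beta), ci = exp(beta + c(-1, 1) * stats::qnorm(0.975) * se),
       log_hr = beta, se = se,
       p = 2 * stats::pnorm(-abs(beta / se)))
}

#' Sex-stratified survival follow-up of candidate combinations
#'
#' For each combination and stratum, classifies case-cohort subjects as
#' carriers or noncarriers, compares their survival from recruitment by
#' the Mantel-Cox log-rank test, and reports the Cox hazard ratio
#' (carrier vs noncarrier). Subjects with zero follow-up get a
#' half-month offset so the product limit is defined. p-values are
#' reported unadjusted across combinations, matching the single-test
#' convention of candidate follow-up; set `by_adjust = TRUE` for a
#' Benjamini-Yekutieli column.
#'
#' @param study A [genotype_study()] with survival fields on cases.
#' @param combinations List of [genotype_combination()] objects.
#' @param strata Subset of `c("male", "female", "all")`.
#' @param alpha Flagging level (default 0.05).
#' @param by_adjust Add a BY-adjusted p column (default FALSE).
#' @return Data.frame of class `survival_screen`, one row per
#'   combination x stratum, with carrier counts, log-rank chi-square and
#'   p, HR and CI; Kaplan-Meier curves per row in the `"km"` attribute.
#' @export
survival_screen <- function(study, combinations,
                            strata = c("male", "female"), alpha = 0.05,
                            by_adjust = FALSE) {
  if (!length(combinations)) {
    out <- data.frame(combination = character(), stratum = character(),
                      n = integer(), n_carriers = integer(),
                      logrank_chi2 = numeric(), logrank_p = numeric(),
                      hr = numeric(), hr_lo = numeric(), hr_hi = numeric(),
                      significant = logical(), stringsAsFactors = FALSE)
    class(out) <- c("survival_screen", "data.frame")
    return(out)
  }
  if (is.null(study$months))
    stop("study carries no survival follow-up", call. = FALSE)
  rows <- list(); km <- list()
  for (comb in combinations) {
    for (st in strata) {
      sub <- study
      if (st != "all") {
        keep <- study$sex == st
        if (!any(keep & study$phenotype == "case")) {
          warning("stratum '", st, "' has no case subjects; skipped")
          next
        }
        sub <- subset_subjects(study, keep)
      }
      res <- tryCatch({
        carrier <- classify_carriers(sub, comb)
        cases <- subset_subjects(sub, sub$phenotype == "case")
        idx <- match(names(carrier), cases$subject_ids)
        tm <- cases$months[idx]; ev <- cases$event[idx]
        ok <- !is.na(tm)
        tm <- tm[ok]; ev <- ev[ok]; cr <- carrier[ok]
        n_zero <- sum(tm == 0)
        if (n_zero) {
          message(n_zero, " subject(s) with zero follow-up offset by ",
                  "0.5 months")
          tm[tm == 0] <- 0.5
        }
        lr <- logrank_test(tm[cr], ev[cr], tm[!cr], ev[!cr])
        cx <- tryCatch(cox_hr(tm, ev, cr),
                       error = function(e) list(hr = NA_real_,
                                                ci = c(NA_real_, NA_real_)))
        km[[paste(comb$label, st, sep = " | ")]] <-
          list(carrier = kaplan_meier(tm[cr], ev[cr]),
               noncarrier = kaplan_meier(tm[!cr], ev[!cr]))
        data.frame(combination = comb$label, stratum = st,
                   n = length(tm), n_carriers = sum(cr),
                   logrank_chi2 = lr$chi2, logrank_p = lr$p,
                   hr = cx$hr, hr_lo = cx$ci[1L], hr_hi = cx$ci[2L],
                   significant = lr$p < alpha, stringsAsFactors = FALSE)
      }, error = function(e) {
        warning("combination '", comb$label, "' in stratum '", st,
                "': ", conditionMessage(e))
        NULL
      })
      if (!is.null(res)) rows[[length(rows) + 1L]] <- res
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no combination/stratum could be analysed",
                         call. = FALSE)
  if (by_adjust) out$by_q <- benjamini_yekutieli(out$logrank_p)
  rownames(out) <- NULL
  attr(out, "km") <- km
  class(out) <- c("survival_screen", "data.frame")
  out
}

#' Write survival-screen results and KM curves as TSV
#'
#' @param screen A `survival_screen`.
#' @param path Results TSV path.
#' @param km_path Optional tidy KM-curve TSV path (time, at_risk,
#'   survival, group, stratum, combination).
#' @export
write_survival <- function(screen, path, km_path = NULL) {
  df <- screen
  attr(df, "km") <- NULL
  class(df) <- "data.frame"
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  if (!is.null(km_path)) {
    km <- attr(screen, "km")
    pieces <- lapply(names(km), function(nm) {
      parts <- strsplit(nm, " | ", fixed = TRUE)[[1L]]
      do.call(rbind, lapply(c("carrier", "noncarrier"), function(gr) {
        cv <- km[[nm]][[gr]]
        data.frame(combination = parts[1L], stratum = parts[2L],
                   group = gr, time = cv$time, at_risk = cv$n_risk,
                   survival = cv$survival, stringsAsFactors = FALSE)
      }))
    })
    utils::write.table(do.call(rbind, pieces), km_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
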