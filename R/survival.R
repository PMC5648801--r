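#' Build a survival cohort stratified by IS score
#'
#' Joins a clinical table with IS scores and dichotomizes samples into
#' high/low IS groups at the cutoff (default 0.5, the IS-call boundary).
#' Subjects with `survival_time == 0` are excluded with a warning
#' (undefined risk interval).
#'
#' @param clinical clinical `data.frame` with `sample_id`,
#'   `survival_time`, `event` (and optionally `cancer_type`).
#' @param is_scores numeric IS scores named by sample id, or a score table
#'   from [score_bccp()].
#' @param cutoff IS-score threshold for the high group (`is_score >
#'   cutoff`).
#' @return `data.frame` with `sample_id`, `time`, `event`, `is_score`,
#'   `group` (`"high"`/`"low"`), `strata` (cancer type or `NA`).
#' @export
survival_cohort <- function(clinical, is_scores, cutoff = 0.5) {
  scores <- as_is_scores(is_scores)
  common <- intersect(clinical$sample_id, names(scores))
  if (!length(common)) stop("no samples shared between clinical table and IS scores")
  cl <- clinical[match(common, clinical$sample_id), , drop = FALSE]
  out <- data.frame(
    sample_id = common,
    time = cl$survival_time,
    event = as.integer(cl$event),
    is_score = unname(scores[common]),
    stringsAsFactors = FALSE
  )
  out$group <- ifelse(out$is_score > cutoff, "high", "low")
  out$strata <- if ("cancer_type" %in% names(cl)) cl$cancer_type else NA_character_
  drop0 <- !is.na(out$time) & out$time == 0
  if (any(drop0)) {
    warning(sprintf("excluding %d subject(s) with survival_time = 0", sum(drop0)))
    out <- out[!drop0, , drop = FALSE]
  }
  ok <- !is.na(out$time) & !is.na(out$event)
  out <- out[ok, , drop = FALSE]
  if (!nrow(out)) stop("no usable (time, event) pairs")
  rownames(out) <- NULL
  out
}

#' Kaplan-Meier estimate per IS group
#'
#' Product-limit survival curves per group: survival starts at 1 and is
#' non-increasing. A group whose subjects are all censored yields a curve
#' flat at 1 and is flagged in the output.
#'
#' @param cohort `data.frame` with `time`, `event`, `group` (e.g. from
#'   [survival_cohort()]).
#' @return `data.frame` with `group`, `time`, `n_risk`, `n_event`,
#'   `survival`, and a logical `all_censored` flag per group.
#' @export
km_estimate <- function(cohort) {
  stopifnot(all(c("time", "event", "group") %in% names(cohort)))
  if (!nrow(cohort)) stop("empty cohort")
  fit <- survival::survfit(
    survival::Surv(time, event) ~ group,
    data = cohort
  )
  sm <- summary(fit, censored = TRUE)
  grp <- if (is.null(sm$strata)) rep(unique(cohort$group), length(sm$time))
         else sub("^group=", "", as.character(sm$strata))
  flat <- tapply(cohort$event, cohort$group, function(e) all(e == 0))
  if (any(flat)) {
    message(sprintf("km_estimate: all-censored group(s): %s (curve flat at 1)",
                    paste(names(flat)[flat], collapse = ", ")))
  }
  data.frame(
    group = grp,
    time = sm$time,
    n_risk = sm$n.risk,
    n_event = sm$n.event,
    survival = sm$surv,
    all_censored = unname(flat[grp]),
    stringsAsFactors = FALSE
  )
}

#' Two-group log-rank test
#'
#' Standard log-rank statistic comparing the high/low IS groups, with a
#' 1-df chi-square p-value (k-1 df for k groups).
#'
#' @param cohort `data.frame` with `time`, `event`, `group`.
#' @return list with `chi_square`, `df`, `p_value`.
#' @export
logrank_test <- function(cohort) {
  stopifnot(all(c("time", "event", "group") %in% names(cohort)))
  if (length(unique(cohort$group)) < 2L) stop("log-rank needs at least 2 groups")
  if (sum(cohort$event) == 0L) stop("log-rank undefined with zero events")
  sd <- survival::survdiff(
    survival::Surv(time, event) ~ group,
    data = cohort
  )
  df <- length(sd$n) - 1L
  list(
    chi_square = unname(sd$chisq),
    df = df,
    p_value = stats::pchisq(sd$chisq, df = df, lower.tail = FALSE)
  )
}

#' Cox proportional-hazards summary
#'
#' Partial-likelihood fit (Efron ties) of survival on either the IS group
#' (high vs low) or the continuous IS score, optionally stratified by
#' cancer type. Reports the hazard ratio with a 95% Wald CI and p-value.
#' Monotone likelihood (infinite coefficient) is flagged.
#'
#' @param cohort `data.frame` with `time`, `event`, and the covariate
#'   columns (`group`, `is_score`, `strata`).
#' @param covariate `"group"` (default; HR of high vs low) or
#'   `"is_score"` (HR per unit of the continuous score).
#' @param stratify_by optional column name used as stratification factor
#'   (e.g. `"strata"` for cancer type).
#' @return `data.frame` with `term`, `hazard_ratio`, `ci_low`, `ci_high`,
#'   `p_value`, `n`, `n_events`, `monotone_likelihood`.
#' @export
cox_summary <- function(cohort, covariate = c("group", "is_score"),
                        stratify_by = NULL) {
  covariate <- match.arg(covariate)
  stopifnot(all(c("time", "event", covariate) %in% names(cohort)))
  if (covariate == "group") {
    if (length(unique(cohort$group)) < 2L) {
      stop("degenerate design: group covariate has a single level")
    }
    cohort$group <- stats::relevel(factor(cohort$group), ref = "low")
  }
  rhs <- covariate
  if (!is.null(stratify_by)) {
    stopifnot(stratify_by %in% names(cohort))
    rhs <- sprintf("%s + survival::strata(%s)", rhs, stratify_by)
  }
  fml <- stats::as.formula(sprintf("survival::Surv(time, event) ~ %s", rhs))
  monotone <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(fml, data = cohort, ties = "efron"),
    warning = function(w) {
      if (grepl("infinite|did not converge|beta may be infinite",
                conditionMessage(w))) {
        monotone <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  sm <- summary(fit)
  co <- sm$coefficients
  ci <- sm$conf.int
  data.frame(
    term = rownames(co),
    hazard_ratio = unname(co[, "exp(coef)"]),
    ci_low = unname(ci[, "lower .95"]),
    ci_high = unname(ci[, "upper .95"]),
    p_value = unname(co[, "Pr(>|z|)"]),
    n = sm$n,
    n_events = sm$nevent,
    monotone_likelihood = monotone,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}
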