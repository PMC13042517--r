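# Survival analysis: Kaplan-Meier estimation, log-rank testing, two-group
# Cox hazard ratios (Breslow ties) and score dichotomization at the median
# or a maximally selected log-rank cutpoint. Estimation is delegated to the
# survival package; the cutpoint search and endpoint construction are local.

#' Kaplan-Meier product-limit estimate
#'
#' Ties between events and censorings at the same time put events first
#' (the product-limit convention); the curve is a right-continuous step
#' function with S(0) = 1.
#'
#' @param records A `SurvivalTable` (see [survival_table()]).
#' @return List of class `KMCurve`: `time`, `n_risk`, `n_event`,
#'   `n_censor`, `surv` plus the fitted `survfit` object.
#' @export
km_estimate <- function(records) {
  stopifnot(nrow(records) >= 1)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           data = as.data.frame(records),
                           conf.type = "log-log")
  structure(list(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
                 n_censor = fit$n.censor, surv = fit$surv, fit = fit),
            class = "KMCurve")
}

#' Query a Kaplan-Meier curve at arbitrary times
#'
#' @param curve A `KMCurve`.
#' @param t Numeric vector of query times.
#' @return S(t): 1 before the first event, then the right-continuous step
#'   value.
#' @export
km_surv_at <- function(curve, t) {
  vapply(t, function(ti) {
    i <- which(curve$time <= ti)
    if (!length(i)) 1 else curve$surv[max(i)]
  }, numeric(1))
}

#' Log-rank test between survival groups
#'
#' Standard log-rank statistic with hypergeometric variance;
#' `df = groups - 1`.
#'
#' @param records A `SurvivalTable` with a group column.
#' @param group Column name holding the group label (default "group").
#' @return List with `statistic`, `df`, `p_value` and the per-group
#'   observed/expected event counts.
#' @export
logrank_test <- function(records, group = "group") {
  df <- as.data.frame(records)
  g <- df[[group]]
  if (is.null(g) || length(unique(g)) < 2)
    stop_validation("log-rank needs >= 2 nonempty groups")
  sd <- survival::survdiff(survival::Surv(time, event) ~ g, data = df)
  list(statistic = unname(sd$chisq), df = length(sd$n) - 1,
       p_value = stats::pchisq(sd$chisq, length(sd$n) - 1, lower.tail = FALSE),
       observed = sd$obs, expected = sd$exp)
}

#' Two-group Cox proportional-hazards ratio
#'
#' Maximizes the Breslow-ties partial likelihood for a single binary group
#' covariate and reports the hazard ratio of `level` versus the reference,
#' with a Wald confidence interval. When either group has zero events the
#' likelihood is monotone and no finite estimate exists: a divergence flag
#' is returned instead of a number.
#'
#' @param records A `SurvivalTable` with a group column.
#' @param group Column name of the binary group (default "group").
#' @param level Group level treated as exposed; default the second sorted
#'   level.
#' @param conf_level Confidence level (default 0.95).
#' @return List with `hr`, `ci`, `p_value`, `log_hr`, `diverged`.
#' @export
cox_hr <- function(records, group = "group", level = NULL, conf_level = 0.95) {
  df <- as.data.frame(records)
  g <- df[[group]]
  lev <- sort(unique(g))
  if (length(lev) != 2) stop_validation("cox_hr needs exactly 2 groups")
  level <- level %||% lev[2]
  x <- as.numeric(g == level)
  if (sum(df$event) == 0) stop_validation("no events at all; hazard ratio undefined")
  ev_by <- tapply(df$event, x, sum)
  if (any(ev_by == 0))
    return(list(hr = NA_real_, ci = c(NA_real_, NA_real_), p_value = NA_real_,
                log_hr = NA_real_, diverged = TRUE))
  fit <- survival::coxph(survival::Surv(time, event) ~ x, data = df,
                         ties = "breslow")
  b <- unname(stats::coef(fit)); se <- sqrt(unname(stats::vcov(fit)[1, 1]))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(hr = exp(b), ci = exp(c(b - z * se, b + z * se)),
       p_value = 2 * stats::pnorm(-abs(b / se)), log_hr = b, diverged = FALSE)
}

#' Cutpoint parameters for score dichotomization
#'
#' @param method `"median"` or `"best"` (maximally selected log-rank
#'   statistic).
#' @param min_prop Minimum fraction of subjects on each side of a candidate
#'   cutpoint (default 0.1).
#' @return A list of class `CutpointParams`.
#' @export
cutpoint_params <- function(method = c("median", "best"), min_prop = 0.1) {
  method <- match.arg(method)
  if (!(min_prop > 0 && min_prop < 0.5))
    stop_validation("min_prop must lie in (0, 0.5)")
  structure(list(method = method, min_prop = min_prop), class = "CutpointParams")
}

#' Dichotomize subjects by a score for survival comparison
#'
#' `median`: subjects strictly above the median score are "high". `best`:
#' among candidate cutpoints (observed score values leaving at least
#' `min_prop` of subjects on each side) the one maximizing the absolute
#' standardized log-rank statistic is chosen; ties go to the lower
#' cutpoint. The log-rank p at the selected cutpoint is reported
#' uncorrected for the search.
#'
#' @param scores Per-subject numeric scores, aligned with `records`.
#' @param records A `SurvivalTable` (needed for `method = "best"`).
#' @param params A `CutpointParams` object.
#' @return List with `labels` ("high"/"low"), `cutpoint`, and for the best
#'   method `statistic` (standardized log-rank) and `p_uncorrected`.
#' @export
dichotomize <- function(scores, records = NULL, params = cutpoint_params()) {
  stopifnot(inherits(params, "CutpointParams"))
  if (length(scores) < 4) stop_validation("need >= 4 subjects to dichotomize")
  if (length(unique(scores)) == 1L)
    stop_validation("all scores equal; no cutpoint exists")
  if (params$method == "median") {
    cut <- stats::median(scores)
    return(list(labels = ifelse(scores > cut, "high", "low"), cutpoint = cut))
  }
  df <- as.data.frame(records)
  if (nrow(df) != length(scores))
    stop_validation("scores and survival records must align")
  if (sum(df$event) < 1) stop_validation("best cutpoint needs >= 1 event")
  n <- length(scores)
  cands <- sort(unique(scores))
  cands <- cands[vapply(cands, function(cc) {
    hi <- sum(scores > cc)
    hi >= params$min_prop * n && (n - hi) >= params$min_prop * n
  }, logical(1))]
  if (!length(cands)) stop_validation("no admissible cutpoint under min_prop")
  stat <- vapply(cands, function(cc) {
    g <- ifelse(scores > cc, "high", "low")
    sd <- survival::survdiff(survival::Surv(df$time, df$event) ~ g)
    sqrt(unname(sd$chisq))
  }, numeric(1))
  best <- cands[which.max(stat)]          # which.max takes the first (lowest) tie
  g <- ifelse(scores > best, "high", "low")
  sd <- survival::survdiff(survival::Surv(df$time, df$event) ~ g)
  list(labels = g, cutpoint = best, statistic = sqrt(unname(sd$chisq)),
       p_uncorrected = stats::pchisq(sd$chisq, 1, lower.tail = FALSE))
}

#' Construct EFS or OS endpoints from component event dates
#'
#' Event-free survival takes the first of progression, recurrence,
#' metastasis or death; overall survival takes death. Subjects without the
#' event are censored at last follow-up (or data cutoff).
#'
#' @param clinical Data frame with `subject_id`, `last_followup` (months)
#'   and optional per-component event-time columns (months, `NA` = did not
#'   occur): `progression`, `recurrence`, `metastasis`, `death`.
#' @param endpoint `"EFS"` or `"OS"`.
#' @param group Optional group column name carried through.
#' @return A `SurvivalTable`.
#' @export
derive_endpoint <- function(clinical, endpoint = c("EFS", "OS"), group = NULL) {
  endpoint <- match.arg(endpoint)
  comp <- if (endpoint == "EFS") c("progression", "recurrence", "metastasis", "death")
          else "death"
  comp <- intersect(comp, names(clinical))
  if (!length(comp)) stop_validation("no component event columns found")
  ev_time <- suppressWarnings(
    apply(as.matrix(clinical[comp]), 1, function(r) min(r, na.rm = TRUE)))
  has_event <- is.finite(ev_time)
  time <- ifelse(has_event, ev_time, clinical$last_followup)
  survival_table(clinical$subject_id, time, as.numeric(has_event),
                 group = if (!is.null(group)) clinical[[group]])
}
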