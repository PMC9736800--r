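#' Two-group log-rank test
#'
#' Standard log-rank comparison: at each distinct event time, observed
#' versus expected events under the hypergeometric variance. A thin,
#' validated wrapper around `survival::survdiff`.
#'
#' @param groups two-level factor/vector of group labels.
#' @param times observed times (> 0).
#' @param events event indicators (1 = event, 0 = censored).
#' @return list with `chi_square` (1 df) and `p`.
#' @export
logrankTest <- function(groups, times, events) {
    groups <- as.factor(groups)
    if (nlevels(droplevels(groups)) != 2L)
        stop("exactly two non-empty groups required", call. = FALSE)
    if (sum(events) == 0L)
        stop("no events observed; log-rank undefined", call. = FALSE)
    fit <- survival::survdiff(
        survival::Surv(times, events) ~ g,
        data = data.frame(times = times, events = events, g = groups))
    chi <- unname(fit$chisq)
    list(chi_square = chi, p = stats::pchisq(chi, df = 1, lower.tail = FALSE))
}

# signed standardized log-rank statistic (O - E)/sqrt(V) for group "high"
.standardizedLogrank <- function(high, times, events) {
    fit <- survival::survdiff(
        survival::Surv(times, events) ~ g,
        data = data.frame(times = times, events = events, g = high))
    V <- if (is.matrix(fit$var)) fit$var[1L, 1L] else fit$var
    if (V <= 0) return(0)
    (fit$obs[1L] - fit$exp[1L]) / sqrt(V)
}

#' Maximally selected log-rank cutpoint
#'
#' Evaluates every candidate threshold on the score that leaves at least
#' `minprop` of the cohort on each side, computes the standardized two-group
#' log-rank statistic for the induced high/low split, and returns the
#' threshold maximizing its absolute value (ties resolved toward the lower
#' threshold). The p-value at the selected cutpoint is anti-conservative by
#' construction (maximal selection); it replicates the common
#' cutpoint-then-log-rank procedure.
#'
#' @param scores per-sample risk scores.
#' @param times,events survival outcome.
#' @param minprop minimum fraction of samples per group, in (0, 0.5).
#' @return a [CutpointResult-class]; group "high" is `score > cutpoint`.
#' @export
optimalCutpoint <- function(scores, times, events, minprop = 0.1) {
    n <- length(scores)
    if (n < 10L) stop("at least 10 samples required", call. = FALSE)
    if (minprop <= 0 || minprop >= 0.5)
        stop("minprop must lie in (0, 0.5)", call. = FALSE)
    cand <- sort(unique(scores))
    cand <- cand[-length(cand)]               # top value leaves 'high' empty
    nmin <- minprop * n
    admissible <- vapply(cand, function(ct) {
        nLow <- sum(scores <= ct)
        nLow >= nmin && (n - nLow) >= nmin
    }, logical(1))
    cand <- cand[admissible]
    if (!length(cand))
        stop("no admissible cutpoint candidate", call. = FALSE)
    stat <- vapply(cand, function(ct)
        .standardizedLogrank(scores > ct, times, events), numeric(1))
    best <- which(abs(stat) == max(abs(stat)))[1L]   # ties: lower threshold
    methods::new("CutpointResult", cutpoint = cand[best],
                 statistic = stat[best], candidates = length(cand))
}

#' Split a cohort at a cutpoint and test survival separation
#'
#' @param scores,times,events as in [optimalCutpoint()].
#' @param cutpoint a [CutpointResult-class] or numeric threshold.
#' @return list with `group` (character "high"/"low"), `chi_square`, `p`.
#' @export
survivalSplit <- function(scores, times, events, cutpoint) {
    ct <- if (methods::is(cutpoint, "CutpointResult")) cutpoint@cutpoint
          else cutpoint
    grp <- ifelse(scores > ct, "high", "low")
    c(list(group = grp), logrankTest(grp, times, events))
}

#' Kaplan-Meier product-limit estimate
#'
#' Right-censored product-limit estimator; at tied times, censorings are
#' handled after events. A thin wrapper around `survival::survfit`.
#'
#' @param times observed times (>= 0).
#' @param events event indicators.
#' @return data.frame with `time`, `n_risk`, `n_event`, `surv`; the survival
#'   curve starts at 1 and is non-increasing.
#' @export
kmEstimate <- function(times, events) {
    if (any(times < 0)) stop("negative times are invalid", call. = FALSE)
    fit <- survival::survfit(survival::Surv(times, events) ~ 1)
    data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
               surv = fit$surv)
}
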