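#' Kaplan-Meier survival curve and median for one group
#'
#' Product-limit estimator `S(t) = prod_{t_i <= t} (1 - d_i / n_i)` over the
#' event times, fit with [survival::survfit()]. Ties between events and
#' censorings at the same time are handled with the standard convention
#' (events precede censorings). The median is the smallest time at which
#' `S(t) <= 0.5`, `NA` if the curve never reaches 0.5.
#'
#' @param records Data frame with columns `months` and `event` (0/1) for a
#'   single endpoint and group.
#' @return List with `time` and `surv` (the step function, one entry per
#'   distinct observed time), `n`, `events` and `median_months`.
#' @export
km_estimate <- function(records) {
  if (!nrow(records)) stop("no records to estimate a survival curve from")
  fit <- survival::survfit(
    survival::Surv(months, event) ~ 1,
    data = records[, c("months", "event"), drop = FALSE])
  # smallest time with S(t) <= 0.5, without interpolation at exact hits
  med <- if (any(fit$surv <= 0.5)) min(fit$time[fit$surv <= 0.5]) else
    NA_real_
  list(time = fit$time, surv = fit$surv, n = nrow(records),
       events = sum(records$event == 1), median_months = med)
}

#' Log-rank comparison of two survival curves
#'
#' Standard unweighted log-rank test with one degree of freedom, via
#' [survival::survdiff()]; the p-value is the chi-square upper tail.
#'
#' @param group_a,group_b Data frames with columns `months` and `event`.
#' @return List with `chi2` and `p`.
#' @export
logrank_test <- function(group_a, group_b) {
  if (!sum(group_a$event == 1) || !sum(group_b$event == 1)) {
    stop("both groups need at least one event")
  }
  dat <- rbind(
    data.frame(months = group_a$months, event = group_a$event, grp = "a",
               stringsAsFactors = FALSE),
    data.frame(months = group_b$months, event = group_b$event, grp = "b",
               stringsAsFactors = FALSE))
  sd <- survival::survdiff(survival::Surv(months, event) ~ grp, data = dat)
  chi2 <- unname(sd$chisq)
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' BH q-values across the four survival endpoints
#'
#' Benjamini-Hochberg step-up adjustment applied across the four endpoint
#' p-values (disease-specific, overall, progression-free, disease-free).
#'
#' @param p_by_endpoint Named numeric vector of exactly four p-values.
#' @return Named numeric vector of q-values in the same order.
#' @export
endpoint_qvalues <- function(p_by_endpoint) {
  if (length(p_by_endpoint) != 4L) {
    stop("expected exactly four endpoint p-values")
  }
  stats::setNames(bh_adjust(as.numeric(p_by_endpoint)),
                  names(p_by_endpoint))
}

#' Per-group summary for one endpoint
#'
#' Counts cases and events and reports the Kaplan-Meier median per group,
#' the per-endpoint group-summary layout.
#'
#' @param records Survival data frame with columns `endpoint`, `months`,
#'   `event`, `group`.
#' @param endpoint Endpoint label to summarize.
#' @return Data frame with columns `group`, `n`, `events`, `median_months`.
#' @export
group_summary <- function(records, endpoint) {
  sub <- records[records$endpoint == endpoint, , drop = FALSE]
  groups <- c("altered", "unaltered")
  present <- groups[groups %in% sub$group]
  absent <- setdiff(groups, present)
  if (length(absent)) {
    warning("group(s) with no records omitted: ",
            paste(absent, collapse = ", "))
  }
  rows <- lapply(present, function(g) {
    r <- sub[sub$group == g, , drop = FALSE]
    km <- km_estimate(r)
    data.frame(group = g, n = km$n, events = km$events,
               median_months = km$median_months, stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(group = character(), n = integer(), events = integer(),
               median_months = numeric(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Altered-vs-unaltered survival comparison across all endpoints
#'
#' For each endpoint in the table: log-rank test between the altered and
#' unaltered groups, then BH q-values across the endpoints.
#'
#' @param records Survival data frame with columns `endpoint`, `months`,
#'   `event`, `group`.
#' @return Data frame with columns `endpoint`, `n_patients`, `p`, `q`.
#' @export
survival_comparison <- function(records) {
  endpoints <- unique(records$endpoint)
  res <- lapply(endpoints, function(ep) {
    sub <- records[records$endpoint == ep, , drop = FALSE]
    a <- sub[sub$group == "altered", , drop = FALSE]
    u <- sub[sub$group == "unaltered", , drop = FALSE]
    lr <- logrank_test(a, u)
    data.frame(endpoint = ep, n_patients = nrow(sub), p = lr$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- if (nrow(out) == 4L) {
    as.numeric(endpoint_qvalues(stats::setNames(out$p, out$endpoint)))
  } else {
    bh_adjust(out$p)
  }
  rownames(out) <- NULL
  out
}
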