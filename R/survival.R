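#' Kaplan-Meier product-limit estimate
#'
#' Thin wrapper around [survival::survfit()] returning the product-limit
#' curve as a plain data.frame. An input with only censored records yields a
#' flat curve at 1.
#'
#' @param time follow-up times in years (>= 0).
#' @param event event indicator (1 = event, 0 = censored).
#' @return data.frame with `time`, `n_risk`, `n_event`, `n_censor`, `surv`;
#'   `surv` starts at <= 1 and is non-increasing.
#' @examples
#' km_estimate(c(1, 2), c(1, 0))
#' @export
km_estimate <- function(time, event) {
  if (!length(time)) stop("need >= 1 record")
  if (any(time < 0)) stop("negative follow-up time")
  stopifnot(length(time) == length(event), all(event %in% c(0, 1)))
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             n_censor = fit$n.censor, surv = fit$surv)
}

.gbw_stat <- function(time, event, g) {
  # Gehan-Breslow-Wilcoxon: log-rank weighted by the number at risk
  et <- sort(unique(time[event == 1]))
  U <- 0; V <- 0
  for (t in et) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & g)
    d <- sum(event == 1 & time == t)
    d1 <- sum(event == 1 & time == t & g)
    e1 <- d * n1 / n
    U <- U + n * (d1 - e1)
    if (n > 1)
      V <- V + n^2 * d * (n - d) * n1 * (n - n1) / (n^2 * (n - 1))
  }
  c(U = U, V = V)
}

#' Gehan-Breslow-Wilcoxon two-group survival test
#'
#' An at-risk-weighted log-rank test: each event time contributes its
#' observed-minus-expected group-1 events weighted by the total number at
#' risk, which emphasizes early differences. The statistic U^2/V is referred
#' to chi-squared with 1 df; a seeded label-permutation p-value is available
#' for small samples.
#'
#' @param time,event follow-up times and event indicators.
#' @param group two-level group labels (logical, factor, or character).
#' @param permutations number of label permutations (0 = asymptotic only).
#' @param seed optional seed for the permutation draw.
#' @return list with `statistic` (chi-squared), `p` (asymptotic),
#'   and `p_permutation` (NA unless requested).
#' @export
gbw_test <- function(time, event, group, permutations = 0, seed = NULL) {
  stopifnot(length(time) == length(event), length(time) == length(group))
  g <- as.factor(group)
  if (nlevels(g) != 2L) stop("group must have exactly two levels")
  g <- g == levels(g)[1L]
  if (sum(event) == 0) stop("no events in either group")
  uv <- .gbw_stat(time, event, g)
  if (uv["V"] <= 0) stop("degenerate at-risk configuration")
  chi <- unname(uv["U"]^2 / uv["V"])
  p <- pchisq(chi, df = 1, lower.tail = FALSE)
  p_perm <- NA_real_
  if (permutations > 0) {
    if (!is.null(seed)) set.seed(seed)
    exceed <- vapply(seq_len(permutations), function(i) {
      gp <- sample(g)
      uvp <- .gbw_stat(time, event, gp)
      if (uvp["V"] <= 0) return(FALSE)
      uvp["U"]^2 / uvp["V"] >= chi - 1e-12
    }, logical(1))
    p_perm <- (1 + sum(exceed)) / (permutations + 1)
  }
  list(statistic = chi, p = p, p_permutation = p_perm)
}

#' Truncate survival records at a follow-up horizon
#'
#' Records with follow-up beyond `horizon` years are administratively
#' censored at the horizon (an event at 12 y under a 10-y horizon becomes a
#' censoring at 10 y).
#'
#' @param time,event follow-up times and event indicators.
#' @param horizon horizon in years.
#' @return list with truncated `time` and `event`.
#' @export
truncate_followup <- function(time, event, horizon) {
  over <- time > horizon
  event[over] <- 0
  time[over] <- horizon
  list(time = time, event = event)
}

#' Scan NAMS cutoffs for the strongest survival split
#'
#' For each candidate cutoff `c`, splits patients into NAMS >= c vs < c,
#' truncates follow-up at `horizon` years, and records the
#' Gehan-Breslow-Wilcoxon p-value. The best cutoff is the one with the
#' smallest p. Cutoffs yielding an empty group (or no events) are skipped
#' with a warning. Because the best cutoff is selected as the minimum over
#' several tested cutoffs, its p-value is not corrected for this multiplicity
#' — the returned `note` says so and downstream reporting should carry it.
#'
#' @param table data.frame with `nams`, `rfs_time`, `rfs_event` (tumor rows;
#'   rows with missing survival are dropped).
#' @param cutoffs candidate NAMS cutoffs (>= 2), default the decade/half
#'   decade grid 60-90.
#' @param horizon follow-up horizon in years (default 10).
#' @return list with `table` (data.frame: `cutoff`, `n_high`, `n_low`,
#'   `statistic`, `p`), `best_cutoff`, `best_p`, `note`.
#' @export
cutoff_scan <- function(table, cutoffs = c(60, 65, 70, 75, 80, 85, 90),
                        horizon = 10) {
  if (length(cutoffs) < 2L) stop("need >= 2 cutoffs")
  ok <- complete.cases(table$nams, table$rfs_time, table$rfs_event)
  tab <- table[ok, , drop = FALSE]
  tr <- truncate_followup(tab$rfs_time, tab$rfs_event, horizon)
  rows <- lapply(sort(cutoffs), function(cc) {
    high <- tab$nams >= cc
    if (!any(high) || all(high)) {
      warning("cutoff ", cc, " leaves an empty group; skipped")
      return(NULL)
    }
    res <- tryCatch(gbw_test(tr$time, tr$event, high),
                    error = function(e) {
                      warning("cutoff ", cc, " skipped: ", conditionMessage(e))
                      NULL
                    })
    if (is.null(res)) return(NULL)
    data.frame(cutoff = cc, n_high = sum(high), n_low = sum(!high),
               statistic = res$statistic, p = res$p)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows) || nrow(rows) == 0L) stop("no valid cutoff")
  best <- rows$cutoff[which.min(rows$p)]
  list(table = rows, best_cutoff = best, best_p = min(rows$p),
       note = paste("best cutoff selected as minimum p over",
                    nrow(rows), "tested cutoffs; p-values are not",
                    "adjusted for this multiplicity"))
}
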