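#' Average the two methylation probes of a gene
#'
#' Per-sample arithmetic mean of the two raw probe scores, with the
#' inter-probe Spearman correlation reported as a concordance diagnostic
#' (two probes measuring one promoter should correlate strongly; the kind of
#' cohort this targets reports rho near 0.7).
#'
#' @param table cohort data.frame.
#' @param probe_ids length-2 character vector of probe column names.
#' @return list with `table` (input plus an `avg_score` column) and `rho`.
#' @export
average_probes <- function(table, probe_ids = c("probe_a", "probe_b")) {
  stopifnot(length(probe_ids) == 2L)
  missing <- setdiff(probe_ids, names(table))
  if (length(missing)) stop("missing probe column(s): ",
                            paste(missing, collapse = ", "))
  a <- table[[probe_ids[1L]]]; b <- table[[probe_ids[2L]]]
  table$avg_score <- (a + b) / 2
  rho <- suppressWarnings(cor.test(a, b, method = "spearman",
                                   exact = FALSE)$estimate)
  list(table = table, rho = unname(rho))
}

#' Normalize methylation scores to the 0-100 NAMS scale
#'
#' Normalized average methylation scores (NAMS): within each dataset the
#' lowest score maps to 0 and the highest to 100. `mode = "linear"` is a
#' plain affine min-max rescale; `mode = "logistic"` squashes scores through
#' a logistic centred on the dataset mean (steepness `k` in units of the
#' score SD) before anchoring the endpoints at 0/100 — a "sigmoidal"
#' normalization that compresses the extremes. Both modes are strictly
#' rank-preserving.
#'
#' @param scores numeric vector of per-sample average scores.
#' @param mode `"linear"` (default) or `"logistic"`.
#' @param k logistic steepness in units of the score SD (default 1).
#' @param dataset optional factor; normalization is applied within each
#'   dataset independently.
#' @return numeric vector of NAMS values in \[0, 100\].
#' @examples
#' nams_normalize(c(10, 20, 30))            # 0, 50, 100
#' nams_normalize(c(10, 20, 30), "logistic")
#' @export
nams_normalize <- function(scores, mode = c("linear", "logistic"), k = 1,
                           dataset = NULL) {
  mode <- match.arg(mode)
  if (!is.null(dataset)) {
    stopifnot(length(dataset) == length(scores))
    out <- numeric(length(scores))
    for (d in unique(dataset)) {
      i <- dataset == d
      out[i] <- nams_normalize(scores[i], mode = mode, k = k)
    }
    return(out)
  }
  if (length(scores) < 2L || diff(range(scores)) == 0)
    stop("need >= 2 distinct scores to normalize")
  if (mode == "linear") {
    (scores - min(scores)) / diff(range(scores)) * 100
  } else {
    z <- (scores - mean(scores)) / (k * sd(scores))
    l <- plogis(z)
    (l - min(l)) / diff(range(l)) * 100
  }
}

#' Call hyper-/hypomethylation against the normal-group mean
#'
#' The normal reference is the mean NAMS of the normal group. A tumor is
#' called hypermethylated when its NAMS exceeds the reference by strictly
#' more than `margin` (default 30) units, hypomethylated when it falls
#' strictly more than `margin` below, and neutral otherwise. Frequencies are
#' reported overall and per grade.
#'
#' @param table cohort data.frame with columns `sample`, `group`
#'   (`"tumor"`/`"normal"`), `nams`, and optionally `grade`.
#' @param margin calling margin in NAMS units (default 30, strict `>`).
#' @return list with `normal_mean`, `calls` (data.frame: `sample`, `nams`,
#'   `margin` = NAMS - normal mean, `call`), and `frequencies` (data.frame
#'   with one row overall and one per grade: `n`, `hyper_n`, `hyper_pct`,
#'   `hypo_n`, `hypo_pct`, `neutral_n`).
#' @export
call_methylation <- function(table, margin = 30) {
  normals <- table$nams[table$group == "normal"]
  if (!length(normals)) stop("no normal samples: reference mean undefined")
  normal_mean <- mean(normals)
  tum <- table[table$group == "tumor", , drop = FALSE]
  delta <- tum$nams - normal_mean
  call <- ifelse(delta > margin, "hyper",
          ifelse(delta < -margin, "hypo", "neutral"))
  calls <- data.frame(sample = tum$sample, nams = tum$nams, margin = delta,
                      call = call, stringsAsFactors = FALSE)
  freq_row <- function(label, calls_sub) {
    n <- nrow(calls_sub)
    data.frame(stratum = label, n = n,
               hyper_n = sum(calls_sub$call == "hyper"),
               hyper_pct = if (n) sum(calls_sub$call == "hyper") / n * 100 else NA,
               hypo_n = sum(calls_sub$call == "hypo"),
               hypo_pct = if (n) sum(calls_sub$call == "hypo") / n * 100 else NA,
               neutral_n = sum(calls_sub$call == "neutral"),
               stringsAsFactors = FALSE)
  }
  freqs <- freq_row("all", calls)
  if (!is.null(tum$grade)) {
    for (g in sort(unique(tum$grade[!is.na(tum$grade)])))
      freqs <- rbind(freqs, freq_row(paste0("grade_", g),
                                     calls[!is.na(tum$grade) & tum$grade == g, ]))
  }
  list(normal_mean = normal_mean, calls = calls, frequencies = freqs)
}

#' Tumors exceeding the normal maximum
#'
#' Percent of tumors whose NAMS exceeds the highest normal NAMS, plus the
#' difference of group means — the two headline separation summaries for a
#' tumor/normal methylation cohort.
#'
#' @param table cohort data.frame with `group` and `nams`.
#' @return list with `pct_above_normal_max`, `normal_max`,
#'   `mean_difference` (tumor mean - normal mean).
#' @export
above_max_normal <- function(table) {
  tum <- table$nams[table$group == "tumor"]
  nor <- table$nams[table$group == "normal"]
  if (!length(nor)) stop("no normal samples")
  if (!length(tum)) stop("no tumor samples")
  list(pct_above_normal_max = mean(tum > max(nor)) * 100,
       normal_max = max(nor),
       mean_difference = mean(tum) - mean(nor))
}

.roc_sweep <- function(scores, is_tumor) {
  u <- sort(unique(scores))
  thr <- c(-Inf, (u[-1L] + u[-length(u)]) / 2, Inf)
  sens <- vapply(thr, function(t) mean(scores[is_tumor] >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(scores[!is_tumor] < t), numeric(1))
  # trapezoid over (1 - spec, sens); points ordered by decreasing threshold
  fpr <- rev(1 - spec); tpr <- rev(sens)
  auc <- sum(diff(fpr) * (tpr[-1L] + tpr[-length(tpr)]) / 2)
  list(thresholds = thr, sensitivity = sens, specificity = spec, auc = auc)
}

#' Diagnostic ROC for tumor/normal discrimination
#'
#' Empirical ROC over all observed score thresholds (classifying a sample as
#' tumor when score >= threshold), trapezoid AUC (numerically identical to
#' the tie-adjusted Mann-Whitney U scaled by n1 n2), a stratified-bootstrap
#' AUC confidence interval, and a chosen operating point. The default
#' operating rule maximizes sensitivity subject to 100% specificity — the
#' natural rule for a rule-in diagnostic biomarker; Youden's J is available
#' as an alternative.
#'
#' @param table cohort data.frame with `group` and `nams` (or pass `scores`
#'   and `is_tumor`).
#' @param scores,is_tumor alternative vector interface.
#' @param n_boot bootstrap replicates for the AUC CI (default 2000; 0
#'   disables).
#' @param conf CI level (default 0.95).
#' @param operating `"max_spec"` (default) or `"youden"`.
#' @param seed optional seed for the bootstrap.
#' @return object of class `roc_result`: list with `thresholds`,
#'   `sensitivity`, `specificity`, `auc`, `auc_ci`, `operating` (list:
#'   `threshold`, `sensitivity`, `specificity`), `n_tumor`, `n_normal`.
#' @export
roc_discriminate <- function(table = NULL, scores = NULL, is_tumor = NULL,
                             n_boot = 2000, conf = 0.95,
                             operating = c("max_spec", "youden"),
                             seed = NULL) {
  operating <- match.arg(operating)
  if (!is.null(table)) {
    scores <- table$nams
    is_tumor <- table$group == "tumor"
  }
  n1 <- sum(is_tumor); n0 <- sum(!is_tumor)
  if (n1 == 0L || n0 == 0L) stop("both groups must be non-empty")
  sweep <- .roc_sweep(scores, is_tumor)

  finite <- is.finite(sweep$thresholds)
  idx_pool <- which(finite & sweep$specificity == 1)
  idx <- if (operating == "max_spec" && length(idx_pool)) {
    idx_pool[which.max(sweep$sensitivity[idx_pool])]
  } else {
    j <- sweep$sensitivity + sweep$specificity - 1
    j[!finite] <- -Inf
    which.max(j)
  }

  auc_ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    if (!is.null(seed)) set.seed(seed)
    ti <- which(is_tumor); ni <- which(!is_tumor)
    boots <- vapply(seq_len(n_boot), function(i) {
      s <- c(sample(ti, n1, replace = TRUE), sample(ni, n0, replace = TRUE))
      .roc_sweep(scores[s], is_tumor[s])$auc
    }, numeric(1))
    auc_ci <- unname(quantile(boots, c((1 - conf) / 2, 1 - (1 - conf) / 2)))
  }
  structure(list(thresholds = sweep$thresholds,
                 sensitivity = sweep$sensitivity,
                 specificity = sweep$specificity,
                 auc = sweep$auc, auc_ci = auc_ci,
                 operating = list(threshold = sweep$thresholds[idx],
                                  sensitivity = sweep$sensitivity[idx],
                                  specificity = sweep$specificity[idx]),
                 n_tumor = n1, n_normal = n0),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: %d tumor vs %d normal; AUC = %.4f (%.0f%% CI %.4f-%.4f)\n",
              x$n_tumor, x$n_normal, x$auc, 95,
              x$auc_ci[1], x$auc_ci[2]))
  cat(sprintf("Operating point: threshold %.4g, sensitivity %.2f%%, specificity %.2f%%\n",
              x$operating$threshold, x$operating$sensitivity * 100,
              x$operating$specificity * 100))
  invisible(x)
}
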