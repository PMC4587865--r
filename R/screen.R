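#' Per-probe differential response to drug treatment in one cell line
#'
#' Computes, for every probe, the log2 fold change (drug minus vehicle) and a
#' two-sample test p-value within a single cell line. The default test is a
#' shrinkage-variance t in the spirit of the random-variance models used for
#' small-sample microarray class comparison: each probe's pooled variance is
#' moderated toward the across-probe mean variance with `prior_df` prior
#' degrees of freedom, and the statistic is referred to a t distribution with
#' `prior_df + n1 + n2 - 2` df. A plain Welch t is available as a fallback.
#'
#' @param mat log2 expression matrix, probes x samples.
#' @param annotation data.frame with `sample`, `cell_line`, `treatment`
#'   (`"drug"`/`"vehicle"`) as produced by [simulate_expression_screen()] or
#'   [read_expression_matrix()].
#' @param cell_line cell line label to analyse.
#' @param method `"shrinkage"` (default) or `"welch"`.
#' @param prior_df prior degrees of freedom for the shrinkage test.
#' @return data.frame with `probe`, `fold_log2`, `t`, `p`, `fdr`
#'   (Benjamini-Hochberg). `fdr` is monotone non-decreasing in `p`.
#' @examples
#' sim <- simulate_expression_screen(n_probes = 50, n_silenced = 5, seed = 1)
#' head(differential_response(sim$matrix, sim$annotation, "BC1"))
#' @export
differential_response <- function(mat, annotation, cell_line,
                                  method = c("shrinkage", "welch"),
                                  prior_df = 10) {
  method <- match.arg(method)
  ann <- annotation[annotation$cell_line == cell_line, , drop = FALSE]
  if (nrow(ann) == 0L) stop("unknown cell line: ", cell_line)
  drug <- ann$sample[ann$treatment == "drug"]
  veh <- ann$sample[ann$treatment == "vehicle"]
  n1 <- length(drug); n2 <- length(veh)
  if (n1 < 2L || n2 < 2L)
    stop("cell line ", cell_line, " needs >= 2 replicates per treatment arm")
  x <- mat[, drug, drop = FALSE]
  y <- mat[, veh, drop = FALSE]
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  v1 <- apply(x, 1L, var); v2 <- apply(y, 1L, var)
  fold <- m1 - m2

  if (method == "welch") {
    se2 <- v1 / n1 + v2 / n2
    tstat <- fold / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  } else {
    d <- n1 + n2 - 2
    s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / d
    s02 <- mean(s2)                       # pooled prior variance across probes
    s2_mod <- (prior_df * s02 + d * s2) / (prior_df + d)
    tstat <- fold / sqrt(s2_mod * (1 / n1 + 1 / n2))
    df <- prior_df + d
  }
  p <- 2 * pt(-abs(tstat), df)
  data.frame(probe = rownames(mat), fold_log2 = fold, t = tstat, p = p,
             fdr = p.adjust(p, "BH"), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Select candidate methylation-silenced probes across cell lines
#'
#' A probe is a candidate when it responds to the drug — |log2 fold| >=
#' log2(`fold_min`) and p <= `p_max` — in *every* designated cancer line,
#' with the same direction in all of them, and does *not* respond in the
#' non-tumorigenic line. Non-response in the non-tumorigenic line means
#' failing either the fold or the significance criterion, so borderline
#' probes weakly perturbed in the control line are not discarded.
#'
#' @param results named list of [differential_response()] data.frames, one
#'   per cell line.
#' @param cancer_lines names of the cancer cell lines in `results` (>= 1).
#' @param ntb_line name of the single non-tumorigenic line in `results`.
#' @param fold_min minimal linear fold change (default 1.5).
#' @param p_max maximal p-value (default 0.05).
#' @return list with `up` and `down` candidate probe-id vectors and `table`,
#'   a per-probe data.frame of per-line pass flags and the candidate call.
#' @examples
#' sim <- simulate_expression_screen(n_probes = 200, n_silenced = 10, seed = 1)
#' res <- lapply(setNames(nm = unique(sim$annotation$cell_line)),
#'               function(cl) differential_response(sim$matrix,
#'                                                  sim$annotation, cl))
#' sel <- select_candidates(res, c("BC1", "BC2"), "NTB1")
#' length(sel$up)
#' @export
select_candidates <- function(results, cancer_lines, ntb_line,
                              fold_min = 1.5, p_max = 0.05) {
  if (length(results) == 0L) stop("empty results")
  stopifnot(length(cancer_lines) >= 1L, length(ntb_line) == 1L)
  if (!all(c(cancer_lines, ntb_line) %in% names(results)))
    stop("results must contain every cancer line and the non-tumorigenic line")
  lf <- log2(fold_min)
  probes <- results[[1L]]$probe
  responds <- function(r) abs(r$fold_log2) >= lf & r$p <= p_max
  canc <- results[cancer_lines]
  for (r in canc) if (!identical(r$probe, probes))
    stop("probe sets differ between cell lines")
  pass <- vapply(canc, responds, logical(length(probes)))
  pass <- matrix(pass, nrow = length(probes))
  sign_mat <- vapply(canc, function(r) sign(r$fold_log2),
                     numeric(length(probes)))
  sign_mat <- matrix(sign_mat, nrow = length(probes))
  same_dir <- apply(sign_mat, 1L, function(s) all(s == s[1L]))
  all_cancer <- rowSums(pass) == length(cancer_lines) & same_dir
  ntb <- results[[ntb_line]]
  if (!identical(ntb$probe, probes)) stop("probe sets differ between cell lines")
  candidate <- all_cancer & !responds(ntb)
  direction <- ifelse(sign_mat[, 1L] > 0, "up", "down")
  table <- data.frame(probe = probes,
                      pass_all_cancer = all_cancer,
                      responds_ntb = responds(ntb),
                      candidate = candidate,
                      direction = ifelse(candidate, direction, NA_character_),
                      stringsAsFactors = FALSE)
  list(up = probes[candidate & direction == "up"],
       down = probes[candidate & direction == "down"],
       table = table)
}

#' Overlap between two probe/gene sets
#'
#' Partitions two id sets into common and set-specific parts and reports the
#' common fraction of each set as a percentage (|common| / |set| x 100).
#'
#' @param set_a,set_b character vectors of ids.
#' @return list with `common`, `a_specific`, `b_specific`, `pct_a`, `pct_b`.
#' @examples
#' overlap_report(letters[1:10], letters[8:12])
#' @export
overlap_report <- function(set_a, set_b) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  common <- intersect(set_a, set_b)
  list(common = common,
       a_specific = setdiff(set_a, set_b),
       b_specific = setdiff(set_b, set_a),
       pct_a = if (length(set_a)) length(common) / length(set_a) * 100 else NA_real_,
       pct_b = if (length(set_b)) length(common) / length(set_b) * 100 else NA_real_)
}

#' Validate candidates against an external paired drug/vehicle panel
#'
#' For each candidate probe, forms the per-cell-line difference
#' (drug minus vehicle, averaging replicates within each arm) in an external
#' dataset and runs a paired t test across cell lines. Reports the fraction
#' of candidates significantly upregulated externally (p < `p_max` and
#' positive mean difference).
#'
#' @param candidates character vector of probe ids.
#' @param mat external log2 matrix (probes x samples).
#' @param annotation annotation data.frame for `mat` (columns `sample`,
#'   `cell_line`, `treatment`).
#' @param p_max significance threshold (default 0.05).
#' @return list with `per_probe` data.frame (`probe`, `mean_diff`, `p`) and
#'   `fraction_validated`.
#' @export
cross_dataset_validation <- function(candidates, mat, annotation,
                                     p_max = 0.05) {
  lines <- unique(annotation$cell_line)
  if (length(lines) < 3L)
    stop("paired t requires >= 3 drug/vehicle cell-line pairs")
  candidates <- intersect(candidates, rownames(mat))
  diffs <- vapply(lines, function(cl) {
    a <- annotation[annotation$cell_line == cl, ]
    drug <- a$sample[a$treatment == "drug"]
    veh <- a$sample[a$treatment == "vehicle"]
    if (!length(drug) || !length(veh))
      stop("cell line ", cl, " lacks a drug/vehicle pair")
    rowMeans(mat[candidates, drug, drop = FALSE]) -
      rowMeans(mat[candidates, veh, drop = FALSE])
  }, numeric(length(candidates)))
  diffs <- matrix(diffs, nrow = length(candidates),
                  dimnames = list(candidates, lines))
  per_probe <- data.frame(
    probe = candidates,
    mean_diff = rowMeans(diffs),
    p = apply(diffs, 1L, function(d) t.test(d)$p.value),
    row.names = NULL, stringsAsFactors = FALSE)
  list(per_probe = per_probe,
       fraction_validated = mean(per_probe$p < p_max & per_probe$mean_diff > 0))
}
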