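#' Simulate an AZA-reactivation expression screen
#'
#' Generates a log2 expression matrix (probes x samples) for a panel of cell
#' lines treated with a demethylating drug (e.g. 5-aza-2'-deoxycytidine) or
#' vehicle, with replicates. A subset of probes is "silenced by promoter
#' methylation": those probes gain `fold_induced` log2 units in the
#' drug-treated columns of the cancer lines only, emulating reactivation of
#' methylation-silenced genes in cancer but not in non-tumorigenic cells.
#'
#' @param n_probes number of probes.
#' @param n_silenced number of probes reactivated in cancer lines only;
#'   must not exceed `n_probes`.
#' @param n_replicates replicates per (cell line, treatment) arm.
#' @param fold_induced log2 induction added to silenced probes in cancer
#'   lines' drug columns.
#' @param noise_sd residual log2 noise standard deviation (> 0).
#' @param cell_lines named character vector mapping cell-line label to class,
#'   each class one of `"cancer"` or `"non_tumorigenic"`.
#' @param baseline_mean,baseline_sd distribution of per-probe baseline log2
#'   intensity.
#' @param silenced_deficit log2 units subtracted from silenced probes'
#'   baseline in cancer lines' vehicle state (the silenced state).
#' @param seed optional integer seed; identical seeds give identical output.
#'
#' @return A list with components:
#'   \describe{
#'     \item{matrix}{numeric matrix, probes x samples, log2 scale.}
#'     \item{annotation}{data.frame with `sample`, `cell_line`, `class`,
#'       `treatment` (`"drug"`/`"vehicle"`), `replicate`.}
#'     \item{truth}{character vector of silenced probe ids.}
#'   }
#' @examples
#' sim <- simulate_expression_screen(n_probes = 100, n_silenced = 5, seed = 1)
#' dim(sim$matrix)
#' @export
simulate_expression_screen <- function(n_probes = 1000,
                                       n_silenced = 50,
                                       n_replicates = 3,
                                       fold_induced = 2,
                                       noise_sd = 0.3,
                                       cell_lines = c(BC1 = "cancer",
                                                      BC2 = "cancer",
                                                      NTB1 = "non_tumorigenic"),
                                       baseline_mean = 7,
                                       baseline_sd = 1.5,
                                       silenced_deficit = fold_induced,
                                       seed = NULL) {
  stopifnot(n_probes >= 1, n_replicates >= 1, noise_sd > 0,
            n_silenced >= 0, n_silenced <= n_probes)
  if (!all(cell_lines %in% c("cancer", "non_tumorigenic")))
    stop("cell line classes must be 'cancer' or 'non_tumorigenic'")
  if (!is.null(seed)) set.seed(seed)

  probes <- sprintf("probe_%04d", seq_len(n_probes))
  silenced <- if (n_silenced > 0) probes[seq_len(n_silenced)] else character(0)

  annotation <- expand.grid(replicate = seq_len(n_replicates),
                            treatment = c("vehicle", "drug"),
                            cell_line = names(cell_lines),
                            KEEP.OUT.ATTRS = FALSE,
                            stringsAsFactors = FALSE)
  annotation$class <- unname(cell_lines[annotation$cell_line])
  annotation$sample <- paste(annotation$cell_line, annotation$treatment,
                             annotation$replicate, sep = "_")
  annotation <- annotation[, c("sample", "cell_line", "class",
                               "treatment", "replicate")]

  baseline <- rnorm(n_probes, baseline_mean, baseline_sd)
  mat <- matrix(baseline, nrow = n_probes, ncol = nrow(annotation))
  dimnames(mat) <- list(probes, annotation$sample)

  is_sil <- probes %in% silenced
  cancer_cols <- annotation$class == "cancer"
  # silenced state: lower baseline in cancer lines, restored (+fold) under drug
  mat[is_sil, cancer_cols] <- mat[is_sil, cancer_cols] - silenced_deficit
  drug_cancer <- cancer_cols & annotation$treatment == "drug"
  mat[is_sil, drug_cancer] <- mat[is_sil, drug_cancer] + fold_induced
  mat <- mat + rnorm(length(mat), 0, noise_sd)

  list(matrix = mat, annotation = annotation, truth = silenced)
}

#' Simulate bisulfite clone sequences from a reference region
#'
#' Produces the bisulfite image of a reference sequence for each clone:
#' cytosines at declared CpG positions are retained (methylated) with the
#' per-CpG probability, all other cytosines are converted to thymine except
#' for a `conversion_failure_rate` fraction that is retained, and uniform
#' substitution errors are overlaid at `seq_error_rate`.
#'
#' @param reference character scalar, uppercase A/C/G/T reference region.
#' @param cpg_offsets strictly increasing 0-based offsets of CpG cytosines
#'   within `reference`; each must be a `C` followed by `G`.
#' @param per_cpg_meth_prob methylation probability per CpG (recycled to the
#'   number of CpGs); all in \[0, 1\].
#' @param n_clones number of clones to draw (the study design sequences 5
#'   clones per sample).
#' @param conversion_failure_rate probability a non-CpG cytosine escapes
#'   conversion.
#' @param seq_error_rate per-base uniform substitution error probability.
#' @param seed optional integer seed.
#'
#' @return list with `clones` (character vector of clone sequences, named
#'   `clone_1` ...) and `truth` (logical matrix clones x CpGs of planted
#'   methylation states).
#' @examples
#' ref <- "TTCGATCGAA"
#' simulate_bisulfite_clones(ref, c(2, 6), per_cpg_meth_prob = 1,
#'                           n_clones = 2, seed = 1)$clones
#' @export
simulate_bisulfite_clones <- function(reference,
                                      cpg_offsets,
                                      per_cpg_meth_prob = 0.5,
                                      n_clones = 5,
                                      conversion_failure_rate = 0,
                                      seq_error_rate = 0,
                                      seed = NULL) {
  stopifnot(is.character(reference), length(reference) == 1L,
            n_clones >= 1,
            conversion_failure_rate >= 0, conversion_failure_rate <= 1,
            seq_error_rate >= 0, seq_error_rate <= 1)
  bases <- strsplit(reference, "")[[1]]
  n <- length(bases)
  if (length(cpg_offsets) &&
      (any(diff(cpg_offsets) <= 0) || min(cpg_offsets) < 0 ||
       max(cpg_offsets) >= n))
    stop("cpg_offsets must be strictly increasing and within the reference")
  idx <- cpg_offsets + 1L
  bad <- which(bases[idx] != "C" | c(bases, "N")[idx + 1L] != "G")
  if (length(bad))
    stop("offset(s) ", paste(cpg_offsets[bad], collapse = ", "),
         " are not CpG-dinucleotide cytosines in the reference")
  p <- rep_len(per_cpg_meth_prob, length(cpg_offsets))
  if (any(p < 0 | p > 1)) stop("per_cpg_meth_prob must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)

  non_cpg_c <- setdiff(which(bases == "C"), idx)
  truth <- matrix(FALSE, n_clones, length(cpg_offsets),
                  dimnames = list(sprintf("clone_%d", seq_len(n_clones)),
                                  as.character(cpg_offsets)))
  clones <- character(n_clones)
  alphabet <- c("A", "C", "G", "T")
  for (k in seq_len(n_clones)) {
    b <- bases
    meth <- runif(length(idx)) < p
    truth[k, ] <- meth
    b[idx[!meth]] <- "T"                       # unmethylated CpG C converts
    retain <- runif(length(non_cpg_c)) < conversion_failure_rate
    b[non_cpg_c[!retain]] <- "T"               # conversion of non-CpG Cs
    if (seq_error_rate > 0) {
      err <- which(runif(n) < seq_error_rate)
      for (i in err) b[i] <- sample(setdiff(alphabet, b[i]), 1L)
    }
    clones[k] <- paste(b, collapse = "")
  }
  names(clones) <- rownames(truth)
  list(clones = clones, truth = truth)
}

#' Simulate an array-methylation cohort with survival follow-up
#'
#' Emulates a two-probe promoter-methylation cohort on a 27K-style 0-100
#' methylation-score scale: per-sample latent scores are drawn from a
#' truncated-normal mixture (bimodal in tumors, low unimodal in normals),
#' two correlated probe scores are derived from the latent score plus
#' independent noise, and relapse-free survival is drawn from an exponential
#' model whose hazard is multiplied by `hazard_ratio` in the high-methylation
#' group. Censoring is exponential, calibrated to the requested rate.
#'
#' The high-methylation (truth) group is by default the tumor mixture
#' component with the highest mean (`hazard_on = "component"`). With
#' `hazard_on = "nams_step"` the hazard step is instead planted exactly at
#' `nams_step` on the cohort's linearly normalized score (NAMS) scale, which
#' is the configuration used to test cutoff recovery.
#'
#' @param n_tumor,n_normal group sizes; `n_normal` must be >= 1 (downstream
#'   calling needs a normal reference).
#' @param tumor_means,tumor_sds,tumor_weights tumor mixture parameters on the
#'   raw 0-100 scale (weights normalized internally).
#' @param normal_means,normal_sds,normal_weights normal mixture parameters.
#' @param probe_noise_sd independent per-probe noise around the latent score;
#'   the default gives an inter-probe Spearman correlation near 0.7.
#' @param score_range raw score clipping range.
#' @param baseline_hazard events per year in the low-methylation group.
#' @param hazard_ratio multiplicative hazard for the high-methylation group
#'   (> 0).
#' @param censoring_rate target fraction of censored records.
#' @param follow_up administrative censoring horizon in years.
#' @param hazard_on `"component"` (truth group = top tumor mixture component)
#'   or `"nams_step"` (truth group = NAMS >= `nams_step`).
#' @param nams_step NAMS threshold for `hazard_on = "nams_step"`.
#' @param seed optional integer seed.
#'
#' @return list with `table` (data.frame: `sample`, `group`, `probe_a`,
#'   `probe_b`, `avg_score`, `nams` (linear min-max, for convenience),
#'   `grade`, `rfs_time`, `rfs_event`) and `truth` (logical vector, TRUE for
#'   high-methylation tumors; FALSE for all normals).
#' @examples
#' coh <- simulate_cohort(n_tumor = 50, n_normal = 10, seed = 1)
#' table(coh$table$group)
#' @export
simulate_cohort <- function(n_tumor = 338,
                            n_normal = 33,
                            tumor_means = c(75, 45),
                            tumor_sds = c(8, 8),
                            tumor_weights = c(0.8, 0.2),
                            normal_means = 40,
                            normal_sds = 8,
                            normal_weights = 1,
                            probe_noise_sd = 10,
                            score_range = c(0, 100),
                            baseline_hazard = 0.03,
                            hazard_ratio = 3,
                            censoring_rate = 0.3,
                            follow_up = 15,
                            hazard_on = c("component", "nams_step"),
                            nams_step = 80,
                            seed = NULL) {
  hazard_on <- match.arg(hazard_on)
  stopifnot(n_tumor >= 1, hazard_ratio > 0, baseline_hazard > 0,
            censoring_rate >= 0, censoring_rate < 1)
  if (n_normal < 1)
    stop("n_normal must be >= 1: downstream calling needs a normal reference")
  if (!is.null(seed)) set.seed(seed)

  draw_mixture <- function(n, means, sds, weights) {
    weights <- weights / sum(weights)
    comp <- sample(seq_along(means), n, replace = TRUE, prob = weights)
    list(value = rnorm(n, means[comp], sds[comp]), component = comp)
  }
  tum <- draw_mixture(n_tumor, tumor_means, tumor_sds, tumor_weights)
  nor <- draw_mixture(n_normal, normal_means, normal_sds, normal_weights)
  latent <- c(tum$value, nor$value)
  n <- n_tumor + n_normal
  clip <- function(x) pmin(pmax(x, score_range[1]), score_range[2])
  probe_a <- clip(latent + rnorm(n, 0, probe_noise_sd))
  probe_b <- clip(latent + rnorm(n, 0, probe_noise_sd))
  avg <- (probe_a + probe_b) / 2
  nams <- (avg - min(avg)) / (max(avg) - min(avg)) * 100

  group <- rep(c("tumor", "normal"), c(n_tumor, n_normal))
  high <- switch(hazard_on,
    component = c(tum$component == which.max(tumor_means),
                  rep(FALSE, n_normal)),
    nams_step = nams >= nams_step & group == "tumor")

  hazard <- baseline_hazard * ifelse(high, hazard_ratio, 1)
  t_event <- rexp(n, hazard)
  # exponential censoring: for T~Exp(a), C~Exp(b), P(censored) = b/(a+b)
  if (censoring_rate > 0) {
    b <- mean(hazard) * censoring_rate / (1 - censoring_rate)
    t_cens <- rexp(n, b)
  } else t_cens <- rep(Inf, n)
  t_cens <- pmin(t_cens, follow_up)
  rfs_time <- pmin(t_event, t_cens)
  rfs_event <- as.integer(t_event <= t_cens)

  grade <- rep(NA_integer_, n)
  grade[group == "tumor"] <- sample(1:3, n_tumor, replace = TRUE,
                                    prob = c(0.2, 0.17, 0.63))
  table <- data.frame(
    sample = sprintf("s_%04d", seq_len(n)),
    group = group,
    probe_a = probe_a,
    probe_b = probe_b,
    avg_score = avg,
    nams = nams,
    grade = grade,
    rfs_time = rfs_time,
    rfs_event = rfs_event,
    stringsAsFactors = FALSE)
  list(table = table, truth = high)
}
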