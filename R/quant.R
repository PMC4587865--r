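#' Two-sided Mann-Whitney U test
#'
#' Wraps [stats::wilcox.test()] with the package's small-sample policy: the
#' exact distribution is used when both groups have n <= 20 and the pooled
#' data are tie-free; otherwise the tie-corrected normal approximation.
#'
#' @param a,b numeric vectors (non-empty).
#' @return list with `statistic` (U, for the first group) and `p`.
#' @examples
#' mann_whitney_test(c(1, 2, 3), c(4, 5, 6))  # exact p = 0.1
#' @export
mann_whitney_test <- function(a, b) {
  if (!length(a) || !length(b)) stop("empty group")
  exact <- length(a) <= 20 && length(b) <= 20 && !any(duplicated(c(a, b)))
  res <- suppressWarnings(wilcox.test(a, b, exact = exact, correct = !exact))
  list(statistic = unname(res$statistic), p = res$p.value)
}

#' Two-sided Wilcoxon signed-rank test
#'
#' Signed-rank test on paired differences. Zero differences are dropped
#' (standard practice); if all differences are zero the test is degenerate
#' and p = 1 is returned with a warning. For n <= 25 the exact sign-flip
#' distribution of the statistic is computed by convolution over (mid)ranks
#' — identical to [stats::wilcox.test()]'s exact p when the absolute
#' differences are tie-free, and still exact (conditional on the observed
#' midranks) when they are tied. Larger n uses the tie-corrected normal
#' approximation.
#'
#' @param d numeric vector of paired differences (or pass `x` and `y`).
#' @param x,y alternative paired-sample interface; `d = x - y`.
#' @return list with `statistic` (V, sum of positive ranks) and `p`.
#' @examples
#' wilcoxon_paired_test(c(0.3, 0.5, 0.2, 0.4, 0.1))  # exact p = 2/2^5
#' @export
wilcoxon_paired_test <- function(d, x = NULL, y = NULL) {
  if (!is.null(x)) {
    if (is.null(y) || length(x) != length(y)) stop("x and y must be paired")
    d <- x - y
  }
  d <- d[!is.na(d)]
  if (!length(d)) stop("no non-missing differences")
  dz <- d[d != 0]
  if (!length(dz)) {
    warning("all paired differences are zero; p reported as 1")
    return(list(statistic = NA_real_, p = 1))
  }
  n <- length(dz)
  r <- rank(abs(dz))
  v <- sum(r[dz > 0])
  if (n <= 25) {
    # exact null distribution of 2V (doubled so midranks are integers)
    r2 <- as.integer(round(2 * r))
    dist <- 1                                  # counts over achievable 2V
    for (rr in r2) {
      grown <- c(dist, numeric(rr))
      grown[(rr + 1):(rr + length(dist))] <-
        grown[(rr + 1):(rr + length(dist))] + dist
      dist <- grown
    }
    v2 <- as.integer(round(2 * v))
    cdf <- cumsum(dist) / 2^n
    p_le <- cdf[v2 + 1]
    p_ge <- 1 - if (v2 >= 1) cdf[v2] else 0
    p <- min(1, 2 * min(p_le, p_ge))
  } else {
    res <- suppressWarnings(wilcox.test(dz, exact = FALSE, correct = TRUE))
    p <- res$p.value
  }
  list(statistic = v, p = p)
}

#' Spearman rank correlation with small-sample exact p
#'
#' Wraps [stats::cor.test()] (method "spearman"); exact p for n <= 9 without
#' ties, t approximation otherwise. Errors on constant input, where the rank
#' correlation is undefined.
#'
#' @param x,y paired numeric vectors.
#' @return list with `rho` and `p`.
#' @examples
#' spearman_test(1:5, c(5, 4, 3, 2, 1))  # rho = -1
#' @export
spearman_test <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired")
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(unique(x)) < 2L || length(unique(y)) < 2L)
    stop("constant input: Spearman correlation undefined")
  exact <- length(x) <= 9 && !any(duplicated(x)) && !any(duplicated(y))
  res <- suppressWarnings(cor.test(x, y, method = "spearman", exact = exact))
  list(rho = unname(res$estimate), p = res$p.value)
}

.mean_ct <- function(ct, max_spread = 0.5, label = "measurement") {
  ct <- ct[!is.na(ct)]
  if (!length(ct)) stop("no Ct values for ", label)
  if (any(ct <= 0)) stop("Ct values must be positive")
  if (length(ct) > 1L && diff(range(ct)) > max_spread)
    warning("replicate Ct spread ", round(diff(range(ct)), 2), " cycles for ",
            label, " exceeds ", max_spread)
  mean(ct)
}

#' Efficiency-corrected delta-Ct relative expression
#'
#' Relative quantification with per-primer amplification efficiencies: the
#' target quantity is `E_target^(-Ct_target)` and the reference quantity is
#' the geometric mean of `E_ref^(-Ct_ref)` over the reference genes (with a
#' single reference this reduces to the classic delta-Ct ratio; with E = 2
#' everywhere it is the textbook `2^(-dCt)`). Replicate Cts are averaged
#' first; spreads beyond `max_spread` cycles are flagged.
#'
#' @param ct_target replicate Ct values for the target gene.
#' @param ct_ref replicate Cts for the reference gene(s): numeric vector
#'   (one reference) or list of numeric vectors (one per reference gene).
#' @param e_target amplification factor per cycle for the target primer pair
#'   (2 = perfect doubling; must be in (1, 2.2\]).
#' @param e_ref efficiency per reference gene (recycled).
#' @param max_spread allowed replicate Ct spread in cycles before flagging.
#' @return list with `value` (linear relative expression, > 0), `log2_value`,
#'   `target_quantity`, `reference_quantity`.
#' @examples
#' relative_expression(25, 22)$value  # 2^-3 = 0.125
#' @export
relative_expression <- function(ct_target, ct_ref, e_target = 2, e_ref = 2,
                                max_spread = 0.5) {
  check_e <- function(e) if (any(e <= 1 | e > 2.2))
    stop("efficiencies must be in (1, 2.2]")
  check_e(e_target)
  if (!is.list(ct_ref)) ct_ref <- list(ct_ref)
  if (!length(ct_ref)) stop("at least one reference gene required")
  e_ref <- rep_len(e_ref, length(ct_ref))
  check_e(e_ref)
  q_t <- e_target^(-.mean_ct(ct_target, max_spread, "target"))
  q_r <- mapply(function(ct, e) e^(-.mean_ct(ct, max_spread, "reference")),
                ct_ref, e_ref)
  ref <- exp(mean(log(q_r)))              # geometric mean over references
  value <- q_t / ref
  list(value = value, log2_value = log2(value),
       target_quantity = q_t, reference_quantity = ref)
}

#' Group summary of relative expression values
#'
#' Average relative expression (ARE, arithmetic mean on the linear scale)
#' with its SEM per group, the ratio of group AREs, and a nonparametric test
#' on the log2 values: Mann-Whitney for independent groups, Wilcoxon
#' signed-rank when `paired = TRUE` (values matched by position).
#'
#' @param values_a,values_b linear-scale relative expression values (> 0).
#' @param paired logical; paired samples must be equal length and ordered
#'   identically.
#' @return list with `are_a`, `sem_a`, `are_b`, `sem_b`, `ratio`
#'   (are_a / are_b), `p`.
#' @export
group_summary <- function(values_a, values_b, paired = FALSE) {
  if (any(c(values_a, values_b) <= 0))
    stop("relative expression values must be positive")
  if (length(values_a) < 2L || length(values_b) < 2L)
    stop("need >= 2 values per group")
  if (paired && length(values_a) != length(values_b))
    stop("paired groups must have matched lengths")
  sem <- function(x) sd(x) / sqrt(length(x))
  test <- if (paired) wilcoxon_paired_test(log2(values_a) - log2(values_b))
          else mann_whitney_test(log2(values_a), log2(values_b))
  list(are_a = mean(values_a), sem_a = sem(values_a),
       are_b = mean(values_b), sem_b = sem(values_b),
       ratio = mean(values_a) / mean(values_b),
       p = test$p)
}

#' Immunohistochemistry H-score
#'
#' H = 1 x p1 + 2 x p2 + 3 x p3 for the percentages of cells staining at
#' intensities 0-3 (percentages must sum to 100 within 0.5); range 0-300.
#'
#' @param p0,p1,p2,p3 percentages of cells at intensities 0, 1, 2, 3.
#' @return list with `h_score` and `percents`.
#' @examples
#' h_score(0, 50, 50, 0)$h_score  # 150
#' @export
h_score <- function(p0, p1, p2, p3) {
  p <- c(p0, p1, p2, p3)
  if (any(p < 0)) stop("percentages must be non-negative")
  if (abs(sum(p) - 100) > 0.5)
    stop("intensity percentages must sum to 100 (got ", sum(p), ")")
  list(h_score = 1 * p1 + 2 * p2 + 3 * p3,
       percents = setNames(p, paste0("intensity_", 0:3)))
}
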