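#' Build a bisulfite reference for a promoter region
#'
#' Bundles a region subsequence with its CpG cytosine offsets and the fully
#' converted image (every non-CpG C replaced by T), which is what a clone
#' with no methylation and complete conversion should read as.
#'
#' @param region list as returned by [extract_region()], or a character
#'   sequence (then `cpg_offsets` must be given).
#' @param cpg_offsets 0-based CpG cytosine offsets; defaults to
#'   `region$cpg_offsets`.
#' @return object of class `bisulfite_reference`: list with `sequence`,
#'   `cpg_offsets`, `converted`.
#' @examples
#' bisulfite_reference("TTCGATCGAC", c(2, 6))$converted
#' @export
bisulfite_reference <- function(region, cpg_offsets = NULL) {
  if (is.list(region)) {
    seq <- region$sequence
    if (is.null(cpg_offsets)) cpg_offsets <- region$cpg_offsets
  } else seq <- as.character(region)
  b <- strsplit(toupper(seq), "")[[1]]
  idx <- cpg_offsets + 1L
  if (any(b[idx] != "C"))
    stop("cpg_offsets must point at cytosines")
  conv <- b
  conv[setdiff(which(b == "C"), idx)] <- "T"
  structure(list(sequence = paste(b, collapse = ""),
                 cpg_offsets = as.integer(cpg_offsets),
                 converted = paste(conv, collapse = "")),
            class = "bisulfite_reference")
}

.bisulfite_submat <- function(match = 1, mismatch = -1) {
  m <- matrix(mismatch, 5, 5,
              dimnames = list(c("A", "C", "G", "T", "N"),
                              c("A", "C", "G", "T", "N")))
  diag(m) <- match
  m["C", "T"] <- match   # reference C read as T: bisulfite conversion
  m[, "N"] <- m["N", ] <- 0
  m
}

#' Align a bisulfite clone to the reference and call CpG methylation
#'
#' Global (Needleman-Wunsch) alignment of a clone sequence against the
#' unconverted reference with bisulfite-aware scoring: a reference C aligned
#' to a clone T scores as a match (conversion), the reverse does not. At each
#' reference CpG cytosine the aligned clone base gives the call: C is
#' methylated, T unmethylated, anything else (gap, substitution) missing.
#' The conversion rate is the fraction of aligned non-CpG reference
#' cytosines read as T (over those read as C or T), and identity is the
#' fraction of alignment columns that match under bisulfite-aware scoring.
#' Clones with identity below `identity_floor` are flagged non-specific
#' (`valid = FALSE`).
#'
#' Scoring: match 1, mismatch -1, gap open -2, gap extend -0.5 per base
#' (a gap of length L scores -(2 + 0.5 L)).
#'
#' @param clone clone sequence (character or `DNAString`).
#' @param ref [bisulfite_reference()] object.
#' @param match,mismatch,gap_open,gap_ext alignment scoring parameters.
#' @param identity_floor hard identity floor below which the clone is
#'   rejected as non-specific (default 0.6).
#' @return object of class `clone_alignment`: list with `calls` (factor
#'   `methylated`/`unmethylated`/`missing`, one per reference CpG),
#'   `conversion_rate`, `identity`, `valid`, `score`.
#' @examples
#' ref <- bisulfite_reference("TTCGATCGAC", c(2, 6))
#' align_clone(ref$converted, ref)$calls
#' @export
align_clone <- function(clone, ref, match = 1, mismatch = -1,
                        gap_open = 2, gap_ext = 0.5,
                        identity_floor = 0.6) {
  stopifnot(inherits(ref, "bisulfite_reference"))
  clone <- toupper(as.character(clone))
  if (!nzchar(clone)) stop("empty clone sequence")
  pa <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(ref$sequence),
    subject = Biostrings::DNAString(clone),
    substitutionMatrix = .bisulfite_submat(match, mismatch),
    gapOpening = gap_open, gapExtension = gap_ext, type = "global")
  ap <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  as_ <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]

  # walk alignment columns; map each reference position to its clone base
  ref_pos <- cumsum(ap != "-")           # reference coordinate per column
  ref_cols <- which(ap != "-")
  clone_base <- as_[ref_cols]            # clone base (or "-") per ref position

  cpg_idx <- ref$cpg_offsets + 1L
  at_cpg <- clone_base[cpg_idx]
  calls <- factor(ifelse(at_cpg == "C", "methylated",
                  ifelse(at_cpg == "T", "unmethylated", "missing")),
                  levels = c("methylated", "unmethylated", "missing"))

  ref_b <- strsplit(ref$sequence, "")[[1]]
  non_cpg_c <- setdiff(which(ref_b == "C"), cpg_idx)
  at_c <- clone_base[non_cpg_c]
  n_conv <- sum(at_c == "T"); n_ret <- sum(at_c == "C")
  conversion_rate <- if (n_conv + n_ret > 0) n_conv / (n_conv + n_ret) else NA_real_

  col_match <- (ap == as_ & ap != "-") | (ap == "C" & as_ == "T")
  identity <- sum(col_match) / length(ap)

  structure(list(calls = calls,
                 conversion_rate = conversion_rate,
                 identity = identity,
                 valid = identity >= identity_floor,
                 score = Biostrings::score(pa)),
            class = "clone_alignment")
}

#' Quality-filter clone alignments
#'
#' Excludes clones whose bisulfite conversion rate or alignment identity
#' falls below QC thresholds (defaults follow common clone-QC practice:
#' conversion >= 95%, identity >= 90%). Clones flagged non-specific at
#' alignment time are always excluded. Filtering never alters the calls of
#' retained clones.
#'
#' @param alignments list of [align_clone()] results.
#' @param min_conversion minimal conversion rate (default 0.95).
#' @param min_identity minimal alignment identity (default 0.9).
#' @return list with `retained` (alignments passing QC), `report`
#'   (data.frame: `clone`, `conversion_rate`, `identity`, `retained`,
#'   `reason`), and `valid` (FALSE when no clone survives — the sample is
#'   unusable).
#' @export
qc_filter <- function(alignments, min_conversion = 0.95, min_identity = 0.9) {
  nm <- names(alignments)
  if (is.null(nm)) nm <- sprintf("clone_%d", seq_along(alignments))
  rows <- lapply(seq_along(alignments), function(i) {
    a <- alignments[[i]]
    reasons <- character(0)
    if (!a$valid) reasons <- c(reasons, "non_specific")
    if (!is.na(a$conversion_rate) && a$conversion_rate < min_conversion)
      reasons <- c(reasons, "low_conversion")
    if (a$identity < min_identity) reasons <- c(reasons, "low_identity")
    data.frame(clone = nm[i], conversion_rate = a$conversion_rate,
               identity = a$identity, retained = length(reasons) == 0L,
               reason = paste(reasons, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rows)
  retained <- alignments[report$retained]
  names(retained) <- nm[report$retained]
  if (length(retained) == 0L)
    warning("all clones failed QC; sample flagged invalid")
  list(retained = retained, report = report, valid = length(retained) > 0L)
}

#' Per-CpG and overall methylation of a clone sample
#'
#' Per-CpG methylation fractions over non-missing calls, and the overall
#' percent methylation pooling every non-missing call across clones and
#' CpGs (methylated / (methylated + unmethylated) x 100). When no calls are
#' missing this equals the average clone methylation — the conventional
#' "average of 5 clones".
#'
#' @param alignments list of retained [align_clone()] results (>= 1).
#' @return list with `per_cpg` (numeric vector of fractions, NA where a CpG
#'   has no callable clone), `n_methylated`, `n_unmethylated`, `percent`.
#' @examples
#' ref <- bisulfite_reference("TTCGATCGAC", c(2, 6))
#' a <- align_clone(ref$converted, ref)
#' sample_methylation(list(a))$percent
#' @export
sample_methylation <- function(alignments) {
  if (length(alignments) == 0L) stop("no retained clones")
  calls <- vapply(alignments, function(a) as.character(a$calls),
                  character(length(alignments[[1L]]$calls)))
  calls <- matrix(calls, ncol = length(alignments))
  meth <- rowSums(calls == "methylated")
  unmeth <- rowSums(calls == "unmethylated")
  per_cpg <- ifelse(meth + unmeth > 0, meth / (meth + unmeth), NA_real_)
  n_m <- sum(meth); n_u <- sum(unmeth)
  if (n_m + n_u == 0L) stop("zero callable CpGs in sample")
  list(per_cpg = per_cpg, n_methylated = n_m, n_unmethylated = n_u,
       percent = n_m / (n_m + n_u) * 100)
}

#' Compare per-sample methylation between two groups (Mann-Whitney)
#'
#' Two-sided Mann-Whitney test on per-sample overall methylation percents,
#' e.g. cancer vs non-tumorigenic cell-line panels. Exact p for small
#' tie-free samples, normal approximation otherwise (see
#' [mann_whitney_test()]).
#'
#' @param percents_a,percents_b numeric vectors of per-sample percents
#'   (>= 2 each).
#' @return list with `statistic` (U) and `p`.
#' @export
compare_methylation_groups <- function(percents_a, percents_b) {
  if (length(percents_a) < 2L || length(percents_b) < 2L)
    stop("need >= 2 samples per group")
  mann_whitney_test(percents_a, percents_b)
}

#' Paired tumor/normal comparison over per-CpG fractions (Wilcoxon)
#'
#' Two-sided Wilcoxon signed-rank test on the paired per-CpG methylation
#' fractions of one tumor/normal tissue pair. The CpGs are the replicated
#' unit within a pair: a pair is significantly hyper(hypo)methylated when
#' the fractions shift consistently across its CpGs. Zero differences are
#' dropped; if every difference is zero the comparison is degenerate and
#' p = 1 is returned with a warning.
#'
#' @param fractions_tumor,fractions_normal per-CpG fraction vectors on the
#'   same CpG grid (equal length; NAs dropped pairwise).
#' @return list with `statistic` (V), `p`, and `direction` (`"hyper"`,
#'   `"hypo"`, or `"none"`, from the median difference).
#' @export
compare_methylation_paired <- function(fractions_tumor, fractions_normal) {
  if (length(fractions_tumor) != length(fractions_normal))
    stop("mismatched CpG grids")
  ok <- complete.cases(fractions_tumor, fractions_normal)
  d <- fractions_tumor[ok] - fractions_normal[ok]
  res <- wilcoxon_paired_test(d)
  dir <- if (res$p > 1 - 1e-12 && all(d == 0)) "none"
         else if (median(d[d != 0]) > 0) "hyper" else "hypo"
  c(res, list(direction = dir))
}

#' Correlate methylation with expression (Spearman)
#'
#' Spearman rank correlation between per-sample methylation percents and
#' log2 expression values, the standard check that promoter methylation
#' tracks transcriptional silencing.
#'
#' @param methylation,expression paired numeric vectors, n >= 5.
#' @return list with `rho` and `p` (exact for n <= 9 without ties).
#' @export
correlate_methylation_expression <- function(methylation, expression) {
  if (length(methylation) != length(expression))
    stop("vectors must be paired")
  if (length(methylation) < 5L) stop("need n >= 5 pairs")
  spearman_test(methylation, expression)
}

#' Render a clone methylation grid as lollipop-style text
#'
#' One row per clone, one column per CpG: `o` methylated, `.` unmethylated,
#' `-` missing (a text rendering of the usual filled/empty lollipop circles).
#'
#' @param alignments list of [align_clone()] results.
#' @return character vector, one string per clone, named by clone.
#' @export
methylation_grid <- function(alignments) {
  vapply(alignments, function(a) {
    paste(c(methylated = "o", unmethylated = ".",
            missing = "-")[as.character(a$calls)], collapse = "")
  }, character(1))
}
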