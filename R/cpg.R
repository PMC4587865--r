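#' Detect CpG islands by sliding-window scan
#'
#' Classic sliding-window CpG-island detection in the Gardiner-Garden &
#' Frommer style: windows of `window` bases advanced by `step` are kept when
#' GC fraction >= `gc_min` and observed/expected CpG >= `oe_min` (expected =
#' countC x countG / window length); overlapping passing windows are merged,
#' and merged runs of at least `min_length` bases are reported with
#' whole-island statistics.
#'
#' @param seq character scalar or `Biostrings::DNAString`, uppercase A/C/G/T/N.
#' @param min_length minimal island length (default 200).
#' @param gc_min minimal GC fraction (default 0.5).
#' @param oe_min minimal observed/expected CpG ratio (default 0.6).
#' @param window,step scan window size and step (defaults 200, 1).
#' @return data.frame with `start`, `end` (0-based, half-open),
#'   `length`, `gc_fraction`, `obs_exp_cpg`, one row per island; zero rows if
#'   none. Islands never overlap.
#' @examples
#' find_cpg_islands(strrep("CG", 200))
#' @export
find_cpg_islands <- function(seq, min_length = 200, gc_min = 0.5,
                             oe_min = 0.6, window = 200, step = 1) {
  s <- toupper(as.character(seq))
  n <- nchar(s)
  if (window > n) stop("window larger than sequence length")
  b <- strsplit(s, "")[[1]]
  is_c <- b == "C"; is_g <- b == "G"
  is_cg <- c(is_c[-n] & is_g[-1L], FALSE)    # CpG starting at each position
  cum_c <- cumsum(is_c); cum_g <- cumsum(is_g); cum_cg <- cumsum(is_cg)
  rng <- function(cum, i, j) cum[j] - c(0, cum)[i]   # vectorized cum[j]-cum[i-1]
  starts <- seq(1L, n - window + 1L, by = step)
  cs <- rng(cum_c, starts, starts + window - 1L)
  gs <- rng(cum_g, starts, starts + window - 1L)
  # dinucleotides fully inside the window start at positions i .. i+w-2
  cgs <- rng(cum_cg, starts, starts + window - 2L)
  gc <- (cs + gs) / window
  exp_cpg <- cs * gs / window
  oe <- ifelse(exp_cpg > 0, cgs / exp_cpg, 0)
  pass <- gc >= gc_min & oe >= oe_min

  if (!any(pass)) {
    return(data.frame(start = integer(0), end = integer(0),
                      length = integer(0), gc_fraction = numeric(0),
                      obs_exp_cpg = numeric(0)))
  }
  # merge overlapping passing windows into runs
  covered <- rep(FALSE, n)
  for (i in which(pass)) covered[starts[i]:(starts[i] + window - 1L)] <- TRUE
  r <- rle(covered)
  ends1 <- cumsum(r$lengths)
  starts1 <- ends1 - r$lengths + 1L
  keep <- r$values & r$lengths >= min_length
  if (!any(keep)) {
    return(data.frame(start = integer(0), end = integer(0),
                      length = integer(0), gc_fraction = numeric(0),
                      obs_exp_cpg = numeric(0)))
  }
  i1 <- starts1[keep]; i2 <- ends1[keep]
  len <- i2 - i1 + 1L
  isl_c <- rng(cum_c, i1, i2); isl_g <- rng(cum_g, i1, i2)
  isl_cg <- rng(cum_cg, i1, pmax(i1, i2 - 1L))
  isl_exp <- isl_c * isl_g / len
  data.frame(start = i1 - 1L, end = i2,          # 0-based half-open
             length = len,
             gc_fraction = (isl_c + isl_g) / len,
             obs_exp_cpg = ifelse(isl_exp > 0, isl_cg / isl_exp, 0),
             row.names = NULL)
}

#' Extract a TSS-relative promoter region and its CpG positions
#'
#' Coordinates are plain integer offsets relative to the transcription start
#' site: position 0 is the TSS base, negative positions are upstream,
#' positive downstream, and the extracted region spans `start_rel` ..
#' `end_rel` inclusive (length `end_rel - start_rel + 1`; -290..+117 spans
#' 408 bases). This convention is used consistently across the package.
#'
#' @param seq character scalar or `DNAString`, the promoter-containing
#'   sequence.
#' @param tss_offset 0-based index of the TSS base within `seq`.
#' @param start_rel,end_rel TSS-relative region bounds (inclusive),
#'   `start_rel <= end_rel`.
#' @return list with `sequence` (character), `start_rel`, `end_rel`, and
#'   `cpg_offsets` — 0-based positions within the extracted region of
#'   cytosines followed by G inside the region.
#' @examples
#' reg <- extract_region("AACGTTACGT", tss_offset = 4, -3, 4)
#' reg$cpg_offsets
#' @export
extract_region <- function(seq, tss_offset, start_rel, end_rel) {
  s <- toupper(as.character(seq))
  n <- nchar(s)
  stopifnot(tss_offset >= 0, tss_offset < n, start_rel <= end_rel)
  i1 <- tss_offset + start_rel + 1L          # 1-based sequence index
  i2 <- tss_offset + end_rel + 1L
  if (i1 < 1L || i2 > n)
    stop("region ", start_rel, "..", end_rel, " out of sequence bounds")
  sub <- substring(s, i1, i2)
  b <- strsplit(sub, "")[[1]]
  m <- length(b)
  cpg <- if (m >= 2L) which(b[-m] == "C" & b[-1L] == "G") - 1L else integer(0)
  list(sequence = sub, start_rel = start_rel, end_rel = end_rel,
       cpg_offsets = as.integer(cpg))
}

#' Flag candidates whose promoter carries a CpG island
#'
#' Runs [find_cpg_islands()] on each candidate's promoter sequence and flags
#' the candidate when at least one island overlaps the promoter window
#' \[TSS - `w_up`, TSS + `w_down`\].
#'
#' @param promoters named list; each element a list with `sequence`
#'   (character) and `tss_offset` (0-based TSS index).
#' @param w_up,w_down promoter window extent upstream/downstream of the TSS
#'   in bases (defaults 1500 and 500).
#' @param ... passed to [find_cpg_islands()].
#' @return data.frame with `candidate`, `n_islands` (overlapping the
#'   window), `flagged`.
#' @export
annotate_candidates <- function(promoters, w_up = 1500, w_down = 500, ...) {
  if (is.null(names(promoters)) || any(names(promoters) == ""))
    stop("promoters must be a named list")
  rows <- lapply(names(promoters), function(id) {
    p <- promoters[[id]]
    if (is.null(p$sequence))
      stop("missing promoter sequence for candidate ", id)
    isl <- find_cpg_islands(p$sequence, ...)
    win1 <- max(0L, p$tss_offset - w_up)             # 0-based half-open
    win2 <- min(nchar(as.character(p$sequence)), p$tss_offset + w_down + 1L)
    hit <- isl$start < win2 & isl$end > win1
    data.frame(candidate = id, n_islands = sum(hit), flagged = any(hit),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
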