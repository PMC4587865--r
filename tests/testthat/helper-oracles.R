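# Independent brute-force oracles used across the test files. These are
# deliberately naive (full enumeration, quadratic pair counting, scalar
# dynamic programming) and share no code with the implementation.

# two-sided exact Mann-Whitney p by enumerating all group assignments
enum_mw_p <- function(a, b) {
  pool <- c(a, b)
  n1 <- length(a)
  idx <- combn(length(pool), n1)
  us <- apply(idx, 2, function(i) {
    x <- pool[i]; y <- pool[-i]
    sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  })
  u <- sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  min(1, 2 * min(mean(us <= u + 1e-12), mean(us >= u - 1e-12)))
}

# two-sided exact Wilcoxon signed-rank p by enumerating all sign patterns
enum_wsr_p <- function(d) {
  d <- d[d != 0]
  r <- rank(abs(d))
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), length(d))))
  vs <- as.numeric(signs %*% r)
  v <- sum(r[d > 0])
  min(1, 2 * min(mean(vs <= v + 1e-12), mean(vs >= v - 1e-12)))
}

# two-sided exact Spearman p by enumerating all permutations of y
enum_spearman_p <- function(x, y) {
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  r <- cor(x, y, method = "spearman")
  rs <- vapply(perms(y), function(yy) cor(x, yy, method = "spearman"),
               numeric(1))
  min(1, 2 * min(mean(rs <= r + 1e-12), mean(rs >= r - 1e-12)))
}

# AUC by exhaustive tumor-normal pair counting (ties get half credit)
auc_paircount <- function(scores, is_tumor) {
  t <- scores[is_tumor]; n <- scores[!is_tumor]
  (sum(outer(t, n, ">")) + 0.5 * sum(outer(t, n, "=="))) /
    (length(t) * length(n))
}

# global affine-gap Needleman-Wunsch score with bisulfite-aware substitution
# (reference C vs clone T is a match); Gotoh three-state recursion
nw_bisulfite_score <- function(ref, clone, match = 1, mismatch = -1,
                               open = 2, ext = 0.5) {
  pb <- strsplit(ref, "")[[1]]; sb <- strsplit(clone, "")[[1]]
  n <- length(pb); m <- length(sb)
  sub <- function(a, b) if (a == b || (a == "C" && b == "T")) match else mismatch
  NEG <- -1e9
  M <- X <- Y <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- -(open + ext * (i - 1))
  for (j in 2:(m + 1)) Y[1, j] <- -(open + ext * (j - 1))
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    sc <- sub(pb[i - 1], sb[j - 1])
    M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + sc
    X[i, j] <- max(M[i - 1, j] - open - ext, X[i - 1, j] - ext,
                   Y[i - 1, j] - open - ext)
    Y[i, j] <- max(M[i, j - 1] - open - ext, Y[i, j - 1] - ext,
                   X[i, j - 1] - open - ext)
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# Gehan-Breslow-Wilcoxon chi-squared computed from an explicit per-event-time
# risk table (hand construction, scalar arithmetic)
gbw_hand <- function(time, event, g) {
  ts <- sort(unique(time[event == 1]))
  num <- 0; den <- 0
  for (tt in ts) {
    n1 <- sum(time >= tt & g); n2 <- sum(time >= tt & !g)
    d1 <- sum(time == tt & event == 1 & g)
    d2 <- sum(time == tt & event == 1 & !g)
    n <- n1 + n2; d <- d1 + d2
    num <- num + n * (d1 - d * n1 / n)
    if (n > 1) den <- den + d * (n - d) * n1 * n2 / (n - 1)
  }
  chi <- num^2 / den
  c(chi = chi, p = pchisq(chi, 1, lower.tail = FALSE))
}

# random DNA helper
random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "T", "C", "G"), n, TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

# mock clone_alignment with given call characters ("m", "u", ".")
mock_alignment <- function(calls, conversion = 1, identity = 1) {
  lev <- c(m = "methylated", u = "unmethylated", "." = "missing")
  structure(list(calls = factor(unname(lev[strsplit(calls, "")[[1]]]),
                                levels = unname(lev)),
                 conversion_rate = conversion, identity = identity,
                 valid = TRUE, score = NA_real_),
            class = "clone_alignment")
}
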