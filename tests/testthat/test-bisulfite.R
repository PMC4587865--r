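ref_seq <- "TACGTTCAGCGATCCGATCGTA"        # CpGs at 0-based 2, 9, 14, 18
ref <- bisulfite_reference(ref_seq, c(2, 9, 14, 18))

test_that("reference conversion keeps C only at CpG sites", {
  conv <- strsplit(ref$converted, "")[[1]]
  expect_equal(which(conv == "C") - 1L, c(2, 9, 14, 18))
  expect_error(bisulfite_reference(ref_seq, c(0, 2)), "cytosine")
})

test_that("fully converted and unconverted clones are called trivially", {
  full_conv <- chartr("C", "T", ref_seq)   # every C reads as T
  a <- align_clone(full_conv, ref)
  expect_equal(as.character(a$calls), rep("unmethylated", 4))
  expect_equal(a$conversion_rate, 1)
  expect_equal(a$identity, 1)
  expect_true(a$valid)

  b <- align_clone(ref_seq, ref)   # raw reference: nothing converted
  expect_equal(as.character(b$calls), rep("methylated", 4))
  expect_equal(b$conversion_rate, 0)
  expect_equal(b$identity, 1)     # C vs C matches everywhere

  # converted image = fully methylated, fully converted clone
  m <- align_clone(ref$converted, ref)
  expect_equal(as.character(m$calls), rep("methylated", 4))
  expect_equal(m$conversion_rate, 1)
})

test_that("a deletion spanning a CpG yields a missing call; score matches NW oracle", {
  conv <- strsplit(chartr("C", "T", ref_seq), "")[[1]]
  del <- paste(conv[-(9:11)], collapse = "")   # removes CpG at offset 9
  a <- align_clone(del, ref)
  expect_equal(sum(a$calls == "missing"), 1)
  expect_equal(as.character(a$calls)[c(1, 3, 4)], rep("unmethylated", 3))
  expect_equal(a$score, nw_bisulfite_score(ref_seq, del), tolerance = 1e-9)
})

test_that("alignment score equals the brute-force oracle on random clones", {
  set.seed(31)
  for (k in 1:10) {
    s <- random_dna(sample(15:30, 1))
    bs <- strsplit(s, "")[[1]]
    cp <- which(bs == "C" & c(bs[-1], "N") == "G") - 1L
    r <- bisulfite_reference(s, cp)
    cb <- strsplit(r$converted, "")[[1]]
    if (runif(1) < 0.5) cb <- cb[-sample(length(cb), sample(1:2, 1))]
    i <- sample(length(cb), 2)
    cb[i] <- sample(c("A", "C", "G", "T"), 2, TRUE)
    clone <- paste(cb, collapse = "")
    expect_equal(align_clone(clone, r)$score, nw_bisulfite_score(s, clone),
                 tolerance = 1e-9)
  }
})

test_that("QC filtering excludes on conversion and identity, never altering calls", {
  sim <- simulate_bisulfite_clones(ref_seq, c(2, 9, 14, 18),
                                   per_cpg_meth_prob = c(1, 0, 1, 0),
                                   n_clones = 4, conversion_failure_rate = 0,
                                   seed = 1)
  al <- lapply(sim$clones, align_clone, ref = ref)
  qc <- qc_filter(al)
  expect_true(qc$valid)
  expect_equal(length(qc$retained), 4)
  expect_identical(qc$retained, al[qc$report$retained])

  low_conv <- mock_alignment("mu..", conversion = 0.80)
  mixed <- qc_filter(c(al, list(bad = low_conv)))
  expect_false(mixed$report$retained[5])
  expect_match(mixed$report$reason[5], "low_conversion")
  expect_warning(res <- qc_filter(list(low_conv)), "invalid")
  expect_false(res$valid)
})

test_that("QC exclusion fraction follows the binomial tail", {
  set.seed(32)
  n_c <- 22                     # non-CpG cytosines
  b <- rep(c("C", "A"), n_c)    # no CpGs at all
  seqc <- paste(b, collapse = "")
  r <- bisulfite_reference(seqc, integer(0))
  sim <- simulate_bisulfite_clones(seqc, integer(0),
                                   n_clones = 300,
                                   conversion_failure_rate = 0.1, seed = 33)
  conv <- vapply(lapply(sim$clones, align_clone, ref = r),
                 `[[`, numeric(1), "conversion_rate")
  excluded <- mean(conv < 0.95)
  # conversion < 0.95 over 22 Cs <=> >= 2 retentions
  p_tail <- 1 - pbinom(1, n_c, 0.1)
  expect_lt(abs(excluded - p_tail), 4 * sqrt(p_tail * (1 - p_tail) / 300))
})

test_that("sample methylation pools calls and ignores clone order", {
  # 5 clones x 22 CpGs, 66 methylated of 110 calls -> 60.0%
  grid <- c(strrep("m", 22), strrep("m", 22), strrep("m", 22),
            paste0(strrep("u", 22)), paste0(strrep("u", 22)))
  al <- lapply(grid, mock_alignment)
  sm <- sample_methylation(al)
  expect_equal(sm$n_methylated + sm$n_unmethylated, 110)
  expect_equal(sm$percent, 60)
  expect_equal(sample_methylation(rev(al))$percent, sm$percent)
  # missing calls drop out of the denominator
  al2 <- list(mock_alignment("mm.."), mock_alignment("mu.."))
  expect_equal(sample_methylation(al2)$percent, 75)
  expect_equal(sample_methylation(al2)$per_cpg, c(1, 0.5, NA, NA))
  expect_error(sample_methylation(list(mock_alignment("...."))), "callable")
})

test_that("noise-free calls equal the planted pattern exactly", {
  set.seed(34)
  s <- random_dna(300, gc = 0.5)
  reg <- extract_region(s, 150, -140, 140)
  r <- bisulfite_reference(reg)
  sim <- simulate_bisulfite_clones(reg$sequence, reg$cpg_offsets,
                                   per_cpg_meth_prob = 0.5, n_clones = 10,
                                   seed = 35)
  al <- lapply(sim$clones, align_clone, ref = r)
  called <- t(vapply(al, function(a) a$calls == "methylated",
                     logical(length(reg$cpg_offsets))))
  expect_equal(unname(called), unname(sim$truth))
})

test_that("group and paired comparisons match their stated conventions", {
  expect_equal(compare_methylation_groups(c(1, 2, 3), c(4, 5, 6))$p, 0.1)
  expect_equal(compare_methylation_groups(c(1, 2, 3), c(4, 5, 6))$statistic, 0)

  f_n <- seq(0.1, 0.5, length.out = 22)
  res <- compare_methylation_paired(f_n + 0.3, f_n)
  expect_equal(res$p, 2 / 2^22, tolerance = 1e-12)
  expect_equal(res$direction, "hyper")
  expect_warning(same <- compare_methylation_paired(f_n, f_n), "zero")
  expect_equal(same$p, 1)
  expect_equal(same$direction, "none")
  expect_error(compare_methylation_paired(1:5 / 10, 1:4 / 10), "mismatch")
})

test_that("methylation-expression correlation matches the rank formula", {
  meth <- c(90, 75, 60, 40, 20, 5)
  expr <- c(1.2, 2.5, 3.1, 4.8, 6.0, 7.5)
  res <- correlate_methylation_expression(meth, expr)
  expect_equal(res$rho, -1)
  # fixed 6-point table against the d^2 rank formula
  x <- c(3, 1, 4, 5, 9, 2); y <- c(7, 2, 8, 3, 9, 5)
  d <- rank(x) - rank(y)
  expect_equal(spearman_test(x, y)$rho, 1 - 6 * sum(d^2) / (6 * 35),
               tolerance = 1e-12)
})

test_that("the text methylation grid encodes calls per clone", {
  al <- list(a = mock_alignment("mu.m"), b = mock_alignment("uuuu"))
  expect_equal(unname(methylation_grid(al)), c("o.-o", "...."))
})
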