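test_that("identical drug and vehicle columns give zero fold changes", {
  sim <- simulate_expression_screen(n_probes = 30, n_silenced = 0, seed = 1)
  ann <- sim$annotation
  drug <- ann$sample[ann$cell_line == "BC1" & ann$treatment == "drug"]
  veh <- ann$sample[ann$cell_line == "BC1" & ann$treatment == "vehicle"]
  sim$matrix[, drug] <- sim$matrix[, veh]
  res <- differential_response(sim$matrix, sim$annotation, "BC1")
  expect_equal(res$fold_log2, rep(0, 30))
  expect_true(all(res$p == 1 | is.na(res$p)))
})

test_that("welch mode reproduces the closed-form Welch t on a 3v3 probe", {
  set.seed(7)
  mat <- rbind(probe_x = c(8.05, 7.95, 8.00, 6.10, 5.90, 6.00),
               probe_y = rnorm(6, 7))
  ann <- data.frame(sample = paste0("s", 1:6), cell_line = "L",
                    class = "cancer",
                    treatment = rep(c("drug", "vehicle"), each = 3),
                    replicate = rep(1:3, 2), stringsAsFactors = FALSE)
  colnames(mat) <- ann$sample
  res <- differential_response(mat, ann, "L", method = "welch")
  oracle <- t.test(mat["probe_x", 1:3], mat["probe_x", 4:6])
  expect_equal(res$fold_log2[1], 2, tolerance = 1e-9)
  expect_equal(res$p[1], oracle$p.value, tolerance = 1e-9)
  expect_equal(res$t[1], unname(oracle$statistic), tolerance = 1e-9)
  expect_error(differential_response(mat, ann, "nope"), "unknown cell line")
})

test_that("shrinkage t approaches Welch t with many replicates", {
  set.seed(10)
  n <- 30
  mat <- matrix(rnorm(200 * 2 * n, 7, 0.5), nrow = 200,
                dimnames = list(sprintf("p%03d", 1:200), NULL))
  mat[1:20, 1:n] <- mat[1:20, 1:n] + 1
  ann <- data.frame(sample = sprintf("s%02d", 1:(2 * n)), cell_line = "L",
                    class = "cancer",
                    treatment = rep(c("drug", "vehicle"), each = n),
                    replicate = c(1:n, 1:n), stringsAsFactors = FALSE)
  colnames(mat) <- ann$sample
  shr <- differential_response(mat, ann, "L", method = "shrinkage")
  wel <- differential_response(mat, ann, "L", method = "welch")
  expect_equal(shr$fold_log2, wel$fold_log2)
  expect_gt(cor(shr$t, wel$t), 0.999)
  expect_lt(max(abs(log10(shr$p) - log10(wel$p)) /
                  pmax(1, abs(log10(wel$p)))), 0.2)
})

test_that("FDR is monotone non-decreasing in p within a cell line", {
  sim <- simulate_expression_screen(n_probes = 300, n_silenced = 30, seed = 2)
  res <- differential_response(sim$matrix, sim$annotation, "BC1")
  o <- order(res$p)
  expect_true(all(diff(res$fdr[o]) >= -1e-12))
})

test_that("candidate selection applies the cancer-only induction rule", {
  probes <- c("a", "b", "c", "d")
  row <- function(fold, p) data.frame(probe = probes, fold_log2 = fold,
                                      t = NA, p = p, fdr = p)
  # a: induced everywhere (excluded); b: cancer-only (candidate);
  # c: one cancer line only (excluded); d: opposite directions (excluded)
  res <- list(
    BC1 = row(c(2, 2, 2, 2), c(0.001, 0.001, 0.001, 0.001)),
    BC2 = row(c(2, 2, 0.1, -2), c(0.001, 0.001, 0.8, 0.001)),
    NTB1 = row(c(2, 0.1, 0.1, 0.1), c(0.001, 0.9, 0.9, 0.9)))
  sel <- select_candidates(res, c("BC1", "BC2"), "NTB1")
  expect_identical(sel$up, "b")
  expect_identical(sel$down, character(0))
  # a is excluded purely by the non-tumorigenic response
  expect_true(sel$table$pass_all_cancer[1])
  expect_true(sel$table$responds_ntb[1])
  expect_error(select_candidates(list(), "BC1", "NTB1"), "empty")
})

test_that("relaxing fold or p thresholds never shrinks the candidate set", {
  sim <- simulate_expression_screen(n_probes = 300, n_silenced = 30,
                                    fold_induced = 1, noise_sd = 0.5,
                                    seed = 6)
  res <- lapply(setNames(nm = unique(sim$annotation$cell_line)),
                function(cl) differential_response(sim$matrix,
                                                   sim$annotation, cl))
  strict <- select_candidates(res, c("BC1", "BC2"), "NTB1",
                              fold_min = 2, p_max = 0.01)
  loose <- select_candidates(res, c("BC1", "BC2"), "NTB1",
                             fold_min = 1.2, p_max = 0.1)
  strict_ids <- c(strict$up, strict$down)
  loose_ids <- c(loose$up, loose$down)
  # NTB exclusion is also relaxed, so compare the cancer-side pass set
  expect_true(all(strict$table$probe[strict$table$pass_all_cancer] %in%
                    loose$table$probe[loose$table$pass_all_cancer]))
  expect_gte(length(loose_ids), length(strict_ids))
})

test_that("overlap report partitions exactly and computes percentages", {
  same <- overlap_report(letters[1:5], letters[1:5])
  expect_equal(same$pct_a, 100); expect_equal(same$pct_b, 100)
  disj <- overlap_report(letters[1:5], letters[6:10])
  expect_equal(disj$pct_a, 0); expect_equal(disj$pct_b, 0)
  a <- sprintf("p%03d", 1:100)
  b <- c(sprintf("p%03d", 1:17), sprintf("q%03d", 1:60))
  ov <- overlap_report(a, b)
  expect_equal(ov$pct_a, 17)
  expect_equal(ov$pct_b, 17 / 77 * 100, tolerance = 1e-9)
  expect_setequal(c(ov$common, ov$a_specific), a)
  expect_length(intersect(ov$common, ov$a_specific), 0)
})

test_that("external paired validation matches the closed-form paired t", {
  diffs <- c(1.0, 1.2, 0.8, 1.1, 0.9, 1.0, 1.05)
  lines <- sprintf("L%d", 1:7)
  ann <- data.frame(sample = c(paste0(lines, "_d"), paste0(lines, "_v")),
                    cell_line = rep(lines, 2), class = "cancer",
                    treatment = rep(c("drug", "vehicle"), each = 7),
                    replicate = 1, stringsAsFactors = FALSE)
  mat <- matrix(5, nrow = 2, ncol = 14,
                dimnames = list(c("cand", "other"), ann$sample))
  mat["cand", paste0(lines, "_d")] <- 5 + diffs
  res <- cross_dataset_validation("cand", mat, ann)
  expect_equal(res$per_probe$p[1], t.test(diffs)$p.value, tolerance = 1e-9)
  expect_equal(res$fraction_validated, 1)
  expect_error(cross_dataset_validation("cand", mat[, 1:4],
                                        ann[c(1, 2, 8, 9), ]), ">= 3")
})
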