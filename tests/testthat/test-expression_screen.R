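counts_fixture <- function(counts, lengths) {
  m <- matrix(counts, ncol = 1, dimnames = list(names(lengths), "s1"))
  expr_matrix(m, "counts", lengths)
}

test_that("TPM and FPKM follow their definitions", {
  one <- counts_fixture(c(g1 = 57), c(g1 = 1234))
  expect_equal(unclass(compute_tpm(one))[1, 1], 1e6)
  two <- counts_fixture(c(g1 = 10, g2 = 10), c(g1 = 1000, g2 = 2000))
  tpm <- unclass(compute_tpm(two))
  expect_equal(tpm[, 1], c(g1 = 666666.67, g2 = 333333.33), tolerance = 1e-8)
  n <- 5
  eq <- counts_fixture(setNames(rep(7, n), paste0("g", 1:n)),
                       setNames(rep(1500, n), paste0("g", 1:n)))
  expect_equal(unname(unclass(compute_tpm(eq))[, 1]), rep(1e6 / n, n))
  fpkm <- unclass(compute_fpkm(two))
  expect_equal(fpkm["g1", 1], 10 * 1e9 / (1000 * 20))
  expect_warning(compute_tpm(counts_fixture(c(g1 = 0), c(g1 = 100))),
                 "all-zero")
})

test_that("TPM columns sum to 1e6 and preserve FPKM rankings", {
  set.seed(21)
  m <- matrix(rpois(200, 50) + 1, nrow = 20,
              dimnames = list(sprintf("g%02d", 1:20), sprintf("s%02d", 1:10)))
  lens <- setNames(sample(500:3000, 20), rownames(m))
  cm <- expr_matrix(m, "counts", lens)
  tpm <- compute_tpm(cm); fpkm <- compute_fpkm(cm)
  expect_true(all(abs(colSums(unclass(tpm)) - 1e6) <= 1e-6 * 1e6))
  for (j in 1:10)
    expect_equal(order(unclass(tpm)[, j]), order(unclass(fpkm)[, j]))
})

test_that("the expression filter is inclusive at 20", {
  m <- matrix(c(20, 1, 19.99, 1, 0, 25), nrow = 3, byrow = TRUE,
              dimnames = list(c("at", "below", "spike"), c("s1", "s2")))
  x <- expr_matrix(m, "FPKM")
  expect_setequal(filter_expressed(x), c("at", "spike"))
  expect_error(filter_expressed(expr_matrix(m, "counts")), "counts")
})

test_that("expression groups use half-open bins at 20 and 300", {
  m <- matrix(c(500, 100, 10, 300, 20, 19.999), ncol = 1,
              dimnames = list(c("a", "b", "c", "a2", "b2", "c2"), "s1"))
  g <- group_by_level(expr_matrix(m, "FPKM"))
  expect_equal(unname(g), c("A", "B", "C", "A", "B", "C"))
  expect_error(group_by_level(expr_matrix(m, "TPM")), "FPKM")
})

dominance_fixture <- function(flesh, peel) {
  m <- cbind(matrix(flesh, ncol = length(flesh) / NROW(flesh)),
             matrix(peel, ncol = length(peel) / NROW(peel)))
  m <- rbind(m); rownames(m) <- paste0("g", seq_len(nrow(m)))
  colnames(m) <- c(paste0("F", seq_len(ncol(m) / 2)),
                   paste0("P", seq_len(ncol(m) / 2)))
  design <- data.frame(sample_id = colnames(m),
                       tissue = rep(c("flesh", "peel"), each = ncol(m) / 2))
  list(x = expr_matrix(m, "FPKM"), design = design)
}

test_that("tissue dominance uses strict ratio thresholds on summed values", {
  fx <- dominance_fixture(matrix(c(60, 60, 5, 5, 25, 25), nrow = 3, byrow = TRUE),
                          matrix(c(10, 10, 50, 50, 5, 5), nrow = 3, byrow = TRUE))
  d <- classify_dominance(fx$x, fx$design)
  expect_equal(d$dominance, c("flesh", "peel", "none"))  # 6, 0.1, exactly 5
  expect_equal(d$ratio, c(6, 0.1, 5))
  # zero peel sum with positive flesh sum is flesh (infinite ratio)
  fz <- dominance_fixture(matrix(c(3, 3), nrow = 1), matrix(c(0, 0), nrow = 1))
  expect_equal(classify_dominance(fz$x, fz$design)$dominance, "flesh")
  # both zero -> none
  f0 <- dominance_fixture(matrix(c(0, 0), nrow = 1), matrix(c(0, 0), nrow = 1))
  expect_equal(classify_dominance(f0$x, f0$design)$dominance, "none")
  expect_error(classify_dominance(fx$x, data.frame(sample_id = "F1",
                                                   tissue = "flesh")),
               "both tissues")
})

test_that("dominance is antisymmetric under tissue swap", {
  set.seed(31)
  m <- matrix(runif(60, 0, 100), nrow = 10,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:6)))
  m[1, 1:3] <- m[1, 1:3] * 50
  design <- data.frame(sample_id = colnames(m),
                       tissue = rep(c("flesh", "peel"), each = 3))
  swapped <- design
  swapped$tissue <- ifelse(design$tissue == "flesh", "peel", "flesh")
  d1 <- classify_dominance(expr_matrix(m, "FPKM"), design)
  d2 <- classify_dominance(expr_matrix(m, "FPKM"), swapped)
  flip <- c(flesh = "peel", peel = "flesh", none = "none")
  expect_equal(unname(flip[d1$dominance]), d2$dominance)
})

correlation_fixture <- function(values) {
  # values: genes x 6 stages for one tissue; replicate once
  m <- values
  colnames(m) <- paste0("F", 1:6)
  rownames(m) <- paste0("g", seq_len(nrow(m)))
  design <- data.frame(sample_id = colnames(m), tissue = "flesh",
                       stage = 1:6)
  list(x = expr_matrix(m, "FPKM"), design = design)
}

test_that("ripening correlation compares late to early stage sums", {
  fx <- correlation_fixture(rbind(c(30, 30, 40, 100, 100, 100),
                                  c(30, 40, 30, 10, 20, 10),
                                  c(50, 50, 50, 50, 50, 50)))
  r <- classify_ripening_correlation(fx$x, fx$design)
  expect_equal(r$correlation, c("positive", "negative", "none"))  # 3, 0.4, 1
  # boundary ratios exactly 2 and 0.5 are 'none' (strict)
  fb <- correlation_fixture(rbind(c(10, 10, 10, 20, 20, 20),
                                  c(20, 20, 20, 10, 10, 10)))
  expect_equal(classify_ripening_correlation(fb$x, fb$design)$correlation,
               c("none", "none"))
  # zero early sum with positive late sum is positive
  fz <- correlation_fixture(rbind(c(0, 0, 0, 5, 5, 5)))
  expect_equal(classify_ripening_correlation(fz$x, fz$design)$correlation,
               "positive")
  expect_error(classify_ripening_correlation(
    fx$x, data.frame(sample_id = "F1", tissue = "flesh", stage = 1)),
    "stages")
})

test_that("ripening correlation is scale-invariant per tissue", {
  set.seed(32)
  vals <- matrix(runif(30, 1, 100), nrow = 5)
  fx <- correlation_fixture(vals)
  fx10 <- correlation_fixture(vals * 10)
  expect_equal(classify_ripening_correlation(fx$x, fx$design)$correlation,
               classify_ripening_correlation(fx10$x, fx10$design)$correlation)
})

test_that("DEG calling implements the pseudocounted fold-change rule", {
  genes <- paste0("g", 1:3)
  case <- matrix(c(10, 10, 63, 63, 10, 10), nrow = 3, byrow = TRUE,
                 dimnames = list(genes, c("c1", "c2")))
  ctrl <- matrix(c(10, 10, 0, 0, 41, 41), nrow = 3, byrow = TRUE,
                 dimnames = list(genes, c("k1", "k2")))
  r <- call_degs(case, ctrl, test = "none")
  expect_equal(r$log2fc, c(0, 6, log2(11 / 42)))
  expect_equal(r$significant, c(FALSE, TRUE, TRUE))
  expect_equal(r$direction, c("up", "up", "down"))
  # |log2fc| = 1 is inclusive
  r2 <- call_degs(matrix(c(3), 1, dimnames = list("g", "a")),
                  matrix(c(1), 1, dimnames = list("g", "b")))
  expect_equal(r2$log2fc, 1)
  expect_true(r2$significant)
  expect_error(call_degs(case[, 0, drop = FALSE], ctrl), "replicate")
})

test_that("Welch test with BH adjustment flags planted fold changes", {
  set.seed(33)
  n <- 50
  genes <- sprintf("g%02d", 1:n)
  base <- matrix(100 + rnorm(n * 3, sd = 1), nrow = n,
                 dimnames = list(genes, paste0("k", 1:3)))
  case <- matrix(100 + rnorm(n * 3, sd = 1), nrow = n,
                 dimnames = list(genes, paste0("c", 1:3)))
  planted <- 1:5
  case[planted, ] <- 4 * (100 + rnorm(15, sd = 1))
  r <- call_degs(case, base, test = "welch")
  expect_true(all(r$significant[planted]))
  expect_false(any(r$significant[-planted]))
  expect_equal(r$log2fc[planted], rep(2, 5), tolerance = 0.05)
  # adjusted p-values equal the brute-force BH of the raw p-values
  expect_equal(r$p_adjust, bh_oracle(r$p), tolerance = 1e-12)
  expect_error(call_degs(case[, 1, drop = FALSE], base, test = "welch"),
               "2 replicates")
})

test_that("BH adjustment matches the brute-force step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(0.07, 6)), rep(0.07, 6))
  set.seed(34)
  for (i in 1:50) {
    p <- runif(sample(1:100, 1))
    a <- bh_adjust(p)
    expect_equal(a, bh_oracle(p), tolerance = 1e-12)
    expect_true(all(a >= p - 1e-15))
    o <- order(p)
    expect_true(all(diff(a[o]) >= -1e-15))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("the intersection screen requires every comparison group", {
  mk <- function(sig) data.frame(
    comparison_id = "x", gene = names(sig), log2fc = ifelse(sig, 2, 0),
    p = NA_real_, p_adjust = NA_real_, significant = unname(sig),
    direction = "up", stringsAsFactors = FALSE)
  genes <- c(all3 = TRUE, two = TRUE, none = FALSE)
  tabs <- list(
    c1 = mk(c(all3 = TRUE, two = TRUE, none = FALSE)),
    c2 = mk(c(all3 = TRUE, two = TRUE, none = FALSE)),
    c3 = mk(c(all3 = TRUE, two = FALSE, none = FALSE)))
  groups <- list(g1 = "c1", g2 = "c2", g3 = "c3")
  r <- intersect_screen(tabs, groups)
  expect_equal(r$key_genes, "all3")
  # one group with either comparison significant suffices
  r2 <- intersect_screen(tabs, list(g1 = c("c1", "c3"), g2 = "c2"))
  expect_setequal(r2$key_genes, c("all3", "two"))
  expect_error(intersect_screen(tabs, list(g1 = character())), "non-empty")
  expect_error(intersect_screen(tabs, list(g1 = "missing")), "missing")
})

test_that("relative expression follows 2^-ddCT", {
  expect_equal(delta_delta_ct(20, 18, 22, 20), 1.0)
  expect_equal(delta_delta_ct(21, 20, 22, 20), 2.0)
  expect_equal(delta_delta_ct(24, 20, 26, 20), 4.0)
  # vectorised over samples
  expect_equal(delta_delta_ct(c(24, 26), c(20, 20), 26, 20), c(4, 1))
})

test_that("Spearman co-expression matches the rank-formula oracle", {
  m <- rbind(a = c(1, 5, 2, 8, 4), b = c(2, 6, 3, 9, 5),
             r = c(9, 5, 8, 2, 6), t = c(1, 1, 2, 2, 3))
  colnames(m) <- paste0("s", 1:5)
  rho <- spearman_coexpression(m)
  expect_equal(diag(rho), setNames(rep(1, 4), rownames(m)))
  expect_equal(rho["a", "r"], -1)
  for (i in c("a", "b", "r", "t")) for (j in c("a", "b", "r", "t"))
    expect_equal(rho[i, j], spearman_oracle(m[i, ], m[j, ]),
                 tolerance = 1e-12)
  # constant gene gives an NA row/column
  m2 <- rbind(m, k = rep(3, 5))
  rho2 <- spearman_coexpression(m2)
  expect_true(all(is.na(rho2["k", ])))
  expect_error(spearman_coexpression(m[, 1:2]), "three samples")
})
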