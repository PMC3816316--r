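mk_fc_table <- function(rnaseq, qpcr, symbols = NULL) {
  n <- length(rnaseq)
  if (is.null(symbols)) symbols <- sprintf("G%03d", seq_len(n))
  fold_change_table(data.frame(symbol = symbols, log2_fc = rnaseq),
                    data.frame(symbol = symbols, log2_fc = qpcr))
}

test_that("log2 fold-change uses condition means with a pseudocount", {
  v <- rbind(up = c(4, 4, 1, 1), flat = c(3, 3, 3, 3),
             onezero = c(0, 0, 2, 2), allzero = c(0, 0, 0, 0))
  m <- expression_matrix(v, condition = factor(
    rep(c("treatment", "control"), each = 2), c("treatment", "control")))
  fc1 <- suppressWarnings(log2_fold_change(m, pseudocount = 0))
  expect_equal(fc1$log2_fc[fc1$id == "up"], 2)
  expect_equal(fc1$log2_fc[fc1$id == "flat"], 0)
  # zero in one condition at pseudocount 0: infinite, dropped with warning
  expect_warning(log2_fold_change(m, pseudocount = 0), "zero mean")
  expect_false("onezero" %in% fc1$id)
  expect_false("allzero" %in% fc1$id)
  expect_equal(attr(fc1, "n_dropped"), 2L)

  fc2 <- log2_fold_change(m, pseudocount = 1)
  expect_equal(fc2$log2_fc[fc2$id == "onezero"], log2(1 / 3))

  # direction is pinned by numerator/denominator
  fc3 <- suppressWarnings(log2_fold_change(m, numerator = "control",
                                           denominator = "treatment"))
  expect_equal(fc3$log2_fc[fc3$id == "up"], -2)
})

test_that("AAD and RMSE follow their definitions and ordering", {
  expect_equal(aad(mk_fc_table(c(1, 2, 3), c(1, 2, 3))), 0)
  expect_equal(rmse(mk_fc_table(c(1, 2), c(1, 2))), 0)
  expect_equal(rmse(mk_fc_table(c(3, 4), c(0, 0))), sqrt(12.5))
  expect_equal(aad(mk_fc_table(c(3, 4), c(0, 0))), 3.5)

  set.seed(61)
  for (rep in 1:20) {
    n <- sample(2:40, 1)
    tbl <- mk_fc_table(rnorm(n), rnorm(n))
    # quadratic mean dominates arithmetic mean
    expect_gte(rmse(tbl), aad(tbl))
    # symmetry in the two columns
    swapped <- tbl
    swapped$fc_rnaseq <- tbl$fc_qpcr
    swapped$fc_qpcr <- tbl$fc_rnaseq
    expect_equal(aad(swapped), aad(tbl))
    expect_equal(rmse(swapped), rmse(tbl))
    # row order is irrelevant
    perm <- tbl[sample.int(n), ]
    class(perm) <- class(tbl)
    expect_equal(aad(perm), aad(tbl))
  }
  # a zero-deviation row never increases the AAD
  tbl <- mk_fc_table(c(1, 3), c(2, 1))
  tbl2 <- mk_fc_table(c(1, 3, 5), c(2, 1, 5))
  expect_lte(aad(tbl2), aad(tbl))
})

test_that("correlation is exact on linear data and attenuates under noise", {
  x <- 1:5
  expect_equal(fc_correlation(mk_fc_table(2 * x + 1, x)), 1)
  expect_equal(fc_correlation(mk_fc_table(-x, x)), -1)
  expect_error(fc_correlation(mk_fc_table(rep(1, 4), 1:4)), "constant")

  # additive noise of known sd: rho = 1/sqrt(1 + sd^2/var(x))
  set.seed(62)
  sd_noise <- 0.5
  r_obs <- replicate(40, {
    x <- rnorm(100, sd = 1)
    fc_correlation(mk_fc_table(x + rnorm(100, sd = sd_noise), x))
  })
  rho <- 1 / sqrt(1 + sd_noise^2)
  expect_lt(abs(mean(r_obs) - rho), 3 * sd(r_obs) / sqrt(length(r_obs)) + 0.01)

  # Spearman is available behind the method flag
  expect_equal(fc_correlation(mk_fc_table(exp(1:5), 1:5),
                              method = "spearman"), 1)
})

test_that("qPCR present filter keeps genes detected in every replicate", {
  flags <- data.frame(symbol = c("ok", "near"),
                      r1 = c("P", "P"), r2 = c("P", "P"), r3 = c("P", "P"),
                      r4 = c("P", "P"), r5 = c("P", "P"), r6 = c("P", "P"),
                      r7 = c("P", "P"), r8 = c("P", "A"))
  expect_equal(qpcr_present_filter(flags), "ok")

  # planted set: 830 all-present genes out of 1,044
  set.seed(63)
  n <- 1044; n_present <- 830
  present <- c(rep(TRUE, n_present), rep(FALSE, n - n_present))
  m <- matrix(TRUE, n, 8)
  m[!present, ] <- matrix(runif(sum(!present) * 8) < 0.6, ncol = 8)
  m[cbind(which(!present), sample.int(8, sum(!present), replace = TRUE))] <-
    FALSE
  tab <- data.frame(symbol = sprintf("T%04d", 1:n), m)
  expect_equal(length(qpcr_present_filter(tab)), 830L)
  expect_equal(qpcr_present_filter(tab), sort(sprintf("T%04d", 1:830)))
})

test_that("top-k overlap counts pairwise and global agreement", {
  base <- sprintf("G%02d", 1:30)
  same <- list(a = base, b = base)
  expect_equal(unname(top_k_overlap(same, k = 20)$pairwise["a", "b"]), 20L)
  disjoint <- list(a = sprintf("A%02d", 1:20), b = sprintf("B%02d", 1:20))
  expect_equal(unname(top_k_overlap(disjoint, k = 20)$pairwise["a", "b"]), 0L)
  expect_equal(top_k_overlap(disjoint, k = 20)$n_shared, 0L)
  expect_equal(top_k_overlap(disjoint, k = 20)$n_specific, 40L)

  # a planted 12-gene core inside every top-20 bounds all pairwise overlaps
  set.seed(64)
  core <- sprintf("CORE%02d", 1:12)
  lists <- lapply(1:4, function(i) {
    fill <- sprintf("L%d_%02d", i, 1:8)
    sample(c(core, fill))
  })
  names(lists) <- paste0("ann", 1:4)
  ov <- top_k_overlap(lists, k = 20)
  off_diag <- ov$pairwise[upper.tri(ov$pairwise)]
  expect_true(all(off_diag >= 12))
  expect_gte(ov$n_shared, 12L)

  expect_error(top_k_overlap(list(a = c("X", "X", "Y"), b = c("A", "B")),
                             k = 2), "duplicate")
  expect_error(top_k_overlap(list(a = "X", b = "Y"), k = 5), "fewer")
})

test_that("platform join drops unmatched and non-finite fold-changes", {
  rnaseq <- data.frame(symbol = c("A", "B", "C"), log2_fc = c(1, 2, Inf))
  qpcr <- data.frame(symbol = c("B", "C", "D"), log2_fc = c(0.5, 1, 2))
  tbl <- fold_change_table(rnaseq, qpcr)
  expect_equal(tbl$symbol, "B")
  expect_error(fold_change_table(rnaseq[c(1, 1), ], qpcr), "duplicate")
  expect_error(fold_change_table(data.frame(symbol = "Z", log2_fc = 1),
                                 qpcr), "shared")
})
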