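test_that("entropy matches analytic cases and an independent summation", {
  expect_equal(cluster_entropy(c(1, 0, 0)), 0)
  expect_equal(cluster_entropy(c(1, 1, 1) / 3), log(3), tolerance = 1e-12)
  q <- c(0.8, 0.15, 0.05)
  oracle <- -(0.8 * log(0.8) + 0.15 * log(0.15) + 0.05 * log(0.05))
  expect_equal(cluster_entropy(q), oracle, tolerance = 1e-12)
  # rowwise on a matrix, bounded by log K
  qm <- rbind(c(1, 0, 0), rep(1 / 3, 3), q)
  ent <- unname(cluster_entropy(qm))
  expect_equal(ent, c(0, log(3), oracle), tolerance = 1e-12)
  expect_true(all(ent <= log(3) + 1e-12))
  expect_error(cluster_entropy(c(0.5, 0.2)), class = "synclust_validation_error")
})

test_that("RMS effect size matches analytic cases over observed variables", {
  expect_equal(rms_effect(c(1, -1)), 1)
  expect_equal(rms_effect(c(0, 0, 0)), 0)
  expect_equal(rms_effect(c(2, 0.5, NA)), sqrt((4 + 0.25) / 2), tolerance = 1e-12)
  expect_equal(rms_effect(c(2, 0.5, NA)), 1.4577, tolerance = 1e-4)
  expect_error(rms_effect(c(NA_real_, NA_real_)),
               class = "synclust_undefined_error")
})

test_that("gene weights conserve one unit of weight per gene", {
  genes <- c("a", "b", "b", "c", "c", "c", "c")
  w <- gene_weights(genes)
  expect_equal(w, c(1, 0.5, 0.5, 0.25, 0.25, 0.25, 0.25))
  expect_equal(as.vector(tapply(w, genes, sum)), c(1, 1, 1))
  # weighted per-gene probability sums equal per-gene averages
  set.seed(61)
  q <- matrix(runif(21), 7)
  q <- q / rowSums(q)
  gs <- gene_cluster_summary(q, genes)
  expect_equal(rowSums(gs[paste0("q", 1:3)]), rep(1, 3), tolerance = 1e-12)
  manual <- tapply(w * q[, 1], genes, sum) /
    tapply(w, genes, sum)
  expect_equal(gs$q1, as.vector(manual), tolerance = 1e-12)
})

test_that("identical group distributions give chi-square near zero and large p", {
  q <- matrix(rep(c(0.6, 0.3, 0.1), each = 20), 20)
  labels <- rep(c("GOF", "LOF"), 10)
  res <- weighted_contingency_test(labels, q, n_rand = 199, seed = 62)
  expect_lt(res$chisq, 1e-20)
  expect_gt(res$p_value, 0.9)
  # table total equals total weight
  expect_equal(sum(res$table), 20)
})

test_that("weighted table matches chisq.test on an integer special case", {
  # degenerate q (one-hot) and unit weights reduce to an ordinary table
  lab <- rep(c("GOF", "LOF"), times = c(12, 18))
  cl <- c(rep(1, 9), rep(2, 3), rep(1, 6), rep(2, 12))
  q <- cbind(cl == 1, cl == 2) * 1
  res <- weighted_contingency_test(lab, q, n_rand = 99, seed = 63)
  ref <- suppressWarnings(stats::chisq.test(table(lab, cl), correct = FALSE))
  expect_equal(res$chisq, unname(ref$statistic), tolerance = 1e-12)
})

test_that("the randomization test detects a planted GOF enrichment", {
  set.seed(64)
  n <- 60
  lab <- rep(c("GOF", "LOF"), times = c(20, 40))
  q <- matrix(0, n, 3)
  for (i in 1:n) {
    if (lab[i] == "GOF") {
      q[i, ] <- c(0.05, 0.05, 0.9)[c(sample(2), 3)]
    } else {
      q[i, ] <- rev(sort(stats::runif(3)))
      q[i, ] <- q[i, sample(3)]
    }
    q[i, ] <- q[i, ] / sum(q[i, ])
  }
  res <- weighted_contingency_test(lab, q, n_rand = 999, seed = 65)
  expect_lt(res$p_value, 0.01)
  expect_gt(res$group_probability["GOF", 3], 0.5)
  expect_error(weighted_contingency_test(rep("GOF", 5), q[1:5, ],
                                         n_rand = 9, seed = 1),
               class = "synclust_validation_error")
})

test_that("gene correction equalizes genes with many labelled perturbations", {
  lab <- c(rep("GOF", 4), "GOF", rep("LOF", 3))
  genes <- c(rep("multi", 4), "solo", "l1", "l2", "l3")
  q <- rbind(matrix(rep(c(0.1, 0.9), 4), 4, byrow = TRUE),
             c(0.9, 0.1),
             matrix(rep(c(0.5, 0.5), 3), 3, byrow = TRUE))
  res <- weighted_contingency_test(lab, q, genes = genes, n_rand = 9, seed = 66)
  # multi's four perturbations share one unit of weight (q 0.1/0.9), solo has
  # a full unit (q 0.9/0.1): GOF row = (0.1 + 0.9, 0.9 + 0.1)
  expect_equal(unname(res$table["GOF", ]), c(1, 1), tolerance = 1e-12)
  expect_equal(unname(res$table["LOF", ]), c(1.5, 1.5), tolerance = 1e-12)
})

test_that("control correlations report r, regression-F p and the Bonferroni threshold", {
  set.seed(67)
  n <- 35
  A <- rlnorm(n, 1, 0.5)
  db <- db_row(author = "ctrl", pubmed_id = 1:n, gene_symbol = "control",
               description = "control")[rep(1, n), ]
  db$wt_reference <- rep(c(1, 2), length.out = n)
  db$mean_A <- A
  db$mean_RRP <- A * 100 * rlnorm(n, 0, 0.3)   # correlated with A
  db$mean_Pv <- rlnorm(n, 3, 0.4)
  db$mean_F <- rlnorm(n, 0.5, 0.6)
  db$mean_F[1:5] <- NA
  cc <- control_correlations(as_synclust_db(db))
  expect_equal(nrow(cc), 6L)
  expect_equal(attr(cc, "bonferroni"), 0.05 / 6)
  expect_equal(round(attr(cc, "bonferroni"), 4), 0.0083)
  expect_equal(attr(cc, "n_controls"), n)
  # cross-check every pair against the regression F-test
  vals <- cbind(A = db$mean_A, RRP = db$mean_RRP, Pv = db$mean_Pv, F = db$mean_F)
  for (i in seq_len(6)) {
    pr <- c(cc$var1[i], cc$var2[i])
    ok <- stats::complete.cases(vals[, pr])
    expect_equal(cc$n[i], sum(ok))
    fit <- stats::lm(vals[ok, pr[2]] ~ vals[ok, pr[1]])
    fp <- stats::anova(fit)[["Pr(>F)"]][1]
    expect_equal(cc$p_value[i], fp, tolerance = 1e-10)
    expect_equal(cc$r[i], stats::cor(vals[ok, pr[1]], vals[ok, pr[2]]),
                 tolerance = 1e-12)
  }
  # perfectly linear pair
  db2 <- db
  db2$mean_RRP <- db2$mean_A * 50
  cc2 <- control_correlations(as_synclust_db(db2))
  expect_equal(cc2$r[cc2$var1 == "A" & cc2$var2 == "RRP"], 1, tolerance = 1e-12)
})

test_that("perturbation diagnostics are pure functions of q and x", {
  db <- as_synclust_db(make_linked_db())
  pv <- normalize_to_controls(db)
  q <- rbind(c(0.7, 0.3), c(0.2, 0.8))
  d <- perturbation_diagnostics(pv, q)
  expect_equal(d$entropy, cluster_entropy(q))
  expect_equal(d$cluster, c(1L, 2L))
  expect_equal(d$rms, rms_effect(pv))
  # identical inputs give identical outputs (purity)
  expect_identical(d, perturbation_diagnostics(pv, q))
})
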