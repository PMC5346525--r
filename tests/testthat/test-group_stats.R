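make_table <- function(n = 40, seed = 1, effect = 0) {
  set.seed(seed)
  grp <- rep(c("patient", "control"), each = n / 2)
  data.frame(
    subject_id = sprintf("s%02d", 1:n),
    group = grp,
    minority = rbinom(n, 1, 0.3),
    cad_score = rnorm(n, 48, 10),
    y = rnorm(n) + effect * (grp == "patient"),
    stringsAsFactors = FALSE
  )
}

test_that("group F equals the squared pooled t without covariates", {
  tab <- make_table(seed = 2, effect = 0.8)
  res <- glm_group_comparison(tab, "y")
  tt <- t.test(y ~ group, tab, var.equal = TRUE)
  expect_equal(res$f, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(res$p, tt$p.value, tolerance = 1e-10)
})

test_that("covariate-adjusted F matches a normal-equations oracle", {
  tab <- make_table(seed = 3, effect = 0.5)
  res <- glm_group_comparison(tab, "y", c("minority", "cad_score"))
  # independent second implementation straight from the normal equations
  y <- tab$y
  x_full <- cbind(1, tab$group == "patient", tab$minority, tab$cad_score)
  x_red <- x_full[, -2]
  rss <- function(x) {
    beta <- solve(t(x) %*% x, t(x) %*% y)
    sum((y - x %*% beta)^2)
  }
  df2 <- nrow(tab) - ncol(x_full)
  f_oracle <- (rss(x_red) - rss(x_full)) / (rss(x_full) / df2)
  expect_equal(res$f, f_oracle, tolerance = 1e-8)
  expect_equal(res$p, pf(f_oracle, 1, df2, lower.tail = FALSE),
               tolerance = 1e-8)
})

test_that("degenerate GLM designs are handled", {
  tab <- make_table(seed = 4)
  tab$y <- 5
  res <- glm_group_comparison(tab, "y")
  expect_equal(res$f, 0)
  expect_equal(res$p, 1)
  tab2 <- make_table(seed = 5)
  tab2$dup <- tab2$cad_score
  expect_error(glm_group_comparison(tab2, "y", c("cad_score", "dup")),
               "collinear")
})

test_that("BH adjustment matches the hand-computed step-up", {
  expect_equal(fdr_adjust(0.05), 0.05)
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_identical(fdr_adjust(numeric(0)), numeric(0))
  set.seed(6)
  p <- runif(25)
  adj <- fdr_adjust(p)
  expect_true(all(adj >= p))
  expect_true(all(diff(sort(adj)) >= 0))
  expect_true(all(adj <= 1))
  # order preserved: the permutation applied to input reorders the output
  o <- sample(25)
  expect_equal(fdr_adjust(p[o]), adj[o], tolerance = 1e-14)
})

test_that("Wilcoxon U and its normal approximation behave", {
  x <- c(1, 2, 3); y <- c(1, 2, 3)
  expect_equal(wilcoxon_rank(x, y)$p, 1, tolerance = 1e-10)
  expect_equal(wilcoxon_rank(rep(2, 4), rep(2, 5))$p, 1)

  # U statistic matches the direct pair count, and agrees with wilcox.test
  set.seed(7)
  a <- rnorm(12); b <- rnorm(15) + 0.5
  res <- wilcoxon_rank(a, b)
  expect_equal(res$u, sum(outer(a, b, "<")))
  wt <- wilcox.test(b, a, exact = FALSE, correct = FALSE)
  expect_equal(res$p, wt$p.value, tolerance = 1e-10)

  # small samples: U matches exhaustive enumeration; normal p approximates
  # the exact permutation p
  xs <- c(1.2, 3.4, 2.2); ys <- c(0.4, 5.0, 2.9)
  res2 <- wilcoxon_rank(xs, ys)
  pool <- c(xs, ys)
  us <- apply(combn(6, 3), 2, function(idx)
    sum(outer(pool[idx], pool[-idx], "<")))
  expect_true(res2$u %in% us)
  p_exact <- mean(abs(us - 4.5) >= abs(res2$u - 4.5))
  expect_lt(abs(res2$p - p_exact), 0.25)
})

test_that("reported U = 1271 with groups 65/50 gives p about .046", {
  res <- wilcoxon_u_p_value(1271, 65, 50)
  expect_equal(res$z, (1271 - 1625) / sqrt(65 * 50 * 116 / 12),
               tolerance = 1e-12)
  expect_equal(round(res$p, 3), 0.046)
})

test_that("correlation p-values match the t reference distribution", {
  pr <- exact_correlation_pair(40, 0.6, seed = 8)
  res <- pearson_correlation(pr$x, pr$y)
  expect_equal(res$r, 0.6, tolerance = 1e-10)
  ct <- cor.test(pr$x, pr$y)
  expect_equal(res$p, ct$p.value, tolerance = 1e-10)
  # numeric quadrature of the t density as an independent oracle
  for (r in c(-0.33, 0.2, 0.7)) {
    n <- 65
    t <- abs(r) * sqrt(n - 2) / sqrt(1 - r^2)
    q <- 2 * integrate(function(u) dt(u, n - 2), t, Inf,
                       rel.tol = 1e-10)$value
    expect_equal(correlation_p_value(r, n), q, tolerance = 1e-6)
  }
  # perfectly linear data
  res1 <- pearson_correlation(1:10, 2 * (1:10) + 3)
  expect_equal(res1$r, 1)
  expect_equal(res1$p, 0)
  expect_error(pearson_correlation(rep(1, 10), rnorm(10)))
})

test_that("Spearman option reports the rank correlation", {
  set.seed(20)
  x <- rnorm(30); y <- exp(x) + rnorm(30, sd = 0.1)
  res <- pearson_correlation(x, y, method = "spearman")
  expect_equal(res$r, cor(x, y, method = "spearman"), tolerance = 1e-12)
})

test_that("Fisher comparison of correlations is calibrated and antisymmetric", {
  expect_equal(compare_correlations(0.4, 30, 0.4, 30)$z, 0)
  expect_equal(compare_correlations(0.4, 30, 0.4, 30)$p, 1)
  a <- compare_correlations(0.5, 40, -0.2, 35)
  b <- compare_correlations(-0.2, 35, 0.5, 40)
  expect_equal(a$z, -b$z, tolerance = 1e-12)
  expect_equal(a$p, b$p, tolerance = 1e-12)
  expect_equal(a$z, (atanh(0.5) - atanh(-0.2)) / sqrt(1 / 37 + 1 / 32),
               tolerance = 1e-12)
  expect_error(compare_correlations(0.5, 3, 0.2, 30))
})

test_that("two-metric PCA follows the closed-form eigenstructure", {
  # exactly anticorrelated columns
  x <- scale(rnorm(50))[, 1]
  tab <- data.frame(sc_global_clust = x, fc_global_clust = -2 * x + 1)
  res <- pca_structure_function(tab)
  expect_equal(res$variance_explained, 1, tolerance = 1e-12)
  expect_equal(unname(res$loadings), c(1, -1) / sqrt(2), tolerance = 1e-10)
  expect_gt(res$loadings["sc_global_clust"], 0)

  # exactly uncorrelated columns split the variance evenly
  pr <- exact_correlation_pair(60, 0, seed = 9)
  tab0 <- data.frame(sc_global_clust = pr$x, fc_global_clust = pr$y)
  expect_equal(pca_structure_function(tab0)$variance_explained, 0.5,
               tolerance = 1e-12)

  # (1 + |r|)/2 identity at r = -0.18
  pr2 <- exact_correlation_pair(60, -0.18, seed = 10)
  tab2 <- data.frame(sc_global_clust = pr2$x, fc_global_clust = pr2$y)
  res2 <- pca_structure_function(tab2)
  expect_equal(res2$r, -0.18, tolerance = 1e-10)
  expect_equal(res2$variance_explained, (1 + 0.18) / 2, tolerance = 1e-10)
  expect_error(pca_structure_function(
    data.frame(sc_global_clust = rep(1, 10), fc_global_clust = rnorm(10))))
})

test_that("Mahalanobis composite measures deviance from controls", {
  set.seed(11)
  controls <- as.data.frame(matrix(rnorm(40 * 4), 40))
  names(controls) <- c("ravlt_total", "ravlt_interference", "ctmt1", "cowa")
  # whiten so the control sample covariance is exactly the identity
  xc <- as.matrix(controls)
  w <- solve(chol(cov(xc)))
  xw <- scale(xc, center = TRUE, scale = FALSE) %*% w
  cw <- as.data.frame(xw); names(cw) <- names(controls)
  pat <- as.data.frame(rbind(colMeans(xw),            # at the control mean
                             colMeans(xw) + c(1, 0, 0, 0)))
  names(pat) <- names(controls)
  res <- mahalanobis_composite(pat, cw)
  expect_equal(res$mhd[1], 0, tolerance = 1e-7)
  expect_equal(res$mhd[2], 1, tolerance = 1e-7)
  expect_equal(res$log_mhd[2], 0, tolerance = 1e-6)
  expect_lt(res$log_mhd[1], -20)   # floored at 1e-12 before the log

  # singular covariance is refused with advice
  cs <- cw; cs$cowa <- cs$ctmt1
  expect_error(mahalanobis_composite(pat, cs), "reduce")
})

test_that("Mahalanobis composite matches a solve oracle and affine invariance", {
  set.seed(12)
  controls <- as.data.frame(matrix(rnorm(30 * 4), 30))
  patients <- as.data.frame(matrix(rnorm(10 * 4, mean = 0.5), 10))
  names(controls) <- names(patients) <-
    c("ravlt_total", "ravlt_interference", "ctmt1", "cowa")
  res <- mahalanobis_composite(patients, controls)
  mu <- colMeans(controls)
  sig <- cov(controls)
  for (i in 1:10) {
    d <- as.numeric(as.matrix(patients)[i, ] - mu)
    expect_equal(res$mhd[i], sqrt(sum(d * solve(sig, d))), tolerance = 1e-10)
  }
  # invariance under a joint invertible affine transform
  a <- matrix(c(2, 0.3, 0, 1, 1.5, 0, 0.2, 0, 1, 0.1, 3, 0, 0.5, 0, 0, 1), 4)
  shift <- c(10, -5, 3, 0)
  tr <- function(df) {
    out <- as.data.frame(sweep(as.matrix(df) %*% a, 2, shift, "+"))
    names(out) <- names(df)
    out
  }
  res2 <- mahalanobis_composite(tr(patients), tr(controls))
  expect_equal(res2$mhd, res$mhd, tolerance = 1e-8)
})

test_that("statistical battery assembles every analysis layer", {
  cfg <- simulation_config(n_patients = 20, n_controls = 20, seed = 15)
  tab <- simulate_cognitive_scores(cfg)
  set.seed(16)
  tab$fc_global_clust <- rnorm(40, 0.5, 0.05)
  tab$sc_global_clust <- rnorm(40, 0.7, 0.01)
  tab$sc_n_nodes <- rpois(40, 270)
  tab$global_h <- rnorm(40, 0.2, 0.05)
  nodal <- list(
    fc_local_clust = matrix(rnorm(40 * 6, 0.5, 0.1), 40,
                            dimnames = list(NULL, paste0("R", 1:6))),
    local_h = matrix(rnorm(40 * 6, 0.2, 0.1), 40,
                     dimnames = list(NULL, paste0("R", 1:6))))
  res <- run_statistical_battery(tab, nodal)
  expect_setequal(names(res), c("cognitive", "global_metrics", "local",
                                "coupling", "pca", "pca_mhd", "composite",
                                "exploratory"))
  # FDR family excludes self-report rows
  expect_true(all(is.na(res$cognitive$p_fdr[res$cognitive$family ==
                                              "self_report"])))
  expect_true(all(!is.na(res$cognitive$p_fdr[res$cognitive$family ==
                                               "performance"])))
  expect_identical(nrow(res$cognitive), 11L)
  # global H uses the rank test
  expect_identical(res$global_metrics$test[3], "wilcoxon_u")
  # local tables carry FDR per metric
  expect_identical(nrow(res$local), 12L)
  expect_true(all(res$local$p_fdr >= res$local$p, na.rm = TRUE))
  # composite covers each patient
  expect_identical(nrow(res$composite), 20L)
  # determinism: same inputs give identical outputs
  res2 <- run_statistical_battery(tab, nodal)
  expect_identical(res, res2)
})
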