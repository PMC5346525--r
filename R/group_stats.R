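#' Covariate-adjusted group comparison by general linear model
#'
#' Ordinary-least-squares fit of `outcome ~ group + covariates`; the group
#' effect is tested by model comparison (full vs group-dropped reduced
#' model), which reproduces the GLM F test for a single two-level factor
#' regardless of contrast coding.
#'
#' @param table data frame with one row per subject, containing `group`
#'   plus the named columns
#' @param outcome name of the numeric outcome column
#' @param covariates character vector of covariate column names (may be
#'   empty)
#' @return list with `outcome`, `f`, `p`, `df`, `covariate_p` (named
#'   p-values of the covariate terms)
#' @export
glm_group_comparison <- function(table, outcome, covariates = character()) {
  stopifnot(outcome %in% names(table), all(covariates %in% names(table)),
            is.numeric(table[[outcome]]))
  d <- table[, c(outcome, "group", covariates), drop = FALSE]
  d$group <- factor(d$group)
  rhs_red <- if (length(covariates)) paste(covariates, collapse = " + ") else "1"
  full <- stats::lm(stats::reformulate(c("group", covariates), outcome), data = d)
  if (any(is.na(stats::coef(full)))) {
    bad <- names(stats::coef(full))[is.na(stats::coef(full))]
    stop("rank-deficient design; collinear terms: ", paste(bad, collapse = ", "))
  }
  reduced <- stats::lm(stats::reformulate(rhs_red, outcome), data = d)
  if (stats::var(d[[outcome]]) == 0) {
    return(list(outcome = outcome, f = 0, p = 1, df = c(NA, NA),
                covariate_p = stats::setNames(rep(NA_real_, length(covariates)),
                                              covariates)))
  }
  a <- stats::anova(reduced, full)
  f <- a$F[2]
  p <- a$`Pr(>F)`[2]
  cov_p <- stats::setNames(rep(NA_real_, length(covariates)), covariates)
  if (length(covariates)) {
    ct <- summary(full)$coefficients
    for (cv in covariates) {
      rows <- grep(paste0("^", cv), rownames(ct))
      if (length(rows)) cov_p[cv] <- min(ct[rows, 4])
    }
  }
  list(outcome = outcome, f = f, p = p, df = unname(a$Df[2]), covariate_p = cov_p)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (monotone, capped at 1), in the input order.
#'
#' @param pvalues numeric vector of p-values in [0, 1]
#' @return adjusted p-values, same order
#' @export
fdr_adjust <- function(pvalues) {
  if (length(pvalues) == 0) return(numeric(0))
  stopifnot(all(pvalues >= 0 & pvalues <= 1, na.rm = TRUE))
  stats::p.adjust(pvalues, method = "BH")
}

#' Wilcoxon rank (Mann-Whitney U) test, normal approximation
#'
#' U is the number of (x, y) pairs with x < y plus half the ties; the
#' two-tailed p comes from the normal approximation
#' \deqn{z = \frac{U - n_1 n_2 / 2}{\sqrt{n_1 n_2 (n_1 + n_2 + 1)/12}}}
#' with tie-corrected variance; no continuity correction. Used for
#' outcomes (such as Hurst long memory) that are not normally distributed.
#'
#' If all values across both samples are tied, p = 1.
#'
#' @param x,y numeric samples
#' @return list with `u`, `z`, `p`
#' @export
wilcoxon_rank <- function(x, y) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  n1 <- length(x); n2 <- length(y)
  u <- sum(outer(x, y, "<")) + 0.5 * sum(outer(x, y, "=="))
  ranks <- rank(c(x, y))
  ties <- table(ranks)
  n <- n1 + n2
  var_u <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (var_u <= 0) return(list(u = u, z = 0, p = 1))
  z <- (u - n1 * n2 / 2) / sqrt(var_u)
  list(u = u, z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Two-tailed p-value for a Pearson correlation
#'
#' @param r correlation
#' @param n sample size (> 2)
#' @return two-tailed p from t = r sqrt(n-2)/sqrt(1-r^2) on n-2 df
#' @export
correlation_p_value <- function(r, n) {
  stopifnot(abs(r) <= 1, n > 2)
  if (abs(r) >= 1) return(0)
  t <- r * sqrt(n - 2) / sqrt(1 - r^2)
  2 * stats::pt(-abs(t), df = n - 2)
}

#' Pearson correlation with two-tailed inference
#'
#' @param x,y numeric vectors of equal length >= 4 with nonzero variance
#' @param method `"pearson"` or `"spearman"` (rank correlation; p from the
#'   same t reference on the rank correlation)
#' @return list with `r`, `n`, `p`
#' @export
pearson_correlation <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y), length(x) >= 4)
  if (stats::var(x) == 0 || stats::var(y) == 0) stop("zero-variance input")
  r <- stats::cor(x, y, method = method)
  list(r = r, n = length(x), p = correlation_p_value(r, length(x)))
}

#' Compare two independent correlations (Fisher r-to-z)
#'
#' Two-tailed test of r1 vs r2 from independent samples:
#' \deqn{z = \frac{\mathrm{atanh}(r_1) - \mathrm{atanh}(r_2)}
#'   {\sqrt{1/(n_1 - 3) + 1/(n_2 - 3)}},}
#' p from the standard normal. Antisymmetric in its arguments.
#'
#' @param r1,r2 correlations, |r| < 1
#' @param n1,n2 sample sizes, > 3
#' @return list with `z`, `p`
#' @export
compare_correlations <- function(r1, n1, r2, n2) {
  stopifnot(abs(r1) < 1, abs(r2) < 1)
  if (n1 <= 3 || n2 <= 3) stop("sample sizes must exceed 3")
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Two-tailed normal p-value for a Fisher comparison z
#'
#' @param z standard-normal test statistic
#' @return 2(1 - Phi(|z|))
#' @export
fisher_z_p_value <- function(z) 2 * stats::pnorm(-abs(z))

#' Two-tailed normal-approximation p-value from a Mann-Whitney U
#'
#' Inference from a reported U statistic and group sizes (no tie
#' information): z = (U - n1 n2/2) / sqrt(n1 n2 (n1 + n2 + 1)/12).
#'
#' @param u the U statistic
#' @param n1,n2 group sizes
#' @return list with `z` and two-tailed `p`
#' @export
wilcoxon_u_p_value <- function(u, n1, n2) {
  z <- (u - n1 * n2 / 2) / sqrt(n1 * n2 * (n1 + n2 + 1) / 12)
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' First principal component of structural and functional clustering
#'
#' Z-scores the two clustering columns across all participants (both
#' groups), eigendecomposes their 2x2 correlation matrix, and returns the
#' first component, oriented so the structural loading is positive. For a
#' 2x2 correlation matrix with off-diagonal r the leading eigenvalue is
#' 1 + |r|, so the first component explains (1 + |r|)/2 of the variance.
#'
#' @param table data frame with `sc_global_clust` and `fc_global_clust`
#' @return list with `loadings` (named, structural first), `scores`,
#'   `variance_explained`, `r` (the cross-metric correlation)
#' @export
pca_structure_function <- function(table) {
  sc <- table$sc_global_clust
  fc <- table$fc_global_clust
  stopifnot(!is.null(sc), !is.null(fc), all(is.finite(sc)), all(is.finite(fc)))
  if (stats::var(sc) == 0 || stats::var(fc) == 0) stop("constant metric column")
  zs <- cbind(sc = scale(sc)[, 1], fc = scale(fc)[, 1])
  cm <- stats::cor(zs)
  e <- eigen(cm, symmetric = TRUE)
  v1 <- e$vectors[, 1]
  if (v1[1] < 0) v1 <- -v1
  list(loadings = stats::setNames(v1, c("sc_global_clust", "fc_global_clust")),
       scores = as.numeric(zs %*% v1),
       variance_explained = e$values[1] / 2,
       r = cm[1, 2])
}

#' Log-Mahalanobis cognitive composite
#'
#' Per-patient Mahalanobis distance of the selected cognitive scores from
#' the control group (control mean and unbiased control covariance define
#' the metric, so the distance measures deviance from controls), then the
#' natural log. Distances are floored at 1e-12 before the log so a patient
#' exactly at the control mean yields a finite (very negative) value.
#'
#' @param patients,controls data frames of score columns
#' @param score_names columns to use; default the four tests that
#'   typically survive FDR in pretreatment cohorts (RAVLT total recall and
#'   interference, CTMT trial 1, COWA)
#' @return list with `mhd` (distances) and `log_mhd`
#' @export
mahalanobis_composite <- function(patients, controls,
                                  score_names = c("ravlt_total",
                                                  "ravlt_interference",
                                                  "ctmt1", "cowa")) {
  stopifnot(all(score_names %in% names(patients)),
            all(score_names %in% names(controls)))
  xc <- as.matrix(controls[, score_names, drop = FALSE])
  xp <- as.matrix(patients[, score_names, drop = FALSE])
  if (nrow(xc) < length(score_names) + 2) {
    stop("need at least ", length(score_names) + 2, " control rows")
  }
  mu <- colMeans(xc)
  sigma <- stats::cov(xc)
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-12 * max(ev)) {
    stop("singular control covariance; reduce the score set")
  }
  d <- sqrt(stats::mahalanobis(xp, mu, sigma))
  d_floor <- pmax(d, 1e-12)
  list(mhd = d, log_mhd = log(d_floor))
}

#' Full statistical battery over a cohort table
#'
#' Reproduces the analysis layers of a two-group multimodal connectome
#' study:
#' \itemize{
#'   \item cognitive group comparisons (GLM with minority status and
#'     distress covariates), BH-FDR over the performance measures;
#'     self-report measures are modeled but kept outside the FDR family
#'   \item global brain metrics: GLM for functional/structural global
#'     clustering (structural additionally covaried for connectome size),
#'     Wilcoxon rank test for global Hurst long memory
#'   \item per-region local comparisons with FDR (functional clustering,
#'     structural clustering, local Hurst), when nodal tables are given
#'   \item within-group correlations among structural clustering,
#'     functional clustering and Hurst, with between-group Fisher
#'     comparisons
#'   \item PCA structure-function component and its correlation with the
#'     log-Mahalanobis cognitive composite (patients)
#'   \item exploratory, uncorrected correlations of patient brain metrics
#'     with demographics (flagged exploratory)
#' }
#'
#' @param table cohort data frame (one row per subject) with columns
#'   `subject_id`, `group` ("patient"/"control"), `minority`, `cad_score`,
#'   the cognitive scores, `fc_global_clust`, `sc_global_clust`,
#'   `sc_n_nodes`, `global_h`
#' @param nodal optional named list of per-region tables (subjects x
#'   regions): `fc_local_clust`, `sc_local_clust`, `local_h`
#' @param composite_scores score set for the Mahalanobis composite
#' @return named list of result data frames
#' @export
run_statistical_battery <- function(table, nodal = NULL,
                                    composite_scores = c("ravlt_total",
                                                         "ravlt_interference",
                                                         "ctmt1", "cowa")) {
  stopifnot(all(c("group", "minority", "cad_score") %in% names(table)))
  table$group <- factor(table$group, levels = c("control", "patient"))
  stopifnot(all(table(table$group) >= 4), !anyDuplicated(table$subject_id))
  is_pat <- table$group == "patient"

  perf <- c("ravlt_total", "ravlt_interference", "ravlt_delayed",
            paste0("ctmt", 1:5), "cowa")
  selfrep <- c("brief_gec", "prmq")
  perf <- intersect(perf, names(table))
  selfrep <- intersect(selfrep, names(table))

  cog_rows <- lapply(c(perf, selfrep), function(v) {
    res <- glm_group_comparison(table, v, c("minority", "cad_score"))
    data.frame(measure = v, f = res$f, p = res$p,
               family = if (v %in% perf) "performance" else "self_report",
               stringsAsFactors = FALSE)
  })
  cognitive <- do.call(rbind, cog_rows)
  cognitive$p_fdr <- NA_real_
  in_fam <- cognitive$family == "performance"
  cognitive$p_fdr[in_fam] <- fdr_adjust(cognitive$p[in_fam])

  glob_fc <- glm_group_comparison(table, "fc_global_clust",
                                  c("minority", "cad_score"))
  glob_sc <- glm_group_comparison(table, "sc_global_clust",
                                  c("minority", "cad_score", "sc_n_nodes"))
  wt <- wilcoxon_rank(table$global_h[is_pat], table$global_h[!is_pat])
  global_metrics <- data.frame(
    metric = c("fc_global_clust", "sc_global_clust", "global_h"),
    statistic = c(glob_fc$f, glob_sc$f, wt$u),
    test = c("glm_f", "glm_f", "wilcoxon_u"),
    p = c(glob_fc$p, glob_sc$p, wt$p),
    stringsAsFactors = FALSE
  )

  local_results <- NULL
  if (!is.null(nodal)) {
    local_results <- do.call(rbind, lapply(names(nodal), function(nm) {
      mat <- as.matrix(nodal[[nm]])
      use_rank <- nm == "local_h"
      p <- apply(mat, 2L, function(col) {
        ok <- is.finite(col)
        if (sum(ok & is_pat) < 4 || sum(ok & !is_pat) < 4) return(NA_real_)
        if (use_rank) {
          wilcoxon_rank(col[ok & is_pat], col[ok & !is_pat])$p
        } else {
          d <- table[ok, ]
          d$.y <- col[ok]
          cv <- if (nm == "sc_local_clust") {
            c("minority", "cad_score", "sc_n_nodes")
          } else c("minority", "cad_score")
          glm_group_comparison(d, ".y", cv)$p
        }
      })
      data.frame(metric = nm, region = colnames(mat), p = p,
                 p_fdr = fdr_adjust(p), stringsAsFactors = FALSE,
                 row.names = NULL)
    }))
  }

  pairs <- list(c("sc_global_clust", "fc_global_clust"),
                c("sc_global_clust", "global_h"),
                c("fc_global_clust", "global_h"))
  corr_rows <- lapply(pairs, function(pr) {
    cp <- pearson_correlation(table[[pr[1]]][is_pat], table[[pr[2]]][is_pat])
    cc <- pearson_correlation(table[[pr[1]]][!is_pat], table[[pr[2]]][!is_pat])
    fz <- compare_correlations(cp$r, cp$n, cc$r, cc$n)
    data.frame(var1 = pr[1], var2 = pr[2],
               r_patient = cp$r, p_patient = cp$p,
               r_control = cc$r, p_control = cc$p,
               fisher_z = fz$z, fisher_p = fz$p, stringsAsFactors = FALSE)
  })
  coupling <- do.call(rbind, corr_rows)

  pca <- pca_structure_function(table)
  comp <- mahalanobis_composite(table[is_pat, ], table[!is_pat, ],
                                score_names = composite_scores)
  pc_cor <- pearson_correlation(pca$scores[is_pat], comp$log_mhd)
  composite <- data.frame(
    subject_id = table$subject_id[is_pat],
    mhd = comp$mhd, log_mhd = comp$log_mhd, pca_score = pca$scores[is_pat],
    stringsAsFactors = FALSE
  )

  demo_vars <- intersect(c("age", "education_years"), names(table))
  exploratory <- NULL
  if (length(demo_vars)) {
    exploratory <- do.call(rbind, lapply(demo_vars, function(v) {
      do.call(rbind, lapply(c("global_h", "fc_global_clust",
                              "sc_global_clust"), function(m) {
        ct <- pearson_correlation(table[[v]][is_pat], table[[m]][is_pat])
        data.frame(variable = v, metric = m, r = ct$r, p = ct$p,
                   note = "exploratory_uncorrected", stringsAsFactors = FALSE)
      }))
    }))
  }

  list(cognitive = cognitive,
       global_metrics = global_metrics,
       local = local_results,
       coupling = coupling,
       pca = pca,
       pca_mhd = data.frame(r = pc_cor$r, n = pc_cor$n, p = pc_cor$p),
       composite = composite,
       exploratory = exploratory)
}
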