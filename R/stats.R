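## Group statistics ----------------------------------------------------------

## Orthonormal contrast matrix over k within-subject levels (k x (k-1)).
orthonormal_contrasts <- function(k) {
  qr.Q(qr(stats::contr.helmert(k)))
}

#' Mauchly's sphericity test
#'
#' Tests sphericity of the covariance of `k` within-subject responses via
#' the likelihood-ratio statistic `W = det(S) / (tr(S)/(k-1))^(k-1)` on the
#' orthonormal-contrast covariance `S`, with the standard chi-square
#' approximation.  With `k = 2` there is a single contrast, `W` is exactly 1
#' and the test is not applicable.
#'
#' @param y numeric matrix, subjects x k within-subject levels.
#' @param df_resid residual degrees of freedom of `S`; defaults to
#'   `nrow(y) - 1` (covariance about the mean).
#' @return list with `W`, `statistic`, `df`, `p.value`, `applicable`.
#' @export
mauchly_test <- function(y, df_resid = nrow(y) - 1) {
  y <- as.matrix(y)
  k <- ncol(y)
  if (k < 2) lp_stop("bad_input", "need at least 2 within-subject levels")
  if (nrow(y) <= k) lp_stop("bad_input", "need more subjects than levels")
  p <- k - 1
  if (k == 2)
    return(list(W = 1, statistic = NA_real_, df = NA_real_,
                p.value = NA_real_, applicable = FALSE))
  S <- crossprod_contrast_cov(y, df_resid)
  mauchly_from_S(S, df_resid)
}

mauchly_from_S <- function(S, df_resid) {
  p <- ncol(S)
  W <- det(S) / (sum(diag(S)) / p)^p
  f <- df_resid - (2 * p^2 + p + 2) / (6 * p)
  chi2 <- -f * log(W)
  df <- p * (p + 1) / 2 - 1
  list(W = W, statistic = chi2, df = df,
       p.value = pchisq(chi2, df, lower.tail = FALSE), applicable = TRUE)
}

crossprod_contrast_cov <- function(y, df_resid) {
  C <- orthonormal_contrasts(ncol(y))
  Z <- y %*% C
  Zc <- scale(Z, center = TRUE, scale = FALSE)
  crossprod(Zc) / df_resid
}

#' Greenhouse-Geisser epsilon
#'
#' `epsilon = (sum lambda)^2 / ((k-1) * sum lambda^2)` over the eigenvalues
#' of the orthonormal-contrast covariance; 1 under sphericity, bounded below
#' by `1/(k-1)`.
#'
#' @inheritParams mauchly_test
#' @return scalar epsilon.
#' @export
gg_epsilon <- function(y, df_resid = nrow(y) - 1) {
  y <- as.matrix(y)
  k <- ncol(y)
  if (k < 2) lp_stop("bad_input", "need at least 2 within-subject levels")
  p <- k - 1
  S <- crossprod_contrast_cov(y, df_resid)
  sum(diag(S))^2 / (p * sum(S * S))
}

#' Split-plot (mixed between-within) repeated-measures ANOVA
#'
#' One between-subject factor (group) and one within-subject factor
#' (condition), complete within-subject data, groups possibly unbalanced
#' (Type-III-style hypotheses via sum-to-zero coding, so the within-subject
#' effects test unweighted group means).  Reports the uncorrected F tests,
#' Mauchly's sphericity test on the residual contrast covariance, the
#' Greenhouse-Geisser epsilon and epsilon-corrected p-values (identical to
#' the uncorrected ones when `k = 2`, where epsilon is 1 by construction).
#'
#' @param data data frame with one row per subject x condition.
#' @param value,subject,group,within names of the respective columns.
#' @return object of class `split_plot_anova`: `table` (one row per effect
#'   with F, df, p, and GG-corrected df/p), `epsilon`, `mauchly`, and the
#'   wide response matrix used.
#' @export
split_plot_anova <- function(data, value = "value", subject = "subject",
                             group = "group", within = "condition") {
  df <- data.frame(subject = factor(data[[subject]]),
                   group = factor(data[[group]]),
                   within = factor(data[[within]]),
                   value = as.numeric(data[[value]]))
  k <- nlevels(df$within)
  subj <- levels(df$subject)
  if (nrow(df) != length(subj) * k || anyNA(df$value))
    lp_stop("incomplete_design",
            "each subject must have exactly one value per within level")
  ## wide response matrix, subjects x k
  Y <- matrix(NA_real_, length(subj), k,
              dimnames = list(subj, levels(df$within)))
  Y[cbind(as.integer(df$subject), as.integer(df$within))] <- df$value
  g <- factor(vapply(subj, function(s) {
    as.character(df$group[df$subject == s][1])
  }, ""))
  N <- nrow(Y); G <- nlevels(g); p <- k - 1
  if (G < 2) lp_stop("bad_input", "need at least 2 groups")
  if (k < 2) lp_stop("bad_input", "need at least 2 within levels")

  ## Effects with numerically zero SS (e.g. constant responses) are reported
  ## as F = 0, p = 1 rather than 0/0.
  tol0 <- 1e-10 * max(1, sum(Y^2))
  safe_f <- function(ss_h, df_h, ss_e, df_e2) {
    if (ss_h < tol0) return(list(F = 0, p = 1))
    f <- (ss_h / df_h) / (ss_e / df_e2)
    list(F = f, p = pf(f, df_h, df_e2, lower.tail = FALSE))
  }

  ## between stratum: one-way decomposition of the subject means
  ## (x k for the SS scale of the full table)
  m <- rowMeans(Y)
  m_g <- tapply(m, g, mean)
  ss_group <- sum(tabulate(g) * (m_g - mean(m))^2)
  ss_subj <- sum((m - m_g[as.integer(g)])^2)
  fb <- safe_f(ss_group, G - 1, ss_subj, N - G)
  between <- data.frame(
    effect = "group", df1 = G - 1, df2 = N - G,
    SS = k * ss_group, F = fb$F, p = fb$p
  )

  ## within stratum: orthonormal contrasts, mlm on the group design
  C <- orthonormal_contrasts(k)
  Z <- Y %*% C
  X <- stats::model.matrix(~g, data = data.frame(g = g),
                           contrasts.arg = list(g = "contr.sum"))
  fit <- lm.fit(X, Z)
  B <- matrix(fit$coefficients, nrow = ncol(X), ncol = ncol(Z))
  E <- crossprod(Z - X %*% B)
  XtXinv <- chol2inv(chol(crossprod(X)))
  SSE <- sum(diag(E))
  df_e <- N - G

  hyp_ss <- function(rows) {
    L <- diag(ncol(X))[rows, , drop = FALSE]
    LB <- L %*% B
    H <- t(LB) %*% solve(L %*% XtXinv %*% t(L)) %*% LB
    sum(diag(H))
  }
  SS_cond <- hyp_ss(1L)
  SS_int <- hyp_ss(seq(2L, G))
  fc <- safe_f(SS_cond, p, SSE, p * df_e)
  fi <- safe_f(SS_int, p * (G - 1), SSE, p * df_e)

  S <- E / df_e
  eps <- if (p == 1) 1 else sum(diag(S))^2 / (p * sum(S * S))
  eps <- min(max(eps, 1 / p), 1)
  mau <- if (k > 2) mauchly_from_S(S, df_e) else
    list(W = 1, statistic = NA_real_, df = NA_real_, p.value = NA_real_,
         applicable = FALSE)

  within_tab <- data.frame(
    effect = c("condition", "group:condition"),
    df1 = c(p, p * (G - 1)), df2 = c(p * df_e, p * df_e),
    SS = c(SS_cond, SS_int), F = c(fc$F, fi$F),
    p = c(fc$p, fi$p)
  )
  within_tab$df1_gg <- within_tab$df1 * eps
  within_tab$df2_gg <- within_tab$df2 * eps
  within_tab$p_gg <- pf(within_tab$F, within_tab$df1_gg, within_tab$df2_gg,
                        lower.tail = FALSE)
  between$df1_gg <- between$df1; between$df2_gg <- between$df2
  between$p_gg <- between$p
  tab <- rbind(between, within_tab)
  rownames(tab) <- NULL

  structure(list(table = tab, epsilon = eps, mauchly = mau,
                 response = Y, group = g, error_ss = SSE),
            class = "split_plot_anova")
}

#' @export
print.split_plot_anova <- function(x, ...) {
  cat("Split-plot repeated-measures ANOVA\n")
  tab <- x$table
  tab$F <- round(tab$F, 3); tab$p <- signif(tab$p, 3)
  tab$p_gg <- signif(tab$p_gg, 3)
  print(tab[, c("effect", "df1", "df2", "F", "p", "p_gg")],
        row.names = FALSE)
  cat(sprintf("Greenhouse-Geisser epsilon: %.3f; Mauchly W = %s (p = %s)\n",
              x$epsilon,
              if (x$mauchly$applicable) sprintf("%.3f", x$mauchly$W) else "1 (k=2, not applicable)",
              if (x$mauchly$applicable) signif(x$mauchly$p.value, 3) else "-"))
  invisible(x)
}

#' Bonferroni adjustment
#'
#' `p_adj = min(1, m * p)` for a family of `m` comparisons.
#'
#' @param p raw p-values.
#' @param m family size (defaults to `length(p)`).
#' @return adjusted p-values.
#' @export
bonferroni_adjust <- function(p, m = length(p)) {
  if (m < 1) lp_stop("bad_input", "m must be >= 1")
  pmin(1, m * p)
}

#' Pairwise group comparisons with Bonferroni correction
#'
#' Two-sample t-tests for every pair of groups with Bonferroni-adjusted
#' p-values (`m = G*(G-1)/2`).
#'
#' @param values numeric response.
#' @param groups group labels.
#' @param var_equal use pooled-variance t-tests.
#' @return data.frame with one row per pair.
#' @export
bonferroni_posthoc <- function(values, groups, var_equal = TRUE) {
  g <- factor(groups)
  pairs <- utils::combn(levels(g), 2)
  m <- ncol(pairs)
  res <- lapply(seq_len(m), function(j) {
    a <- values[g == pairs[1, j]]; b <- values[g == pairs[2, j]]
    tt <- stats::t.test(a, b, var.equal = var_equal)
    data.frame(group1 = pairs[1, j], group2 = pairs[2, j],
               diff = mean(a) - mean(b), t = unname(tt$statistic),
               p = tt$p.value)
  })
  out <- do.call(rbind, res)
  out$p_bonf <- bonferroni_adjust(out$p, m)
  out
}

#' Permutation test of a between-group effect
#'
#' Permutation p-value for the one-way F statistic under random reassignment
#' of group labels; a distribution-free companion to the ANOVA.
#'
#' @param values numeric response (one value per subject).
#' @param groups group labels.
#' @param n_perm number of permutations.
#' @param seed optional seed for the permutation stream.
#' @return list with `p.value`, `F`, `n_perm`.
#' @export
permutation_group_test <- function(values, groups, n_perm = 999,
                                   seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- factor(groups)
  if (nlevels(g) < 2) lp_stop("bad_input", "need at least 2 groups")
  fstat <- function(v, gg) {
    gm <- tapply(v, gg, mean); n <- tapply(v, gg, length)
    ssb <- sum(n * (gm - mean(v))^2)
    ssw <- sum((v - gm[gg])^2)
    (ssb / (nlevels(gg) - 1)) / (ssw / (length(v) - nlevels(gg)))
  }
  f0 <- fstat(values, g)
  hits <- sum(vapply(seq_len(n_perm), function(i) {
    fstat(values, sample(g)) >= f0
  }, logical(1)))
  list(p.value = (1 + hits) / (n_perm + 1), F = f0, n_perm = n_perm)
}
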