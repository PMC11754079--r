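#' @name stats_battery
#' @title Statistical battery
#' @description Two-tailed unpaired t-tests, Mann-Whitney tests, two-way
#'   ANOVAs (with or without repeated measures) with Holm-Sidak post hoc,
#'   Kruskal-Wallis with Dunn's post hoc, Lilliefors-corrected
#'   Kolmogorov-Smirnov normality gating, and ROUT outlier flagging — the
#'   full battery applied to per-cell and per-animal measures, with exact
#'   small-sample behaviour where feasible.
NULL

new_stat_result <- function(test_name, statistic_value, df = NULL, p_value,
                            posthoc = NULL, n_per_group = NULL, extra = list()) {
  structure(c(list(test_name = test_name, statistic_value = statistic_value,
                   df = df, p_value = p_value, posthoc = posthoc,
                   n_per_group = n_per_group), extra),
            class = "stat_test_result")
}

#' @export
print.stat_test_result <- function(x, ...) {
  dfs <- if (is.null(x$df)) "" else sprintf("(%s)", paste(round(x$df, 2), collapse = ", "))
  cat(sprintf("%s: statistic%s = %.4g, p = %.4g\n",
              x$test_name, dfs, x$statistic_value, x$p_value))
  if (!is.null(x$posthoc)) { cat("post hoc:\n"); print(x$posthoc) }
  invisible(x)
}

#' Two-tailed unpaired t-test (pooled variance)
#'
#' Classical two-sample t with pooled variance, df = n1 + n2 - 2. Degenerate
#' zero-variance data with equal means give t = 0, p = 1.
#'
#' @param x,y Numeric samples (n >= 2 each).
#' @return A `stat_test_result`.
#' @export
t_test_unpaired <- function(x, y) {
  stopifnot(length(x) >= 2, length(y) >= 2)
  if (stats::var(x) == 0 && stats::var(y) == 0 && mean(x) == mean(y)) {
    return(new_stat_result("unpaired t", 0, df = length(x) + length(y) - 2,
                           p_value = 1, n_per_group = c(length(x), length(y))))
  }
  tt <- stats::t.test(x, y, var.equal = TRUE)
  new_stat_result("unpaired t", unname(tt$statistic), df = unname(tt$parameter),
                  p_value = tt$p.value, n_per_group = c(length(x), length(y)))
}

#' Mann-Whitney U test
#'
#' U is reported as `min(U1, U2)`. The two-tailed p-value is exact (from the
#' null U distribution) when `n1 + n2 <= 20` and the data are tie-free, and a
#' tie-corrected normal approximation (no continuity correction) otherwise.
#'
#' @param x,y Numeric samples (n >= 1 each).
#' @return A `stat_test_result` with `extra` fields `U1`, `U2`, `z`, `exact`.
#' @export
mann_whitney <- function(x, y) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  R1 <- sum(r[seq_len(n1)])
  U1 <- R1 - n1 * (n1 + 1) / 2
  U2 <- n1 * n2 - U1
  U <- min(U1, U2)
  ties <- any(duplicated(c(x, y)))
  exact <- (n1 + n2 <= 20) && !ties
  if (exact) {
    # two-tailed: twice the lower tail at min(U1, U2) of the symmetric
    # exact null distribution of U
    p <- min(1, 2 * stats::pwilcox(U, n1, n2))
    z <- NA_real_
  } else {
    N <- n1 + n2
    tie_tab <- table(c(x, y))
    tie_term <- sum(tie_tab^3 - tie_tab) / (N * (N - 1))
    sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
    if (sigma2 <= 0) {
      z <- 0; p <- 1
    } else {
      z <- (U1 - n1 * n2 / 2) / sqrt(sigma2)
      p <- 2 * stats::pnorm(-abs(z))
    }
  }
  new_stat_result("Mann-Whitney", U, df = NULL, p_value = min(1, p),
                  n_per_group = c(n1, n2),
                  extra = list(U1 = U1, U2 = U2, z = if (exact) NA_real_ else z,
                               exact = exact))
}

#' Kruskal-Wallis ANOVA on ranks
#'
#' Tie-corrected H with a chi-square p-value on k - 1 df. With two groups the
#' statistic equals the square of the Mann-Whitney normal deviate.
#'
#' @param groups List of numeric vectors (>= 2 groups).
#' @return A `stat_test_result`.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(length(groups) >= 2)
  vals <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (length(unique(vals)) == 1) {
    return(new_stat_result("Kruskal-Wallis", 0, df = length(groups) - 1,
                           p_value = 1, n_per_group = lengths(groups)))
  }
  kt <- stats::kruskal.test(vals, g)
  new_stat_result("Kruskal-Wallis", unname(kt$statistic),
                  df = unname(kt$parameter), p_value = kt$p.value,
                  n_per_group = unname(lengths(groups)))
}

#' Dunn's post-hoc test after Kruskal-Wallis
#'
#' Pairwise z statistics from pooled ranks with tie correction, adjusted for
#' multiplicity over the declared contrast family (Holm-Sidak by default).
#'
#' @param groups Named (or positionally numbered) list of numeric vectors.
#' @param contrasts Optional list of length-2 character vectors naming group
#'   pairs; defaults to all pairwise comparisons.
#' @param adjust `"holm_sidak"`, `"holm"` or `"none"`.
#' @return `data.frame` with `contrast`, `z`, `p_raw`, `p_adjusted`.
#' @export
dunn_posthoc <- function(groups, contrasts = NULL, adjust = "holm_sidak") {
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  vals <- unlist(groups, use.names = FALSE)
  gf <- rep(names(groups), lengths(groups))
  N <- length(vals)
  r <- rank(vals)
  mean_ranks <- tapply(r, gf, mean)
  ns <- tapply(r, gf, length)
  tie_tab <- table(vals)
  tie_term <- sum(tie_tab^3 - tie_tab) / (12 * (N - 1))
  if (is.null(contrasts)) {
    nm <- names(groups)
    contrasts <- utils::combn(nm, 2, simplify = FALSE)
  }
  res <- do.call(rbind, lapply(contrasts, function(ct) {
    a <- ct[1]; b <- ct[2]
    se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / ns[[a]] + 1 / ns[[b]]))
    z <- if (se > 0) (mean_ranks[[a]] - mean_ranks[[b]]) / se else 0
    data.frame(contrast = paste(a, "vs", b), z = z,
               p_raw = 2 * stats::pnorm(-abs(z)))
  }))
  res$p_adjusted <- switch(adjust,
    holm_sidak = holm_sidak(res$p_raw),
    holm = stats::p.adjust(res$p_raw, "holm"),
    none = res$p_raw,
    stop("unknown adjustment"))
  rownames(res) <- NULL
  res
}

#' Holm-Sidak step-down adjusted p-values
#'
#' Sort ascending; the i-th adjusted p is the running maximum of
#' `1 - (1 - p_(j))^(m - j + 1)` over `j <= i`, clipped to 1, mapped back to
#' the input order.
#'
#' @param p_values Numeric vector of raw p-values in \[0, 1\].
#' @return Adjusted p-values in the input order.
#' @export
holm_sidak <- function(p_values) {
  stopifnot(all(p_values >= 0 & p_values <= 1))
  m <- length(p_values)
  o <- order(p_values)
  adj_sorted <- pmin(1, cummax(1 - (1 - p_values[o])^(m - seq_len(m) + 1)))
  out <- numeric(m)
  out[o] <- adj_sorted
  out
}

#' Kolmogorov-Smirnov normality gate (Lilliefors-corrected)
#'
#' KS distance against a normal with estimated mean/SD, p-value with the
#' Lilliefors correction for estimated parameters. Degenerate constant data
#' fail with a warning. A naive-KS mode (parameters treated as known) exists
#' for strict replication.
#'
#' @param x Numeric sample (n >= 5).
#' @param alpha Significance level of the gate.
#' @param naive Use the uncorrected KS p-value.
#' @return List: `pass` (TRUE = consistent with normality), `p_value`,
#'   `statistic`.
#' @export
ks_normality <- function(x, alpha = 0.05, naive = FALSE) {
  stopifnot(length(x) >= 5)
  if (stats::sd(x) == 0) {
    warning("constant data: normality test degenerate, treated as non-normal")
    return(list(pass = FALSE, p_value = 0, statistic = NA_real_))
  }
  if (naive) {
    kt <- stats::ks.test(x, "pnorm", mean(x), stats::sd(x))
  } else {
    kt <- nortest::lillie.test(x)
  }
  list(pass = kt$p.value >= alpha, p_value = kt$p.value,
       statistic = unname(kt$statistic))
}

#' Choose the parametric or nonparametric branch
#'
#' Nonparametric tests are used whenever any group fails the normality gate;
#' the decision and per-group p-values are recorded in the returned log.
#'
#' @param groups List of numeric samples.
#' @param alpha Gate level.
#' @return List: `branch` (`"parametric"`/`"nonparametric"`), `log`
#'   (data.frame of per-group gate results).
#' @export
select_test <- function(groups, alpha = 0.05) {
  stopifnot(length(groups) >= 2)
  gate <- lapply(groups, function(g) {
    if (length(g) < 5) list(pass = TRUE, p_value = NA_real_, statistic = NA_real_)
    else ks_normality(g, alpha = alpha)
  })
  log <- data.frame(group = seq_along(groups),
                    n = lengths(groups),
                    ks_p = vapply(gate, function(g) g$p_value, numeric(1)),
                    normal = vapply(gate, function(g) g$pass, logical(1)))
  branch <- if (all(log$normal)) "parametric" else "nonparametric"
  list(branch = branch, log = log)
}

#' Two-way ANOVA (Type III), optionally with repeated measures
#'
#' Between-subjects designs use Type-III sums of squares (sum-to-zero
#' contrasts) for both main effects and the interaction, tolerating
#' unbalanced cells. With a repeated factor, a mixed within/between partition
#' is fitted with the repeated factor crossed within subject; subjects with
#' incomplete cells are dropped with a warning. The post-hoc family (levels
#' of one factor compared within each level of the other) is adjusted by
#' Holm-Sidak.
#'
#' @param values Response vector.
#' @param factor_a,factor_b Crossed factors (e.g. genotype, time of day).
#' @param subject Optional subject identifier; when supplied, `factor_b` is
#'   treated as the repeated (within-subject) factor.
#' @param posthoc_within Which factor to condition on for post-hoc contrasts:
#'   `"b"` compares levels of `factor_a` within each level of `factor_b`
#'   (default), `"a"` the reverse, `"none"` skips post hoc.
#' @return A `stat_test_result`; `statistic_value` and `p_value` refer to the
#'   interaction, with the full effect table in `extra$effects`.
#' @export
anova_two_way <- function(values, factor_a, factor_b, subject = NULL,
                          posthoc_within = c("b", "a", "none")) {
  posthoc_within <- match.arg(posthoc_within)
  df <- data.frame(y = values, A = factor(factor_a), B = factor(factor_b))
  if (any(table(df$A, df$B) == 0)) {
    tab <- table(df$A, df$B)
    idx <- which(tab == 0, arr.ind = TRUE)[1, ]
    stop(sprintf("empty design cell: A=%s, B=%s",
                 rownames(tab)[idx[1]], colnames(tab)[idx[2]]))
  }
  if (nlevels(df$A) < 2 || nlevels(df$B) < 2) {
    # one factor constant: the design collapses to a one-way comparison
    vary <- if (nlevels(df$A) >= 2) "A" else "B"
    old <- options(contrasts = c("contr.sum", "contr.poly"))
    on.exit(options(old), add = TRUE)
    fit <- stats::lm(stats::reformulate(vary, "y"), data = df)
    a1 <- stats::anova(fit)
    return(new_stat_result("two-way ANOVA (collapsed to one-way)",
                           statistic_value = a1[vary, "F value"],
                           df = c(a1[vary, "Df"], a1["Residuals", "Df"]),
                           p_value = a1[vary, "Pr(>F)"],
                           n_per_group = as.vector(table(df[[vary]])),
                           extra = list(effects = data.frame(
                             effect = vary, F = a1[vary, "F value"],
                             df1 = a1[vary, "Df"], df2 = a1["Residuals", "Df"],
                             p = a1[vary, "Pr(>F)"]))))
  }
  if (is.null(subject)) {
    old <- options(contrasts = c("contr.sum", "contr.poly"))
    on.exit(options(old), add = TRUE)
    fit <- stats::lm(y ~ A * B, data = df)
    a3 <- car::Anova(fit, type = 3)
    effects <- data.frame(
      effect = c("A", "B", "A:B"),
      F = a3[c("A", "B", "A:B"), "F value"],
      df1 = a3[c("A", "B", "A:B"), "Df"],
      df2 = a3["Residuals", "Df"],
      p = a3[c("A", "B", "A:B"), "Pr(>F)"])
  } else {
    df$S <- factor(subject)
    complete <- tapply(seq_len(nrow(df)), df$S, function(i) {
      all(table(factor(df$B[i], levels = levels(df$B))) >= 1)
    })
    keep_s <- names(complete)[unlist(complete)]
    if (length(keep_s) < nlevels(df$S)) {
      warning(sprintf("dropping %d incomplete subject(s) from the repeated-measures fit",
                      nlevels(df$S) - length(keep_s)))
      df <- droplevels(df[df$S %in% keep_s, ])
    }
    fit <- stats::aov(y ~ A * B + Error(S/B), data = df)
    sm <- summary(fit)
    get_row <- function(term) {
      for (stratum in sm) {
        tab <- stratum[[1]]
        hit <- trimws(rownames(tab)) == term
        if (any(hit) && !is.na(tab[hit, "F value"][1])) {
          return(data.frame(effect = term, F = tab[hit, "F value"][1],
                            df1 = tab[hit, "Df"][1],
                            df2 = tab[trimws(rownames(tab)) == "Residuals", "Df"][1],
                            p = tab[hit, "Pr(>F)"][1]))
        }
      }
      NULL
    }
    effects <- do.call(rbind, lapply(c("A", "B", "A:B"), get_row))
  }
  post <- NULL
  if (posthoc_within != "none") {
    cond <- if (posthoc_within == "b") "B" else "A"
    vary <- if (posthoc_within == "b") "A" else "B"
    fam <- list()
    for (lev in levels(df[[cond]])) {
      sub <- df[df[[cond]] == lev, ]
      levs <- levels(droplevels(sub[[vary]]))
      for (pair in utils::combn(levs, 2, simplify = FALSE)) {
        xa <- sub$y[sub[[vary]] == pair[1]]
        xb <- sub$y[sub[[vary]] == pair[2]]
        tt <- t_test_unpaired(xa, xb)
        fam[[length(fam) + 1]] <- data.frame(
          contrast = sprintf("%s vs %s | %s=%s", pair[1], pair[2], cond, lev),
          t = tt$statistic_value, p_raw = tt$p_value)
      }
    }
    post <- do.call(rbind, fam)
    post$p_adjusted <- holm_sidak(post$p_raw)
  }
  inter <- effects[effects$effect == "A:B", ]
  new_stat_result(
    if (is.null(subject)) "two-way ANOVA (Type III)" else "two-way RM ANOVA",
    statistic_value = inter$F, df = c(inter$df1, inter$df2),
    p_value = inter$p, posthoc = post,
    n_per_group = as.vector(table(df$A, df$B)),
    extra = list(effects = effects))
}

#' ROUT outlier flagging
#'
#' Robust outlier detection at FDR level Q: a robust constant fit (median)
#' with scale from the 68.27th percentile of absolute residuals (small-sample
#' corrected), candidate outliers tested outermost-first against
#' t-distribution tails with a Benjamini-Hochberg-style threshold `Q * i / n`.
#' With fewer than 4 values nothing is tested and all points are kept, with a
#' warning.
#'
#' @param x Numeric vector.
#' @param q FDR level (0.001 = the printed Q = 0.1%).
#' @return List: `kept`, `flagged`, `flag_mask`.
#' @export
rout_outliers <- function(x, q = 0.001) {
  n <- length(x)
  if (n < 4) {
    warning("fewer than 4 values: outlier testing skipped, all kept")
    return(list(kept = x, flagged = numeric(0), flag_mask = rep(FALSE, n)))
  }
  center <- stats::median(x)
  res <- x - center
  ares <- abs(res)
  # 68.27th percentile of |residuals| (inverse-ECDF), inflated for the
  # estimated center; a robust analogue of the residual SD
  rsdr <- stats::quantile(ares, 0.6827, type = 1, names = FALSE) * n / (n - 1)
  if (rsdr == 0) return(list(kept = x, flagged = numeric(0), flag_mask = rep(FALSE, n)))
  tstat <- ares / rsdr
  p <- 2 * stats::pt(tstat, df = n - 1, lower.tail = FALSE)
  o <- order(p)  # outermost (smallest p) first
  thresh <- q * seq_len(n) / n
  ok <- p[o] <= thresh
  k <- if (any(ok)) max(which(ok)) else 0
  mask <- rep(FALSE, n)
  if (k > 0) mask[o[seq_len(k)]] <- TRUE
  list(kept = x[!mask], flagged = x[mask], flag_mask = mask)
}
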