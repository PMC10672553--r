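# Three-group statistical comparison workflow: Jarque-Bera normality
# branching, ANOVA / Kruskal-Wallis omnibus tests, Benjamini-Hochberg FDR
# control applied within each branch family, and Tukey / Dunn post hoc
# pairwise comparisons.

#' Jarque-Bera normality test
#'
#' `JB = n/6 * (S^2 + (K - 3)^2 / 4)` with sample skewness S and kurtosis
#' K (moment estimators); the p-value is the upper tail of chi-square with
#' 2 degrees of freedom.
#'
#' @param values numeric vector, length >= 8.
#' @return List with `statistic` and `p`.
#' @export
jarque_bera <- function(values) {
  n <- length(values)
  if (n < 8L) stop("Jarque-Bera requires n >= 8 (got ", n, ")", call. = FALSE)
  mu <- mean(values)
  m2 <- mean((values - mu)^2)
  if (m2 == 0) return(list(statistic = Inf, p = 0))
  S <- mean((values - mu)^3) / m2^1.5
  K <- mean((values - mu)^4) / m2^2
  jb <- n / 6 * (S^2 + (K - 3)^2 / 4)
  list(statistic = jb, p = pchisq(jb, df = 2, lower.tail = FALSE))
}

#' Omnibus three-group test
#'
#' ANOVA branch: one-way fixed-effects F test (equal-variance). KW branch:
#' Kruskal-Wallis rank test with tie correction. When all values are
#' identical across all groups there is no evidence against the null and
#' p = 1 is returned; zero within-group variance with distinct means gives
#' p = 0 (infinite F).
#'
#' @param groups list of three (or more) numeric vectors.
#' @param branch `"ANOVA"` or `"KW"`.
#' @return Raw p-value.
#' @export
omnibus_test <- function(groups, branch = c("ANOVA", "KW")) {
  branch <- match.arg(branch)
  stopifnot(length(groups) >= 2L, all(vapply(groups, length, 1L) >= 3L))
  x <- unlist(groups, use.names = FALSE)
  if (length(unique(x)) == 1L) return(1)
  if (branch == "ANOVA") {
    g <- lengths(groups)
    N <- sum(g); k <- length(groups)
    mu <- mean(x)
    ssb <- sum(g * (vapply(groups, mean, 1) - mu)^2)
    ssw <- sum(vapply(groups, function(v) sum((v - mean(v))^2), 1))
    if (ssw == 0) return(0)    # distinct means, zero within-group variance
    f <- (ssb / (k - 1)) / (ssw / (N - k))
    pf(f, k - 1, N - k, lower.tail = FALSE)
  } else {
    lab <- factor(rep(seq_along(groups), lengths(groups)))
    unname(kruskal.test(x, lab)$p.value)
  }
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' Sorts the m p-values ascending and sets
#' `adjusted_p(i) = min_{j >= i} m * p(j) / j`, capped at 1, restoring the
#' original order; rejections are `adjusted_p <= q`.
#'
#' @param p_values numeric vector in \[0, 1\].
#' @param q target FDR level (default 0.05).
#' @return List with `adjusted` (same order as input) and `reject`
#'   (logical).
#' @export
bh_fdr <- function(p_values, q = 0.05) {
  if (!length(p_values)) return(list(adjusted = numeric(), reject = logical()))
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  m <- length(p_values)
  o <- order(p_values)
  ranked <- p_values[o] * m / seq_len(m)
  adj_sorted <- pmin(rev(cummin(rev(ranked))), 1)
  adjusted <- numeric(m)
  adjusted[o] <- adj_sorted
  list(adjusted = adjusted, reject = adjusted <= q)
}

#' Post hoc pairwise comparison of three groups
#'
#' ANOVA branch: Tukey honest significant difference on the group means.
#' KW branch: Dunn-type comparison of mean ranks with tie-corrected
#' variance and Bonferroni correction over the three pairs.
#'
#' @param groups named list of three numeric vectors (names become the
#'   pair labels, e.g. `BME`, `INJ`, `OST`).
#' @param branch `"ANOVA"` or `"KW"`.
#' @param alpha significance level for a pair (default 0.05).
#' @return Character vector of significant pairs, e.g. `"BME-INJ"`.
#' @export
posthoc_pairwise <- function(groups, branch = c("ANOVA", "KW"),
                             alpha = 0.05) {
  branch <- match.arg(branch)
  stopifnot(length(groups) == 3L, !is.null(names(groups)))
  x <- unlist(groups, use.names = FALSE)
  lab <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  pairs <- combn(names(groups), 2)
  pair_names <- apply(pairs, 2, paste, collapse = "-")
  if (length(unique(x)) == 1L) return(character())
  if (branch == "ANOVA") {
    fit <- aov(x ~ lab)
    tk <- TukeyHSD(fit)$lab
    padj <- tk[, "p adj"]
    # TukeyHSD labels pairs "B-A"; normalize to sorted order
    labs <- vapply(strsplit(rownames(tk), "-"), function(v)
      paste(sort(v), collapse = "-"), "")
    sig <- labs[is.finite(padj) & padj < alpha]
  } else {
    N <- length(x)
    rk <- rank(x)
    ties <- table(rk)
    tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
    v0 <- N * (N + 1) / 12 - tie_term
    mean_rk <- tapply(rk, lab, mean)
    n_g <- tapply(rk, lab, length)
    p_pair <- apply(pairs, 2, function(pr) {
      z <- (mean_rk[pr[1]] - mean_rk[pr[2]]) /
        sqrt(v0 * (1 / n_g[pr[1]] + 1 / n_g[pr[2]]))
      min(1, 2 * pnorm(-abs(z)) * ncol(pairs))   # Bonferroni over 3 pairs
    })
    sig <- pair_names[p_pair < alpha]
  }
  sort(unname(sig))
}

#' Per-feature three-group analysis of a cohort feature table
#'
#' For each of the 81 descriptors of one sequence channel: per-group
#' Jarque-Bera normality at `alpha_norm` decides the branch (ANOVA only
#' when all three groups pass), the omnibus test gives the raw p, and
#' Benjamini-Hochberg adjustment is applied separately within the ANOVA
#' family and within the KW family (set `fdr_scope = "global"` for one
#' 81-test family). Features are flagged at `adjusted_p < alpha_strict`;
#' post hoc pairwise comparisons are run for flagged features at
#' `alpha_strict`. Descriptive summaries follow the branch convention:
#' mean and sd per group on the ANOVA branch, median and IQR on the KW
#' branch.
#'
#' @param table cohort feature table (see [extract_cohort()]).
#' @param sequence `"PDFSE"` or `"STIR"`.
#' @param alpha_norm per-group normality level (default 0.05).
#' @param alpha_strict flagging level on adjusted p (default 0.001).
#' @param q Benjamini-Hochberg FDR level used for the `reject_q` column
#'   (default 0.05).
#' @param fdr_scope `"branch"` (default) or `"global"`.
#' @return Data frame with one row per feature: `feature`, `sequence`,
#'   `branch`, `raw_p`, `adjusted_p`, `flagged`, `reject_q`,
#'   `raw_p_lt_05`, group summary columns, and `pairwise_significant`
#'   (comma-separated pairs).
#' @export
run_group_analysis <- function(table, sequence, alpha_norm = 0.05,
                               alpha_strict = 0.001, q = 0.05,
                               fdr_scope = c("branch", "global")) {
  fdr_scope <- match.arg(fdr_scope)
  table <- validate_feature_table(table)
  sequence <- validate_token(sequence, SEQUENCE_LEVELS, "sequence")
  sub <- table[table$sequence == sequence, , drop = FALSE]
  if (!all(GROUP_LEVELS %in% sub$group)) {
    stop("sequence ", sequence, " is missing one of the three groups",
         call. = FALSE)
  }
  feats <- descriptor_names()
  res <- lapply(feats, function(f) {
    groups <- lapply(GROUP_LEVELS, function(g) sub[sub$group == g, f])
    names(groups) <- GROUP_LEVELS
    jb_p <- vapply(groups, function(v) {
      # constant or too-small groups cannot be called normal
      if (length(v) < 8L || length(unique(v)) == 1L) 0
      else jarque_bera(v)$p
    }, 1)
    branch <- if (all(jb_p >= alpha_norm)) "ANOVA" else "KW"
    raw_p <- omnibus_test(groups, branch)
    summ <- if (branch == "ANOVA") {
      c(vapply(groups, mean, 1), vapply(groups, function(v) sd(v), 1))
    } else {
      c(vapply(groups, median, 1),
        vapply(groups, function(v) unname(diff(quantile(v, c(.25, .75)))), 1))
    }
    list(feature = f, branch = branch, normality_p = min(jb_p),
         raw_p = raw_p, groups = groups, summ = summ)
  })
  branch <- vapply(res, `[[`, "", "branch")
  raw_p <- vapply(res, `[[`, 1, "raw_p")
  adjusted <- numeric(length(res))
  if (fdr_scope == "branch") {
    for (b in unique(branch)) {
      sel <- branch == b
      adjusted[sel] <- bh_fdr(raw_p[sel], q)$adjusted
    }
  } else {
    adjusted <- bh_fdr(raw_p, q)$adjusted
  }
  flagged <- adjusted < alpha_strict
  pairwise <- vapply(seq_along(res), function(k) {
    if (!flagged[k]) return("")
    paste(posthoc_pairwise(res[[k]]$groups, branch[k], alpha_strict),
          collapse = ",")
  }, "")
  summ <- do.call(rbind, lapply(res, `[[`, "summ"))
  colnames(summ) <- c(paste0("loc_", GROUP_LEVELS),
                      paste0("scale_", GROUP_LEVELS))
  out <- data.frame(
    feature = feats, sequence = sequence, branch = branch,
    normality_p = vapply(res, `[[`, 1, "normality_p"),
    raw_p = raw_p, adjusted_p = adjusted, flagged = flagged,
    reject_q = adjusted <= q, raw_p_lt_05 = raw_p < 0.05,
    summ, pairwise_significant = pairwise,
    stringsAsFactors = FALSE, row.names = NULL
  )
  out
}

#' Summarize a group analysis as branch counts
#'
#' Counts mirroring the study-report layout: features per branch, features
#' flagged at the strict level per branch, and features with raw p < 0.05.
#'
#' @param analysis result of [run_group_analysis()].
#' @return Named list of counts.
#' @export
summarize_group_analysis <- function(analysis) {
  list(
    sequence = analysis$sequence[1],
    n_features = nrow(analysis),
    n_normal = sum(analysis$branch == "ANOVA"),
    n_nonnormal = sum(analysis$branch == "KW"),
    n_flagged_anova = sum(analysis$flagged & analysis$branch == "ANOVA"),
    n_flagged_kw = sum(analysis$flagged & analysis$branch == "KW"),
    n_raw_p_lt_05 = sum(analysis$raw_p_lt_05),
    n_reject_q = sum(analysis$reject_q)
  )
}
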