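# Cohort-level statistics: per-line summaries, group comparisons with the
# parametric/non-parametric branching used in single-cell imaging studies,
# and the migration-vs-recovery-rate correlation.

#' Summarize per-cell records into per-line profiles
#'
#' Groups a per-cell results table by cell line and reports mean and
#' standard error of the basal ratio, the submaximal response amplitude and
#' the recovery rate, plus cell and experiment counts. SEs are standard
#' errors of the mean across cells pooled over experiments. Flagged cells
#' (poor fits) are excluded unless `include_flagged`.
#'
#' @param records per-cell results data frame (see [analyze_experiment()])
#'   with a `cell_line` column
#' @param include_flagged keep cells whose `flagged` column is `TRUE`
#' @param sort_by optional profile column to sort by (e.g.
#'   `"recovery_rate_mean"`), ascending
#' @return data frame, one row per line: `cell_line`, `basal_mean`,
#'   `basal_se`, `response50_mean`, `response50_se`, `recovery_rate_mean`,
#'   `recovery_rate_se`, `n_cells`, `n_experiments`
#' @export
summarize_lines <- function(records, include_flagged = FALSE,
                            sort_by = NULL) {
  df <- as.data.frame(records)
  if (is.null(df$cell_line))
    hk_stop("records need a 'cell_line' column", "hyperkin_param_error")
  if (!include_flagged && !is.null(df$flagged)) df <- df[!df$flagged, ]
  df <- df[!is.na(df$cell_line), ]
  groups <- split(df, df$cell_line)
  rows <- lapply(names(groups), function(g) {
    d <- groups[[g]]
    if (!nrow(d)) {
      warning(sprintf("cell line '%s': no usable cells, skipped", g))
      return(NULL)
    }
    data.frame(cell_line = g,
               basal_mean = mean(d$r_basal), basal_se = se(d$r_basal),
               response50_mean = mean(d$delta_r_50),
               response50_se = se(d$delta_r_50),
               recovery_rate_mean = mean(d$k), recovery_rate_se = se(d$k),
               n_cells = nrow(d),
               n_experiments = length(unique(d$experiment_id)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(sort_by)) {
    if (!sort_by %in% names(out))
      hk_stop(sprintf("unknown profile column '%s'", sort_by),
              "hyperkin_param_error")
    out <- out[order(out[[sort_by]]), ]
  }
  rownames(out) <- NULL
  out
}

# Dunn's rank-based post-hoc test (z statistics on mean ranks with tie
# correction), Bonferroni-adjusted. Implemented here because no post-hoc
# package is part of the package's dependency set.
dunn_pairwise <- function(values, groups) {
  N <- length(values)
  rk <- rank(values)
  ties <- table(rk)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  mean_rank <- tapply(rk, groups, mean)
  n <- tapply(rk, groups, length)
  gl <- names(mean_rank)
  pairs <- utils::combn(gl, 2, simplify = FALSE)
  res <- lapply(pairs, function(p) {
    sigma <- sqrt((N * (N + 1) / 12 - tie_corr) *
                    (1 / n[[p[1]]] + 1 / n[[p[2]]]))
    z <- (mean_rank[[p[1]]] - mean_rank[[p[2]]]) / sigma
    data.frame(group1 = p[1], group2 = p[2], statistic = z,
               p_raw = 2 * stats::pnorm(-abs(z)), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adj <- pmin(out$p_raw * nrow(out), 1)
  out
}

#' Compare measurements across groups
#'
#' Omnibus comparison of 2+ groups with the standard decision rule of the
#' field: Shapiro-Wilk normality screening in every group (alpha = 0.05);
#' if all groups pass, one-way ANOVA with Bonferroni-adjusted pairwise
#' t-tests; otherwise Kruskal-Wallis with Dunn's Bonferroni-adjusted
#' post-hoc. Paired before/after designs (two groups, `paired = TRUE`) use
#' the paired Student t-test. Significance is declared at p < 0.05.
#'
#' @param values numeric measurements
#' @param groups group labels (same length as `values`)
#' @param parametric `"auto"` (Shapiro-Wilk screen), `"yes"` or `"no"`
#' @param paired paired two-group design (before/after)
#' @return object of class `group_comparison`: `method`, `statistic`,
#'   `p_value`, `parametric`, `pairwise` (data frame with adjusted p-values
#'   and a `significant` flag), `alpha`
#' @export
compare_groups <- function(values, groups, parametric = c("auto", "yes", "no"),
                           paired = FALSE) {
  parametric <- match.arg(parametric)
  groups <- factor(groups)
  if (length(values) != length(groups))
    hk_stop("'values' and 'groups' must have equal length",
            "hyperkin_param_error")
  n <- table(groups)
  if (length(n) < 2)
    hk_stop("need at least 2 groups", "hyperkin_param_error")
  if (any(n < 3))
    hk_stop("every group needs n >= 3", "hyperkin_param_error")
  alpha <- 0.05
  if (paired) {
    if (length(n) != 2 || n[1] != n[2])
      hk_stop("paired comparison needs exactly 2 groups of equal size",
              "hyperkin_param_error")
    tt <- stats::t.test(values[groups == levels(groups)[1]],
                        values[groups == levels(groups)[2]], paired = TRUE)
    return(structure(list(method = "Paired t-test",
                          statistic = unname(tt$statistic),
                          p_value = tt$p.value, parametric = TRUE,
                          pairwise = NULL, alpha = alpha),
                     class = "group_comparison"))
  }
  use_param <- switch(parametric,
    yes = TRUE, no = FALSE,
    auto = all(vapply(split(values, groups),
                      function(v) stats::shapiro.test(v)$p.value > alpha,
                      logical(1))))
  if (use_param) {
    fit <- stats::aov(values ~ groups)
    an <- summary(fit)[[1]]
    pt <- stats::pairwise.t.test(values, groups, p.adjust.method = "bonferroni",
                                 pool.sd = TRUE)
    pm <- pt$p.value
    pairs <- which(!is.na(pm), arr.ind = TRUE)
    pairwise <- data.frame(group1 = rownames(pm)[pairs[, 1]],
                           group2 = colnames(pm)[pairs[, 2]],
                           p_adj = pm[pairs], stringsAsFactors = FALSE)
    method <- "One-way ANOVA + Bonferroni t-tests"
    statistic <- an$`F value`[1]
    p_value <- an$`Pr(>F)`[1]
  } else {
    kw <- stats::kruskal.test(values, groups)
    pairwise <- dunn_pairwise(values, groups)[, c("group1", "group2", "p_adj")]
    method <- "Kruskal-Wallis + Dunn's method"
    statistic <- unname(kw$statistic)
    p_value <- kw$p.value
  }
  pairwise$significant <- pairwise$p_adj < alpha
  structure(list(method = method, statistic = statistic, p_value = p_value,
                 parametric = use_param, pairwise = pairwise, alpha = alpha),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s\n", x$method))
  cat(sprintf("  omnibus statistic %.4g, p = %.4g\n", x$statistic, x$p_value))
  if (!is.null(x$pairwise)) {
    sig <- x$pairwise[x$pairwise$significant, , drop = FALSE]
    cat(sprintf("  %d pairwise comparison(s), %d significant at p < %.2f\n",
                nrow(x$pairwise), nrow(sig), x$alpha))
  }
  invisible(x)
}

#' Correlate recovery rate with migration efficiency across cell lines
#'
#' Pearson correlation (two-sided test) and least-squares line between
#' per-line mean recovery rates and per-line migration efficiencies,
#' matched by cell-line label.
#'
#' @param profiles data frame with `cell_line` and `recovery_rate_mean`
#'   (as from [summarize_lines()]) or `recovery_rate` (as from
#'   [simulate_migration_cohort()] truth)
#' @param migration data frame with `cell_line` and `migration_efficiency`
#' @return object of class `correlation_result`: `pearson_r`, `p_value`,
#'   `n`, `slope`, `intercept`
#' @export
correlate_migration <- function(profiles, migration) {
  profiles <- as.data.frame(profiles)
  migration <- as.data.frame(migration)
  rate_col <- if ("recovery_rate_mean" %in% names(profiles))
    "recovery_rate_mean" else "recovery_rate"
  if (!all(c("cell_line", rate_col) %in% names(profiles)))
    hk_stop("profiles need columns cell_line and recovery_rate[_mean]",
            "hyperkin_param_error")
  if (!all(c("cell_line", "migration_efficiency") %in% names(migration)))
    hk_stop("migration needs columns cell_line and migration_efficiency",
            "hyperkin_param_error")
  unmatched <- c(setdiff(profiles$cell_line, migration$cell_line),
                 setdiff(migration$cell_line, profiles$cell_line))
  if (length(unmatched))
    hk_stop(sprintf("cell lines not present in both tables: %s",
                    paste(unique(unmatched), collapse = ", ")),
            "hyperkin_join_error")
  m <- merge(profiles[, c("cell_line", rate_col)],
             migration[, c("cell_line", "migration_efficiency")],
             by = "cell_line")
  if (nrow(m) < 3)
    hk_stop("need at least 3 matched lines", "hyperkin_param_error")
  x <- m[[rate_col]]; y <- m$migration_efficiency
  ct <- stats::cor.test(x, y, method = "pearson")
  ls <- stats::lm(y ~ x)
  structure(list(pearson_r = unname(ct$estimate), p_value = ct$p.value,
                 n = nrow(m), slope = unname(stats::coef(ls)[2]),
                 intercept = unname(stats::coef(ls)[1])),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf(
    "<correlation_result> Pearson r = %.3f (p = %.3g, n = %d); fit y = %.3g + %.3g x\n",
    x$pearson_r, x$p_value, x$n, x$intercept, x$slope))
  invisible(x)
}
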