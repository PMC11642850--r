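#' Dunnett many-to-one comparisons against a reference group
#'
#' Fits a one-way ANOVA and computes Dunnett-adjusted p-values comparing
#' each group to the reference, delegating the multiplicity adjustment to
#' the single-step multivariate-t procedure in \pkg{multcomp}.
#'
#' @param data Data frame with numeric `value` and `group` columns.
#' @param reference_group Reference group label (must be present, n >= 2).
#' @return A tibble with `group`, `estimate` (difference from reference),
#'   `se` and `p_adj`.
#' @export
dunnett_vs_reference <- function(data, reference_group) {
  check_grouped(data, min_groups = 2)
  if (!reference_group %in% data$group) {
    stop("reference group '", reference_group, "' not present")
  }
  if (sum(data$group == reference_group) < 2) {
    stop("reference group must have at least 2 observations")
  }
  d <- data.frame(value = data$value,
                  group = stats::relevel(factor(data$group),
                                         ref = reference_group))
  fit <- aov(value ~ group, data = d)
  gl <- multcomp::glht(fit, linfct = multcomp::mcp(group = "Dunnett"))
  s <- summary(gl)
  tibble::tibble(group = sub("^(.*) - .*$", "\\1", names(s$test$coefficients)),
                 estimate = unname(s$test$coefficients),
                 se = unname(s$test$sigma),
                 p_adj = unname(as.numeric(s$test$pvalues)))
}

#' One-way ANOVA with Tukey all-pairs comparisons
#'
#' @param data Data frame with numeric `value` and `group` columns.
#' @return A list with `p_omnibus` (one-way ANOVA F-test p-value) and
#'   `pairwise` (tibble: pair, diff, lwr, upr, p_adj from Tukey's HSD).
#' @export
anova_tukey <- function(data) {
  check_grouped(data, min_groups = 2)
  d <- data.frame(value = data$value, group = factor(data$group))
  fit <- aov(value ~ group, data = d)
  p_omni <- summary(fit)[[1]][["Pr(>F)"]][1]
  tk <- TukeyHSD(fit)$group
  list(p_omnibus = p_omni,
       pairwise = tibble::tibble(pair = rownames(tk),
                                 diff = tk[, "diff"],
                                 lwr = tk[, "lwr"], upr = tk[, "upr"],
                                 p_adj = tk[, "p adj"]))
}

#' Two-sample t-test between exactly two groups
#'
#' Classical equal-variance Student's t by default; Welch behind a flag.
#'
#' @param data Data frame with numeric `value` and `group` columns
#'   containing exactly two groups, each with n >= 2.
#' @param welch Use the Welch unequal-variance form.
#' @return A list with `t`, `df` and `p` (two-sided).
#' @export
two_sample_t <- function(data, welch = FALSE) {
  check_grouped(data, min_groups = 2)
  if (length(unique(data$group)) != 2) {
    stop("two_sample_t requires exactly 2 groups")
  }
  res <- t.test(value ~ group, data = data, var.equal = !welch)
  list(t = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value)
}

check_grouped <- function(data, min_groups) {
  stopifnot(is.data.frame(data),
            all(c("value", "group") %in% names(data)),
            is.numeric(data$value))
  if (length(unique(data$group)) < min_groups) {
    stop("need at least ", min_groups, " groups")
  }
  sizes <- table(data$group)
  if (any(sizes < 2)) {
    stop("every group needs at least 2 observations (variance-based tests)")
  }
  invisible(data)
}
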