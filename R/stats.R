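#' Two-sample t test with normality check
#'
#' Two-tailed pooled-variance t test (df = nA + nB - 2), matching the
#' group-comparison convention used throughout the reporting; Welch's
#' version is available via `var_equal = FALSE`. A Shapiro-Wilk normality
#' test is run per group at alpha = 0.05 and reported, not enforced.
#'
#' @param a,b Numeric vectors of per-animal values (n >= 3 each).
#' @param var_equal Pooled variance if TRUE (default); Welch otherwise.
#' @return A list of class `mf_ttest`: `t`, `df`, `p`, `mean_a`, `mean_b`,
#'   `sem_a`, `sem_b`, `shapiro_p_a`, `shapiro_p_b`, `normal_a`, `normal_b`.
#' @examples
#' two_sample_t(c(1, 2, 3), c(4, 5, 6))  # t = -3.674, df = 4
#' @export
two_sample_t <- function(a, b, var_equal = TRUE) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 3 || length(b) < 3)
    stop("need at least 3 values per group", call. = FALSE)
  if (!all(is.finite(a)) || !all(is.finite(b)))
    stop("group values must be finite", call. = FALSE)
  tt <- stats::t.test(a, b, var.equal = var_equal)
  sw <- function(x) if (stats::sd(x) == 0) NA_real_ else stats::shapiro.test(x)$p.value
  pa <- sw(a); pb <- sw(b)
  structure(list(t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, mean_a = mean(a), mean_b = mean(b),
                 sem_a = sem(a), sem_b = sem(b),
                 shapiro_p_a = pa, shapiro_p_b = pb,
                 normal_a = isTRUE(pa > 0.05), normal_b = isTRUE(pb > 0.05)),
            class = "mf_ttest")
}

#' @export
print.mf_ttest <- function(x, ...) {
  cat(sprintf("t(%g) = %.3f, p = %.4g  (means %.3g vs %.3g)\n",
              x$df, x$t, x$p, x$mean_a, x$mean_b))
  if (!isTRUE(x$normal_a) || !isTRUE(x$normal_b))
    cat("  note: Shapiro-Wilk normality not confirmed for at least one group\n")
  invisible(x)
}

#' Chi-square test on two proportions
#'
#' Pearson chi-square without continuity correction on the 2 x 2 table
#' `[[countA, totalA - countA], [countB, totalB - countB]]`.
#'
#' @param count_a,total_a,count_b,total_b Nonnegative counts with
#'   `total >= count`.
#' @return A list: `statistic`, `df`, `p`, `table`.
#' @examples
#' chi_square_proportions(50, 100, 10, 100)$statistic  # 38.095
#' @export
chi_square_proportions <- function(count_a, total_a, count_b, total_b) {
  stopifnot(count_a >= 0, count_b >= 0, total_a >= count_a, total_b >= count_b)
  tab <- matrix(c(count_a, total_a - count_a, count_b, total_b - count_b),
                nrow = 2, byrow = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero margin in the 2x2 table", call. = FALSE)
  test <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(test$statistic), df = unname(test$parameter),
       p = test$p.value, table = tab)
}

#' Two-way ANOVA with type-II sums of squares
#'
#' For group x condition designs (the condition axis may be time frames or
#' pulse counts; name it explicitly via `condition`). Reports the group
#' main effect as `F(df1, df2)` alongside the full type-II table.
#'
#' @param data A data.frame.
#' @param response,group,condition Column names (strings).
#' @param interaction Include the group:condition interaction; default TRUE.
#' @return A list of class `mf_anova`: `group_F`, `df1`, `df2`, `group_p`,
#'   `table` (the full type-II ANOVA table).
#' @export
two_way_anova <- function(data, response, group, condition,
                          interaction = TRUE) {
  stopifnot(all(c(response, group, condition) %in% names(data)))
  data[[group]] <- factor(data[[group]])
  data[[condition]] <- factor(data[[condition]])
  if (nlevels(data[[group]]) < 2 || nlevels(data[[condition]]) < 2)
    stop("both factors need at least 2 levels", call. = FALSE)
  op <- if (interaction) "*" else "+"
  fml <- stats::as.formula(paste(response, "~", group, op, condition))
  fit <- stats::lm(fml, data = data)
  if (any(is.na(stats::coef(fit)))) stop("singular design", call. = FALSE)
  if (sum(stats::residuals(fit)^2) < 1e-12 * sum((data[[response]] - mean(data[[response]]))^2)) {
    # a perfect fit: any nonzero effect is infinitely significant
    return(structure(list(group_F = Inf, df1 = nlevels(data[[group]]) - 1L,
                          df2 = stats::df.residual(fit), group_p = 0,
                          table = NULL), class = "mf_anova"))
  }
  tab <- car::Anova(fit, type = 2)
  i <- match(group, rownames(tab))
  r <- match("Residuals", rownames(tab))
  structure(list(group_F = tab$`F value`[i], df1 = tab$Df[i], df2 = tab$Df[r],
                 group_p = tab$`Pr(>F)`[i], table = tab),
            class = "mf_anova")
}

#' @export
print.mf_anova <- function(x, ...) {
  cat(sprintf("group effect: F(%d,%d) = %.3f, p = %.4g\n",
              x$df1, x$df2, x$group_F, x$group_p))
  invisible(x)
}

#' Group mean and SEM table
#'
#' @param values Numeric vector.
#' @param groups Group labels, same length.
#' @return data.frame with `group`, `n`, `mean`, `sem`.
#' @export
group_mean_sem <- function(values, groups) {
  out <- do.call(rbind, lapply(split(as.numeric(values), groups), function(v) {
    v <- v[is.finite(v)]
    data.frame(n = length(v), mean = mean(v), sem = sem(v))
  }))
  data.frame(group = rownames(out), out, row.names = NULL)
}

#' Assemble a run report of group statistics
#'
#' One block per analysis (alternation, total entries, morphology metrics,
#' activity changes, ...): group means with SEM plus the appropriate test.
#' Missing analyses are listed as absent and the report continues.
#'
#' @param analyses A named list; each element is a list with `values`
#'   (numeric), `groups` (labels), and optionally `test` (`"t"` for a
#'   two-group t test, `"none"`).
#' @return A list of class `mf_report`: `tables` (one data.frame per
#'   analysis), `tests` (one row per test), `absent`, `n_tests`.
#' @export
build_report <- function(analyses) {
  tables <- list(); tests <- list(); absent <- character(0)
  for (nm in names(analyses)) {
    an <- analyses[[nm]]
    if (is.null(an) || is.null(an$values) || length(an$values) == 0) {
      absent <- c(absent, nm)
      next
    }
    tables[[nm]] <- group_mean_sem(an$values, an$groups)
    test_kind <- if (is.null(an$test)) "t" else an$test
    gl <- unique(an$groups)
    if (identical(test_kind, "t") && length(gl) == 2) {
      va <- an$values[an$groups == gl[1]]
      vb <- an$values[an$groups == gl[2]]
      if (length(va) >= 3 && length(vb) >= 3) {
        tt <- two_sample_t(va, vb)
        tests[[nm]] <- data.frame(analysis = nm, test = "t",
                                  statistic = tt$t, df = tt$df, p = tt$p)
      }
    }
  }
  structure(list(tables = tables,
                 tests = if (length(tests)) do.call(rbind, tests) else NULL,
                 absent = absent, n_tests = length(tests)),
            class = "mf_report")
}

#' @export
print.mf_report <- function(x, ...) {
  for (nm in names(x$tables)) {
    cat("==", nm, "==\n")
    print(x$tables[[nm]])
    if (!is.null(x$tests) && nm %in% x$tests$analysis) {
      r <- x$tests[x$tests$analysis == nm, ]
      cat(sprintf("  t(%g) = %.3f, p = %.4g\n", r$df, r$statistic, r$p))
    }
  }
  if (length(x$absent)) cat("absent analyses:", paste(x$absent, collapse = ", "), "\n")
  cat(sprintf("(%d tests run, no multiplicity correction applied)\n", x$n_tests))
  invisible(x)
}
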