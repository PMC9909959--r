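#' Kolmogorov-Smirnov normality gate
#'
#' One-sample KS test of a sample against a normal law with the sample's own
#' mean and SD, decided at `alpha`. Estimating the parameters from the data
#' makes the test conservative (the Lilliefors caveat); it is used here as a
#' routing gate, not as a calibrated normality test.
#'
#' @param sample Numeric vector, length >= 3.
#' @param alpha Gate level (default 0.05).
#' @return List with `statistic`, `p_value`, `is_normal`.
#' @export
ks_normal <- function(sample, alpha = 0.05) {
  stopifnot(is.numeric(sample))
  if (length(sample) < 3L) stop("need at least 3 observations", call. = FALSE)
  if (sd(sample) == 0) stop("constant sample: normality undefined", call. = FALSE)
  kt <- suppressWarnings(ks.test(sample, "pnorm", mean(sample), sd(sample)))
  list(statistic = unname(kt$statistic), p_value = kt$p.value,
       is_normal = kt$p.value > alpha)
}

#' Normality-gated two-group comparison
#'
#' Each sample is gated with [ks_normal()]; when both pass, a pooled-variance
#' two-sample Student t-test is used (Welch by option), otherwise a two-sided
#' Mann-Whitney U test. Group summaries are mean and SD. A degenerate input
#' (both samples constant and equal) returns p = 1 and is flagged.
#'
#' @param a,b Numeric samples, each of length >= 3.
#' @param alpha Significance level (default 0.05).
#' @param welch Use Welch instead of pooled-variance t (default `FALSE`).
#' @return Object of class `group_comparison`: `group_means_sd` (2x2),
#'   `test_used` (`"student_t"`, `"mann_whitney"` or `"degenerate"`),
#'   `statistic`, `p_value`, `significant`, `direction` (sign of mean(a) -
#'   mean(b)), `degenerate`.
#' @export
compare_groups <- function(a, b, alpha = 0.05, welch = FALSE) {
  stopifnot(length(a) >= 3L, length(b) >= 3L)
  ms <- rbind(a = c(mean = mean(a), sd = sd(a)), b = c(mean = mean(b), sd = sd(b)))
  degenerate <- sd(a) == 0 && sd(b) == 0
  if (degenerate && mean(a) == mean(b)) {
    res <- list(test_used = "degenerate", statistic = NA_real_, p_value = 1)
  } else {
    normal_a <- sd(a) > 0 && ks_normal(a, alpha)$is_normal
    normal_b <- sd(b) > 0 && ks_normal(b, alpha)$is_normal
    if (normal_a && normal_b) {
      tt <- t.test(a, b, var.equal = !welch)
      res <- list(test_used = "student_t", statistic = unname(tt$statistic),
                  p_value = tt$p.value)
    } else {
      wt <- suppressWarnings(wilcox.test(a, b, exact = FALSE))
      res <- list(test_used = "mann_whitney", statistic = unname(wt$statistic),
                  p_value = wt$p.value)
    }
  }
  structure(list(group_means_sd = ms, test_used = res$test_used,
                 statistic = res$statistic, p_value = res$p_value,
                 significant = res$p_value < alpha,
                 direction = sign(mean(a) - mean(b)),
                 degenerate = degenerate, alpha = alpha),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s: p = %.4g (%ssignificant at %.2g); a = %.3f +/- %.3f, b = %.3f +/- %.3f\n",
              x$test_used, x$p_value, if (x$significant) "" else "not ",
              x$alpha, x$group_means_sd[1, 1], x$group_means_sd[1, 2],
              x$group_means_sd[2, 1], x$group_means_sd[2, 2]))
  invisible(x)
}

.profile_matrix <- function(profiles) {
  do.call(rbind, lapply(profiles, `[[`, "pct"))
}

.compare_bins <- function(pa, pb, names_ab, alpha, welch, p_adjust) {
  sc <- density_scheme()
  A <- .profile_matrix(pa); B <- .profile_matrix(pb)
  enough <- nrow(A) >= 3L && nrow(B) >= 3L
  rows <- lapply(1:12, function(i) {
    if (enough) {
      cmp <- compare_groups(A[, i], B[, i], alpha = alpha, welch = welch)
    } else {
      # too few knees per side for inference: report summaries only
      cmp <- list(group_means_sd = rbind(c(mean(A[, i]), sd(A[, i])),
                                         c(mean(B[, i]), sd(B[, i]))),
                  test_used = "insufficient_n", p_value = NA_real_,
                  direction = sign(mean(A[, i]) - mean(B[, i])))
    }
    data.frame(bin = i, density_hu = sc$labels[i], class = sc$class_of_bin[i],
               mean_a = cmp$group_means_sd[1, 1], sd_a = cmp$group_means_sd[1, 2],
               mean_b = cmp$group_means_sd[2, 1], sd_b = cmp$group_means_sd[2, 2],
               test = cmp$test_used, p_value = cmp$p_value,
               direction = cmp$direction)
  })
  df <- do.call(rbind, rows)
  df$p_adjusted <- p.adjust(df$p_value, method = p_adjust)
  df$significant <- !is.na(df$p_adjusted) & df$p_adjusted < alpha
  names(df)[names(df) == "mean_a"] <- paste0("mean_", names_ab[1])
  names(df)[names(df) == "sd_a"] <- paste0("sd_", names_ab[1])
  names(df)[names(df) == "mean_b"] <- paste0("mean_", names_ab[2])
  names(df)[names(df) == "sd_b"] <- paste0("sd_", names_ab[2])
  df
}

#' Cohort %BTV comparison report
#'
#' The full statistics stage for one bone: per density interval and side, a
#' gated two-group comparison of %BTV between cohorts (12 rows per side,
#' mean +/- SD per group), plus within-group left-vs-right contrasts where
#' both sides are present. Left-vs-right is treated as a two-sample
#' comparison (a paired option is available). No multiple-testing correction
#' is applied by default; per-interval p-values are reported as-is, with
#' `p_adjust` available.
#'
#' @param cohort_a,cohort_b Lists of [btv_profile()]s (one bone, mixed sides).
#' @param group_names Length-2 labels, default `c("judo", "control")`.
#' @param alpha Significance level (default 0.05).
#' @param welch,p_adjust,paired Options: Welch t, p-adjust method
#'   (`"none"`), paired left-right contrast.
#' @return Object of class `btv_report`: `group_comparison` (data.frame, 12
#'   rows per side), `left_right` (data.frame per group), `bone`.
#' @export
btv_report <- function(cohort_a, cohort_b, group_names = c("judo", "control"),
                       alpha = 0.05, welch = FALSE, p_adjust = "none",
                       paired = FALSE) {
  bones <- unique(c(vapply(cohort_a, `[[`, "", "bone"),
                    vapply(cohort_b, `[[`, "", "bone")))
  if (length(bones) != 1L) stop("mixed bones in btv_report", call. = FALSE)
  sides_of <- function(ps) vapply(ps, `[[`, "", "side")
  group_tabs <- list()
  for (s in intersect(unique(sides_of(cohort_a)), unique(sides_of(cohort_b)))) {
    df <- .compare_bins(cohort_a[sides_of(cohort_a) == s],
                        cohort_b[sides_of(cohort_b) == s],
                        group_names, alpha, welch, p_adjust)
    df <- cbind(side = s, df)
    group_tabs[[s]] <- df
  }
  lr_tabs <- list()
  for (g in 1:2) {
    ps <- list(cohort_a, cohort_b)[[g]]
    sides <- sides_of(ps)
    if (!all(c("right", "left") %in% sides)) next
    right <- ps[sides == "right"]; left <- ps[sides == "left"]
    if (paired && length(right) == length(left)) {
      R <- .profile_matrix(right); L <- .profile_matrix(left)
      sc <- density_scheme()
      rows <- lapply(1:12, function(i) {
        d <- R[, i] - L[, i]
        p <- if (sd(d) == 0) 1 else t.test(d)$p.value
        data.frame(bin = i, density_hu = sc$labels[i],
                   mean_right = mean(R[, i]), mean_left = mean(L[, i]),
                   test = "paired_t", p_value = p)
      })
      df <- do.call(rbind, rows)
      df$significant <- df$p_value < alpha
    } else {
      df <- .compare_bins(right, left, c("right", "left"), alpha, welch, p_adjust)
    }
    lr_tabs[[group_names[g]]] <- cbind(group = group_names[g], df)
  }
  structure(list(group_comparison = do.call(rbind, c(group_tabs, list(make.row.names = FALSE))),
                 left_right = if (length(lr_tabs))
                   do.call(rbind, c(lr_tabs, list(make.row.names = FALSE))) else NULL,
                 bone = bones, group_names = group_names, alpha = alpha),
            class = "btv_report")
}

#' @export
print.btv_report <- function(x, ...) {
  cat(sprintf("%%BTV report for %s (%s vs %s), alpha = %.2g\n", x$bone,
              x$group_names[1], x$group_names[2], x$alpha))
  print(x$group_comparison, digits = 4)
  invisible(x)
}
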