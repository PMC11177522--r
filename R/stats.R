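#' Mixed-design (split-plot) repeated-measures ANOVA
#'
#' Two-way ANOVA with one between-subject factor (group) and one
#' within-subject factor (task), the design used to compare mean map
#' intensities across healthy and spastic groups over stretch velocities or
#' contraction levels. The classic decomposition is used: the group effect
#' is tested against subjects-within-groups, the task and interaction
#' effects against the task x subject-within-group error term. No sphericity
#' correction is applied by default; `gg_correction = TRUE` applies
#' Greenhouse-Geisser epsilon to the within-subject tests.
#'
#' @param values Numeric matrix, subjects x tasks (complete design).
#' @param group Factor/vector of per-subject group labels (>= 2 per group).
#' @param gg_correction Apply Greenhouse-Geisser correction to within
#'   effects.
#' @return A data.frame with one row per effect (`group`, `task`,
#'   `group:task`): F, df1, df2, p.
#' @export
mixed_anova <- function(values, group, gg_correction = FALSE) {
  values <- as.matrix(values)
  if (anyNA(values)) stop("incomplete design: missing cells in values")
  group <- factor(group)
  stopifnot(nrow(values) == length(group), ncol(values) >= 2)
  if (any(table(group) < 2)) stop("need at least 2 subjects per group")
  n <- nrow(values); k <- ncol(values); G <- nlevels(group)
  gm <- mean(values)
  subj_means <- rowMeans(values)
  task_means <- colMeans(values)
  grp_means <- tapply(subj_means, group, mean)
  n_g <- as.vector(table(group))

  ss_total <- sum((values - gm)^2)
  ss_between_subj <- k * sum((subj_means - gm)^2)
  ss_group <- k * sum(n_g * (grp_means - gm)^2)
  ss_subj_within <- ss_between_subj - ss_group
  ss_within <- ss_total - ss_between_subj
  ss_task <- n * sum((task_means - gm)^2)
  cell_means <- rowsum(values, group) / n_g       # G x k
  ss_cells <- sum(n_g * (cell_means - gm)^2) * 1  # includes group+task+int
  ss_int <- ss_cells - ss_group - ss_task
  ss_err_within <- ss_within - ss_task - ss_int

  df_group <- G - 1; df_swg <- n - G
  df_task <- k - 1; df_int <- (G - 1) * (k - 1); df_err <- (n - G) * (k - 1)

  ms <- function(ss, df) if (df > 0) ss / df else NA_real_
  warned <- FALSE
  f_of <- function(ss1, df1, ss2, df2) {
    m1 <- ms(ss1, df1); m2 <- ms(ss2, df2)
    if (!is.finite(m2) || m2 <= .Machine$double.eps * max(1, abs(gm))^2) {
      if (!warned) warning("zero error variance; F undefined")
      warned <<- TRUE
      return(c(NaN, NA_real_))
    }
    f <- m1 / m2
    c(f, stats::pf(f, df1, df2, lower.tail = FALSE))
  }
  eps <- 1
  if (gg_correction) eps <- .gg_epsilon(values)
  g <- f_of(ss_group, df_group, ss_subj_within, df_swg)
  t_ <- f_of(ss_task, df_task, ss_err_within, df_err)
  i_ <- f_of(ss_int, df_int, ss_err_within, df_err)
  if (gg_correction) {
    t_[2] <- stats::pf(t_[1], df_task * eps, df_err * eps, lower.tail = FALSE)
    i_[2] <- stats::pf(i_[1], df_int * eps, df_err * eps, lower.tail = FALSE)
  }
  data.frame(
    effect = c("group", "task", "group:task"),
    F = c(g[1], t_[1], i_[1]),
    df1 = c(df_group, df_task, df_int),
    df2 = c(df_swg, df_err, df_err),
    p = c(g[2], t_[2], i_[2]),
    stringsAsFactors = FALSE)
}

# Greenhouse-Geisser epsilon from the within-subject covariance matrix
.gg_epsilon <- function(values) {
  S <- stats::cov(values)
  k <- ncol(S)
  dbar <- mean(diag(S)); sbar <- mean(S)
  rm2 <- rowMeans(S)
  num <- (k * (dbar - sbar))^2
  den <- (k - 1) * (sum(S^2) - 2 * k * sum(rm2^2) + k^2 * sbar^2)
  max(1 / (k - 1), min(1, num / den))
}

#' One-way repeated-measures ANOVA within a group
#'
#' Task effect tested against the task x subject error term, for one group's
#' subjects measured at every task.
#'
#' @param values Numeric matrix, subjects x tasks (complete).
#' @return A one-row data.frame: F, df1, df2, p.
#' @export
one_way_rm_anova <- function(values) {
  values <- as.matrix(values)
  if (anyNA(values)) stop("incomplete design: missing cells in values")
  n <- nrow(values); k <- ncol(values)
  stopifnot(n >= 2, k >= 2)
  gm <- mean(values)
  ss_task <- n * sum((colMeans(values) - gm)^2)
  ss_subj <- k * sum((rowMeans(values) - gm)^2)
  ss_total <- sum((values - gm)^2)
  ss_err <- ss_total - ss_task - ss_subj
  df_task <- k - 1; df_err <- (n - 1) * (k - 1)
  ms_err <- ss_err / df_err
  if (ms_err <= .Machine$double.eps * max(1, abs(gm))^2) {
    warning("zero error variance; F undefined")
    return(data.frame(effect = "task", F = NaN, df1 = df_task, df2 = df_err,
                      p = NA_real_, stringsAsFactors = FALSE))
  }
  f <- (ss_task / df_task) / ms_err
  data.frame(effect = "task", F = f, df1 = df_task, df2 = df_err,
             p = stats::pf(f, df_task, df_err, lower.tail = FALSE),
             stringsAsFactors = FALSE)
}

#' Independent-samples t-test (Student, pooled variance)
#'
#' Post hoc comparison of the two groups at one task. Student's
#' equal-variance form by default; `welch = TRUE` switches to the
#' Welch-Satterthwaite form.
#'
#' @param a,b Numeric samples, each of length >= 2.
#' @param welch Use Welch's unequal-variance t.
#' @param label Comparison label carried into the result.
#' @return A data.frame row: comparison, t, df, p, means and SDs.
#' @export
t_independent <- function(a, b, welch = FALSE, label = "a vs b") {
  stopifnot(length(a) >= 2, length(b) >= 2)
  pooled_var <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) /
    (length(a) + length(b) - 2)
  if (pooled_var <= .Machine$double.eps * max(1, mean(abs(c(a, b))))^2) {
    if (isTRUE(all.equal(mean(a), mean(b))))
      return(.t_row(label, 0, length(a) + length(b) - 2, 1, a, b))
    stop("degenerate variance: zero pooled variance with unequal means")
  }
  ht <- stats::t.test(a, b, var.equal = !welch)
  .t_row(label, unname(ht$statistic), unname(ht$parameter), ht$p.value, a, b)
}

#' Paired-samples t-test
#'
#' Used to compare the passive-stretch and active-contraction CoG
#' coordinates within the spastic group. Equivalent to a one-sample t-test
#' on the paired differences.
#'
#' @param x,y Paired numeric samples of equal length >= 2.
#' @param label Comparison label.
#' @return A data.frame row: comparison, t, df, p, means and SDs.
#' @export
t_paired <- function(x, y, label = "x vs y (paired)") {
  stopifnot(length(x) == length(y), length(x) >= 2)
  d <- x - y
  if (stats::sd(d) <= .Machine$double.eps * max(1, mean(abs(c(x, y))))) {
    if (isTRUE(all.equal(mean(d), 0)))
      return(.t_row(label, 0, length(x) - 1, 1, x, y))
    stop("degenerate variance: constant non-zero paired differences")
  }
  ht <- stats::t.test(x, y, paired = TRUE)
  .t_row(label, unname(ht$statistic), unname(ht$parameter), ht$p.value, x, y)
}

.t_row <- function(label, t, df, p, a, b) {
  data.frame(comparison = label, t = t, df = df, p = p,
             mean_a = mean(a), sd_a = stats::sd(a),
             mean_b = mean(b), sd_b = stats::sd(b),
             stringsAsFactors = FALSE)
}
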