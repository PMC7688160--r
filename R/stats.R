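# Statistics engine: the normality-driven decision tree used for every
# endpoint (hemodynamic, morphometric, delta-Ct), with Tukey or Dunn
# post-hoc correction and a tidy report.

#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the D'Agostino skewness z-score and the Anscombe-Glynn
#' kurtosis z-score into the omnibus statistic `K^2 = Z1^2 + Z2^2`,
#' referred to a chi-squared distribution with 2 df. The approximations
#' are undefined below n = 8; smaller groups cannot demonstrate
#' normality and are routed to non-parametric branches by
#' [select_test()].
#'
#' @param x numeric vector, `n >= 8`.
#' @param alpha significance level for the pass/fail call.
#' @return list: `pass` (p >= alpha), `statistic` (K^2), `p`, `n`.
#' @export
assess_normality <- function(x, alpha = 0.05) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 8)
    stop("normality test requires n >= 8 (got ", n, ")")
  if (stats::sd(x) == 0) {
    warning("constant group: normality fails by convention")
    return(list(pass = FALSE, statistic = NA_real_, p = NA_real_, n = n))
  }
  m <- mean(x)
  m2 <- mean((x - m)^2); m3 <- mean((x - m)^3); m4 <- mean((x - m)^4)

  # skewness z (D'Agostino)
  b1 <- m3 / m2^1.5
  y <- b1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(w2)))
  alpha_s <- sqrt(2 / (w2 - 1))
  z1 <- delta * asinh(y / alpha_s)

  # kurtosis z (Anscombe-Glynn)
  b2 <- m4 / m2^2
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xs <- (b2 - eb2) / sqrt(vb2)
  sb <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sb * (2 / sb + sqrt(1 + 4 / sb^2))
  term <- (1 - 2 / a) / (1 + xs * sqrt(2 / (a - 4)))
  z2 <- ((1 - 2 / (9 * a)) - sign(term) * abs(term)^(1 / 3)) /
    sqrt(2 / (9 * a))

  k2 <- z1^2 + z2^2
  p <- stats::pchisq(k2, df = 2, lower.tail = FALSE)
  list(pass = p >= alpha, statistic = k2, p = p, n = n)
}

#' Select the statistical test for a comparison
#'
#' Implements the study decision tree. Non-paired comparisons: 2 groups
#' use Student's t-test, 3+ groups one-way ANOVA with Tukey post-hoc —
#' unless any participating group is small (n < 7) or fails the
#' D'Agostino-Pearson normality test, in which case the whole comparison
#' goes non-parametric (Mann-Whitney U, or Kruskal-Wallis with Dunn
#' post-hoc). Paired change scores (e.g. the absolute change in a metric
#' from four to six months) use a one-sample t-test against zero when
#' normal, otherwise the Wilcoxon signed-rank test. Because the
#' normality test is undefined below n = 8, groups of n = 7 cannot
#' demonstrate normality and are also routed non-parametric.
#'
#' @param groups named list of numeric vectors (one per group); for
#'   `paired_change = TRUE`, a single vector (or 1-element list) of
#'   change scores.
#' @param paired_change are these paired change scores tested against 0?
#' @param alpha significance level.
#' @return object of class `test_plan`: `branch` (one of `t`,
#'   `mann_whitney`, `anova_tukey`, `kruskal_dunn`, `one_sample_t`,
#'   `wilcoxon_signed_rank`), `reason` (per-group n / normality record),
#'   `alpha`.
#' @export
select_test <- function(groups, paired_change = FALSE, alpha = 0.05) {
  if (is.numeric(groups)) groups <- list(change = groups)
  stopifnot(is.list(groups), length(groups) >= 1,
            all(vapply(groups, is.numeric, TRUE)))
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("group", seq_along(groups))
  reason <- data.frame(group = names(groups),
                       n = vapply(groups, length, 0L),
                       small = vapply(groups, length, 0L) < 7,
                       normality_p = NA_real_, normal = FALSE)
  for (i in seq_along(groups)) {
    if (reason$n[i] >= 8) {
      nt <- suppressWarnings(assess_normality(groups[[i]], alpha))
      reason$normality_p[i] <- nt$p
      reason$normal[i] <- isTRUE(nt$pass)
    }  # n of 7 or below: normality cannot be demonstrated
  }
  parametric <- all(!reason$small & reason$normal)
  k <- length(groups)
  branch <- if (paired_change) {
    if (k != 1) stop("paired_change expects a single vector of change scores")
    if (parametric) "one_sample_t" else "wilcoxon_signed_rank"
  } else if (k == 1) {
    stop("a single group requires paired_change = TRUE")
  } else if (k == 2) {
    if (parametric) "t" else "mann_whitney"
  } else {
    if (parametric) "anova_tukey" else "kruskal_dunn"
  }
  structure(list(branch = branch, reason = reason, alpha = alpha,
                 paired_change = paired_change),
            class = "test_plan")
}

#' @export
print.test_plan <- function(x, ...) {
  cat("<test_plan>", x$branch, "(alpha", x$alpha, ")\n")
  print(x$reason, row.names = FALSE)
  invisible(x)
}

#' Dunn's post-hoc test after Kruskal-Wallis
#'
#' All pairwise comparisons using the rank-sum z statistic on the joint
#' ranking (with the standard tie correction), adjusted for multiplicity
#' by the Bonferroni rule over all pairs.
#'
#' @param groups named list of numeric vectors.
#' @return data frame: `pair`, `z`, `p`, `p_adj`.
#' @export
dunn_test <- function(groups) {
  stopifnot(length(groups) >= 2)
  values <- unlist(groups, use.names = FALSE)
  glab <- rep(names(groups), lengths(groups))
  n <- length(values)
  rk <- rank(values)
  mean_rank <- tapply(rk, glab, mean)[names(groups)]
  sizes <- lengths(groups)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  pairs <- t(utils::combn(names(groups), 2))
  z <- p <- numeric(nrow(pairs))
  for (r in seq_len(nrow(pairs))) {
    a <- pairs[r, 1]; b <- pairs[r, 2]
    se <- sqrt((n * (n + 1) / 12 - tie_term) * (1 / sizes[a] + 1 / sizes[b]))
    z[r] <- (mean_rank[a] - mean_rank[b]) / se
    p[r] <- 2 * stats::pnorm(-abs(z[r]))
  }
  data.frame(pair = paste(pairs[, 1], pairs[, 2], sep = "-"),
             z = z, p = p, p_adj = pmin(1, p * nrow(pairs)))
}

#' Run the selected statistical test
#'
#' Executes the branch chosen by [select_test()]. For 3+ groups all
#' pairwise post-hoc comparisons are reported with Tukey (parametric) or
#' Dunn with Bonferroni-style adjustment (non-parametric); one-sample
#' branches test whether the mean/median change differs from zero. A
#' parametric branch encountering degenerate (zero) variance falls back
#' to its non-parametric counterpart with a warning. All tests are
#' two-sided.
#'
#' @param plan a `test_plan` from [select_test()]; `NULL` selects
#'   automatically.
#' @inheritParams select_test
#' @return object of class `test_result`: `branch`, `statistic`,
#'   `p_value`, `posthoc` (data frame or `NULL`), `significant`, `n`,
#'   `alpha`.
#' @export
run_test <- function(groups, plan = NULL, paired_change = FALSE, alpha = 0.05) {
  if (is.numeric(groups)) groups <- list(change = groups)
  if (is.null(plan)) plan <- select_test(groups, paired_change, alpha)
  stopifnot(inherits(plan, "test_plan"))
  alpha <- plan$alpha
  branch <- plan$branch
  values <- unlist(groups, use.names = FALSE)
  glab <- factor(rep(names(groups), lengths(groups)))

  # degenerate-variance guard for the parametric branches
  if (branch %in% c("t", "anova_tukey", "one_sample_t") &&
      stats::sd(values) == 0) {
    branch <- switch(branch, t = "mann_whitney",
                     anova_tukey = "kruskal_dunn",
                     one_sample_t = "wilcoxon_signed_rank")
    warning("degenerate variance in parametric branch; falling back to ",
            branch)
  }

  posthoc <- NULL
  res <- switch(branch,
    t = {
      ht <- stats::t.test(groups[[1]], groups[[2]], var.equal = TRUE)
      list(statistic = unname(ht$statistic), p_value = ht$p.value)
    },
    mann_whitney = {
      ht <- suppressWarnings(stats::wilcox.test(groups[[1]], groups[[2]]))
      list(statistic = unname(ht$statistic), p_value = ht$p.value)
    },
    anova_tukey = {
      fit <- stats::aov(values ~ glab)
      an <- summary(fit)[[1]]
      tk <- stats::TukeyHSD(fit)$glab
      posthoc <- data.frame(pair = rownames(tk), estimate = tk[, "diff"],
                             p_adj = tk[, "p adj"], row.names = NULL)
      list(statistic = an[1, "F value"], p_value = an[1, "Pr(>F)"])
    },
    kruskal_dunn = {
      ht <- stats::kruskal.test(values, glab)
      posthoc <- dunn_test(groups)
      list(statistic = unname(ht$statistic), p_value = ht$p.value)
    },
    one_sample_t = {
      ht <- stats::t.test(groups[[1]], mu = 0)
      list(statistic = unname(ht$statistic), p_value = ht$p.value)
    },
    wilcoxon_signed_rank = {
      ht <- suppressWarnings(stats::wilcox.test(groups[[1]], mu = 0))
      list(statistic = unname(ht$statistic), p_value = ht$p.value)
    },
    stop("unknown branch: ", branch))

  significant <- if (!is.null(posthoc)) any(posthoc$p_adj < alpha)
                 else res$p_value < alpha
  structure(list(branch = branch, statistic = res$statistic,
                 p_value = res$p_value, posthoc = posthoc,
                 significant = significant,
                 n = lengths(groups), alpha = alpha, plan = plan),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<test_result> %s: statistic %.4g, p %.4g%s\n", x$branch,
              x$statistic, x$p_value,
              if (x$significant) " *" else ""))
  if (!is.null(x$posthoc)) print(x$posthoc, row.names = FALSE)
  invisible(x)
}

#' Compare groups end to end
#'
#' Convenience wrapper: select the branch, run it, return the result.
#' @inheritParams select_test
#' @return a `test_result`.
#' @export
compare_groups <- function(groups, paired_change = FALSE, alpha = 0.05) {
  run_test(groups, plan = select_test(groups, paired_change, alpha))
}

#' Tidy study table from a set of test results
#'
#' @param results named list of `test_result` objects (names are
#'   endpoint labels). An empty list yields an empty table with headers.
#' @return data frame: endpoint, branch, n, statistic, p_value,
#'   min_adj_p, significant.
#' @export
report <- function(results) {
  if (!length(results))
    return(data.frame(endpoint = character(0), branch = character(0),
                      n = character(0), statistic = numeric(0),
                      p_value = numeric(0), min_adj_p = numeric(0),
                      significant = logical(0)))
  stopifnot(all(vapply(results, inherits, TRUE, "test_result")))
  if (is.null(names(results)))
    names(results) <- paste0("endpoint", seq_along(results))
  do.call(rbind, lapply(names(results), function(nm) {
    r <- results[[nm]]
    data.frame(endpoint = nm, branch = r$branch,
               n = paste(r$n, collapse = "/"),
               statistic = r$statistic, p_value = r$p_value,
               min_adj_p = if (!is.null(r$posthoc)) min(r$posthoc$p_adj)
                           else NA_real_,
               significant = r$significant)
  }))
}
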