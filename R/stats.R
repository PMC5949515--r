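test_result <- function(test_name, statistic, p_value, decision_path,
                        alpha, ...) {
  tibble::tibble(test_name = test_name, statistic = statistic,
                 p_value = p_value, decision_path = decision_path,
                 alpha = alpha, significant = p_value < alpha, ...)
}

safe_shapiro_p <- function(x) {
  if (length(unique(x)) < 2L) return(0)  # degenerate: treat as non-normal
  tryCatch(shapiro.test(x)$p.value, error = function(e) 0)
}

#' Choose the two-group test by the distributional decision tree
#'
#' Student's t is used only when both groups pass Shapiro-Wilk normality
#' (p > alpha) *and* the two-sided F test of variance homogeneity passes
#' (p > alpha); otherwise the Mann-Whitney U test is used. Groups smaller
#' than 3 (Shapiro-Wilk's minimum) are routed to Mann-Whitney with a note.
#'
#' @param x,y Numeric samples.
#' @param alpha Significance level for the preliminary tests.
#' @return One-row tibble: `decision` (`"t_test"` or `"mann_whitney"`),
#'   the preliminary p-values (`shapiro_p_x`, `shapiro_p_y`, `variance_p`)
#'   and a human-readable `decision_path`.
#' @export
choose_two_group_test <- function(x, y, alpha = 0.05) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (min(length(x), length(y)) < 3L) {
    return(tibble::tibble(
      decision = "mann_whitney", shapiro_p_x = NA_real_,
      shapiro_p_y = NA_real_, variance_p = NA_real_,
      decision_path = "n < 3: Shapiro-Wilk not applicable, forced Mann-Whitney"))
  }
  sw_x <- safe_shapiro_p(x)
  sw_y <- safe_shapiro_p(y)
  normal <- sw_x > alpha && sw_y > alpha
  var_p <- NA_real_
  homo <- FALSE
  if (normal) {
    if (var(x) > 0 && var(y) > 0) {
      var_p <- var.test(x, y)$p.value
      homo <- var_p > alpha
    }
  }
  decision <- if (normal && homo) "t_test" else "mann_whitney"
  tibble::tibble(
    decision = decision, shapiro_p_x = sw_x, shapiro_p_y = sw_y,
    variance_p = var_p,
    decision_path = sprintf(
      "Shapiro-Wilk p = %.3g / %.3g (normal: %s); F-test p = %s (homogeneous: %s) -> %s",
      sw_x, sw_y, normal,
      ifelse(is.na(var_p), "n/a", sprintf("%.3g", var_p)), homo, decision))
}

# Mann-Whitney U from the rank formulation; ties get midranks.
mw_u <- function(r, n1) sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2

#' Two-group comparison (two-sided)
#'
#' `method = "auto"` applies the decision tree of [choose_two_group_test()].
#' The t path is the pooled-variance two-sided Student's t; when both groups
#' are constant (degenerate variance) it warns and falls back to
#' Mann-Whitney. The Mann-Whitney path enumerates all group assignments
#' exactly when `min(n) <= 8`, and otherwise uses the tie-corrected normal
#' approximation (no continuity correction, so that the two-group
#' Kruskal-Wallis chi-square equals z^2).
#'
#' @param x,y Numeric samples.
#' @param method `"auto"`, `"t_test"` or `"mann_whitney"`.
#' @param alpha Significance level.
#' @param exact_max Largest `min(n)` for which the exact permutation null is
#'   enumerated.
#' @return One-row test tibble: `test_name`, `statistic`, `p_value`,
#'   `decision_path`, `alpha`, `significant`, group sizes.
#' @export
two_group_test <- function(x, y, method = c("auto", "t_test", "mann_whitney"),
                           alpha = 0.05, exact_max = 8L) {
  method <- match.arg(method)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  path <- "method forced by caller"
  if (method == "auto") {
    d <- choose_two_group_test(x, y, alpha)
    method <- d$decision
    path <- d$decision_path
  }
  if (method == "t_test" && sd(c(x - mean(x), y - mean(y))) == 0) {
    warning("degenerate (zero) pooled variance: falling back to Mann-Whitney",
            call. = FALSE)
    method <- "mann_whitney"
    path <- paste(path, "| zero pooled variance -> mann_whitney")
  }
  n1 <- length(x); n2 <- length(y)
  if (method == "t_test") {
    tt <- t.test(x, y, var.equal = TRUE)
    return(test_result("t_test", unname(tt$statistic), tt$p.value, path,
                       alpha, n_x = n1, n_y = n2, detail = "pooled variance"))
  }
  r <- rank(c(x, y))
  u_obs <- mw_u(r, n1)
  if (min(n1, n2) <= exact_max) {
    idx <- utils::combn(n1 + n2, n1)
    u_all <- colSums(matrix(r[idx], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
    detail <- sprintf("exact permutation (%d assignments)", ncol(idx))
  } else {
    n <- n1 + n2
    ties <- table(r)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
      detail <- "all observations tied"
    } else {
      z <- (u_obs - n1 * n2 / 2) / sqrt(sigma2)
      p <- 2 * pnorm(-abs(z))
      detail <- "normal approximation, tie-corrected"
    }
  }
  test_result("mann_whitney", u_obs, p, path, alpha,
              n_x = n1, n_y = n2, detail = detail)
}

as_group_df <- function(groups, value = "value", group = "group") {
  if (is.data.frame(groups)) {
    df <- tibble::tibble(value = groups[[value]],
                         group = factor(groups[[group]],
                                        levels = unique(groups[[group]])))
  } else {
    if (is.null(names(groups))) {
      names(groups) <- paste0("g", seq_along(groups))
    }
    df <- tibble::tibble(
      value = unlist(groups, use.names = FALSE),
      group = factor(rep(names(groups), lengths(groups)),
                     levels = names(groups)))
  }
  df[!is.na(df$value), , drop = FALSE]
}

#' Kruskal-Wallis test with Dunn's post hoc comparisons
#'
#' Omnibus Kruskal-Wallis H with tie correction, followed by Dunn's rank-based
#' pairwise z tests on the pooled ranks. Dunn p-values are Bonferroni-adjusted
#' by default (`adjust = "none"` reports raw ones). With all observations
#' identical the omnibus is degenerate: H = 0, p = 1, flagged in the decision
#' path.
#'
#' @param groups Named list of numeric vectors, or a data frame with columns
#'   `value` and `group`.
#' @param alpha Significance level.
#' @param adjust Dunn adjustment method.
#' @return An `ist_omnibus` list: `test` (omnibus tibble) and `posthoc`
#'   (pairwise tibble: `group_a`, `group_b`, `statistic`, `raw_p`,
#'   `adjusted_p`, `method`).
#' @export
kruskal_dunn <- function(groups, alpha = 0.05,
                         adjust = c("bonferroni", "none")) {
  adjust <- match.arg(adjust)
  df <- as_group_df(groups)
  k <- nlevels(df$group)
  if (k < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(table(df$group) < 2L)) {
    stop("every group needs n >= 2", call. = FALSE)
  }
  lev <- levels(df$group)
  if (length(unique(df$value)) == 1L) {
    test <- test_result("kruskal_wallis", 0, 1,
                        "degenerate: all observations identical", alpha,
                        df_stat = k - 1)
    pairs <- t(utils::combn(lev, 2))
    posthoc <- tibble::tibble(
      group_a = pairs[, 1], group_b = pairs[, 2], statistic = 0,
      raw_p = 1, adjusted_p = 1, method = paste0("dunn_", adjust))
  } else {
    kw <- kruskal.test(value ~ group, data = df)
    test <- test_result("kruskal_wallis", unname(kw$statistic), kw$p.value,
                        sprintf("Kruskal-Wallis (tie-corrected), %d groups", k),
                        alpha, df_stat = unname(kw$parameter))
    n <- nrow(df)
    r <- rank(df$value)
    rbar <- tapply(r, df$group, mean)
    ni <- table(df$group)
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
    pairs <- t(utils::combn(lev, 2))
    z <- vapply(seq_len(nrow(pairs)), function(i) {
      a <- pairs[i, 1]; b <- pairs[i, 2]
      se <- sqrt((n * (n + 1) / 12 - tie_term) * (1 / ni[[a]] + 1 / ni[[b]]))
      (rbar[[a]] - rbar[[b]]) / se
    }, numeric(1))
    raw_p <- 2 * pnorm(-abs(z))
    posthoc <- tibble::tibble(
      group_a = pairs[, 1], group_b = pairs[, 2], statistic = z,
      raw_p = raw_p,
      adjusted_p = p.adjust(raw_p, method = if (adjust == "none") "none"
                            else "bonferroni"),
      method = paste0("dunn_", adjust))
  }
  structure(list(test = test, posthoc = posthoc, alpha = alpha),
            class = "ist_omnibus")
}

#' ANOVA with Fisher LSD post hoc comparisons
#'
#' One-way ANOVA (data frame with `value` + `group`, or a named list) or
#' two-way ANOVA (data frame with `value` + `genotype` + `age_months`; type-II
#' sums of squares, so unbalanced layouts are handled), followed by Fisher's
#' LSD: pairwise t tests using the ANOVA residual mean square, unadjusted by
#' definition.
#'
#' @param data Named list of numeric vectors or a data frame (see above).
#' @param alpha Significance level.
#' @return An `ist_omnibus` list: `test` (one row per ANOVA term) and
#'   `posthoc` (pairwise LSD rows).
#' @export
anova_lsd <- function(data, alpha = 0.05) {
  two_way <- is.data.frame(data) &&
    all(c("genotype", "age_months") %in% names(data))
  if (two_way) {
    df <- tibble::tibble(value = data$value,
                         genotype = factor(data$genotype),
                         age = factor(data$age_months))
    df <- df[!is.na(df$value), , drop = FALSE]
    fit <- lm(value ~ genotype * age, data = df)
    if (all(abs(stats::residuals(fit)) < 1e-12) &&
        var(df$value) < 1e-24) {
      test <- test_result(paste0("two_way_anova:",
                                 c("genotype", "age", "genotype:age")),
                          0, 1, "degenerate: all observations identical",
                          alpha)
    } else {
      a2 <- car::Anova(fit, type = 2)
      terms <- c("genotype", "age", "genotype:age")
      test <- test_result(
        paste0("two_way_anova:", terms),
        a2[terms, "F value"], a2[terms, "Pr(>F)"],
        "two-way ANOVA, type-II sums of squares", alpha)
    }
    df$cell <- interaction(df$genotype, df$age, sep = ":")
    mse <- sum(stats::residuals(fit)^2) / fit$df.residual
    df_res <- fit$df.residual
    groups_f <- df$cell
  } else {
    gdf <- as_group_df(data)
    if (var(gdf$value) < 1e-24) {
      # all observations identical: SSbetween = 0, report F = 0
      fit <- aov(value ~ group, data = gdf)
      an <- suppressWarnings(anova(fit))
      f_val <- 0; p_val <- 1
    } else {
      fit <- aov(value ~ group, data = gdf)
      an <- anova(fit)
      f_val <- an[1, "F value"]
      p_val <- an[1, "Pr(>F)"]
      if (!is.finite(p_val)) p_val <- 1
    }
    test <- test_result("one_way_anova", f_val, p_val,
                        sprintf("one-way ANOVA, %d groups",
                                nlevels(gdf$group)), alpha,
                        df1 = an[1, "Df"], df2 = an[2, "Df"])
    mse <- an[2, "Mean Sq"]
    df_res <- an[2, "Df"]
    groups_f <- gdf$group
    df <- gdf
  }
  ni <- table(groups_f)
  mi <- tapply(df$value, groups_f, mean)
  lev <- names(ni)[ni > 0]
  pairs <- t(utils::combn(lev, 2))
  tstat <- vapply(seq_len(nrow(pairs)), function(i) {
    a <- pairs[i, 1]; b <- pairs[i, 2]
    se <- sqrt(mse * (1 / ni[[a]] + 1 / ni[[b]]))
    if (se == 0) return(0)
    (mi[[a]] - mi[[b]]) / se
  }, numeric(1))
  raw_p <- 2 * pt(-abs(tstat), df_res)
  posthoc <- tibble::tibble(
    group_a = pairs[, 1], group_b = pairs[, 2], statistic = tstat,
    raw_p = raw_p, adjusted_p = raw_p, method = "fisher_lsd")
  structure(list(test = test, posthoc = posthoc, alpha = alpha),
            class = "ist_omnibus")
}

#' Linear trend contrast across ordered groups
#'
#' F test of the equally spaced linear contrast over ordered group means,
#' with the error mean square taken from the one-way ANOVA -- the "linear
#' trend" reading of an ordered-group design (e.g. density across ages).
#'
#' @param groups Named list of numeric vectors in the intended order, or a
#'   data frame with `value` and `group` (order of first appearance).
#' @param alpha Significance level.
#' @return One-row test tibble.
#' @export
linear_trend <- function(groups, alpha = 0.05) {
  df <- as_group_df(groups)
  k <- nlevels(df$group)
  if (k < 3L) stop("linear trend needs at least 3 ordered groups",
                   call. = FALSE)
  ni <- table(df$group)
  mi <- tapply(df$value, df$group, mean)
  ssw <- sum(tapply(df$value, df$group,
                    function(v) sum((v - mean(v))^2)))
  df_res <- nrow(df) - k
  mse <- ssw / df_res
  cc <- seq_len(k) - (k + 1) / 2
  l <- sum(cc * mi)
  var_l <- mse * sum(cc^2 / as.numeric(ni))
  if (var_l == 0) {
    f <- if (abs(l) < 1e-12) 0 else Inf
    p <- if (f == 0) 1 else 0
  } else {
    f <- l^2 / var_l
    p <- pf(f, 1, df_res, lower.tail = FALSE)
  }
  test_result("linear_trend", f, p,
              sprintf("linear contrast over %d ordered groups, df = (1, %d)",
                      k, df_res),
              alpha, contrast_estimate = l)
}

#' @export
print.ist_omnibus <- function(x, ...) {
  cat("Omnibus test:\n")
  print(x$test)
  cat("\nPost hoc comparisons:\n")
  print(x$posthoc)
  invisible(x)
}

#' Tidy post hoc comparisons of an omnibus result
#' @param x An `ist_omnibus` from [kruskal_dunn()] or [anova_lsd()].
#' @param ... Unused.
#' @return Tibble of pairwise rows with significance stars.
#' @method tidy ist_omnibus
#' @export
tidy.ist_omnibus <- function(x, ...) {
  dplyr::mutate(x$posthoc, stars = significance_stars(.data$adjusted_p))
}

#' One-row omnibus summary
#' @param x An `ist_omnibus`.
#' @param ... Unused.
#' @return The omnibus test tibble.
#' @method glance ist_omnibus
#' @export
glance.ist_omnibus <- function(x, ...) {
  x$test
}
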