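#' Cronbach's alpha with zero-variance item exclusion
#'
#' Internal-consistency reliability of a set of dichotomous (or ordinal)
#' items. Items with zero variance over the complete rows carry no
#' covariance information and are excluded before estimation, with the
#' exclusions reported; `alpha = k/(k-1) * (1 - sum(item variances) /
#' variance of the total)` over the retained items.
#'
#' @param item_matrix Numeric matrix or data frame, respondents in rows,
#'   items in columns (column names identify items). Rows with any missing
#'   value are dropped (complete-case).
#' @return Object of class `kindex_reliability`: `alpha`, `n_items_input`,
#'   `n_items_retained`, `excluded_items` (tibble `item`, `reason`),
#'   `n_respondents`.
#' @export
#' @examples
#' m <- cbind(a = c(0, 1, 1, 0), b = c(0, 1, 1, 0), c = c(1, 1, 0, 0))
#' cronbach_alpha(m)
cronbach_alpha <- function(item_matrix) {
  m <- as.matrix(item_matrix)
  storage.mode(m) <- "double"
  if (is.null(colnames(m))) colnames(m) <- paste0("item_", seq_len(ncol(m)))
  m <- m[stats::complete.cases(m), , drop = FALSE]
  if (nrow(m) < 2) {
    stop("cronbach_alpha needs at least 2 complete respondents", call. = FALSE)
  }
  v <- apply(m, 2L, stats::var)
  zero <- colnames(m)[v == 0]
  excluded <- tibble::tibble(item = zero,
                             reason = rep("zero_variation", length(zero)))
  keep <- setdiff(colnames(m), zero)
  if (length(keep) < 2) {
    stop("fewer than 2 items with nonzero variance retained", call. = FALSE)
  }
  mk <- m[, keep, drop = FALSE]
  k <- ncol(mk)
  alpha <- k / (k - 1) * (1 - sum(apply(mk, 2L, stats::var)) /
                            stats::var(rowSums(mk)))
  structure(list(alpha = alpha, n_items_input = ncol(m),
                 n_items_retained = k, excluded_items = excluded,
                 n_respondents = nrow(m)),
            class = "kindex_reliability")
}

#' @export
print.kindex_reliability <- function(x, ...) {
  cat("<reliability> Cronbach's alpha = ", format(round(x$alpha, 3)),
      " (", x$n_items_retained, "/", x$n_items_input, " items, n = ",
      x$n_respondents, ")\n", sep = "")
  if (nrow(x$excluded_items)) {
    cat("  excluded (zero variation): ",
        paste(x$excluded_items$item, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' @keywords internal
#' @noRd
spearman_rho <- function(x, y) {
  stats::cor(rank(x), rank(y))
}

#' @keywords internal
#' @noRd
spearman_p <- function(rho, n) {
  # t approximation on n - 2 df, two-sided
  if (is.na(rho) || n < 3 || abs(rho) >= 1) {
    return(if (!is.na(rho) && abs(rho) >= 1 && n >= 3) 0 else NA_real_)
  }
  tval <- rho * sqrt((n - 2) / (1 - rho^2))
  2 * stats::pt(-abs(tval), df = n - 2)
}

#' Pairwise Spearman rank correlations
#'
#' Rank correlation between every pair of columns, computed as the
#' product-moment correlation of midranks over the pairwise-complete cases,
#' with a t-approximation p-value. Constant variables (over the pairwise
#' sample) have undefined rho and are reported as `NA`.
#'
#' @param data Data frame / tibble of numeric columns (e.g. the risk sum
#'   score and the three global composites).
#' @return Tibble of class `kindex_correlations`: `var1`, `var2`, `rho`,
#'   `n`, `p`, one row per unordered pair.
#' @export
spearman_matrix <- function(data) {
  vars <- names(data)
  if (length(vars) < 2) stop("need at least two variables", call. = FALSE)
  rows <- list()
  for (i in seq_along(vars)[-length(vars)]) {
    for (j in (i + 1L):length(vars)) {
      x <- data[[vars[i]]]; y <- data[[vars[j]]]
      ok <- !is.na(x) & !is.na(y)
      n <- sum(ok)
      if (n < 3) {
        stop("fewer than 3 pairwise-complete cases for ", vars[i], " vs ",
             vars[j], call. = FALSE)
      }
      constant <- length(unique(x[ok])) < 2 || length(unique(y[ok])) < 2
      rho <- if (constant) NA_real_ else spearman_rho(x[ok], y[ok])
      rows[[length(rows) + 1L]] <- tibble::tibble(
        var1 = vars[i], var2 = vars[j], rho = rho, n = n,
        p = spearman_p(rho, n))
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("kindex_correlations", class(out))
  out
}

#' @keywords internal
#' @noRd
group_summary <- function(x) {
  tibble::tibble(n = length(x), median = stats::median(x),
                 min = min(x), max = max(x),
                 mean = mean(x), sd = stats::sd(x))
}

#' Mann-Whitney U test
#'
#' Two-sample rank test in the reporting convention of validation-study
#' tables: both U values (`u_a + u_b = n_a * n_b` always), midranks for
#' ties, an exact enumeration p-value when both groups are small
#' (`min(n) <= 8`) and untied, and a tie-corrected normal approximation
#' (no continuity correction) otherwise. Per-group medians, minima and
#' maxima are reported alongside.
#'
#' @param a,b Numeric vectors, both non-empty.
#' @param exact_max Largest `min(n_a, n_b)` for which the exact untied
#'   p-value is enumerated, default 8; enumeration is also skipped when the
#'   number of rank assignments exceeds 5e5.
#' @return Object of class `kindex_test` (test = `"mann_whitney_u"`):
#'   `statistic` (U of group A), `u_a`, `u_b`, `p`, `method`
#'   (`"exact"` or `"normal_approx"`), `groups` (summary tibble).
#' @export
mann_whitney <- function(a, b, exact_max = 8) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (!length(a) || !length(b)) {
    stop("mann_whitney: empty group", call. = FALSE)
  }
  na <- length(a); nb <- length(b); n <- na + nb
  r <- rank(c(a, b))
  ra <- sum(r[seq_len(na)])
  u_a <- ra - na * (na + 1) / 2
  u_b <- na * nb - u_a
  ties <- any(duplicated(c(a, b)))
  k <- min(na, nb)
  if (!ties && k <= exact_max && choose(n, k) <= 5e5) {
    method <- "exact"
    # enumerate rank assignments of the smaller group; the distribution of
    # min(U, nA*nB - U) does not depend on which group is enumerated
    combos <- utils::combn(n, k)
    u_all <- colSums(matrix(r[combos], nrow = k)) - k * (k + 1) / 2
    u_obs <- min(u_a, u_b)
    p <- mean(pmin(u_all, na * nb - u_all) <= u_obs)
    p <- min(1, p)
  } else {
    method <- "normal_approx"
    tie_tab <- table(r)
    tie_term <- sum(tie_tab^3 - tie_tab) / (n * (n - 1))
    sigma2 <- na * nb / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) {
      stop("mann_whitney: all observations tied, U variance is zero",
           call. = FALSE)
    }
    zstat <- (u_a - na * nb / 2) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(zstat))
  }
  groups <- dplyr::bind_rows(A = group_summary(a), B = group_summary(b),
                             .id = "group")
  structure(list(test = "mann_whitney_u", statistic = u_a, u_a = u_a,
                 u_b = u_b, p = p, method = method, groups = groups),
            class = "kindex_test")
}

#' Kruskal-Wallis H test
#'
#' Rank analysis of variance for two or more groups with tie correction,
#' chi-square reference distribution on k - 1 degrees of freedom
#' (via [stats::kruskal.test()]).
#'
#' @param groups List of two or more non-empty numeric vectors.
#' @return `kindex_test` (test = `"kruskal_wallis_h"`): `statistic` (H),
#'   `df`, `p`, `groups` summary tibble.
#' @export
kruskal_wallis <- function(groups) {
  groups <- lapply(groups, function(g) g[!is.na(g)])
  if (length(groups) < 2 || any(!lengths(groups))) {
    stop("kruskal_wallis: need >= 2 non-empty groups", call. = FALSE)
  }
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  kt <- stats::kruskal.test(x, g)
  summaries <- dplyr::bind_rows(lapply(groups, group_summary),
                                .id = "group")
  structure(list(test = "kruskal_wallis_h",
                 statistic = unname(kt$statistic), df = unname(kt$parameter),
                 p = kt$p.value, groups = summaries),
            class = "kindex_test")
}

#' Pooled-variance two-sample t test
#'
#' Student's t test assuming equal variances, `df = n_a + n_b - 2`, as used
#' for interviewer-profession comparisons of the risk sum score. Two
#' zero-variance groups with equal means are degenerate and raise an error.
#'
#' @param a,b Numeric vectors, each with at least 2 non-missing values.
#' @param one_sided Report a one-sided p-value (`P(T > |t|)` direction of
#'   the observed difference); default `FALSE` (two-sided).
#' @return `kindex_test` (test = `"student_t"`): `statistic`, `df`, `p`,
#'   `groups` summary tibble.
#' @export
student_t <- function(a, b, one_sided = FALSE) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) {
    stop("student_t: each group needs n >= 2", call. = FALSE)
  }
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    stop("student_t: zero variance in both groups, t is degenerate",
         call. = FALSE)
  }
  tt <- stats::t.test(a, b, var.equal = TRUE)
  p <- tt$p.value
  if (one_sided) p <- p / 2
  structure(list(test = "student_t", statistic = unname(tt$statistic),
                 df = unname(tt$parameter), p = p,
                 groups = dplyr::bind_rows(A = group_summary(a),
                                           B = group_summary(b),
                                           .id = "group")),
            class = "kindex_test")
}

#' Pearson chi-square test for a 2x2 table
#'
#' Association test for two dichotomous variables, by default without the
#' Yates continuity correction. A zero row or column margin leaves the
#' statistic undefined and raises an error naming the margin.
#'
#' @param contingency 2x2 numeric matrix of counts.
#' @param correct Apply the continuity correction, default `FALSE`.
#' @return `kindex_test` (test = `"chi_square"`): `statistic`, `df` (1),
#'   `p`, `table`.
#' @export
chi_square_2x2 <- function(contingency, correct = FALSE) {
  m <- as.matrix(contingency)
  if (!all(dim(m) == c(2L, 2L))) {
    stop("chi_square_2x2 expects a 2x2 table", call. = FALSE)
  }
  rs <- rowSums(m); cs <- colSums(m)
  if (any(rs == 0)) {
    stop("chi_square_2x2: zero row margin (row ", which(rs == 0)[1], ")",
         call. = FALSE)
  }
  if (any(cs == 0)) {
    stop("chi_square_2x2: zero column margin (column ", which(cs == 0)[1],
         ")", call. = FALSE)
  }
  ct <- suppressWarnings(stats::chisq.test(m, correct = correct))
  structure(list(test = "chi_square", statistic = unname(ct$statistic),
                 df = unname(ct$parameter), p = ct$p.value, table = m),
            class = "kindex_test")
}

#' Lilliefors (Kolmogorov-Smirnov) normality screening
#'
#' Normality gate applied to each composite and to the risk sum score
#' before choosing nonparametric tests. Because the mean and SD are
#' estimated from the data, the Lilliefors correction of the
#' Kolmogorov-Smirnov test is used (via [nortest::lillie.test()]); a
#' significant D flags the variable as non-normal.
#'
#' @param x Numeric vector, at least 4 non-missing distinct-spread values.
#' @param alpha Decision level, default 0.05.
#' @param variable Optional variable name carried into the result.
#' @return Object of class `kindex_normality`: `variable`, `D`, `n`, `p`,
#'   `normal` (logical at `alpha`), `alpha`.
#' @export
ks_normality <- function(x, alpha = 0.05, variable = deparse(substitute(x))) {
  x <- x[!is.na(x)]
  if (length(x) < 4) {
    stop("ks_normality needs at least 4 complete values", call. = FALSE)
  }
  if (stats::sd(x) == 0) {
    stop("ks_normality: constant input", call. = FALSE)
  }
  lt <- nortest::lillie.test(x)
  structure(list(variable = variable, D = unname(lt$statistic),
                 n = length(x), p = lt$p.value,
                 normal = lt$p.value > alpha, alpha = alpha),
            class = "kindex_normality")
}

#' @export
print.kindex_normality <- function(x, ...) {
  cat(sprintf("<normality> %s: D(%d) = %.3f, p = %.4g -> %s at alpha %.2f\n",
              x$variable, x$n, x$D, x$p,
              if (x$normal) "normal not rejected" else "non-normal",
              x$alpha))
  invisible(x)
}

#' @export
print.kindex_test <- function(x, ...) {
  cat("<", x$test, ">", sep = "")
  if (!is.null(x$df)) cat(" df = ", format(x$df), ",", sep = "")
  cat(" statistic = ", format(round(x$statistic, 3)),
      ", p = ", format(signif(x$p, 3)), "\n", sep = "")
  if (!is.null(x$groups)) print(x$groups)
  invisible(x)
}

#' Item-criterion group comparisons
#'
#' For one dichotomous risk indicator, compares indicator-positive and
#' indicator-negative respondents on each criterion scale with the
#' Mann-Whitney U test, emitting rows in the layout of validation-study
#' group-comparison tables (per-group median/min/max, U, p).
#'
#' @param indicator Logical (or 0/1) vector.
#' @param criteria Data frame / tibble of numeric criterion scales over the
#'   same respondents.
#' @return Tibble: `scale`, `n_yes`, `n_no`, `mdn_yes`, `min_yes`,
#'   `max_yes`, `mdn_no`, `min_no`, `max_no`, `U`, `p`.
#' @export
item_criterion_comparison <- function(indicator, criteria) {
  ind <- as.logical(indicator)
  rows <- lapply(names(criteria), function(sc) {
    x <- criteria[[sc]]
    ok <- !is.na(x) & !is.na(ind)
    yes <- x[ok & ind]; no <- x[ok & !ind]
    if (!length(yes) || !length(no)) {
      stop("item_criterion_comparison: empty ",
           if (!length(yes)) "indicator-positive" else "indicator-negative",
           " group for scale ", sc, call. = FALSE)
    }
    mw <- mann_whitney(yes, no)
    tibble::tibble(scale = sc, n_yes = length(yes), n_no = length(no),
                   mdn_yes = stats::median(yes), min_yes = min(yes),
                   max_yes = max(yes),
                   mdn_no = stats::median(no), min_no = min(no),
                   max_no = max(no),
                   U = min(mw$u_a, mw$u_b), p = mw$p)
  })
  dplyr::bind_rows(rows)
}

#' Cohort descriptives in screening-table layout
#'
#' Per-indicator counts and percentages, overall and split by membership in
#' the validation subsample, with a chi-square subgroup-difference test
#' (Mann-Whitney for the rating/score rows). Mirrors the layout of a risk
#' factor overview table.
#'
#' @param profile Tibble from [risk_profile()].
#' @param interviews Raw interview tibble (for the rating rows); optional.
#' @param in_validation Logical vector marking the validation subsample;
#'   default taken from `interviews$in_validation`, else all `TRUE`.
#' @return List of class `kindex_descriptives`: `indicators` (tibble with
#'   `indicator`, `area`, `n`, `pct`, `n_val_yes`, `pct_val_yes`,
#'   `n_val_no`, `pct_val_no`, `p_diff`), `ratings` (mean/SD rows), `n`.
#' @export
descriptives <- function(profile, interviews = NULL, in_validation = NULL) {
  if (!nrow(profile)) stop("empty cohort", call. = FALSE)
  if (is.null(in_validation)) {
    in_validation <- if (!is.null(interviews) &&
                         "in_validation" %in% names(interviews)) {
      interviews$in_validation[match(profile$respondent_id,
                                     interviews$respondent_id)]
    } else rep(TRUE, nrow(profile))
  }
  reg <- kindex_indicator_registry()
  n <- nrow(profile)
  rows <- lapply(seq_len(nrow(reg)), function(i) {
    v <- profile[[reg$indicator[i]]]
    yes <- v[in_validation]; no <- v[!in_validation]
    p_diff <- NA_real_
    if (length(no) && length(unique(stats::na.omit(v))) > 1 &&
        length(unique(in_validation)) > 1) {
      tab <- table(factor(v, c(FALSE, TRUE)),
                   factor(in_validation, c(FALSE, TRUE)))
      if (all(rowSums(tab) > 0) && all(colSums(tab) > 0)) {
        p_diff <- chi_square_2x2(tab)$p
      }
    }
    tibble::tibble(
      indicator = reg$indicator[i], area = reg$area[i],
      n = sum(v, na.rm = TRUE),
      pct = 100 * mean(v, na.rm = TRUE),
      n_val_yes = sum(yes, na.rm = TRUE),
      pct_val_yes = if (length(yes)) 100 * mean(yes, na.rm = TRUE) else NA_real_,
      n_val_no = sum(no, na.rm = TRUE),
      pct_val_no = if (length(no)) 100 * mean(no, na.rm = TRUE) else NA_real_,
      p_diff = p_diff)
  })
  ratings <- NULL
  if (!is.null(interviews)) {
    rate_cols <- intersect(c("age_years", "gestational_week", "joy_mother",
                             "worries_mother", "joy_father", "worries_father"),
                           names(interviews))
    iv <- interviews[match(profile$respondent_id, interviews$respondent_id), ]
    ratings <- dplyr::bind_rows(lapply(rate_cols, function(col) {
      x <- iv[[col]]
      yes <- x[in_validation]; no <- x[!in_validation]
      p_diff <- if (length(no) > 0 && length(yes) > 0 &&
                    length(unique(stats::na.omit(x))) > 1) {
        mann_whitney(yes, no)$p
      } else NA_real_
      tibble::tibble(variable = col, mean = mean(x, na.rm = TRUE),
                     sd = stats::sd(x, na.rm = TRUE),
                     mean_val_yes = mean(yes, na.rm = TRUE),
                     mean_val_no = if (length(no)) mean(no, na.rm = TRUE) else NA_real_,
                     p_diff = p_diff)
    }))
  }
  structure(list(indicators = dplyr::bind_rows(rows), ratings = ratings,
                 n = n, n_validation = sum(in_validation)),
            class = "kindex_descriptives")
}

#' @export
print.kindex_descriptives <- function(x, ...) {
  cat("<descriptives> n = ", x$n, " (validation subsample n = ",
      x$n_validation, ")\n", sep = "")
  print(x$indicators, n = 31)
  invisible(x)
}
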