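test_that("Cronbach's alpha: perfect consistency, independence, exclusions", {
  m <- cbind(a = c(0, 1, 1, 0, 1), b = c(0, 1, 1, 0, 1))
  expect_equal(cronbach_alpha(m)$alpha, 1.0)

  set.seed(51)
  ind <- matrix(rbinom(5000 * 28, 1, 0.3), nrow = 5000,
                dimnames = list(NULL, sprintf("i%02d", 1:28)))
  expect_lt(abs(cronbach_alpha(ind)$alpha), 0.05)

  m31 <- matrix(rbinom(100 * 31, 1, 0.4), nrow = 100,
                dimnames = list(NULL, sprintf("k%02d", 1:31)))
  m31[, c("k03", "k17", "k29")] <- 0
  rel <- cronbach_alpha(m31)
  expect_equal(rel$n_items_input, 31)
  expect_equal(rel$n_items_retained, 28)
  expect_setequal(rel$excluded_items$item, c("k03", "k17", "k29"))
  expect_equal(unique(rel$excluded_items$reason), "zero_variation")

  expect_error(cronbach_alpha(cbind(a = c(0, 0), b = c(1, 1))),
               "fewer than 2 items")
})

test_that("alpha matches the brute-force formula and the equicorrelated closed form", {
  set.seed(52)
  m <- matrix(rbinom(40 * 6, 1, 0.5), nrow = 40,
              dimnames = list(NULL, letters[1:6]))
  m[, 2] <- m[, 1]  # induce covariance so the total varies
  k <- ncol(m)
  brute <- k / (k - 1) * (1 - sum(apply(m, 2, var)) / var(rowSums(m)))
  expect_equal(cronbach_alpha(m)$alpha, brute)

  # exchangeable equicorrelated binary items: alpha ~ k*rbar / (1+(k-1)*rbar)
  n <- 4000; k <- 8
  z <- rnorm(n)
  lat <- sqrt(0.35) * z + sqrt(0.65) * matrix(rnorm(n * k), n)
  bin <- (lat > qnorm(0.6)) * 1
  colnames(bin) <- sprintf("e%d", 1:k)
  rbar <- mean(cor(bin)[lower.tri(diag(k))])
  closed <- k * rbar / (1 + (k - 1) * rbar)
  expect_equal(cronbach_alpha(bin)$alpha, closed, tolerance = 0.02)
})

test_that("Mann-Whitney U: separation, enumeration, symmetry, complements", {
  sep <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(sep$statistic, 0)
  expect_equal(sep$u_b, 9)
  expect_equal(sep$method, "exact")

  inter <- mann_whitney(c(1, 3), c(2, 4))
  expect_equal(inter$statistic, 1)   # one of four cross-pairs favors A

  same <- mann_whitney(c(2, 9, 5, 7), c(9, 5, 7, 2))
  expect_equal(same$u_a, 16 / 2)     # identical multisets: U = n^2 / 2
  expect_equal(same$u_a, same$u_b)

  set.seed(53)
  for (rep in 1:10) {
    a <- rnorm(sample(3:12, 1)); b <- rnorm(sample(3:12, 1))
    mw <- mann_whitney(a, b)
    expect_equal(mw$u_a + mw$u_b, length(a) * length(b))
    # brute-force pair count with half credit for ties
    u_brute <- sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
    expect_equal(mw$u_a, u_brute)
  }
  expect_error(mann_whitney(numeric(0), 1:3), "empty")
})

test_that("Mann-Whitney p-values agree with wilcox.test in both regimes", {
  set.seed(54)
  # small untied: exact enumeration
  for (rep in 1:5) {
    a <- rnorm(5); b <- rnorm(7)
    mw <- mann_whitney(a, b)
    wt <- wilcox.test(a, b, exact = TRUE)
    expect_equal(mw$method, "exact")
    expect_equal(mw$p, wt$p.value)
    expect_equal(mw$u_a, unname(wt$statistic))
  }
  # tied data: tie-corrected normal approximation without continuity
  a <- c(1, 2, 2, 3, 5, 5, 6, 8); b <- c(2, 3, 3, 4, 5, 7, 7, 9, 9)
  mw <- mann_whitney(a, b)
  wt <- wilcox.test(a, b, exact = FALSE, correct = FALSE)
  expect_equal(mw$method, "normal_approx")
  expect_equal(mw$p, wt$p.value)
})

test_that("Kruskal-Wallis H: null, singletons, and the two-group identity", {
  flat <- kruskal_wallis(list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3)))
  expect_equal(flat$statistic, 0)

  tri <- kruskal_wallis(list(1, 2, 3))
  expect_equal(tri$statistic, 2)     # direct formula on ranks 1..3
  expect_equal(tri$df, 2)

  set.seed(55)
  a <- sample(1:6, 12, TRUE); b <- sample(2:8, 9, TRUE)  # ties guaranteed
  kw <- kruskal_wallis(list(a, b))
  mw <- mann_whitney(a, b)
  expect_equal(mw$method, "normal_approx")
  # with two groups H equals the squared tie-corrected U z-statistic,
  # so the chi-square p matches the two-sided normal p
  expect_equal(kw$p, mw$p, tolerance = 1e-10)
  expect_error(kruskal_wallis(list(1:3)), "2 non-empty")
})

test_that("pooled t test: null, hand-computed case, degenerate variance", {
  null <- student_t(c(1, 2, 3), c(3, 1, 2))
  expect_equal(null$statistic, 0)

  tt <- student_t(c(1, 2, 3), c(2, 3, 4))
  expect_equal(tt$statistic, -1.224745, tolerance = 1e-6)
  expect_equal(tt$df, 4)

  # group sizes 73 and 46 give the familiar 117 degrees of freedom
  set.seed(56)
  expect_equal(student_t(rnorm(73), rnorm(46))$df, 117)

  expect_error(student_t(c(0, 0), c(1, 1)), "zero variance")
  one_sided <- student_t(c(1, 2, 3), c(2, 3, 4), one_sided = TRUE)
  expect_equal(one_sided$p, tt$p / 2)
})

test_that("chi-square 2x2: null, perfect association, zero margins", {
  expect_equal(chi_square_2x2(rbind(c(10, 10), c(10, 10)))$statistic, 0)
  perfect <- chi_square_2x2(rbind(c(20, 0), c(0, 20)))
  expect_equal(perfect$statistic, 40)   # equals n under perfect association
  expect_equal(perfect$df, 1)
  expect_error(chi_square_2x2(rbind(c(0, 0), c(5, 5))), "row margin")
  expect_error(chi_square_2x2(rbind(c(5, 0), c(5, 0))), "column margin")
  # cross-check against the stats implementation
  tab <- rbind(c(12, 5), c(7, 9))
  expect_equal(chi_square_2x2(tab)$statistic,
               unname(chisq.test(tab, correct = FALSE)$statistic))
})

test_that("Spearman rho: monotone invariance, sign, small-sample oracle", {
  x <- 1:10
  sm <- spearman_matrix(tibble::tibble(x = x, y = x^2))
  expect_equal(sm$rho, 1)
  sm2 <- spearman_matrix(tibble::tibble(x = x, y = -x))
  expect_equal(sm2$rho, -1)

  sm3 <- spearman_matrix(tibble::tibble(x = c(1, 2, 3, 4),
                                        y = c(2, 1, 4, 3)))
  expect_equal(sm3$rho, 0.6)  # rank-Pearson on 4 points, by hand

  # monotone transform of either margin leaves rho unchanged
  set.seed(57)
  a <- rnorm(40); b <- a + rnorm(40)
  r0 <- spearman_matrix(tibble::tibble(a = a, b = b))$rho
  r1 <- spearman_matrix(tibble::tibble(a = exp(a), b = b^3))$rho
  expect_equal(r1, r0)

  # pairwise-complete n and agreement with cor.test
  b[3:5] <- NA
  sm4 <- spearman_matrix(tibble::tibble(a = a, b = b))
  expect_equal(sm4$n, 37)
  ct <- suppressWarnings(cor.test(a, b, method = "spearman", exact = FALSE))
  expect_equal(sm4$rho, unname(ct$estimate))
  # constant column: undefined rho reported as NA
  smc <- spearman_matrix(tibble::tibble(a = a, c = rep(1, 40)))
  expect_true(is.na(smc$rho))
})

test_that("Lilliefors screening keeps normals and rejects skewed data", {
  set.seed(58)
  ok <- 0L
  for (s in 1:100) {
    set.seed(1000 + s)
    r <- ks_normality(rnorm(5000))
    ok <- ok + r$normal
  }
  expect_gte(ok, 94)

  set.seed(59)
  skew <- ks_normality(exp(rnorm(200)))
  expect_false(skew$normal)
  expect_error(ks_normality(rep(2, 10)), "constant")
  expect_error(ks_normality(c(1, 2, 3)), "at least 4")
})

test_that("item-criterion comparison separates and calibrates", {
  set.seed(60)
  score <- rnorm(80)
  ind <- score > median(score)
  tab <- item_criterion_comparison(ind, tibble::tibble(scale1 = score))
  expect_lt(tab$p, 0.001)
  expect_true(all(c("mdn_yes", "min_no", "U", "p") %in% names(tab)))

  expect_error(
    item_criterion_comparison(rep(FALSE, 10),
                              tibble::tibble(s = rnorm(10))),
    "empty")

  # null calibration: independent indicator rejects at ~ the nominal rate
  set.seed(61)
  rejections <- vapply(1:200, function(i) {
    s <- rnorm(2000)
    g <- sample(c(TRUE, FALSE), 2000, replace = TRUE)
    item_criterion_comparison(g, tibble::tibble(s = s))$p <= 0.05
  }, logical(1))
  expect_gte(mean(rejections), 0.03)
  expect_lte(mean(rejections), 0.07)
})

test_that("descriptives report counts, percentages and subgroup splits", {
  iv <- make_interview(n = 10)
  iv$smoke_mother[c(2, 7)] <- TRUE
  iv$in_validation <- rep(c(TRUE, FALSE), 5)
  prof <- risk_profile(iv)
  d <- descriptives(prof, iv)
  smoking <- d$indicators[d$indicators$indicator == "smoke_mother", ]
  expect_equal(smoking$n, 2)
  expect_equal(smoking$pct, 20)
  expect_equal(smoking$n_val_yes + smoking$n_val_no, 2)
  expect_equal(d$n_validation, 5)
  expect_error(descriptives(prof[0, ]), "empty")
})
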