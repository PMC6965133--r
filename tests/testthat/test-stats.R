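# independent mid-rank computation by explicit sorting (oracle helper)
midranks <- function(v) {
  o <- order(v)
  r <- numeric(length(v))
  i <- 1
  while (i <= length(v)) {
    j <- i
    while (j < length(v) && v[o[j + 1]] == v[o[i]]) j <- j + 1
    r[o[i:j]] <- mean(i:j)
    i <- j + 1
  }
  r
}

rand_groups <- function(seed, k = 3, with_ties = TRUE) {
  set.seed(seed)
  n <- sample(4:9, k, replace = TRUE)
  lapply(setNames(seq_len(k), paste0("g", seq_len(k))), function(i) {
    v <- rnorm(n[i], mean = i * 0.5)
    if (with_ties) v <- round(v, 1)
    v
  })
}

test_that("shannon has its closed forms and matches direct evaluation", {
  expect_equal(shannon(rep(5, 4)), log(4))
  expect_equal(shannon(c(0, 7, 0)), 0)
  expect_equal(shannon(rep(1, 8), base = 2), 3)
  expect_error(shannon(c(0, 0)), "positive")
  set.seed(14)
  for (i in 1:10) {
    x <- rpois(20, 10) + 1
    p <- x / sum(x)
    expect_equal(shannon(x), -sum(p * log(p)), tolerance = 1e-12)
    # uniform maximises H over a fixed support
    expect_lte(shannon(x), log(length(x)) + 1e-12)
  }
})

test_that("kruskal_wallis matches the reference implementation with ties", {
  for (seed in 1:12) {
    g <- rand_groups(seed)
    ref <- stats::kruskal.test(g)
    got <- kruskal_wallis(g)
    expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-6)
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-6)
    expect_equal(got$df, unname(ref$parameter))
  }
  same <- kruskal_wallis(list(a = c(2, 2), b = c(2, 2, 2)))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
})

test_that("kruskal_wallis accepts tidy data-frame input", {
  g <- rand_groups(5)
  df <- tibble::tibble(
    val = unlist(g),
    grp = rep(names(g), lengths(g))
  )
  expect_equal(kruskal_wallis(df, val, grp)$statistic,
               kruskal_wallis(g)$statistic)
})

test_that("chi-squared Nemenyi reduces to Kruskal-Wallis for two groups", {
  for (seed in 1:10) {
    g <- rand_groups(seed + 50, k = 2)
    nem <- nemenyi_allpairs(g)
    kw <- kruskal_wallis(g)
    expect_equal(nem$statistic, kw$statistic, tolerance = 1e-10)
    expect_equal(nem$p_value, kw$p_value, tolerance = 1e-10)
  }
})

test_that("chi-squared Nemenyi matches an independent pooled-rank oracle", {
  for (seed in 1:10) {
    g <- rand_groups(seed + 80, k = 4)
    got <- nemenyi_allpairs(g)
    # oracle: explicit mid-ranks, explicit tie term, pairwise chi-square
    v <- unlist(g); n <- lengths(g); N <- length(v)
    r <- midranks(v)
    idx <- rep(seq_along(g), n)
    rbar <- vapply(seq_along(g), function(i) mean(r[idx == i]), 0)
    tie <- 0
    for (u in unique(v)) { t <- sum(v == u); tie <- tie + t^3 - t }
    C <- 1 - tie / (N^3 - N)
    for (row in seq_len(nrow(got))) {
      i <- match(got$group1[row], names(g))
      j <- match(got$group2[row], names(g))
      chi <- unname((rbar[i] - rbar[j])^2 /
                      ((N * (N + 1) / 12) * (1 / n[i] + 1 / n[j])) / C)
      expect_equal(got$statistic[row], chi, tolerance = 1e-6)
      expect_equal(got$p_value[row],
                   pchisq(chi, length(g) - 1, lower.tail = FALSE),
                   tolerance = 1e-6)
    }
  }
  ident <- nemenyi_allpairs(list(a = c(1, 1), b = c(1, 1), c = c(1, 1)))
  expect_true(all(ident$p_value == 1))
})

test_that("Nemenyi results are symmetric under group permutation", {
  g <- rand_groups(7, k = 3)
  a <- nemenyi_allpairs(g)
  b <- nemenyi_allpairs(g[c(3, 1, 2)])
  key <- function(d) {
    k <- paste(pmin(d$group1, d$group2), pmax(d$group1, d$group2))
    setNames(d$p_value, k)[order(k)]
  }
  expect_equal(key(a), key(b), tolerance = 1e-12)
})

test_that("friedman_blocked matches the reference implementation", {
  for (seed in 1:12) {
    set.seed(seed)
    y <- matrix(round(rnorm(8 * 3), 1), 8, 3)
    ref <- stats::friedman.test(y)
    got <- friedman_blocked(y)
    expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-6)
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-6)
  }
  flat <- friedman_blocked(matrix(3, 5, 4))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)
  expect_error(friedman_blocked(matrix(c(1, NA, 2, 3), 2, 2)), "Missing")
})

test_that("rank tests ignore monotone transformations and block shifts", {
  g <- rand_groups(3, with_ties = FALSE)
  expect_equal(kruskal_wallis(g)$statistic,
               kruskal_wallis(lapply(g, exp))$statistic)
  expect_equal(nemenyi_allpairs(g)$p_value,
               nemenyi_allpairs(lapply(g, function(v) v^3))$p_value)
  set.seed(4)
  y <- matrix(rnorm(6 * 3), 6, 3)
  y2 <- y; y2[2, ] <- y2[2, ] + 100      # constant within one block
  expect_equal(friedman_blocked(y), friedman_blocked(y2))
  expect_equal(nemenyi_blocked(y)$p_value, nemenyi_blocked(exp(y))$p_value)
})

test_that("blocked Nemenyi agrees with Friedman for two treatments", {
  for (seed in 1:10) {
    set.seed(seed)
    y <- matrix(rnorm(7 * 2), 7, 2)     # continuous: no within-block ties
    nb <- nemenyi_blocked(y)
    fr <- friedman_blocked(y)
    expect_equal(nb$p_value, fr$p_value, tolerance = 1e-6)
  }
})

test_that("blocked Nemenyi matches its studentized-range definition", {
  for (seed in 1:10) {
    set.seed(seed + 30)
    n <- 8; k <- 4
    y <- matrix(round(rnorm(n * k), 1), n, k)
    got <- nemenyi_blocked(y)
    r <- t(apply(y, 1, function(row) midranks(row)))
    rbar <- colMeans(r)
    for (row in seq_len(nrow(got))) {
      i <- as.integer(sub("treatment", "", got$group1[row]))
      j <- as.integer(sub("treatment", "", got$group2[row]))
      q <- abs(rbar[i] - rbar[j]) / sqrt(k * (k + 1) / (6 * n))
      expect_equal(got$statistic[row], q, tolerance = 1e-6)
      expect_equal(got$p_value[row],
                   ptukey(q * sqrt(2), k, Inf, lower.tail = FALSE),
                   tolerance = 1e-6)
    }
  }
  flat <- nemenyi_blocked(matrix(1, 5, 3))
  expect_true(all(flat$p_value == 1))
})

test_that("spearman_paired matches cor.test and applies Bonferroni", {
  expect_equal(spearman_paired(1:5, 1:5)$statistic, 1)
  expect_equal(spearman_paired(1:5, 5:1)$statistic, -1)
  for (seed in 1:12) {
    set.seed(seed)
    a <- round(rnorm(12), 1); b <- round(a + rnorm(12), 1)
    ref <- suppressWarnings(
      stats::cor.test(a, b, method = "spearman", exact = FALSE))
    got <- spearman_paired(a, b, family_size = 3)
    expect_equal(got$statistic, unname(ref$estimate), tolerance = 1e-6)
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-6)
    expect_equal(got$p_adjusted, min(1, ref$p.value * 3), tolerance = 1e-6)
  }
  expect_warning(res <- spearman_paired(c(1, 1, 1), c(1, 2, 3)), "variance")
  expect_true(is.na(res$statistic))
})

test_that("mann_whitney matches the reference on both computation paths", {
  # exact enumeration (no ties, both arms <= 8)
  for (seed in 1:10) {
    set.seed(seed)
    x <- rnorm(6); y <- rnorm(7, 0.8)
    ref <- stats::wilcox.test(x, y)
    got <- mann_whitney(x, y)
    expect_identical(got$method, "exact")
    expect_equal(got$statistic, unname(ref$statistic))
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-6)
  }
  # tie-corrected normal approximation
  for (seed in 1:10) {
    set.seed(seed)
    x <- sample(1:6, 11, replace = TRUE)
    y <- sample(2:8, 9, replace = TRUE)
    ref <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                               correct = TRUE))
    got <- mann_whitney(x, y)
    expect_identical(got$method, "normal_approximation")
    expect_equal(got$statistic, unname(ref$statistic))
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-6)
  }
  expect_equal(mann_whitney(c(1, 2, 3), c(10, 20, 30))$statistic, 0)
  expect_equal(mann_whitney(5, 5)$p_value, 1)
})

test_that("mock community check computes deviations and total variation", {
  obs <- c(A = 0.5, B = 0.3, C = 0.2)
  perfect <- mock_community_check(obs, obs)
  expect_true(all(perfect$per_taxon$abs_deviation == 0))
  expect_equal(perfect$total_variation, 0)

  disjoint <- mock_community_check(c(A = 1), c(B = 1))
  expect_equal(disjoint$total_variation, 1)

  set.seed(2)
  for (i in 1:5) {
    o <- runif(4); o <- setNames(o / sum(o), letters[1:4])
    e <- runif(4); e <- setNames(e / sum(e), letters[1:4])
    got <- mock_community_check(o, e)
    expect_equal(got$total_variation, sum(abs(o - e)) / 2, tolerance = 1e-12)
  }
  expect_error(mock_community_check(c(A = 0.5), c(A = 1)), "sum to 1")
})
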