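#' Shannon diversity index
#'
#' \eqn{H = -\sum_i p_i \log p_i} over the nonzero proportions of a count
#' (or abundance) vector. The natural logarithm is the default, matching
#' the convention of the major microbiome ecosystem packages; note the
#' index is depth-dependent, so compare samples sequenced to comparable
#' depth or interpret with care.
#'
#' @param x Non-negative numeric vector (counts or proportions).
#' @param base Logarithm base (default `exp(1)`).
#' @return Non-negative scalar; `ln k` for a uniform vector over `k` taxa.
#' @export
shannon <- function(x, base = exp(1)) {
  if (any(x < 0) || !any(x > 0)) {
    abort("`x` must be non-negative with at least one positive entry.")
  }
  p <- x[x > 0] / sum(x)
  -sum(p * log(p) / log(base))
}

#' Per-sample Shannon diversity of an ASV table
#'
#' @param table ASV table.
#' @inheritParams shannon
#' @return Tibble `sample_id`, `shannon` (`NA` for zero-depth samples).
#' @export
sample_shannon <- function(table, base = exp(1)) {
  m <- asv_matrix(table)
  tibble::tibble(
    sample_id = rownames(m),
    shannon = apply(m, 1, function(r) {
      if (!any(r > 0)) NA_real_ else shannon(r, base)
    })
  )
}

# accept a named list of numeric vectors, or data frame + value/group cols
groups_from <- function(x, value_quo, group_quo) {
  if (is.data.frame(x)) {
    if (rlang::quo_is_null(value_quo) || rlang::quo_is_null(group_quo)) {
      abort("With a data frame input, supply the `value` and `group` columns.")
    }
    v <- as.numeric(rlang::eval_tidy(value_quo, x))
    g <- rlang::eval_tidy(group_quo, x)
    split(v, factor(g, levels = unique(g)))
  } else if (is.list(x)) {
    lapply(x, as.numeric)
  } else {
    abort("Supply a data frame or a list of numeric vectors.")
  }
}

# 1 - sum(t^3 - t) / (N^3 - N), the standard mid-rank ties correction
ties_correction <- function(values) {
  n <- length(values)
  t <- table(values)
  1 - sum(t^3 - t) / (n^3 - n)
}

#' Kruskal-Wallis rank sum test
#'
#' Omnibus comparison of two or more independent groups on pooled
#' mid-ranks, with the standard ties correction; the statistic is referred
#' to a chi-squared distribution with \eqn{k - 1} degrees of freedom. When
#' every observation is identical the statistic is 0 and p is 1.
#'
#' @param x A data frame (with `value`/`group` columns named via the next
#'   two arguments) or a list of numeric vectors, one per group.
#' @param value,group Column selections when `x` is a data frame.
#' @return One-row tibble: `statistic_name`, `statistic`, `df`, `p_value`,
#'   `n`, `k`.
#' @export
kruskal_wallis <- function(x, value = NULL, group = NULL) {
  groups <- groups_from(x, rlang::enquo(value), rlang::enquo(group))
  if (length(groups) < 2 || any(lengths(groups) == 0)) {
    abort("Need at least two non-empty groups.")
  }
  all_v <- unlist(groups, use.names = FALSE)
  n <- lengths(groups)
  N <- sum(n)
  r <- rank(all_v)
  gidx <- rep(seq_along(groups), n)
  rbar <- unname(tapply(r, gidx, mean))
  H <- 12 / (N * (N + 1)) * sum(n * rbar^2) - 3 * (N + 1)
  C <- ties_correction(all_v)
  stat <- if (C > 0) H / C else 0
  k <- length(groups)
  tibble::tibble(
    statistic_name = "chi_squared",
    statistic = stat,
    df = k - 1L,
    p_value = if (C > 0) pchisq(stat, k - 1, lower.tail = FALSE) else 1,
    n = N, k = k
  )
}

#' Nemenyi all-pairs test after Kruskal-Wallis (chi-squared approximation)
#'
#' Post-hoc all-pairs comparison on the pooled mid-ranks: for each pair of
#' groups the squared mean-rank difference is scaled by
#' \eqn{(N(N+1)/12)(1/n_i + 1/n_j)}, divided by the ties correction, and
#' referred to a chi-squared distribution with \eqn{k - 1} degrees of
#' freedom. For \eqn{k = 2} this reproduces the Kruskal-Wallis p-value.
#'
#' @inheritParams kruskal_wallis
#' @return Tibble with one row per unordered group pair: `group1`,
#'   `group2`, `statistic_name`, `statistic`, `df`, `p_value`.
#' @export
nemenyi_allpairs <- function(x, value = NULL, group = NULL) {
  groups <- groups_from(x, rlang::enquo(value), rlang::enquo(group))
  if (length(groups) < 2 || any(lengths(groups) == 0)) {
    abort("Need at least two non-empty groups.")
  }
  nm <- names(groups)
  if (is.null(nm)) nm <- paste0("group", seq_along(groups))
  all_v <- unlist(groups, use.names = FALSE)
  n <- lengths(groups)
  N <- sum(n)
  r <- rank(all_v)
  gidx <- rep(seq_along(groups), n)
  rbar <- unname(tapply(r, gidx, mean))
  C <- ties_correction(all_v)
  k <- length(groups)
  pairs <- combn(k, 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(p) {
    i <- pairs[1, p]; j <- pairs[2, p]
    chi <- unname((rbar[i] - rbar[j])^2 /
                    ((N * (N + 1) / 12) * (1 / n[i] + 1 / n[j])))
    stat <- if (C > 0) chi / C else 0
    tibble::tibble(
      group1 = nm[i], group2 = nm[j],
      statistic_name = "chi_squared", statistic = stat,
      df = k - 1L,
      p_value = if (C > 0) {
        pchisq(stat, k - 1, lower.tail = FALSE)
      } else 1
    )
  })
}

# within-block mid-ranks and the blocked ties term
block_ranks <- function(y) {
  y <- as.matrix(y)
  if (nrow(y) < 2 || ncol(y) < 2) {
    abort("Need at least 2 blocks and 2 treatments.")
  }
  if (anyNA(y)) abort("Missing cells are not allowed (unreplicated design).")
  t(apply(y, 1, rank))
}

#' Friedman rank sum test for unreplicated blocked data
#'
#' Each block (e.g. one foal) ranks the treatments (e.g. the three maternal
#' source compartments it is compared against); the chi-squared statistic
#' with \eqn{k - 1} degrees of freedom tests whether treatment mean ranks
#' differ, with the within-block ties correction. When every block ranks
#' all treatments identically (fully tied) the statistic is 0 and p is 1.
#'
#' @param y Numeric matrix, blocks as rows and treatments as columns, no
#'   missing cells.
#' @return One-row tibble as in [kruskal_wallis()], with `n` = blocks and
#'   `k` = treatments.
#' @export
friedman_blocked <- function(y) {
  y <- as.matrix(y)
  r <- block_ranks(y)
  n <- nrow(r); k <- ncol(r)
  ties_term <- sum(apply(r, 1, function(row) {
    t <- table(row); sum(t^3 - t)
  }))
  denom <- n * k * (k + 1) - ties_term / (k - 1)
  num <- 12 * sum((colSums(r) - n * (k + 1) / 2)^2)
  stat <- if (denom > 0) num / denom else 0
  tibble::tibble(
    statistic_name = "chi_squared",
    statistic = stat,
    df = k - 1L,
    p_value = if (denom > 0) pchisq(stat, k - 1, lower.tail = FALSE) else 1,
    n = n, k = k
  )
}

#' Nemenyi all-pairs test for unreplicated blocked data
#'
#' Post-hoc companion to [friedman_blocked()]: treatment mean ranks
#' (within-block mid-ranks) are compared pairwise with the studentized
#' range distribution, \eqn{q = |\bar R_i - \bar R_j| /
#' \sqrt{k(k+1)/(6n)}} referred to \eqn{q\sqrt{2}} on the range
#' distribution with \eqn{k} means and infinite degrees of freedom.
#'
#' @inheritParams friedman_blocked
#' @return Tibble with one row per unordered treatment pair.
#' @export
nemenyi_blocked <- function(y) {
  y <- as.matrix(y)
  r <- block_ranks(y)
  n <- nrow(r); k <- ncol(r)
  nm <- colnames(y)
  if (is.null(nm)) nm <- paste0("treatment", seq_len(k))
  rbar <- colMeans(r)
  se <- sqrt(k * (k + 1) / (6 * n))
  pairs <- combn(k, 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(p) {
    i <- pairs[1, p]; j <- pairs[2, p]
    q <- abs(rbar[i] - rbar[j]) / se
    tibble::tibble(
      group1 = nm[i], group2 = nm[j],
      statistic_name = "q", statistic = unname(q),
      df = NA_integer_,
      p_value = ptukey(q * sqrt(2), nmeans = k, df = Inf, lower.tail = FALSE)
    )
  })
}

#' Spearman rank correlation between two paired abundance profiles
#'
#' Mid-rank Spearman's rho between two aligned vectors (e.g. a foal's and
#' its dam's relative-abundance profiles over the union of their ASVs),
#' with the t-distribution approximation for the p-value and optional
#' Bonferroni correction over a stated family of comparisons.
#'
#' @param a,b Aligned numeric vectors, length >= 3.
#' @param family_size Number of comparisons in the Bonferroni family
#'   (default 1 = no correction).
#' @return One-row tibble: `statistic_name` (`"rho"`), `statistic`, `df`,
#'   `p_value`, `p_adjusted`, `correction`, `family_size`, `n`. `statistic`
#'   is `NA` (with a warning) when either vector has zero variance.
#' @export
spearman_paired <- function(a, b, family_size = 1) {
  if (length(a) != length(b)) abort("`a` and `b` must be the same length.")
  n <- length(a)
  if (n < 3) abort("Need at least 3 paired observations.")
  if (var(a) == 0 || var(b) == 0) {
    warn("Zero variance in one profile; rho is undefined.")
    return(tibble::tibble(statistic_name = "rho", statistic = NA_real_,
                          df = n - 2L, p_value = NA_real_,
                          p_adjusted = NA_real_, correction = "bonferroni",
                          family_size = family_size, n = n))
  }
  rho <- cor(rank(a), rank(b))
  p <- if (abs(rho) == 1) 0 else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * pt(-abs(tstat), n - 2)
  }
  tibble::tibble(
    statistic_name = "rho", statistic = rho, df = n - 2L, p_value = p,
    p_adjusted = min(1, p * family_size), correction = "bonferroni",
    family_size = family_size, n = n
  )
}

#' Mann-Whitney U test
#'
#' Two-sample rank test, e.g. for comparing qPCR 16S copy numbers between
#' newborn samples and field controls. With both arms at most 8
#' observations and no ties the null distribution of U is enumerated
#' exactly over all group assignments of the pooled ranks; otherwise the
#' tie-corrected normal approximation with continuity correction is used.
#'
#' @param x,y Numeric vectors.
#' @return One-row tibble: `statistic_name` (`"U"`, counting pairs with
#'   `x > y` plus half-ties), `statistic`, `p_value`, `method` (`"exact"`
#'   or `"normal_approximation"`), `n1`, `n2`.
#' @export
mann_whitney <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) abort("Both samples must be non-empty.")
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  pooled <- c(x, y)
  r <- rank(pooled)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  has_ties <- anyDuplicated(pooled) > 0
  if (!has_ties && n1 <= 8 && n2 <= 8) {
    sets <- combn(N, n1)
    allr <- rank(pooled)  # a permutation of 1..N since no ties
    u_null <- apply(sets, 2, function(idx) sum(sort(allr)[idx])) -
      n1 * (n1 + 1) / 2
    p <- min(1, 2 * min(mean(u_null <= U), mean(u_null >= U)))
    method <- "exact"
  } else {
    t <- table(pooled)
    sigma2 <- (n1 * n2 / 12) * ((N + 1) - sum(t^3 - t) / (N * (N - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- U - n1 * n2 / 2
      z <- (z - sign(z) * 0.5) / sqrt(sigma2)
      p <- min(1, 2 * min(stats::pnorm(z), stats::pnorm(z, lower.tail = FALSE)))
    }
    method <- "normal_approximation"
  }
  tibble::tibble(statistic_name = "U", statistic = U, p_value = p,
                 method = method, n1 = n1, n2 = n2)
}

#' Compare an observed mock-community profile to its expected composition
#'
#' Per-taxon absolute deviation and total variation distance between two
#' normalised compositions (e.g. a sequenced commercial community standard
#' versus the manufacturer's declared composition). Labels present in only
#' one profile are pooled into an `"other"` bucket on both sides before
#' comparison.
#'
#' @param observed,expected Named numeric vectors of proportions, each
#'   summing to 1 (tolerance 1e-6).
#' @return List: `per_taxon` tibble (`taxon`, `observed`, `expected`,
#'   `abs_deviation`) and `total_variation` (\eqn{\tfrac12\sum|o - e|}).
#' @export
mock_community_check <- function(observed, expected) {
  for (v in list(observed, expected)) {
    if (is.null(names(v)) || any(v < 0) || abs(sum(v) - 1) > 1e-6) {
      abort("Profiles must be named, non-negative and sum to 1.")
    }
  }
  shared <- intersect(names(observed), names(expected))
  obs <- c(observed[shared],
           other_observed_only = sum(observed[setdiff(names(observed), shared)]),
           other_expected_only = 0)
  exp_ <- c(expected[shared], other_observed_only = 0,
            other_expected_only = sum(expected[setdiff(names(expected), shared)]))
  per_taxon <- tibble::tibble(
    taxon = names(obs),
    observed = unname(obs),
    expected = unname(exp_),
    abs_deviation = abs(unname(obs) - unname(exp_))
  )
  per_taxon <- per_taxon[per_taxon$taxon %in% shared |
                           per_taxon$observed + per_taxon$expected > 0, ]
  list(per_taxon = per_taxon,
       total_variation = sum(per_taxon$abs_deviation) / 2)
}
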