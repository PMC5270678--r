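#' Kruskal-Wallis test with Dunn-Holm post hoc comparisons
#'
#' Rank-based one-way analysis of variance with tie correction. The
#' asymptotic chi-squared p-value is computed with [stats::kruskal.test()];
#' for small designs (`p_method = "auto"`, at most `max_enum` distinct
#' group assignments) the p-value is instead obtained by complete
#' enumeration of the permutation distribution of H, which is exact.
#' Pairwise groups are compared with Dunn's rank-sum z statistics under a
#' Holm family-wise adjustment.
#'
#' @param groups named list of numeric vectors, one per group.
#' @param p_method `"auto"`, `"asymptotic"` or `"permutation"`.
#' @param max_enum enumeration budget for the exact permutation p-value.
#' @return list: `statistic` (tie-corrected H), `df`, `p.value`, `method`,
#'   `posthoc` (data.frame: `group1`, `group2`, `z`, `p`, `p_adj`), `n`.
#' @examples
#' kruskal_wallis(list(a = c(1, 2, 3), b = c(101, 102, 103)))
#' @export
kruskal_wallis <- function(groups, p_method = c("auto", "asymptotic", "permutation"),
                           max_enum = 2e5) {
  p_method <- match.arg(p_method)
  stopifnot(is.list(groups), length(groups) >= 2)
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  values <- unlist(groups, use.names = FALSE)
  if (!all(is.finite(values))) stop("group values must be finite")
  sizes <- lengths(groups)
  if (any(sizes < 1)) stop("every group needs >= 1 value")
  g <- factor(rep(names(groups), sizes), levels = names(groups))
  N <- length(values)
  if (length(unique(values)) < 2) {
    return(list(
      statistic = 0, df = length(groups) - 1, p.value = 1,
      method = "degenerate (all values identical)",
      posthoc = dunn_posthoc(values, g), n = sizes
    ))
  }

  kw <- stats::kruskal.test(values, g)
  H <- unname(kw$statistic)
  n_arrangements <- exp(lgamma(N + 1) - sum(lgamma(sizes + 1)))
  use_perm <- p_method == "permutation" ||
    (p_method == "auto" && n_arrangements <= max_enum)
  if (use_perm) {
    p <- kw_exact_p(values, sizes)
    method <- "exact permutation"
  } else {
    p <- kw$p.value
    method <- "asymptotic chi-squared"
  }
  list(
    statistic = H, df = unname(kw$parameter), p.value = p, method = method,
    posthoc = dunn_posthoc(values, g), n = sizes
  )
}

# Tie-corrected H from ranks for one assignment of ranks to groups.
kw_H <- function(r, grp_index, sizes, tie_corr, N) {
  sums <- vapply(grp_index, function(ix) sum(r[ix]), numeric(1))
  H <- 12 / (N * (N + 1)) * sum(sums^2 / sizes) - 3 * (N + 1)
  H / tie_corr
}

# Exact permutation p-value by complete enumeration of group assignments.
kw_exact_p <- function(values, sizes) {
  r <- rank(values)
  N <- length(values)
  ties <- table(r)
  tie_corr <- 1 - sum(ties^3 - ties) / (N^3 - N)
  k <- length(sizes)
  grp_of <- rep(seq_len(k), sizes)
  H_obs <- kw_H(r, split(seq_len(N), grp_of), sizes, tie_corr, N)

  count <- 0L
  total <- 0L
  # recursively choose index sets for groups 1..k-1; the last takes the rest
  recurse <- function(avail, gi, chosen) {
    if (gi == k) {
      chosen[[k]] <- avail
      H <- kw_H(r, chosen, sizes, tie_corr, N)
      total <<- total + 1L
      if (H >= H_obs - 1e-9) count <<- count + 1L
      return(invisible())
    }
    combs <- utils::combn(length(avail), sizes[gi])
    for (ci in seq_len(ncol(combs))) {
      pick <- avail[combs[, ci]]
      chosen[[gi]] <- pick
      recurse(setdiff(avail, pick), gi + 1L, chosen)
    }
  }
  recurse(seq_len(N), 1L, vector("list", k))
  count / total
}

# Dunn's z statistics with tie correction and Holm adjustment.
dunn_posthoc <- function(values, g) {
  r <- rank(values)
  N <- length(values)
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  lev <- levels(g)
  mean_ranks <- tapply(r, g, mean)
  sizes <- tapply(r, g, length)
  pairs <- utils::combn(lev, 2)
  z <- p <- numeric(ncol(pairs))
  for (i in seq_len(ncol(pairs))) {
    a <- pairs[1, i]; b <- pairs[2, i]
    se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / sizes[[a]] + 1 / sizes[[b]]))
    z[i] <- if (se > 0) (mean_ranks[[a]] - mean_ranks[[b]]) / se else 0
    p[i] <- 2 * stats::pnorm(-abs(z[i]))
  }
  data.frame(
    group1 = pairs[1, ], group2 = pairs[2, ],
    z = z, p = p, p_adj = stats::p.adjust(p, method = "holm")
  )
}

#' Welch's heteroscedastic one-way ANOVA
#'
#' Welch's F statistic with Satterthwaite-type degrees of freedom, used as a
#' complementary test robust to unequal group variances. Wraps
#' [stats::oneway.test()] with `var.equal = FALSE`.
#'
#' @param groups named list of numeric vectors (>= 2 values each, positive
#'   variance).
#' @return list: `statistic` (F), `df` (numerator, denominator), `p.value`.
#' @export
welch_anova <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  if (any(lengths(groups) < 2)) stop("every group needs >= 2 values")
  vars <- vapply(groups, stats::var, numeric(1))
  if (any(vars <= 0)) stop("every group needs positive variance")
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  res <- stats::oneway.test(values ~ g, var.equal = FALSE)
  list(
    statistic = unname(res$statistic),
    df = unname(res$parameter),
    p.value = res$p.value
  )
}

#' Median, mean, SEM and count of a sample
#'
#' @param values non-empty numeric vector.
#' @return list: `median`, `mean`, `sem` (`SD/sqrt(n)`; 0 with a warning
#'   for a single value), `n`.
#' @export
summarize_values <- function(values) {
  x <- as.numeric(values)
  if (!length(x)) stop("empty sample")
  if (!all(is.finite(x))) stop("values must be finite")
  sem <- if (length(x) > 1) {
    stats::sd(x) / sqrt(length(x))
  } else {
    warning("SEM undefined for a single value; reporting 0")
    0
  }
  list(median = stats::median(x), mean = mean(x), sem = sem, n = length(x))
}

#' Optical density of an immunohistochemical stain
#'
#' `OD = log10(max intensity / mean intensity)` (decadic, the optical
#' density convention).
#'
#' @param mean_intensity mean grey value (> 0).
#' @param max_intensity maximum grey value (>= mean).
#' @return the optical density.
#' @examples
#' optical_density(10, 100) # 1
#' @export
optical_density <- function(mean_intensity, max_intensity) {
  if (!is.numeric(mean_intensity) || !is.numeric(max_intensity) ||
    any(mean_intensity <= 0) || any(max_intensity <= 0)) {
    stop("intensities must be positive")
  }
  if (any(max_intensity < mean_intensity)) {
    stop("max intensity must be >= mean intensity")
  }
  log10(max_intensity / mean_intensity)
}
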