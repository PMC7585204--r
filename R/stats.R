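#' Two-sided Welch t-test
#'
#' Welch statistic with Satterthwaite degrees of freedom. When both groups
#' have zero variance and equal means the convention statistic 0 / p 1 is
#' returned.
#'
#' @param x,y Numeric vectors (each of length at least 2).
#' @return A `TestResult` list: `statistic`, `p`, `p_adjusted` (initialised
#'   to `p`), `method`, `n`.
#' @export
welch_t <- function(x, y) {
  stopifnot(length(x) >= 2L, length(y) >= 2L)
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (mean(x) == mean(y)) {
      return(test_result(0, 1, "welch", c(length(x), length(y))))
    }
    return(test_result(ifelse(mean(x) > mean(y), Inf, -Inf), 0, "welch",
                       c(length(x), length(y))))
  }
  tt <- stats::t.test(x, y, var.equal = FALSE)
  test_result(unname(tt$statistic), tt$p.value, "welch",
              c(length(x), length(y)))
}

test_result <- function(statistic, p, method, n, p_adjusted = p) {
  list(statistic = statistic, p = p, p_adjusted = p_adjusted,
       method = method, n = n)
}

#' Normality-gated two-group location test
#'
#' Shapiro-Wilk is applied to each group at `alpha`; if either group rejects
#' normality and the group sizes are below the large-sample exemption
#' (central-limit regime, default 30), a Wilcoxon rank-sum test is used,
#' otherwise Welch's t. The chosen method is recorded in the result.
#'
#' @param x,y Numeric vectors (length at least 2 each).
#' @param alpha Shapiro-Wilk level (default 0.05).
#' @param large_n Group size at which normality of the mean is assumed
#'   (default 30).
#' @return A `TestResult` list (see [welch_t()]); `method` is `"welch"` or
#'   `"wilcoxon"`.
#' @export
location_test_gated <- function(x, y, alpha = 0.05, large_n = 30L) {
  stopifnot(length(x) >= 2L, length(y) >= 2L)
  if (stats::var(x) == 0 && stats::var(y) == 0 && mean(x) == mean(y)) {
    return(test_result(0, 1, "degenerate", c(length(x), length(y))))
  }
  non_normal <- function(v) {
    if (length(v) >= large_n) return(FALSE)
    if (stats::var(v) == 0) return(TRUE)   # shapiro undefined: treat as non-normal
    if (length(v) < 3L) return(FALSE)
    stats::shapiro.test(v)$p.value < alpha
  }
  if (non_normal(x) || non_normal(y)) {
    wt <- suppressWarnings(stats::wilcox.test(x, y, correct = TRUE,
                                              exact = FALSE))
    test_result(unname(wt$statistic), wt$p.value, "wilcoxon",
                c(length(x), length(y)))
  } else {
    welch_t(x, y)
  }
}

#' Factorial ANOVA with type-II sums of squares and Tukey post hoc
#'
#' Fits the main-effects linear model of `response` on the requested factors
#' (interactions only when `interactions = TRUE`), reports per-factor F and
#' p from type-II sums of squares, Tukey studentized-range pairwise
#' comparisons on the requested factors, and the main-effects model
#' coefficients with per-level t tests.
#'
#' @param data `data.frame` holding the response and factor columns.
#' @param response Response column name.
#' @param factors Character vector of factor column names (each with at
#'   least 2 levels present).
#' @param interactions Include all factor interactions (default `FALSE`).
#' @param tukey Factors to run Tukey HSD on (default all).
#' @return List: `anova` (`data.frame` factor/F/p), `tukey` (named list of
#'   pairwise tables), `coefficients` (`data.frame`), `model` (the `lm`).
#' @export
anova_factorial <- function(data, response, factors, interactions = FALSE,
                            tukey = factors) {
  stopifnot(all(c(response, factors) %in% names(data)))
  df <- data
  for (f in factors) {
    df[[f]] <- factor(df[[f]])
    if (nlevels(df[[f]]) < 2L) {
      stop("factor '", f, "' has fewer than 2 levels in the design")
    }
  }
  rhs <- paste(factors, collapse = if (interactions) " * " else " + ")
  fml <- stats::as.formula(paste(response, "~", rhs))
  fit <- stats::lm(fml, data = df)
  if (any(is.na(stats::coef(fit)))) {
    stop("rank-deficient design; aliased terms: ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
               collapse = ", "))
  }
  a2 <- car::Anova(fit, type = 2)
  rows <- rownames(a2) %in% c(factors,
                              grep(":", rownames(a2), value = TRUE))
  anova_tab <- data.frame(factor = rownames(a2)[rows],
                          F = a2[rows, "F value"],
                          p = a2[rows, "Pr(>F)"],
                          stringsAsFactors = FALSE)
  rownames(anova_tab) <- NULL
  aovfit <- stats::aov(fml, data = df)
  tk <- stats::TukeyHSD(aovfit, which = tukey)
  cf <- summary(fit)$coefficients
  coefficients <- data.frame(term = rownames(cf), estimate = cf[, 1L],
                             se = cf[, 2L], t = cf[, 3L], p = cf[, 4L],
                             stringsAsFactors = FALSE)
  rownames(coefficients) <- NULL
  list(anova = anova_tab, tukey = tk, coefficients = coefficients,
       model = fit)
}

#' Bonferroni correction
#'
#' @param ps Raw p-values.
#' @param m Family size (defaults to `length(ps)`; must be at least that).
#' @return `pmin(1, ps * m)`.
#' @export
bonferroni <- function(ps, m = length(ps)) {
  if (m < length(ps)) stop("family size m must be at least length(ps)")
  pmin(ps * m, 1)
}

#' Exact distribution of a k-way intersection size
#'
#' For k sets of given sizes drawn independently and uniformly from a
#' background of size N, the intersection size distribution is computed by
#' iterated hypergeometric convolution: conditional on the first j sets
#' intersecting in m elements, the intersection with the (j+1)-th set is
#' hypergeometric(N, m, n\[j+1\]).
#'
#' @param sizes Integer vector of set sizes (k >= 2).
#' @param N Background size.
#' @return Numeric vector `p[i]` = P(intersection size = i - 1), summing
#'   to 1.
#' @export
intersection_size_distribution <- function(sizes, N) {
  stopifnot(length(sizes) >= 2L, all(sizes >= 0L), all(sizes <= N))
  dist <- numeric(min(sizes) + 1L)
  support <- 0:min(sizes)
  # after the first set the "intersection" is the set itself
  cur <- numeric(sizes[1L] + 1L)
  cur[sizes[1L] + 1L] <- 1
  for (j in 2:length(sizes)) {
    nxt_max <- min(length(cur) - 1L, sizes[j])
    nxt <- numeric(nxt_max + 1L)
    for (m in which(cur > 0) - 1L) {
      t_vals <- 0:min(m, sizes[j])
      nxt[t_vals + 1L] <- nxt[t_vals + 1L] +
        cur[m + 1L] * stats::dhyper(t_vals, m, N - m, sizes[j])
    }
    cur <- nxt
  }
  dist[seq_along(cur)] <- cur
  dist[seq_along(support)]
}

#' Exact multi-set intersection test
#'
#' Tests whether the observed k-way intersection of element sets is larger
#' than expected if each set were an independent uniform draw of its size
#' from the background. The p-value is the exact upper tail
#' P(X >= observed) of the intersection-size distribution
#' ([intersection_size_distribution()]); the expectation is
#' `N * prod(sizes / N)`.
#'
#' @param sets List of k element vectors (k >= 2), each a subset of the
#'   background.
#' @param N Background size.
#' @return List: `observed_overlap`, `expected`, `p`, `sizes`.
#' @export
multiset_intersection_test <- function(sets, N) {
  stopifnot(is.list(sets), length(sets) >= 2L)
  sets <- lapply(sets, unique)
  sizes <- lengths(sets)
  if (any(sizes > N)) stop("set size exceeds background size N")
  observed <- length(Reduce(intersect, sets))
  dist <- intersection_size_distribution(sizes, N)
  p <- sum(dist[(observed + 1L):length(dist)])
  expected <- N * prod(sizes / N)
  list(observed_overlap = observed, expected = expected, p = min(1, p),
       sizes = sizes)
}

#' Pearson correlation with two-sided p
#'
#' @param x,y Numeric vectors (n >= 3). Constant input yields an undefined
#'   flag instead of an error.
#' @return List: `r`, `p`, `undefined`, `n`.
#' @export
pearson_cor <- function(x, y) {
  n <- length(x)
  if (n < 3L || stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(r = NA_real_, p = NA_real_, undefined = TRUE, n = n))
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, undefined = FALSE, n = n)
}
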