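# Nonparametric statistics battery for motility data: D'Agostino-Pearson
# normality gate, Kruskal-Wallis omnibus test, Conover-Iman and Dunn
# rank-based post hocs, Holm-Bonferroni correction.
#
# Rank-based tests use mid-ranks for ties; the tie correction enters both
# the Kruskal-Wallis H statistic and the post hoc variance terms.

test_result <- function(method, statistic, df, p_value) {
  structure(list(method = method, statistic = statistic, df = df,
                 p_value = p_value), class = "motility_test")
}

#' @export
print.motility_test <- function(x, ...) {
  cat(x$method, "\n  statistic = ", format(x$statistic),
      if (!is.null(x$df) && all(is.finite(x$df)))
        paste0(", df = ", paste(x$df, collapse = ", ")) else "",
      ", p = ", format.pval(x$p_value), "\n", sep = "")
  invisible(x)
}

#' D'Agostino-Pearson K-squared normality test
#'
#' Omnibus test combining the transformed sample skewness (D'Agostino 1970)
#' and kurtosis (Anscombe & Glynn 1983) z-scores into K2 = z1^2 + z2^2,
#' referred to a chi-square distribution with 2 degrees of freedom. The
#' moment approximations require a reasonable sample size; below `min_n`
#' the test refuses to run unless `force = TRUE` (then it warns).
#'
#' @param x Numeric sample.
#' @param min_n Minimum sample size accepted without `force` (default 20).
#' @param force Run anyway on small samples, with a warning.
#' @return A `motility_test` with the K2 statistic and chi-square p value.
#' @export
dagostino_pearson <- function(x, min_n = 20, force = FALSE) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 8) stop("D'Agostino-Pearson test requires n >= 8")
  if (n < min_n) {
    if (!force)
      stop("sample size ", n, " below ", min_n,
           "; the normality test is unreliable (use force = TRUE to override)")
    warning("sample size ", n, " below ", min_n,
            "; normality test result is unreliable")
  }
  m <- x - mean(x)
  m2 <- mean(m^2)
  if (m2 == 0) stop("constant sample: normality test undefined")
  b1 <- mean(m^3) / m2^1.5          # sample skewness (ML moments)
  b2 <- mean(m^4) / m2^2            # sample kurtosis, not excess

  # skewness z (D'Agostino 1970)
  y <- b1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(0.5 * log(w2))
  alpha <- sqrt(2 / (w2 - 1))
  z1 <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))

  # kurtosis z (Anscombe & Glynn 1983)
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xs <- (b2 - eb2) / sqrt(vb2)
  sqrtb1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sqrtb1 * (2 / sqrtb1 + sqrt(1 + 4 / sqrtb1^2))
  denom <- 1 + xs * sqrt(2 / (a - 4))
  z2 <- (1 - 2 / (9 * a) - sign(denom) * (abs((1 - 2 / a) / abs(denom)))^(1/3)) /
    sqrt(2 / (9 * a))

  k2 <- z1^2 + z2^2
  test_result("D'Agostino-Pearson K2", k2, 2,
              stats::pchisq(k2, df = 2, lower.tail = FALSE))
}

as_group_list <- function(groups) {
  if (is.data.frame(groups)) stop("supply groups as a list of numeric vectors")
  if (!is.list(groups)) stop("supply groups as a list of numeric vectors")
  if (length(groups) < 2) stop("need at least 2 groups")
  groups <- lapply(groups, function(g) as.numeric(g[is.finite(g)]))
  if (any(vapply(groups, length, 1L) == 0)) stop("empty group")
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("group", seq_along(groups))
  groups
}

#' Kruskal-Wallis omnibus test
#'
#' Tie-corrected H referred to chi-square with k-1 df (via
#' [stats::kruskal.test()]). The degenerate case where every value is
#' identical across all groups returns H = 0, p = 1 rather than an error.
#'
#' @param groups List of numeric vectors, one per experimental group.
#' @return A `motility_test` with statistic H.
#' @export
kruskal_wallis <- function(groups) {
  groups <- as_group_list(groups)
  allv <- unlist(groups, use.names = FALSE)
  if (length(unique(allv)) == 1)
    return(test_result("Kruskal-Wallis H", 0, length(groups) - 1, 1))
  kt <- stats::kruskal.test(groups)
  test_result("Kruskal-Wallis H", unname(kt$statistic),
              unname(kt$parameter), kt$p.value)
}

pairwise_frame <- function(groups, stat, df, p, method) {
  k <- length(groups)
  nm <- names(groups)
  ii <- which(upper.tri(matrix(0, k, k)), arr.ind = TRUE)
  out <- data.frame(
    group1 = nm[ii[, 1]], group2 = nm[ii[, 2]],
    statistic = stat[cbind(ii[, 1], ii[, 2])],
    df = df,
    p_value = p[cbind(ii[, 1], ii[, 2])],
    stringsAsFactors = FALSE
  )
  attr(out, "method") <- method
  out
}

rank_setup <- function(groups) {
  allv <- unlist(groups, use.names = FALSE)
  n <- vapply(groups, length, 1L)
  g <- rep(seq_along(groups), n)
  r <- rank(allv)                    # mid-ranks
  rbar <- tapply(r, g, mean)
  cnt <- table(allv)
  list(N = length(allv), k = length(groups), n = n, r = r, rbar = rbar,
       tie_sum = sum(cnt^3 - cnt))
}

#' Conover-Iman post hoc test on pooled ranks
#'
#' Pairwise t statistics on the pooled mid-ranks following a Kruskal-Wallis
#' test, with the tie-corrected H entering the pooled variance
#' (Conover & Iman 1979; Conover 1999):
#' t_ij = (Rbar_i - Rbar_j) / sqrt(S2 * (N-1-H)/(N-k) * (1/n_i + 1/n_j)),
#' referred to Student's t with N - k df. Raw two-sided p values are
#' returned; apply [holm_bonferroni()] across the comparisons afterwards.
#'
#' @param groups List of numeric vectors.
#' @return Data frame of pairwise comparisons: `group1`, `group2`,
#'   `statistic` (t), `df`, `p_value`.
#' @export
conover_posthoc <- function(groups) {
  groups <- as_group_list(groups)
  s <- rank_setup(groups)
  H <- kruskal_wallis(groups)$statistic
  S2 <- (sum(s$r^2) - s$N * (s$N + 1)^2 / 4) / (s$N - 1)
  stat <- matrix(NA_real_, s$k, s$k)
  p <- matrix(NA_real_, s$k, s$k)
  dfree <- s$N - s$k
  for (i in seq_len(s$k - 1)) for (j in seq((i + 1), s$k)) {
    if (S2 == 0) { tt <- 0 } else {
      se <- sqrt(S2 * (s$N - 1 - H) / (s$N - s$k) * (1 / s$n[i] + 1 / s$n[j]))
      tt <- if (se == 0) 0 else (s$rbar[i] - s$rbar[j]) / se
    }
    stat[i, j] <- tt
    p[i, j] <- 2 * stats::pt(abs(tt), dfree, lower.tail = FALSE)
  }
  pairwise_frame(groups, stat, dfree, p, "Conover-Iman post hoc")
}

#' Dunn post hoc test on pooled ranks
#'
#' Pairwise z statistics on pooled mid-ranks with tie correction
#' (Dunn 1964):
#' z_ij = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T/(12(N-1))) (1/n_i + 1/n_j)),
#' with T = sum(t^3 - t) over tie groups. Raw two-sided normal p values.
#'
#' @param groups List of numeric vectors.
#' @return Data frame of pairwise comparisons (`statistic` is z, `df` Inf).
#' @export
dunn_posthoc <- function(groups) {
  groups <- as_group_list(groups)
  s <- rank_setup(groups)
  varterm <- s$N * (s$N + 1) / 12 - s$tie_sum / (12 * (s$N - 1))
  stat <- matrix(NA_real_, s$k, s$k)
  p <- matrix(NA_real_, s$k, s$k)
  for (i in seq_len(s$k - 1)) for (j in seq((i + 1), s$k)) {
    se <- sqrt(varterm * (1 / s$n[i] + 1 / s$n[j]))
    z <- if (se == 0) 0 else (s$rbar[i] - s$rbar[j]) / se
    stat[i, j] <- z
    p[i, j] <- 2 * stats::pnorm(abs(z), lower.tail = FALSE)
  }
  pairwise_frame(groups, stat, Inf, p, "Dunn post hoc")
}

#' Holm-Bonferroni step-down correction
#'
#' @param p Vector of raw p values in `[0, 1]`.
#' @return Adjusted p values (monotone, capped at 1), same order as input.
#' @export
holm_bonferroni <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p values must lie in [0, 1]")
  stats::p.adjust(p, method = "holm")
}

#' Group comparison battery with normality gating
#'
#' The decision tree used throughout: each group is tested for normality
#' with [dagostino_pearson()]; if every group passes at `gate_alpha`,
#' pairwise two-tailed independent t tests are used; otherwise a
#' Kruskal-Wallis omnibus test followed by the chosen rank-based post hoc.
#' Pairwise p values are corrected with [holm_bonferroni()] (the default)
#' or any [stats::p.adjust()] method.
#'
#' @param groups Named list of numeric vectors (one per condition).
#' @param gate_alpha Significance level of the normality gate (default 0.05).
#' @param posthoc `"conover"` (default) or `"dunn"`.
#' @param adjust Multiple-comparison correction (default `"holm"`).
#' @return List: `path` (`"parametric"`/`"nonparametric"`), `normality`
#'   (per-group data frame; p is NA where the gate refused a small sample,
#'   which routes to the nonparametric path), `omnibus` (`motility_test` or
#'   NULL), `pairwise` (data frame with `p_adjusted`).
#' @export
compare_groups <- function(groups, gate_alpha = 0.05,
                           posthoc = c("conover", "dunn"),
                           adjust = "holm") {
  posthoc <- match.arg(posthoc)
  groups <- as_group_list(groups)
  norm <- do.call(rbind, lapply(names(groups), function(nm) {
    res <- tryCatch(dagostino_pearson(groups[[nm]]),
                    error = function(e) NULL)
    data.frame(group = nm, n = length(groups[[nm]]),
               k2 = if (is.null(res)) NA_real_ else res$statistic,
               p_value = if (is.null(res)) NA_real_ else res$p_value)
  }))
  all_normal <- all(!is.na(norm$p_value)) && all(norm$p_value > gate_alpha)
  if (all_normal) {
    k <- length(groups)
    ii <- which(upper.tri(matrix(0, k, k)), arr.ind = TRUE)
    rows <- lapply(seq_len(nrow(ii)), function(r) {
      i <- ii[r, 1]; j <- ii[r, 2]
      tt <- stats::t.test(groups[[i]], groups[[j]], var.equal = FALSE)
      data.frame(group1 = names(groups)[i], group2 = names(groups)[j],
                 statistic = unname(tt$statistic),
                 df = unname(tt$parameter), p_value = tt$p.value)
    })
    pw <- do.call(rbind, rows)
    attr(pw, "method") <- "Welch two-sample t test"
    omni <- NULL
    path <- "parametric"
  } else {
    omni <- kruskal_wallis(groups)
    pw <- if (posthoc == "conover") conover_posthoc(groups) else dunn_posthoc(groups)
    path <- "nonparametric"
  }
  pw$p_adjusted <- stats::p.adjust(pw$p_value, method = adjust)
  list(path = path, normality = norm, omnibus = omni, pairwise = pw)
}
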