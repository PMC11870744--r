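## Nonparametric group statistics, implemented from first principles.
## Base distribution functions (dhyper, psignrank, pnorm, pchisq) are used as
## numeric primitives; the test logic itself lives here so that every exact
## branch can be validated against enumeration oracles.

#' Fisher's exact test for a 2x2 contingency table
#'
#' Conditional exact test on a 2x2 table of counts (e.g. marker-positive /
#' marker-negative cells in SMI-positive vs SMI-negative neurons). The
#' two-sided p-value follows the probability-mass rule: with both margins
#' fixed, the p-value is the sum of hypergeometric probabilities of all tables
#' whose probability does not exceed that of the observed table.
#'
#' The odds ratio is the sample cross-product ratio; when any cell is zero the
#' Haldane-Anscombe correction (add 0.5 to every cell) is applied and flagged
#' in the result.
#'
#' @param tab 2x2 matrix of non-negative integer counts. Rows are the first
#'   classification (e.g. SMI+ / SMI-), columns the second (marker+ / marker-).
#' @return An object of class `"htest"` with `p.value`, `estimate` (odds
#'   ratio) and a logical attribute `haldane` on the estimate.
#' @examples
#' fisher_exact_2x2(matrix(c(10, 0, 0, 10), 2))$p.value  # ~1.08e-5
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) stop("'tab' must be a 2x2 matrix")
  stop_if_not_count(tab, "tab")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("all margins of 'tab' must be positive")
  a <- tab[1, 1]
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  support <- max(0L, r1 + c1 - n):min(r1, c1)
  probs <- dhyper(support, c1, n - c1, r1)
  p_obs <- dhyper(a, c1, n - c1, r1)
  # relative tolerance guards against FP noise in "<= observed probability"
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  p <- min(1, p)
  haldane <- any(tab == 0)
  tt <- if (haldane) tab + 0.5 else tab
  or <- (tt[1, 1] * tt[2, 2]) / (tt[1, 2] * tt[2, 1])
  est <- c("odds ratio" = or)
  attr(est, "haldane") <- haldane
  structure(list(
    statistic = NULL, p.value = p, estimate = est,
    method = paste0("Fisher's exact test (probability-mass two-sided rule",
                    if (haldane) "; Haldane-corrected OR", ")"),
    data.name = deparse(substitute(tab)), table = tab
  ), class = "htest")
}

#' Mann-Whitney U test (exact for small samples)
#'
#' Rank-sum comparison of two independent samples. For tie-free data with
#' `length(x) + length(y) <= exact_max` the null distribution of U is obtained
#' by full enumeration of all subsets of pooled ranks; otherwise a
#' tie-corrected normal approximation with continuity correction is used. The
#' branch taken is reported in `method`.
#'
#' @param x,y numeric vectors.
#' @param exact_max largest pooled sample size for which the exact enumeration
#'   branch is used (default 12).
#' @return `"htest"` object with `statistic` (U for the first sample),
#'   `p.value` and `method` naming the branch (`"exact"` or `"normal"`).
#' @export
mann_whitney <- function(x, y, exact_max = 12L) {
  x <- as.numeric(x); y <- as.numeric(y)
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  nx <- length(x); ny <- length(y); n <- nx + ny
  if (nx < 1 || ny < 1) stop("both samples must be non-empty")
  r <- rank(c(x, y))
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- table(c(x, y))
  has_ties <- any(ties > 1)
  mu <- nx * ny / 2
  if (!has_ties && n <= exact_max) {
    branch <- "exact"
    # distribution of U over all C(n, nx) equally likely rank assignments
    us <- combn(n, nx, function(idx) sum(idx)) - nx * (nx + 1) / 2
    p <- mean(abs(us - mu) >= abs(u - mu) - 1e-9)
  } else {
    branch <- "normal"
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- nx * ny / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) {          # all values identical
      p <- 1
    } else {
      z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
      p <- min(1, 2 * pnorm(-abs(z)))
    }
  }
  structure(list(
    statistic = c(U = u), p.value = p,
    method = sprintf("Mann-Whitney U test (%s branch)", branch),
    branch = branch, data.name = "x vs y"
  ), class = "htest")
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Two-sided signed-rank test on paired differences. Zero differences are
#' dropped (reported via `n_zero`). For tie-free absolute differences with at
#' most `exact_max` informative pairs the exact null distribution of the
#' positive-rank sum is used (via the signrank distribution, equivalent to
#' enumerating all sign assignments); otherwise a tie-corrected normal
#' approximation with continuity correction.
#'
#' @param x,y paired numeric vectors (`y` defaults to zeros so `x` may already
#'   be differences).
#' @param exact_max largest number of informative pairs for the exact branch
#'   (default 25).
#' @return `"htest"` object; `statistic` is V, the sum of ranks of positive
#'   differences; `branch` records which branch fired.
#' @export
wilcoxon_signed_rank <- function(x, y = NULL, exact_max = 25L) {
  d <- if (is.null(y)) as.numeric(x) else as.numeric(x) - as.numeric(y)
  d <- d[is.finite(d)]
  n_zero <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    return(structure(list(statistic = c(V = 0), p.value = 1,
                          method = "Wilcoxon signed-rank test (degenerate: all differences zero)",
                          branch = "degenerate", n_zero = n_zero,
                          data.name = "paired differences"), class = "htest"))
  }
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  has_ties <- anyDuplicated(abs(d)) > 0
  if (!has_ties && n <= exact_max) {
    branch <- "exact"
    # exact two-sided tail of the signed-rank distribution
    p <- min(1, 2 * min(psignrank(v, n), 1 - psignrank(v - 1, n)))
  } else {
    branch <- "normal"
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    if (sigma2 <= 0) p <- 1 else {
      z <- (v - mu - sign(v - mu) * 0.5) / sqrt(sigma2)
      p <- min(1, 2 * pnorm(-abs(z)))
    }
  }
  structure(list(statistic = c(V = v), p.value = p,
                 method = sprintf("Wilcoxon signed-rank test (%s branch)", branch),
                 branch = branch, n_zero = n_zero,
                 data.name = "paired differences"), class = "htest")
}

# Tie-corrected Kruskal-Wallis H for a value vector and group factor.
kw_h_statistic <- function(x, g) {
  n <- length(x)
  r <- rank(x)
  rb <- tapply(r, g, mean)
  ni <- tabulate(g)
  h <- 12 / (n * (n + 1)) * sum(ni * (rb - (n + 1) / 2)^2)
  ties <- table(x)
  corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  if (corr > 0) h <- h / corr
  h
}

#' Kruskal-Wallis test with Dunn's post hoc comparisons
#'
#' Tie-corrected Kruskal-Wallis H across k groups, with an exact permutation
#' p-value by full enumeration of group assignments when the total sample size
#' is at most `exact_max` (chi-squared approximation otherwise), followed by
#' all-pairs Dunn z tests on pooled-rank means. Dunn p-values are two-sided
#' normal and adjusted for the number of pairs (Bonferroni by default, any
#' [stats::p.adjust()] method accepted).
#'
#' @param groups a named list of numeric vectors, one per group.
#' @param p_adjust_method adjustment for the Dunn pairwise p-values
#'   (default `"bonferroni"`).
#' @param exact_max largest total n for the exact permutation branch
#'   (default 10).
#' @return list of class `"kruskal_dunn"`: `H`, `df`, `p.value`, `branch`, and
#'   a data frame `dunn` with columns `group1`, `group2`, `z`, `p`, `p_adj`.
#' @export
kruskal_dunn <- function(groups, p_adjust_method = "bonferroni",
                         exact_max = 10L) {
  if (!is.list(groups) || length(groups) < 2)
    stop("'groups' must be a list of >= 2 numeric vectors")
  if (is.null(names(groups)))
    names(groups) <- paste0("group", seq_along(groups))
  groups <- lapply(groups, function(v) as.numeric(v)[is.finite(v)])
  if (any(lengths(groups) < 1)) stop("every group needs >= 1 value")
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  n <- length(x); k <- nlevels(g)
  h <- kw_h_statistic(x, as.integer(g))

  if (n <= exact_max) {
    branch <- "exact"
    ni <- lengths(groups)
    # enumerate all distinct assignments of the pooled values to group sizes
    idx_all <- seq_len(n)
    hs <- numeric(0)
    rec <- function(remaining, sizes, assign) {
      if (length(sizes) == 1L) {
        assign[remaining] <- length(ni)
        hs[[length(hs) + 1L]] <<- kw_h_statistic(x, assign)
        return(invisible())
      }
      take <- combn(remaining, sizes[1L], simplify = FALSE)
      for (s in take) {
        a2 <- assign; a2[s] <- length(ni) - length(sizes) + 1L
        rec(setdiff(remaining, s), sizes[-1L], a2)
      }
    }
    rec(idx_all, as.integer(ni), integer(n))
    p <- mean(hs >= h - 1e-9)
  } else {
    branch <- "chisq"
    p <- 1 - pchisq(h, df = k - 1)
  }

  # Dunn pairwise z on pooled-rank means, with tie correction
  r <- rank(x)
  rb <- tapply(r, g, mean)
  ni <- tabulate(as.integer(g))
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  pairs <- combn(k, 2)
  dz <- apply(pairs, 2, function(ij) {
    i <- ij[1]; j <- ij[2]
    se <- sqrt((n * (n + 1) / 12 - tie_term) * (1 / ni[i] + 1 / ni[j]))
    if (se == 0) 0 else (rb[i] - rb[j]) / se
  })
  dp <- 2 * pnorm(-abs(dz))
  dunn <- data.frame(
    group1 = levels(g)[pairs[1, ]], group2 = levels(g)[pairs[2, ]],
    z = as.numeric(dz), p = as.numeric(dp),
    p_adj = p.adjust(dp, method = p_adjust_method),
    stringsAsFactors = FALSE
  )
  structure(list(H = h, df = k - 1, p.value = p, branch = branch,
                 dunn = dunn, p_adjust_method = p_adjust_method,
                 n = n, group_sizes = setNames(ni, levels(g))),
            class = "kruskal_dunn")
}

#' @export
print.kruskal_dunn <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: H = %.4g, df = %d, p = %.4g (%s branch)\n",
              x$H, x$df, x$p.value, x$branch))
  cat(sprintf("Dunn's pairwise comparisons (%s-adjusted):\n", x$p_adjust_method))
  print(x$dunn, row.names = FALSE, ...)
  invisible(x)
}

#' Kaplan-Meier estimator for one arm
#'
#' Right-censored product-limit estimator; returns the step function as a data
#' frame (one row per distinct event time, plus time 0).
#'
#' @param time positive event/censoring times.
#' @param event 1 = event observed, 0 = right-censored.
#' @return data frame with `time`, `n_risk`, `n_event`, `surv`.
#' @export
km_curve <- function(time, event) {
  stopifnot(length(time) == length(event), all(time > 0))
  event <- as.integer(event != 0)
  ut <- sort(unique(time[event == 1]))
  n_risk <- vapply(ut, function(t) sum(time >= t), numeric(1))
  n_event <- vapply(ut, function(t) sum(time == t & event == 1), numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  rbind(data.frame(time = 0, n_risk = length(time), n_event = 0, surv = 1),
        data.frame(time = ut, n_risk = n_risk, n_event = n_event, surv = surv))
}

#' Mantel-Cox log-rank test for two survival arms
#'
#' Observed-vs-expected log-rank chi-squared over the pooled distinct event
#' times, with the hypergeometric variance term, plus Kaplan-Meier curves for
#' both arms.
#'
#' @param arm1,arm2 data frames with columns `time` (> 0) and `event`
#'   (1 = event, 0 = censored); any `arm` column is used for labelling.
#' @return object of class `"logrank"`: `chisq`, `df`, `p.value`, per-arm
#'   observed/expected counts, and `km` (named list of KM step data frames).
#' @export
logrank <- function(arm1, arm2) {
  check_arm <- function(a, default) {
    stopifnot(is.data.frame(a), all(c("time", "event") %in% names(a)))
    if (any(a$time <= 0)) stop("survival times must be positive")
    label <- if ("arm" %in% names(a)) as.character(a$arm[1]) else default
    list(time = a$time, event = as.integer(a$event != 0), label = label)
  }
  a1 <- check_arm(arm1, "arm1"); a2 <- check_arm(arm2, "arm2")
  time <- c(a1$time, a2$time); event <- c(a1$event, a2$event)
  grp <- rep(1:2, c(length(a1$time), length(a2$time)))
  ut <- sort(unique(time[event == 1]))
  o1 <- e1 <- v <- 0
  for (t in ut) {
    at_risk <- time >= t
    n_j <- sum(at_risk); n1_j <- sum(at_risk & grp == 1)
    d_j <- sum(time == t & event == 1)
    d1_j <- sum(time == t & event == 1 & grp == 1)
    o1 <- o1 + d1_j
    e1 <- e1 + n1_j * d_j / n_j
    if (n_j > 1)
      v <- v + d_j * (n1_j / n_j) * (1 - n1_j / n_j) * (n_j - d_j) / (n_j - 1)
  }
  chisq <- if (v > 0) (o1 - e1)^2 / v else 0
  p <- 1 - pchisq(chisq, df = 1)
  km <- list(km_curve(a1$time, a1$event), km_curve(a2$time, a2$event))
  names(km) <- make.unique(c(a1$label, a2$label))
  structure(list(chisq = chisq, df = 1L, p.value = p,
                 observed = c(o1, sum(event) - o1),
                 expected = c(e1, sum(event) - e1),
                 km = km), class = "logrank")
}

#' @export
print.logrank <- function(x, ...) {
  cat(sprintf("Log-rank (Mantel-Cox): chisq = %.4g, df = 1, p = %.4g\n",
              x$chisq, x$p.value))
  cat(sprintf("  %s: observed %d, expected %.2f\n", names(x$km)[1],
              x$observed[1], x$expected[1]))
  cat(sprintf("  %s: observed %d, expected %.2f\n", names(x$km)[2],
              x$observed[2], x$expected[2]))
  invisible(x)
}

#' Plot Kaplan-Meier step curves from a log-rank result
#'
#' @param x `"logrank"` object.
#' @param col colours for the two arms.
#' @param ... passed to [graphics::plot()].
#' @export
plot.logrank <- function(x, col = c("black", "red"), ...) {
  xmax <- max(vapply(x$km, function(k) max(k$time), numeric(1)))
  graphics::plot(NA, xlim = c(0, xmax), ylim = c(0, 1),
                 xlab = "time", ylab = "survival", ...)
  for (i in 1:2) {
    k <- x$km[[i]]
    graphics::lines(stats::stepfun(k$time[-1], k$surv), col = col[i],
                    do.points = FALSE)
  }
  graphics::legend("bottomleft", legend = names(x$km), col = col, lty = 1,
                   bty = "n")
  invisible(x)
}

#' Per-sample marker-positive fractions with group summaries
#'
#' Computes, for every sample, the percentage of neurons (NeuN+) that also
#' express a senescence marker, then summarises per group as mean +/- SEM.
#' Samples with no NeuN+ cells are flagged and excluded from summaries.
#'
#' @param cells data frame with one row per cell and columns `sample`,
#'   `group`, `neun` (logical: neuronal), `marker` (logical: marker-positive).
#' @return list with `per_sample` (sample, group, n_neun, n_marker, percent,
#'   excluded flag) and `summary` (group, n_samples, mean, sem).
#' @export
marker_fraction_report <- function(cells) {
  stopifnot(is.data.frame(cells),
            all(c("sample", "group", "neun", "marker") %in% names(cells)))
  sp <- split(cells, cells$sample)
  per_sample <- do.call(rbind, lapply(names(sp), function(s) {
    d <- sp[[s]]
    n_neun <- sum(d$neun)
    n_marker <- sum(d$neun & d$marker)
    data.frame(sample = s, group = as.character(d$group[1]),
               n_neun = n_neun, n_marker = n_marker,
               percent = if (n_neun > 0) 100 * n_marker / n_neun else NA_real_,
               excluded = n_neun == 0, stringsAsFactors = FALSE)
  }))
  ok <- per_sample[!per_sample$excluded, , drop = FALSE]
  summ <- do.call(rbind, lapply(split(ok, ok$group), function(d) {
    data.frame(group = d$group[1], n_samples = nrow(d),
               mean = mean(d$percent),
               sem = if (nrow(d) > 1) sd(d$percent) / sqrt(nrow(d)) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  list(per_sample = per_sample, summary = summ)
}
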