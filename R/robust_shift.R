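#' Harrell-Davis beta weights
#'
#' Weights over the order statistics for the Harrell-Davis estimator of the
#' q-th quantile of a sample of size n:
#' `w_i = I(i/n; a, b) - I((i-1)/n; a, b)` with `a = (n+1)q`,
#' `b = (n+1)(1-q)` and `I` the regularized incomplete beta function. The
#' weights sum to one.
#'
#' @param n Sample size.
#' @param q Quantile probability in (0, 1).
#' @return Numeric vector of length `n`.
#' @export
hd_weights <- function(n, q) {
  stop_if_not_number(n, "n", lower = 2)
  stop_if_not_number(q, "q", lower = 1e-12, upper = 1 - 1e-12)
  i <- seq_len(n)
  pbeta(i / n, (n + 1) * q, (n + 1) * (1 - q)) -
    pbeta((i - 1) / n, (n + 1) * q, (n + 1) * (1 - q))
}

#' Harrell-Davis quantile estimator
#'
#' Estimates a quantile as the beta-weighted average of all order
#' statistics, which is considerably more efficient than a single order
#' statistic for the small samples typical of training studies.
#'
#' @param x Numeric sample (n >= 2).
#' @param q Quantile probabilities in (0, 1); may be a vector.
#' @return Numeric vector of estimates, one per element of `q`.
#' @export
#' @examples
#' hd_quantile(1:5, 0.5)
#' hd_quantile(rnorm(30), seq(0.1, 0.9, by = 0.1))
hd_quantile <- function(x, q) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 2) stop("Harrell-Davis estimate needs n >= 2", call. = FALSE)
  xs <- sort(x)
  vapply(q, function(qq) sum(hd_weights(n, qq) * xs), numeric(1))
}

# 9 x n weight matrix for the deciles of a sample of size n
hd_decile_weights <- function(n) {
  t(vapply(1:9 / 10, function(q) hd_weights(n, q), numeric(n)))
}

#' Decile shift function between two samples
#'
#' Describes how two distributions differ at each decile: the Harrell-Davis
#' deciles of each group, their differences (`b - a`), a percentile-bootstrap
#' confidence interval per decile from independent resamples of each group,
#' and per-decile bootstrap p-values adjusted across the nine deciles with
#' Hochberg's step-up procedure.
#'
#' The per-decile p-value is `2 * min(P(d* < 0), P(d* > 0))` over the
#' bootstrap distribution of the decile difference (ties split evenly).
#'
#' @param a,b Numeric samples (a warning is given below n = 10).
#' @param n_boot Number of bootstrap resamples (default 2000).
#' @param alpha Family-wise significance level (default 0.05); confidence
#'   intervals are `1 - alpha` percentile intervals.
#' @param seed Optional seed for reproducible resampling.
#' @return A data.frame of class `shift_function` with columns `q`,
#'   `decile_a`, `decile_b`, `difference`, `ci_low`, `ci_high`, `p`,
#'   `p_adj`, `significant`; attributes `n_boot`, `alpha`, `seed`,
#'   `degenerate`.
#' @export
#' @examples
#' sf <- shift_function(rnorm(40), rnorm(40) + 1, n_boot = 200, seed = 1)
#' sf$difference
shift_function <- function(a, b, n_boot = 2000, alpha = 0.05, seed = NULL) {
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) {
    stop("both samples need n >= 2", call. = FALSE)
  }
  if (length(a) < 10 || length(b) < 10) {
    warning("shift function is unreliable below n = 10 per group")
  }
  qs <- 1:9 / 10
  Wa <- hd_decile_weights(length(a))
  Wb <- hd_decile_weights(length(b))
  da <- as.numeric(Wa %*% sort(a))
  db <- as.numeric(Wb %*% sort(b))
  diff <- db - da
  boot <- function() {
    A <- matrix(a[sample.int(length(a), length(a) * n_boot, replace = TRUE)],
                nrow = n_boot)
    B <- matrix(b[sample.int(length(b), length(b) * n_boot, replace = TRUE)],
                nrow = n_boot)
    As <- t(apply(A, 1, sort))
    Bs <- t(apply(B, 1, sort))
    Bs %*% t(Wb) - As %*% t(Wa)  # n_boot x 9
  }
  dstar <- if (is.null(seed)) boot() else with_seed(seed, boot())
  ci <- apply(dstar, 2, quantile, probs = c(alpha / 2, 1 - alpha / 2),
              type = 7, names = FALSE)
  p_lo <- colMeans(dstar < 0) + 0.5 * colMeans(dstar == 0)
  p <- pmin(2 * pmin(p_lo, 1 - p_lo), 1)
  p_adj <- p.adjust(p, method = "hochberg")
  out <- data.frame(q = qs, decile_a = da, decile_b = db, difference = diff,
                    ci_low = ci[1, ], ci_high = ci[2, ], p = p,
                    p_adj = p_adj, significant = p_adj <= alpha)
  attr(out, "n_boot") <- n_boot
  attr(out, "alpha") <- alpha
  attr(out, "seed") <- seed
  attr(out, "degenerate") <- all(dstar == dstar[1])
  class(out) <- c("shift_function", class(out))
  out
}

#' Hedges' g standardized mean difference
#'
#' Cohen's d on the pooled standard deviation multiplied by the small-sample
#' correction `J = 1 - 3 / (4 df - 1)` with `df = n_a + n_b - 2`,
#' appropriate for studies with fewer than about 20 participants.
#'
#' @param a,b Numeric samples (each n >= 2).
#' @return The corrected standardized difference `mean(a) - mean(b)` in
#'   pooled-SD units; antisymmetric in its arguments.
#' @export
hedges_g <- function(a, b) {
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  na <- length(a)
  nb <- length(b)
  if (na < 2 || nb < 2) stop("each group needs n >= 2", call. = FALSE)
  df <- na + nb - 2
  sp <- sqrt(((na - 1) * var(a) + (nb - 1) * var(b)) / df)
  if (sp <= 0) stop("pooled SD is zero; g undefined", call. = FALSE)
  (mean(a) - mean(b)) / sp * (1 - 3 / (4 * df - 1))
}

#' Eta-squared and rank-based epsilon-squared effect sizes
#'
#' `eta^2 = SS_between / SS_total` from a one-way decomposition (sums of
#' squares taken from [stats::aov()]; identical to type II for a single
#' factor), and `epsilon^2 = H / ((n^2 - 1) / (n + 1))` from the
#' Kruskal-Wallis H statistic on ranks.
#'
#' @param values Numeric response vector.
#' @param groups Group labels (coerced to factor, >= 2 levels).
#' @return List with `eta_squared`, `epsilon_squared` and logical
#'   `degenerate` (all values equal; both sizes are then 0).
#' @export
eta_sq_epsilon_sq <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups", call. = FALSE)
  if (var(values) <= 0) {
    warning("all values identical; effect sizes set to 0")
    return(list(eta_squared = 0, epsilon_squared = 0, degenerate = TRUE))
  }
  ss <- anova(aov(values ~ groups))[["Sum Sq"]]
  eta <- ss[1] / sum(ss)
  H <- unname(suppressWarnings(kruskal.test(values, groups))$statistic)
  n <- length(values)
  list(eta_squared = eta, epsilon_squared = H / ((n^2 - 1) / (n + 1)),
       degenerate = FALSE)
}

#' Per-subject learning slope
#'
#' The slope of an ordinary least-squares regression of a participant's
#' handaxe scores on the square root of cumulative practice hours. Because
#' training converges performance, the slope mostly reflects initial
#' aptitude: better initial performance gives a flatter slope.
#'
#' @param hours Cumulative practice hours (>= 2 distinct values).
#' @param score Handaxe scores, same length.
#' @return List with `slope`, `intercept`, `n`.
#' @export
learning_slope <- function(hours, score) {
  keep <- complete.cases(hours, score)
  hours <- hours[keep]
  score <- score[keep]
  if (length(unique(hours)) < 2) {
    stop("learning slope needs >= 2 distinct hour values", call. = FALSE)
  }
  fit <- lm(score ~ sqrt(hours))
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       n = length(score))
}

#' Learning slopes for every subject in a performance table
#'
#' @param performance Data.frame (`subject`, `hours`, `handaxe_score`).
#' @return Data.frame (`subject`, `learning_slope`, `intercept`, `n`).
#' @export
learning_slopes <- function(performance) {
  out <- do.call(rbind, lapply(split(performance, performance$subject),
    function(d) {
      ls <- learning_slope(d$hours, d$handaxe_score)
      data.frame(subject = d$subject[1], learning_slope = ls$slope,
                 intercept = ls$intercept, n = ls$n)
    }))
  rownames(out) <- NULL
  out
}

#' Shuffle subject identity within each condition, then average over windows
#'
#' The subject identifier is permuted independently within every session
#' (condition); the measures themselves stay attached to their rows, so
#' every session-level distribution is unchanged. Afterwards each dependent
#' variable is averaged across all analysis windows, giving one value per
#' (permuted) subject and session.
#'
#' @param table Long data.frame with columns `subject`, `session`, `window`
#'   and one or more numeric measure columns.
#' @param measures Character vector of measure column names; defaults to all
#'   numeric columns other than `window`.
#' @param seed Optional seed for the permutation.
#' @return List with `permuted` (the relabelled long table) and
#'   `session_means` (`subject`, `session`, one mean column per measure).
#' @export
permute_within_condition <- function(table, measures = NULL, seed = NULL) {
  stopifnot(all(c("subject", "session", "window") %in% names(table)))
  measures <- measures %||% setdiff(
    names(table)[vapply(table, is.numeric, logical(1))], "window")
  # completeness: every subject must appear in every window of its session
  miss <- character(0)
  for (sess in unique(table$session)) {
    d <- table[table$session == sess, ]
    tab <- table(d$subject, d$window)
    if (any(tab == 0)) {
      idx <- which(tab == 0, arr.ind = TRUE)
      miss <- c(miss, sprintf("%s/%s/window %s", sess,
                              rownames(tab)[idx[, 1]],
                              colnames(tab)[idx[, 2]]))
    }
  }
  if (length(miss) > 0) {
    stop("incomplete subject x window cells: ",
         paste(head(miss, 5), collapse = "; "),
         if (length(miss) > 5) " ..." else "", call. = FALSE)
  }
  permute <- function() {
    out <- table
    for (sess in unique(out$session)) {
      rows <- out$session == sess
      subj <- sort(unique(as.character(out$subject[rows])))
      new <- setNames(sample(subj), subj)
      out$subject[rows] <- unname(new[as.character(out$subject[rows])])
    }
    out
  }
  permuted <- if (is.null(seed)) permute() else with_seed(seed, permute())
  key <- interaction(permuted$subject, permuted$session, drop = TRUE,
                     sep = "\r")
  means <- do.call(rbind, lapply(split(permuted, key), function(d) {
    row <- data.frame(subject = d$subject[1], session = d$session[1])
    for (mcol in measures) row[[mcol]] <- mean(d[[mcol]])
    row
  }))
  rownames(means) <- NULL
  means <- means[order(means$session, means$subject), ]
  rownames(means) <- NULL
  list(permuted = permuted, session_means = means)
}
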