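#' Z-score the columns of a variate matrix
#'
#' Centers every column to mean 0 and scales to sample SD 1 (denominator
#' n - 1), the standard preprocessing before canonical correlation.
#'
#' @param m Numeric matrix or data.frame.
#' @return A numeric matrix with standardized columns.
#' @export
zscore_columns <- function(m) {
  m <- as.matrix(m)
  sds <- apply(m, 2, sd)
  zero <- which(sds <= 0 | !is.finite(sds))
  if (length(zero) > 0) {
    nm <- colnames(m)[zero] %||% as.character(zero)
    stop("constant column(s): ", paste(nm, collapse = ", "), call. = FALSE)
  }
  scale(m, center = TRUE, scale = sds)[, , drop = FALSE]
}

#' Canonical correlation analysis via whitening and SVD
#'
#' Finds paired linear combinations of two variable sets that maximize
#' their correlation. Both sets are z-scored; the sample covariance blocks
#' (denominator n - 1) are formed; each block is whitened through its
#' Cholesky factor (`Sigma = L L'`); and the SVD of
#' `La^-1 Sigma_ab Lb^-T = U D V'` gives the canonical structure: weights
#' `Wa = La^-T U`, `Wb = Lb^-T V`, variates `Za = Xa_std Wa`,
#' `Zb = Xb_std Wb`, and canonical correlations `S = diag(D)` — verified
#' internally against the Pearson correlations of the paired variates.
#'
#' Weights are sign-indeterminate; the convention here makes the first
#' nonzero element of each `Wa` column positive (flipping the paired `Wb`
#' column with it, so the canonical correlations stay non-negative).
#'
#' @param Xa,Xb Numeric matrices/data.frames with the same subjects in the
#'   same row order.
#' @param session Optional label carried into the result.
#' @return An object of class `cca_result`: list with `Wa`, `Wb`, `Za`,
#'   `Zb`, `cor` (canonical correlations, non-increasing in `[0, 1]`),
#'   `r_squared`, `n`, `session`.
#' @export
#' @examples
#' set.seed(1)
#' u <- rnorm(50)
#' Xa <- cbind(a1 = u + rnorm(50), a2 = rnorm(50))
#' Xb <- cbind(b1 = u + rnorm(50), b2 = rnorm(50))
#' cca(Xa, Xb)$cor
cca <- function(Xa, Xb, session = NULL) {
  Xa <- as.matrix(Xa)
  Xb <- as.matrix(Xb)
  n <- nrow(Xa)
  if (nrow(Xb) != n) stop("Xa and Xb must have the same rows", call. = FALSE)
  if (!is.null(rownames(Xa)) && !is.null(rownames(Xb)) &&
      !identical(rownames(Xa), rownames(Xb))) {
    stop("Xa and Xb must carry the same subjects in the same order",
         call. = FALSE)
  }
  p <- ncol(Xa)
  q <- ncol(Xb)
  if (n <= max(p, q)) stop("need more subjects than variables", call. = FALSE)
  if (n < 5 * max(p, q)) {
    warning(sprintf(
      "n = %d subjects for %d variables: canonical estimates are high-variance",
      n, max(p, q)))
  }
  Za_std <- zscore_columns(Xa)
  Zb_std <- zscore_columns(Xb)
  Saa <- cov(Za_std)
  Sbb <- cov(Zb_std)
  Sab <- cov(Za_std, Zb_std)
  chol_or_stop <- function(S, label) {
    tryCatch(t(chol(S)), error = function(e) {
      stop(sprintf("%s covariance block is rank-deficient (condition number %.3g)",
                   label, kappa(S)), call. = FALSE)
    })
  }
  La <- chol_or_stop(Saa, "first")
  Lb <- chol_or_stop(Sbb, "second")
  M <- forwardsolve(La, Sab)          # La^-1 Sab
  M <- t(forwardsolve(Lb, t(M)))      # ... Lb^-T
  sv <- svd(M)
  S <- pmin(pmax(sv$d, 0), 1)
  Wa <- backsolve(t(La), sv$u)        # La^-T U
  Wb <- backsolve(t(Lb), sv$v)
  for (m in seq_along(S)) {
    first <- Wa[which(Wa[, m] != 0)[1], m]
    if (!is.na(first) && first < 0) {
      Wa[, m] <- -Wa[, m]
      Wb[, m] <- -Wb[, m]
    }
  }
  Za <- Za_std %*% Wa
  Zb <- Zb_std %*% Wb
  got <- vapply(seq_along(S), function(m) cor(Za[, m], Zb[, m]), numeric(1))
  if (max(abs(abs(got) - S)) > 1e-8) {
    stop("internal check failed: variate correlations do not match the SVD",
         call. = FALSE)
  }
  dimnames(Wa) <- list(colnames(Xa), paste0("mode", seq_along(S)))
  dimnames(Wb) <- list(colnames(Xb), paste0("mode", seq_along(S)))
  structure(list(Wa = Wa, Wb = Wb, Za = Za, Zb = Zb, cor = S,
                 r_squared = S^2, n = n, session = session),
            class = "cca_result")
}

#' Tidy per-mode report of a canonical correlation analysis
#'
#' One row per mode and variable: the mode's canonical correlation and
#' r-squared together with the variable's canonical weight, labelled by
#' which variate it belongs to.
#'
#' @param result A `cca_result`, or a list of them (e.g. one per session).
#' @param variate_names Length-2 labels for the two variable sets.
#' @return Data.frame (`session`, `mode`, `canonical_correlation`,
#'   `r_squared`, `variate`, `variable`, `weight`).
#' @export
mode_report <- function(result, variate_names = c("set_a", "set_b")) {
  if (inherits(result, "cca_result")) result <- list(result)
  out <- do.call(rbind, lapply(result, function(res) {
    k <- length(res$cor)
    one <- function(W, vn) {
      data.frame(
        session = res$session %||% NA_character_,
        mode = rep(seq_len(k), each = nrow(W)),
        canonical_correlation = rep(res$cor, each = nrow(W)),
        r_squared = rep(res$r_squared, each = nrow(W)),
        variate = vn,
        variable = rep(rownames(W) %||% paste0("v", seq_len(nrow(W))), k),
        weight = as.numeric(W)
      )
    }
    rbind(one(res$Wa, variate_names[1]), one(res$Wb, variate_names[2]))
  }))
  out <- out[order(out$session, out$mode), ]
  rownames(out) <- NULL
  out
}

#' @export
print.cca_result <- function(x, ...) {
  cat("canonical correlation analysis",
      if (!is.null(x$session)) paste0(" [", x$session, "]"), "\n", sep = "")
  cat("  n =", x$n, " modes:", length(x$cor), "\n")
  cat("  S  =", paste(signif(x$cor, 4), collapse = ", "), "\n")
  cat("  r2 =", paste(signif(x$r_squared, 4), collapse = ", "), "\n")
  invisible(x)
}
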