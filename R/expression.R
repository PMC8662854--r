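#' Counts-per-million filter
#'
#' CPM = count / library size * 1e6 on the raw matrix. The default rule keeps
#' a transcript when its mean CPM across all samples is at least `min_cpm`;
#' alternative readings of "expressed in our samples" are available.
#'
#' @param counts transcript x sample count matrix.
#' @param min_cpm threshold (default 1).
#' @param rule one of "mean", "all", "any", "at_least_k".
#' @param k sample count for rule "at_least_k".
#' @return the retained count matrix (attribute `n_removed`).
#' @export
cpm_filter <- function(counts, min_cpm = 1,
                       rule = c("mean", "all", "any", "at_least_k"), k = 1) {
  rule <- match.arg(rule)
  lib <- colSums(counts)
  if (any(lib <= 0)) stop("library sizes must be positive")
  cpm <- t(t(counts) * (1e6 / lib))
  keep <- switch(rule,
                 mean = rowMeans(cpm) >= min_cpm,
                 all = apply(cpm >= min_cpm, 1, all),
                 any = apply(cpm >= min_cpm, 1, any),
                 at_least_k = rowSums(cpm >= min_cpm) >= k)
  if (!any(keep)) stop("all transcripts removed by the CPM filter")
  out <- counts[keep, , drop = FALSE]
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Log-CPM with mean-variance precision weights
#'
#' Normalises counts to log2 CPM with the half-count offset,
#' log2((count + 0.5) / (libsize + 1) * 1e6), fits per-transcript linear
#' models on the design, smooths sqrt(residual sd) against average log count
#' with lowess, and converts the predicted trend into per-observation inverse
#' variance weights (1 / predicted sd^4 at each fitted log count). This is
#' the standard mean-variance precision-weight recipe for count data.
#'
#' @param counts filtered transcript x sample count matrix.
#' @param design model matrix (default: intercept only).
#' @param span lowess span (default 0.5).
#' @return list(logcpm, weights) — both transcript x sample matrices.
#' @export
mean_variance_weights <- function(counts, design = NULL, span = 0.5) {
  lib <- colSums(counts)
  y <- t(log2((t(counts) + 0.5) / (lib + 1) * 1e6))
  if (is.null(design)) design <- matrix(1, ncol(counts), 1)
  if (nrow(counts) < 10) {
    warning("fewer than 10 transcripts; using unit weights")
    w <- matrix(1, nrow(counts), ncol(counts), dimnames = dimnames(y))
    return(list(logcpm = y, weights = w))
  }
  qx <- qr(design)
  cf <- t(qr.coef(qx, t(y)))
  res <- t(qr.resid(qx, t(y)))
  df_res <- ncol(counts) - qx$rank
  sigma <- sqrt(rowSums(res^2) / df_res)
  amean <- rowMeans(y)
  sx <- amean + mean(log2(lib + 1)) - log2(1e6)
  sy <- sqrt(sigma)
  ok <- is.finite(sx) & is.finite(sy) & sigma > 0
  lo <- stats::lowess(sx[ok], sy[ok], f = span)
  lof <- stats::approxfun(lo$x, lo$y, rule = 2, ties = mean)
  fitted_logcpm <- cf %*% t(design)
  fitted_logcount <- t(t(fitted_logcpm) + log2(lib + 1)) - log2(1e6)
  pred_sqrt_sd <- lof(fitted_logcount)
  pred_sqrt_sd <- pmax(pred_sqrt_sd, 1e-4)
  w <- matrix(1 / pred_sqrt_sd^4, nrow(counts), ncol(counts))
  dimnames(w) <- dimnames(y)
  list(logcpm = y, weights = w)
}

#' Differential expression with covariate adjustment
#'
#' Per transcript, weighted least squares of log-CPM on
#' \[smoking, age, BMI, miner\]; the smoking coefficient is the log2 fold
#' change (smoker vs nonsmoker), tested two-sided against the t distribution;
#' Benjamini-Hochberg q-values are computed over all tested transcripts.
#'
#' @param logcpm,weights matrices from [mean_variance_weights()].
#' @param sheet sample sheet matched to the columns by sample_id.
#' @return data.frame transcript, log2fc, p, q, direction, sorted by p.
#' @export
deg_test <- function(logcpm, weights, sheet) {
  sheet <- sheet[match(colnames(logcpm), sheet$sample_id), , drop = FALSE]
  if (anyNA(sheet$sample_id)) stop("logcpm columns missing from sample sheet")
  X <- cbind(intercept = 1,
             smoker = as.numeric(sheet$group == "smoker"),
             age = sheet$age, bmi = sheet$bmi,
             miner = as.numeric(sheet$miner))
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    drop <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(drop, collapse = ", "))
  }
  n <- ncol(logcpm); pcol <- ncol(X); df_res <- n - pcol
  g <- nrow(logcpm)
  log2fc <- pval <- numeric(g)
  for (i in seq_len(g)) {
    fit <- stats::lm.wfit(X, logcpm[i, ], weights[i, ])
    rss <- sum(weights[i, ] * fit$residuals^2)
    s2 <- rss / df_res
    R <- qr.R(fit$qr)
    xtxinv <- chol2inv(R)
    se <- sqrt(s2 * xtxinv[2, 2])
    b <- fit$coefficients[2]
    tt <- if (se > 0) b / se else 0
    log2fc[i] <- b
    pval[i] <- if (se > 0) 2 * stats::pt(-abs(tt), df_res) else 1
  }
  q <- stats::p.adjust(pval, method = "BH")
  out <- data.frame(transcript = rownames(logcpm), log2fc = log2fc,
                    p = pval, q = q,
                    direction = ifelse(log2fc > 0, "up", "down"),
                    stringsAsFactors = FALSE)
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  out
}
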