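#' Covariate-adjusted cytokine differential analysis
#'
#' Per analyte, ordinary least squares of log2 fluorescence intensity on
#' smoking status, age, BMI and working condition. The smoking coefficient is
#' the smoker-minus-nonsmoker effect on the log2 scale, with a two-sided
#' t-test p and 95% t confidence interval. No multiplicity correction is
#' applied to the reported p (analyte panels are conventionally reported at
#' nominal significance); a BH q column is emitted alongside for
#' transparency.
#'
#' @param panel analyte x sample matrix of log2 intensities.
#' @param sheet sample sheet matched to columns by sample_id.
#' @param conf_level confidence level for the interval (default 0.95).
#' @return data.frame analyte, effect, ci_low, ci_high, p, q.
#' @export
cytokine_diff <- function(panel, sheet, conf_level = 0.95) {
  sheet <- sheet[match(colnames(panel), sheet$sample_id), , drop = FALSE]
  if (anyNA(sheet$sample_id)) stop("panel columns missing from sample sheet")
  if (min(table(sheet$group)) < 3) stop("need >= 3 samples per group")
  X <- cbind(intercept = 1,
             smoker = as.numeric(sheet$group == "smoker"),
             age = sheet$age, bmi = sheet$bmi,
             miner = as.numeric(sheet$miner))
  qx <- qr(X)
  if (qx$rank < ncol(X)) stop("rank-deficient cytokine design matrix")
  df_res <- ncol(panel) - ncol(X)
  xtxinv <- chol2inv(qr.R(qx))
  tcrit <- stats::qt(1 - (1 - conf_level) / 2, df_res)
  res <- lapply(seq_len(nrow(panel)), function(i) {
    y <- panel[i, ]
    cf <- qr.coef(qx, y)
    r <- qr.resid(qx, y)
    s2 <- sum(r^2) / df_res
    if (s2 < 1e-20) s2 <- 0  # numerically perfect fit (constant analyte)
    se <- sqrt(s2 * xtxinv[2, 2])
    b <- cf[2]
    if (se > 0) {
      p <- 2 * stats::pt(-abs(b / se), df_res)
    } else {
      b <- 0; p <- 1  # constant analyte: no estimable effect
    }
    data.frame(analyte = rownames(panel)[i], effect = unname(b),
               ci_low = unname(b - tcrit * se),
               ci_high = unname(b + tcrit * se), p = unname(p))
  })
  out <- do.call(rbind, res)
  out$q <- stats::p.adjust(out$p, "BH")
  rownames(out) <- NULL
  out
}
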