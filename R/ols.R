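# Ordinary least squares on an explicit design matrix, with the regression
# diagnostics the model-acceptance criteria need: per-coefficient SE/t/p,
# overall F, adjusted R-squared, variance inflation factors and the
# Breusch-Pagan heteroscedasticity test.

#' Build a design matrix from an entry table
#'
#' Assembles the response vector and a full-rank design matrix with an
#' intercept, the named numeric predictors as raw columns, 0/1 dummy columns
#' for categorical predictors (via [encode_dummies()]), and raw squared
#' columns (named `I(var^2)`) for the variables listed in `quadratic`.
#' Entries missing any used value are excluded with a warning.
#'
#' @param entries An entry data frame.
#' @param predictors Character vector of predictor column names (numeric or
#'   categorical).
#' @param quadratic Character vector (subset of the numeric predictors) whose
#'   squares are added.
#' @param response Response column name, default `"G"`.
#' @return A list with `X` (matrix, first column `(Intercept)`), `y`, and
#'   `rows` (row indices of `entries` retained).
#' @export
build_design <- function(entries, predictors, quadratic = character(),
                         response = "G") {
  stopifnot(is.data.frame(entries))
  if (anyDuplicated(predictors))
    stop("collinear design: duplicated predictor '",
         predictors[duplicated(predictors)][1], "'")
  miss <- setdiff(c(predictors, response), names(entries))
  if (length(miss)) stop("no such column(s): ", paste(miss, collapse = ", "))
  bad_q <- setdiff(quadratic, predictors)
  if (length(bad_q))
    stop("quadratic term(s) without a linear term: ",
         paste(bad_q, collapse = ", "))
  is_num <- vapply(entries[predictors], is.numeric, logical(1))
  if (any(quadratic %in% predictors[!is_num]))
    stop("quadratic terms are only allowed for continuous variables")
  used <- c(predictors, response)
  keep <- stats::complete.cases(entries[used])
  if (!any(keep)) stop("all entries excluded: missing predictor values")
  if (any(!keep))
    warning(sum(!keep), " entr", if (sum(!keep) == 1) "y" else "ies",
            " excluded for missing predictor values")
  e <- entries[keep, , drop = FALSE]
  cols <- list("(Intercept)" = rep(1, nrow(e)))
  for (v in predictors) {
    if (is_num[[v]]) {
      cols[[v]] <- as.numeric(e[[v]])
      if (v %in% quadratic) cols[[paste0("I(", v, "^2)")]] <- as.numeric(e[[v]])^2
    } else {
      d <- encode_dummies(e, v)
      for (j in colnames(d)) cols[[j]] <- d[, j]
    }
  }
  X <- do.call(cbind, cols)
  if (qr(X)$rank < ncol(X))
    stop("collinear design: rank ", qr(X)$rank, " < ", ncol(X), " columns")
  list(X = X, y = as.numeric(e[[response]]), rows = which(keep))
}

# Bare QR least squares; returns NULL on rank deficiency. Used both by
# ols_fit and by the best-subset scorer, where diagnostics are deferred.
ols_core <- function(X, y) {
  n <- nrow(X); p <- ncol(X)
  if (n <= p) return(NULL)
  qd <- qr(X)
  if (qd$rank < p) return(NULL)
  coef <- qr.coef(qd, y)
  fitted <- drop(X %*% coef)
  res <- y - fitted
  sse <- sum(res^2)
  df <- n - p
  sigma2 <- sse / df
  R <- qr.R(qd)[seq_len(p), seq_len(p), drop = FALSE]
  xtx_inv <- chol2inv(R)
  se <- sqrt(pmax(diag(xtx_inv), 0) * sigma2)
  tval <- coef / se
  pval <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - sse / tss else NA_real_
  r2_adj <- if (tss > 0) 1 - (1 - r2) * (n - 1) / df else NA_real_
  k <- p - 1L
  model_p <- if (k >= 1L && tss > sse && sse > 0)
    stats::pf(((tss - sse) / k) / sigma2, k, df, lower.tail = FALSE)
  else if (k >= 1L && sse == 0) 0 else NA_real_
  list(coefficients = coef, se = se, t = tval, p = pval,
       fitted = fitted, residuals = res, sse = sse, sigma = sqrt(sigma2),
       df.residual = df, r2 = r2, r2_adj = r2_adj, model_p = model_p,
       n = n, xtx_inv = xtx_inv)
}

# Variance inflation factor of every non-intercept column.
ols_vif <- function(X) {
  nm <- colnames(X)
  idx <- which(nm != "(Intercept)")
  vif <- stats::setNames(rep(NA_real_, length(idx)), nm[idx])
  for (j in seq_along(idx)) {
    xj <- X[, idx[j]]
    Z <- X[, -idx[j], drop = FALSE]
    fit <- ols_core(Z, xj)
    tss <- sum((xj - mean(xj))^2)
    r2 <- if (is.null(fit) || tss == 0) 1 else 1 - fit$sse / tss
    vif[j] <- if (r2 >= 1) Inf else 1 / (1 - r2)
  }
  vif
}

# Generalized VIF (Fox & Monette) with design columns grouped by source
# variable, so that a polynomial term and its parent (or the dummy columns of
# one factor) are assessed jointly: the structural collinearity inside such a
# group is not evidence against the model, while collinearity between groups
# is. Returns GVIF^(1/(2*df)) per group, comparable to sqrt(VIF).
ols_gvif <- function(X) {
  nm <- setdiff(colnames(X), "(Intercept)")
  if (!length(nm)) return(numeric(0))
  src <- vapply(nm, function(term) {
    m <- regmatches(term, regexec("^I\\((.+)\\^2\\)$", term))[[1]]
    if (length(m) == 2L) return(m[2])
    sub("=.*$", "", term)
  }, character(1))
  Z <- X[, nm, drop = FALSE]
  if (any(apply(Z, 2, stats::sd) == 0)) return(stats::setNames(Inf, nm[1]))
  R <- stats::cor(Z)
  detR <- det(R)
  groups <- unique(src)
  out <- stats::setNames(numeric(length(groups)), groups)
  for (g in groups) {
    i <- which(src == g)
    if (length(i) == length(nm)) { out[g] <- 1; next }
    gvif <- det(R[i, i, drop = FALSE]) *
      det(R[-i, -i, drop = FALSE]) / detR
    out[g] <- gvif^(1 / (2 * length(i)))
  }
  out
}

# Breusch-Pagan (Koenker studentized) heteroscedasticity test: regress
# squared residuals on the design; LM = n * R^2, chi-squared with k df.
ols_bp_test <- function(X, residuals) {
  k <- ncol(X) - 1L
  if (k < 1L) return(NA_real_)
  aux <- ols_core(X, residuals^2)
  if (is.null(aux) || is.na(aux$r2)) return(NA_real_)
  stats::pchisq(nrow(X) * aux$r2, df = k, lower.tail = FALSE)
}

#' Ordinary least squares with full model-acceptance diagnostics
#'
#' Fits `y` on the given design by QR least squares and reports the
#' quantities used to accept or reject a candidate model: coefficient table
#' (estimate, SE, t, two-tailed p), R-squared and adjusted R-squared, overall
#' F-test p-value, variance inflation factor of every non-intercept column,
#' and the Breusch-Pagan (studentized) heteroscedasticity p-value.
#'
#' @param X Numeric design matrix including an `(Intercept)` column.
#' @param y Numeric response.
#' @return An object of class `gag_ols`.
#' @export
ols_fit <- function(X, y) {
  stopifnot(is.matrix(X), nrow(X) == length(y))
  fit <- ols_core(X, y)
  if (is.null(fit))
    stop("singular design: rank-deficient or fewer rows than columns")
  fit$vif <- ols_vif(X)
  fit$heteroscedasticity_p <- ols_bp_test(X, fit$residuals)
  fit$coef_table <- data.frame(
    term = colnames(X), estimate = unname(fit$coefficients),
    se = unname(fit$se), t = unname(fit$t), p = unname(fit$p),
    stringsAsFactors = FALSE)
  class(fit) <- "gag_ols"
  fit
}

#' @export
print.gag_ols <- function(x, ...) {
  cat(sprintf("OLS fit: n = %d, %d coefficients\n", x$n,
              length(x$coefficients)))
  print(x$coef_table, row.names = FALSE, digits = 4)
  cat(sprintf("R2 = %.4f  adj R2 = %.4f  model p = %.3g  BP p = %.3g\n",
              x$r2, x$r2_adj, x$model_p, x$heteroscedasticity_p))
  invisible(x)
}
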