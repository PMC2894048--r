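# The central model object: a linear-quadratic predictor of the log
# acceleration G. The reference specification is
#   G = y0 + a*P_S + b*P_B + c*P_MR + c'*P_MR^2
# with P_S the GAG sulfation state (sulfates per disaccharide unit), P_B the
# total solute molarity of the buffer in mM, and P_MR the protein:GAG molar
# ratio.

# canonical column names of the three key predictors
EQ_PS <- "sulfates_per_disaccharide"
EQ_PB <- "solute_molarity"
EQ_PMR <- "protein_gag_molar_ratio"
EQ_PMR2 <- "I(protein_gag_molar_ratio^2)"

# Construct a gag_model from an explicit design. `terms` are the design
# column names; predict() re-evaluates them by name on new data.
gag_model_from_design <- function(X, y, rows = NULL, call = NULL) {
  fit <- ols_fit(X, y)
  structure(list(
    coefficients = fit$coefficients,
    se = fit$se,
    coef_table = fit$coef_table,
    r2 = fit$r2, r2_adj = fit$r2_adj, model_p = fit$model_p,
    vif = fit$vif, heteroscedasticity_p = fit$heteroscedasticity_p,
    residuals = fit$residuals, fitted.values = fit$fitted,
    sigma = fit$sigma, df.residual = fit$df.residual, n = fit$n,
    y = y, terms = colnames(X), rows = rows, published = FALSE,
    call = call), class = "gag_model")
}

#' Fit the multivariate acceleration model
#'
#' Fits, by ordinary least squares, a linear model of the log acceleration
#' `G` on the chosen descriptor columns, optionally with raw quadratic terms.
#' The default predictor set is the reference specification of the package:
#' sulfation state, solute molarity, and protein:GAG molar ratio with its
#' square, i.e. `G = y0 + a*P_S + b*P_B + c*P_MR + c'*P_MR^2`.
#'
#' @param entries An entry data frame (see [gag_table_schema()]).
#' @param predictors Predictor column names; categorical columns are dummy
#'   recoded via [encode_dummies()].
#' @param quadratic Continuous predictors whose raw squares are included.
#' @param response Response column, default `"G"`.
#' @return An object of class `gag_model`, with methods `print`, `summary`,
#'   `coef`, `predict`, `residuals`, `fitted`, `plot` and `simulate`.
#' @examples
#' d <- generate_gag_entries(n = 39, seed = 1)
#' m <- fit_gag_model(d)
#' summary(m)
#' predict(m, P_S = 2, P_B = 100, P_MR = 10)
#' @export
fit_gag_model <- function(entries,
                          predictors = c(EQ_PS, EQ_PB, EQ_PMR),
                          quadratic = EQ_PMR,
                          response = "G") {
  dm <- build_design(entries, predictors, quadratic, response)
  gag_model_from_design(dm$X, dm$y, rows = dm$rows, call = match.call())
}

#' The published predictive model of GAG-mediated acceleration
#'
#' The reference coefficient set of the linear-quadratic predictor
#' `G = y0 + a*P_S + b*P_B + c*P_MR + c'*P_MR^2`:
#' `y0 = 2.0 (0.7)`, `a = 0.30 (0.05)` per sulfate/disaccharide,
#' `b = -0.016 (0.004)` per mM, `c = 0.11 (0.03)` per unit molar ratio,
#' `c' = -0.0020 (0.0005)` per squared molar ratio (standard errors in
#' parentheses). The object predicts but carries no residuals or fit
#' diagnostics of its own.
#'
#' @return A `gag_model` with `published = TRUE`.
#' @export
published_gag_model <- function() {
  terms <- c("(Intercept)", EQ_PS, EQ_PB, EQ_PMR, EQ_PMR2)
  structure(list(
    coefficients = stats::setNames(c(2.0, 0.30, -0.016, 0.11, -0.0020), terms),
    se = stats::setNames(c(0.7, 0.05, 0.004, 0.03, 0.0005), terms),
    coef_table = NULL, r2 = NA_real_, r2_adj = 0.74, model_p = 2e-6,
    vif = NULL, heteroscedasticity_p = NA_real_,
    residuals = NULL, fitted.values = NULL, sigma = NA_real_,
    df.residual = NA_integer_, n = 39L, y = NULL, terms = terms,
    rows = NULL, published = TRUE, call = NULL), class = "gag_model")
}

#' Named (y0, a, b, c, c') view of a fitted acceleration model
#'
#' @param model A `gag_model` whose terms are the reference specification.
#' @return Named numeric vector `y0`, `a`, `b`, `c`, `c_prime`.
#' @export
eq_coefficients <- function(model) {
  stopifnot(inherits(model, "gag_model"))
  need <- c("(Intercept)", EQ_PS, EQ_PB, EQ_PMR, EQ_PMR2)
  if (!all(need %in% names(model$coefficients)))
    stop("model does not carry the reference predictor set")
  stats::setNames(unname(model$coefficients[need]),
                  c("y0", "a", "b", "c", "c_prime"))
}

# Evaluate one design column, identified by its term name, on new data.
eval_term <- function(term, data) {
  if (term == "(Intercept)") return(rep(1, nrow(data)))
  m <- regmatches(term, regexec("^I\\((.+)\\^2\\)$", term))[[1]]
  if (length(m) == 2L) {
    v <- m[2]
    if (!v %in% names(data)) stop("no such column: ", v)
    return(as.numeric(data[[v]])^2)
  }
  m <- regmatches(term, regexec("^(.+)=(.+)$", term))[[1]]
  if (length(m) == 3L && m[2] %in% names(data))
    return(as.numeric(as.character(data[[m[2]]]) == m[3]))
  if (!term %in% names(data)) stop("no such column: ", term)
  as.numeric(data[[term]])
}

#' @export
coef.gag_model <- function(object, ...) object$coefficients

#' @export
residuals.gag_model <- function(object, ...) object$residuals

#' @export
fitted.gag_model <- function(object, ...) object$fitted.values

#' Predict G from a fitted acceleration model
#'
#' Either supply `newdata` (a data frame with the model's predictor columns)
#' or, for a model on the reference specification, the three key parameters
#' directly: `P_S` (sulfates per disaccharide), `P_B` (solute molarity, mM)
#' and `P_MR` (protein:GAG molar ratio).
#'
#' @param object A `gag_model`.
#' @param newdata Optional data frame; defaults to the fitted values.
#' @param P_S,P_B,P_MR Optional numeric vectors, recycled to common length.
#' @param ... Unused.
#' @return Predicted G values.
#' @export
predict.gag_model <- function(object, newdata = NULL,
                              P_S = NULL, P_B = NULL, P_MR = NULL, ...) {
  if (is.null(newdata) && is.null(P_S) && is.null(P_B) && is.null(P_MR)) {
    if (is.null(object$fitted.values))
      stop("no fitted values; supply newdata or (P_S, P_B, P_MR)")
    return(object$fitted.values)
  }
  if (is.null(newdata)) {
    if (is.null(P_S) || is.null(P_B) || is.null(P_MR))
      stop("supply all of P_S, P_B and P_MR")
    if (any(P_S < 0) || any(P_B < 0) || any(P_MR < 0))
      stop("P_S, P_B and P_MR must be non-negative")
    n <- max(length(P_S), length(P_B), length(P_MR))
    newdata <- data.frame(rep_len(P_S, n), rep_len(P_B, n), rep_len(P_MR, n))
    names(newdata) <- c(EQ_PS, EQ_PB, EQ_PMR)
  }
  X <- vapply(object$terms, eval_term, numeric(nrow(newdata)), data = newdata)
  if (nrow(newdata) == 1L) X <- matrix(X, nrow = 1, dimnames = list(NULL, object$terms))
  drop(X %*% object$coefficients)
}

#' Predict G from the three key parameters
#'
#' Convenience wrapper around [predict.gag_model()]:
#' `G = y0 + a*P_S + b*P_B + c*P_MR + c'*P_MR^2`.
#'
#' @param model A `gag_model` (default the published coefficient set).
#' @param P_S Sulfates per disaccharide unit (>= 0).
#' @param P_B Total solute molarity in mM (>= 0).
#' @param P_MR Protein:GAG molar ratio (>= 0).
#' @return Predicted G.
#' @export
predict_G <- function(P_S, P_B, P_MR, model = published_gag_model())
  predict(model, P_S = P_S, P_B = P_B, P_MR = P_MR)

#' Molar ratio of maximal predicted acceleration
#'
#' With a negative quadratic coefficient the predicted acceleration is a
#' downward parabola in the protein:GAG molar ratio; its vertex
#' `P_MR* = -c / (2 c')` is the ratio of maximal effect.
#'
#' @param model A `gag_model` carrying the reference specification.
#' @param P_S,P_B Condition at which the maximal G is evaluated (they do not
#'   affect the location of the optimum).
#' @return A list with `ratio` (the vertex) and `G_max` (predicted G there).
#' @export
optimal_molar_ratio <- function(model = published_gag_model(),
                                P_S = 0, P_B = 0) {
  cf <- eq_coefficients(model)
  if (cf[["c_prime"]] >= 0)
    stop("no interior maximum: quadratic coefficient is not negative")
  ratio <- -cf[["c"]] / (2 * cf[["c_prime"]])
  list(ratio = ratio,
       G_max = predict_G(P_S = P_S, P_B = P_B, P_MR = ratio, model = model))
}

#' @export
print.gag_model <- function(x, ...) {
  cat("Linear-quadratic model of GAG-mediated acceleration (G)\n")
  if (x$published) cat("  (published coefficient set)\n")
  cf <- x$coefficients
  for (i in seq_along(cf))
    cat(sprintf("  %-32s %10.4g  (se %.3g)\n", names(cf)[i], cf[i], x$se[i]))
  if (!is.null(x$r2) && !is.na(x$r2))
    cat(sprintf("  n = %d, adj R2 = %.3f, model p = %.2g\n",
                x$n, x$r2_adj, x$model_p))
  invisible(x)
}

#' @export
summary.gag_model <- function(object, ...) {
  structure(list(model = object), class = "summary.gag_model")
}

#' @export
print.summary.gag_model <- function(x, ...) {
  m <- x$model
  print(m)
  if (!is.null(m$coef_table)) {
    cat("\nCoefficients:\n")
    print(m$coef_table, row.names = FALSE, digits = 4)
    cat(sprintf("\nR2 = %.4f, adj R2 = %.4f, model p = %.3g\n",
                m$r2, m$r2_adj, m$model_p))
    if (!is.null(m$vif)) {
      cat("VIF: ")
      cat(paste(sprintf("%s = %.2f", names(m$vif), m$vif), collapse = ", "), "\n")
    }
    cat(sprintf("Breusch-Pagan heteroscedasticity p = %.3g\n",
                m$heteroscedasticity_p))
  }
  invisible(x)
}

#' Diagnostic plots for a fitted acceleration model
#'
#' Panel 1: predicted versus observed G with the line of best fit.
#' Panel 2: residuals versus observed G with their mean.
#'
#' @param x A fitted `gag_model`.
#' @param which Which panel(s), subset of `1:2`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.gag_model <- function(x, which = 1:2, ...) {
  if (is.null(x$fitted.values)) stop("no fitted values to plot")
  obs <- x$y; pred <- x$fitted.values
  if (1 %in% which) {
    graphics::plot(obs, pred, xlab = "observed G", ylab = "predicted G", ...)
    graphics::abline(stats::lm(pred ~ obs))
  }
  if (2 %in% which) {
    graphics::plot(obs, obs - pred, xlab = "observed G", ylab = "residual", ...)
    graphics::abline(h = mean(obs - pred), lty = 2)
  }
  invisible(x)
}

#' Simulate responses from a fitted acceleration model
#'
#' Draws `G = fitted + N(0, sigma^2)` replicates, with `sigma` the residual
#' standard deviation of the fit.
#'
#' @param object A fitted `gag_model`.
#' @param nsim Number of simulated response vectors.
#' @param seed Optional RNG seed (global RNG state is restored on exit).
#' @param ... Unused.
#' @return A data frame with `nsim` columns, as for [stats::simulate()].
#' @export
simulate.gag_model <- function(object, nsim = 1, seed = NULL, ...) {
  if (is.null(object$fitted.values) || is.na(object$sigma))
    stop("simulation requires a model fitted to data")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  n <- length(object$fitted.values)
  out <- as.data.frame(replicate(nsim, object$fitted.values +
                                   stats::rnorm(n, 0, object$sigma)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}
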