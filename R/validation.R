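# Robustness checks of the selected model: repeated 2/3-1/3 train/test
# subsampling, leave-one-out jackknife, and predicted-vs-observed reporting.

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
            else if (exists(".Random.seed", envir = globalenv()))
              rm(".Random.seed", envir = globalenv()))
    set.seed(seed)
  }
  force(code)
}

#' Train/test subsampling validation of the acceleration model
#'
#' Repeatedly partitions the dataset at random into a training set of
#' `round(n * train_frac)` entries (26 of 39 at the defaults) and a disjoint
#' test set of the remainder, refits the model specification on the training
#' set, predicts the held-out entries, and records the Pearson correlation of
#' predicted versus observed G on each test set together with the training
#' model's overall p-value. Sampling is without replacement within each
#' replicate (a partition, not a classical with-replacement bootstrap).
#' Replicates whose training design is singular are redrawn and counted.
#'
#' @param entries An entry data frame.
#' @param predictors,quadratic,response Model specification, as for
#'   [fit_gag_model()].
#' @param n_rep Number of replicates (default 100).
#' @param train_frac Training fraction (default 2/3).
#' @param seed RNG seed (global RNG state restored on exit).
#' @return An object of class `gag_validation`, with `replicates` (data
#'   frame: `train_model_p`, `test_r`, `test_p`), `mean_R`, `se_R`,
#'   `n_redrawn`.
#' @export
bootstrap_validate <- function(entries,
                               predictors = c(EQ_PS, EQ_PB, EQ_PMR),
                               quadratic = EQ_PMR, response = "G",
                               n_rep = 100L, train_frac = 2 / 3,
                               seed = 17L) {
  dm <- build_design(entries, predictors, quadratic, response)
  X <- dm$X; y <- dm$y
  n <- nrow(X)
  n_train <- round(n * train_frac)
  if (n_train < ncol(X) + 2L)
    stop("training sets too small for the model specification")
  with_seed(seed, {
    recs <- vector("list", n_rep)
    n_redrawn <- 0L
    for (i in seq_len(n_rep)) {
      repeat {
        tr <- sample.int(n, n_train)
        fit <- ols_core(X[tr, , drop = FALSE], y[tr])
        if (!is.null(fit)) break
        n_redrawn <- n_redrawn + 1L
      }
      te <- setdiff(seq_len(n), tr)
      pred <- drop(X[te, , drop = FALSE] %*% fit$coefficients)
      ct <- stats::cor.test(pred, y[te])
      recs[[i]] <- c(train_model_p = fit$model_p,
                     test_r = unname(ct$estimate), test_p = ct$p.value)
    }
    reps <- as.data.frame(do.call(rbind, recs))
    structure(list(
      kind = "bootstrap", replicates = reps,
      mean_R = mean(reps$test_r), se_R = stats::sd(reps$test_r) / sqrt(n_rep),
      n_rep = n_rep, n_train = n_train, n_test = n - n_train,
      n_redrawn = n_redrawn, seed = seed), class = "gag_validation")
  })
}

#' Leave-one-out jackknife validation of the acceleration model
#'
#' Removes each entry in turn, refits the model specification on the
#' remaining `n - 1` entries, and predicts the removed entry. The `n`
#' out-of-sample predictions are then regressed on the observed G values;
#' the R-squared and p-value of that regression summarise the model's
#' dependence on dataset composition. Entries whose reduced design is
#' singular get a missing prediction.
#'
#' @inheritParams bootstrap_validate
#' @return An object of class `gag_validation` with `predictions` (data
#'   frame: `observed`, `predicted`), `r2`, `p`, `slope`.
#' @export
jackknife_validate <- function(entries,
                               predictors = c(EQ_PS, EQ_PB, EQ_PMR),
                               quadratic = EQ_PMR, response = "G") {
  dm <- build_design(entries, predictors, quadratic, response)
  X <- dm$X; y <- dm$y
  n <- nrow(X)
  if (n < ncol(X) + 3L) stop("too few entries for a jackknife")
  pred <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    fit <- ols_core(X[-i, , drop = FALSE], y[-i])
    if (!is.null(fit)) pred[i] <- drop(X[i, , drop = FALSE] %*% fit$coefficients)
  }
  ok <- !is.na(pred)
  reg <- stats::lm(pred[ok] ~ y[ok])
  sm <- suppressWarnings(summary(reg))  # perfect fits are legitimate here
  structure(list(
    kind = "jackknife",
    predictions = data.frame(observed = y, predicted = pred),
    r2 = sm$r.squared,
    p = stats::pf(sm$fstatistic[1L], sm$fstatistic[2L], sm$fstatistic[3L],
                  lower.tail = FALSE),
    slope = unname(stats::coef(reg)[2L]), n = sum(ok)),
    class = "gag_validation")
}

#' Predicted-versus-observed report for a model on a dataset
#'
#' Applies a fitted or published model to every entry and summarises the
#' agreement: Pearson r and p of predicted versus observed G, the slope of
#' their line of best fit, and the residuals (observed minus predicted) with
#' their mean.
#'
#' @param entries An entry data frame.
#' @param model A `gag_model`.
#' @param response Response column, default `"G"`.
#' @return A list with `r`, `p`, `slope`, `residuals`, `mean_residual`,
#'   `predicted`, `observed`.
#' @export
prediction_report <- function(entries, model, response = "G") {
  pred <- predict(model, newdata = entries)
  obs <- as.numeric(entries[[response]])
  ok <- !is.na(pred) & !is.na(obs)
  ct <- stats::cor.test(pred[ok], obs[ok])
  fit <- stats::lm(pred[ok] ~ obs[ok])
  res <- obs - pred
  list(r = unname(ct$estimate), p = ct$p.value,
       slope = unname(stats::coef(fit)[2L]),
       residuals = res, mean_residual = mean(res[ok]),
       predicted = pred, observed = obs, n = sum(ok))
}

#' @export
print.gag_validation <- function(x, ...) {
  if (x$kind == "bootstrap") {
    cat(sprintf("Subsampling validation: %d replicates (%d train / %d test)\n",
                x$n_rep, x$n_train, x$n_test))
    cat(sprintf("  mean test-set R = %.3f +/- %.3f (se); %d replicate(s) redrawn\n",
                x$mean_R, x$se_R, x$n_redrawn))
  } else {
    cat(sprintf("Jackknife validation: %d leave-one-out predictions\n", x$n))
    cat(sprintf("  predicted ~ observed: R2 = %.3f, p = %.3g, slope = %.3f\n",
                x$r2, x$p, x$slope))
  }
  invisible(x)
}
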