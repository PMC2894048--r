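# Model selection over the candidate descriptor universe: exhaustive best
# subset and forward/backward stepwise, each screened by the five acceptance
# criteria (per-variable significance, model significance, adjusted
# R-squared, collinearity via VIF, homoscedasticity via Breusch-Pagan).

#' Default candidate predictor universe for model selection
#'
#' Lists the descriptor columns considered for selection: the continuous GAG,
#' condition and protein descriptors (with quadratic expansions allowed), and
#' the dichotomous descriptors as dummy variables. Variables absent from the
#' data, with missing values, or constant are pruned; exact duplicates of an
#' earlier column are pruned; the candidate set is then capped (GAG and
#' condition descriptors have priority over protein descriptors). Quadratic
#' expansions accompany their linear term and do not count toward the cap.
#'
#' @param entries An entry data frame.
#' @param max_columns Cap on the number of base candidate design columns.
#' @return A list with `linear` (continuous columns), `categorical`
#'   (dummy-recoded columns) and `quadratic` (continuous columns whose
#'   squares may enter, only together with their linear term).
#' @export
candidate_universe <- function(entries, max_columns = 12L) {
  continuous <- c("sulfates_per_disaccharide", "charges_per_disaccharide",
                  "solute_molarity", "protein_gag_molar_ratio", "gag_mw",
                  "protein_length", "protein_net_charge", "lys_arg_count")
  # listed in pruning priority: GAG and condition descriptors are kept in
  # preference to protein descriptors when the cap bites
  categorical <- c("uronic_acid", "sulfation_position", "folding_status",
                   "disease_related")
  usable <- function(v) v %in% names(entries) &&
    !anyNA(entries[[v]]) && length(unique(entries[[v]])) > 1L
  continuous <- Filter(usable, continuous)
  categorical <- Filter(usable, categorical)
  # prune exact duplicates among continuous columns
  if (length(continuous) > 1L) {
    keep <- rep(TRUE, length(continuous))
    for (i in seq_along(continuous)[-1L])
      for (j in seq_len(i - 1L))
        if (keep[j] && isTRUE(all.equal(as.numeric(entries[[continuous[i]]]),
                                        as.numeric(entries[[continuous[j]]]))))
          keep[i] <- FALSE
    continuous <- continuous[keep]
  }
  n_cat_cols <- sum(vapply(categorical, function(v)
    length(unique(entries[[v]])) - 1L, integer(1)))
  # the cap counts base design columns (continuous + dummy); quadratic
  # expansions ride along with their linear term and are not counted
  while (length(continuous) + n_cat_cols > max_columns &&
         length(continuous) > 0L)
    continuous <- continuous[-length(continuous)]
  list(linear = continuous, categorical = categorical, quadratic = continuous)
}

# Expand a candidate universe into the full design matrix plus term metadata:
# term names, and for each quadratic term the linear term it depends on.
expand_candidates <- function(entries, universe, response = "G") {
  keep <- stats::complete.cases(
    entries[c(universe$linear, universe$categorical, response)])
  e <- entries[keep, , drop = FALSE]
  cols <- list()
  parent <- character(0)
  for (v in universe$linear) cols[[v]] <- as.numeric(e[[v]])
  for (v in universe$categorical) {
    d <- encode_dummies(e, v)
    for (j in colnames(d)) cols[[j]] <- d[, j]
  }
  for (v in intersect(universe$quadratic, universe$linear)) {
    nm <- paste0("I(", v, "^2)")
    cols[[nm]] <- as.numeric(e[[v]])^2
    parent[nm] <- v
  }
  M <- do.call(cbind, cols)
  list(M = M, y = as.numeric(e[[response]]), parent = parent,
       base_terms = setdiff(colnames(M), names(parent)))
}

# Five acceptance criteria on a scored model. The collinearity screen uses
# grouped generalized VIFs on the GVIF^(1/(2 df)) scale, so the threshold is
# sqrt(vif_max); a variable's own quadratic or dummy columns do not count as
# collinearity against it.
criteria_pass <- function(fit, gvif, bp_p, alpha_coef, alpha_model,
                          vif_max, bp_alpha) {
  pv <- fit$p[-1L]  # non-intercept coefficients
  list(coef_ok = length(pv) > 0L && all(pv < alpha_coef),
       model_ok = !is.na(fit$model_p) && fit$model_p < alpha_model,
       vif_ok = is.null(gvif) || all(gvif < sqrt(vif_max)),
       bp_ok = is.na(bp_p) || bp_p > bp_alpha)
}

#' Select the acceleration model under the five acceptance criteria
#'
#' Searches the candidate universe for the subset of design columns that
#' maximizes the adjusted R-squared among models in which every non-intercept
#' coefficient is significant (`p < alpha_coef`), the overall model is
#' significant (`p < alpha_model`), the collinearity screen passes, and the
#' Breusch-Pagan heteroscedasticity p-value exceeds `bp_alpha`. Quadratic
#' columns may enter only together with their linear term (hierarchy
#' principle). Collinearity is screened with generalized variance inflation
#' factors in which a variable is grouped with its own quadratic and dummy
#' columns (Fox-Monette `GVIF^(1/(2 df))` scaling, threshold
#' `sqrt(vif_max)`): the structural collinearity between a variable and its
#' own square is not treated as evidence against a model, while collinearity
#' between distinct descriptors (e.g. sulfates and charges per disaccharide)
#' still excludes their co-inclusion. Ties in adjusted R-squared are broken toward
#' fewer predictors, then lexicographic term order.
#'
#' `method = "best_subset"` enumerates all admissible subsets exhaustively;
#' `method = "stepwise"` runs forward selection (p-to-enter 0.05) with
#' backward elimination (p-to-remove 0.10) and then applies the same
#' acceptance screen; `method = "both"` (default) runs both and reports
#' whether they agree, returning the best-subset choice.
#'
#' @param entries An entry data frame.
#' @param universe A candidate universe as from [candidate_universe()].
#' @param method `"both"`, `"best_subset"` or `"stepwise"`.
#' @param alpha_coef,alpha_model,vif_max,bp_alpha Acceptance thresholds.
#' @param p_enter,p_remove Stepwise entry/removal thresholds.
#' @param response Response column, default `"G"`.
#' @return An object of class `gag_model_selection`: list with `best` (a
#'   [fit_gag_model()]-style `gag_model`), `terms`, `best_subset_terms`,
#'   `stepwise_terms`, `methods_agree`, and `n_candidates` examined.
#' @export
select_model <- function(entries, universe = candidate_universe(entries),
                         method = c("both", "best_subset", "stepwise"),
                         alpha_coef = 0.05, alpha_model = 0.05,
                         vif_max = 10, bp_alpha = 0.05,
                         p_enter = 0.05, p_remove = 0.10,
                         response = "G") {
  method <- match.arg(method)
  cand <- expand_candidates(entries, universe, response)
  M <- cand$M; y <- cand$y
  intercept <- matrix(1, nrow(M), 1, dimnames = list(NULL, "(Intercept)"))

  # Subset fits are scored from precomputed cross-products, so the per-subset
  # cost is independent of the number of entries; the winning model is
  # re-fitted by QR before acceptance.
  n <- nrow(M)
  Z <- cbind(intercept, M)
  CP <- crossprod(cbind(Z, y))
  ny <- ncol(CP)
  yty <- CP[ny, ny]
  tss <- yty - CP[1L, ny]^2 / n

  score_idx <- function(idx) {  # idx: column indices into M
    cols <- c(1L, idx + 1L)
    p <- length(cols)
    if (n <= p) return(NULL)
    A <- CP[cols, cols, drop = FALSE]
    b <- CP[cols, ny]
    ch <- tryCatch(chol(A), error = function(e) NULL)
    if (is.null(ch) || any(diag(ch) < 1e-10 * sqrt(diag(A)))) return(NULL)
    coef <- backsolve(ch, forwardsolve(t(ch), b))
    sse <- max(yty - sum(coef * b), 0)
    df <- n - p
    sigma2 <- sse / df
    se <- sqrt(pmax(diag(chol2inv(ch)), 0) * sigma2)
    pv <- 2 * stats::pt(abs(coef / se), df, lower.tail = FALSE)
    r2 <- if (tss > 0) 1 - sse / tss else NA_real_
    k <- p - 1L
    list(p = pv, r2_adj = if (tss > 0) 1 - (1 - r2) * (n - 1) / df else NA_real_,
         model_p = if (k >= 1L && tss > sse && sse > 0)
           stats::pf(((tss - sse) / k) / sigma2, k, df, lower.tail = FALSE)
         else if (k >= 1L && sse == 0) 0 else NA_real_)
  }

  score_terms <- function(terms) score_idx(match(terms, colnames(M)))

  bs_terms <- sw_terms <- NULL
  n_candidates <- 0L
  near_misses <- list()

  if (method %in% c("both", "best_subset")) {
    base_idx <- match(cand$base_terms, colnames(M))
    quad_idx <- match(names(cand$parent), colnames(M))
    quad_parent_idx <- match(unname(cand$parent), colnames(M))
    nb <- length(base_idx)
    if (nb > 20L) stop("candidate universe too large to enumerate")
    # enumerate admissible column-index subsets (quadratic only with its
    # linear parent); keep only those passing the significance screens
    kept <- list(); kept_r2 <- numeric(0)
    bit_base <- 2^(seq_len(nb) - 1L)
    for (mask in seq_len(2^nb) - 1L) {
      sel_base <- base_idx[bitwAnd(mask, bit_base) > 0L]
      if (!length(sel_base)) { n_candidates <- n_candidates + 1L; next }
      open <- quad_idx[quad_parent_idx %in% sel_base]
      nq <- length(open)
      bit_q <- 2^(seq_len(nq) - 1L)
      for (qmask in seq_len(max(2^nq, 1L)) - 1L) {
        sel <- c(sel_base, open[bitwAnd(qmask, bit_q) > 0L])
        n_candidates <- n_candidates + 1L
        fit <- score_idx(sel)
        if (is.null(fit)) next
        if (all(fit$p[-1L] < alpha_coef) && !is.na(fit$model_p) &&
            fit$model_p < alpha_model) {
          kept[[length(kept) + 1L]] <- sel
          kept_r2[length(kept)] <- fit$r2_adj
        }
      }
    }
    if (length(kept)) {
      ord <- order(-kept_r2,
                   lengths(kept),
                   vapply(kept, function(s)
                     paste(sort(colnames(M)[s]), collapse = "|"), character(1)))
      for (i in ord) {
        sel <- kept[[i]]
        X <- cbind(intercept, M[, sel, drop = FALSE])
        fit <- ols_core(X, y)
        if (is.null(fit)) next
        vif <- ols_gvif(X)
        bp <- ols_bp_test(X, fit$residuals)
        ok <- criteria_pass(fit, vif, bp, alpha_coef, alpha_model,
                            vif_max, bp_alpha)
        if (all(unlist(ok))) { bs_terms <- colnames(M)[sel]; break }
        if (length(near_misses) < 5L)
          near_misses[[length(near_misses) + 1L]] <-
            list(terms = colnames(M)[sel], r2_adj = kept_r2[i],
                 failed = names(ok)[!unlist(ok)])
      }
    }
  }

  if (method %in% c("both", "stepwise")) {
    current <- character(0)
    repeat {
      changed <- FALSE
      # forward: admissible additions respecting hierarchy
      addable <- c(setdiff(cand$base_terms, current),
                   names(cand$parent)[cand$parent %in% current &
                                        !names(cand$parent) %in% current])
      if (length(addable)) {
        pv <- vapply(addable, function(tm) {
          fit <- score_terms(c(current, tm))
          if (is.null(fit)) NA_real_ else fit$p[length(fit$p)]
        }, numeric(1))
        if (any(!is.na(pv)) && min(pv, na.rm = TRUE) < p_enter) {
          current <- c(current, addable[which.min(pv)])
          changed <- TRUE
        }
      }
      # backward: drop the worst removable term above p_remove
      if (length(current) > 1L) {
        fit <- score_terms(current)
        if (!is.null(fit)) {
          pv <- fit$p[-1L]
          removable <- !(current %in% cand$parent[names(cand$parent) %in% current])
          pv[!removable] <- NA_real_
          if (any(!is.na(pv)) && max(pv, na.rm = TRUE) > p_remove) {
            current <- current[-which.max(pv)]
            changed <- TRUE
          }
        }
      }
      if (!changed) break
    }
    sw_terms <- if (length(current)) sort(current) else NULL
    if (!is.null(sw_terms)) {
      X <- cbind(intercept, M[, current, drop = FALSE])
      fit <- ols_core(X, y)
      ok <- criteria_pass(fit, ols_gvif(X), ols_bp_test(X, fit$residuals),
                          alpha_coef, alpha_model, vif_max, bp_alpha)
      if (!all(unlist(ok))) sw_terms <- structure(sw_terms, criteria_met = FALSE)
      else sw_terms <- structure(sw_terms, criteria_met = TRUE)
    }
  }

  chosen <- if (method == "stepwise") sw_terms else bs_terms
  if (is.null(chosen)) {
    msg <- "no candidate model satisfies all acceptance criteria"
    if (length(near_misses))
      msg <- paste0(msg, "; near misses:\n", paste(vapply(near_misses,
        function(nm) sprintf("  {%s} adjR2=%.3f failed: %s",
                             paste(nm$terms, collapse = ", "), nm$r2_adj,
                             paste(nm$failed, collapse = ",")),
        character(1)), collapse = "\n"))
    stop(msg)
  }
  X <- cbind(intercept, M[, chosen, drop = FALSE])
  best <- gag_model_from_design(X, y, call = match.call())
  structure(list(best = best, terms = sort(unclass(chosen)),
                 best_subset_terms = if (!is.null(bs_terms)) sort(bs_terms),
                 stepwise_terms = if (!is.null(sw_terms)) sort(unclass(sw_terms)),
                 methods_agree = if (method == "both" && !is.null(sw_terms))
                   setequal(bs_terms, unclass(sw_terms)) else NA,
                 n_candidates = n_candidates),
            class = "gag_model_selection")
}

#' @export
print.gag_model_selection <- function(x, ...) {
  cat("Model selection over", x$n_candidates, "candidate subsets\n")
  cat("  chosen terms:", paste(x$terms, collapse = ", "), "\n")
  if (!is.na(x$methods_agree))
    cat("  best-subset and stepwise agree:", x$methods_agree, "\n")
  print(x$best)
  invisible(x)
}
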