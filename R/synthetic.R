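# Synthetic data with the statistical structure of the curated literature
# database: descriptor-complete entries whose G follows the linear-quadratic
# model plus Gaussian noise, and forward-simulated kinetic traces.

# Synthetic GAG catalog. Names are deliberately prefixed "syn-": these are
# fabricated stand-ins spanning realistic descriptor combinations, from
# unsulfated polysaccharides through highly sulfated heparin-like chains.
# Charges per disaccharide are sulfates plus one carboxylate, except for the
# two backbones without a uronic acid.
synthetic_gag_catalog <- function() {
  g <- rbind(
    c("syn-hyaluronate",        0, 1, "glucuronic", "none",  5e5),
    c("syn-desulfated-heparin", 0, 1, "iduronic",   "none",  12e3),
    c("syn-keratan-like",       1, 1, "none",       "O",     10e3),
    c("syn-chondroitin-4S",     1, 2, "glucuronic", "O",     25e3),
    c("syn-dermatan-sulfate",   1, 2, "iduronic",   "O",     30e3),
    c("syn-heparan-sulfate",    2, 3, "iduronic",   "mixed", 15e3),
    c("syn-oversulf-chondroitin", 2, 3, "glucuronic", "O",   28e3),
    c("syn-heparin",            3, 4, "iduronic",   "mixed", 14e3),
    c("syn-dextran-sulfate",    3, 3, "none",       "O",     8e3))
  data.frame(gag = g[, 1],
             sulfates_per_disaccharide = as.numeric(g[, 2]),
             charges_per_disaccharide = as.numeric(g[, 3]),
             uronic_acid = g[, 4], sulfation_position = g[, 5],
             gag_mw = as.numeric(g[, 6]), stringsAsFactors = FALSE)
}

# Synthetic protein catalog: globular and natively unfolded chains, disease
# related and model proteins, with plausible lengths, net charges at pH 7.5
# and Lys+Arg counts.
synthetic_protein_catalog <- function() {
  p <- rbind(
    c("syn-asyn",          140, -9, 17, "natively_unfolded", TRUE),
    c("syn-gelsolin-frag",  71, -2,  8, "natively_unfolded", TRUE),
    c("syn-abeta",          42, -3,  3, "natively_unfolded", TRUE),
    c("syn-lc-vdomain",    110,  1, 12, "globular",          TRUE),
    c("syn-b2m",            99, -1, 10, "globular",          TRUE),
    c("syn-acp-model",      98,  2, 13, "globular",          FALSE))
  data.frame(protein = p[, 1], protein_length = as.integer(p[, 2]),
             protein_net_charge = as.numeric(p[, 3]),
             lys_arg_count = as.integer(p[, 4]),
             folding_status = p[, 5],
             disease_related = as.logical(p[, 6]), stringsAsFactors = FALSE)
}

#' Noise level for a target coefficient of determination
#'
#' Given the noiseless model signal over the sampled covariates, returns the
#' Gaussian noise standard deviation at which the population R-squared equals
#' `target_r2`: `noise_sd = sd(signal) * sqrt(1 / target_r2 - 1)`.
#'
#' @param signal Numeric vector of noiseless responses.
#' @param target_r2 Target R-squared in (0, 1).
#' @return The noise standard deviation.
#' @export
noise_for_target_r2 <- function(signal, target_r2) {
  if (!is.numeric(target_r2) || length(target_r2) != 1L ||
      target_r2 <= 0 || target_r2 >= 1)
    stop("target_r2 must lie strictly between 0 and 1")
  stats::sd(signal) * sqrt(1 / target_r2 - 1)
}

#' Generate a synthetic curated dataset
#'
#' Samples descriptor-complete entries with the covariate structure of the
#' curated literature database and a response following the linear-quadratic
#' acceleration model plus Gaussian noise. Defaults reflect the regime of
#' the literature data: sulfation states 0-3 weighted toward 2-3, solute
#' molarity uniform on 20-300 mM, protein:GAG molar ratio log-uniform on
#' 0.3-60 (most entries at high GAG excess, on the descending arm of the
#' quadratic). GAG and protein descriptors are drawn from small synthetic
#' catalogs; the half-time pair is back-filled as `t0 = 24 h`,
#' `tg = 24 * exp(-G) h`, so every schema invariant holds (G is invariant to
#' the arbitrary 24 h base).
#'
#' @param n Number of entries.
#' @param coefficients Generating model: a `gag_model` or a named vector of
#'   the five reference coefficients; default [published_gag_model()].
#' @param noise_sd Gaussian noise SD on G; if `NULL`, calibrated with
#'   [noise_for_target_r2()] on the sampled covariates.
#' @param target_r2 Target R-squared used when `noise_sd` is `NULL`
#'   (default 0.74).
#' @param ps_weights Sampling weights of the sulfation states `0:3`.
#' @param pb_range Solute molarity range, mM.
#' @param pmr_range Protein:GAG molar ratio range (log-uniform).
#' @param seed RNG seed (global RNG state restored on exit).
#' @return A validated entry data frame with `noise_sd` as an attribute.
#' @export
generate_gag_entries <- function(n = 39L,
                                 coefficients = published_gag_model(),
                                 noise_sd = NULL, target_r2 = 0.74,
                                 ps_weights = c(0.15, 0.15, 0.40, 0.30),
                                 pb_range = c(20, 300),
                                 pmr_range = c(0.3, 60),
                                 seed = NULL) {
  stopifnot(n >= 1L, length(ps_weights) == 4L, all(ps_weights >= 0),
            diff(pb_range) > 0, diff(pmr_range) > 0, all(pmr_range > 0))
  cf <- if (inherits(coefficients, "gag_model"))
    eq_coefficients(coefficients)
  else if (is.numeric(coefficients) && length(coefficients) == 5L)
    stats::setNames(coefficients, c("y0", "a", "b", "c", "c_prime"))
  else stop("coefficients must be a gag_model or a numeric vector of length 5")
  if (!is.null(noise_sd) && noise_sd < 0) stop("noise_sd must be >= 0")
  gags <- synthetic_gag_catalog()
  prots <- synthetic_protein_catalog()
  with_seed(seed, {
    ps_level <- sample(0:3, n, replace = TRUE, prob = ps_weights)
    gag_idx <- vapply(ps_level, function(l) {
      at <- which(gags$sulfates_per_disaccharide == l)
      at[sample.int(length(at), 1L)]
    }, integer(1))
    prot_idx <- sample.int(nrow(prots), n, replace = TRUE)
    pb <- stats::runif(n, pb_range[1], pb_range[2])
    pmr <- exp(stats::runif(n, log(pmr_range[1]), log(pmr_range[2])))
    ps <- gags$sulfates_per_disaccharide[gag_idx]
    signal <- cf[["y0"]] + cf[["a"]] * ps + cf[["b"]] * pb +
      cf[["c"]] * pmr + cf[["c_prime"]] * pmr^2
    if (is.null(noise_sd)) noise_sd <- noise_for_target_r2(signal, target_r2)
    G <- signal + stats::rnorm(n, 0, noise_sd)
    protein_conc <- exp(stats::runif(n, log(10), log(200)))
    entries <- cbind(
      prots[prot_idx, , drop = FALSE],
      gags[gag_idx, , drop = FALSE],
      data.frame(
        solute_molarity = pb,
        protein_conc = protein_conc,
        gag_conc = protein_conc / pmr,
        protein_gag_molar_ratio = pmr,
        pH = 7.4, temperature = 37,
        buffer = "synthetic phosphate buffer",
        t_half_no_gag = 24, t_half_with_gag = 24 * exp(-G),
        time_unit = "h", G = G, source = "synthetic",
        stringsAsFactors = FALSE))
    rownames(entries) <- NULL
    entries <- entries[, gag_table_schema()$column]
    probs <- validate_gag_entries(entries)
    if (nrow(probs)) stop("internal error: generated entries fail validation")
    attr(entries, "noise_sd") <- unname(noise_sd)
    entries
  })
}

#' Forward-simulate a kinetic trace
#'
#' Evaluates the exponential (no lag phase) or sigmoidal (lag phase) growth
#' model on evenly spaced times over `[0, 2 * t_half + 3 / k_agg]` and adds
#' i.i.d. Gaussian noise.
#'
#' @param A0,A_inf Signal at time 0 and at the plateau.
#' @param k_agg Positive apparent elongation rate constant, inverse time.
#' @param t_half Signal midpoint time; defaults to `2 / k_agg` for the
#'   exponential model.
#' @param model `"sigmoid"` or `"exponential"`.
#' @param n_points Number of points (>= 6).
#' @param noise_sd Gaussian noise SD, signal units.
#' @param seed RNG seed (global RNG state restored on exit).
#' @return A [kinetic_trace()].
#' @export
generate_trace <- function(A0, A_inf, k_agg, t_half = NULL,
                           model = c("sigmoid", "exponential"),
                           n_points = 50L, noise_sd = 0, seed = NULL) {
  model <- match.arg(model)
  if (k_agg <= 0) stop("k_agg must be positive")
  if (n_points < 6L) stop("at least 6 points are required")
  if (is.null(t_half)) t_half <- 2 / k_agg
  times <- seq(0, 2 * t_half + 3 / k_agg, length.out = n_points)
  signal <- if (model == "sigmoid")
    kin_sigmoid(times, A0, A_inf, k_agg, t_half)
  else kin_exponential(times, A0, A_inf, k_agg)
  with_seed(seed, {
    kinetic_trace(times, signal + stats::rnorm(n_points, 0, noise_sd))
  })
}
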