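# Shared helpers: the reference coefficient set, the design terms of the
# reference specification, an explicit normal-equations oracle, and the
# bundled synthetic fixture.

eq_truth <- c(y0 = 2.0, a = 0.30, b = -0.016, c = 0.11, c_prime = -0.0020)

reference_terms <- sort(c("sulfates_per_disaccharide", "solute_molarity",
                          "protein_gag_molar_ratio",
                          "I(protein_gag_molar_ratio^2)"))

# textbook normal equations: beta = (X'X)^{-1} X'y, SEs from the unbiased
# residual variance — independent of the package's QR path
normal_equations_oracle <- function(X, y) {
  xtx_inv <- solve(t(X) %*% X)
  beta <- drop(xtx_inv %*% t(X) %*% y)
  res <- y - drop(X %*% beta)
  sigma2 <- sum(res^2) / (nrow(X) - ncol(X))
  list(coefficients = beta, se = sqrt(diag(xtx_inv) * sigma2),
       residuals = res)
}

fixture_entries <- function() {
  path <- system.file("extdata", "table_s1_synthetic.tsv", package = "gagfib")
  read_gag_table(path)
}
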