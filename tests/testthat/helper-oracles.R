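# Independent oracles used across the test suite.  These deliberately do
# not share code paths with the package internals they check.

# exact isotopologue pattern by exhaustive enumeration over all per-atom
# isotope assignments; feasible for formulas with <= 8 atoms
oracle_pattern_enum <- function(formula, isotopes = isotope_table()) {
  if (is.character(formula)) formula <- parse_formula(formula)
  atoms <- character(0)
  for (el in names(formula))
    atoms <- c(atoms, rep(el, element_count(formula, el)))
  stopifnot(length(atoms) <= 8L)
  opts <- lapply(atoms, function(el) {
    e <- isotopes[[el]]
    list(shift = round(e$masses - e$masses[1]), prob = e$abundances)
  })
  grid <- do.call(expand.grid, lapply(opts, function(o) seq_along(o$shift)))
  maxshift <- sum(vapply(opts, function(o) max(o$shift), numeric(1)))
  out <- numeric(maxshift + 1L)
  for (i in seq_len(nrow(grid))) {
    s <- 0; p <- 1
    for (j in seq_along(opts)) {
      k <- grid[i, j]
      s <- s + opts[[j]]$shift[k]
      p <- p * opts[[j]]$prob[k]
    }
    out[s + 1L] <- out[s + 1L] + p
  }
  out
}

# polynomial product via outer() + degree collection: an independent
# convolution route (the package uses an in-place accumulation loop)
oracle_poly_mult <- function(a, b) {
  m <- outer(a, b)
  deg <- outer(seq_along(a) - 1L, seq_along(b) - 1L, "+")
  as.numeric(tapply(as.numeric(m), as.numeric(deg), sum))
}

# natural pattern of a formula by repeated polynomial expansion
oracle_pattern_poly <- function(formula, isotopes = isotope_table()) {
  if (is.character(formula)) formula <- parse_formula(formula)
  pat <- 1
  for (el in names(formula)) {
    e <- isotopes[[el]]
    shifts <- round(e$masses - e$masses[1])
    d <- numeric(max(shifts) + 1L)
    d[shifts + 1L] <- d[shifts + 1L] + e$abundances
    for (k in seq_len(element_count(formula, el)))
      pat <- oracle_poly_mult(pat, d)
  }
  pat
}

# correction-matrix column by polynomial expansion: j tracer-labeled
# positions at `purity`, n - j unlabeled labelable positions at natural
# 13C, all remaining atoms at natural abundance
oracle_matrix_column <- function(frag, j, purity, p_nat, n_obs) {
  n <- frag$n_labelable_carbons
  col <- 1
  if (j > 0)
    for (k in seq_len(j)) col <- oracle_poly_mult(col, c(1 - purity, purity))
  if (n - j > 0)
    for (k in seq_len(n - j)) col <- oracle_poly_mult(col, c(1 - p_nat, p_nat))
  cnt <- unclass(frag$formula)
  attributes(cnt) <- list(names = names(frag$formula))
  cnt["C"] <- cnt["C"] - n
  cnt <- cnt[cnt > 0]
  if (length(cnt)) {
    resid <- mol_formula(cnt)
    col <- oracle_poly_mult(col, oracle_pattern_poly(resid,
                                                     isotope_table(c13 = p_nat)))
  }
  if (length(col) < n_obs) col <- c(col, numeric(n_obs - length(col)))
  col[seq_len(n_obs)]
}

# pure logistic generator for kinetics tests
gen_logistic <- function(times, i_max, a, t_mid) {
  i_max / (1 + exp(-a * (times - t_mid)))
}

# permutation two-sample test oracle (difference of means)
oracle_perm_p <- function(x, y, n_perm = 4000, seed = 1) {
  obs <- abs(mean(x) - mean(y))
  z <- c(x, y)
  set.seed(seed)
  hits <- 0L
  for (i in seq_len(n_perm)) {
    idx <- sample(length(z), length(x))
    if (abs(mean(z[idx]) - mean(z[-idx])) >= obs - 1e-12) hits <- hits + 1L
  }
  hits / n_perm
}
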