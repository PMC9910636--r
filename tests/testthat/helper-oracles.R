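# Independent brute-force oracles used across tests.

# narrowest contiguous window of ceil(mass*n) sorted points, earliest on ties
hpdi_brute <- function(x, mass = 0.89) {
  n <- length(x)
  k <- ceiling(mass * n)
  s <- sort(x)
  if (k >= n) return(c(s[1], s[n]))
  best <- c(-Inf, Inf)
  for (i in seq_len(n - k + 1)) {
    lo <- s[i]; hi <- s[i + k - 1]
    if (hi - lo < best[2] - best[1]) best <- c(lo, hi)
  }
  best
}

# Cohen's kappa from an explicit contingency table
kappa_brute <- function(a, b) {
  lev <- sort(unique(c(a, b)))
  tab <- matrix(0, length(lev), length(lev), dimnames = list(lev, lev))
  for (i in seq_along(a)) {
    tab[as.character(a[i]), as.character(b[i])] <-
      tab[as.character(a[i]), as.character(b[i])] + 1
  }
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  (po - pe) / (1 - pe)
}

# uniform-colour run of one shape class
mono_run <- function(shape, color, n, builder = "x") {
  marble_run(rep(shape, n), rep(color, n), builder = builder)
}

# tiny roster without the generator, for exercising record-level functions
flat_roster <- function(n, positions = 5L) {
  g <- ceiling(n / positions)
  df <- data.frame(
    group_id = rep(sprintf("g%02d", seq_len(g)), each = positions)[1:n],
    community = "A", condition = "unobserved",
    position = rep(seq_len(positions), g)[1:n],
    age_years = 9, sex = "female", stringsAsFactors = FALSE
  )
  cbind(child_id = sprintf("%s_p%d", df$group_id, df$position), df,
        stringsAsFactors = FALSE)
}
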