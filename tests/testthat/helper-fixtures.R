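# Shared helpers: tiny populations built in code.

# A minimal valid population: n individuals in ceiling(n/2) pairs, with
# caller-supplied uc and schedule rows (matrix over levels 0..20, or a
# single vector recycled).
tiny_population <- function(n = 4, uc = 5, sched = 0:20,
                            zygosity = "MZ", dialect = "study2") {
  if (is.null(dim(sched))) sched <- matrix(sched, n, 21, byrow = TRUE)
  prof <- tibble::tibble(
    individual_id = sprintf("i%03d", seq_len(n)),
    pair_id = sprintf("p%03d", ceiling(seq_len(n) / 2)),
    zygosity = rep_len(zygosity, n),
    uc = as.integer(rep_len(uc, n))
  )
  for (k in 0:20) {
    prof[[paste0("c", k)]] <-
      if (dialect == "study1" && k == 0) NA_integer_ else as.integer(sched[, k + 1])
  }
  validate_population(prof, dialect = dialect)
}

# Brute-force mid-rank Spearman oracle (independent of the implementation).
brute_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  mean((rx - mean(rx)) * (ry - mean(ry))) / (stats::sd(rx) * stats::sd(ry)) *
    length(x) / (length(x) - 1)
}

# Brute-force double-entry Pearson ICC oracle.
brute_double_entry <- function(x1, x2) {
  a <- c(x1, x2); b <- c(x2, x1)
  sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
}

reduced_ace_spec <- function(iterations = 4000, burnin = 1000, thin = 5) {
  ace_model_spec(iterations = iterations, burnin = burnin, thin = thin)
}
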