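# Fixture builders: everything is generated in code at test time.

# Cohort from an explicit subjects-x-diseases matrix (NA = missing).
make_cohort <- function(m, cb = NULL, ex = NULL, names = NULL) {
  if (!is.matrix(m)) m <- as.matrix(m)
  if (!is.null(names)) colnames(m) <- names
  if (is.null(colnames(m))) colnames(m) <- LETTERS[seq_len(ncol(m))]
  n <- nrow(m)
  cohort_table(m, cb = cb %||% rep(0L, n), ex = ex %||% rep(0L, n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Cohort with independent Bernoulli(p) diseases.
random_cohort <- function(n, p, seed = 1, cb_frac = 0.5, ex_frac = 0.25) {
  set.seed(seed)
  K <- length(p)
  m <- vapply(p, function(pp) rbinom(n, 1L, pp), integer(n))
  colnames(m) <- sprintf("D%02d", seq_len(K))
  cohort_table(m, cb = rbinom(n, 1L, cb_frac), ex = rbinom(n, 1L, ex_frac))
}

# Write a small cohort CSV by hand (used by read_cohort tests).
write_fixture_csv <- function(lines, path = tempfile(fileext = ".csv")) {
  writeLines(lines, path)
  path
}

fixture_mapping <- function(diseases = c("AHT", "T2DM", "AF")) {
  list(subject = "id", cb = "cb", ex = "ex", diseases = diseases)
}

# Random non-degenerate 2x2 tables for oracle checks.
random_tables <- function(n_tables, seed = 1, max_count = 60) {
  set.seed(seed)
  out <- vector("list", n_tables)
  i <- 1L
  while (i <= n_tables) {
    cells <- rpois(4, lambda = runif(1, 2, max_count / 2))
    t <- two_by_two(cells[1], cells[2], cells[3], cells[4])
    margins <- c(cells[1] + cells[2], cells[3] + cells[4],
                 cells[1] + cells[3], cells[2] + cells[4])
    if (all(margins > 0)) { out[[i]] <- t; i <- i + 1L }
  }
  out
}

# Expand a 2x2 table into the two 0/1 vectors it summarises.
expand_table <- function(t) {
  list(x = rep(c(1, 1, 0, 0), c(t$n11, t$n10, t$n01, t$n00)),
       y = rep(c(1, 0, 1, 0), c(t$n11, t$n10, t$n01, t$n00)))
}
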