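# Shared fixtures, built in code at load time.

# small random pedigree with known structure, parents before offspring
random_pedigree <- function(n, seed = 1, p_parent = 0.8) {
  set.seed(seed)
  si <- di <- integer(n)
  for (i in 3:n) {
    if (runif(1) < p_parent) {
      si[i] <- sample(i - 1L, 1L)
      di[i] <- sample(i - 1L, 1L)
      if (di[i] == si[i]) di[i] <- 0L
    }
  }
  pedigree(data.frame(id = seq_len(n), sire = si, dam = di,
                      birth_year = 2000L + (seq_len(n) %/% 10L),
                      sex = rep_len(c("M", "F"), n)))
}

# dense tabular-method A, independent oracle for relationship computations
tabular_A <- function(si, di) {
  n <- length(si)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    if (i > 1L) {
      prev <- seq_len(i - 1L)
      v <- 0.5 * ((if (s > 0) A[prev, s] else 0) + (if (d > 0) A[prev, d] else 0))
      A[prev, i] <- v
      A[i, prev] <- v
    }
    A[i, i] <- 1 + (if (s > 0 && d > 0) 0.5 * A[s, d] else 0)
  }
  A
}

# compact simulated study used by several suites
small_study <- function(seed = 11, n_years = 8, n_per_year = 40,
                        n_technicians = 8, n_studs = 6, pheno_rate = 0.9) {
  cfg <- sim_config(n_founders = 60, n_years = n_years, n_per_year = n_per_year,
                    pheno_year_first = 4, pheno_rate = pheno_rate,
                    n_studs = n_studs, n_technicians = n_technicians, seed = seed)
  sim_gait_study(cfg)
}

write_ped_csv <- function(df) {
  f <- tempfile(fileext = ".csv")
  write.csv(df, f, row.names = FALSE)
  f
}
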