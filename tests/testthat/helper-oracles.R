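# Naive O(N^2) reference implementations of the template entropies, written
# as literal double loops over template pairs. These are the independent
# oracles the fast implementations are checked against; keep them dumb.

cheb_dist <- function(x, i, j, m) max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)]))

naive_apen <- function(x, m, r) {
  N <- length(x)
  phi <- function(mm) {
    n <- N - mm + 1
    total <- 0
    for (i in seq_len(n)) {
      cnt <- 0
      for (j in seq_len(n)) if (cheb_dist(x, i, j, mm) <= r) cnt <- cnt + 1
      total <- total + log(cnt / n)
    }
    total / n
  }
  phi(m) - phi(m + 1)
}

naive_saen <- function(x, m, r) {
  N <- length(x)
  n <- N - m
  count <- function(mm) {
    cnt <- 0
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (i != j && cheb_dist(x, i, j, mm) <= r) cnt <- cnt + 1
    cnt
  }
  -log(count(m + 1) / count(m))
}

naive_fuen <- function(x, m, r) {
  N <- length(x)
  phi <- function(mm) {
    n <- N - mm + 1
    cis <- numeric(n)
    for (i in seq_len(n)) {
      s <- 0
      for (j in seq_len(n)) {
        if (j == i) next
        d <- cheb_dist(x, i, j, mm)
        s <- s + exp(-log(2) * (d / r)^2)
      }
      cis[i] <- s / (n - 1)
    }
    mean(cis)
  }
  log(phi(m)) - log(phi(m + 1))
}

# Straight-line statement of the team decision principles, used as the
# exhaustive oracle for team_decide().
team_oracle <- function(referred, top, second, dt, elm) {
  if (!referred) return(list(label = top, principle = "I"))
  if (dt == top || elm == top) return(list(label = top, principle = "II"))
  if (dt == second || elm == second)
    return(list(label = second, principle = "III"))
  list(label = top, principle = "FALLBACK")
}
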