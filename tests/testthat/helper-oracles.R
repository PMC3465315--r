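# Independent oracle implementations used to cross-check the package code.
# These deliberately use different numerical routes (explicit normal
# equations, factorial arithmetic, dhyper enumeration) from the package.

`%||%` <- function(a, b) if (is.null(a)) b else a

# nested-model F-test via an explicit normal-equations solve
oracle_f_2df <- function(y, x, d, covars) {
  rss <- function(X) {
    b <- solve(t(X) %*% X, t(X) %*% y)
    sum((y - X %*% b)^2)
  }
  Xf <- cbind(1, x, d, x * d, as.matrix(covars))
  Xr <- cbind(1, d, as.matrix(covars))
  n <- length(y)
  f <- ((rss(Xr) - rss(Xf)) / 2) / (rss(Xf) / (n - ncol(Xf)))
  list(f = f, p = pf(f, 2, n - ncol(Xf), lower.tail = FALSE))
}

# Hardy-Weinberg exact test by direct factorial enumeration (n <= ~80)
oracle_hwe <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  na <- 2 * naa + nAa
  na <- min(na, 2 * n - na)
  if (na == 0) return(1)
  hets <- seq(na %% 2, na, by = 2)
  pr <- vapply(hets, function(h) {
    homa <- (na - h) / 2
    homA <- n - h - homa
    factorial(n) / (factorial(homA) * factorial(h) * factorial(homa)) * 2^h
  }, numeric(1))
  pr <- pr / sum(pr)
  pobs <- pr[hets == nAa]
  min(1, sum(pr[pr <= pobs * (1 + 1e-12)]))
}

# two-sided Fisher exact p for a 2x2 table via dhyper enumeration
oracle_fisher <- function(tab) {
  m <- sum(tab[, 1])           # column-1 total
  n2 <- sum(tab[, 2])
  k <- sum(tab[1, ])           # row-1 total
  xs <- max(0, k - n2):min(k, m)
  pr <- dhyper(xs, m, n2, k)
  pobs <- dhyper(tab[1, 1], m, n2, k)
  sum(pr[pr <= pobs * (1 + 1e-7)])
}

# Meff by definition: eigendecomposition + cumulative variance scan
oracle_meff <- function(R, C = 0.995) {
  ev <- pmax(eigen(R, symmetric = TRUE, only.values = TRUE)$values, 0)
  which(cumsum(ev) / sum(ev) >= C - 1e-12)[1]
}

# AR(1) correlation matrix
ar1_matrix <- function(m, rho) rho^abs(outer(seq_len(m), seq_len(m), `-`))
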