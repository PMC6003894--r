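# Independent oracles: deliberately different algorithms from the package
# implementations they check.

# flood fill by fixpoint iteration of masked 26-neighborhood dilation
# (the package uses a frontier BFS)
floodFillOracle <- function(above, seedLin) {
  d <- dim(above)
  cur <- array(FALSE, d)
  cur[seedLin] <- TRUE
  shift1 <- function(a, ax, k) {
    out <- array(FALSE, d)
    idxS <- lapply(d, seq_len)
    idxT <- idxS
    if (k == 1) {
      idxT[[ax]] <- 2:d[ax]; idxS[[ax]] <- 1:(d[ax] - 1)
    } else if (k == -1) {
      idxT[[ax]] <- 1:(d[ax] - 1); idxS[[ax]] <- 2:d[ax]
    }
    out <- do.call(`[<-`, c(list(out), idxT,
                            list(do.call(`[`, c(list(a), idxS)))))
    out
  }
  offs <- expand.grid(-1:1, -1:1, -1:1)
  offs <- offs[rowSums(abs(offs)) > 0, ]
  repeat {
    grown <- cur
    for (i in seq_len(nrow(offs))) {
      s <- cur
      for (ax in 1:3) if (offs[i, ax] != 0) s <- shift1(s, ax, offs[i, ax])
      grown <- grown | s
    }
    nxt <- (grown & above) | cur
    if (identical(nxt, cur)) break
    cur <- nxt
  }
  cur
}

# exact two-sided Mann-Whitney p by complete enumeration of group labelings,
# using the same two-sided tail-doubling convention as wilcox.test
enumMannWhitneyP <- function(a, b) {
  nA <- length(a); nB <- length(b)
  pool <- c(a, b)
  comb <- utils::combn(nA + nB, nA)
  uObs <- sum(outer(a, b, `>`))
  uAll <- apply(comb, 2, function(ix)
    sum(outer(pool[ix], pool[-ix], `>`)))
  pLe <- mean(uAll <= uObs)
  pGe <- mean(uAll >= uObs)
  min(1, 2 * min(pLe, pGe))
}

# direct maximization of the exact Breslow partial log-likelihood for a
# binary covariate (golden-section search via optimize)
coxBruteForceBeta <- function(time, event, x) {
  logPL <- function(beta) {
    s <- 0
    for (i in which(event)) {
      atRisk <- time >= time[i]
      s <- s + beta * x[i] - log(sum(exp(beta * x[atRisk])))
    }
    s
  }
  stats::optimize(logPL, c(-8, 8), maximum = TRUE, tol = 1e-10)$maximum
}

# two-sided t-test p by numeric quadrature of the t density
tQuadratureP <- function(tstat, df) {
  2 * stats::integrate(function(x) stats::dt(x, df), abs(tstat), Inf,
                       rel.tol = 1e-12)$value
}

# Kaplan-Meier by direct counting when all subjects fail at distinct times
kmCountingOracle <- function(n, k) (n - k) / n
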