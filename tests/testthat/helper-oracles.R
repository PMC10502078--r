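# independent oracles and small fixture builders used across the suite

# closed-form normal-equations OLS: b = (X'X)^-1 X'y, classical SEs
olsOracle <- function(y, X) {
  XtX <- crossprod(X)
  b <- solve(XtX, crossprod(X, y))
  res <- y - X %*% b
  dfres <- nrow(X) - ncol(X)
  sigma2 <- sum(res^2) / dfres
  se <- unname(sqrt(sigma2 * diag(solve(XtX))))
  list(b = as.vector(b), se = se, df = dfres)
}

# brute-force double-loop risk score (deliberately naive)
bruteScore <- function(d, w, scheme) {
  n <- nrow(d)
  out <- numeric(n)
  nonmiss <- integer(n)
  for (i in seq_len(n)) {
    s <- 0
    k <- 0L
    for (j in seq_len(ncol(d))) {
      if (!is.na(d[i, j])) {
        s <- s + w[j] * d[i, j]
        k <- k + 1L
      }
    }
    out[i] <- if (scheme == "unweighted") s else s / k
    nonmiss[i] <- k
  }
  list(values = out, nonmiss = nonmiss)
}

# small ad-hoc panel
makePanel <- function(n_snp, beta = NULL) {
  if (is.null(beta)) beta <- seq(0.05, 0.4, length.out = n_snp)
  new("SNPPanel",
    rsid = sprintf("rs%03d", seq_len(n_snp)),
    riskAllele = rep(c("A", "G", "C", "T"), length.out = n_snp),
    otherAllele = rep(c("G", "A", "T", "C"), length.out = n_snp),
    betaSpeliotes = beta,
    betaFinhit = rev(beta),
    gene = sprintf("GENE%d", seq_len(n_snp))
  )
}

makeGenotypes <- function(d) {
  if (is.null(rownames(d))) rownames(d) <- sprintf("id%04d", seq_len(nrow(d)))
  new("GenotypeMatrix", dosage = d)
}
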