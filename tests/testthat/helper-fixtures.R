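## Shared fixtures and independent oracles for the test suite.

refTruths <- abh2RefParams()

## Independent oracle for the equilibrium complex concentration: numeric
## root of Kd = (E0 - x)(S0 - x)/x on (0, min(E0, S0)).
esOracle <- function(E0, S0, Kd) {
  f <- function(x) (E0 - x) * (S0 - x) / x - Kd
  stats::uniroot(f, c(1e-14, min(E0, S0) * (1 - 1e-12)), tol = 1e-14)$root
}

## Independent all-pairs minimum-distance oracle (plain double loop).
minDistOracle <- function(A, B) {
  best <- Inf
  for (i in seq_len(nrow(A)))
    for (j in seq_len(nrow(B)))
      best <- min(best, sqrt(sum((A[i, ] - B[j, ])^2)))
  best
}

## Build a StructureModel directly from a minimal atom table.
makeModel <- function(df, lesionCodes = "1MA") {
  defaults <- data.frame(type = "ATOM", eleno = seq_len(nrow(df)))
  df <- cbind(defaults[setdiff(names(defaults), names(df))], df)
  df$isLesion <- df$resid %in% lesionCodes
  new("StructureModel", atoms = df, source = "in-memory",
      lesionCodes = lesionCodes)
}

## Apply a random rigid-body motion (rotation + translation) to a model.
rigidTransform <- function(model, seed) {
  set.seed(seed)
  M <- matrix(rnorm(9), 3, 3)
  Q <- qr.Q(qr(M))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  shift <- rnorm(3, 0, 10)
  a <- atoms(model)
  xyz <- as.matrix(a[, c("x", "y", "z")]) %*% t(Q)
  a$x <- xyz[, 1] + shift[1]
  a$y <- xyz[, 2] + shift[2]
  a$z <- xyz[, 3] + shift[3]
  out <- model
  out@atoms <- a
  out
}

## Heavy side-chain/base coordinate blocks for the oracle comparisons.
selXYZ <- function(model, sel, scope = "side_chain") {
  r <- ABH2kinetics:::.selectAtoms(model, sel, scope)
  as.matrix(r[, c("x", "y", "z")])
}
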