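## Shared test fixtures: synthetic parameter sets and seeded sequence suites.

## A minimal, fully synthetic parameter bundle with uniform tables, handy for
## closed-form checks.  All stacks equal `stackVal`, all loop energies equal
## their respective constants, no terminal penalty, no tetraloop bonuses.
makeFlatParams <- function(stackVal = -1, hairpinVal = 4, bulgeVal = 3,
                           internalVal = 3, mlA = 3, mlB = 0.4, mlC = 0.1,
                           dH = 0) {
  hp <- rep(hairpinVal, 30); hp[1:2] <- NA
  il <- rep(internalVal, 30); il[1] <- NA
  new("EnergyParams", name = "flat",
      stackDG = matrix(stackVal, 6, 6, dimnames = list(pairTypes(), pairTypes())),
      stackDH = matrix(dH, 6, 6, dimnames = list(pairTypes(), pairTypes())),
      hairpinDG = hp, hairpinDH = ifelse(is.na(hp), NA, dH),
      bulgeDG = rep(bulgeVal, 30), bulgeDH = rep(dH, 30),
      internalDG = il, internalDH = ifelse(is.na(il), NA, dH),
      multiloop = c(a = mlA, b = mlB, c = mlC, a_dH = dH, b_dH = dH, c_dH = dH),
      terminalNonGC = c(dG37 = 0, dH = 0),
      lxc = 1.07856,
      tetraloopDG = numeric(0), tetraloopDH = numeric(0))
}

## all-zero energies: the partition function equals the structure count
makeZeroParams <- function() {
  makeFlatParams(stackVal = 0, hairpinVal = 0, bulgeVal = 0, internalVal = 0,
                 mlA = 0, mlB = 0, mlC = 0)
}

randomRNA <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

pairKey <- function(p) if (nrow(p)) paste(p[, 1], p[, 2]) else character(0)

## a seeded suite of random sequences reused across oracle tests
oracleSuite <- function(m = 60, minLen = 5, maxLen = 16, seed = 2024) {
  set.seed(seed)
  vapply(seq_len(m), function(i) randomRNA(sample(minLen:maxLen, 1)),
         character(1))
}
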