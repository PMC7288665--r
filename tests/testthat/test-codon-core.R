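# Codon alphabet, substitution classification, frequency estimation and
# the GY94 rate matrix.

test_that("the standard code has 61 sense codons and total translation", {
  code <- standardGeneticCode()
  expect_length(senseCodons(code), 61L)
  expect_length(code@codonToAa, 64L)
  expect_false(anyNA(code@codonToAa))
  expect_setequal(setdiff(names(code@codonToAa), senseCodons(code)),
                  c("TAA", "TAG", "TGA"))
})

test_that("classifySubstitution matches stated examples", {
  expect_identical(classifySubstitution("TTT", "TTC"),
                   "synonymous-transition")
  expect_identical(classifySubstitution("TTT", "GGT"), "multi-step")
  # T<->C at position 2 is a transition, Met -> Thr is nonsynonymous
  expect_identical(classifySubstitution("ATG", "ACG"),
                   "nonsynonymous-transition")
  expect_error(classifySubstitution("TAA", "TAT"), "stop")
  expect_error(classifySubstitution("AAA", "AAA"), "identical")
})

test_that("classification agrees with a brute-force oracle on all pairs
          and is symmetric", {
  codons <- senseCodons()
  set.seed(7)
  # enumerate all 61*60 ordered pairs against the oracle
  pairs <- expand.grid(ci = codons, cj = codons,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$ci != pairs$cj, ]
  got <- mapply(classifySubstitution, pairs$ci, pairs$cj)
  want <- mapply(oracleClassify, pairs$ci, pairs$cj)
  expect_identical(unname(got), unname(want))
  # symmetry spot checks
  for (k in 1:20) {
    pair <- sample(codons, 2)
    expect_identical(classifySubstitution(pair[1], pair[2]),
                     classifySubstitution(pair[2], pair[1]))
  }
})

test_that("codon frequency estimators behave as specified", {
  expect_error(codonFrequencies(rep(1, 60)), "sense codon")
  aln <- codonAlignment(c(a = "AAAAAC", b = "AAAAAG"), "toy")
  eq <- estimateCodonFrequencies(aln, "equal")
  expect_equal(unname(eq@pi), rep(1 / 61, 61))
  expect_equal(sum(eq@pi), 1, tolerance = 1e-13)

  # F3x4 on the toy alignment vs hand-computed position frequencies
  # codons observed: AAA, AAC / AAA, AAG
  # pos1: 4xA; pos2: 4xA; pos3: 2xA, 1xC, 1xG  (+1 pseudocount per cell)
  f1 <- (c(A = 4, C = 0, G = 0, T = 0) + 1) / 8
  f3 <- (c(A = 2, C = 1, G = 1, T = 0) + 1) / 8
  pf <- estimateCodonFrequencies(aln, "F3x4")
  codons <- senseCodons()
  raw <- f1[substr(codons, 1, 1)] * f1[substr(codons, 2, 2)] *
    f3[substr(codons, 3, 3)]
  expect_equal(unname(pf@pi), unname(raw / sum(raw)), tolerance = 1e-12)
  expect_true(all(pf@pi > 0))

  # uniform composition at every position -> 1/61 after renormalisation
  aln2 <- codonAlignment(c(a = "ACGTACGTACGT", b = "CATGCATGCATG"),
                         "uni")
  pu <- estimateCodonFrequencies(aln2, "F3x4")
  expect_equal(unname(pu@pi), rep(1 / 61, 61), tolerance = 1e-12)

  expect_error(estimateCodonFrequencies(
    codonAlignment(setNames(character(0), character(0))), "F3x4"))
})

test_that("the rate matrix satisfies its structural invariants", {
  set.seed(11)
  for (rep in 1:5) {
    kappa <- runif(1, 0.5, 6); omega <- runif(1, 0, 3)
    pi <- codonFrequencies(runif(61, 0.2, 2))
    q <- buildRateMatrix(kappa, omega, pi)
    expect_lt(max(abs(rowSums(q@q))), 1e-10)
    off <- q@q; diag(off) <- 0
    expect_true(all(off >= 0))
    # detailed balance (time reversibility)
    flux <- pi@pi * q@q
    expect_lt(max(abs(flux - t(flux))), 1e-12)
    # scaled: mean equilibrium rate 1
    expect_equal(-sum(pi@pi * diag(q@q)), 1, tolerance = 1e-10)
  }
})

test_that("rate matrix zeroes and ratios follow the GY94 rules", {
  pi <- codonFrequencies(rep(1, 61))
  codons <- senseCodons()
  q0 <- buildRateMatrix(2, 0, pi)@q
  # omega = 0 -> all nonsynonymous rates are 0
  aa <- translateCodon(codons)
  for (i in seq_along(codons)) {
    nz <- which(q0[i, ] > 0)
    expect_true(all(aa[nz] == aa[i]))
  }
  # single-step zero structure: two-position changes have rate 0
  chars <- do.call(rbind, strsplit(codons, ""))
  q <- buildRateMatrix(2, 0.5, pi, scale = FALSE)@q
  for (i in sample(seq_along(codons), 10)) {
    nd <- rowSums(chars != matrix(chars[i, ], 61, 3, byrow = TRUE))
    expect_true(all(q[i, nd >= 2] == 0))
  }
  # (TTT->TTC) / (TTT->TTA) = kappa / omega before scaling
  # (syn transition vs nonsyn transversion, Phe/Phe vs Phe/Leu)
  expect_equal(q["TTT", "TTC"] / q["TTT", "TTA"], 2 / 0.5,
               tolerance = 1e-12)
  # kappa=1, omega=1, equal pi: all single-step rates equal
  q1 <- buildRateMatrix(1, 1, pi)@q
  offs <- q1[q1 > 0]
  expect_lt(diff(range(offs)), 1e-12)
  expect_error(buildRateMatrix(0, 0.5, pi), "kappa")
  expect_error(buildRateMatrix(2, -1, pi), "omega")
})

test_that("transition matrices are stochastic and satisfy the
          semigroup and stationarity properties", {
  set.seed(3)
  pi <- codonFrequencies(runif(61, 0.3, 2))
  q <- buildRateMatrix(2.4, 0.6, pi)
  expect_equal(transitionMatrix(q, 0), diag(61), tolerance = 1e-12,
               ignore_attr = TRUE)
  p <- transitionMatrix(q, 0.3)
  expect_lt(max(abs(rowSums(p) - 1)), 1e-8)
  expect_true(all(p >= 0 & p <= 1 + 1e-12))
  # agreement with an independent dense exponential
  pex <- as.matrix(Matrix::expm(q@q * 0.3))
  expect_lt(max(abs(p - pex)), 1e-10)
  # Chapman-Kolmogorov for random s, t
  for (k in 1:3) {
    s <- runif(1, 0, 2); t <- runif(1, 0, 2)
    expect_lt(max(abs(transitionMatrix(q, s) %*% transitionMatrix(q, t) -
                        transitionMatrix(q, s + t))), 1e-8)
  }
  # stationarity: pi' P(t) = pi'
  expect_lt(max(abs(pi@pi %*% p - pi@pi)), 1e-8)
  # ergodicity: rows approach pi for large t
  plarge <- transitionMatrix(q, 500)
  expect_lt(max(abs(sweep(plarge, 2, pi@pi))), 1e-6)
  expect_error(transitionMatrix(q, -0.1), "non-negative")
})

test_that("the eigendecomposition exponential reproduces a 2-state
          closed form", {
  # reversible 2-state chain: closed-form P(t) known exactly
  a <- 0.3; b <- 0.7   # rates; pi = (b, a)/(a+b)
  Q <- matrix(c(-a, a, b, -b), 2, 2, byrow = TRUE)
  piv <- c(b, a) / (a + b)
  eg <- PSGscan:::.rateMatrixEigen(Q, piv)
  t <- 0.1
  P <- eg$Vh %*% (exp(eg$lam * t) * eg$W)
  lam <- a + b
  Pexact <- rbind(
    c(b / lam + a / lam * exp(-lam * t), a / lam - a / lam * exp(-lam * t)),
    c(b / lam - b / lam * exp(-lam * t), a / lam + b / lam * exp(-lam * t)))
  expect_equal(P, Pexact, tolerance = 1e-12, ignore_attr = TRUE)
})
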