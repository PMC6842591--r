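test_that("model parameters validate their constraints", {
  expect_error(model_params(kappa = -1), "kappa")
  expect_error(model_params(h = c(WRC = -1)), "exceed -1")
  expect_error(model_params(h = c(BAD = 1)), "named with motif names")
  p <- model_params(h = c(GYW = 6))
  expect_identical(unname(p$h["GYW"]), 6)
  expect_identical(unname(p$h["WRC"]), 0)
  expect_equal(sum(p$pi), 1, tolerance = 1e-12)
})

test_that("mean-field context matches within-codon determinism and the
           flank-enumeration oracle", {
  e <- mean_field_context(uniform_pi())
  # fully within-codon occurrences are exact 0/1
  expect_identical(e["TAC", 3, "WRC"], 1)   # T=W, A=R, C target
  expect_identical(e["GCA", 1, "GYW"], 1)   # G target, C=Y, A=W
  expect_identical(e["GGG", 3, "WRC"], 0)
  # one flanking base marginalized: WA at position 1 of ACC needs a W left
  # flank; enumerating the 61 codons' third bases gives 30/61
  expect_equal(e["ACC", 1, "WA"], 30 / 61, tolerance = 1e-12)
  # spot-check a sample of entries against full flank enumeration
  set.seed(3)
  pi <- {x <- rgamma(61, 1); x / sum(x)}
  e2 <- mean_field_context(pi)
  m <- shm_motifs()
  cs <- codon_space()
  for (k in 1:12) {
    a <- sample(61, 1); p <- sample(3, 1); i <- sample(6, 1)
    expect_equal(
      e2[a, p, m$name[i]],
      oracle_context_prob(cs$codons[a], p, m$pattern[i], m$target_offset[i],
                          pi),
      tolerance = 1e-12, info = paste(cs$codons[a], p, m$name[i]))
  }
  expect_true(all(e2 >= 0 & e2 <= 1))
})

test_that("HLP19 rates follow kappa, omega and the motif factor", {
  # all-neutral parameters: every permitted off-diagonal entry equal
  p0 <- model_params(kappa = 1, omega_fwr = 1, omega_cdr = 1)
  q0 <- build_q_hlp19(p0, "FWR")$q
  off <- q0[q0 != 0 & row(q0) != col(q0)]
  expect_true(max(abs(off - off[1])) < 1e-12)

  # a cold spot with deterministic context scales its entry by 1 + h = 0.4
  pc <- model_params(kappa = 1, omega_fwr = 1, omega_cdr = 1,
                     h = c(SYC = -0.6))
  e <- mean_field_context(uniform_pi())
  qc <- build_q_hlp19(pc, "FWR")
  # GCC -> GCA: third-position C is a within-codon SYC target (G=S, C=Y, C);
  # the unnormalized h = 0 entry is 1 (transversion, synonymous Ala), so the
  # cold spot scales it to 1 + h = 0.4
  cs <- codon_space()
  i <- cs$index[["GCC"]]; j <- cs$index[["GCA"]]
  expect_identical(e["GCC", 3, "SYC"], 1)
  expect_equal(qc$q[i, j] * qc$scale, 0.4, tolerance = 1e-12)
})

test_that("HLP19 and HLP17 match the element-wise brute-force oracle", {
  p <- model_params(kappa = 2, omega_fwr = 0.5, omega_cdr = 0.5,
                    h = c(GYW = 6))
  cs <- codon_space()
  q19 <- build_q_hlp19(p, "FWR")
  q17 <- build_q_hlp17(p, "FWR")
  set.seed(11)
  pairs <- cs$subs[sample(nrow(cs$subs), 25), ]
  for (r in seq_len(nrow(pairs))) {
    a <- cs$codons[pairs$a[r]]; b <- cs$codons[pairs$b[r]]
    expect_equal(q19$q[a, b] * q19$scale,
                 oracle_q_entry(a, b, p, p$pi, pi_b_factor = FALSE),
                 tolerance = 1e-10, info = paste("HLP19", a, b))
    expect_equal(q17$q[a, b] * q17$scale,
                 oracle_q_entry(a, b, p, p$pi, pi_b_factor = TRUE),
                 tolerance = 1e-10, info = paste("HLP17", a, b))
  }
  # multi-nucleotide differences carry rate zero
  expect_identical(q19$q[cs$index[["AAA"]], cs$index[["ACC"]]], 0)
})

test_that("GY94 has the pi_b kappa structure and is stationary", {
  pi <- {set.seed(5); x <- rgamma(61, 2); x / sum(x)}
  p <- model_params(kappa = 2, omega_fwr = 0.5, omega_cdr = 0.5, pi = pi)
  g <- build_q_gy94(p, "FWR")
  cs <- codon_space()
  # transition entries are exactly kappa x matched transversions sharing
  # pi_b and synonymy: AAA->AAG (ts, syn, pi_AAG) vs AAA->AAT (tv, syn? AAT
  # is Asn, AAA Lys -> nonsyn). Use CTT->CTC (ts, syn) vs CTT->CTA (tv, syn)
  i <- cs$index[["CTT"]]
  expect_equal(g$q[i, cs$index[["CTC"]]] / g$q[i, cs$index[["CTA"]]],
               2 * pi[cs$index[["CTC"]]] / pi[cs$index[["CTA"]]],
               tolerance = 1e-12)
  expect_lt(max(abs(pi %*% g$q)), 1e-10)
  # HLP17 with h = 0 equals GY94 entry-wise
  h17 <- build_q_hlp17(p, "FWR")
  expect_lt(max(abs(h17$q - g$q)), 1e-12)
})

test_that("rate-matrix invariants hold over random parameter draws", {
  set.seed(99)
  for (k in 1:40) {
    p <- random_params()
    region <- sample(c("FWR", "CDR"), 1)
    rm <- switch(sample(c("hlp19", "gy94", "hlp17"), 1),
                 hlp19 = build_q_hlp19(p, region),
                 gy94 = build_q_gy94(p, region),
                 hlp17 = build_q_hlp17(p, region))
    q <- rm$q
    expect_true(all(q[row(q) != col(q)] >= 0))
    expect_lt(max(abs(rowSums(q))), 1e-10)
    expect_equal(-sum(rm$pi_bar * diag(q)), 1, tolerance = 1e-8)
  }
})

test_that("transition probabilities are stochastic and semigroup-consistent", {
  p <- ref_params()
  rm <- build_q_hlp19(p, "CDR")
  expect_error(transition_probabilities(rm, -0.1), "nonnegative")
  P0 <- transition_probabilities(rm, 0)
  expect_lt(max(abs(P0 - diag(61))), 1e-12)
  P1 <- transition_probabilities(rm, 0.07)
  expect_lt(max(abs(rowSums(P1) - 1)), 1e-10)
  expect_true(all(P1 >= 0 & P1 <= 1))
  P2 <- transition_probabilities(rm, 0.14)
  expect_lt(max(abs(P1 %*% P1 - P2)), 1e-8)
  # GY94 rows approach pi at large t (stationarity oracle)
  g <- build_q_gy94(model_params(kappa = 2, omega_fwr = 0.6,
                                 omega_cdr = 0.6), "FWR")
  Pinf <- transition_probabilities(g, 60)
  expect_lt(max(abs(sweep(Pinf, 2, uniform_pi()))), 1e-6)
})

test_that("midpoint frequency prediction has the right limits", {
  p <- ref_params()
  g <- empirical_codon_freqs("AAATTTCCC")
  expect_equal(unname(predict_midpoint_frequencies(g, 0, p)), unname(g))
  # neutral symmetric chain converges to uniform at large divergence
  p0 <- model_params(kappa = 1, omega_fwr = 1, omega_cdr = 1)
  far <- predict_midpoint_frequencies(g, 400, p0)
  expect_lt(max(abs(far - 1 / 61)), 1e-4)
  # fixed small case against direct expm propagation
  cs <- codon_space()
  g2 <- stats::setNames(rep(0, 61), cs$codons); g2[["AAA"]] <- 1
  p2 <- model_params(kappa = 2, omega_fwr = 1, omega_cdr = 1)
  got <- predict_midpoint_frequencies(g2, 0.1, p2)
  # oracle: same fixed point iterated independently with Matrix::expm
  cur <- g2
  for (it in 1:100) {
    rm <- build_q_hlp19(p2, "FWR", pi_bar = cur)
    nxt <- as.numeric(g2 %*% as.matrix(Matrix::expm(rm$q * 0.05)))
    nxt <- nxt / sum(nxt)
    if (max(abs(nxt - cur)) < 1e-8) break
    cur <- nxt
  }
  expect_equal(unname(got), cur, tolerance = 1e-6)
})

test_that("rate matrices serialize to readable TSV", {
  rm <- build_q_gy94(model_params(), "FWR")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_rate_matrix(rm, f)
  back <- utils::read.table(f, header = TRUE, sep = "\t", check.names = FALSE)
  expect_identical(back$codon, codon_space()$codons)
  expect_equal(as.matrix(back[, -1]), unname(rm$q), tolerance = 1e-12,
               ignore_attr = TRUE)
})
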