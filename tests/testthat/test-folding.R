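test_that("fold_energy scores hairpins by the hand-summed decomposition", {
  p <- PARAMS_PZ
  # 4-bp G-C stem with a T4 loop: 3 stacks + hairpin(4) + first mismatch +
  # exterior terms are absent (helix spans the whole sequence)
  s <- "GGGGTTTTCCCC"
  st <- dotbracket_to_structure("((((....))))")
  by_hand <- 3 * stack_dG37(p, "GG/CC") +
    p$loops$hp_init[4] + p$loops$tmm["G", "C", "T", "T"]
  expect_equal(fold_energy(s, st, p), by_hand)
  # empty structure is the reference state
  expect_equal(fold_energy(s, sec_structure(12), p), 0)
  # swapping the G-C helix for P-Z changes exactly the stack terms
  s2 <- "PPPPTTTTZZZZ"
  by_hand2 <- 3 * stack_dG37(p, "PP/ZZ") +
    p$loops$hp_init[4] + p$loops$tmm["P", "Z", "T", "T"]
  expect_equal(fold_energy(s2, st, p), by_hand2)
})

test_that("disallowed pairs in a structure are rejected by position", {
  p <- PARAMS_PZ
  expect_error(fold_energy("GGGGTTTTCCCA", dotbracket_to_structure("((((....))))"), p),
               "\\(1,12\\)")
})

test_that("partition function, probabilities, NED and MFE match exhaustive enumeration", {
  # spot-check here (the acceptance suite runs the 100-sequence campaign)
  set.seed(303)
  for (rep in 1:8) {
    par <- if (rep %% 2 == 0) PARAMS_PZ else PARAMS_DNA
    alph <- if (rep %% 2 == 0) c("A", "C", "G", "T", "P", "Z")
            else c("A", "C", "G", "T")
    s <- random_pz_string(sample(6:12, 1), alph)
    bf <- brute_force_fold(s, par)
    pf <- partition_function(s, par)
    mf <- mfe_structure(s, par)
    expect_equal(pf$Q, bf$Q, tolerance = 1e-9)
    expect_lt(max(abs(pf$p - bf$p)), 1e-9)
    expect_equal(mf$energy, bf$mfe_energy, tolerance = 1e-9)
    expect_equal(fold_energy(s, mf$structure, par), bf$mfe_energy,
                 tolerance = 1e-9)
    # probability conservation
    expect_lt(max(abs(rowSums(pf$p) + pf$q - 1)), 1e-9)
  }
})

test_that("unpairable sequences give Q = 1, empty MFE, all-unpaired probabilities", {
  p <- PARAMS_PZ
  pf <- partition_function("AAAAA", p)
  expect_equal(pf$Q, 1)
  expect_true(all(pf$p == 0))
  expect_equal(pf$q, rep(1, 5))
  mf <- mfe_structure("AAAAA", p)
  expect_equal(mf$energy, 0)
  expect_equal(nrow(mf$structure$pairs), 0)
})

test_that("a strong P-Z stem hairpin folds with high stem pair probabilities", {
  p <- PARAMS_PZ
  pf <- partition_function("PPPPPPTTTTZZZZZZ", p)
  stem <- vapply(1:6, function(i) pf$p[i, 17 - i], numeric(1))
  expect_gt(min(stem), 0.85)
  expect_gt(stats::median(stem), 0.9)
})

test_that("NED matches the defect definition and brute-force ensemble average", {
  p <- PARAMS_PZ
  s <- "GGGACTTTCGTCC"
  target <- mfe_structure(s, p)$structure
  pf <- partition_function(s, p)
  r <- ned(s, target, pf)
  # direct recomputation from the probability matrix
  P_i <- vapply(seq_len(13), function(i) {
    if (target$pt[i] > 0) pf$p[i, target$pt[i]] else pf$q[i]
  }, numeric(1))
  expect_equal(r$ned, mean(1 - P_i))
  # brute-force ensemble average of the per-structure defect
  bf <- brute_force_fold(s, p)
  structs <- enumerate_structures(s, p$mode)
  w <- vapply(structs, function(prs) {
    exp(-fold_energy(s, sec_structure(13, prs), p) / (1.987e-3 * 310.15))
  }, numeric(1))
  defect <- vapply(structs, function(prs) {
    pt <- sec_structure(13, prs)$pt
    mean(vapply(seq_len(13), function(i) {
      if (target$pt[i] > 0) pt[i] != target$pt[i] else pt[i] != 0
    }, logical(1)))
  }, numeric(1))
  expect_equal(r$ned, sum(w * defect) / sum(w), tolerance = 1e-9)
  # perfect-probability and uniform cases
  expect_error(ned("ACGT", sec_structure(5), params = p), "length")
})

test_that("appending an unpairable 3' base changes Q only through dangle terms", {
  p <- PARAMS_PZ
  s <- "GGGGTTTTCCCC"
  bf1 <- brute_force_fold(s, p)
  bf2 <- brute_force_fold(paste0(s, "A"), p)
  pf2 <- partition_function(paste0(s, "A"), p)
  expect_equal(pf2$Q, bf2$Q, tolerance = 1e-9)
  expect_false(isTRUE(all.equal(bf1$Q, bf2$Q)))  # dangles shift the ensemble
})

test_that("canonical-only sequences fold identically under both alphabets", {
  set.seed(77)
  for (k in 1:5) {
    s <- random_pz_string(sample(8:13, 1), c("A", "C", "G", "T"))
    pf1 <- partition_function(s, PARAMS_PZ)
    pf2 <- partition_function(s, PARAMS_DNA)
    expect_equal(pf1$Q, pf2$Q)
    expect_equal(pf1$p, pf2$p)
  }
})

test_that("MFE energy is a lower bound over valid targets", {
  p <- PARAMS_PZ
  s <- "GGGACGTTTCGTCCC"
  mf <- mfe_structure(s, p)
  structs <- enumerate_structures(s, p$mode)
  for (prs in structs[seq(1, length(structs), length.out = 25)]) {
    expect_lte(mf$energy,
               fold_energy(s, sec_structure(15, prs), p) + 1e-12)
  }
})

test_that("folding away from the 310.15 K reference is refused", {
  expect_error(partition_function("GGGGTTTTCCCC", PARAMS_PZ, T = 300),
               "310.15")
})
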