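test_that("helix duplex free energy equals the hand-summed stack model", {
  p <- PARAMS_PZ
  # (GACGTC)2: stacks GA/CT, AC/TG, CG/GC, GT/CA, TC/AG + init + symmetry
  by_hand <- sum(stack_dG37(p, "GA/CT"), stack_dG37(p, "AC/TG"),
                 stack_dG37(p, "CG/GC"), stack_dG37(p, "GT/CA"),
                 stack_dG37(p, "TC/AG")) + 1.96 + 0.43
  expect_equal(duplex_dG37(duplex_spec("GACGTC"), p), by_hand)
  # (GTPPZZAC)2 uses the P-Z table stacks and the symmetry correction
  by_hand2 <- sum(stack_dG37(p, "GT/CA"), stack_dG37(p, "TP/AZ"),
                  stack_dG37(p, "PP/ZZ"), stack_dG37(p, "PZ/ZP"),
                  stack_dG37(p, "ZZ/PP"), stack_dG37(p, "ZA/PT"),
                  stack_dG37(p, "AC/TG")) + 1.96 + 0.43
  expect_equal(duplex_dG37(duplex_spec("GTPPZZAC"), p), by_hand2)
})

test_that("terminal A-T penalty applies per helix end, P-Z ends cost 0", {
  p <- PARAMS_PZ
  at_ends <- duplex_dG37(duplex_spec("ATGCGCAT", "ATGCGCAT"), p)
  stacks <- sum(stack_dG37(p, "AT/TA"), stack_dG37(p, "TG/AC"),
                stack_dG37(p, "GC/CG"), stack_dG37(p, "CG/GC"),
                stack_dG37(p, "GC/CG"), stack_dG37(p, "CA/GT"),
                stack_dG37(p, "AT/TA"))
  expect_equal(at_ends, stacks + 1.96 + 0.43 + 2 * 0.05)
  # P-Z terminated duplex gets no end penalty
  pz_ends <- duplex_dG37(duplex_spec("PGCGCZ", "PGCGCZ"), p)
  stacks_pz <- sum(stack_dG37(p, "PG/ZC"), stack_dG37(p, "GC/CG"),
                   stack_dG37(p, "CG/GC"), stack_dG37(p, "GC/CG"),
                   stack_dG37(p, "CZ/GP"))
  expect_equal(pz_ends, stacks_pz + 1.96 + 0.43)
})

test_that("rotating a duplex leaves its free energy unchanged", {
  p <- PARAMS_PZ
  set.seed(11)
  for (k in 1:5) {
    n <- sample(6:10, 1)
    pairs <- list(c("G", "C"), c("A", "T"), c("P", "Z"))
    tops <- character(n); bots <- character(n)
    for (i in seq_len(n)) {
      pr <- pairs[[sample.int(3, 1)]]
      if (runif(1) < 0.5) pr <- rev(pr)
      tops[i] <- pr[1]; bots[i] <- pr[2]
    }
    top <- paste(tops, collapse = "")
    bottom <- paste(rev(bots), collapse = "")
    d1 <- duplex_dG37(duplex_spec(top, bottom), p)
    d2 <- duplex_dG37(duplex_spec(bottom, top), p)
    expect_equal(d1, d2)
  }
})

test_that("dangling ends and terminal mismatches score via the loop tables", {
  p <- PARAMS_PZ
  # non-self-complementary core so no symmetry term enters the difference
  core <- duplex_dG37(duplex_spec("GCAGC", "GCTGC"), p)
  # 5' overhanging A on the top strand
  with_dangle <- duplex_dG37(duplex_spec("AGCAGC", "GCTGC"), p)
  expect_equal(with_dangle - core,
               unname(p$loops$d5["G", "C", "A"]))
  # terminal Z-Z mismatch on a T-A closing pair: the measured -0.91
  ref <- duplex_dG37(duplex_spec("TGCGC", "GCGCA"), p)
  mm <- duplex_dG37(duplex_spec("ZTGCGC", "GCGCAZ"), p)
  expect_equal(mm - ref, -0.91)
})

test_that("motif increments recover planted values by subtraction", {
  p <- PARAMS_PZ
  ref <- duplex_spec("GCGCGC", "GCGCGC")
  base <- duplex_dG37(ref, p)
  expect_equal(motif_increment(base, ref, p), 0)
  expect_equal(motif_increment(base - 0.5, ref, p), -0.5)
  expect_equal(motif_increment(-7.2, -6.9, p), -0.3)
  expect_error(motif_increment(-7.2, "not-a-spec", p), "duplex_spec")
})

test_that("enthalpy prediction refuses stacks without dH entries", {
  p <- PARAMS_PZ
  hs <- duplex_dH_dS(duplex_spec("GACGTC"), p)
  expect_lt(hs$dH, 0)
  expect_equal(hs$dH - 310.15 * hs$dS / 1000,
               duplex_dG37(duplex_spec("GACGTC"), p), tolerance = 0.2)
  expect_error(duplex_dH_dS(duplex_spec("GTPPZZAC"), p), "enthalpy")
})

test_that("two-state melting temperature follows the closed form", {
  # independent closed-form evaluation
  dH <- -60; dS <- -170; CT <- 1e-6
  expect_equal(melting_temperature(dH, dS, CT, FALSE),
               dH * 1000 / (dS + 1.987 * log(CT / 4)))
  # monotone in concentration for non-self-complementary duplexes
  expect_gt(melting_temperature(dH, dS, 2e-6, FALSE),
            melting_temperature(dH, dS, 1e-6, FALSE))
  # self-complementary (x = 1) melts higher at equal parameters
  expect_gt(melting_temperature(dH, dS, CT, TRUE),
            melting_temperature(dH, dS, CT, FALSE))
  expect_error(melting_temperature(10, -170, CT, FALSE), "two-state")
})
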