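test_that("sequence parsing maps case-insensitively and reports bad symbols", {
  s <- parse_sequence("GTPPZZAC")
  expect_s3_class(s, "pz_seq")
  expect_equal(unclass(s), c("G", "T", "P", "P", "Z", "Z", "A", "C"),
               ignore_attr = TRUE)
  expect_equal(unclass(parse_sequence("a")), "A", ignore_attr = TRUE)
  expect_equal(unclass(parse_sequence("gtppzzac")), unclass(s),
               ignore_attr = TRUE)
  expect_error(parse_sequence("GXT"), "position 2")
  expect_error(parse_sequence("   "), "empty")
})

test_that("pairing partners follow the alphabet mode", {
  pz <- alphabet_mode("DNA-PZ")
  dna <- alphabet_mode("canonical-DNA")
  expect_setequal(pairing_partner("G", pz), c("C", "Z"))
  expect_equal(pairing_partner("P", pz), "Z")
  expect_equal(pairing_partner("A", dna), "T")
  expect_equal(pairing_partner("A", pz), "T")
  # G-T is never a DNA-PZ pair; optional in legacy canonical mode
  expect_false("T" %in% pairing_partner("G", pz))
  expect_true("T" %in% pairing_partner("G", alphabet_mode("canonical-DNA",
                                                          allow_GT = TRUE)))
  # symmetry over all base pairs and both modes
  for (mode in list(pz, dna)) {
    for (b1 in c("A", "C", "G", "T", "P", "Z")) {
      for (b2 in pairing_partner(b1, mode)) {
        expect_true(b1 %in% pairing_partner(b2, mode))
      }
    }
  }
})

test_that("self-complementarity uses strict complements (P<->Z, never G-Z)", {
  expect_true(is_self_complementary("GACGTC"))
  expect_true(is_self_complementary("GTPPZZAC"))
  expect_true(is_self_complementary("GAZZPPTC"))
  expect_false(is_self_complementary("GACGTT"))
  expect_false(is_self_complementary("GZ"))  # wobble is not a complement
  # implies even length
  for (s in c("GACGTC", "GTPPZZAC", "AT", "CG", "PZ")) {
    if (is_self_complementary(s)) expect_equal(nchar(s) %% 2, 0)
  }
})

test_that("canonical stack keys are rotation-invariant with deterministic ties", {
  expect_equal(canonical_stack_key("PP", "ZZ"), canonical_stack_key("ZZ", "PP"))
  expect_equal(canonical_stack_key("AA", "TT"), canonical_stack_key("TT", "AA"))
  # ZP/PZ and PZ/ZP are physically different stacks
  expect_false(canonical_stack_key("ZP", "PZ") == canonical_stack_key("PZ", "ZP"))
  expect_error(canonical_stack_key("GT", "CA", alphabet_mode("DNA-PZ")), NA)
  expect_error(canonical_stack_key("GG", "CT", alphabet_mode("DNA-PZ")),
               "not an allowed pair")
})

test_that("canonical_stack_key is idempotent and rotation-invariant exhaustively", {
  mode <- alphabet_mode("DNA-PZ")
  B <- c("A", "C", "G", "T", "P", "Z")
  set.seed(4)
  n_checked <- 0
  for (x1 in B) for (y1 in B) {
    if (!mode$allowed[x1, y1]) next
    for (x2 in B) for (y2 in B) {
      if (!mode$allowed[x2, y2]) next
      k1 <- canonical_stack_key(c(x1, x2), c(y1, y2), mode)
      # 180-degree rotation
      k2 <- canonical_stack_key(c(y2, y1), c(x2, x1), mode)
      expect_identical(k1, k2)
      sk <- split_stack_key <- strsplit(k1, "/")[[1]]
      k3 <- canonical_stack_key(strsplit(sk[1], "")[[1]],
                                strsplit(sk[2], "")[[1]], mode)
      expect_identical(k1, k3)  # idempotent
      n_checked <- n_checked + 1
    }
  }
  expect_equal(n_checked, 64)
})
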