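test_that("stack lookups return the published values with rotational symmetry", {
  p <- PARAMS_PZ
  expect_equal(stack_dG37(p, "ZP/PZ"), -3.35)
  expect_equal(stack_dG37(p, "GZ/ZG"), 1.70)
  expect_equal(stack_dG37(p, "CP/GZ"), -2.77)
  expect_equal(stack_dG37(p, "PG/ZZ"), -2.47)
  expect_equal(stack_dG37(p, "PP/ZZ"), stack_dG37(p, "ZZ/PP"))
  expect_equal(stack_dG37(p, "AA/TT"), stack_dG37(p, "TT/AA"))
  expect_error(stack_dG37(p, "AG/TT"), "not an allowed pair")  # G-T column
})

test_that("the parameter set is complete: 36 unique stacks, families sized 10/11/15", {
  p <- PARAMS_PZ
  expect_length(p$stacks, 36)
  fams <- vapply(names(p$stacks), pzfold:::stack_family, character(1))
  expect_equal(sum(fams == "canonical"), 10)
  expect_equal(sum(fams == "pz"), 11)
  expect_equal(sum(fams == "gz"), 15)
})

test_that("dG37 is consistent with dH - T*dS where both are tabulated", {
  p <- PARAMS_PZ
  has <- !is.na(p$stack_dH)
  expect_true(any(has))
  recomputed <- p$stack_dH[has] - 310.15 * p$stack_dS[has] / 1000
  expect_true(all(abs(recomputed - p$stacks[has]) < 0.15))
})

test_that("every legal loop query resolves to a finite value", {
  p <- PARAMS_PZ
  B <- c("A", "C", "G", "T", "P", "Z")
  closings <- which(p$mode$allowed, arr.ind = TRUE)
  for (r in seq_len(nrow(closings))) {
    x <- B[closings[r, 1]]; y <- B[closings[r, 2]]
    cl <- paste0(x, "-", y)
    for (a in B) {
      expect_true(is.finite(loop_dangle(p, "5p", cl, a)))
      expect_true(is.finite(loop_dangle(p, "3p", cl, a)))
      for (b in B) {
        expect_true(is.finite(loop_tmm(p, cl, paste0(a, "-", b))))
      }
    }
  }
  for (r1 in seq_len(nrow(closings))) for (r2 in seq_len(nrow(closings))) {
    slab <- p$loops$int11[closings[r1, 1], closings[r1, 2],
                          closings[r2, 1], closings[r2, 2], , ]
    expect_false(anyNA(slab))
  }
})

test_that("internal-loop extrapolation equals mapped canonical entry minus 0.6 per P/Z mismatch", {
  p <- PARAMS_PZ
  cases <- list(
    list(c1 = "G-C", c2 = "G-C", mm = "P-C", k = 1),
    list(c1 = "C-G", c2 = "A-T", mm = "Z-A", k = 1),
    list(c1 = "P-Z", c2 = "G-C", mm = "A-A", k = 0),
    list(c1 = "G-Z", c2 = "T-A", mm = "P-T", k = 1))
  for (cs in cases) {
    got <- loop_int11(p, cs$c1, cs$c2, cs$mm)
    src <- pzfold:::int11_canonical_source(p, cs$c1, cs$c2, cs$mm)
    expect_equal(got - src, -0.6 * cs$k, tolerance = 1e-12)
  }
})

test_that("stack table round-trips bit-identically through plain text", {
  p <- PARAMS_PZ
  path <- withr::local_tempfile(fileext = ".tsv")
  write_stack_table(p, path)
  back <- read_stack_table(path)
  expect_identical(unname(back[names(p$stacks)]), unname(p$stacks))
})

test_that("measured loop overlays override extrapolated defaults", {
  extra <- data.frame(type = "tmm", closing = "G-C", content = "P-A",
                      dG37 = -1.23)
  p2 <- load_parameter_set(alphabet_mode("DNA-PZ"), measured_loops = extra)
  expect_equal(loop_tmm(p2, "G-C", "P-A"), -1.23)
  # the untouched defaults survive
  expect_equal(loop_tmm(p2, "T-A", "Z-Z"), -0.91)
})
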