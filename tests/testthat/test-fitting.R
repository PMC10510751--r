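test_that("residual stability isolates the free-term contribution", {
  p <- PARAMS_PZ
  spec <- fit_stage_spec("PZ", p)
  # all-canonical duplex: residual = experimental - full prediction
  pred <- duplex_dG37(duplex_spec("GACGTC"), p)
  ms <- melt_summary("GACGTC", "GACGTC", dG37_exp = pred)
  expect_equal(residual_stability(ms, spec), 0)
  ms2 <- melt_summary("GACGTC", "GACGTC", dG37_exp = pred - 1.5)
  expect_equal(residual_stability(ms2, spec), -1.5)
  # one planted P-Z stack: residual equals the planted stack total
  truth <- p$stacks
  ms3 <- melt_summary("GCPZGC", "GCPZGC",
                      dG37_exp = pzfold:::predict_helix_dG("GCPZGC", "GCPZGC",
                                                           truth, p))
  prof <- pzfold:::duplex_stack_profile("GCPZGC", "GCPZGC", p$mode)
  free <- Filter(function(k) pzfold:::stack_family(k) == "pz",
                 names(prof$stacks))
  planted <- sum(vapply(free, function(k) prof$stacks[[k]] * truth[[k]],
                        numeric(1)))
  expect_equal(residual_stability(ms3, spec), planted)
  # G-Z stacks are unresolvable in the PZ stage
  msz <- melt_summary("GCGZGC", "GCGZGC", dG37_exp = -5)
  expect_error(residual_stability(msz, spec), "not resolvable")
})

test_that("OLS recovers planted stack values exactly on noise-free data", {
  p <- PARAMS_PZ
  ds <- gen_duplex_dataset(n = 40, noise_sd = 0, seed = 7, params = p)
  fit <- fit_stage(ds, fit_stage_spec("PZ", p))
  keys <- names(fit$estimates)
  expect_true(all(abs(fit$estimates - p$stacks[keys]) < 1e-9))
  expect_equal(unname(fit$design_matrix_rank), length(keys))
})

test_that("OLS equals brute-force minimization of the squared residuals", {
  p <- PARAMS_PZ
  ds <- gen_duplex_dataset(n = 25, noise_sd = 0.3, seed = 3, params = p)
  spec <- fit_stage_spec("PZ", p)
  fit <- fit_stage(ds, spec)
  X <- fit$X; y <- fit$y
  # independent route: generic optimizer on the least-squares objective
  obj <- function(beta) sum((y - X %*% beta)^2)
  opt <- optim(rep(0, ncol(X)), obj, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-14))
  expect_equal(unname(fit$estimates), opt$par, tolerance = 1e-4)
  # residual identity
  expect_equal(unname(fit$residuals), unname(y - drop(X %*% fit$estimates)))
})

test_that("G-Z stage fits with canonical and P-Z stacks fixed", {
  p <- PARAMS_PZ
  ds <- gen_duplex_dataset(n = 45, noise_sd = 0, seed = 5, params = p,
                           families = c("WC", "PZ", "GZ"), free_family = "gz")
  fit <- fit_stage(ds, fit_stage_spec("GZ", p))
  keys <- names(fit$estimates)
  expect_true(all(vapply(keys, pzfold:::stack_family, character(1)) == "gz"))
  expect_true(all(abs(fit$estimates - p$stacks[keys]) < 1e-9))
})

test_that("end-penalty report recovers planted penalties and flags outliers", {
  p <- PARAMS_PZ
  spec <- fit_stage_spec("PZ", p)
  set.seed(21)
  ds <- gen_duplex_dataset(n = 40, noise_sd = 0.05, seed = 21, params = p)
  # plant a +0.35 penalty on every terminal P-Z end
  ends_pz <- vapply(seq_len(nrow(ds)), function(r) {
    sum(pzfold:::duplex_stack_profile(ds$top[r], ds$bottom[r],
                                      p$mode)$ends == "PZ")
  }, numeric(1))
  expect_gt(sum(ends_pz), 0)
  ds_pen <- ds
  ds_pen$dG37_exp <- ds$dG37_exp + 0.35 * ends_pz
  rep1 <- end_penalty_report(ds_pen, spec)
  expect_lt(abs(rep1$penalty_estimate - 0.35), 3 * rep1$penalty_stderr)
  # plant one outlier duplex (+2 kcal/mol): it tops the residual ranking
  ds_out <- ds
  victim <- which(ends_pz > 0)[1]
  ds_out$dG37_exp[victim] <- ds_out$dG37_exp[victim] + 2
  rep2 <- end_penalty_report(ds_out, spec)
  expect_equal(rep2$top_residual_without, ds_out$id[victim])
})

test_that("excluding the planted outlier restores a near-zero penalty", {
  p <- PARAMS_PZ
  spec <- fit_stage_spec("PZ", p)
  ds <- gen_duplex_dataset(n = 40, noise_sd = 0.05, seed = 22, params = p)
  victim <- ds$id[5]
  ds$dG37_exp[5] <- ds$dG37_exp[5] + 2
  refit <- exclude_and_refit(ds, spec, victim)
  keys <- names(refit$estimates)
  expect_true(all(abs(refit$estimates - p$stacks[keys]) < 0.1))
  # excluding nothing reproduces fit_stage bit-for-bit
  expect_identical(exclude_and_refit(ds, spec, character(0))$estimates,
                   fit_stage(ds, spec)$estimates)
  expect_error(exclude_and_refit(ds, spec, "nonexistent"), "not present")
})

test_that("a duplex lying exactly on the fitted model leaves estimates unchanged", {
  p <- PARAMS_PZ
  spec <- fit_stage_spec("PZ", p)
  ds <- gen_duplex_dataset(n = 30, noise_sd = 0.2, seed = 9, params = p)
  fit <- fit_stage(ds, spec)
  fitted_stacks <- p$stacks
  fitted_stacks[names(fit$estimates)] <- fit$estimates
  extra_top <- "GCPZPZGC"
  new_dg <- pzfold:::predict_helix_dG(extra_top, extra_top, fitted_stacks, p)
  ds2 <- rbind(ds, melt_summary(extra_top, extra_top, new_dg, id = "onmodel"))
  fit2 <- fit_stage(ds2, spec)
  expect_equal(fit2$estimates, fit$estimates, tolerance = 1e-9)
})

test_that("enthalpy and entropy stages are dG = dH - T dS consistent", {
  p <- PARAMS_PZ
  # synthetic truth: dH/dS for P-Z stacks consistent with packaged dG37
  set.seed(14)
  keys <- names(p$stacks)[vapply(names(p$stacks), pzfold:::stack_family,
                                 character(1)) == "pz"]
  truth_dH <- p$stack_dH
  truth_dS <- p$stack_dS
  truth_dH[keys] <- p$stacks[keys] * 8   # plausible enthalpy scale
  truth_dS[keys] <- (truth_dH[keys] - p$stacks[keys]) / 310.15 * 1000
  ds <- gen_duplex_dataset(n = 40, noise_sd = 0, seed = 15, params = p)
  ph <- p; ph$stacks <- truth_dH
  ps <- p; ps$stacks <- truth_dS
  ds$dH_exp <- vapply(seq_len(nrow(ds)), function(r) {
    prof <- pzfold:::duplex_stack_profile(ds$top[r], ds$bottom[r], p$mode)
    v <- p$penalties$intermolecular_initiation[["dH"]]
    for (end in prof$ends) if (end == "AT") v <- v + p$penalties$terminal_AT[["dH"]]
    for (k in names(prof$stacks)) v <- v + prof$stacks[[k]] * truth_dH[[k]]
    v
  }, numeric(1))
  ds$dS_exp <- vapply(seq_len(nrow(ds)), function(r) {
    prof <- pzfold:::duplex_stack_profile(ds$top[r], ds$bottom[r], p$mode)
    v <- p$penalties$intermolecular_initiation[["dS"]]
    if (prof$self_comp) v <- v + p$penalties$symmetry_correction[["dS"]]
    for (end in prof$ends) if (end == "AT") v <- v + p$penalties$terminal_AT[["dS"]]
    for (k in names(prof$stacks)) v <- v + prof$stacks[[k]] * truth_dS[[k]]
    v
  }, numeric(1))
  fh <- fit_stage(ds, fit_stage_spec("enthalpy-PZ", p))
  fs <- fit_stage(ds, fit_stage_spec("entropy-PZ", p))
  fg <- fit_stage(ds, fit_stage_spec("PZ", p))
  shared <- names(fg$estimates)
  expect_equal(unname(fh$estimates[shared] - 310.15 * fs$estimates[shared] / 1000),
               unname(fg$estimates[shared]), tolerance = 1e-6)
})
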