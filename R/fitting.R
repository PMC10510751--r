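# Staged ordinary-least-squares fitting of nearest-neighbor stack parameters
# from per-duplex melting summaries. Canonical Watson-Crick-Franklin values
# are always held fixed; the P-Z stage fits P-Z-containing stacks; the G-Z
# stage additionally fixes the P-Z stacks and fits G-Z-containing stacks.

#' Assemble a melt-summary dataset
#'
#' One row per duplex: strand sequences (5'->3'), experimental dG37 and
#' optionally dH/dS, an id and a free-text source.
#'
#' @param top,bottom character vectors of strand sequences.
#' @param dG37_exp experimental free energies (kcal/mol).
#' @param dH_exp,dS_exp optional experimental enthalpies (kcal/mol) and
#'   entropies (cal/(mol*K)).
#' @param id duplex identifiers (default `top` sequence).
#' @param source free text provenance.
#' @return data frame of class `melt_summary`.
#' @export
melt_summary <- function(top, bottom = top, dG37_exp,
                         dH_exp = NA_real_, dS_exp = NA_real_,
                         id = top, source = "") {
  stopifnot(length(top) == length(bottom), length(top) == length(dG37_exp))
  df <- data.frame(id = id, top = toupper(top), bottom = toupper(bottom),
                   dG37_exp = dG37_exp, dH_exp = dH_exp, dS_exp = dS_exp,
                   source = source, stringsAsFactors = FALSE)
  class(df) <- c("melt_summary", "data.frame")
  df
}

# Classify a canonical stack key by its most exotic pair column.
stack_family <- function(key) {
  s <- split_stack_key(key)
  fam <- "canonical"
  for (k in 1:2) {
    pr <- sort(c(s$top[k], s$bottom[k]))
    if (identical(pr, c("G", "Z"))) return("gz")
    if (identical(pr, c("P", "Z"))) fam <- "pz"
  }
  fam
}

# Count canonical stack keys and terminal pair types of a fully paired duplex.
duplex_stack_profile <- function(top, bottom, mode = alphabet_mode("DNA-PZ")) {
  t <- unclass(as_pz_seq(top))
  b <- rev(unclass(as_pz_seq(bottom)))
  if (length(t) != length(b)) stop("fit duplexes must be fully paired")
  ok <- mode$allowed[cbind(t, b)]
  if (!all(ok)) {
    stop("column ", which(!ok)[1], " (", t[which(!ok)[1]], "-",
         b[which(!ok)[1]], ") is not an allowed pair")
  }
  keys <- duplex_stack_keys(t, b, mode)
  ends <- c(paste(sort(c(t[1], b[1])), collapse = ""),
            paste(sort(c(t[length(t)], b[length(b)])), collapse = ""))
  list(stacks = table(keys), ends = ends,
       self_comp = identical(unclass(as_pz_seq(top)),
                             unclass(as_pz_seq(bottom))) &&
         is_self_complementary(top))
}

#' Define a fitting stage
#'
#' @param stage `"PZ"` (fit P-Z stacks, canonical fixed), `"GZ"` (fit G-Z
#'   stacks, canonical and P-Z fixed), `"enthalpy-PZ"` or `"entropy-PZ"`
#'   (same design as PZ on the dH/dS channel).
#' @param params parameter set providing the fixed values.
#' @param include_end_penalty add a free terminal P-Z end-penalty column.
#' @return `fit_stage_spec` list.
#' @export
fit_stage_spec <- function(stage = c("PZ", "GZ", "enthalpy-PZ", "entropy-PZ"),
                           params = load_parameter_set(),
                           include_end_penalty = FALSE) {
  stage <- match.arg(stage)
  channel <- switch(stage, PZ = "dG37", GZ = "dG37",
                    `enthalpy-PZ` = "dH", `entropy-PZ` = "dS")
  free_family <- if (stage == "GZ") "gz" else "pz"
  structure(list(stage = stage, channel = channel, free_family = free_family,
                 include_end_penalty = include_end_penalty, params = params),
            class = "fit_stage_spec")
}

stage_fixed_value <- function(spec, key) {
  params <- spec$params
  fam <- stack_family(key)
  tab <- switch(spec$channel, dG37 = params$stacks, dH = params$stack_dH,
                dS = params$stack_dS)
  if (fam == "gz" && spec$free_family != "gz") {
    stop("stack ", key, " is not resolvable in stage ", spec$stage,
         " (G-Z stacks are neither free nor fixed here)")
  }
  v <- tab[key]
  if (is.na(v)) stop("no fixed ", spec$channel, " value for stack ", key)
  unname(v)
}

stage_penalty_value <- function(spec, term) {
  spec$params$penalties[[term]][[spec$channel]]
}

stage_response_column <- function(spec) {
  switch(spec$channel, dG37 = "dG37_exp", dH = "dH_exp", dS = "dS_exp")
}

#' Residual stability after subtracting fixed contributions
#'
#' Subtracts intermolecular initiation, the symmetry correction (for
#' self-complementary duplexes), terminal A-T penalties and all fixed-family
#' stack values from the experimental value; what remains is attributable to
#' the stage's free terms.
#'
#' @param data a [melt_summary()] data frame.
#' @param spec a [fit_stage_spec()].
#' @return numeric vector of residual stabilities (one per duplex).
#' @export
residual_stability <- function(data, spec) {
  y <- data[[stage_response_column(spec)]]
  if (anyNA(y)) stop("missing experimental values for channel ", spec$channel)
  vapply(seq_len(nrow(data)), function(r) {
    prof <- duplex_stack_profile(data$top[r], data$bottom[r],
                                 spec$params$mode)
    v <- y[r] - stage_penalty_value(spec, "intermolecular_initiation")
    if (prof$self_comp) v <- v - stage_penalty_value(spec, "symmetry_correction")
    for (end in prof$ends) {
      if (end == "AT") v <- v - stage_penalty_value(spec, "terminal_AT")
      # terminal P-Z contributes 0 (or the free penalty column); G-Z ends 0
    }
    for (key in names(prof$stacks)) {
      if (stack_family(key) != spec$free_family) {
        v <- v - prof$stacks[[key]] * stage_fixed_value(spec, key)
      }
    }
    v
  }, numeric(1))
}

stage_design_matrix <- function(data, spec) {
  profs <- lapply(seq_len(nrow(data)), function(r) {
    duplex_stack_profile(data$top[r], data$bottom[r], spec$params$mode)
  })
  free_keys <- sort(unique(unlist(lapply(profs, function(p) {
    ks <- names(p$stacks)
    ks[vapply(ks, stack_family, character(1)) == spec$free_family]
  }))))
  cols <- free_keys
  if (spec$include_end_penalty) cols <- c(cols, "terminal_PZ")
  X <- matrix(0, nrow(data), length(cols), dimnames = list(data$id, cols))
  for (r in seq_along(profs)) {
    for (key in names(profs[[r]]$stacks)) {
      if (key %in% free_keys) X[r, key] <- profs[[r]]$stacks[[key]]
    }
    if (spec$include_end_penalty) {
      X[r, "terminal_PZ"] <- sum(profs[[r]]$ends == "PZ")
    }
  }
  X
}

#' Fit one stage of stack parameters by ordinary least squares
#'
#' The design matrix counts occurrences of each free canonical stack per
#' duplex (rotational symmetry collapsed, so e.g. PP/ZZ and ZZ/PP increment
#' the same column); the response is the residual stability after all fixed
#' contributions. Reported uncertainties are standard errors of the
#' regression.
#'
#' @param data a [melt_summary()] data frame.
#' @param spec a [fit_stage_spec()].
#' @return `regression_result` list: `estimates`, `stderrs`, `residuals`
#'   (experimental minus fitted, named by duplex id), `design_matrix_rank`,
#'   `sigma`, plus the design matrix and response used.
#' @export
fit_stage <- function(data, spec) {
  X <- stage_design_matrix(data, spec)
  y <- residual_stability(data, spec)
  if (nrow(X) < ncol(X)) {
    stop("fewer duplexes (", nrow(X), ") than free terms (", ncol(X), ")")
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop <- colnames(X)[setdiff(seq_len(ncol(X)), qrX$pivot[seq_len(qrX$rank)])]
    stop("rank-deficient design matrix; unidentifiable terms: ",
         paste(drop, collapse = ", "))
  }
  beta <- qr.coef(qrX, y)
  fitted <- drop(X %*% beta)
  resid <- y - fitted
  dfres <- nrow(X) - ncol(X)
  sigma <- if (dfres > 0) sqrt(sum(resid^2) / dfres) else NA_real_
  XtXinv <- chol2inv(qr.R(qrX))[order(qrX$pivot), order(qrX$pivot), drop = FALSE]
  stderrs <- sigma * sqrt(diag(XtXinv))
  names(stderrs) <- colnames(X)
  structure(list(estimates = beta, stderrs = stderrs,
                 residuals = stats::setNames(resid, data$id),
                 design_matrix_rank = qrX$rank, sigma = sigma,
                 X = X, y = y, stage = spec$stage),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat("<regression_result>", x$stage, "stage:", length(x$estimates),
      "terms, rank", x$design_matrix_rank, ", sigma =",
      format(x$sigma, digits = 3), "\n")
  print(data.frame(estimate = round(x$estimates, 3),
                   stderr = round(x$stderrs, 3)))
  invisible(x)
}

#' Terminal P-Z end-penalty comparison report
#'
#' Fits the stage with and without a free terminal P-Z end-penalty column
#' and reports both penalty estimates with their standard errors plus the
#' largest-|residual| duplex of each fit, supporting the judgement of
#' whether helix-end P-Z pairs need a correction term.
#'
#' @param data a [melt_summary()] data frame containing duplexes with
#'   terminal P-Z pairs.
#' @param spec a [fit_stage_spec()] (the end-penalty flag is overridden).
#' @return list with both fits, the penalty estimate and stderr, and the
#'   top-residual duplex ids.
#' @export
end_penalty_report <- function(data, spec) {
  has_pz_end <- vapply(seq_len(nrow(data)), function(r) {
    any(duplex_stack_profile(data$top[r], data$bottom[r],
                             spec$params$mode)$ends == "PZ")
  }, logical(1))
  if (!any(has_pz_end)) stop("no duplexes with terminal P-Z pairs in data")
  spec_with <- spec; spec_with$include_end_penalty <- TRUE
  spec_without <- spec; spec_without$include_end_penalty <- FALSE
  fw <- fit_stage(data, spec_with)
  fo <- fit_stage(data, spec_without)
  list(
    with_penalty = fw, without_penalty = fo,
    penalty_estimate = unname(fw$estimates["terminal_PZ"]),
    penalty_stderr = unname(fw$stderrs["terminal_PZ"]),
    top_residual_with = names(which.max(abs(fw$residuals))),
    top_residual_without = names(which.max(abs(fo$residuals)))
  )
}

#' Refit after excluding duplexes by id
#'
#' Exclusion is explicit user input (the judgement call of removing an
#' outlier); no automatic thresholding is applied.
#'
#' @param data a [melt_summary()] data frame.
#' @param spec a [fit_stage_spec()].
#' @param excluded_ids ids to drop (may be empty).
#' @return `regression_result` for the reduced dataset.
#' @export
exclude_and_refit <- function(data, spec, excluded_ids = character(0)) {
  missing <- setdiff(excluded_ids, data$id)
  if (length(missing)) {
    stop("excluded ids not present in data: ", paste(missing, collapse = ", "))
  }
  fit_stage(data[!data$id %in% excluded_ids, , drop = FALSE], spec)
}
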