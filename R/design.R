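# Stochastic inverse folding: minimize the normalized ensemble defect
# against a target structure with biased pair/loop selection. Folding is
# always evaluated with the DNA+PZ parameter tables; the alphabet mode only
# restricts which pair types the designer may assign.

#' Selection biases for pairs and loop nucleotides
#'
#' Defaults: in DNA-PZ mode P-Z pairs are drawn with probability 0.20,
#' G-C with 0.50 and A-T with 0.30; in canonical mode G-C and A-T are drawn
#' with equal probability. Loop nucleotides are drawn A/C/G/T with
#' probabilities 0.60/0.10/0.10/0.20 (the A bias of natural loops); P and Z
#' are never placed in loops.
#'
#' @param mode an [alphabet_mode()] or mode name.
#' @param pair_weights,loop_weights optional named overrides (must sum to 1).
#' @return `selection_bias` list.
#' @export
selection_bias <- function(mode = alphabet_mode("DNA-PZ"),
                           pair_weights = NULL, loop_weights = NULL) {
  if (is.character(mode)) mode <- alphabet_mode(mode)
  if (is.null(pair_weights)) {
    pair_weights <- if (mode$name == "DNA-PZ") {
      c(GC = 0.50, AT = 0.30, PZ = 0.20)
    } else {
      c(GC = 0.50, AT = 0.50)
    }
  }
  if (is.null(loop_weights)) {
    loop_weights <- c(A = 0.60, C = 0.10, G = 0.10, T = 0.20)
  }
  stopifnot(abs(sum(pair_weights) - 1) < 1e-9,
            abs(sum(loop_weights) - 1) < 1e-9)
  if (any(names(loop_weights) %in% c("P", "Z"))) {
    stop("P and Z are never selected for loops")
  }
  structure(list(mode = mode, pair_weights = pair_weights,
                 loop_weights = loop_weights), class = "selection_bias")
}

#' Design configuration
#'
#' @param bias a [selection_bias()].
#' @param seed integer RNG seed; if `NULL` one is drawn from the clock and
#'   recorded in the result.
#' @param ned_threshold stop once the best NED is at or below this value.
#' @param max_iterations maximum refinement proposals.
#' @param wall_time_limit seconds; `Inf` for unlimited.
#' @param allow_isolated_pairs kept for interface completeness; the engine
#'   permits isolated pairs (targets may contain them).
#' @return `design_config` list.
#' @export
design_config <- function(bias = selection_bias(), seed = NULL,
                          ned_threshold = 0.01, max_iterations = 2000,
                          wall_time_limit = Inf, allow_isolated_pairs = TRUE) {
  stopifnot(ned_threshold > 0, ned_threshold <= 1, max_iterations >= 0)
  structure(list(bias = bias, seed = seed, ned_threshold = ned_threshold,
                 max_iterations = max_iterations,
                 wall_time_limit = wall_time_limit,
                 allow_isolated_pairs = allow_isolated_pairs),
            class = "design_config")
}

draw_pair <- function(bias) {
  type <- sample(names(bias$pair_weights), 1, prob = bias$pair_weights)
  halves <- strsplit(type, "")[[1]]
  if (stats::runif(1) < 0.5) halves else rev(halves)
}

#' Initialize a sequence for a target structure
#'
#' Each target pair is assigned a pair type from the pair weights and an
#' orientation uniformly at random; each unpaired position is assigned a
#' base from the loop weights. Deterministic given the RNG state.
#'
#' @param target a [sec_structure()].
#' @param bias a [selection_bias()].
#' @return `pz_seq`.
#' @export
initialize_sequence <- function(target, bias = selection_bias()) {
  s <- character(target$length)
  for (r in seq_len(nrow(target$pairs))) {
    pr <- draw_pair(bias)
    s[target$pairs[r, 1]] <- pr[1]
    s[target$pairs[r, 2]] <- pr[2]
  }
  un <- which(target$pt == 0)
  if (length(un)) {
    s[un] <- sample(names(bias$loop_weights), length(un), TRUE,
                    prob = bias$loop_weights)
  }
  structure(s, id = "design", class = "pz_seq")
}

#' Refine a sequence toward a target structure by NED minimization
#'
#' Iterates: pick a position (a pair, counted jointly, or an unpaired site)
#' with probability proportional to its current defect contribution, redraw
#' its identity from the bias, recompute the NED, and keep the change only
#' if the NED strictly decreases. Stops at the NED threshold, the iteration
#' cap, or the wall-time limit, returning the best sequence seen.
#'
#' @param seq starting sequence consistent with the target (e.g. from
#'   [initialize_sequence()]); if `NULL` one is initialized.
#' @param target a [sec_structure()].
#' @param config a [design_config()].
#' @param params folding parameter set (DNA-PZ tables).
#' @return `design_result`: `sequence`, `ned`, `iterations_used`, `elapsed`
#'   (seconds), `seed`, `trajectory` (best NED per iteration).
#' @export
refine <- function(seq = NULL, target, config = design_config(),
                   params = load_parameter_set()) {
  if (min(target$pairs[, 2] - target$pairs[, 1] - 1, Inf) < 3) {
    stop("infeasible target: hairpin loop shorter than 3")
  }
  seed <- config$seed
  if (is.null(seed)) seed <- as.integer(Sys.time()) %% .Machine$integer.max
  set.seed(seed)
  t0 <- proc.time()[["elapsed"]]
  if (is.null(seq)) seq <- initialize_sequence(target, config$bias)
  s <- unclass(as_pz_seq(seq))
  check_structure_sequence(s, target, config$bias$mode)

  eval_ned <- function(sch) {
    ned(paste(sch, collapse = ""), target, params = params)
  }
  cur <- eval_ned(s)
  best_s <- s
  best_ned <- cur$ned
  traj <- numeric(0)
  iters <- 0
  pairs <- target$pairs
  un <- which(target$pt == 0)

  while (best_ned > config$ned_threshold &&
         iters < config$max_iterations &&
         proc.time()[["elapsed"]] - t0 < config$wall_time_limit) {
    iters <- iters + 1
    # defect-weighted position selection: pairs weighted by the joint defect
    # of their two nucleotides, unpaired sites by their own defect
    d <- cur$per_position
    w_pairs <- if (nrow(pairs)) d[pairs[, 1]] + d[pairs[, 2]] else numeric(0)
    w_un <- d[un]
    w <- c(w_pairs, w_un)
    if (sum(w) <= 0) break
    pick <- sample.int(length(w), 1, prob = w)
    cand <- s
    if (pick <= length(w_pairs)) {
      pr <- draw_pair(config$bias)
      cand[pairs[pick, 1]] <- pr[1]
      cand[pairs[pick, 2]] <- pr[2]
    } else {
      site <- un[pick - length(w_pairs)]
      cand[site] <- sample(names(config$bias$loop_weights), 1,
                           prob = config$bias$loop_weights)
    }
    if (identical(cand, s)) {
      traj <- c(traj, best_ned)
      next
    }
    cand_ned <- eval_ned(cand)
    if (cand_ned$ned < cur$ned) {
      s <- cand
      cur <- cand_ned
      if (cur$ned < best_ned) {
        best_ned <- cur$ned
        best_s <- s
      }
    }
    traj <- c(traj, best_ned)
  }
  structure(list(
    sequence = structure(best_s, id = "design", class = "pz_seq"),
    ned = best_ned, iterations_used = iters,
    elapsed = proc.time()[["elapsed"]] - t0, seed = seed,
    trajectory = traj
  ), class = "design_result")
}

#' @export
print.design_result <- function(x, ...) {
  cat("<design_result> NED =", format(x$ned, digits = 4), "after",
      x$iterations_used, "iterations (seed", x$seed, ")\n ",
      seq_string(x$sequence), "\n")
  invisible(x)
}

#' Run several independent seeded design attempts
#'
#' @param target a [sec_structure()].
#' @param config a [design_config()]; attempt k uses `config$seed + k - 1`.
#' @param n_attempts number of attempts.
#' @param params folding parameter set.
#' @return list with `results` (one [refine()] result per attempt) and
#'   `summary` (best NED, mean NED, mean time) - the two evaluation views:
#'   lowest-across-attempts and mean-across-attempts.
#' @export
design_batch <- function(target, config = design_config(seed = 1),
                         n_attempts = 5, params = load_parameter_set()) {
  stopifnot(n_attempts >= 1)
  base_seed <- config$seed
  if (is.null(base_seed)) base_seed <- as.integer(Sys.time()) %% 2000000000L
  results <- lapply(seq_len(n_attempts), function(k) {
    cfg <- config
    cfg$seed <- base_seed + k - 1
    refine(NULL, target, cfg, params)
  })
  neds <- vapply(results, `[[`, numeric(1), "ned")
  list(results = results,
       summary = list(best_ned = min(neds), mean_ned = mean(neds),
                      mean_time = mean(vapply(results, `[[`, numeric(1),
                                              "elapsed"))))
}

#' Paired or two-sample comparison of design metrics
#'
#' One-sided paired t test (matched targets) or Welch two-sample t test on
#' NED or time, with alpha = 0.05 as the reference level. The alternative
#' `"less"` tests whether group a is better (smaller metric) than group b.
#'
#' @param a,b numeric vectors of the metric (e.g. best NED per target).
#' @param paired logical; `TRUE` for matched targets.
#' @param alternative passed to [stats::t.test()]; default `"less"`.
#' @return list with `t`, `df`, `p_value`, `alpha`, and the test used.
#' @export
paired_comparison <- function(a, b, paired = TRUE, alternative = "less") {
  if (length(a) < 2 || (!paired && length(b) < 2)) {
    stop("need at least two observations per group")
  }
  ht <- stats::t.test(a, b, paired = paired, alternative = alternative,
                      var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p_value = unname(ht$p.value), alpha = 0.05,
       test = if (paired) "paired t" else "Welch t",
       alternative = alternative)
}
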