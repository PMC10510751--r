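# R interface to the dynamic-programming folding engine.

# Dense lookup tables for the C++ engine, cached on the parameter set.
fold_tables <- function(params, nmax = 30) {
  cache <- params$cache
  if (!is.null(cache$ctab) && cache$ctab_n >= nmax) return(cache$ctab)
  mode <- params$mode
  stackE <- array(Inf, c(6, 6, 6, 6))
  closings <- which(mode$allowed, arr.ind = TRUE)
  B <- PZ_BASES
  for (r1 in seq_len(nrow(closings))) for (r2 in seq_len(nrow(closings))) {
    x1 <- closings[r1, 1]; y1 <- closings[r1, 2]
    x2 <- closings[r2, 1]; y2 <- closings[r2, 2]
    key <- canonical_stack_key(c(B[x1], B[x2]), c(B[y1], B[y2]), mode)
    stackE[x1, x2, y1, y2] <- unname(params$stacks[key])
  }
  pen <- matrix(0, 6, 6)
  for (r in seq_len(nrow(closings))) {
    pen[closings[r, 1], closings[r, 2]] <-
      terminal_pair_penalty(params, B[closings[r, 1]], B[closings[r, 2]])
  }
  lp <- params$loops
  hp <- lp$hp_init
  if (nmax > length(hp)) {
    ext <- (length(hp) + 1):nmax
    hp <- c(hp, hp[length(hp)] + 1.75 * RT_REF * log(ext / length(hp)))
  }
  fill0 <- function(x) {
    x[is.na(x)] <- Inf
    x
  }
  ctab <- list(
    stackE = as.vector(stackE),
    tmm = fill0(as.vector(lp$tmm)),
    d5 = fill0(as.vector(lp$d5)), d3 = fill0(as.vector(lp$d3)),
    pen = as.vector(pen),
    allowed = as.integer(mode$allowed),
    int11 = fill0(as.vector(lp$int11)),
    int21 = fill0(as.vector(lp$int21)),
    int22 = fill0(as.vector(lp$int22)),
    hp_init = fill0(hp),
    bulge_init = fill0(lp$bulge_init), intl_init = fill0(lp$intl_init),
    mb = unname(lp$mb), RT = RT_REF,
    max_loop = as.integer(lp$max_loop), min_hairpin = 3L
  )
  if (!is.null(cache)) {
    cache$ctab <- ctab
    cache$ctab_n <- nmax
  }
  ctab
}

check_fold_temperature <- function(T) {
  if (abs(T - T_REF) > 1e-9) {
    stop("folding is parameterized at 310.15 K only (loop and G-Z terms ",
         "have no enthalpy parameters)")
  }
}

#' Partition function and base-pair probabilities
#'
#' Computes the equilibrium partition function over all valid secondary
#' structures (nested pairs, hairpins >= 3, internal loops capped at 30
#' unpaired nucleotides) and the Boltzmann base-pair probability matrix by
#' inside-outside dynamic programming.
#'
#' @param seq sequence (string or `pz_seq`).
#' @param params `pz_params`.
#' @param T temperature in K; only the 310.15 K reference is parameterized.
#' @return object of class `pz_fold` with elements `Q`, `p` (n x n matrix),
#'   `q` (unpaired probabilities), and the sequence.
#' @examples
#' p <- load_parameter_set()
#' pf <- partition_function("GGGGCTTTTGCCCC", p)
#' pf$Q
#' @export
partition_function <- function(seq, params, T = 310.15) {
  check_fold_temperature(T)
  seq <- as_pz_seq(seq)
  codes <- base_index(unclass(seq)) - 1L
  res <- c_fold(codes, fold_tables(params, length(seq)), TRUE, FALSE)
  p <- res$p
  structure(list(Q = res$Q, p = p, q = 1 - rowSums(p), seq = seq),
            class = "pz_fold")
}

#' @export
print.pz_fold <- function(x, ...) {
  cat("<pz_fold>", length(x$seq), "nt, Q =", format(x$Q), "\n")
  invisible(x)
}

#' Base-pair probability matrix of a folded sequence
#'
#' @param pf a `pz_fold` from [partition_function()].
#' @return symmetric n x n matrix of pair probabilities.
#' @export
pair_probabilities <- function(pf) pf$p

#' Minimum free energy structure
#'
#' @inheritParams partition_function
#' @return list with `energy` (kcal/mol) and `structure` (a
#'   [sec_structure()]); the traceback is deterministic with ties resolved
#'   in enumeration order.
#' @export
mfe_structure <- function(seq, params, T = 310.15) {
  check_fold_temperature(T)
  seq <- as_pz_seq(seq)
  codes <- base_index(unclass(seq)) - 1L
  res <- c_fold(codes, fold_tables(params, length(seq)), FALSE, TRUE)
  list(energy = res$mfe_energy,
       structure = sec_structure(length(seq), res$mfe_pairs))
}

#' Normalized ensemble defect
#'
#' NED = (1/N) sum_i (1 - P_i), where P_i is the probability that nucleotide
#' i is paired with its intended partner (paired positions of the target) or
#' unpaired (unpaired positions), over the Boltzmann ensemble.
#'
#' @param seq sequence.
#' @param target target [sec_structure()].
#' @param probs a `pz_fold` (or its probability matrix) for `seq`; computed
#'   if missing.
#' @param params parameter set, needed when `probs` is missing.
#' @return list of class `ned_report`: `ned`, `per_position` (1 - P_i), `N`.
#' @export
ned <- function(seq, target, probs = NULL, params = NULL) {
  seq <- as_pz_seq(seq)
  n <- length(seq)
  if (target$length != n) {
    stop("target length (", target$length, ") does not match sequence (", n, ")")
  }
  if (is.null(probs)) {
    if (is.null(params)) stop("supply either probs or params")
    probs <- partition_function(seq, params)
  }
  p <- if (inherits(probs, "pz_fold")) probs$p else probs
  q <- 1 - rowSums(p)
  P_i <- numeric(n)
  for (i in seq_len(n)) {
    P_i[i] <- if (target$pt[i] > 0) p[i, target$pt[i]] else q[i]
  }
  structure(list(ned = mean(1 - P_i), per_position = 1 - P_i, N = n),
            class = "ned_report")
}

#' @export
print.ned_report <- function(x, ...) {
  cat("<ned_report> N =", x$N, " NED =", format(x$ned, digits = 4), "\n")
  invisible(x)
}
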