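# Exhaustive enumeration over all valid secondary structures. Tractable for
# short sequences only; used as the independent reference for the
# dynamic-programming engine.

#' Enumerate all valid secondary structures of a sequence
#'
#' All nested pair sets with allowed pairs and hairpin loops of at least
#' three unpaired nucleotides. Exponential in length; intended for
#' sequences of up to ~16 nt.
#'
#' @param seq sequence (string or `pz_seq`).
#' @param mode alphabet mode.
#' @return list of two-column pair matrices (the first entry is the empty
#'   structure).
#' @export
enumerate_structures <- function(seq, mode = alphabet_mode("DNA-PZ")) {
  s <- unclass(as_pz_seq(seq))
  n <- length(s)
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (i >= j) return(list(matrix(integer(0), 0, 2)))
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    out <- rec(i + 1, j)  # i unpaired
    if (j - i >= 4) {
      for (k in (i + 4):j) {
        if (!mode$allowed[s[i], s[k]]) next
        inner <- rec(i + 1, k - 1)
        outer <- rec(k + 1, j)
        for (a in inner) for (b in outer) {
          out <- c(out, list(rbind(c(i, k), a, b)))
        }
      }
    }
    memo[[key]] <- out
    out
  }
  rec(1L, n)
}

#' Brute-force ensemble quantities
#'
#' Computes the partition function, pair probabilities, unpaired
#' probabilities, and the minimum free energy structure by exhaustive
#' enumeration with [enumerate_structures()], scoring every structure with
#' [fold_energy()].
#'
#' @param seq sequence.
#' @param params `pz_params`.
#' @return list with `Q`, `p` (n x n matrix), `q` (unpaired probabilities),
#'   `mfe_energy`, `mfe` (a `sec_structure`), and `n_structures`.
#' @export
brute_force_fold <- function(seq, params) {
  seq <- as_pz_seq(seq)
  n <- length(seq)
  structs <- enumerate_structures(seq, params$mode)
  energies <- vapply(structs, function(prs) {
    fold_energy(seq, sec_structure(n, prs), params)
  }, numeric(1))
  w <- exp(-energies / RT_REF)
  Q <- sum(w)
  p <- matrix(0, n, n)
  for (t in seq_along(structs)) {
    prs <- structs[[t]]
    for (r in seq_len(nrow(prs))) {
      p[prs[r, 1], prs[r, 2]] <- p[prs[r, 1], prs[r, 2]] + w[t]
    }
  }
  p <- (p + t(p)) / Q
  best <- which.min(energies)
  list(Q = Q, p = p, q = 1 - rowSums(p),
       mfe_energy = energies[best],
       mfe = sec_structure(n, structs[[best]]),
       n_structures = length(structs))
}
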