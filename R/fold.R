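# Folding free energy model, shared by the reference evaluator (R) and the
# dynamic-programming engine (C++).
#
# Model summary (all terms kcal/mol at 310.15 K):
#  * helix stacks from the stack table;
#  * hairpins: length initiation + first-mismatch (terminal-mismatch table)
#    + helix-end pair penalty;
#  * bulges: length initiation only, end penalties on both flanking pairs;
#  * 1x1/2x1/2x2 internal loops from the sequence tables (+ end penalties);
#  * larger internal loops: length initiation + an end mismatch on each side
#    (+ end penalties), loops capped at 30 unpaired nucleotides;
#  * multibranch loops: linear model (offset + per-branch + per-unpaired)
#    with a terminal-stack term per helix end ("d2" convention: the
#    mismatch/dangle uses the immediate sequence neighbours regardless of
#    their pairing state);
#  * exterior helix ends: terminal mismatch when both neighbours exist,
#    otherwise a single 5'/3' dangle;
#  * the terminal-pair penalty (A-T from the canonical set; P-Z and G-Z 0 by
#    default) is charged once per helix-end side that does not stack on an
#    adjacent pair.

# Internal lookups on a pz_params object (character base arguments).
.stackE <- function(params, x1, x2, y1, y2) {
  key <- canonical_stack_key(c(x1, x2), c(y1, y2), params$mode)
  v <- params$stacks[key]
  if (is.na(v)) stop("no stack parameter for ", key)
  unname(v)
}

.hp_init <- function(params, n) {
  tab <- params$loops$hp_init
  if (n <= length(tab)) tab[n]
  else tab[length(tab)] + 1.75 * RT_REF * log(n / length(tab))
}

# Interior-loop (stack/bulge/internal) energy for outer pair (i,j) and inner
# pair (k,l), sequence s as character vector.
interior_energy <- function(params, s, i, j, k, l) {
  n1 <- k - i - 1
  n2 <- j - l - 1
  lp <- params$loops
  pens <- terminal_pair_penalty(params, s[i], s[j]) +
    terminal_pair_penalty(params, s[k], s[l])
  if (n1 == 0 && n2 == 0) {
    .stackE(params, s[i], s[k], s[j], s[l])
  } else if (n1 == 0 || n2 == 0) {
    sz <- n1 + n2
    if (sz > lp$max_loop) stop("bulge loop larger than ", lp$max_loop)
    lp$bulge_init[sz] + pens
  } else if (n1 == 1 && n2 == 1) {
    lp$int11[base_index(s[i]), base_index(s[j]), base_index(s[k]),
             base_index(s[l]), base_index(s[i + 1]), base_index(s[j - 1])] + pens
  } else if (n1 == 2 && n2 == 1) {
    lp$int21[base_index(s[i]), base_index(s[j]), base_index(s[k]),
             base_index(s[l]), base_index(s[i + 1]), base_index(s[i + 2]),
             base_index(s[j - 1])] + pens
  } else if (n1 == 1 && n2 == 2) {
    # rotated rendering: the strand with two loop nucleotides on top
    lp$int21[base_index(s[l]), base_index(s[k]), base_index(s[j]),
             base_index(s[i]), base_index(s[l + 1]), base_index(s[l + 2]),
             base_index(s[i + 1])] + pens
  } else if (n1 == 2 && n2 == 2) {
    lp$int22[base_index(s[i]), base_index(s[j]), base_index(s[k]),
             base_index(s[l]), base_index(s[i + 1]), base_index(s[i + 2]),
             base_index(s[j - 1]), base_index(s[j - 2])] + pens
  } else {
    sz <- n1 + n2
    if (sz > lp$max_loop) stop("internal loop larger than ", lp$max_loop)
    lp$intl_init[sz] +
      lp$tmm[s[i], s[j], s[i + 1], s[j - 1]] +
      lp$tmm[s[l], s[k], s[l + 1], s[k - 1]] + pens
  }
}

#' Free energy of a sequence folded into a given structure
#'
#' Evaluates the nearest-neighbor secondary-structure model (stacks, loop
#' initiations and sequence tables, multibranch linear model, exterior
#' dangles/terminal stacks, helix-end pair penalties) for one structure.
#' The empty structure is the zero reference state.
#'
#' @param seq sequence (string or `pz_seq`).
#' @param structure a [sec_structure()].
#' @param params a `pz_params` set.
#' @return free energy change in kcal/mol at 37 C.
#' @export
fold_energy <- function(seq, structure, params) {
  seq <- as_pz_seq(seq)
  check_structure_sequence(seq, structure, params$mode)
  s <- unclass(seq)
  n <- length(s)
  pt <- structure$pt
  lp <- params$loops
  total <- 0

  # children of each pair / of the exterior
  children_of <- function(i, j) {
    kids <- matrix(integer(0), 0, 2)
    k <- i + 1
    while (k < j) {
      if (pt[k] > k) {
        kids <- rbind(kids, c(k, pt[k]))
        k <- pt[k] + 1
      } else {
        k <- k + 1
      }
    }
    kids
  }

  tmm_in <- function(i, j) unname(lp$tmm[s[i], s[j], s[i + 1], s[j - 1]])
  tmm_out <- function(k, l) unname(lp$tmm[s[l], s[k], s[l + 1], s[k - 1]])
  pen <- function(i, j) terminal_pair_penalty(params, s[i], s[j])

  for (r in seq_len(nrow(structure$pairs))) {
    i <- structure$pairs[r, 1]; j <- structure$pairs[r, 2]
    kids <- children_of(i, j)
    if (nrow(kids) == 0) {
      total <- total + .hp_init(params, j - i - 1) + tmm_in(i, j) + pen(i, j)
    } else if (nrow(kids) == 1) {
      total <- total + interior_energy(params, s, i, j, kids[1, 1], kids[1, 2])
    } else {
      unpaired <- (j - i - 1) - sum(kids[, 2] - kids[, 1] + 1)
      total <- total + lp$mb[["offset"]] +
        lp$mb[["branch"]] * (nrow(kids) + 1) +
        lp$mb[["unpaired"]] * unpaired +
        tmm_in(i, j) + pen(i, j)
      for (q in seq_len(nrow(kids))) {
        total <- total + tmm_out(kids[q, 1], kids[q, 2]) +
          pen(kids[q, 1], kids[q, 2])
      }
    }
  }

  # exterior loop
  tops <- children_of(0, n + 1)
  for (q in seq_len(nrow(tops))) {
    k <- tops[q, 1]; l <- tops[q, 2]
    total <- total + pen(k, l) +
      if (k > 1 && l < n) tmm_out(k, l)
      else if (k > 1) unname(lp$d5[s[k], s[l], s[k - 1]])
      else if (l < n) unname(lp$d3[s[l], s[k], s[l + 1]])
      else 0
  }
  total
}
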