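# Two-state duplex thermodynamics from the nearest-neighbor model.

#' Specify a duplex
#'
#' Two strands hybridized antiparallel over their full length. Single-base
#' 5'/3' overhangs (scored as dangling ends), terminal mismatches, and
#' interior 1x1 or tandem 2x2 mismatches are supported; anything larger is
#' the folding engine's job.
#'
#' @param top top strand, 5'->3'.
#' @param bottom bottom strand, 5'->3'.
#' @param mode alphabet mode (defaults to DNA-PZ).
#' @return object of class `duplex_spec`.
#' @export
duplex_spec <- function(top, bottom = top, mode = alphabet_mode("DNA-PZ")) {
  top <- as_pz_seq(top)
  bottom <- as_pz_seq(bottom)
  structure(list(top = top, bottom = bottom, mode = mode),
            class = "duplex_spec")
}

#' @export
print.duplex_spec <- function(x, ...) {
  cat("<duplex_spec>\n  top    5'-", seq_string(x$top), "-3'\n  bottom 3'-",
      paste(rev(unclass(x$bottom)), collapse = ""), "-5'\n", sep = "")
  invisible(x)
}

# Align the two strands column by column (top 5'->3' over bottom 3'->5'),
# permitting at most one overhanging base per end. Picks the alignment with
# the most allowed-pair columns.
align_duplex <- function(spec) {
  t <- unclass(spec$top)
  b <- rev(unclass(spec$bottom))   # aligned 3'->5' under the top strand
  n1 <- length(t); n2 <- length(b)
  if (abs(n1 - n2) > 2) stop("strand lengths differ by more than two")
  best <- NULL
  for (off_t in 0:1) for (off_b in 0:1) {
    # off_t: top bases hanging off the left end; off_b: bottom bases ditto
    if (off_t > 0 && off_b > 0) next
    ncol_core <- min(n1 - off_t, n2 - off_b)
    right_t <- n1 - off_t - ncol_core
    right_b <- n2 - off_b - ncol_core
    if (right_t > 1 || right_b > 1 || (right_t > 0 && right_b > 0)) next
    tt <- t[(off_t + 1):(off_t + ncol_core)]
    bb <- b[(off_b + 1):(off_b + ncol_core)]
    paired <- spec$mode$allowed[cbind(tt, bb)]
    cand <- list(top = tt, bottom = bb, paired = paired,
                 left_t = if (off_t) t[1] else NA_character_,
                 left_b = if (off_b) b[1] else NA_character_,
                 right_t = if (right_t) t[n1] else NA_character_,
                 right_b = if (right_b) b[n2] else NA_character_)
    if (is.null(best) || sum(paired) > sum(best$paired)) best <- cand
  }
  if (is.null(best)) stop("no admissible antiparallel alignment")
  best
}

duplex_is_self_complementary <- function(spec) {
  identical(unclass(spec$top), unclass(spec$bottom)) &&
    is_self_complementary(spec$top)
}

terminal_pair_penalty <- function(params, x, y, what = "dG37") {
  pr <- sort(c(x, y))
  term <- if (identical(pr, c("A", "T"))) "terminal_AT"
  else if (identical(pr, c("P", "Z"))) "terminal_PZ"
  else if (identical(pr, c("G", "Z"))) "terminal_GZ"
  else return(0)
  params$penalties[[term]][[what]]
}

# Shared engine for dG37 / dH / dS prediction. `what` selects the parameter
# channel; loop motifs are only parameterized for free energy.
duplex_predict <- function(spec, params, what = c("dG37", "dH", "dS")) {
  what <- match.arg(what)
  al <- align_duplex(spec)
  n <- length(al$top)
  paired <- al$paired
  core <- range(which(paired))
  if (!any(paired)) stop("no base pairs in duplex")
  c1 <- core[1]; c2 <- core[2]

  stack_tab <- switch(what, dG37 = params$stacks, dH = params$stack_dH,
                      dS = params$stack_dS)
  pen_val <- function(term) {
    params$penalties[[term]][[if (what == "dG37") "dG37" else what]]
  }

  total <- pen_val("intermolecular_initiation")
  if (duplex_is_self_complementary(spec)) total <- total + pen_val("symmetry_correction")

  loop_only <- function() {
    if (what != "dG37") {
      stop("enthalpy/entropy parameters are not available for loop motifs")
    }
  }

  # interior columns of the core
  i <- c1
  while (i <= c2) {
    if (paired[i]) {
      if (i < c2 && paired[i + 1]) {
        key <- canonical_stack_key(al$top[i:(i + 1)], al$bottom[i:(i + 1)],
                                   params$mode)
        v <- stack_tab[key]
        if (is.na(v)) {
          stop("no ", what, " parameter for stack ", key,
               " (G-Z stacks have no enthalpy/entropy parameters)")
        }
        total <- total + v
      }
      i <- i + 1
    } else {
      run <- i
      while (run <= c2 && !paired[run]) run <- run + 1
      len <- run - i
      loop_only()
      if (len == 1) {
        total <- total + unname(params$loops$int11[
          base_index(al$top[i - 1]), base_index(al$bottom[i - 1]),
          base_index(al$top[i + 1]), base_index(al$bottom[i + 1]),
          base_index(al$top[i]), base_index(al$bottom[i])])
      } else if (len == 2) {
        total <- total + unname(params$loops$int22[
          base_index(al$top[i - 1]), base_index(al$bottom[i - 1]),
          base_index(al$top[i + 2]), base_index(al$bottom[i + 2]),
          base_index(al$top[i]), base_index(al$top[i + 1]),
          base_index(al$bottom[i]), base_index(al$bottom[i + 1])])
      } else {
        stop("interior loop of ", len,
             " columns is beyond duplex motifs; use the folding engine")
      }
      i <- run
    }
  }

  # helix-end penalties for the core's terminal pairs
  total <- total +
    terminal_pair_penalty(params, al$top[c1], al$bottom[c1], what) +
    terminal_pair_penalty(params, al$top[c2], al$bottom[c2], what)

  # left end: terminal mismatch or dangling end
  left_extra <- c1 > 1
  if (left_extra || !is.na(al$left_t) || !is.na(al$left_b)) {
    loop_only()
    if (left_extra) {
      # one unpaired column immediately outside the core
      if (c1 - 1 > 1) stop("more than one terminal mismatch column")
      total <- total + unname(
        params$loops$tmm[al$bottom[c1], al$top[c1], al$bottom[c1 - 1],
                         al$top[c1 - 1]])
    } else if (!is.na(al$left_t)) {
      total <- total + unname(params$loops$d5[al$top[c1], al$bottom[c1],
                                              al$left_t])
    } else {
      total <- total + unname(params$loops$d3[al$bottom[c1], al$top[c1],
                                              al$left_b])
    }
  }
  # right end
  right_extra <- c2 < n
  if (right_extra || !is.na(al$right_t) || !is.na(al$right_b)) {
    loop_only()
    if (right_extra) {
      if (c2 + 1 < n) stop("more than one terminal mismatch column")
      total <- total + unname(
        params$loops$tmm[al$top[c2], al$bottom[c2], al$top[c2 + 1],
                         al$bottom[c2 + 1]])
    } else if (!is.na(al$right_t)) {
      total <- total + unname(params$loops$d3[al$top[c2], al$bottom[c2],
                                              al$right_t])
    } else {
      total <- total + unname(params$loops$d5[al$bottom[c2], al$top[c2],
                                              al$right_b])
    }
  }
  unname(total)
}

#' Duplex formation free energy at 37 C
#'
#' Sum of interior stacks, intermolecular initiation, symmetry correction
#' (self-complementary duplexes only), helix-end pair penalties (terminal
#' A-T penalized; terminal P-Z and G-Z contribute 0 by default), and
#' dangling-end / terminal-mismatch / small-internal-loop increments.
#'
#' @param spec a [duplex_spec()].
#' @param params a `pz_params` set.
#' @return dG37 in kcal/mol.
#' @examples
#' p <- load_parameter_set()
#' duplex_dG37(duplex_spec("GTPPZZAC"), p)
#' @export
duplex_dG37 <- function(spec, params) duplex_predict(spec, params, "dG37")

#' Duplex formation enthalpy and entropy
#'
#' Available only when every constituent stack has enthalpy/entropy entries
#' (canonical stacks from the packaged set; P-Z stacks require a user
#' overlay; G-Z stacks never have them).
#'
#' @inheritParams duplex_dG37
#' @return list with `dH` (kcal/mol) and `dS` (cal/(mol*K)).
#' @export
duplex_dH_dS <- function(spec, params) {
  list(dH = duplex_predict(spec, params, "dH"),
       dS = duplex_predict(spec, params, "dS"))
}

#' Loop-motif stability increment by reference subtraction
#'
#' The increment of a motif is the measured duplex stability minus the
#' nearest-neighbor-predicted stability of its motif-free reference: a
#' reference helix for dangling ends and terminal mismatches, or the sum of
#' the flanking helical stack terms for internal loops (pass that sum, or a
#' reference `duplex_spec`, as `reference`).
#'
#' @param measured_dG37 experimental duplex dG37 (kcal/mol).
#' @param reference a [duplex_spec()] (predicted with [duplex_dG37()]) or a
#'   precomputed reference free energy in kcal/mol.
#' @param params `pz_params`.
#' @return motif increment in kcal/mol.
#' @export
motif_increment <- function(measured_dG37, reference, params) {
  ref <- if (inherits(reference, "duplex_spec")) {
    duplex_dG37(reference, params)
  } else if (is.numeric(reference) && length(reference) == 1) {
    reference
  } else {
    stop("reference must be a duplex_spec or a single reference free energy")
  }
  measured_dG37 - ref
}

#' Two-state melting temperature
#'
#' Tm = dH * 1000 / (dS + R ln(C_T / x)) with x = 1 for self-complementary
#' duplexes and 4 otherwise, R = 1.987 cal/(mol K).
#'
#' @param dH formation enthalpy, kcal/mol (must be negative).
#' @param dS formation entropy, cal/(mol*K).
#' @param C_T total strand concentration, mol/L.
#' @param self_complementary logical.
#' @return Tm in Kelvin.
#' @examples
#' melting_temperature(-60, -170, 1e-6, FALSE)
#' @export
melting_temperature <- function(dH, dS, C_T, self_complementary = FALSE) {
  if (dH >= 0) stop("not a two-state forming duplex (dH must be < 0)")
  x <- if (self_complementary) 1 else 4
  dH * 1000 / (dS + 1.987 * log(C_T / x))
}
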