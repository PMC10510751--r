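# Parameter store: nearest-neighbor stacks, global penalties, and the loop
# tables for the expanded alphabet built by rule-based extrapolation from
# canonical DNA values plus the measured P/Z loop increments.

R_KCAL <- 1.987e-3          # gas constant, kcal/(mol*K)
T_REF <- 310.15             # reference temperature, K (37 C)
RT_REF <- R_KCAL * T_REF

param_file <- function(name) {
  system.file("extdata", "params", name, package = "pzfold", mustWork = TRUE)
}

read_param_table <- function(path) {
  # Whitespace-delimited dialect with '#' comments and '.' for unavailable.
  # The commented header line directly above the data names the columns.
  lines <- readLines(path)
  hdr <- grep("^#\\s*\\w+\\t", lines, value = TRUE)
  cols <- strsplit(sub("^#\\s*", "", hdr[length(hdr)]), "\t")[[1]]
  df <- utils::read.table(path, header = FALSE, sep = "\t", comment.char = "#",
                          na.strings = ".", stringsAsFactors = FALSE)
  names(df) <- cols
  df
}

# ---------------------------------------------------------------------------
# Canonical loop-sequence surrogates.
#
# The canonical DNA terminal-mismatch, dangling-end and internal-loop sequence
# tables are not packaged verbatim; they are generated here from compact
# additive models calibrated to the printed canonical aggregates (mismatch
# means on G-C and T-A closings, canonical dangling-end examples). They are
# synthetic stand-ins for the reference tables, and every expanded-alphabet
# rule operates relative to them, so extrapolation offsets (for example the
# -0.6 kcal/mol internal-loop stabilizer) are exact by construction.

# Per-base stacking increment for a mismatched/unpaired nucleotide.
.mm_inc <- c(A = -0.2425, C = -0.10, G = -0.2425, T = -0.10)

closing_class <- function(x, y) {
  # "GC" for a C-G/G-C closing, otherwise "AT" (A-T, T-A and legacy G-T).
  if ((x == "C" && y == "G") || (x == "G" && y == "C")) "GC" else "AT"
}

canonical_tmm_synthetic <- function(x, y, a, b) {
  base <- if (closing_class(x, y) == "GC") -0.585 else -0.015
  base + .mm_inc[[a]] + .mm_inc[[b]]
}

.dangle_inc <- c(A = -0.35, C = -0.05, G = -0.15, T = -0.15)

canonical_dangle_synthetic <- function(side, x, y, b) {
  base <- if (side == "5p") {
    if (closing_class(x, y) == "GC") -0.55 else -0.15
  } else {
    if (closing_class(x, y) == "GC") -0.45 else -0.05
  }
  base + .dangle_inc[[b]]
}

n_at_closings <- function(x1, y1, x2, y2) {
  (closing_class(x1, y1) == "AT") + (closing_class(x2, y2) == "AT")
}

canonical_int11_synthetic <- function(x1, y1, x2, y2, a, b) {
  1.1 + .mm_inc[[a]] + .mm_inc[[b]] + 0.25 * n_at_closings(x1, y1, x2, y2)
}

canonical_int21_synthetic <- function(x1, y1, x2, y2, a1, a2, b) {
  2.4 + 0.5 * (.mm_inc[[a1]] + .mm_inc[[a2]] + .mm_inc[[b]]) +
    0.25 * n_at_closings(x1, y1, x2, y2)
}

canonical_int22_synthetic <- function(x1, y1, x2, y2, a1, a2, b1, b2) {
  1.3 + .mm_inc[[a1]] + .mm_inc[[a2]] + .mm_inc[[b1]] + .mm_inc[[b2]] +
    0.25 * n_at_closings(x1, y1, x2, y2)
}

# ---------------------------------------------------------------------------
# Extrapolation rules for the expanded alphabet.

is_pz_base <- function(b) b %in% c("P", "Z")

# Map a loop nucleotide to its canonical surrogate: P -> G, Z -> C.
map_loop_base <- function(b) switch(b, P = "G", Z = "C", b)

is_wcf_pair <- function(a, b) {
  (a == "A" && b == "T") || (a == "T" && b == "A") ||
    (a == "C" && b == "G") || (a == "G" && b == "C")
}

# Map a mismatch column; if the mapped column would be a Watson-Crick-Franklin
# pair, remap to A-C preserving purine-pyrimidine orientation.
map_mismatch_column <- function(a, b) {
  a2 <- map_loop_base(a)
  b2 <- map_loop_base(b)
  if (is_wcf_pair(a2, b2)) {
    a2 <- if (PZ_CLASS[[a2]] == "purine") "A" else "C"
    b2 <- if (a2 == "A") "C" else "A"
  }
  c(a2, b2)
}

# Map a closing pair: P-Z -> G-C and G-Z -> A-T, preserving orientation.
map_closing_pair <- function(x, y) {
  m <- function(b, partner) {
    if (b == "P") "G" else if (b == "Z" && partner == "P") "C"
    else if (b == "Z" && partner == "G") "T"
    else if (b == "G" && partner == "Z") "A"
    else b
  }
  c(m(x, y), m(y, x))
}

measured_default <- function() {
  read_param_table(param_file("measured_loops.tsv"))
}

parse_closing <- function(s) strsplit(s, "-", fixed = TRUE)[[1]]

#' Build the loop parameter tables for an alphabet mode
#'
#' Assembles the complete dangling-end, terminal-mismatch and 1x1/2x1/2x2
#' internal-loop tables over the alphabet, applying, in order: measured
#' values verbatim; dangling-end and mismatch means for unmeasured P/Z
#' contexts; the fixed -0.2 kcal/mol default for terminal mismatches on
#' P-Z/Z-G/G-Z closings; and the canonical-remapping rule (P to G, Z to C,
#' Watson-Crick-Franklin results remapped to A-C) with a -0.6 kcal/mol
#' stabilizer per P/Z-containing mismatch for the internal-loop tables.
#' Hairpin first-mismatch, large-internal-loop end-mismatch and coaxial
#' mismatch energies are taken equal to the terminal-mismatch table.
#'
#' @param mode an [alphabet_mode()].
#' @param measured data frame of measured loop increments (columns `type`,
#'   `closing`, `content`, `dG37`); defaults to the packaged main-text values.
#'   Supplementary measurements can be overlaid by row-binding.
#' @return A `loop_tables` list of dense arrays indexed by base (A,C,G,T,P,Z)
#'   plus loop-length initiation vectors and multibranch coefficients.
#' @export
extrapolate_loop_tables <- function(mode = alphabet_mode("DNA-PZ"),
                                    measured = measured_default()) {
  B <- PZ_BASES
  closings <- which(mode$allowed, arr.ind = TRUE)  # ordered (x, y) pairs

  tmm <- array(NA_real_, c(6, 6, 6, 6), dimnames = list(B, B, B, B))
  d5 <- array(NA_real_, c(6, 6, 6), dimnames = list(B, B, B))
  d3 <- array(NA_real_, c(6, 6, 6), dimnames = list(B, B, B))

  meas_key <- function(type, x, y, content) paste(type, x, y, content, sep = "|")
  meas <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(measured))) {
    cl <- parse_closing(measured$closing[i])
    cn <- measured$content[i]
    v <- measured$dG37[i]
    # measured increments are applied to both orientations of the closing pair
    for (ori in list(cl, rev(cl))) {
      assign(meas_key(measured$type[i], ori[1], ori[2], cn), v, envir = meas)
    }
  }
  get_meas <- function(type, x, y, content) {
    k <- meas_key(type, x, y, content)
    if (exists(k, envir = meas)) get(k, envir = meas) else NULL
  }

  closing_has_pz <- function(x, y) is_pz_base(x) || is_pz_base(y)

  for (r in seq_len(nrow(closings))) {
    x <- B[closings[r, 1]]
    y <- B[closings[r, 2]]
    # --- terminal mismatches -------------------------------------------
    for (a in B) for (b in B) {
      v <- get_meas("tmm", x, y, paste0(a, "-", b))
      if (is.null(v)) v <- get_meas("tmm", x, y, paste0(b, "-", a))
      if (is.null(v)) {
        if (a == "P" && b == "P") {
          v <- -0.5
        } else if (a == "Z" && b == "Z") {
          v <- -0.8
        } else if (closing_has_pz(x, y)) {
          v <- -0.2
        } else if (is_pz_base(a) || is_pz_base(b)) {
          m <- map_mismatch_column(a, b)
          v <- canonical_tmm_synthetic(x, y, m[1], m[2])
        } else {
          v <- canonical_tmm_synthetic(x, y, a, b)
        }
      }
      tmm[x, y, a, b] <- v
    }
    # --- dangling ends --------------------------------------------------
    for (b in B) {
      for (side in c("5p", "3p")) {
        v <- get_meas(if (side == "5p") "d5" else "d3", x, y, b)
        if (is.null(v)) {
          if (b == "P") {
            v <- if (side == "5p") -0.5 else 0.1
          } else if (b == "Z") {
            v <- if (side == "5p") -0.7 else -0.1
          } else if ((x == "P" && y == "Z") || (x == "Z" && y == "P")) {
            v <- -0.1
          } else if (closing_has_pz(x, y)) {
            m <- map_closing_pair(x, y)
            v <- canonical_dangle_synthetic(side, m[1], m[2], b)
          } else {
            v <- canonical_dangle_synthetic(side, x, y, b)
          }
        }
        if (side == "5p") d5[x, y, b] <- v else d3[x, y, b] <- v
      }
    }
  }

  # --- internal loop sequence tables -----------------------------------
  int11 <- array(NA_real_, c(6, 6, 6, 6, 6, 6))
  int21 <- array(NA_real_, rep(6, 7))
  int22 <- array(NA_real_, rep(6, 8))
  for (r1 in seq_len(nrow(closings))) {
    x1 <- B[closings[r1, 1]]; y1 <- B[closings[r1, 2]]
    c1 <- map_closing_pair(x1, y1)
    for (r2 in seq_len(nrow(closings))) {
      x2 <- B[closings[r2, 1]]; y2 <- B[closings[r2, 2]]
      c2 <- map_closing_pair(x2, y2)
      i1 <- base_index(x1); j1 <- base_index(y1)
      i2 <- base_index(x2); j2 <- base_index(y2)
      for (a in B) for (b in B) {
        m <- map_mismatch_column(a, b)
        pen <- -0.6 * (is_pz_base(a) || is_pz_base(b))
        int11[i1, j1, i2, j2, base_index(a), base_index(b)] <-
          canonical_int11_synthetic(c1[1], c1[2], c2[1], c2[2], m[1], m[2]) + pen
      }
      for (a1 in B) for (a2 in B) for (b in B) {
        pen <- -0.6 * (is_pz_base(a1) || is_pz_base(a2) || is_pz_base(b))
        int21[i1, j1, i2, j2, base_index(a1), base_index(a2), base_index(b)] <-
          canonical_int21_synthetic(c1[1], c1[2], c2[1], c2[2],
                                    map_loop_base(a1), map_loop_base(a2),
                                    map_loop_base(b)) + pen
      }
      for (a1 in B) for (a2 in B) for (b1 in B) for (b2 in B) {
        m1 <- map_mismatch_column(a1, b1)
        m2 <- map_mismatch_column(a2, b2)
        pen <- -0.6 * ((is_pz_base(a1) || is_pz_base(b1)) +
                         (is_pz_base(a2) || is_pz_base(b2)))
        int22[i1, j1, i2, j2, base_index(a1), base_index(a2),
              base_index(b1), base_index(b2)] <-
          canonical_int22_synthetic(c1[1], c1[2], c2[1], c2[2],
                                    m1[1], m2[1], m1[2], m2[2]) + pen
      }
    }
  }

  # --- loop length initiations -----------------------------------------
  len <- read_param_table(param_file("loop_lengths.tsv"))
  max_tab <- 30
  js_extend <- function(v) {
    known <- which(!is.na(v))
    top <- max(known)
    out <- c(v, rep(NA_real_, max_tab - length(v)))
    for (n in seq_len(max_tab)) {
      if (is.na(out[n]) && n > top) {
        out[n] <- v[top] + 1.75 * RT_REF * log(n / top)
      }
    }
    out
  }
  hp_init <- js_extend(
    vapply(1:10, function(s) {
      i <- match(s, len$size)
      if (is.na(i)) NA_real_ else len$hairpin[i]
    }, numeric(1)))
  bulge_init <- js_extend(
    vapply(1:10, function(s) len$bulge[match(s, len$size)], numeric(1)))
  intl_init <- js_extend(
    vapply(1:10, function(s) len$internal[match(s, len$size)], numeric(1)))

  structure(list(
    tmm = tmm, d5 = d5, d3 = d3,
    int11 = int11, int21 = int21, int22 = int22,
    hp_init = hp_init, bulge_init = bulge_init, intl_init = intl_init,
    max_loop = 30,
    # multibranch linear model: offset, per-branch, per-unpaired (kcal/mol)
    mb = c(offset = 3.4, branch = 0.4, unpaired = 0.0)
  ), class = "loop_tables")
}

# ---------------------------------------------------------------------------
# Parameter set assembly.

#' Load a complete nearest-neighbor parameter set
#'
#' Reads the packaged stack tables (canonical Watson-Crick-Franklin values,
#' the 11 unique P-Z stacks and, in DNA-PZ mode, the 15 G-Z stacks), global
#' penalties, and builds the full loop tables via [extrapolate_loop_tables()].
#' Loading is deterministic and validated: in DNA-PZ mode every one of the 36
#' unique helix stacks must resolve.
#'
#' @param mode an [alphabet_mode()] or a mode name.
#' @param measured_loops optional data frame overriding/extending the packaged
#'   measured loop increments.
#' @return An object of class `pz_params`.
#' @examples
#' p <- load_parameter_set()
#' stack_dG37(p, "ZP/PZ")   # -3.35
#' @export
load_parameter_set <- function(mode = alphabet_mode("DNA-PZ"),
                               measured_loops = NULL) {
  if (is.character(mode)) mode <- alphabet_mode(mode)
  dna <- read_param_table(param_file("dna_stacks.tsv"))
  pen <- read_param_table(param_file("penalties.tsv"))

  stacks <- numeric(0)
  stack_dH <- numeric(0)
  stack_dS <- numeric(0)
  stack_stderr <- numeric(0)
  add_stack <- function(rendering, dG, dH = NA_real_, dS = NA_real_,
                        se = NA_real_) {
    sk <- split_stack_key(rendering)
    key <- canonical_stack_key(sk$top, sk$bottom, mode)
    stacks[key] <<- dG
    stack_dH[key] <<- dH
    stack_dS[key] <<- dS
    stack_stderr[key] <<- se
  }
  for (i in seq_len(nrow(dna))) {
    add_stack(dna$stack[i], dna$dG37[i], dna$dH[i], dna$dS[i])
  }
  pz <- NULL
  gz <- NULL
  if (mode$name == "DNA-PZ") {
    pz <- read_param_table(param_file("pz_stacks.tsv"))
    for (i in seq_len(nrow(pz))) {
      add_stack(pz$stack[i], pz$dG37[i], se = pz$stderr[i])
    }
    gz <- read_param_table(param_file("gz_stacks.tsv"))
    for (i in seq_len(nrow(gz))) {
      add_stack(gz$stack[i], gz$dG37[i], se = gz$stderr[i])
    }
  }

  penalties <- lapply(seq_len(nrow(pen)), function(i) {
    c(dG37 = pen$dG37[i], dH = pen$dH[i], dS = pen$dS[i])
  })
  names(penalties) <- pen$term

  measured <- measured_default()
  if (!is.null(measured_loops)) measured <- rbind(measured, measured_loops)
  loops <- extrapolate_loop_tables(mode, measured)

  params <- structure(list(
    mode = mode,
    stacks = stacks, stack_dH = stack_dH, stack_dS = stack_dS,
    stack_stderr = stack_stderr,
    penalties = penalties,
    loops = loops,
    temperature_reference = T_REF,
    pz_table = pz, gz_table = gz, dna_table = dna,
    cache = new.env(parent = emptyenv())
  ), class = "pz_params")
  validate_parameter_set(params)
  params
}

validate_parameter_set <- function(params) {
  mode <- params$mode
  closings <- which(mode$allowed, arr.ind = TRUE)
  B <- PZ_BASES
  for (r1 in seq_len(nrow(closings))) for (r2 in seq_len(nrow(closings))) {
    key <- canonical_stack_key(
      c(B[closings[r1, 1]], B[closings[r2, 1]]),
      c(B[closings[r1, 2]], B[closings[r2, 2]]), mode)
    if (is.na(params$stacks[key])) {
      stop("missing stack parameter after load: ", key)
    }
  }
  # every legal loop query must resolve to a finite value
  for (r in seq_len(nrow(closings))) {
    x <- closings[r, 1]; y <- closings[r, 2]
    if (anyNA(params$loops$tmm[x, y, , ]) ||
        anyNA(params$loops$d5[x, y, ]) || anyNA(params$loops$d3[x, y, ])) {
      stop("incomplete loop table for closing pair ", B[x], "-", B[y])
    }
  }
  invisible(params)
}

#' @export
print.pz_params <- function(x, ...) {
  cat("<pz_params>", x$mode$name, "-", length(x$stacks), "stacks,",
      "T_ref =", x$temperature_reference, "K\n")
  invisible(x)
}

#' Stack free energy lookup
#'
#' @param params a `pz_params` set.
#' @param key a stack in any rendering (`"XY/WV"`), or `top` given with
#'   `bottom`; rotation-equivalent renderings return the same value.
#' @param top,bottom alternative to `key`: two bases each (top 5'->3',
#'   bottom 3'->5').
#' @return dG37 in kcal/mol.
#' @export
stack_dG37 <- function(params, key = NULL, top = NULL, bottom = NULL) {
  if (is.null(key)) {
    key <- canonical_stack_key(top, bottom, params$mode)
  } else {
    sk <- split_stack_key(key)
    key <- canonical_stack_key(sk$top, sk$bottom, params$mode)
  }
  v <- params$stacks[key]
  if (is.na(v)) stop("no parameter for stack ", key)
  unname(v)
}

# Loop table accessors ------------------------------------------------------

check_closing <- function(params, x, y) {
  if (!params$mode$allowed[x, y]) {
    stop(sprintf("%s-%s is not an allowed closing pair in %s", x, y,
                 params$mode$name))
  }
}

#' Terminal-mismatch increment
#'
#' @param params `pz_params`.
#' @param closing closing pair, e.g. `"T-A"` (helix-end pair, top base first).
#' @param mismatch mismatch pair, e.g. `"Z-Z"` (first base stacks 3' of the
#'   top closing base).
#' @return kcal/mol.
#' @examples
#' p <- load_parameter_set()
#' loop_tmm(p, "T-A", "Z-Z")  # -0.91
#' @export
loop_tmm <- function(params, closing, mismatch) {
  cl <- parse_closing(closing)
  mm <- parse_closing(mismatch)
  check_closing(params, cl[1], cl[2])
  unname(params$loops$tmm[cl[1], cl[2], mm[1], mm[2]])
}

#' Dangling-end increment
#'
#' @param params `pz_params`.
#' @param side `"5p"` or `"3p"` (dangle on the 5' or 3' side of the top
#'   closing base).
#' @param closing closing pair, e.g. `"P-Z"`.
#' @param base the dangling base.
#' @return kcal/mol.
#' @examples
#' p <- load_parameter_set()
#' loop_dangle(p, "5p", "P-Z", "C")  # -0.1 (extrapolated mean)
#' @export
loop_dangle <- function(params, side = c("5p", "3p"), closing, base) {
  side <- match.arg(side)
  cl <- parse_closing(closing)
  check_closing(params, cl[1], cl[2])
  tab <- if (side == "5p") params$loops$d5 else params$loops$d3
  unname(tab[cl[1], cl[2], toupper(base)])
}

#' 1x1 internal-loop (single mismatch) increment
#'
#' @param params `pz_params`.
#' @param closing1,closing2 outer and inner closing pairs, e.g. `"G-C"`.
#' @param mismatch the mismatched pair, e.g. `"P-C"`.
#' @return kcal/mol.
#' @export
loop_int11 <- function(params, closing1, closing2, mismatch) {
  c1 <- parse_closing(closing1); c2 <- parse_closing(closing2)
  mm <- parse_closing(mismatch)
  check_closing(params, c1[1], c1[2]); check_closing(params, c2[1], c2[2])
  unname(params$loops$int11[base_index(c1[1]), base_index(c1[2]),
                            base_index(c2[1]), base_index(c2[2]),
                            base_index(mm[1]), base_index(mm[2])])
}

# Canonical source entry for an extrapolated int11 entry (the remapped
# all-canonical lookup before the P/Z stabilizer is applied).
int11_canonical_source <- function(params, closing1, closing2, mismatch) {
  c1 <- map_closing_pair(parse_closing(closing1)[1], parse_closing(closing1)[2])
  c2 <- map_closing_pair(parse_closing(closing2)[1], parse_closing(closing2)[2])
  mm <- parse_closing(mismatch)
  m <- map_mismatch_column(mm[1], mm[2])
  canonical_int11_synthetic(c1[1], c1[2], c2[1], c2[2], m[1], m[2])
}

# Stack table round-trip -----------------------------------------------------

#' Write the stack table to a plain-text file
#' @param params `pz_params`.
#' @param path output path.
#' @export
write_stack_table <- function(params, path) {
  df <- data.frame(stack = names(params$stacks),
                   dG37 = sprintf("%.17g", unname(params$stacks)),
                   dH = ifelse(is.na(params$stack_dH), ".",
                               sprintf("%.17g", params$stack_dH)),
                   dS = ifelse(is.na(params$stack_dS), ".",
                               sprintf("%.17g", params$stack_dS)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# stack\tdG37\tdH\tdS", con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a stack table written by [write_stack_table()]
#' @param path file path.
#' @return named numeric vector of dG37 values (attributes `dH`, `dS`).
#' @export
read_stack_table <- function(path) {
  df <- read_param_table(path)
  v <- as.numeric(df$dG37)
  names(v) <- df$stack
  attr(v, "dH") <- suppressWarnings(as.numeric(df$dH))
  attr(v, "dS") <- suppressWarnings(as.numeric(df$dS))
  v
}

# ---------------------------------------------------------------------------
# Aggregate statistics over the stack tables.

#' Summary statistics of the expanded-alphabet stack tables
#'
#' Reports (a) the mean ddG37 per P-Z substitution relative to the analogous
#' G-C stack over the 11 unique P-Z stacks (each stack's difference divided
#' by its number of P-Z pairs); (b) means over the six XP/YZ (5'-side Z) and
#' six XZ/YP (3'-side Z) stack forms; (c) extrema per stack family; and (d)
#' the G-Z substitution mean plus 5'/3'-Z G-Z means under the documented
#' partition (a stack is counted on the side where the Z of a G-Z pair sits
#' at the 5' end of its strand in the canonical or rotated rendering).
#'
#' @param params a DNA-PZ `pz_params`.
#' @return named list of statistics (kcal/mol).
#' @export
table_statistics <- function(params) {
  if (params$mode$name != "DNA-PZ") stop("requires the DNA-PZ parameter set")
  pz <- params$pz_table
  gz <- params$gz_table

  npz <- vapply(pz$stack, function(k) count_pairs_in_stack(k, "P", "Z"),
                numeric(1))
  analog <- vapply(pz$gc_analog, function(k) stack_dG37(params, k), numeric(1))
  ddG_per_sub <- (pz$dG37 - analog) / npz

  rotate_key <- function(k) {
    s <- split_stack_key(k)
    paste0(s$bottom[2], s$bottom[1], "/", s$top[2], s$top[1])
  }
  matches_form <- function(k, pos2_top, pos2_bottom) {
    test <- function(kk) {
      s <- split_stack_key(kk)
      s$top[2] == pos2_top && s$bottom[2] == pos2_bottom
    }
    test(k) || test(rotate_key(k))
  }
  xp_yz <- vapply(pz$stack, matches_form, logical(1), "P", "Z")
  xz_yp <- vapply(pz$stack, matches_form, logical(1), "Z", "P")

  ngz <- vapply(gz$stack, function(k) count_pairs_in_stack(k, "G", "Z"),
                numeric(1))
  at_analog <- vapply(gz$at_analog, function(k) {
    sk <- split_stack_key(k)
    if (any(c(sk$top, sk$bottom) %in% c("P", "Z"))) {
      stack_dG37(params, k)
    } else {
      stack_dG37(params, k)
    }
  }, numeric(1))
  gz_per_sub <- (gz$dG37 - at_analog) / ngz

  # 5'/3' Z partition for G-Z stacks: the Z of a G-Z pair is at the 5' end of
  # the top strand (position 1) or of the bottom strand (position 2, since the
  # bottom is written 3'->5').
  z5 <- logical(nrow(gz)); z3 <- logical(nrow(gz))
  for (i in seq_len(nrow(gz))) {
    for (k in c(gz$stack[i], rotate_key(gz$stack[i]))) {
      s <- split_stack_key(k)
      if (s$top[1] == "Z" && s$bottom[1] == "G") z5[i] <- TRUE
      if (s$bottom[2] == "Z" && s$top[2] == "G") z5[i] <- TRUE
      if (s$top[2] == "Z" && s$bottom[2] == "G") z3[i] <- TRUE
      if (s$bottom[1] == "Z" && s$top[1] == "G") z3[i] <- TRUE
    }
  }

  list(
    pz_mean_ddG_per_substitution = mean(ddG_per_sub),
    pz_mean_xp_yz = mean(pz$dG37[xp_yz]),
    pz_mean_xz_yp = mean(pz$dG37[xz_yp]),
    pz_min = min(pz$dG37), pz_max = max(pz$dG37),
    pz_min_stack = pz$stack[which.min(pz$dG37)],
    gz_min = min(gz$dG37), gz_max = max(gz$dG37),
    gz_min_stack = gz$stack[which.min(gz$dG37)],
    gz_max_stack = gz$stack[which.max(gz$dG37)],
    gz_mean_ddG_per_substitution = mean(gz_per_sub),
    gz_mean_z5 = mean(gz$dG37[z5]),
    gz_mean_z3 = mean(gz$dG37[z3])
  )
}
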