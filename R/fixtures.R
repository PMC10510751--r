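# Synthetic inputs: duplex-stability datasets with planted parameters,
# Eterna-like symmetric cross targets, and melt-curve fixtures. Everything
# is reproducible bit-for-bit from (parameters, seed).

#' Duplex sequences discussed with the stack tables
#'
#' The self-complementary helix duplexes named in the stack-fitting
#' narrative, as named fixtures (experimental values live with the full melt
#' datasets and are not packaged).
#' @return named character vector of top-strand sequences.
#' @export
named_duplexes <- function() {
  c(`(GTPPZZAC)2` = "GTPPZZAC",
    `(GAZZPPTC)2` = "GAZZPPTC",
    `(ZGCATGCP)2` = "ZGCATGCP")
}

# Nearest-neighbor helix prediction from an explicit stack-value vector
# (used to plant truth values that differ from the packaged tables).
predict_helix_dG <- function(top, bottom, stacks, params) {
  prof <- duplex_stack_profile(top, bottom, params$mode)
  v <- params$penalties$intermolecular_initiation[["dG37"]]
  if (prof$self_comp) v <- v + params$penalties$symmetry_correction[["dG37"]]
  for (end in prof$ends) {
    if (end == "AT") v <- v + params$penalties$terminal_AT[["dG37"]]
  }
  for (key in names(prof$stacks)) {
    if (is.na(stacks[key])) stop("truth value missing for stack ", key)
    v <- v + prof$stacks[[key]] * stacks[[key]]
  }
  unname(v)
}

random_helix_duplex <- function(len, pair_pool, mode) {
  repeat {
    tops <- character(len)
    bots <- character(len)
    for (k in seq_len(len)) {
      pr <- pair_pool[[sample.int(length(pair_pool), 1)]]
      if (stats::runif(1) < 0.5) pr <- rev(pr)
      tops[k] <- pr[1]; bots[k] <- pr[2]
    }
    # bottom strand 5'->3'
    bottom <- paste(rev(bots), collapse = "")
    top <- paste(tops, collapse = "")
    return(list(top = top, bottom = bottom))
  }
}

#' Generate a synthetic duplex-stability dataset
#'
#' Random fully paired duplexes (length 6-12 pairs) over the requested pair
#' families, with `dG37_exp` set to the nearest-neighbor prediction from the
#' planted `truth` stack values plus Gaussian noise. The composition is
#' checked (and, if needed, completed with targeted duplexes) so that every
#' free-family stack appearing in the data occurs at least twice.
#'
#' @param n number of duplexes.
#' @param truth named stack-value vector (canonical keys); defaults to the
#'   packaged table values of `params`.
#' @param noise_sd Gaussian noise, kcal/mol.
#' @param seed RNG seed.
#' @param params parameter set (alphabet, penalties).
#' @param families pair families to draw from: subset of
#'   `c("WC", "PZ", "GZ")`.
#' @param free_family which family's stacks must be covered >= 2 times.
#' @return a [melt_summary()] data frame with attribute `truth`.
#' @export
gen_duplex_dataset <- function(n = 40, truth = NULL, noise_sd = 0.3, seed = 1,
                               params = load_parameter_set(),
                               families = c("WC", "PZ"),
                               free_family = "pz") {
  set.seed(seed)
  if (is.null(truth)) truth <- params$stacks
  pool <- list()
  if ("WC" %in% families) {
    pool <- c(pool, list(c("G", "C"), c("A", "T")))
  }
  if ("PZ" %in% families) pool <- c(pool, list(c("P", "Z")))
  if ("GZ" %in% families) pool <- c(pool, list(c("G", "Z")))
  mode <- params$mode

  make_n <- function(k) {
    lapply(seq_len(k), function(i) {
      random_helix_duplex(sample(6:12, 1), pool, mode)
    })
  }
  dups <- make_n(n)
  count_free <- function(dups) {
    tab <- integer(0)
    for (d in dups) {
      st <- duplex_stack_profile(d$top, d$bottom, mode)$stacks
      for (key in names(st)) {
        if (stack_family(key) == free_family) {
          tab[key] <- (if (is.na(tab[key])) 0L else tab[key]) + st[[key]]
        }
      }
    }
    tab
  }
  # top up coverage with targeted duplexes embedding under-represented stacks
  for (round in 1:50) {
    cov <- count_free(dups)
    lacking <- names(cov)[cov < 2]
    if (!length(lacking)) break
    if (length(dups) >= n + 20) {
      stop("coverage unattainable at requested n for: ",
           paste(lacking, collapse = ", "))
    }
    sk <- split_stack_key(lacking[1])
    top <- paste(c("G", "C", sk$top, "G", "C"), collapse = "")
    bottom <- paste(rev(c("C", "G", sk$bottom, "C", "G")), collapse = "")
    dups <- c(dups, list(list(top = top, bottom = bottom)))
  }
  tops <- vapply(dups, `[[`, character(1), "top")
  bots <- vapply(dups, `[[`, character(1), "bottom")
  dg <- vapply(seq_along(dups), function(i) {
    predict_helix_dG(tops[i], bots[i], truth, params) +
      stats::rnorm(1, 0, noise_sd)
  }, numeric(1))
  out <- melt_summary(tops, bots, dg, id = sprintf("dup%02d", seq_along(dups)),
                      source = "synthetic")
  attr(out, "truth") <- truth
  out
}

#' Generate a symmetric cross ("Iron-Cross-like") target structure
#'
#' `arms` helices radiate from a central loop; with `branches = TRUE` each
#' arm ends in a three-way junction carrying two hairpin helices, mimicking
#' the fourfold-symmetric benchmark topology at a configurable scale.
#'
#' @param arms number of arms (>= 3).
#' @param stem_len helix length in base pairs (>= 1).
#' @param branches add a three-way branch (two hairpins) per arm.
#' @param hairpin hairpin loop size (>= 3).
#' @param spacer unpaired nucleotides between arms and between branch
#'   helices.
#' @return a [sec_structure()].
#' @export
gen_cross_target <- function(arms = 4, stem_len = 3, branches = TRUE,
                             hairpin = 4, spacer = 1) {
  stopifnot(arms >= 3, stem_len >= 1, hairpin >= 3, spacer >= 0)
  hp <- paste0(strrep("(", stem_len), strrep(".", hairpin),
               strrep(")", stem_len))
  inner <- if (branches) {
    paste0(strrep(".", spacer), hp, strrep(".", spacer), hp,
           strrep(".", spacer))
  } else {
    strrep(".", hairpin)
  }
  arm <- paste0(strrep("(", stem_len), inner, strrep(")", stem_len))
  db <- paste(rep(paste0(arm, strrep(".", max(1, spacer))), arms),
              collapse = "")
  dotbracket_to_structure(db)
}

#' Generate a synthetic melt-curve fixture
#'
#' Simulates a pair of absorbance melts from a planted truth model, then
#' applies Gaussian absorbance noise and (optionally) a planted pipetting
#' error on the concentrations relative to the nominal values.
#'
#' @param truth a [global_melt_model()]; its `conc` holds the true
#'   (pipetting-perturbed) concentrations.
#' @param baselines list of two single-strand baseline functions.
#' @param grid temperature grid, Celsius.
#' @param noise_rel relative absorbance noise (fraction of the local signal;
#'   the default is 0.3\% photometric noise).
#' @param seed RNG seed.
#' @return list: `curves` (what [global_fit()] ingests), `truth`,
#'   `baselines`, `nominal_CT`.
#' @export
gen_melt_fixture <- function(truth, baselines, grid = seq(10, 95, by = 0.5),
                             noise_rel = 0.003, seed = 1) {
  set.seed(seed)
  curves <- simulate_melt(truth, baselines, grid)
  curves <- lapply(curves, function(cv) {
    cv$absorbance <- cv$absorbance +
      stats::rnorm(nrow(cv), 0, noise_rel * abs(cv$absorbance))
    cv
  })
  list(curves = curves, truth = truth, baselines = baselines,
       nominal_CT = rowSums(truth$conc))
}

# Default melt-fixture truth: distinct strand baselines, ~60 C Tm duplex,
# nominal 1 uM and 5 uM total strand with a planted pipetting error.
default_melt_truth <- function(pipetting = c(1.05, 0.97, 1.02, 0.95)) {
  conc <- rbind(c(0.5e-6, 0.5e-6) * pipetting[1:2],
                c(2.5e-6, 2.5e-6) * pipetting[3:4])
  global_melt_model(dH = -65, dS = -165, hypochromicity = 0.25,
                    ds_slope = 150, conc = conc)
}

default_melt_baselines <- function() {
  # spectrally distinct strands (different extinction and temperature slope)
  list(ss_baseline(0.080e6, 4.5e2), ss_baseline(0.140e6, 1.2e2))
}
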