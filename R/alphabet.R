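#' @useDynLib pzfold, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats lm optim pt qt rnorm runif sd setNames t.test
#' @importFrom utils read.table write.table
"_PACKAGE"

# The six-letter alphabet. Order is load-bearing: integer codes 1..6 are used
# as array indices throughout (including in the C++ folding engine).
PZ_BASES <- c("A", "C", "G", "T", "P", "Z")

# P is a purine analog, Z a pyrimidine analog.
PZ_CLASS <- c(A = "purine", C = "pyrimidine", G = "purine", T = "pyrimidine",
              P = "purine", Z = "pyrimidine")

# Strict complements used for self-complementarity (G-Z is never a complement).
PZ_COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C", P = "Z", Z = "P")

base_index <- function(b) match(b, PZ_BASES)

#' Alphabet modes
#'
#' `alphabet_mode()` constructs one of the two folding alphabets:
#' \describe{
#'   \item{`"canonical-DNA"`}{allows C-G and A-T pairs. The G-T wobble is off
#'     by default so that the two modes differ only by P/Z availability; it can
#'     be re-enabled with `allow_GT = TRUE` for legacy comparisons.}
#'   \item{`"DNA-PZ"`}{allows C-G, A-T, P-Z and the G-Z wobble. G-T is never
#'     a pair in this mode; it is treated as a mismatch.}
#' }
#'
#' @param name `"canonical-DNA"` or `"DNA-PZ"`.
#' @param allow_GT re-enable the G-T wobble (canonical-DNA only).
#' @return An object of class `alphabet_mode` with the 6x6 logical pairing
#'   matrix in `$allowed`.
#' @export
alphabet_mode <- function(name = c("DNA-PZ", "canonical-DNA"), allow_GT = FALSE) {
  name <- match.arg(name)
  allowed <- matrix(FALSE, 6, 6, dimnames = list(PZ_BASES, PZ_BASES))
  pair_on <- function(x, y) {
    allowed[x, y] <<- TRUE
    allowed[y, x] <<- TRUE
  }
  pair_on("C", "G")
  pair_on("A", "T")
  if (name == "DNA-PZ") {
    if (allow_GT) stop("G-T pairs are not part of the DNA-PZ alphabet")
    pair_on("P", "Z")
    pair_on("G", "Z")
  } else if (allow_GT) {
    pair_on("G", "T")
  }
  structure(list(name = name, allowed = allowed, allow_GT = allow_GT),
            class = "alphabet_mode")
}

#' @export
print.alphabet_mode <- function(x, ...) {
  prs <- allowed_pairs(x)
  cat("<alphabet_mode>", x$name, "\n  pairs:",
      paste(apply(prs, 1, paste, collapse = "-"), collapse = ", "), "\n")
  invisible(x)
}

# Ordered list of allowed pairs (both orientations collapsed to i<=j order).
allowed_pairs <- function(mode) {
  idx <- which(mode$allowed & upper.tri(mode$allowed, diag = TRUE), arr.ind = TRUE)
  cbind(PZ_BASES[idx[, 1]], PZ_BASES[idx[, 2]])
}

#' Parse a nucleotide sequence over the expanded alphabet
#'
#' Case-insensitive; whitespace is stripped. Any symbol outside
#' \{A,C,G,T,P,Z\} is an error naming the offending position.
#'
#' @param text character scalar.
#' @param id optional sequence identifier.
#' @return An object of class `pz_seq`: a character vector of one-letter
#'   codes with an `id` attribute.
#' @examples
#' parse_sequence("gtppzzac")
#' @export
parse_sequence <- function(text, id = "") {
  stopifnot(is.character(text), length(text) == 1)
  text <- gsub("[[:space:]]", "", text)
  if (!nzchar(text)) stop("empty sequence")
  ch <- toupper(strsplit(text, "")[[1]])
  bad <- which(!ch %in% PZ_BASES)
  if (length(bad)) {
    stop(sprintf("unknown symbol '%s' at position %d", ch[bad[1]], bad[1]))
  }
  structure(ch, id = id, class = "pz_seq")
}

#' @export
print.pz_seq <- function(x, ...) {
  cat("<pz_seq>", if (nzchar(attr(x, "id") %||% "")) attr(x, "id") else "",
      paste(unclass(x), collapse = ""), "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

as_pz_seq <- function(x, id = "") {
  if (inherits(x, "pz_seq")) return(x)
  if (is.character(x) && length(x) == 1) return(parse_sequence(x, id))
  if (is.character(x)) {
    return(structure(toupper(x), id = id, class = "pz_seq"))
  }
  stop("cannot interpret input as a sequence")
}

#' Collapse a sequence object to a plain string
#' @param seq a `pz_seq` or character vector of bases.
#' @return character scalar.
#' @export
seq_string <- function(seq) paste(unclass(seq), collapse = "")

#' Pairing partners of a base under an alphabet mode
#'
#' @param base one-letter base code.
#' @param mode an [alphabet_mode()].
#' @return Character vector of bases the input can pair with (possibly empty).
#' @examples
#' pairing_partner("G", alphabet_mode("DNA-PZ"))  # C and Z
#' @export
pairing_partner <- function(base, mode) {
  base <- toupper(base)
  if (!base %in% PZ_BASES) stop("unknown base: ", base)
  PZ_BASES[mode$allowed[base, ]]
}

#' Strict reverse complement
#'
#' Uses the strict complements C-G, A-T and P-Z only; G-Z is a wobble, never
#' a complement.
#'
#' @param seq sequence (string or `pz_seq`).
#' @return `pz_seq` of the reverse complement.
#' @export
reverse_complement <- function(seq) {
  seq <- as_pz_seq(seq)
  structure(rev(unname(PZ_COMPLEMENT[unclass(seq)])),
            id = attr(seq, "id"), class = "pz_seq")
}

#' Is a strand self-complementary?
#'
#' TRUE iff the strand equals its own strict reverse complement, the condition
#' under which a duplex of two identical strands incurs the symmetry
#' correction. P-Z counts as a complement pair; G-Z never does.
#'
#' @param seq sequence (string or `pz_seq`).
#' @param mode unused except for validation; kept for interface symmetry.
#' @return logical.
#' @examples
#' is_self_complementary("GTPPZZAC")  # TRUE via P<->Z
#' @export
is_self_complementary <- function(seq, mode = NULL) {
  seq <- as_pz_seq(seq)
  if (length(seq) %% 2 == 1) return(FALSE)
  identical(unclass(reverse_complement(seq)), unclass(seq))
}

#' Canonical key for a dinucleotide stack
#'
#' A stack is two adjacent base pairs written top strand 5'->3' over bottom
#' strand 3'->5'. A stack and its 180-degree rotation (reverse both strands
#' and swap them) are the same physical object; the canonical key is the
#' lexicographically smaller of the two renderings, written `"XY/WV"`.
#'
#' @param top two bases, 5'->3' (string of length 2 or character vector).
#' @param bottom two bases, 3'->5', so `top[1]` pairs `bottom[1]`.
#' @param mode alphabet mode used to validate the two pair columns.
#' @return canonical key string such as `"PP/ZZ"`.
#' @examples
#' canonical_stack_key("ZZ", "PP")  # "PP/ZZ"
#' @export
canonical_stack_key <- function(top, bottom, mode = alphabet_mode("DNA-PZ")) {
  top <- unclass(as_pz_seq(top))
  bottom <- unclass(as_pz_seq(bottom))
  stopifnot(length(top) == 2, length(bottom) == 2)
  for (k in 1:2) {
    if (!mode$allowed[top[k], bottom[k]]) {
      stop(sprintf("column %d (%s-%s) is not an allowed pair in %s",
                   k, top[k], bottom[k], mode$name))
    }
  }
  a <- paste0(top[1], top[2], "/", bottom[1], bottom[2])
  # 180-degree rotation: bottom read 5'->3' becomes the new top.
  b <- paste0(bottom[2], bottom[1], "/", top[2], top[1])
  if (a <= b) a else b
}

# Split a "XY/WV" key into top/bottom character vectors.
split_stack_key <- function(key) {
  halves <- strsplit(key, "/", fixed = TRUE)[[1]]
  list(top = strsplit(halves[1], "")[[1]], bottom = strsplit(halves[2], "")[[1]])
}

# All stacks (as canonical keys) appearing in a fully paired duplex given as
# top strand 5'->3' and bottom strand 3'->5' aligned position by position.
duplex_stack_keys <- function(top, bottom, mode = alphabet_mode("DNA-PZ")) {
  n <- length(top)
  if (n < 2) return(character(0))
  vapply(seq_len(n - 1), function(i) {
    canonical_stack_key(top[i:(i + 1)], bottom[i:(i + 1)], mode)
  }, character(1))
}

# Does the canonical key contain a pair of the given unordered type?
stack_contains_pair <- function(key, b1, b2) {
  s <- split_stack_key(key)
  any((s$top == b1 & s$bottom == b2) | (s$top == b2 & s$bottom == b1))
}

count_pairs_in_stack <- function(key, b1, b2) {
  s <- split_stack_key(key)
  sum((s$top == b1 & s$bottom == b2) | (s$top == b2 & s$bottom == b1))
}
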