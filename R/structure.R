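# Secondary structures: pair lists with nesting and hairpin-size rules.

#' Construct a secondary structure
#'
#' @param length sequence length in nucleotides.
#' @param pairs two-column matrix of 1-based (i, j) pairs with i < j, or an
#'   empty/NULL value for the open structure.
#' @return object of class `sec_structure` with a partner vector in `$pt`
#'   (0 = unpaired).
#' @export
sec_structure <- function(length, pairs = NULL) {
  length <- as.integer(length)
  stopifnot(length >= 1)
  if (is.null(pairs) || NROW(pairs) == 0) {
    pairs <- matrix(integer(0), 0, 2)
  } else {
    pairs <- matrix(as.integer(pairs), ncol = 2)
    pairs <- t(apply(pairs, 1, sort))
    pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
  }
  pt <- integer(length)
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    if (i < 1 || j > length) stop("pair index out of range: (", i, ",", j, ")")
    if (pt[i] != 0 || pt[j] != 0) {
      stop("nucleotide in more than one pair at (", i, ",", j, ")")
    }
    if (j - i - 1 < 3) {
      stop("hairpin loop shorter than 3 at pair (", i, ",", j, ")")
    }
    pt[i] <- j; pt[j] <- i
  }
  # nesting (no pseudoknots)
  stack <- integer(0)
  for (k in seq_len(length)) {
    if (pt[k] > k) {
      stack <- c(stack, pt[k])
    } else if (pt[k] != 0 && pt[k] < k) {
      if (!length(stack) || stack[length(stack)] != k) {
        stop("pseudoknot not supported (crossing pair ending at ", k, ")")
      }
      stack <- stack[-length(stack)]
    }
  }
  structure(list(length = length, pairs = pairs, pt = pt),
            class = "sec_structure")
}

#' @export
print.sec_structure <- function(x, ...) {
  cat("<sec_structure>", x$length, "nt,", nrow(x$pairs), "pairs\n ",
      structure_to_dotbracket(x), "\n")
  invisible(x)
}

#' Convert a structure to dot-bracket notation
#' @param structure a `sec_structure`.
#' @return character scalar over `().`.
#' @export
structure_to_dotbracket <- function(structure) {
  db <- rep(".", structure$length)
  db[structure$pairs[, 1]] <- "("
  db[structure$pairs[, 2]] <- ")"
  paste(db, collapse = "")
}

#' Parse dot-bracket notation
#' @param db character scalar over `().` (no pseudoknot bracket families).
#' @return a [sec_structure()].
#' @export
dotbracket_to_structure <- function(db) {
  ch <- strsplit(gsub("[[:space:]]", "", db), "")[[1]]
  bad <- which(!ch %in% c("(", ")", "."))
  if (length(bad)) {
    stop("invalid dot-bracket symbol '", ch[bad[1]], "' at position ", bad[1])
  }
  open <- integer(0)
  pairs <- matrix(integer(0), 0, 2)
  for (k in seq_along(ch)) {
    if (ch[k] == "(") {
      open <- c(open, k)
    } else if (ch[k] == ")") {
      if (!length(open)) stop("unbalanced ')' at position ", k)
      pairs <- rbind(pairs, c(open[length(open)], k))
      open <- open[-length(open)]
    }
  }
  if (length(open)) stop("unbalanced '(' at position ", open[1])
  sec_structure(length(ch), pairs)
}

# Check that every pair of the structure is allowed for the sequence under
# the mode; returns invisibly or stops naming the offending pair.
check_structure_sequence <- function(seq, structure, mode) {
  seq <- as_pz_seq(seq)
  if (length(seq) != structure$length) {
    stop("sequence length (", length(seq), ") does not match structure length (",
         structure$length, ")")
  }
  for (r in seq_len(nrow(structure$pairs))) {
    i <- structure$pairs[r, 1]; j <- structure$pairs[r, 2]
    if (!mode$allowed[seq[[i]], seq[[j]]]) {
      stop(sprintf("pair (%d,%d) %s-%s is not allowed in %s", i, j,
                   seq[[i]], seq[[j]], mode$name))
    }
  }
  invisible(TRUE)
}
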