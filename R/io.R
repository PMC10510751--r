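# Readers and writers: FASTA over the extended letters, CT (RNAstructure
# dialect), dot-bracket, and sparse probability-matrix text files.

#' Read sequences from a FASTA file with extended letters
#'
#' P and Z are not IUPAC nucleotide codes, so the reader treats all letters
#' literally and validates them against the six-letter alphabet.
#'
#' @param path file path.
#' @return list of `pz_seq` objects named by record id.
#' @export
read_fasta_pz <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grep("^>", lines)
  if (!length(hdr)) stop("no FASTA records in ", path)
  out <- list()
  for (k in seq_along(hdr)) {
    from <- hdr[k] + 1
    to <- if (k < length(hdr)) hdr[k + 1] - 1 else length(lines)
    if (from > to) stop("empty FASTA record at line ", hdr[k])
    id <- sub("^>\\s*", "", lines[hdr[k]])
    out[[id]] <- parse_sequence(paste(lines[from:to], collapse = ""), id = id)
  }
  out
}

#' Write sequences to FASTA
#' @param seqs a `pz_seq`, character vector, or list thereof (names become
#'   record ids).
#' @param path output path.
#' @export
write_fasta_pz <- function(seqs, path) {
  if (!is.list(seqs)) seqs <- list(seqs)
  con <- file(path, "w")
  on.exit(close(con))
  nms <- names(seqs)
  for (k in seq_along(seqs)) {
    sq <- as_pz_seq(seqs[[k]])
    id <- if (!is.null(nms) && nzchar(nms[k])) nms[k]
    else if (nzchar(attr(sq, "id") %||% "")) attr(sq, "id")
    else paste0("seq", k)
    writeLines(c(paste0(">", id), seq_string(sq)), con)
  }
  invisible(path)
}

#' Write a structure (and sequence) as a CT file
#'
#' RNAstructure dialect: a header line with the count and title, then one
#' line per nucleotide: index, base, previous, next, pairing partner
#' (0 = unpaired), natural index.
#'
#' @param seq sequence.
#' @param structure a [sec_structure()].
#' @param path output path.
#' @param title header title.
#' @export
write_ct <- function(seq, structure, path, title = "pzfold") {
  seq <- as_pz_seq(seq)
  n <- length(seq)
  stopifnot(n == structure$length)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d %s", n, title), con)
  for (i in seq_len(n)) {
    writeLines(sprintf("%d %s %d %d %d %d", i, seq[[i]], i - 1,
                       if (i < n) i + 1 else 0, structure$pt[i], i), con)
  }
  invisible(path)
}

#' Read a CT file
#' @param path file path.
#' @return list with `seq` (`pz_seq`) and `structure` ([sec_structure()]).
#' @export
read_ct <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  n <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]][1])
  if (is.na(n) || length(lines) < n + 1) stop("malformed CT header in ", path)
  bases <- character(n)
  pt <- integer(n)
  for (i in seq_len(n)) {
    f <- strsplit(trimws(lines[i + 1]), "\\s+")[[1]]
    if (length(f) < 6) stop("malformed CT line ", i + 1, " in ", path)
    bases[i] <- f[2]
    pt[i] <- as.integer(f[5])
  }
  pairs <- cbind(which(pt > seq_len(n)), pt[pt > seq_len(n)])
  for (i in seq_len(n)) {
    if (pt[i] != 0 && pt[pt[i]] != i) {
      stop("inconsistent pairing at position ", i, " in ", path)
    }
  }
  list(seq = parse_sequence(paste(bases, collapse = "")),
       structure = sec_structure(n, pairs))
}

#' Read a target structure from CT or dot-bracket
#'
#' @param path file path.
#' @param format `"auto"` (by extension/content), `"ct"` or `"dotbracket"`.
#' @return list with `structure` and, for CT input, `seq`.
#' @export
read_structure <- function(path, format = c("auto", "ct", "dotbracket")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.ct$", path, ignore.case = TRUE)) "ct"
    else if (grepl("\\.(db|dbn|dot)$", path, ignore.case = TRUE)) "dotbracket"
    else {
      first <- trimws(readLines(path, n = 1))
      if (grepl("^[0-9]+(\\s|$)", first)) "ct" else "dotbracket"
    }
  }
  if (format == "ct") {
    read_ct(path)
  } else {
    lines <- trimws(readLines(path))
    lines <- lines[nzchar(lines) & !startsWith(lines, ">")]
    db <- lines[grepl("^[().]+$", lines)][1]
    if (is.na(db)) stop("no dot-bracket line found in ", path)
    list(structure = dotbracket_to_structure(db))
  }
}

#' Write a pair-probability matrix as sparse text
#'
#' Triplets `i j p` (1-based, i < j, probabilities above `threshold`)
#' followed by `i 0 q` unpaired rows, so a reader can re-verify the
#' conservation invariant.
#'
#' @param pf a `pz_fold` from [partition_function()].
#' @param path output path.
#' @param threshold drop pair entries below this probability.
#' @export
write_probability_matrix <- function(pf, path, threshold = 0) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- length(pf$seq)
  writeLines(sprintf("# n=%d columns: i j p (j=0 rows hold q_unpaired)", n),
             con)
  for (i in seq_len(n)) {
    js <- which(pf$p[i, ] > threshold)
    js <- js[js > i]
    for (j in js) {
      writeLines(sprintf("%d %d %.12g", i, j, pf$p[i, j]), con)
    }
  }
  for (i in seq_len(n)) {
    writeLines(sprintf("%d 0 %.12g", i, pf$q[i]), con)
  }
  invisible(path)
}

#' Read a sparse probability matrix written by [write_probability_matrix()]
#' @param path file path.
#' @return list with `p` (symmetric matrix) and `q` (unpaired vector).
#' @export
read_probability_matrix <- function(path) {
  hdr <- readLines(path, n = 1)
  n <- as.integer(sub(".*n=(\\d+).*", "\\1", hdr))
  df <- utils::read.table(path, comment.char = "#",
                          col.names = c("i", "j", "p"))
  p <- matrix(0, n, n)
  q <- numeric(n)
  for (r in seq_len(nrow(df))) {
    if (df$j[r] == 0) {
      q[df$i[r]] <- df$p[r]
    } else {
      p[df$i[r], df$j[r]] <- df$p[r]
      p[df$j[r], df$i[r]] <- df$p[r]
    }
  }
  list(p = p, q = q)
}

#' Write a run manifest
#'
#' Records the command, configuration values, seeds, package version and
#' input digests of a command-line run so that deterministic runs can be
#' reproduced.
#'
#' @param path output path (JSON).
#' @param command command name.
#' @param args named list of configuration values.
#' @param seed integer seed or `NA`.
#' @param inputs character vector of input file paths (digested by size).
#' @export
write_run_manifest <- function(path, command, args = list(), seed = NA,
                               inputs = character(0)) {
  esc <- function(x) gsub("\"", "\\\\\"", as.character(x))
  kv <- vapply(names(args), function(k) {
    sprintf("    \"%s\": \"%s\"", esc(k), esc(args[[k]]))
  }, character(1))
  digests <- vapply(inputs, function(f) {
    sprintf("    \"%s\": %d", esc(f), file.size(f))
  }, character(1))
  json <- c(
    "{",
    sprintf("  \"command\": \"%s\",", esc(command)),
    sprintf("  \"package\": \"pzfold %s\",",
            as.character(utils::packageVersion("pzfold"))),
    sprintf("  \"seed\": %s,", if (is.na(seed)) "null" else seed),
    sprintf("  \"time\": \"%s\",", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
    "  \"args\": {",
    paste(kv, collapse = ",\n"),
    "  },",
    "  \"input_sizes\": {",
    paste(digests, collapse = ",\n"),
    "  }",
    "}")
  writeLines(json, path)
  invisible(path)
}
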