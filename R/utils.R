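# Internal helpers shared across modules.

#' Read protein or nucleotide sequences from a FASTA file
#'
#' Thin wrapper around [Biostrings::readBStringSet()] returning a plain
#' named character vector, the internal sequence representation used
#' throughout the package.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  out <- as.character(ss)
  # drop description after first whitespace
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line width for wrapping.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(is.character(seqs))
  con <- file(path, open = "wb") # binary mode: LF line endings, byte-stable
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    n <- nchar(s)
    if (n == 0L) next
    starts <- seq(1L, n, by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, n)), con)
  }
  invisible(path)
}

# Reverse-complement of an ACGT string (vectorised over characters).
revcomp <- function(seq) {
  chars <- rev(strsplit(seq, "", fixed = TRUE)[[1]])
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(comp[chars], collapse = "")
}

# Split a string into a character vector of single characters.
str_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

# Collapse a character vector back into a string.
chars_str <- function(x) paste(x, collapse = "")

# Deterministic TSV writer (no quoting, LF endings).
write_tsv <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE, eol = "\n")
  invisible(path)
}

read_tsv <- function(path) {
  read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

# BLOSUM62 without loading the data set into the user's workspace.
blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

# Run code with a temporarily seeded RNG, restoring the caller's stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}
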