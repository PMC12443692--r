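#' Sentinel-terminated text
#'
#' Wraps a character string as the input of [build_suffix_tree()].  The text
#' must be terminated by a single sentinel character that occurs nowhere
#' else; by convention the sentinel is `"$"`, which sorts before all ASCII
#' letters and digits so that child ordering (and hence every canonical node
#' numbering in the package) is deterministic.
#'
#' @param x single character string.  Unless `append_sentinel = TRUE` it
#'   must already end with the sentinel, which must occur exactly once.
#' @param sentinel sentinel character (single byte, default `"$"`).
#' @param append_sentinel if `TRUE`, `x` must not contain the sentinel and
#'   it is appended.
#' @return An object of class `st_text`: a list with elements `string`
#'   (including the sentinel), `n` (length including the sentinel), `sigma`
#'   (number of distinct characters including the sentinel), `sentinel` and
#'   `raw` (the bytes handed to the construction routine).
#' @examples
#' st_text("AGCATAATTTAACTAAG", append_sentinel = TRUE)
#' @export
st_text <- function(x, sentinel = "$", append_sentinel = FALSE) {
  if (!is.character(x) || length(x) != 1L || is.na(x))
    stop("text must be a single character string")
  if (nchar(sentinel) != 1L)
    stop("sentinel must be a single character")
  if (append_sentinel) {
    if (grepl(sentinel, x, fixed = TRUE))
      stop("text already contains the sentinel character '", sentinel, "'")
    x <- paste0(x, sentinel)
  }
  n <- nchar(x)
  if (n < 2L)
    stop("text must contain at least one character before the sentinel")
  hits <- gregexpr(sentinel, x, fixed = TRUE)[[1L]]
  if (length(hits) != 1L || hits[1L] == -1L || hits[1L] != n)
    stop("sentinel '", sentinel, "' must occur exactly once, at the final position")
  bytes <- charToRaw(x)
  if (length(bytes) != n)
    stop("text must be single-byte encoded (ASCII)")
  structure(
    list(string = x, n = n, sigma = length(unique(as.integer(bytes))),
         sentinel = sentinel, raw = bytes),
    class = "st_text")
}

#' @export
print.st_text <- function(x, ...) {
  shown <- if (x$n > 60L) paste0(substr(x$string, 1L, 57L), "...") else x$string
  cat(sprintf("<st_text> n = %d, sigma = %d, sentinel = '%s'\n  %s\n",
              x$n, x$sigma, x$sentinel, shown))
  invisible(x)
}

#' Read and preprocess a FASTA or raw text file
#'
#' Mirrors the preprocessing applied to genome assemblies before indexing:
#' header lines and newlines are removed, lowercase letters are converted to
#' uppercase, records are concatenated in file order (or rejected), and the
#' sentinel is appended.  The same function accepts plain text files with no
#' FASTA headers.
#'
#' @param path file path.
#' @param concatenate for multi-record FASTA, `TRUE` concatenates the
#'   records in file order; `FALSE` rejects files with more than one record.
#' @param sentinel sentinel character appended after preprocessing.
#' @return An [st_text] object.
#' @export
read_and_preprocess_fasta <- function(path, concatenate = TRUE, sentinel = "$") {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty input file: ", path)
  headers <- startsWith(lines, ">")
  if (!concatenate && sum(headers) > 1L)
    stop("multi-record FASTA rejected (", sum(headers), " records); set concatenate = TRUE")
  seq <- paste(toupper(lines[!headers]), collapse = "")
  if (!nzchar(seq)) stop("no sequence content in ", path)
  if (grepl(sentinel, seq, fixed = TRUE))
    stop("input contains the sentinel character '", sentinel, "'")
  st_text(seq, sentinel = sentinel, append_sentinel = TRUE)
}

#' Generate a deterministic synthetic text
#'
#' Fixture generator standing in for genome downloads.  Four models:
#' \describe{
#'   \item{`uniform`}{i.i.d. uniform draws over `alphabet`; the default
#'     four-letter DNA alphabet mimics the tested genomes, whose effective
#'     alphabet is 4--5 symbols.}
#'   \item{`markov`}{first-order Markov chain with a random (seeded)
#'     transition matrix, giving mildly skewed composition.}
#'   \item{`repeat_heavy`}{a random core of about a tenth of the target
#'     length is tandem-duplicated with 1\% point substitutions, stressing
#'     deep internal nodes and suffix-link fan-in.}
#'   \item{`run`}{the single-character run `X^length`, the maximal-height
#'     degenerate case.}
#' }
#' Output is identical for identical arguments.
#'
#' @param model one of `"uniform"`, `"markov"`, `"repeat_heavy"`, `"run"`.
#' @param length number of characters before the sentinel (>= 1).
#' @param alphabet character vector of single characters (sentinel excluded).
#' @param seed integer seed; the caller's RNG state is left untouched.
#' @param sentinel sentinel character.
#' @return An [st_text] object of total length `length + 1`.
#' @export
generate_synthetic <- function(model = c("uniform", "markov", "repeat_heavy", "run"),
                               length, alphabet = c("A", "C", "G", "T"),
                               seed = 1L, sentinel = "$") {
  model <- match.arg(model)
  if (length < 1L) stop("length must be >= 1")
  if (any(nchar(alphabet) != 1L)) stop("alphabet entries must be single characters")
  if (sentinel %in% alphabet) stop("alphabet must not contain the sentinel")
  alphabet <- unique(alphabet)
  s <- withr::with_seed(seed, {
    switch(model,
      uniform = paste(sample(alphabet, length, replace = TRUE), collapse = ""),
      markov = {
        k <- length(alphabet)
        trans <- matrix(stats::rgamma(k * k, shape = 1), nrow = k)
        trans <- trans / rowSums(trans)
        out <- integer(length)
        out[1L] <- sample.int(k, 1L)
        if (length > 1L)
          for (i in 2L:length)
            out[i] <- sample.int(k, 1L, prob = trans[out[i - 1L], ])
        paste(alphabet[out], collapse = "")
      },
      repeat_heavy = {
        core_len <- max(2L, length %/% 10L)
        core <- sample(alphabet, core_len, replace = TRUE)
        out <- character(0)
        while (sum(nchar(out)) < length) {
          unit <- core
          mut <- which(stats::runif(core_len) < 0.01)
          if (length(mut) > 0L)
            unit[mut] <- sample(alphabet, length(mut), replace = TRUE)
          out <- c(out, paste(unit, collapse = ""))
        }
        substr(paste(out, collapse = ""), 1L, length)
      },
      run = strrep(alphabet[1L], length)
    )
  })
  st_text(s, sentinel = sentinel, append_sentinel = TRUE)
}
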