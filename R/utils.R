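#' Reverse complement of DNA strings
#'
#' @param x character vector of sequences over A,C,G,T,N (case-insensitive).
#' @return character vector of reverse complements, uppercased.
#' @export
#' @examples
#' reverse_complement("ACGTN")
reverse_complement <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(toupper(x))))
}

# Derive a reproducible 31-bit substream seed from a master seed and a
# stage name, so that pipeline stages can be re-run in isolation.
substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  val <- (as.double(seed) * 48271 + h * 16807) %% 2147483629
  as.integer(val %% 2147483647L)
}

# Run code under a local RNG state seeded from (seed, name); restores the
# caller's RNG afterwards.
with_substream <- function(seed, name, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(substream_seed(seed, name))
  force(code)
}

# Random DNA string(s) at a given GC content.
random_dna <- function(n_bases, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  intToUtf8(utf8ToInt("ACGT")[sample.int(4L, n_bases, replace = TRUE, prob = p)],
            multiple = FALSE)
}

fmt_count <- function(x) format(x, big.mark = ",", scientific = FALSE, trim = TRUE)

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Write a TSV report with a fixed column order; never quotes, never rownames.
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE, ...)
}
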