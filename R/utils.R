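# Internal helpers: hierarchical seeding and sequence utilities.
#
# One global integer seed is split into per-entity streams by hashing the
# entity's string key, so any subset of a community regenerates identically.

hash_key <- function(key) {
  h <- 17
  for (c in utf8ToInt(key)) h <- (h * 31 + c) %% 2147483647
  h
}

split_seed <- function(seed, ...) {
  key <- paste(..., sep = "/")
  ((as.numeric(seed) %% 2147483647) * 48271 + hash_key(key)) %% 2147483629 + 1
}

# Evaluate `code` under a fixed RNG state, restoring the caller's stream.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% 2147483647))
  force(code)
}

DNA_BASES <- c("A", "C", "G", "T")

random_dna <- function(n) {
  if (n <= 0) return("")
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# k-mer decomposition of a nucleotide string
kmers <- function(x, k) {
  n <- nchar(x)
  if (n < k) return(character(0))
  substring(x, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L)
}

check_dna_alphabet <- function(x) {
  if (!grepl("^[ACGTN]*$", x)) {
    stop("sequence contains characters outside {A,C,G,T,N}", call. = FALSE)
  }
  invisible(x)
}

stop_codons <- function(table) {
  table <- as.integer(table)
  if (table == 11L) c("TAA", "TAG", "TGA")
  else if (table == 25L) c("TAA", "TAG")
  else stop("unsupported translation table: ", table, call. = FALSE)
}

# genetic code for translation; table 25 reads TGA as glycine
genetic_code_table <- function(table) {
  table <- as.integer(table)
  code <- Biostrings::GENETIC_CODE
  if (table == 25L) code["TGA"] <- "G"
  else if (table != 11L) stop("unsupported translation table: ", table, call. = FALSE)
  code
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE, comment.char = "")
}
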