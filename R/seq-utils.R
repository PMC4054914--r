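#' @importFrom Biostrings DNAString DNAStringSet AAString AAStringSet
#'   reverseComplement pairwiseAlignment writeXStringSet readDNAStringSet
#'   nucleotideSubstitutionMatrix matchPattern translate pattern subject
#'   alignedPattern alignedSubject score nedit GENETIC_CODE
#' @importFrom stringi stri_locate_all_fixed stri_sub stri_rand_strings
#' @importFrom stats setNames runif rbinom
#' @importFrom utils head tail write.table read.table
NULL

DNA_BASES <- c("A", "C", "G", "T")
AA20 <- c("A","R","N","D","C","Q","E","G","H","I",
          "L","K","M","F","P","S","T","W","Y","V")

#' Reverse complement of a DNA string
#'
#' Thin character-level wrapper around [Biostrings::reverseComplement()].
#'
#' @param x single DNA character string.
#' @return reverse-complemented character string.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

## Run code under a locally-set RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

## Derive a child seed from a parent seed and a stream index; stays < 2^31.
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1103L + 12345 * as.numeric(k)) %% 2147483629)
}

## Split a string into single characters.
chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

## Reverse codon table: amino acid -> codons (DNA).
aa_codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
}

## Encode a protein as DNA, picking codons uniformly at random (seeded caller).
encode_protein <- function(protein) {
  tab <- aa_codon_table()
  aa <- chars(protein)
  paste(vapply(aa, function(a) {
    cods <- tab[[a]]
    if (is.null(cods)) stop("cannot encode residue: ", a)
    cods[sample.int(length(cods), 1L)]
  }, character(1)), collapse = "")
}

## Fast conceptual translation of one frame: vectorized codon lookup in the
## standard genetic code; non-standard/ambiguous codons become X, stops "*".
translate_frame <- function(dna, off = 0L) {
  L <- nchar(dna) - off
  L <- L - L %% 3L
  if (L < 3L) return("")
  starts <- seq.int(off + 1L, off + L, by = 3L)
  aa <- unname(Biostrings::GENETIC_CODE[substring(dna, starts, starts + 2L)])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

## Random DNA of given length and GC content (uses the current RNG stream).
random_dna <- function(length, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(DNA_BASES, length, replace = TRUE, prob = p), collapse = "")
}

## Substitution matrix for DNA global alignments (shared across modules).
dna_submat <- function() {
  Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -2,
                                           baseOnly = FALSE)
}

blosum62 <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      e <- new.env()
      data("BLOSUM62", package = "Biostrings", envir = e)
      m <<- e$BLOSUM62
    }
    m
  }
})

## Columns of a pairwise alignment as two equal-length character vectors.
alignment_rows <- function(aln) {
  list(p = chars(as.character(Biostrings::alignedPattern(aln))),
       s = chars(as.character(Biostrings::alignedSubject(aln))))
}

## Drop leading/trailing columns where either row has a terminal gap run.
trim_terminal_gaps <- function(p, s) {
  n <- length(p)
  gap <- p == "-" | s == "-"
  i <- 1L
  while (i <= n && gap[i]) i <- i + 1L
  j <- n
  while (j >= i && gap[j]) j <- j - 1L
  if (i > j) return(list(p = character(0), s = character(0)))
  list(p = p[i:j], s = s[i:j])
}
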