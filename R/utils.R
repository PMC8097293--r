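# Internal helpers shared across modules.

#' @import methods
#' @importFrom stats runif rbinom rgamma setNames optim pchisq qnorm qlnorm sd median
#' @importFrom utils head tail
NULL

# Evaluate expr under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is left untouched. seed = NULL means "use the current stream".
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

.DNA_BASES <- c("A", "C", "G", "T")

.asDnaString <- function(x) {
  if (is(x, "DNAString")) x else Biostrings::DNAString(as.character(x))
}

.dnaChars <- function(x) strsplit(as.character(x), "", fixed = TRUE)[[1]]

.complementChars <- function(chars) {
  chartr("ACGTN", "TGCAN", chars)
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

.checkDnaAlphabet <- function(x, allow_n = TRUE) {
  s <- as.character(x)
  pat <- if (allow_n) "^[ACGTN]*$" else "^[ACGT]*$"
  if (!grepl(pat, s))
    stop("sequence contains non-nucleotide symbols (alphabet ACGT",
         if (allow_n) "N", ")", call. = FALSE)
  invisible(TRUE)
}

# Coerce an aligned sequence collection (XStringSet, character vector or
# character matrix) to a character matrix, one row per sequence.
.alignmentMatrix <- function(aln) {
  if (is.matrix(aln) && is.character(aln)) return(aln)
  if (is(aln, "XStringSet")) aln <- as.character(aln)
  if (!is.character(aln)) stop("alignment must be an XStringSet, character ",
                               "vector or character matrix", call. = FALSE)
  w <- nchar(aln)
  if (length(unique(w)) != 1L)
    stop("ragged alignment: sequences have unequal widths", call. = FALSE)
  m <- do.call(rbind, strsplit(aln, "", fixed = TRUE))
  rownames(m) <- names(aln)
  m
}

.GAP_CHARS <- c("-", ".")

`%||%` <- function(a, b) if (is.null(a)) b else a
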