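DNA_BASES <- c("A", "C", "G", "T")

# single-character complement lookup (hot path; chartr is too slow per call)
COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N", `-` = "-")

#' Complement and reverse-complement of DNA strings
#'
#' Vectorised over input. `N` is self-complementary; any other character is
#' left untouched (callers validate alphabets at the package boundary).
#'
#' @param x character vector of DNA sequences.
#' @return character vector of the same length.
#' @export
#' @examples
#' dna_revcomp("ACGTN")
dna_revcomp <- function(x) {
  stringi::stri_reverse(dna_complement(x))
}

#' @rdname dna_revcomp
#' @export
dna_complement <- function(x) {
  chartr("ACGTacgtN", "TGCAtgcaN", x)
}

# split a sequence into single characters (hot path helper)
seq_chars <- function(s) {
  strsplit(s, "", fixed = TRUE)[[1]]
}

# run `code` under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# 0-based half-open interval overlap length
interval_overlap <- function(s1, e1, s2, e2) {
  pmax(0L, pmin(e1, e2) - pmax(s1, s2))
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single number in [%s, %s]", name, lower, upper))
  }
  invisible(x)
}
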