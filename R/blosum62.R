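# The standard BLOSUM62 amino-acid substitution matrix (half-bit log-odds),
# embedded as a constant so recoding edits can be scored without any
# external dependency. Letters include ambiguity codes (B, J, Z, X) and the
# stop symbol '*'.
.blosum62_letters <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M",
                       "F","P","S","T","W","Y","V","B","J","Z","X","*")

.blosum62_values <- c(
  c(4, -1, -2, -2, 0, -1, -1, 0, -2, -1, -1, -1, -1, -2, -1, 1, 0, -3, -2, 0, -2, -1, -1, -1, -4),
  c(-1, 5, 0, -2, -3, 1, 0, -2, 0, -3, -2, 2, -1, -3, -2, -1, -1, -3, -2, -3, -1, -2, 0, -1, -4),
  c(-2, 0, 6, 1, -3, 0, 0, 0, 1, -3, -3, 0, -2, -3, -2, 1, 0, -4, -2, -3, 4, -3, 0, -1, -4),
  c(-2, -2, 1, 6, -3, 0, 2, -1, -1, -3, -4, -1, -3, -3, -1, 0, -1, -4, -3, -3, 4, -3, 1, -1, -4),
  c(0, -3, -3, -3, 9, -3, -4, -3, -3, -1, -1, -3, -1, -2, -3, -1, -1, -2, -2, -1, -3, -1, -3, -1, -4),
  c(-1, 1, 0, 0, -3, 5, 2, -2, 0, -3, -2, 1, 0, -3, -1, 0, -1, -2, -1, -2, 0, -2, 4, -1, -4),
  c(-1, 0, 0, 2, -4, 2, 5, -2, 0, -3, -3, 1, -2, -3, -1, 0, -1, -3, -2, -2, 1, -3, 4, -1, -4),
  c(0, -2, 0, -1, -3, -2, -2, 6, -2, -4, -4, -2, -3, -3, -2, 0, -2, -2, -3, -3, -1, -4, -2, -1, -4),
  c(-2, 0, 1, -1, -3, 0, 0, -2, 8, -3, -3, -1, -2, -1, -2, -1, -2, -2, 2, -3, 0, -3, 0, -1, -4),
  c(-1, -3, -3, -3, -1, -3, -3, -4, -3, 4, 2, -3, 1, 0, -3, -2, -1, -3, -1, 3, -3, 3, -3, -1, -4),
  c(-1, -2, -3, -4, -1, -2, -3, -4, -3, 2, 4, -2, 2, 0, -3, -2, -1, -2, -1, 1, -4, 3, -3, -1, -4),
  c(-1, 2, 0, -1, -3, 1, 1, -2, -1, -3, -2, 5, -1, -3, -1, 0, -1, -3, -2, -2, 0, -3, 1, -1, -4),
  c(-1, -1, -2, -3, -1, 0, -2, -3, -2, 1, 2, -1, 5, 0, -2, -1, -1, -1, -1, 1, -3, 2, -1, -1, -4),
  c(-2, -3, -3, -3, -2, -3, -3, -3, -1, 0, 0, -3, 0, 6, -4, -2, -2, 1, 3, -1, -3, 0, -3, -1, -4),
  c(-1, -2, -2, -1, -3, -1, -1, -2, -2, -3, -3, -1, -2, -4, 7, -1, -1, -4, -3, -2, -2, -3, -1, -1, -4),
  c(1, -1, 1, 0, -1, 0, 0, 0, -1, -2, -2, 0, -1, -2, -1, 4, 1, -3, -2, -2, 0, -2, 0, -1, -4),
  c(0, -1, 0, -1, -1, -1, -1, -2, -2, -1, -1, -1, -1, -2, -1, 1, 5, -2, -2, 0, -1, -1, -1, -1, -4),
  c(-3, -3, -4, -4, -2, -2, -3, -2, -2, -3, -2, -3, -1, 1, -4, -3, -2, 11, 2, -3, -4, -2, -2, -1, -4),
  c(-2, -2, -2, -3, -2, -1, -2, -3, 2, -1, -1, -2, -1, 3, -3, -2, -2, 2, 7, -1, -3, -1, -2, -1, -4),
  c(0, -3, -3, -3, -1, -2, -2, -3, -3, 3, 1, -2, 1, -1, -2, -2, 0, -3, -1, 4, -3, 2, -2, -1, -4),
  c(-2, -1, 4, 4, -3, 0, 1, -1, 0, -3, -4, 0, -3, -3, -2, 0, -1, -4, -3, -3, 4, -3, 0, -1, -4),
  c(-1, -2, -3, -3, -1, -2, -3, -4, -3, 3, 3, -3, 2, 0, -3, -2, -1, -2, -1, 2, -3, 3, -3, -1, -4),
  c(-1, 0, 0, 1, -3, 4, 4, -2, 0, -3, -3, 1, -1, -3, -1, 0, -1, -2, -2, -2, 0, -3, 4, -1, -4),
  c(-1, -1, -1, -1, -1, -1, -1, -1, -1, -1, -1, -1, -1, -1, -1, -1, -1, -1, -1, -1, -1, -1, -1, -1, -4),
  c(-4, -4, -4, -4, -4, -4, -4, -4, -4, -4, -4, -4, -4, -4, -4, -4, -4, -4, -4, -4, -4, -4, -4, -4, 1)
)

#' The embedded BLOSUM62 matrix
#' @return A 25 x 25 integer matrix with amino-acid letters (plus B, J, Z,
#'   X and `*`) as dimnames.
#' @export
blosum62_matrix <- function() {
  n <- length(.blosum62_letters)
  matrix(as.integer(.blosum62_values), n, n, byrow = TRUE,
         dimnames = list(.blosum62_letters, .blosum62_letters))
}

#' BLOSUM62 substitution score of an amino-acid change
#'
#' @param ref_aa,alt_aa single-letter amino-acid codes (vectorised); the
#'   stop codon is `"*"`.
#' @return Integer BLOSUM62 scores; `NA` for letters outside the matrix.
#' @export
#' @examples
#' blosum62_score("K", "E")  # 1: a conservative change
#' blosum62_score("Y", "C")  # -2
blosum62_score <- function(ref_aa, alt_aa) {
  m <- blosum62_matrix()
  i <- match(ref_aa, rownames(m))
  j <- match(alt_aa, colnames(m))
  out <- rep(NA_integer_, max(length(i), length(j)))
  i <- rep_len(i, length(out))
  j <- rep_len(j, length(out))
  ok <- !is.na(i) & !is.na(j)
  out[ok] <- m[cbind(i[ok], j[ok])]
  out
}
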