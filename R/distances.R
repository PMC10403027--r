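.asStateInts <- function(x) {
  if (is(x, "CareSequences")) {
    if (length(x) != 1L)
      stop("expected a single sequence; subset the CareSequences object first")
    return(as.integer(x@states[1L, ]))
  }
  .stateToInt(x)
}

#' Optimal-matching distance between two state sequences
#'
#' The minimum total cost of transforming one sequence into the other using
#' insertions, deletions (indels) and substitutions, computed by dynamic
#' programming over the (|x|+1) x (|y|+1) grid. Substituting a state for
#' itself costs 0. Under the default scheme (indel 1, constant substitution
#' 2) the distance equals the longest-common-subsequence metric
#' `|x| + |y| - 2 * lcsLength(x, y)`.
#'
#' Sequences of any length over the five-state alphabet are accepted; they
#' need not be equal-length 365-day sequences.
#'
#' @param x,y state sequences: vectors of state labels, single-character
#'   codes or integer codes, or single-row [CareSequences-class] objects.
#' @param scheme a [CostScheme-class]; default [costScheme()].
#' @return a single non-negative number.
#' @examples
#' omDistance(c("ACUTE", "HOME", "HOME"), c("ACUTE", "HOME"))  # one deletion
#' @seealso [lcsLength()], [dissimilarityMatrix()]
#' @export
omDistance <- function(x, y, scheme = costScheme()) {
  stopifnot(is(scheme, "CostScheme"))
  cpp_om_distance(.asStateInts(x), .asStateInts(y), scheme@indel, scheme@sub)
}

#' Longest common subsequence length
#'
#' Length of the longest (not necessarily contiguous) subsequence common to
#' both sequences, by the standard dynamic programme.
#'
#' @inheritParams omDistance
#' @return a non-negative integer.
#' @examples
#' lcsLength(c("A", "R", "H", "R"), c("R", "H", "A", "R"))
#' @export
lcsLength <- function(x, y) {
  cpp_lcs_length(.asStateInts(x), .asStateInts(y))
}

#' Pairwise optimal-matching dissimilarity matrix
#'
#' Compares every pair of sequences with [omDistance()] (only the upper
#' triangle is computed and mirrored) and returns the dense symmetric
#' matrix used for the pathway classification.
#'
#' @param seqs a [CareSequences-class] object (>= 1 sequence).
#' @param scheme a [CostScheme-class].
#' @return a symmetric numeric matrix with zero diagonal, patient ids as
#'   dimnames.
#' @export
dissimilarityMatrix <- function(seqs, scheme = costScheme()) {
  stopifnot(is(seqs, "CareSequences"), is(scheme, "CostScheme"))
  if (length(seqs) < 1L) stop("at least one sequence is required")
  D <- cpp_om_matrix(seqs@states, scheme@indel, scheme@sub)
  dimnames(D) <- list(seqIds(seqs), seqIds(seqs))
  D
}

#' Draw a simple random sample of patients
#'
#' Sampling without replacement, reproducible under a seed; used to bring
#' the pairwise sequence comparison down to a tractable sample (the
#' reference analysis samples 10,000 patients per disease population).
#' If `n` is at least the population size the full population is returned.
#'
#' @param ids character vector of patient ids.
#' @param n sample size (>= 0).
#' @param seed integer seed; if `NULL` the current RNG state is used.
#' @return a character vector of sampled ids.
#' @export
samplePatients <- function(ids, n, seed = NULL) {
  stopifnot(n >= 0)
  if (n >= length(ids)) return(ids)
  if (!is.null(seed)) {
    old <- .saveSeed()
    on.exit(.restoreSeed(old))
    set.seed(seed)
  }
  ids[sort(sample.int(length(ids), n))]
}

#' Write or read a dissimilarity matrix
#'
#' Dense symmetric matrix with an id header row; plain delimited text.
#'
#' @param D symmetric matrix with id dimnames.
#' @param file path.
#' @return `writeDissimilarity()` returns `file` invisibly;
#'   `readDissimilarity()` the matrix.
#' @export
writeDissimilarity <- function(D, file) {
  df <- data.frame(patient_id = rownames(D), D, check.names = FALSE)
  data.table::fwrite(df, file)
  invisible(file)
}

#' @rdname writeDissimilarity
#' @export
readDissimilarity <- function(file) {
  df <- as.data.frame(data.table::fread(file))
  ids <- as.character(df$patient_id)
  D <- as.matrix(df[, -1, drop = FALSE])
  dimnames(D) <- list(ids, ids)
  D
}

# save/restore .Random.seed so seeded helpers do not disturb the caller
.saveSeed <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.restoreSeed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
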