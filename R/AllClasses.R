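#' @useDynLib CarePathways, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
NULL

#' The daily care-state alphabet
#'
#' The care-location variable takes one of five values on each day: acute
#' hospitalization (`ACUTE`), rehabilitation (`REHAB`), hospital at home
#' (`HAH`), psychiatry (`PSY`) and home care (`HOME`, covering home,
#' community care and nursing homes). `HOME` is the background state: any
#' day not covered by a care episode is at home.
#'
#' @return `careStates()` returns the five state labels in priority order
#'   (most intensive first); `careStateCodes()` returns the single-character
#'   serialization code of each state, named by label.
#' @examples
#' careStates()
#' careStateCodes()
#' @export
careStates <- function() c("ACUTE", "REHAB", "HAH", "PSY", "HOME")

#' @rdname careStates
#' @export
careStateCodes <- function() {
  c(ACUTE = "A", REHAB = "R", HAH = "D", PSY = "P", HOME = "H")
}

.N_STATES <- 5L
.HOME <- 5L

# map labels / single-char codes / integers to internal integer codes 1..5
.stateToInt <- function(x) {
  if (is.numeric(x)) {
    xi <- as.integer(x)
    if (anyNA(xi) || any(xi < 1L) || any(xi > .N_STATES))
      stop("invalid state code: integer states must be in 1..", .N_STATES)
    return(xi)
  }
  x <- as.character(x)
  i <- match(x, careStates())
  bad <- is.na(i)
  if (any(bad)) {
    i[bad] <- match(x[bad], unname(careStateCodes()))
    if (anyNA(i))
      stop("invalid state code: ", paste(unique(x[is.na(i)]), collapse = ", "))
  }
  i
}

#' CareSequences: daily care-state sequences
#'
#' An S4 container for a set of per-patient daily care-state sequences.
#' Column t holds the state on day t of the observation window; with the
#' default 365-day window, column 1 is 365 days before death and column 365
#' is the day of death itself (the death day is included in the window).
#' States are stored as integer codes `1:5` in the order of [careStates()].
#'
#' @slot ids character vector of patient identifiers, one per row.
#' @slot states integer matrix, one row per patient, entries in `1:5`.
#' @export
setClass("CareSequences",
  representation(ids = "character", states = "matrix"),
  validity = function(object) {
    msg <- character()
    if (!is.integer(object@states))
      msg <- c(msg, "'states' must be an integer matrix")
    if (length(object@ids) != nrow(object@states))
      msg <- c(msg, "length(ids) must equal nrow(states)")
    if (anyDuplicated(object@ids))
      msg <- c(msg, "patient ids must be unique")
    if (ncol(object@states) < 1L)
      msg <- c(msg, "sequences must have length >= 1")
    v <- object@states
    if (length(v) && (anyNA(v) || any(v < 1L) || any(v > .N_STATES)))
      msg <- c(msg, sprintf("states must be integer codes in 1..%d", .N_STATES))
    if (length(msg)) msg else TRUE
  }
)

#' Construct a CareSequences object
#'
#' @param states a matrix of states, one row per patient: integer codes
#'   (`1:5`), state labels (`"ACUTE"`, ...) or single-character codes
#'   (`"A"`, ...). A character vector of packed strings (one string per
#'   patient, one character per day) is also accepted.
#' @param ids patient identifiers; defaults to rownames or `seq_len(n)`.
#' @return a [CareSequences-class] object.
#' @examples
#' cs <- CareSequences(rbind(rep("HOME", 10), rep("ACUTE", 10)))
#' cs
#' @export
CareSequences <- function(states, ids = NULL) {
  if (is.character(states) && !is.matrix(states)) {
    # packed single-character-code strings
    L <- unique(nchar(states))
    if (length(L) != 1L)
      stop("all packed sequence strings must have equal length")
    states <- matrix(unlist(strsplit(states, "", fixed = TRUE), use.names = FALSE),
                     nrow = length(states), byrow = TRUE)
  }
  if (!is.matrix(states)) states <- matrix(states, nrow = 1L)
  if (is.null(ids)) {
    ids <- rownames(states)
    if (is.null(ids)) ids <- as.character(seq_len(nrow(states)))
  }
  m <- matrix(.stateToInt(states), nrow = nrow(states))
  new("CareSequences", ids = as.character(ids), states = m)
}

#' @describeIn CareSequences-class patient identifiers.
#' @param x,object a `CareSequences` object.
#' @export
setGeneric("seqIds", function(x) standardGeneric("seqIds"))

#' @rdname CareSequences-class
#' @export
setMethod("seqIds", "CareSequences", function(x) x@ids)

#' @describeIn CareSequences-class the state matrix, as integer codes
#'   (`as = "integer"`), labels (`"label"`) or single-character codes
#'   (`"code"`).
#' @param as output representation.
#' @export
setGeneric("seqStates", function(x, as = c("integer", "label", "code"))
  standardGeneric("seqStates"))

#' @rdname CareSequences-class
#' @export
setMethod("seqStates", "CareSequences", function(x, as = c("integer", "label", "code")) {
  as <- match.arg(as)
  m <- x@states
  out <- switch(as,
    integer = m,
    label = matrix(careStates()[m], nrow = nrow(m)),
    code = matrix(unname(careStateCodes())[m], nrow = nrow(m))
  )
  rownames(out) <- x@ids
  out
})

#' @describeIn CareSequences-class number of sequences.
#' @export
setMethod("length", "CareSequences", function(x) nrow(x@states))

#' @describeIn CareSequences-class window length in days.
#' @export
setGeneric("seqDays", function(x) standardGeneric("seqDays"))

#' @rdname CareSequences-class
#' @export
setMethod("seqDays", "CareSequences", function(x) ncol(x@states))

#' @describeIn CareSequences-class subset sequences by index or patient id.
#' @param i row (patient) index or character ids.
#' @param j,...,drop ignored.
#' @export
setMethod("[", "CareSequences", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) {
    i <- match(i, x@ids)
    if (anyNA(i)) stop("unknown patient id")
  }
  new("CareSequences", ids = x@ids[i], states = x@states[i, , drop = FALSE])
})

setMethod("show", "CareSequences", function(object) {
  n <- length(object)
  cat(sprintf("CareSequences: %d sequence%s of %d daily states\n",
              n, if (n == 1) "" else "s", seqDays(object)))
  if (n) {
    tab <- table(factor(careStates()[object@states], levels = careStates()))
    pct <- 100 * as.numeric(tab) / sum(tab)
    cat("state occupancy: ",
        paste(sprintf("%s %.1f%%", names(tab), pct), collapse = ", "), "\n",
        sep = "")
  }
})

#' CostScheme: edit-operation costs for optimal matching
#'
#' Holds the indel (insertion/deletion) cost and the symmetric
#' substitution-cost matrix used by [omDistance()]. The default scheme is
#' the one inducing the longest-common-subsequence metric: indel cost 1 and
#' a constant substitution cost of 2 between any two distinct states, so
#' that d(x, y) = |x| + |y| - 2 * LCS(x, y).
#'
#' @slot indel non-negative indel cost.
#' @slot sub symmetric 5x5 substitution-cost matrix with zero diagonal.
#' @export
setClass("CostScheme",
  representation(indel = "numeric", sub = "matrix"),
  validity = function(object) {
    msg <- character()
    if (length(object@indel) != 1L || is.na(object@indel) || object@indel < 0)
      msg <- c(msg, "'indel' must be a single non-negative number")
    s <- object@sub
    if (!is.numeric(s) || nrow(s) != .N_STATES || ncol(s) != .N_STATES)
      msg <- c(msg, sprintf("'sub' must be a numeric %dx%d matrix", .N_STATES, .N_STATES))
    else {
      if (any(s < 0)) msg <- c(msg, "substitution costs must be non-negative")
      if (any(abs(s - t(s)) > 1e-9)) msg <- c(msg, "substitution matrix must be symmetric")
      if (any(abs(diag(s)) > 0)) msg <- c(msg, "substitution matrix must have zero diagonal")
    }
    if (length(msg)) msg else TRUE
  }
)

#' Construct a CostScheme
#'
#' @param indel indel cost (default 1).
#' @param substitution either a single constant off-diagonal substitution
#'   cost (default 2) or a full symmetric 5x5 matrix with zero diagonal.
#' @return a [CostScheme-class] object.
#' @examples
#' costScheme()            # the LCS-inducing scheme: indel 1, substitution 2
#' costScheme(1, 1.5)
#' @export
costScheme <- function(indel = 1, substitution = 2) {
  if (length(substitution) == 1L) {
    s <- matrix(substitution, .N_STATES, .N_STATES)
    diag(s) <- 0
  } else {
    s <- substitution
  }
  dimnames(s) <- list(careStates(), careStates())
  new("CostScheme", indel = as.numeric(indel), sub = s)
}

#' @describeIn CostScheme-class the indel cost.
#' @param x,object a `CostScheme`.
#' @export
setGeneric("indelCost", function(x) standardGeneric("indelCost"))

#' @rdname CostScheme-class
#' @export
setMethod("indelCost", "CostScheme", function(x) x@indel)

#' @describeIn CostScheme-class the substitution-cost matrix.
#' @export
setGeneric("substitutionCosts", function(x) standardGeneric("substitutionCosts"))

#' @rdname CostScheme-class
#' @export
setMethod("substitutionCosts", "CostScheme", function(x) x@sub)

setMethod("show", "CostScheme", function(object) {
  off <- object@sub[upper.tri(object@sub)]
  if (length(unique(off)) == 1L)
    cat(sprintf("CostScheme: indel = %g, substitution = %g (constant)\n",
                object@indel, off[1]))
  else
    cat(sprintf("CostScheme: indel = %g, state-dependent substitution costs\n",
                object@indel))
})

#' ClusterTypology: a care-pathway partition
#'
#' The result of cutting a Ward linkage tree: an assignment of every patient
#' to one of `k` non-empty pathway clusters, optionally with descriptive
#' cluster names.
#'
#' @slot k number of clusters.
#' @slot labels integer cluster labels in `1:k`, named by patient id.
#' @slot clusterNames character vector of length `k` with descriptive names.
#' @export
setClass("ClusterTypology",
  representation(k = "integer", labels = "integer", clusterNames = "character"),
  validity = function(object) {
    msg <- character()
    if (length(object@k) != 1L || object@k < 1L)
      msg <- c(msg, "'k' must be a single positive integer")
    l <- object@labels
    if (is.null(names(l)) || anyDuplicated(names(l)))
      msg <- c(msg, "'labels' must be uniquely named by patient id")
    if (length(l) && (anyNA(l) || any(l < 1L) || any(l > object@k)))
      msg <- c(msg, "labels must lie in 1..k")
    if (length(l) && length(unique(l)) != object@k)
      msg <- c(msg, "all k clusters must be non-empty")
    if (length(object@clusterNames) != object@k)
      msg <- c(msg, "'clusterNames' must have length k")
    if (length(msg)) msg else TRUE
  }
)

ClusterTypology <- function(labels, k = max(labels), clusterNames = NULL) {
  if (is.null(clusterNames)) clusterNames <- paste("cluster", seq_len(k))
  new("ClusterTypology", k = as.integer(k), labels = as.integer(labels) |>
        stats::setNames(names(labels)), clusterNames = as.character(clusterNames))
}

#' @describeIn ClusterTypology-class cluster labels named by patient id.
#' @param x,object a `ClusterTypology`.
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))

#' @rdname ClusterTypology-class
#' @export
setMethod("clusterLabels", "ClusterTypology", function(x)
  stats::setNames(x@labels, names(x@labels)))

#' @describeIn ClusterTypology-class number of clusters.
#' @export
setGeneric("nClusters", function(x) standardGeneric("nClusters"))

#' @rdname ClusterTypology-class
#' @export
setMethod("nClusters", "ClusterTypology", function(x) x@k)

#' @describeIn ClusterTypology-class descriptive cluster names.
#' @export
setGeneric("clusterNames", function(x) standardGeneric("clusterNames"))

#' @rdname ClusterTypology-class
#' @export
setMethod("clusterNames", "ClusterTypology", function(x) x@clusterNames)

#' @describeIn ClusterTypology-class replace the descriptive cluster names.
#' @param value character vector of length `k`.
#' @export
setGeneric("clusterNames<-", function(x, value) standardGeneric("clusterNames<-"))

#' @rdname ClusterTypology-class
#' @export
setMethod("clusterNames<-", "ClusterTypology", function(x, value) {
  x@clusterNames <- as.character(value)
  validObject(x)
  x
})

setMethod("show", "ClusterTypology", function(object) {
  cat(sprintf("ClusterTypology: %d patients in %d clusters\n",
              length(object@labels), object@k))
  tab <- table(object@labels)
  for (i in seq_len(object@k))
    cat(sprintf("  %d: %-45s n = %d\n", i, object@clusterNames[i],
                as.integer(tab[as.character(i)])))
})
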