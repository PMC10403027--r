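# Independent oracles used to validate the package's kernels. Each is a
# deliberately naive implementation sharing no code with the package.

# random state sequences as integer codes 1..5
rand_seq <- function(len, n_states = 5L) {
  sample.int(n_states, len, replace = TRUE)
}

# plain recursive edit distance over all edit scripts, memoized in R;
# independent of the C++ dynamic programme
oracle_om_memo <- function(x, y, indel = 1, subcost = 2) {
  memo <- new.env(hash = TRUE)
  rec <- function(i, j) {
    if (i == 0L) return(j * indel)
    if (j == 0L) return(i * indel)
    key <- paste(i, j)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    s <- if (x[i] == y[j]) 0 else subcost
    v <- min(rec(i - 1L, j - 1L) + s,
             rec(i - 1L, j) + indel,
             rec(i, j - 1L) + indel)
    memo[[key]] <- v
    v
  }
  rec(length(x), length(y))
}

# exhaustive un-memoized recursion: explores every edit script (lengths <= 6)
oracle_om_exhaustive <- function(x, y, indel = 1, subcost = 2) {
  rec <- function(i, j) {
    if (i == 0L && j == 0L) return(0)
    best <- Inf
    if (i > 0L && j > 0L) {
      s <- if (x[i] == y[j]) 0 else subcost
      best <- min(best, rec(i - 1L, j - 1L) + s)
    }
    if (i > 0L) best <- min(best, rec(i - 1L, j) + indel)
    if (j > 0L) best <- min(best, rec(i, j - 1L) + indel)
    best
  }
  rec(length(x), length(y))
}

# brute-force LCS: enumerate every subsequence of x, test if it is a
# subsequence of y (lengths <= ~12)
oracle_lcs_brute <- function(x, y) {
  is_subseq <- function(s, v) {
    if (!length(s)) return(TRUE)
    j <- 1L
    for (e in v) {
      if (e == s[j]) {
        j <- j + 1L
        if (j > length(s)) return(TRUE)
      }
    }
    FALSE
  }
  best <- 0L
  n <- length(x)
  for (mask in 0:(2^n - 1)) {
    s <- x[bitwAnd(mask, 2^(seq_len(n) - 1)) > 0]
    if (length(s) > best && is_subseq(s, y)) best <- length(s)
  }
  best
}

# greedy Ward agglomeration recomputing within-cluster sum-of-squares
# increases from raw coordinates at every step; returns the merge order as
# sorted member sets
oracle_ward_merges <- function(X) {
  clusters <- lapply(seq_len(nrow(X)), identity)
  wss <- function(members) {
    M <- X[members, , drop = FALSE]
    sum(sweep(M, 2, colMeans(M))^2)
  }
  merges <- list()
  while (length(clusters) > 1L) {
    best <- NULL; best_inc <- Inf
    for (a in seq_along(clusters)) {
      for (b in seq_along(clusters)) {
        if (b <= a) next
        inc <- wss(c(clusters[[a]], clusters[[b]])) -
          wss(clusters[[a]]) - wss(clusters[[b]])
        if (inc < best_inc - 1e-12) {
          best_inc <- inc; best <- c(a, b)
        }
      }
    }
    merged <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    merges[[length(merges) + 1L]] <- merged
    clusters <- c(clusters[-best], list(merged))
  }
  merges
}

# member sets created by each hclust merge, in merge order
hclust_merge_sets <- function(tree) {
  n <- nrow(tree$merge) + 1L
  sets <- vector("list", n - 1L)
  for (i in seq_len(n - 1L)) {
    grab <- function(v) if (v < 0) -v else sets[[v]]
    sets[[i]] <- sort(c(grab(tree$merge[i, 1]), grab(tree$merge[i, 2])))
  }
  sets
}

# naive summary-statistics oracle for cost fixtures
oracle_summary <- function(v) {
  q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
  list(mean = sum(v) / length(v),
       sd = sqrt(sum((v - mean(v))^2) / (length(v) - 1)),
       median = q[2], iqr = q[3] - q[1])
}

# adjusted Rand index (used where mclust is unavailable it is skipped;
# mclust is the primary cross-check)
ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab))
  si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab)))
  nt <- comb2(sum(tab))
  exp_idx <- si * sj / nt
  (sij - exp_idx) / ((si + sj) / 2 - exp_idx)
}
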