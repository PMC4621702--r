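# Independent reference implementations used as oracles.

# Literal, scalar-loop transcription of the DP-means pass structure:
# sequential scan in input order, spawn when farther than lam from every
# centre, join nearest otherwise (ties -> lowest cluster index), centres
# recomputed as plain means after each pass, empty clusters dropped, stop
# when an assignment pass changes nothing. Kept deliberately naive and
# separate from the package's vectorised implementation.
refDpMeans <- function(X, lam) {
  n <- nrow(X)
  if (n == 0L) return(list(assign = integer(0), centres = matrix(0, 0, 3)))
  centres <- list(X[1, ])
  assign <- rep(0L, n)
  assign[1] <- 1L
  first <- TRUE
  repeat {
    changed <- FALSE
    for (p in seq_len(n)) {
      if (first && p == 1L) next
      dmin <- Inf
      best <- 0L
      for (c in seq_along(centres)) {
        d <- sqrt(sum((X[p, ] - centres[[c]])^2))
        if (d < dmin) { dmin <- d; best <- c }
      }
      if (dmin > lam) {
        centres[[length(centres) + 1L]] <- X[p, ]
        best <- length(centres)
      }
      if (assign[p] != best) changed <- TRUE
      assign[p] <- best
    }
    first <- FALSE
    newCentres <- list()
    newIdx <- rep(0L, length(centres))
    for (c in seq_along(centres)) {
      mem <- which(assign == c)
      if (length(mem) > 0L) {
        newCentres[[length(newCentres) + 1L]] <- colMeans(X[mem, , drop = FALSE])
        newIdx[c] <- length(newCentres)
      }
    }
    assign <- newIdx[assign]
    centres <- newCentres
    if (!changed) break
  }
  list(assign = assign,
       centres = do.call(rbind, centres))
}

# canonical form of a partition (for comparing cluster assignments that may
# use different label orders)
partitionOf <- function(assign) {
  unname(lapply(split(seq_along(assign), assign), sort))
}
samePartition <- function(a, b) {
  pa <- partitionOf(a); pb <- partitionOf(b)
  setequal(lapply(pa, paste, collapse = ","),
           lapply(pb, paste, collapse = ","))
}

# all set partitions of 1..n (restricted growth strings)
allPartitions <- function(n) {
  out <- list()
  rec <- function(assign, maxUsed) {
    k <- length(assign) + 1L
    if (k > n) { out[[length(out) + 1L]] <<- assign; return() }
    for (c in seq_len(maxUsed + 1L))
      rec(c(assign, c), max(maxUsed, c))
  }
  rec(integer(0), 0L)
  out
}

# brute-force search for valid medoid fixed points: every member within lam
# of its cluster's medoid, the medoid minimising the within-cluster
# dissimilarity sum (ties -> lowest index), and every item at least as close
# to its own medoid as to any other cluster's medoid it lies within lam of
validMedoidPartitions <- function(D, lam) {
  n <- nrow(D)
  Filter(Negate(is.null), lapply(allPartitions(n), function(assign) {
    k <- max(assign)
    med <- integer(k)
    for (c in seq_len(k)) {
      mem <- which(assign == c)
      tot <- rowSums(D[mem, mem, drop = FALSE])
      med[c] <- mem[which.min(tot)]
    }
    for (p in seq_len(n)) {
      own <- D[p, med[assign[p]]]
      if (own > lam) return(NULL)
      if (any(D[p, med] < own - 1e-12)) return(NULL)
    }
    assign
  }))
}

# nearest-generating-centre labelling oracle for planted Gaussian draws
nearestCentreLabels <- function(X, centres) {
  apply(X, 1L, function(p)
    which.min(colSums((t(centres) - p)^2)))
}
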