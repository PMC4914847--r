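# Brute-force reference implementations ("oracles") used to validate the
# package's scanners and parsimony algorithms. These are deliberately slow,
# direct transcriptions of each definition, sharing no code with the package.

.AA <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
         "F", "P", "S", "T", "W", "Y", "V")

.KD_ORACLE <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
                E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
                M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
                Y = -1.3, V = 4.2)

chars1 <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

randomSeq <- function(n, alphabet = .AA) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# ---- EGF six-cysteine motif oracle ----------------------------------------
# Exhaustive six-deep search over cysteine positions; greedy left-to-right
# over starts, minimal end among all matches sharing a start.
oracleEgfMotifs <- function(s, gmin = c(3, 3, 1, 1, 4),
                            gmax = c(14, 7, 16, 2, 15)) {
  cpos <- which(chars1(s) == "C")
  minEndFrom <- function(start) {
    best <- Inf
    for (c2 in cpos[cpos >= start + gmin[1] + 1 & cpos <= start + gmax[1] + 1])
      for (c3 in cpos[cpos >= c2 + gmin[2] + 1 & cpos <= c2 + gmax[2] + 1])
        for (c4 in cpos[cpos >= c3 + gmin[3] + 1 & cpos <= c3 + gmax[3] + 1])
          for (c5 in cpos[cpos >= c4 + gmin[4] + 1 & cpos <= c4 + gmax[4] + 1])
            for (c6 in cpos[cpos >= c5 + gmin[5] + 1 &
                              cpos <= c5 + gmax[5] + 1])
              if (c6 < best) best <- c6
    best
  }
  out <- data.frame(start = integer(0), end = integer(0))
  i <- 1L
  while (i <= length(cpos)) {
    e <- minEndFrom(cpos[i])
    if (is.finite(e)) {
      out <- rbind(out, data.frame(start = cpos[i], end = as.integer(e)))
      nxt <- which(cpos > e)
      i <- if (length(nxt)) nxt[1] else length(cpos) + 1L
    } else i <- i + 1L
  }
  out
}

# ---- windowed scanners: quadratic references ------------------------------
oracleTm <- function(s, w = 19L, threshold = 1.6, minLen = 15L) {
  h <- unname(.KD_ORACLE[chars1(s)])
  n <- length(h)
  covered <- rep(FALSE, n)
  wm <- rep(NA_real_, max(0L, n - w + 1L))
  for (i in seq_len(max(0L, n - w + 1L))) {
    wm[i] <- mean(h[i:(i + w - 1L)])
    if (wm[i] >= threshold - 1e-9) covered[i:(i + w - 1L)] <- TRUE
  }
  r <- rle(covered)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  seg <- data.frame(start = starts[r$values], end = ends[r$values])
  seg <- seg[seg$end - seg$start + 1L >= minLen, , drop = FALSE]
  seg$score <- vapply(seq_len(nrow(seg)), function(i) {
    ws <- which(!is.na(wm) & seq_along(wm) >= seg$start[i] &
                  seq_along(wm) <= seg$end[i] - w + 1L)
    max(wm[ws][wm[ws] >= threshold - 1e-9])
  }, numeric(1))
  rownames(seg) <- NULL
  seg
}

oracleSignal <- function(s, searchLen = 35L, minLen = 8L, threshold = 2.0,
                         maxStart = 11L) {
  n <- nchar(s)
  lim <- min(searchLen, n)
  h <- unname(.KD_ORACLE[chars1(substr(s, 1, lim))])
  for (st in seq_len(min(maxStart, lim - minLen + 1L))) {
    best <- NULL
    for (e in (st + minLen - 1L):lim) {
      if (mean(h[st:e]) >= threshold - 1e-9) best <- e
    }
    if (!is.null(best))
      return(data.frame(start = st, end = best,
                        score = mean(h[st:best])))
  }
  data.frame(start = integer(0), end = integer(0), score = numeric(0))
}

oracleCysRich <- function(s, mask = NULL, w = 60L, cmin = 6L) {
  n <- nchar(s)
  isC <- chars1(s) == "C"
  if (!is.null(mask) && nrow(mask))
    for (i in seq_len(nrow(mask))) isC[mask$start[i]:mask$end[i]] <- FALSE
  ww <- min(w, n)
  covered <- rep(FALSE, n)
  for (i in seq_len(n - ww + 1L))
    if (sum(isC[i:(i + ww - 1L)]) >= cmin) covered[i:(i + ww - 1L)] <- TRUE
  r <- rle(covered)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  seg <- data.frame(start = starts[r$values], end = ends[r$values])
  out <- data.frame(start = integer(0), end = integer(0), score = numeric(0))
  for (i in seq_len(nrow(seg))) {
    cp <- which(isC[seg$start[i]:seg$end[i]]) + seg$start[i] - 1L
    out <- rbind(out, data.frame(start = min(cp), end = max(cp),
                                 score = length(cp)))
  }
  out
}

# ---- Smith-Waterman (Gotoh affine gaps) oracle ----------------------------
# A gap of length L costs gapOpening + L * gapExtension, matching the
# Biostrings convention.
oracleSmithWaterman <- function(a, b, gapOpening = 11, gapExtension = 1,
                                submat = NULL) {
  if (is.null(submat)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    submat <- e$BLOSUM62
  }
  ca <- chars1(a); cb <- chars1(b)
  n <- length(ca); m <- length(cb)
  M <- matrix(0, n + 1L, m + 1L)
  Ix <- matrix(-Inf, n + 1L, m + 1L)
  Iy <- matrix(-Inf, n + 1L, m + 1L)
  best <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      Ix[i + 1L, j + 1L] <- max(M[i, j + 1L] - gapOpening - gapExtension,
                                Ix[i, j + 1L] - gapExtension)
      Iy[i + 1L, j + 1L] <- max(M[i + 1L, j] - gapOpening - gapExtension,
                                Iy[i + 1L, j] - gapExtension)
      M[i + 1L, j + 1L] <- submat[ca[i], cb[j]] +
        max(0, M[i, j], Ix[i, j], Iy[i, j])
      if (M[i + 1L, j + 1L] > best) best <- M[i + 1L, j + 1L]
    }
  }
  best
}

# ---- Dollo parsimony oracle ------------------------------------------------
# Exhaustive search over all internal-node 0/1 assignments; keeps assignments
# with a single origin (at most one 0->1 edge, none if the root is 1) and
# returns the minimum number of 1->0 edges together with the gain node of an
# optimal assignment.
oracleDollo <- function(tree, states) {
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  root <- ntip + 1L
  tipStates <- states[tree$tip.label]
  bestLoss <- Inf
  bestGain <- NA_integer_
  internal <- (ntip + 1L):nn
  for (mask in 0:(2^tree$Nnode - 1L)) {
    st <- integer(nn)
    st[seq_len(ntip)] <- tipStates
    st[internal] <- bitwAnd(mask %/% 2^(seq_along(internal) - 1L), 1L)
    gains <- which(st[tree$edge[, 1]] == 0L & st[tree$edge[, 2]] == 1L)
    losses <- which(st[tree$edge[, 1]] == 1L & st[tree$edge[, 2]] == 0L)
    nOrigins <- length(gains) + st[root]
    if (nOrigins != 1L) next
    if (length(losses) < bestLoss) {
      bestLoss <- length(losses)
      bestGain <- if (st[root] == 1L) root else tree$edge[gains, 2]
    }
  }
  list(losses = bestLoss, gain = as.integer(bestGain))
}

# ---- Sankoff parsimony oracle ----------------------------------------------
# Exhaustive enumeration of internal-node assignments over 0..maxCount under
# the linear |parent - child| cost; returns the minimal total cost and the
# smallest root state realizing it.
oracleSankoff <- function(tree, counts, maxCount = max(counts)) {
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  root <- ntip + 1L
  tipCounts <- counts[tree$tip.label]
  k <- maxCount + 1L
  bestCost <- Inf
  bestRoot <- NA_integer_
  internal <- (ntip + 1L):nn
  for (idx in 0:(k^tree$Nnode - 1L)) {
    st <- integer(nn)
    st[seq_len(ntip)] <- tipCounts
    st[internal] <- (idx %/% k^(seq_along(internal) - 1L)) %% k
    cost <- sum(abs(st[tree$edge[, 1]] - st[tree$edge[, 2]]))
    if (cost < bestCost || (cost == bestCost && st[root] < bestRoot)) {
      bestCost <- cost
      bestRoot <- st[root]
    }
  }
  list(cost = bestCost, root = as.integer(bestRoot))
}

# deterministic random rooted binary tree with tip labels t1..tn
randomRootedTree <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n)
  tr$edge.length <- NULL
  tr
}
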