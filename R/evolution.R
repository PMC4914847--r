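#' Derive a character matrix from a complement matrix
#'
#' Binary presence characters (\code{EGFR_PRESENT}, \code{EGF_TYPE_PRESENT},
#' \code{NRG_TYPE_PRESENT}) and the corresponding copy-number characters,
#' with PRESENT = (COUNT >= 1) for every taxon.
#'
#' @param m a \linkS4class{ComplementMatrix} with complete rows.
#' @return data.frame with column \code{taxon} (tree tip labels) plus the six
#'   characters.
#' @export
characterMatrixFromComplements <- function(m) {
  tab <- complementTable(m)
  if (anyNA(tab$egfr_count) || anyNA(tab$egf_like_count) ||
      anyNA(tab$nrg_like_count))
    stop("complement matrix rows must be complete (see combineComplements)")
  if (any(tab$egfr_count < 0 | tab$egf_like_count < 0 | tab$nrg_like_count < 0))
    stop("negative counts")
  data.frame(taxon = .tipName(tab$species),
             EGFR_COUNT = as.integer(tab$egfr_count),
             EGF_TYPE_COUNT = as.integer(tab$egf_like_count),
             NRG_TYPE_COUNT = as.integer(tab$nrg_like_count),
             EGFR_PRESENT = as.integer(tab$egfr_count >= 1),
             EGF_TYPE_PRESENT = as.integer(tab$egf_like_count >= 1),
             NRG_TYPE_PRESENT = as.integer(tab$nrg_like_count >= 1),
             stringsAsFactors = FALSE)
}

.checkTips <- function(tree, states) {
  if (is.null(names(states))) stop("states must be named by tip label")
  miss <- setdiff(tree$tip.label, names(states))
  if (length(miss))
    stop("no state for tip(s): ", paste(utils::head(miss, 3), collapse = ", "))
  states[tree$tip.label]
}

# children list indexed by node number
.childrenOf <- function(tree) {
  nn <- ape::Ntip(tree) + tree$Nnode
  ch <- vector("list", nn)
  for (i in seq_len(nrow(tree$edge)))
    ch[[tree$edge[i, 1]]] <- c(ch[[tree$edge[i, 1]]], tree$edge[i, 2])
  ch
}

# all tip numbers under each node
.tipsUnder <- function(tree) {
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  po <- ape::reorder.phylo(tree, "postorder")
  under <- vector("list", nn)
  for (i in seq_len(ntip)) under[[i]] <- i
  for (i in seq_len(nrow(po$edge))) {
    p <- po$edge[i, 1]; c <- po$edge[i, 2]
    under[[p]] <- c(under[[p]], under[[c]])
  }
  under
}

#' Dollo parsimony reconstruction of a binary character
#'
#' A single gain is placed at the most recent common ancestor of all taxa
#' possessing the character (on the terminal edge when only one taxon has it);
#' within the gain clade, one loss is placed on the root edge of every maximal
#' all-absent subtree. This is the unique minimal-loss reconstruction under
#' the single-gain constraint; tip states are reproduced exactly and no
#' 0-to-1 transition occurs below the gain node.
#'
#' @param tree rooted \code{phylo} tree (polytomies allowed).
#' @param states named 0/1 vector over the tip labels.
#' @param character character name (for reporting).
#' @return a \linkS4class{DolloReconstruction}.
#' @examples
#' tr <- bundledSpeciesTree()
#' cm <- characterMatrixFromComplements(combineComplements())
#' st <- stats::setNames(cm$NRG_TYPE_PRESENT, cm$taxon)
#' dolloReconstruct(tr, st, "NRG_TYPE_PRESENT")
#' @export
dolloReconstruct <- function(tree, states, character = "character") {
  states <- .checkTips(tree, states)
  if (!all(states %in% c(0L, 1L))) stop("states must be binary 0/1")
  ones <- which(states == 1L)
  if (length(ones) == 0L)
    stop("character is absent from every taxon: no gain can be placed")
  ntip <- ape::Ntip(tree)
  gain <- if (length(ones) == 1L) as.integer(ones) else
    as.integer(ape::getMRCA(tree, tree$tip.label[ones]))
  under <- .tipsUnder(tree)
  nn <- ntip + tree$Nnode
  inGain <- rep(FALSE, nn)
  inGain[gain] <- TRUE
  if (gain > ntip) inGain[.descendants(tree, gain)] <- TRUE
  nodeStates <- integer(nn)
  for (v in seq_len(nn))
    nodeStates[v] <- as.integer(inGain[v] &&
                                  length(intersect(under[[v]], ones)) > 0L)
  losses <- tree$edge[nodeStates[tree$edge[, 1]] == 1L &
                        nodeStates[tree$edge[, 2]] == 0L, , drop = FALSE]
  lossEdges <- data.frame(parent = losses[, 1], child = losses[, 2],
                          child_label = vapply(losses[, 2], .nodeLabel,
                                               character(1), tree = tree),
                          stringsAsFactors = FALSE)
  new("DolloReconstruction", character = character, tree = tree,
      gainNode = gain, lossEdges = lossEdges, nodeStates = nodeStates)
}

# all node numbers (tips and internals) descending from node, excluding it
.descendants <- function(tree, node) {
  ch <- .childrenOf(tree)
  out <- integer(0)
  stack <- ch[[node]]
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    out <- c(out, v)
    if (!is.null(ch[[v]])) stack <- c(stack, ch[[v]])
  }
  out
}

#' Sankoff parsimony reconstruction of a copy-number character
#'
#' Minimum total-cost ancestral assignment over states \code{0..maxCount} by
#' dynamic programming (bottom-up cost tables, top-down backtrace), with the
#' linear cost |child - parent| by default. Ties are broken toward the smaller
#' ancestral count, a conservative-ancestor convention. Polytomies are handled
#' natively.
#'
#' @param tree rooted \code{phylo} tree.
#' @param counts named non-negative integer vector over the tip labels.
#' @param maxCount largest ancestral state considered; defaults to the tip
#'   maximum.
#' @param costMatrix optional (maxCount+1) x (maxCount+1) matrix of
#'   state-change costs (rows = parent state 0.., columns = child state 0..).
#' @param character character name (for reporting).
#' @return a \linkS4class{SankoffReconstruction}.
#' @examples
#' tr <- ape::read.tree(text = "((a,b),c);")
#' sankoffCounts(tr, c(a = 1, b = 1, c = 1))
#' @export
sankoffCounts <- function(tree, counts, maxCount = max(counts),
                          costMatrix = NULL, character = "character") {
  counts <- .checkTips(tree, counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(counts > maxCount))
    stop("tip count exceeds maxCount")
  S <- as.integer(maxCount)
  states <- 0:S
  if (is.null(costMatrix))
    costMatrix <- abs(outer(states, states, "-"))
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  cost <- matrix(Inf, nn, S + 1L)
  for (i in seq_len(ntip)) cost[i, counts[i] + 1L] <- 0
  po <- ape::reorder.phylo(tree, "postorder")
  edges <- po$edge
  # bottom-up: children appear before parents in postorder edge list
  parents <- unique(edges[, 1])
  for (p in parents) {
    kids <- edges[edges[, 1] == p, 2]
    acc <- rep(0, S + 1L)
    for (k in kids) {
      # min over child states of (child cost + transition cost)
      conv <- vapply(states, function(s)
        min(cost[k, ] + costMatrix[s + 1L, ]), numeric(1))
      acc <- acc + conv
    }
    cost[p, ] <- acc
  }
  root <- ntip + 1L
  totalCost <- min(cost[root, ])
  nodeCounts <- integer(nn)
  nodeCounts[root] <- states[which(cost[root, ] == totalCost)[1]]
  # top-down backtrace in preorder (reverse postorder)
  for (i in rev(seq_len(nrow(edges)))) {
    p <- edges[i, 1]; k <- edges[i, 2]
    v <- cost[k, ] + costMatrix[nodeCounts[p] + 1L, ]
    nodeCounts[k] <- states[which(v == min(v))[1]]
  }
  chg <- which(nodeCounts[edges[, 2]] != nodeCounts[edges[, 1]])
  ev <- data.frame(parent = edges[chg, 1], child = edges[chg, 2],
                   child_label = vapply(edges[chg, 2], .nodeLabel,
                                        character(1), tree = tree),
                   from = nodeCounts[edges[chg, 1]],
                   to = nodeCounts[edges[chg, 2]],
                   stringsAsFactors = FALSE)
  ev$delta <- ev$to - ev$from
  ev <- ev[order(ev$parent, ev$child), , drop = FALSE]
  rownames(ev) <- NULL
  new("SankoffReconstruction", character = character, tree = tree,
      nodeCounts = nodeCounts, totalCost = totalCost, events = ev)
}

#' Copy-number expansions in a reconstruction
#'
#' Edges along which the reconstructed count increases from an already
#' non-zero ancestral count, i.e. duplications of an existing gene rather than
#' de novo gains.
#'
#' @param recon a \linkS4class{SankoffReconstruction}.
#' @return data.frame with columns \code{parent}, \code{child},
#'   \code{child_label}, \code{from}, \code{to}.
#' @export
detectExpansions <- function(recon) {
  ev <- recon@events
  out <- ev[ev$to > ev$from & ev$from >= 1L,
            c("parent", "child", "child_label", "from", "to"), drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Ancestral-scenario report for the pathway complement
#'
#' Reconstructs all six characters on the tree and merges the inferred events
#' into one ordered table: Dollo gains and losses for the presence characters,
#' Sankoff expansions and contractions for the copy-number characters. Also
#' reports the reconstructed complement (EGFR, EGF-type and NRG-type counts)
#' at the metazoan root and at the bilaterian root.
#'
#' @param tree rooted \code{phylo} tree; the bilaterian root is located by the
#'   node label \code{"Bilateria"} when present, otherwise as the MRCA of the
#'   protostome + deuterostome + xenacoelomorph tips present in the matrix.
#' @param matrix character matrix from
#'   \code{\link{characterMatrixFromComplements}}.
#' @return list with elements \code{events} (data.frame: character, type,
#'   node/edge labels, from, to), \code{rootComplement} (data.frame) and
#'   \code{reconstructions} (named list of reconstruction objects).
#' @export
scenarioReport <- function(tree, matrix) {
  stopifnot(all(c("taxon", "EGFR_COUNT") %in% colnames(matrix)))
  ntip <- ape::Ntip(tree)
  root <- ntip + 1L
  recs <- list()
  events <- data.frame(character = character(0), type = character(0),
                       node = character(0), from = integer(0),
                       to = integer(0), stringsAsFactors = FALSE)
  for (ch in c("EGFR_PRESENT", "EGF_TYPE_PRESENT", "NRG_TYPE_PRESENT")) {
    st <- stats::setNames(matrix[[ch]], matrix$taxon)
    if (all(st == 0L)) next
    d <- dolloReconstruct(tree, st, ch)
    recs[[ch]] <- d
    events <- rbind(events,
                    data.frame(character = ch, type = "gain",
                               node = .nodeLabel(tree, d@gainNode),
                               from = 0L, to = 1L, stringsAsFactors = FALSE))
    if (nrow(d@lossEdges))
      events <- rbind(events,
                      data.frame(character = ch, type = "loss",
                                 node = d@lossEdges$child_label,
                                 from = 1L, to = 0L, stringsAsFactors = FALSE))
  }
  for (ch in c("EGFR_COUNT", "EGF_TYPE_COUNT", "NRG_TYPE_COUNT")) {
    cnt <- stats::setNames(matrix[[ch]], matrix$taxon)
    s <- sankoffCounts(tree, cnt, character = ch)
    recs[[ch]] <- s
    ex <- detectExpansions(s)
    if (nrow(ex))
      events <- rbind(events,
                      data.frame(character = ch, type = "expansion",
                                 node = ex$child_label, from = ex$from,
                                 to = ex$to, stringsAsFactors = FALSE))
    ctr <- s@events[s@events$delta < 0 & s@events$to >= 1L, , drop = FALSE]
    if (nrow(ctr))
      events <- rbind(events,
                      data.frame(character = ch, type = "contraction",
                                 node = ctr$child_label, from = ctr$from,
                                 to = ctr$to, stringsAsFactors = FALSE))
  }
  labs <- if (!is.null(tree$node.label)) tree$node.label else character(0)
  bil <- if ("Bilateria" %in% labs) ntip + which(labs == "Bilateria") else root
  rootComplement <- data.frame(
    node = c(.nodeLabel(tree, root), .nodeLabel(tree, bil)),
    egfr_count = c(recs$EGFR_COUNT@nodeCounts[root],
                   recs$EGFR_COUNT@nodeCounts[bil]),
    egf_type_count = c(recs$EGF_TYPE_COUNT@nodeCounts[root],
                       recs$EGF_TYPE_COUNT@nodeCounts[bil]),
    nrg_type_count = c(recs$NRG_TYPE_COUNT@nodeCounts[root],
                       recs$NRG_TYPE_COUNT@nodeCounts[bil]),
    stringsAsFactors = FALSE)
  rownames(events) <- NULL
  list(events = events, rootComplement = rootComplement,
       reconstructions = recs)
}
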