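# Kyte-Doolittle hydropathy scale, hard-coded.
.KD <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
         G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
         P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)

.AA20 <- names(.KD)

# Evaluate expr under a temporary RNG seed, restoring global RNG state after.
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Deterministic sub-seed derivation, kept within 32-bit integer range.
.deriveSeed <- function(seed, key) {
  h <- sum(utf8ToInt(key) * (seq_len(nchar(key)) %% 97L + 1L))
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483647)
}

.chars <- function(x) strsplit(as.character(x), "", fixed = TRUE)[[1]]

.hydropathy <- function(seq) unname(.KD[.chars(seq)])

# Rolling window means of a numeric vector (window w), one value per start.
.windowMeans <- function(v, w) {
  n <- length(v)
  if (n < w) return(numeric(0))
  cs <- cumsum(c(0, v))
  (cs[(w + 1):(n + 1)] - cs[1:(n - w + 1)]) / w
}

# Merge 1-based inclusive [start, end] intervals (sorted or not); idempotent.
.mergeIntervals <- function(starts, ends) {
  if (length(starts) == 0L)
    return(data.frame(start = integer(0), end = integer(0)))
  o <- order(starts, ends)
  starts <- starts[o]; ends <- ends[o]
  ms <- starts[1]; me <- ends[1]
  out_s <- integer(0); out_e <- integer(0)
  for (i in seq_along(starts)[-1]) {
    if (starts[i] <= me + 1L) me <- max(me, ends[i])
    else { out_s <- c(out_s, ms); out_e <- c(out_e, me); ms <- starts[i]; me <- ends[i] }
  }
  data.frame(start = c(out_s, ms), end = c(out_e, me))
}

.nodeLabel <- function(tree, node) {
  ntip <- ape::Ntip(tree)
  if (node <= ntip) return(tree$tip.label[node])
  lab <- if (!is.null(tree$node.label)) tree$node.label[node - ntip] else ""
  if (is.null(lab) || is.na(lab) || !nzchar(lab)) paste0("node", node) else lab
}

.emptyHits <- function() {
  data.frame(kind = character(0), start = integer(0), end = integer(0),
             score = numeric(0), gly_loop = logical(0), vaik_k = logical(0),
             hrd_d = logical(0), dfg_d = logical(0),
             stringsAsFactors = FALSE)
}

.hitRow <- function(kind, start, end, score, gly = NA, vaik = NA, hrd = NA,
                    dfg = NA) {
  data.frame(kind = kind, start = as.integer(start), end = as.integer(end),
             score = score, gly_loop = gly, vaik_k = vaik, hrd_d = hrd,
             dfg_d = dfg, stringsAsFactors = FALSE)
}
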