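#' Scanner parameter profile constructor
#'
#' @param ... slots of \linkS4class{ScanProfile} to override, e.g.
#'   \code{tmThreshold = 1.8}.
#' @return a \linkS4class{ScanProfile}.
#' @examples
#' scanProfile(tmWindow = 21L)
#' @export
scanProfile <- function(...) new("ScanProfile", ...)

.asSeq <- function(x) {
  if (is(x, "AAStringSet")) {
    if (length(x) != 1L) stop("expected a single sequence")
    return(as.character(x[[1]]))
  }
  if (is(x, "AAString")) return(as.character(x))
  as.character(x)
}

# minimal end coordinate of a six-cysteine match whose first cysteine is
# cpos[idx]; Inf when no match starts there.
.egfMinEnd <- function(cpos, idx, gmin, gmax) {
  rec <- function(prev, stage) {
    if (stage > 5L) return(prev)
    lo <- prev + gmin[stage] + 1L
    hi <- prev + gmax[stage] + 1L
    cands <- cpos[cpos >= lo & cpos <= hi]
    best <- Inf
    for (p in cands) {
      r <- rec(p, stage + 1L)
      if (r < best) best <- r
    }
    best
  }
  rec(cpos[idx], 1L)
}

#' Scan a protein for six-cysteine EGF motifs
#'
#' Finds maximal non-overlapping matches of the spacing pattern
#' C-x(3,14)-C-x(3,7)-C-x(1,16)-C-x(1,2)-C-x(4,15)-C, greedily left to right
#' with a shortest-match tie-break; each hit spans the first to the last
#' cysteine of the match, inclusive.
#'
#' @param x a single amino-acid sequence (character, \code{AAString} or
#'   length-1 \code{AAStringSet}).
#' @param profile a \linkS4class{ScanProfile}.
#' @return data.frame of hits (kind \code{EGF_MOTIF}), in coordinate order.
#' @export
scanEgfMotifs <- function(x, profile = scanProfile()) {
  s <- .asSeq(x)
  cpos <- which(.chars(s) == "C")
  hits <- .emptyHits()
  i <- 1L
  while (i <= length(cpos)) {
    e <- .egfMinEnd(cpos, i, profile@egfGapMin, profile@egfGapMax)
    if (is.finite(e)) {
      hits <- rbind(hits, .hitRow("EGF_MOTIF", cpos[i], e, 6))
      nxt <- which(cpos > e)
      i <- if (length(nxt)) nxt[1] else length(cpos) + 1L
    } else i <- i + 1L
  }
  hits
}

#' Predict transmembrane segments by sliding-window hydropathy
#'
#' Kyte-Doolittle mean hydropathy over windows of \code{tmWindow} residues;
#' windows reaching \code{tmThreshold} are merged into segments and segments
#' shorter than \code{tmMinLen} residues are discarded. A sequence shorter
#' than the window yields no hits.
#'
#' @inheritParams scanEgfMotifs
#' @return data.frame of hits (kind \code{TM}); score is the best window mean.
#' @export
predictTmSegments <- function(x, profile = scanProfile()) {
  s <- .asSeq(x)
  h <- .hydropathy(s)
  w <- profile@tmWindow
  wm <- .windowMeans(h, w)
  # tolerance keeps windows whose true mean equals the threshold from being
  # dropped by floating-point rounding; distinct achievable means differ by
  # at least 0.1 / window, far above it
  fire <- which(wm >= profile@tmThreshold - 1e-9)
  if (length(fire) == 0L) return(.emptyHits())
  seg <- .mergeIntervals(fire, fire + w - 1L)
  seg <- seg[seg$end - seg$start + 1L >= profile@tmMinLen, , drop = FALSE]
  if (nrow(seg) == 0L) return(.emptyHits())
  do.call(rbind, lapply(seq_len(nrow(seg)), function(i) {
    ws <- fire[fire >= seg$start[i] & fire <= seg$end[i] - w + 1L]
    .hitRow("TM", seg$start[i], seg$end[i], max(wm[ws]))
  }))
}

#' Detect an N-terminal signal peptide
#'
#' Present iff, within the first \code{spSearchLen} residues, a hydrophobic
#' stretch of at least \code{spMinLen} residues with mean Kyte-Doolittle
#' hydropathy >= \code{spThreshold} starts no later than position
#' \code{spMaxStart}. The reported hit spans the longest qualifying stretch at
#' the earliest qualifying start; downstream transmembrane counting excludes
#' it.
#'
#' @inheritParams scanEgfMotifs
#' @return one-row data.frame (kind \code{SIGNAL}) or a zero-row data.frame.
#' @export
detectSignalPeptide <- function(x, profile = scanProfile()) {
  s <- .asSeq(x)
  n <- nchar(s)
  lim <- min(profile@spSearchLen, n)
  if (lim < profile@spMinLen) return(.emptyHits())
  h <- .hydropathy(substr(s, 1L, lim))
  cs <- cumsum(c(0, h))
  for (st in seq_len(min(profile@spMaxStart, lim - profile@spMinLen + 1L))) {
    ends <- (st + profile@spMinLen - 1L):lim
    means <- (cs[ends + 1L] - cs[st]) / (ends - st + 1L)
    ok <- which(means >= profile@spThreshold - 1e-9)
    if (length(ok)) {
      e <- ends[ok[length(ok)]]
      return(.hitRow("SIGNAL", st, e, means[ok[length(ok)]]))
    }
  }
  .emptyHits()
}

#' Detect cysteine-rich clusters
#'
#' Outside the masked regions (EGF-motif and kinase hits, which are themselves
#' cysteine-containing), windows of \code{cysWindow} residues holding at least
#' \code{cysMin} cysteines are merged and each merged region is trimmed to the
#' span from its first to its last cysteine. The number of clusters is the
#' "Cys rich" copy-number statistic of the receptor survey.
#'
#' @inheritParams scanEgfMotifs
#' @param mask data.frame of hits to exclude (columns \code{start},
#'   \code{end}), or NULL.
#' @return data.frame of hits (kind \code{CYS_RICH}); score is the cysteine
#'   count of the cluster.
#' @export
detectCysRich <- function(x, mask = NULL, profile = scanProfile()) {
  s <- .asSeq(x)
  n <- nchar(s)
  isC <- .chars(s) == "C"
  if (!is.null(mask) && nrow(mask)) {
    for (i in seq_len(nrow(mask)))
      isC[mask$start[i]:mask$end[i]] <- FALSE
  }
  w <- min(profile@cysWindow, n)
  counts <- .windowMeans(as.numeric(isC), w) * w
  fire <- which(counts >= profile@cysMin - 1e-9)
  if (length(fire) == 0L) return(.emptyHits())
  seg <- .mergeIntervals(fire, fire + w - 1L)
  out <- .emptyHits()
  for (i in seq_len(nrow(seg))) {
    cp <- which(isC[seg$start[i]:seg$end[i]]) + seg$start[i] - 1L
    out <- rbind(out, .hitRow("CYS_RICH", min(cp), max(cp), length(cp)))
  }
  out
}

#' Detect a tyrosine-kinase domain and audit its catalytic residues
#'
#' A kinase is called when the ordered motifs G-x-G-x-x-G (glycine loop),
#' [LIVMF]-A-[IV]-[KR] (VAIK, ATP-binding lysine position),
#' H-R-[DN] (catalytic HRD aspartate position) and [DN]-F-G (DFG aspartate
#' position) occur in order within a 200-350 residue span. The hit records,
#' per catalytic position, whether the canonical residue (K, D, D) is present;
#' substitutions there mark a potentially inactive (pseudokinase) domain, as
#' in human ErbB3.
#'
#' @inheritParams scanEgfMotifs
#' @return one-row data.frame (kind \code{TK}) with logical annotation columns
#'   \code{gly_loop}, \code{vaik_k}, \code{hrd_d}, \code{dfg_d}, or a zero-row
#'   data.frame.
#' @export
detectTkDomain <- function(x, profile = scanProfile()) {
  s <- .asSeq(x)
  glys <- gregexpr("G.G..G", s)[[1]]
  if (glys[1] == -1L) return(.emptyHits())
  after <- function(pat, from) {
    from <- unname(from)
    m <- regexpr(pat, substr(s, from, nchar(s)))
    if (m == -1L) return(NULL)
    c(start = from + as.integer(m) - 1L,
      len = attr(m, "match.length"))
  }
  for (g in as.integer(glys)) {
    vaik <- after("[LIVMF]A[IV][KR]", g + 6L)
    if (is.null(vaik)) next
    hrd <- after("HR[DN]", vaik["start"] + 4L)
    if (is.null(hrd)) next
    dfg <- after("[DN]FG", hrd["start"] + 3L)
    if (is.null(dfg)) next
    end <- dfg["start"] + 2L
    span <- end - g + 1L
    if (span < 200L || span > 350L) next
    vk <- substr(s, vaik["start"] + 3L, vaik["start"] + 3L) == "K"
    hd <- substr(s, hrd["start"] + 2L, hrd["start"] + 2L) == "D"
    dd <- substr(s, dfg["start"], dfg["start"]) == "D"
    return(.hitRow("TK", g, end, sum(c(TRUE, vk, hd, dd)),
                   gly = TRUE, vaik = vk, hrd = hd, dfg = dd))
  }
  .emptyHits()
}

#' Classify a kinase hit as active or inactive
#'
#' \code{INACTIVE} iff any of the canonical catalytic residues (VAIK lysine,
#' HRD aspartate, DFG aspartate) is substituted; \code{ACTIVE} otherwise.
#'
#' @param hit a one-row data.frame of kind \code{TK} as returned by
#'   \code{\link{detectTkDomain}}.
#' @return \code{"ACTIVE"} or \code{"INACTIVE"}.
#' @export
assessTkActivity <- function(hit) {
  if (!is.data.frame(hit) || nrow(hit) != 1L || hit$kind != "TK")
    stop("assessTkActivity expects a single TK hit")
  if (isTRUE(hit$vaik_k) && isTRUE(hit$hrd_d) && isTRUE(hit$dfg_d))
    "ACTIVE" else "INACTIVE"
}

#' Detect the immunoglobulin I-set tag
#'
#' Exact-tag matching of the fixed 90-residue I-set stand-in with at most
#' \code{igMaxMismatch} mismatches (10 percent). This replaces profile-based
#' domain detection, which is out of scope; see the package vignette.
#'
#' @inheritParams scanEgfMotifs
#' @return data.frame of hits (kind \code{IG_ISET}); score is the number of
#'   matching positions.
#' @export
detectIgIset <- function(x, profile = scanProfile()) {
  s <- .asSeq(x)
  n <- nchar(s)
  tag <- .chars(.IG_TAG)
  L <- length(tag)
  if (n < L) return(.emptyHits())
  ch <- .chars(s)
  mism <- integer(n - L + 1L)
  for (k in seq_len(L))
    mism <- mism + (ch[k:(n - L + k)] != tag[k])
  cand <- which(mism <= profile@igMaxMismatch)
  if (length(cand) == 0L) return(.emptyHits())
  grp <- cumsum(c(TRUE, diff(cand) >= L))
  out <- .emptyHits()
  for (g in unique(grp)) {
    p <- cand[grp == g]
    best <- p[which.min(mism[p])]
    out <- rbind(out, .hitRow("IG_ISET", best, best + L - 1L,
                              L - mism[best]))
  }
  out
}

#' Run all domain scanners on a set of proteins
#'
#' For each record: EGF motifs, kinase domain, signal peptide, transmembrane
#' segments (dropping any segment overlapping the signal peptide), cysteine-
#' rich clusters (masking EGF and kinase hits) and the Ig I-set tag. Hits are
#' returned in coordinate order per record. Coordinates are 1-based inclusive.
#'
#' @param x an \code{AAStringSet} (or single sequence).
#' @param profile a \linkS4class{ScanProfile}.
#' @return data.frame with a leading \code{record} column and one row per
#'   \code{DomainHit}.
#' @examples
#' p <- generateProtein(architectureSpec(list(elSignal(), elEgfMotif(),
#'                                            elTm())), seed = 7)
#' scanDomains(p)
#' @export
scanDomains <- function(x, profile = scanProfile()) {
  if (!is(x, "AAStringSet")) x <- AAStringSet(.asSeq(x))
  if (is.null(names(x))) names(x) <- paste0("record", seq_along(x))
  res <- lapply(seq_along(x), function(i) {
    s <- as.character(x[[i]])
    egf <- scanEgfMotifs(s, profile)
    tk <- detectTkDomain(s, profile)
    sp <- detectSignalPeptide(s, profile)
    tm <- predictTmSegments(s, profile)
    if (nrow(sp) && nrow(tm)) {
      keep <- !(tm$start <= sp$end[1] & tm$end >= sp$start[1])
      tm <- tm[keep, , drop = FALSE]
    }
    cys <- detectCysRich(s, mask = rbind(egf, tk), profile = profile)
    ig <- detectIgIset(s, profile)
    h <- rbind(egf, tk, sp, tm, cys, ig)
    if (nrow(h) == 0L) return(cbind(record = character(0), h))
    h <- h[order(h$start, h$end), , drop = FALSE]
    cbind(record = names(x)[i], h, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
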