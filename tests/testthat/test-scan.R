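pad <- function(n) paste(rep("A", n), collapse = "")
motif <- function(gaps) {
  paste0("C", paste(vapply(gaps, pad, character(1)), collapse = "C"), "C")
}

test_that("the EGF scanner matches the six-cysteine spacing pattern", {
  s <- paste0(pad(10), motif(c(3, 3, 1, 1, 4)), pad(10))
  h <- scanEgfMotifs(s)
  expect_identical(nrow(h), 1L)
  expect_identical(h$kind, "EGF_MOTIF")
  expect_identical(h$start, 11L)
  expect_identical(h$end, 11L + 5L + 3L + 3L + 1L + 1L + 4L)
  # widest allowed gaps
  expect_identical(nrow(scanEgfMotifs(motif(c(14, 7, 16, 2, 15)))), 1L)
  # each gap violated by one residue kills the match
  expect_identical(nrow(scanEgfMotifs(motif(c(2, 3, 1, 1, 4)))), 0L)
  expect_identical(nrow(scanEgfMotifs(motif(c(15, 3, 1, 1, 4)))), 0L)
  expect_identical(nrow(scanEgfMotifs(motif(c(3, 8, 1, 1, 4)))), 0L)
  expect_identical(nrow(scanEgfMotifs(motif(c(3, 3, 17, 1, 4)))), 0L)
  expect_identical(nrow(scanEgfMotifs(motif(c(3, 3, 1, 3, 4)))), 0L)
  expect_identical(nrow(scanEgfMotifs(motif(c(3, 3, 1, 1, 3)))), 0L)
  expect_identical(nrow(scanEgfMotifs(motif(c(3, 3, 1, 1, 16)))), 0L)
})

test_that("EGF matches are greedy, non-overlapping and shortest-first", {
  two <- paste0(motif(c(3, 3, 1, 1, 4)), pad(5), motif(c(5, 4, 2, 2, 6)))
  h <- scanEgfMotifs(two)
  expect_identical(nrow(h), 2L)
  expect_true(h$start[2] > h$end[1])
})

test_that("the EGF scanner agrees with the exhaustive oracle", {
  set.seed(41)
  for (i in 1:60) {
    s <- randomSeq(120, c("C", "A", "G", "S", "T"))
    got <- scanEgfMotifs(s)
    want <- oracleEgfMotifs(s)
    expect_identical(got$start, want$start, info = s)
    expect_identical(got$end, want$end, info = s)
  }
})

test_that("TM prediction finds hydrophobic segments and drops short ones", {
  s <- paste0(pad(0), strrep("N", 20), strrep("L", 21), strrep("N", 20))
  h <- predictTmSegments(s)
  expect_identical(nrow(h), 1L)
  expect_identical(h$kind, "TM")
  expect_true(h$start <= 21L && h$end >= 41L)
  expect_gte(h$score, 1.6)
  # hydrophilic sequence: nothing
  expect_identical(nrow(predictTmSegments(strrep("N", 80))), 0L)
  # sequence shorter than the window: nothing
  expect_identical(nrow(predictTmSegments(strrep("L", 10))), 0L)
})

test_that("TM prediction agrees with the quadratic oracle", {
  set.seed(42)
  for (i in 1:50) {
    s <- randomSeq(150, c("L", "I", "V", "N", "Q", "S", "G", "A", "F"))
    got <- predictTmSegments(s)
    want <- oracleTm(s)
    expect_identical(got$start, want$start, info = s)
    expect_identical(got$end, want$end, info = s)
    expect_equal(got$score, want$score, info = s)
  }
})

test_that("signal peptides require an early hydrophobic stretch", {
  sp <- paste0("M", "ST", strrep("L", 10), "ANA")
  h <- detectSignalPeptide(paste0(sp, strrep("N", 60)))
  expect_identical(nrow(h), 1L)
  expect_identical(h$kind, "SIGNAL")
  expect_lte(h$start, 11L)
  # the same stretch too far downstream is not a signal peptide
  late <- paste0(strrep("N", 14), strrep("L", 10), strrep("N", 60))
  expect_identical(nrow(detectSignalPeptide(late)), 0L)
  # stretch outside the 35-residue search window: nothing
  far <- paste0(strrep("N", 40), strrep("L", 12), strrep("N", 20))
  expect_identical(nrow(detectSignalPeptide(far)), 0L)
})

test_that("signal-peptide detection agrees with the brute-force oracle", {
  set.seed(43)
  for (i in 1:60) {
    s <- randomSeq(60, c("M", "L", "A", "V", "N", "S", "T"))
    got <- detectSignalPeptide(s)
    want <- oracleSignal(s)
    expect_identical(got$start, want$start, info = s)
    expect_identical(got$end, want$end, info = s)
  }
})

test_that("cysteine-rich clusters are windowed counts outside the mask", {
  block <- paste(rep("C", 8), collapse = strrep("A", 3))
  s <- paste0(pad(20), block, pad(90), block, pad(20))
  h <- detectCysRich(s)
  expect_identical(nrow(h), 2L)
  expect_identical(h$kind, c("CYS_RICH", "CYS_RICH"))
  expect_identical(h$score, c(8L, 8L))
  expect_identical(substr(s, h$start[1], h$start[1]), "C")
  expect_identical(substr(s, h$end[1], h$end[1]), "C")
  # masking the first block removes it
  m <- detectCysRich(s, mask = data.frame(start = h$start[1],
                                          end = h$end[1]))
  expect_identical(nrow(m), 1L)
  expect_identical(m$start, h$start[2])
  # five cysteines per window are not enough
  sparse <- paste(rep("C", 5), collapse = pad(8))
  expect_identical(nrow(detectCysRich(paste0(pad(10), sparse, pad(10)))), 0L)
})

test_that("cysteine-cluster detection agrees with the quadratic oracle", {
  set.seed(44)
  for (i in 1:50) {
    s <- randomSeq(250, c("C", "A", "S", "T", "N", "G"))
    got <- detectCysRich(s)
    want <- oracleCysRich(s)
    expect_identical(got$start, want$start, info = s)
    expect_identical(got$end, want$end, info = s)
    expect_equal(got$score, want$score, info = s)
  }
})

test_that("kinase detection requires the ordered catalytic motifs in span", {
  p <- generateProtein(architectureSpec(list(elTk(active = TRUE))), seed = 9)
  h <- detectTkDomain(as.character(p[[1]]))
  expect_identical(nrow(h), 1L)
  expect_identical(h$kind, "TK")
  expect_true(h$gly_loop && h$vaik_k && h$hrd_d && h$dfg_d)
  expect_identical(assessTkActivity(h), "ACTIVE")

  pin <- generateProtein(architectureSpec(list(elTk(active = FALSE))),
                         seed = 9)
  hin <- detectTkDomain(as.character(pin[[1]]))
  expect_identical(nrow(hin), 1L)
  expect_false(hin$vaik_k && hin$hrd_d)
  expect_identical(assessTkActivity(hin), "INACTIVE")

  # motifs too close together: span below 200 residues, no kinase
  tight <- paste0("GAGAAG", pad(10), "LAIK", pad(10), "HRD", pad(10), "DFG")
  expect_identical(nrow(detectTkDomain(tight)), 0L)
  # no glycine loop, no kinase
  s <- as.character(p[[1]])
  noGly <- sub("G.G..G", "AAAAAA", s)
  expect_identical(nrow(detectTkDomain(noGly)), 0L)
  expect_error(assessTkActivity(data.frame(kind = "TM")), "TK hit")
})

test_that("each catalytic substitution flips the kinase to INACTIVE", {
  p <- as.character(generateProtein(
    architectureSpec(list(elTk(active = TRUE))), seed = 21)[[1]])
  h <- detectTkDomain(p)
  vaikStart <- regexpr("[LIVMF]A[IV][KR]", substr(p, h$start, nchar(p)))
  subAt <- function(s, pos, ch) {
    substr(s, pos, pos) <- ch
    s
  }
  hrdPos <- h$start + as.integer(regexpr("HRD", substr(p, h$start, nchar(p)))) - 1L
  dfgPos <- h$start + as.integer(regexpr("DFG", substr(p, h$start, nchar(p)))) - 1L
  vaikPos <- h$start + as.integer(vaikStart) - 1L
  forms <- list(subAt(p, vaikPos + 3L, "R"),
                subAt(p, hrdPos + 2L, "N"),
                subAt(p, dfgPos, "N"))
  for (f in forms) {
    hf <- detectTkDomain(f)
    expect_identical(nrow(hf), 1L)
    expect_identical(assessTkActivity(hf), "INACTIVE")
  }
})

test_that("the Ig I-set tag is found up to 10 percent mismatches", {
  tag <- EGFRcomplement:::.IG_TAG
  s <- paste0(pad(30), tag, pad(30))
  h <- detectIgIset(s)
  expect_identical(nrow(h), 1L)
  expect_identical(h$start, 31L)
  expect_identical(h$end, 31L + nchar(tag) - 1L)
  mut <- function(x, k) {
    ch <- strsplit(x, "")[[1]]
    at <- seq_len(k) * 7L
    ch[at] <- ifelse(ch[at] == "G", "A", "G")
    paste(ch, collapse = "")
  }
  expect_identical(nrow(detectIgIset(paste0(pad(30), mut(tag, 9), pad(30)))),
                   1L)
  expect_identical(nrow(detectIgIset(paste0(pad(30), mut(tag, 10), pad(30)))),
                   0L)
  set.seed(45)
  expect_identical(nrow(detectIgIset(randomSeq(400))), 0L)
})

test_that("scanDomains recovers exactly the planted architecture", {
  sp <- architectureSpec(list(elSignal(), elCysRich(), elCysRich(),
                              elCysRich(), elTm(), elTk(active = TRUE)),
                         label = "egfr01")
  p <- generateProtein(sp, seed = 17)
  h <- scanDomains(p)
  counts <- as.integer(table(h$kind)[c("SIGNAL", "CYS_RICH", "TM", "TK")])
  expect_identical(counts, c(1L, 3L, 1L, 1L))
  expect_false("EGF_MOTIF" %in% h$kind)
  expect_false("IG_ISET" %in% h$kind)
  expect_true(all(h$start >= 1L & h$end <= nchar(as.character(p[[1]]))))
  expect_true(all(diff(h$start) >= 0L))
  # cysteine-rich clusters all sit N-terminal of the TM segment
  expect_true(all(h$end[h$kind == "CYS_RICH"] < min(h$start[h$kind == "TM"])))
})

test_that("scan profile parameters are honoured", {
  s <- paste0(strrep("N", 20), strrep("L", 21), strrep("N", 20))
  expect_identical(nrow(predictTmSegments(s)), 1L)
  strict <- scanProfile(tmThreshold = 4.0)
  expect_identical(nrow(predictTmSegments(s, strict)), 0L)
  expect_error(scanProfile(egfGapMin = c(5L, 5L, 5L, 5L, 5L),
                           egfGapMax = c(4L, 7L, 16L, 2L, 15L)),
               "minima")
})
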