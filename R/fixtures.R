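#' @importFrom Biostrings AAStringSet
NULL

# Background (linker) residues: no cysteine, no strongly hydrophobic
# residues, hydropathy-negative on average. The alphabet is kept wide
# (14 letters spanning small, polar, charged and aromatic residues) so that
# unrelated linkers align no better than random protein background; a
# narrower alphabet would manufacture low-complexity similarity that real
# proteins do not share.
.LINKER_ALPHABET <- c("A", "G", "S", "T", "N", "Q", "D", "E", "P",
                      "K", "R", "H", "W", "Y")
# Spacers used inside domain templates: as above but glycine-free (so a
# template can never seed a spurious kinase glycine loop) and arginine-free
# (so the kinase scaffold can never seed a spurious HR[DN] catalytic motif
# ahead of the planted one).
.SPACER_ALPHABET <- c("A", "S", "T", "N", "Q", "D", "E", "P",
                      "K", "H", "W", "Y")

# Fixed 90-residue immunoglobulin I-set tag. A synthetic stand-in recognized
# by exact-tag matching (<= 10% mismatches), not a real I-set profile: it
# avoids cysteine, glycine, the hydrophobic alphabet and all kinase motif
# anchors so that no other scanner can fire on it.
.IG_TAG <- paste0("PAQESDHWPSYWEKEDANRTMWDQPTMTSPWMPDYHYSSRPWAPPTEHATTETQMADE",
                  "SKQMMQNAQAAYSWYSWHPTNDSQYSSPMRPY")

#' Architecture element constructors
#'
#' Small helpers building the elements of an \linkS4class{ArchitectureSpec}.
#' \code{elTk(active = FALSE)} requests a tyrosine-kinase domain whose
#' ATP-binding lysine (VAIK) and catalytic aspartate (HRD) are substituted,
#' mimicking a pseudokinase; \code{elLinker} inserts an explicit spacer.
#'
#' @param active logical; canonical catalytic residues present?
#' @param length linker length in residues.
#' @return a list element usable in \code{\link{architectureSpec}}.
#' @export
elSignal <- function() list(type = "SIGNAL")

#' @rdname elSignal
#' @export
elCysRich <- function() list(type = "CYS_RICH")

#' @rdname elSignal
#' @export
elEgfMotif <- function() list(type = "EGF_MOTIF")

#' @rdname elSignal
#' @export
elIgIset <- function() list(type = "IG_ISET")

#' @rdname elSignal
#' @export
elTm <- function() list(type = "TM")

#' @rdname elSignal
#' @export
elTk <- function(active = TRUE) list(type = "TK", active = isTRUE(active))

#' @rdname elSignal
#' @export
elLinker <- function(length) list(type = "LINKER", length = as.integer(length))

#' Create an architecture specification
#'
#' @param elements list of elements (see \code{\link{elSignal}} and friends).
#' @param isFullLength logical; FALSE marks a truncated protein.
#' @param label free-text label carried into generated record ids.
#' @return an \linkS4class{ArchitectureSpec}.
#' @examples
#' architectureSpec(list(elSignal(), elEgfMotif(), elTm()), label = "egf01")
#' @export
architectureSpec <- function(elements, isFullLength = TRUE, label = "spec") {
  new("ArchitectureSpec", elements = elements,
      isFullLength = isTRUE(isFullLength), label = label)
}

#' Compact element signature of an architecture
#'
#' @param spec an \linkS4class{ArchitectureSpec}.
#' @return a string such as \code{"SP+CRx3+TM+TK"}.
#' @export
architectureSignature <- function(spec) {
  tok <- vapply(spec@elements, function(e) {
    switch(e$type,
           SIGNAL = "SP", CYS_RICH = "CR", EGF_MOTIF = "EGF", IG_ISET = "IG",
           TM = "TM", LINKER = "LNK",
           TK = if (isTRUE(e$active)) "TK" else "TKi")
  }, character(1))
  r <- rle(tok)
  paste(ifelse(r$lengths > 1L, paste0(r$values, "x", r$lengths), r$values),
        collapse = "+")
}

# ---- element sequence templates (RNG must be active when called) ----

.sampleChars <- function(n, alphabet) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

.tplLinker <- function(n) {
  if (n <= 0L) return("")
  repeat {
    s <- .sampleChars(n, .LINKER_ALPHABET)
    if (grepl("G.G..G", s)) next
    if (n >= 8L && max(.windowMeans(.hydropathy(s), 8L)) >= 1.6) next
    return(s)
  }
}

.tplSignal <- function() {
  repeat {
    core <- sample(c("L", "A", "V"), 10, replace = TRUE)
    wm <- .windowMeans(.KD[core], 8L)
    if (min(wm) >= 2.0 && mean(.KD[core]) >= 2.2) break
  }
  paste0("M", .sampleChars(2, c("S", "T", "N", "Q")),
         paste(core, collapse = ""),
         "A", sample(c("S", "T", "N", "Q"), 1), "A")
}

.tplTm <- function() .sampleChars(21, c("L", "I", "V", "F", "A"))

.tplEgf <- function() {
  gaps <- c(8L, 5L, 8L, 2L, 9L)
  paste0("C", paste(vapply(gaps, .sampleChars, character(1),
                           alphabet = .SPACER_ALPHABET), collapse = "C"), "C")
}

.tplCysRich <- function() {
  paste0("C", paste(replicate(7, .sampleChars(3, .SPACER_ALPHABET)),
                    collapse = "C"), "C")
}

.tplTk <- function(active = TRUE) {
  s <- .chars(.sampleChars(270, .SPACER_ALPHABET))
  gx <- function() sample(.SPACER_ALPHABET, 1)
  s[6:11] <- c("G", gx(), "G", gx(), gx(), "G")
  s[46:49] <- c("V", "A", "I", if (active) "K" else "R")
  s[216:218] <- c("H", "R", if (active) "D" else "N")
  s[241:243] <- c("D", "F", "G")
  paste(s, collapse = "")
}

.elementSeq <- function(e) {
  switch(e$type,
         SIGNAL = .tplSignal(),
         CYS_RICH = .tplCysRich(),
         EGF_MOTIF = .tplEgf(),
         IG_ISET = .IG_TAG,
         TM = .tplTm(),
         TK = .tplTk(isTRUE(e$active)),
         LINKER = .tplLinker(e$length))
}

#' Generate a synthetic protein from an architecture specification
#'
#' Concatenates sequence templates for each element, separated by random
#' cysteine-free, hydropathy-negative linkers on which no scanner can fire.
#' Consecutive cysteine-rich elements get a longer spacer so that windowed
#' cluster detection cannot merge them. Identical \code{(spec, seed)} pairs
#' yield byte-identical sequences.
#'
#' @param spec an \linkS4class{ArchitectureSpec}.
#' @param seed integer seed.
#' @param id record id; defaults to the spec label.
#' @param species,clade optional annotations.
#' @return an \code{AAStringSet} of length 1 with metadata columns
#'   \code{species}, \code{clade}, \code{label}, \code{signature},
#'   \code{is_full_length}.
#' @examples
#' p <- generateProtein(architectureSpec(list(elSignal(), elEgfMotif(),
#'                                            elTm())), seed = 7)
#' @export
generateProtein <- function(spec, seed, id = NULL, species = NA_character_,
                            clade = NA_character_) {
  validObject(spec)
  seq <- .withSeed(seed, {
    parts <- character(0)
    els <- spec@elements
    for (i in seq_along(els)) {
      if (i == 1L) {
        if (els[[i]]$type != "SIGNAL" && els[[i]]$type != "LINKER")
          parts <- c(parts, .tplLinker(20L))
      } else if (els[[i - 1]]$type != "LINKER" && els[[i]]$type != "LINKER") {
        gap <- if (els[[i - 1]]$type == "CYS_RICH" &&
                   els[[i]]$type == "CYS_RICH") 90L else 40L
        parts <- c(parts, .tplLinker(gap))
      }
      parts <- c(parts, .elementSeq(els[[i]]))
    }
    paste(c(parts, .tplLinker(20L)), collapse = "")
  })
  out <- AAStringSet(seq)
  names(out) <- if (is.null(id)) spec@label else id
  mcols(out) <- DataFrame(species = species, clade = clade,
                          label = spec@label,
                          signature = architectureSignature(spec),
                          is_full_length = spec@isFullLength)
  out
}

#' Create a per-species fixture specification
#'
#' @param species,clade names.
#' @param receptorSpecs,ligandSpecs,decoySpecs lists of
#'   \linkS4class{ArchitectureSpec}.
#' @return a \linkS4class{SpeciesFixtureSpec}.
#' @export
speciesFixtureSpec <- function(species, clade, receptorSpecs = list(),
                               ligandSpecs = list(), decoySpecs = list()) {
  new("SpeciesFixtureSpec", species = species, clade = clade,
      receptorSpecs = receptorSpecs, ligandSpecs = ligandSpecs,
      decoySpecs = decoySpecs)
}

#' Generate the synthetic proteome of one species fixture
#'
#' One record per receptor/ligand/decoy specification. Per-protein seeds are
#' derived deterministically from the global seed, the species and the spec
#' label, so the full set is reproducible and two species never share a
#' sequence.
#'
#' @param fixture a \linkS4class{SpeciesFixtureSpec}.
#' @param seed integer seed.
#' @return an \code{AAStringSet} with metadata columns as in
#'   \code{\link{generateProtein}}.
#' @export
generateSpeciesSet <- function(fixture, seed) {
  specs <- c(fixture@receptorSpecs, fixture@ligandSpecs, fixture@decoySpecs)
  if (length(specs) == 0L) return(AAStringSet())
  tip <- .tipName(fixture@species)
  recs <- lapply(specs, function(sp) {
    s <- .deriveSeed(seed, paste(fixture@species, sp@label))
    generateProtein(sp, s,
                    id = paste(tip, sp@label, architectureSignature(sp),
                               sep = "|"),
                    species = fixture@species, clade = fixture@clade)
  })
  out <- do.call(c, recs)
  out
}

# printed species name <-> tree tip label
.tipName <- function(species) gsub("\\.\\s*", "_", species)
.printedName <- function(tip) sub("_", ". ", tip)

# ---- fixtures instantiating the bundled survey tables ----

# expand a printed multiplicity string like "1(6), ?(2)" into a length-n
# vector; a bare value (no parentheses) applies to all n genes.
.parseMulti <- function(x, n, default) {
  x <- trimws(x)
  if (x %in% c("-", "–", "")) return(rep(default, n))
  toks <- trimws(strsplit(x, ",")[[1]])
  m <- regmatches(toks, regexec("^(.+?)\\((\\d+)\\)$", toks))
  vals <- character(0)
  for (i in seq_along(toks)) {
    if (length(m[[i]]) == 3L)
      vals <- c(vals, rep(m[[i]][2], as.integer(m[[i]][3])))
    else if (length(toks) == 1L)
      vals <- rep(toks[1], n)
    else stop("cannot parse multiplicity token: ", toks[i])
  }
  if (length(vals) != n)
    stop("multiplicity '", x, "' expands to ", length(vals), " genes, not ", n)
  vals[vals == "?"] <- default
  vals
}

#' Architecture fixtures for all surveyed species
#'
#' Instantiates, from the bundled survey tables, one
#' \linkS4class{SpeciesFixtureSpec} per species: receptor specifications with
#' the printed per-gene transmembrane, signal-peptide, cysteine-rich and
#' kinase-activity values (unknown entries take the clade-typical values
#' TM = 1, SP present, 3 cysteine-rich clusters); EGF-type ligand
#' specifications with a transmembrane count cycling 1, 0, 2; NRG-type ligand
#' specifications with the EGF + Ig I-set + TM architecture; and three decoys
#' per species, each exercising one rejection rule (two EGF motifs, truncated
#' single-motif, kinase without ectodomain).
#'
#' @param species optional character vector restricting to these (printed)
#'   species names.
#' @param decoys logical; include the decoy specifications (default TRUE).
#' @return named list of \linkS4class{SpeciesFixtureSpec} (names are printed
#'   species names, in table order).
#' @export
speciesFixtures <- function(species = NULL, decoys = TRUE) {
  et <- .readBundledTable("egfr_table.tsv")
  lt <- .readBundledTable("ligand_table.tsv")
  if (is.null(species)) species <- et$species
  out <- list()
  for (sp in species) {
    er <- et[et$species == sp, ]
    if (nrow(er) != 1L) stop("unknown species: ", sp)
    n <- as.integer(er$n_egfr)
    rspecs <- list()
    if (n > 0L) {
      tm <- as.integer(.parseMulti(er$tm, n, "1"))
      sig <- .parseMulti(er$sp, n, "Yes")
      cys <- as.integer(.parseMulti(er$cys_rich, n, "3"))
      inact <- .parseMulti(er$inactive_tk, n, "No")
      for (i in seq_len(n)) {
        els <- list()
        if (sig[i] == "Yes") els <- c(els, list(elSignal()))
        els <- c(els, rep(list(elCysRich()), cys[i]),
                 rep(list(elTm()), tm[i]),
                 list(elTk(active = inact[i] != "Yes")))
        rspecs[[i]] <- architectureSpec(els, label = sprintf("egfr%02d", i))
      }
    }
    lr <- lt[lt$species == sp, ]
    lspecs <- list()
    if (nrow(lr) == 1L) {
      ne <- suppressWarnings(as.integer(lr$egf_like))
      nn <- suppressWarnings(as.integer(lr$nrg_like))
      if (is.na(ne)) ne <- 0L
      if (is.na(nn)) nn <- 0L
      tmcycle <- c(1L, 0L, 2L)
      for (i in seq_len(ne)) {
        els <- c(list(elSignal(), elEgfMotif()),
                 rep(list(elTm()), tmcycle[(i - 1L) %% 3L + 1L]))
        lspecs[[length(lspecs) + 1L]] <-
          architectureSpec(els, label = sprintf("egf%02d", i))
      }
      for (i in seq_len(nn)) {
        lspecs[[length(lspecs) + 1L]] <-
          architectureSpec(list(elSignal(), elEgfMotif(), elIgIset(), elTm()),
                           label = sprintf("nrg%02d", i))
      }
    }
    dspecs <- if (decoys) list(
      architectureSpec(list(elSignal(), elEgfMotif(), elEgfMotif(), elTm()),
                       label = "decoy_multi_egf"),
      architectureSpec(list(elSignal(), elEgfMotif(), elTm()),
                       isFullLength = FALSE, label = "decoy_truncated"),
      architectureSpec(list(elTk(active = TRUE)), label = "decoy_tk_only")
    ) else list()
    out[[sp]] <- speciesFixtureSpec(sp, er$clade, rspecs, lspecs, dspecs)
  }
  out
}

#' Generate the full synthetic survey proteome
#'
#' Convenience wrapper generating the proteomes of all (or selected) species
#' fixtures into one record set.
#'
#' @inheritParams speciesFixtures
#' @param seed integer seed.
#' @return an \code{AAStringSet}.
#' @export
generateSurveyProteins <- function(seed, species = NULL, decoys = TRUE) {
  fx <- speciesFixtures(species = species, decoys = decoys)
  do.call(c, unname(lapply(fx, generateSpeciesSet, seed = seed)))
}
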