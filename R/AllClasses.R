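#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<-
NULL

.ELEMENT_TYPES <- c("SIGNAL", "CYS_RICH", "EGF_MOTIF", "IG_ISET", "TM", "TK", "LINKER")

.HIT_KINDS <- c("EGF_MOTIF", "IG_ISET", "TM", "SIGNAL", "CYS_RICH", "TK")

.CATEGORIES <- c("EGFR", "EGF_TYPE_LIGAND", "NRG_TYPE_LIGAND", "REJECTED")

.REJECTION_REASONS <- c("TK_WITHOUT_ECTODOMAIN", "NO_EGF_MOTIF",
                        "MULTIPLE_EGF_MOTIFS", "NOT_FULL_LENGTH",
                        "INCOHERENT_ARCHITECTURE")

#' Declarative protein architecture specification
#'
#' An ordered list of structural elements from which a synthetic protein is
#' generated. Supported element types are \code{SIGNAL} (signal peptide),
#' \code{CYS_RICH} (cysteine-rich cluster), \code{EGF_MOTIF} (six-cysteine
#' EGF module), \code{IG_ISET} (immunoglobulin I-set tag), \code{TM}
#' (transmembrane segment), \code{TK} (tyrosine-kinase domain, with an
#' \code{active} flag) and \code{LINKER} (explicit spacer of given length).
#'
#' @slot elements list of elements; each a list with at least \code{$type}.
#' @slot isFullLength logical scalar, whether the protein is complete.
#' @slot label free-text label carried into generated record ids.
#' @export
setClass("ArchitectureSpec",
         representation(elements = "list",
                        isFullLength = "logical",
                        label = "character"))

setValidity("ArchitectureSpec", function(object) {
  msgs <- character(0)
  if (length(object@elements) == 0L)
    msgs <- c(msgs, "element list must be non-empty")
  types <- vapply(object@elements, function(e) e$type, character(1))
  if (!all(types %in% .ELEMENT_TYPES))
    msgs <- c(msgs, paste("unknown element type(s):",
                          paste(setdiff(types, .ELEMENT_TYPES), collapse = ", ")))
  if (sum(types == "TK") > 1L)
    msgs <- c(msgs, "at most one TK element is allowed")
  if (length(object@isFullLength) != 1L || is.na(object@isFullLength))
    msgs <- c(msgs, "isFullLength must be TRUE or FALSE")
  if (length(msgs)) msgs else TRUE
})

#' Per-species fixture specification
#'
#' Bundles the receptor, ligand and decoy architecture specifications for one
#' species of the bundled complement survey.
#'
#' @slot species species name as printed in the bundled tables.
#' @slot clade major clade the species belongs to.
#' @slot receptorSpecs,ligandSpecs,decoySpecs lists of
#'   \linkS4class{ArchitectureSpec}.
#' @export
setClass("SpeciesFixtureSpec",
         representation(species = "character",
                        clade = "character",
                        receptorSpecs = "list",
                        ligandSpecs = "list",
                        decoySpecs = "list"))

#' Scanner parameter profile
#'
#' Tunable parameters of the lightweight domain scanners. Hydropathy values
#' refer to the Kyte-Doolittle scale.
#'
#' @slot tmWindow sliding-window size for transmembrane prediction (residues).
#' @slot tmThreshold mean hydropathy a window must reach to fire.
#' @slot tmMinLen minimum merged segment length retained as a TM.
#' @slot spSearchLen how many N-terminal residues to search for a signal
#'   peptide.
#' @slot spMinLen minimum hydrophobic stretch length for a signal peptide.
#' @slot spThreshold mean hydropathy the stretch must reach.
#' @slot spMaxStart latest 1-based start position of the stretch.
#' @slot cysWindow window size for cysteine-rich cluster detection.
#' @slot cysMin minimum cysteines per window.
#' @slot egfGapMin,egfGapMax per-gap residue spacing bounds of the
#'   six-cysteine EGF pattern C-x(3,14)-C-x(3,7)-C-x(1,16)-C-x(1,2)-C-x(4,15)-C.
#' @slot igMaxMismatch maximum mismatches tolerated against the I-set tag.
#' @export
setClass("ScanProfile",
         representation(tmWindow = "integer", tmThreshold = "numeric",
                        tmMinLen = "integer",
                        spSearchLen = "integer", spMinLen = "integer",
                        spThreshold = "numeric", spMaxStart = "integer",
                        cysWindow = "integer", cysMin = "integer",
                        egfGapMin = "integer", egfGapMax = "integer",
                        igMaxMismatch = "integer"),
         prototype(tmWindow = 19L, tmThreshold = 1.6, tmMinLen = 15L,
                   spSearchLen = 35L, spMinLen = 8L, spThreshold = 2.0,
                   spMaxStart = 11L,
                   cysWindow = 60L, cysMin = 6L,
                   egfGapMin = c(3L, 3L, 1L, 1L, 4L),
                   egfGapMax = c(14L, 7L, 16L, 2L, 15L),
                   igMaxMismatch = 9L))

setValidity("ScanProfile", function(object) {
  msgs <- character(0)
  if (object@tmWindow < 1L || object@cysWindow < 1L || object@spSearchLen < 1L)
    msgs <- c(msgs, "all windows must be >= 1")
  if (length(object@egfGapMin) != 5L || length(object@egfGapMax) != 5L)
    msgs <- c(msgs, "EGF spacing must give 5 gap ranges")
  else if (any(object@egfGapMin > object@egfGapMax))
    msgs <- c(msgs, "EGF spacing minima must not exceed maxima")
  if (length(msgs)) msgs else TRUE
})

#' Species-by-component complement matrix
#'
#' Species x character table of pathway-component counts: number of EGFRs,
#' of receptors with an inactive tyrosine-kinase domain, and of EGF-type and
#' NRG-type ligands. Rows rejected by the classifier are kept in a QC side
#' table.
#'
#' @slot table data.frame with columns \code{species}, \code{clade},
#'   \code{egfr_count}, \code{inactive_tk_count}, \code{egf_like_count},
#'   \code{nrg_like_count}.
#' @slot qc data.frame of rejected records (may be empty).
#' @slot provenance either \code{"SCANNED"} (computed from sequences) or
#'   \code{"TRANSCRIBED"} (bundled published survey).
#' @export
setClass("ComplementMatrix",
         representation(table = "data.frame",
                        qc = "data.frame",
                        provenance = "character"))

setValidity("ComplementMatrix", function(object) {
  need <- c("species", "clade", "egfr_count", "inactive_tk_count",
            "egf_like_count", "nrg_like_count")
  msgs <- character(0)
  if (!all(need %in% colnames(object@table)))
    msgs <- c(msgs, paste("table must have columns:", paste(need, collapse = ", ")))
  else {
    cnt <- object@table[, need[-(1:2)]]
    if (any(cnt < 0, na.rm = TRUE))
      msgs <- c(msgs, "all counts must be >= 0")
  }
  if (!object@provenance %in% c("SCANNED", "TRANSCRIBED"))
    msgs <- c(msgs, "provenance must be SCANNED or TRANSCRIBED")
  if (length(msgs)) msgs else TRUE
})

#' Threshold similarity graph over protein records
#'
#' All-vs-all local-alignment similarity graph: nodes are record ids, edges
#' connect pairs whose (normalized) score reaches the threshold, and the
#' component partition is the connected components of that edge set.
#'
#' @slot nodes character vector of record ids.
#' @slot edges data.frame with columns \code{from}, \code{to}, \code{score}
#'   (raw Smith-Waterman), \code{normalized} and \code{attraction} (in [0,1]).
#' @slot threshold numeric threshold the edges satisfy.
#' @slot normalization \code{"RAW"} or \code{"BITS_PER_SHORTER"}.
#' @slot membership named integer vector: component id per node.
#' @export
setClass("SimilarityGraph",
         representation(nodes = "character", edges = "data.frame",
                        threshold = "numeric", normalization = "character",
                        membership = "integer"))

#' Dollo parsimony reconstruction of a binary character
#'
#' Single-gain, multiple-loss reconstruction: the gain is placed on the most
#' recent common ancestor of all taxa possessing the character, and one loss
#' on the root edge of every maximal character-free subtree within the gain
#' clade.
#'
#' @slot character character name.
#' @slot tree the \code{phylo} tree used.
#' @slot gainNode ape node number of the gain.
#' @slot lossEdges data.frame with columns \code{parent}, \code{child},
#'   \code{child_label}.
#' @slot nodeStates integer vector of 0/1 states indexed by ape node number.
#' @export
setClass("DolloReconstruction",
         representation(character = "character", tree = "ANY",
                        gainNode = "integer", lossEdges = "data.frame",
                        nodeStates = "integer"))

#' Sankoff parsimony reconstruction of a count character
#'
#' Minimum-cost ancestral copy-number assignment over states 0..maxCount under
#' a linear cost |child - parent| (configurable), with ties broken toward the
#' smaller ancestral count.
#'
#' @slot character character name.
#' @slot tree the \code{phylo} tree used.
#' @slot nodeCounts integer vector of counts indexed by ape node number.
#' @slot totalCost total parsimony cost of the reconstruction.
#' @slot events data.frame of edges with a count change: columns
#'   \code{parent}, \code{child}, \code{child_label}, \code{from}, \code{to},
#'   \code{delta}.
#' @export
setClass("SankoffReconstruction",
         representation(character = "character", tree = "ANY",
                        nodeCounts = "integer", totalCost = "numeric",
                        events = "data.frame"))
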