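.emptyCalls <- function() {
  data.frame(record_id = character(0), species = character(0),
             category = character(0), cys_rich_count = integer(0),
             tm_count = integer(0), has_signal = logical(0),
             tk_status = character(0), egf_motif_count = integer(0),
             ig_iset = logical(0), rejection_reason = character(0),
             stringsAsFactors = FALSE)
}

#' Classify one scanned protein
#'
#' Applies the inclusion and typing rules, in order:
#' \enumerate{
#'   \item kinase domain present, at least one transmembrane segment, and at
#'     least one cysteine-rich cluster N-terminal of the first transmembrane
#'     segment: \code{EGFR} (kinase status from
#'     \code{\link{assessTkActivity}});
#'   \item otherwise, kinase present: \code{REJECTED}
#'     (\code{TK_WITHOUT_ECTODOMAIN});
#'   \item otherwise, exactly one EGF motif, full length, and at most two
#'     transmembrane segments: a ligand, typed \code{NRG_TYPE_LIGAND} when an
#'     Ig I-set domain is present together with a transmembrane segment, else
#'     \code{EGF_TYPE_LIGAND};
#'   \item otherwise \code{REJECTED} with reason \code{NO_EGF_MOTIF},
#'     \code{MULTIPLE_EGF_MOTIFS}, \code{NOT_FULL_LENGTH} or
#'     \code{INCOHERENT_ARCHITECTURE}.
#' }
#' The classifier is a pure function of its inputs.
#'
#' @param recordId record identifier (for the output row).
#' @param hits data.frame of hits for this record, as produced by
#'   \code{\link{scanDomains}} (with or without the \code{record} column).
#' @param isFullLength logical completeness flag carried as metadata.
#' @param seqLength optional sequence length; when given, hit coordinates are
#'   checked against it.
#' @return a one-row \code{ComponentCall} data.frame.
#' @export
classifyRecord <- function(recordId, hits, isFullLength = TRUE,
                           seqLength = NULL) {
  if (!is.null(seqLength) &&
      nrow(hits) && any(hits$start < 1L | hits$end > seqLength))
    stop("hit coordinates out of range for record ", recordId)
  kind <- hits$kind
  tkHit <- hits[kind == "TK", , drop = FALSE]
  tmHits <- hits[kind == "TM", , drop = FALSE]
  cysHits <- hits[kind == "CYS_RICH", , drop = FALSE]
  nEgf <- sum(kind == "EGF_MOTIF")
  nTm <- nrow(tmHits)
  hasSignal <- any(kind == "SIGNAL")
  hasIg <- any(kind == "IG_ISET")
  tkStatus <- if (nrow(tkHit)) assessTkActivity(tkHit[1, ]) else "NONE"

  category <- "REJECTED"
  reason <- ""
  if (nrow(tkHit)) {
    ecto <- nTm >= 1L && nrow(cysHits) > 0L &&
      any(cysHits$end < min(tmHits$start))
    if (ecto) category <- "EGFR"
    else reason <- "TK_WITHOUT_ECTODOMAIN"
  } else if (nEgf == 1L && isTRUE(isFullLength) && nTm <= 2L) {
    category <- if (hasIg && nTm >= 1L) "NRG_TYPE_LIGAND" else "EGF_TYPE_LIGAND"
  } else {
    reason <- if (nEgf == 0L) "NO_EGF_MOTIF"
    else if (nEgf > 1L) "MULTIPLE_EGF_MOTIFS"
    else if (!isTRUE(isFullLength)) "NOT_FULL_LENGTH"
    else "INCOHERENT_ARCHITECTURE"
  }
  data.frame(record_id = recordId, species = NA_character_,
             category = category, cys_rich_count = nrow(cysHits),
             tm_count = nTm, has_signal = hasSignal, tk_status = tkStatus,
             egf_motif_count = nEgf, ig_iset = hasIg,
             rejection_reason = reason, stringsAsFactors = FALSE)
}

#' Scan and classify a set of proteins
#'
#' Runs \code{\link{scanDomains}} and \code{\link{classifyRecord}} on every
#' record. Species and completeness are read from the records' metadata
#' columns when present.
#'
#' @param x an \code{AAStringSet} with optional metadata columns
#'   \code{species} and \code{is_full_length}.
#' @param profile a \linkS4class{ScanProfile}.
#' @param hits optional precomputed hit table from \code{\link{scanDomains}}.
#' @return data.frame of \code{ComponentCall} rows, one per record.
#' @examples
#' fx <- speciesFixtures("C. elegans")[[1]]
#' calls <- classifyProteins(generateSpeciesSet(fx, seed = 1))
#' table(calls$category)
#' @export
classifyProteins <- function(x, profile = scanProfile(), hits = NULL) {
  if (length(x) == 0L) return(.emptyCalls())
  if (is.null(names(x))) names(x) <- paste0("record", seq_along(x))
  if (is.null(hits)) hits <- scanDomains(x, profile)
  meta <- mcols(x)
  fl <- if (!is.null(meta) && "is_full_length" %in% colnames(meta))
    meta$is_full_length else rep(TRUE, length(x))
  spp <- if (!is.null(meta) && "species" %in% colnames(meta))
    meta$species else rep(NA_character_, length(x))
  calls <- do.call(rbind, lapply(seq_along(x), function(i) {
    id <- names(x)[i]
    h <- hits[hits$record == id, , drop = FALSE]
    r <- classifyRecord(id, h, isFullLength = isTRUE(fl[i]),
                        seqLength = nchar(as.character(x[[i]])))
    r$species <- spp[i]
    r
  }))
  rownames(calls) <- NULL
  calls
}

#' Aggregate component calls into a complement matrix
#'
#' Per-species counts of EGFR calls, of EGFRs with an inactive kinase domain,
#' and of EGF-type and NRG-type ligand calls. Rejected records are not counted
#' in the matrix; they are kept in the QC side table.
#'
#' @param calls data.frame from \code{\link{classifyProteins}}.
#' @param speciesOf optional named character vector mapping record ids to
#'   species; defaults to the calls' own \code{species} column.
#' @param cladeOf optional named character vector mapping species to clades.
#' @return a \linkS4class{ComplementMatrix} with provenance \code{"SCANNED"}.
#' @export
buildComplementMatrix <- function(calls, speciesOf = NULL, cladeOf = NULL) {
  if (!is.null(speciesOf)) {
    miss <- setdiff(calls$record_id, names(speciesOf))
    if (length(miss))
      stop("unmapped record id(s): ", paste(utils::head(miss, 3), collapse = ", "))
    calls$species <- unname(speciesOf[calls$record_id])
  }
  if (nrow(calls) && anyNA(calls$species))
    stop("records without a species mapping")
  spp <- unique(calls$species)
  tab <- do.call(rbind, lapply(spp, function(sp) {
    cc <- calls[calls$species == sp, ]
    data.frame(species = sp,
               clade = if (!is.null(cladeOf)) unname(cladeOf[sp]) else NA_character_,
               egfr_count = sum(cc$category == "EGFR"),
               inactive_tk_count = sum(cc$category == "EGFR" &
                                         cc$tk_status == "INACTIVE"),
               egf_like_count = sum(cc$category == "EGF_TYPE_LIGAND"),
               nrg_like_count = sum(cc$category == "NRG_TYPE_LIGAND"),
               stringsAsFactors = FALSE)
  }))
  if (is.null(tab))
    tab <- data.frame(species = character(0), clade = character(0),
                      egfr_count = integer(0), inactive_tk_count = integer(0),
                      egf_like_count = integer(0), nrg_like_count = integer(0),
                      stringsAsFactors = FALSE)
  qc <- calls[calls$category == "REJECTED", , drop = FALSE]
  rownames(tab) <- rownames(qc) <- NULL
  new("ComplementMatrix", table = tab, qc = qc, provenance = "SCANNED")
}
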