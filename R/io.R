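#' Read and write protein FASTA with record metadata
#'
#' Headers follow the convention \code{species|label|signature} for the id,
#' followed by whitespace-separated \code{key=value} annotations
#' (\code{species}, \code{clade}, \code{full_length}). Bare ids are accepted
#' with empty metadata; a write followed by a read restores identical records.
#'
#' @param x an \code{AAStringSet} with the package's metadata columns.
#' @param path file path.
#' @return \code{readProteinFasta}: an \code{AAStringSet} with metadata
#'   columns restored.
#' @export
writeProteinFasta <- function(x, path) {
  meta <- mcols(x)
  hdr <- names(x)
  if (!is.null(meta) && "species" %in% colnames(meta)) {
    ann <- sprintf(" species=%s clade=%s full_length=%s label=%s",
                   .tipName(ifelse(is.na(meta$species), ".", meta$species)),
                   ifelse(is.na(meta$clade), ".", meta$clade),
                   meta$is_full_length, meta$label)
    hdr <- paste0(hdr, ann)
  }
  y <- x
  names(y) <- hdr
  Biostrings::writeXStringSet(y, path)
  invisible(path)
}

#' @rdname writeProteinFasta
#' @export
readProteinFasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  toks <- strsplit(names(x), "\\s+")
  ids <- vapply(toks, `[`, character(1), 1L)
  getkv <- function(tk, key) {
    hit <- grep(paste0("^", key, "="), tk, value = TRUE)
    if (length(hit)) sub(paste0("^", key, "="), "", hit[1]) else NA_character_
  }
  species <- vapply(toks, getkv, character(1), key = "species")
  clade <- vapply(toks, getkv, character(1), key = "clade")
  fl <- vapply(toks, getkv, character(1), key = "full_length")
  lab <- vapply(toks, getkv, character(1), key = "label")
  idparts <- strsplit(ids, "|", fixed = TRUE)
  sig <- vapply(idparts, function(p) if (length(p) >= 3L) p[3] else
    NA_character_, character(1))
  lab2 <- vapply(idparts, function(p) if (length(p) >= 2L) p[2] else
    NA_character_, character(1))
  names(x) <- ids
  mcols(x) <- DataFrame(
    species = ifelse(is.na(species) | species == ".", NA,
                     .printedName(species)),
    clade = ifelse(is.na(clade) | clade == ".", NA, clade),
    label = ifelse(is.na(lab), lab2, lab),
    signature = sig,
    is_full_length = ifelse(is.na(fl), TRUE, fl == "TRUE"))
  x
}

#' Read and write Newick trees
#'
#' Thin wrappers preserving topology, tip labels and node labels (polytomies
#' included).
#'
#' @param tree a \code{phylo} object.
#' @param path file path.
#' @export
writeNewickTree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname writeNewickTree
#' @export
readNewickTree <- function(path) ape::read.tree(path)

#' Read and write complement matrices as TSV
#'
#' Columns: \code{species}, \code{clade}, \code{egfr_count},
#' \code{inactive_tk_count}, \code{egf_like_count}, \code{nrg_like_count}.
#'
#' @param m a \linkS4class{ComplementMatrix}.
#' @param path file path.
#' @param provenance provenance of a read matrix.
#' @export
writeComplementTsv <- function(m, path) {
  utils::write.table(complementTable(m), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeComplementTsv
#' @export
readComplementTsv <- function(path, provenance = "TRANSCRIBED") {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  new("ComplementMatrix", table = tab, qc = data.frame(),
      provenance = provenance)
}

#' Write and read domain hits as protein-space GFF3
#'
#' One feature line per hit: seqid = record id, 1-based inclusive protein
#' coordinates, score column = hit score, attributes carrying the kinase
#' catalytic-residue flags when applicable. Malformed lines on reading raise
#' an error naming the line number.
#'
#' @param hits data.frame from \code{\link{scanDomains}}.
#' @param path file path.
#' @export
writeGff3 <- function(hits, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(hits)) {
    attrs <- vapply(seq_len(nrow(hits)), function(i) {
      a <- sprintf("ID=%s.%d;kind=%s", hits$record[i], i, hits$kind[i])
      if (hits$kind[i] == "TK")
        a <- paste0(a, sprintf(";gly_loop=%s;vaik_k=%s;hrd_d=%s;dfg_d=%s",
                               hits$gly_loop[i], hits$vaik_k[i],
                               hits$hrd_d[i], hits$dfg_d[i]))
      a
    }, character(1))
    writeLines(sprintf("%s\tEGFRcomplement\t%s\t%d\t%d\t%.4g\t.\t.\t%s",
                       hits$record, hits$kind, hits$start, hits$end,
                       hits$score, attrs), con)
  }
  invisible(path)
}

#' @rdname writeGff3
#' @export
readGff3 <- function(path) {
  lines <- readLines(path)
  body <- which(!startsWith(lines, "#") & nzchar(lines))
  out <- .emptyHits()
  out <- cbind(record = character(0), out)
  rows <- lapply(body, function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != 9L)
      stop("malformed GFF3 line ", i, ": expected 9 fields, got ", length(f))
    getf <- function(key) {
      m <- regmatches(f[9], regexec(paste0(key, "=([^;]+)"), f[9]))[[1]]
      if (length(m) == 2L) m[2] else NA_character_
    }
    cbind(record = f[1],
          .hitRow(f[3], as.integer(f[4]), as.integer(f[5]), as.numeric(f[6]),
                  gly = as.logical(getf("gly_loop")),
                  vaik = as.logical(getf("vaik_k")),
                  hrd = as.logical(getf("hrd_d")),
                  dfg = as.logical(getf("dfg_d"))))
  })
  if (length(rows)) out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
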