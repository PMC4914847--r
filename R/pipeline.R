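.CONFIG_DEFAULTS <- list(
  seed = 1L,
  outDir = "egfr_run",
  species = NULL,        # NULL = full survey
  decoys = TRUE,
  threshold = 0.5,       # ligand-cluster cutoff, bits per residue
  cluster = TRUE,        # run the ligand-clustering stage
  ancestral = TRUE,      # run the parsimony stage
  profile = list(),      # ScanProfile overrides
  verbose = TRUE
)

#' Validate a pipeline run configuration
#'
#' Fills defaults and rejects unknown keys before any stage runs.
#'
#' @param config named list (or path to a JSON file) of settings; see
#'   \code{\link{runPipeline}}.
#' @return the completed configuration list.
#' @export
validateRunConfig <- function(config = list()) {
  if (is.character(config) && length(config) == 1L)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  unknown <- setdiff(names(config), names(.CONFIG_DEFAULTS))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  out <- utils::modifyList(.CONFIG_DEFAULTS, config)
  out$seed <- suppressWarnings(as.integer(out$seed))
  if (is.na(out$seed)) stop("seed must be an integer")
  if (!is.numeric(out$threshold) || out$threshold < 0)
    stop("threshold must be a non-negative number")
  badp <- setdiff(names(out$profile), slotNames("ScanProfile"))
  if (length(badp))
    stop("unknown scan profile key(s): ", paste(badp, collapse = ", "))
  out
}

.stageLog <- function(verbose, stage, ...) {
  if (verbose) message(sprintf("[%s] %s", stage, sprintf(...)))
}

#' Run the end-to-end pipeline
#'
#' Stages: synthetic-fixture generation, domain scanning, classification,
#' ligand clustering, ancestral-state reconstruction, and a human-readable
#' summary. All stage outputs are written under \code{config$outDir} along
#' with a JSON provenance manifest (configuration, seed, per-file MD5
#' checksums). Reruns with the same configuration produce byte-identical
#' outputs. The parsimony stage uses the scanned complement matrix when the
#' run covers the whole survey, and the transcribed one otherwise.
#'
#' @param config named list or JSON path; keys: \code{seed}, \code{outDir},
#'   \code{species} (NULL = all), \code{decoys}, \code{threshold},
#'   \code{cluster}, \code{ancestral}, \code{profile} (ScanProfile overrides),
#'   \code{verbose}.
#' @return (invisibly) a list with the main in-memory artifacts: records,
#'   hits, calls, complement, similarity graph, scenario, manifest path.
#' @export
runPipeline <- function(config = list()) {
  cfg <- validateRunConfig(config)
  dir.create(cfg$outDir, recursive = TRUE, showWarnings = FALSE)
  pth <- function(f) file.path(cfg$outDir, f)
  profile <- do.call(scanProfile, cfg$profile)
  v <- isTRUE(cfg$verbose)

  fx <- speciesFixtures(species = cfg$species, decoys = isTRUE(cfg$decoys))
  records <- do.call(c, unname(lapply(fx, generateSpeciesSet, seed = cfg$seed)))
  writeProteinFasta(records, pth("proteins.fasta"))
  .stageLog(v, "fixtures", "%d species, %d records", length(fx),
            length(records))

  hits <- scanDomains(records, profile)
  writeGff3(hits, pth("domain_hits.gff3"))
  .stageLog(v, "scan", "%d hits (%s)", nrow(hits),
            paste(sprintf("%s=%d", names(table(hits$kind)),
                          as.integer(table(hits$kind))), collapse = ", "))

  calls <- classifyProteins(records, profile, hits = hits)
  utils::write.table(calls, pth("component_calls.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cm <- buildComplementMatrix(
    calls, cladeOf = stats::setNames(vapply(fx, function(f) f@clade,
                                            character(1)), names(fx)))
  writeComplementTsv(cm, pth("complement_scanned.tsv"))
  utils::write.table(rejectedCalls(cm), pth("qc_rejections.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  .stageLog(v, "classify", "EGFR=%d EGF-type=%d NRG-type=%d rejected=%d",
            sum(calls$category == "EGFR"),
            sum(calls$category == "EGF_TYPE_LIGAND"),
            sum(calls$category == "NRG_TYPE_LIGAND"),
            sum(calls$category == "REJECTED"))

  graph <- NULL
  if (isTRUE(cfg$cluster)) {
    lig <- records[names(records) %in%
                     calls$record_id[calls$category %in%
                                       c("EGF_TYPE_LIGAND", "NRG_TYPE_LIGAND")]]
    if (length(lig) >= 2L) {
      graph <- clusterLigands(lig, threshold = cfg$threshold)
      utils::write.table(graphEdges(graph), pth("ligand_edges.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      memb <- componentMembership(graph)
      utils::write.table(data.frame(record = names(memb), component = memb),
                         pth("ligand_components.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      .stageLog(v, "cluster", "%d nodes, %d edges, %d components",
                length(memb), nrow(graphEdges(graph)), length(unique(memb)))
    }
  }

  scen <- NULL
  if (isTRUE(cfg$ancestral)) {
    tree <- bundledSpeciesTree()
    full <- setequal(.tipName(complementTable(cm)$species), tree$tip.label)
    source_cm <- if (full) cm else combineComplements()
    chm <- characterMatrixFromComplements(source_cm)
    scen <- scenarioReport(tree, chm)
    counts <- vapply(c("EGFR_COUNT", "EGF_TYPE_COUNT", "NRG_TYPE_COUNT"),
                     function(ch) scen$reconstructions[[ch]]@nodeCounts,
                     integer(ape::Ntip(tree) + tree$Nnode))
    nodeTab <- data.frame(node = seq_len(nrow(counts)),
                          label = vapply(seq_len(nrow(counts)), .nodeLabel,
                                         character(1), tree = tree),
                          counts)
    utils::write.table(nodeTab, pth("node_states.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(scen$events, pth("events.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    atree <- tree
    ntip <- ape::Ntip(tree)
    atree$node.label <- sprintf(
      "%s_E%d_G%d_N%d",
      vapply(ntip + seq_len(tree$Nnode), .nodeLabel, character(1),
             tree = tree),
      counts[ntip + seq_len(tree$Nnode), 1],
      counts[ntip + seq_len(tree$Nnode), 2],
      counts[ntip + seq_len(tree$Nnode), 3])
    writeNewickTree(atree, pth("annotated_tree.nwk"))
    .stageLog(v, "ancestral", "root complement: EGFR=%d EGF=%d NRG=%d",
              scen$rootComplement$egfr_count[1],
              scen$rootComplement$egf_type_count[1],
              scen$rootComplement$nrg_type_count[1])
  }

  summaryLines <- c(
    sprintf("EGFR pathway complement run (seed %d)", cfg$seed),
    sprintf("species: %d, records: %d", length(fx), length(records)),
    sprintf("calls: EGFR=%d, EGF-type=%d, NRG-type=%d, rejected=%d",
            sum(calls$category == "EGFR"),
            sum(calls$category == "EGF_TYPE_LIGAND"),
            sum(calls$category == "NRG_TYPE_LIGAND"),
            sum(calls$category == "REJECTED")),
    if (!is.null(scen))
      sprintf("root complement (metazoan / bilaterian): EGFR %d/%d, EGF-type %d/%d, NRG-type %d/%d",
              scen$rootComplement$egfr_count[1],
              scen$rootComplement$egfr_count[2],
              scen$rootComplement$egf_type_count[1],
              scen$rootComplement$egf_type_count[2],
              scen$rootComplement$nrg_type_count[1],
              scen$rootComplement$nrg_type_count[2]))
  writeLines(summaryLines, pth("summary.txt"))

  outFiles <- setdiff(list.files(cfg$outDir), "manifest.json")
  manifest <- list(
    config = cfg[setdiff(names(cfg), "outDir")],
    files = as.list(unname(tools::md5sum(file.path(cfg$outDir, outFiles)))))
  names(manifest$files) <- outFiles
  jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, null = "null")
  invisible(list(records = records, hits = hits, calls = calls,
                 complement = cm, graph = graph, scenario = scen,
                 manifest = pth("manifest.json")))
}
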