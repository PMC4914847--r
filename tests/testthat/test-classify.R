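hit <- function(kind, start, end, ...) {
  EGFRcomplement:::.hitRow(kind, start, end, 1, ...)
}
tkHit <- function(start = 100L, active = TRUE) {
  hit("TK", start, start + 237L, gly = TRUE, vaik = active, hrd = TRUE,
      dfg = TRUE)
}

test_that("classifyRecord applies the decision rules in order", {
  # rule 1: TK + TM + Cys-rich N-terminal of the first TM -> EGFR
  egfr <- rbind(hit("SIGNAL", 1, 13), hit("CYS_RICH", 20, 45),
                hit("TM", 60, 80), tkHit(100))
  r <- classifyRecord("r1", egfr)
  expect_identical(r$category, "EGFR")
  expect_identical(r$tk_status, "ACTIVE")
  expect_identical(r$cys_rich_count, 1L)
  expect_identical(r$rejection_reason, "")

  # inactive kinase stays an EGFR but is flagged
  r2 <- classifyRecord("r2", rbind(hit("CYS_RICH", 20, 45), hit("TM", 60, 80),
                                   tkHit(100, active = FALSE)))
  expect_identical(r2$category, "EGFR")
  expect_identical(r2$tk_status, "INACTIVE")

  # a single Cys-rich cluster suffices
  one <- rbind(hit("CYS_RICH", 5, 50), hit("TM", 60, 80), tkHit(100))
  expect_identical(classifyRecord("r3", one)$category, "EGFR")

  # rule 2: kinase without an ectodomain is rejected
  expect_identical(classifyRecord("r4", tkHit(10))$rejection_reason,
                   "TK_WITHOUT_ECTODOMAIN")
  # Cys-rich cluster C-terminal of the TM does not count as an ectodomain
  inverted <- rbind(hit("TM", 10, 30), hit("CYS_RICH", 40, 70), tkHit(100))
  expect_identical(classifyRecord("r5", inverted)$rejection_reason,
                   "TK_WITHOUT_ECTODOMAIN")

  # rule 3: one EGF motif, full length, <= 2 TM -> ligand
  lig <- rbind(hit("SIGNAL", 1, 13), hit("EGF_MOTIF", 30, 60))
  expect_identical(classifyRecord("r6", lig)$category, "EGF_TYPE_LIGAND")
  lig2 <- rbind(lig, hit("TM", 80, 100), hit("TM", 110, 130))
  expect_identical(classifyRecord("r7", lig2)$category, "EGF_TYPE_LIGAND")
  nrg <- rbind(lig, hit("IG_ISET", 70, 159), hit("TM", 170, 190))
  expect_identical(classifyRecord("r8", nrg)$category, "NRG_TYPE_LIGAND")
  # an Ig I-set without a TM stays EGF-type
  soluble <- rbind(lig, hit("IG_ISET", 70, 159))
  expect_identical(classifyRecord("r9", soluble)$category, "EGF_TYPE_LIGAND")

  # rule 4: rejection reasons
  expect_identical(classifyRecord("r10", lig[1, , drop = FALSE]
                                  )$rejection_reason, "NO_EGF_MOTIF")
  multi <- rbind(lig, hit("EGF_MOTIF", 80, 110))
  expect_identical(classifyRecord("r11", multi)$rejection_reason,
                   "MULTIPLE_EGF_MOTIFS")
  expect_identical(classifyRecord("r12", lig, isFullLength = FALSE
                                  )$rejection_reason, "NOT_FULL_LENGTH")
  tm3 <- rbind(lig, hit("TM", 80, 100), hit("TM", 110, 130),
               hit("TM", 140, 160))
  expect_identical(classifyRecord("r13", tm3)$rejection_reason,
                   "INCOHERENT_ARCHITECTURE")
})

test_that("classifyRecord rejects out-of-range hit coordinates", {
  expect_error(classifyRecord("r", hit("TM", 10, 300), seqLength = 100),
               "out of range")
})

test_that("classifyProteins reproduces a species complement end to end", {
  fx <- speciesFixtures("S. mediterranea")[[1]]
  records <- generateSpeciesSet(fx, seed = 1)
  calls <- classifyProteins(records)
  expect_identical(nrow(calls), length(records))
  expect_identical(sum(calls$category == "EGFR"), 6L)
  expect_identical(sum(calls$category == "EGFR" &
                         calls$tk_status == "INACTIVE"), 1L)
  expect_identical(sum(calls$category == "EGF_TYPE_LIGAND"), 8L)
  expect_identical(sum(calls$category == "NRG_TYPE_LIGAND"), 1L)
  expect_identical(sum(calls$category == "REJECTED"), 3L)
})

test_that("buildComplementMatrix aggregates calls per species", {
  fx <- speciesFixtures("C. elegans")
  records <- generateSpeciesSet(fx[[1]], seed = 2)
  calls <- classifyProteins(records)
  cm <- buildComplementMatrix(
    calls, cladeOf = c("C. elegans" = "Nematoda"))
  tab <- complementTable(cm)
  expect_identical(provenance(cm), "SCANNED")
  expect_identical(tab$species, "C. elegans")
  expect_identical(tab$clade, "Nematoda")
  expect_identical(tab$egfr_count, 1L)
  expect_identical(tab$egf_like_count, 1L)
  expect_identical(tab$nrg_like_count, 0L)
  qc <- rejectedCalls(cm)
  expect_identical(nrow(qc), 3L)
  expect_setequal(qc$rejection_reason,
                  c("MULTIPLE_EGF_MOTIFS", "NOT_FULL_LENGTH",
                    "TK_WITHOUT_ECTODOMAIN"))
  # unmapped record ids are an error
  expect_error(buildComplementMatrix(calls, speciesOf = c(bogus = "X")),
               "unmapped record")
})
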