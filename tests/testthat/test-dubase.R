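# Queryable substrate store

test_that("the published substrate table loads with the expected worked examples", {
  st <- dubase_store_from_table1()
  expect_equal(nrow(st$evidence), 56L)
  expect_equal(nrow(query_by_dub(st, "USP7")), 6L)
  expect_equal(nrow(query_by_dub(st, "USP11")), 3L)
  q11 <- query_by_dub(st, "USP11")
  expect_equal(q11$gene_name[1], "RPS2")
  rnf2 <- query_by_substrate(st, "RNF2")
  expect_setequal(rnf2$dub_name, c("USP7", "USP42"))
  pcna <- query_by_substrate(st, "PCNA")
  expect_equal(pcna$dub_name, "USP1")
  # raising the fold-change threshold leaves only the strongest USP7 hit
  q7 <- query_by_dub(st, "USP7", default_thresholds(min_abs_log2_fc = 2))
  expect_equal(q7$gene_name, "TTK")
  # case-insensitive matching, unknown names empty with a notice
  expect_equal(nrow(query_by_dub(st, "usp7")), 6L)
  unk <- query_by_dub(st, "USP99")
  expect_equal(nrow(unk), 0L)
  expect_match(attr(unk, "notice"), "no records")
  expect_equal(nrow(query_by_substrate(st, "NOSUCHGENE")), 0L)
})

test_that("ingest stores everything unfiltered and rejects duplicates", {
  st <- dubase_store()
  recs <- data.frame(dub_name = "USP7", gene_name = c("A", "B"),
                     description = "", log2_fc = c(0.1, -3),
                     stringsAsFactors = FALSE)
  st <- dubase_ingest(st, recs, "exp1")
  expect_equal(nrow(st$evidence), 2L)            # sub-threshold rows kept
  expect_equal(nrow(query_by_dub(st, "USP7")), 0L)
  expect_error(dubase_ingest(st, recs, "exp1"), "already ingested")
  dup <- data.frame(dub_name = "USP7", gene_name = c("C", "C"),
                    description = "", log2_fc = c(1, 2),
                    stringsAsFactors = FALSE)
  expect_error(dubase_ingest(st, dup, "exp2"), "USP7 C")
  # empty ingest leaves an empty evidence table
  st0 <- dubase_ingest(dubase_store(), recs[0, ], "empty")
  expect_equal(nrow(st0$evidence), 0L)
})

test_that("session thresholds persist until changed and reset to defaults", {
  st <- dubase_store_from_table1()
  st <- set_thresholds(st, default_thresholds(min_abs_log2_fc = 2))
  expect_equal(nrow(query_by_dub(st, "USP7")), 1L)
  expect_equal(nrow(query_by_dub(st, "USP9X")), 8L)
  st <- reset_thresholds(st)
  expect_equal(nrow(query_by_dub(st, "USP7")), 6L)
  # direction = down lists reduced-ubiquitination records
  down <- data.frame(dub_name = "USP7", gene_name = "LOST",
                     description = "", log2_fc = -2.5,
                     stringsAsFactors = FALSE)
  st <- dubase_ingest(st, down, "down_exp")
  st <- set_thresholds(st, default_thresholds(direction = "down"))
  expect_equal(query_by_dub(st, "USP7")$gene_name, "LOST")
})

test_that("DUB and substrate queries are bidirectionally consistent", {
  st <- dubase_store_from_table1()
  for (thr in list(default_thresholds(),
                   default_thresholds(min_abs_log2_fc = 1.5),
                   default_thresholds(min_abs_log2_fc = 2.5))) {
    for (dub in unique(st$evidence$dub_name)) {
      hits <- query_by_dub(st, dub, thr)$gene_name
      for (g in hits) {
        expect_true(dub %in% query_by_substrate(st, g, thr)$dub_name)
      }
    }
    # and queries shrink monotonically as thresholds tighten
  }
  loose <- query_by_dub(st, "USP42", default_thresholds())
  tight <- query_by_dub(st, "USP42", default_thresholds(min_abs_log2_fc = 2))
  expect_true(all(tight$gene_name %in% loose$gene_name))
  expect_lte(nrow(tight), nrow(loose))
})

test_that("fixture records lacking p-values pass those filters with a notice", {
  st <- dubase_store_from_table1()
  q <- query_by_dub(st, "USP1")
  expect_true(all(is.na(q$p_value)))
  expect_match(paste(attr(q, "notice"), collapse = " "), "vacuously")
  # but a strict p filter still applies to records that do carry p-values
  recs <- data.frame(dub_name = "USP3", gene_name = c("A", "B"),
                     description = "", log2_fc = c(2, 2),
                     p_value = c(0.2, 0.001), stringsAsFactors = FALSE)
  st <- dubase_ingest(st, recs, "exp_p")
  expect_equal(query_by_dub(st, "USP3")$gene_name, "B")
})

test_that("volcano includes sub-threshold records and export round-trips", {
  syn <- generate_synthetic(synthetic_config(n_proteins = 100L,
                                             n_substrates = 6L, n_down = 2L,
                                             seed = 51L))
  res <- quiet_pipeline(syn$protein_groups, seed = 51L)
  v <- volcano_for_dub(res$store, "USP9X")
  expect_equal(nrow(v), nrow(res$differential))  # one point per tested protein
  expect_true(any(!v$passes_thresholds))
  # CSV export of a query result re-imports losslessly
  q <- query_by_dub(res$store, "USP9X")
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_results_csv(q, tmp)
  back <- read.csv(tmp, stringsAsFactors = FALSE)
  expect_equal(back$gene_name, q$gene_name)
  expect_identical(back$log2_fc, q$log2_fc)
  expect_identical(back$p_value, q$p_value)
  # empty query exports a header-only file
  write_results_csv(query_by_dub(res$store, "USP99"), tmp)
  expect_length(readLines(tmp), 1L)
})
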