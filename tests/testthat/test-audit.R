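# Record assembly, curation filters, subset classification, CSV I/O.

make_record <- function(entry_id = "0001", year = 2010, resolution = 2,
                        aniso = 30, ratio = 0.4) {
  r <- anisoaudit:::.empty_records(1)
  r$entry_id <- entry_id; r$year <- as.integer(year)
  r$resolution <- resolution; r$aniso_b_amp <- aniso
  r$contacts_ratio <- ratio
  r
}

test_that("header solvent content takes precedence over the computed value", {
  hdr <- parse_pdb_header(gen_header(entry_id = "1AAA", year = 2010,
                                     resolution = 2,
                                     cell = unit_cell(40, 40, 40),
                                     solvent_content = 55))
  pk <- list(matthews = 2.6, solvent_pct = 52, n_contacts = 10L,
             n_atoms_total = 100L, contacts_ratio = 0.1, asu_mass = 9000)
  class(pk) <- "packing_result"
  rec <- build_record(hdr, packing = pk)
  expect_equal(rec$solvent_pct, 55)
  hdr2 <- parse_pdb_header(gen_header(entry_id = "1AAB", year = 2010,
                                      resolution = 2))
  rec2 <- build_record(hdr2, packing = pk)
  expect_equal(rec2$solvent_pct, 52)
  # no aniso result: metric fields absent, record still built
  expect_true(is.na(rec2$aniso_b_amp))
  expect_true(is.na(rec2$wilson_b_int))
})

test_that("curation applies the four rules with the documented boundaries", {
  recs <- rbind(
    make_record("0001", year = 2004),                      # year
    make_record("0002", year = 2005),                      # year boundary: out
    make_record("0003", year = 2006),                      # year boundary: in
    make_record("0004", resolution = 5.0),                 # res boundary: in
    make_record("0005", resolution = 5.01),                # resolution
    make_record("0006", aniso = 150.0),                    # aniso boundary: in
    make_record("0007", aniso = 150.1),                    # aniso_b
    make_record("0008", ratio = 1.0),                      # ratio boundary: in
    make_record("0009", ratio = 1.01),                     # contacts_ratio
    make_record("0010", aniso = NA_real_, ratio = NA_real_))  # missing: kept
  out <- curate(recs)
  expect_setequal(out$kept$entry_id,
                  c("0003", "0004", "0006", "0008", "0010"))
  reasons <- setNames(out$dropped$drop_reason, out$dropped$entry_id)
  expect_equal(reasons[["0001"]], "year")
  expect_equal(reasons[["0002"]], "year")
  expect_equal(reasons[["0005"]], "resolution")
  expect_equal(reasons[["0007"]], "aniso_b")
  expect_equal(reasons[["0009"]], "contacts_ratio")
})

test_that("a record failing several rules reports the first failing one", {
  rec <- make_record("0001", year = 2000, resolution = 8, aniso = 200)
  out <- curate(rec)
  expect_equal(out$dropped$drop_reason, "year")
})

test_that("curation is idempotent, order-independent and partitioning", {
  pop <- gen_audit_population(400, seed = 3)
  out <- curate(pop)
  expect_equal(nrow(out$kept) + nrow(out$dropped), nrow(pop))
  expect_length(intersect(out$kept$entry_id, out$dropped$entry_id), 0)
  again <- curate(out$kept)
  expect_equal(again$kept, out$kept)
  expect_equal(nrow(again$dropped), 0)
  shuf <- pop[sample(nrow(pop)), ]
  out2 <- curate(shuf)
  expect_setequal(out2$kept$entry_id, out$kept$entry_id)
})

test_that("curation recovers planted ground truth per rule", {
  pop <- gen_audit_population(1000, violation_fractions =
                                c(year = 0.1, resolution = 0.08,
                                  aniso_b = 0.12, contacts_ratio = 0.05),
                              seed = 17)
  out <- curate(pop)
  expect_setequal(out$kept$entry_id,
                  pop$entry_id[pop$planted_verdict == "kept"])
  got <- table(out$dropped$drop_reason)
  planted <- table(pop$planted_reason[pop$planted_reason != "none"])
  expect_equal(as.vector(got[names(planted)]), as.vector(planted))
})

test_that("subset classification follows the annotation vocabularies", {
  annot_path <- write_annot_fixture(tempfile(fileext = ".tsv"))
  annot <- read_annotation(annot_path)
  rec <- make_record("MEM1")
  expect_setequal(classify_subsets(rec, annot),
                  c("membrane", "beta_barrel", "detergent", "transporter",
                    "embedded"))
  # unannotated entries default to soluble
  expect_equal(classify_subsets(make_record("XXXX"), annot), "soluble")
  expect_equal(classify_subsets(make_record("XXXX"), NULL), "soluble")
  # membrane sub-labels only ever ride with the membrane label
  for (id in annot$entry_id) {
    lab <- classify_subsets(make_record(id), annot)
    expect_true("membrane" %in% lab)
    expect_false("soluble" %in% lab)
  }
})

test_that("LCP is inferred from keywords/het ids when crystallization unknown", {
  annot_path <- write_annot_fixture(tempfile(fileext = ".tsv"))
  annot <- read_annotation(annot_path)
  rec <- make_record("MEM2")                 # crystallization: unknown
  rec$het_ids <- "OLC"
  expect_true("lcp" %in% classify_subsets(rec, annot))
  rec2 <- make_record("MEM2")
  rec2$keywords <- "LIPIDIC CUBIC PHASE;TRANSPORT"
  expect_true("lcp" %in% classify_subsets(rec2, annot))
  rec3 <- make_record("MEM2")                # no marker -> no lcp label
  expect_false("lcp" %in% classify_subsets(rec3, annot))
  # known crystallization is never overridden by keywords
  rec4 <- make_record("MEM1")
  rec4$het_ids <- "OLC"
  expect_false("lcp" %in% classify_subsets(rec4, annot))
})

test_that("contradictory annotation raises a validation error", {
  annot <- data.frame(entry_id = "BAD1", is_membrane = FALSE,
                      fold = "beta_barrel", crystallization = "unknown",
                      fn = NA_character_, topology = NA_character_)
  expect_error(classify_subsets(make_record("BAD1"), annot), "contradictory")
})

test_that("annotation tables with bad vocabulary are rejected", {
  path <- tempfile(fileext = ".tsv")
  tab <- data.frame(entry_id = "A", is_membrane = TRUE, fold = "spiral",
                    crystallization = "detergent", check.names = FALSE)
  tab[["function"]] <- "channel"; tab$topology <- "unknown"
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_annotation(path), "vocabulary")
})

test_that("the audit table round-trips through CSV with absences preserved", {
  recs <- rbind(make_record("0002"), make_record("0001"),
                make_record("0003", aniso = NA_real_))
  recs$subset_labels <- c("soluble", "membrane;lcp", "soluble")
  path <- tempfile(fileext = ".csv")
  write_audit_table(recs, path)
  lines <- readLines(path)
  expect_length(lines, 4)  # header + 3 rows
  back <- read_audit_table(path)
  expect_equal(back$entry_id, c("0001", "0002", "0003"))  # sorted
  expect_true(is.na(back$aniso_b_amp[back$entry_id == "0003"]))
  # absence serialized as an empty field, never 0
  row3 <- grep("0003", lines, value = TRUE)
  expect_true(grepl(",,", row3, fixed = TRUE))
  sorted <- recs[order(recs$entry_id), ]
  for (col in names(anisoaudit:::.audit_schema)) {
    expect_equal(back[[col]], sorted[[col]], ignore_attr = TRUE,
                 tolerance = 1e-9, label = col)
  }
})
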