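test_that("the bundled registry loads with the expected shape", {
  reg <- load_registry()
  expect_s3_class(reg, "hv_registry")
  expect_gte(nrow(reg), 40)
  expect_named(reg, c("old_name", "organism_scope", "unified_name",
                      "descriptors", "case_sensitive", "note"))
  expect_type(reg$case_sensitive, "logical")
  # every unified name strict-parses (checked again here on the loaded copy)
  for (u in unique(reg$unified_name)) {
    expect_silent(parse_histone_name(u, "strict"))
  }
})

test_that("malformed registries are rejected with a line number", {
  dir <- withr::local_tempdir()
  hdr <- "old_name\torganism_scope\tunified_name\tdescriptors\tcase_sensitive\tnote"

  f1 <- file.path(dir, "bad_unified.tsv")
  writeLines(c(hdr, "Foo\t\tNotAHistone\t\t0\t"), f1)
  expect_error(load_registry(f1), regexp = "line 2")

  f2 <- file.path(dir, "dup.tsv")
  writeLines(c(hdr, "Foo\tx\tH2A.Z\t\t0\t", "foo\tX\tH2A.Z\t\t0\t"), f2)
  expect_error(load_registry(f2), regexp = "duplicate")

  f3 <- file.path(dir, "fields.tsv")
  writeLines(c(hdr, "Foo\tx\tH2A.Z\t\t0\textra\ttoomuch"), f3)
  expect_error(load_registry(f3), regexp = "line 2")

  f4 <- file.path(dir, "flag.tsv")
  writeLines(c(hdr, "Foo\tx\tH2A.Z\t\t2\t"), f4)
  expect_error(load_registry(f4), regexp = "case_sensitive")
})

test_that("user overrides shadow bundled records", {
  dir <- withr::local_tempdir()
  hdr <- "old_name\torganism_scope\tunified_name\tdescriptors\tcase_sensitive\tnote"
  ov <- file.path(dir, "override.tsv")
  writeLines(c(hdr, "H5\tbirds\tH1.9\t\t0\tlocal disagreement"), ov)
  reg <- load_registry(overrides = ov)
  expect_equal(unified_of(normalize_name("H5", "birds", reg)), "H1.9")
  expect_equal(nrow(reg), nrow(load_registry()))
})

test_that("historical names normalize to unified names", {
  expect_equal(unified_of(normalize_name("H5", "birds")), "H1.0")
  expect_equal(unified_of(normalize_name("H2BFWT")), "H2B.W")
  res <- normalize_name("TH2B")
  expect_equal(unified_of(res), "H2B.1")
  expect_equal(res$recommended_descriptors, "TS")
  # already-canonical input passes through with no matched record
  res <- normalize_name("H2A.Z")
  expect_equal(unified_of(res), "H2A.Z")
  expect_null(res$matched_record)
  expect_error(normalize_name("XYZZY"), class = "hv_unresolvable")
})

test_that("homographs resolve by organism and are ambiguous without one", {
  res <- normalize_name("H2Bv")
  expect_null(res$unified)
  expect_gte(nrow(res$ambiguous_candidates), 2)
  expect_setequal(res$ambiguous_candidates$unified_name, c("H2B.Z", "H2B.V"))

  expect_equal(unified_of(normalize_name("H2Bv", "apicomplexans")), "H2B.Z")
  expect_equal(unified_of(normalize_name("H2BV", "trypanosomes")), "H2B.V")
  # scheme homographs for H1 letters
  expect_equal(unified_of(normalize_name("H1a", "human")), "H1.5")
  expect_equal(unified_of(normalize_name("H1a", "mouse")), "H1.1")
  expect_null(normalize_name("H1a")$unified)
})

test_that("normalization is idempotent", {
  reg <- default_registry()
  for (k in seq_len(nrow(reg))) {
    org <- reg$organism_scope[k]
    res <- normalize_name(reg$old_name[k],
                          if (nzchar(org)) org else NULL, reg)
    expect_false(is.null(res$unified), info = reg$old_name[k])
    again <- normalize_name(format_histone_name(res$unified), NULL, reg)
    expect_true(same_variant(again$unified, reg$unified_name[k]),
                info = reg$old_name[k])
    expect_null(again$matched_record)
  }
})

test_that("synonym listing and normalization are mutually consistent", {
  syn <- synonyms_of("H2A.Z")
  expect_true(all(c("D2", "Htz1p", "hv1", "H2Av", "H2AvD") %in% syn))
  expect_true(all(c("CENP-A", "Cse4p") %in% synonyms_of("cenH3")))
  expect_length(synonyms_of("H2B.9"), 0)

  for (s in synonyms_of("H2A.Z")) {
    res <- normalize_name(s)
    if (is.null(res$unified)) {
      expect_true("H2A.Z" %in% res$ambiguous_candidates$unified_name)
    } else {
      expect_true(same_variant(res$unified, "H2A.Z"))
    }
  }
})

test_that("search queries cover the canonical name, wildcard and synonyms", {
  q <- build_search_query("H2A.Z")
  expect_match(q, "\"H2A.Z\\*\"")
  for (s in c("D2", "Htz1p", "hv1", "H2Av", "H2AvD", "H2Az")) {
    expect_match(q, s, fixed = TRUE)
  }
  q0 <- build_search_query("H1.0")
  expect_match(q0, "H5", fixed = TRUE)
  expect_match(q0, "H1\u00b0", fixed = TRUE)
  # no synonyms: exactly the two terms
  expect_equal(build_search_query("H2B.9"), "\"H2B.9\" OR \"H2B.9*\"")
})

test_that("series expansion renames every member of the range", {
  tab <- expand_series("H3v1", "H3v10")
  expect_equal(nrow(tab), 10)
  expect_equal(tab$unified_name, paste0("H3.", 1:10))
  tab <- expand_series("H2Asq.1", "H2Asq.3")
  expect_equal(tab$unified_name, paste0("H2A.Q.", 1:3))
  tab <- expand_series("H3v2", "H3v2")
  expect_equal(nrow(tab), 1)
  expect_error(expand_series("H3v2", "H3v1"), class = "hv_series_error")
  expect_error(expand_series("H3v1", "H4w2"), class = "hv_series_error")
  expect_error(expand_series("Qux1", "Qux3"), class = "hv_series_error")
})

test_that("paralog-number suggestions take the smallest free integer", {
  expect_equal(format_histone_name(
    suggest_paralog_number("H2A", c("H2A.1", "H2A.2"))), "H2A.3")
  expect_equal(format_histone_name(
    suggest_paralog_number("H2A", c("H2A.1", "H2A.3"))), "H2A.2")
  expect_equal(format_histone_name(
    suggest_paralog_number("H2A", c("H2A.Z.1", "H2A.Z.2"), parent = "H2A.Z")),
    "H2A.Z.3")
  expect_equal(format_histone_name(suggest_paralog_number("H2B")), "H2B.1")
  # names outside the family or level are ignored
  expect_equal(format_histone_name(
    suggest_paralog_number("H2A", c("H2A.1", "H2B.2", "macroH2A.2", "H2A.Z.2"))),
    "H2A.2")
})

test_that("batch normalization reports per-name status", {
  tab <- normalize_table(c("H5", "H2A.Z", "H2Bv", "???"),
                         organisms = c("birds", NA, NA, NA))
  expect_equal(tab$unified, c("H1.0", "H2A.Z", NA, NA))
  expect_equal(tab$status, c("renamed", "canonical", "ambiguous", "unresolvable"))
})
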