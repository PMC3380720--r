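test_that("structured parts come out of canonical and historical forms", {
  p <- parse_histone_name("H2A.Z.1")
  expect_equal(p$family, "H2A")
  expect_equal(vapply(p$suffix_path, `[[`, "", "kind"),
               c("clade_letter", "paralog_number"))
  expect_equal(p$suffix_path[[1]]$value, "Z")
  expect_equal(p$suffix_path[[2]]$value, 1L)

  p <- parse_histone_name("macroH2A.1.s1")
  expect_equal(p$prefix, "macro")
  expect_equal(p$family, "H2A")
  expect_equal(vapply(p$suffix_path, `[[`, "", "kind"),
               c("paralog_number", "splice_number"))
  expect_equal(p$suffix_path[[2]]$value, 1L)

  p <- parse_histone_name("TS H3.4")
  expect_equal(p$descriptors, "TS")
  expect_equal(p$family, "H3")
  expect_equal(p$suffix_path[[1]]$value, 4L)

  p <- parse_histone_name("H3")
  expect_equal(p$family, "H3")
  expect_length(p$suffix_path, 0)
  expect_length(p$descriptors, 0)
})

test_that("the Brno modification suffix splits off the label chain", {
  p <- parse_histone_name("H2A.ZS138ph")
  expect_equal(vapply(p$suffix_path, `[[`, "", "value"), "Z")
  expect_equal(p$modifications$residue, "S")
  expect_equal(p$modifications$position, 138L)
  expect_equal(p$modifications$type, "ph")

  p <- parse_histone_name("H3K27me3")
  expect_length(p$suffix_path, 0)
  expect_equal(p$modifications$position, 27L)
  expect_equal(p$modifications$type, "me")
  expect_equal(p$modifications$multiplicity, 3L)

  p <- parse_histone_name("H2A.Z2K4acK11ac", mode = "lenient")
  expect_equal(vapply(p$suffix_path, function(l) as.character(l$value), ""),
               c("Z", "2"))
  expect_equal(p$modifications$position, c(4L, 11L))
  expect_equal(p$modifications$type, c("ac", "ac"))
  expect_true("missing_period" %in% attr(p, "findings")$rule)
})

test_that("gamma marker and parenthesized descriptors are detached from identity", {
  p <- parse_histone_name("\u03b3H2A.X")
  expect_true(p$gamma)
  expect_equal(p$suffix_path[[1]]$value, "X")

  p <- parse_histone_name("(TS) H3.4")
  expect_equal(p$descriptors, "TS")

  p <- parse_histone_name("gammaH2A.X", mode = "lenient")
  expect_true(p$gamma)
})

test_that("case is not significant for grammar-parsable names", {
  for (s in c("H2A.Z.1", "MACROH2A.1.S2", "TS H3.4", "cenH3", "H1.0")) {
    a <- parse_histone_name(s, "lenient")
    b <- parse_histone_name(tolower(s), "lenient")
    expect_true(same_variant(a, b), info = s)
  }
})

test_that("strict mode rejects grammar violations with named rules", {
  expect_error(parse_histone_name("Htz1p"), class = "hv_parse_error")
  expect_error(parse_histone_name("  "), class = "hv_parse_error")
  expect_error(parse_histone_name("H2A.1.Z"),
               regexp = "clade letter may not follow", class = "hv_parse_error")
  expect_error(parse_histone_name("H2A.s1.2"),
               regexp = "terminal", class = "hv_parse_error")
  expect_error(parse_histone_name("H2A.s1.s2"), class = "hv_parse_error")
  expect_error(parse_histone_name("H2A.Bbd"), class = "hv_parse_error")
  expect_error(parse_histone_name("H2A.Z-1"), class = "hv_parse_error")
  expect_error(parse_histone_name("H3.03"), class = "hv_parse_error")
  # the parse error names the offending token
  err <- tryCatch(parse_histone_name("CENP-A"), error = function(e) e)
  expect_match(conditionMessage(err), "CENP-A", fixed = TRUE)
})

test_that("lenient mode accepts superseded styles with warnings attached", {
  p <- parse_histone_name("H2A.Z-1", mode = "lenient")
  expect_equal(format_histone_name(p), "H2A.Z.1")
  expect_true("dash_separator" %in% attr(p, "findings")$rule)

  p <- parse_histone_name("H2A.Bbd", mode = "lenient")
  expect_equal(p$suffix_path[[1]]$value, "Bbd")
  expect_true("multi_letter_clade" %in% attr(p, "findings")$rule)

  p <- parse_histone_name("H1\u00b0", mode = "lenient")
  expect_equal(format_histone_name(p), "H1.0")
  expect_true("legacy_glyph" %in% attr(p, "findings")$rule)
})

test_that("paralog zero is legal everywhere but flagged outside H1", {
  expect_equal(format_histone_name(parse_histone_name("H1.0")), "H1.0")
  expect_length(attr(parse_histone_name("H1.0"), "findings")$rule, 0)
  p <- parse_histone_name("H2A.0")
  expect_true("paralog_zero" %in% attr(p, "findings")$rule)
})

test_that("unknown modification types warn instead of failing", {
  p <- parse_histone_name("H3K9cr")
  expect_equal(p$modifications$type, "cr")
  expect_true("unknown_mod_type" %in% attr(p, "findings")$rule)
  withr::with_options(list(histvar.mod_types = "cr"), {
    p2 <- parse_histone_name("H3K9cr")
    expect_false("unknown_mod_type" %in% attr(p2, "findings")$rule)
  })
})

test_that("json rendering exposes stable field names", {
  j <- jsonlite::fromJSON(histone_name_json("H2A.ZS138ph"),
                          simplifyVector = FALSE)
  expect_named(j, c("family", "prefix", "suffix_path", "descriptors",
                    "modifications", "gamma"))
  expect_equal(j$suffix_path[[1]]$value, "Z")
  expect_equal(j$modifications[[1]]$position, 138L)
})
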