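test_that("terminal motif calls reproduce the diagnostic fragments", {
  # canonical SQ(E/D)-hydrophobic terminus
  m <- detect_h2ax_motif("PNIQAVLLPKKSATVGPKAPSGGKKATQASQEY")
  expect_equal(m$status, "canonical")
  expect_equal(m$matched_window, "SQEY")
  # noncanonical SQ-x-hydrophobic terminus
  m <- detect_h2ax_motif("PTPQQSTGEKKKKPSKKAAEGSSQIY")
  expect_equal(m$status, "noncanonical")
  expect_equal(m$matched_window, "SQIY")
  # no motif at the terminus
  m <- detect_h2ax_motif("PNIHAILLPKKSGPTK")
  expect_equal(m$status, "absent")
  expect_true(is.na(m$matched_window))
  # the motif is only read at the C-terminus, never internally
  expect_equal(detect_h2ax_motif("SQEYAAAA")$status, "absent")
  expect_error(detect_h2ax_motif("SQE"), class = "hv_seq_error")
})

test_that("every bundled H2A row yields its printed motif status", {
  rows <- h2a_diagnostic_rows()
  is_x <- startsWith(gsub("\\?$", "", rows$variant_label), "H2A.X")
  for (k in seq_len(nrow(rows))) {
    status <- detect_h2ax_motif(rows$cterm_fragment[k])$status
    want <- if (!is_x[k]) "absent" else if (rows$uncertain[k]) "noncanonical"
            else "canonical"
    expect_equal(status, want,
                 info = paste(rows$organism[k], rows$variant_label[k]))
  }
})

test_that("the hydrophobic set is configurable", {
  expect_equal(detect_h2ax_motif("AAAASQEA")$status, "absent")
  expect_equal(detect_h2ax_motif("AAAASQEA", phi = c("A", phi_set()))$status,
               "canonical")
})

test_that("H3 site classification is lookup-first over the bundled table", {
  expect_equal(classify_h3_site("S", "AAIG")$class, "RI_like")
  expect_equal(classify_h3_site("S", "AAIG")$organism, "Homo")
  expect_equal(classify_h3_site("A", "SAVM")$class, "RC_like")
  expect_equal(classify_h3_site("STQP", "AAIQ")$class, "uncertain")
  # each bundled row maps back to its own class
  tab <- h3_diagnostic_rows()
  for (k in seq_len(nrow(tab))) {
    call <- classify_h3_site(tab$residue31[k], tab$window_85_89[k])
    expect_equal(call$class, tab$class[k],
                 info = paste(tab$organism[k], tab$variant_label[k]))
    expect_equal(call$confidence, "exact")
    if (tab$uncertain[k]) expect_equal(call$class, "uncertain")
  }
})

test_that("unmatched H3 sites fall back to a flagged heuristic or unknown", {
  call <- classify_h3_site("S", "QQQQ")
  expect_equal(call$class, "RI_like")
  expect_equal(call$confidence, "low")
  # residue 31 not phosphorylatable: no guess
  call <- classify_h3_site("G", "QQQQ")
  expect_equal(call$class, "unknown")
  expect_equal(call$confidence, "none")
  # window identical to an RC row blocks the heuristic
  call <- classify_h3_site("T", "SAVM")
  expect_equal(call$class, "unknown")
})

test_that("family assignment picks the best-scoring reference deterministically", {
  panel <- reference_panel(seed = 42)
  # a panel sequence is its own best match
  for (k in seq_len(nrow(panel))) {
    expect_equal(assign_family(panel$sequence[k], panel)$family,
                 panel$family[k])
  }
  # two substitutions leave the family call unchanged; verify by brute force
  q <- panel$sequence[panel$family == "H3"]
  substr(q, 5, 5) <- "W"; substr(q, 50, 50) <- "W"
  call <- assign_family(q, panel)
  brute <- vapply(panel$sequence, function(r) global_align(q, r)$score,
                  numeric(1))
  expect_equal(call$family, panel$family[which.max(brute)])
  expect_equal(call$family, "H3")
  expect_equal(call$scores$score, sort(unname(brute), decreasing = TRUE))
  expect_error(assign_family(q, panel[0, ]), class = "hv_panel_error")
})

test_that("family ties break toward the smallest reference id, whatever the panel order", {
  panel <- tibble::tibble(id = c("zeta", "alpha"), family = c("H2B", "H4"),
                          sequence = c("AAAA", "AAAA"))
  expect_equal(assign_family("AAAA", panel)$best_id, "alpha")
  expect_equal(assign_family("AAAA", panel)$family, "H4")
  expect_equal(assign_family("AAAA", panel[2:1, ])$family, "H4")

  panel5 <- reference_panel(seed = 9)
  shuffled <- panel5[c(4, 2, 5, 1, 3), ]
  q <- panel5$sequence[2]
  expect_equal(assign_family(q, panel5)$family, assign_family(q, shuffled)$family)
})

test_that("name proposals compose family, motif evidence and free paralog number", {
  panel <- reference_panel(seed = 42)
  base <- panel$sequence[panel$family == "H2A"]
  q <- paste0(substr(base, 1, nchar(base) - 4), "SQEL")
  prop <- propose_name(q, "human", panel = panel)
  expect_equal(prop$family, "H2A")
  expect_true(any(grepl("H2A.X-like terminal motif", prop$evidence)))
  # suggestion is family + smallest free paralog number, never a letter suffix
  expect_equal(prop$suggestion$suffix_path[[1]]$kind, "paralog_number")
  # empty registry scope: numbering starts at 1
  reg0 <- default_registry()[0, ]
  prop0 <- propose_name(q, "nowhere", registry = reg0, panel = panel)
  expect_equal(format_histone_name(prop0$suggestion), "H2A.1")
})
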