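test_that("evaluability classifies the four states in order", {
  expect_identical(evaluability(c(3, 0, 4, 11)), "evaluable")
  expect_identical(evaluability(c(1, 1, 1, 1)), "not_significant")
  expect_identical(evaluability(c(5, 0, 5, 10)), "tied_events")
  expect_identical(evaluability(c(0, 0, 1, 1)), "degenerate")
})

test_that("arm selection picks the arm with fewer events, ties flagged", {
  expect_identical(select_arm(c(3, 0, 4, 11)), "A")
  expect_identical(select_arm(c(9, 35, 8, 8)), "B")
  expect_identical(select_arm(c(2, 2, 2, 2)), "tied")
})

test_that("a toggle converts one nonevent to an event, preserving arm totals", {
  expect_identical(toggle(c(9, 35, 8, 8), "B"), as_ct(c(9, 35, 9, 7)))
  expect_identical(toggle(c(9, 1, 10, 90), "A"), as_ct(c(10, 0, 10, 90)))
  expect_error(toggle(c(3, 0, 4, 11), "A"), "no legal move")
})

test_that("counterexamples are classified with the right mechanism", {
  f1 <- fragility(c(3, 0, 4, 11))
  expect_identical(f1$status, "not_attainable")
  expect_identical(f1$mechanism, "no_legal_move")
  expect_identical(nrow(f1$trajectory), 1L)

  f2 <- fragility(c(9, 1, 10, 90))
  expect_identical(f2$status, "not_attainable")
  expect_identical(f2$mechanism, "path_exhausted")
  expect_identical(nrow(f2$trajectory), 2L) # baseline + 1 toggle
  expect_identical(unlist(f2$trajectory[2, c("a", "b", "c", "d")]),
                   c(a = 10L, b = 0L, c = 10L, d = 90L))

  f3 <- fragility(c(9, 35, 8, 8))
  expect_identical(f3$status, "not_attainable")
  expect_identical(f3$mechanism, "path_exhausted")
  expect_identical(nrow(f3$trajectory), 9L) # baseline + 8 toggles
  expect_true(all(f3$trajectory$p < 0.05))
  expect_identical(f3$trajectory$d[9], 0L) # arm B exhausted
})

test_that("attainable tables report fi with a consistent trajectory", {
  f <- fragility(c(10, 40, 25, 25))
  expect_identical(f$status, "attainable")
  expect_identical(nrow(f$trajectory), f$fi + 1L)
  expect_true(all(f$trajectory$p[seq_len(f$fi)] < f$alpha))
  expect_gte(f$trajectory$p[f$fi + 1L], f$alpha)
  # fi bounded by the selected arm's baseline nonevents
  expect_lte(f$fi, 40L)
})

test_that("non-evaluable tables carry the reason, never an error", {
  expect_identical(fragility(c(1, 1, 1, 1))$reason, "not_significant")
  expect_identical(fragility(c(5, 0, 5, 10))$reason, "tied_events")
  expect_identical(fragility(c(0, 0, 2, 2))$reason, "degenerate")
  expect_true(is.na(fragility(c(0, 0, 2, 2))$p_baseline))
})

test_that("alpha is honoured as a parameter", {
  # p = 0.0487: significant at 0.05, not at 0.01
  expect_identical(fragility(c(9, 35, 8, 8), alpha = 0.01)$reason,
                   "not_significant")
  f <- fragility(c(10, 40, 25, 25), alpha = 0.01)
  expect_identical(f$status, "attainable")
  expect_gte(f$trajectory$p[f$fi + 1L], 0.01)
})

test_that("fragility agrees with an independent path replay on all evaluable tables N <= 20", {
  skipped <- 0L
  for (n in c(8, 12, 16, 20)) {
    g <- enumerate_tables(n)
    for (i in seq_len(nrow(g))) {
      ct <- unlist(g[i, ])
      p0 <- oracle_two_sided(ct[1], ct[2], ct[3], ct[4])
      # boundary tables are covered by the exact-arbitration test below
      if (abs(p0 - 0.05) < 1e-9) { skipped <- skipped + 1L; next }
      orc <- oracle_fi(ct[1], ct[2], ct[3], ct[4])
      if (orc$status == "not_evaluable") next
      f <- fragility(ct)
      expect_identical(f$status, orc$status,
                       label = paste("status of", paste(ct, collapse = ",")))
      if (orc$status == "attainable") {
        expect_identical(f$fi, orc$fi,
                         label = paste("fi of", paste(ct, collapse = ",")))
      } else {
        expect_identical(f$mechanism, orc$mechanism,
                         label = paste("mechanism of",
                                       paste(ct, collapse = ",")))
      }
    }
  }
  expect_lte(skipped, 20L)
})

test_that("toggle paths conserve N and arm totals and move one cell per step", {
  tabs <- random_tables(400, 60, seed = 20240131)
  for (i in seq_len(nrow(tabs))) {
    ct <- unlist(tabs[i, ])
    f <- fragility(ct)
    tr <- f$trajectory
    expect_true(all(tr$a + tr$b + tr$c + tr$d == sum(ct)))
    expect_true(all(tr$a + tr$b == ct[1] + ct[2]))
    expect_true(all(tr$c + tr$d == ct[3] + ct[4]))
    if (nrow(tr) > 1L) {
      da <- diff(tr$a); dc <- diff(tr$c)
      if (f$arm == "A") {
        expect_true(all(da == 1L) && all(dc == 0L))
      } else {
        expect_true(all(dc == 1L) && all(da == 0L))
      }
    }
    if (f$status == "attainable")
      expect_lte(f$fi, if (f$arm == "A") ct[2] else ct[4])
    if (f$status == "not_attainable") {
      expect_true(f$mechanism %in% c("no_legal_move", "path_exhausted"))
      if (f$mechanism == "no_legal_move") {
        expect_identical(nrow(tr), 1L)
        expect_identical(unname(ct[if (f$arm == "A") 2L else 4L]), 0L)
      } else {
        expect_identical(tr[[if (f$arm == "A") "b" else "d"]][nrow(tr)], 0L)
        expect_true(all(tr$p < f$alpha))
      }
    }
  }
})

test_that("tables with p exactly at alpha are resolved as nonsignificant", {
  # exact two-sided p of these tables is the rational 1/20 == alpha
  for (ct in list(c(0, 1, 19, 0), c(0, 2, 19, 4), c(1, 0, 2, 57)))
    expect_identical(evaluability(ct), "not_significant",
                     label = paste(ct, collapse = ","))
})
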