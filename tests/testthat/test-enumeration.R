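test_that("N = 2 yields exactly the two nondegenerate tables, in order", {
  g <- enumerate_tables(2)
  expect_identical(nrow(g), 2L)
  expect_identical(unlist(g[1, ]), c(a = 0L, b = 1L, c = 1L, d = 0L))
  expect_identical(unlist(g[2, ]), c(a = 1L, b = 0L, c = 0L, d = 1L))
})

test_that("enumeration matches a brute-force filter over all quadruples", {
  for (n in 3:8) {
    raw <- expand.grid(c = 0:n, b = 0:n, a = 0:n)
    raw <- raw[raw$a + raw$b + raw$c <= n, ]
    raw$d <- n - raw$a - raw$b - raw$c
    ok <- with(raw, a + b > 0 & c + d > 0 & a + c > 0 & b + d > 0)
    expect_identical(nrow(enumerate_tables(n)), sum(ok),
                     label = paste("count at N =", n))
    # raw quadruple count before filtering is stars-and-bars
    expect_identical(nrow(raw), as.integer(choose(n + 3, 3)))
  }
  g <- enumerate_tables(5)
  expect_false(is.unsorted(g$a))
  expect_identical(g, g[order(g$a, g$b, g$c), ], ignore_attr = TRUE)
})

test_that("range and argument validation", {
  expect_error(enumerate_tables(1), ">= 2")
  expect_error(enumerate_tables(4.5), "integer")
  expect_error(fragility_enumeration(5, 4), "n_min")
  expect_error(fragility_enumeration(1, 4), "n_min")
})

test_that("vectorised classification agrees with per-table fragility calls", {
  e <- fragility_enumeration(13, 13)
  rec <- e$records
  expect_gt(nrow(rec), 0L)
  for (i in seq_len(nrow(rec))) {
    ct <- unlist(rec[i, c("a", "b", "c", "d")])
    f <- fragility(ct)
    expect_identical(two_sided_p(ct)$p_two_sided, rec$p_baseline[i])
    if (rec$status[i] == "tied_events") {
      expect_identical(f$reason, "tied_events")
    } else {
      expect_identical(f$status, rec$status[i],
                       label = paste("status of", paste(ct, collapse = ",")))
      if (!is.na(rec$fi[i])) expect_identical(f$fi, rec$fi[i])
      if (!is.na(rec$mechanism[i]))
        expect_identical(f$mechanism, rec$mechanism[i])
    }
    expect_identical(rec$min_cell[i], min(ct))
    expect_equal(rec$imbalance_ratio[i],
                 max(ct[1] + ct[2], ct[3] + ct[4]) /
                   min(ct[1] + ct[2], ct[3] + ct[4]))
  }
})

test_that("per-N summaries partition every table exactly once", {
  e <- fragility_enumeration(2, 16)
  s <- e$summary
  expect_identical(s$total_significant,
                   s$fi_attainable + s$fi_unattainable + s$ties_excluded)
  for (n in c(5, 10, 16)) {
    row <- s[s$n_total == n, ]
    expect_identical(row$total_tables, nrow(enumerate_tables(n)))
    nsig <- sum(e$records$n_total == n)
    expect_identical(row$total_significant, nsig)
  }
  # no unattainable cases this early
  expect_identical(sum(s$fi_unattainable), 0L)
  expect_true(all(is.na(s$unattainability_rate) |
                    s$unattainability_rate == 0))
})

test_that("summary rate follows unattainable / (attainable + unattainable)", {
  e <- fragility_enumeration(18, 18)
  s <- e$summary
  expect_equal(s$unattainability_rate,
               s$fi_unattainable / (s$fi_attainable + s$fi_unattainable))
})

test_that("tallies work on edge inputs and agree with mechanism semantics", {
  expect_identical(nrow(min_cell_tally(data.frame(status = character(),
                                                  min_cell = integer()))), 0L)
  one <- data.frame(a = 3, b = 0, c = 4, d = 11, status = "not_attainable",
                    mechanism = "no_legal_move", min_cell = 0)
  expect_identical(mechanism_tally(one),
                   c(no_legal_move = 1L, path_exhausted = 0L))
  t1 <- min_cell_tally(one)
  expect_identical(t1$count, 1L)
  expect_equal(sum(t1$percent), 100)
})

test_that("every no-legal-move table has zero nonevents in its selected arm", {
  e <- fragility_enumeration(18, 22)
  un <- e$records[e$records$status == "not_attainable", ]
  expect_gt(nrow(un), 0L)
  nlm <- un[un$mechanism == "no_legal_move", ]
  sel_ne <- ifelse(nlm$a < nlm$c, nlm$b, nlm$d)
  expect_true(all(sel_ne == 0L))
  expect_true(all(nlm$min_cell == 0L))
  pe <- un[un$mechanism == "path_exhausted", ]
  expect_true(all(ifelse(pe$a < pe$c, pe$b, pe$d) > 0L))
  m <- mechanism_tally(e)
  expect_identical(sum(m), nrow(un))
})

test_that("repeated runs produce identical results", {
  e1 <- fragility_enumeration(2, 14)
  e2 <- fragility_enumeration(2, 14)
  expect_identical(e1$summary, e2$summary)
  expect_identical(e1$records, e2$records)
})
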