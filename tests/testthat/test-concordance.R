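# Agreement and screening statistics on the packaged diagnosis table.

test_that("the packaged diagnosis table loads and validates", {
  rec <- load_pilot_records()
  expect_identical(nrow(rec), 32L)
  expect_identical(anyDuplicated(rec$slide_number), 0L)
  neg <- rec$study_id[rec$histology_call == "negative"]
  expect_setequal(neg, c("CS002", "CS036"))

  # malformed inputs
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(character(0), tmp)
  expect_error(load_records(tmp), "malformed|columns|records")
  writeLines("slide_number,study_id", tmp)
  expect_error(load_records(tmp), "lacks columns")
  bad <- load_pilot_records()
  bad$rater1_call[3] <- "maybe"
  utils::write.csv(bad, tmp, row.names = FALSE)
  expect_error(load_records(tmp), "non-binary")
  dup <- load_pilot_records()
  dup$slide_number[2] <- 1
  utils::write.csv(dup, tmp, row.names = FALSE)
  expect_error(load_records(tmp), "unique")

  # a truncated fixture fails its checksum
  trunc <- readLines(diagnosis_fixture_path())
  writeLines(trunc[1:20], tmp)
  expect_error(load_records(tmp, checksum = slidescope:::FIXTURE_MD5),
               "checksum")
})

test_that("discordant records are exactly the five known cases", {
  rec <- load_pilot_records()
  disc <- discordant_records(rec, "rater1_call", "rater2_call")
  expect_identical(disc$study_id,
                   c("CS016", "CS010", "CS012", "CS011", "CS038"))
  expect_identical(nrow(discordant_records(rec, "cytology_call",
                                           "cytology_call")), 0L)
  toy <- data.frame(slide_number = 1:2, study_id = c("A", "B"),
                    r1 = c("positive", "negative"),
                    r2 = c("positive", "positive"))
  expect_identical(discordant_records(toy, "r1", "r2")$study_id, "B")
  expect_error(discordant_records(rec, "rater1_call", "nope"),
               "unknown column")
})

test_that("agreement tables count the 2x2 cells correctly", {
  rec <- load_pilot_records()
  tab <- agreement_table(rec, "rater1_call", "rater2_call")
  expect_identical(tab[c("a", "b", "c", "d")],
                   list(a = 14L, b = 0L, c = 5L, d = 13L))
  expect_identical(tab$n, 32L)
  # swapping raters transposes b and c
  swapped <- agreement_table(rec, "rater2_call", "rater1_call")
  expect_identical(swapped$b, tab$c)
  expect_identical(swapped$c, tab$b)
  # identical columns: no disagreement cells
  self <- agreement_table(rec, "rater1_call", "rater1_call")
  expect_identical(self$b + self$c, 0L)
  # hand-built 4-record set covering every cell once
  toy <- data.frame(slide_number = 1:4, study_id = letters[1:4],
                    r1 = c("positive", "positive", "negative", "negative"),
                    r2 = c("positive", "negative", "positive", "negative"))
  tt <- agreement_table(toy, "r1", "r2")
  expect_identical(tt[c("a", "b", "c", "d")],
                   list(a = 1L, b = 1L, c = 1L, d = 1L))
})

test_that("Cohen's kappa reproduces the rater-agreement statistics", {
  res <- cohen_kappa(slidescope:::agreement_cells(14, 0, 5, 13))
  expect_identical(res$pr_a, 27 / 32)
  expect_identical(res$pr_e, 500 / 1024)
  expect_identical(round_half_up(100 * res$pr_a, 2), 84.38)
  expect_identical(round_half_up(100 * res$pr_e, 2), 48.83)
  expect_identical(round_half_up(res$kappa, 3), 0.695)

  # perfect agreement and chance-level agreement
  expect_identical(cohen_kappa(slidescope:::agreement_cells(10, 0, 0, 10))$kappa, 1)
  mid <- cohen_kappa(slidescope:::agreement_cells(5, 5, 5, 5))
  expect_identical(mid$pr_a, 0.5)
  expect_identical(mid$pr_e, 0.5)
  expect_identical(mid$kappa, 0)

  # degenerate marginals: Pr(e) = 1 is an explicit error
  expect_error(cohen_kappa(slidescope:::agreement_cells(7, 0, 0, 0)),
               "undefined")
  expect_error(cohen_kappa(slidescope:::agreement_cells(0, 0, 0, 0)),
               "empty")
})

test_that("kappa formula agrees with a brute-force enumeration oracle", {
  withr::local_seed(42)
  for (i in 1:300) {
    cells <- stats::rmultinom(1, size = sample(1:50, 1),
                              prob = stats::runif(4, 0.05, 1))[, 1]
    a <- cells[1]; b <- cells[2]; c <- cells[3]; d <- cells[4]
    n <- sum(cells)
    # oracle: expand to per-record calls and enumerate proportions
    r1 <- rep(c(TRUE, TRUE, FALSE, FALSE), times = cells)
    r2 <- rep(c(TRUE, FALSE, TRUE, FALSE), times = cells)
    pr_a <- mean(r1 == r2)
    pr_e <- mean(r1) * mean(r2) + mean(!r1) * mean(!r2)
    if (pr_e == 1) {
      expect_error(cohen_kappa(slidescope:::agreement_cells(a, b, c, d)))
      next
    }
    got <- cohen_kappa(slidescope:::agreement_cells(a, b, c, d))
    expect_equal(got$pr_a, pr_a, tolerance = 1e-12)
    expect_equal(got$pr_e, pr_e, tolerance = 1e-12)
    expect_equal(got$kappa, (pr_a - pr_e) / (1 - pr_e), tolerance = 1e-12)
    expect_lte(got$kappa, 1)
    # invariances: swapping raters, swapping both labels
    expect_equal(cohen_kappa(slidescope:::agreement_cells(a, c, b, d))$kappa,
                 got$kappa, tolerance = 1e-12)
    expect_equal(cohen_kappa(slidescope:::agreement_cells(d, c, b, a))$kappa,
                 got$kappa, tolerance = 1e-12)
    # kappa = 1 iff no disagreement
    if (got$kappa == 1) expect_identical(b + c, 0L)
  }
})

test_that("confusion tables and screening metrics match the study tables", {
  rec <- load_pilot_records()
  ct1 <- confusion(rec, "rater1_call", "histology_call")
  expect_identical(ct1[c("tp", "fp", "fn", "tn")],
                   list(tp = 14L, fp = 0L, fn = 16L, tn = 2L))
  m1 <- screening_metrics(ct1, "percent")
  expect_identical(m1, list(sensitivity = 47, specificity = 100))

  cyt <- confusion(rec, "cytology_call", "histology_call")
  expect_identical(cyt[c("tp", "fp", "fn", "tn")],
                   list(tp = 21L, fp = 0L, fn = 9L, tn = 2L))
  expect_identical(screening_metrics(cyt, "percent"),
                   list(sensitivity = 70, specificity = 100))

  m2 <- screening_metrics(slidescope:::confusion_cells(tp = 19, fp = 0,
                                                       fn = 2, tn = 11),
                          "percent")
  expect_identical(m2, list(sensitivity = 90, specificity = 100))

  # gold identical to test: no errors at all
  self <- confusion(rec, "cytology_call", "cytology_call")
  expect_identical(self$fp + self$fn, 0L)

  # zero denominators are explicit NA, not zero
  und <- screening_metrics(slidescope:::confusion_cells(0, 1, 0, 1))
  expect_true(is.na(und$sensitivity))
  expect_identical(und$specificity, 0.5)

  # Se + FN/(TP+FN) = 1 whenever defined
  prop <- screening_metrics(ct1)
  expect_equal(prop$sensitivity + ct1$fn / (ct1$tp + ct1$fn), 1)
})

test_that("the concordance report reproduces every published figure", {
  rep <- concordance_report()
  expect_identical(round_half_up(rep$agreement$kappa, 3), 0.695)
  expect_identical(rep$concordant, 27L)
  expect_identical(rep$concordance_pct, 84.4)
  expect_length(rep$discordant_ids, 5)
  se <- vapply(rep$screening, `[[`, numeric(1), "sensitivity")
  expect_identical(unname(se), c(47, 63, 67, 90, 70))
  sp <- vapply(rep$screening, `[[`, numeric(1), "specificity")
  expect_true(all(sp == 100))
})

test_that("percentage rounding is half away from zero", {
  expect_identical(round_half_up(c(46.67, 63.33, 66.67, 90.48, 70)),
                   c(47, 63, 67, 90, 70))
  expect_identical(round_half_up(0.5), 1)
  expect_identical(round_half_up(-0.5), -1)
  expect_identical(round_half_up(0.6945, 3), 0.695)
})
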