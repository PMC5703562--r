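# Inter-rater agreement (Cohen's kappa) and screening metrics against a
# gold standard, plus the packaged 32-patient oral-lesion diagnosis
# table from the telecytology pilot this instrument emulates.

FIXTURE_MD5 <- "262f94cce026502e0f8fabc068984a26"

CALL_COLUMNS <- c("histology_call", "cytology_call",
                  "rater1_call", "rater2_call")

#' Path to the packaged diagnosis table
#'
#' A 32-patient table of per-patient binary diagnosis calls from an
#' oral brush-biopsy telecytology pilot: scalpel-biopsy histology,
#' conventional-microscope cytology, and two pathologists' independent
#' readings of the tablet-microscope images ("positive" = carcinoma or
#' dysplasia observed). One non-squamous (lymphoma) case is encoded
#' histology-negative, squamous carcinoma being the screening target.
#'
#' @return path to the CSV fixture.
#' @export
diagnosis_fixture_path <- function() {
  system.file("extdata", "oral_cytology_calls.csv", package = "slidescope",
              mustWork = TRUE)
}

#' Load and validate a per-patient diagnosis table
#'
#' @param path CSV with one header row and columns `slide_number`,
#'   `study_id`, `age`, `sex`, `clinical_diagnosis`, `site`, and the
#'   four call columns (`histology_call`, `cytology_call`,
#'   `rater1_call`, `rater2_call`), calls being
#'   `positive`/`negative` case-insensitively.
#' @param checksum optional md5 the file must match (used for the
#'   packaged fixture).
#' @return validated data frame with calls normalised to lower case.
#' @export
#' @examples
#' rec <- load_records(diagnosis_fixture_path())
#' nrow(rec)  # 32
load_records <- function(path, checksum = NULL) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  if (!is.null(checksum)) {
    got <- unname(tools::md5sum(path))
    if (!identical(got, checksum)) {
      stopf("diagnosis table %s fails its checksum (got %s)", path, got)
    }
  }
  rec <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                  error = function(e) stopf("malformed CSV: %s",
                                            conditionMessage(e)))
  required <- c("slide_number", "study_id", "age", "sex",
                "clinical_diagnosis", "site", CALL_COLUMNS)
  missing <- setdiff(required, names(rec))
  if (length(missing)) {
    stopf("diagnosis table lacks columns: %s",
          paste(missing, collapse = ", "))
  }
  if (nrow(rec) == 0) stopf("diagnosis table has no records")
  if (anyNA(rec$slide_number) || anyDuplicated(rec$slide_number)) {
    stopf("slide_number must be present and unique")
  }
  for (col in CALL_COLUMNS) {
    v <- tolower(trimws(rec[[col]]))
    bad <- !v %in% c("positive", "negative")
    if (any(bad)) {
      stopf("column %s has non-binary calls: %s", col,
            paste(unique(rec[[col]][bad]), collapse = ", "))
    }
    rec[[col]] <- v
  }
  rec
}

#' Load the packaged pilot diagnosis table
#'
#' [load_records()] applied to [diagnosis_fixture_path()] with its
#' frozen checksum enforced.
#'
#' @return the 32-record data frame.
#' @export
load_pilot_records <- function() {
  load_records(diagnosis_fixture_path(), checksum = FIXTURE_MD5)
}

check_call_column <- function(records, column) {
  if (!column %in% names(records)) stopf("unknown column: %s", column)
  v <- tolower(trimws(records[[column]]))
  if (!all(v %in% c("positive", "negative"))) {
    stopf("column %s is not a binary positive/negative call", column)
  }
  v == "positive"
}

#' Records where two raters disagree
#'
#' @param records a diagnosis table (see [load_records()]).
#' @param raterA_column,raterB_column names of the two call columns.
#' @return the discordant records, in slide order.
#' @export
discordant_records <- function(records, raterA_column, raterB_column) {
  a <- check_call_column(records, raterA_column)
  b <- check_call_column(records, raterB_column)
  out <- records[a != b, , drop = FALSE]
  out[order(out$slide_number), , drop = FALSE]
}

#' 2x2 agreement table between two raters
#'
#' Counts `a` (both positive), `b` (A positive, B negative), `c` (A
#' negative, B positive) and `d` (both negative); swapping the raters
#' transposes `b` and `c`.
#'
#' @inheritParams discordant_records
#' @return an object of class `agreement_table` with integer cells
#'   `a`, `b`, `c`, `d` and total `n`.
#' @export
agreement_table <- function(records, raterA_column, raterB_column) {
  pa <- check_call_column(records, raterA_column)
  pb <- check_call_column(records, raterB_column)
  tab <- list(a = sum(pa & pb), b = sum(pa & !pb),
              c = sum(!pa & pb), d = sum(!pa & !pb))
  tab <- lapply(tab, as.integer)
  tab$n <- tab$a + tab$b + tab$c + tab$d
  structure(tab, class = "agreement_table")
}

# Build an agreement_table directly from cell counts.
agreement_cells <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0)) stopf("cell counts must be non-negative")
  structure(list(a = as.integer(a), b = as.integer(b),
                 c = as.integer(c), d = as.integer(d),
                 n = as.integer(a + b + c + d)),
            class = "agreement_table")
}

#' @export
print.agreement_table <- function(x, ...) {
  m <- matrix(c(x$a, x$c, x$b, x$d), 2, 2,
              dimnames = list(`rater B` = c("positive", "negative"),
                              `rater A` = c("positive", "negative")))
  print(m)
  invisible(x)
}

#' Cohen's kappa from a 2x2 agreement table
#'
#' Chance-corrected agreement `kappa = (Pr(a) - Pr(e)) / (1 - Pr(e))`,
#' with observed agreement `Pr(a) = (a + d) / n` and chance agreement
#' `Pr(e)` the sum of products of the marginal proportions. Internally
#' everything is integer arithmetic over the exact denominators `n` and
#' `n^2`; rounding to the conventional reporting precisions (Pr as
#' percent to 2 dp, kappa to 3 dp) happens only in the print/format
#' methods.
#'
#' @param table an [agreement_table()] (or anything with `a`, `b`, `c`,
#'   `d` counts).
#' @return an object of class `agreement_result` with `pr_a`, `pr_e`,
#'   `kappa` (proportions/value on the natural scale) and the table.
#' @export
#' @examples
#' cohen_kappa(agreement_table(load_pilot_records(),
#'                             "rater1_call", "rater2_call"))
cohen_kappa <- function(table) {
  a <- table$a; b <- table$b; c <- table$c; d <- table$d
  n <- a + b + c + d
  if (n < 1) stopf("agreement table is empty")
  # exact integer numerators over n and n^2
  num_a <- a + d                                   # Pr(a) = num_a / n
  num_e <- (a + b) * (a + c) + (c + d) * (b + d)   # Pr(e) = num_e / n^2
  if (num_e == n^2) {
    stopf("chance agreement Pr(e) = 1: kappa undefined for degenerate marginals")
  }
  kappa <- (num_a * n - num_e) / (n^2 - num_e)
  structure(list(pr_a = num_a / n, pr_e = num_e / n^2, kappa = kappa,
                 table = table),
            class = "agreement_result")
}

#' @export
format.agreement_result <- function(x, ...) {
  sprintf("Pr(a) %.2f%%, Pr(e) %.2f%%, kappa %.3f",
          round_half_up(100 * x$pr_a, 2),
          round_half_up(100 * x$pr_e, 2),
          round_half_up(x$kappa, 3))
}

#' @export
print.agreement_result <- function(x, ...) {
  cat("<agreement_result>", format(x), "\n")
  invisible(x)
}

#' Confusion table of a screening test against a gold standard
#'
#' `tp` = gold positive and test positive, `fp` = gold negative but test
#' positive, `fn` = gold positive but test negative, `tn` = both
#' negative.
#'
#' @param records a diagnosis table.
#' @param test_column,gold_column call column names.
#' @return an object of class `confusion_table` with `tp`, `fp`, `fn`,
#'   `tn`.
#' @export
confusion <- function(records, test_column, gold_column) {
  test <- check_call_column(records, test_column)
  gold <- check_call_column(records, gold_column)
  confusion_cells(tp = sum(gold & test), fp = sum(!gold & test),
                  fn = sum(gold & !test), tn = sum(!gold & !test))
}

confusion_cells <- function(tp, fp, fn, tn) {
  if (any(c(tp, fp, fn, tn) < 0)) stopf("cell counts must be non-negative")
  structure(list(tp = as.integer(tp), fp = as.integer(fp),
                 fn = as.integer(fn), tn = as.integer(tn)),
            class = "confusion_table")
}

#' @export
print.confusion_table <- function(x, ...) {
  cat(sprintf("<confusion_table> tp %d, fp %d, fn %d, tn %d\n",
              x$tp, x$fp, x$fn, x$tn))
  invisible(x)
}

#' Sensitivity and specificity of a screening test
#'
#' `Se = tp / (tp + fn)`, `Sp = tn / (tn + fp)`. A zero denominator
#' makes that metric explicitly undefined (`NA`), never 0. With
#' `rounding = "percent"` values are reported as nearest-integer
#' percentages, rounding half away from zero — the convention under
#' which 46.67 prints as 47 and 90.48 as 90.
#'
#' @param ct a [confusion()] table.
#' @param rounding `"none"` for proportions, `"percent"` for
#'   integer-rounded percentages.
#' @return list with `sensitivity` and `specificity`.
#' @export
screening_metrics <- function(ct, rounding = c("none", "percent")) {
  rounding <- match.arg(rounding)
  se <- if (ct$tp + ct$fn > 0) ct$tp / (ct$tp + ct$fn) else NA_real_
  sp <- if (ct$tn + ct$fp > 0) ct$tn / (ct$tn + ct$fp) else NA_real_
  if (rounding == "percent") {
    se <- round_half_up(100 * se)
    sp <- round_half_up(100 * sp)
  }
  list(sensitivity = se, specificity = sp)
}

#' Full concordance report for a diagnosis table
#'
#' Recomputes, from the per-patient calls alone: Cohen's kappa (with
#' Pr(a), Pr(e)) between the two image raters, the rater concordance
#' fraction, the discordant records, and all sensitivity/specificity
#' pairs — each image rater against histology and against cytology, and
#' cytology against histology.
#'
#' @param records a diagnosis table; defaults to the packaged
#'   32-patient pilot fixture (checksum-verified).
#' @return an object of class `concordance_report` (a nested list; see
#'   the print method for the layout).
#' @export
#' @examples
#' concordance_report()
concordance_report <- function(records = load_pilot_records()) {
  agr <- cohen_kappa(agreement_table(records, "rater1_call", "rater2_call"))
  disc <- discordant_records(records, "rater1_call", "rater2_call")
  pairs <- list(
    rater1_vs_histology = c("rater1_call", "histology_call"),
    rater2_vs_histology = c("rater2_call", "histology_call"),
    rater1_vs_cytology  = c("rater1_call", "cytology_call"),
    rater2_vs_cytology  = c("rater2_call", "cytology_call"),
    cytology_vs_histology = c("cytology_call", "histology_call")
  )
  screening <- lapply(pairs, function(p) {
    ct <- confusion(records, p[1], p[2])
    c(list(test = p[1], gold = p[2]),
      ct[c("tp", "fp", "fn", "tn")],
      screening_metrics(ct, "percent"))
  })
  n <- nrow(records)
  n_agree <- agr$table$a + agr$table$d
  structure(
    list(n = n,
         agreement = agr,
         concordant = n_agree,
         concordance_pct = round_half_up(100 * n_agree / n, 1),
         discordant_ids = disc$study_id,
         screening = screening),
    class = "concordance_report"
  )
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf("Concordance report, n = %d patients\n", x$n))
  cat(sprintf("  Rater agreement: %s\n", format(x$agreement)))
  cat(sprintf("  Concordant calls: %d/%d = %.1f%%\n",
              x$concordant, x$n, x$concordance_pct))
  cat(sprintf("  Discordant records: %s\n",
              paste(x$discordant_ids, collapse = ", ")))
  for (nm in names(x$screening)) {
    s <- x$screening[[nm]]
    cat(sprintf("  %-22s Se %3.0f%%  Sp %3.0f%%  (tp %d, fp %d, fn %d, tn %d)\n",
                nm, s$sensitivity, s$specificity, s$tp, s$fp, s$fn, s$tn))
  }
  invisible(x)
}
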