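lex <- default_sign_lexicon()

test_that("clinical signs standardize through the lexicon and synonym map", {
  expect_equal(standardize_clinical_sign("gasping", lex), "gasping")
  expect_equal(standardize_clinical_sign("Tachypnoea", lex),
               "rapid/fast respiration")
  expect_equal(standardize_clinical_sign("bradypnoea", lex),
               "slow respiration")
  expect_equal(standardize_clinical_sign("piloerection", lex), "unmapped")
  expect_equal(standardize_clinical_sign(c("gasps", "rales"), lex),
               c("gasping", "noisy respiration"))
})

test_that("clinical reference label scores respiratory signs within H0-H2 only", {
  expect_true(clinical_reference_label("gasping@H1", lex))
  expect_true(clinical_reference_label("piloerection@H0;rales@H2", lex))
  expect_false(clinical_reference_label("irregular respiration@later", lex))
  expect_false(clinical_reference_label("piloerection@H0", lex))
  expect_false(clinical_reference_label("", lex))
  expect_error(clinical_reference_label("gasping", lex),
               class = "schema_error")
})

test_that("GHS reference label covers categories 3 and 4 only", {
  expect_true(ghs_reference_label("cat3"))
  expect_true(ghs_reference_label("cat4"))
  expect_false(ghs_reference_label("not_classified"))
  expect_false(ghs_reference_label("cat5"))
})

test_that("confusion tables count and respect label symmetry", {
  one <- data.frame(chemical_id = "a", invitro_inhibitory = TRUE,
                    ghs_category = "cat3", signs = "")
  ct <- build_confusion(one, "ghs", lex)
  expect_equal(c(ct$TP, ct$FP, ct$TN, ct$FN), c(1, 0, 0, 0))
  expect_error(build_confusion(one[0, ], "ghs", lex),
               class = "parameter_error")
  # flipping the in vitro outcome swaps TP<->FN and FP<->TN
  rec <- make_table1_fixture(seed = 5)
  flipped <- rec
  flipped$invitro_inhibitory <- !rec$invitro_inhibitory
  a <- build_confusion(rec, "ghs", lex)
  b <- build_confusion(flipped, "ghs", lex)
  expect_equal(c(a$TP, a$FP, a$TN, a$FN), c(b$FN, b$TN, b$FP, b$TP))
})

test_that("predictivity metrics reproduce the published two-scenario values", {
  ghs <- compute_metrics(
    structure(list(TP = 10, FN = 5, FP = 8, TN = 3, n = 26, scenario = "ghs"),
              class = "confusion_table"))
  got <- setNames(ghs$rounded, ghs$metric)
  expect_equal(got, c(sensitivity = 0.67, specificity = 0.27, ppv = 0.56,
                      npv = 0.38, accuracy = 0.50))
  expect_equal(setNames(ghs$fraction, ghs$metric)[["accuracy"]], "13/26")
  clin <- compute_metrics(
    structure(list(TP = 17, FN = 4, FP = 1, TN = 4, n = 26,
                   scenario = "clinical"), class = "confusion_table"))
  expect_equal(setNames(clin$rounded, clin$metric),
               c(sensitivity = 0.81, specificity = 0.80, ppv = 0.94,
                 npv = 0.50, accuracy = 0.81))
})

test_that("zero denominators yield undefined metrics, not coerced zeros", {
  ct <- structure(list(TP = 0, FN = 0, FP = 2, TN = 3, n = 5,
                       scenario = "ghs"), class = "confusion_table")
  m <- compute_metrics(ct)
  expect_true(is.na(m$value[m$metric == "sensitivity"]))
  expect_match(m$note[m$metric == "sensitivity"], "zero denominator")
  expect_equal(m$value[m$metric == "specificity"], 0.6)
})

test_that("metric identities hold on random confusion tables", {
  set.seed(7)
  for (i in 1:50) {
    cts <- structure(as.list(c(setNames(as.list(rpois(4, 5) + 1),
                                        c("TP", "FN", "FP", "TN")))),
                     class = "confusion_table")
    cts$n <- cts$TP + cts$FN + cts$FP + cts$TN
    m <- compute_metrics(cts)
    v <- setNames(m$value, m$metric)
    P <- cts$TP + cts$FN; N2 <- cts$TN + cts$FP
    expect_equal(v[["accuracy"]],
                 (v[["sensitivity"]] * P + v[["specificity"]] * N2) / (P + N2))
    expect_equal(v[["ppv"]],
                 v[["sensitivity"]] * P /
                   (v[["sensitivity"]] * P + (1 - v[["specificity"]]) * N2))
    expect_true(all(v >= 0 & v <= 1))
  }
  # an all-correct classifier scores 1 everywhere defined
  perfect <- structure(list(TP = 4, FN = 0, FP = 0, TN = 3, n = 7,
                            scenario = "ghs"), class = "confusion_table")
  expect_true(all(compute_metrics(perfect)$value == 1))
})

test_that("rounding is half-up to two decimals", {
  expect_equal(round_half_up(0.125, 2), 0.13)
  expect_equal(round_half_up(0.375, 2), 0.38)
  expect_equal(round_half_up(17 / 21, 2), 0.81)
  expect_equal(round_half_up(-0.125, 2), -0.13)
})

test_that("Wilson intervals are produced on request and contain the estimate", {
  ct <- structure(list(TP = 10, FN = 5, FP = 8, TN = 3, n = 26,
                       scenario = "ghs"), class = "confusion_table")
  m <- compute_metrics(ct, conf_level = 0.95)
  expect_true(all(m$ci_lower <= m$value & m$value <= m$ci_upper))
  expect_true(all(m$ci_lower >= 0 & m$ci_upper <= 1))
})

test_that("the two-scenario report surfaces unmapped terms and formats Table-1 style", {
  rec <- make_table1_fixture(seed = 2)
  rep <- predictivity_report(rec, lex)
  expect_equal(rep$ghs$confusion$TP, 10)
  expect_equal(rep$clinical$confusion$TP, 17)
  md <- format_report_table(rep)
  expect_match(md[3], "Sensitivity")
  expect_match(paste(md, collapse = "\n"), "0.67 \\(10/15\\)")
  expect_match(paste(md, collapse = "\n"), "0.94 \\(17/18\\)")
  # piloerection appears among reference-negative chemicals for some seeds
  rec$signs[1] <- "piloerection@H0"
  expect_true("piloerection" %in% predictivity_report(rec, lex)$unmapped_terms)
})
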