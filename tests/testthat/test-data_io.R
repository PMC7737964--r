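make_csv <- function(lines) {
  tf <- tempfile(fileext = ".csv")
  writeLines(lines, tf)
  tf
}

small_csv <- function() {
  make_csv(c(
    "pig,pen,Sex,Trx1,Trx2,met1,met2,met3",
    "1,p1,M,N,CON,1.5,10,100",
    "2,p1,F,N,CON,.,11,110",
    "3,p2,M,P,CON,2.5,12,120",
    "4,p2,F,P,CON,2.6,13,130",
    "5,p3,M,N,HFF,3.5,14,140",
    "6,p3,F,N,HFF,3.6,15,150",
    "7,p4,M,P,HFF,4.5,16,160",
    "8,p4,F,P,HFF,4.6,17,170"
  ))
}

test_that("wide reader separates factors, responses and missing values", {
  ft <- read_wide_table(small_csv(), "Trx1", "Trx2",
                        exclude_vars = c("pig", "pen"), ignore_vars = "Sex")
  expect_s3_class(ft, "feature_table")
  expect_identical(dim(ft), c(8L, 3L))
  expect_identical(ft$metabolite_names, c("met1", "met2", "met3"))
  expect_identical(sort(names(ft$factors)), sort(c("Trx1", "Trx2", "pig", "pen")))
  expect_false("Sex" %in% names(ft$factors))
  expect_true(is.na(ft$responses[2, "met1"]))
  expect_equal(sum(is.na(ft$responses)), 1L)
  expect_equal(unname(ft$responses[1, "met3"]), 100)
})

test_that("a single non-factor column yields a one-response table", {
  tf <- make_csv(c("Trx1,Trx2,only_met", "N,CON,1", "P,HFF,2"))
  ft <- read_wide_table(tf, "Trx1", "Trx2")
  expect_identical(ft$metabolite_names, "only_met")
})

test_that("reader raises named errors on malformed input", {
  expect_error(
    read_wide_table(small_csv(), "Trx1", "Trx2", exclude_vars = "nonexistent"),
    class = "missing_column"
  )
  tf_all_factor <- make_csv(c("Trx1,Trx2", "N,CON", "P,HFF"))
  expect_error(read_wide_table(tf_all_factor, "Trx1", "Trx2"),
               class = "no_response_columns")
  tf_bad <- make_csv(c("Trx1,Trx2,met1", "N,CON,abc", "P,HFF,2"))
  err <- expect_error(read_wide_table(tf_bad, "Trx1", "Trx2"),
                      class = "invalid_numeric")
  expect_match(conditionMessage(err), "met1")
  expect_match(conditionMessage(err), "row 1")
})

test_that("name validation flags length, special characters and leading digits", {
  clean <- validate_names(c("pyridoxate", "acetylchol"))
  expect_true(clean$is_clean)
  too_long <- validate_names(strrep("a", 32))
  expect_false(too_long$is_clean)
  expect_identical(too_long$violations$rule, "too_long")
  special <- validate_names("C18:1 FA")
  expect_false(special$is_clean)
  expect_true("special_characters" %in% special$violations$rule)
  digit <- validate_names("5HT")
  expect_true("leading_digit" %in% digit$violations$rule)
  tf <- make_csv(c("Trx1,Trx2,C18:1 FA", "N,CON,1", "P,HFF,2"))
  expect_warning(read_wide_table(tf, "Trx1", "Trx2"),
                 class = "invalid_metabolite_names")
  expect_error(read_wide_table(tf, "Trx1", "Trx2", strict_names = TRUE),
               class = "invalid_metabolite_names")
})

test_that("long reshape is complete, grouped, and lossless", {
  ft <- read_wide_table(small_csv(), "Trx1", "Trx2",
                        exclude_vars = c("pig", "pen"), ignore_vars = "Sex")
  long <- to_long(ft)
  expect_equal(nrow(long), 8 * 3)
  expect_identical(unique(long$response_name), ft$metabolite_names)
  # grouped by metabolite, original sample order within each group
  expect_identical(long$response_name, rep(ft$metabolite_names, each = 8))
  expect_identical(long$sample_id[1:8], ft$sample_id)
  # regrouping reproduces the responses matrix including the missing pattern
  rebuilt <- matrix(long$value, nrow = 8,
                    dimnames = list(NULL, ft$metabolite_names))
  expect_identical(rebuilt, ft$responses)

  one <- feature_table(matrix(3.14, 1, 1, dimnames = list(NULL, "m")),
                       data.frame(Trx1 = "N"))
  expect_equal(nrow(to_long(one)), 1L)
})

test_that("feature tables round-trip through the wide CSV dialect", {
  ft <- simulate_feature_table(sim_design(n_metabolites = 3, missing_rate = 0.1,
                                          seed = 5))
  tf <- tempfile(fileext = ".csv")
  write_feature_table(ft, tf)
  expect_true(any(grepl(",\\.", readLines(tf))))  # canonical dot for missing
  back <- read_wide_table(tf, "Trx1", "Trx2", exclude_vars = "pen")
  expect_equal(back$responses, ft$responses, tolerance = 1e-12)
  expect_identical(back$factors$pen, ft$factors$pen)
})

test_that("export writes one consolidated file or one file per component", {
  ft <- simulate_feature_table(sim_design(n_metabolites = 3, seed = 9))
  res <- run_two_way(ft, "Trx1", "Trx2", random_unit = "pen")
  dir1 <- withr::local_tempdir()
  files <- export_results(res, dir1, name = "demo", singlefile = TRUE)
  expect_length(files, 1L)
  out <- read.csv(files, check.names = FALSE)
  expect_equal(nrow(out), 3L)
  expect_identical(names(out), names(res$table))

  files5 <- export_results(res, dir1, name = "demo_parts", singlefile = FALSE)
  expect_length(files5, 5L)
  expect_false(any(grepl(" ", basename(files5))))
  norm <- read.csv(grep("normality", files5, value = TRUE), check.names = FALSE)
  expect_true(all(c("Response", "Shapiro_Wilk", "Kolmogorov") %in% names(norm)))

  expect_error(export_results(res, file.path(dir1, "missing_dir"), "x"),
               class = "unwritable_path")
})

test_that("rows sort by the first factor's raw p-value with failures last", {
  ft <- simulate_feature_table(sim_design(n_metabolites = 4, seed = 21))
  ft$responses[, 2] <- NA_real_  # metabolite with no data: fit must fail
  res <- run_two_way(ft, "Trx1", "Trx2", random_unit = "pen")
  tab <- res$table
  expect_equal(nrow(tab), 4L)  # failed metabolite kept, not dropped
  expect_identical(tab$Response[4], "met002")
  expect_true(is.na(tab$Pvalue_Trx1[4]))
  expect_false(tab$Status[4] %in% c("ok", "ok_boundary"))
  p_ok <- tab$Pvalue_Trx1[1:3]
  expect_identical(p_ok, sort(p_ok))
})
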