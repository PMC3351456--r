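write_lines_tmp <- function(lines, ext) {
  path <- withr::local_tempfile(fileext = ext, .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("delimited collections read with column order, headers and defaults", {
  path <- write_lines_tmp(c("A,B", "x,y", "y,z"), ".csv")
  cl <- read_collection(path)
  expect_s3_class(cl, "set_collection")
  expect_equal(names(cl$sets), c("A", "B"))
  expect_equal(cl$sets$A, c("x", "y"))
  expect_equal(cl$sets$B, c("y", "z"))
  expect_length(unique(unlist(cl$sets)), 3L)

  headerless <- read_collection(path, header = FALSE)
  expect_equal(names(headerless$sets), c("Set1", "Set2"))
  expect_true("A" %in% headerless$sets$Set1)

  tsv <- write_lines_tmp(c("A\tB", "x\ty"), ".tsv")
  expect_equal(names(read_collection(tsv)$sets), c("A", "B"))

  # numeric-looking identifiers survive verbatim
  nums <- write_lines_tmp(c("A,B", "007,1e3", "2.50,x"), ".csv")
  cln <- read_collection(nums)
  expect_equal(cln$sets$A, c("007", "2.50"))
  expect_equal(cln$sets$B, c("1e3", "x"))
})

test_that("unreadable inputs and bad column structure are format/set-count errors", {
  expect_error(read_collection(tempfile(fileext = ".csv")),
               class = "cogwheel_format")
  one_col <- write_lines_tmp(c("A", "x"), ".csv")
  expect_error(read_collection(one_col), class = "cogwheel_set_count")
  seven <- write_lines_tmp(c(paste(LETTERS[1:7], collapse = ","),
                             paste(letters[1:7], collapse = ",")), ".csv")
  expect_error(read_collection(seven), class = "cogwheel_set_count")
  dup <- write_lines_tmp(c("A,A", "x,y"), ".csv")
  expect_error(read_collection(dup), class = "cogwheel_format")
  not_xlsx <- write_lines_tmp("this is not a workbook", ".xlsx")
  expect_error(read_collection(not_xlsx), class = "cogwheel_format")
})

test_that("fixtures round-trip exactly through CSV and XLSX", {
  fx <- generate_collection(random_plan(4, seed = 42))
  for (ext in c(".csv", ".xlsx")) {
    path <- withr::local_tempfile(fileext = ext)
    write_collection(fx$collection, path)
    back <- read_collection(path)
    expect_equal(lapply(back$sets, sort), lapply(fx$collection$sets, sort),
                 info = ext)
    expect_equal(compute_partition(back)$regions, fx$partition$regions,
                 info = ext)
    # read -> write -> read is idempotent on canonical content
    path2 <- withr::local_tempfile(fileext = ext)
    write_collection(back, path2)
    expect_equal(read_collection(path2)$sets, back$sets, info = ext)
  }
})

test_that("only the first worksheet of a workbook is read", {
  fx <- generate_collection(random_plan(6, seed = 7))
  mat <- cogwheel:::cols_to_matrix(fx$collection$sets)
  clean <- withr::local_tempfile(fileext = ".xlsx")
  junked <- withr::local_tempfile(fileext = ".xlsx")
  cogwheel:::write_xlsx_sheets(list(Sheet1 = mat), clean)
  junk <- matrix(c("JUNK1", "JUNK2", "garbage", "noise"), 2, 2)
  cogwheel:::write_xlsx_sheets(list(Sheet1 = mat, Extra = junk), junked)
  expect_equal(read_collection(junked)$sets, read_collection(clean)$sets)
})

test_that("the in-package workbook writer agrees with an independent xlsx reader", {
  fx <- generate_collection(random_plan(3, seed = 9))
  path <- withr::local_tempfile(fileext = ".xlsx")
  write_collection(fx$collection, path)
  via_readxl <- readxl::read_excel(path, col_types = "text")
  expect_equal(names(via_readxl), names(fx$collection$sets))
  for (j in seq_along(via_readxl)) {
    col <- via_readxl[[j]]
    expect_equal(sort(col[!is.na(col)]), sort(fx$collection$sets[[j]]))
  }
})

test_that("region table columns follow region-index order and the empty-region flag", {
  p2 <- disjoint_pair()
  rt <- write_region_table(p2)
  expect_equal(rt$header, c("1:A", "2:B"))
  rt_all <- write_region_table(p2, include_empty = TRUE)
  expect_equal(rt_all$header, c("1:A", "2:B", "3:A∩B"))
  expect_equal(lengths(rt_all$members), c(1L, 1L, 0L))
  expect_true(all(diff(rt_all$region_index) > 0))

  p6 <- identical_six()
  rt6 <- write_region_table(p6)
  expect_equal(rt6$region_index, 63L)
  expect_length(rt6$header, 1L)

  # writing then re-pooling the columns reproduces the union exactly
  fx <- generate_collection(random_plan(5, seed = 21))
  p <- compute_partition(fx$collection)
  path <- withr::local_tempfile(fileext = ".csv")
  write_region_table(p, path)
  mat <- as.matrix(utils::read.csv(path, header = FALSE,
                                   colClasses = "character"))
  pooled <- mat[-1, , drop = FALSE]
  pooled <- sort(pooled[pooled != ""])
  expect_equal(pooled, sort(unique(unlist(fx$collection$sets))))
})

test_that("the region summary serializes sizes and categories for every region", {
  df <- write_summary(disjoint_pair())
  expect_equal(nrow(df), 3L)
  expect_equal(df$size, c(1L, 1L, 0L))
  expect_equal(df$category, c("BLUE", "RED", "GREEN"))

  p6 <- identical_six()
  path <- withr::local_tempfile(fileext = ".csv")
  df6 <- write_summary(p6, path = path)
  expect_equal(nrow(df6), 63L)
  expect_equal(df6$size[63], 8L)
  expect_equal(df6$category[63], "GREEN")
  expect_true(file.exists(path))

  fx <- generate_collection(random_plan(4, seed = 31))
  dfx <- write_summary(compute_partition(fx$collection))
  expect_equal(dfx$size, fx$plan$counts)          # planted counts recovered
  expect_equal(sum(dfx$size), sum(fx$plan$counts))
})
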