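test_that("bundled synthetic table loads, validates and summarises", {
  d <- fixture_entries()
  expect_equal(nrow(d), 39L)
  expect_equal(nrow(validate_gag_entries(d)), 0L)
  s <- gag_table_summary(d)
  expect_gt(s$n_proteins, 1L)
  expect_gt(s$n_gags, 1L)
  # stored G agrees with the half-time pair for every entry
  expect_equal(d$G, log(d$t_half_no_gag / d$t_half_with_gag),
               tolerance = 1e-6)
})

test_that("save/load round trip is the identity on valid entry sets", {
  d <- generate_gag_entries(n = 50, seed = 3)
  attr(d, "noise_sd") <- NULL
  path <- withr::local_tempfile(fileext = ".tsv")
  write_gag_table(d, path)
  d2 <- read_gag_table(path)
  expect_equal(d2, d, tolerance = 1e-12)
  # second round trip is bit-identical at the written precision
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_gag_table(d2, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("degenerate and malformed inputs produce informative errors", {
  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines(character(0), empty)
  expect_error(read_gag_table(empty), "empty")

  header_only <- withr::local_tempfile(fileext = ".tsv")
  d <- generate_gag_entries(n = 3, seed = 1)
  write_gag_table(d[0, ], header_only)   # zero entries -> header-only file
  expect_identical(length(readLines(header_only)), 1L)
  expect_error(read_gag_table(header_only), "empty")

  # missing required column
  broken <- withr::local_tempfile(fileext = ".tsv")
  write_gag_table(d, broken)
  tab <- utils::read.delim(broken, check.names = FALSE, colClasses = "character")
  utils::write.table(tab[setdiff(names(tab), "G")], broken, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  expect_error(read_gag_table(broken), "missing required column")

  # non-numeric value named by row and column
  bad <- withr::local_tempfile(fileext = ".tsv")
  write_gag_table(d, bad)
  lines <- readLines(bad)
  lines[2] <- sub("^syn-([^\t]*)\t[^\t]*", "syn-\\1\tnot_a_number", lines[2])
  writeLines(lines, bad)
  expect_error(read_gag_table(bad), "protein_length.*row")
})

test_that("invariant-violating rows are rejected with diagnostics", {
  d <- generate_gag_entries(n = 10, seed = 2)
  d$G[4] <- d$G[4] + 1        # break G == log(t0/tg)
  probs <- validate_gag_entries(d)
  expect_equal(probs$row, 4L)
  expect_equal(probs$column, "G")
  # writer refuses invalid entries
  expect_error(write_gag_table(d, withr::local_tempfile()), "refusing")
  # non-strict load drops the bad row and reports it
  d_ok <- generate_gag_entries(n = 10, seed = 2)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_gag_table(d_ok, path)
  tab <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
  tab$G[4] <- as.character(as.numeric(tab$G[4]) + 1)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_gag_table(path), "invalid entries")
  expect_warning(d2 <- read_gag_table(path, strict = FALSE), "dropped")
  expect_equal(nrow(d2), 9L)
  expect_equal(attr(d2, "rejected")$row, 4L)
})

test_that("further schema invariants are enforced", {
  d <- generate_gag_entries(n = 5, seed = 5)
  d$charges_per_disaccharide[1] <- d$sulfates_per_disaccharide[1] - 0.5
  d$lys_arg_count[2] <- d$protein_length[2] + 1L
  d$protein_gag_molar_ratio[3] <- d$protein_gag_molar_ratio[3] * 1.2
  d$sulfation_position[4] <- "none"   # despite sulfates > 0
  probs <- validate_gag_entries(d)
  expect_setequal(probs$row, 1:4)
  expect_true("charges_per_disaccharide" %in% probs$column)
  expect_true("protein_gag_molar_ratio" %in% probs$column)
})

test_that("half-times are normalised to hours when a unit column is present", {
  d <- generate_gag_entries(n = 4, seed = 9)
  path <- withr::local_tempfile(fileext = ".tsv")
  d$t_half_no_gag <- d$t_half_no_gag * 60
  d$t_half_with_gag <- d$t_half_with_gag * 60
  d$time_unit <- "min"
  write_gag_table(d, path)
  d2 <- read_gag_table(path)
  expect_equal(d2$t_half_no_gag, rep(24, 4), tolerance = 1e-9)
  expect_equal(d2$time_unit, rep("h", 4))
  expect_equal(d2$G, d$G, tolerance = 1e-9)
})

test_that("dummy recoding drops one reference level and is deterministic", {
  d <- fixture_entries()
  m <- encode_dummies(d, "uronic_acid")
  lev <- sort(unique(d$uronic_acid))
  expect_equal(ncol(m), length(lev) - 1L)       # k levels -> k - 1 columns
  expect_false("uronic_acid=glucuronic" %in% colnames(m))  # reference level
  for (col in colnames(m)) {
    l <- sub("^uronic_acid=", "", col)
    expect_equal(sum(m[, col]), sum(d$uronic_acid == l))   # column sums
    expect_true(all(m[, col] %in% c(0, 1)))
  }
  # dichotomous variables give exactly one column each
  m4 <- encode_dummies(d, c("folding_status", "disease_related"))
  expect_equal(colnames(m4),
               c("folding_status=natively_unfolded", "disease_related=TRUE"))
  # single observed level cannot be encoded
  d1 <- d[d$folding_status == "globular", ]
  expect_error(encode_dummies(d1, "folding_status"), "degenerate")
})

test_that("a YAML schema maps verbose headers onto canonical columns", {
  d <- generate_gag_entries(n = 5, seed = 11)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_gag_table(d, path)
  tab <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
  names(tab)[names(tab) == "sulfates_per_disaccharide"] <-
    "sulfates per disaccharide"
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  expect_error(read_gag_table(path), "missing required column")
  schema <- system.file("extdata", "schema.yaml", package = "gagfib")
  d2 <- read_gag_table(path, schema = schema)
  expect_equal(d2$sulfates_per_disaccharide, d$sulfates_per_disaccharide)
})
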