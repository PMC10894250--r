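test_that("tabular_dataset enforces its invariants", {
  X <- matrix(1:6, 3, 2)
  expect_s3_class(tabular_dataset(X, c(0, 1, 0)), "tabular_dataset")
  expect_error(tabular_dataset(X, c(0, 1)), "target length")
  expect_error(tabular_dataset(X, c(0, 2, 1)), "only 0 and 1")
  expect_error(tabular_dataset(X, c(1, 1, 1)), "both target classes")
  expect_error(tabular_dataset(X, c(0, 1, 0), c("a", "a")), "unique")
  Xna <- X; Xna[1, 1] <- NA
  expect_error(tabular_dataset(Xna, c(0, 1, 0)), "missing")
})

test_that("load_dataset applies categorical encodings per schema", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("famhist,sex,sbp,chd",
               "Present,Male,120,1",
               "Absent,Female,140,0",
               "Present,Female,130,1"), f)
  schema <- dataset_schema("chd", "1", "0",
                          list(famhist = c(Present = 1, Absent = 0),
                               sex = c(Male = 1, Female = 0)))
  ds <- load_dataset(f, schema)
  expect_equal(unname(ds$features[, "famhist"]), c(1, 0, 1))
  expect_equal(unname(ds$features[, "sex"]), c(1, 0, 0))
  expect_equal(ds$target, c(1L, 0L, 1L))
  # unmapped categorical value must raise, naming column and value
  writeLines(c("famhist,sex,sbp,chd", "Unknown,Male,120,1", "Absent,Female,1,0"), f)
  expect_error(load_dataset(f, schema), "famhist.*Unknown")
})

test_that("fully numeric CSV loads unchanged and round-trips", {
  f <- write_tiny_csv(tempfile(fileext = ".csv"))
  schema <- dataset_schema("target")
  ds <- load_dataset(f, schema)
  expect_equal(unname(ds$features[, "a"]), 1:10)
  f2 <- tempfile(fileext = ".csv")
  write_dataset_csv(ds, f2)
  ds2 <- load_dataset(f2, schema)
  expect_identical(ds$features, ds2$features)
  expect_identical(ds$target, ds2$target)
})

test_that("load_dataset drops missing targets and median-imputes features", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("x1,x2,target",
               "1,5,1", "2,,0", "3,7,1", "4,9,0", "5,11,"), f)
  expect_message(ds <- load_dataset(f, dataset_schema("target")),
                 "dropped 1 rows.*imputed 1")
  expect_equal(nrow(ds$features), 4)
  # median of observed x2 (5,7,9) imputed into row 2
  expect_equal(unname(ds$features[2, "x2"]), 7)
  expect_equal(attr(ds, "n_dropped_target"), 1)
  expect_equal(attr(ds, "n_imputed_cells"), 1)
})

test_that("load_dataset errors on schema problems", {
  f <- write_tiny_csv(tempfile(fileext = ".csv"))
  expect_error(load_dataset(f, dataset_schema("nope")), "target column")
  expect_error(dataset_schema("y", "1", "1"), "must differ")
  expect_error(dataset_schema("y", categorical_maps = list(a = c(x = 1, y = 1))),
               "injective")
  # single-class target
  f2 <- tempfile(fileext = ".csv")
  writeLines(c("a,target", "1,1", "2,1"), f2)
  expect_error(load_dataset(f2, dataset_schema("target")), "both target classes")
})

test_that("schema registry ships the five benchmark entries", {
  reg <- schema_registry()
  expect_setequal(names(reg),
                  c("combined_uci", "cleveland_uci", "framingham",
                    "south_african_heart", "z_alizadeh_sani"))
  sa <- schema_registry("south_african_heart")
  expect_s3_class(sa, "dataset_schema")
  expect_equal(sa$categorical_maps$famhist[["Present"]], 1)
  expect_match(reg$z_alizadeh_sani$notes, "54.*53")
  expect_error(schema_registry("nope"), "no registry entry")
})

test_that("stratified_split is stratified, disjoint and deterministic", {
  rng <- local_rng(9)
  ds <- tabular_dataset(matrix(rng$rnorm(40), 20, 2),
                        rep(c(0L, 1L), each = 10))
  sp <- stratified_split(ds, 0.2, seed = 4)
  expect_equal(sort(c(sp$test_rows, setdiff(1:20, sp$test_rows))), 1:20)
  expect_equal(sum(sp$test$target == 0), 2)
  expect_equal(sum(sp$test$target == 1), 2)
  sp2 <- stratified_split(ds, 0.2, seed = 4)
  expect_identical(sp$train$features, sp2$train$features)
  expect_identical(sp$test_rows, sp2$test_rows)
  # 10 rows, 5 per class, 0.2 -> exactly 1 of each class in test
  ds10 <- tabular_dataset(matrix(1:20, 10, 2), rep(c(0L, 1L), 5))
  sp10 <- stratified_split(ds10, 0.2, seed = 1)
  expect_equal(as.vector(table(sp10$test$target)), c(1, 1))
  # 4 balanced rows at 0.5 -> 2/2 with 1 of each class per side
  ds4 <- tabular_dataset(matrix(1:8, 4, 2), c(0L, 1L, 0L, 1L))
  sp4 <- stratified_split(ds4, 0.5, seed = 1)
  expect_equal(as.vector(table(sp4$test$target)), c(1, 1))
  expect_equal(as.vector(table(sp4$train$target)), c(1, 1))
  # unsatisfiable: a class with a single row cannot be split
  ds_bad <- tabular_dataset(matrix(1:8, 4, 2), c(0L, 0L, 0L, 1L))
  expect_error(stratified_split(ds_bad, 0.25, seed = 1), "validation error")
})

test_that("split preserves original row order within partitions", {
  rng <- local_rng(2)
  X <- matrix(seq_len(30), 30, 1)
  ds <- tabular_dataset(X, rep(c(0L, 1L), 15))
  sp <- stratified_split(ds, 0.2, seed = 0)
  expect_false(is.unsorted(sp$train$features[, 1]))
  expect_false(is.unsorted(sp$test$features[, 1]))
})
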