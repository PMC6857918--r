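test_that("global z-scoring uses a single mean/sd over all entries", {
  # 2x2 oracle: mu = 2, sigma^2 = sum((e - 2)^2) / 3 = 8/3
  out <- normalize_expression(tiny_expression())
  expect_equal(out$mean, 2)
  expect_equal(out$sd^2, 8 / 3)
  expect_equal(out$z[1, 1], -2 / sqrt(8 / 3), tolerance = 1e-12)
  # definition: all-entry mean 0, sample sd 1
  expect_equal(mean(out$z), 0, tolerance = 1e-12)
  expect_equal(sd(as.numeric(out$z)), 1, tolerance = 1e-12)
})

test_that("z-scoring round-trips and rejects degenerate input", {
  set.seed(42)
  x <- matrix(rnorm(60, 8, 2), 10, 6)
  out <- normalize_expression(x)
  expect_equal(out$z * out$sd + out$mean, x, tolerance = 1e-10)
  # log2 of an all-ones matrix is constant -> sd 0
  expect_error(normalize_expression(matrix(1, 2, 2), log2_transform = TRUE),
               "constant")
  expect_error(normalize_expression(matrix(c(1, NA, 2, 3), 2, 2)), "missing")
})

test_that("invariant-gene filter drops exactly the genes inside [-1, 1]", {
  z <- cbind(inside = c(-0.5, 0.9, 0.0),
             outside = c(1.2, 0, 0),
             boundary = c(-1.0, 0, 0),
             far = c(0, -3, 2))
  keep <- filter_invariant_genes(z)
  expect_setequal(names(keep), c("outside", "far"))
  # oracle: direct scan for max|z| > 1
  set.seed(7)
  zr <- matrix(rnorm(200, 0, 0.8), 20, 10)
  keep2 <- filter_invariant_genes(zr)
  expect_equal(sort(unname(keep2)), which(apply(abs(zr), 2, max) > 1))
  expect_error(filter_invariant_genes(matrix(0.2, 3, 3)), "no features")
})

test_that("clinical preparation imputes and one-hot encodes with state", {
  df <- data.frame(num = c(1, 2, NA, 3),
                   cat = c("a", "b", NA, "a"),
                   stringsAsFactors = FALSE)
  prep <- prepare_clinical(df)
  expect_equal(prep$impute_values$num, 2)        # mean of observed
  expect_equal(prep$x[3, "num"], 2)
  expect_equal(prep$impute_values$cat, "a")      # mode
  expect_equal(unname(prep$x[3, c("cat=a", "cat=b")]), c(1, 0))
  # one column per level, exactly one 1 per patient
  expect_equal(unname(rowSums(prep$x[, c("cat=a", "cat=b")])), rep(1, 4))
})

test_that("a 12-level categorical becomes 12 binary columns", {
  levs <- paste0("type", sprintf("%02d", 1:12))
  df <- data.frame(hist = rep(levs, 2), stringsAsFactors = FALSE)
  prep <- prepare_clinical(df)
  expect_equal(ncol(prep$x), 12)
  expect_true(all(rowSums(prep$x) == 1))
})

test_that("clinical with no missing values is a plain encoding; all-missing errors", {
  df <- data.frame(a = c(1, 2), b = c("x", "y"), stringsAsFactors = FALSE)
  prep <- prepare_clinical(df)
  expect_equal(unname(prep$x[, "a"]), c(1, 2))
  expect_equal(unname(prep$x[, "b=x"]), c(1, 0))
  expect_error(prepare_clinical(data.frame(bad = c(NA_real_, NA_real_))), "bad")
})

test_that("one-hot rows sum to the number of categorical features", {
  df <- data.frame(c1 = c("a", "b", "a"), c2 = c("x", "y", "z"),
                   num = 1:3, stringsAsFactors = FALSE)
  prep <- prepare_clinical(df)
  onehot_cols <- grep("=", colnames(prep$x))
  expect_equal(unname(rowSums(prep$x[, onehot_cols])), rep(2, 3))
})

test_that("apply_preprocess replays the stored transform exactly", {
  set.seed(11)
  x <- matrix(rnorm(80, 8, 2), 8, 10,
              dimnames = list(paste0("p", 1:8), paste0("g", 1:10)))
  clin <- data.frame(age = c(50, NA, 60, 55, 70, 65, NA, 58),
                     grade = c("I", "II", NA, "I", "III", "II", "I", "III"),
                     stringsAsFactors = FALSE)
  st <- fit_preprocess(x, clin)
  re <- apply_preprocess(st, x, clin)
  # idempotence on training patients
  expect_equal(re$z, st$z)
  expect_equal(re$clinical_x, st$clinical_x)
  # stored training mean is used for new missing values, not the new cohort's
  newx <- x[1:2, ]
  newc <- data.frame(age = c(NA, 40), grade = c("II", "I"), stringsAsFactors = FALSE)
  out <- apply_preprocess(st, newx, newc)
  expect_equal(out$clinical_x[1, "age"], st$impute_values$age)
})

test_that("unseen categorical level maps to an all-zero block with a warning", {
  x <- matrix(rnorm(40, 8, 2), 4, 10,
              dimnames = list(paste0("p", 1:4), paste0("g", 1:10)))
  clin <- data.frame(grade = c("I", "II", "I", "II"), stringsAsFactors = FALSE)
  st <- fit_preprocess(x, clin)
  newc <- data.frame(grade = "IV", stringsAsFactors = FALSE)
  expect_warning(out <- apply_preprocess(st, x[1, , drop = FALSE], newc), "unseen")
  expect_equal(unname(out$clinical_x[1, ]), c(0, 0))
})

test_that("apply_preprocess validates the gene set", {
  x <- matrix(rnorm(40, 8, 2), 4, 10,
              dimnames = list(paste0("p", 1:4), paste0("g", 1:10)))
  st <- fit_preprocess(x)
  bad <- x
  colnames(bad)[1] <- "unknown_gene"
  expect_error(apply_preprocess(st, bad), "gene ID")
})

test_that("readers round-trip the delimited formats", {
  dir <- withr::local_tempdir()
  ch <- generate_cohort(simulation_config(n = 20, p = 10, signature_size = 3,
                                          doc_length = 10, seed = 4))
  paths <- write_cohort(ch, dir)
  expr <- read_expression(file.path(dir, "expression.tsv"))
  expect_equal(expr, ch$expression)
  # transposed orientation resolves via the flag
  t_path <- file.path(dir, "expression_t.tsv")
  tdf <- data.frame(gene_id = colnames(ch$expression), t(ch$expression),
                    check.names = FALSE)
  utils::write.table(tdf, t_path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(read_expression(t_path, transpose = TRUE), ch$expression)
  clin <- read_clinical(file.path(dir, "clinical.csv"),
                        file.path(dir, "clinical_schema.csv"))
  expect_equal(clin$types[["age"]], "numeric")
  expect_equal(clin$types[["sex"]], "categorical")
  lbl <- read_labels(file.path(dir, "labels.csv"))
  expect_equal(lbl$time, ch$labels$time)
  expect_equal(lbl$event, ch$labels$event)
})
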