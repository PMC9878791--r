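test_that("group labels parse, reject ambiguity, pass plain headers through", {
  expect_equal(parse_group_label("Acetone::NbReactions"),
               list(group = "Acetone", variable = "NbReactions"))
  expect_equal(parse_group_label("HotPlate50::Latency"),
               list(group = "HotPlate50", variable = "Latency"))
  expect_equal(parse_group_label("vonFrey"),
               list(group = NA_character_, variable = "vonFrey"))
  expect_error(parse_group_label("A::B::C"), "pd_ambiguous_header")
  expect_error(parse_group_label("::B"), "pd_ambiguous_header")
  expect_error(parse_group_label("A::"), "pd_ambiguous_header")
})

test_that("CSV round-trips through read/write with types, roles and groups", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,genotype,sex,HotPlate50::Latency,vonFrey,note",
               "m1,WT,F,3.2,1.1,ok",
               "m2,Het,M,4.1,NA,bad",
               "m3,WT,M,na,2.2,ok"), f)
  cfg <- pd_config(dependent = "genotype", id = "id", conditioning = "sex")
  tab <- read_pheno_table(f, cfg)
  expect_s3_class(tab, "pheno_table")
  expect_equal(nrow(tab$data), 3L)
  expect_equal(unname(tab$var_types[c("Latency", "vonFrey", "note")]),
               c("quantitative", "quantitative", "qualitative"))
  expect_equal(unname(tab$var_groups[["Latency"]]), "HotPlate50")
  expect_true(is.na(tab$data$vonFrey[2]))    # NA stays missing, never 0
  expect_true(is.na(tab$data$Latency[3]))    # lower-case "na" spelling
  expect_false(any(tab$imputed))

  out <- withr::local_tempfile(fileext = ".tsv")
  write_pheno_table(tab, out)
  tab2 <- read_pheno_table(out, pd_config(dependent = "genotype", id = "id",
                                          conditioning = "sex"))
  expect_equal(tab2$data, tab$data)
  expect_equal(tab2$var_groups, tab$var_groups)
  expect_equal(tab2$var_roles, tab$var_roles)
})

test_that("import errors are distinct and named", {
  cfg <- pd_config(dependent = "genotype")
  expect_error(read_pheno_table("no/such/file.csv", cfg), "pd_unreadable_file")

  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("a::x,b::x,genotype", "1,2,WT", "3,4,Het", "5,6,WT"), f)
  expect_error(read_pheno_table(f, cfg), "pd_duplicate_columns")

  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("a,b", "1,2", "3,4", "5,6"), f2)
  expect_error(read_pheno_table(f2, cfg), "pd_no_dependent")
})

test_that("type inference respects the 90% rule and overrides", {
  f <- withr::local_tempfile(fileext = ".csv")
  # 'mixed' is numeric-parseable in 8/10 cells (80% < 90%) -> qualitative
  writeLines(c("genotype,mixed,score",
               paste(rep(c("WT", "Het"), 5),
                     c(1:8, "x", "y"),
                     round(rnorm(10), 2), sep = ",")), f)
  tab <- read_pheno_table(f, pd_config(dependent = "genotype"))
  expect_equal(unname(tab$var_types[["mixed"]]), "qualitative")
  tab2 <- read_pheno_table(f, pd_config(
    dependent = "genotype",
    type_overrides = c(score = "qualitative")))
  expect_equal(unname(tab2$var_types[["score"]]), "qualitative")
})

test_that("anonymization is a unique bijection, idempotent, and flags true duplicates only", {
  tab <- tiny_table()
  tab$ids <- c("M1", "M1", rep(sprintf("X%02d", 3:12)))
  # rows 1 and 2 share the id but differ in genotype (WT vs Mut): not duplicates
  a <- anonymize_ids(tab, conditioning = c("genotype", "sex"))
  expect_false(anyDuplicated(a$ids) > 0)
  expect_equal(nrow(a$id_mapping), nrow(a$data))
  expect_false(any(a$id_mapping$duplicate_of_earlier_row))

  tab2 <- tiny_table()
  tab2$ids[2] <- tab2$ids[1]
  tab2$data$genotype[2] <- tab2$data$genotype[1]
  tab2$data$sex[2] <- tab2$data$sex[1]
  b <- anonymize_ids(tab2, conditioning = c("genotype", "sex"))
  expect_true(b$id_mapping$duplicate_of_earlier_row[2])
  expect_false(anyDuplicated(b$ids) > 0)

  # idempotence
  expect_equal(anonymize_ids(b, conditioning = c("genotype", "sex"))$ids, b$ids)
})

test_that("pheno_table invariants are enforced at construction", {
  d <- data.frame(genotype = c("WT", "WT", "WT"), x = c(1, 2, 3))
  roles <- c(genotype = "dependent", x = "predictor")
  types <- c(genotype = "qualitative", x = "quantitative")
  expect_error(pheno_table(d, c("a", "b", "c"), roles, types),
               "pd_degenerate_dependent")
  d$genotype <- c("WT", "Het", "WT")
  types["genotype"] <- "quantitative"
  expect_error(pheno_table(d, c("a", "b", "c"), roles, types),
               "pd_bad_dependent")
  roles["x"] <- "nonsense"
  expect_error(pheno_table(d, c("a", "b", "c"), roles,
                           c(genotype = "qualitative", x = "quantitative")),
               "pd_bad_roles")
})
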