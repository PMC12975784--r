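test_that("contemporary groups split on every component, sex except for TH", {
  rec <- make_records(4, trait = "FL", sex = c("M", "M", "F", "F"),
                      score = c(0, 1, 0, 1))
  asm <- assemble_contemporary_groups(rec, "FL")
  expect_equal(length(unique(asm$records$cg)), 2L)  # sex splits

  rec_th <- make_records(4, trait = "TH", sex = c("M", "M", "F", "F"),
                         score = c(0, 1, 0, 1))
  asm_th <- assemble_contemporary_groups(rec_th, "TH")
  expect_equal(length(unique(asm_th$records$cg)), 1L)  # sex ignored

  rec2 <- make_records(2, trait = "FL", farm = c(1L, 2L))
  expect_equal(length(unique(
    assemble_contemporary_groups(rec2, "FL")$records$cg)), 2L)
})

test_that("record filters drop exactly the offending groups and records", {
  # CG A: 9 animals (too small); CG B: 12 all-zero (no variability);
  # CG C: 12 with variability, one record out of the age window
  rec <- rbind(
    make_records(9, farm = rep(1L, 9), score = c(1, rep(0, 8)),
                 animal = paste0("a", 1:9)),
    make_records(12, farm = rep(2L, 12), score = rep(0, 12),
                 animal = paste0("b", 1:12)),
    make_records(12, farm = rep(3L, 12), score = c(rep(1, 2), rep(0, 10)),
                 age_days = c(rep(400L, 11), 700L),
                 animal = paste0("c", 1:12)))
  flt <- filter_records(rec, "FL")
  expect_equal(sort(flt$records$animal), sort(paste0("c", 1:11)))
  expect_equal(nrow(flt$exclusions), 22L)
  reasons <- table(flt$exclusions$reason)
  expect_equal(as.integer(reasons[["age outside yearling window"]]), 1L)
  expect_equal(
    as.integer(reasons[["contemporary group without phenotypic variability"]]),
    12L)
  # idempotence: filtering the surviving records changes nothing
  again <- filter_records(flt$records, "FL")
  expect_equal(again$records$animal, flt$records$animal)
  expect_equal(nrow(again$exclusions), 0L)
})

test_that("group-size filter re-checks after the age filter (fixpoint)", {
  # 10-member group that falls to 9 after one age exclusion must be dropped
  rec <- rbind(
    make_records(10, farm = rep(1L, 10), score = c(1, rep(0, 9)),
                 age_days = c(rep(400L, 9), 700L),
                 animal = paste0("a", 1:10)),
    make_records(12, farm = rep(2L, 12), score = c(1, rep(0, 11)),
                 animal = paste0("b", 1:12)))
  flt <- filter_records(rec, "FL")
  expect_equal(sort(flt$records$animal), sort(paste0("b", 1:12)))
})

test_that("TH records on females are rejected", {
  rec <- make_records(12, trait = "TH", sex = c(rep("M", 11), "F"),
                      score = c(1, rep(0, 11)))
  flt <- filter_records(rec, "TH")
  expect_equal(nrow(flt$records), 11L)
  expect_true("TH recorded on non-male" %in% flt$exclusions$reason)
})

test_that("everything filtered away is an error", {
  rec <- make_records(5, score = c(1, rep(0, 4)))
  expect_error(filter_records(rec, "FL"), "no records survive")
})

test_that("occurrence arithmetic reproduces printed-table percentages", {
  expect_equal(occurrence_pct(6263, 136842), 4.58)
  expect_equal(occurrence_pct(166, 8054), 2.06)
  expect_equal(occurrence_pct(3805, 87017), 4.37)
  expect_equal(occurrence_pct(0, 100), 0)
  expect_error(occurrence_pct(0, 0), "occurrence undefined")
})

test_that("occurrence summary counts are consistent", {
  rec <- rbind(make_records(40, score = c(rep(1, 3), rep(0, 37))),
               make_records(20, trait = "MO", score = c(1, rep(0, 19)),
                            animal = as.character(41:60)))
  occ <- occurrence_summary(rec)
  expect_equal(occ$trait, c("FL", "MO"))
  expect_equal(occ$n0 + occ$n1, occ$n)
  expect_equal(occ$occurrence, c(7.5, 5))
})

test_that("design matrices have the stated incidence structure", {
  df <- random_pedigree_frame(30, seed = 3)
  ped <- ped_table(df$animal, df$sire, df$dam)
  rec <- make_records(12, farm = rep(1:3, each = 4),
                      region = rep(1:2, 6),
                      score = rep(c(0, 1), 6),
                      animal = as.character(7:18))
  flt <- filter_records(rec, "FL", min_cg = 2)
  des <- build_design(flt$records, ped, reduce = "none")
  # one 1 per categorical factor per row: 3 CG + 2 region columns
  expect_equal(ncol(des$X), 5L)
  expect_equal(unname(Matrix::rowSums(des$X)), rep(2, nrow(flt$records)))
  expect_equal(unname(Matrix::rowSums(des$Z)), rep(1, nrow(flt$records)))
  # reduced coding keeps one intercept plus levels-1 per factor
  des2 <- build_design(flt$records, ped, reduce = "drop_first")
  expect_equal(ncol(des2$X), 1L + 2L + 1L)

  # yearling-weight covariate adds centered linear and quadratic columns
  rec$yearling_weight <- seq(250, 360, by = 10)
  flt2 <- filter_records(rec, "FL", min_cg = 2)
  des3 <- build_design(flt2$records, ped, yw_covariate = TRUE)
  expect_true(all(c("yw", "yw2") %in% des3$columns))
  expect_equal(sum(des3$X[, "yw"]), 0, tolerance = 1e-12)

  # phenotyped animal missing from pedigree is an error listing the id
  rec_bad <- make_records(12, farm = rep(1L, 12), score = rep(c(0, 1), 6),
                          animal = c(as.character(7:17), "zz"))
  flt_bad <- filter_records(rec_bad, "FL", min_cg = 2)
  expect_error(build_design(flt_bad$records, ped), "zz")
})
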