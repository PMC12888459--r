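test_that("sample-dialect CSV parses into a validated peak table", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("peak_id,s1,s2", "P1,1,2", "P2,3,4"), f)
  pt <- load_peak_table(f, dialect = "samples")
  expect_equal(unname(pt$areas), matrix(c(1, 3, 2, 4), 2))
  expect_equal(rownames(pt$areas), c("P1", "P2"))
  expect_equal(colnames(pt$areas), c("s1", "s2"))
})

test_that("group-mean dialect parses both cell encodings", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("peak_id,g1,g2", "P1,10 +/- 1,20 +/- 2", "P2,5 +/- 0.5,6 +/- 0"),
             f)
  pt <- load_peak_table(f, dialect = "group_means")
  expect_equal(unname(pt$areas[, "g2"]), c(20, 6))
  expect_equal(unname(pt$area_sd[, "g1"]), c(1, 0.5))

  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("peak_id,g1_mean,g1_sd,g2_mean,g2_sd",
               "P1,10,1,20,2", "P2,5,0.5,6,0"), f2)
  pt2 <- load_peak_table(f2, dialect = "group_means")
  expect_equal(pt2$areas, pt$areas)
  expect_equal(pt2$area_sd, pt$area_sd)
})

test_that("validation rejects duplicate ids, negatives and ragged rows", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("peak_id,s1,s2", "P1,1,2", "P1,3,4"), f)
  expect_error(load_peak_table(f), "duplicate peak id")

  expect_error(peak_table(matrix(c(1, -2, 3, 4), 2)), "negative")
  expect_error(peak_table(matrix(c(1, NA, 3, 4), 2)), "missing")

  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("peak_id,s1,s2", "P1,1,2", "P2,3"), f2)
  expect_error(load_peak_table(f2), "ragged")
})

test_that("peak tables and efficacy panels round-trip through CSV", {
  set.seed(7)
  areas <- matrix(rlnorm(40, 10, 1), 8,
                  dimnames = list(paste0("P", 1:8), paste0("s", 1:5)))
  pt <- peak_table(areas)
  f <- withr::local_tempfile(fileext = ".csv")
  write_peak_table(pt, f)
  back <- load_peak_table(f, dialect = "samples")
  expect_equal(back$areas, pt$areas, tolerance = 1e-12)

  gm <- peak_table(areas, area_sd = areas * 0.05)
  write_peak_table(gm, f)
  back2 <- load_peak_table(f, dialect = "group_means")
  expect_equal(back2$areas, gm$areas, tolerance = 1e-12)
  expect_equal(back2$area_sd, gm$area_sd, tolerance = 1e-12)

  ep <- efficacy_panel(matrix(rnorm(12) * 50, 4,
                              dimnames = list(paste0("G", 1:4),
                                              paste0("i", 1:3))))
  write_efficacy_panel(ep, f)
  expect_equal(load_efficacy_panel(f)$values, ep$values, tolerance = 1e-12)
})

test_that("standardization gives exact z-scores with the n-1 convention", {
  pt <- peak_table(rbind(P1 = c(1, 2, 3)))
  expect_equal(unname(standardize_peaks(pt)$areas[1, ]), c(-1, 0, 1))

  pt2 <- peak_table(rbind(P1 = c(2, 4, 4, 4, 5, 5, 7, 9)))
  z <- standardize_peaks(pt2)$areas
  expect_equal(z[1, 1], (2 - 5) / sqrt(32 / 7), tolerance = 1e-12,
               ignore_attr = TRUE)

  expect_warning(z3 <- standardize_peaks(
    peak_table(rbind(P1 = c(5, 5, 5), P2 = c(1, 2, 3)))), "constant")
  expect_equal(unname(z3$areas["P1", ]), c(0, 0, 0))

  expect_error(standardize_peaks(peak_table(rbind(P1 = 3))), "2 observations")
})

test_that("standardized rows have zero mean and unit sample sd", {
  set.seed(11)
  pt <- peak_table(matrix(rlnorm(200, 8, 1), 20))
  z <- standardize_peaks(pt)$areas
  expect_true(all(abs(rowMeans(z)) < 1e-12))
  expect_true(all(abs(apply(z, 1, sd) - 1) < 1e-12))
})

test_that("fixtures match the published tables cell by cell", {
  t3 <- load_fixture("table3")
  expect_equal(dim(t3$areas), c(57L, 4L))
  expect_equal(t3$areas["A11", "PW4"], 765815)
  expect_equal(t3$area_sd["A11", "PW4"], 23316)
  expect_equal(t3$areas["A1", "PW1"], 2998)
  expect_equal(t3$areas["A24", "PW4"], 8451971)
  expect_equal(t3$areas["A34", "PW1"], 2251622)
  expect_equal(t3$areas["B6", "PW3"], 524700)
  expect_equal(t3$areas["B17", "PW2"], 1193)
  expect_equal(t3$areas["B17", "PW1"], 0)
  expect_equal(t3$areas["A27", "PW2"], 53118)
  expect_equal(t3$areas["A40", "PW3"], 28551)
  expect_equal(t3$meta$rt[t3$meta$peak_id == "A11"], 17.226)
  expect_equal(t3$meta$herb[t3$meta$peak_id == "A24"], "SR")
  expect_equal(t3$meta$compound[t3$meta$peak_id == "A24"], "Baicalin")

  t6 <- load_fixture("table6")
  expect_equal(dim(t6$values), c(4L, 8L))
  expect_equal(t6$values["PW4", "Overall rating"], 51.46)
  expect_equal(t6$values["PW1", "W/D ratio of Lung"], 4.88)
  expect_equal(t6$values["PW2", "TNF-a"], 80.12)
  expect_equal(t6$values["PW3", "Lung injury score"], 53.49)
  expect_equal(t6$values["PW1", "IL-6"], 27.13)
  expect_equal(t6$values["PW4", "Neutrophils in BALF"], 75.00)
  expect_equal(t6$values["PW2", "Protein in BALF"], 32.39)
  expect_equal(t6$values["PW3", "IL-1b"], 51.57)
  expect_equal(t6$values["PW4", "IL-6"], 45.17)
  expect_equal(t6$values["PW1", "Overall rating"], 43.35)

  t8 <- load_fixture("table8")
  expect_length(t8$sets, 8L)
  expect_setequal(t8$sets[["Lung injury score"]],
                  c("A40", "A27", "A11", "B14", "B16"))
  expect_setequal(t8$sets[["Neutrophils in BALF"]],
                  c("A24", "A26", "A30", "A34", "A17", "B11"))
  expect_setequal(t8$sets[["Overall rating"]],
                  c("A11", "B16", "A27", "A1", "B17"))
  expect_setequal(t8$sets[["TNF-a"]], c("A7", "A32", "A18", "A6"))

  t9 <- load_fixture("table9")
  expect_equal(nrow(t9), 20L)
  expect_equal(t9$degree[t9$peak_id == "A27"], 5L)
  expect_equal(t9$betweenness[t9$peak_id == "A27"], 0.1878)
  expect_equal(t9$closeness[t9$peak_id == "A27"], 0.4531)
  expect_equal(t9$degree[t9$peak_id == "A24"], 2L)
  expect_equal(t9$closeness[t9$peak_id == "A18"], 0.4028)
  expect_equal(t9$betweenness[t9$peak_id == "B11"], 0.0611)
  expect_equal(t9$source[t9$peak_id == "A11"], "GF")

  hm <- load_fixture("herb_map")
  expect_equal(nrow(hm), 57L)
  expect_setequal(unique(hm$herb), c("SR", "GF"))

  w <- load_fixture("weights")
  expect_equal(sum(w$weights), 1, tolerance = 1e-9)
  expect_equal(unname(w$weights["Lung injury score"]), 0.3080,
               tolerance = 1e-9)

  expect_error(load_fixture("table99"), "unknown fixture")
})
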