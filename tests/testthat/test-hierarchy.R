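test_that("bundled default hierarchy has 6 domains and 33 coded indicators", {
  h <- default_hierarchy()
  expect_equal(nrow(h$domains), 6L)
  expect_equal(n_indicators(h), 33L)
  counts <- table(factor(h$indicators$domain_id, levels = h$domains$id))
  expect_equal(unname(as.integer(counts)), c(4L, 8L, 4L, 8L, 4L, 5L))
  # code prefix matches the domain's ordinal position
  prefix <- as.integer(sub("^W(\\d)\\..*$", "\\1", h$indicators$code))
  expect_equal(prefix, match(h$indicators$domain_id, h$domains$id))
  expect_true("W6.5" %in% h$indicators$code)
  # the shipped YAML config reproduces the in-code default exactly
  yml <- system.file("extdata", "hierarchy.yaml", package = "washpriority")
  expect_identical(load_hierarchy(yml), h)
})

test_that("hierarchy validation rejects malformed schemas and accepts a minimal one", {
  one <- load_hierarchy(
    "domains:\n- id: d1\n  label: only\n  indicators:\n  - {code: a, label: A}\n  - {code: b, label: B}\n")
  expect_s3_class(one, "hierarchy_spec")
  expect_equal(n_indicators(one), 2L)

  expect_error(
    hierarchy_spec(data.frame(id = c("d1", "d1"), label = c("x", "y")),
                   data.frame(code = c("a", "b", "c", "d"),
                              domain_id = "d1", label = "z")),
    "duplicate domain id")
  expect_error(
    hierarchy_spec(data.frame(id = "d1", label = "x"),
                   data.frame(code = c("a", "a"), domain_id = "d1",
                              label = "z")),
    "duplicate indicator code")
  expect_error(
    hierarchy_spec(data.frame(id = "d1", label = "x"),
                   data.frame(code = c("a", "b"),
                              domain_id = c("d1", "nope"), label = "z")),
    "unknown domain: nope")
  expect_error(
    hierarchy_spec(data.frame(id = c("d1", "d2"), label = "x"),
                   data.frame(code = c("a", "b"), domain_id = "d1",
                              label = "z")),
    "fewer than 2 indicators: d2")
})

test_that("comparison matrices enforce reciprocity, positivity and the Saaty scale", {
  expect_error(comparison_matrix(rbind(c(1, 3), c(0.5, 1)), c("a", "b")),
               "reciprocity violated")
  expect_error(comparison_matrix(rbind(c(1, -2), c(-0.5, 1)), c("a", "b")),
               "positive")
  expect_error(comparison_matrix(rbind(c(2, 3), c(1 / 3, 1)), c("a", "b")),
               "diagonal")
  expect_error(comparison_matrix(rbind(c(1, 2.5), c(0.4, 1)), c("a", "b"),
                                 raw = TRUE),
               "off the Saaty")
  # decimal renderings of scale reciprocals validate under raw
  v <- as.numeric(formatC(1 / 7, digits = 12, format = "g"))
  expect_s3_class(comparison_matrix(rbind(c(1, v), c(1 / v, 1)),
                                    c("a", "b"), raw = TRUE),
                  "comparison_matrix")
})

test_that("swing tables require a 100 anchor and strict positivity", {
  expect_error(swing_table("d", c(a = 90, b = 40)), "anchor missing")
  expect_error(swing_table("d", c(a = 100, b = 0)), "strictly positive")
  expect_error(swing_table("d", c(a = 100, b = 120)), "exceed")
  t <- swing_table("d", c(a = 100, b = 40))
  expect_equal(t$k, 2L)
})

test_that("judgment sets must cover all domains and use known group labels", {
  expect_error(tiny_judgment(group = "Visitors"), "unknown group")
  h <- tiny_hierarchy()
  m <- comparison_matrix(rbind(c(1, 3), c(1 / 3, 1)), c("d1", "d2"))
  expect_error(
    judgment_set("p1", "Regulators", m, list(swing_table("d1", c(W1.1 = 100, W1.2 = 50))), h),
    "cover every domain")
  expect_error(
    judgment_set("p1", "Regulators", m,
                 list(swing_table("d1", c(W1.1 = 100, W1.2 = 50)),
                      swing_table("d2", c(W2.1 = 100, W2.2 = 80))), h),
    "exactly its indicators")
})

test_that("judgment files round-trip losslessly", {
  path <- withr::local_tempfile(fileext = ".csv")
  h <- tiny_hierarchy()

  # empty cohort -> header-only file that reads back empty
  write_judgments(list(), path)
  expect_equal(length(readLines(path)), 1L)
  expect_equal(read_judgments(path, h), list())

  js <- list(tiny_judgment("p1"), tiny_judgment("p2", "Researchers", a12 = 5))
  write_judgments(js, path)
  back <- read_judgments(path, h)
  expect_equal(length(back), 2L)
  expect_equal(back, js, tolerance = 1e-12)

  # full synthetic 35-participant cohort (unsnapped -> free scale)
  cohort <- generate_cohort(cohort_config(seed = 11))
  write_judgments(cohort, path)
  back <- read_judgments(path, default_hierarchy(), scale = "free")
  expect_equal(back, cohort, tolerance = 1e-10)

  # property: arbitrary random valid judgment sets round-trip
  set.seed(99)
  for (rep in 1:10) {
    a12 <- sample(c(1:9, 1 / (2:9)), 1L)
    s2 <- c(W2.1 = 100, W2.2 = runif(1, 1, 100), W2.3 = runif(1, 1, 100))
    j <- list(tiny_judgment("px", "Practitioners", a12 = a12, s2 = s2))
    write_judgments(j, path)
    expect_equal(read_judgments(path, h), j, tolerance = 1e-10)
  }
})

test_that("judgment-file validation errors carry participant and location", {
  path <- withr::local_tempfile(fileext = ".csv")
  h <- tiny_hierarchy()
  hdr <- '"record","participant","group","item1","item2","value"'
  sw <- c('"SWING","p1","Regulators","d1","W1.1",100',
          '"SWING","p1","Regulators","d1","W1.2",50',
          '"SWING","p1","Regulators","d2","W2.1",100',
          '"SWING","p1","Regulators","d2","W2.2",80',
          '"SWING","p1","Regulators","d2","W2.3",40')

  # explicit non-reciprocal lower triangle: 3 * 0.5 != 1
  writeLines(c(hdr, '"PAIR","p1","Regulators","d1","d2",3',
               '"PAIR","p1","Regulators","d2","d1",0.5', sw), path)
  expect_error(read_judgments(path, h), "p1.*reciprocity")

  # missing comparison cell
  writeLines(c(hdr, sw), path)
  expect_error(read_judgments(path, h), "p1.*missing comparison")

  # off-scale raw entry rejected under saaty, accepted under free
  writeLines(c(hdr, '"PAIR","p1","Regulators","d1","d2",2.5', sw), path)
  expect_error(read_judgments(path, h, scale = "saaty"), "Saaty")
  expect_length(read_judgments(path, h, scale = "free"), 1L)

  # swing anchor of 90 rejected, named by participant
  writeLines(c(hdr, '"PAIR","p1","Regulators","d1","d2",3',
               sub(",100$", ",90", sw[1]), sw[-1]), path)
  expect_error(read_judgments(path, h), "p1.*anchor")
})
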