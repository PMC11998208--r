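# Data model and I/O for airway trees and per-segment measurement tables.

test_that("valid trees are constructed and invalid ones rejected", {
  tr <- make_tree(c("R", "A", "B"), c(NA, "R", "R"))
  expect_s3_class(tr, "airway_tree")
  expect_identical(tr$root_id, "R")
  expect_length(validate_tree(tr), 0)

  # two segments naming each other as parent: cycle (and no root)
  cyc <- make_tree(c("A", "B"), c("B", "A"), validate = FALSE)
  v <- validate_tree(cyc)
  expect_true(any(grepl("root", v)))

  # a cycle hanging off a rooted component is unreachable
  cyc2 <- make_tree(c("R", "A", "B"), c(NA, "B", "A"), validate = FALSE)
  expect_true(any(grepl("unreachable", validate_tree(cyc2))))

  # forest with two parentless segments
  forest <- make_tree(c("R1", "R2", "A"), c(NA, NA, "R1"), validate = FALSE)
  expect_true(any(grepl("multiple roots", validate_tree(forest))))

  # nonexistent parent names the offending segment
  orphan <- make_tree(c("R", "A"), c(NA, "ZZ"), validate = FALSE)
  expect_true(any(grepl("'A'.*nonexistent parent 'ZZ'", validate_tree(orphan))))

  # self-parenting
  selfp <- make_tree(c("R", "A"), c(NA, "A"), validate = FALSE)
  expect_true(any(grepl("own parent", validate_tree(selfp))))

  # nonpositive lumen
  badl <- make_tree(c("R", "A"), c(NA, "R"), lumen = c(100, -1),
                    validate = FALSE)
  expect_true(any(grepl("nonpositive lumen", validate_tree(badl))))

  expect_error(make_tree(c("A", "B"), c("B", "A")),
               class = "airway_integrity_error")
})

test_that("terminal segments are exactly the leaves", {
  expect_identical(terminal_segments(make_tree("R", NA)), "R")
  expect_setequal(terminal_segments(make_tree(c("R", "A", "B"), c(NA, "R", "R"))),
                  c("A", "B"))
  # monopodial caterpillar, trunk 10: ten laterals plus the trunk tip
  cat10 <- caterpillar_tree(10)
  expect_length(terminal_segments(cat10), 11)
  expect_true("TIP" %in% terminal_segments(cat10))
  # terminals + internals partition the tree
  term <- terminal_segments(cat10)
  expect_identical(length(term) + (nrow(cat10$segments) - length(term)),
                   nrow(cat10$segments))
  expect_error(terminal_segments(make_tree(c("A", "B"), c("B", "A"),
                                           validate = FALSE)),
               class = "airway_validation_error")
})

test_that("a minimal three-row table reads into one tree", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("subject_id,group,segment_id,parent_id,inner_diameter,outer_diameter",
               "S1,NOX,root,,200,240",
               "S1,NOX,childA,root,100,120",
               "S1,NOX,childB,root,90,110"), f)
  coh <- read_segment_table(f)
  expect_s3_class(coh, "airway_cohort")
  expect_length(coh, 1)
  expect_identical(nrow(coh$S1$segments), 3L)
  expect_identical(coh$S1$root_id, "root")
  expect_equal(coh$S1$segments$wall_thickness,
               c(20, 10, 10)[match(coh$S1$segments$segment_id,
                                   c("root", "childA", "childB"))])
})

test_that("multi-image rows are averaged during reading", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("subject_id,group,segment_id,parent_id,image_index,inner_diameter,outer_diameter",
               "S1,NOX,root,,1,20,30",
               "S1,NOX,root,,2,22,30",
               "S1,NOX,a,root,1,10,14"), f)
  coh <- read_segment_table(f)
  seg <- coh$S1$segments
  expect_equal(seg$lumen_diameter[seg$segment_id == "root"], 21)
  expect_equal(seg$wall_thickness[seg$segment_id == "root"], 4.5)
})

test_that("format, integrity and validation errors carry their classes", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("subject_id,group,segment_id", "S1,NOX,a"), f)
  expect_error(read_segment_table(f), "parent_id",
               class = "airway_format_error")

  writeLines(c("subject_id,group,segment_id,parent_id,inner_diameter,outer_diameter",
               "S1,NOX,a,,100,120",
               "S1,NOX,a,,100,120"), f)
  expect_error(read_segment_table(f), "duplicate",
               class = "airway_integrity_error")

  writeLines(c("subject_id,group,segment_id,parent_id,inner_diameter,outer_diameter",
               "S1,NOX,a,,-5,120"), f)
  expect_error(read_segment_table(f), "row 2",
               class = "airway_validation_error")

  writeLines(c("subject_id,group,segment_id,parent_id,inner_diameter,outer_diameter",
               "S1,NOX,a,,100,120",
               "S1,NOX,b,zz,50,60"), f)
  expect_error(read_segment_table(f), "'b'.*'zz'",
               class = "airway_integrity_error")
})

test_that("tab-separated input and dialect remapping are accepted", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("animal\tgrp\tid\tpid\tlumen\twall",
               "S1\tNOX\troot\t\t200\t20",
               "S1\tNOX\ta\troot\t100\t10"), f)
  coh <- read_segment_table(f, dialect = list(
    subject_id = "animal", group = "grp", segment_id = "id",
    parent_id = "pid", lumen_diameter = "lumen", wall_thickness = "wall"))
  expect_identical(nrow(coh$S1$segments), 2L)
  expect_equal(sort(coh$S1$segments$lumen_diameter), c(100, 200))
})

test_that("write-then-read round-trips a synthetic cohort exactly", {
  gen <- generate_cohort(synthetic_config(seed = 11))
  f <- withr::local_tempfile(fileext = ".csv")
  write_segment_table(gen$cohort, f)
  back <- read_segment_table(f)   # reader orders subjects alphabetically
  expect_setequal(names(back), names(gen$cohort))
  expect_identical(sort(unique(vapply(back, `[[`, "", "group"))),
                   c("HYX", "NOX"))
  for (sid in names(gen$cohort)) {
    a <- gen$cohort[[sid]]$segments
    b <- back[[sid]]$segments
    b <- b[match(a$segment_id, b$segment_id), ]
    expect_identical(a$parent_id, b$parent_id)
    expect_identical(a$lumen_diameter, b$lumen_diameter)  # full precision
    expect_identical(a$wall_thickness, b$wall_thickness)
    expect_identical(a$epithelium_height, b$epithelium_height)
    expect_identical(a$n_ciliated, b$n_ciliated)
  }
})

test_that("segment_table derives density and cell percentages", {
  gen <- generate_cohort(synthetic_config(seed = 5))
  tab <- segment_table(gen$cohort)
  expect_identical(nrow(tab), nrow(gen$truth))
  counted <- !is.na(tab$density) & tab$density > 0
  expect_true(any(counted))
  pc <- tab[counted, c("pct_ciliated", "pct_goblet", "pct_basal",
                       "pct_club", "pct_other")]
  expect_true(all(abs(rowSums(pc) - 100) < 1e-9))
  # zero-count profiles yield NA percentages, not NaN
  zero <- !is.na(tab$density) & tab$density == 0
  if (any(zero)) expect_true(all(is.na(tab$pct_ciliated[zero])))
})

test_that("JSON tree export nests children under parents", {
  tr <- make_tree(c("R", "A", "B"), c(NA, "R", "A"))
  js <- jsonlite::fromJSON(tree_to_json(tr), simplifyVector = FALSE)
  expect_identical(js$segment_id, "R")
  expect_identical(js$children[[1]]$segment_id, "A")
  expect_identical(js$children[[1]]$children[[1]]$segment_id, "B")
})
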