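test_that("load_registry enforces schema, window and value contracts", {
  f <- withr::local_tempfile(fileext = ".csv")

  write_mini_registry(f, character(0))
  expect_equal(nrow(suppressMessages(load_registry(f))), 0L)

  write_mini_registry(f, c(
    "A,male,,,,2005-03-01,true,true,mild,false",
    "B,female,,,,2003-12-31,true,false,,false",
    "C,female,,,,2013-12-31,yes,1,,0"
  ))
  reg <- suppressMessages(load_registry(f))
  expect_equal(reg$dog_id, c("A", "C"))
  expect_true(reg$distichiasis[1])
  expect_equal(reg$grade, c("mild", "ungraded"))

  write_mini_registry(f, c(
    "A,male,,,,2005-03-01,true,true,mild,false",
    "B,female,,,,2005-04-01,true,maybe,,false"
  ))
  expect_error(suppressMessages(load_registry(f)), "row 2")

  writeLines(c("dog_id,sex,exam_date", "A,male,2005-01-01"), f)
  expect_error(suppressMessages(load_registry(f)), "sire_id")
})

test_that("certificate filter keeps only valid certificates", {
  f <- withr::local_tempfile(fileext = ".csv")
  write_mini_registry(f, c(
    "A,male,,,,2005-03-01,false,true,,false",
    "B,male,,,,2005-03-01,true,true,,false"
  ))
  reg <- suppressMessages(load_registry(f))
  expect_equal(reg$dog_id, "B")
})

test_that("a single positive examination makes a dog affected, with worst grade kept", {
  f <- withr::local_tempfile(fileext = ".csv")
  write_mini_registry(f, c(
    "A,male,,,,2005-03-01,true,false,,false",
    "A,male,,,,2008-06-01,true,true,,false",
    "B,female,,,,2005-03-01,true,false,,false",
    "B,female,,,,2009-03-01,true,false,,false",
    "C,female,,,,2005-03-01,true,true,mild,false",
    "C,female,,,,2007-03-01,true,true,moderate,false"
  ))
  dogs <- resolve_dogs(suppressMessages(load_registry(f)))
  expect_equal(dogs$status[dogs$dog_id == "A"], "affected")
  expect_equal(dogs$grade[dogs$dog_id == "A"], "ungraded")
  expect_equal(dogs$status[dogs$dog_id == "B"], "unaffected")
  expect_equal(dogs$grade[dogs$dog_id == "B"], "none")
  expect_equal(dogs$grade[dogs$dog_id == "C"], "moderate")
  expect_equal(dogs$n_exams, c(2L, 2L, 2L))
})

test_that("conflicting sex entries are fatal and status never reverts on extra positives", {
  f <- withr::local_tempfile(fileext = ".csv")
  write_mini_registry(f, c(
    "A,male,,,,2005-03-01,true,false,,false",
    "A,female,,,,2006-03-01,true,false,,false"
  ))
  expect_error(resolve_dogs(suppressMessages(load_registry(f))), "conflicting sex")

  # property: appending a positive exam can only move status towards affected
  base <- data.frame(
    dog_id = "X", sex = "male", sire_id = NA_character_, dam_id = NA_character_,
    litter_id = NA_character_, exam_date = as.Date("2005-01-01"),
    certificate_valid = TRUE, distichiasis = FALSE, grade = "none",
    other_diagnosis = FALSE, stringsAsFactors = FALSE
  )
  pos <- base; pos$distichiasis <- TRUE; pos$grade <- "ungraded"
  for (k in 1:5) {
    exams <- rbind(base[rep(1, k), ], pos)
    expect_equal(resolve_dogs(exams)$status, "affected")
  }
})

test_that("trio cohort contains exactly the dogs with two examined parents", {
  dogs <- data.frame(
    dog_id = c("s", "d", "kid1", "kid2"),
    sex = c("male", "female", "male", "female"),
    sire_id = c(NA, NA, "s", "ghost"),
    dam_id = c(NA, NA, "d", "d"),
    litter_id = NA_character_,
    status = c("affected", "unaffected", "affected", "affected"),
    grade = "ungraded", other_diagnosis = FALSE, n_exams = 1L,
    stringsAsFactors = FALSE
  )
  dogs$grade[dogs$status == "unaffected"] <- "none"
  trio <- suppressMessages(build_trio_cohort(dogs))
  expect_equal(trio$members$dog_id, "kid1")
  expect_equal(trio$members$mating_class, "one_affected")
  expect_equal(trio$members$affected_parent_role, "sire")
  expect_equal(trio$n_excluded, 3L)

  # closure: dropping the sire record removes the member
  trio2 <- suppressMessages(build_trio_cohort(dogs[dogs$dog_id != "s", ]))
  expect_false("kid1" %in% trio2$members$dog_id)
})

test_that("reference cohort reproduces the published trio structure", {
  fx <- fixture_bundle()
  m <- fx$mating
  expect_equal(unname(m["both_affected", ]), c(105L, 52L))
  expect_equal(unname(m["one_affected", ]), c(106L, 123L))
  expect_equal(unname(m["neither_affected", ]), c(60L, 103L))
  expect_equal(sum(m), 549L)
  roles <- table(fx$trio$members$affected_parent_role[
    fx$trio$members$mating_class == "one_affected"])
  expect_equal(as.integer(roles[c("sire", "dam")]), c(111L, 118L))
  # partition invariant
  expect_equal(sum(fx$dogs$status == "affected") + sum(fx$dogs$status == "unaffected"),
               nrow(fx$dogs))
})

test_that("sire limit is 25 percent of average yearly registrations", {
  expect_equal(sire_limit(420), 105L)
  expect_equal(sire_limit(4), 1L)
  expect_error(sire_limit(0))
})

test_that("sire summaries aggregate offspring, litters and limit exceedance", {
  sr <- reference_sire_registry()
  dogs <- resolve_dogs(sr)
  ss <- summarize_sires(dogs, 105)
  g <- ss$groups[order(ss$groups$status), ]
  expect_equal(round(g$mean_offspring[g$status == "unaffected"], 1), 40.2)
  expect_equal(round(g$mean_offspring[g$status == "affected"], 1), 49.2)
  expect_equal(g$total_offspring, c(2708L, 3820L))
  expect_equal(g$total_litters, c(509L, 756L))
  expect_equal(g$n_exceeding, c(6L, 4L))
  exc <- ss$sires$excess[ss$sires$exceeds_limit]
  expect_equal(mean(exc), 35.4)
  expect_equal(range(exc), c(5L, 69L))

  one <- data.frame(dog_id = c("S", sprintf("o%d", 1:106)),
                    sex = "male", sire_id = c(NA, rep("S", 106)),
                    dam_id = NA_character_, litter_id = c(NA, rep("L1", 106)),
                    status = "unaffected", grade = "none",
                    other_diagnosis = FALSE, n_exams = 1L,
                    stringsAsFactors = FALSE)
  s1 <- summarize_sires(one, 105)
  expect_true(s1$sires$exceeds_limit)
  expect_equal(s1$sires$excess, 1L)
})

test_that("a resolved cohort round-trips through TSV unchanged", {
  fx <- fixture_bundle()
  f <- withr::local_tempfile(fileext = ".tsv")
  write_cohort(fx$dogs, f)
  back <- read_cohort(f)
  cols <- c("dog_id", "sex", "sire_id", "dam_id", "litter_id", "status",
            "grade", "other_diagnosis", "n_exams")
  expect_identical(back[, cols], fx$dogs[, cols])
})
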