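# Registry I/O and per-dog phenotype resolution.
#
# A registry is a flat CSV with one row per eye examination:
#   dog_id, sex, sire_id, dam_id, litter_id, exam_date, certificate_valid,
#   distichiasis, grade, other_diagnosis
# Dogs may be examined several times; a dog counts as affected if any single
# examination records the trait.

REGISTRY_COLUMNS <- c("dog_id", "sex", "sire_id", "dam_id", "litter_id",
                      "exam_date", "certificate_valid", "distichiasis",
                      "grade", "other_diagnosis")

GRADE_LEVELS <- c("none", "ungraded", "mild", "moderate", "severe")

# Booleans accepted in registry files (case-insensitive).
.parse_flag <- function(x, column) {
  x0 <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(x0))
  out[x0 %in% c("1", "true", "yes")] <- TRUE
  out[x0 %in% c("0", "false", "no")] <- FALSE
  bad <- which(is.na(out) & !(is.na(x) | x0 == "" | x0 == "na"))
  if (length(bad)) {
    stop(sprintf("column '%s': unparseable boolean %s at row %d",
                 column, dQuote(x[bad[1]]), bad[1]), call. = FALSE)
  }
  out
}

.parse_date <- function(x, column) {
  d <- as.Date(as.character(x), format = "%Y-%m-%d")
  bad <- which(is.na(d) & !(is.na(x) | trimws(x) == ""))
  if (length(bad)) {
    stop(sprintf("column '%s': unparseable ISO date %s at row %d",
                 column, dQuote(x[bad[1]]), bad[1]), call. = FALSE)
  }
  d
}

.na_id <- function(x) {
  x <- trimws(as.character(x))
  x[x == "" | toupper(x) == "NA"] <- NA_character_
  x
}

#' Load an examination registry
#'
#' Reads a registry CSV and keeps the examinations that carry a valid
#' certificate and fall inside the study window.  The window is closed on
#' both ends; input order is preserved.
#'
#' @param path Path to a comma-separated registry file with a header row and
#'   columns `dog_id, sex, sire_id, dam_id, litter_id, exam_date,
#'   certificate_valid, distichiasis, grade, other_diagnosis`.
#' @param window Length-2 vector coercible to `Date`: the closed inclusion
#'   window for examination dates.  Defaults to the ten calendar years
#'   2004--2013.
#' @return A `data.frame` of examination records (one row per retained
#'   examination) with typed columns; grades are normalised to
#'   `none/ungraded/mild/moderate/severe`.
#' @export
load_registry <- function(path, window = c("2004-01-01", "2013-12-31")) {
  if (!file.exists(path)) stop("registry file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         fileEncoding = "UTF-8")
  missing_cols <- setdiff(REGISTRY_COLUMNS, names(raw))
  if (length(missing_cols)) {
    stop("registry is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  window <- as.Date(window)
  stopifnot(length(window) == 2L, !anyNA(window))

  n_raw <- nrow(raw)
  exams <- data.frame(
    dog_id = .na_id(raw$dog_id),
    sex = .normalise_sex(raw$sex),
    sire_id = .na_id(raw$sire_id),
    dam_id = .na_id(raw$dam_id),
    litter_id = .na_id(raw$litter_id),
    exam_date = .parse_date(raw$exam_date, "exam_date"),
    certificate_valid = .parse_flag(raw$certificate_valid, "certificate_valid"),
    distichiasis = .parse_flag(raw$distichiasis, "distichiasis"),
    grade = .normalise_grade(raw$grade, raw$distichiasis),
    other_diagnosis = .parse_flag(raw$other_diagnosis, "other_diagnosis"),
    stringsAsFactors = FALSE
  )
  if (anyNA(exams$dog_id)) stop("registry contains rows without a dog_id", call. = FALSE)
  if (anyNA(exams$distichiasis)) {
    stop(sprintf("column 'distichiasis': missing value at row %d",
                 which(is.na(exams$distichiasis))[1]), call. = FALSE)
  }

  keep <- !is.na(exams$certificate_valid) & exams$certificate_valid &
    !is.na(exams$exam_date) &
    exams$exam_date >= window[1] & exams$exam_date <= window[2]
  out <- exams[keep, , drop = FALSE]
  rownames(out) <- NULL
  message(sprintf("load_registry: %d rows read, %d retained (%d without valid certificate or outside [%s, %s])",
                  n_raw, nrow(out), n_raw - nrow(out), window[1], window[2]))
  out
}

.normalise_sex <- function(x) {
  x0 <- tolower(trimws(as.character(x)))
  out <- rep("unknown", length(x0))
  out[x0 %in% c("m", "male")] <- "male"
  out[x0 %in% c("f", "female", "bitch")] <- "female"
  out
}

.normalise_grade <- function(grade, distichiasis) {
  g <- tolower(trimws(as.character(grade)))
  pos <- .parse_flag(distichiasis, "distichiasis")
  g[is.na(g) | g == "" | g == "na"] <- ifelse(pos[is.na(g) | g == "" | g == "na"] %in% TRUE,
                                              "ungraded", "none")
  bad <- which(!g %in% GRADE_LEVELS)
  if (length(bad)) {
    stop(sprintf("column 'grade': unknown grade %s at row %d",
                 dQuote(g[bad[1]]), bad[1]), call. = FALSE)
  }
  conflict <- which(g %in% c("mild", "moderate", "severe") & !(pos %in% TRUE))
  if (length(conflict)) {
    stop(sprintf("row %d: severity grade recorded for an examination without a positive diagnosis",
                 conflict[1]), call. = FALSE)
  }
  g
}

#' Resolve per-dog records from repeated examinations
#'
#' Collapses examination rows to one record per dog.  A dog is affected if
#' at least one examination was positive; the recorded grade is the worst
#' over all examinations (severity order `none < ungraded < mild < moderate
#' < severe`, so a positive examination that was never graded stays
#' `ungraded`).  Sex and pedigree links are taken from the examination rows
#' themselves unless a separate pedigree table is supplied.
#'
#' @param exams Examination records as returned by [load_registry()].
#' @param pedigree Optional `data.frame` with columns `dog_id`, `sex`, and
#'   optionally `sire_id`, `dam_id`, `litter_id`, overriding the pedigree
#'   fields carried on the examination rows.  Dogs absent from the table are
#'   kept with `sex = "unknown"` and a warning.
#' @return A `data.frame` with one row per dog: `dog_id`, `sex`, `sire_id`,
#'   `dam_id`, `litter_id`, `status` (`affected`/`unaffected`), `grade`,
#'   `other_diagnosis`, `n_exams`.
#' @export
resolve_dogs <- function(exams, pedigree = NULL) {
  stopifnot(is.data.frame(exams), nrow(exams) > 0L)
  id <- exams$dog_id
  if (!anyDuplicated(id)) {
    # one examination per dog: no aggregation needed
    dogs <- data.frame(
      dog_id = id,
      sex = exams$sex,
      sire_id = exams$sire_id,
      dam_id = exams$dam_id,
      litter_id = exams$litter_id,
      status = ifelse(exams$distichiasis, "affected", "unaffected"),
      grade = exams$grade,
      other_diagnosis = exams$other_diagnosis %in% TRUE,
      n_exams = 1L,
      stringsAsFactors = FALSE
    )
    return(.apply_pedigree(dogs, pedigree))
  }
  first <- !duplicated(id)
  ord_ids <- id[first]
  idx <- match(id, ord_ids)

  # conflicting sex entries across a dog's rows are fatal; 'unknown' yields
  sex_known <- ifelse(exams$sex == "unknown", NA_character_, exams$sex)
  n_sex <- tapply(sex_known, idx, function(s) length(unique(s[!is.na(s)])))
  if (any(n_sex > 1L)) {
    stop("conflicting sex entries for dog(s): ",
         paste(utils::head(ord_ids[which(n_sex > 1L)], 3L), collapse = ", "),
         call. = FALSE)
  }
  pick_first <- function(x) {
    x <- x[!is.na(x)]
    if (length(x)) x[1] else NA_character_
  }
  sex <- as.character(tapply(sex_known, idx, pick_first))
  sex[is.na(sex)] <- "unknown"
  sire <- as.character(tapply(exams$sire_id, idx, pick_first))
  dam <- as.character(tapply(exams$dam_id, idx, pick_first))
  litter <- as.character(tapply(exams$litter_id, idx, pick_first))

  affected <- as.logical(tapply(exams$distichiasis, idx, any))
  grade_rank <- match(exams$grade, GRADE_LEVELS)
  worst <- GRADE_LEVELS[as.integer(tapply(grade_rank, idx, max))]
  other <- as.logical(tapply(exams$other_diagnosis %in% TRUE, idx, any))
  n_exams <- as.integer(tabulate(idx, nbins = length(ord_ids)))

  dogs <- data.frame(
    dog_id = ord_ids,
    sex = sex,
    sire_id = sire,
    dam_id = dam,
    litter_id = litter,
    status = ifelse(affected, "affected", "unaffected"),
    grade = worst,
    other_diagnosis = other,
    n_exams = n_exams,
    stringsAsFactors = FALSE
  )

  .apply_pedigree(dogs, pedigree)
}

.apply_pedigree <- function(dogs, pedigree) {
  if (!is.null(pedigree)) {
    stopifnot(is.data.frame(pedigree), all(c("dog_id", "sex") %in% names(pedigree)))
    dup_sex <- tapply(pedigree$sex, pedigree$dog_id,
                      function(s) length(unique(.normalise_sex(s))))
    if (any(dup_sex > 1L)) stop("conflicting sex entries in pedigree table", call. = FALSE)
    m <- match(dogs$dog_id, pedigree$dog_id)
    absent <- sum(is.na(m))
    if (absent > 0L) {
      warning(sprintf("%d examined dog(s) absent from pedigree table; kept with sex = unknown", absent))
    }
    dogs$sex <- ifelse(is.na(m), "unknown", .normalise_sex(pedigree$sex[m]))
    for (col in c("sire_id", "dam_id", "litter_id")) {
      if (col %in% names(pedigree)) {
        dogs[[col]] <- ifelse(is.na(m), dogs[[col]], .na_id(pedigree[[col]][m]))
      }
    }
  }
  rownames(dogs) <- NULL
  dogs
}

#' Build the trio cohort
#'
#' Restricts a resolved cohort to the dogs whose sire and dam both have a
#' resolved record in the same cohort (i.e. both parents hold a valid
#' certificate), and classifies each member by parental mating type.
#'
#' @param dogs Resolved dog records from [resolve_dogs()].
#' @return An object of class `trio_cohort`: a list with `members` (the dog
#'   records plus `mating_class` in `both_affected/one_affected/
#'   neither_affected` and `affected_parent_role` in `sire/dam/both/none`)
#'   and `n_excluded`, the number of dogs dropped for lack of two examined
#'   parents.
#' @export
build_trio_cohort <- function(dogs) {
  stopifnot(is.data.frame(dogs))
  si <- match(dogs$sire_id, dogs$dog_id)
  di <- match(dogs$dam_id, dogs$dog_id)
  keep <- !is.na(si) & !is.na(di)
  members <- dogs[keep, , drop = FALSE]
  sire_aff <- dogs$status[si[keep]] == "affected"
  dam_aff <- dogs$status[di[keep]] == "affected"
  members$mating_class <- ifelse(sire_aff & dam_aff, "both_affected",
                          ifelse(!sire_aff & !dam_aff, "neither_affected",
                                 "one_affected"))
  members$affected_parent_role <- ifelse(sire_aff & dam_aff, "both",
                                  ifelse(sire_aff, "sire",
                                  ifelse(dam_aff, "dam", "none")))
  rownames(members) <- NULL
  message(sprintf("build_trio_cohort: %d of %d dogs have both parents examined (%d excluded)",
                  nrow(members), nrow(dogs), nrow(dogs) - nrow(members)))
  structure(list(members = members, n_excluded = nrow(dogs) - nrow(members)),
            class = "trio_cohort")
}

#' @export
print.trio_cohort <- function(x, ...) {
  cat("Trio cohort:", nrow(x$members), "offspring with both parents examined\n")
  print(table(x$members$mating_class, x$members$status))
  invisible(x)
}

#' Recommended offspring limit per sire
#'
#' The kennel-club recommendation caps each sire at 25 % of the breed's
#' average yearly number of registrations.
#'
#' @param avg_yearly_registrations Positive number of registrations per year.
#' @return Integer limit, `floor(0.25 * avg_yearly_registrations)`.
#' @export
sire_limit <- function(avg_yearly_registrations) {
  if (!is.numeric(avg_yearly_registrations) || length(avg_yearly_registrations) != 1L ||
      is.na(avg_yearly_registrations) || avg_yearly_registrations <= 0) {
    stop("avg_yearly_registrations must be a single positive number", call. = FALSE)
  }
  as.integer(floor(0.25 * avg_yearly_registrations))
}

#' Summarize sire usage
#'
#' Counts offspring and litters per sire and flags sires exceeding the
#' recommended limit, with aggregates by sire affection status.
#'
#' @param dogs Resolved dog records; rows whose `sire_id` is non-missing are
#'   counted as offspring, and sires are looked up among the same records
#'   for their affection status (status `unknown` when the sire has no
#'   record of its own).
#' @param limit Offspring limit per sire, e.g. from [sire_limit()].
#' @return An object of class `sire_summary`: `sires`, a per-sire
#'   `data.frame` (`sire_id`, `status`, `n_offspring`, `n_litters`, `limit`,
#'   `exceeds_limit`, `excess`), and `groups`, aggregates per status group
#'   (totals, mean offspring per sire, litters, number exceeding, mean
#'   excess among exceeders).
#' @export
summarize_sires <- function(dogs, limit) {
  stopifnot(is.data.frame(dogs), is.numeric(limit), limit > 0)
  off <- dogs[!is.na(dogs$sire_id), , drop = FALSE]
  if (!nrow(off)) stop("no offspring with a recorded sire", call. = FALSE)
  have_litter <- !all(is.na(off$litter_id))
  if (!have_litter) warning("litter_id absent; litter counts omitted")

  n_off <- table(off$sire_id)
  sire_ids <- names(n_off)
  n_lit <- if (have_litter) {
    tapply(off$litter_id, off$sire_id, function(l) length(unique(l[!is.na(l)])))[sire_ids]
  } else rep(NA_integer_, length(sire_ids))
  st <- dogs$status[match(sire_ids, dogs$dog_id)]
  st[is.na(st)] <- "unknown"

  sires <- data.frame(
    sire_id = sire_ids,
    status = st,
    n_offspring = as.integer(n_off),
    n_litters = as.integer(n_lit),
    limit = as.integer(limit),
    stringsAsFactors = FALSE
  )
  sires$exceeds_limit <- sires$n_offspring > sires$limit
  sires$excess <- pmax(0L, sires$n_offspring - sires$limit)
  rownames(sires) <- NULL

  agg <- function(sub) {
    exc <- sub$excess[sub$exceeds_limit]
    data.frame(
      status = sub$status[1],
      n_sires = nrow(sub),
      total_offspring = sum(sub$n_offspring),
      total_litters = if (have_litter) sum(sub$n_litters) else NA_integer_,
      mean_offspring = sum(sub$n_offspring) / nrow(sub),
      n_exceeding = sum(sub$exceeds_limit),
      mean_excess = if (length(exc)) mean(exc) else 0,
      stringsAsFactors = FALSE
    )
  }
  groups <- do.call(rbind, lapply(split(sires, sires$status), agg))
  rownames(groups) <- NULL
  structure(list(sires = sires, groups = groups, limit = as.integer(limit)),
            class = "sire_summary")
}

#' @export
print.sire_summary <- function(x, ...) {
  cat("Sire usage (offspring limit ", x$limit, "):\n", sep = "")
  g <- x$groups
  g$mean_offspring <- round(g$mean_offspring, 1)
  g$mean_excess <- round(g$mean_excess, 1)
  print(g, row.names = FALSE)
  invisible(x)
}

#' Write / read a resolved cohort as TSV
#'
#' Stable column order, ISO dates, integer counts; `read_cohort()` is the
#' exact inverse so a cohort round-trips identically.
#'
#' @param dogs Resolved dog records.
#' @param path Output file path.
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()`
#'   returns the dog `data.frame`.
#' @export
write_cohort <- function(dogs, path) {
  cols <- c("dog_id", "sex", "sire_id", "dam_id", "litter_id", "status",
            "grade", "other_diagnosis", "n_exams")
  stopifnot(all(cols %in% names(dogs)))
  utils::write.table(dogs[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  d <- utils::read.delim(path, colClasses = "character", na.strings = "NA",
                         fileEncoding = "UTF-8")
  d$other_diagnosis <- as.logical(d$other_diagnosis)
  d$n_exams <- as.integer(d$n_exams)
  d
}
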