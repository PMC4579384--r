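# Contingency-table statistics: prevalence, sex association, the 2x3
# omnibus test over parental mating types, pairwise 2x2 tests with Yates
# continuity correction, relative risks and continuity-corrected Wald
# intervals for the risk difference.  Rows of a 2x2 table are groups,
# columns are outcome (affected, unaffected).

#' 2x2 contingency table
#'
#' @param a,b First group: affected, unaffected counts.
#' @param c,d Second group: affected, unaffected counts.
#' @return A 2x2 integer matrix of class `contingency_2x2` with outcome
#'   columns `affected`/`unaffected`.
#' @export
contingency_2x2 <- function(a, b, c, d) {
  cnt <- c(a, b, c, d)
  if (any(!is.finite(cnt)) || any(cnt < 0) || any(cnt != round(cnt))) {
    stop("cell counts must be nonnegative integers", call. = FALSE)
  }
  m <- matrix(as.integer(cnt), nrow = 2, byrow = TRUE,
              dimnames = list(group = c("group1", "group2"),
                              outcome = c("affected", "unaffected")))
  class(m) <- c("contingency_2x2", class(m))
  m
}

.check_margins <- function(m) {
  rs <- rowSums(m); cs <- colSums(m)
  if (any(rs == 0)) stop("zero row margin: ", rownames(m)[rs == 0][1], call. = FALSE)
  if (any(cs == 0)) stop("zero column margin: ", colnames(m)[cs == 0][1], call. = FALSE)
  invisible(m)
}

#' Chi-square test on a 2x2 table
#'
#' With `continuity = TRUE` (the default) the Yates-corrected statistic
#' `n * (max(0, |ad - bc| - n/2))^2 / (r1 r2 c1 c2)` is used; the `max(0,.)`
#' clamp guards against over-correction on near-proportional tables.
#'
#' @param t A `contingency_2x2` or any 2x2 count matrix.
#' @param continuity Apply the continuity correction (default `TRUE`).
#' @return An object of class `association_result` with fields `statistic`,
#'   `df`, `p_value`, `corrected` and the input `table`.
#' @export
chi2_2x2 <- function(t, continuity = TRUE) {
  m <- .as_2x2(t)
  .check_margins(m)
  a <- m[1, 1]; b <- m[1, 2]; c <- m[2, 1]; d <- m[2, 2]
  n <- sum(m)
  cross <- abs(a * d - b * c)
  if (continuity) cross <- max(0, cross - n / 2)
  stat <- n * cross^2 / (prod(rowSums(m)) * prod(colSums(m)))
  association_result(stat, df = 1L, corrected = continuity, table = m)
}

.as_2x2 <- function(t) {
  m <- unclass(as.matrix(t))
  if (!all(dim(m) == c(2L, 2L))) stop("a 2x2 table is required", call. = FALSE)
  storage.mode(m) <- "double"
  m
}

association_result <- function(statistic, df, corrected, table = NULL,
                               rr = NULL, rd_ci = NULL) {
  structure(list(statistic = statistic, df = as.integer(df),
                 p_value = stats::pchisq(statistic, df, lower.tail = FALSE),
                 corrected = isTRUE(corrected), table = table,
                 rr = rr, rd_ci = rd_ci),
            class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf("chi-square = %.4f (df = %d%s), p = %.4g\n", x$statistic, x$df,
              if (x$corrected) ", continuity-corrected" else "", x$p_value))
  if (!is.null(x$rr)) cat(sprintf("relative risk = %.2f\n", x$rr))
  if (!is.null(x$rd_ci)) {
    cat(sprintf("risk difference 95%% CI = [%.2f, %.2f]\n",
                x$rd_ci[1], x$rd_ci[2]))
  }
  invisible(x)
}

#' Trait prevalence in a cohort
#'
#' @param dogs Resolved dog records (or a `trio_cohort`).
#' @return List with `n_affected`, `n_total`, `proportion` and `percent`
#'   (rounded to 2 decimals).
#' @export
prevalence <- function(dogs) {
  if (inherits(dogs, "trio_cohort")) dogs <- dogs$members
  stopifnot(is.data.frame(dogs))
  if (!nrow(dogs)) stop("empty cohort", call. = FALSE)
  k <- sum(dogs$status == "affected")
  n <- nrow(dogs)
  list(n_affected = k, n_total = n, proportion = k / n,
       percent = round(100 * k / n, 2))
}

#' Sex association of the trait
#'
#' Continuity-corrected chi-square on the sex-by-status 2x2 table; dogs of
#' unknown sex are excluded (their number is reported in a message).
#'
#' @param dogs Resolved dog records.
#' @param continuity Apply the Yates correction (default `TRUE`).
#' @return An `association_result`; its `table` rows are male, female.
#' @export
sex_association <- function(dogs, continuity = TRUE) {
  stopifnot(is.data.frame(dogs))
  known <- dogs[dogs$sex %in% c("male", "female"), , drop = FALSE]
  n_unknown <- nrow(dogs) - nrow(known)
  if (n_unknown > 0) message(sprintf("sex_association: %d dog(s) of unknown sex excluded", n_unknown))
  if (!all(c("male", "female") %in% known$sex)) {
    stop("both sexes must be represented", call. = FALSE)
  }
  t <- contingency_2x2(
    sum(known$sex == "male" & known$status == "affected"),
    sum(known$sex == "male" & known$status == "unaffected"),
    sum(known$sex == "female" & known$status == "affected"),
    sum(known$sex == "female" & known$status == "unaffected")
  )
  dimnames(t)[[1]] <- c("male", "female")
  chi2_2x2(t, continuity = continuity)
}

#' Mating-type count table
#'
#' Tabulates affected/unaffected offspring by parental mating class from a
#' trio cohort.
#'
#' @param trio A `trio_cohort` from [build_trio_cohort()].
#' @return A 3x2 integer matrix of class `mating_type_table` with rows
#'   `both_affected`, `one_affected`, `neither_affected` and columns
#'   `affected`, `unaffected`.
#' @export
mating_type_table <- function(trio) {
  members <- if (inherits(trio, "trio_cohort")) trio$members else trio
  stopifnot(is.data.frame(members),
            all(c("mating_class", "status") %in% names(members)))
  classes <- c("both_affected", "one_affected", "neither_affected")
  m <- matrix(0L, nrow = 3, ncol = 2,
              dimnames = list(mating_class = classes,
                              outcome = c("affected", "unaffected")))
  for (cl in classes) {
    sub <- members[members$mating_class == cl, , drop = FALSE]
    m[cl, "affected"] <- sum(sub$status == "affected")
    m[cl, "unaffected"] <- sum(sub$status == "unaffected")
  }
  class(m) <- c("mating_type_table", class(m))
  m
}

.class_pair_table <- function(m, first, second) {
  t <- contingency_2x2(m[first, "affected"], m[first, "unaffected"],
                       m[second, "affected"], m[second, "unaffected"])
  dimnames(t)[[1]] <- c(first, second)
  t
}

#' Omnibus association of mating type with offspring status
#'
#' Pearson chi-square on the full 2x3 table (no continuity correction),
#' df = 2.
#'
#' @param m A `mating_type_table` (or any 3x2 count matrix).
#' @return An `association_result`.
#' @export
omnibus_association <- function(m) {
  m <- unclass(as.matrix(m))
  stopifnot(nrow(m) == 3L, ncol(m) == 2L)
  if (any(rowSums(m) == 0)) stop("empty mating class", call. = FALSE)
  if (any(colSums(m) == 0)) stop("empty outcome column", call. = FALSE)
  e <- outer(rowSums(m), colSums(m)) / sum(m)
  stat <- sum((m - e)^2 / e)
  association_result(stat, df = 2L, corrected = FALSE, table = m)
}

#' Relative risk from a 2x2 table
#'
#' Risk of the first group divided by risk of the second,
#' `(a/(a+b)) / (c/(c+d))`.
#'
#' @param t A `contingency_2x2` or 2x2 count matrix.
#' @return List with `rr` (full precision), `rr_rounded` (1 decimal) and the
#'   two group risks.
#' @export
relative_risk <- function(t) {
  m <- .as_2x2(t)
  n1 <- sum(m[1, ]); n2 <- sum(m[2, ])
  if (n1 == 0 || n2 == 0) stop("empty group", call. = FALSE)
  p1 <- m[1, 1] / n1; p2 <- m[2, 1] / n2
  if (p2 == 0) stop("reference-group risk is zero; relative risk undefined", call. = FALSE)
  list(rr = p1 / p2, rr_rounded = round(p1 / p2, 1), risk1 = p1, risk2 = p2)
}

#' Confidence interval for the risk difference
#'
#' Wald interval for `p1 - p2` with a continuity correction that widens the
#' half-width by `(1/n1 + 1/n2)/2` (default on), matching the corrected
#' chi-square test.
#'
#' @param t A `contingency_2x2` or 2x2 count matrix.
#' @param level Confidence level in (0, 1); default 0.95.
#' @param continuity Apply the continuity correction (default `TRUE`).
#' @return List with `estimate`, `lower`, `upper` (full precision) and
#'   `rounded` (2 decimals).
#' @export
risk_difference_ci <- function(t, level = 0.95, continuity = TRUE) {
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level >= 1) {
    stop("level must be in (0, 1)", call. = FALSE)
  }
  m <- .as_2x2(t)
  n1 <- sum(m[1, ]); n2 <- sum(m[2, ])
  if (n1 == 0 || n2 == 0) stop("empty group", call. = FALSE)
  p1 <- m[1, 1] / n1; p2 <- m[2, 1] / n2
  z <- stats::qnorm(1 - (1 - level) / 2)
  hw <- z * sqrt(p1 * (1 - p1) / n1 + p2 * (1 - p2) / n2)
  if (continuity) hw <- hw + (1 / n1 + 1 / n2) / 2
  est <- p1 - p2
  list(estimate = est, lower = est - hw, upper = est + hw,
       rounded = round(c(est - hw, est + hw), 2))
}

#' Pairwise mating-type comparisons
#'
#' Reproduces the three pairwise contrasts of the mating-type table from a
#' single `mating_type_table` object: one-affected vs neither,
#' both-affected vs one-affected, both-affected vs neither.  Each contrast
#' reports the continuity-corrected chi-square, p-value, relative risk and
#' continuity-corrected risk-difference interval.
#'
#' @param m A `mating_type_table`.
#' @param level Confidence level for the risk-difference intervals.
#' @param continuity Continuity correction flag for tests and intervals.
#' @return A `data.frame` with one row per contrast: `comparison`,
#'   `statistic`, `p_value`, `rd_lower`, `rd_upper`, `rr` (full precision)
#'   plus report-rounded columns `statistic_2dp`, `rd_lower_2dp`,
#'   `rd_upper_2dp`, `rr_1dp`.
#' @export
mating_comparisons <- function(m, level = 0.95, continuity = TRUE) {
  stopifnot(inherits(m, "mating_type_table") ||
              (is.matrix(m) && all(dim(m) == c(3L, 2L))))
  pairs <- list(
    c("one_affected", "neither_affected"),
    c("both_affected", "one_affected"),
    c("both_affected", "neither_affected")
  )
  labels <- c("+/- vs -/-", "+/+ vs +/-", "+/+ vs -/-")
  rows <- lapply(seq_along(pairs), function(i) {
    t <- .class_pair_table(m, pairs[[i]][1], pairs[[i]][2])
    test <- chi2_2x2(t, continuity = continuity)
    rr <- relative_risk(t)
    ci <- risk_difference_ci(t, level = level, continuity = continuity)
    data.frame(
      comparison = labels[i],
      statistic = test$statistic,
      p_value = test$p_value,
      rd_lower = ci$lower,
      rd_upper = ci$upper,
      rr = rr$rr,
      statistic_2dp = round(test$statistic, 2),
      rd_lower_2dp = round(ci$lower, 2),
      rd_upper_2dp = round(ci$upper, 2),
      rr_1dp = rr$rr_rounded,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
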