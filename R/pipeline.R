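# End-to-end orchestration: registry -> cohort -> trio -> association ->
# liability -> sire/grading summaries, with TSV/JSON/markdown rendering.

#' Analysis configuration
#'
#' @param registry Path to a registry CSV, or a registry `data.frame`
#'   already in the schema of [load_registry()].
#' @param window Closed date window for examinations (used when `registry`
#'   is a path).
#' @param continuity Continuity-correction flag for all 2x2 tests and
#'   risk-difference intervals.
#' @param ci_level Confidence level for risk-difference intervals.
#' @param h2_method Default heritability estimator, `"reich"` (corrected)
#'   or `"falconer"`.
#' @param bootstrap_B Bootstrap replicates for heritability intervals; 0
#'   disables the bootstrap.
#' @param seed Seed for the bootstrap.
#' @param avg_yearly_registrations Average yearly registrations used to
#'   derive the per-sire offspring limit; alternatively give `limit`
#'   directly.  Both `NULL` skips the sire summary.
#' @param limit Explicit per-sire offspring limit.
#' @return List of class `analysis_config`.
#' @export
analysis_config <- function(registry, window = c("2004-01-01", "2013-12-31"),
                            continuity = TRUE, ci_level = 0.95,
                            h2_method = c("reich", "falconer"),
                            bootstrap_B = 0L, seed = 1L,
                            avg_yearly_registrations = NULL, limit = NULL) {
  h2_method <- match.arg(h2_method)
  stopifnot(ci_level > 0, ci_level < 1, bootstrap_B >= 0)
  structure(list(registry = registry, window = window,
                 continuity = isTRUE(continuity), ci_level = ci_level,
                 h2_method = h2_method, bootstrap_B = as.integer(bootstrap_B),
                 seed = as.integer(seed),
                 avg_yearly_registrations = avg_yearly_registrations,
                 limit = limit),
            class = "analysis_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full registry analysis
#'
#' Executes every stage of the cohort analysis: registry loading, per-dog
#' resolution, prevalence and sex association, trio-cohort construction,
#' the omnibus and pairwise mating-type tests with relative risks and
#' risk-difference intervals, the heritability variant grid with default
#' estimates (and optional bootstrap intervals), and — when an offspring
#' limit is configured and sires are present — the sire-usage and grading
#' summaries.  Inclusion/exclusion counts are reported via messages.
#'
#' @param cfg An [analysis_config()] (or a registry path/`data.frame`,
#'   which is wrapped in a default configuration).
#' @return An object of class `report_bundle`: a list of blocks
#'   (`cohort`, `sex`, `mating_table`, `omnibus`, `comparisons`,
#'   `heritability`, `sires`, `grading`) whose every printed number is also
#'   available at full precision.
#' @export
run_analysis <- function(cfg) {
  if (!inherits(cfg, "analysis_config")) cfg <- analysis_config(cfg)
  exams <- .stage("load", {
    if (is.character(cfg$registry)) {
      load_registry(cfg$registry, cfg$window)
    } else if (is.data.frame(cfg$registry)) {
      cfg$registry
    } else stop("registry must be a path or a data.frame")
  })
  dogs <- .stage("resolve", resolve_dogs(exams))
  prev <- .stage("prevalence", prevalence(dogs))
  sexres <- .stage("sex_association",
                   sex_association(dogs, continuity = cfg$continuity))
  trio <- .stage("trio", build_trio_cohort(dogs))
  mt <- .stage("mating_table", mating_type_table(trio))
  omni <- .stage("omnibus", omnibus_association(mt))
  comps <- .stage("comparisons",
                  mating_comparisons(mt, level = cfg$ci_level,
                                     continuity = cfg$continuity))

  herit <- .stage("heritability", {
    p_cohort <- prev$proportion
    p_by_class <- mt[, "affected"] / rowSums(mt)
    variants <- h2_variants(p_cohort,
                            p_neither = p_by_class[["neither_affected"]],
                            p_one = p_by_class[["one_affected"]],
                            p_both = p_by_class[["both_affected"]])
    # package defaults: corrected estimator; midparent (r = 1) against the
    # full-cohort prevalence for the both-affected contrast, r = 0.5
    # against the neither-affected-offspring incidence for one affected
    defaults <- variants[variants$method == cfg$h2_method &
                           ((variants$contrast == "both_affected" & variants$control == "cohort") |
                            (variants$contrast == "one_affected" & variants$control == "neither_offspring")), ,
                         drop = FALSE]
    ci <- NULL
    if (cfg$bootstrap_B > 0) {
      k_ctl <- mt["neither_affected", "affected"]
      n_ctl <- sum(mt["neither_affected", ])
      ci <- list(
        both_affected = bootstrap_h2_ci(
          prev$n_affected, prev$n_total,
          mt["both_affected", "affected"], sum(mt["both_affected", ]),
          method = cfg$h2_method, r = 1, B = cfg$bootstrap_B, seed = cfg$seed),
        one_affected = bootstrap_h2_ci(
          k_ctl, n_ctl,
          mt["one_affected", "affected"], sum(mt["one_affected", ]),
          method = cfg$h2_method, r = 0.5, B = cfg$bootstrap_B, seed = cfg$seed)
      )
    }
    list(variants = variants, defaults = defaults, ci = ci,
         class_incidence = p_by_class, cohort_prevalence = p_cohort)
  })

  limit <- cfg$limit
  if (is.null(limit) && !is.null(cfg$avg_yearly_registrations)) {
    limit <- sire_limit(cfg$avg_yearly_registrations)
  }
  sires <- NULL
  if (!is.null(limit) && any(!is.na(dogs$sire_id))) {
    sires <- .stage("sires", summarize_sires(dogs, limit))
  }

  grading <- .stage("grading", {
    aff <- dogs[dogs$status == "affected", , drop = FALSE]
    graded <- aff$grade[aff$grade %in% c("mild", "moderate", "severe")]
    counts <- c(mild = sum(graded == "mild"),
                moderate = sum(graded == "moderate"),
                severe = sum(graded == "severe"))
    list(n_affected = nrow(aff), n_graded = length(graded), counts = counts,
         percent = if (length(graded)) round(100 * counts / length(graded)) else counts)
  })

  structure(list(config = cfg, n_dogs = nrow(dogs),
                 cohort = prev, sex = sexres, trio_size = nrow(trio$members),
                 mating_table = mt, omnibus = omni, comparisons = comps,
                 heritability = herit, sires = sires, grading = grading),
            class = "report_bundle")
}

#' @export
print.report_bundle <- function(x, ...) {
  cat(sprintf("Cohort: %d dogs, %d affected (prevalence %.2f %%)\n",
              x$cohort$n_total, x$cohort$n_affected, x$cohort$percent))
  cat(sprintf("Sex association: chi-square = %.4f, p = %.6f\n",
              x$sex$statistic, x$sex$p_value))
  cat(sprintf("Trio cohort: %d offspring; omnibus chi-square = %.2f (df 2), p = %.3g\n",
              x$trio_size, x$omnibus$statistic, x$omnibus$p_value))
  cat("Mating-type table:\n")
  print(unclass(x$mating_table))
  cat("Pairwise comparisons:\n")
  print(x$comparisons[, c("comparison", "statistic_2dp", "p_value",
                          "rd_lower_2dp", "rd_upper_2dp", "rr_1dp")],
        row.names = FALSE)
  cat("Heritability (default variants):\n")
  d <- x$heritability$defaults
  for (i in seq_len(nrow(d))) {
    cat(sprintf("  %s contrast (%s, control = %s, r = %g): h2 = %.2f\n",
                d$contrast[i], d$method[i], d$control[i], d$r[i], d$h2[i]))
  }
  if (!is.null(x$sires)) print(x$sires)
  if (x$grading$n_graded > 0) {
    cat(sprintf("Grading: %d of %d affected graded (mild/moderate/severe = %s)\n",
                x$grading$n_graded, x$grading$n_affected,
                paste(x$grading$counts, collapse = "/")))
  }
  invisible(x)
}

.bundle_as_list <- function(bundle) {
  mt <- bundle$mating_table
  list(
    cohort = bundle$cohort,
    sex = list(statistic = bundle$sex$statistic, df = bundle$sex$df,
               p_value = bundle$sex$p_value, corrected = bundle$sex$corrected),
    trio_size = bundle$trio_size,
    mating_table = list(classes = rownames(mt),
                        affected = unname(mt[, "affected"]),
                        unaffected = unname(mt[, "unaffected"])),
    omnibus = list(statistic = bundle$omnibus$statistic, df = bundle$omnibus$df,
                   p_value = bundle$omnibus$p_value),
    comparisons = bundle$comparisons,
    heritability = list(
      cohort_prevalence = bundle$heritability$cohort_prevalence,
      class_incidence = as.list(bundle$heritability$class_incidence),
      variants = bundle$heritability$variants,
      defaults = bundle$heritability$defaults,
      ci = bundle$heritability$ci),
    sires = if (!is.null(bundle$sires)) {
      list(groups = bundle$sires$groups, limit = bundle$sires$limit)
    },
    grading = bundle$grading
  )
}

#' Render a report bundle to files
#'
#' Writes deterministic, locale-independent report files: `tsv` emits a
#' mating-type count table (`table_counts.tsv`) and a comparison table
#' (`table_comparisons.tsv`) plus summary/heritability tables; `json`
#' emits the whole bundle at full precision; `markdown` emits a
#' human-readable report with the conventional rounding (chi-square to 2
#' decimals, the sex test to 4, relative risk to 1, intervals to 2).
#'
#' @param bundle A `report_bundle` from [run_analysis()].
#' @param format One of `"tsv"`, `"json"`, `"markdown"`.
#' @param dir Output directory (created if needed).
#' @return Character vector of files written, invisibly.
#' @export
render_report <- function(bundle, format = c("tsv", "json", "markdown"),
                          dir = ".") {
  stopifnot(inherits(bundle, "report_bundle"))
  format <- match.arg(format)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character(0)
  wt <- function(d, name) {
    f <- file.path(dir, name)
    utils::write.table(d, f, sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "NA", fileEncoding = "UTF-8")
    f
  }
  if (format == "tsv") {
    mt <- bundle$mating_table
    files <- c(files, wt(data.frame(mating_class = rownames(mt),
                                    affected = mt[, "affected"],
                                    unaffected = mt[, "unaffected"],
                                    total = rowSums(mt)),
                         "table_counts.tsv"))
    files <- c(files, wt(bundle$comparisons, "table_comparisons.tsv"))
    files <- c(files, wt(data.frame(
      quantity = c("n_dogs", "n_affected", "prevalence_percent",
                   "sex_chi2", "sex_p", "trio_size", "omnibus_chi2", "omnibus_p"),
      value = c(bundle$cohort$n_total, bundle$cohort$n_affected,
                bundle$cohort$percent, bundle$sex$statistic, bundle$sex$p_value,
                bundle$trio_size, bundle$omnibus$statistic, bundle$omnibus$p_value)),
      "summary.tsv"))
    files <- c(files, wt(bundle$heritability$variants, "heritability.tsv"))
    if (!is.null(bundle$sires)) files <- c(files, wt(bundle$sires$groups, "sires.tsv"))
  } else if (format == "json") {
    f <- file.path(dir, "report.json")
    jsonlite::write_json(.bundle_as_list(bundle), f, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, na = "null")
    files <- f
  } else {
    f <- file.path(dir, "report.md")
    writeLines(.render_markdown(bundle), f, useBytes = TRUE)
    files <- f
  }
  invisible(files)
}

.render_markdown <- function(b) {
  mt <- b$mating_table
  cm <- b$comparisons
  fmt_p <- function(p) {
    if (p < 1e-4) sprintf("%.1e", p) else sprintf("%.4g", p)
  }
  lines <- c(
    "# Registry analysis report", "",
    sprintf("Cohort: %d dogs, %d affected, prevalence %.2f %%.",
            b$cohort$n_total, b$cohort$n_affected, b$cohort$percent),
    sprintf("Sex association: chi-square %.4f, p = %.6f.",
            b$sex$statistic, b$sex$p_value), "",
    "## Parental mating type and offspring status", "",
    "| Breeding combination | Affected | Unaffected | Total |",
    "|---|---|---|---|",
    sprintf("| %s | %d | %d | %d |", rownames(mt), mt[, "affected"],
            mt[, "unaffected"], rowSums(mt)),
    sprintf("| Total | %d | %d | %d |", sum(mt[, "affected"]),
            sum(mt[, "unaffected"]), sum(mt)), "",
    sprintf("Omnibus chi-square %.2f (df 2), p = %s.",
            b$omnibus$statistic, fmt_p(b$omnibus$p_value)), "",
    "## Pairwise comparisons", "",
    "| Comparison | Chi-square | p-value | 95 % CI | RR |",
    "|---|---|---|---|---|",
    vapply(seq_len(nrow(cm)), function(i) {
      sprintf("| %s | %.2f | %s | [%.2f; %.2f] | %.1f |", cm$comparison[i],
              cm$statistic[i], fmt_p(cm$p_value[i]), cm$rd_lower[i],
              cm$rd_upper[i], cm$rr[i])
    }, character(1)), "",
    "## Heritability (liability scale)", "",
    sprintf("Cohort prevalence control: %.6f.", b$heritability$cohort_prevalence),
    "",
    "| Method | Control | Contrast | r | h2 |",
    "|---|---|---|---|---|",
    {
      v <- b$heritability$variants
      vapply(seq_len(nrow(v)), function(i) {
        sprintf("| %s | %s | %s | %g | %.2f |", v$method[i], v$control[i],
                v$contrast[i], v$r[i], v$h2[i])
      }, character(1))
    })
  if (!is.null(b$sires)) {
    g <- b$sires$groups
    lines <- c(lines, "", "## Sires", "",
               "| Status | Sires | Offspring | Litters | Mean offspring | Over limit |",
               "|---|---|---|---|---|---|",
               vapply(seq_len(nrow(g)), function(i) {
                 sprintf("| %s | %d | %d | %s | %.1f | %d |", g$status[i],
                         g$n_sires[i], g$total_offspring[i],
                         ifelse(is.na(g$total_litters[i]), "-",
                                as.character(g$total_litters[i])),
                         g$mean_offspring[i], g$n_exceeding[i])
               }, character(1)))
  }
  if (b$grading$n_graded > 0) {
    lines <- c(lines, "", "## Grading", "",
               sprintf("%d of %d affected dogs graded: %d mild, %d moderate, %d severe.",
                       b$grading$n_graded, b$grading$n_affected,
                       b$grading$counts[["mild"]], b$grading$counts[["moderate"]],
                       b$grading$counts[["severe"]]))
  }
  lines
}
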