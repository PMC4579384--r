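# Liability-scale machinery for threshold characters.
#
# A binary trait is modelled as a standard-normal latent liability exceeding
# a threshold.  From an incidence p the threshold deviate is
# x = qnorm(1 - p), z is the normal density at x, and a = z/p is the mean
# liability of affected individuals (the selection intensity of truncation
# at x).  Heritability is estimated from the shift in threshold deviate
# between a control group and relatives of affected individuals.

#' Standard-normal quantile
#'
#' Thin validated wrapper around the rational-approximation quantile in
#' `stats::qnorm` (AS 241), accurate far beyond the 1e-9 round-trip
#' tolerance the liability machinery requires.
#'
#' @param q Probability (vectorised), strictly inside (0, 1).
#' @return Deviate(s) `x` with `pnorm(x) = q`.
#' @export
normal_quantile <- function(q) {
  if (!is.numeric(q) || !length(q) || any(!is.finite(q)) ||
      any(q <= 0) || any(q >= 1)) {
    stop("q must lie strictly inside (0, 1)", call. = FALSE)
  }
  stats::qnorm(q)
}

#' Liability point for an incidence
#'
#' @param p Incidence (proportion affected), strictly inside (0, 1).
#' @return Object of class `liability_point`: list with `p`, `x` (threshold
#'   deviate, `qnorm(1 - p)`), `z` (normal density at `x`) and `a = z/p`
#'   (mean liability of affected).
#' @export
liability_point <- function(p) {
  if (!is.numeric(p) || length(p) != 1L || !is.finite(p) || p <= 0 || p >= 1) {
    stop("incidence p must lie strictly inside (0, 1)", call. = FALSE)
  }
  x <- stats::qnorm(p, lower.tail = FALSE)
  z <- stats::dnorm(x)
  structure(list(p = p, x = x, z = z, a = z / p), class = "liability_point")
}

#' @export
print.liability_point <- function(x, ...) {
  cat(sprintf("liability point: p = %.6f, x = %.5f, z = %.5f, a = %.5f\n",
              x$p, x$x, x$z, x$a))
  invisible(x)
}

# Vectorised estimator cores (used by the bootstrap).
.b_falconer <- function(pc, pr) {
  xc <- stats::qnorm(pc, lower.tail = FALSE)
  xr <- stats::qnorm(pr, lower.tail = FALSE)
  ac <- stats::dnorm(xc) / pc
  (xc - xr) / ac
}

.b_reich <- function(pc, pr) {
  xc <- stats::qnorm(pc, lower.tail = FALSE)
  xr <- stats::qnorm(pr, lower.tail = FALSE)
  ac <- stats::dnorm(xc) / pc
  arg <- 1 - (xc^2 - xr^2) * (1 - xc / ac)
  b <- rep(NA_real_, length(arg))
  ok <- arg >= 0
  b[ok] <- (xc[ok] - xr[ok] * sqrt(arg[ok])) / (ac[ok] + xr[ok]^2 * (ac[ok] - xc[ok]))
  b
}

.h2_estimate <- function(method, control, relatives, r, b) {
  h2 <- b / r
  structure(list(method = method,
                 control = liability_point(control),
                 relatives = liability_point(relatives),
                 b = b, r = r, h2 = h2,
                 negative = h2 < 0),
            class = "h2_estimate")
}

.check_h2_args <- function(control, relatives, r) {
  for (p in c(control, relatives)) {
    if (!is.numeric(p) || length(p) != 1L || !is.finite(p) || p <= 0 || p >= 1) {
      stop("incidences must lie strictly inside (0, 1)", call. = FALSE)
    }
  }
  if (!is.numeric(r) || length(r) != 1L || r <= 0) {
    stop("relationship r must be positive", call. = FALSE)
  }
  if (!r %in% c(0.5, 1)) {
    warning(sprintf("unusual relationship coefficient r = %g (expected 0.5 or 1)", r))
  }
  invisible(NULL)
}

#' Classical threshold-character heritability (regression on liability)
#'
#' Falconer's estimator: `b = (x_control - x_relatives) / a_control`,
#' `h2 = b / r`, with `x` the threshold deviate of each group's incidence
#' and `a_control` the mean liability of affected in the control group.
#' Use `r = 0.5` when the relatives share one affected parent
#' (parent-offspring regression) and `r = 1` for a both-affected-parents
#' (midparent) contrast.
#'
#' @param control Incidence in the control group.
#' @param relatives Incidence among relatives of affected individuals.
#' @param r Relationship coefficient (0.5 or 1; others allowed with
#'   warning).
#' @return Object of class `h2_estimate` with `h2`, `b`, `r`, the two
#'   [liability_point()]s and a `negative` flag.  Negative estimates are
#'   returned as-is with a warning, never clipped.
#' @export
falconer_h2 <- function(control, relatives, r = 0.5) {
  .check_h2_args(control, relatives, r)
  est <- .h2_estimate("falconer", control, relatives, r,
                      .b_falconer(control, relatives))
  if (est$negative) warning("negative heritability estimate (relatives' incidence below control)")
  est
}

#' Variance-corrected threshold-character heritability
#'
#' Corrected estimator accounting for the reduced liability variance among
#' relatives of affected individuals:
#' `b = [x_c - x_r * sqrt(1 - (x_c^2 - x_r^2)(1 - x_c/a_c))] /
#'      [a_c + x_r^2 (a_c - x_c)]`, `h2 = b / r`.  It agrees with
#' [falconer_h2()] to first order as the two incidences approach each other
#' and is the package default.
#'
#' @inheritParams falconer_h2
#' @return Object of class `h2_estimate`, as for [falconer_h2()].
#' @export
reich_h2 <- function(control, relatives, r = 0.5) {
  .check_h2_args(control, relatives, r)
  b <- .b_reich(control, relatives)
  if (is.na(b)) {
    stop("incidence pair outside the estimator's domain (negative square-root argument)",
         call. = FALSE)
  }
  est <- .h2_estimate("reich", control, relatives, r, b)
  if (est$negative) warning("negative heritability estimate (relatives' incidence below control)")
  est
}

#' @export
print.h2_estimate <- function(x, ...) {
  cat(sprintf("h2 = %.4f  (%s estimator, b = %.4f, r = %g)\n",
              x$h2, x$method, x$b, x$r))
  cat(sprintf("  control p = %.4f (x = %.4f, a = %.4f); relatives p = %.4f (x = %.4f)\n",
              x$control$p, x$control$x, x$control$a, x$relatives$p, x$relatives$x))
  if (x$negative) cat("  note: negative estimate\n")
  invisible(x)
}

#' Bootstrap percentile interval for a heritability estimate
#'
#' Nonparametric bootstrap by binomial resampling of both group counts.
#' Replicates with a degenerate incidence (0 or 1) or outside the corrected
#' estimator's domain are dropped and counted.
#'
#' @param k_control,n_control Affected count and group size of the control
#'   group.
#' @param k_relatives,n_relatives Affected count and group size of the
#'   relatives group.
#' @param method `"reich"` (default) or `"falconer"`.
#' @param r Relationship coefficient.
#' @param B Number of bootstrap replicates (at least 200).
#' @param seed Integer seed; the interval is reproducible under a fixed
#'   seed and the caller's random state is left untouched.
#' @param level Confidence level (default 0.95).
#' @return List with `lower`, `upper`, `point` (estimate on the observed
#'   counts), `B_used` (non-degenerate replicates) and `B_dropped`.
#' @export
bootstrap_h2_ci <- function(k_control, n_control, k_relatives, n_relatives,
                            method = c("reich", "falconer"), r = 0.5,
                            B = 2000L, seed = 1L, level = 0.95) {
  method <- match.arg(method)
  stopifnot(B >= 200L, n_control > 0, n_relatives > 0,
            k_control > 0, k_relatives > 0,
            k_control <= n_control, k_relatives <= n_relatives)
  core <- if (method == "reich") .b_reich else .b_falconer
  point <- core(k_control / n_control, k_relatives / n_relatives) / r
  h2s <- with_local_seed(seed, {
    kc <- stats::rbinom(B, n_control, k_control / n_control)
    kr <- stats::rbinom(B, n_relatives, k_relatives / n_relatives)
    ok <- kc > 0 & kc < n_control & kr > 0 & kr < n_relatives
    core(kc[ok] / n_control, kr[ok] / n_relatives) / r
  })
  h2s <- h2s[!is.na(h2s)]
  if (length(h2s) < B / 2) stop("too many degenerate bootstrap replicates", call. = FALSE)
  qs <- stats::quantile(h2s, c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE, type = 7)
  list(lower = qs[1], upper = qs[2], point = point,
       B_used = length(h2s), B_dropped = B - length(h2s))
}

#' Heritability estimates over the standard variant grid
#'
#' Computes both estimators for the two contrasts of the mating-type design
#' (one affected parent, `r = 0.5`; both parents affected, midparent
#' `r = 1`) under both control choices (full-cohort prevalence and the
#' neither-affected-offspring incidence).  The corrected estimator is the
#' package default; the grid makes the sensitivity to these choices
#' explicit.
#'
#' @param p_cohort Full-cohort prevalence.
#' @param p_neither,p_one,p_both Offspring incidences in the
#'   neither-/one-/both-affected mating classes.
#' @return `data.frame` with columns `method`, `control`, `contrast`, `r`,
#'   `control_p`, `relatives_p`, `b`, `h2`; rows outside the corrected
#'   estimator's domain carry `NA`.
#' @export
h2_variants <- function(p_cohort, p_neither, p_one, p_both) {
  controls <- c(cohort = p_cohort, neither_offspring = p_neither)
  contrasts <- list(one_affected = list(p = p_one, r = 0.5),
                    both_affected = list(p = p_both, r = 1.0))
  rows <- list()
  for (method in c("reich", "falconer")) {
    core <- if (method == "reich") .b_reich else .b_falconer
    for (ctl in names(controls)) {
      for (ctr in names(contrasts)) {
        pr <- contrasts[[ctr]]$p; r <- contrasts[[ctr]]$r
        b <- suppressWarnings(core(controls[[ctl]], pr))
        rows[[length(rows) + 1L]] <- data.frame(
          method = method, control = ctl, contrast = ctr, r = r,
          control_p = unname(controls[[ctl]]), relatives_p = pr,
          b = b, h2 = b / r, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Run `expr` under a fixed seed without disturbing the caller's RNG state.
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}
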