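# Group-level inference: ANCOVA on input/output similarity points,
# classical t-tests, and two-way ANOVA with Tukey post hoc tests for
# immediate-early-gene densities.

new_test_result <- function(statistic, df, p_value, estimate, n, method,
                            note = NULL) {
  structure(list(statistic = statistic, df = df, p_value = p_value,
                 estimate = estimate, n = n, method = method, note = note),
            class = "patsep_test")
}

#' @export
print.patsep_test <- function(x, ...) {
  cat(sprintf("%s: t = %.4g, df = %.4g, p = %.4g\n",
              x$method, x$statistic, x$df, x$p_value))
  if (!is.null(x$note)) cat("note:", x$note, "\n")
  invisible(x)
}

#' Two-sample t-test (classical, pooled variance)
#'
#' Two-tailed two-sample t-test with pooled variance.  When both samples
#' are constant with equal means the statistic is taken as 0 with p = 1
#' (logged via a message); constant samples with different means yield an
#' infinite statistic with p = 0.
#'
#' @param x,y Numeric samples with at least two observations each.
#' @return A `patsep_test` with `statistic`, `df`, `p_value`, group means
#'   and per-group `n`.
#' @export
two_sample_t <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 2L || length(y) < 2L)
    stop("each sample needs at least two observations", call. = FALSE)
  nx <- length(x); ny <- length(y)
  est <- c(mean_x = mean(x), mean_y = mean(y))
  pooled <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) /
    (nx + ny - 2)
  if (pooled == 0) {
    if (mean(x) == mean(y)) {
      message("zero variance with equal means; returning t = 0, p = 1")
      return(new_test_result(0, nx + ny - 2L, 1, est, c(nx, ny),
                             "two-sample t-test (pooled)",
                             note = "degenerate: zero variance"))
    }
    message("zero variance with unequal means; returning p = 0")
    return(new_test_result(Inf, nx + ny - 2L, 0, est, c(nx, ny),
                           "two-sample t-test (pooled)",
                           note = "degenerate: zero variance"))
  }
  tt <- stats::t.test(x, y, var.equal = TRUE)
  new_test_result(unname(tt$statistic), unname(tt$parameter),
                  tt$p.value, est, c(nx, ny),
                  "two-sample t-test (pooled)")
}

#' One-sample t-test
#'
#' Two-tailed one-sample t-test of the mean against `mu` (e.g. a
#' discrimination index against the chance level 0.5).  Constant samples
#' follow the same degenerate conventions as [two_sample_t()].
#'
#' @param x Numeric sample with at least two observations.
#' @param mu Null-hypothesis mean.
#' @return A `patsep_test`.
#' @export
one_sample_t <- function(x, mu) {
  x <- as.numeric(x)
  if (length(x) < 2L)
    stop("the sample needs at least two observations", call. = FALSE)
  est <- c(mean = mean(x))
  if (stats::var(x) == 0) {
    if (mean(x) == mu) {
      message("zero variance with mean equal to mu; returning t = 0, p = 1")
      return(new_test_result(0, length(x) - 1L, 1, est, length(x),
                             "one-sample t-test",
                             note = "degenerate: zero variance"))
    }
    message("zero variance with mean different from mu; returning p = 0")
    return(new_test_result(Inf, length(x) - 1L, 0, est, length(x),
                           "one-sample t-test",
                           note = "degenerate: zero variance"))
  }
  tt <- stats::t.test(x, mu = mu)
  new_test_result(unname(tt$statistic), unname(tt$parameter), tt$p.value,
                  est, length(x), "one-sample t-test")
}

#' ANCOVA comparison of input/output similarity between groups
#'
#' Fits output similarity on input similarity with housing group as a
#' factor.  The headline group effect comes from the parallel-lines model
#' `s_output ~ s_input + group` (tested against `s_output ~ s_input`), and
#' slope heterogeneity from adding the `s_input:group` interaction.
#' Per-group slopes and intercepts come from separate per-group fits, as
#' drawn for the linear fits in a similarity scatter.
#'
#' @param points A data frame with columns `s_input`, `s_output`, `group`
#'   (two or more levels; rows with undefined similarity are dropped).
#' @return An object of class `patsep_ancova`: `coefficients` (per-group
#'   intercept/slope data frame), `p_group`, `p_interaction`, `n_per_group`.
#' @export
ancova_compare <- function(points) {
  stopifnot(is.data.frame(points),
            all(c("s_input", "s_output", "group") %in% names(points)))
  d <- points[!is.na(points$s_input) & !is.na(points$s_output), , drop = FALSE]
  d$group <- factor(as.character(d$group))
  if (nlevels(d$group) < 2L)
    stop("ANCOVA needs at least two groups", call. = FALSE)
  n_per_group <- table(d$group)
  if (any(n_per_group < 3L))
    stop("each group needs at least 3 points", call. = FALSE)
  if (stats::var(d$s_input) == 0)
    stop("the covariate s_input is constant", call. = FALSE)
  m0 <- stats::lm(s_output ~ s_input, data = d)
  m1 <- stats::lm(s_output ~ s_input + group, data = d)
  m2 <- stats::lm(s_output ~ s_input * group, data = d)
  p_group <- stats::anova(m0, m1)[2L, "Pr(>F)"]
  p_inter <- stats::anova(m1, m2)[2L, "Pr(>F)"]
  coefs <- do.call(rbind, lapply(levels(d$group), function(g) {
    fit <- stats::lm(s_output ~ s_input, data = d[d$group == g, ])
    data.frame(group = g, intercept = unname(stats::coef(fit)[1L]),
               slope = unname(stats::coef(fit)[2L]),
               stringsAsFactors = FALSE)
  }))
  structure(list(coefficients = coefs,
                 p_group = p_group, p_interaction = p_inter,
                 n_per_group = as.integer(n_per_group),
                 groups = levels(d$group),
                 models = list(parallel = m1, interaction = m2)),
            class = "patsep_ancova")
}

#' @export
print.patsep_ancova <- function(x, ...) {
  cat("ANCOVA of s_output on s_input by group\n")
  print(x$coefficients, row.names = FALSE)
  cat(sprintf("group effect (parallel lines): p = %.4g\n", x$p_group))
  cat(sprintf("slope heterogeneity:           p = %.4g\n", x$p_interaction))
  invisible(x)
}

#' Two-way ANOVA with Tukey post hoc tests on cell densities
#'
#' Fits `density ~ group * condition` (housing by behavioral condition) on
#' per-animal mean densities — the animal is the analysis unit — followed
#' by Tukey HSD comparisons of the four design cells.  When the densities
#' have zero variance every p-value is reported as 1 by convention (logged
#' via a message).
#'
#' @param densities A data frame with columns `animal_id`, `group`
#'   (`SH`/`EE`), `condition` (e.g. `HC`/`NOE`), `density`; typically the
#'   `per_animal` table of [ieg_density()] restricted to one marker, or use
#'   `marker` to select one.
#' @param marker Optional marker name to filter a multi-marker table.
#' @return An object of class `patsep_anova`: `anova` (effects table),
#'   `p_housing`, `p_condition`, `p_interaction`, `tukey` (Tukey HSD on the
#'   interaction cells, `NULL` in the degenerate case), `n_per_cell`.
#' @export
two_way_anova_tukey <- function(densities, marker = NULL) {
  stopifnot(is.data.frame(densities),
            all(c("group", "condition", "density") %in% names(densities)))
  d <- densities
  if (!is.null(marker)) {
    if (!"marker" %in% names(d))
      stop("`densities` has no marker column to filter on", call. = FALSE)
    d <- d[d$marker == marker, , drop = FALSE]
  } else if ("marker" %in% names(d) && length(unique(d$marker)) > 1L) {
    stop("table contains several markers; pass `marker` to select one",
         call. = FALSE)
  }
  d$group <- factor(as.character(d$group))
  d$condition <- factor(as.character(d$condition))
  cells <- table(d$group, d$condition)
  if (any(cells == 0L)) {
    empty <- which(cells == 0L, arr.ind = TRUE)[1L, ]
    stop(sprintf("design cell %s:%s is empty",
                 rownames(cells)[empty[1L]], colnames(cells)[empty[2L]]),
         call. = FALSE)
  }
  if (stats::var(d$density) == 0) {
    message("all densities are equal (zero variance); returning p = 1")
    return(structure(list(anova = NULL, p_housing = 1, p_condition = 1,
                          p_interaction = 1, tukey = NULL,
                          n_per_cell = cells,
                          note = "degenerate: zero variance"),
                     class = "patsep_anova"))
  }
  fit <- stats::aov(density ~ group * condition, data = d)
  tab <- summary(fit)[[1L]]
  pvals <- tab[["Pr(>F)"]]
  terms <- trimws(rownames(tab))
  tukey <- stats::TukeyHSD(fit, "group:condition")
  structure(list(anova = tab,
                 p_housing = pvals[terms == "group"],
                 p_condition = pvals[terms == "condition"],
                 p_interaction = pvals[terms == "group:condition"],
                 tukey = tukey, n_per_cell = cells, note = NULL),
            class = "patsep_anova")
}

#' @export
print.patsep_anova <- function(x, ...) {
  cat("Two-way ANOVA (housing x condition) on per-animal densities\n")
  if (!is.null(x$note)) cat("note:", x$note, "\n")
  cat(sprintf("housing p = %.4g, condition p = %.4g, interaction p = %.4g\n",
              x$p_housing, x$p_condition, x$p_interaction))
  invisible(x)
}
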