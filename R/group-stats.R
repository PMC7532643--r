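#' Contingency table of extravasated vessels, control vs treated
#'
#' Counts extravasated and not-extravasated vessels on each side of a paired
#' comparison.
#'
#' @param profiles_control,profiles_treated `vessel_profiles` lists (or plain
#'   lists of `vessel_profile`s, or logical vectors of extravasated flags).
#' @return Object of class `contingency_table`: list with `control_exv`,
#'   `control_not`, `treated_exv`, `treated_not`.
#' @export
tabulate_extravasation <- function(profiles_control, profiles_treated) {
  flags <- function(x, what) {
    if (is.logical(x)) return(x)
    if (is.list(x)) {
      return(vapply(x, function(p) isTRUE(p$extravasated), logical(1)))
    }
    stop(sprintf("`%s` must be a list of vessel profiles or a logical vector",
                 what), call. = FALSE)
  }
  fc <- flags(profiles_control, "profiles_control")
  ft <- flags(profiles_treated, "profiles_treated")
  if (length(fc) == 0L || length(ft) == 0L) {
    stop("both sides must contribute at least one vessel", call. = FALSE)
  }
  contingency_table(control_exv = sum(fc), control_not = sum(!fc),
                    treated_exv = sum(ft), treated_not = sum(!ft))
}

#' @rdname tabulate_extravasation
#' @param control_exv,control_not,treated_exv,treated_not Nonnegative counts.
#' @export
contingency_table <- function(control_exv, control_not, treated_exv,
                              treated_not) {
  counts <- c(control_exv = control_exv, control_not = control_not,
              treated_exv = treated_exv, treated_not = treated_not)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be nonnegative integers", call. = FALSE)
  }
  if (sum(counts) == 0) stop("at least one count must be positive", call. = FALSE)
  structure(as.list(stats::setNames(as.integer(counts), names(counts))),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  pct <- percent_extravasated(x)
  cat("<contingency_table>\n")
  cat(sprintf("  control: %d ExV / %d not (%d%%)\n", x$control_exv,
              x$control_not, pct[["control"]]))
  cat(sprintf("  treated: %d ExV / %d not (%d%%)\n", x$treated_exv,
              x$treated_not, pct[["treated"]]))
  invisible(x)
}

#' Percent extravasated vessels per side
#'
#' @param tab A `contingency_table`.
#' @param digits Rounding digits (default 0, integer percent).
#' @return Named numeric vector `c(control = , treated = )`.
#' @export
percent_extravasated <- function(tab, digits = 0) {
  c(control = round(100 * tab$control_exv /
                      (tab$control_exv + tab$control_not), digits),
    treated = round(100 * tab$treated_exv /
                      (tab$treated_exv + tab$treated_not), digits))
}

#' Two-sided Fisher's exact test on a 2x2 contingency table
#'
#' The two-sided p-value is the sum of hypergeometric probabilities, over all
#' tables with the observed margins, of the tables at most as probable as the
#' observed one (within a relative tolerance of 1e-7 for the comparison, the
#' convention of the major statistics packages). A table with a zero row or
#' column margin carries no information and returns p = 1.
#'
#' @param tab A `contingency_table`, or a 2x2 integer matrix with rows =
#'   sides and columns = (extravasated, not extravasated).
#' @return The two-sided exact p-value in `[0, 1]`.
#' @examples
#' fisher_exact_2x2(contingency_table(27, 32, 46, 18))
#' @export
fisher_exact_2x2 <- function(tab) {
  m <- if (inherits(tab, "contingency_table")) {
    matrix(c(tab$control_exv, tab$control_not,
             tab$treated_exv, tab$treated_not), 2, 2, byrow = TRUE)
  } else if (is.matrix(tab) && all(dim(tab) == c(2L, 2L))) {
    tab
  } else {
    stop("`tab` must be a contingency_table or a 2x2 matrix", call. = FALSE)
  }
  if (any(m < 0) || any(m != round(m))) {
    stop("counts must be nonnegative integers", call. = FALSE)
  }
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) return(1)
  stats::fisher.test(m, alternative = "two.sided")$p.value
}

#' Two-way analysis of variance with interaction
#'
#' Fits the two-factor cell-means model with interaction and returns the F
#' statistic and p-value for each main effect and the interaction. For
#' unbalanced data the default partitioning uses Type III sums of squares on
#' sum-to-zero contrasts (the convention of common GUI statistics software);
#' Type I (sequential) is available as an option. For balanced data the two
#' coincide.
#'
#' @param data Data frame of observations.
#' @param response Name of the numeric response column.
#' @param factor_a,factor_b Names of the two factor columns (each with at
#'   least two observed levels).
#' @param ss_type `"III"` (default) or `"I"`.
#' @return Object of class `vx_anova`: list with `table` (data frame: `term`,
#'   `df`, `sum_sq`, `statistic`, `p_value`), the fitted `lm` object `fit`,
#'   the pooled error variance `mse` and its degrees of freedom `df_error`.
#' @export
two_way_anova <- function(data, response, factor_a, factor_b,
                          ss_type = c("III", "I")) {
  ss_type <- match.arg(ss_type)
  for (nm in c(response, factor_a, factor_b)) {
    if (!nm %in% names(data)) {
      stop(sprintf("column `%s` not found in `data`", nm), call. = FALSE)
    }
  }
  d <- data
  d[[factor_a]] <- factor(d[[factor_a]])
  d[[factor_b]] <- factor(d[[factor_b]])
  for (nm in c(factor_a, factor_b)) {
    if (nlevels(d[[nm]]) < 2L) {
      stop(sprintf("factor `%s` has a single level", nm), call. = FALSE)
    }
  }
  fml <- stats::reformulate(sprintf("%s * %s", factor_a, factor_b),
                            response = response)
  contr <- stats::setNames(list("contr.sum", "contr.sum"),
                           c(factor_a, factor_b))
  fit <- stats::lm(fml, data = d, contrasts = contr)
  if (ss_type == "III") {
    a <- car::Anova(fit, type = 3)
    a <- a[!rownames(a) %in% "(Intercept)", ]
    tab <- data.frame(term = rownames(a), df = a[["Df"]],
                      sum_sq = a[["Sum Sq"]], statistic = a[["F value"]],
                      p_value = a[["Pr(>F)"]], row.names = NULL)
  } else {
    a <- stats::anova(fit)
    tab <- data.frame(term = rownames(a), df = a[["Df"]],
                      sum_sq = a[["Sum Sq"]], statistic = a[["F value"]],
                      p_value = a[["Pr(>F)"]], row.names = NULL)
  }
  res <- tab$term == "Residuals"
  structure(list(table = tab, fit = fit,
                 mse = tab$sum_sq[res] / tab$df[res],
                 df_error = tab$df[res]),
            class = "vx_anova")
}

#' @export
print.vx_anova <- function(x, ...) {
  cat("<vx_anova>\n")
  print(x$table, digits = 4)
  invisible(x)
}

#' Pairwise post-hoc comparisons from a pooled error variance
#'
#' Compares all pairs of group means with t tests that use the pooled error
#' variance of a previously fitted ANOVA (Fisher's protected LSD when left
#' unadjusted). The Sidak method adjusts each p-value as `1 - (1 - p)^m`
#' where `m` is the number of comparisons.
#'
#' @param values Numeric response vector.
#' @param groups Grouping vector (coerced to factor); to compare cells of a
#'   two-factor design pass the interaction, e.g. `interaction(side, time)`.
#' @param method `"fisher_lsd"` (unadjusted) or `"sidak"`.
#' @param mse Pooled error variance; by default the within-group pooled
#'   variance of `values` by `groups`.
#' @param df_error Degrees of freedom of `mse`; by default `N - G`.
#' @return Data frame with one row per pair: `group1`, `group2`, `estimate`
#'   (difference of means), `se`, `statistic`, `df`, `p_value`, `p_adjusted`.
#' @export
posthoc_pairwise <- function(values, groups,
                             method = c("fisher_lsd", "sidak"),
                             mse = NULL, df_error = NULL) {
  method <- match.arg(method)
  g <- factor(groups)
  g <- droplevels(g)
  if (nlevels(g) < 2L) {
    stop("need at least two groups for pairwise comparisons", call. = FALSE)
  }
  means <- tapply(values, g, mean)
  ns <- tapply(values, g, length)
  if (is.null(mse) || is.null(df_error)) {
    ss <- tapply(values, g, function(v) sum((v - mean(v))^2))
    df_error <- sum(ns) - nlevels(g)
    if (df_error <= 0) stop("no residual degrees of freedom", call. = FALSE)
    mse <- sum(ss) / df_error
  }
  pairs <- utils::combn(levels(g), 2)
  m <- ncol(pairs)
  est <- means[pairs[1, ]] - means[pairs[2, ]]
  se <- sqrt(mse * (1 / ns[pairs[1, ]] + 1 / ns[pairs[2, ]]))
  tstat <- as.numeric(est / se)
  p_raw <- 2 * stats::pt(-abs(tstat), df_error)
  p_adj <- switch(method,
                  fisher_lsd = p_raw,
                  sidak = 1 - (1 - p_raw)^m)
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
             estimate = as.numeric(est), se = as.numeric(se),
             statistic = tstat, df = df_error, p_value = p_raw,
             p_adjusted = pmin(p_adj, 1), row.names = NULL)
}

#' Paired biofluorescence differences and normalization
#'
#' For whole-body fluorescence records of a paired bilateral design (each
#' animal carries a treated and a control tumor), computes per animal and
#' time point the treated-minus-control intensity difference, and normalizes
#' both sides to the group's control-side mean at the reference (earliest)
#' time so that the control side at the reference time averages exactly 1.
#'
#' @param records Data frame with columns `animal_id`, `side` (`"control"` or
#'   `"treated"`), `time_h`, `mean_intensity`, and optionally `group` (e.g.
#'   the ultrasound pulse); one row per animal/side/time.
#' @return Data frame with one row per group/time/animal: `delta`
#'   (treated - control intensity), `norm_control`, `norm_treated`.
#' @export
paired_delta_and_normalize <- function(records) {
  req <- c("animal_id", "side", "time_h", "mean_intensity")
  if (!all(req %in% names(records))) {
    stop(sprintf("`records` must have columns %s", paste(req, collapse = ", ")),
         call. = FALSE)
  }
  if (!all(records$side %in% c("control", "treated"))) {
    stop('`side` must be "control" or "treated"', call. = FALSE)
  }
  if (!"group" %in% names(records)) records$group <- "all"
  wide <- merge(
    records[records$side == "control",
            c("group", "animal_id", "time_h", "mean_intensity")],
    records[records$side == "treated",
            c("group", "animal_id", "time_h", "mean_intensity")],
    by = c("group", "animal_id", "time_h"),
    suffixes = c("_control", "_treated"), all = TRUE)
  if (anyNA(wide$mean_intensity_control) || anyNA(wide$mean_intensity_treated)) {
    stop("missing pair member: every animal needs both sides at each time",
         call. = FALSE)
  }
  out <- do.call(rbind, lapply(split(wide, wide$group), function(g) {
    t0 <- min(g$time_h)
    ref <- mean(g$mean_intensity_control[g$time_h == t0])
    if (ref == 0) stop("reference control intensity is zero", call. = FALSE)
    data.frame(group = g$group, animal_id = g$animal_id, time_h = g$time_h,
               delta = g$mean_intensity_treated - g$mean_intensity_control,
               norm_control = g$mean_intensity_control / ref,
               norm_treated = g$mean_intensity_treated / ref)
  }))
  rownames(out) <- NULL
  out[order(out$group, out$time_h, out$animal_id), , drop = FALSE]
}
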