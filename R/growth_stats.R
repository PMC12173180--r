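# Per-time-point treatment comparison on OD680 growth series: one-way ANOVA,
# Tukey HSD and a compact letter display.  The ANOVA, Tukey adjustment and
# t-tests are delegated to stats::aov / stats::TukeyHSD / stats::t.test; the
# insert-and-absorb letter-display construction is implemented here.

#' Validate an OD680 growth table
#'
#' @param data Data frame with columns `treatment`, `time`, `replicate`,
#'   `od680`.
#' @return The data frame, invisibly, after validation.
#' @export
validate_growth_data <- function(data) {
  need <- c("treatment", "time", "replicate", "od680")
  if (!is.data.frame(data) || !all(need %in% names(data))) {
    .fame_error(sprintf("growth table must have columns %s",
                        paste(need, collapse = ", ")),
                "famefuel_io_error")
  }
  if (any(data$od680 < 0)) {
    .fame_error("OD680 values must be non-negative", "famefuel_value_error")
  }
  invisible(data)
}

# Compact letter display by insert-and-absorb.  `labels` are treatment names
# (sorted for determinism); `sig` is a symmetric logical matrix with TRUE
# where the pair is significantly different.  Two treatments end up sharing
# a letter iff their pair is not significant.
.cld_insert_absorb <- function(labels, sig) {
  labels <- sort(labels)
  cols <- list(labels)
  for (i in seq_along(labels)) {
    for (j in seq_along(labels)) {
      if (j <= i || !sig[labels[i], labels[j]]) next
      touched <- FALSE
      new_cols <- list()
      for (col in cols) {
        if (labels[i] %in% col && labels[j] %in% col) {
          touched <- TRUE
          new_cols <- c(new_cols, list(setdiff(col, labels[i])),
                        list(setdiff(col, labels[j])))
        } else {
          new_cols <- c(new_cols, list(col))
        }
      }
      if (touched) {
        # absorb: drop any column whose members are a subset of another's
        keep <- rep(TRUE, length(new_cols))
        for (a in seq_along(new_cols)) {
          for (b in seq_along(new_cols)) {
            if (a == b || !keep[a]) next
            if (all(new_cols[[a]] %in% new_cols[[b]]) &&
                (length(new_cols[[a]]) < length(new_cols[[b]]) ||
                 (length(new_cols[[a]]) == length(new_cols[[b]]) && a > b))) {
              keep[a] <- FALSE
            }
          }
        }
        cols <- new_cols[keep]
      }
    }
  }
  cols <- cols[order(vapply(cols, function(col) col[1], ""))]
  out <- stats::setNames(rep("", length(labels)), labels)
  for (k in seq_along(cols)) {
    for (lab in cols[[k]]) out[lab] <- paste0(out[lab], letters[k])
  }
  out
}

#' Compare treatments at one time point (ANOVA + Tukey HSD letters)
#'
#' Runs a one-way ANOVA on the replicate OD680 values at the requested time,
#' follows it with Tukey's HSD over all treatment pairs, and summarizes the
#' pairwise decisions as a compact letter display: treatments sharing a
#' letter are not significantly different at `alpha`.  When every
#' observation is identical the no-effect convention `p = 1` is applied and
#' all treatments share the letter "a".
#'
#' @param data Growth table (see [validate_growth_data()]).
#' @param time Time point (days) at which to compare.
#' @param alpha Significance level; default 0.05.
#' @return A `treatment_comparison` object: list with `time`, `f_statistic`,
#'   `p_value`, `letters` (named by treatment), `tukey` (pair, diff,
#'   p_adjusted, significant) and `alpha`.
#'
#' @examples
#' set.seed(1)
#' d <- data.frame(treatment = rep(c("a", "b"), each = 3), time = 9,
#'                 replicate = rep(1:3, 2),
#'                 od680 = c(rnorm(3, 0.4, 0.01), rnorm(3, 1.1, 0.01)))
#' compare_treatments(d, time = 9)$letters
#' @export
compare_treatments <- function(data, time, alpha = 0.05) {
  validate_growth_data(data)
  if (alpha <= 0 || alpha >= 1) {
    .fame_error("alpha must lie in (0, 1)", "famefuel_value_error")
  }
  sub <- data[data$time == time, , drop = FALSE]
  if (nrow(sub) == 0L) {
    .fame_error(sprintf("no observations at time %g", time),
                "famefuel_value_error")
  }
  sub$treatment <- as.character(sub$treatment)
  counts <- table(sub$treatment)
  if (length(counts) < 2L) {
    .fame_error("at least two treatments are required", "famefuel_value_error")
  }
  if (any(counts < 2L)) {
    .fame_error("every treatment needs at least two replicates",
                "famefuel_value_error")
  }
  labs <- sort(names(counts))
  if (stats::var(sub$od680) == 0) {
    # all observations identical: no effect by convention
    letters_out <- stats::setNames(rep("a", length(labs)), labs)
    pairs <- t(utils::combn(labs, 2))
    tukey <- data.frame(pair = paste(pairs[, 2], pairs[, 1], sep = "-"),
                        diff = 0, p_adjusted = 1, significant = FALSE,
                        stringsAsFactors = FALSE)
    return(structure(list(time = time, f_statistic = NA_real_, p_value = 1,
                          letters = letters_out, tukey = tukey,
                          alpha = alpha),
                     class = "treatment_comparison"))
  }
  sub$treatment <- factor(sub$treatment, levels = labs)
  fit <- stats::aov(od680 ~ treatment, data = sub)
  anova_tab <- summary(fit)[[1]]
  f_stat <- anova_tab[["F value"]][1]
  p_val <- anova_tab[["Pr(>F)"]][1]
  hsd <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$treatment
  sig <- matrix(FALSE, length(labs), length(labs),
                dimnames = list(labs, labs))
  pair_names <- rownames(hsd)
  for (k in seq_along(pair_names)) {
    ab <- strsplit(pair_names[k], "-", fixed = TRUE)[[1]]
    significant <- hsd[k, "p adj"] < alpha
    sig[ab[1], ab[2]] <- significant
    sig[ab[2], ab[1]] <- significant
  }
  structure(
    list(time = time, f_statistic = f_stat, p_value = p_val,
         letters = .cld_insert_absorb(labs, sig),
         tukey = data.frame(pair = pair_names, diff = hsd[, "diff"],
                            p_adjusted = hsd[, "p adj"],
                            significant = hsd[, "p adj"] < alpha,
                            row.names = NULL, stringsAsFactors = FALSE),
         alpha = alpha),
    class = "treatment_comparison")
}

#' @export
print.treatment_comparison <- function(x, ...) {
  cat(sprintf("Treatment comparison at day %g (alpha = %g)\n", x$time,
              x$alpha))
  cat(sprintf("  one-way ANOVA: F = %s, p = %s\n",
              format(x$f_statistic, digits = 4),
              format.pval(x$p_value, digits = 3)))
  for (lab in names(x$letters)) {
    cat(sprintf("  %-12s %s\n", lab, x$letters[lab]))
  }
  invisible(x)
}

#' Compare all time points of a growth table
#'
#' @param data Growth table.
#' @param alpha Significance level.
#' @return Data frame with one row per (time, treatment): F, p and letter.
#' @export
compare_all_timepoints <- function(data, alpha = 0.05) {
  validate_growth_data(data)
  do.call(rbind, lapply(sort(unique(data$time)), function(tt) {
    cmp <- compare_treatments(data, tt, alpha)
    data.frame(time = tt, treatment = names(cmp$letters),
               f_statistic = cmp$f_statistic, p_value = cmp$p_value,
               letter = unname(cmp$letters), row.names = NULL,
               stringsAsFactors = FALSE)
  }))
}

#' Two-sample t-test on replicate OD680 values
#'
#' Classic equal-variance independent-sample t-test by default (set
#' `var_equal = FALSE` for Welch).  The degenerate case of two
#' zero-variance groups with equal means is reported as `p = 1` by
#' convention.
#'
#' @param a,b Numeric replicate vectors, or growth tables (then `treatment`
#'   columns must each hold one treatment and `time` selects the rows).
#' @param time Time point when `a`/`b` are growth tables.
#' @param alpha Significance level for the decision; default 0.05.
#' @param var_equal Pool variances (classic t-test); default `TRUE`.
#' @return List with `p_value`, `statistic`, `significant`, `alpha`,
#'   `method`.
#' @export
two_sample_t <- function(a, b, time = NULL, alpha = 0.05, var_equal = TRUE) {
  pick <- function(x) {
    if (is.data.frame(x)) {
      validate_growth_data(x)
      if (is.null(time)) {
        .fame_error("a time point is required with growth-table input",
                    "famefuel_value_error")
      }
      x$od680[x$time == time]
    } else as.numeric(x)
  }
  xa <- pick(a); xb <- pick(b)
  if (length(xa) < 2L || length(xb) < 2L) {
    .fame_error("both groups need at least two replicates",
                "famefuel_value_error")
  }
  if (stats::sd(xa) == 0 && stats::sd(xb) == 0) {
    p <- if (isTRUE(all.equal(mean(xa), mean(xb)))) 1 else 0
    return(list(p_value = p, statistic = NA_real_, significant = p < alpha,
                alpha = alpha,
                method = "degenerate (zero variance in both groups)"))
  }
  tt <- stats::t.test(xa, xb, var.equal = var_equal)
  list(p_value = tt$p.value, statistic = unname(tt$statistic),
       significant = tt$p.value < alpha, alpha = alpha, method = tt$method)
}
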