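# Accuracy and precision estimators for the measurement table: bias with
# t confidence intervals, intra-/inter-/internodule variability (the first
# two with the small-sample c4 correction), repeated-measures ANOVA on
# absolute errors with Bonferroni post hoc tests, Kendall rank
# correlation, and non-measurable tallies.

#' Unbiasing constant c4 for the sample standard deviation
#'
#' For a normal sample of size `n`, `E[s] = c4(n) * sigma` with
#' `c4(n) = sqrt(2/(n-1)) * Gamma(n/2) / Gamma((n-1)/2)`; dividing the
#' sample SD by `c4(n)` removes the small-sample bias. c4(2) ~ 0.7979,
#' c4(4) ~ 0.9213, c4(n) -> 1 as n grows.
#'
#' @param n Sample size (>= 2); vectorised.
#' @return The constant(s), dimensionless.
#' @export
c4 <- function(n) {
  if (any(n < 2)) stop("c4 requires n >= 2")
  sqrt(2 / (n - 1)) * exp(lgamma(n / 2) - lgamma((n - 1) / 2))
}

# Merge the truths into the table and keep measurable rows of one round.
measurable_round <- function(table, truths, round = 1L) {
  df <- merge(table[table$round == round & !table$nonmeasurable, ],
              truths[, c("nodule_id", "true_diameter")], by = "nodule_id")
  df$diff <- df$measured_diameter - df$true_diameter
  df
}

# Mean and t-based 95% CI of a vector.
mean_ci <- function(x, level = 0.95) {
  n <- length(x)
  m <- mean(x)
  if (n < 2) return(c(mean = m, lo = NA_real_, hi = NA_real_, n = n))
  hw <- stats::qt(1 - (1 - level) / 2, n - 1) * stats::sd(x) / sqrt(n)
  c(mean = m, lo = m - hw, hi = m + hw, n = n)
}

#' Measurement accuracy (mean signed error) per stratum
#'
#' Mean of (measured - true) over measurable round-1 measurements, per
#' observer, size group and dose level, with a t-based 95% confidence
#' interval.
#'
#' @param table A measurement table ([simulate_measurements()] format).
#' @param truths A [nodule_truths()] data frame.
#' @return Data frame: observer_id, size_group, dose_level, mean_diff,
#'   ci_lo, ci_hi, n. Strata with no measurable nodules are absent.
#' @export
accuracy <- function(table, truths) {
  df <- measurable_round(table, truths)
  out <- do.call(rbind, lapply(
    split(df, list(df$observer_id, df$size_group, df$dose_level),
          drop = TRUE),
    function(g) {
      ci <- mean_ci(g$diff)
      data.frame(observer_id = g$observer_id[1],
                 size_group = g$size_group[1],
                 dose_level = g$dose_level[1],
                 mean_diff = ci["mean"], ci_lo = ci["lo"], ci_hi = ci["hi"],
                 n = as.integer(ci["n"]))
    }))
  rownames(out) <- NULL
  out
}

#' Intraobserver variability per stratum
#'
#' Per nodule, the SD of the two rounds' measurements divided by `c4(2)`;
#' averaged over the nodules of each (observer, size group, dose level)
#' stratum. Nodules with a non-measurable round are excluded. The CI is
#' t-based over the per-nodule corrected SDs.
#'
#' @inheritParams accuracy
#' @return Data frame: observer_id, size_group, dose_level, value, ci_lo,
#'   ci_hi, n (nodules contributing).
#' @export
intraobserver_variability <- function(table, truths = NULL) {
  df <- table[!table$nonmeasurable, ]
  key <- interaction(df$observer_id, df$nodule_id, df$dose_level, drop = TRUE)
  per <- do.call(rbind, lapply(split(df, key), function(g) {
    if (nrow(g) < 2) return(NULL)
    data.frame(observer_id = g$observer_id[1], size_group = g$size_group[1],
               dose_level = g$dose_level[1],
               sd_c4 = stats::sd(g$measured_diameter) / c4(nrow(g)))
  }))
  if (is.null(per) || nrow(per) == 0) {
    return(data.frame(observer_id = integer(0), size_group = character(0),
                      dose_level = numeric(0), value = numeric(0),
                      ci_lo = numeric(0), ci_hi = numeric(0), n = integer(0)))
  }
  out <- do.call(rbind, lapply(
    split(per, list(per$observer_id, per$size_group, per$dose_level),
          drop = TRUE),
    function(g) {
      ci <- mean_ci(g$sd_c4)
      data.frame(observer_id = g$observer_id[1], size_group = g$size_group[1],
                 dose_level = g$dose_level[1],
                 value = ci["mean"], ci_lo = ci["lo"], ci_hi = ci["hi"],
                 n = as.integer(ci["n"]))
    }))
  rownames(out) <- NULL
  out
}

#' Interobserver variability per stratum
#'
#' Per nodule, the SD of the round-1 measurements across observers divided
#' by `c4(m)` for the `m >= 2` observers who measured it; averaged over
#' the nodules of each (size group, dose level) stratum.
#'
#' @inheritParams accuracy
#' @return Data frame: size_group, dose_level, value, ci_lo, ci_hi, n.
#' @export
interobserver_variability <- function(table, truths = NULL) {
  df <- table[table$round == 1L & !table$nonmeasurable, ]
  key <- interaction(df$nodule_id, df$dose_level, drop = TRUE)
  per <- do.call(rbind, lapply(split(df, key), function(g) {
    if (nrow(g) < 2) return(NULL)
    data.frame(size_group = g$size_group[1], dose_level = g$dose_level[1],
               sd_c4 = stats::sd(g$measured_diameter) / c4(nrow(g)))
  }))
  if (is.null(per) || nrow(per) == 0) {
    stop("no nodule was measured by two or more observers")
  }
  out <- do.call(rbind, lapply(
    split(per, list(per$size_group, per$dose_level), drop = TRUE),
    function(g) {
      ci <- mean_ci(g$sd_c4)
      data.frame(size_group = g$size_group[1], dose_level = g$dose_level[1],
                 value = ci["mean"], ci_lo = ci["lo"], ci_hi = ci["hi"],
                 n = as.integer(ci["n"]))
    }))
  rownames(out) <- NULL
  out
}

#' Internodule variability per stratum
#'
#' SD over nodules of the round-1 signed errors (measured - true), per
#' observer, size group and dose level. The nodule count is not small, so
#' no c4 correction is applied; the CI is the chi-square interval for a
#' normal SD.
#'
#' @inheritParams accuracy
#' @return Data frame: observer_id, size_group, dose_level, value, ci_lo,
#'   ci_hi, n.
#' @export
internodule_variability <- function(table, truths) {
  df <- measurable_round(table, truths)
  out <- do.call(rbind, lapply(
    split(df, list(df$observer_id, df$size_group, df$dose_level),
          drop = TRUE),
    function(g) {
      n <- nrow(g)
      if (n < 2) return(NULL)
      s <- stats::sd(g$diff)
      data.frame(observer_id = g$observer_id[1], size_group = g$size_group[1],
                 dose_level = g$dose_level[1], value = s,
                 ci_lo = s * sqrt((n - 1) / stats::qchisq(0.975, n - 1)),
                 ci_hi = s * sqrt((n - 1) / stats::qchisq(0.025, n - 1)),
                 n = n)
    }))
  if (is.null(out)) stop("fewer than 2 measurable nodules in every stratum")
  rownames(out) <- NULL
  out
}

#' Repeated-measures ANOVA of absolute errors across dose levels
#'
#' One-way repeated-measures ANOVA on |measured - true| (round 1) with
#' nodule as subject and dose level as the within factor, run separately
#' per observer and size group. Only nodules measured at every dose level
#' enter (complete-case rule). No sphericity correction is applied. When
#' the overall effect is significant at `alpha`, all pairwise paired
#' t-tests are reported with Bonferroni-corrected p-values (multiplied by
#' the number of pairs, capped at 1).
#'
#' @inheritParams accuracy
#' @param alpha Significance level gating the post hoc tests.
#' @return List with one element per (observer, size group): `F`, `df`
#'   (between, error), `p`, `n_complete`, per-dose means with 95% CI
#'   half-widths, and `posthoc` (NULL unless p < alpha).
#' @export
rm_anova_abs_diff <- function(table, truths, alpha = 0.05) {
  df <- measurable_round(table, truths)
  df$abs_diff <- abs(df$diff)
  doses <- sort(unique(df$dose_level), decreasing = TRUE)
  k <- length(doses)
  if (k < 2) stop("at least two dose levels are required")
  res <- list()
  for (key in split(df, list(df$observer_id, df$size_group), drop = TRUE)) {
    tab <- table(key$nodule_id)
    complete <- names(tab)[tab == k]
    n <- length(complete)
    if (n < 2) next
    d <- key[key$nodule_id %in% complete, ]
    d$dose_f <- factor(d$dose_level, levels = doses)
    d$nodule_f <- factor(d$nodule_id)
    fit <- stats::aov(abs_diff ~ dose_f + Error(nodule_f), data = d)
    s <- summary(fit)
    within <- s[["Error: Within"]][[1]]
    rn <- trimws(rownames(within))
    F_val <- within[rn == "dose_f", "F value"]
    p_val <- within[rn == "dose_f", "Pr(>F)"]
    df_b <- within[rn == "dose_f", "Df"]
    df_e <- within[rn == "Residuals", "Df"]
    if (!is.finite(F_val)) stop("degenerate data: zero error mean square")
    means <- do.call(rbind, lapply(doses, function(s0) {
      ci <- mean_ci(d$abs_diff[d$dose_level == s0])
      data.frame(dose_level = s0, mean_abs_diff = ci["mean"],
                 ci_halfwidth = ci["mean"] - ci["lo"])
    }))
    rownames(means) <- NULL
    posthoc <- NULL
    if (is.finite(p_val) && p_val < alpha) {
      pairs <- utils::combn(doses, 2)
      n_cmp <- ncol(pairs)
      posthoc <- do.call(rbind, lapply(seq_len(n_cmp), function(j) {
        a <- d$abs_diff[d$dose_level == pairs[1, j]][order(d$nodule_id[d$dose_level == pairs[1, j]])]
        b <- d$abs_diff[d$dose_level == pairs[2, j]][order(d$nodule_id[d$dose_level == pairs[2, j]])]
        tt <- stats::t.test(a, b, paired = TRUE)
        data.frame(dose_a = pairs[1, j], dose_b = pairs[2, j],
                   mean_a = mean(a), mean_b = mean(b),
                   p_bonferroni = min(1, tt$p.value * n_cmp))
      }))
    }
    res[[paste0("obs", key$observer_id[1], "_", key$size_group[1])]] <-
      list(observer_id = key$observer_id[1],
           size_group = as.character(key$size_group[1]),
           F = unname(F_val), df = c(between = df_b, error = df_e),
           p = unname(p_val), n_complete = n, means = means,
           posthoc = posthoc)
  }
  res
}

#' Kendall rank correlation between dose level and a variability measure
#'
#' Kendall's tau-b over the (dose, value) pairs. For n <= 5 the two-sided
#' p-value is exact, by enumeration of all permutations of the values
#' (the asymptotic approximation is meaningless at n = 3); otherwise
#' [stats::cor.test()] supplies it.
#'
#' @param doses Dose levels (no missing values).
#' @param values Variability values, same length.
#' @return List with `tau` and `p` (`tau = NA` when either input is
#'   constant).
#' @export
kendall_tau_dose_vs_variability <- function(doses, values) {
  stopifnot(length(doses) == length(values), !anyNA(doses), !anyNA(values))
  n <- length(doses)
  if (length(unique(values)) == 1L || length(unique(doses)) == 1L) {
    return(list(tau = NA_real_, p = NA_real_, note = "constant input"))
  }
  tau <- stats::cor(doses, values, method = "kendall")
  if (n <= 5) {
    perms <- permutations_of(seq_len(n))
    taus <- vapply(seq_len(nrow(perms)), function(i) {
      stats::cor(doses, values[perms[i, ]], method = "kendall")
    }, numeric(1))
    p <- mean(abs(taus) >= abs(tau) - 1e-12)
  } else {
    p <- suppressWarnings(
      stats::cor.test(doses, values, method = "kendall")$p.value)
  }
  list(tau = tau, p = p)
}

# All permutations of a small vector (n! rows).
permutations_of <- function(x) {
  n <- length(x)
  if (n == 1L) return(matrix(x, 1, 1))
  out <- NULL
  for (i in seq_len(n)) {
    sub <- permutations_of(x[-i])
    out <- rbind(out, cbind(x[i], sub))
  }
  out
}

#' Tally non-measurable judgements per stratum
#'
#' Round-1 non-measurable flags per observer, size group and dose level,
#' with the stratum denominator.
#'
#' @inheritParams accuracy
#' @return Data frame: observer_id, size_group, dose_level,
#'   n_nonmeasurable, n_total.
#' @export
count_nonmeasurable <- function(table) {
  df <- table[table$round == 1L, ]
  out <- do.call(rbind, lapply(
    split(df, list(df$observer_id, df$size_group, df$dose_level),
          drop = TRUE),
    function(g) {
      data.frame(observer_id = g$observer_id[1], size_group = g$size_group[1],
                 dose_level = g$dose_level[1],
                 n_nonmeasurable = sum(g$nonmeasurable),
                 n_total = nrow(g))
    }))
  rownames(out) <- NULL
  out[order(out$observer_id, out$size_group, -out$dose_level), ]
}
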