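#' Construct a labelled 2x2 contingency table
#'
#' @param a,b,c,d non-negative integer cell counts; row 1 (`a`, `b`) is the
#'   exposure-present row, column 1 (`a`, `c`) the outcome-present column.
#' @param labels optional list with `rows` and `cols` character vectors of
#'   length 2.
#' @return A 2x2 integer matrix of class `contingency_2x2`.
#' @export
contingency_2x2 <- function(a, b, c, d, labels = NULL) {
  cells <- c(a, b, c, d)
  if (any(!is.finite(cells)) || any(cells < 0) || any(cells != round(cells))) {
    abort("cell counts must be non-negative integers",
          class = "gabrisk_bad_table")
  }
  m <- matrix(as.integer(cells), nrow = 2, byrow = TRUE)
  if (!is.null(labels)) dimnames(m) <- list(labels$rows, labels$cols)
  class(m) <- c("contingency_2x2", class(m))
  m
}

#' Cross-classify variant records into a 2x2 table
#'
#' Evaluates two logical predicates over the records (tidy evaluation, so
#' bare column expressions work) and counts the four combinations. Row 1 is
#' predicate-true, column 1 is predicate-true.
#'
#' @param records a data frame of variant records.
#' @param row_predicate,col_predicate logical expressions in the records'
#'   columns, e.g. `domain %in% c("NT", "TM")` or `reduced_current`.
#' @return A [contingency_2x2()].
#' @export
#' @examples
#' build_contingency(gabr_functional_catalog(),
#'                   polyphen_category == "damaging", reduced_current)
build_contingency <- function(records, row_predicate, col_predicate) {
  rq <- enquo(row_predicate); cq <- enquo(col_predicate)
  r <- eval_tidy(rq, records); cc <- eval_tidy(cq, records)
  if (!is.logical(r) || !is.logical(cc) || anyNA(r) || anyNA(cc)) {
    abort("predicates must evaluate to logicals without NA for every record",
          class = "gabrisk_bad_input")
  }
  contingency_2x2(sum(r & cc), sum(r & !cc), sum(!r & cc), sum(!r & !cc),
                  labels = list(rows = c(rlang::as_label(rq),
                                         paste0("!", rlang::as_label(rq))),
                                cols = c(rlang::as_label(cq),
                                         paste0("!", rlang::as_label(cq)))))
}

#' Two-tailed Fisher exact test for a 2x2 table
#'
#' Computes the exact two-tailed p by the minimum-likelihood rule: with the
#' margins fixed, the p-value is the sum of hypergeometric probabilities of
#' all tables no more probable than the observed one. The comparison uses a
#' 1e-7 relative tolerance so that floating-point noise cannot flip the
#' inclusion of borderline tables, and the summation is done in log space.
#'
#' @param x a [contingency_2x2()] or any 2x2 matrix of counts.
#' @return The two-tailed p-value.
#' @export
#' @examples
#' fisher_exact_2x2(contingency_2x2(9, 1, 9, 13)) # ~0.0189
fisher_exact_2x2 <- function(x) {
  m <- unclass(x)
  if (!is.matrix(m) || !all(dim(m) == 2L)) {
    abort("`x` must be a 2x2 table", class = "gabrisk_bad_table")
  }
  if (any(m < 0) || sum(m) == 0) {
    abort("table must have non-negative counts and a positive total",
          class = "gabrisk_bad_table")
  }
  r1 <- sum(m[1, ]); r2 <- sum(m[2, ]); c1 <- sum(m[, 1]); n <- sum(m)
  support <- max(0, c1 - r2):min(r1, c1)
  logp <- lchoose(r1, support) + lchoose(r2, c1 - support) - lchoose(n, c1)
  logp_obs <- logp[support == m[1, 1]]
  sel <- logp <= logp_obs + log1p(1e-7)
  exp(logsumexp(logp[sel]))
}

logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

# ---- Dunnett many-to-one machinery -------------------------------------

# Gauss-Legendre nodes/weights on [-1, 1] via the Golub-Welsch eigenvalue
# method; deterministic.
gauss_legendre <- function(n) {
  i <- seq_len(n - 1)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- b
  J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(nodes = e$values[ord], weights = 2 * e$vectors[1, ord]^2)
}

#' Joint probability that all Dunnett statistics stay below a bound
#'
#' `P(max_i |T_i| <= q)` for the many-to-one comparison statistics
#' `T_i = (mean_i - mean_0) / (s * sqrt(1/n_i + 1/n_0))` sharing the control
#' mean and the pooled error estimate (df degrees of freedom). Evaluated by
#' deterministic Gauss-Legendre quadrature of the classical double integral
#' over the control-mean and pooled-SD factors; handles unbalanced group
#' sizes through the exact correlation structure.
#'
#' @param q non-negative bound.
#' @param n_groups per-comparison group sizes (length k).
#' @param n_control control group size.
#' @param df error degrees of freedom of the pooled variance.
#' @return The joint probability.
#' @keywords internal
#' @export
dunnett_prob <- function(q, n_groups, n_control, df) {
  if (q <= 0) return(0)
  gl_z <- gauss_legendre(96)
  gl_u <- gauss_legendre(96)
  # control-mean factor: z ~ N(0,1) on [-9, 9]
  z <- gl_z$nodes * 9
  wz <- gl_z$weights * 9 * dnorm(z)
  # pooled-SD factor: u = s/sigma, u^2 ~ chi^2_df / df
  ulo <- sqrt(qchisq(1e-13, df) / df)
  uhi <- sqrt(qchisq(1 - 1e-13, df) / df)
  u <- (gl_u$nodes + 1) / 2 * (uhi - ulo) + ulo
  ldens <- log(2) + df / 2 * log(df / 2) - lgamma(df / 2) +
    (df - 1) * log(u) - df * u^2 / 2
  wu <- gl_u$weights * (uhi - ulo) / 2 * exp(ldens)
  b <- sqrt(n_groups / n_control)
  cc <- sqrt(1 + n_groups / n_control)
  total <- 0
  for (iu in seq_along(u)) {
    inner <- rep(1, length(z))
    for (i in seq_along(n_groups)) {
      inner <- inner * (pnorm(b[i] * z + cc[i] * q * u[iu]) -
                          pnorm(b[i] * z - cc[i] * q * u[iu]))
    }
    total <- total + wu[iu] * sum(wz * inner)
  }
  min(max(total, 0), 1)
}

#' Two-sided Dunnett critical value
#'
#' @inheritParams dunnett_prob
#' @param alpha familywise error rate.
#' @return The critical value `q` with `dunnett_prob(q, ...) = 1 - alpha`.
#' @export
dunnett_critical <- function(alpha, n_groups, n_control, df) {
  uniroot(function(q) dunnett_prob(q, n_groups, n_control, df) - (1 - alpha),
          interval = c(1, 12), extendInt = "upX", tol = 1e-8)$root
}

#' Compare variant groups to wild type
#'
#' `test = "t"` runs classical unpaired two-tailed Student t tests (pooled
#' variance) of each variant group against wild type. `test =
#' "anova_dunnett"` runs a one-way ANOVA over all groups and then Dunnett's
#' many-to-one comparisons against wild type: each comparison's t statistic
#' uses the pooled ANOVA error, and its familywise-adjusted p-value is
#' `1 - P(max |T| <= |t|)` from [dunnett_prob()].
#'
#' @param wt_values numeric wild-type observations.
#' @param variant_groups named list of numeric vectors (one per variant), or
#'   a data frame with `group` and `value` columns.
#' @param test `"anova_dunnett"` or `"t"`.
#' @param alpha significance threshold for the `significant` flags.
#' @return An object of class `group_comparison`: a tibble with one row per
#'   variant group (`group`, `n`, `mean`, `diff`, `statistic`, `df`,
#'   `p_value`, `significant`), with the omnibus ANOVA p (when applicable),
#'   the wild-type mean and the test recorded as attributes.
#' @export
#' @examples
#' set.seed(1)
#' compare_to_wt(rnorm(10), list(shifted = rnorm(10, 3), null = rnorm(10)))
compare_to_wt <- function(wt_values, variant_groups,
                          test = c("anova_dunnett", "t"), alpha = 0.05) {
  test <- match.arg(test)
  if (is.data.frame(variant_groups)) {
    stopifnot(all(c("group", "value") %in% names(variant_groups)))
    variant_groups <- split(variant_groups$value, variant_groups$group)
  }
  if (!length(variant_groups)) {
    abort("no variant groups supplied", class = "gabrisk_bad_input")
  }
  if (is.null(names(variant_groups)) || any(names(variant_groups) == "")) {
    names(variant_groups) <- paste0("group", seq_along(variant_groups))
  }
  sizes <- lengths(variant_groups)
  if (length(wt_values) < 2L || any(sizes < 2L)) {
    abort("every group needs >= 2 observations", class = "gabrisk_bad_input")
  }
  k <- length(variant_groups)
  wt_mean <- mean(wt_values)
  anova_p <- NA_real_

  if (test == "t") {
    rows <- purrr::imap_dfr(variant_groups, function(v, nm) {
      tt <- t.test(v, wt_values, var.equal = TRUE)
      tibble(group = nm, n = length(v), mean = mean(v),
             diff = mean(v) - wt_mean,
             statistic = unname(tt$statistic), df = unname(tt$parameter),
             p_value = tt$p.value)
    })
  } else {
    all_vals <- c(wt_values, unlist(variant_groups, use.names = FALSE))
    grp <- factor(rep(c("wt", names(variant_groups)),
                      times = c(length(wt_values), sizes)),
                  levels = c("wt", names(variant_groups)))
    fit <- aov(all_vals ~ grp)
    anova_p <- summary(fit)[[1]][["Pr(>F)"]][1]
    df_err <- fit$df.residual
    s2 <- sum(resid(fit)^2) / df_err
    n0 <- length(wt_values)
    rows <- purrr::imap_dfr(variant_groups, function(v, nm) {
      se <- sqrt(s2 * (1 / length(v) + 1 / n0))
      tstat <- (mean(v) - wt_mean) / se
      p_adj <- 1 - dunnett_prob(abs(tstat), n_groups = sizes,
                                n_control = n0, df = df_err)
      tibble(group = nm, n = length(v), mean = mean(v),
             diff = mean(v) - wt_mean,
             statistic = tstat, df = df_err, p_value = p_adj)
    })
  }
  rows <- mutate(rows, significant = .data$p_value < alpha)
  class(rows) <- c("group_comparison", class(rows))
  attr(rows, "test") <- test
  attr(rows, "wt_mean") <- wt_mean
  attr(rows, "wt_n") <- length(wt_values)
  attr(rows, "anova_p") <- anova_p
  attr(rows, "alpha") <- alpha
  rows
}

#' Call the reduced-current and gating-defect flags for variants
#'
#' `reduced_current` is flagged when the variant's current density is
#' significantly lower than wild type (p below `alpha` with a negative mean
#' difference); `gating_defect` is flagged when the gating impairment ratio
#' reaches `ratio_threshold`. The default threshold of 1.2 separates the
#' published calls computed from the summary kinetics (largest
#' non-defective ratio ~1.17, smallest defective ~1.24), with one discordant
#' borderline case (alpha4 H372P, ratio ~1.25 yet called intact) that a
#' threshold cannot reproduce; the threshold is configurable for exactly
#' that reason.
#'
#' @param comparison a `group_comparison` from [compare_to_wt()] on current
#'   densities (one row per variant), or a data frame with `p_value` and
#'   `diff` (variant minus wild type) columns.
#' @param impairment_ratio numeric gating impairment ratios (one per row of
#'   `comparison`), or a `gating_impairment` tibble.
#' @param ratio_threshold gating-defect threshold on the ratio.
#' @param alpha significance threshold for the density comparison.
#' @return A tibble with `group` (when available), `reduced_current` and
#'   `gating_defect` logical flags.
#' @export
classify_variant <- function(comparison, impairment_ratio,
                             ratio_threshold = 1.2, alpha = 0.05) {
  comparison <- as_tibble(comparison)
  if (!all(c("p_value", "diff") %in% names(comparison))) {
    abort("missing wild-type comparison statistics (`p_value`, `diff`)",
          class = "gabrisk_bad_input")
  }
  if (inherits(impairment_ratio, "gating_impairment") ||
      (is.data.frame(impairment_ratio) && "ratio" %in% names(impairment_ratio))) {
    impairment_ratio <- impairment_ratio$ratio
  }
  if (length(impairment_ratio) != nrow(comparison)) {
    abort("need one impairment ratio per comparison row",
          class = "gabrisk_bad_input")
  }
  tibble(
    group = if ("group" %in% names(comparison)) comparison$group else
      paste0("variant", seq_len(nrow(comparison))),
    reduced_current = comparison$p_value < alpha & comparison$diff < 0,
    gating_defect = impairment_ratio >= ratio_threshold
  )
}
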