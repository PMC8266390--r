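#' Two-tailed paired Student's t test
#'
#' Classical paired t test on within-subject differences, two-tailed.
#' Zero-variance differences are rejected with an informative error.
#'
#' @param x,y per-subject values, equal length >= 2.
#' @return One-row tibble: `statistic`, `df`, `p_value`, `mean_diff`,
#'   `conf_low`, `conf_high`, `method`.
#' @examples
#' paired_t(c(1, 2, 3, 5), c(2, 2, 4, 7))
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2L) {
    stop("x and y must have equal length >= 2", call. = FALSE)
  }
  d <- x - y
  if (stats::var(d) == 0) {
    stop("zero-variance differences: paired t test undefined", call. = FALSE)
  }
  ht <- stats::t.test(x, y, paired = TRUE)
  tibble::tibble(
    statistic = unname(ht$statistic),
    df = unname(ht$parameter),
    p_value = ht$p.value,
    mean_diff = unname(ht$estimate),
    conf_low = ht$conf.int[1],
    conf_high = ht$conf.int[2],
    method = "paired t (two-tailed)"
  )
}

#' Two-tailed unpaired (Student's) t test
#'
#' Equal-variance two-sample t test, two-tailed.
#'
#' @param x,y group values, each length >= 2.
#' @return One-row tibble, as [paired_t()].
#' @export
unpaired_t <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L) {
    stop("both groups need >= 2 values", call. = FALSE)
  }
  ht <- stats::t.test(x, y, var.equal = TRUE)
  tibble::tibble(
    statistic = unname(ht$statistic),
    df = unname(ht$parameter),
    p_value = ht$p.value,
    mean_diff = unname(ht$estimate[1] - ht$estimate[2]),
    conf_low = ht$conf.int[1],
    conf_high = ht$conf.int[2],
    method = "unpaired t (two-tailed)"
  )
}

#' Greenhouse-Geisser sphericity estimate
#'
#' The standard estimator
#' \deqn{\hat\epsilon = (\sum_i \lambda_i)^2 / ((k-1) \sum_i \lambda_i^2)}
#' where the lambdas are the eigenvalues of the double-centered sample
#' covariance of the k within-subject levels; computed here directly from
#' the double-centered covariance entries (trace and sum of squares), no
#' eigendecomposition needed. Bounded by `1/(k-1) <= epsilon <= 1`, with
#' `epsilon = 1` exactly for k = 2.
#'
#' @param data numeric matrix, subjects x within-levels (n >= 2, k >= 2).
#' @return Scalar epsilon.
#' @export
gg_epsilon <- function(data) {
  data <- as.matrix(data)
  n <- nrow(data)
  k <- ncol(data)
  if (n < 2L || k < 2L) stop("need >= 2 subjects and >= 2 levels",
                             call. = FALSE)
  s <- stats::cov(data)
  sc <- sweep(sweep(s, 1, rowMeans(s)), 2, colMeans(s)) + mean(s)
  denom <- sum(sc^2)
  if (denom == 0) stop("degenerate (all-zero) double-centered covariance",
                       call. = FALSE)
  sum(diag(sc))^2 / ((k - 1) * denom)
}

# Orthonormal contrast rows for one factor: (k-1) x k, rows orthonormal and
# orthogonal to the unit vector.
orthonormal_contrasts <- function(k) {
  m <- stats::contr.helmert(k)            # k x (k-1)
  m <- sweep(m, 2, sqrt(colSums(m^2)), "/")
  t(m)
}

# Greenhouse-Geisser epsilon from contrast scores (n x q): trace form on the
# sample covariance of the scores. For a single within factor this equals
# gg_epsilon() on the raw level matrix.
epsilon_from_scores <- function(scores) {
  q <- ncol(scores)
  s <- stats::cov(scores)
  denom <- sum(s^2)
  if (denom == 0) return(NA_real_)
  sum(diag(s))^2 / (q * denom)
}

anova_row <- function(effect, ss, df_num, ss_err, df_den, epsilon = 1) {
  f <- (ss / df_num) / (ss_err / df_den)
  tibble::tibble(
    effect = effect,
    statistic = f,
    df_num = df_num,
    df_den = df_den,
    epsilon_gg = epsilon,
    df_num_gg = epsilon * df_num,
    df_den_gg = epsilon * df_den,
    p_uncorrected = stats::pf(f, df_num, df_den, lower.tail = FALSE),
    p_gg = stats::pf(f, epsilon * df_num, epsilon * df_den,
                     lower.tail = FALSE)
  )
}

new_anova_fit <- function(table, n, design) {
  structure(list(table = table, n = n, design = design),
            class = "anova_fit")
}

#' @export
print.anova_fit <- function(x, ...) {
  cat("<anova_fit> ", x$design, " (n = ", x$n, ")\n", sep = "")
  print(as.data.frame(x$table), digits = 4, row.names = FALSE)
  invisible(x)
}

#' Repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Within-subject ANOVA for one or more crossed within factors on a complete
#' balanced table (one observation per subject and cell). For each within
#' effect the error term is its interaction with subjects. The
#' Greenhouse-Geisser epsilon is estimated per effect from the covariance of
#' that effect's orthonormal contrast scores and, when `apply_gg = TRUE`
#' (default, matching the convention of applying the correction
#' unconditionally rather than after a sphericity pretest), multiplies both
#' degrees of freedom of the F test; for two-level effects epsilon is exactly
#' 1 and the correction is the identity.
#'
#' @param data either a numeric matrix (subjects x levels of a single within
#'   factor) or a long data frame.
#' @param dv,subject,within for long data: column names (strings) of the
#'   dependent variable, the subject id, and one or more within-factor
#'   columns.
#' @param apply_gg apply the Greenhouse-Geisser df correction (default TRUE).
#' @return An `anova_fit`; `tidy()` returns the effect table (`effect`,
#'   `statistic` (F), `df_num`, `df_den`, `epsilon_gg`, corrected dfs,
#'   `p_uncorrected`, `p_gg`), `glance()` a one-row design summary.
#' @examples
#' y <- matrix(rnorm(24), nrow = 6)  # 6 subjects x 4 levels
#' tidy(rm_anova(y))
#' @export
rm_anova <- function(data, dv = "value", subject = "subject",
                     within = "condition", apply_gg = TRUE) {
  if (is.matrix(data) || (is.data.frame(data) &&
                          all(vapply(data, is.numeric, logical(1))) &&
                          !all(c(dv, subject) %in% names(data)))) {
    y <- as.matrix(data)
    cells <- tibble::tibble(level = factor(colnames(y) %||%
                                             paste0("L", seq_len(ncol(y)))))
    factors <- "level"
    k_per <- ncol(y)
  } else {
    long <- tibble::as_tibble(data)
    missing_cols <- setdiff(c(dv, subject, within), names(long))
    if (length(missing_cols)) {
      stop("missing column(s): ", paste(missing_cols, collapse = ", "),
           call. = FALSE)
    }
    long[within] <- lapply(long[within], factor)
    cells <- do.call(tidyr::expand_grid,
                     lapply(long[within], function(f) factor(levels(f),
                                                             levels(f))))
    names(cells) <- within
    factors <- within
    k_per <- vapply(long[within], nlevels, integer(1))
    wide <- tidyr::pivot_wider(
      long,
      id_cols = dplyr::all_of(subject),
      names_from = dplyr::all_of(within),
      values_from = dplyr::all_of(dv),
      names_sep = "\r"
    )
    cell_names <- apply(as.data.frame(lapply(cells, as.character)), 1, paste,
                        collapse = "\r")
    if (!all(cell_names %in% names(wide)) || anyNA(wide[cell_names])) {
      stop("design must be complete and balanced: one observation per ",
           "subject per cell", call. = FALSE)
    }
    y <- as.matrix(wide[cell_names])
  }
  n <- nrow(y)
  if (n < 2L) stop("need >= 2 subjects", call. = FALSE)
  if (stats::var(as.vector(y)) == 0) {
    stop("all values identical: zero residual variance", call. = FALSE)
  }

  effects <- unlist(lapply(seq_along(factors), function(m) {
    utils::combn(factors, m, simplify = FALSE)
  }), recursive = FALSE)

  rows <- purrr::map_dfr(effects, function(eff) {
    mats <- lapply(factors, function(f) {
      k <- if (length(factors) == 1L) k_per else k_per[[f]]
      if (f %in% eff) orthonormal_contrasts(k)
      else matrix(1 / sqrt(k), nrow = 1, ncol = k)
    })
    # cell order from expand_grid: first factor varies slowest
    m_eff <- Reduce(`%x%`, mats)
    scores <- y %*% t(m_eff)
    q <- ncol(scores)
    ss_eff <- n * sum(colMeans(scores)^2)
    centered <- sweep(scores, 2, colMeans(scores))
    ss_err <- sum(centered^2)
    if (ss_err == 0) {
      stop("zero residual variance for effect ",
           paste(eff, collapse = ":"), call. = FALSE)
    }
    eps <- if (apply_gg) epsilon_from_scores(scores) else 1
    if (is.na(eps)) eps <- 1
    anova_row(paste(eff, collapse = ":"), ss_eff, q, ss_err, q * (n - 1),
              eps)
  })
  new_anova_fit(rows, n,
                paste0("repeated-measures ANOVA (",
                       paste(factors, collapse = " x "), ")"))
}

#' Mixed (split-plot) ANOVA: one between-subjects group factor, one within
#' factor, with Greenhouse-Geisser correction on the within terms
#'
#' Standard split-plot decomposition: the between effect is tested against
#' between-subject variation within groups; the within main effect and the
#' group x within interaction are tested against the pooled
#' subject-by-within residual. Greenhouse-Geisser epsilon is estimated from
#' the pooled within-group covariance of the orthonormal contrast scores and
#' applied to the within and interaction terms (identity for two-level
#' within factors). Groups may differ in size; with a single group the fit
#' reduces to the repeated-measures ANOVA (between and interaction rows are
#' dropped).
#'
#' @param data numeric matrix, subjects x within-levels, or a long data
#'   frame (see [rm_anova()]).
#' @param group per-subject group labels (for matrix input), or the group
#'   column name (for long input).
#' @param dv,subject,within long-format column names.
#' @param apply_gg apply the Greenhouse-Geisser correction (default TRUE).
#' @return An `anova_fit` with rows `group`, `within`, and
#'   `group:within`.
#' @export
mixed_anova <- function(data, group, dv = "value", subject = "subject",
                        within = "condition", apply_gg = TRUE) {
  if (is.matrix(data)) {
    y <- data
    g <- factor(group)
  } else {
    long <- tibble::as_tibble(data)
    stopifnot(all(c(dv, subject, within, group) %in% names(long)))
    long[[within]] <- factor(long[[within]])
    wide <- tidyr::pivot_wider(long,
                               id_cols = dplyr::all_of(c(subject, group)),
                               names_from = dplyr::all_of(within),
                               values_from = dplyr::all_of(dv))
    lev <- levels(long[[within]])
    if (anyNA(wide[lev])) {
      stop("design must have one observation per subject per within level",
           call. = FALSE)
    }
    y <- as.matrix(wide[lev])
    g <- factor(wide[[group]])
  }
  n <- nrow(y)
  k <- ncol(y)
  if (length(g) != n) stop("group must have one label per subject",
                           call. = FALSE)
  n_g <- table(g)
  if (nlevels(g) > 1L && any(n_g < 2L)) {
    stop("every group needs >= 2 subjects", call. = FALSE)
  }

  # between-subjects stratum, on subject means
  m_i <- rowMeans(y)
  m_g <- tapply(m_i, g, mean)
  grand <- mean(m_i)
  ss_group <- k * sum(n_g * (m_g - grand)^2)
  ss_subj <- k * sum((m_i - m_g[g])^2)
  df_group <- nlevels(g) - 1L
  df_subj <- n - nlevels(g)
  if (ss_subj == 0) stop("zero between-subject residual variance",
                         call. = FALSE)

  # within stratum, on orthonormal contrast scores
  cmat <- orthonormal_contrasts(k)
  scores <- y %*% t(cmat)                       # n x (k-1)
  q <- k - 1L
  col_grand <- colMeans(scores)
  group_means <- rowsum(scores, g) / as.vector(n_g)   # G x q
  ss_within <- n * sum(col_grand^2)
  ss_inter <- sum(as.vector(n_g) *
                    rowSums(sweep(group_means, 2, col_grand)^2))
  resid <- scores - group_means[g, , drop = FALSE]
  ss_err <- sum(resid^2)
  df_err <- (n - nlevels(g)) * q
  if (ss_err == 0) stop("zero within-subject residual variance",
                        call. = FALSE)

  pooled <- Reduce(`+`, lapply(levels(g), function(gl) {
    sub <- scores[g == gl, , drop = FALSE]
    if (nrow(sub) < 2L) matrix(0, q, q) else (nrow(sub) - 1L) *
      stats::cov(sub)
  })) / max(n - nlevels(g), 1L)
  eps <- if (apply_gg) {
    e <- epsilon_from_scores_cov(pooled, q)
    if (is.na(e)) 1 else e
  } else 1

  rows <- dplyr::bind_rows(
    if (nlevels(g) > 1L) {
      anova_row("group", ss_group, df_group, ss_subj, df_subj, 1)
    },
    anova_row("within", ss_within, q, ss_err, df_err, eps),
    if (nlevels(g) > 1L) {
      anova_row("group:within", ss_inter, df_group * q, ss_err, df_err, eps)
    }
  )
  new_anova_fit(rows, n, "mixed (split-plot) ANOVA")
}

epsilon_from_scores_cov <- function(s, q) {
  denom <- sum(s^2)
  if (denom == 0) return(NA_real_)
  sum(diag(s))^2 / (q * denom)
}

#' Bonferroni correction
#'
#' `p_adj = min(1, m * p)` over a family of m p values.
#'
#' @param p_values numeric vector in \[0, 1\].
#' @return Adjusted p values, same length.
#' @export
bonferroni <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "bonferroni")
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname rm_anova
#' @param x an `anova_fit`.
#' @param ... unused.
#' @method tidy anova_fit
#' @export
tidy.anova_fit <- function(x, ...) x$table

#' @rdname rm_anova
#' @method glance anova_fit
#' @export
glance.anova_fit <- function(x, ...) {
  tibble::tibble(n_subjects = x$n, n_effects = nrow(x$table),
                 design = x$design)
}
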