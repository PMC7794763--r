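#' Significance stars
#'
#' Annotation convention: `*` p < 0.05, `**` p < 0.01, `***` p < 0.001,
#' `****` p < 0.0001; empty otherwise.
#'
#' @param p Vector of p-values.
#' @return Character vector of stars.
#' @export
significance_stars <- function(p) {
  vapply(p, function(x) {
    if (is.na(x)) return("")
    if (x < 1e-4) "****" else if (x < 1e-3) "***"
    else if (x < 1e-2) "**" else if (x < 0.05) "*" else ""
  }, character(1))
}

rss_of <- function(fit) sum(stats::residuals(fit)^2)

new_anova_result <- function(table, cells, mse, df_resid, posthoc = NULL) {
  structure(list(table = table, cells = cells, mse = mse,
                 df_resid = df_resid, posthoc = posthoc),
            class = "erg_anova")
}

#' @export
print.erg_anova <- function(x, ...) {
  cat("Fixed-effects ANOVA\n")
  tab <- x$table
  tab$stars <- significance_stars(tab$p)
  print(tab, row.names = FALSE, digits = 5)
  if (!is.null(x$posthoc)) {
    cat("\nBonferroni post-hoc:\n")
    print(x$posthoc, row.names = FALSE, digits = 5)
  }
  invisible(x)
}

# F and p from SS/df against a residual mean square; degenerate (zero)
# residual variance yields F = NA, p = 1 when the effect SS is also ~0
f_and_p <- function(ss, df, mse, df_resid, scale) {
  eps <- 1e-12 * max(scale, 1)
  if (mse <= eps) {
    if (ss <= eps) return(c(f = NA_real_, p = 1))
    return(c(f = Inf, p = 0))
  }
  if (ss <= eps) return(c(f = 0, p = 1))  # effect SS is numerical noise
  f <- (ss / df) / mse
  c(f = f, p = stats::pf(f, df, df_resid, lower.tail = FALSE))
}

#' Ordinary two-way (factorial) ANOVA
#'
#' Fixed-effects factorial decomposition of `value` over two crossed
#' factors.  For unbalanced designs the sum-of-squares type matters;
#' Type II is the default (each main effect adjusted for the other, the
#' interaction tested from the full model), with Types I and III
#' switchable.  All types coincide for balanced data.
#'
#' @param value Numeric response vector.
#' @param factor_a,factor_b Factor (or coercible) vectors, full crossing
#'   with at least 2 observations per cell.
#' @param ss_type 1, 2 (default) or 3.
#' @return An object of class `erg_anova`; `$table` holds one row per
#'   effect (A, B, A:B, residual) with sum of squares, df, F and p;
#'   `$cells` holds per-cell means and sizes for post-hoc tests.
#' @export
two_way_anova <- function(value, factor_a, factor_b, ss_type = 2) {
  y <- as.numeric(value)
  A <- factor(factor_a); B <- factor(factor_b)
  if (length(y) != length(A) || length(y) != length(B))
    stop("value and factors must have equal length")
  counts <- table(A, B)
  if (nlevels(A) < 2 || nlevels(B) < 2 || any(counts == 0))
    stop(errorCondition("empty cell: full factorial crossing required",
                        class = c("erg_empty_cell", "error", "condition")))
  if (any(counts < 2))
    stop(errorCondition("each cell needs at least 2 observations",
                        class = c("erg_small_cell", "error", "condition")))
  n <- length(y); a <- nlevels(A); b <- nlevels(B)
  df <- data.frame(y = y, A = A, B = B)
  if (ss_type == 3) {
    op <- options(contrasts = c("contr.sum", "contr.poly")); on.exit(options(op))
  }
  fit_full <- stats::lm(y ~ A * B, data = df)
  fit_ab <- stats::lm(y ~ A + B, data = df)
  rss_full <- rss_of(fit_full)
  if (ss_type == 1) {
    tab <- stats::anova(stats::lm(y ~ A * B, data = df))
    ss <- tab$`Sum Sq`[1:3]
  } else if (ss_type == 2) {
    ss_a <- rss_of(stats::lm(y ~ B, data = df)) - rss_of(fit_ab)
    ss_b <- rss_of(stats::lm(y ~ A, data = df)) - rss_of(fit_ab)
    ss_ab <- rss_of(fit_ab) - rss_full
    ss <- c(ss_a, ss_b, ss_ab)
  } else if (ss_type == 3) {
    dr <- stats::drop1(fit_full, scope = ~ A + B + A:B, test = "F")
    ss <- dr$`Sum of Sq`[match(c("A", "B", "A:B"), rownames(dr))]
  } else stop("ss_type must be 1, 2 or 3")
  ss <- pmax(ss, 0)                       # guard fp round-off
  df_eff <- c(a - 1, b - 1, (a - 1) * (b - 1))
  df_resid <- n - a * b
  mse <- rss_full / df_resid
  scale <- sum((y - mean(y))^2)
  if (scale <= 1e-12 * max(1, mean(y)^2) * n)
    warning("zero total variance: degenerate ANOVA (F undefined, p = 1)")
  fp <- t(vapply(1:3, function(i)
    f_and_p(ss[i], df_eff[i], mse, df_resid, scale), numeric(2)))
  table <- data.frame(
    effect = c("factor_a", "factor_b", "interaction", "residual"),
    sum_sq = c(ss, rss_full), df = c(df_eff, df_resid),
    F = c(fp[, 1], NA), p = c(fp[, 2], NA))
  cell_stats <- do.call(rbind, lapply(levels(A), function(la)
    do.call(rbind, lapply(levels(B), function(lb) {
      v <- y[A == la & B == lb]
      data.frame(factor_a = la, factor_b = lb, mean = mean(v),
                 n = length(v), stringsAsFactors = FALSE)
    }))))
  new_anova_result(table, cell_stats, mse, df_resid)
}

#' Ordinary one-way ANOVA
#'
#' @param value Numeric response.
#' @param group Grouping factor with >= 2 levels, each with >= 2
#'   observations.
#' @return An `erg_anova` with effects `group` and `residual`.
#' @export
one_way_anova <- function(value, group) {
  y <- as.numeric(value)
  G <- factor(group)
  if (nlevels(G) < 2) stop("need at least two groups")
  counts <- table(G)
  if (any(counts < 2))
    stop(errorCondition("each group needs at least 2 observations",
                        class = c("erg_small_cell", "error", "condition")))
  n <- length(y); k <- nlevels(G)
  gm <- tapply(y, G, mean); gn <- tapply(y, G, length)
  ss_between <- sum(gn * (gm - mean(y))^2)
  ss_within <- sum((y - gm[G])^2)
  df_b <- k - 1; df_w <- n - k
  mse <- ss_within / df_w
  scale <- sum((y - mean(y))^2)
  if (scale <= 1e-12 * max(1, mean(y)^2) * n)
    warning("zero total variance: degenerate ANOVA (F undefined, p = 1)")
  fp <- f_and_p(ss_between, df_b, mse, df_w, scale)
  table <- data.frame(effect = c("group", "residual"),
                      sum_sq = c(ss_between, ss_within),
                      df = c(df_b, df_w), F = c(fp["f"], NA),
                      p = c(fp["p"], NA))
  cells <- data.frame(factor_a = levels(G), factor_b = NA_character_,
                      mean = as.numeric(gm), n = as.integer(gn),
                      stringsAsFactors = FALSE)
  new_anova_result(table, cells, mse, df_w)
}

# default post-hoc family for a 2x2: the simple-effect contrasts the study
# tables annotate — factor_a effect within each level of factor_b, and
# factor_b effect within each level of factor_a (m = 4)
default_comparisons <- function(cells) {
  la <- unique(cells$factor_a); lb <- unique(cells$factor_b)
  comps <- list()
  for (bb in lb) for (i in seq_along(la)[-1])
    comps[[length(comps) + 1]] <- list(a = c(la[1], bb), b = c(la[i], bb))
  for (aa in la) for (j in seq_along(lb)[-1])
    comps[[length(comps) + 1]] <- list(a = c(aa, lb[1]), b = c(aa, lb[j]))
  comps
}

cell_lookup <- function(cells, key) {
  i <- which(cells$factor_a == key[1] &
               (is.na(cells$factor_b) | cells$factor_b == key[2]))
  if (length(i) != 1)
    stop(errorCondition(paste0("unknown cell: ", paste(key, collapse = ":")),
                        class = c("erg_unknown_cell", "error", "condition")))
  i
}

#' Bonferroni-corrected pairwise post-hoc comparisons
#'
#' Pairwise cell comparisons using the ANOVA residual mean square as the
#' pooled error; each raw p is multiplied by the number of comparisons and
#' capped at 1.  The default family for a 2x2 design is the four
#' simple-effect contrasts (factor A within each level of B, and B within
#' each level of A).
#'
#' @param fit An `erg_anova`.
#' @param comparisons List of comparisons; each element is a list with
#'   elements `a` and `b`, each a `c(factor_a_level, factor_b_level)` pair
#'   (the second entry ignored for one-way fits).  `NULL` uses the default
#'   family.
#' @param alpha Significance level.
#' @return Data frame (also stored in `fit$posthoc`) with comparison label,
#'   mean difference, t, raw and adjusted p, significance and stars.
#' @export
bonferroni_posthoc <- function(fit, comparisons = NULL, alpha = 0.05) {
  cells <- fit$cells
  if (is.null(comparisons)) comparisons <- default_comparisons(cells)
  m <- length(comparisons)
  rows <- lapply(comparisons, function(cmp) {
    i <- cell_lookup(cells, cmp$a); j <- cell_lookup(cells, cmp$b)
    diff <- cells$mean[j] - cells$mean[i]
    se <- sqrt(fit$mse * (1 / cells$n[i] + 1 / cells$n[j]))
    if (se == 0) {
      tval <- if (diff == 0) 0 else sign(diff) * Inf
      p <- if (diff == 0) 1 else 0
    } else {
      tval <- diff / se
      p <- 2 * stats::pt(-abs(tval), fit$df_resid)
    }
    lab_cell <- function(k) {
      if (is.na(cells$factor_b[k])) return(cells$factor_a[k])
      paste(cells$factor_a[k], cells$factor_b[k], sep = ":")
    }
    data.frame(comparison = paste(lab_cell(i), "vs", lab_cell(j)),
               diff = diff, t = tval, p_raw = p,
               p_adj = min(1, m * p), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$significant <- out$p_adj < alpha
  out$stars <- significance_stars(out$p_adj)
  out
}

#' Unpaired two-sample t-test
#'
#' Student's pooled-variance t-test by default; Welch's unequal-variance
#' form optionally.  Degenerate zero-variance input returns t = 0, p = 1
#' when the means agree (and ±Inf, p = 0 otherwise) with a warning, rather
#' than failing, so simulation sweeps never crash.
#'
#' @param values_a,values_b Numeric vectors, each of length >= 2.
#' @param welch Use Welch's correction.
#' @return List with `t`, `df`, `p`.
#' @export
unpaired_t <- function(values_a, values_b, welch = FALSE) {
  a <- as.numeric(values_a); b <- as.numeric(values_b)
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2) stop("each group needs n >= 2")
  va <- stats::var(a); vb <- stats::var(b)
  d <- mean(a) - mean(b)
  if (welch) {
    se2 <- va / na + vb / nb
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  } else {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se2 <- sp2 * (1 / na + 1 / nb)
    df <- na + nb - 2
  }
  if (!is.finite(se2) || se2 <= 0) {
    warning("zero variance in t-test: degenerate result")
    return(list(t = if (d == 0) 0 else sign(d) * Inf,
                df = df, p = if (d == 0) 1 else 0))
  }
  tval <- d / sqrt(se2)
  list(t = tval, df = df, p = 2 * stats::pt(-abs(tval), df))
}

#' Realize a raw sample with exact mean, SEM and n
#'
#' Constructs a numeric vector of length `n` whose sample mean and standard
#' error equal the given summaries exactly (affine transform of a
#' standardized sequence).  Mean, SEM and n are sufficient statistics for
#' the fixed-effects ANOVA, so any realization yields the same result.
#'
#' @param mean,sem,n Cell summaries (`n >= 2`, `sem > 0` or 0).
#' @return Numeric vector of length `n`.
#' @export
realize_cell <- function(mean, sem, n) {
  if (n < 2) stop("n must be >= 2")
  z <- seq_len(n)
  z <- (z - base::mean(z)) / stats::sd(z)
  mean + sem * sqrt(n) * z
}

#' Factorial ANOVA from printed summary statistics
#'
#' Runs the two-way fixed-effects ANOVA given only per-cell mean, SEM and
#' n — the format of published group tables.  Because (mean, SEM, n) are
#' sufficient for the factorial decomposition, the result equals
#' [two_way_anova()] on any raw data with those summaries, balanced or not;
#' internally a sample realizing the summaries exactly is constructed with
#' [realize_cell()] and analysed by the raw-data path.
#'
#' @param cells A `summary_table` (or data frame) with columns `factor_a`,
#'   `factor_b`, `mean`, `sem`, `n`, one row per cell of a full crossing.
#' @param ss_type Sum-of-squares type, as in [two_way_anova()].
#' @return An `erg_anova`.
#' @export
summary_stats_anova <- function(cells, ss_type = 2) {
  cells <- validate_summary(as.data.frame(cells), require_crossing = TRUE)
  y <- unlist(lapply(seq_len(nrow(cells)), function(i)
    realize_cell(cells$mean[i], cells$sem[i], cells$n[i])))
  A <- rep(cells$factor_a, cells$n)
  B <- rep(cells$factor_b, cells$n)
  two_way_anova(y, A, B, ss_type = ss_type)
}

#' Write an ANOVA report as TSV
#'
#' Emits the effect table and, when present, the Bonferroni post-hoc table
#' with significance stars, in a fixed deterministic format.
#'
#' @param fit An `erg_anova`.
#' @param path Output TSV path.
#' @param posthoc Optional post-hoc data frame from [bonferroni_posthoc()].
#' @export
write_anova <- function(fit, path, posthoc = NULL) {
  tab <- fit$table
  tab$stars <- significance_stars(tab$p)
  for (col in c("sum_sq", "F", "p")) tab[[col]] <- fmt_num(tab[[col]])
  con <- file(path, open = "wt")
  on.exit(close(con))
  utils::write.table(tab, con, sep = "\t", row.names = FALSE, quote = FALSE,
                     na = "")
  if (!is.null(posthoc)) {
    writeLines("", con)
    ph <- posthoc
    for (col in c("diff", "t", "p_raw", "p_adj"))
      ph[[col]] <- fmt_num(ph[[col]])
    utils::write.table(ph, con, sep = "\t", row.names = FALSE, quote = FALSE,
                       na = "")
  }
  invisible(path)
}
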