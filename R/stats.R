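# Rank-based factorial statistics ---------------------------------------------
#
# The kinematic endpoint data are non-parametric; the factorial analysis is a
# Scheirer-Ray-Hare test (a two-way ANOVA on mid-ranks with a
# chi-square-referred H statistic), followed by pairwise Wilcoxon rank-sum
# post-hoc tests with Bonferroni adjustment.

#' Scheirer-Ray-Hare rank-based two-way test
#'
#' Responses are replaced by mid-ranks over the whole dataset and a two-way
#' ANOVA is computed on the ranks. For each effect (A, B, A:B) the test
#' statistic is \eqn{H = SS_{effect} / MS_{total}} with
#' \eqn{MS_{total} = SS_{total} / (N - 1)}, referred to a chi-square
#' distribution at the effect's degrees of freedom. The ordinary rank-ANOVA
#' F statistic (with its denominator degrees of freedom) is reported
#' alongside, since published analyses sometimes quote that convention.
#'
#' Balanced designs use closed-form sums of squares; unbalanced designs use
#' type-II sums of squares on ranks via nested model comparisons.
#'
#' @param formula two-sided formula `response ~ A + B` (an `A:B` interaction
#'   is always included in the decomposition).
#' @param data data frame holding the response and the two factors.
#' @return object of class `srh_test`: a data frame with one row per effect
#'   (`df`, `ss_ranks`, `H`, `p_chisq`, `F`, `df1`, `df2`, `p_F`) plus
#'   attributes `N`, `ms_total`, `balanced` and `degenerate`.
#' @examples
#' d <- expand.grid(A = c("a1", "a2"), B = c("b1", "b2"), rep = 1:5)
#' d$y <- rnorm(nrow(d))
#' scheirer_ray_hare(y ~ A + B, d)
#' @export
scheirer_ray_hare <- function(formula, data) {
  mf <- stats::model.frame(formula, data)
  if (ncol(mf) != 3L) {
    stop("formula must be of the form response ~ A + B", call. = FALSE)
  }
  y <- mf[[1L]]
  A <- factor(mf[[2L]]); B <- factor(mf[[3L]])
  if (anyNA(y) || anyNA(A) || anyNA(B)) {
    stop("missing values are not allowed", call. = FALSE)
  }
  if (nlevels(A) < 2L || nlevels(B) < 2L) {
    stop("both factors need at least two levels", call. = FALSE)
  }
  cell_n <- table(A, B)
  if (any(cell_n == 0L)) {
    stop("every cell of the A x B design must be non-empty", call. = FALSE)
  }
  N <- length(y)
  a <- nlevels(A); b <- nlevels(B)
  df <- c(A = a - 1L, B = b - 1L, `A:B` = (a - 1L) * (b - 1L))
  eff_names <- c(attr(stats::terms(formula), "term.labels")[1:2],
                 paste(attr(stats::terms(formula), "term.labels")[1:2],
                       collapse = ":"))

  r <- rank(y)                                  # mid-ranks
  ss_total <- sum((r - mean(r))^2)
  degenerate <- ss_total <= .Machine$double.eps * N

  if (degenerate) {
    warning("constant response: H statistics undefined, reporting H = 0, ",
            "p = 1", call. = FALSE)
    tab <- data.frame(effect = eff_names, df = as.integer(df),
                      ss_ranks = 0, H = 0, p_chisq = 1,
                      F = 0, df1 = as.integer(df),
                      df2 = N - a * b, p_F = 1)
    return(structure(tab, class = c("srh_test", "data.frame"),
                     N = N, ms_total = 0, balanced = TRUE,
                     degenerate = TRUE))
  }

  balanced <- length(unique(as.vector(cell_n))) == 1L
  if (balanced) {
    rb <- mean(r)
    ss_A <- sum(tapply(r, A, function(z) length(z) * (mean(z) - rb)^2))
    ss_B <- sum(tapply(r, B, function(z) length(z) * (mean(z) - rb)^2))
    cell_means <- tapply(r, list(A, B), mean)
    cell_sizes <- table(A, B)
    ss_cells <- sum(cell_sizes * (cell_means - rb)^2)
    ss_AB <- ss_cells - ss_A - ss_B
    ss_within <- ss_total - ss_cells
  } else {
    # type-II sums of squares on ranks via nested model comparisons
    rss <- function(X) sum(stats::lm.fit(X, r)$residuals^2)
    dat <- data.frame(A = A, B = B)
    r_A <- rss(stats::model.matrix(~A, dat))
    r_B <- rss(stats::model.matrix(~B, dat))
    r_AB <- rss(stats::model.matrix(~A + B, dat))
    r_full <- rss(stats::model.matrix(~A * B, dat))
    ss_A <- r_B - r_AB
    ss_B <- r_A - r_AB
    ss_AB <- r_AB - r_full
    ss_within <- r_full
  }

  ms_total <- ss_total / (N - 1L)
  ss <- c(ss_A, ss_B, ss_AB)
  H <- pmax(0, ss / ms_total)
  p_chisq <- stats::pchisq(H, df, lower.tail = FALSE)
  df2 <- N - a * b
  ms_within <- ss_within / df2
  Fstat <- (ss / df) / ms_within
  p_F <- stats::pf(Fstat, df, df2, lower.tail = FALSE)

  tab <- data.frame(effect = eff_names, df = as.integer(df),
                    ss_ranks = ss, H = H, p_chisq = p_chisq,
                    F = Fstat, df1 = as.integer(df), df2 = df2, p_F = p_F)
  rownames(tab) <- NULL
  structure(tab, class = c("srh_test", "data.frame"),
            N = N, ms_total = ms_total, balanced = balanced,
            degenerate = FALSE)
}

#' @export
print.srh_test <- function(x, ...) {
  cat("Scheirer-Ray-Hare rank-based two-way test (N =", attr(x, "N"), ")\n")
  print.data.frame(cbind(x, stars = significance_stars(x$p_chisq)),
                   digits = 4, row.names = FALSE)
  invisible(x)
}

# Wilcoxon / Mann-Whitney -----------------------------------------------------

#' Two-sample Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Two-sided; mid-ranks for ties. The exact null distribution is used when
#' both samples have at most 12 observations and there are no ties;
#' otherwise the normal approximation with tie-corrected variance and
#' continuity correction. `W` is the rank sum of `x` minus its minimum
#' (the Mann-Whitney U statistic for the first sample).
#'
#' @param x,y numeric samples.
#' @return list with `W`, `p` and `exact` (logical).
#' @examples
#' wilcoxon_mann_whitney(c(1, 2, 3), c(10, 11, 12))
#' @export
wilcoxon_mann_whitney <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y),
            length(x) >= 1L, length(y) >= 1L)
  if (anyNA(x) || anyNA(y)) stop("missing values are not allowed",
                                 call. = FALSE)
  ties <- any(duplicated(c(x, y)))
  exact <- !ties && length(x) <= 12L && length(y) <= 12L
  wt <- suppressWarnings(stats::wilcox.test(x, y, alternative = "two.sided",
                                            exact = exact, correct = TRUE))
  list(W = unname(wt$statistic), p = unname(wt$p.value), exact = exact)
}

#' Pairwise Wilcoxon rank-sum post-hoc tests
#'
#' All pairwise two-sided comparisons between groups, with Bonferroni
#' adjustment \eqn{p_{adj} = \min(1, m \cdot p)} over the m comparisons.
#'
#' @param response numeric response vector.
#' @param group grouping factor (>= 2 levels, each non-empty).
#' @param adjust `"bonferroni"` or `"none"`.
#' @return data frame with one row per pair: `group1`, `group2`, `W`, `p`,
#'   `p_adj`, `stars`.
#' @export
pairwise_wilcoxon <- function(response, group,
                              adjust = c("bonferroni", "none")) {
  adjust <- match.arg(adjust)
  group <- as.factor(group)   # declared-but-empty levels are an error
  stopifnot(length(response) == length(group))
  if (nlevels(group) < 2L) stop("need at least two groups", call. = FALSE)
  if (any(table(group) == 0L)) stop("every group needs at least one ",
                                    "observation", call. = FALSE)
  pairs <- utils::combn(levels(group), 2L)
  m <- ncol(pairs)
  rows <- lapply(seq_len(m), function(i) {
    g1 <- pairs[1L, i]; g2 <- pairs[2L, i]
    res <- wilcoxon_mann_whitney(response[group == g1],
                                 response[group == g2])
    data.frame(group1 = g1, group2 = g2, W = res$W, p = res$p)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- if (adjust == "bonferroni") pmin(1, m * out$p) else out$p
  out$stars <- significance_stars(out$p_adj)
  out
}

# Auxiliary tests --------------------------------------------------------------

#' Auxiliary univariate and bivariate tests
#'
#' Standard checks used around the rank-based battery: Shapiro-Wilk
#' normality (`"shapiro"`), classic Levene homoscedasticity with mean
#' centring (`"levene"`), unpaired/paired two-sample t-tests (`"t"`,
#' `"t_paired"`), and Spearman rank-order correlation with mid-ranks
#' (`"spearman"`).
#'
#' @param type which test to run.
#' @param x numeric vector (first sample).
#' @param y numeric vector (second sample); unused for `"shapiro"`.
#' @return data frame with columns `method`, `statistic`, `p`.
#' @export
aux_test <- function(type = c("shapiro", "levene", "t", "t_paired",
                              "spearman"),
                     x, y = NULL) {
  type <- match.arg(type)
  if (type != "shapiro" && is.null(y)) {
    stop("`y` is required for this test", call. = FALSE)
  }
  res <- switch(type,
    shapiro = {
      ht <- stats::shapiro.test(x)
      c(ht$statistic, ht$p.value)
    },
    levene = {
      g <- factor(rep(c("x", "y"), c(length(x), length(y))))
      lt <- car::leveneTest(c(x, y), g, center = mean)
      c(lt[1L, "F value"], lt[1L, "Pr(>F)"])
    },
    t = {
      ht <- stats::t.test(x, y, paired = FALSE)
      c(ht$statistic, ht$p.value)
    },
    t_paired = {
      d <- x - y
      if (stats::sd(d) == 0 && mean(d) == 0) {
        c(0, 1)                      # identical pairs: no evidence either way
      } else {
        ht <- stats::t.test(x, y, paired = TRUE)
        c(ht$statistic, ht$p.value)
      }
    },
    spearman = {
      # mid-rank Pearson correlation; p via t approximation as in cor.test
      ht <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                             exact = FALSE))
      c(ht$estimate, ht$p.value)
    })
  data.frame(method = type, statistic = unname(res[1L]),
             p = unname(res[2L]))
}

#' Significance stars
#'
#' Banding with inclusive boundaries: `p > 0.05` not significant (`"ns"`),
#' `p <= 0.05` `"*"`, `p <= 0.01` `"**"`, `p <= 0.001` `"***"`.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return character vector of labels.
#' @examples
#' significance_stars(c(0.2, 0.05, 0.01, 0.001))
#' @export
significance_stars <- function(p) {
  stopifnot(is.numeric(p))
  if (any(!is.finite(p) | p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  ifelse(p <= 0.001, "***",
         ifelse(p <= 0.01, "**",
                ifelse(p <= 0.05, "*", "ns")))
}
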