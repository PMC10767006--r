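## Group statistics following the study conventions: one-way ANOVA with
## Bonferroni-corrected pairwise post hoc t tests; mean +/- SEM for
## biomechanical metrics and mean +/- SD for image metrics.

#' One-way analysis of variance across groups
#'
#' Classical fixed-effects one-way ANOVA (F = MSB/MSW); the workhorse for
#' three-group comparisons of biomechanical and microstructural metrics.
#'
#' @param groups named list of numeric vectors, one per group (>= 2 groups,
#'   each with >= 2 values)
#' @return list with `F`, `dfBetween`, `dfWithin`, `p`, and `groups` (the
#'   group sizes)
#' @examples
#' oneWayAnova(list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(3, 4, 5)))
#' @export
oneWayAnova <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  n <- lengths(groups)
  if (any(n < 2)) stop("every group needs n >= 2", call. = FALSE)
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  df <- data.frame(value = unlist(groups, use.names = FALSE),
                   group = factor(rep(names(groups), n)))
  if (stats::var(df$value) == 0) {
    stop("undefined F: zero variance within and between groups",
         call. = FALSE)
  }
  a <- stats::anova(stats::lm(value ~ group, data = df))
  list(F = a[["F value"]][1],
       dfBetween = a[["Df"]][1],
       dfWithin = a[["Df"]][2],
       p = a[["Pr(>F)"]][1],
       groups = n)
}

#' Bonferroni-corrected pairwise comparisons
#'
#' Two-sample t tests (equal-variance by default, the classical
#' Bonferroni-after-ANOVA choice; Welch optional) for every pair of groups,
#' with adjusted p = min(1, m p) for m pairs.
#'
#' @param groups named list of numeric vectors (>= 2 groups, each n >= 2)
#' @param varEqual pool variances (default TRUE); FALSE gives Welch tests
#' @return data.frame with columns `group1`, `group2`, `t`, `p`,
#'   `pAdjusted`, `significant` (at 0.05)
#' @export
bonferroniPairwise <- function(groups, varEqual = TRUE) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (any(lengths(groups) < 2)) stop("every group needs n >= 2",
                                     call. = FALSE)
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  pairs <- utils::combn(names(groups), 2)
  res <- apply(pairs, 2, function(pr) {
    tt <- stats::t.test(groups[[pr[1]]], groups[[pr[2]]],
                        var.equal = varEqual)
    c(t = unname(tt$statistic), p = tt$p.value)
  })
  m <- ncol(pairs)
  out <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                    t = res["t", ], p = res["p", ],
                    pAdjusted = pmin(1, m * res["p", ]))
  out$significant <- out$pAdjusted < 0.05
  rownames(out) <- NULL
  out
}

#' Mean with dispersion under a stated convention
#'
#' `SEM = SD / sqrt(n)`; the convention used is recorded so downstream
#' tables can label error bars correctly. Sample (n - 1) SD throughout.
#' A single value yields dispersion 0 with `flagged = TRUE` rather than an
#' error, so tables always render.
#'
#' @param values numeric vector, n >= 1
#' @param convention `"SEM"` (biomechanics default) or `"SD"` (imaging)
#' @return list with `n`, `mean`, `dispersion`, `convention`, `flagged`
#' @export
summarizeValues <- function(values, convention = c("SEM", "SD")) {
  convention <- match.arg(convention)
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 1) stop("need at least one finite value", call. = FALSE)
  s <- if (n == 1) 0 else stats::sd(values)
  list(n = n, mean = mean(values),
       dispersion = if (convention == "SEM") s / sqrt(n) else s,
       convention = convention, flagged = n == 1)
}

#' Assemble a metric-by-group comparison table
#'
#' Takes tidy per-specimen values (one row per specimen and metric) and
#' builds the group-comparison layout used for "at MAP" biomechanical
#' metrics: mean, dispersion and n per metric and group, the one-way ANOVA
#' p across groups, and Bonferroni pairwise significance flags (p < 0.05).
#' A metric missing for a group is emitted with `NA` entries and
#' `gap = TRUE`.
#'
#' @param data data.frame with columns `group`, `metric`, `value`
#' @param convention dispersion convention, `"SEM"` (default) or `"SD"`
#' @return data.frame with one row per metric x group; ANOVA and pairwise
#'   results are attached as attributes `"anova"` and `"pairwise"` (named
#'   by metric)
#' @export
buildGroupTable <- function(data, convention = c("SEM", "SD")) {
  convention <- match.arg(convention)
  stopifnot(all(c("group", "metric", "value") %in% names(data)))
  groups <- unique(as.character(data$group))
  metrics <- unique(as.character(data$metric))
  rows <- list()
  anovas <- list()
  pws <- list()
  for (m in metrics) {
    sub <- data[data$metric == m, ]
    byGroup <- split(sub$value, factor(as.character(sub$group),
                                       levels = groups))
    testable <- lengths(byGroup) >= 2
    av <- if (sum(testable) >= 2) {
      tryCatch(oneWayAnova(byGroup[testable]), error = function(e) NULL)
    }
    pw <- if (sum(testable) >= 2) {
      tryCatch(bonferroniPairwise(byGroup[testable]), error = function(e) NULL)
    }
    anovas[[m]] <- av
    pws[[m]] <- pw
    for (g in groups) {
      v <- byGroup[[g]]
      if (is.null(v) || length(v) == 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          metric = m, group = g, n = 0L, mean = NA_real_,
          dispersion = NA_real_, convention = convention,
          anova_p = if (is.null(av)) NA_real_ else av$p,
          significant_vs = "", gap = TRUE)
        next
      }
      sm <- summarizeValues(v, convention)
      sig <- ""
      if (!is.null(pw)) {
        hit <- pw[(pw$group1 == g | pw$group2 == g) & pw$significant, ]
        other <- setdiff(unlist(hit[c("group1", "group2")]), g)
        sig <- paste(other, collapse = ",")
      }
      rows[[length(rows) + 1L]] <- data.frame(
        metric = m, group = g, n = sm$n, mean = sm$mean,
        dispersion = sm$dispersion, convention = convention,
        anova_p = if (is.null(av)) NA_real_ else av$p,
        significant_vs = sig, gap = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "anova") <- anovas
  attr(out, "pairwise") <- pws
  out
}
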