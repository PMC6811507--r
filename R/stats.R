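# Group-comparison battery: one-way / two-way / mixed (repeated-measures)
# ANOVA, Holm-Sidak step-down, paired and unpaired two-tailed t tests, and
# the Brown-Forsythe equal-variance test. Classical fits are delegated to
# stats::oneway.test / stats::aov / stats::t.test and car::Anova; only the
# Holm-Sidak step-down is computed directly (no installed equivalent).

testResult <- function(comparison, statistic, df1, df2 = NA_real_, p) {
  data.frame(
    comparison = comparison, statistic = statistic,
    df1 = df1, df2 = df2, p = p, stringsAsFactors = FALSE
  )
}

#' One-way ANOVA
#'
#' Classical between/within sums-of-squares F test across independent
#' groups.
#'
#' @param groups list of numeric vectors (>= 2 groups, each n >= 2).
#' @return data.frame: comparison, statistic (F), df1, df2, p.
#' @examples
#' oneWayAnova(list(c(1, 2, 3), c(4, 5, 6))) # F = 13.5 on (1, 4) df
#' @export
oneWayAnova <- function(groups) {
  stopifnot(length(groups) >= 2, all(lengths(groups) >= 2))
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  withinVar <- vapply(groups, function(x) sum((x - mean(x))^2), numeric(1))
  if (sum(withinVar) == 0) {
    means <- vapply(groups, mean, numeric(1))
    if (max(means) - min(means) == 0) {
      stop("F is undefined: zero within-group variance with equal means")
    }
  }
  ft <- oneway.test(values ~ g, var.equal = TRUE)
  testResult(
    "one_way_anova", unname(ft$statistic),
    unname(ft$parameter[1]), unname(ft$parameter[2]), ft$p.value
  )
}

#' Two-way ANOVA (two between-subject factors)
#'
#' Type-III sums of squares (sum-to-zero contrasts, via \code{car::Anova})
#' for a two-factor between-subjects layout such as age group x sex;
#' appropriate for balanced and mildly unbalanced designs.
#'
#' @param table data.frame with a numeric \code{value} column and two factor
#'   columns.
#' @param factors character length-2: the factor column names (default
#'   \code{c("group", "sex")}).
#' @return data.frame with one row per main effect and the interaction.
#' @export
twoWayAnova <- function(table, factors = c("group", "sex")) {
  f1 <- factor(table[[factors[1]]])
  f2 <- factor(table[[factors[2]]])
  if (any(table(f1, f2) == 0)) {
    stop("every ", factors[1], " x ", factors[2], " cell must be non-empty")
  }
  dat <- data.frame(value = table$value, f1 = f1, f2 = f2)
  fit <- lm(
    value ~ f1 * f2,
    data = dat,
    contrasts = list(f1 = "contr.sum", f2 = "contr.sum")
  )
  aovtab <- car::Anova(fit, type = 3)
  effects <- c("f1", "f2", "f1:f2")
  labels <- c(factors[1], factors[2], paste(factors, collapse = ":"))
  dfRes <- aovtab[["Df"]][rownames(aovtab) == "Residuals"]
  do.call(rbind, lapply(seq_along(effects), function(i) {
    r <- which(rownames(aovtab) == effects[i])
    testResult(
      labels[i], aovtab[["F value"]][r], aovtab[["Df"]][r], dfRes,
      aovtab[["Pr(>F)"]][r]
    )
  }))
}

#' Mixed (group x repeated condition) ANOVA
#'
#' Two-way repeated-measures ANOVA with one between-subject factor and one
#' within-subject (condition) factor, subject as the repeated unit
#' (univariate \code{aov} with an \code{Error(subject)} stratum). No
#' sphericity correction is applied.
#'
#' @param table data.frame with columns subject, value, a between factor and
#'   a within factor; every subject must have every condition.
#' @param between between-subjects factor column (default "group").
#' @param within within-subjects factor column (default "condition").
#' @return data.frame with rows for the between effect, the within effect
#'   and their interaction.
#' @export
mixedAnova <- function(table, between = "group", within = "condition") {
  subj <- factor(table$subject)
  wf <- factor(table[[within]])
  counts <- table(subj, wf)
  bad <- rownames(counts)[apply(counts, 1, function(r) any(r == 0))]
  if (length(bad)) {
    stop(
      "subject(s) missing a condition: ",
      paste(bad, collapse = ", ")
    )
  }
  dat <- data.frame(
    value = table$value, subject = subj,
    B = factor(table[[between]]), W = wf
  )
  fit <- aov(value ~ B * W + Error(subject), data = dat)
  s <- summary(fit)
  betweenTab <- s[["Error: subject"]][[1]]
  withinTab <- s[["Error: Within"]][[1]]
  grab <- function(tab, row, label) {
    r <- which(trimws(rownames(tab)) == row)
    res <- which(trimws(rownames(tab)) == "Residuals")
    testResult(
      label, tab[["F value"]][r], tab[["Df"]][r], tab[["Df"]][res],
      tab[["Pr(>F)"]][r]
    )
  }
  rbind(
    grab(betweenTab, "B", between),
    grab(withinTab, "W", within),
    grab(withinTab, "B:W", paste(between, within, sep = ":"))
  )
}

#' Holm-Sidak step-down multiple-comparison adjustment
#'
#' Sorted ascending, the k-th of m p values is adjusted to
#' \eqn{1 - (1-p)^{m-k+1}} (enforced monotone non-decreasing); hypotheses
#' are rejected sequentially while the adjusted p is below alpha, stopping
#' at the first failure.
#'
#' @param pvalues numeric p values in [0, 1].
#' @param alpha family-wise error rate (default 0.05).
#' @return data.frame in the original order: p, p_adjusted, reject.
#' @examples
#' holmSidak(c(0.01, 0.04, 0.30)) # exactly one rejection at alpha = 0.05
#' @export
holmSidak <- function(pvalues, alpha = 0.05) {
  stopifnot(all(pvalues >= 0 & pvalues <= 1))
  m <- length(pvalues)
  ord <- order(pvalues)
  padj <- numeric(m)
  rej <- logical(m)
  running <- 0
  alive <- TRUE
  for (k in seq_len(m)) {
    i <- ord[k]
    a <- 1 - (1 - pvalues[i])^(m - k + 1)
    running <- max(running, a)
    padj[i] <- running
    if (alive && running < alpha) {
      rej[i] <- TRUE
    } else {
      alive <- FALSE
    }
  }
  data.frame(p = pvalues, p_adjusted = padj, reject = rej)
}

#' Two-tailed t tests
#'
#' Paired or unpaired two-tailed t test; the unpaired default pools
#' variances (preserving the F = t^2 identity with the one-way ANOVA),
#' with Welch's correction available by flag.
#'
#' @param a,b numeric samples (equal length when paired).
#' @param paired paired test (default FALSE).
#' @param welch unpaired only: Welch's unequal-variance form.
#' @return data.frame: comparison, statistic (t), df1 (df), p.
#' @examples
#' tTest(c(2, 4, 6), c(1, 2, 3), paired = TRUE) # t = 3.464, df = 2
#' @export
tTest <- function(a, b, paired = FALSE, welch = FALSE) {
  if (paired) {
    stopifnot(length(a) == length(b), length(a) >= 2)
    if (sd(a - b) == 0) {
      stop("paired differences have zero variance; t is undefined")
    }
    tt <- t.test(a, b, paired = TRUE)
    lab <- "paired_t"
  } else {
    stopifnot(length(a) >= 2, length(b) >= 2)
    tt <- t.test(a, b, var.equal = !welch)
    lab <- if (welch) "welch_t" else "unpaired_t"
  }
  testResult(
    lab, unname(tt$statistic), unname(tt$parameter), NA_real_, tt$p.value
  )
}

#' Brown-Forsythe equal-variance test
#'
#' One-way ANOVA applied to absolute deviations from the group medians.
#'
#' @param groups list of numeric vectors.
#' @return data.frame: comparison, statistic (F), df1, df2, p.
#' @export
brownForsythe <- function(groups) {
  devs <- lapply(groups, function(x) abs(x - median(x)))
  out <- oneWayAnova(devs)
  out$comparison <- "brown_forsythe"
  out
}

#' Group-comparison battery on a CVR results table
#'
#' Convenience wrapper reproducing the study's analysis plan on a tidy
#' per-subject results table: one-way ANOVA between age groups on each
#' scope's slope, two-way (group x sex) ANOVA, and Holm-Sidak adjustment
#' across scopes.
#'
#' @param results data.frame: subject, scope, slope.
#' @param subjectsTable data.frame: subject, group, sex.
#' @param alpha family-wise alpha for the Holm-Sidak step.
#' @return data.frame: scope, effect, statistic, df1, df2, p, p_adjusted.
#' @export
groupComparison <- function(results, subjectsTable, alpha = 0.05) {
  m <- merge(results, subjectsTable, by = "subject")
  rows <- list()
  for (sc in unique(m$scope)) {
    sub <- m[m$scope == sc, ]
    groups <- split(sub$slope, sub$group)
    ow <- oneWayAnova(groups)
    ow$scope <- sc
    ow$effect <- "group"
    rows[[length(rows) + 1L]] <- ow
  }
  out <- do.call(rbind, rows)
  hs <- holmSidak(out$p, alpha = alpha)
  out$p_adjusted <- hs$p_adjusted
  out$reject <- hs$reject
  out[, c(
    "scope", "effect", "statistic", "df1", "df2", "p", "p_adjusted",
    "reject"
  )]
}
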