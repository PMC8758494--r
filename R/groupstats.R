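# Genotype x age statistical comparison layer: Shapiro-Wilk normality
# screen (reported, never used to switch tests), ROUT-style robust outlier
# exclusion at Q = 1%, two-way ANOVA with Type-II sums of squares, and
# per-age control-vs-disease contrasts with Holm-Sidak step-down adjustment.

#' Assemble and validate a cohort table
#'
#' One row per cell/recording: a metric value plus genotype and age factor
#' labels and animal/cell ids (both ids are carried so either unit of
#' analysis can be selected downstream).
#'
#' @param value numeric metric values.
#' @param genotype,age factor labels (no missing values).
#' @param animalId,cellId identifiers (optional; autogenerated if missing).
#' @return a data.frame of class `CohortTable` with columns `value`,
#'   `genotype`, `age`, `animalId`, `cellId`.
#' @export
cohortTable <- function(value, genotype, age, animalId = NULL, cellId = NULL) {
  n <- length(value)
  if (length(genotype) != n || length(age) != n)
    stop("'value', 'genotype' and 'age' must have equal length", call. = FALSE)
  genotype <- as.character(genotype)
  age <- as.character(age)
  if (anyNA(genotype) || anyNA(age) || any(!nzchar(genotype)) || any(!nzchar(age)))
    stop("factor labels must not be missing", call. = FALSE)
  if (is.null(cellId)) cellId <- sprintf("cell%03d", seq_len(n))
  if (is.null(animalId)) animalId <- cellId
  df <- data.frame(value = as.numeric(value), genotype = genotype, age = age,
                   animalId = as.character(animalId),
                   cellId = as.character(cellId), stringsAsFactors = FALSE)
  class(df) <- c("CohortTable", "data.frame")
  df
}

#' Per-group Shapiro-Wilk normality screen
#'
#' Reported alongside the parametric pipeline, never used to auto-switch
#' tests. Groups with fewer than 3 finite values or zero variance are
#' flagged instead of tested.
#'
#' @param table a [cohortTable()].
#' @return data.frame with one row per genotype x age group: `n`, `shapiroP`
#'   and a `flag` (`""`, `"n < 3"` or `"degenerate"`).
#' @export
normalityScreen <- function(table) {
  stopifnot(is.data.frame(table))
  groups <- unique(table[, c("genotype", "age")])
  res <- lapply(seq_len(nrow(groups)), function(i) {
    g <- groups[i, ]
    v <- table$value[table$genotype == g$genotype & table$age == g$age]
    v <- v[is.finite(v)]
    flag <- ""
    p <- NA_real_
    if (length(v) < 3L) {
      flag <- "n < 3"
    } else if (sd(v) == 0) {
      flag <- "degenerate"
    } else {
      p <- shapiro.test(v)$p.value
    }
    data.frame(genotype = g$genotype, age = g$age, n = length(v),
               shapiroP = p, flag = flag, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(res, list(make.row.names = FALSE)))
}

#' Robust outlier flags (ROUT-style, Q = 1%)
#'
#' For a single descriptive group the ROUT procedure degenerates to a robust
#' location fit: residuals from the median, scaled by the MAD, are converted
#' to two-sided normal p values and thresholded with a
#' Benjamini-Hochberg-style false-discovery cut at rate `Q`. Returns flags
#' only; the input is never mutated. With fewer than 5 values the screen is
#' a no-op (with a warning).
#'
#' @param values numeric vector.
#' @param Q expected false-outlier rate (default 0.01, i.e. Q = 1%).
#' @return logical vector of outlier flags, same length as `values`.
#' @export
#' @examples
#' routOutliers(c(9.9, 10, 10.1, 10.05, 9.95, 50))
routOutliers <- function(values, Q = 0.01) {
  assertScalar(Q, "Q", lower = 0, upper = 1, strictLower = TRUE,
               strictUpper = TRUE)
  n <- length(values)
  if (n < 5L) {
    warning("fewer than 5 values: outlier screen skipped")
    return(rep(FALSE, n))
  }
  med <- median(values)
  s <- mad(values)
  if (s == 0) {
    # no spread among the bulk: flag only points off the median, if the
    # majority is exactly constant; otherwise nothing can be scaled
    dev <- values != med
    if (mean(dev) <= 0.5 && any(dev) && all(values[!dev] == med))
      return(dev & abs(values - med) > 0)
    return(rep(FALSE, n))
  }
  z <- (values - med) / s
  p <- 2 * pnorm(-abs(z))
  ord <- order(p)
  thresh <- Q * seq_len(n) / n
  passed <- p[ord] <= thresh
  k <- if (any(passed)) max(which(passed)) else 0L
  flags <- rep(FALSE, n)
  if (k > 0L) flags[ord[seq_len(k)]] <- TRUE
  flags
}

#' Two-way ANOVA (genotype x age) with Type-II sums of squares
#'
#' Type-II SS are the standard choice for the unbalanced factorial layouts
#' that arise when per-group cell counts differ. Requires at least two
#' levels per factor and no empty design cell.
#'
#' @param table a [cohortTable()].
#' @return data.frame with one row per term (`genotype`, `age`,
#'   `genotype:age`, `Residuals`): `sumsq`, `df`, `F`, `p`.
#' @export
twoWayAnova <- function(table) {
  stopifnot(is.data.frame(table))
  df <- table[is.finite(table$value), ]
  df$genotype <- factor(df$genotype)
  df$age <- factor(df$age)
  if (nlevels(df$genotype) < 2L || nlevels(df$age) < 2L)
    stop("two-way ANOVA requires at least 2 levels per factor", call. = FALSE)
  counts <- table(df$genotype, df$age)
  if (any(counts == 0L)) {
    bad <- which(counts == 0L, arr.ind = TRUE)[1, ]
    stop(sprintf("empty design cell: %s x %s",
                 rownames(counts)[bad[1]], colnames(counts)[bad[2]]),
         call. = FALSE)
  }
  if (any(counts < 2L)) {
    bad <- which(counts < 2L, arr.ind = TRUE)[1, ]
    stop(sprintf("design cell %s x %s has fewer than 2 observations",
                 rownames(counts)[bad[1]], colnames(counts)[bad[2]]),
         call. = FALSE)
  }
  fit <- lm(value ~ genotype * age, data = df)
  a <- car::Anova(fit, type = 2)
  data.frame(term = rownames(a), sumsq = a[["Sum Sq"]], df = a[["Df"]],
             F = a[["F value"]], p = a[["Pr(>F)"]],
             stringsAsFactors = FALSE)
}

#' Holm-Sidak step-down adjusted p values
#'
#' Step-down Sidak: with the raw p values sorted ascending, the i-th
#' adjusted value is `max_{j <= i} (1 - (1 - p_(j))^(m - j + 1))`, clipped to
#' 1 and returned in the input order. Adjusted values are monotone in, and
#' never below, the raw values.
#'
#' @param rawP numeric vector of p values in `(0, 1]`.
#' @return adjusted p values, same order as the input.
#' @export
#' @examples
#' holmSidak(c(0.01, 0.04, 0.03))
holmSidak <- function(rawP) {
  if (!length(rawP)) return(numeric(0))
  if (any(!is.finite(rawP)) || any(rawP <= 0) || any(rawP > 1))
    stop("all p values must lie in (0, 1]", call. = FALSE)
  m <- length(rawP)
  ord <- order(rawP)
  sorted <- rawP[ord]
  adj <- 1 - (1 - sorted)^(m - seq_len(m) + 1)
  adj <- pmin(cummax(adj), 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}

#' Full group-comparison pipeline for one metric
#'
#' Pipeline: ROUT-style outlier exclusion (per group by default) ->
#' Shapiro-Wilk normality screen (reported) -> two-way genotype x age ANOVA
#' (Type-II SS) -> per-age control-vs-disease contrasts on the ANOVA pooled
#' error with Holm-Sidak adjustment across ages. Excluded rows are recorded
#' by id, never silently dropped.
#'
#' @param table a [cohortTable()] with exactly two genotypes.
#' @param alpha significance level for flagging contrasts (default 0.05).
#' @param Q ROUT false-outlier rate (default 0.01).
#' @param controlLabel genotype label of the control group (default `"WT"`).
#' @param routScope `"per_group"` (default) or `"pooled"` outlier screening.
#' @return a [ComparisonResult-class].
#' @export
compareGroups <- function(table, alpha = 0.05, Q = 0.01,
                          controlLabel = "WT",
                          routScope = c("per_group", "pooled")) {
  routScope <- match.arg(routScope)
  stopifnot(is.data.frame(table))
  if (!controlLabel %in% table$genotype)
    stop("control genotype '", controlLabel, "' not present", call. = FALSE)
  genos <- unique(table$genotype)
  if (length(genos) != 2L)
    stop("compareGroups expects exactly two genotypes (got ",
         length(genos), ")", call. = FALSE)
  testLabel <- setdiff(genos, controlLabel)

  flags <- rep(FALSE, nrow(table))
  if (routScope == "pooled") {
    flags <- suppressWarnings(routOutliers(table$value, Q))
  } else {
    for (g in genos) for (a in unique(table$age)) {
      idx <- which(table$genotype == g & table$age == a)
      if (length(idx))
        flags[idx] <- suppressWarnings(routOutliers(table$value[idx], Q))
    }
  }
  clean <- table[!flags, ]
  normality <- normalityScreen(clean)
  anova <- twoWayAnova(clean)

  fitDf <- clean[is.finite(clean$value), ]
  fitDf$genotype <- factor(fitDf$genotype)
  fitDf$age <- factor(fitDf$age)
  fit <- lm(value ~ genotype * age, data = fitDf)
  mse <- sum(residuals(fit)^2) / df.residual(fit)
  ages <- sort(unique(fitDf$age))
  rows <- lapply(as.character(ages), function(a) {
    v1 <- fitDf$value[fitDf$genotype == controlLabel & fitDf$age == a]
    v2 <- fitDf$value[fitDf$genotype == testLabel & fitDf$age == a]
    est <- mean(v2) - mean(v1)
    se <- sqrt(mse * (1 / length(v1) + 1 / length(v2)))
    tval <- est / se
    data.frame(age = a, control = controlLabel, test = testLabel,
               nControl = length(v1), nTest = length(v2),
               difference = est, t = tval, df = df.residual(fit),
               rawP = 2 * pt(-abs(tval), df.residual(fit)),
               stringsAsFactors = FALSE)
  })
  pairwise <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  pairwise$adjP <- holmSidak(pairwise$rawP)
  pairwise$significant <- pairwise$adjP < alpha

  new("ComparisonResult", anova = anova, pairwise = pairwise,
      outliersRemoved = table$cellId[flags], normality = normality,
      alpha = alpha,
      notes = paste("outlier screen: robust median/MAD location variant of",
                    sprintf("ROUT at Q = %g%%, scope '%s'", Q * 100, routScope)))
}
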