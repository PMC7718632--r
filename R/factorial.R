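# Per-trait, per-DAT factorial linear mixed model: genotype x heat x
# drought fixed, block random (REML variance component), Wald F tests
# against the fixed-effects residual df.

#' Derived temperature-difference traits
#'
#' T1 = bud - ambient, T2 = leaf - ambient, T3 = bud - leaf; the identity
#' T3 = T1 - T2 holds exactly.
#'
#' @param tBud,tLeaf,tAmbient temperatures, degrees C (vectorised)
#' @return data frame with columns T1, T2, T3
#' @examples
#' tempDifferences(30, 28, 29)  # 1, -1, 2
#' @export
tempDifferences <- function(tBud, tLeaf, tAmbient) {
  stopifnot(all(is.finite(c(tBud, tLeaf, tAmbient))))
  data.frame(T1 = tBud - tAmbient, T2 = tLeaf - tAmbient,
             T3 = tBud - tLeaf)
}

#' Append T1/T2/T3 rows to a trait table
#'
#' Joins the Tbud, Tleaf and Tambient rows of each experimental unit and
#' emits the three derived difference traits.
#'
#' @param table long-format trait table with Tbud/Tleaf/Tambient rows
#' @return the table with T1, T2, T3 rows appended
#' @export
deriveTemperatureTraits <- function(table) {
  key <- c("genotype", "block", "heat", "drought", "dat")
  w <- stats::reshape(
    table[table$trait %in% c("Tbud", "Tleaf", "Tambient"), ],
    idvar = key, timevar = "trait", direction = "wide")
  names(w) <- sub("^value\\.", "", names(w))
  td <- tempDifferences(w$Tbud, w$Tleaf, w$Tambient)
  out <- lapply(c("T1", "T2", "T3"), function(tr)
    cbind(w[key], trait = tr, value = td[[tr]], stringsAsFactors = FALSE))
  rbind(table, do.call(rbind, out))
}

#' Residual degrees of freedom of the factorial model
#'
#' N minus the rank of the fixed-effects design matrix. Under the REML
#' convention used throughout this package the random block does not
#' consume residual degrees of freedom: a complete g x 2 x 2 x b design
#' with all interactions has residual df g*2*2*(b - 1).
#'
#' @param nGenotypes,nBlocks design dimensions
#' @param nHeat,nDrought factor levels (default 2)
#' @param nObs total observations (default the complete design)
#' @return integer residual df
#' @examples
#' residualDf(12, 3)  # 96
#' residualDf(12, 2)  # 48
#' @export
residualDf <- function(nGenotypes, nBlocks, nHeat = 2, nDrought = 2,
                       nObs = nGenotypes * nHeat * nDrought * nBlocks) {
  p <- nGenotypes * nHeat * nDrought
  df <- as.integer(nObs - p)
  if (df < 0) stop("design matrix rank exceeds the number of observations")
  df
}

#' Factorial mixed-model ANOVA for one trait at one DAT
#'
#' Fits value ~ genotype * heat * drought with block as a random effect
#' (single REML variance component via \pkg{lme4}) and computes Wald F
#' statistics for every fixed term against the residual variance, with
#' denominator df equal to N minus the fixed-effects rank (the random
#' block does not consume residual df). P-values come from the F
#' distribution; stars follow the usual codes ("*" for
#' 0.01 < p < 0.05, "**" for p < 0.01). When the block variance
#' component is estimated as zero the result coincides exactly with the
#' ordinary least-squares ANOVA that ignores block. When the design has
#' a single block (or block is confounded), an OLS fit is used directly.
#'
#' @param table long-format trait table
#' @param trait trait code to analyse
#' @param dat measurement day (NA for day-less traits such as SY)
#' @param transform "none" or "log" (natural log; requires positive
#'   values, offending rows are named in the error)
#' @param covariate optional data frame (genotype, block, heat, drought,
#'   value) of a DAT0 baseline to adjust for; reduces residual df by 1
#' @return data frame with one row per fixed term (term, df, meanSq, F,
#'   p, stars) and attributes \code{residualDf}, \code{residualMS},
#'   \code{blockVar}, \code{nObs}
#' @export
fitFactorialLmm <- function(table, trait, dat = NA, transform = "none",
                            covariate = NULL) {
  rows <- table$trait == trait &
    (if (is.na(dat)) TRUE else (!is.na(table$dat) & table$dat == dat))
  df <- table[rows, , drop = FALSE]
  df <- df[is.finite(df$value), , drop = FALSE]
  if (nrow(df) == 0) stop(sprintf("no observations for trait %s", trait))
  if (transform == "log") {
    bad <- which(df$value <= 0)
    if (length(bad))
      stop(sprintf("log transform requires positive values; offending rows: %s",
                   paste(utils::head(bad, 10), collapse = ", ")))
    df$value <- log(df$value)
  }
  df$genotype <- factor(df$genotype)
  df$heat <- factor(df$heat)
  df$drought <- factor(df$drought)
  df$block <- factor(df$block)
  form <- value ~ genotype * heat * drought
  if (!is.null(covariate)) {
    key <- c("genotype", "block", "heat", "drought")
    df$baseline <- covariate$value[match(
      do.call(paste, df[key]), do.call(paste, covariate[key]))]
    if (any(is.na(df$baseline))) stop("covariate does not cover all cells")
    form <- value ~ baseline + genotype * heat * drought
  }

  # sum-to-zero contrasts: with a balanced design the per-term Wald
  # tests then coincide with the classical sequential ANOVA
  ctr <- list(genotype = "contr.sum", heat = "contr.sum",
              drought = "contr.sum")
  X <- stats::model.matrix(form, df, contrasts.arg = ctr)
  asgn <- attr(X, "assign")
  termLabels <- attr(stats::terms(form), "term.labels")
  rankX <- qr(X)$rank
  dfResid <- nrow(df) - rankX

  useLmm <- nlevels(df$block) > 1L
  blockVar <- 0
  if (useLmm) {
    fit <- tryCatch(
      lme4::lmer(stats::update(form, . ~ . + (1 | block)), data = df,
                 REML = TRUE, contrasts = ctr,
                 control = lme4::lmerControl(check.conv.singular = "ignore",
                                             calc.derivs = FALSE)),
      error = function(e) NULL)
    if (is.null(fit)) useLmm <- FALSE
  }
  if (useLmm) {
    beta <- lme4::fixef(fit)
    V <- as.matrix(stats::vcov(fit))
    s2 <- stats::sigma(fit)^2
    blockVar <- as.numeric(lme4::VarCorr(fit)$block[1])
  } else {
    fit <- stats::lm(form, df, contrasts = ctr)
    beta <- stats::coef(fit)
    ok <- !is.na(beta)
    beta <- beta[ok]
    V <- stats::vcov(fit)[names(beta), names(beta), drop = FALSE]
    s2 <- sum(stats::residuals(fit)^2) / dfResid
  }

  terms_out <- lapply(seq_along(termLabels), function(t) {
    idx <- which(asgn == t)
    idx <- idx[match(colnames(X)[idx], names(beta), nomatch = 0) > 0]
    q <- length(idx)
    if (q == 0)
      return(data.frame(term = termLabels[t], df = 0, meanSq = NA_real_,
                        F = NA_real_, p = NA_real_, stars = "",
                        stringsAsFactors = FALSE))
    bi <- beta[colnames(X)[idx]]
    Vi <- V[colnames(X)[idx], colnames(X)[idx], drop = FALSE]
    Fv <- as.numeric(crossprod(bi, solve(Vi, bi))) / q
    pv <- stats::pf(Fv, q, dfResid, lower.tail = FALSE)
    data.frame(term = termLabels[t], df = q, meanSq = Fv * s2, F = Fv,
               p = pv, stars = starCode(pv), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, terms_out)
  prettify <- c(genotype = "G", heat = "H", drought = "D",
                baseline = "DAT0")
  out$term <- vapply(strsplit(out$term, ":", fixed = TRUE), function(parts)
    paste(ifelse(parts %in% names(prettify), prettify[parts], parts),
          collapse = "x"), character(1))
  attr(out, "residualDf") <- dfResid
  attr(out, "residualMS") <- s2
  attr(out, "blockVar") <- blockVar
  attr(out, "nObs") <- nrow(df)
  out
}

# Table-2-style significance codes.
starCode <- function(p) {
  ifelse(is.na(p), "", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' Screen traits for variance heterogeneity and log-transform
#'
#' Applies the natural-log transform to traits selected either
#' explicitly or automatically (Bartlett test of homogeneity across the
#' G x H x D cells rejecting at \code{alpha}); automatic selection skips
#' traits with non-positive values.
#'
#' @param table long-format trait table
#' @param policy "none", "explicit" (use \code{traits}) or "auto"
#' @param traits trait codes for the explicit policy
#' @param alpha screen level for the automatic policy
#' @return the table with transformed values; transformed trait codes are
#'   recorded in the \code{"logTraits"} attribute
#' @export
heterogeneityTransform <- function(table, policy = c("none", "explicit", "auto"),
                                   traits = character(), alpha = 0.05) {
  policy <- match.arg(policy)
  if (policy == "none") {
    attr(table, "logTraits") <- character()
    return(table)
  }
  if (policy == "explicit") {
    sel <- traits
    for (tr in sel)
      if (any(table$value[table$trait == tr] <= 0, na.rm = TRUE))
        stop(sprintf("trait %s has non-positive values; cannot log-transform", tr))
  } else {
    sel <- character()
    for (tr in unique(table$trait)) {
      sub <- table[table$trait == tr & is.finite(table$value), ]
      if (any(sub$value <= 0)) next
      cell <- interaction(sub$genotype, sub$heat, sub$drought, drop = TRUE)
      if (nlevels(cell) < 2 || min(table(cell)) < 2) next
      p <- tryCatch(stats::bartlett.test(sub$value, cell)$p.value,
                    error = function(e) NA_real_)
      if (!is.na(p) && p < alpha) sel <- c(sel, tr)
    }
  }
  for (tr in sel) {
    i <- table$trait == tr
    table$value[i] <- log(table$value[i])
  }
  attr(table, "logTraits") <- sel
  table
}

#' Run the factorial ANOVA across traits and days
#'
#' Convenience wrapper: one \code{\link{fitFactorialLmm}} per trait x DAT
#' combination present in the table, assembled in the long layout
#' (trait, dat, term, df, meanSq, F, p, stars, residualDf, residualMS).
#'
#' @param table long-format trait table
#' @param transform passed through to \code{\link{fitFactorialLmm}}
#' @return data frame of stacked ANOVA tables
#' @export
anovaAllTraits <- function(table, transform = "none") {
  combos <- unique(table[, c("trait", "dat")])
  out <- lapply(seq_len(nrow(combos)), function(i) {
    a <- tryCatch(
      fitFactorialLmm(table, combos$trait[i], combos$dat[i],
                      transform = transform),
      error = function(e) NULL)
    if (is.null(a)) return(NULL)
    cbind(trait = combos$trait[i], dat = combos$dat[i], a,
          residualDf = attr(a, "residualDf"),
          residualMS = attr(a, "residualMS"), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
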