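# A/Ci fitting: exhaustive enumeration of contiguous limitation
# partitions along ascending Ci; conditional on a partition (and known
# kinetic constants) the model is linear in (Vcmax, J, TPU, Rd), so each
# candidate is solved exactly by least squares and checked for internal
# consistency with the min rule.

#' Kinetic constants at leaf temperature
#'
#' Resolves the Rubisco kinetic constants (gammaStar, Kc, Ko) to use when
#' fitting a curve: user-supplied constants are Arrhenius-adjusted from
#' their stated temperature to the curve's leaf temperature.
#'
#' @param curve an \code{AciCurve}
#' @param kinetics \code{FvCBParameters} carrying the constants (default:
#'   the standard 25 C values of \code{FvCBParameters()})
#' @param energies activation energies for the adjustment
#' @return \code{FvCBParameters} at the curve's leaf temperature
#' @export
kineticsAtLeafTemp <- function(curve, kinetics = NULL,
                               energies = arrheniusEnergies()) {
  if (is.null(kinetics)) kinetics <- FvCBParameters(o2 = curve@o2)
  if (abs(kinetics@temp - curve@leafTemp) < 1e-9) return(kinetics)
  if (abs(kinetics@temp - 25) > 1e-9)
    stop("supply kinetics at 25 C or at the curve's leaf temperature")
  temperatureAdjust(kinetics, curve@leafTemp, energies)
}

# Enumerate admissible (n_rubisco, n_rubp, n_tpu) splits of n points.
segmentSplits <- function(n, minSeg) {
  out <- list()
  sizes <- function(min, n) if (min == 0) 0:n else c(0L, seq(min, n))
  for (n1 in sizes(minSeg[["rubisco"]], n)) {
    for (n2 in sizes(minSeg[["rubp"]], n - n1)) {
      n3 <- n - n1 - n2
      if (n3 < 0) next
      if (n3 > 0 && n3 < max(1L, minSeg[["tpu"]])) next
      if (n1 + n2 + n3 == n && (n1 + n2 + n3) > 0)
        out[[length(out) + 1L]] <- c(rubisco = n1, rubp = n2, tpu = n3)
    }
  }
  out
}

# Least-squares solve for one partition. Returns NULL when the partition
# is infeasible (non-positive capacity estimates, unresolvable rank loss).
# Works on plain numerics; the S4 result object is built once, for the
# selected partition only.
solvePartition <- function(ci, a, split, kin, rdBounds, x, y) {
  n <- length(ci)
  seg <- rep(c("rubisco", "rubp", "tpu"), times = split)
  cols <- list()
  if (split[["rubisco"]] > 0) cols$vcmax <- ifelse(seg == "rubisco", x, 0)
  if (split[["rubp"]] > 0) cols$j <- ifelse(seg == "rubp", y, 0)
  if (split[["tpu"]] > 0) cols$tpu <- ifelse(seg == "tpu", 3, 0)
  cols$rd <- rep(-1, n)
  X <- do.call(cbind, cols)

  fitOnce <- function(X, a, fixedRd = NULL) {
    if (!is.null(fixedRd)) {
      X <- X[, setdiff(colnames(X), "rd"), drop = FALSE]
      a <- a + fixedRd
    }
    qr.X <- qr(X)
    if (qr.X$rank < ncol(X)) return(NULL)
    b <- qr.coef(qr.X, a)
    if (!is.null(fixedRd)) b <- c(b, rd = fixedRd)
    b
  }

  beta <- fitOnce(X, a)
  rdClamped <- FALSE
  if (is.null(beta)) {           # rd aliased (e.g. TPU-only): pin rd at 0
    beta <- fitOnce(X, a, fixedRd = 0)
    rdClamped <- TRUE
    if (is.null(beta)) return(NULL)
  } else if (beta[["rd"]] < rdBounds[1] || beta[["rd"]] > rdBounds[2]) {
    rdFix <- min(max(beta[["rd"]], rdBounds[1]), rdBounds[2])
    beta <- fitOnce(X, a, fixedRd = rdFix)
    rdClamped <- TRUE
    if (is.null(beta)) return(NULL)
  }
  caps <- beta[setdiff(names(beta), "rd")]
  if (any(!is.finite(caps)) || any(caps <= 0)) return(NULL)

  vc <- if (split[["rubisco"]] > 0) beta[["vcmax"]] else NA_real_
  jj <- if (split[["rubp"]] > 0) beta[["j"]] else NA_real_
  tp <- if (split[["tpu"]] > 0) beta[["tpu"]] else NA_real_
  rdv <- beta[["rd"]]
  acNet <- if (is.na(vc)) rep(Inf, n) else vc * x - rdv
  ajNet <- if (is.na(jj)) rep(Inf, n) else jj * y - rdv
  apNet <- if (is.na(tp)) Inf else 3 * tp - rdv
  fitted <- ifelse(seg == "rubisco", acNet,
                   ifelse(seg == "rubp", ajNet, apNet))
  # consistency: the fitted parameters' own min rule (gross-rate
  # comparison for the carboxylation branches) reproduces the assignment
  if (is.na(vc)) {
    carb <- ajNet
  } else if (is.na(jj)) {
    carb <- acNet
  } else {
    kmEff <- kin@kc * (1 + kin@o2 / kin@ko)
    wc <- vc * ci / (ci + kmEff)
    wj <- jj * ci / (4 * ci + 8 * kin@gammaStar)
    useC <- ifelse(ci == 0, vc / kmEff <= jj / (8 * kin@gammaStar), wc <= wj)
    carb <- ifelse(useC, acNet, ajNet)
  }
  modelA <- pmin(carb, apNet)
  tol <- 1e-6 * (1 + abs(fitted))
  consistent <- all(abs(fitted - modelA) <= tol)
  list(vcmax = vc, j = jj, tpu = tp, rd = rdv, seg = seg,
       sse = sum((a - fitted)^2), consistent = consistent,
       rdClamped = rdClamped, split = split)
}

#' Fit the FvCB model to an A/Ci curve
#'
#' Enumerates every admissible contiguous partition of the ascending-Ci
#' points into (Rubisco | RuBP-regeneration | TPU) segments subject to
#' minimum segment sizes, solves each by exact least squares for
#' (Vcmax, J, TPU, Rd) with the kinetic constants fixed, rejects
#' partitions whose fitted min-rule disagrees with their own limitation
#' assignment, and returns the admissible fit with smallest SSE. Ties in
#' SSE are broken toward the partition with more Rubisco-limited points.
#' Segments may be absent, in which case the corresponding parameter is
#' \code{NA} and flagged unidentifiable. Rd is bounded to
#' \code{rdBounds}; estimates outside are clamped and flagged.
#'
#' If no partition passes the consistency check (possible on very noisy
#' curves) the lowest-SSE inconsistent fit is returned with
#' \code{consistent = FALSE}.
#'
#' @param curve an \code{AciCurve}
#' @param kinetics optional \code{FvCBParameters} carrying gammaStar, Kc,
#'   Ko (see \code{\link{kineticsAtLeafTemp}})
#' @param minSegment named minimum sizes, default
#'   \code{c(rubisco = 3, rubp = 2, tpu = 0)} (0 = segment optional)
#' @param rdBounds bounds for day respiration, umol m-2 s-1
#' @param energies activation energies for kinetics adjustment
#' @return an \code{AciFit}
#' @examples
#' p <- FvCBParameters(vcmax = 90, j = 150, tpu = 9, rd = 1.2)
#' ci <- c(50, 75, 100, 150, 400, 800, 1200, 1600)
#' fit <- fitAci(aciCurve(ci, forwardAci(ci, p)))
#' vcmax(fit)
#' @export
fitAci <- function(curve, kinetics = NULL,
                   minSegment = c(rubisco = 3L, rubp = 2L, tpu = 0L),
                   rdBounds = c(0, 10), energies = arrheniusEnergies()) {
  stopifnot(is(curve, "AciCurve"))
  if (any(!is.finite(curve@a))) stop("non-finite assimilation values")
  n <- length(curve@ci)
  if (n < max(minSegment[c("rubisco", "rubp")]))
    stop("fewer points than the minimum segment sizes allow")
  kin <- kineticsAtLeafTemp(curve, kinetics, energies)
  ci <- curve@ci
  x <- (ci - kin@gammaStar) / (ci + kin@kc * (1 + kin@o2 / kin@ko))
  y <- (ci - kin@gammaStar) / (4 * ci + 8 * kin@gammaStar)
  fits <- Filter(Negate(is.null),
                 lapply(segmentSplits(n, minSegment), solvePartition,
                        ci = ci, a = curve@a, kin = kin,
                        rdBounds = rdBounds, x = x, y = y))
  if (!length(fits)) stop("no feasible limitation partition for this curve")
  pick <- function(fs) {
    sses <- vapply(fs, `[[`, numeric(1), "sse")
    best <- min(sses)
    cand <- fs[sses <= best + 1e-9]
    # ties broken toward the earlier limitation segments: most rubisco
    # points first, then most rubp points
    nr <- vapply(cand, function(f) f$split[["rubisco"]], numeric(1))
    nj <- vapply(cand, function(f) f$split[["rubp"]], numeric(1))
    cand[[order(-nr, -nj)[1]]]
  }
  cons <- Filter(function(f) f$consistent, fits)
  sel <- if (length(cons)) pick(cons) else pick(fits)
  params <- FvCBParameters(vcmax = sel$vcmax, j = sel$j, tpu = sel$tpu,
                           rd = sel$rd, gammaStar = kin@gammaStar,
                           kc = kin@kc, ko = kin@ko, o2 = kin@o2,
                           temp = kin@temp)
  new("AciFit", params = params, limitation = sel$seg, sse = sel$sse,
      vcmaxIdentifiable = sel$split[["rubisco"]] > 0,
      jIdentifiable = sel$split[["rubp"]] > 0,
      tpuIdentifiable = sel$split[["tpu"]] > 0,
      nPerSegment = as.integer(sel$split), rdClamped = sel$rdClamped,
      consistent = sel$consistent, curveId = curve@curveId)
}

#' Brute-force grid-search fit (test oracle)
#'
#' Exhaustive search over a parameter grid: for every combination the
#' min-rule forward model is evaluated and the SSE against the measured
#' curve computed; the grid minimum is returned. Intended as an
#' independent reference to bound \code{\link{fitAci}}'s SSE in tests,
#' not for production use.
#'
#' Grid points whose implied limitation split violates the minimum
#' segment sizes are skipped, so the search space matches
#' \code{\link{fitAci}}'s.
#'
#' @param curve an \code{AciCurve}
#' @param grid named list with numeric vectors \code{vcmax}, \code{j},
#'   \code{tpu}, \code{rd}
#' @param minSegment minimum segment sizes, as in \code{\link{fitAci}}
#' @param kinetics,energies as in \code{\link{fitAci}}
#' @return an \code{AciFit} (limitation labels from the grid-best
#'   parameters; identifiability flags reflect which branches bind)
#' @export
bruteForceFit <- function(curve, grid,
                          minSegment = c(rubisco = 3L, rubp = 2L, tpu = 0L),
                          kinetics = NULL,
                          energies = arrheniusEnergies()) {
  stopifnot(is(curve, "AciCurve"),
            all(c("vcmax", "j", "tpu", "rd") %in% names(grid)))
  kin <- kineticsAtLeafTemp(curve, kinetics, energies)
  ci <- curve@ci; a <- curve@a
  combos <- expand.grid(vcmax = grid$vcmax, j = grid$j, tpu = grid$tpu,
                        rd = grid$rd, KEEP.OUT.ATTRS = FALSE)
  kmEff <- kin@kc * (1 + kin@o2 / kin@ko)
  best <- NULL; bestSse <- Inf
  for (i in seq_len(nrow(combos))) {
    cb <- combos[i, ]
    # same gross-rate minimum rule as the forward model
    wc <- cb$vcmax * ci / (ci + kmEff)
    wj <- cb$j * ci / (4 * ci + 8 * kin@gammaStar)
    useC <- ifelse(ci == 0,
                   cb$vcmax / kmEff <= cb$j / (8 * kin@gammaStar), wc <= wj)
    ac <- cb$vcmax * (ci - kin@gammaStar) / (ci + kmEff) - cb$rd
    aj <- cb$j * (ci - kin@gammaStar) / (4 * ci + 8 * kin@gammaStar) - cb$rd
    ap <- 3 * cb$tpu - cb$rd
    carb <- ifelse(useC, ac, aj)
    f <- pmin(carb, ap)
    lab <- ifelse(carb <= ap, ifelse(useC, "rubisco", "rubp"), "tpu")
    cnt <- c(rubisco = sum(lab == "rubisco"), rubp = sum(lab == "rubp"),
             tpu = sum(lab == "tpu"))
    ok <- all(cnt == 0 | cnt >= pmax(minSegment[names(cnt)], 1L) |
                names(cnt) == "tpu" & cnt >= minSegment[["tpu"]])
    if (!ok) next
    s <- sum((a - f)^2)
    if (s < bestSse) { bestSse <- s; best <- cb }
  }
  p <- FvCBParameters(vcmax = best$vcmax, j = best$j, tpu = best$tpu,
                      rd = best$rd, gammaStar = kin@gammaStar, kc = kin@kc,
                      ko = kin@ko, o2 = kin@o2, temp = kin@temp)
  lab <- limitationStates(ci, p)
  cnt <- vapply(c("rubisco", "rubp", "tpu"),
                function(s) sum(lab == s), integer(1))
  new("AciFit", params = p, limitation = lab, sse = bestSse,
      vcmaxIdentifiable = cnt[["rubisco"]] > 0,
      jIdentifiable = cnt[["rubp"]] > 0,
      tpuIdentifiable = cnt[["tpu"]] > 0,
      nPerSegment = cnt, rdClamped = FALSE, consistent = TRUE,
      curveId = curve@curveId)
}
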