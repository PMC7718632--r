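# Genotype-level trait correlations per treatment, hierarchical
# clustering for heatmap ordering, and heatmap rendering.

#' Genotype x trait_DAT mean matrix for one treatment
#'
#' Averages the trait table over blocks (and any replicate plants) per
#' genotype within one treatment. Columns are trait_DAT codes
#' (e.g. \code{Vcmax_DAT1}); traits without a DAT (SY, SW) keep their
#' bare code. Missing genotype x trait combinations stay \code{NA} and
#' are listed in the \code{"missing"} attribute.
#'
#' @param table long-format trait table
#' @param treatment one of "C", "D", "H", "HD"
#' @return numeric matrix, rows = genotypes, columns = trait_DAT codes
#' @export
genotypeMeans <- function(table, treatment = c("C", "D", "H", "HD")) {
  treatment <- match.arg(treatment)
  h <- as.integer(treatment %in% c("H", "HD"))
  d <- as.integer(treatment %in% c("D", "HD"))
  sub <- table[table$heat == h & table$drought == d & is.finite(table$value), ]
  code <- ifelse(is.na(sub$dat), sub$trait,
                 sprintf("%s_DAT%g", sub$trait, sub$dat))
  gen <- sort(unique(table$genotype))
  cols <- unique(code[order(sub$trait, sub$dat)])
  m <- matrix(NA_real_, length(gen), length(cols),
              dimnames = list(gen, cols))
  agg <- tapply(sub$value, list(factor(sub$genotype, gen), factor(code, cols)),
                mean)
  m[] <- agg
  attr(m, "treatment") <- treatment
  attr(m, "missing") <- which(is.na(m), arr.ind = TRUE)
  m
}

#' Genotypic Pearson correlations with significance
#'
#' Pearson correlation of every pair of columns across genotype means,
#' with two-sided p-values from \eqn{t = r \sqrt{(n-2)/(1-r^2)}} on
#' n - 2 df (n = genotypes with complete pairs) and the usual star codes.
#' Zero-variance columns give \code{NA} correlations (flagged, not
#' fabricated).
#'
#' @param m matrix from \code{\link{genotypeMeans}} (>= 3 rows)
#' @return a \code{CorrelationMatrix}
#' @export
correlate <- function(m) {
  stopifnot(nrow(m) >= 3)
  k <- ncol(m)
  r <- p <- matrix(NA_real_, k, k, dimnames = list(colnames(m), colnames(m)))
  n <- matrix(0L, k, k, dimnames = dimnames(r))
  for (i in seq_len(k)) for (j in i:k) {
    ok <- is.finite(m[, i]) & is.finite(m[, j])
    nn <- sum(ok)
    n[i, j] <- n[j, i] <- nn
    if (nn < 3) next
    si <- stats::sd(m[ok, i]); sj <- stats::sd(m[ok, j])
    if (si == 0 || sj == 0) next
    rij <- stats::cor(m[ok, i], m[ok, j])
    r[i, j] <- r[j, i] <- rij
    if (i == j) { p[i, j] <- NA_real_; next }
    tv <- rij * sqrt((nn - 2) / max(1 - rij^2, .Machine$double.eps))
    pv <- 2 * stats::pt(-abs(tv), nn - 2)
    p[i, j] <- p[j, i] <- pv
  }
  stars <- matrix(starCode(p), k, k, dimnames = dimnames(r))
  diag(stars) <- ""
  trt <- attr(m, "treatment")
  new("CorrelationMatrix", r = r, p = p, n = n, stars = stars,
      treatment = if (is.null(trt)) "" else trt)
}

#' Long-format pair list of a correlation matrix
#'
#' @param cm a \code{CorrelationMatrix}
#' @return data frame (treatment, traitA, traitB, r, p, n, stars), upper
#'   triangle only
#' @export
correlationPairs <- function(cm) {
  k <- nrow(cm@r)
  idx <- which(upper.tri(cm@r), arr.ind = TRUE)
  data.frame(treatment = cm@treatment,
             traitA = rownames(cm@r)[idx[, 1]],
             traitB = colnames(cm@r)[idx[, 2]],
             r = cm@r[idx], p = cm@p[idx], n = cm@n[idx],
             stars = cm@stars[idx], stringsAsFactors = FALSE)
}

#' Heatmap leaf ordering by hierarchical clustering
#'
#' Average-linkage hierarchical clustering on the distance 1 - r.
#' Subtrees at every merge are oriented deterministically (the side
#' containing the alphabetically first column name goes left), so the
#' ordering is invariant, up to whole-tree reflection, to the input
#' column permutation.
#'
#' @param cm a \code{CorrelationMatrix} with no missing off-diagonal
#'   entries among the clustered columns (columns with NA correlations
#'   are dropped with a warning)
#' @param linkage linkage method for \code{\link[stats]{hclust}}
#' @return character vector of column names in leaf order
#' @export
clusterOrder <- function(cm, linkage = "average") {
  r <- cm@r
  bad <- apply(r, 1, function(x) any(is.na(x)))
  if (any(bad)) {
    warning("dropping columns with undefined correlations: ",
            paste(rownames(r)[bad], collapse = ", "))
    r <- r[!bad, !bad, drop = FALSE]
  }
  if (nrow(r) < 2) return(rownames(r))
  d <- stats::as.dist(1 - r)
  hc <- stats::hclust(d, method = linkage)
  # deterministic orientation: recurse over the merge table
  leaves <- function(node) {
    if (node < 0) return(rownames(r)[-node])
    l <- leaves(hc$merge[node, 1])
    rgt <- leaves(hc$merge[node, 2])
    if (min(l) <= min(rgt)) c(l, rgt) else c(rgt, l)
  }
  leaves(nrow(hc$merge))
}

# Diverging blue-white-red palette lookup for r in [-1, 1].
divergingColour <- function(r) {
  r <- pmin(1, pmax(-1, r))
  lo <- c(0.13, 0.40, 0.67)   # blue at r = -1
  mid <- c(1, 1, 1)
  hi <- c(0.70, 0.09, 0.17)   # red at r = +1
  t(vapply(r, function(x) {
    if (is.na(x)) return(c(0.85, 0.85, 0.85))
    if (x < 0) mid + (-x) * (lo - mid) else mid + x * (hi - mid)
  }, numeric(3)))
}

#' Render a correlation heatmap as PNG
#'
#' Draws the reordered correlation matrix on a diverging colour scale
#' centred at zero (blue = -1, white = 0, red = +1), one square cell per
#' pair, rendered directly to pixels so the output is byte-identical for
#' identical input.
#'
#' @param cm a \code{CorrelationMatrix}
#' @param ordering leaf order from \code{\link{clusterOrder}} (default:
#'   computed)
#' @param path output PNG path
#' @param cellPx cell side length in pixels
#' @return \code{path}, invisibly
#' @export
renderHeatmap <- function(cm, ordering = clusterOrder(cm), path,
                          cellPx = 12) {
  ordering <- ordering[ordering %in% rownames(cm@r)]
  r <- cm@r[ordering, ordering, drop = FALSE]
  k <- nrow(r)
  img <- array(0, c(k * cellPx, k * cellPx, 3))
  cols <- divergingColour(as.vector(r))  # column-major over r
  for (j in seq_len(k)) for (i in seq_len(k)) {
    rc <- cols[(j - 1) * k + i, ]
    ri <- ((i - 1) * cellPx + 1):(i * cellPx)
    cj <- ((j - 1) * cellPx + 1):(j * cellPx)
    for (ch in 1:3) img[ri, cj, ch] <- rc[ch]
  }
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  png::writePNG(img, path)
  invisible(path)
}
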