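# Genotype means, correlations, clustering, heatmap rendering.

makeTraitTable <- function() {
  grid <- expand.grid(genotype = sprintf("G%d", 1:4), block = 1:2,
                      heat = 0:1, drought = 0:1, stringsAsFactors = FALSE)
  rbind(cbind(grid, dat = 1, trait = "a",
              value = match(grid$genotype, sprintf("G%d", 1:4)) * 10 +
                grid$block),
        cbind(grid, dat = NA, trait = "b", value = grid$block * 2))
}

test_that("genotype means average over blocks within a treatment", {
  tab <- makeTraitTable()
  gm <- genotypeMeans(tab, "C")
  # blocks carry values v and v+1 -> mean v + 0.5
  expect_equal(unname(gm[, "a_DAT1"]), c(11.5, 21.5, 31.5, 41.5))
  # dat-less trait keeps its bare code, mean of 2 and 4 is 3
  expect_equal(unname(gm[, "b"]), rep(3, 4))
  # single block: means equal the raw values
  gm1 <- genotypeMeans(tab[tab$block == 1, ], "C")
  expect_equal(unname(gm1[, "a_DAT1"]), c(11, 21, 31, 41))
})

test_that("correlations match the closed-form covariance formula", {
  set.seed(55)
  m <- cbind(x = rnorm(12), y = rnorm(12))
  m <- cbind(m, negx = -m[, "x"], z = rnorm(12))
  cm <- correlate(m)
  r <- corValues(cm)
  expect_equal(diag(r), c(x = 1, y = 1, negx = 1, z = 1))
  expect_equal(r["x", "negx"], -1)
  expect_equal(r, t(r), tolerance = 1e-12)
  # hand-computed Pearson r for one pair
  x <- m[, "x"]; y <- m[, "y"]; n <- 12
  rOracle <- (sum(x * y) - n * mean(x) * mean(y)) /
    sqrt((sum(x^2) - n * mean(x)^2) * (sum(y^2) - n * mean(y)^2))
  expect_equal(r["x", "y"], rOracle, tolerance = 1e-12)
  # p-value against the independent cor.test implementation
  ct <- cor.test(x, y)
  expect_equal(pValues(cm)["x", "y"], ct$p.value, tolerance = 1e-10)
  expect_equal(cm@n["x", "y"], 12L)
})

test_that("zero-variance columns are flagged, not fabricated", {
  m <- cbind(x = rnorm(10), const = rep(5, 10))
  cm <- correlate(m)
  expect_true(is.na(corValues(cm)["x", "const"]))
  expect_equal(corValues(cm)["x", "x"], 1)
})

test_that("clustering orders correlated columns together deterministically", {
  set.seed(66)
  base <- rnorm(20)
  m <- cbind(a = base, b = base + rnorm(20, 0, 0.05), c = rnorm(20),
             d = rnorm(20))
  cm <- correlate(m)
  ord <- clusterOrder(cm)
  # near-identical columns are adjacent
  expect_equal(abs(diff(match(c("a", "b"), ord))), 1)
  # three-column single-linkage logic: the r = 0.99 pair merges first
  m3 <- cbind(a = base, b = base + rnorm(20, 0, 0.02), c = rnorm(20))
  ord3 <- clusterOrder(correlate(m3))
  expect_equal(abs(diff(match(c("a", "b"), ord3))), 1)
  # ordering is invariant to input column permutation
  perm <- c("d", "b", "c", "a")
  ordP <- clusterOrder(correlate(m[, perm]))
  expect_true(identical(ord, ordP) || identical(ord, rev(ordP)))
})

test_that("heatmap rendering is decodable and byte-deterministic", {
  set.seed(77)
  m <- matrix(rnorm(60), 12, 5,
              dimnames = list(NULL, sprintf("t%d", 1:5)))
  cm <- correlate(m)
  f1 <- tempfile(fileext = ".png"); f2 <- tempfile(fileext = ".png")
  renderHeatmap(cm, path = f1, cellPx = 8)
  renderHeatmap(cm, path = f2, cellPx = 8)
  expect_true(file.exists(f1))
  img <- png::readPNG(f1)
  expect_equal(dim(img)[1:2], c(40, 40))
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  # identity matrix renders its diagonal at the maximum (red) colour
  eye <- new("CorrelationMatrix",
             r = diag(3), p = matrix(NA_real_, 3, 3),
             n = matrix(3L, 3, 3),
             stars = matrix("", 3, 3), treatment = "C")
  dimnames(eye@r) <- list(letters[1:3], letters[1:3])
  f3 <- tempfile(fileext = ".png")
  renderHeatmap(eye, ordering = letters[1:3], path = f3, cellPx = 4)
  img3 <- png::readPNG(f3)
  topRed <- phenomicStress:::divergingColour(1)
  expect_equal(as.numeric(img3[1, 1, ]), as.numeric(topRed), tolerance = 0.01)
  unlink(c(f1, f2, f3))
})

test_that("correlation pair list matches the matrix", {
  set.seed(88)
  m <- matrix(rnorm(48), 12, 4, dimnames = list(NULL, letters[1:4]))
  cm <- correlate(m)
  pl <- correlationPairs(cm)
  expect_equal(nrow(pl), choose(4, 2))
  i <- which(pl$traitA == "a" & pl$traitB == "c")
  expect_equal(pl$r[i], corValues(cm)["a", "c"])
})
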