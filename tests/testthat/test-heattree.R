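# direct piecewise-linear RGB interpolation, written independently of
# grDevices::colorRamp, used as the color-mapping oracle
oracleColor <- function(pos, palette) {
  anchors <- t(grDevices::col2rgb(palette))
  k <- nrow(anchors)
  vapply(pos, function(p) {
    x <- p * (k - 1)
    i <- min(floor(x), k - 2)
    f <- x - i
    ch <- (1 - f) * anchors[i + 1, ] + f * anchors[i + 2, ]
    grDevices::rgb(ch[1], ch[2], ch[3], maxColorValue = 255)
  }, character(1))
}

test_that("layered layout places chains on distinct layers and stars evenly", {
  chain <- chainTaxmap(5)
  lay <- layoutTree(chain)
  expect_equal(length(unique(lay$nodes$y)), 5L)  # five layers
  expect_equal(length(unique(lay$nodes$x)), 1L)  # collinear

  star <- taxmap(data.frame(taxon_id = c("r", "c1", "c2", "c3", "c4"),
                            supertaxon_id = c(NA, "r", "r", "r", "r")))
  ls <- layoutTree(star)
  kids <- ls$nodes[ls$nodes$taxon_id != "r", ]
  expect_equal(length(unique(kids$y)), 1L)
  expect_equal(diff(sort(kids$x)), rep(1 / 3, 3), tolerance = 1e-9)
})

test_that("layered layout has no overlapping subtree extents and no coincident nodes", {
  fx <- randomTaxmap(nTaxa = 100, nObs = 0, seed = 55)
  tm <- fx$taxmap
  lay <- layoutTree(tm)
  pts <- lay$nodes
  expect_false(any(duplicated(pts[, c("x", "y")])))
  # sibling subtrees must occupy disjoint x-extents
  xs <- stats::setNames(pts$x, pts$taxon_id)
  sub <- subtaxa(tm, includeInput = TRUE)
  extent <- function(id) range(xs[sub[[id]]])
  for (id in taxonIds(tm)) {
    kids <- subtaxa(tm, id, recursive = FALSE)[[1]]
    if (length(kids) < 2) next
    exts <- lapply(kids, extent)
    for (i in seq_along(exts)[-1]) {
      for (j in seq_len(i - 1)) {
        lo <- max(exts[[i]][1], exts[[j]][1])
        hi <- min(exts[[i]][2], exts[[j]][2])
        expect_false(lo < hi - 1e-9)  # extents may touch but not interleave
      }
    }
  }
})

test_that("force-directed layout is reproducible under the seed", {
  fx <- randomTaxmap(nTaxa = 30, nObs = 0, seed = 56)
  a <- layoutTree(fx$taxmap, "fruchterman-reingold", seed = 3)
  b <- layoutTree(fx$taxmap, "fruchterman-reingold", seed = 3)
  expect_identical(a, b)
})

test_that("mapAesthetic is an affine monotone map attaining its endpoints", {
  expect_equal(mapAesthetic(c(0, 5, 10), c(1, 3)), c(1, 2, 3))
  expect_equal(mapAesthetic(rep(4, 5), c(1, 3)), rep(2, 5))
  set.seed(2)
  for (i in 1:20) {
    v <- stats::runif(sample(3:30, 1), -5, 5)
    out <- mapAesthetic(v, c(0.2, 0.9))
    expect_equal(order(v), order(out))
    expect_equal(min(out), 0.2)
    expect_equal(max(out), 0.9)
  }
  expect_error(mapAesthetic(c(-1, 2), c(0, 1), transform = "log10"), "positive")
  expect_error(mapAesthetic(c(0, 2), c(0, 1), transform = "log10",
                            names = c("bad_taxon", "ok")), "bad_taxon")
})

test_that("mapColor interpolates the palette channel-wise", {
  pal2 <- c("#0000FF", "#FF0000")
  expect_equal(mapColor(c(1, 9), pal2), c("#0000FF", "#FF0000"))
  pal3 <- c("#2166AC", "#F7F7F7", "#B2182B")
  expect_equal(mapColor(c(-2, 0, 2), pal3, interval = c(-2, 2))[2], "#F7F7F7")
  # values outside an explicit interval clamp to the endpoints
  expect_equal(mapColor(c(-9, 9), pal3, interval = c(-2, 2)),
               c("#2166AC", "#B2182B"))
  set.seed(3)
  for (i in 1:10) {
    v <- stats::runif(20)
    pal <- sample(grDevices::colors(), sample(2:5, 1))
    pos <- (v - min(v)) / diff(range(v))
    expect_equal(mapColor(v, pal), oracleColor(pos, pal))
  }
})

test_that("optimizeSizeRange maximizes size subject to the overlap bound", {
  two <- taxmap(data.frame(taxon_id = c("a", "b"), supertaxon_id = c(NA, "a")))
  lay <- layoutTree(two)
  rng <- optimizeSizeRange(lay, candidateRange = c(0.005, 0.05))
  expect_equal(rng[2], 0.05)  # two distant nodes never overlap

  overlapArea <- function(lay, r) {
    pts <- heattree:::.figureCoords(lay)
    tot <- 0
    for (i in seq_len(nrow(pts) - 1)) for (j in (i + 1):nrow(pts)) {
      d <- sqrt((pts$fx[i] - pts$fx[j])^2 + (pts$fy[i] - pts$fy[j])^2)
      tot <- tot + heattree:::.lensArea(d, r[i], r[j])
    }
    tot
  }
  for (s in 1:8) {
    fx <- randomTaxmap(nTaxa = sample(10:60, 1), nObs = 0, seed = 600 + s)
    lay <- layoutTree(fx$taxmap)
    vals <- stats::runif(nTaxa(fx$taxmap))
    rng <- optimizeSizeRange(lay, vals)
    r <- mapAesthetic(vals, rng)
    expect_lte(overlapArea(lay, r), 0.01 * sum(pi * r^2) + 1e-12)
  }
  # two adjacent nodes at close distance: radius cannot exceed the spacing
  lay2 <- layoutTree(chainTaxmap(2))
  pts <- heattree:::.figureCoords(lay2)
  d <- sqrt(diff(pts$fx)^2 + diff(pts$fy)^2)
  rng2 <- optimizeSizeRange(lay2, candidateRange = c(0.001, 10))
  expect_lte(rng2[2], d)
})

test_that("SVG output is byte-identical for a fixed input, spec and seed", {
  fx <- randomTaxmap(nTaxa = 25, nObs = 80, nRoots = 2, seed = 77)
  a <- heatTree(fx$taxmap, nodeSize = n_obs, nodeColor = n_obs, seed = 4)
  b <- heatTree(fx$taxmap, nodeSize = n_obs, nodeColor = n_obs, seed = 4)
  expect_identical(a$svg, b$svg)
})

test_that("each root becomes its own sub-tree in the rendered grid", {
  for (k in 1:5) {
    fx <- randomTaxmap(nTaxa = max(k, 8), nObs = 0, nRoots = k, seed = 80 + k)
    ht <- heatTree(fx$taxmap, nodeLabel = NULL)
    cells <- unique(ht$layout$nodes[, c("grid_x", "grid_y")])
    expect_equal(nrow(cells), k)
    expect_setequal(unique(ht$layout$nodes$root), roots(fx$taxmap))
  }
})

test_that("a single-taxon tree renders one node and no edges", {
  tm <- taxmap(data.frame(taxon_id = "only", supertaxon_id = NA,
                          name = "Only"))
  ht <- heatTree(tm)
  expect_equal(length(gregexpr("<circle", ht$svg)[[1]]), 1L)
  expect_false(grepl("<polygon", ht$svg))
  expect_true(grepl(">Only<", ht$svg))
  expect_error(heatTree(taxmap(data.frame(taxon_id = character(),
                                          supertaxon_id = character()))),
               "empty")
  expect_error(heatTree(tm, nodeColor = nope), "unknown column")
})

test_that("normalized coordinates are invariant to the output pixel size", {
  fx <- randomTaxmap(nTaxa = 20, nObs = 30, seed = 88)
  small <- heatTree(fx$taxmap, nodeSize = n_obs, width = 400, height = 300)$svg
  large <- heatTree(fx$taxmap, nodeSize = n_obs, width = 1600, height = 1200)$svg
  stripHeader <- function(s) sub('width="[^"]*" height="[^"]*"', "", s)
  expect_identical(stripHeader(small), stripHeader(large))
  expect_false(identical(small, large))
})

test_that("aesthetic monotonicity: bigger statistic, never smaller node", {
  fx <- randomTaxmap(nTaxa = 30, nObs = 100, seed = 90)
  tm <- fx$taxmap
  ht <- heatTree(tm, nodeSize = n_obs, nodeColor = n_obs)
  stat <- nObs(tm)
  radii <- mapAesthetic(stat, ht$sizeRange)
  ord <- order(stat)
  expect_true(all(diff(radii[ord]) >= -1e-12))
})

test_that("legend metadata reproduces the drawn aesthetics at its ticks", {
  fx <- randomTaxmap(nTaxa = 30, nObs = 100, seed = 91)
  tm <- fx$taxmap
  out <- withr::local_tempfile(fileext = ".svg")
  ht <- heatTree(tm, nodeSize = n_obs, nodeColor = n_obs, output = out)
  expect_true(file.exists(out))
  expect_true(file.exists(paste0(out, ".legend.json")))
  legend <- jsonlite::read_json(paste0(out, ".legend.json"),
                                simplifyVector = TRUE)
  stat <- nObs(tm)
  pal <- heattree:::.DEFAULT_PALETTE
  expect_equal(mapColor(legend$node_color$ticks, pal, interval = range(stat)),
               legend$node_color$mapped)
  expect_equal(mapAesthetic(legend$node_size$ticks, ht$sizeRange,
                            valueInterval = range(stat)),
               legend$node_size$mapped)
  # ticks lie within the data range
  expect_true(all(legend$node_size$ticks >= min(stat) &
                  legend$node_size$ticks <= max(stat)))
})

test_that("pdf and png devices accept the same geometry", {
  fx <- randomTaxmap(nTaxa = 10, nObs = 15, seed = 92)
  pdfOut <- withr::local_tempfile(fileext = ".pdf")
  pngOut <- withr::local_tempfile(fileext = ".png")
  heatTree(fx$taxmap, nodeSize = n_obs, output = pdfOut, format = "pdf")
  heatTree(fx$taxmap, nodeSize = n_obs, output = pngOut, format = "png")
  expect_gt(file.size(pdfOut), 0)
  expect_gt(file.size(pngOut), 0)
})
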