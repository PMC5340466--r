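# Heat trees: quantitative taxonomic tree plots. Up to four per-taxon
# statistics drive node/edge color and size; legends show the value ->
# aesthetic relationship; multiple roots become multiple sub-trees in a
# near-square grid; all geometry is expressed in normalized figure units
# so the plot looks the same at any output size.

#' Lay out the taxon forest
#'
#' One layout per root. `"reingold-tilford"` (default) is the deterministic
#' layered tree layout with children centered under parents;
#' `"fruchterman-reingold"` is force-directed, seeded and initialized from
#' the layered layout so it is reproducible. Each tree's coordinates are
#' normalized to the unit square; `grid_x`/`grid_y` place the trees in a
#' near-square grid of unit cells.
#'
#' @param tm a [Taxmap-class] object.
#' @param algorithm layout algorithm.
#' @param seed integer seed (used by the force-directed layout).
#' @return A `TreeLayout`: list with `nodes` (`data.frame`: `taxon_id`,
#'   `x`, `y` in \[0,1\] within the tree cell, `grid_x`, `grid_y`, `root`),
#'   `edges` (`taxon_id`, `parent_id`), `nrow`, `ncol`.
#' @export
layoutTree <- function(tm, algorithm = c("reingold-tilford",
                                         "fruchterman-reingold"),
                       seed = 1L) {
  algorithm <- match.arg(algorithm)
  tx <- tm@taxa
  if (!nrow(tx)) stop("empty Taxmap", call. = FALSE)
  rootIds <- roots(tm)
  k <- length(rootIds)
  ncol <- ceiling(sqrt(k))
  nrow <- ceiling(k / ncol)

  nodes <- data.frame(taxon_id = character(), x = numeric(), y = numeric(),
                      grid_x = integer(), grid_y = integer(),
                      root = character(), stringsAsFactors = FALSE)
  for (r in seq_along(rootIds)) {
    rid <- rootIds[r]
    members <- subtaxa(tm, rid, recursive = TRUE, includeInput = TRUE)[[1]]
    sub <- tx[tx$taxon_id %in% members, , drop = FALSE]
    coords <- .layoutOneTree(sub, rid, algorithm, seed + r)
    nodes <- rbind(nodes, data.frame(
      taxon_id = sub$taxon_id, x = coords[, 1L], y = coords[, 2L],
      grid_x = (r - 1L) %% ncol, grid_y = (r - 1L) %/% ncol,
      root = rid, stringsAsFactors = FALSE))
  }
  edges <- tx[!is.na(tx$supertaxon_id), c("taxon_id", "supertaxon_id")]
  names(edges) <- c("taxon_id", "parent_id")
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges, nrow = nrow, ncol = ncol),
            class = "TreeLayout")
}

# Layout one tree; returns a matrix of coordinates normalized to [0,1]^2.
.layoutOneTree <- function(sub, rootId, algorithm, seed) {
  n <- nrow(sub)
  if (n == 1L) return(matrix(0.5, 1L, 2L))
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = sub$supertaxon_id[!is.na(sub$supertaxon_id)],
                   to = sub$taxon_id[!is.na(sub$supertaxon_id)]),
    directed = TRUE,
    vertices = data.frame(name = sub$taxon_id))
  base <- igraph::layout_as_tree(g, root = rootId, mode = "out")
  if (algorithm == "fruchterman-reingold") {
    coords <- .withSeed(seed,
      igraph::layout_with_fr(g, coords = base, niter = 200))
  } else {
    coords <- base
  }
  # normalize to the unit square; degenerate extents collapse to 0.5
  for (d in 1:2) {
    rng <- range(coords[, d])
    coords[, d] <- if (diff(rng) > 0) (coords[, d] - rng[1]) / diff(rng) else 0.5
  }
  coords
}

#' Map statistic values onto an aesthetic interval
#'
#' Affine map of (optionally transformed) values from their observed range
#' onto `[lo, hi]`; a constant column maps to the interval midpoint. The
#' map is monotone non-decreasing and attains both endpoints.
#'
#' @param values numeric vector.
#' @param outInterval numeric \[lo, hi\].
#' @param transform `"identity"`, `"log10"` or `"sqrt"`, applied before
#'   mapping.
#' @param valueInterval optional explicit \[lo, hi\] on the (untransformed)
#'   value scale overriding the data range; values outside clamp.
#' @param names optional labels used in error messages.
#' @param naTo value assigned to NA entries, or `NULL` to error on them.
#' @return Numeric vector in `[lo, hi]`.
#' @export
mapAesthetic <- function(values, outInterval, transform = "identity",
                         valueInterval = NULL, names = NULL, naTo = NULL) {
  if (anyNA(values)) {
    if (is.null(naTo)) {
      bad <- if (!is.null(names)) paste(names[is.na(values)], collapse = ", ")
             else "some values"
      stop("missing values in aesthetic mapping: ", bad, call. = FALSE)
    }
    out <- rep(naTo, length(values))
    ok <- !is.na(values)
    out[ok] <- mapAesthetic(values[ok], outInterval, transform,
                            valueInterval, names[ok])
    return(out)
  }
  v <- .applyTransform(values, transform, names)
  if (is.null(valueInterval)) {
    rng <- range(v)
  } else {
    rng <- .applyTransform(valueInterval, transform, NULL)
    v <- pmin(pmax(v, rng[1]), rng[2])
  }
  if (diff(rng) == 0) {
    return(rep(mean(outInterval), length(v)))
  }
  outInterval[1] + (v - rng[1]) / diff(rng) * diff(outInterval)
}

.applyTransform <- function(values, transform, names) {
  transform <- match.arg(transform, c("identity", "log10", "sqrt"))
  v <- switch(transform,
    identity = values,
    log10 = {
      if (any(values <= 0)) {
        bad <- if (!is.null(names)) paste(names[values <= 0], collapse = ", ")
               else "some values"
        stop("log10 transform needs positive values; offending: ", bad,
             call. = FALSE)
      }
      log10(values)
    },
    sqrt = {
      if (any(values < 0)) stop("sqrt transform needs non-negative values",
                                call. = FALSE)
      sqrt(values)
    })
  if (any(!is.finite(v))) {
    bad <- if (!is.null(names)) paste(names[!is.finite(v)], collapse = ", ")
           else "some values"
    stop("non-finite values after transform: ", bad, call. = FALSE)
  }
  v
}

#' Map statistic values onto colors
#'
#' Channel-wise linear interpolation through the palette's anchor colors
#' over the value interval (by default the data range). With an explicit
#' interval, values outside clamp to the endpoints; for a palette with an
#' odd number of anchors the middle anchor sits exactly at the interval
#' midpoint (natural for diverging palettes around zero).
#'
#' @param values numeric vector.
#' @param palette character vector of >= 2 colors (any form
#'   [grDevices::col2rgb()] accepts).
#' @param interval optional explicit \[lo, hi\]; defaults to the data range.
#' @param transform as in [mapAesthetic()].
#' @param naColor color assigned to NA entries, or `NULL` to error on them.
#' @return Character vector of `#RRGGBB` colors.
#' @export
mapColor <- function(values, palette, interval = NULL, transform = "identity",
                     naColor = NULL) {
  if (length(palette) < 2L) stop("palette needs at least 2 colors", call. = FALSE)
  if (anyNA(values)) {
    if (is.null(naColor)) stop("missing values in color mapping", call. = FALSE)
    out <- rep(naColor, length(values))
    ok <- !is.na(values)
    out[ok] <- mapColor(values[ok], palette, interval, transform)
    return(out)
  }
  pos <- mapAesthetic(values, c(0, 1), transform = transform,
                      valueInterval = interval)
  ramp <- grDevices::colorRamp(palette, space = "rgb")
  m <- ramp(pos)
  grDevices::rgb(m[, 1L], m[, 2L], m[, 3L], maxColorValue = 255)
}

# Area of intersection of two discs at distance d.
.lensArea <- function(d, r1, r2) {
  if (d >= r1 + r2) return(0)
  if (d <= abs(r1 - r2)) return(pi * min(r1, r2)^2)
  a1 <- r1^2 * acos((d^2 + r1^2 - r2^2) / (2 * d * r1))
  a2 <- r2^2 * acos((d^2 + r2^2 - r1^2) / (2 * d * r2))
  a3 <- 0.5 * sqrt((-d + r1 + r2) * (d + r1 - r2) * (d - r1 + r2) * (d + r1 + r2))
  a1 + a2 - a3
}

#' Optimize the node size range for a layout
#'
#' Picks the largest maximum node radius `hi` (with `lo` a fixed fraction
#' of `hi`) such that the total pairwise disc-overlap area stays within
#' `tolerance` of the total disc area, by bisection; if even the smallest
#' candidate violates the bound it is returned anyway. This makes the
#' "minimize overlap, maximize size" goal explicit and testable.
#'
#' @param layout a `TreeLayout` from [layoutTree()].
#' @param values per-taxon statistic mapped to node size (defaults to
#'   equal sizes).
#' @param candidateRange `[hiMin, hiMax]` radii in figure units.
#' @param loFraction `lo = loFraction * hi`.
#' @param tolerance allowed overlap area as a fraction of total disc area.
#' @param iterations bisection iterations.
#' @return Numeric `[lo, hi]` radius range in figure units.
#' @export
optimizeSizeRange <- function(layout, values = NULL,
                              candidateRange = c(0.005, 0.05),
                              loFraction = 0.25, tolerance = 0.01,
                              iterations = 20L) {
  pts <- .figureCoords(layout)
  n <- nrow(pts)
  if (is.null(values)) values <- rep(1, n)
  feasible <- function(hi) {
    lo <- loFraction * hi
    r <- mapAesthetic(values, c(lo, hi))
    total <- sum(pi * r^2)
    overlap <- 0
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        d <- sqrt((pts$fx[i] - pts$fx[j])^2 + (pts$fy[i] - pts$fy[j])^2)
        overlap <- overlap + .lensArea(d, r[i], r[j])
        if (overlap > tolerance * total) return(FALSE)
      }
    }
    TRUE
  }
  if (n <= 1L || feasible(candidateRange[2])) {
    return(c(loFraction * candidateRange[2], candidateRange[2]))
  }
  if (!feasible(candidateRange[1])) {
    return(c(loFraction * candidateRange[1], candidateRange[1]))
  }
  lo <- candidateRange[1]
  hi <- candidateRange[2]
  for (it in seq_len(iterations)) {
    mid <- (lo + hi) / 2
    if (feasible(mid)) lo <- mid else hi <- mid
  }
  c(loFraction * lo, lo)
}

# Figure-level coordinates in [0,1]^2: place each tree's unit cell into
# the near-square grid (y axis grows downwards like SVG).
.figureCoords <- function(layout) {
  nd <- layout$nodes
  pad <- 0.06  # inner padding of each grid cell
  cw <- 1 / layout$ncol
  ch <- 1 / layout$nrow
  fx <- (nd$grid_x + pad + nd$x * (1 - 2 * pad)) * cw
  fy <- (nd$grid_y + pad + (1 - nd$y) * (1 - 2 * pad)) * ch
  data.frame(taxon_id = nd$taxon_id, fx = fx, fy = fy,
             stringsAsFactors = FALSE)
}

.DEFAULT_PALETTE <- c("#2166AC", "#F7F7F7", "#B2182B")  # diverging blue-red
.SINGLE_PALETTE <- c("#C6DBEF", "#08306B")              # sequential blues

#' Render a Taxmap as a heat tree
#'
#' Draws one sub-tree per root in a near-square grid. Node and edge size
#' and color are mapped from per-taxon statistics (columns or expressions
#' over columns and computed columns, as in [filterTaxa()]); quantitative
#' legends are drawn for each mapping and their tick/value pairs are also
#' returned (and written next to SVG output as
#' `<output>.legend.json`). All element geometry is in normalized figure
#' units, so changing the output pixel size rescales everything uniformly;
#' SVG output is byte-deterministic for a fixed input, spec and seed.
#'
#' @param tm a [Taxmap-class] object (non-empty).
#' @param nodeSize,nodeColor,edgeSize,edgeColor statistic mappings:
#'   expressions over taxon columns (e.g. `n_obs`), or `NULL` for a
#'   constant aesthetic.
#' @param nodeLabel label mapping (default `name`); `NULL` for no labels.
#' @param transform transform name applied to all size mappings, or a
#'   named list, e.g. `list(node_size = "log10")`, with entries
#'   `node_size`, `node_color`, `edge_size`, `edge_color`.
#' @param palette colors for the color mappings (anchors of the ramp).
#' @param sizeInterval explicit `[lo, hi]` radius range in figure units,
#'   or `NULL` to optimize via [optimizeSizeRange()].
#' @param colorInterval explicit value interval for color, or `NULL` for
#'   the data range.
#' @param layoutAlgorithm,seed passed to [layoutTree()].
#' @param output file path, or `NULL` to return the SVG text only.
#' @param format `"svg"`, `"pdf"` or `"png"` (non-SVG formats draw the
#'   same normalized geometry on a grDevices device).
#' @param width,height output size in pixels (pdf: 1/100 inch).
#' @return Invisibly, a list with `svg` (character, for svg format),
#'   `layout`, `legend` (per-mapping tick values and their mapped
#'   aesthetics) and `sizeRange`.
#' @examples
#' tm <- parseRecords(c("A;B", "A;C", "A;C"), parseSpec("(.*)", "class", ";"))
#' ht <- heatTree(tm, nodeSize = n_obs, nodeColor = n_obs)
#' substr(ht$svg, 1, 4)  # "<svg"
#' @export
heatTree <- function(tm, nodeSize = NULL, nodeColor = NULL, edgeSize = NULL,
                     edgeColor = NULL, nodeLabel = name,
                     transform = "identity",
                     palette = NULL, sizeInterval = NULL, colorInterval = NULL,
                     layoutAlgorithm = "reingold-tilford", seed = 1L,
                     output = NULL, format = c("svg", "pdf", "png"),
                     width = 800, height = 800) {
  format <- match.arg(format)
  if (!nTaxa(tm)) stop("empty Taxmap", call. = FALSE)
  env <- parent.frame()
  getStat <- function(expr) {
    if (is.null(expr)) return(NULL)
    v <- .evalInTable(tm, "taxa", expr, env)
    v <- .recycleToRows(v, nTaxa(tm), "aesthetic mapping")
    v
  }
  exprs <- list(node_size = substitute(nodeSize),
                node_color = substitute(nodeColor),
                edge_size = substitute(edgeSize),
                edge_color = substitute(edgeColor))
  stats <- lapply(exprs, getStat)
  labExpr <- substitute(nodeLabel)
  labels <- if (is.null(labExpr)) NULL else as.character(getStat(labExpr))

  trOf <- function(key) {
    if (is.list(transform)) transform[[key]] %||% "identity" else transform
  }

  lay <- layoutTree(tm, algorithm = layoutAlgorithm, seed = seed)
  pts <- .figureCoords(lay)

  # taxa with a missing statistic (e.g. prop_amplified where a taxon has no
  # observations) are drawn at the minimum size / in neutral gray
  for (k in names(stats)) {
    if (!is.null(stats[[k]]) && all(is.na(stats[[k]]))) {
      stop("aesthetic statistic '", k, "' is entirely NA", call. = FALSE)
    }
  }

  # node radii
  sizeVals <- stats$node_size %||% rep(1, nTaxa(tm))
  sizeTrans <- trOf("node_size")
  if (is.null(sizeInterval)) {
    transformed <- .applyTransform(sizeVals[!is.na(sizeVals)], sizeTrans, NULL)
    sizeInterval <- optimizeSizeRange(lay, transformed)
  }
  radii <- mapAesthetic(sizeVals, sizeInterval, transform = sizeTrans,
                        names = tm@taxa$taxon_id, naTo = sizeInterval[1])

  # node colors
  legend <- list()
  if (!is.null(stats$node_size)) {
    srng <- range(stats$node_size, na.rm = TRUE)
    ticks <- pretty(stats$node_size[!is.na(stats$node_size)], n = 4L)
    ticks <- ticks[ticks >= srng[1] & ticks <= srng[2]]
    legend$node_size <- list(
      ticks = ticks,
      mapped = if (length(ticks))
        mapAesthetic(ticks, sizeInterval, transform = sizeTrans,
                     valueInterval = srng)
      else numeric())
  }
  nodeCols <- rep("#888888", nTaxa(tm))
  if (!is.null(stats$node_color)) {
    pal <- palette %||% .DEFAULT_PALETTE
    nodeCols <- mapColor(stats$node_color, pal, interval = colorInterval,
                         transform = trOf("node_color"), naColor = "#CCCCCC")
    lohi <- colorInterval %||% range(stats$node_color, na.rm = TRUE)
    ticks <- pretty(lohi, n = 4L)
    ticks <- ticks[ticks >= lohi[1] & ticks <= lohi[2]]
    legend$node_color <- list(
      ticks = ticks,
      mapped = .legendColors(ticks, stats$node_color, pal, colorInterval,
                             trOf("node_color")))
  }

  # edges: statistic belongs to the child taxon
  idx <- stats::setNames(seq_len(nTaxa(tm)), tm@taxa$taxon_id)
  ed <- lay$edges
  childIdx <- idx[ed$taxon_id]
  parentIdx <- idx[ed$parent_id]
  edgeCols <- rep("#BBBBBB", nrow(ed))
  if (!is.null(stats$edge_color)) {
    pal <- palette %||% .DEFAULT_PALETTE
    allCols <- mapColor(stats$edge_color, pal, interval = colorInterval,
                        transform = trOf("edge_color"), naColor = "#CCCCCC")
    edgeCols <- allCols[childIdx]
  }
  if (!is.null(stats$edge_size)) {
    ew <- mapAesthetic(stats$edge_size, sizeInterval * 0.6,
                       transform = trOf("edge_size"), naTo = sizeInterval[1] * 0.6)
    wChild <- ew[childIdx]
    wParent <- ew[parentIdx]
  } else {
    wChild <- radii[childIdx] * 0.5
    wParent <- radii[parentIdx] * 0.5
  }

  geom <- list(pts = pts, radii = radii, nodeCols = nodeCols,
               labels = labels, ed = ed, childIdx = childIdx,
               parentIdx = parentIdx, wChild = wChild, wParent = wParent,
               edgeCols = edgeCols, legend = legend)

  svg <- NULL
  if (format == "svg") {
    svg <- .renderSvg(geom, width, height)
    if (!is.null(output)) {
      writeLines(svg, output, sep = "")
      jsonlite::write_json(legend, paste0(output, ".legend.json"),
                           auto_unbox = FALSE, digits = NA)
    }
  } else {
    if (is.null(output)) stop("output path required for ", format, call. = FALSE)
    .renderDevice(geom, output, format, width, height)
    jsonlite::write_json(legend, paste0(output, ".legend.json"),
                         auto_unbox = FALSE, digits = NA)
  }
  invisible(list(svg = svg, layout = lay, legend = legend,
                 sizeRange = sizeInterval))
}

.legendColors <- function(ticks, values, pal, interval, transform) {
  if (!length(ticks)) return(character())
  # evaluate the same value->color map at the tick positions
  lohi <- interval %||% range(values, na.rm = TRUE)
  pos <- mapAesthetic(ticks, c(0, 1), transform = transform,
                      valueInterval = lohi)
  m <- grDevices::colorRamp(pal, space = "rgb")(pos)
  grDevices::rgb(m[, 1L], m[, 2L], m[, 3L], maxColorValue = 255)
}

.fmtNum <- function(x) formatC(x, format = "f", digits = 4)

# Hand-written SVG with a fixed 1000x1000 viewBox: coordinates depend only
# on the geometry, never on the requested pixel size, so output at two
# sizes differs only in the width/height attributes.
.renderSvg <- function(geom, width, height) {
  U <- 1000  # viewBox units
  plotW <- 0.78  # fraction of figure reserved for trees; rest is legend
  px <- function(v) .fmtNum(v * U * plotW)
  py <- function(v) .fmtNum(v * U)
  out <- character()
  add <- function(...) out <<- c(out, paste0(...))
  add(sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%s" height="%s" viewBox="0 0 1000 1000">',
              .fmtNum(width), .fmtNum(height)))
  add('<rect x="0" y="0" width="1000" height="1000" fill="#FFFFFF"/>')
  pts <- geom$pts
  # tapered edges: quad from parent to child, width tied to node radii
  for (e in seq_len(nrow(geom$ed))) {
    ci <- geom$childIdx[e]
    pi_ <- geom$parentIdx[e]
    x1 <- pts$fx[pi_]; y1 <- pts$fy[pi_]
    x2 <- pts$fx[ci];  y2 <- pts$fy[ci]
    dx <- x2 - x1; dy <- y2 - y1
    len <- sqrt(dx^2 + dy^2)
    if (len == 0) next
    nx <- -dy / len; ny <- dx / len
    w1 <- geom$wParent[e]; w2 <- geom$wChild[e]
    add(sprintf('<polygon points="%s,%s %s,%s %s,%s %s,%s" fill="%s"/>',
                px(x1 + nx * w1), py(y1 + ny * w1),
                px(x1 - nx * w1), py(y1 - ny * w1),
                px(x2 - nx * w2), py(y2 - ny * w2),
                px(x2 + nx * w2), py(y2 + ny * w2),
                geom$edgeCols[e]))
  }
  for (i in seq_len(nrow(pts))) {
    add(sprintf('<circle cx="%s" cy="%s" r="%s" fill="%s"/>',
                px(pts$fx[i]), py(pts$fy[i]),
                .fmtNum(geom$radii[i] * U), geom$nodeCols[i]))
  }
  if (!is.null(geom$labels)) {
    for (i in seq_len(nrow(pts))) {
      lab <- geom$labels[i]
      if (is.na(lab) || !nzchar(lab)) next
      fs <- geom$radii[i] * U * 0.8
      # shrink to a floor, then truncate with an ellipsis
      maxChars <- max(3L, floor(2 * geom$radii[i] * U / (fs * 0.55)))
      if (nchar(lab) > maxChars) {
        fs <- max(fs * 0.6, 8)
        maxChars <- max(3L, floor(2.6 * geom$radii[i] * U / (fs * 0.55)))
        if (nchar(lab) > maxChars) {
          lab <- paste0(substr(lab, 1L, maxChars - 1L), "\u2026")
        }
      }
      add(sprintf('<text x="%s" y="%s" font-size="%s" text-anchor="middle" font-family="sans-serif" fill="#000000">%s</text>',
                  px(pts$fx[i]), py(pts$fy[i]), .fmtNum(fs), .xmlEscape(lab)))
    }
  }
  out <- c(out, .renderSvgLegend(geom$legend))
  add("</svg>")
  paste(out, collapse = "\n")
}

.xmlEscape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

# Legend panel in viewBox units x in [800, 1000].
.renderSvgLegend <- function(legend) {
  out <- character()
  y0 <- 60
  if (!is.null(legend$node_color) && length(legend$node_color$ticks)) {
    lc <- legend$node_color
    out <- c(out, sprintf('<text x="%s" y="%s" font-size="18" font-family="sans-serif">node color</text>',
                          .fmtNum(810), .fmtNum(y0 - 20)))
    n <- length(lc$ticks)
    for (i in seq_len(n)) {
      y <- y0 + (i - 1) * 26
      out <- c(out, sprintf('<rect x="%s" y="%s" width="22" height="22" fill="%s"/>',
                            .fmtNum(810), .fmtNum(y), lc$mapped[i]))
      out <- c(out, sprintf('<text x="%s" y="%s" font-size="16" font-family="sans-serif">%s</text>',
                            .fmtNum(840), .fmtNum(y + 16), .fmtNum(lc$ticks[i])))
    }
    y0 <- y0 + n * 26 + 60
  }
  if (!is.null(legend$node_size) && length(legend$node_size$ticks)) {
    ls <- legend$node_size
    out <- c(out, sprintf('<text x="%s" y="%s" font-size="18" font-family="sans-serif">node size</text>',
                          .fmtNum(810), .fmtNum(y0 - 20)))
    for (i in seq_along(ls$ticks)) {
      r <- ls$mapped[i] * 1000
      y <- y0 + (i - 1) * 50 + 20
      out <- c(out, sprintf('<circle cx="%s" cy="%s" r="%s" fill="#888888"/>',
                            .fmtNum(825), .fmtNum(y), .fmtNum(r)))
      out <- c(out, sprintf('<text x="%s" y="%s" font-size="16" font-family="sans-serif">%s</text>',
                            .fmtNum(860), .fmtNum(y + 6), .fmtNum(ls$ticks[i])))
    }
  }
  out
}

# Draw the same normalized geometry on a pdf/png device.
.renderDevice <- function(geom, output, format, width, height) {
  if (format == "pdf") {
    grDevices::pdf(output, width = width / 100, height = height / 100)
  } else {
    grDevices::png(output, width = width, height = height)
  }
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(0, 0, 0, 0))
  graphics::plot.new()
  graphics::plot.window(xlim = c(0, 1), ylim = c(1, 0), asp = 1)
  pts <- geom$pts
  plotW <- 0.78
  for (e in seq_len(nrow(geom$ed))) {
    ci <- geom$childIdx[e]; pi_ <- geom$parentIdx[e]
    x1 <- pts$fx[pi_] * plotW; y1 <- pts$fy[pi_]
    x2 <- pts$fx[ci] * plotW;  y2 <- pts$fy[ci]
    dx <- x2 - x1; dy <- y2 - y1
    len <- sqrt(dx^2 + dy^2)
    if (len == 0) next
    nx <- -dy / len; ny <- dx / len
    w1 <- geom$wParent[e]; w2 <- geom$wChild[e]
    graphics::polygon(c(x1 + nx * w1, x1 - nx * w1, x2 - nx * w2, x2 + nx * w2),
                      c(y1 + ny * w1, y1 - ny * w1, y2 - ny * w2, y2 + ny * w2),
                      col = geom$edgeCols[e], border = NA)
  }
  graphics::symbols(pts$fx * plotW, pts$fy, circles = geom$radii,
                    inches = FALSE, add = TRUE, bg = geom$nodeCols, fg = NA)
  if (!is.null(geom$labels)) {
    keep <- !is.na(geom$labels) & nzchar(geom$labels)
    graphics::text(pts$fx[keep] * plotW, pts$fy[keep], geom$labels[keep],
                   cex = 0.6)
  }
  invisible(output)
}
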