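#' Matrix-backed raster grid
#'
#' A raster is a numeric matrix with grid geometry attached: row 1 is the
#' north edge, values sit at cell centers, coordinates are projected
#' metres. `xll`/`yll` locate the lower-left corner of the grid.
#'
#' @param values numeric matrix (rows = north to south)
#' @param xll,yll lower-left corner coordinates (m)
#' @param cellsize cell edge length (m), > 0
#' @return a `raster_grid`
#' @export
raster_grid <- function(values, xll = 0, yll = 0, cellsize = 30) {
  stopifnot(is.matrix(values), cellsize > 0)
  structure(values, xll = xll, yll = yll, cellsize = cellsize,
            class = c("raster_grid", "matrix"))
}

#' @export
print.raster_grid <- function(x, ...) {
  cat(sprintf("raster_grid: %d x %d cells, cellsize %g m, origin (%g, %g)\n",
              nrow(x), ncol(x), attr(x, "cellsize"),
              attr(x, "xll"), attr(x, "yll")))
  invisible(x)
}

grid_geometry <- function(r) {
  list(xll = attr(r, "xll"), yll = attr(r, "yll"),
       cellsize = attr(r, "cellsize"), nrow = nrow(r), ncol = ncol(r))
}

same_raster <- function(values, template) {
  raster_grid(values, attr(template, "xll"), attr(template, "yll"),
              attr(template, "cellsize"))
}

#' Co-registered stack of raster layers
#' @param ... named `raster_grid` layers sharing one geometry
#' @return a `landscape_stack` (named list)
#' @export
landscape_stack <- function(...) {
  layers <- list(...)
  if (length(layers) == 1L && is.list(layers[[1]]) &&
      !inherits(layers[[1]], "raster_grid")) layers <- layers[[1]]
  stopifnot(length(layers) >= 1L, !is.null(names(layers)),
            all(nzchar(names(layers))))
  g0 <- grid_geometry(layers[[1]])
  for (nm in names(layers))
    if (!identical(grid_geometry(layers[[nm]]), g0))
      stop("layer '", nm, "' is not co-registered with the first layer")
  structure(layers, class = "landscape_stack")
}

#' Read / write ESRI ASCII grid
#'
#' Plain-text headered grid (ncols/nrows/xllcorner/yllcorner/cellsize/
#' NODATA_value followed by rows north to south).
#'
#' @param path file path
#' @return a `raster_grid`
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1L
  }
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA_real_
  raster_grid(m, xll = hdr$xllcorner %||% 0, yll = hdr$yllcorner %||% 0,
              cellsize = hdr$cellsize)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname read_ascii_grid
#' @param r a `raster_grid`
#' @export
write_ascii_grid <- function(r, path) {
  g <- grid_geometry(r)
  hdr <- c(sprintf("ncols %d", g$ncol), sprintf("nrows %d", g$nrow),
           sprintf("xllcorner %.10g", g$xll), sprintf("yllcorner %.10g", g$yll),
           sprintf("cellsize %.10g", g$cellsize), "NODATA_value -9999")
  m <- unclass(r)
  m[is.na(m)] <- -9999
  body <- apply(m, 1, function(row) paste(format(row, trim = TRUE,
                                                 scientific = FALSE),
                                          collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

# window offsets for an integer window width: centered for odd widths,
# split -floor((w-1)/2)..floor(w/2) for even
window_offsets <- function(window) {
  stopifnot(window >= 1L)
  (-((window - 1L) %/% 2L)):(window %/% 2L)
}

# summed-area table with an extra zero row/col on top/left
integral_image <- function(m) {
  s <- apply(m, 2, cumsum)
  if (is.null(dim(s))) s <- matrix(s, nrow = 1L)
  s <- t(apply(s, 1, cumsum))
  if (nrow(m) == 1L) s <- matrix(s, nrow = 1L)
  rbind(0, cbind(0, s))
}

# windowed sum via integral image, truncated at edges
window_sum <- function(m, window) {
  off <- window_offsets(window)
  nr <- nrow(m); nc <- ncol(m)
  s <- integral_image(m)
  r1 <- pmax(seq_len(nr) + off[1], 1L); r2 <- pmin(seq_len(nr) + off[length(off)], nr)
  c1 <- pmax(seq_len(nc) + off[1], 1L); c2 <- pmin(seq_len(nc) + off[length(off)], nc)
  out <- matrix(0, nr, nc)
  for (j in seq_len(nc)) {
    out[, j] <- s[r2 + 1L, c2[j] + 1L] - s[r1, c2[j] + 1L] -
                s[r2 + 1L, c1[j]] + s[r1, c1[j]]
  }
  out
}

#' Percent cover in a moving window
#'
#' Fraction (in percent) of non-missing cells equal to 1 within a
#' `window` x `window` neighborhood of each cell; edge cells use the
#' truncated window.
#'
#' @param mask binary `raster_grid` (0/1/NA)
#' @param window window width in cells
#' @return `raster_grid` of percentages in [0, 100]
#' @export
percent_cover <- function(mask, window) {
  if (window > nrow(mask) && window > ncol(mask))
    stop("window exceeds the raster in both dimensions")
  v <- unclass(mask)
  if (!all(v %in% c(0, 1) | is.na(v)))
    stop("mask must be binary (0/1/NA)")
  ones <- v; ones[is.na(ones)] <- 0
  valid <- (!is.na(v)) + 0
  n1 <- window_sum(ones, window)
  nv <- window_sum(valid, window)
  out <- 100 * n1 / nv
  out[nv == 0] <- NA_real_
  same_raster(out, mask)
}

# generic truncated-window statistic by offset accumulation
window_reduce <- function(m, window, init, fun) {
  off <- window_offsets(window)
  nr <- nrow(m); nc <- ncol(m)
  acc <- matrix(init, nr, nc)
  for (dr in off) for (dc in off) {
    shifted <- matrix(init, nr, nc)
    r_src <- intersect(seq_len(nr) + dr, seq_len(nr))
    c_src <- intersect(seq_len(nc) + dc, seq_len(nc))
    shifted[r_src - dr, c_src - dc] <- m[r_src, c_src]
    acc <- fun(acc, shifted)
  }
  acc
}

#' Surface relief ratio in a moving window
#'
#' `(mean - min) / (max - min)` of elevation over the neighborhood; flat
#' neighborhoods (max = min) report 0. Values always lie in [0, 1].
#'
#' @param dem `raster_grid` of elevations (m)
#' @param window window width in cells (3 and 27 are the usual scales)
#' @return `raster_grid` of relief ratios
#' @export
surface_relief_ratio <- function(dem, window) {
  m <- unclass(dem)
  mn <- window_reduce(m, window, Inf, pmin)
  mx <- window_reduce(m, window, -Inf, pmax)
  sm <- window_sum(m, window)
  cnt <- window_sum(matrix(1, nrow(m), ncol(m)), window)
  mean_ <- sm / cnt
  rng <- mx - mn
  out <- ifelse(rng > 0, (mean_ - mn) / rng, 0)
  same_raster(out, dem)
}

#' Slope and aspect by Horn's 8-neighbor method
#'
#' @param dem `raster_grid` of elevations (m)
#' @return list of `raster_grid`: `slope` (radians) and `aspect`
#'   (degrees clockwise from north; `NA` on flat cells)
#' @export
slope_aspect <- function(dem) {
  m <- unclass(dem)
  cs <- attr(dem, "cellsize")
  nr <- nrow(m); nc <- ncol(m)
  # replicate-pad the border
  p <- m[c(1, seq_len(nr), nr), c(1, seq_len(nc), nc)]
  z <- function(dr, dc) p[seq_len(nr) + 1L + dr, seq_len(nc) + 1L + dc]
  # row +1 = south, col +1 = east
  dzdx <- ((z(-1, 1) + 2 * z(0, 1) + z(1, 1)) -
           (z(-1, -1) + 2 * z(0, -1) + z(1, -1))) / (8 * cs)
  dzdy <- ((z(-1, -1) + 2 * z(-1, 0) + z(-1, 1)) -
           (z(1, -1) + 2 * z(1, 0) + z(1, 1))) / (8 * cs)
  slope <- atan(sqrt(dzdx^2 + dzdy^2))
  aspect <- (atan2(-dzdx, -dzdy) * 180 / pi) %% 360
  aspect[slope == 0] <- NA_real_
  list(slope = same_raster(slope, dem), aspect = same_raster(aspect, dem))
}

#' Heat load index (McCune & Keon 2002)
#'
#' Terrain proxy for incident solar heating, from slope, aspect folded
#' about the southwest (225 degree) axis, and latitude:
#' `exp(-1.467 + 1.582 cos(L) cos(S) - 1.500 cos(A) sin(S) sin(L)
#'  - 0.262 sin(L) sin(S) + 0.607 sin(A) sin(S))`
#' with `A` the folded aspect. Positive everywhere; flat cells take the
#' aspect-neutral value (the aspect terms vanish with sin(S) = 0).
#'
#' @param dem `raster_grid` of elevations (m)
#' @param latitude site latitude in degrees (0 to 60)
#' @return `raster_grid` of heat load values
#' @export
heat_load_index <- function(dem, latitude) {
  stopifnot(latitude >= 0, latitude <= 60)
  sa <- slope_aspect(dem)
  s <- unclass(sa$slope)
  asp <- unclass(sa$aspect) * pi / 180
  asp[is.na(asp)] <- 5 * pi / 4  # flat: sin(S)=0 makes the choice inert
  folded <- abs(pi - abs(asp - 5 * pi / 4))
  l <- latitude * pi / 180
  hli <- exp(-1.467 + 1.582 * cos(l) * cos(s) -
             1.500 * cos(folded) * sin(s) * sin(l) -
             0.262 * sin(l) * sin(s) + 0.607 * sin(folded) * sin(s))
  same_raster(hli, dem)
}

# cell indices (row, col) for points; NA outside extent
point_to_cell <- function(r, x, y) {
  g <- grid_geometry(r)
  col <- floor((x - g$xll) / g$cellsize) + 1L
  row <- g$nrow - floor((y - g$yll) / g$cellsize)
  bad <- col < 1L | col > g$ncol | row < 1L | row > g$nrow
  col[bad] <- NA_integer_; row[bad] <- NA_integer_
  cbind(row = row, col = col)
}

raster_lookup <- function(r, x, y) {
  rc <- point_to_cell(r, x, y)
  out <- rep(NA_real_, length(x))
  ok <- !is.na(rc[, 1])
  out[ok] <- unclass(r)[rc[ok, , drop = FALSE]]
  out
}

#' At-site covariates: layer means over a disc around each site
#'
#' Averages each layer over cells whose centers fall within `radius` of
#' the site point (at minimum the containing cell). The default radius of
#' 370 m gives a disc of about 0.43 km^2, matching a typical occupied-site
#' footprint when true site polygons are unavailable.
#'
#' @param stack a `landscape_stack`
#' @param sites a `site_table`
#' @param radius disc radius in metres
#' @param layers which layers to extract (default all)
#' @return data.frame: population plus one column per layer
#' @export
at_site_covariates <- function(stack, sites, radius = 370, layers = names(stack)) {
  r0 <- stack[[1]]
  g <- grid_geometry(r0)
  xs <- g$xll + (seq_len(g$ncol) - 0.5) * g$cellsize
  ys <- g$yll + (g$nrow - seq_len(g$nrow) + 0.5) * g$cellsize
  out <- data.frame(population = sites$population)
  cell_sets <- lapply(seq_len(nrow(sites)), function(i) {
    if (is.na(point_to_cell(r0, sites$x[i], sites$y[i])[1, 1]))
      stop("site outside raster extent: ", sites$population[i])
    dx <- outer(ys - sites$y[i], xs - sites$x[i],
                function(a, b) sqrt(a^2 + b^2))
    sel <- which(dx <= radius)
    if (length(sel) == 0L)
      sel <- which(dx == min(dx))[1]
    sel
  })
  for (nm in layers) {
    vals <- unclass(stack[[nm]])
    out[[nm]] <- vapply(cell_sets, function(sel)
      mean(vals[sel], na.rm = TRUE), numeric(1))
  }
  out
}

#' Mean and variance of layers along an edge transect
#'
#' Samples the straight segment between two points at `step` spacing, with
#' perpendicular offsets filling each requested corridor width, and
#' reports the mean and variance of the sampled cell values per layer per
#' width.
#'
#' @param stack a `landscape_stack`
#' @param p1,p2 numeric length-2 points (x, y), distinct, inside extent
#' @param widths corridor widths in metres (default 30)
#' @param step sampling interval in metres (default the cell size)
#' @param layers which layers to sample
#' @return data.frame: layer, width, mean, var, n
#' @export
edge_transect_stats <- function(stack, p1, p2, widths = 30,
                                step = NULL, layers = names(stack)) {
  r0 <- stack[[1]]
  if (isTRUE(all.equal(p1, p2))) stop("transect endpoints must differ")
  cs <- attr(r0, "cellsize")
  if (is.null(step)) step <- cs
  v <- c(p2[1] - p1[1], p2[2] - p1[2])
  len <- sqrt(sum(v^2))
  u <- v / len
  perp <- c(-u[2], u[1])
  ts <- seq(0, len, by = step)
  rows <- list()
  for (w in widths) {
    offs <- if (w <= step) 0 else seq(-w / 2, w / 2, by = step)
    px <- outer(p1[1] + ts * u[1], offs * perp[1], `+`)
    py <- outer(p1[2] + ts * u[2], offs * perp[2], `+`)
    for (nm in layers) {
      vals <- raster_lookup(stack[[nm]], as.vector(px), as.vector(py))
      vals <- vals[!is.na(vals)]
      if (length(vals) == 0L)
        stop("transect falls entirely outside the raster extent")
      rows[[length(rows) + 1L]] <- data.frame(
        layer = nm, width = w, mean = mean(vals),
        var = if (length(vals) > 1L) stats::var(vals) else 0,
        n = length(vals))
    }
  }
  do.call(rbind, rows)
}

#' Between-site covariates for every site pair
#'
#' Straight-line transect means (30 m corridor by default) for each
#' unordered site pair, symmetric across orientations.
#'
#' @param stack a `landscape_stack`
#' @param sites a `site_table`
#' @param width corridor width in metres
#' @param step sampling interval (default cell size)
#' @param layers which layers to extract
#' @param stat `"mean"` or `"var"`
#' @return data.frame: pop_i, pop_j plus one column per layer
#' @export
between_site_covariates <- function(stack, sites, width = 30, step = NULL,
                                    layers = names(stack), stat = "mean") {
  n <- nrow(sites)
  rows <- list()
  for (i in seq_len(n)) for (j in seq_len(i - 1L)) {
    st <- edge_transect_stats(stack, c(sites$x[i], sites$y[i]),
                              c(sites$x[j], sites$y[j]),
                              widths = width, step = step, layers = layers)
    vals <- stats::setNames(st[[stat]], st$layer)
    rows[[length(rows) + 1L]] <- c(list(pop_i = sites$population[i],
                                        pop_j = sites$population[j]),
                                   as.list(vals))
  }
  do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
}
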