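# Unit-cell geometry and structured mesh.
#
# The domain is a half unit cell exploiting lateral symmetry: x runs from the
# mid-chloroplast plane (x = 0) to the mid-gap plane (x = W/2), y runs from
# the wall surface facing the intercellular airspace (y = 0) inward to the
# tonoplast. Depth ordering: wall | plasma membrane | outer cytosol |
# envelope | stroma | envelope | inner cytosol | tonoplast (no flux).
# The cytosol gap between neighbouring chloroplasts spans
# x in (sc_sm * W/2, W/2] over the stroma depth range and is contiguous with
# the outer and inner cytosol layers (no membrane).

LAYER_LEVELS <- c("wall", "outer_cytosol", "stroma", "gap_cytosol",
                  "inner_cytosol")

SCENARIOS <- c("inner", "gaps", "outer")

scenario_source_layer <- function(scenario) {
  switch(scenario,
         inner = "inner_cytosol",
         gaps  = "gap_cytosol",
         outer = "outer_cytosol",
         stop("unknown scenario '", scenario,
              "'; must be one of inner, gaps, outer", call. = FALSE))
}

#' Build the simplified 2D mesophyll unit cell
#'
#' Constructs the layer rectangles, membrane interfaces and the
#' (photo)respiratory source region for one of the three release scenarios:
#' `"inner"` (cytosol layer between chloroplast and tonoplast), `"gaps"`
#' (cytosol between neighbouring chloroplasts) or `"outer"` (cytosol between
#' plasma membrane and chloroplast).
#'
#' @param anatomy A [leaf_anatomy()] object.
#' @param scenario One of `"inner"`, `"gaps"`, `"outer"`.
#' @return An object of class `cell_geometry`: a list with `layers` (a tibble
#'   of axis-aligned rectangles), `interfaces` (membrane segments with a
#'   permeability slot), the half-width `W2`, the chloroplast lateral span
#'   `x_chl`, depth breaks `y_breaks`, and `source_layer`.
#' @export
build_unit_cell <- function(anatomy, scenario = c("inner", "gaps", "outer")) {
  stopifnot(inherits(anatomy, "leaf_anatomy"))
  scenario <- match.arg(scenario)
  W2 <- anatomy$lchl / anatomy$sc_sm
  x_chl <- anatomy$lchl
  gap_width <- W2 - x_chl
  if (scenario == "gaps" && gap_width <= 0) {
    stop("scenario 'gaps' has an empty source region when sc_sm = 1",
         call. = FALSE)
  }
  y0 <- 0
  y1 <- anatomy$twall
  y2 <- y1 + anatomy$tcyt
  y3 <- y2 + anatomy$tstr
  y4 <- y3 + anatomy$tcyt_inner

  layers <- tibble::tibble(
    layer = c("wall", "outer_cytosol", "stroma", "gap_cytosol",
              "inner_cytosol"),
    x0 = c(0, 0, 0, x_chl, 0),
    x1 = c(W2, W2, x_chl, W2, W2),
    y0 = c(y0, y1, y2, y2, y3),
    y1 = c(y1, y2, y3, y3, y4)
  )
  if (gap_width <= 0) {
    layers <- layers[layers$layer != "gap_cytosol", ]
  }

  interfaces <- tibble::tibble(
    interface = c("plasma_membrane", "envelope_outer", "envelope_inner"),
    orientation = "horizontal",
    position = c(y1, y2, y3),
    from = c(0, 0, 0),
    to = c(W2, x_chl, x_chl),
    permeability = c("p_pm", "p_env", "p_env")
  )
  if (gap_width > 0) {
    interfaces <- dplyr::bind_rows(
      interfaces,
      tibble::tibble(interface = "envelope_lateral",
                     orientation = "vertical", position = x_chl,
                     from = y2, to = y3, permeability = "p_env")
    )
  }

  structure(
    list(layers = layers, interfaces = interfaces,
         W2 = W2, x_chl = x_chl, gap_width = gap_width,
         y_breaks = c(y0, y1, y2, y3, y4),
         scenario = scenario,
         source_layer = scenario_source_layer(scenario),
         anatomy = anatomy),
    class = "cell_geometry"
  )
}

#' @export
print.cell_geometry <- function(x, ...) {
  cat("<cell_geometry>\n")
  cat(sprintf("  half-width W/2 = %.3f um, chloroplast span %.3f um, gap %.3f um\n",
              x$W2 * 1e6, x$x_chl * 1e6, x$gap_width * 1e6))
  cat(sprintf("  depth %.3f um, scenario '%s' (source: %s)\n",
              max(x$y_breaks) * 1e6, x$scenario, x$source_layer))
  invisible(x)
}

# Allocate n grid intervals across segments of given lengths, at least
# `minimum` per (positive-length) segment, proportionally to length.
allocate_cells <- function(lengths, n, minimum = 2L) {
  pos <- lengths > 0
  k <- sum(pos)
  if (n < minimum * k) {
    worst <- which(pos)[which.min(lengths[pos])]
    stop(sprintf(
      "resolution too coarse to resolve layer '%s' (need >= %d cells across %d layers)",
      names(lengths)[worst], minimum, k), call. = FALSE)
  }
  alloc <- rep(0L, length(lengths))
  raw <- lengths[pos] / sum(lengths[pos]) * n
  a <- pmax(minimum, floor(raw))
  # distribute the remainder to the largest fractional parts
  while (sum(a) > n) {
    i <- which.max(a - minimum)
    if (a[i] <= minimum) break
    a[i] <- a[i] - 1L
  }
  frac <- raw - floor(raw)
  while (sum(a) < n) {
    i <- which.max(frac)
    a[i] <- a[i] + 1L
    frac[i] <- -1
  }
  alloc[pos] <- a
  alloc
}

#' Generate a structured finite-volume mesh on the unit cell
#'
#' Cell-centered rectangular mesh whose grid lines include every layer
#' boundary and membrane interface, so that each cell lies wholly inside one
#' layer and interfaces coincide with cell faces. Rows (depth) are allocated
#' to the four depth layers, and columns (lateral) to the chloroplast span
#' and the gap, proportionally to extent with at least two cells each.
#'
#' @param geometry A [build_unit_cell()] object.
#' @param resolution Integer vector `c(nx, ny)`: lateral columns and depth
#'   rows. Both must be >= 4 and large enough to resolve every layer.
#' @return An object of class `cell_mesh`: grid spacings `dx`, `dy`, centers
#'   `xc`, `yc`, an `ny x nx` integer `layer` matrix (levels
#'   `mesodiff:::LAYER_LEVELS`), membrane codes on horizontal faces
#'   (`(ny+1) x nx`) and vertical faces (`ny x (nx+1)`), and bookkeeping
#'   copied from the geometry.
#' @export
generate_mesh <- function(geometry, resolution = c(12L, 40L)) {
  stopifnot(inherits(geometry, "cell_geometry"))
  nx <- as.integer(resolution[1]); ny <- as.integer(resolution[2])
  if (nx < 4L || ny < 4L) stop("resolution must be at least 4 x 4", call. = FALSE)

  an <- geometry$anatomy
  depth_lengths <- c(wall = an$twall, outer_cytosol = an$tcyt,
                     stroma = an$tstr, inner_cytosol = an$tcyt_inner)
  n_rows <- allocate_cells(depth_lengths, ny, minimum = 2L)
  lateral_lengths <- c(chloroplast = geometry$x_chl, gap = geometry$gap_width)
  n_cols <- allocate_cells(lateral_lengths, nx,
                           minimum = if (geometry$gap_width > 0) 2L else 0L)
  if (geometry$gap_width <= 0) n_cols <- c(chloroplast = nx, gap = 0L)

  dy <- unlist(lapply(seq_along(depth_lengths), function(i) {
    rep(depth_lengths[i] / n_rows[i], n_rows[i])
  }), use.names = FALSE)
  dx <- unlist(lapply(seq_along(lateral_lengths), function(i) {
    if (n_cols[i] == 0) return(numeric(0))
    rep(lateral_lengths[i] / n_cols[i], n_cols[i])
  }), use.names = FALSE)
  yc <- cumsum(dy) - dy / 2
  xc <- cumsum(dx) - dx / 2

  row_layer <- rep(names(depth_lengths), n_rows)   # depth layer per row
  col_in_gap <- rep(c(FALSE, TRUE), n_cols)        # lateral region per column

  layer <- matrix(0L, nrow = ny, ncol = nx)
  for (j in seq_len(nx)) {
    lab <- row_layer
    if (col_in_gap[j]) lab[lab == "stroma"] <- "gap_cytosol"
    layer[, j] <- match(lab, LAYER_LEVELS)
  }

  # membrane codes: 0 none, 1 plasma membrane, 2 envelope
  row_cum <- cumsum(n_rows)
  hface <- matrix(0L, nrow = ny + 1L, ncol = nx)
  hface[row_cum[1] + 1L, ] <- 1L                        # wall | outer cytosol
  env_cols <- which(!col_in_gap)
  hface[row_cum[2] + 1L, env_cols] <- 2L                # outer cytosol | stroma
  hface[row_cum[3] + 1L, env_cols] <- 2L                # stroma | inner cytosol
  vface <- matrix(0L, nrow = ny, ncol = nx + 1L)
  if (n_cols[2] > 0) {
    stroma_rows <- which(row_layer == "stroma")
    vface[stroma_rows, n_cols[1] + 1L] <- 2L            # stroma | gap cytosol
  }

  structure(
    list(nx = nx, ny = ny, dx = dx, dy = dy, xc = xc, yc = yc,
         layer = layer, hface = hface, vface = vface,
         row_layer = row_layer, col_in_gap = col_in_gap,
         W2 = geometry$W2, scenario = geometry$scenario,
         source_layer = geometry$source_layer, anatomy = an),
    class = "cell_mesh"
  )
}

#' Mesh cells as a tibble
#'
#' One row per finite-volume cell with its center coordinates, widths, area
#' (per unit depth in the homogeneous third dimension) and layer label.
#'
#' @param mesh A [generate_mesh()] object.
#' @return A tibble with columns `row`, `col`, `x`, `y`, `dx`, `dy`, `area`,
#'   `layer`.
#' @export
mesh_cells <- function(mesh) {
  stopifnot(inherits(mesh, "cell_mesh"))
  grid <- expand.grid(row = seq_len(mesh$ny), col = seq_len(mesh$nx))
  tibble::tibble(
    row = grid$row, col = grid$col,
    x = mesh$xc[grid$col], y = mesh$yc[grid$row],
    dx = mesh$dx[grid$col], dy = mesh$dy[grid$row],
    area = mesh$dx[grid$col] * mesh$dy[grid$row],
    layer = LAYER_LEVELS[mesh$layer[cbind(grid$row, grid$col)]]
  )
}

#' @export
print.cell_mesh <- function(x, ...) {
  cat(sprintf("<cell_mesh> %d x %d cells (%d unknowns), scenario '%s'\n",
              x$nx, x$ny, x$nx * x$ny, x$scenario))
  invisible(x)
}
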