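#' Sentinel returned by `patch_at()` for coordinates beyond the island border
#'
#' Seeds whose dispersal trajectory ends outside the island die; `patch_at()`
#' signals such positions by returning this sentinel instead of a patch.
#'
#' @export
OFF_ISLAND <- structure("OFF_ISLAND", class = "invasim_off_island")

#' Construct the gridded island landscape
#'
#' Builds a square island of one-hectare patches with a radially symmetric
#' mountain and a linear precipitation gradient. Elevation rises in concentric
#' rings from 0 at the outer edge to `(side - 1) / 2` at the central peak
#' (Chebyshev rings); temperature drops by 2 degrees Celsius per unit of
#' height from the lowland `base_temperature`. Precipitation is an abstract
#' resource that varies only with column, interpolated linearly across
#' `precip_range`. One patch is flagged as the point of entry where all alien
#' propagules arrive.
#'
#' @param side odd integer >= 3; number of patches along one island edge.
#' @param base_temperature lowland (edge ring) temperature in degrees Celsius.
#' @param precip_range length-2 numeric, `(min, max)` of the abstract
#'   precipitation gradient across columns; `min < max`.
#' @param entry_cell length-2 integer `(row, col)`, 0-based grid indices of
#'   the point of entry. Defaults to the mid-edge lowland cell
#'   `((side - 1) / 2, 0)`.
#' @param capacity biomass carrying capacity of every patch, in grams.
#'
#' @return An object of class `invasim_island`: a list with the grid geometry
#'   and a `patches` data frame (one row per patch) holding `row`, `col`
#'   (0-based), `elevation`, `temperature`, `precipitation`, `capacity` and
#'   `is_entry`. Patch `i` of the data frame is the patch with
#'   `row * side + col + 1 == i`.
#'
#' @examples
#' isl <- build_island(side = 5, base_temperature = 15)
#' range(isl$patches$temperature)   # 11 at the peak, 15 on the edge ring
#' @export
build_island <- function(side = 5L,
                         base_temperature = 15,
                         precip_range = c(0, 10),
                         entry_cell = c((side - 1L) %/% 2L, 0L),
                         capacity = 2e6) {
  side <- as.integer(side)
  if (is.na(side) || side < 3L || side %% 2L == 0L)
    stop("`side` must be an odd integer >= 3", call. = FALSE)
  if (length(precip_range) != 2L || !(precip_range[1] < precip_range[2]))
    stop("`precip_range` must be (min, max) with min < max", call. = FALSE)
  entry_cell <- as.integer(entry_cell)
  if (length(entry_cell) != 2L || any(is.na(entry_cell)) ||
      any(entry_cell < 0L) || any(entry_cell >= side))
    stop("`entry_cell` must be 0-based (row, col) inside the grid",
         call. = FALSE)
  if (!is.numeric(capacity) || capacity <= 0)
    stop("`capacity` must be a positive biomass in grams", call. = FALSE)

  idx <- 0L:(side - 1L)
  grid <- expand.grid(col = idx, row = idx)[, c("row", "col")]
  half <- (side - 1L) %/% 2L
  # ring index from the outside in: Chebyshev distance from the center cell
  cheb <- pmax(abs(grid$row - half), abs(grid$col - half))
  elevation <- half - cheb
  temperature <- base_temperature - 2 * elevation
  precipitation <- precip_range[1] +
    grid$col * (precip_range[2] - precip_range[1]) / (side - 1L)
  patches <- data.frame(
    row = grid$row,
    col = grid$col,
    elevation = elevation,
    temperature = temperature,
    precipitation = precipitation,
    capacity = capacity,
    is_entry = grid$row == entry_cell[1] & grid$col == entry_cell[2]
  )
  structure(
    list(side = side,
         base_temperature = base_temperature,
         precip_range = precip_range,
         entry_cell = entry_cell,
         capacity = capacity,
         patches = patches,
         entry_patch = which(patches$is_entry)),
    class = "invasim_island"
  )
}

#' @export
print.invasim_island <- function(x, ...) {
  cat(sprintf(
    "Island: %d x %d one-hectare patches, lowland %g degC, precip %g-%g, entry (%d,%d)\n",
    x$side, x$side, x$base_temperature, x$precip_range[1], x$precip_range[2],
    x$entry_cell[1], x$entry_cell[2]))
  invisible(x)
}

# vectorized continuous-coordinate -> patch index; NA marks off-island.
# Patch centers sit on integer coordinates, cells are unit squares with
# half-open bounds [k - 0.5, k + 0.5).
patch_index_at <- function(island, x, y) {
  r <- floor(x + 0.5)
  c <- floor(y + 0.5)
  off <- r < 0 | r >= island$side | c < 0 | c >= island$side
  out <- as.integer(r * island$side + c + 1L)
  out[off] <- NA_integer_
  out
}

#' Map a continuous coordinate to the containing patch
#'
#' Patch centers lie on integer coordinates `(row, col)` and each patch is a
#' unit square with half-open bounds, so the island occupies
#' `[-0.5, side - 0.5)` in both axes. Coordinates outside that square return
#' the [OFF_ISLAND] sentinel (the fate of seeds dispersing over the border).
#'
#' @param island an `invasim_island`.
#' @param x,y scalar continuous coordinates along the row and column axes.
#' @return A one-row data frame (the patch), or [OFF_ISLAND].
#' @examples
#' isl <- build_island()
#' patch_at(isl, 0, 0)$temperature
#' patch_at(isl, -0.6, 2)      # OFF_ISLAND
#' @export
patch_at <- function(island, x, y) {
  stopifnot(inherits(island, "invasim_island"),
            length(x) == 1L, length(y) == 1L)
  i <- patch_index_at(island, x, y)
  if (is.na(i)) OFF_ISLAND else island$patches[i, , drop = FALSE]
}

#' Test whether `patch_at()` fell off the island
#'
#' @param x a return value of [patch_at()].
#' @return `TRUE` if `x` is the [OFF_ISLAND] sentinel.
#' @export
is_off_island <- function(x) inherits(x, "invasim_off_island")
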