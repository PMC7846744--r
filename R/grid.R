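#' Number of cells in a grid
#' @param grid a [GridSpec-class].
#' @return integer cell count.
#' @export
nCell <- function(grid) grid@nrow * grid@ncol

#' Cell center coordinates
#'
#' Cell ids are 1-based row-major from the north-west corner.
#'
#' @param grid a [GridSpec-class].
#' @param cells cell ids; default all cells.
#' @return data.frame with `cell`, `row`, `col`, `lon`, `lat`.
#' @export
cellCenters <- function(grid, cells = seq_len(nCell(grid))) {
  row <- (cells - 1L) %/% grid@ncol + 1L
  col <- (cells - 1L) %% grid@ncol + 1L
  data.frame(cell = cells, row = row, col = col,
             lon = grid@xmin + (col - 0.5) * grid@cellSize,
             lat = grid@ymax - (row - 0.5) * grid@cellSize)
}

sameGrid <- function(a, b, tol = 1e-9) {
  a@nrow == b@nrow && a@ncol == b@ncol &&
    abs(a@cellSize - b@cellSize) < tol &&
    abs(a@xmin - b@xmin) < tol && abs(a@ymax - b@ymax) < tol
}

#' Realm names used for a given number of realms
#'
#' With six realms the six classic biogeographic realm names are used;
#' otherwise realms are labeled `realm_1`, `realm_2`, ...
#'
#' @param nRealms number of realms.
#' @return character vector of realm names.
#' @export
realmLevels <- function(nRealms) {
  if (nRealms == 6L) SIX_REALMS else paste0("realm_", seq_len(nRealms))
}

# Partition grid columns into nRealms contiguous longitudinal bands.
makeRealmMask <- function(grid, nRealms) {
  breaks <- floor(seq(0, grid@ncol, length.out = nRealms + 1))
  colRealm <- rep(seq_len(nRealms), times = diff(breaks))
  realm <- colRealm[cellCenters(grid)$col]
  new("RealmMask", realm = as.integer(realm),
      levels = realmLevels(nRealms), grid = grid)
}

#' Realm membership queries
#'
#' @param mask a [RealmMask-class].
#' @param realm a realm name.
#' @return `realmCells`: integer cell ids belonging to `realm`;
#'   `realmOf`: the realm name of each cell id in `cells`.
#' @export
realmCells <- function(mask, realm) {
  i <- match(realm, mask@levels)
  if (is.na(i)) stop(sprintf("unknown realm '%s'", realm))
  which(mask@realm == i)
}

#' @param cells integer cell ids.
#' @rdname realmCells
#' @export
realmOf <- function(mask, cells) mask@levels[mask@realm[cells]]

# Map fine-grid cell ids to coarse-grid cell ids for block aggregation.
coarseIndex <- function(grid, factor) {
  if (factor < 1 || factor != round(factor)) stop("aggregation factor must be a positive integer")
  if (grid@nrow %% factor != 0L || grid@ncol %% factor != 0L)
    stop(sprintf("grid %dx%d not divisible by factor %d",
                 grid@nrow, grid@ncol, factor))
  cc <- cellCenters(grid)
  cr <- (cc$row - 1L) %/% factor + 1L
  cl <- (cc$col - 1L) %/% factor + 1L
  (cr - 1L) * (grid@ncol %/% factor) + cl
}

coarsenGrid <- function(grid, factor) {
  gridSpec(grid@nrow %/% factor, grid@ncol %/% factor,
           cellSize = grid@cellSize * factor, xmin = grid@xmin, ymax = grid@ymax)
}

#' Write a per-cell field as an ESRI ASCII grid
#'
#' Plain-text raster interchange: a 6-line header followed by `nrow` rows of
#' `ncol` values, north to south.  `NA` is written as the nodata value.
#'
#' @param values numeric vector over grid cells (row-major from NW).
#' @param grid a [GridSpec-class].
#' @param path output file path.
#' @param nodata nodata sentinel written for `NA`.
#' @export
writeAsciiGrid <- function(values, grid, path, nodata = -9999) {
  stopifnot(length(values) == nCell(grid))
  hdr <- c(sprintf("ncols %d", grid@ncol),
           sprintf("nrows %d", grid@nrow),
           sprintf("xllcorner %.10g", grid@xmin),
           sprintf("yllcorner %.10g", grid@ymax - grid@nrow * grid@cellSize),
           sprintf("cellsize %.10g", grid@cellSize),
           sprintf("NODATA_value %.10g", nodata))
  v <- ifelse(is.na(values), nodata, values)
  body <- apply(matrix(format(v, trim = TRUE, digits = 10),
                       nrow = grid@nrow, byrow = TRUE), 1, paste, collapse = " ")
  writeLines(c(hdr, body), path)
}

#' Read an ESRI ASCII grid written by [writeAsciiGrid()]
#' @param path file path.
#' @return list with `values` (numeric, `NA` for nodata) and `grid`.
#' @export
readAsciiGrid <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(lines[1:6], " +")
  key <- vapply(hdr, `[`, "", 1)
  val <- as.numeric(vapply(hdr, `[`, "", 2))
  names(val) <- tolower(key)
  g <- gridSpec(val["nrows"], val["ncols"], cellSize = val["cellsize"],
                xmin = val["xllcorner"],
                ymax = val["yllcorner"] + val["nrows"] * val["cellsize"])
  v <- as.numeric(unlist(strsplit(lines[-(1:6)], " +")))
  v[v == val["nodata_value"]] <- NA_real_
  list(values = v, grid = g)
}

setMethod("show", "GridSpec", function(object) {
  cat(sprintf("GridSpec: %d x %d cells of %.4g deg (lon >= %.4g, lat <= %.4g)\n",
              object@nrow, object@ncol, object@cellSize, object@xmin, object@ymax))
})

setMethod("show", "RealmMask", function(object) {
  cat(sprintf("RealmMask on %d x %d grid; %d realm(s):\n",
              object@grid@nrow, object@grid@ncol, length(object@levels)))
  print(table(factor(object@levels[object@realm], levels = object@levels)))
})
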