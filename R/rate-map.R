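#' Construct a rate-map object
#'
#' A rate map is a 2D grid of firing rates (Hz) with a visited-bin mask.
#' All analyses in the package consume this container: estimated maps from
#' [average_rate_map()], ideal simulated maps from [ideal_rate_map()], and
#' field-shuffled controls from [shuffle_fields()].
#'
#' @param values Numeric matrix of rates, dim1 = x, dim2 = y.
#' @param visited Logical matrix, same dim; unvisited bins must hold rate 0.
#' @param origin Coordinates (cm) of the lower-left corner of bin (1, 1).
#' @param bin_size Bin size in cm.
#' @return An object of class \code{gp_rate_map}.
#' @export
rate_map <- function(values, visited, origin = c(0, 0), bin_size = 1) {
  stopifnot(is.matrix(values), all(dim(values) == dim(visited)))
  if (any(values < 0, na.rm = TRUE)) stop("rates must be non-negative")
  values[!visited] <- 0
  structure(
    list(values = values, visited = visited, origin = origin,
         bin_size = bin_size),
    class = "gp_rate_map"
  )
}

#' @export
print.gp_rate_map <- function(x, ...) {
  cat(sprintf("<rate map: %d x %d bins of %g cm, %d visited, peak %.2f Hz>\n",
              nrow(x$values), ncol(x$values), x$bin_size,
              sum(x$visited), max(x$values)))
  invisible(x)
}

# Bin-center coordinate vectors of a rate map.
map_coords <- function(map) {
  list(
    xs = map$origin[1] + (seq_len(nrow(map$values)) - 0.5) * map$bin_size,
    ys = map$origin[2] + (seq_len(ncol(map$values)) - 0.5) * map$bin_size
  )
}
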