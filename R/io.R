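#' Write / read a trajectory as delimited text
#'
#' The on-disk format is comma-delimited with a one-line header
#' \code{t_seconds,x_cm,y_cm}; the same format is the input contract for
#' real recording sessions.
#'
#' @param traj A trajectory object.
#' @param path File path.
#' @return \code{read_trajectory} returns a \code{gp_trajectory}.
#' @export
write_trajectory <- function(traj, path) {
  df <- data.frame(t_seconds = traj$times,
                   x_cm = traj$positions[, 1],
                   y_cm = traj$positions[, 2])
  utils::write.table(df, path, sep = ",", row.names = FALSE,
                     col.names = TRUE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  df <- utils::read.csv(path)
  need <- c("t_seconds", "x_cm", "y_cm")
  if (!all(need %in% names(df)))
    stop("trajectory file must have columns t_seconds,x_cm,y_cm")
  bad <- which(!stats::complete.cases(df[need]) |
                 vapply(seq_len(nrow(df)), function(i)
                   any(!is.finite(suppressWarnings(
                     as.numeric(df[i, need])))), logical(1)))
  if (length(bad))
    stop(sprintf("malformed trajectory row at line %d", bad[1] + 1L))
  if (is.unsorted(df$t_seconds, strictly = TRUE)) {
    i <- which(diff(df$t_seconds) <= 0)[1]
    stop(sprintf("non-monotone timestamps at line %d", i + 2L))
  }
  structure(list(times = df$t_seconds,
                 positions = cbind(df$x_cm, df$y_cm)),
            class = "gp_trajectory")
}

#' Write / read spike times (one spike time per line)
#'
#' @param spikes A [spike_train()].
#' @param path File path.
#' @return \code{read_spikes} returns a \code{gp_spike_train}.
#' @export
write_spikes <- function(spikes, path) {
  writeLines(format(spikes$spike_times, digits = 17, trim = TRUE,
                    scientific = FALSE),
             path)
  invisible(path)
}

#' @rdname write_spikes
#' @export
read_spikes <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  st <- suppressWarnings(as.numeric(lines))
  if (anyNA(st))
    stop(sprintf("malformed spike time at line %d", which(is.na(st))[1]))
  spike_train(st)
}

#' Write / read a rate map as delimited text with a metadata header
#'
#' The matrix is written comma-delimited, one row per x index, preceded by
#' \code{#}-prefixed metadata lines (bin size, origin, dimensions); the
#' visited mask goes to a sidecar file \code{<path>.mask}.
#'
#' @param map A [rate_map()].
#' @param path File path.
#' @return \code{read_rate_map} returns a \code{gp_rate_map}.
#' @export
write_rate_map <- function(map, path) {
  hdr <- c(sprintf("# bin_size %.17g", map$bin_size),
           sprintf("# origin %.17g %.17g", map$origin[1], map$origin[2]),
           sprintf("# dim %d %d", nrow(map$values), ncol(map$values)))
  writeLines(c(hdr, apply(map$values, 1, function(r)
    paste(format(r, digits = 17, trim = TRUE), collapse = ","))), path)
  writeLines(apply(map$visited, 1, function(r)
    paste(as.integer(r), collapse = ",")), paste0(path, ".mask"))
  invisible(path)
}

#' @rdname write_rate_map
#' @export
read_rate_map <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  getv <- function(key) {
    l <- hdr[grepl(paste0("^# ", key, " "), hdr)]
    as.numeric(strsplit(sub(paste0("^# ", key, " "), "", l), " ")[[1]])
  }
  bin_size <- getv("bin_size")
  origin <- getv("origin")
  vals <- do.call(rbind, lapply(body, function(l)
    as.numeric(strsplit(l, ",")[[1]])))
  mask_lines <- readLines(paste0(path, ".mask"))
  vis <- do.call(rbind, lapply(mask_lines, function(l)
    as.integer(strsplit(l, ",")[[1]]))) > 0L
  rate_map(vals, vis, origin = origin, bin_size = bin_size)
}

#' Read a full recording session
#'
#' @param trajectory_path Path to the trajectory file.
#' @param spike_paths Named character vector of spike files (names =
#'   cell ids).
#' @return List with \code{trajectory} and \code{spikes} (named list of
#'   spike trains). Spikes outside the session time range are an error.
#' @export
read_session <- function(trajectory_path, spike_paths) {
  traj <- read_trajectory(trajectory_path)
  if (is.null(names(spike_paths)) || any(!nzchar(names(spike_paths))))
    names(spike_paths) <- paste0("cell", seq_along(spike_paths))
  spikes <- lapply(spike_paths, function(p) {
    s <- read_spikes(p)
    if (length(s$spike_times) &&
        (min(s$spike_times) < traj$times[1] ||
         max(s$spike_times) > traj$times[length(traj$times)]))
      stop(sprintf("spikes in '%s' fall outside the session time range", p))
    s
  })
  list(trajectory = traj, spikes = spikes)
}
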