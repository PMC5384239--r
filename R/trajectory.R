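# Trajectory container: time-ordered coordinate frames plus per-frame
# metadata (region label, bias and potential energy) and provenance.

new_trajectory <- function(topology, coords, frames, schedule = NULL,
                           params = NULL, provenance = list()) {
  stopifnot(is.array(coords), length(dim(coords)) == 3,
            dim(coords)[2] == nrow(topology), dim(coords)[3] == 3,
            nrow(frames) == dim(coords)[1])
  if (is.unsorted(frames$step, strictly = TRUE)) {
    abort("Frame step indices must be strictly increasing")
  }
  structure(list(topology = as_tibble(topology), coords = coords,
                 frames = as_tibble(frames), schedule = schedule,
                 params = params, provenance = provenance),
            class = "cg_trajectory")
}

#' Number of frames in a trajectory
#' @param traj A `cg_trajectory`.
#' @return Integer frame count.
#' @export
n_frames <- function(traj) dim(traj$coords)[1]

#' Coordinates of one trajectory frame
#' @param traj A `cg_trajectory`.
#' @param frame Frame index (1-based).
#' @return n x 3 coordinate matrix.
#' @export
frame_coords <- function(traj, frame) {
  matrix(traj$coords[frame, , ], ncol = 3)
}

# a frame as a bead-level structure table (for per-frame analyses)
frame_structure <- function(traj, frame) {
  top <- traj$topology
  xyz <- frame_coords(traj, frame)
  as_structure(tibble(
    chain = top$chain, resno = top$resno, ins = "",
    resname = top$resname, atom = "CA", element = "C",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], mass = top$mass
  ))
}

#' @export
print.cg_trajectory <- function(x, ...) {
  reg <- unique(x$frames$region)
  cat(sprintf("<cg_trajectory> %d frames x %d beads; regions: %s\n",
              n_frames(x), nrow(x$topology),
              paste(reg[!is.na(reg)], collapse = ",")))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.cg_trajectory <- function(x, ...) x$frames

#' @exportS3Method generics::glance
glance.cg_trajectory <- function(x, ...) {
  tibble(
    n_frames = n_frames(x), n_beads = nrow(x$topology),
    n_regions = length(unique(stats::na.omit(x$frames$region))),
    final_potential = tail(x$frames$potential_energy, 1),
    final_bias = tail(x$frames$bias_energy, 1),
    seed = x$provenance$seed %||% NA_integer_
  )
}

#' Reproducibility digest of a trajectory
#'
#' Hash of the coordinate array; identical inputs and seed give an
#' identical digest.
#'
#' @param traj A `cg_trajectory`.
#' @return Character hash.
#' @export
trajectory_digest <- function(traj) rlang::hash(traj$coords)

#' Per-frame CV value of a COM restraint along a trajectory
#'
#' @param traj A `cg_trajectory`.
#' @param restraint A [com_restraint()] (resolved against the bead
#'   topology).
#' @return A `metric_series` tibble (columns `step`, `region`, `value`).
#' @export
restraint_distance_series <- function(traj, restraint) {
  res <- resolve_restraint(restraint, traj$topology, policy = "all")
  vals <- vapply(seq_len(n_frames(traj)), function(f) {
    xyz <- frame_coords(traj, f)
    ca <- colSums(xyz[res$ia, , drop = FALSE] * res$ma) / sum(res$ma)
    cb <- colSums(xyz[res$ib, , drop = FALSE] * res$mb) / sum(res$mb)
    sqrt(sum((ca - cb)^2))
  }, numeric(1))
  metric_series(traj$frames$step, vals, metric = "com_distance",
                units = "angstrom", region = traj$frames$region,
                selection = restraint$label)
}

# MetricSeries: a tibble of (index, value) with metric metadata
metric_series <- function(index, values, metric, units,
                          region = NULL, selection = "", extra = NULL) {
  stopifnot(length(index) == length(values))
  tb <- tibble(step = index, value = values)
  if (!is.null(region)) tb <- tibble(step = index, region = region,
                                     value = values)
  if (!is.null(extra)) tb <- dplyr::bind_cols(tb, extra)
  structure(tb, class = c("metric_series", class(tb)),
            metric = metric, units = units, selection = selection)
}

#' @export
print.metric_series <- function(x, ...) {
  cat(sprintf("<metric_series> %s [%s] %s, %d points\n",
              attr(x, "metric"), attr(x, "units"),
              attr(x, "selection"), nrow(x)))
  NextMethod()
}

#' Write a metric series as CSV
#'
#' Metadata (metric name, units, selection) is written as `#` comment
#' header lines above the table.
#'
#' @param x A `metric_series`.
#' @param path Output path.
#' @param extra_header Named character vector of extra header fields.
#' @return Invisibly, `path`.
#' @export
write_metric_csv <- function(x, path, extra_header = c()) {
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- c(metric = attr(x, "metric"), units = attr(x, "units"),
           selection = attr(x, "selection"), extra_header)
  writeLines(paste0("# ", names(hdr), ": ", hdr), con)
  write.csv(as.data.frame(x), con, row.names = FALSE)
  invisible(path)
}

#' Read a metric series CSV written by [write_metric_csv()]
#' @param path CSV path.
#' @return A `metric_series`.
#' @export
read_metric_csv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  meta <- list()
  for (h in lines[hdr]) {
    kv <- sub("^# *", "", h)
    key <- sub(":.*$", "", kv)
    meta[[key]] <- trimws(sub("^[^:]*: *", "", kv))
  }
  df <- read.csv(text = paste(lines[-hdr], collapse = "\n"))
  structure(as_tibble(df), class = c("metric_series", class(as_tibble(df))),
            metric = meta$metric %||% "", units = meta$units %||% "",
            selection = meta$selection %||% "")
}
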