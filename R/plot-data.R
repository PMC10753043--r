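#' Export plot-ready stimulation geometry
#'
#' Writes (or returns) a flat table from which stimulation panels can be
#' redrawn: one `"ommatidium"` row per receptive field (axis offset, radius,
#' stimulation percentage) and one `"outline"` polygon -- the target's angular
#' image -- stored as one row per vertex sharing `id = 0`. The companion
#' reader [read_stimulation_plot_data()] restores the table losslessly.
#'
#' @param map A [eye_stimulation()] result.
#' @param image The `angular_image` the map was computed from.
#' @param eye The [ommatidial_array()] used.
#' @param file Optional path; when given, the table is written as CSV.
#' @return (Invisibly, when writing) a data frame with columns `kind`, `id`,
#'   `x_deg`, `y_deg`, `radius_deg`, `stimulation_pct`.
#' @export
export_stimulation_plot_data <- function(map, image, eye, file = NULL) {
  stopifnot(inherits(map, "stimulation_map"), inherits(image, "angular_image"))
  if (nrow(eye) != length(map$per_ommatidium_pct)) {
    stop("eye array and stimulation map disagree in size", call. = FALSE)
  }
  rf_radius <- map$params$receptive_field_deg / 2
  circles <- data.frame(
    kind = "ommatidium",
    id = eye$index,
    x_deg = eye$x_deg,
    y_deg = eye$y_deg,
    radius_deg = rf_radius,
    stimulation_pct = map$per_ommatidium_pct
  )
  outline <- data.frame(
    kind = "outline",
    id = 0L,
    x_deg = image$outline$x_deg,
    y_deg = image$outline$y_deg,
    radius_deg = NA_real_,
    stimulation_pct = NA_real_
  )
  out <- rbind(circles, outline)
  if (!is.null(file)) {
    utils::write.csv(out, file, row.names = FALSE)
    return(invisible(out))
  }
  out
}

#' Read back exported stimulation plot data
#'
#' @param file Path to a CSV written by [export_stimulation_plot_data()].
#' @return The data frame as written (same columns, same row order).
#' @export
read_stimulation_plot_data <- function(file) {
  out <- utils::read.csv(file, stringsAsFactors = FALSE)
  required <- c("kind", "id", "x_deg", "y_deg", "radius_deg",
                "stimulation_pct")
  missing <- setdiff(required, names(out))
  if (length(missing) > 0L) {
    stop("plot-data file lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  out
}
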