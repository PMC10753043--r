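#' Read a plain-text key-value configuration file
#'
#' Parses files of `key = value` lines (one per line; `#` starts a comment;
#' blank lines ignored). Values that parse as numbers become numeric; values
#' containing commas become vectors. Used by the command-line interface to
#' mirror its flags and by [read_layout()].
#'
#' @param file Path to the configuration file.
#' @return A named list.
#' @export
read_keyvalue_config <- function(file) {
  lines <- readLines(file, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "=", fixed = TRUE)[[1L]]
    if (length(parts) < 2L) {
      stop("malformed config line: '", lines[i], "'", call. = FALSE)
    }
    key <- trimws(parts[1L])
    value <- trimws(paste(parts[-1L], collapse = "="))
    items <- trimws(strsplit(value, ",", fixed = TRUE)[[1L]])
    nums <- suppressWarnings(as.numeric(items))
    out[[key]] <- if (all(is.finite(nums))) nums else items
  }
  out
}

#' Read an arena/target layout file
#'
#' A layout file describes the targets of one assay as key-value groups with
#' dotted keys, all lengths in cm:
#' \preformatted{
#' target.big.footprint  = 45, 75, 80, 120   # x_min, x_max, y_min, y_max
#' target.big.orientation = horizontal
#' target.big.landings    = 12
#' target.big.area_cm2    = 1200
#' }
#' Any number of targets may be listed; the group name (`big` above) becomes
#' the cuboid label.
#'
#' @param file Path to the layout file.
#' @param arena An [arena_bounds()] object.
#' @param buffer_cm Cuboid buffer per side in X and Y. Default 10.
#' @return A list of per-target descriptors, each with `cuboid` (an
#'   [build_cuboid()] result), `landings`, `area_cm2`.
#' @export
read_layout <- function(file, arena = arena_bounds(), buffer_cm = 10) {
  cfg <- read_keyvalue_config(file)
  keys <- names(cfg)
  target_keys <- keys[startsWith(keys, "target.")]
  labels <- unique(vapply(strsplit(target_keys, ".", fixed = TRUE),
                          `[[`, character(1), 2L))
  if (length(labels) == 0L) {
    stop("layout file defines no 'target.<label>.*' entries", call. = FALSE)
  }
  out <- list()
  for (label in labels) {
    get <- function(field, default = NULL) {
      v <- cfg[[paste("target", label, field, sep = ".")]]
      if (is.null(v)) default else v
    }
    fp <- get("footprint")
    if (is.null(fp) || length(fp) != 4L) {
      stop("target '", label, "' needs footprint = x_min, x_max, y_min, y_max",
           call. = FALSE)
    }
    orientation <- as.character(get("orientation", "horizontal"))
    out[[label]] <- list(
      cuboid = build_cuboid(fp[1:2], fp[3:4], orientation,
                            buffer_cm = buffer_cm, label = label,
                            arena = arena),
      landings = as.integer(get("landings", 0)),
      area_cm2 = as.numeric(get("area_cm2", NA_real_))
    )
  }
  out
}
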