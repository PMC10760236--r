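#' Construct a spot table
#'
#' A spot table is one detection channel of one cell: x, y, z coordinates
#' in nm plus the integrated spot intensity, the format spot-detection
#' tools export as tabulated text.
#'
#' @param x,y,z coordinates, nm (z may be 0 for 2D data).
#' @param intensity integrated spot intensities, arbitrary units, > 0.
#' @param channel_label nonempty channel name (e.g. the probed mRNA).
#' @param cell_id cell identifier.
#' @param id integer spot ids, unique within the table (default 1..n).
#' @param source_file provenance path, if any.
#' @return An object of class \code{spot_table} (a data frame with columns
#'   id, x, y, z, intensity).
#' @export
spot_table <- function(x, y, z = 0, intensity = 1, channel_label,
                       cell_id = "cell1", id = NULL, source_file = NA_character_) {
  n <- length(x)
  z <- rep_len(z, n); intensity <- rep_len(intensity, n)
  id <- if (is.null(id)) seq_len(n) else as.integer(id)
  stopifnot(length(y) == n, length(id) == n)
  if (n > 0) {
    if (!all(is.finite(x), is.finite(y), is.finite(z)))
      stop("spot table invariant violated: non-finite coordinate")
    if (any(intensity <= 0))
      stop("spot table invariant violated: intensity must be > 0")
    if (anyDuplicated(id)) stop("spot table invariant violated: duplicate id")
  }
  if (!nzchar(channel_label)) stop("channel_label must be nonempty")
  structure(data.frame(id = id, x = as.numeric(x), y = as.numeric(y),
                       z = as.numeric(z), intensity = as.numeric(intensity)),
            class = c("spot_table", "data.frame"),
            channel = channel_label, cell_id = cell_id, source_file = source_file)
}

#' @export
print.spot_table <- function(x, ...) {
  cat(sprintf("Spot table: channel '%s', cell '%s', %d spots\n",
              attr(x, "channel"), attr(x, "cell_id"), nrow(x)))
  if (nrow(x)) print(utils::head(as.data.frame(x), 5))
  invisible(x)
}

#' Read a tab-delimited spot table
#'
#' Columns are located by name: \code{x}, \code{y}, \code{z} and
#' \code{intensity} (or \code{int}). A \code{_nm} suffix marks nm
#' coordinates, a \code{_px} suffix pixel units converted with
#' \code{pixel_size_xy} (x, y) and \code{z_step} (z); bare names are taken
#' as nm. The z column is optional (0 for 2D data). Decimal point only.
#'
#' @param path file path.
#' @param channel_label channel name to attach.
#' @param cell_id cell identifier.
#' @param pixel_size_xy,z_step conversion factors for pixel-unit columns, nm.
#' @return A \code{spot_table}.
#' @export
read_spot_table <- function(path, channel_label, cell_id = "cell1",
                            pixel_size_xy = 107.5, z_step = 200) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.delim(path, colClasses = "character", check.names = FALSE)
  nm <- names(raw)
  pick <- function(base, aliases = base) {
    for (a in aliases) {
      hits <- which(nm %in% c(a, paste0(a, "_nm"), paste0(a, "_px")))
      if (length(hits)) return(nm[hits[1L]])
    }
    NA_character_
  }
  cx <- pick("x"); cy <- pick("y"); cz <- pick("z")
  ci <- pick("intensity", c("intensity", "int"))
  cols <- c(x = cx, y = cy, intensity = ci)
  if (anyNA(cols))
    stop(sprintf("format error: missing column '%s' in %s",
                 names(cols)[which(is.na(cols))[1L]], path))
  num <- function(col, scale_px) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !is.na(raw[[col]]) & nzchar(raw[[col]]))
    if (length(bad))
      stop(sprintf("parse error: non-numeric value '%s' in column '%s', row %d",
                   raw[[col]][bad[1]], col, bad[1]))
    if (anyNA(v)) stop(sprintf("parse error: empty cell in column '%s'", col))
    if (grepl("_px$", col)) v * scale_px else v
  }
  if (nrow(raw) == 0L)
    return(spot_table(numeric(0), numeric(0), numeric(0), numeric(0),
                      channel_label = channel_label, cell_id = cell_id,
                      source_file = path))
  x <- num(cx, pixel_size_xy)
  y <- num(cy, pixel_size_xy)
  z <- if (is.na(cz)) 0 else num(cz, z_step)
  spot_table(x, y, z, num(ci, 1), channel_label = channel_label,
             cell_id = cell_id, source_file = path)
}

#' Write a spot table as tab-delimited text (nm units)
#' @param spots a \code{spot_table}.
#' @param path output path.
#' @export
write_spot_table <- function(spots, path) {
  df <- data.frame(id = spots$id, x_nm = spots$x, y_nm = spots$y,
                   z_nm = spots$z, intensity = spots$intensity)
  utils::write.table(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read neuron geometry from a JSON outline file
#'
#' The file holds polygon outlines in image pixel units (0-based, y
#' increasing downward): a closed \code{soma} vertex ring, a list of
#' \code{branches} each with a \code{skeleton} polyline (ordered from the
#' soma outward) and a \code{half_width_px}, and \code{pixel_size_xy} in nm.
#' Vertices are converted to nm on read.
#'
#' @param path JSON file path.
#' @return A \code{neuron_geometry}.
#' @export
read_geometry <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  px <- j$pixel_size_xy %||% 107.5
  soma <- as.matrix(j$soma) * px
  br_in <- j$branches
  branches <- list()
  if (!is.null(br_in) && length(br_in)) {
    # jsonlite may simplify the branch list to a data frame
    if (is.data.frame(br_in)) {
      branches <- lapply(seq_len(nrow(br_in)), function(i)
        list(skeleton = as.matrix(br_in$skeleton[[i]]) * px,
             half_width = br_in$half_width_px[i] * px))
    } else {
      branches <- lapply(br_in, function(b)
        list(skeleton = as.matrix(b$skeleton) * px,
             half_width = b$half_width_px * px))
    }
  }
  neuron_geometry(soma, branches, pixel_size_xy = px)
}

#' Write neuron geometry to JSON (pixel units)
#' @param geometry a \code{neuron_geometry}.
#' @param path output path.
#' @export
write_geometry <- function(geometry, path) {
  px <- geometry$pixel_size_xy
  soma <- rbind(geometry$soma, geometry$soma[1, ]) / px
  j <- list(pixel_size_xy = px,
            soma = unname(apply(soma, 1, as.list)),
            branches = lapply(geometry$branches, function(b)
              list(skeleton = unname(apply(b$skeleton / px, 1, as.list)),
                   half_width_px = b$half_width / px)))
  jsonlite::write_json(j, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a result table with a run manifest
#'
#' Writes the flat result table as CSV (reals at 12+ significant digits so
#' a read round-trips exactly for counts and to numerical precision for
#' reals) and a JSON manifest recording the configuration, the RNG seed
#' and the package version next to it (\code{<path>.manifest.json}).
#'
#' @param results a data frame or any result object with an
#'   \code{\link{as_result_table}} method.
#' @param path CSV output path.
#' @param config optional \code{analysis_config} recorded in the manifest.
#' @param seed optional RNG seed recorded in the manifest.
#' @export
write_results <- function(results, path, config = NULL, seed = NULL) {
  df <- as_result_table(results)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) {
    out <- formatC(v, digits = 15, format = "g")
    out[is.na(v)] <- NA
    out
  })
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  manifest <- list(package = "dendrofish",
                   version = as.character(utils::packageVersion("dendrofish")),
                   rng_seed = seed %||% (if (!is.null(config)) config$rng_seed),
                   config = if (!is.null(config)) unclass(config))
  jsonlite::write_json(manifest, paste0(path, ".manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read back a result table written by \code{write_results}
#' @param path CSV path.
#' @return Data frame.
#' @export
read_results <- function(path) utils::read.csv(path)

#' Flatten a result object to a tabular form
#' @param x a result object.
#' @param ... unused.
#' @return A data frame, one row per unit x bin x statistic.
#' @export
as_result_table <- function(x, ...) UseMethod("as_result_table")

#' @export
as_result_table.data.frame <- function(x, ...) x

#' @export
as_result_table.default <- function(x, ...) as.data.frame(x)
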