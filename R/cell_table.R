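#' Cell tables
#'
#' A `cell_table` is the package's representation of a measured cell
#' population: one record per cell, with an opaque unique identifier, an
#' optional pair of spatial coordinates in micrometers, and a type label.
#' Tables are either fully spatial (every record has coordinates) or fully
#' non-spatial (none do); the spatial flag is a table-level property.
#'
#' @param id character vector of unique cell identifiers.
#' @param type character vector of type labels, same length as `id`.
#' @param x,y numeric coordinate vectors in micrometers, or `NULL` for a
#'   non-spatial table. Both must be given or both omitted.
#'
#' @return An object of class `cell_table`: a data frame with columns
#'   `cell_id`, `type` and, for spatial tables, `x` and `y`, plus an
#'   attribute `spatial` (logical scalar).
#'
#' @details Duplicate coordinates are allowed (two cells may share a spot
#'   centroid); only identifiers must be unique. Coordinates must be finite.
#'
#' @examples
#' tab <- cell_table(id = c("a", "b"), type = c("cancer", "CD8"),
#'                   x = c(0, 10), y = c(5, -5))
#' is_spatial(tab)
#' @export
cell_table <- function(id, type, x = NULL, y = NULL) {
  id <- as.character(id)
  type <- as.character(type)
  if (length(type) != length(id)) {
    stop("`id` and `type` must have the same length", call. = FALSE)
  }
  if (anyDuplicated(id)) {
    dup <- unique(id[duplicated(id)])
    stop("duplicate cell ids: ", paste(utils::head(dup, 5L), collapse = ", "),
         call. = FALSE)
  }
  spatial <- !is.null(x) || !is.null(y)
  if (spatial) {
    if (is.null(x) || is.null(y)) {
      stop("either both coordinates or neither must be supplied", call. = FALSE)
    }
    x <- as.numeric(x)
    y <- as.numeric(y)
    if (length(x) != length(id) || length(y) != length(id)) {
      stop("coordinate vectors must match the number of records", call. = FALSE)
    }
    if (!all(is.finite(x)) || !all(is.finite(y))) {
      bad <- which(!is.finite(x) | !is.finite(y))
      stop("non-finite coordinate at record ", bad[1L], call. = FALSE)
    }
    out <- data.frame(cell_id = id, x = x, y = y, type = type,
                      stringsAsFactors = FALSE)
  } else {
    out <- data.frame(cell_id = id, type = type, stringsAsFactors = FALSE)
  }
  structure(out, spatial = spatial, class = c("cell_table", "data.frame"))
}

#' @rdname cell_table
#' @param tab a `cell_table`.
#' @export
is_spatial <- function(tab) {
  stopifnot(inherits(tab, "cell_table"))
  isTRUE(attr(tab, "spatial"))
}

#' @export
print.cell_table <- function(x, ...) {
  n <- nrow(x)
  cat(sprintf("<cell_table> %d cells, %s\n", n,
              if (is_spatial(x)) "spatial (um)" else "non-spatial"))
  if (n > 0L) {
    tb <- sort(table(x$type), decreasing = TRUE)
    cat("  types:", paste(sprintf("%s (%d)", names(tb), tb), collapse = ", "),
        "\n")
    print(utils::head(as.data.frame(x), 6L))
    if (n > 6L) cat("  ...", n - 6L, "more rows\n")
  }
  invisible(x)
}

#' Read a cell table from CSV
#'
#' Parses a comma-separated table of measured cells. Column names are mapped
#' explicitly so that arbitrary exports can be read; the coordinate columns
#' are optional, producing a non-spatial table when either is unmapped.
#'
#' @param path path to a CSV file.
#' @param id_col,type_col names of the identifier and type-label columns.
#' @param x_col,y_col names of the coordinate columns (micrometers), or
#'   `NULL` to read a non-spatial table.
#' @return A [cell_table].
#' @export
read_cell_table_csv <- function(path, id_col = "cell_id", type_col = "cell_type",
                                x_col = "x", y_col = "y") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", check.names = FALSE,
                        fileEncoding = "UTF-8")
  for (col in c(id_col, type_col)) {
    if (!col %in% names(df)) {
      stop("mapped column not found in ", path, ": '", col, "'", call. = FALSE)
    }
  }
  spatial <- !is.null(x_col) && !is.null(y_col) &&
    all(c(x_col, y_col) %in% names(df))
  # if the caller explicitly mapped a coordinate column, it must exist
  for (col in c(x_col, y_col)) {
    if (!is.null(col) && !col %in% names(df) &&
        !identical(col, "x") && !identical(col, "y")) {
      stop("mapped coordinate column not found: '", col, "'", call. = FALSE)
    }
  }
  if (!spatial) {
    return(cell_table(id = df[[id_col]], type = df[[type_col]]))
  }
  xy <- lapply(c(x_col, y_col), function(col) {
    raw <- df[[col]]
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(val) | !is.finite(val))
    if (length(bad) > 0L) {
      stop(sprintf("non-numeric coordinate in column '%s' at row %d: '%s'",
                   col, bad[1L], raw[bad[1L]]), call. = FALSE)
    }
    val
  })
  cell_table(id = df[[id_col]], type = df[[type_col]],
             x = xy[[1L]], y = xy[[2L]])
}

#' Read a cell table from an AnnData h5ad container
#'
#' Reads the per-cell type annotation and, when present, the first two
#' columns of a spatial-coordinate matrix from an h5ad file. Cell
#' identifiers are taken from the container's per-cell index. Expression
#' matrices are never touched.
#'
#' @param path path to an `.h5ad` file.
#' @param type_key name of the per-cell annotation column holding type
#'   labels (in `obs`).
#' @param spatial_key name of the coordinate matrix in `obsm`; the default
#'   `"spatial"` is the dominant convention. If the key is absent the table
#'   is returned non-spatial.
#' @return A [cell_table].
#' @export
read_cell_table_h5ad <- function(path, type_key, spatial_key = "spatial") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  contents <- rhdf5::h5ls(path)
  obs_cols <- contents$name[contents$group == "/obs"]
  obs_cols <- setdiff(obs_cols, "_index")
  if (!type_key %in% obs_cols) {
    stop("annotation column '", type_key, "' not found in obs; available: ",
         paste(obs_cols, collapse = ", "), call. = FALSE)
  }
  attrs <- rhdf5::h5readAttributes(path, "obs")
  index_key <- if (!is.null(attrs[["_index"]])) attrs[["_index"]] else "_index"
  ids <- as.character(rhdf5::h5read(path, paste0("obs/", index_key)))
  labels <- .decode_obs_column(rhdf5::h5read(path, paste0("obs/", type_key)))
  if (length(labels) != length(ids)) {
    stop("annotation column '", type_key, "' length does not match cell index",
         call. = FALSE)
  }
  obsm_keys <- contents$name[contents$group == "/obsm"]
  if (!spatial_key %in% obsm_keys) {
    return(cell_table(id = ids, type = labels))
  }
  m <- rhdf5::h5read(path, paste0("obsm/", spatial_key))
  # HDF5 stores the n_cells x k matrix row-major; rhdf5 returns it as k x n
  if (!is.matrix(m)) m <- as.matrix(m)
  if (nrow(m) != length(ids) && ncol(m) == length(ids)) m <- t(m)
  if (ncol(m) < 2L) {
    stop("spatial matrix '", spatial_key, "' has fewer than 2 columns",
         call. = FALSE)
  }
  cell_table(id = ids, type = labels, x = m[, 1L], y = m[, 2L])
}

# AnnData encodes categoricals as list(categories, codes) with 0-based codes.
.decode_obs_column <- function(col) {
  if (is.list(col) && all(c("categories", "codes") %in% names(col))) {
    codes <- as.integer(col$codes)
    cats <- as.character(col$categories)
    out <- rep(NA_character_, length(codes))
    valid <- codes >= 0L
    out[valid] <- cats[codes[valid] + 1L]
    return(out)
  }
  as.character(col)
}

#' Select cell types and relabel them to model type names
#'
#' Applies a label mapping to a cell table: measured labels are either
#' renamed to model type names or dropped. Every label present in the table
#' must be covered by the mapping (or by `default = "DROP"`); coordinates
#' are never altered.
#'
#' @param tab a [cell_table].
#' @param mapping named character vector: `measured label -> model type
#'   name`, with the special value `"DROP"` removing that label's records.
#' @param default either `"error"` (unmapped labels are a validation error)
#'   or `"DROP"` (unmapped labels are silently removed).
#' @return A [cell_table] containing only retained records, relabeled.
#'   Model type names are restricted to `[A-Za-z0-9_]`.
#' @export
select_and_relabel <- function(tab, mapping, default = c("error", "DROP")) {
  stopifnot(inherits(tab, "cell_table"))
  default <- match.arg(default)
  mapping <- vapply(mapping, as.character, character(1L))
  if (is.null(names(mapping)) || any(names(mapping) == "")) {
    stop("`mapping` must be a fully named character vector", call. = FALSE)
  }
  targets <- setdiff(unname(mapping), "DROP")
  bad <- targets[!grepl("^[A-Za-z0-9_]+$", targets)]
  if (length(bad) > 0L) {
    stop("model type names must match [A-Za-z0-9_]: ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  }
  present <- unique(tab$type)
  unmapped <- setdiff(present, names(mapping))
  if (length(unmapped) > 0L) {
    if (default == "error") {
      stop("unmapped cell type label(s): ", paste(unmapped, collapse = ", "),
           call. = FALSE)
    }
    mapping <- c(mapping, stats::setNames(rep("DROP", length(unmapped)),
                                          unmapped))
  }
  new_label <- unname(mapping[tab$type])
  keep <- new_label != "DROP"
  if (is_spatial(tab)) {
    cell_table(id = tab$cell_id[keep], type = new_label[keep],
               x = tab$x[keep], y = tab$y[keep])
  } else {
    cell_table(id = tab$cell_id[keep], type = new_label[keep])
  }
}

#' Write an initial state as a PhysiCell-style cells.csv
#'
#' Emits the minimal `cells.csv` dialect understood by off-lattice ABM
#' frameworks: header `x,y,z,type`, one row per cell, `z = 0` for this 2D
#' model, `.` decimal separator, UTF-8. Positions round-trip exactly as
#' printed (17 significant digits).
#'
#' @param state an [initial_state].
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_physicell_cells_csv <- function(state, path) {
  stopifnot(inherits(state, "initial_state"))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("x,y,z,type", con)
  n <- nrow(state$cells)
  if (n > 0L) {
    writeLines(sprintf("%.17g,%.17g,0,%s",
                       state$cells$x, state$cells$y, state$cells$type), con)
  }
  invisible(path)
}

#' Read a PhysiCell-style cells.csv back into an initial state
#'
#' Inverse of [write_physicell_cells_csv()]; the `z` column is ignored.
#' Domain bounds are the bounding box of the cells expanded by `padding`.
#'
#' @param path path to a `cells.csv` file with header `x,y,z,type`.
#' @param padding margin in micrometers added around the bounding box.
#' @return An [initial_state].
#' @export
read_physicell_cells_csv <- function(path, padding = 50) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("x", "y", "type")
  if (!all(need %in% names(df))) {
    stop("not a cells.csv file (expected header x,y,z,type): ", path,
         call. = FALSE)
  }
  if (nrow(df) == 0L) {
    return(initial_state(x = numeric(0), y = numeric(0), type = character(0),
                         domain = c(-padding, padding, -padding, padding)))
  }
  dom <- c(min(df$x) - padding, max(df$x) + padding,
           min(df$y) - padding, max(df$y) + padding)
  initial_state(x = df$x, y = df$y, type = as.character(df$type), domain = dom)
}

#' Write replicate summary time series to a long-format CSV
#'
#' @param trajectories a list of [abm_trajectory] objects sharing a common
#'   time grid (one per replicate).
#' @param path output file path.
#' @return Invisibly, `path`. Columns: `time_min`, `replicate`,
#'   `cancer_count`, `healthy_count`, `tcell_count`, `ongoing_attacks`.
#' @export
write_timeseries_csv <- function(trajectories, path) {
  if (inherits(trajectories, "abm_trajectory")) {
    trajectories <- list(trajectories)
  }
  if (length(trajectories) == 0L) {
    utils::write.csv(
      data.frame(time_min = numeric(0), replicate = integer(0),
                 cancer_count = integer(0), healthy_count = integer(0),
                 tcell_count = integer(0), ongoing_attacks = integer(0)),
      path, row.names = FALSE, quote = FALSE)
    return(invisible(path))
  }
  grids <- lapply(trajectories, function(tr) tr$summary$time_min)
  ref <- grids[[1L]]
  for (g in grids[-1L]) {
    if (length(g) != length(ref) || any(g != ref)) {
      stop("trajectories do not share a common time grid", call. = FALSE)
    }
  }
  col_or_zero <- function(s, nm) if (is.null(s[[nm]])) 0L else s[[nm]]
  rows <- lapply(seq_along(trajectories), function(i) {
    s <- trajectories[[i]]$summary
    data.frame(time_min = s$time_min, replicate = i,
               cancer_count = col_or_zero(s, "cancer"),
               healthy_count = col_or_zero(s, "healthy"),
               tcell_count = col_or_zero(s, "CD8"),
               ongoing_attacks = s$ongoing_attacks)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write one snapshot as a flat CSV
#'
#' Columns: `time`, `id`, `x`, `y`, `type`, `attack_state` (partner agent id
#' for cells locked in an attack, empty otherwise).
#'
#' @param snap an [abm_snapshot].
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_snapshot_csv <- function(snap, path) {
  stopifnot(inherits(snap, "abm_snapshot"))
  ag <- snap$agents
  partner <- ifelse(is.na(ag$partner), "", as.character(ag$partner))
  df <- data.frame(time = snap$time, id = ag$id, x = ag$x, y = ag$y,
                   type = ag$type, attack_state = partner)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
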