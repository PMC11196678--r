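# Occurrence handling: reading, the minimum-record filter, and rasterization
# of point records into per-species presence grids.

#' Read an occurrence CSV
#'
#' Expected columns: `species_id`, `longitude`, `latitude`, optional
#' `year`; header required, UTF-8. Records are assumed to be upstream-
#' cleaned (taxonomically standardized, dereplicated, and restricted to
#' each species' known distribution); no such filtering happens here.
#'
#' @param path file path
#' @return data.frame of records
#' @export
read_occurrences <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  need <- c("species_id", "longitude", "latitude")
  if (!all(need %in% names(df)))
    stop("occurrence file must have columns ", paste(need, collapse = ", "))
  df
}

#' Write an occurrence CSV
#' @param records data.frame of records
#' @param path output path
#' @return `path`, invisibly
#' @export
write_occurrences <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' Filter species by minimum record count
#'
#' Species with fewer than `min_n` records carry too little information
#' for a hull or a model and are dropped.
#'
#' @param records occurrence data.frame (column `species_id`)
#' @param min_n minimum records to retain a species (default 10)
#' @return list with `retained` and `dropped` data.frames
#'   (`species_id`, `n_records`) and `records`, the retained records
#' @export
filter_min_records <- function(records, min_n = 10) {
  if (!nrow(records)) stop("no occurrence records supplied")
  counts <- as.data.frame(table(species_id = records$species_id),
                          stringsAsFactors = FALSE)
  names(counts)[2] <- "n_records"
  keep <- counts$n_records >= min_n
  list(retained = counts[keep, , drop = FALSE],
       dropped = counts[!keep, , drop = FALSE],
       records = records[records$species_id %in% counts$species_id[keep], ,
                         drop = FALSE])
}

#' Rasterize records of one species into a presence grid
#'
#' A cell is a presence cell when at least one record falls in it (by the
#' half-open cell convention) and the cell is light-valid. Records on
#' invalid cells (land, or below the light threshold) are dropped and
#' counted, not snapped.
#'
#' @param records data.frame of one species' records
#' @param grid a [grid_spec()]
#' @param light_valid logical validity matrix on `grid` (or `NULL`)
#' @param label species or group label
#' @return object of class `presence_grid`: `label`, `grid`, `presence`
#'   (logical matrix), `n_records`, `n_dropped_invalid`
#' @export
rasterize_presence <- function(records, grid, light_valid = NULL,
                               label = records$species_id[1]) {
  idx <- cell_index(grid, records$longitude, records$latitude)
  oob <- sum(is.na(idx))
  idx <- idx[!is.na(idx)]
  pres <- matrix(FALSE, grid$n_rows, grid$n_cols)
  pres[idx] <- TRUE
  dropped <- oob
  if (!is.null(light_valid)) {
    dropped <- dropped + sum(idx %in% which(!light_valid))
    pres <- pres & light_valid
  }
  structure(list(label = label, grid = grid, presence = pres,
                 n_records = nrow(records), n_dropped_invalid = dropped),
            class = "presence_grid")
}

#' Combine species presence grids into a group presence grid
#'
#' Cell-wise OR: the group is present wherever at least one member
#' species is.
#'
#' @param grids list of `presence_grid`s on one grid
#' @param label group label (e.g. `"brown_macroalgae"`)
#' @return a `presence_grid`
#' @export
group_presence <- function(grids, label) {
  stopifnot(length(grids) >= 1)
  g <- grids[[1]]$grid
  pres <- Reduce(`|`, lapply(grids, function(p) {
    stopifnot(identical(p$grid, g))
    p$presence
  }))
  structure(list(label = label, grid = g, presence = pres,
                 n_records = sum(vapply(grids, function(p) p$n_records, 1)),
                 n_dropped_invalid = sum(vapply(grids, function(p) p$n_dropped_invalid, 1))),
            class = "presence_grid")
}
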