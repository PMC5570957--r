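#' Build a 96-well compound-library plate layout
#'
#' Standard library geometry: column 11 carries the intra-plate vehicle
#' controls, columns 1 and 12 and rows A and H hold assay medium only (to
#' avoid edge effects), and the remaining 54 wells (rows B-G, columns 2-10)
#' carry one compound each at a single concentration in vehicle.
#'
#' @param compound_ids Character vector of at most 54 compound identifiers;
#'   assigned to compound wells in column-major order. Unassigned compound
#'   wells become medium-only.
#' @param conc_uM Screening concentration (µM) applied to every compound.
#' @param vehicle Vehicle description for control wells.
#' @return A data frame with one row per well: `well`, `row`, `col`, `role`
#'   (`compound`, `vehicle_control` or `medium_only`), `compound`, `conc_uM`.
#' @export
plate_layout <- function(compound_ids = sprintf("C%03d", 1:54),
                         conc_uM = 20, vehicle = "0.4% DMSO") {
  if (length(compound_ids) > 54)
    stop("a single plate holds at most 54 compounds; see multi_plate_layout()")
  rows <- LETTERS[1:8]; cols <- 1:12
  grid <- expand.grid(row = rows, col = cols, stringsAsFactors = FALSE)
  grid <- grid[order(grid$col, grid$row), ]
  role <- ifelse(grid$col %in% c(1, 12) | grid$row %in% c("A", "H"),
                 "medium_only",
                 ifelse(grid$col == 11, "vehicle_control", "compound"))
  layout <- data.frame(well = paste0(grid$row, grid$col),
                       row = grid$row, col = grid$col, role = role,
                       compound = NA_character_, conc_uM = NA_real_,
                       stringsAsFactors = FALSE)
  slots <- which(layout$role == "compound")
  n <- length(compound_ids)
  layout$compound[slots[seq_len(n)]] <- compound_ids
  layout$conc_uM[slots[seq_len(n)]] <- conc_uM
  if (n < length(slots)) layout$role[slots[-seq_len(n)]] <- "medium_only"
  layout$vehicle <- ifelse(layout$role == "medium_only", NA_character_, vehicle)
  rownames(layout) <- NULL
  validate_layout(layout)
}

#' Lay a compound library out over as many plates as needed
#'
#' @param compound_ids Character vector of compound identifiers (any length).
#' @param conc_uM,vehicle Passed to [plate_layout()].
#' @return A layout data frame as from [plate_layout()] with an extra
#'   `plate` column; well ids are prefixed `P<plate>:` to stay unique.
#' @export
multi_plate_layout <- function(compound_ids, conc_uM = 20,
                               vehicle = "0.4% DMSO") {
  chunks <- split(compound_ids, ceiling(seq_along(compound_ids) / 54))
  plates <- lapply(seq_along(chunks), function(i) {
    p <- plate_layout(chunks[[i]], conc_uM = conc_uM, vehicle = vehicle)
    p$plate <- i
    p$well <- paste0("P", i, ":", p$well)
    p
  })
  do.call(rbind, plates)
}

#' Validate a plate layout
#'
#' @param layout A layout data frame (see [plate_layout()]).
#' @return The layout, invisibly usable, after checking the contract:
#'   required columns, known roles, unique well ids, and a concentration on
#'   every compound well.
#' @export
validate_layout <- function(layout) {
  need <- c("well", "role", "compound", "conc_uM")
  miss <- setdiff(need, names(layout))
  if (length(miss)) stop("layout lacks columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(layout$well)) stop("duplicate well ids in layout")
  bad <- setdiff(unique(layout$role),
                 c("compound", "vehicle_control", "medium_only"))
  if (length(bad)) stop("unknown roles: ", paste(bad, collapse = ", "))
  comp <- layout$role == "compound"
  if (any(comp & (is.na(layout$compound) | is.na(layout$conc_uM))))
    stop("every compound well needs a compound id and a concentration")
  layout
}

#' Read / write a plate layout as YAML
#'
#' @param layout A layout data frame.
#' @param path File path.
#' @return `read_layout()` returns the validated layout data frame.
#' @export
write_layout <- function(layout, path) {
  validate_layout(layout)
  yaml::write_yaml(as.list(layout), path, column.major = TRUE)
  invisible(path)
}

#' @rdname write_layout
#' @export
read_layout <- function(path) {
  cols <- yaml::read_yaml(path)
  cols <- lapply(cols, function(x) if (is.list(x)) unlist(
    lapply(x, function(v) if (is.null(v)) NA else v)) else x)
  layout <- as.data.frame(cols, stringsAsFactors = FALSE)
  layout$compound <- as.character(layout$compound)
  layout$conc_uM <- as.numeric(layout$conc_uM)
  validate_layout(layout)
}
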