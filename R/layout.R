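#' Panel / plate layout handling
#'
#' A panel layout maps each well of a set of 96-well plates to the reagent it
#' carries: a marker antibody, an isotype control, an unstained control, or
#' nothing (empty). Marker wells are linked to their matched isotype-control
#' well on the same plate through `isotype_group`.
#'
#' @name panel-layout
NULL

.WELL_ROWS <- LETTERS[1:8]
.WELL_COLS <- 1:12
.REAGENT_CLASSES <- c("marker", "isotype", "unstained", "empty")

#' All 96 well coordinates of a plate, row-major ("A1" ... "H12")
#' @return character vector of length 96
#' @export
well_grid <- function() {
  as.vector(t(outer(.WELL_ROWS, .WELL_COLS, paste0)))
}

.valid_well <- function(well) {
  grepl("^[A-H](1[0-2]|[1-9])$", well)
}

#' Validate a panel layout data frame
#'
#' Checks the structural invariants: unique (plate, well) pairs, well
#' coordinates on the A-H x 1-12 grid, known reagent classes, and that every
#' marker well's `isotype_group` resolves to exactly one isotype well on the
#' same plate.
#'
#' @param layout data.frame with columns `plate`, `well`, `reagent_name`,
#'   `reagent_class`, `isotype_group`
#' @return the layout, invisibly, with class `panel_layout`
#' @export
validate_layout <- function(layout) {
  req <- c("plate", "well", "reagent_name", "reagent_class", "isotype_group")
  missing_cols <- setdiff(req, names(layout))
  if (length(missing_cols) > 0)
    stop("layout is missing required columns: ",
         paste(missing_cols, collapse = ", "))
  bad <- !.valid_well(layout$well)
  if (any(bad))
    stop("invalid well coordinate(s) for a 96-well grid: ",
         paste(unique(layout$well[bad]), collapse = ", "))
  key <- paste(layout$plate, layout$well)
  if (anyDuplicated(key))
    stop("duplicate (plate, well) entries: ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  bad_class <- setdiff(unique(layout$reagent_class), .REAGENT_CLASSES)
  if (length(bad_class) > 0)
    stop("unknown reagent_class: ", paste(bad_class, collapse = ", "))
  markers <- layout[layout$reagent_class == "marker", ]
  isotypes <- layout[layout$reagent_class == "isotype", ]
  for (i in seq_len(nrow(markers))) {
    grp <- markers$isotype_group[i]
    hits <- isotypes$plate == markers$plate[i] & isotypes$isotype_group == grp
    if (sum(hits) != 1)
      stop("marker well ", markers$plate[i], ":", markers$well[i],
           " references isotype group '", grp, "' which resolves to ",
           sum(hits), " isotype wells on its plate (expected exactly 1)")
  }
  class(layout) <- unique(c("panel_layout", class(layout)))
  invisible(layout)
}

#' Read a panel layout from a TSV file
#'
#' @param path path to a tab-separated file with columns `plate`, `well`,
#'   `reagent_name`, `reagent_class`, `isotype_group`
#' @param quiet suppress the per-class count message
#' @return validated `panel_layout` data.frame
#' @export
read_panel_layout <- function(path, quiet = FALSE) {
  if (!file.exists(path)) stop("layout file not found: ", path)
  layout <- utils::read.table(path, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE, quote = "",
                              colClasses = "character")
  layout <- validate_layout(layout)
  if (!quiet) {
    counts <- table(factor(layout$reagent_class, levels = .REAGENT_CLASSES))
    message("panel layout: ",
            paste(names(counts), as.integer(counts), sep = "=", collapse = ", "))
  }
  layout
}

#' Write a panel layout to a TSV file
#' @param layout a `panel_layout` data.frame
#' @param path output path
#' @export
write_panel_layout <- function(layout, path) {
  utils::write.table(layout, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Default four-plate screening panel layout
#'
#' Builds the packaged stand-in for the commercial 96-well antibody panel:
#' 356 marker wells and 9 isotype-control wells arrayed over four plates,
#' plus one unstained-control well per plate; remaining wells are empty.
#' The 13 markers known to discriminate the two culture conditions and the
#' canonical mesenchymal markers carry their field names; the remaining
#' panel positions carry synthetic `SP-###` labels (the commercial
#' well-to-antibody map is not public).
#'
#' Plate 1 carries isotype controls in wells A1-A3, plates 2-4 in A1-A2;
#' the unstained well follows; markers fill the next 89 wells of each plate
#' row-major and are assigned round-robin to their plate's isotype groups.
#'
#' @return validated `panel_layout` data.frame with 384 rows
#' @export
default_panel_layout <- function() {
  markers <- default_marker_names()
  grid <- well_grid()
  rows <- list()
  iso_per_plate <- c(3L, 2L, 2L, 2L)
  marker_chunks <- split(markers, rep(1:4, each = 89))
  for (p in 1:4) {
    plate <- paste0("P", p)
    n_iso <- iso_per_plate[p]
    iso_names <- paste0("IgG", seq_len(n_iso), "-", plate)
    idx <- 1L
    # isotype wells
    for (g in seq_len(n_iso)) {
      rows[[length(rows) + 1L]] <- data.frame(
        plate = plate, well = grid[idx], reagent_name = iso_names[g],
        reagent_class = "isotype", isotype_group = iso_names[g],
        stringsAsFactors = FALSE)
      idx <- idx + 1L
    }
    # one unstained control per plate
    rows[[length(rows) + 1L]] <- data.frame(
      plate = plate, well = grid[idx], reagent_name = "unstained",
      reagent_class = "unstained", isotype_group = NA_character_,
      stringsAsFactors = FALSE)
    idx <- idx + 1L
    # marker wells, round-robin isotype assignment
    mk <- marker_chunks[[p]]
    for (j in seq_along(mk)) {
      rows[[length(rows) + 1L]] <- data.frame(
        plate = plate, well = grid[idx], reagent_name = mk[j],
        reagent_class = "marker",
        isotype_group = iso_names[((j - 1L) %% n_iso) + 1L],
        stringsAsFactors = FALSE)
      idx <- idx + 1L
    }
    # pad the remaining wells as empty
    while (idx <= 96L) {
      rows[[length(rows) + 1L]] <- data.frame(
        plate = plate, well = grid[idx], reagent_name = "empty",
        reagent_class = "empty", isotype_group = NA_character_,
        stringsAsFactors = FALSE)
      idx <- idx + 1L
    }
  }
  layout <- do.call(rbind, rows)
  validate_layout(layout)
  layout
}

#' Marker names of the default panel
#'
#' 356 labels: the 13 condition-discriminating surface proteins, 51
#' canonical/equally-expressed mesenchymal markers, and synthetic labels
#' for the remainder of the panel.
#' @return character vector of length 356
#' @export
default_marker_names <- function() {
  enriched <- c("CD318", "MSCA-1", "CD26", "CD54", "CD106", "CD312",
                "CD49d", "CD40", "HLA-E", "CD97", "Notch2", "MCSP", "CD31")
  equal_named <- c("CD73", "CD90", "CD105", "CD44", "CD29", "CD166", "CD95",
                   "CD46", "CD47", "CD49a", "CD9", "CD81", "CD63")
  negative_named <- c("CD45", "CD34", "CD3", "CD19", "CD14", "CD11b",
                      "CD79a", "HLA-DR")
  n_named <- length(enriched) + length(equal_named) + length(negative_named)
  synth <- sprintf("SP-%03d", seq_len(356 - n_named))
  c(enriched, equal_named, negative_named, synth)
}
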