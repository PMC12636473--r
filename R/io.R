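fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- NA_character_
  out
}

write_exact_csv <- function(df, path) {
  out <- df
  for (nm in names(out)) {
    if (is.double(out[[nm]])) out[[nm]] <- fmt_num(out[[nm]])
  }
  readr::write_csv(out, path, na = "", progress = FALSE)
}

# base read.csv: its strtod-based double parsing is correctly rounded,
# which the bit-exact round-trip guarantee relies on
read_csv_quiet <- function(path, classes, optional = character()) {
  if (!file.exists(path)) {
    abort(sprintf("Load error: file does not exist: %s", path))
  }
  header <- strsplit(readLines(path, n = 1), ",")[[1]]
  use <- classes[intersect(names(classes), header)]
  df <- utils::read.csv(path, colClasses = use, stringsAsFactors = FALSE)
  missing <- setdiff(setdiff(names(classes), optional), names(df))
  if (length(missing)) {
    abort(sprintf("%s is missing column(s): %s", path,
                  paste(missing, collapse = ", ")))
  }
  as_tibble(df)
}

#' Read and write SWC skeleton files
#'
#' The SWC dialect used by this package: whitespace-separated columns
#' `node_id type x y z radius parent_id`, with type codes 1 = soma,
#' 2 = axon, 3 = dendrite, coordinates in nanometres, radius in
#' micrometres, and `parent_id` -1 for a root. Myelination flags live in a
#' sidecar CSV (`cell_id, node_id, myelinated`), since SWC has no myelin
#' column.
#'
#' @param path File path.
#' @param skeleton One cell's skeleton node tibble (see [connectome()]).
#' @return `read_swc()`: a skeleton node tibble without `cell_id` or
#'   `myelinated` (the caller supplies these).
#' @export
read_swc <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Load error: file does not exist: %s", path))
  }
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (!length(lines)) {
    return(tibble(node_id = integer(), parent_id = integer(), x_nm = double(),
                  y_nm = double(), z_nm = double(), radius_um = double(),
                  compartment = character()))
  }
  m <- do.call(rbind, lapply(strsplit(trimws(lines), "\\s+"), as.numeric))
  type_code <- m[, 2]
  comp <- c("soma", "axon", "dendrite")[type_code]
  if (anyNA(comp)) abort(sprintf("Unknown SWC type code in %s", path))
  tibble(
    node_id = as.integer(m[, 1]),
    parent_id = ifelse(m[, 7] < 0, NA_integer_, as.integer(m[, 7])),
    x_nm = m[, 3], y_nm = m[, 4], z_nm = m[, 5],
    radius_um = m[, 6],
    compartment = comp
  )
}

#' @rdname read_swc
#' @export
write_swc <- function(skeleton, path) {
  code <- match(skeleton$compartment, c("soma", "axon", "dendrite"))
  parent <- ifelse(is.na(skeleton$parent_id), -1L, skeleton$parent_id)
  writeLines(
    c("# node_id type x_nm y_nm z_nm radius_um parent_id",
      sprintf("%d %d %s %s %s %s %d", skeleton$node_id, code,
              fmt_num(skeleton$x_nm), fmt_num(skeleton$y_nm),
              fmt_num(skeleton$z_nm), fmt_num(skeleton$radius_um), parent)),
    path)
  invisible(path)
}

#' Write a connectome to a directory
#'
#' Serialises a connectome losslessly: `cells.csv`, `synapses.csv`,
#' `organelles.csv`, `spines.csv` and `geometry.json` at the top level, one
#' SWC file per cell plus the myelin sidecar under `skeletons/`, and one
#' soma vertex CSV per cell under `soma/`. Numbers are written with 17
#' significant digits so that [load_connectome()] round-trips bit-exactly.
#'
#' @param x A `connectome`.
#' @param out_dir Output directory (created if needed).
#' @return A tibble manifest of the five top-level files and the two
#'   per-cell directories, invisibly the same object written.
#' @export
write_connectome <- function(x, out_dir) {
  stopifnot(inherits(x, "connectome"))
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE,
                                          showWarnings = FALSE)
  if (!ok || file.access(out_dir, 2) != 0) {
    abort(sprintf("I/O error: cannot write to directory: %s", out_dir))
  }
  dir.create(file.path(out_dir, "skeletons"), showWarnings = FALSE)
  dir.create(file.path(out_dir, "soma"), showWarnings = FALSE)

  write_exact_csv(x$cells, file.path(out_dir, "cells.csv"))
  write_exact_csv(
    x$synapses[, c("synapse_id", "pre_id", "post_id", "probability",
                   "mesh_area_um2", "x_nm", "y_nm", "z_nm",
                   "post_compartment", "pre_compartment")],
    file.path(out_dir, "synapses.csv"))
  write_exact_csv(x$organelles, file.path(out_dir, "organelles.csv"))
  write_exact_csv(x$spine_counts, file.path(out_dir, "spines.csv"))
  jsonlite::write_json(
    list(bbox_min_nm = x$geometry$bbox_min_nm,
         bbox_max_nm = x$geometry$bbox_max_nm,
         voxel_size_nm = x$geometry$voxel_size_nm,
         boundary_margin_um = x$geometry$boundary_margin_um),
    file.path(out_dir, "geometry.json"), digits = NA)

  for (id in unique(x$skeletons$cell_id)) {
    write_swc(x$skeletons[x$skeletons$cell_id == id, , drop = FALSE],
              file.path(out_dir, "skeletons", sprintf("%s.swc", id)))
  }
  write_exact_csv(
    x$skeletons[, c("cell_id", "node_id", "myelinated")],
    file.path(out_dir, "skeletons", "myelin.csv"))
  for (id in unique(x$soma_vertices$cell_id)) {
    write_exact_csv(
      x$soma_vertices[x$soma_vertices$cell_id == id,
                      c("x_nm", "y_nm", "z_nm"), drop = FALSE],
      file.path(out_dir, "soma", sprintf("%s.csv", id)))
  }

  tibble(
    path = c("cells.csv", "synapses.csv", "organelles.csv", "spines.csv",
             "geometry.json", "skeletons/", "soma/"),
    kind = c(rep("file", 5), rep("directory", 2))
  )
}

#' Load a connectome from a directory
#'
#' Reads the layout written by [write_connectome()] and validates every
#' referential-integrity invariant. Individual paths can be overridden to
#' assemble a dataset from scattered files.
#'
#' @param dir Directory containing the dataset.
#' @param cells_path,synapses_path,organelles_path,spines_path Paths to the
#'   CSV tables.
#' @param skeletons_dir Directory of per-cell SWC files plus `myelin.csv`.
#' @param soma_dir Directory of per-cell soma vertex CSVs.
#' @param geometry_path Path to the geometry JSON.
#' @return A validated `connectome`.
#' @export
load_connectome <- function(dir,
                            cells_path = file.path(dir, "cells.csv"),
                            synapses_path = file.path(dir, "synapses.csv"),
                            organelles_path = file.path(dir, "organelles.csv"),
                            spines_path = file.path(dir, "spines.csv"),
                            skeletons_dir = file.path(dir, "skeletons"),
                            soma_dir = file.path(dir, "soma"),
                            geometry_path = file.path(dir, "geometry.json")) {
  cells <- read_csv_quiet(cells_path, c(
    cell_id = "integer", type = "character", is_fragment = "logical"))
  syn <- read_csv_quiet(synapses_path, c(
    synapse_id = "integer", pre_id = "integer", post_id = "integer",
    probability = "numeric", mesh_area_um2 = "numeric", x_nm = "numeric",
    y_nm = "numeric", z_nm = "numeric", post_compartment = "character",
    pre_compartment = "character"), optional = "pre_compartment")
  org <- read_csv_quiet(organelles_path, c(
    organelle_id = "integer", kind = "character", voxel_count = "numeric",
    x_nm = "numeric", y_nm = "numeric", z_nm = "numeric",
    owner_cell_id = "integer"))
  spines <- if (file.exists(spines_path)) {
    read_csv_quiet(spines_path, c(cell_id = "integer",
                                  n_spines = "integer"))
  } else NULL

  if (!file.exists(geometry_path)) {
    abort(sprintf("Load error: file does not exist: %s", geometry_path))
  }
  gj <- jsonlite::read_json(geometry_path, simplifyVector = TRUE)
  geometry <- dataset_geometry(gj$bbox_min_nm, gj$bbox_max_nm,
                               gj$voxel_size_nm, gj$boundary_margin_um)

  if (!dir.exists(skeletons_dir)) {
    abort(sprintf("Load error: directory does not exist: %s", skeletons_dir))
  }
  swc_files <- list.files(skeletons_dir, pattern = "\\.swc$",
                          full.names = TRUE)
  skel <- purrr::map_dfr(swc_files, function(f) {
    s <- read_swc(f)
    s$cell_id <- as.integer(sub("\\.swc$", "", basename(f)))
    s
  })
  if (!nrow(skel)) {
    skel <- tibble(cell_id = integer(), node_id = integer(),
                   parent_id = integer(), x_nm = double(), y_nm = double(),
                   z_nm = double(), radius_um = double(),
                   compartment = character())
  }
  skel <- dplyr::arrange(skel, .data$cell_id, .data$node_id)
  myelin_path <- file.path(skeletons_dir, "myelin.csv")
  if (file.exists(myelin_path) && nrow(skel)) {
    my <- read_csv_quiet(myelin_path, c(
      cell_id = "integer", node_id = "integer", myelinated = "logical"))
    m <- match(paste(skel$cell_id, skel$node_id),
               paste(my$cell_id, my$node_id))
    skel$myelinated <- !is.na(m) & my$myelinated[m]
  } else {
    skel$myelinated <- rep(FALSE, nrow(skel))
  }
  skel <- skel[, c("cell_id", "node_id", "parent_id", "x_nm", "y_nm", "z_nm",
                   "radius_um", "compartment", "myelinated")]

  soma <- if (dir.exists(soma_dir)) {
    purrr::map_dfr(list.files(soma_dir, pattern = "\\.csv$",
                              full.names = TRUE), function(f) {
      v <- read_csv_quiet(f, c(x_nm = "numeric", y_nm = "numeric",
                               z_nm = "numeric"))
      v$cell_id <- as.integer(sub("\\.csv$", "", basename(f)))
      v[, c("cell_id", "x_nm", "y_nm", "z_nm")]
    })
  } else NULL
  if (!is.null(soma) && nrow(soma)) {
    soma <- dplyr::arrange(soma, .data$cell_id)
  } else {
    soma <- NULL
  }

  connectome(cells = cells, synapses = syn, organelles = org,
             skeletons = skel, soma_vertices = soma, spine_counts = spines,
             geometry = geometry)
}
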