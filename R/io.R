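# Plain-text I/O: ESRI ASCII grids for raster layers (GDAL-compatible),
# CSV sidecars for tabular data, JSON for fitted models.

#' Write a matrix as an ESRI ASCII grid
#'
#' Standard `.asc` text raster: header (ncols, nrows, xllcorner, yllcorner,
#' cellsize, NODATA_value) followed by rows north to south.
#'
#' @param m numeric matrix (row 1 = southernmost row, package convention).
#' @param geom a [grid_geometry()].
#' @param file output path.
#' @param nodata NODATA sentinel (default -9999).
#' @export
write_ascii_grid <- function(m, geom, file, nodata = -9999) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", geom$n_cols),
    sprintf("nrows %d", geom$n_rows),
    sprintf("xllcorner %.10g", geom$xmin),
    sprintf("yllcorner %.10g", geom$ymin),
    sprintf("cellsize %.10g", geom$cell_size_km),
    sprintf("NODATA_value %g", nodata)
  ), con)
  m[is.na(m)] <- nodata
  for (r in rev(seq_len(geom$n_rows))) {     # file rows run north to south
    writeLines(paste(format(m[r, ], trim = TRUE, digits = 10), collapse = " "), con)
  }
  invisible(file)
}

#' Read an ESRI ASCII grid
#'
#' @param file `.asc` path.
#' @return list with `m` (matrix, row 1 = south) and `geom`.
#' @export
read_ascii_grid <- function(file) {
  lines <- readLines(file)
  hdr <- lines[1:6]
  val <- function(key) {
    ln <- hdr[grepl(paste0("^", key), hdr, ignore.case = TRUE)]
    as.numeric(strsplit(trimws(ln), "\\s+")[[1]][2])
  }
  nc <- val("ncols"); nr <- val("nrows")
  nodata <- val("NODATA_value")
  body <- do.call(rbind, lapply(lines[-(1:6)], function(l) {
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])
  }))
  m <- body[rev(seq_len(nr)), , drop = FALSE]
  m[m == nodata] <- NA_real_
  list(m = m, geom = grid_geometry(nr, nc, val("cellsize"),
                                   xmin = val("xllcorner"),
                                   ymin = val("yllcorner")))
}

#' Write a climate stack to a directory
#'
#' One ASCII grid per variable, named `bio_<var>_<age>ka.asc`, plus
#' `dem.asc` for elevation.
#'
#' @param stack a [climate_stack()].
#' @param dir output directory (created if needed).
#' @export
write_climate_stack <- function(stack, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(stack$layers)) {
    write_ascii_grid(stack$layers[[nm]], stack$geom,
                     file.path(dir, sprintf("bio_%s_%gka.asc",
                                            sub("^bio", "", nm), stack$age_ka)))
  }
  write_ascii_grid(stack$elevation, stack$geom, file.path(dir, "dem.asc"))
  invisible(dir)
}

#' Read a climate stack written by [write_climate_stack()]
#'
#' @param dir directory holding `bio_*_<age>ka.asc` files and `dem.asc`.
#' @param age_ka slice age to read.
#' @return A [climate_stack()].
#' @export
read_climate_stack <- function(dir, age_ka) {
  pat <- sprintf("^bio_.+_%gka\\.asc$", age_ka)
  files <- list.files(dir, pattern = pat, full.names = TRUE)
  if (length(files) == 0) stopf("no layers for age %g ka in %s", age_ka, dir)
  layers <- list()
  geom <- NULL
  for (f in files) {
    var <- sub(sprintf("^bio_(.+)_%gka\\.asc$", age_ka), "bio\\1", basename(f))
    g <- read_ascii_grid(f)
    layers[[var]] <- g$m
    geom <- g$geom
  }
  dem <- read_ascii_grid(file.path(dir, "dem.asc"))$m
  climate_stack(layers, dem, geom, age_ka = age_ka)
}

#' Write a vegetation map as categorical ASCII grid plus legend CSV
#'
#' @param vumap a [vegetation_map()].
#' @param file `.asc` path; the legend (`id,label`) goes to
#'   `<file>.legend.csv`.
#' @export
write_vegetation_map <- function(vumap, file) {
  labels <- sort(unique(as.vector(vumap$labels)))
  ids <- seq_along(labels)
  code <- matrix(match(vumap$labels, labels), vumap$geom$n_rows,
                 vumap$geom$n_cols)
  write_ascii_grid(code, vumap$geom, file)
  utils::write.csv(data.frame(id = ids, label = labels),
                   paste0(file, ".legend.csv"), row.names = FALSE)
  invisible(file)
}

#' Read a vegetation map written by [write_vegetation_map()]
#' @param file `.asc` path with a `<file>.legend.csv` sidecar.
#' @param age_ka slice age to record on the map.
#' @return A [vegetation_map()].
#' @export
read_vegetation_map <- function(file, age_ka = 0) {
  g <- read_ascii_grid(file)
  legend <- utils::read.csv(paste0(file, ".legend.csv"),
                            stringsAsFactors = FALSE)
  lab <- matrix(legend$label[match(as.vector(g$m), legend$id)],
                g$geom$n_rows, g$geom$n_cols)
  vegetation_map(lab, g$geom, age_ka = age_ka)
}

#' Write/read occurrence sets as CSV (`vu_id,x,y`)
#' @param occ occurrence set.
#' @param file CSV path.
#' @export
write_occurrences <- function(occ, file) {
  utils::write.csv(occ[, c("vu_id", "x", "y")], file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_occurrences
#' @export
read_occurrences <- function(file) {
  occ <- utils::read.csv(file, stringsAsFactors = FALSE)
  attr(occ, "provenance") <- "file"
  class(occ) <- c("occurrence_set", "data.frame")
  occ
}

#' Serialize a fitted niche model to versioned JSON
#'
#' Stores feature definitions, scaling ranges, weights, normalizer,
#' entropy, penalty scales and training metadata; [read_niche_model()]
#' restores a model whose predictions are bit-identical.
#'
#' @param model a [fit_maxent()] model.
#' @param file output path.
#' @export
write_niche_model <- function(model, file) {
  payload <- list(
    format = "paleoveg-niche-model", version = 1L,
    vu_id = model$vu_id,
    variables = model$features$variables,
    min = as.list(model$features$min), max = as.list(model$features$max),
    classes = model$features$classes, knots = model$features$knots,
    labels = model$features$labels,
    lambda = model$lambda, log_z = model$log_z, entropy = model$entropy,
    beta = model$beta, penalty_scale = model$penalty_scale,
    kkt_residual = model$kkt_residual, meta = model$meta
  )
  jsonlite::write_json(payload, file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname write_niche_model
#' @export
read_niche_model <- function(file) {
  p <- jsonlite::read_json(file, simplifyVector = TRUE)
  if (!identical(p$format, "paleoveg-niche-model")) {
    stopf("'%s' is not a serialized niche model", file)
  }
  fe <- structure(
    list(variables = p$variables,
         min = unlist(p$min), max = unlist(p$max),
         classes = p$classes, knots = as.numeric(p$knots %||% numeric()),
         labels = p$labels),
    class = "feature_expansion"
  )
  structure(
    list(vu_id = p$vu_id, features = fe, lambda = as.numeric(p$lambda),
         log_z = p$log_z, entropy = p$entropy, beta = p$beta,
         penalty_scale = as.numeric(p$penalty_scale),
         objective_path = numeric(), kkt_residual = p$kkt_residual,
         meta = p$meta),
    class = "niche_model"
  )
}

#' Write/read a pollen record as CSV files
#'
#' Counts go to `<prefix>_counts.csv` (sample x taxon matrix with a
#' `sample_id` first column), the chronology to `<prefix>_chronology.csv`
#' (`sample_id,age_ka`), and the site to `<prefix>_site.csv`
#' (`x,y,elevation`).
#'
#' @param record a `pollen_record`.
#' @param prefix path prefix for the three CSV files.
#' @export
write_pollen_record <- function(record, prefix) {
  counts <- data.frame(sample_id = record$samples$sample_id,
                       record$counts, check.names = FALSE)
  utils::write.csv(counts, paste0(prefix, "_counts.csv"), row.names = FALSE)
  utils::write.csv(record$samples, paste0(prefix, "_chronology.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(record$site), paste0(prefix, "_site.csv"),
                   row.names = FALSE)
  invisible(prefix)
}

#' @rdname write_pollen_record
#' @export
read_pollen_record <- function(prefix) {
  counts <- utils::read.csv(paste0(prefix, "_counts.csv"),
                            check.names = FALSE, stringsAsFactors = FALSE)
  chron <- utils::read.csv(paste0(prefix, "_chronology.csv"),
                           stringsAsFactors = FALSE)
  site <- utils::read.csv(paste0(prefix, "_site.csv"),
                          stringsAsFactors = FALSE)
  m <- as.matrix(counts[, -1, drop = FALSE])
  rownames(m) <- counts$sample_id
  ord <- match(counts$sample_id, chron$sample_id)
  structure(
    list(site = as.list(site[1, ]),
         samples = data.frame(sample_id = counts$sample_id,
                              age_ka = chron$age_ka[ord]),
         counts = m),
    class = "pollen_record"
  )
}
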