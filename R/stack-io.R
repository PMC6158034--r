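# Stack and table I/O: multi-channel TIFF with OME companion metadata,
# ground-truth / per-vesicle CSVs, per-cell JSON summaries, config files.

OME_NS <- "http://www.openmicroscopy.org/Schemas/OME/2016-06"

companion_path <- function(path) {
  base <- sub("\\.ome\\.tiff?$", "", path, ignore.case = TRUE)
  base <- sub("\\.tiff?$", "", base, ignore.case = TRUE)
  paste0(base, ".companion.ome")
}

#' Write a multi-channel stack as TIFF with OME companion metadata
#'
#' Pages are 32-bit float, channel-major (all z planes of channel 1, then
#' channel 2, ...). Because baseline float TIFF samples live in `[0, 1]`,
#' intensities are divided by a global scale (the maximum over all channels)
#' that is recorded, together with PhysicalSizeX/Y/Z, Size* and the channel
#' names, in an OME companion XML file next to the TIFF
#' (`<base>.companion.ome`). [read_stack()] restores the original intensities
#' and voxel sizes exactly.
#'
#' @param channels list of [voxel_grid()]s sharing one shape and voxel size,
#'   or a `synthetic_cell`.
#' @param path output TIFF path (e.g. `cell.ome.tiff`).
#' @return Invisibly, a character vector with the TIFF and companion paths.
#' @export
write_stack <- function(channels, path) {
  if (inherits(channels, "synthetic_cell")) channels <- channels$channels
  stopifnot(length(channels) >= 1L)
  dims <- dim(channels[[1]]$data)
  for (g in channels) {
    stopifnot(inherits(g, "voxel_grid"))
    if (!all(dim(g$data) == dims)) stopf("all channels must share one shape")
  }
  scale <- max(1e-12, max(vapply(channels, function(g) max(g$data), 0)))
  pages <- list()
  for (g in channels) {
    for (z in seq_len(dims[1])) {
      pages[[length(pages) + 1L]] <- g$data[z, , ] / scale
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none",
                  reduce = FALSE)

  vxy_um <- channels[[1]]$voxel_xy_nm / 1000
  vz_um <- channels[[1]]$voxel_z_nm / 1000
  doc <- xml2::xml_new_root("OME", xmlns = OME_NS)
  img <- xml2::xml_add_child(doc, "Image", ID = "Image:0", Name = basename(path))
  px <- xml2::xml_add_child(img, "Pixels", ID = "Pixels:0",
                            DimensionOrder = "XYZCT", Type = "float",
                            SizeX = dims[3], SizeY = dims[2], SizeZ = dims[1],
                            SizeC = length(channels), SizeT = 1,
                            PhysicalSizeX = format(vxy_um, digits = 15),
                            PhysicalSizeXUnit = "µm",
                            PhysicalSizeY = format(vxy_um, digits = 15),
                            PhysicalSizeYUnit = "µm",
                            PhysicalSizeZ = format(vz_um, digits = 15),
                            PhysicalSizeZUnit = "µm")
  for (k in seq_along(channels)) {
    xml2::xml_add_child(px, "Channel", ID = sprintf("Channel:0:%d", k - 1),
                        Name = channels[[k]]$channel, SamplesPerPixel = 1)
  }
  xml2::xml_add_child(px, "TiffData")
  sa <- xml2::xml_add_child(doc, "StructuredAnnotations")
  ann <- xml2::xml_add_child(sa, "XMLAnnotation", ID = "Annotation:0",
                             Namespace = "vesicoloc")
  val <- xml2::xml_add_child(ann, "Value")
  xml2::xml_add_child(val, "IntensityScale", format(scale, digits = 17))
  comp <- companion_path(path)
  xml2::write_xml(doc, comp)
  invisible(c(tiff = path, companion = comp))
}

#' Read a multi-channel z-stack with physical metadata
#'
#' Reads a TIFF written by [write_stack()] (or any channel-major float TIFF)
#' together with its OME companion metadata. Voxel sizes come from the
#' metadata and can be overridden; without companion metadata both overrides
#' (and `n_channels`) are required.
#'
#' @param path TIFF path.
#' @param voxel_xy_nm,voxel_z_nm optional overrides of PhysicalSizeX/Y and
#'   PhysicalSizeZ (nm).
#' @param n_channels expected channel count; the default 3 is required by the
#'   triplex co-localization pipeline. Use `NA` to accept any count (the
#'   companion metadata must then supply SizeC).
#' @return List of [voxel_grid()]s in file order.
#' @export
read_stack <- function(path, voxel_xy_nm = NULL, voxel_z_nm = NULL,
                       n_channels = 3L) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!length(pages)) stopf("no pages in %s", path)
  comp <- companion_path(path)
  meta <- NULL
  if (file.exists(comp)) {
    doc <- xml2::read_xml(comp)
    ns <- c(d1 = OME_NS)
    px <- xml2::xml_find_first(doc, ".//d1:Pixels", ns)
    get_attr <- function(a) xml2::xml_attr(px, a)
    chn <- xml2::xml_attr(xml2::xml_find_all(doc, ".//d1:Channel", ns), "Name")
    sc <- xml2::xml_text(xml2::xml_find_first(doc, ".//d1:IntensityScale", ns))
    meta <- list(size_z = as.integer(get_attr("SizeZ")),
                 size_c = as.integer(get_attr("SizeC")),
                 physical_x_um = as.numeric(get_attr("PhysicalSizeX")),
                 physical_z_um = as.numeric(get_attr("PhysicalSizeZ")),
                 channels = chn,
                 scale = if (is.na(sc)) 1 else as.numeric(sc))
  }
  if (is.null(meta)) {
    if (is.null(voxel_xy_nm) || is.null(voxel_z_nm))
      stopf(paste("no OME companion metadata at %s: PhysicalSizeX/Y and",
                  "PhysicalSizeZ unknown; pass voxel_xy_nm and voxel_z_nm"),
            comp)
    if (is.na(n_channels))
      stopf("no companion metadata: channel count unknown; pass n_channels")
    size_c <- as.integer(n_channels)
    if (length(pages) %% size_c != 0L)
      stopf("page count %d is not divisible by %d channels",
            length(pages), size_c)
    meta <- list(size_z = length(pages) %/% size_c, size_c = size_c,
                 physical_x_um = voxel_xy_nm / 1000,
                 physical_z_um = voxel_z_nm / 1000,
                 channels = paste0("channel", seq_len(size_c)), scale = 1)
  }
  vxy <- voxel_xy_nm %||% (meta$physical_x_um * 1000)
  vz <- voxel_z_nm %||% (meta$physical_z_um * 1000)
  if (!is.na(n_channels) && meta$size_c != n_channels)
    stopf("expected %d channels for the co-localization pipeline, found %d",
          n_channels, meta$size_c)
  if (meta$size_z * meta$size_c != length(pages))
    stopf("metadata (SizeZ %d x SizeC %d) does not match %d TIFF pages",
          meta$size_z, meta$size_c, length(pages))
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  out <- vector("list", meta$size_c)
  for (k in seq_len(meta$size_c)) {
    arr <- array(0, dim = c(meta$size_z, ny, nx))
    for (z in seq_len(meta$size_z)) {
      arr[z, , ] <- pages[[(k - 1L) * meta$size_z + z]] * meta$scale
    }
    out[[k]] <- voxel_grid(arr, vxy, vz, channel = meta$channels[k])
  }
  names(out) <- meta$channels
  out
}

#' Write / read a ground-truth vesicle table
#'
#' @param truth a `ground_truth` data frame from [sample_vesicle_field()].
#' @param path CSV path.
#' @return `write_ground_truth()` returns the path invisibly;
#'   `read_ground_truth()` returns the data frame.
#' @export
write_ground_truth <- function(truth, path) {
  utils::write.csv(as.data.frame(truth), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(out) <- c("ground_truth", "data.frame")
  out
}

#' Write per-vesicle records and the per-cell summary
#'
#' Emits `vesicles.csv` (one row per vesicle: id, per-channel positions in
#' nm, per-channel normalized intensities and calls, prefilter flag,
#' category) and `summary.json`. [read_results()] reproduces the structures.
#'
#' @param records `vesicle_records` from [classify_cell()].
#' @param summary `cell_summary` from [summarize_cell()].
#' @param out_dir output directory (created if missing).
#' @return Invisibly, named character vector of the two paths.
#' @export
write_results <- function(records, summary, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stopf("cannot create output directory '%s'", out_dir)
  }
  csv <- file.path(out_dir, "vesicles.csv")
  js <- file.path(out_dir, "summary.json")
  utils::write.csv(as.data.frame(records), csv, row.names = FALSE)
  jsonlite::write_json(as.list(as.data.frame(summary)), js, auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(c(vesicles = csv, summary = js))
}

#' Read back results written by [write_results()]
#'
#' @param out_dir directory holding `vesicles.csv` and `summary.json`.
#' @return List with `records` and `summary`.
#' @export
read_results <- function(out_dir) {
  csv <- file.path(out_dir, "vesicles.csv")
  js <- file.path(out_dir, "summary.json")
  records <- utils::read.csv(csv, stringsAsFactors = FALSE)
  class(records) <- c("vesicle_records", "data.frame")
  raw <- jsonlite::read_json(js)
  summary <- as.data.frame(lapply(raw, function(x) x %||% NA),
                           stringsAsFactors = FALSE)
  class(summary) <- c("cell_summary", "data.frame")
  list(records = records, summary = summary)
}

#' Save / load an analysis configuration as JSON
#'
#' Every run of the pipeline should log the fully resolved configuration;
#' these helpers serialize an [analysis_config()] losslessly.
#'
#' @param config an [analysis_config()].
#' @param path JSON path.
#' @return `write_analysis_config()` the path, invisibly;
#'   `read_analysis_config()` the config.
#' @export
write_analysis_config <- function(config, path) {
  stopifnot(inherits(config, "analysis_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_analysis_config
#' @export
read_analysis_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(analysis_config, raw)
}
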