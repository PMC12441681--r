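# imzML 1.1 + ibd reader/writer.
#
# The XML part follows the mzML schema with the imaging-MS controlled
# vocabulary (IMS:*) for pixel positions and external binary arrays; the ibd
# companion holds a 16-byte UUID followed by the arrays. "processed" mode
# stores one m/z axis per pixel, "continuous" mode a single shared axis.

IMS_CV <- list(
  continuous = "IMS:1000030", processed = "IMS:1000031",
  uuid = "IMS:1000080", sha1 = "IMS:1000091",
  max_x = "IMS:1000042", max_y = "IMS:1000043",
  pixel_x = "IMS:1000046", pixel_y = "IMS:1000047",
  pos_x = "IMS:1000050", pos_y = "IMS:1000051",
  ext_offset = "IMS:1000102", ext_len = "IMS:1000103",
  ext_enc_len = "IMS:1000104", ext_data = "IMS:1000101"
)
MS_CV <- list(mz_array = "MS:1000514", int_array = "MS:1000515",
              f32 = "MS:1000521", f64 = "MS:1000523",
              no_compression = "MS:1000576")

random_uuid <- function() {
  bytes <- as.raw(sample(0:255, 16, replace = TRUE))
  # RFC 4122 version/variant bits
  bytes[7] <- as.raw(bitwOr(bitwAnd(as.integer(bytes[7]), 0x0F), 0x40))
  bytes[9] <- as.raw(bitwOr(bitwAnd(as.integer(bytes[9]), 0x3F), 0x80))
  bytes
}

uuid_to_string <- function(bytes) {
  h <- paste(sprintf("%02x", as.integer(bytes)), collapse = "")
  sprintf("{%s-%s-%s-%s-%s}", substr(h, 1, 8), substr(h, 9, 12),
          substr(h, 13, 16), substr(h, 17, 20), substr(h, 21, 32))
}

normalize_uuid <- function(s) tolower(gsub("[{}-]", "", s))

cv <- function(parent, ref, accession, name, value = NULL, unit = NULL) {
  node <- xml2::xml_add_child(parent, "cvParam", cvRef = ref,
                              accession = accession, name = name)
  if (!is.null(value)) xml2::xml_set_attr(node, "value", as.character(value))
  invisible(node)
}

imzml_paths <- function(path) {
  base <- sub("\\.imzML$", "", path, ignore.case = TRUE)
  list(imzml = paste0(base, ".imzML"), ibd = paste0(base, ".ibd"))
}

#' Write an MSI dataset as an imzML + ibd file pair
#'
#' Produces a standards-conformant imzML 1.1 XML file and its binary ibd
#' companion, linked by a shared UUID (and an ibd SHA-1 checksum when the
#' digest package is available). `"processed"` mode (default) stores one m/z
#' axis per pixel; `"continuous"` mode requires all spectra to share an
#' identical m/z axis and stores it once.
#'
#' @param dataset `MSIDataset`.
#' @param path output path; the `.imzML`/`.ibd` pair is derived from it.
#' @param mode `"processed"` or `"continuous"`.
#' @param mz_type,intensity_type binary encodings, `"float64"` (default,
#'   lossless round trip) or `"float32"`.
#' @return named character vector with the two file paths, invisibly.
#' @export
write_imzml <- function(dataset, path, mode = c("processed", "continuous"),
                        mz_type = c("float64", "float32"),
                        intensity_type = c("float64", "float32")) {
  stopifnot(inherits(dataset, "MSIDataset"))
  mode <- match.arg(mode)
  mz_type <- match.arg(mz_type); intensity_type <- match.arg(intensity_type)
  files <- imzml_paths(path)
  n <- n_pixels(dataset)
  if (mode == "continuous" && n > 0) {
    ax <- dataset$mz[[1]]
    same <- vapply(dataset$mz, function(m) identical(length(m), length(ax)) &&
                     (length(m) == 0L || max(abs(m - ax)) == 0), TRUE)
    if (!all(same))
      stop("continuous mode requires an identical m/z axis in every pixel")
  }
  size_of <- c(float32 = 4L, float64 = 8L)

  # ---- ibd ----
  uuid <- random_uuid()
  con <- file(files$ibd, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(uuid, con)
  offset <- 16
  offs <- vector("list", n)
  write_array <- function(x, type) {
    writeBin(as.numeric(x), con, size = size_of[[type]], endian = "little")
    rec <- c(offset = offset, length = length(x),
             enc = length(x) * size_of[[type]])
    offset <<- offset + rec[["enc"]]
    rec
  }
  mz_shared <- NULL
  if (mode == "continuous" && n > 0)
    mz_shared <- write_array(dataset$mz[[1]], mz_type)
  for (i in seq_len(n)) {
    mz_rec <- if (mode == "continuous") mz_shared
              else write_array(dataset$mz[[i]], mz_type)
    int_rec <- write_array(dataset$intensity[[i]], intensity_type)
    offs[[i]] <- list(mz = mz_rec, int = int_rec)
  }
  close(con); on.exit(NULL)

  sha1 <- NULL
  if (requireNamespace("digest", quietly = TRUE))
    sha1 <- digest::digest(files$ibd, algo = "sha1", file = TRUE)

  # ---- imzML ----
  doc <- xml2::xml_new_root("mzML",
    xmlns = "http://psi.hupo.org/ms/mzml", version = "1.1")
  cvl <- xml2::xml_add_child(doc, "cvList", count = "2")
  xml2::xml_add_child(cvl, "cv", id = "MS",
    fullName = "Proteomics Standards Initiative Mass Spectrometry Ontology",
    URI = "https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo")
  xml2::xml_add_child(cvl, "cv", id = "IMS",
    fullName = "Imaging MS Ontology",
    URI = "https://raw.githubusercontent.com/imzML/imzML/master/imagingMS.obo")
  fd <- xml2::xml_add_child(doc, "fileDescription")
  fc <- xml2::xml_add_child(fd, "fileContent")
  if (mode == "continuous") cv(fc, "IMS", IMS_CV$continuous, "continuous")
  else cv(fc, "IMS", IMS_CV$processed, "processed")
  cv(fc, "IMS", IMS_CV$uuid, "universally unique identifier",
     uuid_to_string(uuid))
  if (!is.null(sha1)) cv(fc, "IMS", IMS_CV$sha1, "ibd SHA-1", sha1)
  up <- xml2::xml_add_child(fc, "userParam", name = "mz_range_low",
                            value = as.character(dataset$mz_range[1]))
  xml2::xml_add_child(fc, "userParam", name = "mz_range_high",
                      value = as.character(dataset$mz_range[2]))
  xml2::xml_add_child(fc, "userParam", name = "normalization",
                      value = dataset$normalization)

  rpg <- xml2::xml_add_child(doc, "referenceableParamGroupList", count = "2")
  g1 <- xml2::xml_add_child(rpg, "referenceableParamGroup", id = "mzArray")
  cv(g1, "MS", MS_CV$mz_array, "m/z array")
  cv(g1, "MS", if (mz_type == "float64") MS_CV$f64 else MS_CV$f32,
     paste0(sub("float", "", mz_type), "-bit float"))
  cv(g1, "MS", MS_CV$no_compression, "no compression")
  cv(g1, "IMS", IMS_CV$ext_data, "external data", "true")
  g2 <- xml2::xml_add_child(rpg, "referenceableParamGroup",
                            id = "intensityArray")
  cv(g2, "MS", MS_CV$int_array, "intensity array")
  cv(g2, "MS", if (intensity_type == "float64") MS_CV$f64 else MS_CV$f32,
     paste0(sub("float", "", intensity_type), "-bit float"))
  cv(g2, "MS", MS_CV$no_compression, "no compression")
  cv(g2, "IMS", IMS_CV$ext_data, "external data", "true")

  ssl <- xml2::xml_add_child(doc, "scanSettingsList", count = "1")
  ss <- xml2::xml_add_child(ssl, "scanSettings", id = "scanSettings1")
  max_x <- if (n) max(dataset$coords$x) + 1L else 0L
  max_y <- if (n) max(dataset$coords$y) + 1L else 0L
  cv(ss, "IMS", IMS_CV$max_x, "max count of pixels x", max_x)
  cv(ss, "IMS", IMS_CV$max_y, "max count of pixels y", max_y)
  cv(ss, "IMS", IMS_CV$pixel_x, "pixel size (x)", dataset$pixel_size)
  cv(ss, "IMS", IMS_CV$pixel_y, "pixel size y", dataset$pixel_size)

  run <- xml2::xml_add_child(doc, "run", id = "run1")
  sl <- xml2::xml_add_child(run, "spectrumList", count = as.character(n))
  for (i in seq_len(n)) {
    sp <- xml2::xml_add_child(sl, "spectrum",
      id = sprintf("spectrum=%d", i), index = as.character(i - 1L),
      defaultArrayLength = "0")
    scl <- xml2::xml_add_child(sp, "scanList", count = "1")
    sc <- xml2::xml_add_child(scl, "scan")
    # imzML positions are 1-based; internal indices are 0-based
    cv(sc, "IMS", IMS_CV$pos_x, "position x", dataset$coords$x[i] + 1L)
    cv(sc, "IMS", IMS_CV$pos_y, "position y", dataset$coords$y[i] + 1L)
    bal <- xml2::xml_add_child(sp, "binaryDataArrayList", count = "2")
    for (which in c("mz", "int")) {
      rec <- offs[[i]][[which]]
      ba <- xml2::xml_add_child(bal, "binaryDataArray", encodedLength = "0")
      xml2::xml_add_child(ba, "referenceableParamGroupRef",
        ref = if (which == "mz") "mzArray" else "intensityArray")
      cv(ba, "IMS", IMS_CV$ext_len, "external array length", rec[["length"]])
      cv(ba, "IMS", IMS_CV$ext_offset, "external offset", rec[["offset"]])
      cv(ba, "IMS", IMS_CV$ext_enc_len, "external encoded length", rec[["enc"]])
      xml2::xml_add_child(ba, "binary")
    }
  }
  xml2::write_xml(doc, files$imzml)
  invisible(c(imzml = files$imzml, ibd = files$ibd))
}

#' Read an imzML + ibd file pair into an MSI dataset
#'
#' Supports both `"continuous"` and `"processed"` binary modes with 32- or
#' 64-bit float arrays. The UUID stored in the XML must match the first 16
#' bytes of the ibd file, and every declared array must lie within the ibd
#' file; otherwise a corrupt-pair error is raised and no partial dataset is
#' returned.
#'
#' @param path path to the `.imzML` file (the `.ibd` is derived from it).
#' @return `MSIDataset` with 0-based internal pixel indices.
#' @export
read_imzml <- function(path) {
  files <- imzml_paths(path)
  if (!file.exists(files$imzml)) stop("missing imzML file: ", files$imzml)
  if (!file.exists(files$ibd)) stop("corrupt imzML pair: missing ibd file")
  doc <- xml2::read_xml(files$imzml)
  xml2::xml_ns_strip(doc)

  fc <- xml2::xml_find_first(doc, ".//fileDescription/fileContent")
  acc <- function(node, accession)
    xml2::xml_find_first(node, sprintf(".//cvParam[@accession='%s']", accession))
  mode <- if (!inherits(acc(fc, IMS_CV$processed), "xml_missing")) "processed"
          else if (!inherits(acc(fc, IMS_CV$continuous), "xml_missing")) "continuous"
          else stop("unsupported imzML: neither continuous nor processed mode declared")
  uuid_node <- acc(fc, IMS_CV$uuid)
  if (inherits(uuid_node, "xml_missing"))
    stop("unsupported imzML: no UUID declared")
  uuid_xml <- normalize_uuid(xml2::xml_attr(uuid_node, "value"))

  ibd_size <- file.size(files$ibd)
  if (is.na(ibd_size) || ibd_size < 16)
    stop("corrupt imzML pair: ibd file too short for a UUID")
  con <- file(files$ibd, "rb")
  on.exit(close(con), add = TRUE)
  uuid_ibd <- paste(sprintf("%02x", as.integer(readBin(con, "raw", 16))),
                    collapse = "")
  if (!identical(uuid_xml, uuid_ibd))
    stop("corrupt imzML pair: UUID mismatch between imzML and ibd")

  group_type <- function(id) {
    g <- xml2::xml_find_first(doc,
      sprintf(".//referenceableParamGroup[@id='%s']", id))
    if (inherits(g, "xml_missing")) return(NULL)
    if (!inherits(acc(g, MS_CV$f64), "xml_missing")) return("float64")
    if (!inherits(acc(g, MS_CV$f32), "xml_missing")) return("float32")
    stop("unsupported binary encoding in imzML (only 32/64-bit float)")
  }
  group_types <- list(mzArray = group_type("mzArray"),
                      intensityArray = group_type("intensityArray"))

  cv_value <- function(node, accession) {
    p <- acc(node, accession)
    if (inherits(p, "xml_missing")) NA else xml2::xml_attr(p, "value")
  }
  user_value <- function(name) {
    p <- xml2::xml_find_first(fc, sprintf(".//userParam[@name='%s']", name))
    if (inherits(p, "xml_missing")) NA else xml2::xml_attr(p, "value")
  }

  spectra <- xml2::xml_find_all(doc, ".//run/spectrumList/spectrum")
  n <- length(spectra)
  coords <- data.frame(x = integer(n), y = integer(n))
  mz <- vector("list", n); intensity <- vector("list", n)
  size_of <- c(float32 = 4L, float64 = 8L)

  read_array <- function(offset, len, type) {
    if (offset + len * size_of[[type]] > ibd_size)
      stop("corrupt imzML pair: ibd file truncated (array exceeds file size)")
    seek(con, where = offset, origin = "start")
    readBin(con, "numeric", n = len, size = size_of[[type]],
            endian = "little")
  }

  for (i in seq_len(n)) {
    sp <- spectra[[i]]
    px <- as.integer(cv_value(sp, IMS_CV$pos_x))
    py <- as.integer(cv_value(sp, IMS_CV$pos_y))
    if (is.na(px) || is.na(py)) stop("spectrum without pixel position")
    coords$x[i] <- px - 1L; coords$y[i] <- py - 1L
    arrays <- xml2::xml_find_all(sp, ".//binaryDataArray")
    got <- list()
    for (ba in arrays) {
      ref <- xml2::xml_attr(
        xml2::xml_find_first(ba, ".//referenceableParamGroupRef"), "ref")
      type <- if (!is.na(ref) && !is.null(group_types[[ref]]))
        group_types[[ref]]
      else if (!inherits(acc(ba, MS_CV$f64), "xml_missing")) "float64"
      else if (!inherits(acc(ba, MS_CV$f32), "xml_missing")) "float32"
      else stop("unsupported binary encoding in imzML (only 32/64-bit float)")
      kind <- if (identical(ref, "mzArray") ||
                  !inherits(acc(ba, MS_CV$mz_array), "xml_missing")) "mz"
              else "int"
      offset <- as.numeric(cv_value(ba, IMS_CV$ext_offset))
      len <- as.integer(cv_value(ba, IMS_CV$ext_len))
      got[[kind]] <- read_array(offset, len, type)
    }
    if (is.null(got$mz) || is.null(got$int))
      stop("spectrum missing m/z or intensity array")
    mz[[i]] <- got$mz; intensity[[i]] <- got$int
  }

  ss <- xml2::xml_find_first(doc, ".//scanSettings")
  px_size <- if (!inherits(ss, "xml_missing")) {
    v <- as.numeric(cv_value(ss, IMS_CV$pixel_x)); if (is.na(v)) 20 else v
  } else 20
  lo <- as.numeric(user_value("mz_range_low"))
  hi <- as.numeric(user_value("mz_range_high"))
  if (is.na(lo) || is.na(hi)) {
    all_mz <- unlist(mz)
    if (length(all_mz)) { lo <- min(all_mz); hi <- max(all_mz) }
    else { lo <- 0; hi <- 1 }
  }
  norm <- user_value("normalization")
  if (is.na(norm) || !norm %in% c("raw", "TIC")) norm <- "raw"
  msi_dataset(coords, mz, intensity, pixel_size = px_size,
              mz_range = c(lo, hi), normalization = norm)
}
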