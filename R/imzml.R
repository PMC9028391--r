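# Minimal imzML 1.1 + ibd reader/writer. Continuous mode stores one shared
# m/z axis (float64) and per-pixel intensities (float32); processed mode
# stores a per-pixel m/z axis. Coordinates are 1-based per the imzML
# convention and kept verbatim.

imzml_uuid <- function() {
  paste(sprintf("%02x", as.integer(sample(0:255, 16, replace = TRUE))),
        collapse = "")
}

ibd_path <- function(path) sub("\\.imzML$", ".ibd", path, ignore.case = TRUE)

#' Write pixel spectra as an imzML/ibd pair
#'
#' @param x List with `mz` (numeric vector for continuous mode, or list of
#'   per-pixel vectors for processed mode), `intensity` (pixels x grid
#'   matrix, or list of vectors), and `coords` (tibble with integer `x`,
#'   `y`).
#' @param path Output `.imzML` path; the `.ibd` is written alongside.
#' @param mode `"continuous"` or `"processed"`.
#' @return `path`, invisibly.
#' @export
write_imzml <- function(x, path, mode = c("continuous", "processed")) {
  mode <- match.arg(mode)
  uuid <- imzml_uuid()
  ibd <- ibd_path(path)
  con <- file(ibd, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(as.raw(strtoi(substring(uuid, seq(1, 31, 2), seq(2, 32, 2)), 16L)),
           con)
  offset <- 16

  n <- nrow(x$coords)
  entries <- vector("list", max(n, 0))
  if (mode == "continuous") {
    mz <- x$mz
    writeBin(as.numeric(mz), con, size = 8, endian = "little")
    mz_off <- offset
    mz_len <- length(mz)
    offset <- offset + 8 * mz_len
    for (i in seq_len(n)) {
      writeBin(as.numeric(x$intensity[i, ]), con, size = 4, endian = "little")
      entries[[i]] <- list(mz_off = mz_off, mz_len = mz_len,
                           int_off = offset, int_len = mz_len)
      offset <- offset + 4 * mz_len
    }
  } else {
    for (i in seq_len(n)) {
      mzi <- x$mz[[i]]
      writeBin(as.numeric(mzi), con, size = 8, endian = "little")
      mz_off <- offset
      offset <- offset + 8 * length(mzi)
      writeBin(as.numeric(x$intensity[[i]]), con, size = 4, endian = "little")
      entries[[i]] <- list(mz_off = mz_off, mz_len = length(mzi),
                           int_off = offset, int_len = length(mzi))
      offset <- offset + 4 * length(mzi)
    }
  }

  spec_xml <- vapply(seq_len(n), function(i) {
    e <- entries[[i]]
    paste0(
      '<spectrum id="spectrum=', i, '" index="', i - 1,
      '" defaultArrayLength="', e$mz_len, '">',
      '<scanList count="1"><scan>',
      '<cvParam cvRef="IMS" accession="IMS:1000050" name="position x" value="',
      x$coords$x[i], '"/>',
      '<cvParam cvRef="IMS" accession="IMS:1000051" name="position y" value="',
      x$coords$y[i], '"/>',
      '</scan></scanList>',
      '<binaryDataArrayList count="2">',
      '<binaryDataArray encodedLength="0">',
      '<referenceableParamGroupRef ref="mzArray"/>',
      '<cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="',
      e$mz_len, '"/>',
      '<cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="',
      e$mz_off, '"/>',
      '<cvParam cvRef="IMS" accession="IMS:1000104" name="external encoded length" value="',
      8 * e$mz_len, '"/>',
      '<binary/></binaryDataArray>',
      '<binaryDataArray encodedLength="0">',
      '<referenceableParamGroupRef ref="intensityArray"/>',
      '<cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="',
      e$int_len, '"/>',
      '<cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="',
      e$int_off, '"/>',
      '<cvParam cvRef="IMS" accession="IMS:1000104" name="external encoded length" value="',
      4 * e$int_len, '"/>',
      '<binary/></binaryDataArray>',
      '</binaryDataArrayList></spectrum>')
  }, "")

  mode_acc <- if (mode == "continuous") "IMS:1000030" else "IMS:1000031"
  xml <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1">',
    '<cvList count="2">',
    '<cv id="MS" fullName="Proteomics Standards Initiative Mass Spectrometry Ontology" URI="http://psidev.info/ms/mzML/psi-ms.obo"/>',
    '<cv id="IMS" fullName="Imaging MS Ontology" URI="http://www.maldi-msi.org/download/imzml/imagingMS.obo"/>',
    '</cvList>',
    '<fileDescription><fileContent>',
    '<cvParam cvRef="IMS" accession="', mode_acc, '" name="', mode, '"/>',
    '<cvParam cvRef="IMS" accession="IMS:1000080" name="universally unique identifier" value="{',
    uuid, '}"/>',
    '</fileContent></fileDescription>',
    '<referenceableParamGroupList count="2">',
    '<referenceableParamGroup id="mzArray">',
    '<cvParam cvRef="MS" accession="MS:1000514" name="m/z array"/>',
    '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/>',
    '<cvParam cvRef="MS" accession="MS:1000576" name="no compression"/>',
    '<cvParam cvRef="IMS" accession="IMS:1000101" name="external data" value="true"/>',
    '</referenceableParamGroup>',
    '<referenceableParamGroup id="intensityArray">',
    '<cvParam cvRef="MS" accession="MS:1000515" name="intensity array"/>',
    '<cvParam cvRef="MS" accession="MS:1000521" name="32-bit float"/>',
    '<cvParam cvRef="MS" accession="MS:1000576" name="no compression"/>',
    '<cvParam cvRef="IMS" accession="IMS:1000101" name="external data" value="true"/>',
    '</referenceableParamGroup>',
    '</referenceableParamGroupList>',
    '<run id="run0">',
    '<spectrumList count="', n, '">',
    paste(spec_xml, collapse = ""),
    '</spectrumList></run></mzML>')
  writeLines(xml, path)
  invisible(path)
}

imzml_param <- function(node, accession) {
  p <- xml2::xml_find_first(
    node, paste0(".//cvParam[@accession='", accession, "']"))
  if (inherits(p, "xml_missing")) return(NA_character_)
  xml2::xml_attr(p, "value")
}

#' Read an imzML/ibd pair
#'
#' Both continuous and processed imzML are supported; processed-mode spectra
#' are resampled onto a common grid by linear interpolation (zero outside
#' the recorded range).
#'
#' @param path Path to the `.imzML` file (the `.ibd` must sit alongside).
#' @param mz_out Optional target grid for processed-mode resampling; by
#'   default a regular grid over the observed range at the median spacing of
#'   the first spectrum.
#' @return List: `mz` (common grid), `intensity` (pixels x grid matrix),
#'   `coords` tibble, `mode`.
#' @export
read_imzml <- function(path, mz_out = NULL) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  ibd <- ibd_path(path)
  if (!file.exists(ibd)) abort(paste0("missing ibd file: ", ibd))
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)

  fc <- xml2::xml_find_first(doc, ".//fileContent")
  mode <- if (!inherits(xml2::xml_find_first(
    fc, ".//cvParam[@accession='IMS:1000030']"), "xml_missing")) {
    "continuous"
  } else "processed"

  specs <- xml2::xml_find_all(doc, ".//spectrum")
  n <- length(specs)
  if (n == 0) {
    return(list(mz = numeric(), intensity = matrix(0, 0, 0),
                coords = tibble::tibble(x = integer(), y = integer()),
                mode = mode))
  }

  con <- file(ibd, "rb")
  on.exit(close(con), add = TRUE)
  read_array <- function(offset, len, size) {
    seek(con, offset)
    readBin(con, "numeric", n = len, size = size, endian = "little")
  }

  mz_list <- vector("list", n)
  int_list <- vector("list", n)
  coords <- tibble::tibble(x = integer(n), y = integer(n))
  for (i in seq_len(n)) {
    s <- specs[[i]]
    coords$x[i] <- as.integer(imzml_param(s, "IMS:1000050"))
    coords$y[i] <- as.integer(imzml_param(s, "IMS:1000051"))
    arrays <- xml2::xml_find_all(s, ".//binaryDataArray")
    for (a in arrays) {
      ref <- xml2::xml_attr(
        xml2::xml_find_first(a, ".//referenceableParamGroupRef"), "ref")
      off <- as.numeric(imzml_param(a, "IMS:1000102"))
      len <- as.integer(imzml_param(a, "IMS:1000103"))
      if (is.na(off) || is.na(len)) {
        abort(paste0("malformed binary array in spectrum index ", i - 1))
      }
      if (identical(ref, "mzArray")) {
        mz_list[[i]] <- read_array(off, len, 8)
      } else if (identical(ref, "intensityArray")) {
        int_list[[i]] <- read_array(off, len, 4)
      }
    }
    if (is.null(mz_list[[i]]) || is.null(int_list[[i]])) {
      abort(paste0("spectrum index ", i - 1, " lacks m/z or intensity array"))
    }
    if (is.unsorted(mz_list[[i]], strictly = TRUE)) {
      abort(paste0("m/z not strictly increasing in spectrum index ", i - 1))
    }
  }

  if (mode == "continuous") {
    mz <- mz_list[[1]]
    Y <- do.call(rbind, int_list)
  } else {
    mz <- mz_out %||% {
      rng <- range(unlist(lapply(mz_list, range)))
      step <- median(diff(mz_list[[1]]))
      seq(rng[1], rng[2], by = step)
    }
    Y <- t(vapply(seq_len(n), function(i) {
      stats::approx(mz_list[[i]], int_list[[i]], xout = mz,
                    yleft = 0, yright = 0)$y
    }, numeric(length(mz))))
  }
  list(mz = mz, intensity = Y, coords = coords, mode = mode)
}
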