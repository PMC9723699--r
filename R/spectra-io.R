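## Reading and writing spectra, peak tables, metadata and feature matrices.
## All tables are tab-separated UTF-8 with a required header; '#' lines are
## provenance comments and are skipped on read. Collections are canonically
## sorted by (isolate_id, replicate) after load so file order never matters.

#' Read MALDI-TOF spectra from an mzML file
#'
#' Reads every MS1 acquisition in an mzML file through \pkg{mzR} and tags it
#' with the requested acquisition mode. Isolate id and replicate number are
#' parsed from the spectrum id with a configurable regular expression with
#' named capture groups `isolate` and `replicate`.
#'
#' @param path path to an mzML file.
#' @param mode `"protein"` or `"sm"`.
#' @param idPattern PCRE with named groups `isolate` and `replicate`;
#'   the default expects ids like `iso7_rep2`. Deposited naming schemes
#'   vary, so override per dataset.
#' @return list of [MaldiSpectrum-class], sorted by (isolate, replicate).
#'   Acquisitions with zero points are kept (empty arrays) and reported via
#'   a message.
#' @export
readMzml <- function(path, mode = c("protein", "sm"),
                     idPattern = "(?<isolate>.+)_rep(?<replicate>[0-9]+)") {
  mode <- match.arg(mode)
  if (!file.exists(path)) stop("no such file: ", path)
  ms <- tryCatch(mzR::openMSfile(path),
                 error = function(e) stop("malformed mzML '", path, "': ",
                                          conditionMessage(e)))
  on.exit(try(close(ms), silent = TRUE))
  hd <- suppressWarnings(mzR::header(ms))
  ids <- as.character(hd$spectrumId)
  m <- regexpr(idPattern, ids, perl = TRUE)
  if (any(m == -1L))
    stop("spectrum id(s) not matching idPattern in '", path, "': ",
         paste(ids[m == -1L], collapse = ", "))
  cs <- attr(m, "capture.start"); cl <- attr(m, "capture.length")
  isolate <- substr(ids, cs[, "isolate"], cs[, "isolate"] + cl[, "isolate"] - 1L)
  replicate <- as.integer(substr(ids, cs[, "replicate"],
                                 cs[, "replicate"] + cl[, "replicate"] - 1L))
  out <- vector("list", nrow(hd))
  nEmpty <- 0L
  for (i in seq_len(nrow(hd))) {
    p <- mzR::peaks(ms, hd$seqNum[i])
    if (is.null(dim(p)) || nrow(p) == 0L) {
      p <- matrix(numeric(0), ncol = 2)
      nEmpty <- nEmpty + 1L
    }
    o <- order(p[, 1])
    out[[i]] <- MaldiSpectrum(isolate[i], replicate[i], mode,
                              p[o, 1], p[o, 2])
  }
  if (nEmpty) message(nEmpty, " empty spectrum(s) in ", basename(path))
  out[order(isolate, replicate)]
}

#' Write spectra to a minimal mzML file
#'
#' Emits a standards-shaped mzML document (64-bit little-endian floats, no
#' compression, spectrum ids `<isolate>_rep<replicate>`) that reads back
#' identically through [readMzml()]. Intended for fixtures written by the
#' synthetic-data generator; it is not a general-purpose mzML exporter.
#'
#' @param spectra list of [MaldiSpectrum-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeMzml <- function(spectra, path) {
  enc64 <- function(x) {
    raw <- writeBin(as.double(x), raw(), size = 8, endian = "little")
    gsub("[\r\n]", "", jsonlite::base64_enc(raw))
  }
  specs <- vapply(seq_along(spectra), function(i) {
    s <- spectra[[i]]
    id <- sprintf("%s_rep%d", s@isolateId, s@replicate)
    mzb <- enc64(s@mz); inb <- enc64(s@intensity)
    sprintf(paste0(
      '<spectrum index="%d" id="%s" defaultArrayLength="%d">',
      '<cvParam cvRef="MS" accession="MS:1000511" name="ms level" value="1"/>',
      '<cvParam cvRef="MS" accession="MS:1000294" name="mass spectrum" value=""/>',
      '<cvParam cvRef="MS" accession="MS:1000127" name="centroid spectrum" value=""/>',
      '<binaryDataArrayList count="2">',
      '<binaryDataArray encodedLength="%d">',
      '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>',
      '<cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>',
      '<cvParam cvRef="MS" accession="MS:1000514" name="m/z array" value="" unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"/>',
      '<binary>%s</binary></binaryDataArray>',
      '<binaryDataArray encodedLength="%d">',
      '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>',
      '<cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>',
      '<cvParam cvRef="MS" accession="MS:1000515" name="intensity array" value="" unitCvRef="MS" unitAccession="MS:1000131" unitName="number of detector counts"/>',
      '<binary>%s</binary></binaryDataArray>',
      '</binaryDataArrayList></spectrum>'),
      i - 1L, id, length(s@mz), nchar(mzb), mzb, nchar(inb), inb)
  }, character(1))
  xml <- paste0(
    '<?xml version="1.0" encoding="utf-8"?>',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">',
    '<cvList count="2">',
    '<cv id="MS" fullName="Proteomics Standards Initiative Mass Spectrometry Ontology" URI="https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo"/>',
    '<cv id="UO" fullName="Unit Ontology" URI="https://raw.githubusercontent.com/bio-ontology-research-group/unit-ontology/master/unit.obo"/>',
    '</cvList>',
    '<fileDescription><fileContent>',
    '<cvParam cvRef="MS" accession="MS:1000579" name="MS1 spectrum" value=""/>',
    '</fileContent></fileDescription>',
    '<softwareList count="1"><software id="spectrotype" version="0.1"/></softwareList>',
    '<instrumentConfigurationList count="1"><instrumentConfiguration id="IC1"/></instrumentConfigurationList>',
    '<dataProcessingList count="1"><dataProcessing id="dp1">',
    '<processingMethod order="1" softwareRef="spectrotype">',
    '<cvParam cvRef="MS" accession="MS:1000544" name="Conversion to mzML" value=""/>',
    '</processingMethod></dataProcessing></dataProcessingList>',
    '<run id="run1" defaultInstrumentConfigurationRef="IC1">',
    sprintf('<spectrumList count="%d" defaultDataProcessingRef="dp1">',
            length(spectra)),
    paste0(specs, collapse = ''),
    '</spectrumList></run></mzML>')
  writeLines(xml, path)
  invisible(path)
}

#' Read a peak table
#'
#' Tab-separated text with columns `isolate_id`, `replicate`, `mz`,
#' `intensity` and optionally `snr`. Missing `snr` defaults to the `Inf`
#' sentinel (passes any SNR filter). Rows are sorted on load; duplicate
#' (isolate, replicate, mz) rows are an error.
#'
#' @param path input path.
#' @param mode `"protein"` or `"sm"`.
#' @return a [PeakSet-class].
#' @export
readPeakTable <- function(path, mode = c("protein", "sm")) {
  mode <- match.arg(mode)
  df <- readTsv(path)
  need <- c("isolate_id", "replicate", "mz", "intensity")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("peak table '", path, "' missing column(s): ",
         paste(miss, collapse = ", "))
  for (col in c("replicate", "mz", "intensity")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (anyNA(v) && !anyNA(df[[col]])) {
      bad <- which(is.na(v))
      stop("non-numeric ", col, " in '", path, "' at data row(s): ",
           paste(utils::head(bad, 5), collapse = ", "))
    }
    df[[col]] <- v
  }
  key <- paste(df$isolate_id, df$replicate, df$mz)
  if (anyDuplicated(key)) {
    dups <- unique(key[duplicated(key)])
    stop("duplicate (isolate, replicate, mz) rows: ",
         paste(utils::head(dups, 5), collapse = "; "))
  }
  PeakSet(df, mode)
}

#' Write a peak table
#' @param x a [PeakSet-class].
#' @param path output path.
#' @param comment optional provenance line written as a '#' header.
#' @return `path`, invisibly.
#' @export
writePeakTable <- function(x, path, comment = NULL) {
  stopifnot(is(x, "PeakSet"))
  df <- x@peaks
  df$mz <- sprintf("%.6f", df$mz)
  df$intensity <- sprintf("%.6g", df$intensity)
  df$snr <- ifelse(is.finite(df$snr), sprintf("%.4g", df$snr), "Inf")
  writeTsv(df, path, comment)
}

#' Read and validate isolate metadata
#'
#' One row per isolate with columns `isolate_id`, `source` (host A/B),
#' `plate_id`, `media`, `pretreatment` (`none`/`heat`) and `dilution`
#' (`0`, `1/10`, `1/100`), plus optional `genus`. A plate id must map to a
#' single (source, media, pretreatment, dilution) combination.
#'
#' @param path input path.
#' @return data.frame of validated metadata, sorted by isolate id.
#' @export
readMetadata <- function(path) {
  df <- readTsv(path, colClasses = "character")
  need <- c("isolate_id", "source", "plate_id", "media", "pretreatment",
            "dilution")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("metadata '", path, "' missing column(s): ",
         paste(miss, collapse = ", "))
  validateMetadata(df)
}

#' Validate an isolate metadata data.frame
#'
#' @param df data.frame as described in [readMetadata()].
#' @return the validated data.frame, sorted by isolate id.
#' @export
validateMetadata <- function(df) {
  if (anyDuplicated(df$isolate_id))
    stop("duplicate isolate_id: ",
         paste(unique(df$isolate_id[duplicated(df$isolate_id)]), collapse = ", "))
  badP <- setdiff(unique(df$pretreatment), c("none", "heat"))
  if (length(badP)) stop("unknown pretreatment token(s): ",
                         paste(badP, collapse = ", "))
  badD <- setdiff(unique(df$dilution), c("0", "1/10", "1/100"))
  if (length(badD)) stop("unknown dilution token(s): ",
                         paste(badD, collapse = ", "))
  combo <- paste(df$source, df$media, df$pretreatment, df$dilution)
  byPlate <- split(combo, df$plate_id)
  bad <- names(byPlate)[vapply(byPlate, function(v) length(unique(v)) > 1L,
                               logical(1))]
  if (length(bad))
    stop("plate_id maps to multiple conditions: ", paste(bad, collapse = ", "))
  df <- df[order(df$isolate_id), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Cross-check metadata against loaded spectra
#'
#' Isolates present in metadata but carrying no spectra (or vice versa) are
#' reported as a warning, not a failure.
#'
#' @param meta metadata data.frame.
#' @param peakSet a [PeakSet-class] (or character vector of isolate ids).
#' @return invisibly, the number of metadata isolates without spectra.
#' @export
checkMetadataCoverage <- function(meta, peakSet) {
  ids <- if (is.character(peakSet)) peakSet else isolateIds(peakSet)
  noSpec <- setdiff(meta$isolate_id, ids)
  noMeta <- setdiff(ids, meta$isolate_id)
  if (length(noSpec))
    warning(length(noSpec), " isolate(s) in metadata without spectra: ",
            paste(utils::head(noSpec, 5), collapse = ", "), call. = FALSE)
  if (length(noMeta))
    warning(length(noMeta), " isolate(s) with spectra but no metadata: ",
            paste(utils::head(noMeta, 5), collapse = ", "), call. = FALSE)
  invisible(length(noSpec))
}

#' Write / read a feature matrix as TSV
#'
#' Lossless round trip of isolate ids, bin reference m/z (>= 6 significant
#' digits preserved; `%.10g` is used) and values. First column is
#' `isolate_id`; remaining column names encode the bin m/z as `mz_<value>`.
#'
#' @param x a [FeatureMatrix-class].
#' @param path file path.
#' @param comment optional provenance line written as a '#' header.
#' @return `path` (write) or a [FeatureMatrix-class] (read).
#' @export
writeFeatureMatrix <- function(x, path, comment = NULL) {
  stopifnot(is(x, "FeatureMatrix"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  writeLines(paste0("# mode=", x@msMode), con)
  header <- c("isolate_id", sprintf("mz_%.17g", x@bins))
  writeLines(paste(header, collapse = "\t"), con)
  v <- x@values
  for (i in seq_len(nrow(v)))
    writeLines(paste(c(rownames(v)[i], sprintf("%.10g", v[i, ])),
                     collapse = "\t"), con)
  invisible(path)
}

#' @rdname writeFeatureMatrix
#' @export
readFeatureMatrix <- function(path) {
  lines <- readLines(path)
  modeLine <- grep("^# mode=", lines, value = TRUE)
  mode <- if (length(modeLine)) sub("^# mode=", "", modeLine[1]) else "protein"
  lines <- lines[!startsWith(lines, "#")]
  if (!length(lines)) stop("empty feature matrix file: ", path)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (header[1] != "isolate_id")
    stop("feature matrix '", path, "': first column must be isolate_id")
  bins <- as.numeric(sub("^mz_", "", header[-1]))
  if (anyNA(bins)) stop("unparseable bin header in '", path, "'")
  body <- strsplit(lines[-1], "\t", fixed = TRUE)
  nc <- lengths(body)
  if (any(nc != length(header)))
    stop("row length mismatch in '", path, "' at data row(s): ",
         paste(utils::head(which(nc != length(header)), 5), collapse = ", "))
  ids <- vapply(body, `[`, character(1), 1L)
  v <- matrix(0, nrow = length(body), ncol = length(bins),
              dimnames = list(ids, NULL))
  for (i in seq_along(body)) v[i, ] <- as.numeric(body[[i]][-1L])
  if (anyNA(v)) stop("non-numeric value in '", path, "'")
  FeatureMatrix(v, bins, mode)
}

#' Write a partition as TSV
#'
#' Columns: isolate_id, group_id, method, parameter.
#'
#' @param p an [IsolatePartition-class].
#' @param path output path.
#' @param comment optional provenance line.
#' @return `path`, invisibly.
#' @export
writePartition <- function(p, path, comment = NULL) {
  stopifnot(is(p, "IsolatePartition"))
  a <- groupAssignments(p)
  df <- data.frame(isolate_id = names(a), group_id = unname(a),
                   method = p@method,
                   parameter = paste(unlist(p@parameter), collapse = ","),
                   stringsAsFactors = FALSE)
  writeTsv(df[order(df$isolate_id), ], path, comment)
}
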