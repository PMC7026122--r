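## Minimal mzML 1.1 support: centroided spectra, 64-bit (or 32-bit) float
## arrays, no compression. Covers what the engine needs; vendor conversion
## tools produce files of this shape.

.decode_binary <- function(b64, size) {
  raw <- jsonlite::base64_dec(gsub("[[:space:]]", "", b64))
  readBin(raw, "double", n = length(raw) / size, size = size, endian = "little")
}

.encode_binary <- function(x) {
  jsonlite::base64_enc(writeBin(as.numeric(x), raw(), size = 8, endian = "little"))
}

#' Read an mzML file
#'
#' Parses centroided spectra of the requested MS levels. MS2 spectra carry
#' their native id, retention time (seconds), precursor m/z and charge;
#' spectra declared as profile data are rejected, and MS2 spectra without a
#' precursor are skipped with a warning. Negative polarity is asserted
#' (this engine is negative-mode only).
#'
#' @param path Path to an mzML file.
#' @param ms_levels Integer vector of MS levels to load (default `c(1, 2)`).
#' @return An `ms_run`: list with `ms1` (list of MS1 scans: `native_id`,
#'   `rt`, `mz`, `intensity`) and `ms2` (list of [ms2_spectrum()]).
#' @export
read_mzml <- function(path, ms_levels = c(1L, 2L)) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  nodes <- xml2::xml_find_all(doc, ".//spectrumList/spectrum")
  run <- list(ms1 = list(), ms2 = list())
  cv <- function(node, acc) {
    xml2::xml_find_first(node, sprintf(".//cvParam[@accession='%s']", acc))
  }
  cv_value <- function(node, acc) {
    n <- cv(node, acc)
    if (inherits(n, "xml_missing")) NA_character_ else xml2::xml_attr(n, "value")
  }
  for (sp in nodes) {
    level <- as.integer(cv_value(sp, "MS:1000511"))
    if (is.na(level) || !level %in% ms_levels) next
    if (!inherits(cv(sp, "MS:1000128"), "xml_missing")) {
      stop("profile-mode spectrum found; centroided data required: ",
           xml2::xml_attr(sp, "id"))
    }
    if (!inherits(cv(sp, "MS:1000130"), "xml_missing")) {
      stop("positive-polarity spectrum found; this engine is negative-mode only")
    }
    native_id <- xml2::xml_attr(sp, "id")
    rt_node <- xml2::xml_find_first(sp, ".//scanList/scan/cvParam[@accession='MS:1000016']")
    rt <- NA_real_
    if (!inherits(rt_node, "xml_missing")) {
      rt <- as.numeric(xml2::xml_attr(rt_node, "value"))
      unit <- xml2::xml_attr(rt_node, "unitName")
      if (!is.na(unit) && unit == "minute") rt <- rt * 60
    }
    arrays <- xml2::xml_find_all(sp, ".//binaryDataArray")
    mz <- numeric(); inten <- numeric()
    for (arr in arrays) {
      size <- if (!inherits(cv(arr, "MS:1000523"), "xml_missing")) 8L
              else if (!inherits(cv(arr, "MS:1000521"), "xml_missing")) 4L
              else stop("unsupported binary data encoding in ", native_id)
      if (!inherits(cv(arr, "MS:1000574"), "xml_missing")) {
        stop("compressed binary data not supported (write without compression)")
      }
      vals <- .decode_binary(xml2::xml_text(xml2::xml_find_first(arr, ".//binary")),
                             size)
      if (!inherits(cv(arr, "MS:1000514"), "xml_missing")) mz <- vals
      if (!inherits(cv(arr, "MS:1000515"), "xml_missing")) inten <- vals
    }
    if (level == 1L) {
      run$ms1[[length(run$ms1) + 1L]] <-
        list(native_id = native_id, rt = rt, mz = mz, intensity = inten)
    } else {
      ion <- xml2::xml_find_first(sp, ".//precursorList/precursor//selectedIon")
      if (inherits(ion, "xml_missing")) {
        warning("MS2 spectrum without precursor skipped: ", native_id)
        next
      }
      pmz <- as.numeric(cv_value(ion, "MS:1000744"))
      z <- suppressWarnings(as.integer(cv_value(ion, "MS:1000041")))
      if (is.na(z)) z <- 0L
      if (z > 0) z <- -z  # charge magnitude in a negative-mode file
      run$ms2[[length(run$ms2) + 1L]] <-
        ms2_spectrum(native_id, rt, pmz, z, mz, inten)
    }
  }
  structure(run, class = "ms_run")
}

#' @export
print.ms_run <- function(x, ...) {
  cat("<ms_run> ", length(x$ms1), " MS1 + ", length(x$ms2), " MS2 spectra\n",
      sep = "")
  invisible(x)
}

#' Write an `ms_run` to a minimal mzML file
#'
#' Emits uncompressed 64-bit float peak arrays and the cvParams the reader
#' (and typical downstream tools) need. Used by the simulator and for
#' fixtures; not a full mzML implementation.
#'
#' @param run An `ms_run` (see [read_mzml()]).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_mzml <- function(run, path) {
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  esc <- function(x) gsub("&", "&amp;", gsub("<", "&lt;", x, fixed = TRUE), fixed = TRUE)
  all_spectra <- c(lapply(run$ms1, function(s) c(s, list(level = 1L))),
                   lapply(run$ms2, function(s) c(unclass(s), list(level = 2L))))
  # interleave by retention time so the file is RT-ordered like a real run
  rts <- vapply(all_spectra, function(s) s$rt, 0)
  all_spectra <- all_spectra[order(rts)]
  w('<?xml version="1.0" encoding="utf-8"?>')
  w('<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">')
  w('  <run id="run" defaultInstrumentConfigurationRef="IC1">')
  w('    <spectrumList count="', length(all_spectra), '">')
  for (i in seq_along(all_spectra)) {
    s <- all_spectra[[i]]
    w('      <spectrum index="', i - 1L, '" id="', esc(s$native_id),
      '" defaultArrayLength="', length(s$mz), '">')
    w('        <cvParam cvRef="MS" accession="MS:1000511" name="ms level" value="',
      s$level, '"/>')
    w('        <cvParam cvRef="MS" accession="MS:1000129" name="negative scan"/>')
    w('        <cvParam cvRef="MS" accession="MS:1000127" name="centroid spectrum"/>')
    w('        <scanList count="1"><scan>')
    w('          <cvParam cvRef="MS" accession="MS:1000016" name="scan start time" value="',
      format(s$rt, digits = 12), '" unitName="second"/>')
    w('        </scan></scanList>')
    if (s$level == 2L) {
      w('        <precursorList count="1"><precursor><selectedIonList count="1"><selectedIon>')
      w('          <cvParam cvRef="MS" accession="MS:1000744" name="selected ion m/z" value="',
        format(s$precursor_mz, digits = 15), '"/>')
      if (!is.null(s$precursor_charge) && s$precursor_charge != 0L) {
        w('          <cvParam cvRef="MS" accession="MS:1000041" name="charge state" value="',
          s$precursor_charge, '"/>')
      }
      w('        </selectedIon></selectedIonList></precursor></precursorList>')
    }
    w('        <binaryDataArrayList count="2">')
    for (arr in list(list(acc = "MS:1000514", name = "m/z array", data = s$mz),
                     list(acc = "MS:1000515", name = "intensity array",
                          data = s$intensity))) {
      enc <- .encode_binary(arr$data)
      w('          <binaryDataArray encodedLength="', nchar(enc), '">')
      w('            <cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/>')
      w('            <cvParam cvRef="MS" accession="MS:1000576" name="no compression"/>')
      w('            <cvParam cvRef="MS" accession="', arr$acc, '" name="', arr$name, '"/>')
      w('            <binary>', enc, '</binary>')
      w('          </binaryDataArray>')
    }
    w('        </binaryDataArrayList>')
    w('      </spectrum>')
  }
  w('    </spectrumList>')
  w('  </run>')
  w('</mzML>')
  invisible(path)
}
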