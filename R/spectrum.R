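#' Construct an MS2 spectrum
#'
#' A centroided peak list with precursor metadata. Peaks are stored sorted
#' by m/z. Charges are negative (negative ion mode); a precursor charge of
#' 0 means "unknown" and makes the search iterate over its configured
#' charge range.
#'
#' @param native_id Spectrum identifier (string).
#' @param rt Retention time in seconds.
#' @param precursor_mz Selected-ion m/z.
#' @param precursor_charge Negative integer, or 0 if unknown.
#' @param mz,intensity Numeric peak vectors of equal length.
#' @return An `ms2_spectrum` object.
#' @export
ms2_spectrum <- function(native_id, rt, precursor_mz, precursor_charge,
                         mz = numeric(), intensity = numeric()) {
  stopifnot(length(mz) == length(intensity), all(mz > 0), all(intensity >= 0))
  if (precursor_charge > 0) stop("precursor charge must be negative (or 0 = unknown)")
  ord <- order(mz)
  structure(list(native_id = as.character(native_id), rt = as.numeric(rt),
                 precursor_mz = as.numeric(precursor_mz),
                 precursor_charge = as.integer(precursor_charge),
                 mz = mz[ord], intensity = intensity[ord],
                 peak_charge = rep(NA_integer_, length(mz))),
            class = "ms2_spectrum")
}

#' @export
print.ms2_spectrum <- function(x, ...) {
  cat("<ms2_spectrum> ", x$native_id, ": ", length(x$mz), " peaks, precursor ",
      sprintf("%.4f", x$precursor_mz), " Th (z=", x$precursor_charge,
      "), RT ", sprintf("%.1f", x$rt), " s\n", sep = "")
  invisible(x)
}

#' Intensity filtering of a peak list
#'
#' `relative_threshold` keeps peaks with intensity at least `threshold`
#' times the base-peak intensity; `top_n_per_100Th` keeps the `threshold`
#' most intense peaks per 100-Th window. Both are idempotent.
#'
#' @param spectrum An `ms2_spectrum`.
#' @param mode `"relative_threshold"` or `"top_n_per_100Th"`.
#' @param threshold Relative intensity in \[0, 1\], or the per-window peak
#'   count, depending on `mode`.
#' @return The filtered spectrum.
#' @export
filter_peaks <- function(spectrum, mode = c("relative_threshold", "top_n_per_100Th"),
                         threshold = 0) {
  mode <- match.arg(mode)
  if (!length(spectrum$mz)) return(spectrum)
  keep <- switch(mode,
    relative_threshold = spectrum$intensity >= threshold * max(spectrum$intensity),
    top_n_per_100Th = {
      win <- floor(spectrum$mz / 100)
      k <- logical(length(spectrum$mz))
      for (w in unique(win)) {
        i <- which(win == w)
        k[i[rank(-spectrum$intensity[i], ties.method = "first") <= threshold]] <- TRUE
      }
      k
    }
  )
  spectrum$mz <- spectrum$mz[keep]
  spectrum$intensity <- spectrum$intensity[keep]
  spectrum$peak_charge <- spectrum$peak_charge[keep]
  spectrum
}

#' Collapse isotopic envelopes to monoisotopic peaks
#'
#' Scans peaks in order of increasing m/z. A series of peaks spaced by
#' 1.00335/z (the C13-C12 mass difference over the charge) within the given
#' tolerance, with non-increasing intensities beyond the first member, is
#' collapsed onto its lightest peak, whose intensity becomes the cluster sum
#' and which is annotated with the inferred charge magnitude. Peaks outside
#' any envelope are kept with unknown charge.
#'
#' @param spectrum An `ms2_spectrum`.
#' @param fragment_tol_ppm Matching tolerance for the expected spacing.
#' @param max_charge Largest fragment charge magnitude to consider.
#' @return The deisotoped spectrum (`peak_charge` holds inferred charges).
#' @export
deisotope <- function(spectrum, fragment_tol_ppm = 10, max_charge = 4L) {
  stopifnot(max_charge >= 1)
  n <- length(spectrum$mz)
  if (n < 2) return(spectrum)
  mz <- spectrum$mz; inten <- spectrum$intensity
  used <- logical(n)
  keep_mz <- numeric(); keep_int <- numeric(); keep_z <- integer()
  for (i in seq_len(n)) {
    if (used[i]) next
    best_chain <- integer(); best_z <- NA_integer_
    for (z in seq_len(max_charge)) {
      spacing <- mass_constants[["c13_spacing"]] / z
      chain <- i
      cur <- i
      repeat {
        target <- mz[cur] + spacing
        tol <- target * fragment_tol_ppm * 1e-6
        cand <- which(!used & mz >= target - tol & mz <= target + tol)
        if (!length(cand)) break
        nxt <- cand[which.min(abs(mz[cand] - target))]
        # beyond the first member intensities must not increase
        if (length(chain) >= 2 && inten[nxt] > inten[cur]) break
        chain <- c(chain, nxt)
        cur <- nxt
      }
      if (length(chain) > length(best_chain)) { best_chain <- chain; best_z <- z }
    }
    if (length(best_chain) >= 2) {
      used[best_chain] <- TRUE
      keep_mz <- c(keep_mz, mz[i])
      keep_int <- c(keep_int, sum(inten[best_chain]))
      keep_z <- c(keep_z, best_z)
    } else {
      used[i] <- TRUE
      keep_mz <- c(keep_mz, mz[i])
      keep_int <- c(keep_int, inten[i])
      keep_z <- c(keep_z, NA_integer_)
    }
  }
  ord <- order(keep_mz)
  spectrum$mz <- keep_mz[ord]
  spectrum$intensity <- keep_int[ord]
  spectrum$peak_charge <- keep_z[ord]
  spectrum
}
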