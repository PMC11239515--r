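# Quality-control metrics: temporal SNR, DVARS and Pearson correlation to
# the reference, globally and within ROI masks.

#' Temporal signal-to-noise ratio
#'
#' Per voxel, the temporal mean divided by the temporal standard deviation
#' (sample SD, denominator nt - 1); voxels with zero temporal SD map to 0
#' by convention. A better motion correction leaves a steadier time course
#' and thus a higher tSNR.
#'
#' @param series a [VolumeSeries-class] with at least 2 volumes
#' @param mask optional [RoiMask-class] restricting the reported mean
#' @return list with `map` (3D tSNR map) and `mean` (over the mask, or all
#'   voxels when no mask)
#' @export
tsnr <- function(series, mask = NULL) {
  stopifnot(is(series, "VolumeSeries"))
  d <- series@data
  dm <- dim(d)
  if (dm[4] < 2) stop("tSNR needs at least 2 volumes")
  m <- matrix(d, ncol = dm[4])
  mu <- rowMeans(m)
  sdv <- sqrt(pmax(0, (rowSums(m^2) - dm[4] * mu^2) / (dm[4] - 1)))
  tmap <- ifelse(sdv > 1e-12, mu / sdv, 0)
  tmap <- array(tmap, dm[1:3])
  mn <- if (is.null(mask)) mean(tmap) else {
    if (!all(dim(mask@data) == dm[1:3])) stop("mask grid mismatch")
    mean(tmap[mask@data > 0])
  }
  list(map = tmap, mean = mn)
}

#' DVARS: RMS frame-to-frame intensity change
#'
#' For frames i = 2..nt, the root mean square over all voxels of
#' `I_i - I_{i-1}`, computed on min-max normalized data so values are
#' comparable across correction methods. Zero means perfectly steady
#' consecutive frames; lower is better.
#'
#' @param series a min-max normalized [VolumeSeries-class], nt >= 2
#' @param requireNormalized refuse raw series (default TRUE); set FALSE to
#'   evaluate the bare RMS-difference formula on raw intensities
#' @return list with `series` (length nt - 1) and `mean`
#' @export
dvars <- function(series, requireNormalized = TRUE) {
  stopifnot(is(series, "VolumeSeries"))
  if (requireNormalized && series@normalized != "minmax")
    stop("DVARS is computed on min-max normalized data; normalize first")
  d <- series@data
  nt <- dim(d)[4]
  if (nt < 2) stop("DVARS needs at least 2 volumes")
  vals <- vapply(2:nt, function(i)
    sqrt(mean((d[, , , i] - d[, , , i - 1])^2)), numeric(1))
  list(series = vals, mean = mean(vals))
}

#' Per-volume Pearson correlation to a reference volume
#'
#' @param series a [VolumeSeries-class]
#' @param reference 3D array on the series' spatial grid
#' @return list with `series` (per-volume r), `mean`, and `degenerate`
#'   (logical: volumes, or the reference, that were constant and scored 0)
#' @export
volumeCC <- function(series, reference) {
  d <- series@data
  dm <- dim(d)
  if (!all(dim(reference) == dm[1:3])) stop("reference grid mismatch")
  rv <- as.vector(reference)
  refConst <- sd(rv) == 0
  if (refConst) warning("constant reference: correlations undefined, set to 0")
  nt <- dm[4]
  vals <- numeric(nt)
  degen <- logical(nt)
  for (t in seq_len(nt)) {
    v <- as.vector(d[, , , t])
    if (refConst || sd(v) == 0) {
      vals[t] <- 0; degen[t] <- TRUE
      if (!refConst) warning("constant volume ", t, ": correlation set to 0")
    } else {
      vals[t] <- cor(v, rv)
    }
  }
  list(series = vals, mean = mean(vals), degenerate = degen | refConst)
}

buildQcReport <- function(series, cordMask, csfMask, referencePolicy,
                          label) {
  ts <- tsnr(series)
  tm <- c(global = ts$mean)
  if (!is.null(cordMask)) tm["cord"] <- tsnr(series, cordMask)$mean
  if (!is.null(csfMask)) tm["csf"] <- tsnr(series, csfMask)$mean
  dv <- dvars(series)
  ref <- selectReference(series, referencePolicy)
  cc <- volumeCC(series, ref)
  new("QCReport", tsnrMap = ts$map, tsnrMean = tm,
      dvarsSeries = dv$series, dvarsMean = dv$mean,
      ccSeries = cc$series, ccMean = cc$mean,
      provenance = list(method = label, referencePolicy = referencePolicy))
}

#' Compare raw and corrected series
#'
#' Computes full QC reports for both series on identical grids and returns
#' them with a tidy comparison table (method x metric x ROI).
#'
#' @param raw,corrected min-max normalized [VolumeSeries-class] on the same
#'   grid
#' @param cordMask,csfMask optional [RoiMask-class]
#' @param referencePolicy reference-volume policy for the correlation metric
#' @return list with `raw`, `corrected` ([QCReport-class]) and `table`
#'   (data.frame: method, metric, roi, value)
#' @export
qcReport <- function(raw, corrected, cordMask = NULL, csfMask = NULL,
                     referencePolicy = c("first", "mid", "mean")) {
  referencePolicy <- match.arg(referencePolicy)
  if (!all(dim(raw@data) == dim(corrected@data)))
    stop("raw and corrected series are on different grids")
  rep1 <- buildQcReport(raw, cordMask, csfMask, referencePolicy, "raw")
  rep2 <- buildQcReport(corrected, cordMask, csfMask, referencePolicy,
                        "corrected")
  rows <- function(r, method) {
    out <- data.frame(method = method, metric = "tsnr",
                      roi = names(r@tsnrMean),
                      value = unname(r@tsnrMean))
    rbind(out,
          data.frame(method = method, metric = "dvars", roi = "global",
                     value = r@dvarsMean),
          data.frame(method = method, metric = "cc", roi = "global",
                     value = r@ccMean))
  }
  list(raw = rep1, corrected = rep2,
       table = rbind(rows(rep1, "raw"), rows(rep2, "corrected")))
}

#' Write / read a QC comparison table as CSV
#' @param table the data.frame from [qcReport()]
#' @param path CSV path
#' @return `writeQcCsv`: invisibly, the path; `readQcCsv`: the data.frame
#' @export
writeQcCsv <- function(table, path) {
  utils::write.csv(format(table, digits = 15, scientific = FALSE,
                          trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeQcCsv
#' @export
readQcCsv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$value <- as.numeric(df$value)
  df
}

#' Write a tSNR map as NIfTI
#' @param map 3D tSNR array
#' @param path output path
#' @param affine optional 4x4 affine
#' @return invisibly, the path
#' @export
writeTsnrNifti <- function(map, path, affine = NULL) {
  if (is.null(affine)) affine <- diag(4)
  img <- RNifti::asNifti(array(map, dim(map)))
  img <- RNifti::`sform<-`(img, structure(affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}
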