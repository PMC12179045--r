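# Published reference results on the four public vessel benchmarks, shipped
# so that headline improvements of the distilled student over the plain
# U-Net baseline can be recomputed from the printed rows.

#' Published benchmark rows (percent scale)
#'
#' Reference test-set metrics of the baseline U-Net and of the multi-teacher
#' distilled student (plain, and with loss penalization, "LP") on the four
#' public vessel segmentation benchmarks: DRIVE and CHASEDB1 (retinal
#' fundus) and CHUAC and DCA1 (coronary angiography).
#'
#' @return data.frame with columns `dataset`, `method`, `ACC`, `SEN`,
#'   `SPE`, `F1`, `IOU` (percent).
#' @export
published_benchmarks <- function() {
  rbind(
    data.frame(dataset = "DRIVE", method = "U-Net",
               ACC = 96.78, SEN = 80.57, SPE = 98.33, F1 = 81.41, IOU = 68.64),
    data.frame(dataset = "DRIVE", method = "MTKD-UNet",
               ACC = 96.72, SEN = 80.22, SPE = 98.32, F1 = 80.74, IOU = 67.82),
    data.frame(dataset = "DRIVE", method = "MTKD-UNet-LP",
               ACC = 96.93, SEN = 79.54, SPE = 98.60, F1 = 81.66, IOU = 69.08),
    data.frame(dataset = "CHASEDB1", method = "U-Net",
               ACC = 97.43, SEN = 76.50, SPE = 98.84, F1 = 78.98, IOU = 65.26),
    data.frame(dataset = "CHASEDB1", method = "MTKD-UNet",
               ACC = 97.26, SEN = 74.90, SPE = 98.76, F1 = 77.48, IOU = 63.28),
    data.frame(dataset = "CHASEDB1", method = "MTKD-UNet-LP",
               ACC = 97.54, SEN = 78.09, SPE = 98.83, F1 = 79.95, IOU = 66.62),
    data.frame(dataset = "CHUAC", method = "U-Net",
               ACC = 97.84, SEN = 58.81, SPE = 99.40, F1 = 67.68, IOU = 51.15),
    data.frame(dataset = "CHUAC", method = "MTKD-UNet",
               ACC = 98.23, SEN = 73.33, SPE = 99.40, F1 = 76.02, IOU = 61.41),
    data.frame(dataset = "CHUAC", method = "MTKD-UNet-LP",
               ACC = 98.19, SEN = 75.34, SPE = 99.10, F1 = 76.12, IOU = 61.57),
    data.frame(dataset = "DCA1", method = "U-Net",
               ACC = 97.58, SEN = 78.16, SPE = 98.66, F1 = 77.35, IOU = 63.07),
    data.frame(dataset = "DCA1", method = "MTKD-UNet",
               ACC = 97.84, SEN = 80.19, SPE = 98.84, F1 = 79.38, IOU = 66.00),
    data.frame(dataset = "DCA1", method = "MTKD-UNet-LP",
               ACC = 97.79, SEN = 84.48, SPE = 98.54, F1 = 79.87, IOU = 66.63)
  )
}

#' Improvement of the distilled student over the U-Net baseline
#'
#' Recomputes, per dataset, the difference in a metric between a distilled
#' method and the plain U-Net baseline from the published rows; the maximum
#' over datasets is the headline "up to" improvement.
#'
#' @param metric metric column (`"F1"`, `"IOU"`, ...).
#' @param method distilled method to compare (default the penalized
#'   student).
#' @return data.frame with per-dataset improvements in percentage points.
#' @export
benchmark_improvement <- function(metric = "F1", method = "MTKD-UNet-LP") {
  tab <- published_benchmarks()
  datasets <- unique(tab$dataset)
  rows <- lapply(datasets, function(d) {
    base <- tab[tab$dataset == d & tab$method == "U-Net", metric]
    ours <- tab[tab$dataset == d & tab$method == method, metric]
    data.frame(dataset = d, baseline = base, distilled = ours,
               improvement = ours - base)
  })
  do.call(rbind, rows)
}
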