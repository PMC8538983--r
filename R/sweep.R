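#' Sampling-rate sweep benchmark
#'
#' For every combination of sampling rate, method and mask replicate:
#' draws an independent random mask, simulates the sparse acquisition of
#' the phantom, reconstructs, and computes PSNR and RLNE against the
#' full-scan reference. The mask seed for cell (rate index `ri`, replicate
#' `k`) is `baseSeed + 1000 * ri + k`, recorded in the output so the sweep
#' is reproducible bit-for-bit.
#'
#' @param phantom a [THzPhantom-class] or a reference image matrix.
#' @param rates sampling fractions in (0, 1].
#' @param methods subset of `c("hsm", "ssc")`.
#' @param nSeeds mask replicates per (rate, method) cell.
#' @param config a [SolverConfig-class] used for the hybrid method; the
#'   baseline runs the same settings through [sscConfig()] overrides.
#' @param baseSeed base of the mask-seed formula.
#' @return long-format `data.frame` with columns `method`, `rate`, `seed`,
#'   `psnr_db`, `rlne`.
#' @seealso [summarizeSweep()]
#' @export
runRateSweep <- function(phantom, rates = seq(0.1, 0.5, by = 0.1),
                         methods = c("hsm", "ssc"), nSeeds = 5L,
                         config = solverConfig(), baseSeed = 1L) {
  ref <- if (is(phantom, "THzPhantom")) phantom@image else phantom
  if (any(rates <= 0 | rates > 1)) stop("rates must lie in (0, 1]")
  methods <- match.arg(methods, c("hsm", "ssc"), several.ok = TRUE)
  sscCfg <- configFromList(utils::modifyList(
    configAsList(config), list(gamma = 0, baseA = 1, weighted = FALSE)))
  rows <- list()
  for (ri in seq_along(rates)) {
    for (k in seq_len(nSeeds)) {
      mseed <- as.integer(baseSeed + 1000L * ri + k)
      mask <- randomMask(dim(ref), rates[ri], seed = mseed)
      y <- measure(ref, mask)
      for (m in methods) {
        rec <- if (m == "hsm") reconstructHSM(y, mask, config)
               else reconstructSSC(y, mask, sscCfg)
        rows[[length(rows) + 1L]] <- data.frame(
          method = m, rate = rates[ri], seed = mseed,
          psnr_db = psnr(ref, reconImage(rec)),
          rlne = rlne(ref, reconImage(rec)))
      }
    }
  }
  do.call(rbind, rows)
}

#' Summarize a sweep table
#'
#' Mean and standard deviation of both metrics per (method, rate) cell.
#'
#' @param results a `data.frame` from [runRateSweep()].
#' @return `data.frame` with columns `method`, `rate`, `psnr_mean`,
#'   `psnr_sd`, `rlne_mean`, `rlne_sd`, `n`.
#' @export
summarizeSweep <- function(results) {
  agg <- function(f) stats::aggregate(
    cbind(psnr_db, rlne) ~ method + rate, data = results, FUN = f)
  m <- agg(mean); s <- agg(stats::sd); n <- agg(length)
  out <- data.frame(method = m$method, rate = m$rate,
                    psnr_mean = m$psnr_db, psnr_sd = s$psnr_db,
                    rlne_mean = m$rlne, rlne_sd = s$rlne, n = n$psnr_db)
  out[order(out$method, out$rate), , drop = FALSE]
}
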