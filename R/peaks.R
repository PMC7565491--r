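# Native vs reduced/alkylated peak pairing and cysteine counting.
# Peaks are plain data.frames (mz, intensity), mz increasing.

.PER_CYS_SHIFT <- .MASS_CAM + .MASS_H  # 58.0293 Da: one liberated thiol + CAM

.as_peaklist <- function(x) {
  if (is.numeric(x)) x <- data.frame(mz = x, intensity = rep(1, length(x)))
  if (!is.data.frame(x) || !all(c("mz", "intensity") %in% names(x)))
    stop("a peak list needs columns mz and intensity")
  if (any(x$intensity < 0)) stop("intensities must be non-negative")
  x <- x[order(x$mz), , drop = FALSE]
  rownames(x) <- NULL
  x
}

#' Infer a cysteine count from an alkylation mass shift
#'
#' Finds the integer `k` such that `delta` is within `tol` of
#' `k * per_cys_shift`, i.e. the number of cysteines explaining the observed
#' native-to-alkylated mass difference. The default per-cysteine shift,
#' 58.029 Da, is reduction (+1.008) plus carbamidomethylation (+57.021) and
#' applies to disulfide-oxidized native peptides; use 57.021 for free-thiol
#' species.
#'
#' @param delta observed mass shift(s) in Da (vectorized).
#' @param per_cys_shift Da per cysteine.
#' @param tol matching tolerance in Da.
#' @return integer vector; `NA` where no integer count matches within `tol`.
#' @examples
#' count_cys_from_shift(348.1)  # 6
#' @export
count_cys_from_shift <- function(delta, per_cys_shift = .PER_CYS_SHIFT,
                                 tol = 0.3) {
  if (tol <= 0) stop("tol must be positive")
  k <- round(delta / per_cys_shift)
  k[k < 0] <- 0L
  res <- abs(delta - k * per_cys_shift)
  ifelse(res <= tol, as.integer(k), NA_integer_)
}

#' Pair native and alkylated peaks and count cysteines
#'
#' For every native peak, reports each alkylated peak whose mass excess is
#' within `tol` of an integer multiple (1..`max_cys`) of the per-cysteine
#' shift. All matches are reported, ranked by absolute residual; the best
#' match per native peak is flagged `primary`. Ambiguous pairings are never
#' silently dropped.
#'
#' @param native,alkylated peak lists: data.frames with `mz`, `intensity`
#'   columns, or bare numeric m/z vectors.
#' @param per_cys_shift Da per cysteine (see [count_cys_from_shift()]).
#' @param max_cys largest cysteine count considered.
#' @param tol pairing tolerance in Da (default 0.3, covering the observed
#'   +-0.2 Da spread of MALDI calibration).
#' @return data.frame with columns `native_mz`, `alkylated_mz`, `delta`,
#'   `n_cys`, `residual`, `primary`.
#' @examples
#' pair_peaks(3734.2, 4082.3)
#' @export
pair_peaks <- function(native, alkylated, per_cys_shift = .PER_CYS_SHIFT,
                       max_cys = 20, tol = 0.3) {
  if (tol <= 0) stop("tol must be positive")
  native <- .as_peaklist(native)
  alkylated <- .as_peaklist(alkylated)
  out <- data.frame(native_mz = numeric(0), alkylated_mz = numeric(0),
                    delta = numeric(0), n_cys = integer(0),
                    residual = numeric(0), primary = logical(0))
  if (!nrow(native) || !nrow(alkylated)) return(out)
  rows <- vector("list", nrow(native))
  for (i in seq_len(nrow(native))) {
    d <- alkylated$mz - native$mz[i]
    k <- round(d / per_cys_shift)
    res <- d - k * per_cys_shift
    ok <- which(k >= 1 & k <= max_cys & abs(res) <= tol)
    if (!length(ok)) next
    ok <- ok[order(abs(res[ok]))]
    rows[[i]] <- data.frame(native_mz = native$mz[i],
                            alkylated_mz = alkylated$mz[ok],
                            delta = d[ok], n_cys = as.integer(k[ok]),
                            residual = res[ok],
                            primary = seq_along(ok) == 1L)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(out)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
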