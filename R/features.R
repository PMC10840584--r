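#' Alpha-band power per region
#'
#' Sums the dB-scale PSD over all grid frequencies in the closed alpha band
#' \[8, 12\] Hz, giving the spatial distribution of alpha power.
#'
#' @param psd_db N x F real matrix (regions x frequencies, dB).
#' @param grid `sgm_grid` matching the columns of `psd_db`.
#' @return Length-N numeric vector.
#' @export
alpha_band_power <- function(psd_db, grid) {
  in_band <- grid$frequencies_hz >= 8 & grid$frequencies_hz <= 12
  if (!any(in_band))
    stop("frequency grid has no point in the 8-12 Hz alpha band")
  rowSums(psd_db[, in_band, drop = FALSE])
}

#' Z-score the PSD along the frequency axis
#'
#' Each region's row is standardized to mean 0, sd 1 across its F
#' frequencies. The population convention (denominator n) is used for the
#' standard deviation throughout the package.
#'
#' @param psd_db N x F real matrix with F >= 2.
#' @return N x F matrix of z-scores.
#' @export
standardize_psd <- function(psd_db) {
  psd_db <- as.matrix(psd_db)
  if (ncol(psd_db) < 2) stop("need at least 2 frequencies to standardize")
  mu <- rowMeans(psd_db)
  centered <- psd_db - mu
  sd_pop <- sqrt(rowMeans(centered^2))
  zero <- which(sd_pop == 0)
  if (length(zero))
    stop("zero variance across frequency in region(s): ",
         paste(zero, collapse = ", "))
  centered / sd_pop
}

.zscore_pop <- function(x) {
  s <- sqrt(mean((x - mean(x))^2))
  if (s == 0) stop("zero variance across regions in the alpha-band vector")
  (x - mean(x)) / s
}

#' Observation features from a regional PSD
#'
#' The observation map used for inference: the dB PSD is z-scored per
#' region across frequency, the alpha-band (8-12 Hz) power vector is
#' z-scored across regions, and the two are concatenated into a single
#' vector of length `N*F + N` (PSD segment first, region-major: region 1's
#' F values, then region 2's, ...). Because both segments are z-scored,
#' the features are invariant to any constant rescaling of the underlying
#' linear-scale spectrum.
#'
#' @param psd_db N x F real matrix (dB).
#' @param grid `sgm_grid`.
#' @return Object of class `sgm_features`: numeric vector of length
#'   `N*F + N` with a `layout` attribute recording `(n_regions, n_freqs,`
#'   ordering and standardization conventions).
#' @export
build_features <- function(psd_db, grid) {
  psd_db <- as.matrix(psd_db)
  if (ncol(psd_db) != length(grid$frequencies_hz))
    stop("psd_db has ", ncol(psd_db), " columns but the grid has ",
         length(grid$frequencies_hz), " frequencies")
  z <- standardize_psd(psd_db)
  a <- .zscore_pop(alpha_band_power(psd_db, grid))
  v <- c(as.vector(t(z)), a)
  structure(v, class = "sgm_features",
            layout = feature_layout(nrow(psd_db), ncol(psd_db)))
}

feature_layout <- function(n_regions, n_freqs) {
  list(n_regions = n_regions, n_freqs = n_freqs,
       length = n_regions * n_freqs + n_regions,
       ordering = "region_major",
       psd_standardize = "per_region_population_sd",
       alpha_standardize = "across_regions_population_sd",
       db = "20log10_magnitude")
}

#' @export
print.sgm_features <- function(x, ...) {
  lay <- attr(x, "layout")
  cat(sprintf("Feature vector: length %d (%d regions x %d freqs + %d alpha)\n",
              length(x), lay$n_regions, lay$n_freqs, lay$n_regions))
  invisible(x)
}

#' Split a feature vector back into its segments
#'
#' @param features `sgm_features` (or numeric vector with a layout
#'   attribute).
#' @return List with `psd` (N x F matrix of standardized PSD z-scores) and
#'   `alpha` (length-N standardized alpha-band vector).
#' @export
split_features <- function(features) {
  lay <- attr(features, "layout")
  if (is.null(lay)) stop("features carry no layout attribute")
  n <- lay$n_regions; f <- lay$n_freqs
  psd <- matrix(features[seq_len(n * f)], nrow = n, ncol = f, byrow = TRUE)
  list(psd = psd, alpha = unclass(features)[n * f + seq_len(n)])
}

# Features of a forward simulation at parameters s on a connectome.
.sgm_features_at <- function(params, conn, grid, norm = "symmetric") {
  spec <- forward_spectrum(params, conn, grid, norm = norm)
  build_features(spec$psd_db, grid)
}
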