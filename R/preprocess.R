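# Spectral preprocessing: replicate averaging, per-band z-score
# standardization (fit on training data only), and band-block bookkeeping
# for ablation studies.

#' Average replicate scans of one leaf
#'
#' @param scans Matrix of replicate spectra (replicates x bands) sharing a
#'   wavelength grid, or a list of numeric vectors.
#' @return Single averaged spectrum (named numeric vector).
#' @export
average_replicates <- function(scans) {
  if (is.list(scans)) {
    grids <- lapply(scans, names)
    if (length(unique(vapply(scans, length, integer(1)))) != 1L ||
        length(unique(grids)) != 1L) {
      stop("replicate scans must share an identical wavelength grid")
    }
    scans <- do.call(rbind, scans)
  }
  if (!is.matrix(scans) || nrow(scans) < 1L) {
    stop("need at least one replicate scan")
  }
  colMeans(scans)
}

#' Fit a per-band z-score standardizer
#'
#' Records each band's training mean and sample standard deviation
#' (n - 1 denominator). Zero-variance bands are flagged and dropped when
#' the model is applied, so every retained band has S > 0.
#'
#' @param train Training spectra matrix (samples x bands).
#' @return An object of class `standardizer` with fields `mean`, `sd`
#'   (named by wavelength) and `dropped_bands`.
#' @export
fit_standardizer <- function(train) {
  check_spectra_matrix(train, "train")
  if (nrow(train) < 2L) {
    stop("standardizer needs at least 2 training samples")
  }
  mu <- colMeans(train)
  sdv <- apply(train, 2L, stats::sd)
  dropped <- colnames(train)[sdv == 0]
  keep <- sdv > 0
  structure(list(mean = mu[keep], sd = sdv[keep],
                 dropped_bands = as.numeric(dropped)),
            class = "standardizer")
}

#' Apply a fitted standardizer
#'
#' Transforms each retained band to `z = (R - mean) / sd` using the
#' training statistics; training-only fitting keeps test data leakage-free.
#'
#' @param model A [fit_standardizer()] result.
#' @param X Spectra matrix containing at least the model's retained bands.
#' @return Standardized matrix restricted to the retained bands.
#' @export
apply_standardizer <- function(model, X) {
  stopifnot(inherits(model, "standardizer"))
  check_spectra_matrix(X, "X")
  bands <- names(model$mean)
  missing <- setdiff(bands, colnames(X))
  if (length(missing) > 0L) {
    stop("X is missing band(s) required by the standardizer: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  }
  Z <- X[, bands, drop = FALSE]
  Z <- sweep(Z, 2L, model$mean, "-")
  sweep(Z, 2L, model$sd, "/")
}

#' Invert a standardizer
#'
#' @param model A [fit_standardizer()] result.
#' @param Z Standardized matrix over the model's retained bands.
#' @return Reflectance-scale matrix.
#' @export
invert_standardizer <- function(model, Z) {
  stopifnot(inherits(model, "standardizer"))
  X <- sweep(Z, 2L, model$sd, "*")
  sweep(X, 2L, model$mean, "+")
}

#' Partition the spectrum into labeled band blocks
#'
#' First block A spans 350-400 nm, then contiguous 100-nm blocks follow up
#' to 2500 nm (labels A..V). All blocks are half-open `[low, high)` so a
#' 1-nm band belongs to exactly one block, except the final block whose
#' upper edge is closed so the last grid point is covered.
#'
#' @param low,high Overall range in nm (defaults 350, 2500).
#' @return Data frame with columns `label`, `low`, `high`,
#'   `closed_upper`.
#' @export
make_band_blocks <- function(low = 350, high = 2500) {
  if (low >= high) stop("low must be < high")
  edges <- c(low, seq(ceiling(low / 100) * 100, high, by = 100))
  edges <- unique(edges)
  if (edges[length(edges)] != high) {
    stop("range [", low, ", ", high,
         "] cannot be tiled by the 100-nm block scheme")
  }
  n <- length(edges) - 1L
  if (n > 26L) stop("block scheme would need more than 26 labels")
  data.frame(
    label = LETTERS[seq_len(n)],
    low = edges[-length(edges)],
    high = edges[-1L],
    closed_upper = c(rep(FALSE, n - 1L), TRUE)
  )
}

#' Which block does a wavelength fall in?
#'
#' @param wavelength Wavelengths in nm.
#' @param blocks Block table from [make_band_blocks()].
#' @return Character vector of block labels (`NA` when outside all blocks).
#' @export
block_of <- function(wavelength, blocks = make_band_blocks()) {
  vapply(wavelength, function(w) {
    hit <- which(w >= blocks$low &
                   (w < blocks$high | (blocks$closed_upper & w <= blocks$high)))
    if (length(hit) == 0L) NA_character_ else blocks$label[hit[1L]]
  }, character(1))
}

#' Remove all bands that fall inside the given blocks
#'
#' @param X Spectra (or standardized) matrix with wavelength column names.
#' @param blocks Rows of a [make_band_blocks()] table to exclude; `NULL`
#'   or zero rows returns `X` unchanged.
#' @return Matrix with the excluded bands removed, column order preserved.
#' @export
exclude_blocks <- function(X, blocks) {
  check_spectra_matrix(X, "X")
  if (is.null(blocks) || nrow(blocks) == 0L) return(X)
  wl <- spectra_wavelengths(X)
  drop <- rep(FALSE, length(wl))
  for (i in seq_len(nrow(blocks))) {
    inside <- wl >= blocks$low[i] &
      (wl < blocks$high[i] |
         (isTRUE(blocks$closed_upper[i]) & wl <= blocks$high[i]))
    drop <- drop | inside
  }
  if (all(drop)) stop("excluding these blocks would leave zero bands")
  X[, !drop, drop = FALSE]
}

#' Serialize a standardizer to JSON
#'
#' @param model A [fit_standardizer()] result.
#' @param path Optional file path; when `NULL` the JSON string is
#'   returned.
#' @return JSON string (invisibly when written to file).
#' @export
standardizer_to_json <- function(model, path = NULL) {
  stopifnot(inherits(model, "standardizer"))
  payload <- list(wavelengths = as.numeric(names(model$mean)),
                  mean = unname(model$mean), sd = unname(model$sd),
                  dropped_bands = model$dropped_bands)
  txt <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Restore a standardizer from JSON
#'
#' @param json JSON string or file path produced by
#'   [standardizer_to_json()].
#' @return A `standardizer` object.
#' @export
standardizer_from_json <- function(json) {
  p <- jsonlite::fromJSON(json)
  wl <- as.character(p$wavelengths)
  structure(list(mean = stats::setNames(p$mean, wl),
                 sd = stats::setNames(p$sd, wl),
                 dropped_bands = as.numeric(p$dropped_bands)),
            class = "standardizer")
}
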