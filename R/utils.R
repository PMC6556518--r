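# Internal helpers shared across modules.

# Evaluate `code` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so library code never clobbers a user's random stream.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Named substreams derived from one master seed so pipeline stages are
# independently reproducible. Kept strictly below 2^31 - 1.
substream_seed <- function(seed, name) {
  offsets <- c(
    traits = 101L, spectra = 211L, aci = 307L, splits = 401L,
    learners = 503L, folds = 601L, level2 = 701L, noise = 809L,
    importance = 907L
  )
  if (!name %in% names(offsets)) {
    stop("unknown substream name: ", name)
  }
  (abs(as.integer(seed)) + offsets[[name]] * 9973L) %% 2147483562L
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == round(x)
}

is_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

# Stop unless a matrix of spectra: numeric, wavelength colnames strictly
# increasing, rownames present.
check_spectra_matrix <- function(X, arg = "X") {
  if (!is.matrix(X) || !is.numeric(X)) {
    stop(arg, " must be a numeric matrix of spectra (samples x bands)")
  }
  wl <- spectra_wavelengths(X)
  if (anyNA(wl)) stop(arg, " column names must be numeric wavelengths (nm)")
  if (is.unsorted(wl, strictly = TRUE)) {
    stop(arg, " wavelengths must be strictly increasing")
  }
  if (is.null(rownames(X))) stop(arg, " must carry sample ids as rownames")
  invisible(X)
}

#' Wavelength grid of a spectra matrix
#'
#' @param X A spectra matrix (samples in rows, bands in columns, column
#'   names giving wavelength in nm).
#' @return Numeric vector of wavelengths in nm.
#' @export
spectra_wavelengths <- function(X) {
  suppressWarnings(as.numeric(colnames(X)))
}
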