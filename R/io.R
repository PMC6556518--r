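# CSV dialects: spectra (sample_id + integer-nm wavelength columns),
# traits (sample_id, genotype, vcmax, j1800 with empty cell when absent),
# and A/Ci observations (sample_id, obs, Ci, A, Tleaf).
# Numeric columns are written with 17 significant digits so write/read
# round-trips reproduce doubles bit-identically.

format_lossless <- function(df) {
  for (nm in names(df)) {
    if (is.double(df[[nm]])) {
      v <- sprintf("%.17g", df[[nm]])
      v[is.na(df[[nm]])] <- NA_character_
      df[[nm]] <- v
    }
  }
  df
}

#' Write a spectra matrix to CSV
#'
#' @param X Spectra matrix (samples x bands).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_spectra_csv <- function(X, path) {
  check_spectra_matrix(X, "X")
  dt <- data.table::as.data.table(X, keep.rownames = "sample_id")
  data.table::fwrite(format_lossless(dt), path)
  invisible(path)
}

#' Load a spectra matrix from CSV
#'
#' Expects a `sample_id` column followed by integer-nm wavelength
#' columns. Validates uniqueness of ids, numeric cells, a strictly
#' increasing wavelength grid, and warns on reflectance outside
#' [0, 1.05].
#'
#' @param path CSV file.
#' @return Spectra matrix with sample ids as rownames.
#' @export
load_spectra_csv <- function(path) {
  dt <- data.table::fread(path, header = TRUE)
  if (!"sample_id" %in% names(dt)) {
    stop("spectra CSV must have a sample_id column: ", path)
  }
  ids <- as.character(dt$sample_id)
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    stop("duplicated sample_id in ", path, ": ",
         paste(unique(dup), collapse = ", "))
  }
  wl <- suppressWarnings(as.numeric(setdiff(names(dt), "sample_id")))
  if (anyNA(wl)) stop("non-numeric wavelength column names in ", path)
  if (is.unsorted(wl, strictly = TRUE)) {
    stop("wavelength columns must be strictly increasing in ", path)
  }
  band_cols <- setdiff(names(dt), "sample_id")
  numeric_col <- vapply(dt[, band_cols, with = FALSE], is.numeric,
                        logical(1))
  if (!all(numeric_col)) {
    stop("non-numeric cell(s) in ", path, ", column ",
         band_cols[which(!numeric_col)[1]])
  }
  X <- as.matrix(dt[, band_cols, with = FALSE])
  if (anyNA(X)) {
    bad <- which(is.na(X), arr.ind = TRUE)
    stop("non-numeric cell(s) in ", path, ", e.g. row ", bad[1, 1],
         " column ", colnames(X)[bad[1, 2]])
  }
  rownames(X) <- ids
  if (any(X < 0) || any(X > 1.05)) {
    warning("reflectance values outside [0, 1.05] in ", path)
  }
  X
}

#' Write a trait table to CSV
#'
#' @param traits Tibble with `sample_id`, `genotype`, `vcmax`, `j1800`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_traits_csv <- function(traits, path) {
  data.table::fwrite(format_lossless(traits), path, na = "")
  invisible(path)
}

#' Load a trait table from CSV
#'
#' @param path CSV with `sample_id`, `genotype`, `vcmax`, `j1800` (empty
#'   cell = absent).
#' @return Tibble of trait records.
#' @export
load_traits_csv <- function(path) {
  dt <- data.table::fread(path, header = TRUE, na.strings = "")
  need <- c("sample_id", "genotype", "vcmax")
  if (!all(need %in% names(dt))) {
    stop("traits CSV must have columns ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(dt$sample_id)) stop("duplicated sample_id in ", path)
  if (!"j1800" %in% names(dt)) dt$j1800 <- NA_real_
  tibble::tibble(sample_id = as.character(dt$sample_id),
                 genotype = as.character(dt$genotype),
                 vcmax = as.numeric(dt$vcmax),
                 j1800 = as.numeric(dt$j1800))
}

#' Write A/Ci curves to CSV
#'
#' @param curves List of [aci_curve()] objects.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_aci_csv <- function(curves, path) {
  rows <- lapply(curves, function(cv) {
    data.frame(sample_id = cv$sample_id,
               obs = seq_len(nrow(cv$observations)),
               Ci = cv$observations$ci, A = cv$observations$a,
               Tleaf = cv$leaf_temp)
  })
  data.table::fwrite(format_lossless(do.call(rbind, rows)), path)
  invisible(path)
}

#' Load A/Ci curves from CSV
#'
#' Groups rows by `sample_id`, preserving observation order.
#'
#' @param path CSV with columns `sample_id`, `Ci`, `A`, `Tleaf`
#'   (an `obs` order column is honored when present).
#' @return Named list of [aci_curve()] objects (empty list, with a
#'   warning, for an empty file).
#' @export
load_aci_csv <- function(path) {
  dt <- data.table::fread(path, header = TRUE)
  if (nrow(dt) == 0L) {
    warning("A/Ci file is empty: ", path)
    return(list())
  }
  need <- c("sample_id", "Ci", "A")
  if (!all(need %in% names(dt))) {
    stop("A/Ci CSV must have columns ", paste(need, collapse = ", "))
  }
  if (any(dt$Ci <= 0)) stop("non-positive Ci values in ", path)
  if (!"Tleaf" %in% names(dt)) dt$Tleaf <- 25
  ids <- unique(dt$sample_id)
  curves <- lapply(ids, function(id) {
    sub <- dt[dt$sample_id == id, ]
    if ("obs" %in% names(sub)) sub <- sub[order(sub$obs), ]
    aci_curve(id, sub$Ci, sub$A, leaf_temp = sub$Tleaf[1L])
  })
  names(curves) <- ids
  curves
}
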