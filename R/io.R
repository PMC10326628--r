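#' Write a spectrum as two-column CSV
#'
#' @param s A [raman_spectrum()].
#' @param path Output file; the header is `shift_cm1,intensity`.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(s, path) {
  stopifnot(inherits(s, "raman_spectrum"))
  utils::write.csv(as.data.frame(s), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a spectrum from a two-column text file
#'
#' Expects a CSV with columns Raman shift (cm-1) and intensity; a header line
#' is detected and skipped. A descending axis is re-sorted ascending with a
#' warning. Non-numeric rows, duplicated shifts and length mismatches are
#' format errors reported with the offending line number.
#'
#' @param path File to read.
#' @param id_fields Named list of metadata passed to [raman_spectrum()]
#'   (`spectrum_id`, `sample_id`, `replicate`, `platform`, `label`). The
#'   default spectrum id is the file name without extension.
#' @return A validated [raman_spectrum()].
#' @export
read_spectrum <- function(path, id_fields = list()) {
  if (!file.exists(path)) stop("spectrum file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("format error in ", path, ": empty file")
  first_data <- 1L
  probe <- strsplit(lines[1], "[,\t;]")[[1]]
  if (any(is.na(suppressWarnings(as.numeric(probe))))) first_data <- 2L
  if (length(lines) < first_data) stop("format error in ", path, ": no data rows")
  shifts <- numeric(0); intens <- numeric(0)
  for (ln in seq(first_data, length(lines))) {
    parts <- strsplit(lines[ln], "[,\t;]")[[1]]
    vals <- suppressWarnings(as.numeric(parts))
    if (length(vals) != 2 || anyNA(vals)) {
      stop("format error in ", path, " at line ", ln,
           ": expected two numeric columns, got '", lines[ln], "'")
    }
    shifts <- c(shifts, vals[1]); intens <- c(intens, vals[2])
  }
  if (anyDuplicated(shifts)) {
    dup <- which(duplicated(shifts))[1]
    stop("format error in ", path, " at line ", dup + first_data - 1L,
         ": duplicate Raman shift ", shifts[dup])
  }
  if (all(diff(shifts) < 0)) {
    warning("descending shift axis in ", path, "; re-sorted ascending")
    o <- order(shifts); shifts <- shifts[o]; intens <- intens[o]
  } else if (is.unsorted(shifts)) {
    o <- order(shifts); shifts <- shifts[o]; intens <- intens[o]
    warning("unsorted shift axis in ", path, "; re-sorted ascending")
  }
  args <- c(list(shifts = shifts, intensities = intens), id_fields)
  if (is.null(args$spectrum_id)) {
    args$spectrum_id <- sub("\\.[^.]*$", "", basename(path))
  }
  do.call(raman_spectrum, args)
}

manifest_columns <- function() {
  c("spectrum_file", "sample_id", "replicate", "platform", "label")
}

#' Validate a cohort manifest
#'
#' @param manifest Data frame with at least the columns `spectrum_file`,
#'   `sample_id`, `replicate`, `platform`, `label`.
#' @return The manifest, invisibly, after checking that (sample, replicate)
#'   pairs are unique, every sample carries exactly one label, and labels are
#'   drawn from the two-class outcome set (NA allowed for unlabeled data).
#' @export
validate_manifest <- function(manifest) {
  missing_cols <- setdiff(manifest_columns(), names(manifest))
  if (length(missing_cols)) {
    stop("manifest lacks required column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!nrow(manifest)) stop("empty manifest")
  key <- paste(manifest$sample_id, manifest$replicate)
  if (anyDuplicated(key)) {
    stop("manifest consistency error: duplicated (sample_id, replicate) pair: ",
         key[duplicated(key)][1])
  }
  check_label(manifest$label)
  labs <- unique(manifest[, c("sample_id", "label")])
  if (anyDuplicated(labs$sample_id)) {
    stop("manifest consistency error: sample ",
         labs$sample_id[duplicated(labs$sample_id)][1],
         " carries conflicting labels")
  }
  invisible(manifest)
}

#' Read a cohort manifest (TSV)
#'
#' @param path Manifest file, tab-separated with header.
#' @param check_files If `TRUE`, verify the referenced spectrum files exist
#'   in `dir`.
#' @param dir Directory holding the spectrum files (default: the manifest's).
#' @return Validated manifest data frame (with a `spectrum_id` column derived
#'   from `spectrum_file` when absent).
#' @export
read_manifest <- function(path, check_files = FALSE, dir = dirname(path)) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  m <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!nrow(m)) stop("empty manifest: ", path)
  if (is.null(m$spectrum_id)) {
    m$spectrum_id <- sub("\\.[^.]*$", "", basename(m$spectrum_file))
  }
  validate_manifest(m)
  if (check_files) {
    missing <- !file.exists(file.path(dir, m$spectrum_file))
    if (any(missing)) {
      stop("manifest references missing spectrum file(s): ",
           paste(utils::head(m$spectrum_file[missing], 5), collapse = ", "))
    }
  }
  m
}

#' Write a cohort manifest (TSV)
#'
#' @param manifest Manifest data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  validate_manifest(manifest)
  utils::write.table(manifest, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read all spectra referenced by a manifest
#'
#' @param manifest Validated manifest data frame.
#' @param dir Directory holding the spectrum files.
#' @return List of [raman_spectrum()] in manifest order.
#' @export
read_cohort_spectra <- function(manifest, dir) {
  validate_manifest(manifest)
  lapply(seq_len(nrow(manifest)), function(i) {
    read_spectrum(file.path(dir, manifest$spectrum_file[i]),
                  id_fields = list(
                    spectrum_id = if (!is.null(manifest$spectrum_id))
                      manifest$spectrum_id[i] else NULL,
                    sample_id = manifest$sample_id[i],
                    replicate = manifest$replicate[i],
                    platform = manifest$platform[i],
                    label = manifest$label[i]))
  })
}
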