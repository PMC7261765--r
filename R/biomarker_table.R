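# Biomarker-table IO and validation.
#
# A biomarker table is one row per subject: metadata columns `subject_id`,
# `group` ("patient"/"control"), optional `age` (years) and `site`, followed
# by one numeric column per region (mean FA, strictly inside (0, 1) when
# validated in "fa" mode).

metadata_cols <- c("subject_id", "group", "age", "site")

#' Read and validate a cross-sectional biomarker table
#'
#' Reads a delimited text file (CSV by default) with a header row, checks it
#' against a region set, and returns the table with region columns reordered
#' to the region-set order.
#'
#' @param path Path to a delimited text file with a header row.
#' @param region_set An [canonical_region_set()] tibble (or character vector
#'   of region labels) the file must provide one numeric column for.
#' @param values Validation mode for region values: `"fa"` requires all values
#'   strictly inside (0, 1); `"free"` only requires finite numbers.
#' @param delim Field delimiter, default `","`.
#'
#' @return A tibble with columns `subject_id`, `group`, optionally `age` and
#'   `site`, then the region columns in region-set order.
#' @export
read_biomarker_table <- function(path, region_set, values = c("fa", "free"),
                                 delim = ",") {
  values <- match.arg(values)
  # read everything as character: numeric conversion happens in the validator
  # via R's correctly-rounded strtod, so 17-digit values round-trip exactly
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE,
                           col_types = readr::cols(.default = "c"))
  validate_biomarker_table(raw, region_set, values = values)
}

#' Validate a biomarker table against a region set
#'
#' @param data A data frame with metadata columns and one column per region.
#' @inheritParams read_biomarker_table
#' @return The validated tibble, region columns reordered to region-set order.
#' @export
validate_biomarker_table <- function(data, region_set, values = c("fa", "free")) {
  values <- match.arg(values)
  data <- tibble::as_tibble(data)
  labels <- region_labels(region_set)

  missing_meta <- setdiff(c("subject_id", "group"), names(data))
  if (length(missing_meta)) {
    abort_schema(paste0("Missing required metadata column(s): ",
                        paste(missing_meta, collapse = ", ")))
  }
  missing_regions <- setdiff(labels, names(data))
  if (length(missing_regions)) {
    abort_schema(paste0("Missing region column(s): ",
                        paste(missing_regions, collapse = ", ")))
  }

  for (lab in labels) {
    col <- data[[lab]]
    if (!is.numeric(col)) {
      suppressWarnings(num <- as.numeric(col))
      bad <- which(is.na(num) & !is.na(col))
      if (length(bad)) {
        abort_parse(paste0("Non-numeric value in column '", lab, "', row ",
                           bad[1], ": '", col[bad[1]], "'"))
      }
      data[[lab]] <- num
    }
  }

  if ("age" %in% names(data) && !is.numeric(data$age)) {
    suppressWarnings(age <- as.numeric(data$age))
    bad <- which(is.na(age) & !is.na(data$age))
    if (length(bad)) {
      abort_parse(paste0("Non-numeric age in row ", bad[1], ": '",
                         data$age[bad[1]], "'"))
    }
    data$age <- age
  }

  data$group <- as.character(data$group)
  bad_group <- setdiff(unique(data$group), c("patient", "control"))
  if (length(bad_group)) {
    abort_validation(paste0("Unknown group label(s): ",
                            paste(bad_group, collapse = ", "),
                            " (expected 'patient' or 'control')"))
  }

  vals <- as.matrix(data[labels])
  if (anyNA(vals) || any(!is.finite(vals))) {
    abort_validation("Region values must be finite and non-missing (no imputation is performed).")
  }
  if (values == "fa" && (any(vals <= 0) || any(vals >= 1))) {
    abort_validation("In 'fa' mode all region values must lie strictly in (0, 1).")
  }

  meta_present <- intersect(metadata_cols, names(data))
  data[c(meta_present, labels)]
}

#' Write a biomarker table to CSV
#'
#' Region values are written with 17 significant digits so that
#' write-then-read round-trips every double bit-identically.
#'
#' @param data A validated biomarker table.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_biomarker_table <- function(data, path) {
  out <- data
  for (lab in region_cols(out)) {
    out[[lab]] <- sprintf("%.17g", out[[lab]])
  }
  readr::write_csv(out, path)
  invisible(path)
}

# Split helpers used throughout the inference path.
patient_rows <- function(data) dplyr::filter(data, .data$group == "patient")
control_rows <- function(data) dplyr::filter(data, .data$group == "control")

region_cols <- function(data) setdiff(names(data), metadata_cols)

biomarker_matrix <- function(data, labels = region_cols(data)) {
  m <- as.matrix(data[labels])
  rownames(m) <- data$subject_id
  m
}
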