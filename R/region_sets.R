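# Canonical white-matter region sets for FA-based event modelling.
#
# The combined set holds 11 regions: the corticospinal tract split into
# inferior/middle/superior segments along the MNI z-axis, the corpus callosum
# split into genu/body/splenium, and five long association / limbic tracts
# (cingulum, SLF, ILF, IFOF, UF), each pooled across hemispheres. The split
# set keeps the three corpus-callosum subdivisions unilateral (the CC is a
# commissural structure and is never split) and subdivides the remaining
# eight regions by hemisphere, giving 19 regions.

cst_z_intervals <- list(
  CST_inf = c(-Inf, -5),
  CST_mid = c(-4, 18),
  CST_sup = c(19, Inf)
)

combined_region_defs <- tibble::tribble(
  ~label,         ~tract,                                  ~segment,
  "CST_inf",      "Corticospinal tract",                   "inferior",
  "CST_mid",      "Corticospinal tract",                   "middle",
  "CST_sup",      "Corticospinal tract",                   "superior",
  "CC_genu",      "Corpus callosum",                       "genu",
  "CC_body",      "Corpus callosum",                       "body",
  "CC_splenium",  "Corpus callosum",                       "splenium",
  "Cingulum",     "Cingulum (dorsal section)",             NA,
  "SLF",          "Superior longitudinal fasciculus",      NA,
  "ILF",          "Inferior longitudinal fasciculus",      NA,
  "IFOF",         "Inferior fronto-occipital fasciculus",  NA,
  "UF",           "Uncinate fasciculus",                   NA
)

#' Canonical white-matter region sets
#'
#' Returns the region set used for fractional-anisotropy event modelling:
#' either 11 regions combined across hemispheres, or 19 regions in which every
#' tract except the corpus callosum is subdivided by hemisphere. The three
#' corticospinal-tract segments carry their MNI z-axis boundaries as metadata
#' (inferior: z <= -5, middle: -4 <= z <= 18, superior: z >= 19).
#'
#' @param mode `"combined"` (11 regions) or `"split"` (19 regions).
#'
#' @return A tibble of class `ebm_region_set` with columns `label`, `tract`,
#'   `hemisphere` (`NA` for midline / pooled regions), `z_min`, `z_max`
#'   (`NA` except for corticospinal-tract segments). The mode is stored in
#'   attribute `"mode"`.
#'
#' @examples
#' canonical_region_set("combined")
#' nrow(canonical_region_set("split"))
#' @export
canonical_region_set <- function(mode = c("combined", "split")) {
  mode <- match.arg(mode)
  base <- combined_region_defs
  if (mode == "combined") {
    out <- tibble::tibble(
      label = base$label,
      tract = base$tract,
      hemisphere = NA_character_
    )
  } else {
    rows <- purrr::map(seq_len(nrow(base)), function(i) {
      row <- base[i, ]
      if (row$tract == "Corpus callosum") {
        tibble::tibble(label = row$label, tract = row$tract,
                       hemisphere = NA_character_)
      } else {
        tibble::tibble(
          label = paste(row$label, c("L", "R"), sep = "_"),
          tract = row$tract,
          hemisphere = c("L", "R")
        )
      }
    })
    out <- dplyr::bind_rows(rows)
  }
  zi <- purrr::map(out$label, function(lab) {
    seg <- sub("_(L|R)$", "", lab)
    if (seg %in% names(cst_z_intervals)) cst_z_intervals[[seg]] else c(NA_real_, NA_real_)
  })
  out$z_min <- purrr::map_dbl(zi, 1)
  out$z_max <- purrr::map_dbl(zi, 2)
  new_region_set(out, mode)
}

new_region_set <- function(df, mode) {
  stopifnot(all(c("label", "tract", "hemisphere", "z_min", "z_max") %in% names(df)))
  if (anyDuplicated(df$label) || any(!nzchar(df$label))) {
    abort_validation("Region labels must be unique and non-empty.")
  }
  structure(df, mode = mode, class = c("ebm_region_set", class(tibble::tibble())))
}

#' Read a region-set definition from a YAML file
#'
#' A region-set file holds a `mode` and a list of `regions`, each with `label`
#' and optional `tract`, `hemisphere`, `z_min`, `z_max`. A canonical definition
#' matching [canonical_region_set()] ships with the package under
#' `system.file("extdata", "region_sets.yaml", package = "ebmseq")`.
#'
#' @param path Path to a YAML region-set file.
#' @param mode For the shipped multi-set file, which set to load
#'   (`"combined"` or `"split"`); ignored when the file defines a single set.
#' @return An `ebm_region_set` tibble.
#' @export
read_region_set <- function(path, mode = "combined") {
  doc <- yaml::read_yaml(path)
  if (!is.null(doc$region_sets)) {
    if (!mode %in% names(doc$region_sets)) {
      abort_schema(paste0("Region set '", mode, "' not found in ", path))
    }
    doc <- doc$region_sets[[mode]]
  } else {
    mode <- doc$mode %||% "custom"
  }
  regions <- doc$regions
  if (is.null(regions) || !length(regions)) {
    abort_schema("Region-set file defines no regions.")
  }
  df <- purrr::map_dfr(regions, function(r) {
    tibble::tibble(
      label = as.character(r$label),
      tract = as.character(r$tract %||% r$label),
      hemisphere = if (is.null(r$hemisphere)) NA_character_ else as.character(r$hemisphere),
      z_min = as.numeric(r$z_min %||% NA_real_),
      z_max = as.numeric(r$z_max %||% NA_real_)
    )
  })
  new_region_set(df, doc$mode %||% mode)
}

region_labels <- function(region_set) {
  if (inherits(region_set, "ebm_region_set")) region_set$label else as.character(region_set)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
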